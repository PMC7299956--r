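#' Default atlas-building parameters
#'
#' All thresholds used by \code{\link{buildAtlas}} in one list, so a run
#' manifest can echo exactly what was applied: the 600-gene cell filter, the
#' merge rule (at most 5 DE genes at |logFC| >= 1.1, adjusted p < 0.001),
#' marker criteria (detection > 20%, logFC >= 0.5, p < 0.001), the doublet
#' gene-count factor 1.2 and the low-quality rule (median depth < 0.5x
#' siblings and median mitochondrial fraction > 10%).
#'
#' @param ... overrides for any element of the returned list.
#' @return named list of parameters.
#' @export
atlasConfig <- function(...) {
    cfg <- list(
        minGenes = 600, mitoPrefix = "MT-", scaleFactor = "median",
        nTopHVG = 600, nTopHVGClass = 300,
        pcaMax = 50, twQuantile = 0.99,
        k = 30, resolution = 1, seed = 0,
        mergeMaxDE = 5, mergeMinLfc = 1.1, mergeAlpha = 0.001,
        mergeMinPct = 0.05,
        markerMinPct = 0.2, markerMinLfc = 0.5, markerAlpha = 0.001,
        doubletGeneFactor = 1.2, doubletMarkerZ = 0.5,
        lowqDepthRatio = 0.5, lowqMitoThreshold = 0.10,
        renormalizeClasses = "RGC")
    ov <- list(...)
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    cfg[names(ov)] <- ov
    cfg
}

#' Subcluster one cell class into types
#'
#' Re-runs the clustering workflow on the cells of a single class:
#' normalization (recomputed on the submatrix when \code{renormalize = TRUE},
#' as done for retinal ganglion cells whose per-cell gene counts run several
#' fold higher than other classes), HVG selection, batch regression, PCA with
#' RMT component selection, Jaccard-kNN graph, Louvain, and the dendrogram
#' merge rule, followed by within-class artifact flagging.
#'
#' @param sce \code{SingleCellExperiment} with \code{counts} (and
#'   \code{logcounts} unless \code{renormalize}).
#' @param cells cell selection for the class.
#' @param renormalize recompute \code{\link{normalizeLog}} on the submatrix.
#' @param params list from \code{\link{atlasConfig}} (\code{nTopHVGClass},
#'   \code{k}, ... are used).
#' @return a \linkS4class{ClusterModel} with integer-string labels.
#' @export
subclusterClass <- function(sce, cells, renormalize = FALSE,
                            params = atlasConfig()) {
    sub <- sce[, cells]
    counts <- SummarizedExperiment::assay(sub, "counts")
    n <- ncol(sub)
    qc <- perCellQC(sub, params$mitoPrefix)
    E <- if (renormalize)
        normalizeLog(counts, params$scaleFactor)
    else as.matrix(SummarizedExperiment::assay(sub, "logcounts"))
    if (n < 2 * params$k) {
        warning("class has fewer than 2k cells; returned as a single type")
        return(.singleClusterModel(colnames(sub), qc, params))
    }
    hvgs <- selectHVGs(counts, min(params$nTopHVGClass, nrow(counts)))
    Eh <- E[hvgs, , drop = FALSE]
    batch <- SummarizedExperiment::colData(sub)$batch
    if (!is.null(batch) && length(unique(batch)) > 1)
        Eh <- regressBatch(Eh, batch)
    emb <- pcaRMT(Eh, params$pcaMax, params$twQuantile)
    if (emb$nSig == 0 || ncol(emb$scores) == 0)
        return(.singleClusterModel(colnames(sub), qc, params))
    g <- buildJaccardGraph(emb$scores, min(params$k, n - 1))
    lab <- louvainCluster(g, seed = params$seed,
                          resolution = params$resolution)
    mg <- mergeClusters(lab, E, hvgs, maxDE = params$mergeMaxDE,
                        minLfc = params$mergeMinLfc,
                        alpha = params$mergeAlpha,
                        minPct = params$mergeMinPct)
    labs <- setNames(as.character(mg$labels), colnames(sub))
    cl <- sort(unique(mg$labels))
    if (length(cl) >= 2) {
        fl <- flagArtifactClusters(mg$labels, NULL, qc, E,
                                   withinClass = TRUE,
                                   geneFactor = params$doubletGeneFactor,
                                   depthRatio = params$lowqDepthRatio,
                                   mitoThreshold = params$lowqMitoThreshold,
                                   minPct = params$markerMinPct,
                                   minLfc = params$markerMinLfc,
                                   alpha = params$markerAlpha)
    } else {
        fl <- data.frame(cluster = cl, doublet = FALSE, low_quality = FALSE)
    }
    tab <- data.frame(cluster = as.character(fl$cluster),
                      class = NA_character_,
                      n_cells = as.integer(table(labs)[as.character(fl$cluster)]),
                      doublet = fl$doublet, low_quality = fl$low_quality,
                      ambiguous = FALSE, margin = NA_real_,
                      stringsAsFactors = FALSE)
    methods::new("ClusterModel", labels = labs,
                 classes = character(), clusterTable = tab,
                 dendrogram = mg$dendrogram, params = params)
}

.singleClusterModel <- function(cellIds, qc, params) {
    labs <- setNames(rep("1", length(cellIds)), cellIds)
    tab <- data.frame(cluster = "1", class = NA_character_,
                      n_cells = length(cellIds), doublet = FALSE,
                      low_quality = FALSE, ambiguous = FALSE,
                      margin = NA_real_, stringsAsFactors = FALSE)
    methods::new("ClusterModel", labels = labs, classes = character(),
                 clusterTable = tab, dendrogram = NULL, params = params)
}

#' Build a cell-type atlas from a count matrix
#'
#' The full two-stage workflow. Stage 1 (classes): filter cells with fewer
#' than 600 detected genes, normalize, select HVGs, regress chemistry batch,
#' PCA with RMT selection, Jaccard-kNN Louvain clustering, marker-panel class
#' assignment, and doublet / low-quality cluster flagging. Stage 2 (types):
#' each class is subclustered with \code{\link{subclusterClass}} (RGCs are
#' re-normalized), oversplit clusters are merged by the dendrogram rule, and
#' within-class artifact clusters are flagged. Flagged clusters are retained
#' in the model but excluded from \code{\link{retainedLabels}}.
#'
#' @param sce \code{SingleCellExperiment} with a \code{counts} assay and,
#'   optionally, \code{batch} in its \code{colData}.
#' @param panel marker panel: named list class -> marker gene ids.
#' @param params list from \code{\link{atlasConfig}}.
#' @return a \linkS4class{ClusterModel}; type labels have the form
#'   \code{<class>_<i>}. \code{params$manifest} records thresholds, the
#'   number of significant PCs and per-class cluster counts.
#' @export
buildAtlas <- function(sce, panel, params = atlasConfig()) {
    sce <- filterCells(sce, params$minGenes)
    qc <- perCellQC(sce, params$mitoPrefix)
    sce <- normalizeLog(sce, params$scaleFactor)
    E <- as.matrix(SummarizedExperiment::assay(sce, "logcounts"))
    counts <- SummarizedExperiment::assay(sce, "counts")
    hvgs <- selectHVGs(counts, min(params$nTopHVG, nrow(counts)))
    Eh <- E[hvgs, , drop = FALSE]
    batch <- SummarizedExperiment::colData(sce)$batch
    if (!is.null(batch) && length(unique(batch)) > 1)
        Eh <- regressBatch(Eh, batch)
    emb <- pcaRMT(Eh, params$pcaMax, params$twQuantile)
    g <- buildJaccardGraph(emb$scores, params$k)
    lab0 <- louvainCluster(g, seed = params$seed,
                           resolution = params$resolution)
    ca <- assignClasses(lab0, E, panel)
    fl <- flagArtifactClusters(lab0, ca, qc, E, panel,
                               withinClass = FALSE,
                               geneFactor = params$doubletGeneFactor,
                               markerZ = params$doubletMarkerZ,
                               depthRatio = params$lowqDepthRatio,
                               mitoThreshold = params$lowqMitoThreshold,
                               minPct = params$markerMinPct,
                               minLfc = params$markerMinLfc,
                               alpha = params$markerAlpha)
    classOfCluster <- setNames(ca$class, as.character(ca$cluster))
    flagged <- fl$cluster[fl$doublet | fl$low_quality]

    cells <- colnames(sce)
    typeLab <- setNames(rep(NA_character_, length(cells)), cells)
    classLab <- setNames(classOfCluster[as.character(lab0)], cells)
    rows <- list()
    for (q in flagged) {
        id <- paste0(classOfCluster[as.character(q)], "_flagged", q)
        typeLab[lab0 == q] <- id
        r <- fl[fl$cluster == q, ]
        rows[[id]] <- data.frame(
            cluster = id, class = classOfCluster[as.character(q)],
            n_cells = sum(lab0 == q), doublet = r$doublet,
            low_quality = r$low_quality, ambiguous = FALSE,
            margin = NA_real_, stringsAsFactors = FALSE)
    }
    perClassN <- list()
    for (cl in unique(ca$class[!(ca$cluster %in% flagged)])) {
        qs <- ca$cluster[ca$class == cl & !(ca$cluster %in% flagged)]
        cIdx <- which(lab0 %in% qs)
        renorm <- cl %in% params$renormalizeClasses
        sub <- subclusterClass(sce, cIdx, renormalize = renorm,
                               params = params)
        subTab <- clusterInfo(sub)
        keepIds <- subTab$cluster[!(subTab$doublet | subTab$low_quality)]
        newId <- setNames(character(nrow(subTab)), subTab$cluster)
        ki <- 0
        for (q in subTab$cluster) {
            if (q %in% keepIds) {
                ki <- ki + 1
                newId[q] <- paste0(cl, "_", ki)
            } else newId[q] <- paste0(cl, "_flaggedsub", q)
        }
        subLabs <- clusterLabels(sub)
        typeLab[names(subLabs)] <- newId[subLabs]
        for (i in seq_len(nrow(subTab))) {
            id <- newId[subTab$cluster[i]]
            rows[[id]] <- data.frame(
                cluster = id, class = cl, n_cells = subTab$n_cells[i],
                doublet = subTab$doublet[i],
                low_quality = subTab$low_quality[i],
                ambiguous = FALSE, margin = NA_real_,
                stringsAsFactors = FALSE)
        }
        perClassN[[cl]] <- length(keepIds)
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    keep <- tab$cluster[!(tab$doublet | tab$low_quality)]
    dend <- NULL
    if (length(keep) >= 2) {
        means <- t(vapply(keep, function(q)
            rowMeans(E[hvgs, typeLab == q, drop = FALSE]),
            numeric(length(hvgs))))
        rownames(means) <- keep
        dend <- hclust(dist(means), method = "complete")
    }
    params$manifest <- list(
        nCellsIn = length(cells), nSigPCs = emb$nSig,
        hvgs = hvgs, scaleFactor = S4Vectors::metadata(sce)$scaleFactor,
        classClusters = nrow(ca), flaggedClassClusters = length(flagged),
        typesPerClass = perClassN,
        thresholds = params[setdiff(names(params), "manifest")])
    methods::new("ClusterModel", labels = typeLab, classes = classLab,
                 clusterTable = tab, dendrogram = dend, params = params)
}
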