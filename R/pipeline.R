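#' Run the analysis pipeline end to end on synthetic or supplied data
#'
#' Orchestrates the stages as named steps writing TSV artifacts plus a JSON
#' run manifest that snapshots every threshold actually used (the 600-gene
#' filter; the merge rule 5 / 1.1 / 0.001; marker criteria 0.2 / 0.5 / 0.001;
#' the regional criteria 20 cells / 1.0 / 0.001; the screen thresholds
#' 20% / 0.5) together with the seed, so deterministic stages can be re-run
#' bit-identically.
#'
#' @param stage one of \code{"all"}, \code{"simulate"}, \code{"qc"},
#'   \code{"cluster"}, \code{"map"}, \code{"regional"}, \code{"disease"}.
#'   Stages other than \code{"all"}/\code{"simulate"} require the artifacts
#'   of the preceding stages in \code{outDir} (or a \code{sim} argument).
#' @param outDir output directory; created if missing.
#' @param simCfg \linkS4class{SimConfig} for the synthetic input.
#' @param params list from \code{\link{atlasConfig}}.
#' @param tau correspondence threshold (percent) for the cross-species map.
#' @param sim optionally, a pre-generated \code{\link{generateAtlas}} result
#'   (bypasses the simulate stage).
#' @return invisibly, a list of stage results (those computed).
#' @export
runPipeline <- function(stage = c("all", "simulate", "qc", "cluster",
                                  "map", "regional", "disease"),
                        outDir = tempfile("retina_run_"),
                        simCfg = simConfig(), params = atlasConfig(),
                        tau = 50, sim = NULL) {
    stage <- match.arg(stage)
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    manifestPath <- file.path(outDir, "manifest.json")
    manifest <- if (file.exists(manifestPath))
        jsonlite::read_json(manifestPath, simplifyVector = TRUE) else list()
    res <- list()

    doAll <- stage == "all"
    if (is.null(sim) && (doAll || stage == "simulate")) {
        sim <- generateAtlas(simCfg)
        writeCounts(sim$sce, file.path(outDir, "counts_a"))
        writeCounts(sim$sceB, file.path(outDir, "counts_b"))
        .writeTsv(sim$truth, file.path(outDir, "truth_a.tsv"))
        .writeTsv(sim$truthB, file.path(outDir, "truth_b.tsv"))
        .writeTsv(sim$orthologs, file.path(outDir, "orthologs.tsv"))
        .writeTsv(data.frame(
            class = rep(names(sim$panel), lengths(sim$panel)),
            gene = unlist(sim$panel)), file.path(outDir, "panel.tsv"))
        manifest$simulate <- list(seed = simCfg@seed,
                                  nCells = ncol(sim$sce),
                                  nGenes = nrow(sim$sce))
        res$sim <- sim
    }
    if (is.null(sim) && stage %in% c("qc", "cluster", "map", "regional",
                                     "disease")) {
        if (!dir.exists(file.path(outDir, "counts_a")))
            stop("stage '", stage, "' needs simulate artifacts in ", outDir,
                 " (missing counts_a/); run stage='simulate' first or ",
                 "pass sim=")
        sim <- .loadSimArtifacts(outDir)
    }

    if (doAll || stage == "qc") {
        qcTab <- perCellQC(sim$sce, params$mitoPrefix)
        filtered <- filterCells(sim$sce, params$minGenes)
        .writeTsv(data.frame(cell_id = rownames(qcTab), qcTab),
                  file.path(outDir, "qc_metrics.tsv"))
        manifest$qc <- list(min_genes = params$minGenes,
                            cells_in = ncol(sim$sce),
                            cells_retained = ncol(filtered))
        res$qc <- qcTab
        if (!doAll) res$filtered <- filtered
    }

    model <- NULL
    if (doAll || stage == "cluster") {
        model <- buildAtlas(sim$sce, sim$panel, params)
        out <- data.frame(cell_id = names(clusterLabels(model)),
                          class = classLabels(model),
                          type = clusterLabels(model))
        .writeTsv(out, file.path(outDir, "cell_labels.tsv"))
        .writeTsv(clusterInfo(model), file.path(outDir, "clusters.tsv"))
        if (!is.null(model@dendrogram) &&
            requireNamespace("ape", quietly = TRUE))
            ape::write.tree(ape::as.phylo(model@dendrogram),
                            file.path(outDir, "dendrogram.nwk"))
        manifest$cluster <- list(
            thresholds = model@params$manifest$thresholds[
                c("minGenes", "k", "resolution", "mergeMaxDE",
                  "mergeMinLfc", "mergeAlpha", "markerMinPct",
                  "markerMinLfc", "markerAlpha", "doubletGeneFactor",
                  "lowqDepthRatio", "lowqMitoThreshold", "seed")],
            n_sig_pcs = model@params$manifest$nSigPCs,
            n_types = sum(!(clusterInfo(model)$doublet |
                            clusterInfo(model)$low_quality)))
        res$model <- model
    }

    if (doAll || stage %in% c("map", "regional", "disease")) {
        if (is.null(model)) {
            if (!file.exists(file.path(outDir, "cell_labels.tsv")))
                stop("stage '", stage, "' needs cluster artifacts in ",
                     outDir, " (missing cell_labels.tsv); run ",
                     "stage='cluster' first")
            model <- .loadModelArtifacts(outDir, params)
        }
        sceN <- normalizeLog(sim$sce[, names(clusterLabels(model))],
                             params$scaleFactor)
        E <- as.matrix(SummarizedExperiment::assay(sceN, "logcounts"))
        keepLab <- retainedLabels(model)
        cellsKeep <- names(keepLab)
        classKeep <- classLabels(model)[cellsKeep]
        meta <- SummarizedExperiment::colData(sceN)[cellsKeep, ]
    }

    if (doAll || stage == "map") {
        sceBN <- normalizeLog(sim$sceB, params$scaleFactor)
        EB <- as.matrix(SummarizedExperiment::assay(sceBN, "logcounts"))
        confs <- list(); corrs <- list()
        for (cl in unique(sim$truthB$true_class)) {
            refCells <- sim$truthB$true_class == cl
            qCells <- cellsKeep[classKeep == cl]
            if (sum(refCells) < 20 || length(qCells) < 20) next
            if (length(unique(sim$truthB$true_type[refCells])) < 2) next
            clf <- trainTypeClassifier(EB[, refCells],
                                       sim$truthB$true_type[refCells],
                                       ortho = sim$orthologs,
                                       seed = params$seed)
            pred <- mapCells(clf, E[, qCells, drop = FALSE])
            conf <- confusionMatrix(keepLab[qCells], pred)
            confs[[cl]] <- conf
            corrs[[cl]] <- callCorrespondences(conf, tau = tau)
        }
        corr <- do.call(rbind, corrs)
        .writeTsv(corr, file.path(outDir, "correspondences.tsv"))
        manifest$map <- list(tau = tau,
                             matched = sum(corr$matched),
                             queries = nrow(corr))
        res$confusions <- confs
        res$correspondences <- corr
    }

    if (doAll || stage == "regional") {
        rde <- regionalDE(E[, cellsKeep], keepLab, meta$region)
        props <- typeProportions(keepLab, classKeep, meta$region,
                                 meta$donor)
        .writeTsv(rde$summary, file.path(outDir, "regional_de.tsv"))
        .writeTsv(props$perDonor, file.path(outDir, "proportions.tsv"))
        manifest$regional <- list(min_cells = 20, min_lfc = 1.0,
                                  alpha = 0.001,
                                  types_tested = sum(rde$summary$tested))
        res$regionalDE <- rde
        res$proportions <- props
    }

    if (doAll || stage == "disease") {
        panelTab <- spikeDiseasePanel(sim)
        scr <- screenGenes(panelTab, E[, cellsKeep], classKeep,
                           meta$region)
        .writeTsv(scr, file.path(outDir, "disease_screen.tsv"))
        hm <- classHeatmap(scr$gene[which(scr$passes)], E[, cellsKeep],
                           classKeep)
        .writeTsv(data.frame(gene = rownames(hm$scaled), hm$scaled),
                  file.path(outDir, "disease_heatmap.tsv"))
        manifest$disease <- list(pct_min = 20, expr_min = 0.5,
                                 passing = sum(scr$passes, na.rm = TRUE))
        res$screen <- scr
    }

    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    invisible(res)
}

.writeTsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.loadSimArtifacts <- function(outDir) {
    rd <- function(f) read.table(file.path(outDir, f), sep = "\t",
                                 header = TRUE, stringsAsFactors = FALSE)
    truth <- rd("truth_a.tsv")
    meta <- truth[, c("cell_id", "donor", "region", "species")]
    meta$enrichment <- "none"; meta$batch <- "b1"
    sce <- attachMetadata(readCounts(file.path(outDir, "counts_a")), meta)
    panelTab <- rd("panel.tsv")
    out <- list(sce = sce, truth = truth,
                panel = split(panelTab$gene, panelTab$class),
                orthologs = rd("orthologs.tsv"))
    if (dir.exists(file.path(outDir, "counts_b"))) {
        out$truthB <- rd("truth_b.tsv")
        out$sceB <- readCounts(file.path(outDir, "counts_b"))
    }
    out
}

.loadModelArtifacts <- function(outDir, params) {
    lab <- read.table(file.path(outDir, "cell_labels.tsv"), sep = "\t",
                      header = TRUE, stringsAsFactors = FALSE)
    tab <- read.table(file.path(outDir, "clusters.tsv"), sep = "\t",
                      header = TRUE, stringsAsFactors = FALSE)
    methods::new("ClusterModel",
                 labels = setNames(lab$type, lab$cell_id),
                 classes = setNames(lab$class, lab$cell_id),
                 clusterTable = tab, dendrogram = NULL, params = params)
}
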