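#' Screen a disease-gene list for robust retinal expression
#'
#' A gene passes the screen when, in at least one (class x region) stratum,
#' it is detected in more than \code{pctMin} percent of cells \emph{and} its
#' mean normalized expression over all cells of the stratum exceeds
#' \code{exprMin}. Both inequalities are strict, so a gene at exactly 20%
#' detection or mean exactly 0.5 fails. Genes named in \code{overrides} are
#' forced in (clinical-interest inclusion) and flagged. Genes absent from the
#' matrix are recorded as absent, not failed.
#'
#' @param geneTable data.frame with columns \code{gene}, \code{group} (see
#'   \code{\link{readGeneList}}); an optional logical \code{override} column
#'   is honoured in addition to \code{overrides}.
#' @param norm normalized matrix.
#' @param classLabels,regionLabels class and region per cell.
#' @param pctMin detection threshold in percent (default 20).
#' @param exprMin mean-expression threshold (default 0.5).
#' @param overrides genes forced into the passing set.
#' @return data.frame: gene, group, present, max_detection_pct,
#'   mean_expression (in the stratum with maximal detection), best_class,
#'   best_region, passes, override.
#' @export
screenGenes <- function(geneTable, norm, classLabels, regionLabels,
                        pctMin = 20, exprMin = 0.5,
                        overrides = character()) {
    stopifnot(length(classLabels) == ncol(norm),
              length(regionLabels) == ncol(norm))
    if ("override" %in% colnames(geneTable) &&
        is.logical(geneTable$override))
        overrides <- union(overrides,
                           geneTable$gene[which(geneTable$override)])
    strata <- split(seq_len(ncol(norm)),
                    list(class = classLabels, region = regionLabels),
                    drop = TRUE)
    genes <- geneTable$gene
    have <- genes %in% rownames(norm)
    out <- data.frame(
        gene = genes, group = geneTable$group, present = have,
        max_detection_pct = NA_real_, mean_expression = NA_real_,
        best_class = NA_character_, best_region = NA_character_,
        passes = NA, override = genes %in% overrides,
        stringsAsFactors = FALSE)
    if (!any(have)) return(out)
    sub <- norm[genes[have], , drop = FALSE]
    det <- vapply(strata, function(i)
        rowMeans(sub[, i, drop = FALSE] > 0) * 100, numeric(sum(have)))
    avg <- vapply(strata, function(i)
        rowMeans(sub[, i, drop = FALSE]), numeric(sum(have)))
    det <- matrix(det, nrow = sum(have),
                  dimnames = list(genes[have], names(strata)))
    avg <- matrix(avg, nrow = sum(have),
                  dimnames = list(genes[have], names(strata)))
    passAny <- rowSums(det > pctMin & avg > exprMin) > 0
    bestIx <- max.col(det, ties.method = "first")
    parts <- strsplit(names(strata)[bestIx], ".", fixed = TRUE)
    hi <- which(have)
    out$max_detection_pct[hi] <- det[cbind(seq_along(hi), bestIx)]
    out$mean_expression[hi] <- avg[cbind(seq_along(hi), bestIx)]
    out$best_class[hi] <- vapply(parts, `[`, "", 1)
    out$best_region[hi] <- vapply(parts, `[`, "", 2)
    out$passes[hi] <- passAny | out$override[hi]
    out
}

#' Row-scaled class expression heat map values
#'
#' Per-gene class means of normalized expression, scaled within each gene row
#' either to [0, 1] by dividing by the row maximum (default; preserves the
#' order of expression among classes but not absolute levels) or to z-scores.
#' All-zero rows are emitted as zeros and flagged; rows constant across
#' classes are flagged uninformative.
#'
#' @param genes character vector of genes (absent genes are dropped).
#' @param norm normalized matrix.
#' @param classLabels class per cell.
#' @param scale \code{"max"} or \code{"z"}.
#' @return list: \code{means} (genes x classes), \code{scaled},
#'   \code{flags} (data.frame gene, all_zero, uninformative).
#' @export
classHeatmap <- function(genes, norm, classLabels, scale = c("max", "z")) {
    scale <- match.arg(scale)
    genes <- intersect(genes, rownames(norm))
    if (!length(genes)) stop("no requested gene is present in the matrix")
    classes <- sort(unique(classLabels))
    means <- vapply(classes, function(cl)
        rowMeans(norm[genes, classLabels == cl, drop = FALSE]),
        numeric(length(genes)))
    means <- matrix(means, nrow = length(genes),
                    dimnames = list(genes, classes))
    rmax <- apply(means, 1, max)
    rsd <- apply(means, 1, sd)
    scaled <- if (scale == "max") {
        s <- means / ifelse(rmax > 0, rmax, 1)
        s[rmax == 0, ] <- 0
        s
    } else {
        (means - rowMeans(means)) / ifelse(rsd > 0, rsd, 1)
    }
    list(means = means, scaled = scaled,
         flags = data.frame(gene = genes, all_zero = rmax == 0,
                            uninformative = rsd == 0 & rmax > 0,
                            stringsAsFactors = FALSE))
}

#' Dot-plot statistics per gene and cluster
#'
#' For every (gene, cluster): the percentage of cells with non-zero
#' expression (dot size) and the mean expression within expressing cells only
#' (dot color; 0 when no cell expresses the gene).
#'
#' @param genes character vector of genes (absent genes are dropped).
#' @param norm normalized matrix.
#' @param clusterLabels cluster/type per cell.
#' @return long data.frame: gene, cluster, pct_nonzero (0-100),
#'   mean_expressing.
#' @export
dotplotStats <- function(genes, norm, clusterLabels) {
    genes <- intersect(genes, rownames(norm))
    clusters <- sort(unique(clusterLabels))
    rows <- lapply(clusters, function(q) {
        m <- norm[genes, clusterLabels == q, drop = FALSE]
        nz <- rowSums(m > 0)
        data.frame(gene = genes, cluster = q,
                   pct_nonzero = 100 * nz / ncol(m),
                   mean_expressing = ifelse(nz > 0, rowSums(m) / nz, 0),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Regional expression profile of disease genes per class
#'
#' For every gene and class present in both regions: the foveal and
#' peripheral mean expression and the adjusted p-value of the gene in a
#' fovea-versus-periphery DE test within the class. Classes missing from one
#' region, and genes absent from the matrix, are skipped with a flag.
#'
#' @param genes character vector of genes.
#' @param norm normalized matrix.
#' @param classLabels,regionLabels class and region per cell.
#' @param alpha significance level reported alongside (default 0.001).
#' @return data.frame: gene, class, mean_fovea, mean_periphery, logFC,
#'   p_adj, significant, skipped.
#' @export
regionalDiseaseProfile <- function(genes, norm, classLabels, regionLabels,
                                   alpha = 0.001) {
    present <- intersect(genes, rownames(norm))
    classes <- if (length(present)) sort(unique(classLabels)) else character()
    out <- list()
    for (cl in classes) {
        iF <- which(classLabels == cl & regionLabels == "fovea")
        iP <- which(classLabels == cl & regionLabels == "periphery")
        if (length(iF) < 3 || length(iP) < 3) {
            out[[cl]] <- data.frame(
                gene = present, class = cl, mean_fovea = NA_real_,
                mean_periphery = NA_real_, logFC = NA_real_,
                p_adj = NA_real_, significant = NA, skipped = TRUE,
                stringsAsFactors = FALSE)
            next
        }
        res <- deTest(norm, iF, iP, minPct = 0, minLfc = 0)
        res <- res[match(present, res$gene), ]
        out[[cl]] <- data.frame(
            gene = present, class = cl,
            mean_fovea = rowMeans(norm[present, iF, drop = FALSE]),
            mean_periphery = rowMeans(norm[present, iP, drop = FALSE]),
            logFC = res$logFC, p_adj = res$p_adj,
            significant = !is.na(res$p_adj) & res$p_adj < alpha,
            skipped = FALSE, stringsAsFactors = FALSE)
    }
    skipped <- setdiff(genes, present)
    if (length(skipped))
        out$absent <- data.frame(
            gene = skipped, class = NA_character_, mean_fovea = NA_real_,
            mean_periphery = NA_real_, logFC = NA_real_, p_adj = NA_real_,
            significant = NA, skipped = TRUE, stringsAsFactors = FALSE)
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
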