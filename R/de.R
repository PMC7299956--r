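#' Hurdle differential-expression test between two cell groups
#'
#' The single DE engine used by cluster merging, marker finding,
#' cross-species comparison and the regional analysis. For every gene passing
#' the detection prefilter (detected in more than \code{minPct} of cells in
#' either group) with \eqn{|logFC| \ge minLfc}, a two-part hurdle p-value is
#' computed: (i) a 2x2 chi-square test with continuity correction on
#' detected/undetected counts and (ii) a Welch t-test on normalized
#' expression within expressing cells, combined by Fisher's method. When only
#' one part is defined (e.g. too few expressing cells for the location test)
#' the available part is used alone. Benjamini-Hochberg adjustment is applied
#' over tested genes only; untested genes carry \code{NA} p-values.
#'
#' The log fold change is the difference of group means of the normalized
#' values over \emph{all} cells (zeros included), i.e. natural-log scale, so
#' thresholds of 0.5, 1.0 and 1.1 used elsewhere are directly comparable.
#'
#' @param norm normalized gene x cell matrix (\code{\link{normalizeLog}}).
#' @param cellsA,cellsB disjoint cell selections (indices, names or logical),
#'   each with at least 3 cells.
#' @param minPct detection prefilter (fraction, default 0 = genes detected
#'   anywhere).
#' @param minLfc absolute logFC prefilter (default 0).
#' @return data.frame: \code{gene}, \code{logFC} (A minus B), \code{pct_a},
#'   \code{pct_b}, \code{p_raw}, \code{p_adj}, \code{tested}.
#' @export
deTest <- function(norm, cellsA, cellsB, minPct = 0, minLfc = 0) {
    iA <- .resolveCells(norm, cellsA)
    iB <- .resolveCells(norm, cellsB)
    if (length(intersect(iA, iB))) stop("cell groups overlap")
    if (length(iA) < 3 || length(iB) < 3)
        stop("both groups need at least 3 cells")
    A <- as.matrix(norm[, iA, drop = FALSE])
    B <- as.matrix(norm[, iB, drop = FALSE])
    nA <- ncol(A); nB <- ncol(B)
    detA <- rowSums(A > 0); detB <- rowSums(B > 0)
    pctA <- detA / nA; pctB <- detB / nB
    logFC <- rowMeans(A) - rowMeans(B)
    tested <- (pctA > minPct | pctB > minPct) & abs(logFC) >= minLfc &
        (detA + detB) > 0

    ## detection part: 2x2 chi-square with continuity correction
    a <- detA; b <- nA - detA; cc <- detB; d <- nB - detB
    N <- nA + nB
    num <- pmax(abs(a * d - b * cc) - N / 2, 0)
    den <- (a + b) * (cc + d) * (a + cc) * (b + d)
    chi2 <- ifelse(den > 0, N * num^2 / den, 0)
    p1 <- pchisq(chi2, df = 1, lower.tail = FALSE)

    ## location part: Welch t on expressing cells
    sA <- rowSums(A); sB <- rowSums(B)
    mA <- ifelse(detA > 0, sA / detA, 0)
    mB <- ifelse(detB > 0, sB / detB, 0)
    vA <- ifelse(detA > 1, (rowSums(A^2) - detA * mA^2) / (detA - 1), NA)
    vB <- ifelse(detB > 1, (rowSums(B^2) - detB * mB^2) / (detB - 1), NA)
    vA <- pmax(vA, 0); vB <- pmax(vB, 0)
    se2 <- vA / detA + vB / detB
    okT <- !is.na(se2) & detA > 1 & detB > 1
    p2 <- rep(NA_real_, nrow(A))
    pos <- okT & se2 > 0
    tstat <- (mA[pos] - mB[pos]) / sqrt(se2[pos])
    df <- se2[pos]^2 /
        ((vA[pos] / detA[pos])^2 / (detA[pos] - 1) +
         (vB[pos] / detB[pos])^2 / (detB[pos] - 1))
    p2[pos] <- 2 * pt(-abs(tstat), df)
    zeroSe <- okT & se2 == 0
    p2[zeroSe] <- ifelse(mA[zeroSe] == mB[zeroSe], 1, .Machine$double.xmin)

    ## Fisher combination where both parts exist
    pRaw <- p1
    both <- !is.na(p2)
    cl <- function(p) pmin(pmax(p, 1e-300), 1)
    pRaw[both] <- pchisq(-2 * (log(cl(p1[both])) + log(cl(p2[both]))),
                         df = 4, lower.tail = FALSE)
    pRaw[!tested] <- NA_real_
    pAdj <- rep(NA_real_, length(pRaw))
    pAdj[tested] <- p.adjust(pRaw[tested], method = "BH")
    data.frame(gene = rownames(norm), logFC = logFC,
               pct_a = pctA, pct_b = pctB,
               p_raw = pRaw, p_adj = pAdj, tested = tested,
               row.names = NULL, stringsAsFactors = FALSE)
}

.resolveCells <- function(norm, cells) {
    if (is.logical(cells)) which(cells)
    else if (is.character(cells)) {
        i <- match(cells, colnames(norm))
        if (anyNA(i)) stop("unknown cell id(s)")
        i
    } else as.integer(cells)
}

#' Find genes enriched in one cluster versus its siblings
#'
#' One-vs-rest \code{\link{deTest}} restricted to a scope (typically the
#' cells of one class), returning genes enriched in the target cluster at
#' \code{logFC >= minLfc} (positive direction) and \code{p_adj < alpha},
#' considering only genes detected in more than \code{minPct} of cells of
#' either side.
#'
#' @param norm normalized matrix.
#' @param labels cluster labels, one per column of \code{norm}.
#' @param target the cluster of interest.
#' @param scope optional cell selection defining the comparison universe
#'   (default: all cells).
#' @param minPct,minLfc,alpha selection criteria (defaults 0.2, 0.5, 0.001).
#' @return data.frame of passing genes (subset of \code{deTest} output),
#'   ordered by adjusted p-value.
#' @export
findMarkers <- function(norm, labels, target, scope = NULL,
                        minPct = 0.2, minLfc = 0.5, alpha = 0.001) {
    stopifnot(length(labels) == ncol(norm))
    idx <- if (is.null(scope)) seq_len(ncol(norm))
           else .resolveCells(norm, scope)
    inT <- idx[labels[idx] == target]
    if (!length(inT)) stop("target cluster not present within scope")
    rest <- setdiff(idx, inT)
    if (!length(rest)) stop("scope contains only the target cluster")
    res <- deTest(norm, inT, rest, minPct = minPct, minLfc = minLfc)
    hit <- res$tested & res$logFC >= minLfc & !is.na(res$p_adj) &
        res$p_adj < alpha
    out <- res[hit, , drop = FALSE]
    out[order(out$p_adj, -out$logFC), , drop = FALSE]
}
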