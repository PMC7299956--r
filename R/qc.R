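.countsOf <- function(x) {
    if (methods::is(x, "SummarizedExperiment"))
        SummarizedExperiment::assay(x, "counts") else x
}

#' Per-cell quality-control metrics
#'
#' Number of detected genes (nonzero counts), total transcripts (column sum)
#' and the fraction of counts on mitochondrial genes, identified by gene-name
#' prefix.
#'
#' @param x a \code{SingleCellExperiment} or a gene x cell count matrix.
#' @param mitoPrefix prefix of mitochondrial gene names (default
#'   \code{"MT-"}).
#' @return data.frame with columns \code{n_genes}, \code{n_transcripts},
#'   \code{mito_fraction}, one row per cell. All-zero cells get
#'   \code{mito_fraction} 0.
#' @export
perCellQC <- function(x, mitoPrefix = "MT-") {
    m <- .countsOf(x)
    nTranscripts <- Matrix::colSums(m)
    nGenes <- Matrix::colSums(m > 0)
    mito <- startsWith(rownames(m), mitoPrefix)
    mitoCounts <- if (any(mito)) Matrix::colSums(m[mito, , drop = FALSE])
        else rep(0, ncol(m))
    mf <- ifelse(nTranscripts > 0, mitoCounts / nTranscripts, 0)
    data.frame(n_genes = as.integer(nGenes),
               n_transcripts = nTranscripts,
               mito_fraction = mf,
               row.names = colnames(m))
}

#' Filter cells on detected genes
#'
#' Retains exactly the cells with at least \code{minGenes} detected genes
#' (inclusive threshold), preserving cell order. This is the initial
#' debris/low-quality filter applied before normalization.
#'
#' @param x a \code{SingleCellExperiment} or count matrix.
#' @param minGenes minimum detected genes per cell (default 600).
#' @return the input subset to passing cells.
#' @export
filterCells <- function(x, minGenes = 600) {
    stopifnot(minGenes >= 0)
    m <- .countsOf(x)
    keep <- Matrix::colSums(m > 0) >= minGenes
    if (!any(keep))
        stop("all cells removed: no cell has >= ", minGenes,
             " detected genes (max observed ",
             max(Matrix::colSums(m > 0)), ")")
    x[, keep]
}

#' Median-scaled log normalization
#'
#' Computes expression values \eqn{E_{i,j} = \ln(1 + c_{i,j} \; s / T_j)}
#' where \eqn{T_j} is the total count of cell \eqn{j} and the scale factor
#' \eqn{s} is the median library size (or a fixed number). Zero counts map to
#' zero; values are monotone in counts within a cell.
#'
#' @param x a \code{SingleCellExperiment} (gains a \code{logcounts} assay and
#'   a \code{scaleFactor} metadata entry) or a count matrix (returns a dense
#'   matrix with a \code{scaleFactor} attribute).
#' @param scaleFactor \code{"median"} or a positive number.
#' @param ... unused.
#' @export
setGeneric("normalizeLog",
           function(x, scaleFactor = "median", ...)
               standardGeneric("normalizeLog"))

#' @rdname normalizeLog
#' @export
setMethod("normalizeLog", "ANY", function(x, scaleFactor = "median", ...) {
    tot <- Matrix::colSums(x)
    if (any(tot == 0))
        stop("zero-total cell(s) present; run filterCells first")
    s <- if (identical(scaleFactor, "median")) median(tot)
         else as.numeric(scaleFactor)
    stopifnot(s > 0)
    e <- as.matrix(x)
    e <- log1p(e * rep(s / tot, each = nrow(e)))
    dimnames(e) <- dimnames(x)
    attr(e, "scaleFactor") <- s
    e
})

#' @rdname normalizeLog
#' @export
setMethod("normalizeLog", "SingleCellExperiment",
    function(x, scaleFactor = "median", ...) {
        e <- normalizeLog(SummarizedExperiment::assay(x, "counts"),
                          scaleFactor)
        SummarizedExperiment::assay(x, "logcounts") <- e
        S4Vectors::metadata(x)$scaleFactor <- attr(e, "scaleFactor")
        x
    })

#' Select highly variable genes by binned dispersion
#'
#' Genes are ranked by the z-score of \eqn{\log(\mathrm{variance}/\mathrm{mean})}
#' of their counts within 20 equal-frequency bins of mean expression, so that
#' variability is judged against expression-matched genes. Undetected and
#' zero-variance genes are never selected ahead of overdispersed ones. Ties
#' break deterministically by gene id; the result is invariant to cell order.
#'
#' @param x a \code{SingleCellExperiment} or count matrix.
#' @param nTop number of genes to return.
#' @param nBins number of mean-expression bins (default 20).
#' @return character vector of gene ids, ranked.
#' @export
selectHVGs <- function(x, nTop, nBins = 20) {
    m <- .countsOf(x)
    if (ncol(m) < 2) stop("need at least 2 cells to estimate dispersion")
    stopifnot(nTop <= nrow(m))
    mu <- Matrix::rowMeans(m)
    ex2 <- Matrix::rowMeans(m^2)
    v <- (ex2 - mu^2) * ncol(m) / (ncol(m) - 1)
    genes <- rownames(m)
    det <- mu > 0
    logDisp <- rep(-Inf, nrow(m))
    pos <- det & v > 0
    logDisp[pos] <- log(v[pos] / mu[pos])
    z <- rep(-Inf, nrow(m))
    idx <- which(det)
    nb <- min(nBins, max(1, floor(length(idx) / 2)))
    br <- unique(quantile(mu[idx], probs = seq(0, 1, length.out = nb + 1)))
    bin <- cut(mu[idx], breaks = br, include.lowest = TRUE)
    for (lv in levels(bin)) {
        bi <- idx[bin == lv]
        ld <- logDisp[bi]
        fin <- is.finite(ld)
        if (sum(fin) >= 2 && sd(ld[fin]) > 0) {
            z[bi[fin]] <- (ld[fin] - mean(ld[fin])) / sd(ld[fin])
        } else z[bi[fin]] <- 0
    }
    ord <- order(-z, genes)
    genes[ord][seq_len(nTop)]
}

#' Remove batch effects by per-gene linear regression
#'
#' Fits, for every gene, a least-squares regression of normalized expression
#' on batch indicators and returns the residuals plus the gene's grand mean
#' (negative values are allowed in the output). With a single batch the input
#' is returned unchanged.
#'
#' @param norm normalized gene x cell matrix (see \code{\link{normalizeLog}}).
#' @param batch character/factor of batch labels, one per cell.
#' @return corrected matrix of the same shape.
#' @export
regressBatch <- function(norm, batch) {
    stopifnot(length(batch) == ncol(norm))
    f <- if (is.factor(batch)) batch else factor(batch)
    if (any(table(f) == 0)) stop("batch level with 0 cells")
    if (nlevels(f) < 2) return(norm)
    out <- limma::removeBatchEffect(norm, batch = f)
    attr(out, "scaleFactor") <- attr(norm, "scaleFactor")
    out
}

## Tracy-Widom (beta = 1) quantiles for the largest-eigenvalue test
.TW1 <- c("0.9" = 0.4501, "0.95" = 0.9793, "0.975" = 1.4538,
          "0.99" = 2.0234, "0.995" = 2.4224, "0.999" = 3.2724)

#' PCA with random-matrix-theory selection of significant components
#'
#' Standardizes every gene to mean 0 / unit variance, eigendecomposes the
#' gene covariance across cells and counts components whose eigenvalues
#' exceed what pure noise would produce. The null spectrum of a standardized
#' p x n matrix follows the Marchenko-Pastur law with upper edge
#' \eqn{\lambda_+ = (1 + \sqrt{p/n})^2}; the largest noise eigenvalue
#' fluctuates around that edge on the Tracy-Widom scale, so significance is
#' called at the Johnstone threshold
#' \eqn{(\mu_{np} + \sigma_{np} q_{TW1}) / (n-1)} (default quantile 0.99),
#' i.e. the MP edge with its finite-size correction.
#'
#' @param x gene x cell matrix of normalized expression (usually the HVG
#'   subset), or a \code{SingleCellExperiment} with \code{logcounts}.
#' @param nMax maximum number of components to return scores for.
#' @param twQuantile one of 0.9, 0.95, 0.975, 0.99, 0.995, 0.999.
#' @return list with \code{scores} (cells x nSig), \code{loadings},
#'   \code{eigenvalues} (descending, full spectrum), \code{nSig},
#'   \code{threshold} and \code{mpEdge}.
#' @export
pcaRMT <- function(x, nMax = 50, twQuantile = 0.99) {
    if (methods::is(x, "SummarizedExperiment"))
        x <- SummarizedExperiment::assay(x, "logcounts")
    x <- as.matrix(x)
    n <- ncol(x)
    if (n < 3) stop("need at least 3 cells")
    mu <- rowMeans(x)
    sdv <- apply(x, 1, sd)
    keep <- sdv > 0
    X <- (x[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
    p <- nrow(X)
    qkey <- as.character(twQuantile)
    if (!qkey %in% names(.TW1))
        stop("twQuantile must be one of ",
             paste(names(.TW1), collapse = ", "))
    muNP <- (sqrt(n - 1) + sqrt(p))^2
    sigNP <- (sqrt(n - 1) + sqrt(p)) *
        (1 / sqrt(n - 1) + 1 / sqrt(p))^(1 / 3)
    threshold <- (muNP + sigNP * .TW1[[qkey]]) / (n - 1)
    mpEdge <- (1 + sqrt(p / n))^2
    if (p <= n) {
        eg <- eigen(tcrossprod(X) / (n - 1), symmetric = TRUE)
        ev <- pmax(eg$values, 0)
        nSig <- sum(ev > threshold)
        nk <- min(max(nSig, 1), nMax, p)
        U <- eg$vectors[, seq_len(nk), drop = FALSE]
        scores <- crossprod(X, U)
    } else {
        eg <- eigen(crossprod(X) / (n - 1), symmetric = TRUE)
        ev <- pmax(eg$values, 0)
        nSig <- sum(ev > threshold)
        nk <- min(max(nSig, 1), nMax, n)
        V <- eg$vectors[, seq_len(nk), drop = FALSE]
        d <- sqrt(ev[seq_len(nk)] * (n - 1))
        scores <- V %*% diag(d, nk)
        U <- X %*% V
        U <- sweep(U, 2, pmax(d, 1e-12), "/")
    }
    take <- min(nSig, nMax)
    rownames(scores) <- colnames(x)
    list(scores = scores[, seq_len(take), drop = FALSE],
         loadings = U[, seq_len(take), drop = FALSE],
         eigenvalues = ev, nSig = as.integer(min(nSig, nMax)),
         threshold = threshold, mpEdge = mpEdge,
         nGenes = p, nCells = n)
}
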