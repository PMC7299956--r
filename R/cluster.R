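#' Jaccard-weighted k-nearest-neighbor graph
#'
#' Builds the cell graph used for community detection: k nearest neighbors by
#' Euclidean distance in the significant-PC space, with each edge between
#' cells that are (one-way or mutual) neighbors weighted by the Jaccard
#' overlap of their neighbor sets, \eqn{|N(i) \cap N(j)| / |N(i) \cup N(j)|}.
#' Pairs with disjoint neighbor sets are dropped.
#'
#' @param scores cells x dims matrix (e.g. \code{pcaRMT(...)$scores}).
#' @param k neighbors per cell (must satisfy \code{0 < k < n}).
#' @return an \code{igraph} undirected graph with a \code{weight} edge
#'   attribute in (0, 1]; vertex names are cell ids.
#' @export
buildJaccardGraph <- function(scores, k = 30) {
    n <- nrow(scores)
    if (k <= 0) stop("k must be positive")
    if (k >= n) stop("k must be smaller than the number of cells")
    nn <- BiocNeighbors::findKNN(as.matrix(scores), k = k)
    A <- Matrix::sparseMatrix(i = rep(seq_len(n), k),
                              j = as.vector(nn$index),
                              x = 1, dims = c(n, n))
    Inter <- Matrix::tcrossprod(A)
    Mask <- ((A + Matrix::t(A)) > 0) * 1
    W <- Inter * Mask
    S <- Matrix::summary(Matrix::triu(W, 1))
    S <- S[S$x > 0, , drop = FALSE]
    jac <- S$x / (2 * k - S$x)
    ids <- rownames(scores)
    if (is.null(ids)) ids <- as.character(seq_len(n))
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = ids)
    g <- igraph::add_edges(g, rbind(S$i, S$j))
    igraph::E(g)$weight <- jac
    g$k <- k
    g
}

#' Louvain community detection on the cell graph
#'
#' Weighted modularity optimization; deterministic for a given seed. Cluster
#' labels are renumbered by descending cluster size (ties by first
#' occurrence).
#'
#' @param graph graph from \code{\link{buildJaccardGraph}}.
#' @param seed RNG seed (Louvain's vertex sweep consumes R randomness).
#' @param resolution modularity resolution (default 1).
#' @return integer cluster label per cell, named by cell id.
#' @export
louvainCluster <- function(graph, seed = 0, resolution = 1) {
    if (igraph::vcount(graph) == 0) stop("empty graph")
    memb <- .withSeed(seed, igraph::membership(
        igraph::cluster_louvain(graph, resolution = resolution)))
    sizes <- table(memb)
    ord <- order(-as.integer(sizes), as.integer(names(sizes)))
    renum <- setNames(seq_along(ord), names(sizes)[ord])
    out <- as.integer(renum[as.character(memb)])
    names(out) <- igraph::V(graph)$name
    out
}

#' Assign cell classes to clusters from a marker panel
#'
#' Scores every (cluster, class) pair as the mean over the class's markers of
#' the cluster-mean expression standardized across clusters, and assigns the
#' argmax class. Markers absent from the matrix are dropped with a warning; a
#' class whose markers are all absent is an error. Exact ties are broken
#' alphabetically and flagged ambiguous.
#'
#' @param labels cluster labels, one per column of \code{norm}.
#' @param norm normalized matrix.
#' @param panel named list: class -> marker gene ids.
#' @return data.frame (cluster, class, margin, ambiguous), one row per
#'   cluster.
#' @export
assignClasses <- function(labels, norm, panel) {
    stopifnot(length(panel) >= 1, length(labels) == ncol(norm))
    present <- lapply(panel, intersect, rownames(norm))
    dropped <- sum(lengths(panel)) - sum(lengths(present))
    if (dropped > 0)
        warning(dropped, " marker(s) absent from the matrix were dropped")
    empty <- names(present)[lengths(present) == 0]
    if (length(empty))
        stop("class(es) with no surviving markers: ",
             paste(empty, collapse = ", "))
    clusters <- sort(unique(labels))
    allMk <- unique(unlist(present))
    cm <- vapply(clusters, function(q)
        rowMeans(norm[allMk, labels == q, drop = FALSE]),
        numeric(length(allMk)))
    cm <- matrix(cm, nrow = length(allMk),
                 dimnames = list(allMk, as.character(clusters)))
    mu <- rowMeans(cm)
    sdv <- apply(cm, 1, sd)
    z <- (cm - mu) / ifelse(sdv > 0, sdv, 1)
    scores <- vapply(present, function(mk)
        colMeans(z[mk, , drop = FALSE]), numeric(length(clusters)))
    scores <- matrix(scores, nrow = length(clusters),
                     dimnames = list(as.character(clusters), names(present)))
    cls <- colnames(scores)[apply(scores, 1, which.max)]
    margin <- apply(scores, 1, function(s) {
        s <- sort(s, decreasing = TRUE)
        if (length(s) > 1) s[1] - s[2] else Inf
    })
    data.frame(cluster = clusters, class = cls, margin = margin,
               ambiguous = margin <= .Machine$double.eps,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Flag doublet and low-quality clusters
#'
#' Applies the post-clustering artifact heuristics. A cluster is flagged as
#' doublets when (i) at the class stage, the marker panels of two or more
#' classes score highly (mean marker z-score across clusters of at least
#' \code{markerZ}; a mixed transcriptome scores high for both parental
#' classes); (ii) it has no \emph{uniquely} expressed marker gene, i.e. no
#' gene that both passes the one-vs-rest \code{\link{findMarkers}} criteria
#' and exceeds the mean of every other cluster by at least \code{minLfc}
#' (a doublet's candidate genes are always matched by one of its parent
#' clusters); and (iii) the mean number of detected genes exceeds
#' \code{geneFactor} times that of the other clusters. Within a class
#' (\code{withinClass = TRUE}, the second clustering round) condition (i) is
#' dropped. A cluster is flagged low-quality when its median transcript count
#' falls below \code{depthRatio} times the median of the other clusters while
#' its median mitochondrial fraction exceeds \code{mitoThreshold} (damaged
#' cells leak cytoplasmic RNA but retain mitochondrial transcripts).
#'
#' @param labels cluster labels, one per column of \code{norm}.
#' @param classAssign output of \code{\link{assignClasses}} (may be
#'   \code{NULL} when \code{withinClass = TRUE}).
#' @param qc per-cell metrics from \code{\link{perCellQC}}, aligned to the
#'   columns of \code{norm}.
#' @param norm normalized matrix.
#' @param panel marker panel (used for the multi-class condition).
#' @param withinClass logical; use the within-class rule (no marker-panel
#'   condition).
#' @param geneFactor,markerZ,depthRatio,mitoThreshold rule thresholds
#'   (defaults 1.2, 0.5, 0.5, 0.10).
#' @param minPct,minLfc,alpha unique-marker criteria passed to
#'   \code{\link{findMarkers}}.
#' @return data.frame per cluster: \code{cluster}, \code{doublet},
#'   \code{low_quality}, \code{n_classes_high}, \code{n_unique_markers},
#'   \code{gene_ratio}, \code{depth_ratio}, \code{mito_median}.
#' @export
flagArtifactClusters <- function(labels, classAssign, qc, norm, panel = NULL,
                                 withinClass = FALSE, geneFactor = 1.2,
                                 markerZ = 0.5, depthRatio = 0.5,
                                 mitoThreshold = 0.10, minPct = 0.2,
                                 minLfc = 0.5, alpha = 0.001) {
    stopifnot(length(labels) == ncol(norm), nrow(qc) == ncol(norm))
    clusters <- sort(unique(labels))
    cn <- as.character(clusters)
    nHigh <- setNames(rep(0L, length(clusters)), cn)
    if (!withinClass) {
        if (is.null(panel)) stop("panel required at the class stage")
        present <- lapply(panel, intersect, rownames(norm))
        allMk <- unique(unlist(present))
        cm <- vapply(clusters, function(q)
            rowMeans(norm[allMk, labels == q, drop = FALSE]),
            numeric(length(allMk)))
        cm <- matrix(cm, nrow = length(allMk),
                     dimnames = list(allMk, cn))
        sdv <- apply(cm, 1, sd)
        z <- (cm - rowMeans(cm)) / ifelse(sdv > 0, sdv, 1)
        score <- vapply(present, function(mk)
            colMeans(z[mk, , drop = FALSE]), numeric(length(clusters)))
        score <- matrix(score, nrow = length(clusters),
                        dimnames = list(cn, names(present)))
        nHigh[] <- rowSums(score >= markerZ)
    }
    ## per-cluster mean expression, for the uniqueness margin
    cmAll <- vapply(clusters, function(q)
        rowMeans(norm[, labels == q, drop = FALSE]),
        numeric(nrow(norm)))
    cmAll <- matrix(cmAll, nrow = nrow(norm),
                    dimnames = list(rownames(norm), cn))
    out <- lapply(clusters, function(q) {
        inQ <- labels == q
        nUnique <- NA_integer_
        if (sum(!inQ) >= 3 && sum(inQ) >= 3) {
            fm <- findMarkers(norm, labels, q, minPct = minPct,
                              minLfc = minLfc, alpha = alpha)
            if (nrow(fm)) {
                others <- cmAll[fm$gene, cn != as.character(q),
                                drop = FALSE]
                margin <- cmAll[fm$gene, as.character(q)] -
                    apply(others, 1, max)
                nUnique <- sum(margin >= minLfc)
            } else nUnique <- 0L
        }
        gRatio <- mean(qc$n_genes[inQ]) / mean(qc$n_genes[!inQ])
        dRatio <- median(qc$n_transcripts[inQ]) /
            median(qc$n_transcripts[!inQ])
        mitoMed <- median(qc$mito_fraction[inQ])
        doubletGate <- if (withinClass) TRUE
                       else nHigh[as.character(q)] >= 2
        doublet <- isTRUE(doubletGate && !is.na(nUnique) && nUnique == 0 &&
                          gRatio > geneFactor)
        lowq <- isTRUE(dRatio < depthRatio && mitoMed > mitoThreshold)
        data.frame(cluster = q, doublet = doublet, low_quality = lowq,
                   n_classes_high = nHigh[as.character(q)],
                   n_unique_markers = nUnique, gene_ratio = gRatio,
                   depth_ratio = dRatio, mito_median = mitoMed,
                   row.names = NULL, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Iteratively merge transcriptomically indistinct clusters
#'
#' Builds a dendrogram over clusters (hierarchical agglomerative clustering
#' with complete linkage of the Euclidean distance between per-cluster mean
#' HVG expression) and iteratively merges neighboring clusters: the two
#' clusters joined at the lowest untested node are compared with the DE
#' engine and merged if no more than \code{maxDE} genes show
#' \eqn{|logFC| \ge minLfc} at adjusted p < \code{alpha}. After every merge
#' the dendrogram is recomputed; the procedure stops when no neighboring pair
#' merges (a fixed point, so rerunning changes nothing). Clusters too small
#' to test (< 3 cells) are merged into their dendrogram neighbor.
#'
#' @param labels initial cluster labels, one per column of \code{norm}.
#' @param norm normalized matrix (all genes; DE is genome-wide).
#' @param hvgs gene ids used for the dendrogram distances.
#' @param maxDE maximum DE genes tolerated between merged clusters
#'   (default 5).
#' @param minLfc,alpha DE-gene criteria (defaults 1.1, 0.001).
#' @param minPct detection prefilter inside the DE test (default 0.05).
#' @param deFn DE engine, interface-compatible with \code{\link{deTest}}.
#' @return list: \code{labels} (merged, renumbered by descending size),
#'   \code{dendrogram} (final \code{hclust} or \code{NULL}),
#'   \code{nMerges}.
#' @export
mergeClusters <- function(labels, norm, hvgs, maxDE = 5, minLfc = 1.1,
                          alpha = 0.001, minPct = 0.05, deFn = deTest) {
    stopifnot(length(labels) == ncol(norm))
    lab <- labels
    failed <- character()
    nMerges <- 0L
    repeat {
        cl <- sort(unique(lab))
        if (length(cl) < 2) break
        means <- t(vapply(cl, function(q)
            rowMeans(norm[hvgs, lab == q, drop = FALSE]),
            numeric(length(hvgs))))
        rownames(means) <- as.character(cl)
        hc <- hclust(dist(means), method = "complete")
        pairs <- .leafSiblingPairs(hc)
        merged <- FALSE
        for (pi in seq_len(nrow(pairs))) {
            a <- cl[pairs[pi, 1]]; b <- cl[pairs[pi, 2]]
            key <- paste(sort(c(a, b)), collapse = "|")
            if (key %in% failed) next
            nA <- sum(lab == a); nB <- sum(lab == b)
            if (nA >= 3 && nB >= 3) {
                res <- deFn(norm, which(lab == a), which(lab == b),
                            minPct = minPct, minLfc = 0)
                nDE <- sum(res$tested & abs(res$logFC) >= minLfc &
                           !is.na(res$p_adj) & res$p_adj < alpha)
            } else nDE <- 0L  # untestable pair: collapse
            if (nDE <= maxDE) {
                lab[lab == b] <- a
                failed <- failed[!grepl(paste0("(^|\\|)(", a, "|", b,
                                               ")(\\||$)"), failed)]
                nMerges <- nMerges + 1L
                merged <- TRUE
                break
            } else failed <- c(failed, key)
        }
        if (!merged) break
    }
    lab <- .renumberBySize(lab)
    cl <- sort(unique(lab))
    dend <- NULL
    if (length(cl) >= 2) {
        means <- t(vapply(cl, function(q)
            rowMeans(norm[hvgs, lab == q, drop = FALSE]),
            numeric(length(hvgs))))
        rownames(means) <- as.character(cl)
        dend <- hclust(dist(means), method = "complete")
    }
    list(labels = lab, dendrogram = dend, nMerges = nMerges)
}

## sibling pairs = dendrogram joins of two leaves, ascending by height
.leafSiblingPairs <- function(hc) {
    leaf <- hc$merge < 0
    both <- leaf[, 1] & leaf[, 2]
    m <- -hc$merge[both, , drop = FALSE]
    m[order(hc$height[both]), , drop = FALSE]
}

.renumberBySize <- function(lab) {
    sizes <- table(lab)
    ord <- order(-as.integer(sizes), names(sizes))
    map <- setNames(seq_along(ord), names(sizes)[ord])
    out <- as.integer(map[as.character(lab)])
    names(out) <- names(lab)
    out
}
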