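#' Train a multi-class cell-type classifier on a reference species
#'
#' Gradient-boosted decision trees (xgboost, softmax over types) trained on
#' per-cell normalized expression of 1:1 orthologs, used to map cells of a
#' second species onto the reference type labels. Intended to be trained per
#' cell class, one model per class. Class imbalance is capped by downsampling
#' types to at most \code{maxImbalance} times the smallest retained type;
#' types with fewer than 10 cells are excluded with a warning. Held-out
#' accuracy on a stratified split is recorded.
#'
#' @param refNorm normalized gene x cell matrix of the reference species.
#' @param refTypes type label per reference cell.
#' @param ortho 1:1 ortholog table (\code{species_a}, \code{species_b});
#'   features are restricted to ortholog genes present in \code{refNorm}.
#'   \code{NULL} uses all reference genes (same-species use).
#' @param refSide which ortholog column names the reference genes
#'   (\code{"species_b"} by default: the reference is the second species).
#' @param nRounds,maxDepth,eta xgboost hyperparameters.
#' @param holdout fraction held out for the accuracy report.
#' @param maxImbalance cap on type size ratio.
#' @param seed RNG seed (downsampling and split).
#' @return object of class \code{typeClassifier}: the fitted model, the
#'   feature genes in reference and query namespaces, the type levels and
#'   \code{heldOutAccuracy}.
#' @export
trainTypeClassifier <- function(refNorm, refTypes, ortho = NULL,
                                refSide = c("species_b", "species_a"),
                                nRounds = 60, maxDepth = 4, eta = 0.3,
                                holdout = 0.2, maxImbalance = 10,
                                seed = 0) {
    refSide <- match.arg(refSide)
    stopifnot(length(refTypes) == ncol(refNorm))
    if (!is.null(ortho)) {
        qSide <- setdiff(c("species_a", "species_b"), refSide)
        keep <- ortho[[refSide]] %in% rownames(refNorm)
        featRef <- ortho[[refSide]][keep]
        featQuery <- ortho[[qSide]][keep]
    } else {
        featRef <- featQuery <- rownames(refNorm)
    }
    if (length(featRef) < 20)
        stop("fewer than 20 shared orthologs; cannot train")
    sizes <- table(refTypes)
    small <- names(sizes)[sizes < 10]
    if (length(small)) {
        warning("excluding type(s) with < 10 cells: ",
                paste(small, collapse = ", "))
        keepC <- !(refTypes %in% small)
        refNorm <- refNorm[, keepC, drop = FALSE]
        refTypes <- refTypes[keepC]
        sizes <- table(refTypes)
    }
    if (length(sizes) < 2) stop("need at least 2 reference types")
    .withSeed(seed, {
        cap <- max(min(sizes) * maxImbalance, 10)
        sel <- unlist(lapply(names(sizes), function(tp) {
            i <- which(refTypes == tp)
            if (length(i) > cap) sample(i, cap) else i
        }))
        sel <- sort(sel)
        X <- t(as.matrix(refNorm[featRef, sel, drop = FALSE]))
        yFac <- factor(refTypes[sel])
        y <- as.integer(yFac) - 1L
        test <- unlist(lapply(levels(yFac), function(tp) {
            i <- which(yFac == tp)
            sample(i, max(1, floor(holdout * length(i))))
        }))
        train <- setdiff(seq_along(y), test)
        pars <- list(objective = "multi:softprob",
                     num_class = nlevels(yFac), max_depth = maxDepth,
                     eta = eta, nthread = 1, subsample = 1,
                     verbosity = 0)
        dtrain <- xgboost::xgb.DMatrix(X[train, , drop = FALSE],
                                       label = y[train])
        splitModel <- xgboost::xgb.train(params = pars, data = dtrain,
                                         nrounds = nRounds)
        predTest <- .predictTypes(splitModel, X[test, , drop = FALSE],
                                  levels(yFac))
        acc <- mean(predTest == as.character(yFac)[test])
        ## final model refit on every (downsampled) reference cell: the
        ## hold-out only measures accuracy, it should not cost training data
        model <- xgboost::xgb.train(params = pars,
                                    data = xgboost::xgb.DMatrix(X,
                                                                label = y),
                                    nrounds = nRounds)
        structure(list(model = model, featureGenesRef = featRef,
                       featureGenesQuery = featQuery,
                       types = levels(yFac), heldOutAccuracy = acc,
                       params = pars, nRounds = nRounds),
                  class = "typeClassifier")
    })
}

.predictTypes <- function(model, X, types) {
    pr <- predict(model, xgboost::xgb.DMatrix(X))
    if (!is.matrix(pr))
        pr <- matrix(pr, ncol = length(types), byrow = TRUE)
    types[max.col(pr, ties.method = "first")]
}

#' @export
print.typeClassifier <- function(x, ...) {
    cat("typeClassifier:", length(x$types), "types,",
        length(x$featureGenesRef), "ortholog features, held-out accuracy",
        round(x$heldOutAccuracy, 3), "\n")
    invisible(x)
}

#' Map query cells onto reference type labels
#'
#' Applies a trained \code{typeClassifier} to every query cell independently
#' (cluster identities are never consulted), returning one hard reference
#' type label per cell (argmax of the class scores).
#'
#' @param clf a \code{typeClassifier}.
#' @param queryNorm normalized gene x cell matrix of the query species; must
#'   contain every query-side feature gene.
#' @return character vector of predicted reference types, named by cell id.
#' @export
mapCells <- function(clf, queryNorm) {
    miss <- setdiff(clf$featureGenesQuery, rownames(queryNorm))
    if (length(miss))
        stop("feature mismatch: ", length(miss),
             " ortholog gene(s) absent from the query matrix")
    X <- t(as.matrix(queryNorm[clf$featureGenesQuery, , drop = FALSE]))
    setNames(.predictTypes(clf$model, X, clf$types), colnames(queryNorm))
}

#' Confusion matrix of query clusters against reference types
#'
#' For each query cluster (column), the percentage of its cells assigned to
#' each reference type (row). Columns sum to 100.
#'
#' @param queryClusters cluster label per query cell.
#' @param predictedTypes predicted reference type per query cell (from
#'   \code{\link{mapCells}}).
#' @return numeric matrix, reference types x query clusters, in percent.
#' @export
confusionMatrix <- function(queryClusters, predictedTypes) {
    stopifnot(length(queryClusters) == length(predictedTypes))
    qf <- if (is.factor(queryClusters)) queryClusters
          else factor(queryClusters)
    pf <- if (is.factor(predictedTypes)) predictedTypes
          else factor(predictedTypes)
    tab <- table(pf, qf)
    cs <- colSums(tab)
    if (any(cs == 0)) stop("empty query cluster")
    m <- sweep(unclass(tab), 2, cs, "/") * 100
    dimnames(m) <- list(rownames(tab), colnames(tab))
    m
}

#' Call near 1:1 type correspondences from a confusion matrix
#'
#' A query cluster q is matched to reference type r when at least \code{tau}
#' percent of q's cells map to r, r is the plurality row of column q, and q
#' is reciprocally the plurality column of row r. Clusters failing the rule
#' are reported unmapped.
#'
#' @param conf matrix from \code{\link{confusionMatrix}}.
#' @param tau forward-percentage threshold in (0, 100] (default 50).
#' @return data.frame: \code{query}, \code{ref}, \code{forward_pct},
#'   \code{reciprocal}, \code{matched}; one row per query cluster.
#' @export
callCorrespondences <- function(conf, tau = 50) {
    stopifnot(tau > 0, tau <= 100)
    out <- lapply(colnames(conf), function(q) {
        col <- conf[, q]
        r <- rownames(conf)[which.max(col)]
        fwd <- max(col)
        recip <- colnames(conf)[which.max(conf[r, ])] == q
        matched <- fwd >= tau && recip
        data.frame(query = q, ref = if (matched) r else NA_character_,
                   forward_pct = fwd, reciprocal = recip,
                   matched = matched, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Shared proportion of type-specific DE genes across species
#'
#' For a shared type, the percentage of its species-A differential markers
#' that are also differential markers of the corresponding species-B type:
#' \eqn{100 \cdot |hDE \cap mDE| / |hDE|}. Species-B genes are translated to
#' species-A symbols through the 1:1 ortholog table first; species-B genes
#' without an ortholog are dropped from the species-B set only. The statistic
#' is intentionally asymmetric (the denominator is the species-A list). An
#' empty species-A set yields \code{NA} (undefined), not 0.
#'
#' @param hDE character, species-A DE gene set.
#' @param mDE character, species-B DE gene set.
#' @param ortho optional ortholog table used to translate \code{mDE}.
#' @return percentage in [0, 100], or \code{NA_real_}.
#' @export
computePDE <- function(hDE, mDE, ortho = NULL) {
    if (length(hDE) == 0) return(NA_real_)
    if (!is.null(ortho)) {
        i <- match(mDE, ortho$species_b)
        mDE <- ortho$species_a[i[!is.na(i)]]
    }
    100 * length(intersect(hDE, mDE)) / length(unique(hDE))
}
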