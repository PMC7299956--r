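#' Fovea-versus-periphery differential expression per type
#'
#' For every type with at least \code{minCells} cells in \emph{both} regions
#' (inclusive boundary: exactly 20 cells qualifies), runs the DE engine
#' between the type's foveal and peripheral cells and counts genes with
#' \eqn{|logFC| \ge minLfc} at adjusted p < \code{alpha}. Types below the
#' cell threshold are reported untested.
#'
#' @param norm normalized matrix.
#' @param typeLabels type per cell.
#' @param regionLabels region per cell (\code{fovea} / \code{periphery}).
#' @param minCells minimum cells per region (default 20).
#' @param minLfc,alpha DE-gene criteria (defaults 1.0, 0.001).
#' @param minPct detection prefilter for the underlying test (default 0.05).
#' @return list with \code{summary} (data.frame: type, n_fovea, n_periphery,
#'   tested, n_de) and \code{results} (named list of DE tables restricted to
#'   the passing genes, fovea relative to periphery).
#' @export
regionalDE <- function(norm, typeLabels, regionLabels, minCells = 20,
                       minLfc = 1.0, alpha = 0.001, minPct = 0.05) {
    stopifnot(length(typeLabels) == ncol(norm),
              length(regionLabels) == ncol(norm))
    bad <- setdiff(unique(regionLabels), c("fovea", "periphery"))
    if (length(bad))
        stop("unknown region label(s): ", paste(bad, collapse = ", "))
    types <- sort(unique(typeLabels))
    results <- list()
    rows <- lapply(types, function(tp) {
        iF <- which(typeLabels == tp & regionLabels == "fovea")
        iP <- which(typeLabels == tp & regionLabels == "periphery")
        tested <- length(iF) >= minCells && length(iP) >= minCells
        nDE <- NA_integer_
        if (tested) {
            res <- deTest(norm, iF, iP, minPct = minPct, minLfc = 0)
            hit <- res$tested & abs(res$logFC) >= minLfc &
                !is.na(res$p_adj) & res$p_adj < alpha
            nDE <- sum(hit)
            results[[tp]] <<- res[hit, , drop = FALSE]
        }
        data.frame(type = tp, n_fovea = length(iF),
                   n_periphery = length(iP), tested = tested, n_de = nDE,
                   stringsAsFactors = FALSE)
    })
    list(summary = do.call(rbind, rows), results = results)
}

#' Per-donor cell-type proportions by class and region
#'
#' Within every (class, region, donor) stratum, the fraction of the class's
#' cells belonging to each type (fractions sum to 1 per stratum), plus the
#' median and interquartile range across donors for each (class, region,
#' type) — the quantities behind per-donor box plots of regional type
#' composition.
#'
#' @param typeLabels,classLabels type and class per cell.
#' @param region,donor region and donor per cell.
#' @return list with \code{perDonor} (class, region, donor, type, n,
#'   fraction) and \code{summary} (class, region, type, median, iqr,
#'   n_donors).
#' @export
typeProportions <- function(typeLabels, classLabels, region, donor) {
    n <- length(typeLabels)
    stopifnot(length(classLabels) == n, length(region) == n,
              length(donor) == n)
    df <- data.frame(type = typeLabels, class = classLabels,
                     region = region, donor = donor,
                     stringsAsFactors = FALSE)
    cnt <- aggregate(list(n = rep(1L, nrow(df))),
                     df[, c("class", "region", "donor", "type")], sum)
    tot <- aggregate(list(total = cnt$n),
                     cnt[, c("class", "region", "donor")], sum)
    perDonor <- merge(cnt, tot, by = c("class", "region", "donor"))
    perDonor$fraction <- perDonor$n / perDonor$total
    perDonor <- perDonor[order(perDonor$class, perDonor$region,
                               perDonor$donor, perDonor$type), ]
    rownames(perDonor) <- NULL
    ## across-donor summary; donors lacking a type contribute fraction 0
    sumRows <- list()
    for (key in unique(paste(perDonor$class, perDonor$region, sep = "\r"))) {
        parts <- strsplit(key, "\r")[[1]]
        sub <- perDonor[perDonor$class == parts[1] &
                        perDonor$region == parts[2], ]
        donors <- unique(sub$donor)
        for (tp in unique(sub$type)) {
            fr <- setNames(rep(0, length(donors)), donors)
            have <- sub[sub$type == tp, ]
            fr[have$donor] <- have$fraction
            sumRows[[length(sumRows) + 1]] <- data.frame(
                class = parts[1], region = parts[2], type = tp,
                median = median(fr), iqr = unname(
                    quantile(fr, 0.75) - quantile(fr, 0.25)),
                n_donors = length(donors), stringsAsFactors = FALSE)
        }
    }
    list(perDonor = perDonor[, c("class", "region", "donor", "type",
                                 "n", "fraction")],
         summary = do.call(rbind, sumRows))
}

#' Per-region abundance ratio between two groups of types
#'
#' Pooled-cell ratio of numerator to denominator types within each region
#' (e.g. GABAergic vs glycinergic amacrine types, or H1 vs H2 horizontal
#' cells), plus the same ratio per donor. An empty numerator gives 0; an
#' empty denominator gives \code{Inf} with a flag.
#'
#' @param typeLabels type per cell.
#' @param region,donor region and donor per cell.
#' @param numerator,denominator character vectors of type names.
#' @return data.frame: region, donor (\code{"pooled"} for the pooled rows),
#'   n_numerator, n_denominator, ratio, degenerate.
#' @export
ratioSummary <- function(typeLabels, region, donor, numerator, denominator) {
    stopifnot(length(numerator) >= 1, length(denominator) >= 1)
    mk <- function(reg, don, sel) {
        nN <- sum(typeLabels[sel] %in% numerator)
        nD <- sum(typeLabels[sel] %in% denominator)
        data.frame(region = reg, donor = don, n_numerator = nN,
                   n_denominator = nD,
                   ratio = if (nD == 0) Inf else nN / nD,
                   degenerate = nD == 0, stringsAsFactors = FALSE)
    }
    out <- list()
    for (reg in sort(unique(region))) {
        out[[length(out) + 1]] <- mk(reg, "pooled", region == reg)
        for (don in sort(unique(donor[region == reg])))
            out[[length(out) + 1]] <-
                mk(reg, don, region == reg & donor == don)
    }
    do.call(rbind, out)
}
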