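#' @import methods
#' @importFrom stats median quantile rnorm runif rbinom rgamma rnbinom rlnorm
#'   sd var dist hclust cutree p.adjust pchisq pt setNames rmultinom aggregate
#'   predict
#' @importFrom utils read.table write.table head
NULL

#' Simulation configuration for a synthetic retina atlas
#'
#' Parameters controlling \code{\link{generateAtlas}}. The defaults emulate
#' the structure of a pooled fovea/periphery retina dataset: 6 cell classes
#' subdivided into 20 types, class- and type-specific marker genes,
#' region-dependent type proportions (e.g. rod bipolar cells scarce in the
#' fovea, H1:H2 ratio much higher in fovea than periphery), region-specific
#' differentially expressed genes, doublets, low-quality high-mitochondrial
#' cells, and a second species whose types share perturbed signatures over a
#' partial set of 1:1 orthologs.
#'
#' @slot classes character, class names.
#' @slot typesPerClass integer, number of types within each class.
#' @slot nCellsFovea,nCellsPeriphery integer, cells per region (species A).
#' @slot nGenes integer, total genes including mitochondrial genes.
#' @slot baselineMean numeric, mean of the per-gene Gamma baseline.
#' @slot markerFold numeric > 1, fold-up of class/type markers.
#' @slot nMarkersPerType,nMarkersPerClass integer, planted marker counts.
#' @slot regionDEGenesPerType integer, planted region-DE genes per type.
#' @slot regionFold numeric > 1, fold-up of region-DE genes in their region.
#' @slot typeProportionsByRegion matrix (types x {fovea, periphery}); each
#'   column sums to 1.
#' @slot doubletRate,lowqRate numeric in [0,1], per-cell artifact rates.
#' @slot doubletDepthFactor numeric >= 1, multiple of a typical library size
#'   that a two-cell droplet is rescaled to (droplet RNA content is roughly
#'   additive but capture efficiency caps it below 2x).
#' @slot lowqDepthFactor numeric in (0,1), binomial thinning factor for
#'   low-quality cells.
#' @slot lowqMitoFrac numeric in [0,1], target mitochondrial fraction of
#'   low-quality cells.
#' @slot mitoGeneCount integer, number of genes named \code{MT-k}.
#' @slot dispersionRange numeric length 2, log-uniform range of the
#'   negative-binomial gene dispersions.
#' @slot speciesBPerturbSD numeric >= 0, sd of the per-gene log-normal
#'   perturbation applied to species-B expression profiles.
#' @slot orthologFraction numeric in (0,1], fraction of genes with a 1:1
#'   ortholog (species B is generated over exactly these genes).
#' @slot nCellsSpeciesB integer, species-B cells.
#' @slot nExtraTypesB integer, species-B-only types absent from species A.
#' @slot batchShiftSD numeric >= 0, sd of a per-gene log-normal shift applied
#'   to the second chemistry batch (0 = no batch effect).
#' @slot nDonors integer, donors used for round-robin assignment.
#' @slot libSizeMeanLog,libSizeSDLog numeric, log-normal library-size
#'   parameters.
#' @slot seed integer, RNG seed; identical configs give identical output.
#'
#' @seealso \code{\link{simConfig}}, \code{\link{generateAtlas}}
#' @export
setClass("SimConfig", representation(
    classes = "character",
    typesPerClass = "integer",
    nCellsFovea = "integer",
    nCellsPeriphery = "integer",
    nGenes = "integer",
    baselineMean = "numeric",
    markerFold = "numeric",
    nMarkersPerType = "integer",
    nMarkersPerClass = "integer",
    regionDEGenesPerType = "integer",
    regionFold = "numeric",
    typeProportionsByRegion = "matrix",
    doubletRate = "numeric",
    doubletDepthFactor = "numeric",
    lowqRate = "numeric",
    lowqDepthFactor = "numeric",
    lowqMitoFrac = "numeric",
    mitoGeneCount = "integer",
    dispersionRange = "numeric",
    speciesBPerturbSD = "numeric",
    orthologFraction = "numeric",
    nCellsSpeciesB = "integer",
    nExtraTypesB = "integer",
    batchShiftSD = "numeric",
    nDonors = "integer",
    libSizeMeanLog = "numeric",
    libSizeSDLog = "numeric",
    seed = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (length(object@classes) != length(object@typesPerClass))
        msg <- c(msg, "classes and typesPerClass lengths differ")
    nt <- sum(object@typesPerClass)
    tp <- object@typeProportionsByRegion
    if (!identical(colnames(tp), c("fovea", "periphery")))
        msg <- c(msg, "typeProportionsByRegion columns must be fovea, periphery")
    if (nrow(tp) != nt)
        msg <- c(msg, "typeProportionsByRegion must have one row per type")
    if (any(abs(colSums(tp) - 1) > 1e-9))
        msg <- c(msg, "type proportions must sum to 1 per region")
    if (any(tp < 0)) msg <- c(msg, "type proportions must be non-negative")
    for (r in c("doubletRate", "lowqRate", "lowqMitoFrac", "orthologFraction"))
        if (slot(object, r) < 0 || slot(object, r) > 1)
            msg <- c(msg, paste(r, "must be in [0,1]"))
    if (object@lowqDepthFactor <= 0 || object@lowqDepthFactor >= 1)
        msg <- c(msg, "lowqDepthFactor must be in (0,1)")
    if (object@doubletDepthFactor < 1)
        msg <- c(msg, "doubletDepthFactor must be >= 1")
    if (object@markerFold <= 1) msg <- c(msg, "markerFold must exceed 1")
    if (object@regionFold <= 1) msg <- c(msg, "regionFold must exceed 1")
    needed <- nt * object@nMarkersPerType +
        length(object@classes) * object@nMarkersPerClass +
        nt * object@regionDEGenesPerType +
        object@nExtraTypesB * object@nMarkersPerType +
        object@mitoGeneCount
    if (needed > object@nGenes)
        msg <- c(msg, sprintf(
            "infeasible config: %d marker/region-DE/mito genes requested but only %d genes",
            needed, object@nGenes))
    if (length(object@dispersionRange) != 2 || any(object@dispersionRange <= 0))
        msg <- c(msg, "dispersionRange must be two positive values")
    if (object@speciesBPerturbSD < 0) msg <- c(msg, "speciesBPerturbSD must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Cluster model for an atlas or a single class
#'
#' Holds the per-cell partition produced by graph clustering together with
#' per-cluster annotation: assigned class, size, and artifact flags (doublet,
#' low-quality). Flagged clusters are excluded from type-level summaries.
#'
#' @slot labels character, cluster/type label per cell, named by cell id.
#' @slot classes character, class label per cell, named by cell id.
#' @slot clusterTable data.frame with one row per cluster: \code{cluster},
#'   \code{class}, \code{n_cells}, \code{doublet}, \code{low_quality},
#'   \code{ambiguous}, \code{margin}.
#' @slot dendrogram the final \code{hclust} dendrogram over clusters (or
#'   \code{NULL} for a single cluster).
#' @slot params list of parameters used (k, resolution, seed, thresholds).
#'
#' @seealso \code{\link{buildAtlas}}, \code{\link{subclusterClass}}
#' @export
setClass("ClusterModel", representation(
    labels = "character",
    classes = "character",
    clusterTable = "data.frame",
    dendrogram = "ANY",
    params = "list"
))

setValidity("ClusterModel", function(object) {
    msg <- character()
    if (is.null(names(object@labels)))
        msg <- c(msg, "labels must be named by cell id")
    if (length(object@classes) && length(object@classes) != length(object@labels))
        msg <- c(msg, "classes and labels lengths differ")
    tab <- object@clusterTable
    need <- c("cluster", "class", "n_cells", "doublet", "low_quality")
    if (!all(need %in% colnames(tab)))
        msg <- c(msg, paste("clusterTable must contain:", paste(need, collapse = ", ")))
    else {
        if (!setequal(unique(object@labels), tab$cluster))
            msg <- c(msg, "clusterTable rows must match label values")
        if (sum(tab$n_cells) != length(object@labels))
            msg <- c(msg, "cluster sizes must sum to the number of cells")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn ClusterModel per-cell cluster/type labels (named character).
#' @param object,x a \code{ClusterModel}.
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname ClusterModel
#' @export
setMethod("clusterLabels", "ClusterModel", function(x) x@labels)

#' @describeIn ClusterModel per-cell class labels (named character).
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname ClusterModel
#' @export
setMethod("classLabels", "ClusterModel", function(x) x@classes)

#' @describeIn ClusterModel per-cluster annotation table.
#' @export
setGeneric("clusterInfo", function(x) standardGeneric("clusterInfo"))

#' @rdname ClusterModel
#' @export
setMethod("clusterInfo", "ClusterModel", function(x) x@clusterTable)

#' @describeIn ClusterModel labels of cells in unflagged (retained) clusters.
#' @export
setGeneric("retainedLabels", function(x) standardGeneric("retainedLabels"))

#' @rdname ClusterModel
#' @export
setMethod("retainedLabels", "ClusterModel", function(x) {
    tab <- x@clusterTable
    keep <- tab$cluster[!(tab$doublet | tab$low_quality)]
    x@labels[x@labels %in% keep]
})

setMethod("show", "ClusterModel", function(object) {
    tab <- object@clusterTable
    cat("ClusterModel:", length(object@labels), "cells,",
        nrow(tab), "clusters (",
        sum(tab$doublet), "doublet-flagged,",
        sum(tab$low_quality), "low-quality-flagged )\n")
    cat("classes:", paste(unique(tab$class), collapse = ", "), "\n")
    invisible(NULL)
})

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", length(object@classes), "classes /",
        sum(object@typesPerClass), "types;",
        object@nCellsFovea, "foveal +", object@nCellsPeriphery,
        "peripheral cells;", object@nGenes, "genes\n")
    cat("  markerFold", object@markerFold,
        "| doubletRate", object@doubletRate,
        "| lowqRate", object@lowqRate,
        "| seed", object@seed, "\n")
    invisible(NULL)
})
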