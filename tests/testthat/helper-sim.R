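## shared fixtures, generated once per test run and cached

.fixtures <- new.env(parent = emptyenv())

.cached <- function(key, expr) {
    if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
    get(key, envir = .fixtures)
}

## small three-class atlas used by most unit tests (median ~320 genes/cell,
## so cell filtering in tests uses minGenes = 200)
smallSimConfig <- function(seed = 42, ...) {
    args <- list(classes = c("PR", "HC", "BC"), typesPerClass = c(2, 2, 1),
                 nCellsFovea = 500, nCellsPeriphery = 500, nGenes = 500,
                 nMarkersPerType = 10, nMarkersPerClass = 8,
                 regionDEGenesPerType = 6, mitoGeneCount = 5,
                 nCellsSpeciesB = 400, libSizeMeanLog = log(1200),
                 seed = seed)
    args[names(list(...))] <- list(...)
    do.call(simConfig, args)
}

smallSim <- function() .cached("smallSim", generateAtlas(smallSimConfig()))

smallAtlasParams <- function() atlasConfig(minGenes = 200, k = 15)

## full-size atlas at the default study conditions
defaultSim <- function(seed = 7)
    .cached(paste0("defaultSim", seed), generateAtlas(simConfig(seed = seed)))

defaultModel <- function(seed = 7)
    .cached(paste0("defaultModel", seed),
            buildAtlas(defaultSim(seed)$sce, defaultSim(seed)$panel))

## two types, ~200 cells per type and region, 12 planted region-DE genes at
## fold e^1.5 (the regional-recovery experiment's conditions)
pairSim <- function(regionDEGenes = 12, seed = 5)
    .cached(paste0("pairSim", regionDEGenes, "_", seed),
            generateAtlas(simConfig(
                classes = c("A", "B"), typesPerClass = c(1, 1),
                nCellsFovea = 400, nCellsPeriphery = 400, nGenes = 800,
                nMarkersPerType = 10, nMarkersPerClass = 8,
                regionDEGenesPerType = regionDEGenes,
                regionFold = exp(1.5), mitoGeneCount = 5,
                nCellsSpeciesB = 50, doubletRate = 0, lowqRate = 0,
                seed = seed)))

logcountsOf <- function(sce)
    as.matrix(SummarizedExperiment::assay(normalizeLog(sce), "logcounts"))

countsOf <- function(sce)
    as.matrix(SummarizedExperiment::assay(sce, "counts"))

singletCells <- function(truth)
    truth$cell_id[!truth$is_doublet & !truth$is_low_quality]

## adjusted Rand index oracle (mclust)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
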