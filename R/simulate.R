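#' Construct a simulation configuration
#'
#' Builds a validated \linkS4class{SimConfig}. Defaults describe a pooled
#' fovea/periphery retina: 6 classes (photoreceptor, horizontal, bipolar,
#' amacrine, ganglion, non-neuronal) subdivided into 20 types, 8,000 cells
#' split evenly between regions, 2,000 genes, 8-fold planted class/type
#' markers, region-dependent type proportions (rod bipolar cells 3% of foveal
#' but 35% of peripheral bipolars; H1:H2 at 7.3:1 in fovea vs 1.9:1 in
#' periphery; GABAergic:glycinergic amacrines at 1.8:1 vs 1.1:1), 12 planted
#' region-DE genes per type, 5% doublets, 5% low-quality cells, and a second
#' species over 80% of genes as 1:1 orthologs. The default regional fold
#' (2.5) keeps regional differences real but weaker than type identity, so
#' foveal and peripheral cohorts of one type remain one cluster, as in the
#' emulated data; regional-recovery experiments pass a stronger
#' \code{regionFold} explicitly.
#'
#' @param classes,typesPerClass class layout.
#' @param typeProportionsByRegion optional types x c(fovea, periphery)
#'   matrix; defaults to \code{defaultTypeProportions(classes, typesPerClass)}.
#' @param nCellsFovea,nCellsPeriphery,nGenes,baselineMean,markerFold
#'   see \linkS4class{SimConfig}.
#' @param nMarkersPerType,nMarkersPerClass,regionDEGenesPerType,regionFold
#'   see \linkS4class{SimConfig}.
#' @param doubletRate,lowqRate,lowqDepthFactor,lowqMitoFrac,mitoGeneCount
#'   see \linkS4class{SimConfig}.
#' @param dispersionRange,speciesBPerturbSD,orthologFraction,nCellsSpeciesB
#'   see \linkS4class{SimConfig}.
#' @param nExtraTypesB,batchShiftSD,nDonors,libSizeMeanLog,libSizeSDLog,seed
#'   see \linkS4class{SimConfig}.
#' @return a \code{SimConfig}.
#' @export
simConfig <- function(classes = c("PR", "HC", "BC", "AC", "RGC", "NN"),
                      typesPerClass = c(3L, 2L, 6L, 5L, 2L, 2L),
                      typeProportionsByRegion = NULL,
                      nCellsFovea = 4000L, nCellsPeriphery = 4000L,
                      nGenes = 2000L, baselineMean = 1,
                      markerFold = 8, nMarkersPerType = 15L,
                      nMarkersPerClass = 10L,
                      regionDEGenesPerType = 12L, regionFold = 2.5,
                      doubletRate = 0.05, doubletDepthFactor = 1.6,
                      lowqRate = 0.05,
                      lowqDepthFactor = 0.3, lowqMitoFrac = 0.3,
                      mitoGeneCount = 10L,
                      dispersionRange = c(0.1, 1),
                      speciesBPerturbSD = 0.1, orthologFraction = 0.8,
                      nCellsSpeciesB = 4000L, nExtraTypesB = 0L,
                      batchShiftSD = 0, nDonors = 7L,
                      libSizeMeanLog = log(2500), libSizeSDLog = 0.35,
                      seed = 1L) {
    typesPerClass <- as.integer(typesPerClass)
    if (is.null(typeProportionsByRegion))
        typeProportionsByRegion <-
            defaultTypeProportions(classes, typesPerClass)
    methods::new("SimConfig",
        classes = classes, typesPerClass = typesPerClass,
        nCellsFovea = as.integer(nCellsFovea),
        nCellsPeriphery = as.integer(nCellsPeriphery),
        nGenes = as.integer(nGenes), baselineMean = baselineMean,
        markerFold = markerFold,
        nMarkersPerType = as.integer(nMarkersPerType),
        nMarkersPerClass = as.integer(nMarkersPerClass),
        regionDEGenesPerType = as.integer(regionDEGenesPerType),
        regionFold = regionFold,
        typeProportionsByRegion = typeProportionsByRegion,
        doubletRate = doubletRate,
        doubletDepthFactor = doubletDepthFactor, lowqRate = lowqRate,
        lowqDepthFactor = lowqDepthFactor, lowqMitoFrac = lowqMitoFrac,
        mitoGeneCount = as.integer(mitoGeneCount),
        dispersionRange = dispersionRange,
        speciesBPerturbSD = speciesBPerturbSD,
        orthologFraction = orthologFraction,
        nCellsSpeciesB = as.integer(nCellsSpeciesB),
        nExtraTypesB = as.integer(nExtraTypesB),
        batchShiftSD = batchShiftSD, nDonors = as.integer(nDonors),
        libSizeMeanLog = libSizeMeanLog, libSizeSDLog = libSizeSDLog,
        seed = as.integer(seed))
}

#' Default region-dependent type proportions
#'
#' For the canonical 6-class/20-type layout the table encodes the regional
#' structure the pipeline is meant to detect: rod bipolars at 3% of foveal vs
#' 35% of peripheral bipolar cells, H1:H2 horizontal ratio 7.3:1 (fovea) vs
#' 1.9:1 (periphery), GABAergic:glycinergic amacrine ratio 1.8:1 vs 1.1:1
#' (first three amacrine types GABAergic, last two glycinergic), S-cone
#' scarcity in the fovea, and astrocyte depletion from the fovea. For any
#' other layout, types are uniform within classes and classes equal.
#'
#' @param classes,typesPerClass class layout.
#' @return matrix (types x c("fovea", "periphery")); columns sum to 1.
#' @export
defaultTypeProportions <- function(classes, typesPerClass) {
    nt <- sum(typesPerClass)
    types <- unlist(mapply(function(cl, k) paste0(cl, seq_len(k)),
                           classes, typesPerClass, SIMPLIFY = FALSE))
    canonical <- identical(classes, c("PR", "HC", "BC", "AC", "RGC", "NN")) &&
        identical(as.integer(typesPerClass), c(3L, 2L, 6L, 5L, 2L, 2L))
    if (!canonical) {
        w <- unlist(lapply(typesPerClass,
                           function(k) rep(1 / (length(classes) * k), k)))
        m <- cbind(fovea = w, periphery = w)
        rownames(m) <- types
        return(m)
    }
    classShare <- c(PR = 0.20, HC = 0.08, BC = 0.25, AC = 0.20,
                    RGC = 0.15, NN = 0.12)
    within <- list(
        fovea = list(
            PR = c(0.60, 0.03, 0.37),
            HC = c(7.3, 1) / 8.3,
            BC = c(0.03, rep(0.97 / 5, 5)),
            AC = c(rep(1.8 / 3, 3), rep(1 / 2, 2)) / 2.8,
            RGC = c(0.5, 0.5),
            NN = c(0.99, 0.01)),
        periphery = list(
            PR = c(0.70, 0.08, 0.22),
            HC = c(1.9, 1) / 2.9,
            BC = c(0.35, rep(0.65 / 5, 5)),
            AC = c(rep(1.1 / 3, 3), rep(1 / 2, 2)) / 2.1,
            RGC = c(0.45, 0.55),
            NN = c(0.88, 0.12)))
    m <- sapply(c("fovea", "periphery"), function(r)
        unlist(lapply(classes, function(cl)
            classShare[cl] * within[[r]][[cl]])))
    rownames(m) <- types
    m
}

## binomial thinning of a count vector to (approximately) a target total;
## with target >= sum(x) the vector is returned unchanged.
#' Depth-rescale a count vector by binomial thinning
#'
#' Each UMI is kept independently with probability \code{target/sum(x)},
#' giving an expected total of \code{target}. Used by the generator to
#' rescale doublets to a typical library size and to create depth-thinned
#' low-quality cells.
#'
#' @param x non-negative integer vector.
#' @param target desired total count.
#' @return integer vector of the same length.
#' @export
thinCounts <- function(x, target) {
    tot <- sum(x)
    if (target >= tot || tot == 0) return(x)
    rbinom(length(x), x, target / tot)
}

#' Synthesize a doublet from two parent count vectors
#'
#' A doublet is the element-wise sum of two singlet transcriptomes,
#' depth-rescaled to a typical library size. With \code{target} at least the
#' summed depth, the result is exactly the parent sum.
#'
#' @param c1,c2 parent count vectors.
#' @param target library size to rescale to.
#' @return integer count vector.
#' @export
makeDoublet <- function(c1, c2, target) thinCounts(c1 + c2, target)

.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else on.exit(rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    force(expr)
}

#' Generate a synthetic two-species retina atlas with ground truth
#'
#' Draws UMI counts from a negative-binomial model with log-normal library
#' sizes around per-type mean expression profiles. Type and class markers are
#' up-regulated \code{markerFold}-fold in their own type/class; designated
#' region-DE genes are up-regulated \code{regionFold}-fold in one region.
#' Doublets are element-wise sums of two singlets of different types,
#' depth-rescaled to a typical library size; low-quality cells are
#' depth-thinned singlets with mitochondrial counts inflated to
#' \code{lowqMitoFrac} of the library. A second species is generated from the
#' same type profiles (plus \code{nExtraTypesB} species-B-only types) over
#' the 1:1-ortholog gene subset, with a per-gene log-normal perturbation of
#' the profiles. All randomness derives from \code{config@seed}.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a list with elements
#'   \describe{
#'     \item{sce}{species-A \code{SingleCellExperiment} (counts + metadata)}
#'     \item{truth}{per-cell truth: \code{cell_id, true_type, true_class,
#'       region, donor, is_doublet, is_low_quality, species, doublet_type1,
#'       doublet_type2, parent1, parent2}}
#'     \item{panel}{marker panel: named list class -> class marker genes}
#'     \item{orthologs}{1:1 ortholog table (\code{species_a, species_b})}
#'     \item{sceB, truthB}{species-B experiment and truth}
#'     \item{typeMarkers}{data.frame (type, gene) of planted type markers}
#'     \item{regionDE}{data.frame (type, gene, up_region) of planted
#'       region-DE genes}
#'     \item{classOfType}{named character, class of every type}
#'     \item{geneInfo}{data.frame (gene, baseline, role)}
#'     \item{totalCount}{total UMI count of the species-A matrix}
#'   }
#' @export
generateAtlas <- function(config) {
    methods::validObject(config)
    .withSeed(config@seed, .generateAtlas(config))
}

.generateAtlas <- function(cfg) {
    nG <- cfg@nGenes
    nMito <- cfg@mitoGeneCount
    nGm <- nG - nMito
    genes <- c(sprintf("G%04d", seq_len(nGm)), paste0("MT-", seq_len(nMito)))
    mitoIdx <- nGm + seq_len(nMito)

    classes <- cfg@classes
    nt <- sum(cfg@typesPerClass)
    types <- rownames(cfg@typeProportionsByRegion)
    classOfType <- setNames(rep(classes, cfg@typesPerClass), types)

    ## per-gene baseline; mitochondrial genes scaled to ~5% of expression
    b <- rgamma(nG, shape = 2, rate = 2 / cfg@baselineMean)
    b[b < 1e-3] <- 1e-3
    b[mitoIdx] <- b[mitoIdx] *
        (0.05 / 0.95) * sum(b[-mitoIdx]) / sum(b[mitoIdx])

    ## assign gene roles from a shuffled pool of non-mito genes
    pool <- sample(nGm)
    take <- function(n) {
        if (n == 0) return(integer())
        out <- pool[seq_len(n)]
        pool <<- pool[-seq_len(n)]
        out
    }
    classMarkers <- lapply(classes, function(cl) take(cfg@nMarkersPerClass))
    names(classMarkers) <- classes
    typeMarkers <- lapply(types, function(tp) take(cfg@nMarkersPerType))
    names(typeMarkers) <- types
    extraTypes <- if (cfg@nExtraTypesB > 0)
        paste0("X", seq_len(cfg@nExtraTypesB)) else character()
    extraMarkers <- lapply(extraTypes, function(tp) take(cfg@nMarkersPerType))
    names(extraMarkers) <- extraTypes
    ## region-DE effects are planted on expressed genes (upper half of the
    ## remaining baselines): a regional fold on a barely-detected gene is not
    ## a measurable regional difference
    bMed <- median(b[pool])
    pool <- c(pool[b[pool] >= bMed], pool[b[pool] < bMed])
    regionDEIdx <- lapply(types, function(tp) take(cfg@regionDEGenesPerType))
    names(regionDEIdx) <- types

    role <- rep("baseline", nG)
    role[mitoIdx] <- "mito"
    for (cl in classes) role[classMarkers[[cl]]] <- paste0("classMarker:", cl)
    for (tp in types) role[typeMarkers[[tp]]] <- paste0("typeMarker:", tp)
    for (tp in types) role[regionDEIdx[[tp]]] <- paste0("regionDE:", tp)

    ## expression profiles
    classProf <- lapply(classes, function(cl) {
        p <- b * exp(rnorm(nG, 0, 0.25))
        p[classMarkers[[cl]]] <- p[classMarkers[[cl]]] * cfg@markerFold
        p
    })
    names(classProf) <- classes
    typeProf <- lapply(types, function(tp) {
        p <- classProf[[classOfType[tp]]]
        p[typeMarkers[[tp]]] <- p[typeMarkers[[tp]]] * cfg@markerFold
        p
    })
    names(typeProf) <- types

    regionDE <- do.call(rbind, lapply(types, function(tp) {
        idx <- regionDEIdx[[tp]]
        if (!length(idx)) return(NULL)
        data.frame(type = tp, gene = genes[idx],
                   up_region = ifelse(seq_along(idx) %% 2 == 1,
                                      "fovea", "periphery"),
                   stringsAsFactors = FALSE)
    }))
    if (is.null(regionDE))
        regionDE <- data.frame(type = character(), gene = character(),
                               up_region = character(),
                               stringsAsFactors = FALSE)

    regionProf <- function(tp, region) {
        p <- typeProf[[tp]]
        de <- regionDE[regionDE$type == tp & regionDE$up_region == region, ]
        p[match(de$gene, genes)] <- p[match(de$gene, genes)] * cfg@regionFold
        p / sum(p)
    }

    disp <- exp(runif(nG, log(cfg@dispersionRange[1]),
                      log(cfg@dispersionRange[2])))
    sizeG <- 1 / disp

    ## species-A cells
    nF <- cfg@nCellsFovea
    nP <- cfg@nCellsPeriphery
    n <- nF + nP
    region <- c(rep("fovea", nF), rep("periphery", nP))
    donors <- paste0("D", seq_len(cfg@nDonors))
    donor <- character(n)
    if (cfg@nDonors >= 3) {
        donor[region == "fovea"] <-
            rep_len(donors[seq_len(cfg@nDonors - 1)], nF)
        donor[region == "periphery"] <-
            rep_len(donors[c(cfg@nDonors - 1, cfg@nDonors)], nP)
    } else donor <- rep_len(donors, n)
    batch <- rep_len(c("v2", "v3"), n)
    enrichment <- ifelse(region == "fovea", "none",
                         rep_len(c("CD73_depleted", "CD90_enriched"), n))
    cellType <- character(n)
    for (r in c("fovea", "periphery")) {
        idx <- which(region == r)
        cellType[idx] <- sample(types, length(idx), replace = TRUE,
                                prob = cfg@typeProportionsByRegion[, r])
    }
    libSize <- rlnorm(n, cfg@libSizeMeanLog, cfg@libSizeSDLog)
    batchFac <- if (cfg@batchShiftSD > 0)
        exp(rnorm(nG, 0, cfg@batchShiftSD)) else NULL

    counts <- matrix(0L, nG, n)
    for (tp in types) for (r in c("fovea", "periphery")) {
        idx <- which(cellType == tp & region == r)
        if (!length(idx)) next
        p <- regionProf(tp, r)
        mu <- p %o% libSize[idx]
        if (!is.null(batchFac)) {
            v3 <- batch[idx] == "v3"
            if (any(v3)) mu[, v3] <- mu[, v3] * batchFac
        }
        counts[, idx] <- rnbinom(length(mu), mu = mu,
                                 size = rep(sizeG, length(idx)))
    }

    ## artifacts: doublets then low-quality cells
    isDoublet <- runif(n) < cfg@doubletRate
    isLowq <- !isDoublet & runif(n) < cfg@lowqRate
    singlet <- which(!isDoublet & !isLowq)
    dType1 <- dType2 <- parent1 <- parent2 <- rep(NA_character_, n)
    for (j in which(isDoublet)) {
        cand <- singlet[region[singlet] == region[j]]
        p1 <- sample(cand, 1)
        cand2 <- cand[cellType[cand] != cellType[p1]]
        p2 <- sample(cand2, 1)
        target <- round(cfg@doubletDepthFactor *
                        rlnorm(1, cfg@libSizeMeanLog, cfg@libSizeSDLog))
        counts[, j] <- makeDoublet(counts[, p1], counts[, p2], target)
        dType1[j] <- cellType[p1]; dType2[j] <- cellType[p2]
        parent1[j] <- p1; parent2[j] <- p2
    }
    mitoProb <- b[mitoIdx] / sum(b[mitoIdx])
    for (j in which(isLowq)) {
        x <- rbinom(nG, counts[, j], cfg@lowqDepthFactor)
        nonMito <- sum(x[-mitoIdx])
        mitoTot <- round(cfg@lowqMitoFrac / (1 - cfg@lowqMitoFrac) * nonMito)
        x[mitoIdx] <- as.integer(rmultinom(1, mitoTot, mitoProb))
        counts[, j] <- x
    }

    cellIds <- sprintf("cell%05d", seq_len(n))
    dimnames(counts) <- list(genes, cellIds)
    totalCount <- as.numeric(sum(counts))
    parent1[!is.na(parent1)] <- cellIds[as.integer(parent1[!is.na(parent1)])]
    parent2[!is.na(parent2)] <- cellIds[as.integer(parent2[!is.na(parent2)])]

    meta <- S4Vectors::DataFrame(
        donor = donor, region = region, enrichment = enrichment,
        batch = batch, species = "human", row.names = cellIds)
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = as(Matrix::Matrix(counts, sparse = TRUE),
                                  "CsparseMatrix")),
        colData = meta)

    truth <- data.frame(
        cell_id = cellIds,
        true_type = ifelse(isDoublet, NA_character_, cellType),
        true_class = ifelse(isDoublet, NA_character_,
                            classOfType[cellType]),
        region = region, donor = donor,
        is_doublet = isDoublet, is_low_quality = isLowq,
        species = "human",
        doublet_type1 = dType1, doublet_type2 = dType2,
        parent1 = parent1, parent2 = parent2,
        stringsAsFactors = FALSE)

    panel <- lapply(classMarkers, function(i) genes[i])

    ## species B over the 1:1-ortholog gene subset
    nOrtho <- floor(cfg@orthologFraction * nG)
    orthoIdx <- sort(sample(nG, nOrtho))
    orthologs <- data.frame(species_a = genes[orthoIdx],
                            species_b = paste0("m", genes[orthoIdx]),
                            stringsAsFactors = FALSE)
    typesB <- c(types, extraTypes)
    classOfTypeB <- c(classOfType,
                      setNames(rep_len(classes, length(extraTypes)),
                               extraTypes))
    perturb <- exp(rnorm(nOrtho, 0, cfg@speciesBPerturbSD))
    profB <- lapply(typesB, function(tp) {
        p <- if (tp %in% types) typeProf[[tp]]
        else {
            q <- classProf[[classOfTypeB[tp]]]
            q[extraMarkers[[tp]]] <- q[extraMarkers[[tp]]] * cfg@markerFold
            q
        }
        p <- p[orthoIdx] * perturb
        p / sum(p)
    })
    names(profB) <- typesB

    nB <- cfg@nCellsSpeciesB
    typeB <- sample(typesB, nB, replace = TRUE)
    libB <- rlnorm(nB, cfg@libSizeMeanLog, cfg@libSizeSDLog)
    countsB <- matrix(0L, nOrtho, nB)
    sizeB <- sizeG[orthoIdx]
    for (tp in typesB) {
        idx <- which(typeB == tp)
        if (!length(idx)) next
        mu <- profB[[tp]] %o% libB[idx]
        countsB[, idx] <- rnbinom(length(mu), mu = mu,
                                  size = rep(sizeB, length(idx)))
    }
    cellIdsB <- sprintf("mcell%05d", seq_len(nB))
    dimnames(countsB) <- list(orthologs$species_b, cellIdsB)
    regionB <- rep_len(c("fovea", "periphery"), nB)
    donorB <- rep_len(paste0("M", 1:4), nB)
    metaB <- S4Vectors::DataFrame(
        donor = donorB, region = regionB, enrichment = "none",
        batch = "bx", species = "macaque", row.names = cellIdsB)
    sceB <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = as(Matrix::Matrix(countsB, sparse = TRUE),
                                  "CsparseMatrix")),
        colData = metaB)
    truthB <- data.frame(
        cell_id = cellIdsB, true_type = typeB,
        true_class = classOfTypeB[typeB], region = regionB,
        donor = donorB, is_doublet = FALSE, is_low_quality = FALSE,
        species = "macaque", stringsAsFactors = FALSE)

    geneInfo <- data.frame(gene = genes, baseline = b, role = role,
                           stringsAsFactors = FALSE)
    typeMarkersDf <- do.call(rbind, lapply(types, function(tp)
        data.frame(type = tp, gene = genes[typeMarkers[[tp]]],
                   stringsAsFactors = FALSE)))

    list(sce = sce, truth = truth, panel = panel, orthologs = orthologs,
         sceB = sceB, truthB = truthB, typeMarkers = typeMarkersDf,
         regionDE = regionDE, classOfType = classOfType,
         geneInfo = geneInfo, totalCount = totalCount, config = cfg)
}

#' Spike a disease-gene panel with known screen outcomes
#'
#' Returns a gene list mixing (a) robustly class-enriched genes, drawn from
#' the planted class markers with the strongest baselines (expected to pass a
#' detection >20% / mean >0.5 screen in their class), and (b) broadly
#' low-expressed genes drawn from the weakest unassigned baselines (expected
#' to fail). The \code{robust} column carries the truth labels.
#'
#' @param sim output of \code{\link{generateAtlas}}.
#' @param classes classes whose markers provide robust genes; defaults to
#'   all.
#' @param nRobust,nFailing panel sizes.
#' @param groups disease group names cycled over the panel.
#' @return data.frame (gene, group, robust, override).
#' @export
spikeDiseasePanel <- function(sim, classes = NULL, nRobust = 10L,
                              nFailing = 10L,
                              groups = c("RP", "CRD", "LCA", "POAG")) {
    cfg <- sim$config
    if (is.null(classes)) classes <- cfg@classes
    if (!all(classes %in% cfg@classes))
        stop("unknown class(es): ",
             paste(setdiff(classes, cfg@classes), collapse = ", "))
    gi <- sim$geneInfo
    cand <- gi[gi$role %in% paste0("classMarker:", classes), ]
    cand <- cand[order(-cand$baseline), ]
    if (nrow(cand) < nRobust)
        stop("not enough class markers for the requested robust panel")
    robust <- cand$gene[seq_len(nRobust)]
    low <- gi[gi$role == "baseline", ]
    low <- low[order(low$baseline), ]
    failing <- low$gene[seq_len(nFailing)]
    out <- data.frame(
        gene = c(robust, failing),
        group = rep_len(groups, nRobust + nFailing),
        robust = rep(c(TRUE, FALSE), c(nRobust, nFailing)),
        override = FALSE, stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}
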