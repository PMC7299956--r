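test_that("per-cell QC metrics are exact arithmetic", {
    m <- cbind(zero = c(0, 0, 0), mixed = c(3, 0, 1))
    rownames(m) <- c("GENE1", "GENE2", "MT-1")
    qc <- perCellQC(m)
    expect_equal(unlist(qc["zero", ]), c(n_genes = 0, n_transcripts = 0,
                                         mito_fraction = 0))
    expect_equal(unlist(qc["mixed", ]), c(n_genes = 2, n_transcripts = 4,
                                          mito_fraction = 0.25))
})

test_that("cell filter is inclusive at the threshold and idempotent", {
    set.seed(1)
    m <- matrix(0L, 10, 3, dimnames = list(paste0("g", 1:10), c("a", "b", "c")))
    m[1:5, 1] <- 1L   # exactly 5 detected
    m[1:4, 2] <- 1L   # 4 detected
    m[1:6, 3] <- 1L   # 6 detected
    f <- filterCells(m, minGenes = 5)
    expect_identical(colnames(f), c("a", "c"))
    expect_identical(filterCells(f, minGenes = 5), f)
    expect_error(filterCells(m, minGenes = 100), "all cells removed")
})

test_that("filter removes exactly the planted low-coverage cells", {
    set.seed(2)
    m <- matrix(rpois(200 * 100, 2), 200, 100)
    low <- sample(100, 50)
    m[, low] <- 0L
    m[1:3, low] <- 1L  # 3 detected genes
    dimnames(m) <- list(paste0("g", 1:200), paste0("c", 1:100))
    expect_identical(ncol(filterCells(m, minGenes = 10)), 50L)
})

test_that("log normalization matches an independent oracle", {
    m <- matrix(c(0, 3, 7, 2, 0, 5), 3, 2,
                dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
    E <- normalizeLog(m)
    tot <- colSums(m); s <- median(tot)
    oracle <- log(1 + m %*% diag(s / tot))
    dimnames(oracle) <- dimnames(m)
    expect_equal(E, oracle, tolerance = 1e-12, ignore_attr = "scaleFactor")
    expect_identical(attr(E, "scaleFactor"), s)
    ## zeros map to zero and values are monotone within a cell
    expect_identical(E[1, 1], 0)
    expect_true(all(diff(E[order(m[, 1]), 1]) >= 0))
    ## single cell: scale cancels, E = ln(1 + c)
    one <- m[, 1, drop = FALSE]
    expect_equal(normalizeLog(one)[, 1], log(1 + m[, 1]),
                 ignore_attr = TRUE)
    bad <- m; bad[, 1] <- 0
    expect_error(normalizeLog(bad), "zero-total")
})

test_that("normalizeLog on a SingleCellExperiment records the scale factor", {
    sim <- smallSim()
    sce <- normalizeLog(sim$sce)
    expect_true("logcounts" %in% SummarizedExperiment::assayNames(sce))
    expect_identical(S4Vectors::metadata(sce)$scaleFactor,
                     median(Matrix::colSums(countsOf(sce))))
})

test_that("HVG selection favors overdispersed genes deterministically", {
    set.seed(3)
    n <- 200
    flat <- rep(5L, n)                       # zero dispersion
    noisy <- rnbinom(n, mu = 5, size = 0.3)  # strongly overdispersed
    filler <- matrix(rpois(198 * n, 5), 198, n)
    m <- rbind(flat, noisy, filler)
    rownames(m) <- c("flat", "noisy", paste0("f", 1:198))
    colnames(m) <- paste0("c", 1:n)
    top <- selectHVGs(m, 10)
    expect_true("noisy" %in% top)
    expect_false("flat" %in% top)
    ## invariance to cell order
    perm <- sample(n)
    expect_identical(selectHVGs(m[, perm], 10), top)
    expect_error(selectHVGs(m[, 1, drop = FALSE], 5), "at least 2 cells")
})

test_that("planted markers dominate the selected HVG set", {
    sim <- defaultSim()
    markers <- unique(c(sim$typeMarkers$gene, unlist(sim$panel)))
    top <- selectHVGs(sim$sce, 200)
    enrichment <- mean(top %in% markers) /
        (length(markers) / nrow(sim$sce))
    expect_gte(enrichment, 5)
})

test_that("batch regression removes pure batch offsets exactly", {
    set.seed(4)
    E <- matrix(rnorm(50 * 60), 50, 60,
                dimnames = list(paste0("g", 1:50), paste0("c", 1:60)))
    batch <- rep(c("A", "B"), each = 30)
    expect_identical(regressBatch(E, rep("A", 60)), E)
    shifted <- E; shifted[1, batch == "A"] <- shifted[1, batch == "A"] + 2
    corrected <- regressBatch(shifted, batch)
    expect_lt(abs(mean(corrected[1, batch == "A"]) -
                  mean(corrected[1, batch == "B"])), 1e-9)
    expect_error(regressBatch(E, factor(batch, levels = c("A", "B", "C"))),
                 "0 cells")
})

test_that("batch regression reduces batch structure in PC space", {
    sim <- generateAtlas(simConfig(
        classes = c("PR", "HC", "BC"), typesPerClass = c(2, 2, 1),
        nCellsFovea = 400, nCellsPeriphery = 400, nGenes = 500,
        nMarkersPerType = 10, nMarkersPerClass = 8,
        regionDEGenesPerType = 6, mitoGeneCount = 5, nCellsSpeciesB = 50,
        libSizeMeanLog = log(1200), batchShiftSD = 0.3,
        doubletRate = 0, lowqRate = 0, seed = 9))
    E <- logcountsOf(sim$sce)
    hv <- selectHVGs(sim$sce, 100)
    batch <- SummarizedExperiment::colData(sim$sce)$batch
    silh <- function(M) {
        emb <- pcaRMT(M, 20)
        mean(cluster::silhouette(as.integer(factor(batch)),
                                 dist(emb$scores))[, 3])
    }
    expect_lt(silh(regressBatch(E[hv, ], batch)), silh(E[hv, ]))
})

test_that("RMT selection finds no structure in pure noise", {
    nsig <- vapply(1:5, function(s) {
        set.seed(s)
        X <- matrix(rnorm(100 * 500), 100, 500)
        pcaRMT(X)$nSig
    }, integer(1))
    expect_true(all(nsig == 0))
})

test_that("RMT selection recovers a planted rank-5 signal", {
    set.seed(6)
    p <- 200; n <- 1000; k <- 5
    X <- 0.6 * matrix(rnorm(p * k), p, k) %*% matrix(rnorm(k * n), k, n) +
        matrix(rnorm(p * n), p, n)
    emb <- pcaRMT(X, nMax = 50)
    expect_identical(emb$nSig, 5L)
    expect_identical(ncol(emb$scores), 5L)
})

test_that("RMT eigenvalues conserve the standardized variance", {
    set.seed(7)
    X <- matrix(rnorm(100 * 300), 100, 300)
    emb <- pcaRMT(X)
    expect_equal(sum(emb$eigenvalues), emb$nGenes, tolerance = 1e-6)
    expect_true(all(diff(emb$eigenvalues) <= 1e-12))
    expect_error(pcaRMT(X[, 1:2]), "at least 3 cells")
})

test_that("duplicating every cell leaves the leading eigenvector span intact", {
    set.seed(8)
    p <- 50; n <- 200
    X <- matrix(rnorm(p * 2), p, 2) %*% matrix(rnorm(2 * n), 2, n) +
        0.5 * matrix(rnorm(p * n), p, n)
    e1 <- pcaRMT(X)
    e2 <- pcaRMT(cbind(X, X))
    expect_identical(e1$nSig, e2$nSig)
    k <- min(ncol(e1$loadings), ncol(e2$loadings))
    ## principal angles between the two loading subspaces
    sv <- svd(crossprod(e1$loadings[, 1:k], e2$loadings[, 1:k]))$d
    expect_true(all(acos(pmin(sv, 1)) < 1e-6))
})
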