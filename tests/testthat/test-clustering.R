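test_that("Jaccard graph weights match a brute-force oracle", {
    set.seed(20)
    pts <- rbind(matrix(rnorm(10, 0, 0.3), 5, 2),
                 matrix(rnorm(10, 5, 0.3), 5, 2))
    rownames(pts) <- paste0("p", 1:10)
    k <- 3
    g <- buildJaccardGraph(pts, k = k)
    ## oracle: neighbor sets by exhaustive distances, Jaccard by set ops
    D <- as.matrix(dist(pts)); diag(D) <- Inf
    nset <- lapply(1:10, function(i) order(D[i, ])[1:k])
    for (e in seq_len(igraph::ecount(g))) {
        ij <- igraph::ends(g, e)
        i <- match(ij[1], rownames(pts)); j <- match(ij[2], rownames(pts))
        inter <- length(intersect(nset[[i]], nset[[j]]))
        expect_gt(inter, 0)
        expect_equal(igraph::E(g)$weight[e], inter / (2 * k - inter))
    }
    ## no edges cross the blobs: disjoint neighbor sets are dropped
    memb <- rep(1:2, each = 5)
    ends <- igraph::ends(g, igraph::E(g))
    expect_true(all(memb[match(ends[, 1], rownames(pts))] ==
                    memb[match(ends[, 2], rownames(pts))]))
    expect_error(buildJaccardGraph(pts, k = 0), "positive")
    expect_error(buildJaccardGraph(pts, k = 10), "smaller")
})

test_that("Louvain separates disconnected communities deterministically", {
    ## two disconnected cliques: the modularity optimum is 2 communities
    g <- igraph::disjoint_union(igraph::make_full_graph(8),
                                igraph::make_full_graph(8))
    igraph::V(g)$name <- paste0("v", 1:16)
    igraph::E(g)$weight <- 1
    lab1 <- louvainCluster(g, seed = 1)
    lab2 <- louvainCluster(g, seed = 1)
    expect_identical(lab1, lab2)
    expect_identical(length(unique(lab1)), 2L)
    expect_identical(length(unique(lab1[1:8])), 1L)
    ## no Jaccard edges cross well-separated blobs, so neither do communities
    set.seed(21)
    pts <- rbind(matrix(rnorm(40, 0, 0.3), 20, 2),
                 matrix(rnorm(40, 8, 0.3), 20, 2))
    rownames(pts) <- paste0("p", 1:40)
    labB <- louvainCluster(buildJaccardGraph(pts, k = 5), seed = 1)
    expect_identical(length(intersect(unique(labB[1:20]),
                                      unique(labB[21:40]))), 0L)
    expect_error(louvainCluster(igraph::make_empty_graph(0)), "empty")
})

test_that("clusters are assigned to classes by marker score", {
    panel <- list(A = c("a1", "a2"), B = c("b1", "b2"))
    E <- matrix(0.1, 5, 30,
                dimnames = list(c("a1", "a2", "b1", "b2", "x"),
                                paste0("c", 1:30)))
    lab <- rep(1:3, each = 10)
    E[c("a1", "a2"), lab == 1] <- 3     # cluster 1: class A
    E[c("b1", "b2"), lab == 2] <- 3     # cluster 2: class B
    E[c("a1", "b1"), lab == 3] <- 3     # cluster 3: symmetric tie
    ca <- assignClasses(lab, E, panel)
    expect_identical(ca$class[ca$cluster == 1], "A")
    expect_gt(ca$margin[ca$cluster == 1], 0)
    expect_identical(ca$class[ca$cluster == 2], "B")
    expect_identical(ca$class[ca$cluster == 3], "A")  # alphabetical tie-break
    expect_true(ca$ambiguous[ca$cluster == 3])
    expect_warning(
        assignClasses(lab, E, list(A = c("a1", "missing"), B = "b1")),
        "absent")
    suppressWarnings(
        expect_error(assignClasses(lab, E, list(A = "a1", Z = "zz")),
                     "no surviving markers"))
})

test_that("doublet clusters are flagged; real types and parents are not", {
    sim <- generateAtlas(simConfig(seed = 7, doubletRate = 0, lowqRate = 0,
                                   nCellsFovea = 1000,
                                   nCellsPeriphery = 1000,
                                   nCellsSpeciesB = 50))
    truth <- sim$truth
    cnt <- countsOf(sim$sce)
    set.seed(22)
    s1 <- truth$cell_id[truth$true_type == "PR1"][1:50]
    s2 <- truth$cell_id[truth$true_type == "AC1"][1:50]
    dbl <- sapply(seq_len(50), function(i)
        makeDoublet(cnt[, s1[i]], cnt[, s2[i]],
                    round(1.6 * rlnorm(1, log(2500), 0.35))))
    colnames(dbl) <- paste0("dbl", 1:50)
    m <- cbind(cnt, dbl)
    E <- normalizeLog(m)
    qc <- perCellQC(m)
    lab <- c(truth$true_type, rep("DBL", 50))
    fl <- flagArtifactClusters(lab, NULL, qc, E, sim$panel,
                               withinClass = FALSE)
    expect_true(fl$doublet[fl$cluster == "DBL"])
    expect_gte(fl$n_classes_high[fl$cluster == "DBL"], 2)
    expect_identical(fl$n_unique_markers[fl$cluster == "DBL"], 0L)
    expect_false(any(fl$doublet[fl$cluster != "DBL"]))
    expect_false(any(fl$low_quality))
})

test_that("depth-thinned high-mito clusters are flagged low-quality", {
    sim <- smallSim()
    truth <- sim$truth
    cnt <- countsOf(sim$sce)[, singletCells(sim$truth)]
    tr <- truth[match(colnames(cnt), truth$cell_id), ]
    set.seed(23)
    nG <- nrow(cnt); mito <- startsWith(rownames(cnt), "MT-")
    lq <- sapply(1:40, function(i) {
        x <- rbinom(nG, cnt[, i], 0.3)
        nm <- sum(x[!mito])
        x[mito] <- as.integer(rmultinom(1, round(0.3 / 0.7 * nm),
                                        rep(1, sum(mito))))
        x
    })
    rownames(lq) <- rownames(cnt); colnames(lq) <- paste0("lq", 1:40)
    m <- cbind(cnt, lq)
    E <- normalizeLog(m); qc <- perCellQC(m)
    lab <- c(tr$true_type, rep("LQ", 40))
    fl <- flagArtifactClusters(lab, NULL, qc, E, sim$panel,
                               withinClass = FALSE)
    expect_true(fl$low_quality[fl$cluster == "LQ"])
    expect_false(any(fl$low_quality[fl$cluster != "LQ"]))
})

test_that("merge rule collapses oversplits and respects real differences", {
    sim <- smallSim()
    truth <- sim$truth
    E <- logcountsOf(sim$sce)
    hv <- selectHVGs(sim$sce, 100)
    pr <- truth$cell_id[!truth$is_doublet & !truth$is_low_quality &
                        !is.na(truth$true_type) &
                        truth$true_type %in% c("PR1", "PR2")]
    lab <- setNames(truth$true_type[match(pr, truth$cell_id)], pr)
    En <- E[, pr]
    ## force one type into two clusters: they must merge back
    set.seed(24)
    split <- lab
    split[names(split)[split == "PR1"][
        runif(sum(split == "PR1")) < 0.5]] <- "PR1b"
    m1 <- mergeClusters(split, En, hv)
    expect_identical(length(unique(m1$labels)), 2L)
    expect_gte(m1$nMerges, 1L)
    ## two types with >= 30 planted marker differences never merge
    m2 <- mergeClusters(lab, En, hv)
    expect_identical(length(unique(m2$labels)), 2L)
    expect_identical(m2$nMerges, 0L)
    ## fixed point: rerunning on merged output changes nothing
    m3 <- mergeClusters(m1$labels, En, hv)
    expect_identical(m3$nMerges, 0L)
    expect_identical(m3$labels, m1$labels)
    ## partition property
    expect_identical(sum(table(m1$labels)), length(pr))
})

test_that("subclustering a class recovers its planted types", {
    sim <- smallSim()
    sceN <- normalizeLog(sim$sce)
    truth <- sim$truth
    params <- smallAtlasParams()
    for (cl in c("PR", "HC")) {   # two planted types each
        cells <- which(!is.na(truth$true_class) & truth$true_class == cl &
                       !truth$is_doublet & !truth$is_low_quality)
        mod <- subclusterClass(sceN, cells, params = params)
        tab <- clusterInfo(mod)
        keep <- tab$cluster[!(tab$doublet | tab$low_quality)]
        expect_identical(length(keep), 2L)
        expect_equal(ari(clusterLabels(mod),
                         truth$true_type[cells]), 1)
    }
    ## single-type class collapses to one cluster
    bc <- which(!is.na(truth$true_class) & truth$true_class == "BC" &
                !truth$is_doublet & !truth$is_low_quality)
    modBC <- subclusterClass(sceN, bc, params = params)
    expect_identical(nrow(clusterInfo(modBC)), 1L)
})

test_that("cell order does not change the recovered partition", {
    sim <- smallSim()
    sceN <- normalizeLog(sim$sce)
    truth <- sim$truth
    cells <- which(!is.na(truth$true_class) & truth$true_class == "PR" &
                   !truth$is_doublet & !truth$is_low_quality)
    params <- smallAtlasParams()
    m1 <- subclusterClass(sceN, cells, params = params)
    set.seed(25)
    m2 <- subclusterClass(sceN, sample(cells), params = params)
    shared <- intersect(names(clusterLabels(m1)), names(clusterLabels(m2)))
    expect_equal(ari(clusterLabels(m1)[shared],
                     clusterLabels(m2)[shared]), 1)
})
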