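test_that("the classifier separates well-separated reference types", {
    sim <- smallSim()
    EB <- logcountsOf(sim$sceB)
    pr <- sim$truthB$true_class == "PR"
    clf <- trainTypeClassifier(EB[, pr], sim$truthB$true_type[pr],
                               ortho = sim$orthologs, seed = 1)
    expect_gte(clf$heldOutAccuracy, 0.95)
    ## self-map (same-species feature space): per-type majority label
    ## equals own type
    clfSelf <- trainTypeClassifier(EB[, pr], sim$truthB$true_type[pr],
                                   seed = 1)
    pred <- mapCells(clfSelf, EB[, pr])
    for (tp in unique(sim$truthB$true_type[pr])) {
        maj <- names(which.max(table(pred[sim$truthB$true_type[pr] == tp])))
        expect_identical(maj, tp)
    }
})

test_that("shuffled labels give chance-level held-out accuracy", {
    sim <- smallSim()
    EB <- logcountsOf(sim$sceB)
    y <- sim$truthB$true_type
    set.seed(26)
    yShuf <- sample(y)
    clf <- trainTypeClassifier(EB, yShuf, ortho = sim$orthologs, seed = 1)
    k <- length(unique(y))
    nTest <- round(0.2 * ncol(EB))
    expect_lt(abs(clf$heldOutAccuracy - 1 / k),
              3 * sqrt((1 / k) * (1 - 1 / k) / nTest))
})

test_that("training and mapping are deterministic for a fixed seed", {
    sim <- smallSim()
    EB <- logcountsOf(sim$sceB)
    E <- logcountsOf(sim$sce)
    hc <- sim$truthB$true_class == "HC"
    c1 <- trainTypeClassifier(EB[, hc], sim$truthB$true_type[hc],
                              ortho = sim$orthologs, seed = 5)
    c2 <- trainTypeClassifier(EB[, hc], sim$truthB$true_type[hc],
                              ortho = sim$orthologs, seed = 5)
    q <- sim$truth$cell_id[!is.na(sim$truth$true_class) &
                           sim$truth$true_class == "HC"]
    expect_identical(mapCells(c1, E[, q]), mapCells(c2, E[, q]))
    expect_identical(c1$heldOutAccuracy, c2$heldOutAccuracy)
    expect_error(mapCells(c1, E[1:10, q]), "feature mismatch")
    expect_error(trainTypeClassifier(EB[, hc],
                                     sim$truthB$true_type[hc],
                                     ortho = sim$orthologs[1:5, ]),
                 "fewer than 20")
})

test_that("cross-species mapping recovers matched types", {
    sim <- smallSim()
    EB <- logcountsOf(sim$sceB)
    E <- logcountsOf(sim$sce)
    truth <- sim$truth
    pr <- sim$truthB$true_class == "PR"
    clf <- trainTypeClassifier(EB[, pr], sim$truthB$true_type[pr],
                               ortho = sim$orthologs, seed = 1)
    qCells <- truth$cell_id[!is.na(truth$true_class) &
                            truth$true_class == "PR" &
                            !truth$is_doublet & !truth$is_low_quality]
    pred <- mapCells(clf, E[, qCells])
    conf <- confusionMatrix(truth$true_type[match(qCells, truth$cell_id)],
                            pred)
    expect_true(all(diag(conf[c("PR1", "PR2"), c("PR1", "PR2")]) >= 90))
    corr <- callCorrespondences(conf, tau = 50)
    expect_true(all(corr$matched))
    expect_identical(corr$ref, corr$query)
})

test_that("confusion matrices are column percentages", {
    conf <- confusionMatrix(rep("q1", 10), rep("r1", 10))
    expect_identical(conf["r1", "q1"], 100)
    conf2 <- confusionMatrix(rep("q1", 8), rep(c("r1", "r2", "r3", "r4"), 2))
    expect_true(all(conf2[, "q1"] == 25))
    expect_equal(colSums(conf2), c(q1 = 100), tolerance = 1e-6)
    expect_error(confusionMatrix(factor(rep("a", 3), levels = c("a", "b")),
                                 rep("r", 3)), "empty")
})

test_that("correspondence calling follows the near-1:1 rule", {
    id <- diag(100, 3)
    dimnames(id) <- list(paste0("r", 1:3), paste0("q", 1:3))
    corr <- callCorrespondences(id)
    expect_true(all(corr$matched))
    expect_true(all(corr$reciprocal))
    ## a 45/45/10 split is below tau = 50: unmapped
    conf <- cbind(q1 = c(45, 45, 10), q2 = c(100, 0, 0))
    rownames(conf) <- paste0("r", 1:3)
    corr2 <- callCorrespondences(conf, tau = 50)
    expect_false(corr2$matched[corr2$query == "q1"])
    expect_true(is.na(corr2$ref[corr2$query == "q1"]))
    ## permutation equivariance
    set.seed(27)
    conf3 <- matrix(runif(16, 0, 100), 4, 4,
                    dimnames = list(paste0("r", 1:4), paste0("q", 1:4)))
    conf3 <- sweep(conf3, 2, colSums(conf3), "/") * 100
    perm <- sample(4)
    c1 <- callCorrespondences(conf3)
    c2 <- callCorrespondences(conf3[perm, ])
    expect_identical(c1[order(c1$query), ], c2[order(c2$query), ],
                     ignore_attr = TRUE)
})

test_that("pDE follows the exact shared-marker formula", {
    expect_identical(computePDE(c("a", "b", "c"), c("a", "b", "c")), 100)
    expect_identical(computePDE(c("a", "b", "c", "d"), c("c", "d", "e")), 50)
    expect_identical(computePDE(c("a", "b"), c("x", "y")), 0)
    expect_identical(computePDE(character(), c("a")), NA_real_)
    ## intentional asymmetry: the denominator is the first set
    expect_false(isTRUE(all.equal(
        computePDE(c("a", "b", "c", "d"), c("a", "b")),
        computePDE(c("a", "b"), c("a", "b", "c", "d")))))
    ## species-B genes are translated through the ortholog table
    ortho <- data.frame(species_a = c("A1", "A2"),
                        species_b = c("mB1", "mB2"))
    expect_identical(computePDE(c("A1", "A2"), c("mB1", "mXX"), ortho), 50)
})
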