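test_that("the screen applies strict thresholds per stratum", {
    ## one class x one region stratum of 20 cells, constructed exactly
    mk <- function(values) {
        m <- matrix(rep(values, each = 1), nrow = 1,
                    dimnames = list("G", paste0("c", seq_along(values))))
        m
    }
    tab <- data.frame(gene = "G", group = "RP")
    cls <- rep("AC", 20); reg <- rep("fovea", 20)
    ## 25% detection, stratum mean 0.6: passes
    passes <- screenGenes(tab, mk(c(rep(2.4, 5), rep(0, 15))), cls, reg)
    expect_true(passes$passes)
    expect_equal(passes$max_detection_pct, 25)
    expect_equal(passes$mean_expression, 0.6)
    ## high mean but 19% detection everywhere: fails
    cls100 <- rep("AC", 100); reg100 <- rep("fovea", 100)
    fails <- screenGenes(tab, mk(c(rep(4.75, 19), rep(0, 81))),
                         cls100, reg100)
    expect_false(fails$passes)
    ## boundaries are strict: exactly 20% fails, exactly 0.5 fails
    at20 <- screenGenes(tab, mk(c(rep(3, 4), rep(0, 16))), cls, reg)
    expect_equal(at20$max_detection_pct, 20)
    expect_false(at20$passes)
    atHalf <- screenGenes(tab, mk(c(rep(2, 5), rep(0, 15))), cls, reg)
    expect_equal(atHalf$mean_expression, 0.5)
    expect_false(atHalf$passes)
    ## override forces inclusion
    forced <- screenGenes(tab, mk(rep(0.01, 20)), cls, reg, overrides = "G")
    expect_true(forced$passes)
    expect_true(forced$override)
})

test_that("absent genes are recorded as absent, not failed", {
    m <- matrix(1, 2, 10, dimnames = list(c("A", "B"), paste0("c", 1:10)))
    tab <- data.frame(gene = c("A", "MISSING"), group = "RP")
    scr <- screenGenes(tab, m, rep("PR", 10), rep("fovea", 10))
    expect_false(scr$present[2])
    expect_true(is.na(scr$passes[2]))
    expect_true(scr$present[1])
})

test_that("screen outcome matches a brute-force stratum oracle", {
    sim <- smallSim()
    truth <- sim$truth
    cells <- singletCells(truth)
    E <- logcountsOf(sim$sce)[, cells]
    tr <- truth[match(cells, truth$cell_id), ]
    genes <- sample(rownames(E), 25)
    scr <- screenGenes(data.frame(gene = genes, group = "g"), E,
                       tr$true_class, tr$region)
    for (i in seq_along(genes)) {
        pass <- FALSE
        for (cl in unique(tr$true_class)) for (rg in unique(tr$region)) {
            idx <- tr$true_class == cl & tr$region == rg
            pct <- 100 * mean(E[genes[i], idx] > 0)
            mu <- mean(E[genes[i], idx])
            if (pct > 20 && mu > 0.5) pass <- TRUE
        }
        expect_identical(scr$passes[i], pass)
    }
})

test_that("class heat maps are row-scaled with rank preserved", {
    E <- rbind(
        only = c(rep(0, 20), rep(2, 10)),
        const = rep(1, 30),
        zero = rep(0, 30),
        grad = c(rep(1, 10), rep(2, 10), rep(4, 10)))
    colnames(E) <- paste0("c", 1:30)
    cls <- rep(c("AC", "BC", "RGC"), each = 10)
    hm <- classHeatmap(rownames(E), E, cls)
    expect_equal(hm$scaled["only", ], c(AC = 0, BC = 0, RGC = 1))
    expect_true(all(hm$scaled["const", ] == 1))
    expect_true(hm$flags$uninformative[hm$flags$gene == "const"])
    expect_true(hm$flags$all_zero[hm$flags$gene == "zero"])
    expect_true(all(hm$scaled["zero", ] == 0))
    ## scaling preserves within-row order
    expect_identical(order(hm$scaled["grad", ]), order(hm$means["grad", ]))
    expect_identical(unname(which.max(hm$scaled["grad", ])),
                     unname(which.max(hm$means["grad", ])))
    ## z-scale alternative
    hmz <- classHeatmap(rownames(E), E, cls, scale = "z")
    expect_equal(unname(rowMeans(hmz$scaled["grad", , drop = FALSE])), 0)
})

test_that("planted class-enriched genes peak in their class", {
    sim <- smallSim()
    truth <- sim$truth
    cells <- singletCells(truth)
    E <- logcountsOf(sim$sce)[, cells]
    tr <- truth[match(cells, truth$cell_id), ]
    panel <- spikeDiseasePanel(sim, nRobust = 12, nFailing = 0)
    hm <- classHeatmap(panel$gene, E, tr$true_class)
    gi <- sim$geneInfo[match(panel$gene, sim$geneInfo$gene), ]
    plantedClass <- sub("classMarker:", "", gi$role)
    argmax <- colnames(hm$scaled)[max.col(hm$scaled)]
    expect_gte(mean(argmax == plantedClass), 0.95)
})

test_that("dot-plot statistics use expressing cells only", {
    E <- matrix(c(0, 0, 2, 4, 0, 0, 0, 0), 2, 4, byrow = TRUE,
                dimnames = list(c("g1", "g2"), paste0("c", 1:4)))
    st <- dotplotStats(c("g1", "g2"), E, rep("K", 4))
    expect_equal(st$pct_nonzero[st$gene == "g1"], 50)
    expect_equal(st$mean_expressing[st$gene == "g1"], 3)
    expect_equal(st$pct_nonzero[st$gene == "g2"], 0)
    expect_equal(st$mean_expressing[st$gene == "g2"], 0)
    ## mean within expressing >= overall mean whenever zeros exist
    sim <- smallSim()
    E2 <- logcountsOf(sim$sce)[1:50, 1:200]
    lab <- rep(c("a", "b"), each = 100)
    st2 <- dotplotStats(rownames(E2), E2, lab)
    for (q in c("a", "b")) {
        overall <- rowMeans(E2[, lab == q])
        sub <- st2[st2$cluster == q, ]
        expect_true(all(sub$mean_expressing >= overall[sub$gene] - 1e-12))
    }
})

test_that("regional disease profiles detect planted regional genes", {
    sim <- pairSim()
    truth <- sim$truth
    E <- logcountsOf(sim$sce)
    up <- sim$regionDE[sim$regionDE$type == "A1" &
                       sim$regionDE$up_region == "fovea", ]
    prof <- regionalDiseaseProfile(up$gene, E, truth$true_class,
                                   truth$region)
    inA <- prof[prof$class == "A", ]
    expect_true(all(inA$mean_fovea > inA$mean_periphery))
    expect_true(all(inA$significant))
    ## class missing from one region is skipped with a flag
    reg2 <- truth$region
    reg2[truth$true_class == "B" & reg2 == "fovea"] <- "periphery"
    prof2 <- regionalDiseaseProfile(up$gene[1], E, truth$true_class, reg2)
    expect_true(all(prof2$skipped[prof2$class == "B"]))
    ## absent gene flagged
    prof3 <- regionalDiseaseProfile("NOPE", E, truth$true_class,
                                    truth$region)
    expect_true(all(prof3$skipped))
})
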