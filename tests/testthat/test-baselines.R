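test_that("the t statistic matches the hand formula and a naive loop", {
    ds <- GroupedDataset(matrix(c(1, 2, 3), 3, 1), matrix(c(0, 1, 2), 3, 1),
                         featureIds = "f1")
    expect_equal(unname(tStatistic(ds)), 1.0)
    for (k in 1:10) {
        set.seed(200 + k)
        Tm <- matrix(rnorm(10 * 50, 5), 10, 50)
        Fm <- matrix(rnorm(10 * 50, 5), 10, 50)
        ds <- GroupedDataset(Tm, Fm, featureIds = paste0("f", 1:50))
        expect_equal(unname(tStatistic(ds)), naiveT(Tm, Fm),
                     tolerance = 1e-12)
        expect_equal(unname(tStatistic(swapGroups(ds))),
                     -unname(tStatistic(ds)), tolerance = 1e-12)
    }
})

test_that("degenerate features get sentinel t values", {
    Tm <- rbind(c(1, 1, 3), c(1, 1, 4))
    Fm <- rbind(c(1, 0, 3.5), c(1, 0, 4.5))
    ds <- GroupedDataset(Tm, Fm, featureIds = c("same", "shift", "noisy"))
    t <- tStatistic(ds)
    expect_equal(unname(t[1]), 0)        # sd 0, equal means
    expect_equal(unname(t[2]), Inf)      # sd 0, case above control
    expect_true(is.finite(t[3]))
    expect_error(tStatistic(GroupedDataset(matrix(1, 2, 1),
                                           matrix(1, 2, 1), "f")),
                 NA)  # 2 per group is the minimum, allowed
})

test_that("t tail probabilities follow the Student distribution", {
    expect_equal(tPValue(0, df = 18, sided = "one"), 0.5)
    p <- tPValue(1.734, df = 18, sided = "one")
    expect_gt(p, 0.049); expect_lt(p, 0.051)
    expect_lt(tPValue(50, df = 18, sided = "one"), 1e-10)
    expect_equal(tPValue(1.5, df = 10, sided = "two"),
                 2 * pt(1.5, 10, lower.tail = FALSE))
    expect_error(tPValue(1, df = 0), "df")
})

test_that("fold change is the ratio of raw group means", {
    ds <- GroupedDataset(matrix(4, 2, 1), matrix(2, 2, 1),
                         featureIds = "f1")
    expect_equal(unname(foldChange(ds)), 2)
    same <- randomGrouped(n = 4, seed = 6)
    eq <- GroupedDataset(caseMatrix(same), caseMatrix(same),
                         featureIds = featureIds(same))
    expect_equal(unname(foldChange(eq)), rep(1, 4))
    for (k in 1:5) {
        set.seed(300 + k)
        Tm <- matrix(runif(8 * 12, 1, 10), 8, 12)
        Fm <- matrix(runif(8 * 12, 1, 10), 8, 12)
        ds <- GroupedDataset(Tm, Fm, featureIds = paste0("f", 1:12))
        expect_equal(unname(foldChange(ds)), naiveFC(Tm, Fm),
                     tolerance = 1e-12)
        expect_equal(unname(foldChange(swapGroups(ds))),
                     1 / unname(foldChange(ds)), tolerance = 1e-12)
    }
    neg <- GroupedDataset(matrix(1, 2, 1), matrix(c(-1, 1), 2, 1),
                          featureIds = "bad")
    expect_error(foldChange(neg), "bad")
})

test_that("log fold change ranking selects strictly above the cutoff", {
    Tm <- rbind(c(3, -5, 0.1), c(3, -5, 0.1))
    Fm <- rbind(c(0, 0, 0), c(0, 0, 0))
    ds <- GroupedDataset(Tm, Fm, featureIds = c("a", "b", "c"))
    r <- rankByAbsLogFC(ds, cutoff = 2)
    expect_equal(r$order, c(2L, 1L, 3L))
    expect_setequal_int(r$selected, c(1L, 2L))
    expect_equal(unname(r$score), c(3, 5, 0.1))
    expect_setequal_int(rankByAbsLogFC(ds, cutoff = 0)$selected, 1:3)
    expect_length(rankByAbsLogFC(ds, cutoff = Inf)$selected, 0)
})

test_that("feature statistics combine both scales consistently", {
    sim <- syntheticProfiles(nFeatures = 12, m1 = 5, m2 = 5, planted = 4,
                             shift = 5, seed = 31)
    fs <- featureStats(sim$dataset)
    expect_equal(nrow(fs), 12)
    expect_equal(fs$fc, unname(foldChange(sim$dataset)), tolerance = 1e-12)
    expect_equal(fs$absLogFC, abs(fs$meanCaseLog - fs$meanControlLog),
                 tolerance = 1e-12)
    expect_equal(which.max(abs(fs$t)), 4L)
})

test_that("SVM-RFE is deterministic and keeps strong features longest", {
    sim <- syntheticProfiles(nFeatures = 20, m1 = 6, m2 = 6,
                             planted = c(4, 15), shift = 6, seed = 77)
    r1 <- svmRfe(sim$dataset, computeAccuracy = FALSE)
    r2 <- svmRfe(sim$dataset, computeAccuracy = FALSE)
    expect_identical(r1$ranking, r2$ranking)
    expect_setequal_int(r1$ranking, 1:20)
    expect_true(all(c(4, 15) %in% r1$ranking[1:4]))
    # stopAt = n performs no elimination
    rAll <- svmRfe(sim$dataset, stopAt = 20, computeAccuracy = FALSE)
    expect_length(rAll$eliminationOrder, 0)
    expect_setequal_int(rAll$ranking, 1:20)
})

test_that("planted features survive elimination down to the final eight", {
    hits <- vapply(1:20, function(k) {
        set.seed(400 + k)
        planted <- sample(50, 4)
        sim <- syntheticProfiles(nFeatures = 50, m1 = 6, m2 = 6,
                                 planted = planted, shift = 5,
                                 seed = 500 + k)
        r <- svmRfe(sim$dataset, stopAt = 8, computeAccuracy = FALSE)
        all(planted %in% r$ranking[1:8])
    }, logical(1))
    expect_gte(sum(hits), 18)  # >= 90% of seeds
})

test_that("the SVM-RFE accuracy curve tracks retained-set size", {
    sim <- syntheticProfiles(nFeatures = 6, m1 = 4, m2 = 4, planted = 2,
                             shift = 6, seed = 9)
    r <- svmRfe(sim$dataset, stopAt = 2, step = 2)
    expect_equal(r$accuracy$size, c(6, 4, 2))
    expect_true(all(r$accuracy$looAccuracy >= 0 &
                    r$accuracy$looAccuracy <= 1))
})
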