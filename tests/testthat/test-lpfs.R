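test_that("distance gaps measure the pull toward the correct centroid", {
    g <- distanceGap(c(0, 0), "case", muCase = c(1, 0), muControl = c(3, 0))
    expect_equal(g, c(2, 0))
    g2 <- distanceGap(c(0, 0), "control", muCase = c(1, 0),
                      muControl = c(3, 0))
    expect_equal(g2, c(-2, 0))
    # per-coordinate midpoints give zero gap
    expect_equal(distanceGap(c(2, 5), "case", c(1, 4), c(3, 6)), c(0, 0))
    expect_error(distanceGap(1:3, "case", 1:2, 1:2), "equal length")
})

test_that("the LOO problem uses fold centroids, one constraint per sample", {
    ds <- tinyGrouped()
    pr <- buildLooProblem(ds, lambda = 1, rowNormalize = FALSE)
    expect_equal(nrow(pr@G), 4)
    # held-out case sample 0: own-group centroid 2, opposite centroid 11
    expect_equal(pr@G[1, 1], abs(0 - 11) - abs(0 - 2)) # = 9
    expect_equal(pr@G[1, 1], 9)
    expect_identical(pr@validation, "loo")
    expect_equal(pr@rowScale, rep(1, 4))
})

test_that("the resubstitution problem uses full-group centroids", {
    ds <- tinyGrouped()
    pr <- buildResubProblem(ds, lambda = 1, rowNormalize = FALSE)
    expect_equal(nrow(pr@G), 4)
    # case sample 0 against full centroids 1 and 11
    expect_equal(pr@G[1, 1], abs(0 - 11) - abs(0 - 1)) # = 10
    expect_equal(pr@G[1, 1], 10)
})

test_that("gap rows are label-consistent: full swaps preserve, single flips negate", {
    ds <- tinyGrouped()
    a <- buildResubProblem(ds, lambda = 1, rowNormalize = FALSE)
    # the gap is defined relative to each sample's CORRECT class, so swapping
    # both labels and centroid roles leaves every row invariant (up to order)
    b <- buildResubProblem(swapGroups(ds), lambda = 1, rowNormalize = FALSE)
    reorder <- c(3, 4, 1, 2)  # swapped problem lists old control rows first
    expect_equal(b@G[reorder, , drop = FALSE], a@G, ignore_attr = TRUE)
    # whereas relabeling one sample alone (same centroids) negates its row
    f <- looFolds(ds)[[1]]
    expect_equal(distanceGap(f$sample, "control", f$muCase, f$muControl),
                 -distanceGap(f$sample, "case", f$muCase, f$muControl))
})

test_that("row normalization records scales and rejects all-zero rows", {
    ds <- tinyGrouped()
    pr <- buildLooProblem(ds, lambda = 1, rowNormalize = TRUE)
    expect_equal(pr@G[, 1], rep(1, 4))  # n = 1: each row scaled to unit mean
    # hand-computed raw gaps: |0-11|-|0-2|, |2-11|-|2-0|, |10-1|-|10-12|,
    # |12-1|-|12-10|
    expect_equal(pr@rowScale, c(9, 7, 7, 9))
    dup <- GroupedDataset(rbind(c(1, 1), c(1, 1)), rbind(c(1, 1), c(1, 1)),
                          featureIds = c("f1", "f2"))
    expect_error(buildLooProblem(dup, lambda = 1), "all-zero gap row")
})

test_that("the worked instance solves to objective 2 for LP and exact ILP", {
    pr <- workedProblem()
    lp <- solveLP(pr)
    expect_identical(lp@status, "optimal")
    expect_equal(lp@objective, 2, tolerance = 1e-9)
    expect_equal(lp@x, c(1, 1), tolerance = 1e-9)
    expect_equal(lp@y, rep(0, 4), tolerance = 1e-9)
    expect_equal(lp@accuracy, 1)
    ilp <- solveILPExhaustive(pr)
    expect_equal(ilp@objective, 2, tolerance = 1e-12)
    expect_equal(ilp@x, c(1, 1))
    expect_setequal_int(lp@selected, ilp@selected)
})

test_that("a single active constraint returns one optimal vertex", {
    pr <- rawProblem(matrix(c(2, 2), 1, 2))
    sol <- solveLP(pr)
    expect_equal(sol@objective, 0.5, tolerance = 1e-9)
    expect_equal(sum(sol@x), 0.5, tolerance = 1e-9)
    expect_equal(sum(sol@x > 1e-8), 1)  # a vertex, not the face interior
})

test_that("tiny lambda collapses to x = 0 with full tolerable errors", {
    pr <- workedProblem(lambda = 1e-9)
    sol <- solveLP(pr)
    expect_equal(sol@x, c(0, 0))
    expect_equal(sol@y, rep(1, 4))
    expect_equal(accuracyFromErrors(sol), 0)
})

test_that("no feature can help when the gap matrix is zero", {
    pr <- rawProblem(matrix(0, 3, 2), delta = 1, lambda = 1)
    ilp <- solveILPExhaustive(pr)
    expect_equal(ilp@x, c(0, 0))
    expect_equal(ilp@y, rep(1, 3))
    expect_equal(ilp@objective, 3)
})

test_that("the exhaustive solver refuses oversized enumerations", {
    pr <- rawProblem(matrix(1, 2, 25))
    expect_error(solveILPExhaustive(pr), "refusing")
})

test_that("the LP relaxation is bounded by the exact integer optimum", {
    nInt <- 0
    for (k in 1:50) {
        set.seed(100 + k)
        n <- sample(2:8, 1)
        ds <- randomGrouped(n = n, m1 = 4, m2 = 4, seed = 500 + k)
        pr <- buildLooProblem(ds, lambda = 10^runif(1, -1, 1.5),
                              rowNormalize = FALSE, xUpper = 1)
        lp <- solveLP(pr)
        ilp <- solveILPExhaustive(pr)
        expect_identical(lp@status, "optimal")
        expect_lte(lp@objective, ilp@objective + 1e-8)
        integral <- all(abs(lp@x) < 1e-6 | abs(lp@x - 1) < 1e-6)
        if (integral) {
            # an integral LP optimum is ILP-feasible, so its support must be
            # an ILP-optimal support: rounding it reproduces the ILP optimum
            nInt <- nInt + 1
            xr <- round(lp@x)
            yr <- pmax(0, pr@delta - as.vector(pr@G %*% xr))
            expect_equal(sum(xr) + pr@lambda * sum(yr), ilp@objective,
                         tolerance = 1e-7)
        }
    }
    expect_gt(nInt, 0)
})

test_that("the simplex agrees with an independent LP solver on random instances", {
    library(pracma)
    for (k in 1:25) {
        set.seed(900 + k)
        L <- sample(3:8, 1); n <- sample(2:8, 1)
        G <- matrix(rnorm(L * n), L, n)
        lam <- 10^runif(1, -2, 2)
        delta <- runif(1, 0.5, 2)
        xu <- sample(c(1, Inf), 1)
        mine <- solveLP(rawProblem(G, delta = delta, lambda = lam,
                                   xUpper = xu))
        cc <- c(rep(1, n), rep(lam, L))
        A <- cbind(-G, -diag(L)); b <- rep(-delta, L)
        if (is.finite(xu)) {
            A <- rbind(A, cbind(diag(n), matrix(0, n, L)))
            b <- c(b, rep(xu, n))
        }
        ref <- pracma::linprog(cc, A = A, b = b, maxiter = 2000)
        expect_equal(mine@objective, ref$fval,
                     tolerance = 1e-6 * max(1, abs(ref$fval)))
    }
})

test_that("feature selection orders the strictly positive support by score", {
    sol <- new("LPFSSolution", x = c(0.5, 0, 1e-12), y = 0,
               objective = 0.5, selected = 1L, nCorrect = 1L, nWrong = 0L,
               accuracy = 1, status = "optimal", featureIds = character(0),
               lambda = 1, delta = 1, solver = "test")
    expect_equal(selectFeatures(sol), 1L)
    sol@x <- c(0.002, 0.015, 0.006)
    expect_equal(selectFeatures(sol), c(2L, 3L, 1L))
    sol@x <- c(0, 0, 0)
    expect_equal(selectFeatures(sol), integer(0))
})

test_that("error-variable accuracy counts near-zero tolerable errors", {
    sol <- new("LPFSSolution", x = 1, y = c(0, 0, 0.5, 0), objective = 1,
               selected = 1L, nCorrect = 3L, nWrong = 1L, accuracy = 0.75,
               status = "optimal", featureIds = character(0), lambda = 1,
               delta = 1, solver = "test")
    expect_equal(accuracyFromErrors(sol), 0.75)
    sol@y <- rep(0, 4)
    expect_equal(accuracyFromErrors(sol), 1)
    sol@y <- rep(1, 4)  # all at the margin
    expect_equal(accuracyFromErrors(sol), 0)
})

test_that("resubstitution is never harder than leave-one-out at the optimum", {
    for (k in 1:8) {
        ds <- randomGrouped(n = 5, m1 = 4, m2 = 4, seed = 40 + k)
        loo <- solveLP(buildLooProblem(ds, lambda = 5, rowNormalize = FALSE))
        res <- solveLP(buildResubProblem(ds, lambda = 5,
                                         rowNormalize = FALSE))
        expect_lte(res@objective, loo@objective + 1e-7)
    }
})

test_that("with a margin and large lambda the zero solution is not optimal", {
    ds <- separableGrouped(n = 25, planted = c(4, 9), shift = 6, seed = 5)
    sol <- solveLP(buildLooProblem(ds, lambda = 1000))
    expect_gt(sum(sol@x), 0)
    expect_equal(sum(sol@y), 0, tolerance = 1e-7)
})

test_that("selection is invariant to a global intensity rescaling", {
    ds <- separableGrouped(n = 50, planted = c(7, 21, 40), shift = 5,
                           seed = 12)
    ds1000 <- GroupedDataset(caseMatrix(ds) * 1000,
                             controlMatrix(ds) * 1000,
                             featureIds = featureIds(ds))
    p1 <- lambdaPath(ds)
    p2 <- lambdaPath(ds1000)
    expect_identical(selectedFeatures(p1), selectedFeatures(p2))
    expect_equal(p1@summary$posthocAccuracy, p2@summary$posthocAccuracy)
    expect_equal(p1@summary$errorAccuracy, p2@summary$errorAccuracy)
})

test_that("the lambda path chooses by accuracy, then parsimony, then lambda", {
    ds <- separableGrouped(n = 30, planted = c(3, 11), shift = 6, seed = 2)
    one <- lambdaPath(ds, lambdas = 10)
    expect_equal(chosenLambda(one), 10)
    expect_equal(nrow(one@summary), 1)
    path <- lambdaPath(ds)
    s <- path@summary
    best <- max(s$posthocAccuracy, na.rm = TRUE)
    ch <- path@chosen
    expect_equal(s$posthocAccuracy[ch], best)
    atBest <- which(!is.na(s$posthocAccuracy) & s$posthocAccuracy == best)
    expect_equal(s$nSelected[ch], min(s$nSelected[atBest]))
    # large-lambda end of the grid drives all tolerable errors to zero
    expect_equal(sum(chosenSolution(lambdaPath(ds, lambdas = 1e3))@y), 0,
                 tolerance = 1e-7)
})

test_that("selected-set size is essentially monotone along the lambda grid", {
    for (k in 1:6) {
        ds <- separableGrouped(n = 60, planted = c(5, 22, 47), shift = 4,
                               seed = 60 + k, m1 = 8, m2 = 8)
        s <- lambdaPath(ds)@summary
        drops <- diff(s$nSelected) < 0
        expect_lte(sum(drops), 1)  # solver ties may flip one adjacency
    }
})

test_that("permuted labels bring post-hoc LOO accuracy to chance", {
    accs <- vapply(1:20, function(k) {
        sim <- syntheticProfiles(nFeatures = 20, m1 = 6, m2 = 6,
                                 planted = 3, shift = 5, seed = 700 + k)
        ds <- sim$dataset
        all <- rbind(caseMatrix(ds), controlMatrix(ds))
        set.seed(k)
        perm <- sample(nrow(all))
        dsPerm <- GroupedDataset(all[perm[1:6], ], all[perm[7:12], ],
                                 featureIds = featureIds(ds))
        suppressWarnings(posthocLooAccuracy(dsPerm, 3))
    }, numeric(1))
    expect_gt(mean(accs), 0.3)
    expect_lt(mean(accs), 0.7)
})

test_that("problems export to the CPLEX-LP text format", {
    pr <- buildLooProblem(tinyGrouped(), lambda = 2)
    f <- tempfile(fileext = ".lp")
    writeLPFile(pr, f)
    txt <- readLines(f)
    expect_identical(txt[1], "Minimize")
    expect_true(any(grepl("^Subject To$", txt)))
    expect_equal(sum(grepl(">=", txt)), 4)
    expect_true(any(grepl("0 <= x1 <= 1", txt)))
})
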