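# Fixtures are built in code; nothing is read from disk.

# 4-sample, 1-feature dataset with hand-checkable centroids:
# T = {0, 2}, F = {10, 12}.
tinyGrouped <- function() {
    GroupedDataset(matrix(c(0, 2), 2, 1), matrix(c(10, 12), 2, 1),
                   featureIds = "f1")
}

# Wrap a raw gap matrix into a problem without any row normalization.
rawProblem <- function(G, delta = 1, lambda = 10, xUpper = Inf) {
    new("LPFSProblem", G = G, delta = delta, lambda = lambda,
        xUpper = xUpper, rowScale = rep(1, nrow(G)),
        validation = "resubstitution",
        featureIds = paste0("f", seq_len(ncol(G))),
        sampleInfo = data.frame(group = rep("case", nrow(G)),
                                index = seq_len(nrow(G))))
}

# The worked 4-row instance whose LP and integer optima are both 2.
workedProblem <- function(lambda = 10) {
    rawProblem(rbind(c(2, -1), c(2, 0), c(-1, 2), c(0, 2)),
               delta = 1, lambda = lambda, xUpper = Inf)
}

# Random small grouped dataset for oracle round trips.
randomGrouped <- function(n, m1 = 4, m2 = 4, seed = 1) {
    set.seed(seed)
    GroupedDataset(matrix(rnorm(m1 * n, 10), m1, n),
                   matrix(rnorm(m2 * n, 10), m2, n),
                   featureIds = paste0("f", seq_len(n)))
}

# Small separable dataset: planted features at a large shift.
separableGrouped <- function(n = 30, planted = c(3, 11), shift = 6,
                             seed = 1, m1 = 5, m2 = 5) {
    syntheticProfiles(nFeatures = n, m1 = m1, m2 = m2, planted = planted,
                      shift = shift, seed = seed)$dataset
}

# A small ProfileMatrix with a ppm axis.
tinyProfile <- function(values = rbind(c(1, 2, 3), c(4, 5, 6)),
                        ppm = c(5.0, 4.0, 4.7)) {
    rownames(values) <- paste0("s", seq_len(nrow(values)))
    colnames(values) <- paste0("f", seq_len(ncol(values)))
    ProfileMatrix(values, ppm = ppm)
}

# Swap the case/control roles of a dataset.
swapGroups <- function(ds) {
    GroupedDataset(controlMatrix(ds), caseMatrix(ds),
                   featureIds = featureIds(ds), ppm = ppm(ds))
}

expect_setequal_int <- function(a, b) expect_true(setequal(a, b))

# Independent naive re-implementations (direct per-feature loops) used to
# cross-check the vectorized filter statistics.
naiveT <- function(Tm, Fm) {
    vapply(seq_len(ncol(Tm)), function(i) {
        x <- Tm[, i]; y <- Fm[, i]
        sx <- sum((x - mean(x))^2); sy <- sum((y - mean(y))^2)
        s <- sqrt((sx + sy) / (length(x) + length(y) - 2))
        if (s == 0) {
            if (mean(x) == mean(y)) 0 else sign(mean(x) - mean(y)) * Inf
        } else (mean(x) - mean(y)) / s
    }, numeric(1))
}

naiveFC <- function(Tm, Fm) {
    vapply(seq_len(ncol(Tm)), function(i) mean(Tm[, i]) / mean(Fm[, i]),
           numeric(1))
}
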