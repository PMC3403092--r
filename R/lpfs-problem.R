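#' Per-feature distance gap of a validated sample
#'
#' For a sample of known group and a pair of centroids, the gap of feature
#' `i` is the amount by which including feature `i` pushes the nearest-
#' centroid rule toward the *correct* class:
#' for a case sample `g_i = |s_i - muF_i| - |s_i - muT_i|`, for a control
#' sample the sign flips.  Every correct-classification constraint then
#' takes the uniform form `sum(g * x) + y >= delta`.
#'
#' @param sample numeric vector.
#' @param group `"case"` or `"control"` — the sample's true group.
#' @param muCase,muControl centroid vectors of matching length.
#' @return Numeric gap vector; positive entries favor correct
#'   classification.
#' @export
distanceGap <- function(sample, group = c("case", "control"),
                        muCase, muControl) {
    group <- match.arg(group)
    if (length(sample) != length(muCase) ||
        length(sample) != length(muControl))
        stop("sample and centroids must have equal length")
    g <- abs(sample - muControl) - abs(sample - muCase)
    if (group == "control") -g else g
}

.assembleProblem <- function(rows, info, ds, lambda, delta, rowNormalize,
                             xUpper, validation) {
    G <- do.call(rbind, rows)
    scale <- rep(1, nrow(G))
    if (rowNormalize) {
        scale <- rowMeans(abs(G))
        zero <- scale <= 0
        if (any(zero))
            stop("all-zero gap row (no feature separates sample ",
                 paste0(info$group[zero], "[", info$index[zero], "]",
                        collapse = ", "),
                 " from the opposite centroid); cannot row-normalize")
        G <- G / scale
    }
    if (length(lambda) != 1L || !is.finite(lambda) || lambda <= 0)
        stop("'lambda' must be a single positive number")
    if (length(delta) != 1L || !is.finite(delta) || delta <= 0)
        stop("'delta' must be a single positive number")
    new("LPFSProblem", G = G, delta = delta, lambda = lambda,
        xUpper = xUpper, rowScale = scale, validation = validation,
        featureIds = ds@featureIds, sampleInfo = info)
}

#' Build the leave-one-out LPFS problem
#'
#' One constraint per sample: the held-out sample's gap row is computed
#' against fold centroids in which the sample is removed from its own
#' group's mean only (see [looFolds()]).  The strict inequalities of the
#' underlying classification rule are replaced by a positive margin `delta`:
#' without it, `x = 0, y = 0` would be feasible and trivially optimal.
#'
#' With `rowNormalize = TRUE` (default) each gap row is divided by its mean
#' absolute entry, making `delta` and `lambda` scale-free so that one lambda
#' grid works across datasets; the factors are recorded in `rowScale`.
#'
#' @param ds a [GroupedDataset-class].
#' @param lambda positive trade-off between feature count and total
#'   tolerable error.
#' @param delta positive margin (default 1, natural on normalized rows).
#' @param rowNormalize divide each row by its mean absolute gap
#'   (default `TRUE`); rows with all-zero gap raise an error naming the
#'   sample.
#' @param xUpper upper bound on each feature score: 1 by default (the LP
#'   relaxation of the binary selection variables), `Inf` for the
#'   unbounded-score variant.
#' @return An [LPFSProblem-class] with `m1 + m2` rows.
#' @export
buildLooProblem <- function(ds, lambda, delta = 1, rowNormalize = TRUE,
                            xUpper = 1) {
    folds <- looFolds(ds)
    rows <- lapply(folds, function(f)
        distanceGap(f$sample, f$group, f$muCase, f$muControl))
    info <- data.frame(group = vapply(folds, `[[`, "", "group"),
                       index = vapply(folds, `[[`, 0L, "index"))
    .assembleProblem(rows, info, ds, lambda, delta, rowNormalize, xUpper,
                     "loo")
}

#' Build the resubstitution-validation LPFS problem
#'
#' Like [buildLooProblem()] but every constraint uses the centroids of the
#' *full* groups, held-out sample included — the optimistic variant whose
#' information leak underestimates the classification error.  Retained for
#' comparison and for data too scarce even for leave-one-out.
#'
#' @inheritParams buildLooProblem
#' @return An [LPFSProblem-class] with `m1 + m2` rows.
#' @export
buildResubProblem <- function(ds, lambda, delta = 1, rowNormalize = TRUE,
                              xUpper = 1) {
    muT <- computeCentroid(ds@caseMatrix)
    muF <- computeCentroid(ds@controlMatrix)
    m1 <- nrow(ds@caseMatrix); m2 <- nrow(ds@controlMatrix)
    rows <- c(
        lapply(seq_len(m1), function(l)
            distanceGap(ds@caseMatrix[l, ], "case", muT, muF)),
        lapply(seq_len(m2), function(l)
            distanceGap(ds@controlMatrix[l, ], "control", muT, muF)))
    info <- data.frame(group = rep(c("case", "control"), c(m1, m2)),
                       index = c(seq_len(m1), seq_len(m2)))
    .assembleProblem(rows, info, ds, lambda, delta, rowNormalize, xUpper,
                     "resubstitution")
}

#' Export an LPFSProblem in CPLEX-LP format
#'
#' Writes the assembled program in the plain-text LP file dialect so the
#' instance can be checked with an external solver.
#'
#' @param problem an [LPFSProblem-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeLPFile <- function(problem, path) {
    G <- problem@G
    n <- ncol(G); L <- nrow(G)
    xs <- paste0("x", seq_len(n)); ys <- paste0("y", seq_len(L))
    con <- file(path, "w"); on.exit(close(con))
    writeLines("Minimize", con)
    writeLines(paste0(" obj: ",
        paste(c(paste0("1 ", xs),
                paste0(format(problem@lambda, digits = 17), " ", ys)),
              collapse = " + ")), con)
    writeLines("Subject To", con)
    for (l in seq_len(L)) {
        coef <- G[l, ]
        terms <- paste0(ifelse(coef >= 0, "+ ", "- "),
                        format(abs(coef), digits = 17), " ", xs)
        writeLines(paste0(" c", l, ": ", paste(terms, collapse = " "),
                          " + 1 ", ys[l], " >= ",
                          format(problem@delta, digits = 17)), con)
    }
    writeLines("Bounds", con)
    if (is.finite(problem@xUpper))
        for (i in seq_len(n))
            writeLines(paste0(" 0 <= ", xs[i], " <= ",
                              format(problem@xUpper, digits = 17)), con)
    writeLines("End", con)
    invisible(path)
}
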