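#' Two-sample t statistic per feature
#'
#' Signal-to-noise form: `T_i = (mean_case_i - mean_control_i) / s_i` with
#' `s_i` the pooled two-group standard deviation
#' `sqrt(((m1-1) s_case^2 + (m2-1) s_ctrl^2) / (m1 + m2 - 2))` — no
#' `sqrt(1/m1 + 1/m2)` factor, matching the plain ratio convention used for
#' feature ranking.  P-values from [tPValue()] then treat `T_i` as
#' approximately t-distributed.
#'
#' Constant features (pooled sd 0) yield `0` when the group means agree and
#' a signed `Inf` sentinel otherwise, which ranks above every finite value.
#'
#' @param ds a [GroupedDataset-class], on the log scale by convention
#'   (the caller transforms; see [logTransform()]).
#' @return Named numeric vector of per-feature statistics.
#' @export
tStatistic <- function(ds) {
    Tm <- ds@caseMatrix; Fm <- ds@controlMatrix
    m1 <- nrow(Tm); m2 <- nrow(Fm)
    if (m1 < 2L || m2 < 2L)
        stop("each group needs >= 2 samples for a pooled sd")
    diff <- colMeans(Tm) - colMeans(Fm)
    v1 <- apply(Tm, 2L, var); v2 <- apply(Fm, 2L, var)
    s <- sqrt(((m1 - 1) * v1 + (m2 - 1) * v2) / (m1 + m2 - 2))
    t <- ifelse(s > 0, diff / s,
                ifelse(diff == 0, 0, sign(diff) * Inf))
    setNames(t, ds@featureIds)
}

#' Student-t tail probability for a feature statistic
#'
#' @param t statistic value(s).
#' @param df degrees of freedom (conventionally `m1 + m2 - 2`).
#' @param sided `"one"` (upper tail `P(T >= t)`) or `"two"`
#'   (`2 P(T >= |t|)`).
#' @return P-value(s) in `(0, 1]`.
#' @export
tPValue <- function(t, df, sided = c("one", "two")) {
    sided <- match.arg(sided)
    if (length(df) != 1L || !is.finite(df) || df < 1)
        stop("'df' must be a single value >= 1")
    if (sided == "one") pt(t, df = df, lower.tail = FALSE)
    else 2 * pt(abs(t), df = df, lower.tail = FALSE)
}

#' Fold change per feature
#'
#' Ratio of raw (unlogged) group means, case over control.
#'
#' @param ds a [GroupedDataset-class] of raw intensities with positive
#'   control means.
#' @return Named numeric vector of fold changes.
#' @export
foldChange <- function(ds) {
    mc <- colMeans(ds@caseMatrix)
    mf <- colMeans(ds@controlMatrix)
    bad <- which(mf <= 0)
    if (length(bad))
        stop("non-positive control mean for feature(s): ",
             paste(head(ds@featureIds[bad], 5L), collapse = ", "))
    setNames(mc / mf, ds@featureIds)
}

#' Rank features by absolute log fold change
#'
#' On log-scale data the difference of group means is the log fold change;
#' features are ranked by its absolute value and selected above a cutoff
#' (the conventional cutoff 2, i.e. a four-fold change on the log2 scale).
#'
#' @param ds a [GroupedDataset-class] on the log scale.
#' @param cutoff nonnegative selection threshold on `|logFC|` (strict).
#' @return List with `score` (named `|logFC|`), `logFC` (signed), `order`
#'   (feature indices by decreasing score, ties by index), and `selected`
#'   (indices with score strictly above the cutoff, in ranked order).
#' @export
rankByAbsLogFC <- function(ds, cutoff = 2) {
    if (cutoff < 0) stop("'cutoff' must be nonnegative")
    lfc <- colMeans(ds@caseMatrix) - colMeans(ds@controlMatrix)
    score <- abs(lfc)
    ord <- order(-score, seq_along(score))
    list(score = setNames(score, ds@featureIds),
         logFC = setNames(lfc, ds@featureIds),
         order = ord,
         selected = ord[score[ord] > cutoff])
}

#' Per-feature summary statistics on both scales
#'
#' Convenience table combining the raw-scale fold change with the
#' log-scale means, pooled sd, t statistic and log fold change.
#'
#' @param dsRaw a [GroupedDataset-class] of raw positive intensities.
#' @param base log base for the internal transform.
#' @return data.frame with one row per feature.
#' @export
featureStats <- function(dsRaw, base = 2) {
    logCase <- log(dsRaw@caseMatrix, base = base)
    logCtrl <- log(dsRaw@controlMatrix, base = base)
    if (any(!is.finite(logCase)) || any(!is.finite(logCtrl)))
        stop("raw intensities must be positive to take logs; ",
             "use logTransform() with a pseudocount upstream")
    dsLog <- GroupedDataset(logCase, logCtrl, dsRaw@featureIds,
                            ppm = ppm(dsRaw))
    m1 <- nrow(logCase); m2 <- nrow(logCtrl)
    t <- tStatistic(dsLog)
    data.frame(
        featureId = dsRaw@featureIds,
        ppm = if (length(dsRaw@ppm)) dsRaw@ppm else NA_real_,
        meanCaseLog = colMeans(logCase),
        meanControlLog = colMeans(logCtrl),
        pooledSdLog = unname(.pooledSd(logCase, logCtrl)),
        t = unname(t),
        pValue = unname(tPValue(abs(t), df = m1 + m2 - 2, sided = "two")),
        meanCaseRaw = colMeans(dsRaw@caseMatrix),
        meanControlRaw = colMeans(dsRaw@controlMatrix),
        fc = unname(foldChange(dsRaw)),
        absLogFC = unname(abs(colMeans(logCase) - colMeans(logCtrl))),
        row.names = NULL)
}

.pooledSd <- function(Tm, Fm) {
    m1 <- nrow(Tm); m2 <- nrow(Fm)
    sqrt(((m1 - 1) * apply(Tm, 2L, var) + (m2 - 1) * apply(Fm, 2L, var)) /
         (m1 + m2 - 2))
}

#' SVM recursive feature elimination
#'
#' Wrapper baseline: trains a linear soft-margin SVM on the current feature
#' set, eliminates the `step` features with the smallest squared weight,
#' and repeats until `stopAt` features remain.  The ranking is the reverse
#' elimination order (later-eliminated features are more important).
#' Optionally reports the leave-one-out SVM accuracy at every retained-set
#' size.  Deterministic for fixed data (the quadratic program has a unique
#' solution; `seed` is recorded for provenance only).
#'
#' @param ds a [GroupedDataset-class] (any scale; no internal rescaling).
#' @param step features removed per round (default 1).
#' @param stopAt stop when this many features remain.
#' @param cost soft-margin regularization constant of the linear SVM.
#' @param computeAccuracy evaluate the leave-one-out accuracy curve
#'   (default `TRUE`; disable for pure-ranking runs).
#' @param seed integer recorded in the result.
#' @return List with `ranking` (feature indices, most important first),
#'   `eliminationOrder` (indices in the order removed; survivors of the
#'   final round first by final weight), and `accuracy` (data.frame of
#'   retained-set size vs leave-one-out accuracy, or `NULL`).
#' @export
svmRfe <- function(ds, step = 1L, stopAt = 1L, cost = 1,
                   computeAccuracy = TRUE, seed = 1L) {
    Tm <- ds@caseMatrix; Fm <- ds@controlMatrix
    n <- ncol(Tm)
    if (stopAt < 1L || stopAt > n) stop("'stopAt' must be in [1, n]")
    X <- rbind(Tm, Fm)
    yy <- factor(rep(c("case", "control"), c(nrow(Tm), nrow(Fm))))
    if (all(apply(X, 2L, var) == 0))
        stop("all features have zero variance")
    remaining <- seq_len(n)
    eliminated <- integer(0)
    accRows <- list()
    repeat {
        if (computeAccuracy)
            accRows[[length(accRows) + 1L]] <- data.frame(
                size = length(remaining),
                looAccuracy = .svmLooAccuracy(X[, remaining, drop = FALSE],
                                              yy, cost))
        if (length(remaining) <= stopAt) break
        w2 <- .svmWeights(X[, remaining, drop = FALSE], yy, cost)^2
        k <- min(step, length(remaining) - stopAt)
        drop <- order(w2, seq_along(w2))[seq_len(k)]   # ties by index
        eliminated <- c(eliminated, remaining[drop])
        remaining <- remaining[-drop]
    }
    finalW2 <- .svmWeights(X[, remaining, drop = FALSE], yy, cost)^2
    survivors <- remaining[order(-finalW2, seq_along(finalW2))]
    ranking <- c(survivors, rev(eliminated))
    list(ranking = ranking,
         eliminationOrder = eliminated,
         accuracy = if (computeAccuracy) do.call(rbind, accRows) else NULL,
         parameters = list(step = step, stopAt = stopAt, cost = cost,
                           seed = seed))
}

.svmWeights <- function(X, yy, cost) {
    fit <- e1071::svm(X, yy, kernel = "linear", cost = cost, scale = FALSE)
    as.vector(t(fit$coefs) %*% fit$SV)
}

.svmLooAccuracy <- function(X, yy, cost) {
    m <- nrow(X)
    correct <- vapply(seq_len(m), function(i) {
        fit <- e1071::svm(X[-i, , drop = FALSE], yy[-i], kernel = "linear",
                          cost = cost, scale = FALSE)
        as.character(predict(fit, X[i, , drop = FALSE])) ==
            as.character(yy[i])
    }, logical(1))
    mean(correct)
}
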