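#' Columnwise arithmetic-mean centroid
#'
#' The class prototype of the nearest-centroid rule: the mean profile of a
#' group of samples.
#'
#' @param samples numeric matrix, samples in rows (m >= 1).
#' @return Numeric vector of length `ncol(samples)`.
#' @export
computeCentroid <- function(samples) {
    samples <- as.matrix(samples)
    if (nrow(samples) < 1L)
        stop("cannot compute a centroid from zero samples")
    colMeans(samples)
}

#' L1 (city-block) distance between two vectors
#'
#' The metric of the centroid classifier; robust to single-feature outliers
#' compared with the Euclidean distance.
#'
#' @param a,b numeric vectors of equal length.
#' @return Nonnegative scalar `sum(abs(a - b))`.
#' @export
l1Distance <- function(a, b) {
    if (length(a) != length(b))
        stop("vectors must have equal length")
    sum(abs(a - b))
}

#' Fit a nearest-centroid model on a grouped dataset
#'
#' @param ds a [GroupedDataset-class].
#' @param features optional feature subset (integer indices or ids) to
#'   restrict the model to.
#' @return A [CentroidModel-class].
#' @export
centroidModel <- function(ds, features = NULL) {
    idx <- .resolveFeatures(ds, features)
    new("CentroidModel",
        muCase = computeCentroid(ds@caseMatrix[, idx, drop = FALSE]),
        muControl = computeCentroid(ds@controlMatrix[, idx, drop = FALSE]),
        featureIds = ds@featureIds[idx])
}

.resolveFeatures <- function(ds, features) {
    if (is.null(features)) return(seq_along(ds@featureIds))
    if (is.character(features)) {
        idx <- match(features, ds@featureIds)
        if (anyNA(idx))
            stop("unknown feature id(s): ",
                 paste(head(features[is.na(idx)], 5L), collapse = ", "))
        idx
    } else {
        idx <- as.integer(features)
        if (any(idx < 1L | idx > length(ds@featureIds)))
            stop("feature index out of range")
        idx
    }
}

#' Classify a sample with a nearest-centroid model
#'
#' Assigns `"case"` when the sample is strictly closer (L1) to the case
#' centroid, `"control"` when strictly closer to the control centroid.  An
#' exact tie is resolved to `"control"` — the null, no-treatment-effect
#' class, the conservative call for a biomarker claim — with a warning.
#'
#' @param sample numeric vector matching the model's feature axis.
#' @param model a [CentroidModel-class].
#' @return `"case"` or `"control"`.
#' @export
classifyCentroid <- function(sample, model) {
    dT <- l1Distance(sample, model@muCase)
    dF <- l1Distance(sample, model@muControl)
    if (dT == dF) {
        warning("sample equidistant from both centroids; assigning 'control'")
        return("control")
    }
    if (dT < dF) "case" else "control"
}

#' Leave-one-out folds with group-specific centroid recomputation
#'
#' One fold per sample.  In each fold the held-out sample is removed from
#' its own group's centroid only; the opposite group's centroid keeps all
#' its samples.  This is exactly the constraint structure used when the
#' leave-one-out validation is embedded into the selection program.
#'
#' @param ds a [GroupedDataset-class] (both groups >= 2 samples).
#' @return List of length `m1 + m2`; each element has `group` (`"case"` or
#'   `"control"`), `index` (row within its group), `sample` (the held-out
#'   profile), `muCase` and `muControl` (the fold centroids).
#' @export
looFolds <- function(ds) {
    Tm <- ds@caseMatrix; Fm <- ds@controlMatrix
    muT <- computeCentroid(Tm); muF <- computeCentroid(Fm)
    m1 <- nrow(Tm); m2 <- nrow(Fm)
    folds <- vector("list", m1 + m2)
    for (l in seq_len(m1)) {
        folds[[l]] <- list(group = "case", index = l, sample = Tm[l, ],
                           muCase = (muT * m1 - Tm[l, ]) / (m1 - 1),
                           muControl = muF)
    }
    for (l in seq_len(m2)) {
        folds[[m1 + l]] <- list(group = "control", index = l,
                                sample = Fm[l, ], muCase = muT,
                                muControl = (muF * m2 - Fm[l, ]) / (m2 - 1))
    }
    folds
}

#' Leave-one-out accuracy of a feature subset under the centroid rule
#'
#' The externally reportable accuracy of a selected biomarker set: a plain
#' leave-one-out run of the L1 nearest-centroid classifier restricted to the
#' selected features, independent of any optimization variables.
#'
#' @param ds a [GroupedDataset-class].
#' @param selected non-empty feature subset (integer indices or ids).
#' @return Fraction of the `m1 + m2` held-out samples classified correctly.
#' @export
posthocLooAccuracy <- function(ds, selected) {
    idx <- .resolveFeatures(ds, selected)
    if (length(idx) == 0L)
        stop("'selected' must be a non-empty feature set")
    folds <- looFolds(ds)
    correct <- vapply(folds, function(f) {
        model <- new("CentroidModel",
                     muCase = f$muCase[idx], muControl = f$muControl[idx],
                     featureIds = character(0))
        classifyCentroid(f$sample[idx], model) == f$group
    }, logical(1))
    mean(correct)
}
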