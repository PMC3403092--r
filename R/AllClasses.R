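#' ProfileMatrix: a samples-by-features intensity table
#'
#' Container for a two-group profiling experiment: one intensity value per
#' sample and feature (for binned 1H NMR data, one value per 0.01-ppm
#' chemical-shift bin).  Extends
#' [SummarizedExperiment::SummarizedExperiment-class], so all its accessors
#' (`assay()`, `rowData()`, `colData()`, subsetting) apply.  Following the
#' Bioconductor convention the assay is stored features-in-rows; use
#' [profileValues()] for the samples-by-features orientation that the
#' selection machinery works in.
#'
#' The optional per-feature chemical shift (ppm) lives in `rowData(x)$ppm`.
#'
#' Validity requires a single assay named `"intensity"` with finite numeric
#' values and unique sample and feature identifiers.  Negative values are
#' permitted (log-transformed or Pareto-scaled data); rawness is enforced by
#' the operations that need it, not by the container.
#'
#' @seealso [ProfileMatrix()], [readProfileTable()], [splitGroups()]
#' @export
setClass("ProfileMatrix", contains = "SummarizedExperiment")

setValidity("ProfileMatrix", function(object) {
    msg <- character()
    if (length(assays(object)) != 1L || assayNames(object)[1L] != "intensity")
        msg <- c(msg, "exactly one assay named 'intensity' is required")
    v <- assay(object, withDimnames = FALSE)
    if (!is.numeric(v))
        msg <- c(msg, "intensity assay must be numeric")
    else if (!all(is.finite(v)))
        msg <- c(msg, "intensity assay contains non-finite values")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "feature ids must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be present and unique")
    if (!is.null(rowData(object)$ppm)) {
        p <- rowData(object)$ppm
        if (!is.numeric(p) || any(!is.finite(p)))
            msg <- c(msg, "ppm annotation must be finite numeric")
    }
    if (length(msg)) msg else TRUE
})

#' GroupedDataset: case and control profiles on a shared feature axis
#'
#' Holds the case matrix T (m1 x n) and control matrix F (m2 x n), both
#' samples-in-rows, with a common feature axis.  Every selection and
#' validation routine in the package consumes this class.  Both groups must
#' have at least two samples so that leave-one-out centroids remain defined.
#'
#' @slot caseMatrix numeric matrix, m1 x n, case (treated) samples.
#' @slot controlMatrix numeric matrix, m2 x n, control samples.
#' @slot featureIds character vector of length n, unique.
#' @slot ppm numeric vector of length n (chemical shift), or length 0 if
#'   the feature axis carries no ppm annotation.
#'
#' @seealso [splitGroups()], [syntheticProfiles()]
#' @export
setClass("GroupedDataset",
    representation(caseMatrix = "matrix", controlMatrix = "matrix",
                   featureIds = "character", ppm = "numeric"))

setValidity("GroupedDataset", function(object) {
    msg <- character()
    Tm <- object@caseMatrix; Fm <- object@controlMatrix
    if (!is.numeric(Tm) || !is.numeric(Fm))
        msg <- c(msg, "case and control matrices must be numeric")
    if (ncol(Tm) != ncol(Fm))
        msg <- c(msg, "case and control matrices must share the feature axis")
    if (nrow(Tm) < 2L || nrow(Fm) < 2L)
        msg <- c(msg, "each group needs >= 2 samples (leave-one-out centroids)")
    if (!all(is.finite(Tm)) || !all(is.finite(Fm)))
        msg <- c(msg, "matrices contain non-finite values")
    if (length(object@featureIds) != ncol(Tm))
        msg <- c(msg, "featureIds length must equal the number of features")
    if (anyDuplicated(object@featureIds))
        msg <- c(msg, "featureIds must be unique")
    if (length(object@ppm) && length(object@ppm) != ncol(Tm))
        msg <- c(msg, "ppm must be empty or one value per feature")
    if (length(msg)) msg else TRUE
})

#' CentroidModel: the two class prototypes of the nearest-centroid rule
#'
#' Arithmetic-mean prototypes of the case and control groups.  A sample is
#' assigned to the class whose centroid is nearer in L1 distance; exact ties
#' go to control (the null class) with a warning.
#'
#' @slot muCase numeric vector, case centroid.
#' @slot muControl numeric vector, control centroid.
#' @slot featureIds character, feature identifiers (may be empty).
#'
#' @seealso [centroidModel()], [classifyCentroid()]
#' @export
setClass("CentroidModel",
    representation(muCase = "numeric", muControl = "numeric",
                   featureIds = "character"))

setValidity("CentroidModel", function(object) {
    msg <- character()
    if (length(object@muCase) != length(object@muControl))
        msg <- c(msg, "centroids must have equal length")
    if (!all(is.finite(object@muCase)) || !all(is.finite(object@muControl)))
        msg <- c(msg, "centroids must be finite")
    if (length(object@featureIds) &&
        length(object@featureIds) != length(object@muCase))
        msg <- c(msg, "featureIds must be empty or match centroid length")
    if (length(msg)) msg else TRUE
})

#' LPFSProblem: the assembled feature-selection constraint system
#'
#' One row of the gap matrix `G` per validated sample: for a sample `s` of
#' known group, `G[l, i]` is the per-feature distance gap (see
#' [distanceGap()]), so that the correct-classification constraint reads
#' `G[l, ] %*% x + y[l] >= delta`.  Feature scores `x` (0 <= x <= xUpper) and
#' tolerable errors `y >= 0` are the optimization variables; the objective is
#' `sum(x) + lambda * sum(y)`.
#'
#' @slot G numeric matrix, L x n, the (possibly row-normalized) gap matrix.
#' @slot delta positive margin replacing the strict inequalities.
#' @slot lambda positive trade-off between feature count and total error.
#' @slot xUpper upper bound on each feature score (1 by default, may be Inf).
#' @slot rowScale numeric length L: the factor each raw gap row was divided
#'   by (all 1 when row normalization is off).
#' @slot validation `"loo"` or `"resubstitution"`.
#' @slot featureIds character length n.
#' @slot sampleInfo data.frame with columns `group` and `index`, one row per
#'   constraint, recording which held-out sample generated it.
#'
#' @seealso [buildLooProblem()], [buildResubProblem()], [solveLP()]
#' @export
setClass("LPFSProblem",
    representation(G = "matrix", delta = "numeric", lambda = "numeric",
                   xUpper = "numeric", rowScale = "numeric",
                   validation = "character", featureIds = "character",
                   sampleInfo = "data.frame"))

setValidity("LPFSProblem", function(object) {
    msg <- character()
    if (!all(is.finite(object@G)))
        msg <- c(msg, "gap matrix G must be finite")
    if (length(object@delta) != 1L || !is.finite(object@delta) ||
        object@delta <= 0)
        msg <- c(msg, "delta must be a single positive number")
    if (length(object@lambda) != 1L || !is.finite(object@lambda) ||
        object@lambda <= 0)
        msg <- c(msg, "lambda must be a single positive number")
    if (length(object@xUpper) != 1L || is.na(object@xUpper) ||
        object@xUpper <= 0)
        msg <- c(msg, "xUpper must be a single positive number (possibly Inf)")
    if (length(object@rowScale) != nrow(object@G))
        msg <- c(msg, "rowScale must have one entry per constraint row")
    if (!object@validation %in% c("loo", "resubstitution"))
        msg <- c(msg, "validation must be 'loo' or 'resubstitution'")
    if (length(object@featureIds) &&
        length(object@featureIds) != ncol(object@G))
        msg <- c(msg, "featureIds must be empty or match ncol(G)")
    if (length(msg)) msg else TRUE
})

#' LPFSSolution: scores, tolerable errors and accuracy of a solved problem
#'
#' @slot x numeric length n: feature scores (the LPFS scores; fractional for
#'   the LP relaxation, 0/1 for the exhaustive integer solve).
#' @slot y numeric length L: tolerable errors, one per validated sample.
#' @slot objective value of `sum(x) + lambda * sum(y)` at the optimum.
#' @slot selected integer indices with score above the selection tolerance,
#'   ordered by decreasing score.
#' @slot nCorrect,nWrong integer: constraints with (near-)zero and positive
#'   tolerable error; `nCorrect + nWrong = L`.
#' @slot accuracy `nCorrect / L`, the error-variable accuracy.  The headline
#'   accuracy reported for a selected set is [posthocLooAccuracy()], not this.
#' @slot status `"optimal"`, `"infeasible"`, `"unbounded"` or
#'   `"numeric_failure"`.
#' @slot featureIds character length n (may be empty).
#' @slot lambda,delta the parameters the problem was solved with.
#' @slot solver character, identity of the solver used.
#'
#' @seealso [solveLP()], [solveILPExhaustive()], [selectFeatures()]
#' @export
setClass("LPFSSolution",
    representation(x = "numeric", y = "numeric", objective = "numeric",
                   selected = "integer", nCorrect = "integer",
                   nWrong = "integer", accuracy = "numeric",
                   status = "character", featureIds = "character",
                   lambda = "numeric", delta = "numeric",
                   solver = "character"))

setValidity("LPFSSolution", function(object) {
    msg <- character()
    if (!object@status %in%
        c("optimal", "infeasible", "unbounded", "numeric_failure"))
        msg <- c(msg, "unknown solver status")
    if (object@status == "optimal") {
        if (any(object@x < -1e-7) || any(object@y < -1e-7))
            msg <- c(msg, "x and y must be nonnegative at an optimum")
        if (object@nCorrect + object@nWrong != length(object@y))
            msg <- c(msg, "nCorrect + nWrong must equal the constraint count")
    }
    if (length(msg)) msg else TRUE
})

#' LPFSPath: solutions along a lambda grid and the chosen trade-off
#'
#' @slot summary data.frame, one row per grid point: `lambda`, `objective`,
#'   `nSelected`, `errorAccuracy` (from the tolerable errors),
#'   `posthocAccuracy` (binary re-use of the selected set in a plain
#'   leave-one-out nearest-centroid run; `NA` for empty selections), `status`.
#' @slot solutions list of [LPFSSolution-class] objects, one per grid point.
#' @slot chosen integer index into the grid of the selected lambda.
#' @slot validation `"loo"` or `"resubstitution"`.
#'
#' @seealso [lambdaPath()]
#' @export
setClass("LPFSPath",
    representation(summary = "data.frame", solutions = "list",
                   chosen = "integer", validation = "character"))

setValidity("LPFSPath", function(object) {
    msg <- character()
    if (nrow(object@summary) != length(object@solutions))
        msg <- c(msg, "summary and solutions must have equal length")
    if (length(object@chosen) != 1L || object@chosen < 1L ||
        object@chosen > length(object@solutions))
        msg <- c(msg, "chosen must index a grid point")
    if (length(msg)) msg else TRUE
})

#' SelectionResult: a named set of selected features from one method run
#'
#' @slot method character, e.g. `"lpfs"`, `"t"`, `"fc"`, `"svm-rfe"`.
#' @slot label character, free-text run label (e.g. the experiment name).
#' @slot selected character vector of selected feature ids.
#' @slot scores named numeric vector of per-feature scores (may be empty).
#' @slot accuracy numeric, post-hoc leave-one-out accuracy (`NA` if unknown).
#' @slot parameters list of parameters the run used.
#'
#' @seealso [SelectionResult()], [controlFilter()], [overlapVenn()]
#' @export
setClass("SelectionResult",
    representation(method = "character", label = "character",
                   selected = "character", scores = "numeric",
                   accuracy = "numeric", parameters = "list"))

setValidity("SelectionResult", function(object) {
    msg <- character()
    if (length(object@method) != 1L) msg <- c(msg, "method must be length 1")
    if (length(object@label) != 1L) msg <- c(msg, "label must be length 1")
    if (anyDuplicated(object@selected))
        msg <- c(msg, "selected feature ids must be unique")
    if (length(msg)) msg else TRUE
})
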