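#' @name LPFS-accessors
#' @title Accessor generics for LPFS classes
#'
#' @description Small accessor layer so user code never touches slots:
#' `profileValues()` returns the samples-by-features intensity matrix,
#' `featureIds()` / `sampleIds()` the identifier axes, `ppm()` the
#' chemical-shift annotation (or `NULL`), `caseMatrix()` / `controlMatrix()`
#' the two group matrices, `lpfsScores()` / `tolerableErrors()` the solution
#' variables, `selectedFeatures()` the selected feature ids, and
#' `selectionAccuracy()` the accuracy attached to a result.
#'
#' @param x an LPFS object.
#' @param ... passed to methods.
#' @return See the individual method descriptions.
#'
#' @examples
#' sim <- syntheticProfiles(nFeatures = 10, m1 = 2, m2 = 2, seed = 1)
#' dim(caseMatrix(sim$dataset))
#' head(featureIds(sim$dataset))
NULL

#' @rdname LPFS-accessors
#' @export
setGeneric("profileValues", function(x, ...) standardGeneric("profileValues"))

#' @rdname LPFS-accessors
#' @export
setGeneric("featureIds", function(x, ...) standardGeneric("featureIds"))

#' @rdname LPFS-accessors
#' @export
setGeneric("sampleIds", function(x, ...) standardGeneric("sampleIds"))

#' @rdname LPFS-accessors
#' @export
setGeneric("ppm", function(x, ...) standardGeneric("ppm"))

#' @rdname LPFS-accessors
#' @export
setGeneric("caseMatrix", function(x, ...) standardGeneric("caseMatrix"))

#' @rdname LPFS-accessors
#' @export
setGeneric("controlMatrix", function(x, ...) standardGeneric("controlMatrix"))

#' @rdname LPFS-accessors
#' @export
setGeneric("lpfsScores", function(x, ...) standardGeneric("lpfsScores"))

#' @rdname LPFS-accessors
#' @export
setGeneric("tolerableErrors", function(x, ...)
    standardGeneric("tolerableErrors"))

#' @rdname LPFS-accessors
#' @export
setGeneric("selectedFeatures", function(x, ...)
    standardGeneric("selectedFeatures"))

#' @rdname LPFS-accessors
#' @export
setGeneric("selectionAccuracy", function(x, ...)
    standardGeneric("selectionAccuracy"))
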