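#' Construct a SelectionResult
#'
#' @param method method name (`"lpfs"`, `"t"`, `"fc"`, `"logfc"`,
#'   `"svm-rfe"`, or any external method).
#' @param selected character vector of selected feature ids.
#' @param label free-text run label.
#' @param scores optional named numeric scores.
#' @param accuracy optional post-hoc leave-one-out accuracy.
#' @param parameters optional list of run parameters.
#' @return A [SelectionResult-class].
#' @export
SelectionResult <- function(method, selected, label = method,
                            scores = numeric(0), accuracy = NA_real_,
                            parameters = list()) {
    new("SelectionResult", method = method, label = label,
        selected = as.character(selected), scores = scores,
        accuracy = accuracy, parameters = parameters)
}

#' @rdname LPFS-accessors
#' @export
setMethod("selectedFeatures", "SelectionResult", function(x) x@selected)

#' @rdname LPFS-accessors
#' @export
setMethod("selectionAccuracy", "SelectionResult", function(x) x@accuracy)

#' Volcano-style per-feature summary
#'
#' For log-scale data, the difference of group means (log fold change) and
#' the pooled standard deviation per feature — the two axes on which good
#' biomarkers separate: large absolute mean difference, small sd.
#'
#' @param ds a [GroupedDataset-class] on the log scale.
#' @return data.frame with `featureId`, `ppm`, `meanDiff`, `pooledSd`.
#' @export
volcanoTable <- function(ds) {
    data.frame(featureId = ds@featureIds,
               ppm = if (length(ds@ppm)) ds@ppm else NA_real_,
               meanDiff = unname(colMeans(ds@caseMatrix) -
                                 colMeans(ds@controlMatrix)),
               pooledSd = unname(.pooledSd(ds@caseMatrix, ds@controlMatrix)),
               row.names = NULL)
}

.asFeatureSet <- function(x) {
    if (is(x, "SelectionResult")) x@selected else as.character(x)
}

#' Venn region counts and Jaccard table for 2-4 selections
#'
#' @param results list of 2 to 4 [SelectionResult-class] objects (or plain
#'   character vectors of feature ids), optionally named.
#' @return List with `regions` (named counts, one per membership pattern,
#'   e.g. `"A&B"`), `union` (size of the union) and `jaccard` (pairwise
#'   Jaccard similarity matrix).  More than 4 sets is an error; use
#'   [jaccardMatrix()] for larger comparisons.
#' @export
overlapVenn <- function(results) {
    k <- length(results)
    if (k < 2L || k > 4L)
        stop("overlapVenn supports 2-4 sets (got ", k, "); ",
             "use jaccardMatrix() for larger comparisons")
    sets <- lapply(results, .asFeatureSet)
    nm <- names(results)
    if (is.null(nm) || any(!nzchar(nm))) nm <- LETTERS[seq_len(k)]
    universe <- unique(unlist(sets))
    member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
    if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
    patterns <- apply(member, 1L, function(row)
        paste(nm[row], collapse = "&"))
    regionNames <- unlist(lapply(seq_len(k), function(r)
        apply(combn(nm, r), 2L, paste, collapse = "&")))
    regions <- setNames(integer(length(regionNames)), regionNames)
    tab <- table(patterns)
    regions[names(tab)] <- as.integer(tab)
    list(regions = regions, union = length(universe),
         jaccard = jaccardMatrix(setNames(sets, nm)))
}

#' Pairwise Jaccard similarity of feature selections
#'
#' @param results list of [SelectionResult-class] objects or character
#'   vectors.
#' @return Symmetric matrix of Jaccard indices (empty-vs-empty counts 1).
#' @export
jaccardMatrix <- function(results) {
    sets <- lapply(results, .asFeatureSet)
    k <- length(sets)
    nm <- names(sets)
    if (is.null(nm)) nm <- paste0("set", seq_len(k))
    J <- matrix(1, k, k, dimnames = list(nm, nm))
    for (i in seq_len(k)) for (j in seq_len(k)) {
        u <- length(union(sets[[i]], sets[[j]]))
        J[i, j] <- if (u == 0L) 1 else
            length(intersect(sets[[i]], sets[[j]])) / u
    }
    J
}

#' Remove sham-attributable features from a treatment selection
#'
#' The control-experiment filter: features also selected in a sham or
#' temporal-drift run are excluded from the treatment result, since they
#' reflect change that happens without treatment.  Implemented as plain set
#' difference with provenance of the removals recorded in
#' `parameters$removed`.  Idempotent.
#'
#' @param treatment,sham [SelectionResult-class] objects on a shared
#'   feature axis.
#' @return The filtered treatment [SelectionResult-class]; a warning is
#'   emitted when nothing survives.
#' @export
controlFilter <- function(treatment, sham) {
    removed <- intersect(treatment@selected, sham@selected)
    kept <- setdiff(treatment@selected, sham@selected)
    if (length(kept) == 0L && length(treatment@selected) > 0L)
        warning("control filter removed every selected feature")
    out <- treatment
    out@selected <- kept
    out@parameters$removed <- union(out@parameters$removed, removed)
    out@parameters$shamLabel <- sham@label
    out
}

#' Precision, recall and exact match of a selection against ground truth
#'
#' Empty selections get precision 0 (with `emptySelection = TRUE`) rather
#' than NaN, so aggregate tables stay numeric.
#'
#' @param selected selected feature set (ids or indices).
#' @param planted true planted set on the same axis.
#' @return List with `precision`, `recall`, `exact` and `emptySelection`.
#' @export
recoveryMetrics <- function(selected, planted) {
    selected <- unique(as.character(selected))
    planted <- unique(as.character(planted))
    hits <- length(intersect(selected, planted))
    empty <- length(selected) == 0L
    list(precision = if (empty) 0 else hits / length(selected),
         recall = if (length(planted) == 0L) {
             if (empty) 1 else 0
         } else hits / length(planted),
         exact = setequal(selected, planted),
         emptySelection = empty)
}
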