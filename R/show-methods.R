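#' @describeIn GroupedDataset Compact display.
#' @param object a `GroupedDataset`.
#' @export
setMethod("show", "GroupedDataset", function(object) {
    cat("GroupedDataset:", nrow(object@caseMatrix), "case /",
        nrow(object@controlMatrix), "control samples,",
        ncol(object@caseMatrix), "features",
        if (length(object@ppm)) "(ppm-annotated)" else "", "\n")
})

#' @describeIn LPFSProblem Compact display.
#' @param object an `LPFSProblem`.
#' @export
setMethod("show", "LPFSProblem", function(object) {
    cat("LPFSProblem (", object@validation, "): ", nrow(object@G),
        " constraints x ", ncol(object@G), " features; delta = ",
        object@delta, ", lambda = ", format(object@lambda),
        ", xUpper = ", object@xUpper, "\n", sep = "")
})

#' @describeIn LPFSSolution Compact display.
#' @param object an `LPFSSolution`.
#' @export
setMethod("show", "LPFSSolution", function(object) {
    cat("LPFSSolution [", object@status, "] objective = ",
        format(object@objective), "; ", length(object@selected),
        " feature(s) selected; error-variable accuracy = ",
        format(object@accuracy), "\n", sep = "")
    if (length(object@selected)) {
        ids <- if (length(object@featureIds))
            object@featureIds[object@selected] else object@selected
        cat("  top scores:",
            paste0(head(ids, 5L), "=",
                   signif(object@x[head(object@selected, 5L)], 3L),
                   collapse = ", "), "\n")
    }
})

#' @describeIn LPFSPath Compact display.
#' @param object an `LPFSPath`.
#' @export
setMethod("show", "LPFSPath", function(object) {
    s <- object@summary[object@chosen, ]
    cat("LPFSPath (", object@validation, "): ", nrow(object@summary),
        " lambdas; chosen lambda = ", format(s$lambda), " with ",
        s$nSelected, " feature(s), post-hoc LOO accuracy = ",
        format(s$posthocAccuracy), "\n", sep = "")
})

#' @describeIn SelectionResult Compact display.
#' @param object a `SelectionResult`.
#' @export
setMethod("show", "SelectionResult", function(object) {
    cat("SelectionResult [", object@method, "/", object@label, "]: ",
        length(object@selected), " feature(s)",
        if (!is.na(object@accuracy))
            paste0(", LOO accuracy ", format(object@accuracy)),
        "\n", sep = "")
    if (length(object@selected))
        cat(" ", paste(head(object@selected, 10L), collapse = ", "),
            if (length(object@selected) > 10L) "...", "\n")
})

#' @describeIn CentroidModel Compact display.
#' @param object a `CentroidModel`.
#' @export
setMethod("show", "CentroidModel", function(object) {
    cat("CentroidModel over", length(object@muCase), "features\n")
})
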