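#' Construct a ProfileMatrix from a samples-by-features matrix
#'
#' @param values numeric matrix, samples in rows, features in columns.
#'   All entries must be finite.
#' @param sampleIds,featureIds unique identifier vectors; default to the
#'   dimnames of `values`.
#' @param ppm optional numeric chemical-shift annotation, one value per
#'   feature.
#' @param checkRaw if `TRUE`, reject negative entries (raw intensities are
#'   nonnegative by nature); leave `FALSE` for transformed data.
#' @return A [ProfileMatrix-class] object.
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("s1", "s2"), c("f1", "f2", "f3")))
#' pm <- ProfileMatrix(m, ppm = c(1.0, 2.0, 3.0))
#' profileValues(pm)
#' @export
ProfileMatrix <- function(values, sampleIds = rownames(values),
                          featureIds = colnames(values), ppm = NULL,
                          checkRaw = FALSE) {
    values <- as.matrix(values)
    if (!is.numeric(values))
        stop("'values' must be a numeric matrix")
    if (is.null(sampleIds) || is.null(featureIds))
        stop("sample and feature ids are required (dimnames or arguments)")
    if (checkRaw && any(values < 0, na.rm = TRUE))
        stop("raw intensities must be nonnegative")
    assay <- t(values)                       # features-in-rows storage
    rownames(assay) <- as.character(featureIds)
    colnames(assay) <- as.character(sampleIds)
    rd <- if (is.null(ppm)) DataFrame(row.names = rownames(assay))
          else {
              if (length(ppm) != nrow(assay))
                  stop("'ppm' must have one value per feature")
              DataFrame(ppm = as.numeric(ppm), row.names = rownames(assay))
          }
    se <- SummarizedExperiment(assays = list(intensity = assay), rowData = rd)
    new("ProfileMatrix", se)
}

#' @describeIn ProfileMatrix Samples-by-features intensity matrix.
#' @param x a `ProfileMatrix`.
#' @export
setMethod("profileValues", "ProfileMatrix", function(x) t(assay(x, "intensity")))

#' @rdname LPFS-accessors
#' @export
setMethod("featureIds", "ProfileMatrix", function(x) rownames(x))

#' @rdname LPFS-accessors
#' @export
setMethod("sampleIds", "ProfileMatrix", function(x) colnames(x))

#' @rdname LPFS-accessors
#' @export
setMethod("ppm", "ProfileMatrix", function(x) {
    p <- rowData(x)$ppm
    if (is.null(p)) NULL else as.numeric(p)
})

#' @rdname LPFS-accessors
#' @export
setMethod("featureIds", "GroupedDataset", function(x) x@featureIds)

#' @rdname LPFS-accessors
#' @export
setMethod("ppm", "GroupedDataset", function(x)
    if (length(x@ppm)) x@ppm else NULL)

#' @rdname LPFS-accessors
#' @export
setMethod("caseMatrix", "GroupedDataset", function(x) x@caseMatrix)

#' @rdname LPFS-accessors
#' @export
setMethod("controlMatrix", "GroupedDataset", function(x) x@controlMatrix)

.delimForPath <- function(path, sep = NULL) {
    if (!is.null(sep)) return(sep)
    if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a profile table from CSV or TSV
#'
#' Expects one header row and one id column; the body must be fully numeric
#' and nonnegative (raw intensities).  The delimiter is inferred from the
#' file extension (`.tsv`/`.txt` tab, otherwise comma) and can be overridden.
#'
#' @param path file path.
#' @param orientation `"samples_in_rows"` (default) or `"features_in_rows"`;
#'   the result is always normalized to samples-in-rows.
#' @param sep optional explicit field delimiter.
#' @param ppm optional numeric ppm annotation attached to the features.
#' @return A [ProfileMatrix-class].
#' @export
readProfileTable <- function(path,
                             orientation = c("samples_in_rows",
                                             "features_in_rows"),
                             sep = NULL, ppm = NULL) {
    orientation <- match.arg(orientation)
    sep <- .delimForPath(path, sep)
    df <- read.table(path, sep = sep, header = TRUE, row.names = 1L,
                     check.names = FALSE, colClasses = NA,
                     stringsAsFactors = FALSE, comment.char = "")
    if (anyDuplicated(rownames(df)))
        stop("duplicate ids in first column of ", path)
    if (anyDuplicated(colnames(df)))
        stop("duplicate ids in header of ", path)
    bad <- which(!vapply(df, is.numeric, logical(1)))
    if (length(bad)) {
        col <- colnames(df)[bad[1L]]
        row <- rownames(df)[which(is.na(suppressWarnings(
            as.numeric(df[[bad[1L]]]))))[1L]]
        stop("non-numeric cell in column '", col, "'",
             if (!is.na(row)) paste0(", row '", row, "'"))
    }
    m <- as.matrix(df)
    if (anyNA(m)) {
        idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
        stop("missing value at row '", rownames(m)[idx[1L]],
             "', column '", colnames(m)[idx[2L]], "'")
    }
    if (orientation == "features_in_rows") m <- t(m)
    if (any(m < 0)) {
        idx <- which(m < 0, arr.ind = TRUE)[1L, ]
        stop("negative intensity at sample '", rownames(m)[idx[1L]],
             "', feature '", colnames(m)[idx[2L]], "'")
    }
    ProfileMatrix(m, ppm = ppm, checkRaw = TRUE)
}

#' Write a ProfileMatrix to CSV or TSV
#'
#' Values are written with full double precision so that a read/write
#' round trip reproduces the matrix.
#'
#' @param pm a [ProfileMatrix-class].
#' @param path output file path.
#' @param orientation layout of the written table.
#' @param sep optional delimiter override (extension-inferred by default).
#' @return `path`, invisibly.
#' @export
writeProfileTable <- function(pm, path,
                              orientation = c("samples_in_rows",
                                              "features_in_rows"),
                              sep = NULL) {
    orientation <- match.arg(orientation)
    sep <- .delimForPath(path, sep)
    m <- profileValues(pm)
    if (orientation == "features_in_rows") m <- t(m)
    out <- cbind(id = rownames(m),
                 as.data.frame(format(m, digits = 17, trim = TRUE,
                                      scientific = NA)))
    colnames(out)[1L] <- ""
    write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a sample-label table
#'
#' Two columns, `sample_id` and `group`, with group values `case` or
#' `control`.
#'
#' @param path file path (CSV/TSV, delimiter inferred from extension).
#' @param sep optional delimiter override.
#' @return Named character vector mapping sample id to group.
#' @export
readSampleLabels <- function(path, sep = NULL) {
    sep <- .delimForPath(path, sep)
    df <- read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE)
    need <- c("sample_id", "group")
    if (!all(need %in% colnames(df)))
        stop("label table must have columns 'sample_id' and 'group'")
    bad <- setdiff(unique(df$group), c("case", "control"))
    if (length(bad))
        stop("unknown group label(s): ", paste(bad, collapse = ", "))
    setNames(df$group, df$sample_id)
}

#' Read a feature-annotation table
#'
#' Columns `feature_id`, `ppm` and optionally `name`.
#'
#' @param path file path.
#' @param sep optional delimiter override.
#' @return data.frame with the annotation.
#' @export
readFeatureAnnotation <- function(path, sep = NULL) {
    sep <- .delimForPath(path, sep)
    df <- read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE)
    if (!all(c("feature_id", "ppm") %in% colnames(df)))
        stop("annotation table must have columns 'feature_id' and 'ppm'")
    df
}

#' Attach a ppm (and name) annotation to a ProfileMatrix
#'
#' @param pm a [ProfileMatrix-class].
#' @param annotation data.frame as returned by [readFeatureAnnotation()].
#' @return The annotated `ProfileMatrix`.
#' @export
addFeatureAnnotation <- function(pm, annotation) {
    idx <- match(featureIds(pm), annotation$feature_id)
    if (anyNA(idx))
        stop("annotation missing for feature(s): ",
             paste(head(featureIds(pm)[is.na(idx)], 5L), collapse = ", "))
    rowData(pm)$ppm <- as.numeric(annotation$ppm[idx])
    if (!is.null(annotation$name))
        rowData(pm)$name <- as.character(annotation$name[idx])
    validObject(pm)
    pm
}

#' Drop all features inside a chemical-shift window
#'
#' Removes every feature whose ppm lies in the closed interval
#' `[lo, hi]` — the standard treatment of the residual-water region
#' (4.6–5.1 ppm) in binned plasma 1H NMR spectra.  Window exclusion must
#' precede constant-sum normalization: the excluded bins would otherwise
#' still contribute to each sample's total.
#'
#' @param pm a [ProfileMatrix-class] with ppm annotation.
#' @param lo,hi window bounds, `lo < hi`; boundary bins are excluded too.
#' @return The `ProfileMatrix` without the windowed features, order of the
#'   remaining features preserved.
#' @export
excludePpmWindow <- function(pm, lo = 4.6, hi = 5.1) {
    p <- ppm(pm)
    if (is.null(p))
        stop("ProfileMatrix carries no ppm annotation")
    if (!(lo < hi)) stop("'lo' must be smaller than 'hi'")
    keep <- !(p >= lo & p <= hi)
    if (!any(keep))
        stop("no features remain after excluding [", lo, ", ", hi, "] ppm")
    pm[keep, ]
}

#' Constant-sum normalization of each sample
#'
#' Scales every sample so its intensities sum to `total` — the usual way to
#' remove overall-concentration differences between binned NMR spectra.
#' Idempotent: re-applying changes nothing beyond floating-point tolerance.
#'
#' @param pm a [ProfileMatrix-class] with positive row sums.
#' @param total target sum per sample (default 1, so profiles read as
#'   fractions of total signal).
#' @return The normalized `ProfileMatrix`.
#' @export
normalizeConstantSum <- function(pm, total = 1) {
    if (!is.finite(total) || total <= 0)
        stop("'total' must be positive")
    m <- profileValues(pm)
    s <- rowSums(m)
    if (any(s <= 0))
        stop("sample(s) with non-positive total intensity: ",
             paste(head(rownames(m)[s <= 0], 5L), collapse = ", "))
    .replaceValues(pm, m * (total / s))
}

#' Elementwise log transform
#'
#' @param pm a [ProfileMatrix-class].
#' @param base logarithm base (default 2, the fold-change convention).
#' @param pseudocount nonnegative constant added before taking logs.
#' @return The transformed `ProfileMatrix`.
#' @export
logTransform <- function(pm, base = 2, pseudocount = 0) {
    if (pseudocount < 0) stop("'pseudocount' must be nonnegative")
    m <- profileValues(pm) + pseudocount
    if (any(m <= 0))
        stop("log of non-positive value; supply a positive 'pseudocount'")
    .replaceValues(pm, log(m, base = base))
}

#' Pareto scaling
#'
#' Centers each feature and divides by the square root of its sample
#' standard deviation (ddof 1), the usual compromise between no scaling and
#' unit-variance scaling for spectral data: the variance of a scaled column
#' equals the original column's standard deviation.  Constant features are
#' centered to all-zero without division.
#'
#' @param pm a [ProfileMatrix-class] with at least two samples.
#' @return The scaled `ProfileMatrix`.
#' @export
paretoScale <- function(pm) {
    m <- profileValues(pm)
    if (nrow(m) < 2L)
        stop("Pareto scaling needs >= 2 samples")
    mu <- colMeans(m)
    s <- apply(m, 2L, sd)
    ctr <- sweep(m, 2L, mu, "-")
    pos <- s > 0
    ctr[, pos] <- sweep(ctr[, pos, drop = FALSE], 2L, sqrt(s[pos]), "/")
    .replaceValues(pm, ctr)
}

.replaceValues <- function(pm, values) {
    assay(pm, "intensity", withDimnames = FALSE) <- t(values)
    validObject(pm)
    pm
}

#' Split a ProfileMatrix into case and control groups
#'
#' @param pm a [ProfileMatrix-class].
#' @param labels named character vector (or data.frame with columns
#'   `sample_id`, `group`) mapping every sample to `"case"` or `"control"`.
#' @return A [GroupedDataset-class] with the original feature axis.
#' @export
splitGroups <- function(pm, labels) {
    if (is.data.frame(labels))
        labels <- setNames(labels$group, labels$sample_id)
    ids <- sampleIds(pm)
    missing <- setdiff(ids, names(labels))
    if (length(missing))
        stop("unlabeled sample(s): ", paste(head(missing, 5L), collapse = ", "))
    grp <- labels[ids]
    bad <- setdiff(unique(grp), c("case", "control"))
    if (length(bad))
        stop("labels must be 'case' or 'control'; found: ",
             paste(bad, collapse = ", "))
    m <- profileValues(pm)
    Tm <- m[grp == "case", , drop = FALSE]
    Fm <- m[grp == "control", , drop = FALSE]
    if (nrow(Tm) < 2L || nrow(Fm) < 2L)
        stop("each group needs >= 2 samples (got ", nrow(Tm), " case, ",
             nrow(Fm), " control)")
    p <- ppm(pm)
    new("GroupedDataset", caseMatrix = Tm, controlMatrix = Fm,
        featureIds = featureIds(pm),
        ppm = if (is.null(p)) numeric(0) else p)
}

#' Construct a GroupedDataset from two matrices
#'
#' @param caseMatrix,controlMatrix samples-by-features numeric matrices on a
#'   shared feature axis.
#' @param featureIds feature identifiers (defaults to the case matrix's
#'   column names, or `f1..fn`).
#' @param ppm optional chemical-shift annotation.
#' @return A [GroupedDataset-class].
#' @export
GroupedDataset <- function(caseMatrix, controlMatrix,
                           featureIds = colnames(caseMatrix), ppm = NULL) {
    caseMatrix <- as.matrix(caseMatrix)
    controlMatrix <- as.matrix(controlMatrix)
    if (is.null(featureIds))
        featureIds <- paste0("f", seq_len(ncol(caseMatrix)))
    new("GroupedDataset", caseMatrix = caseMatrix,
        controlMatrix = controlMatrix,
        featureIds = as.character(featureIds),
        ppm = if (is.null(ppm)) numeric(0) else as.numeric(ppm))
}
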