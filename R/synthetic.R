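#' Seeded two-group synthetic profiles with planted biomarkers
#'
#' Emulates the structure of a binned plasma 1H NMR study: two groups of
#' ten samples over 400 chemical-shift bins, strictly nonnegative
#' intensities, heterogeneous per-feature noise, and a small planted subset
#' of features whose group means differ.  Feature `i` draws a baseline
#' `b_i ~ U(baselineRange)` and a noise level `sigma_i ~ U(noiseSdRange)`;
#' control samples are `Normal(b_i, sigma_i)` truncated at zero, and case
#' samples add `shift * sigma_i * direction` to the mean of each planted
#' feature.  Shifts are expressed in units of the feature's own noise sd so
#' that effect sizes are comparable across features.
#'
#' The ppm axis mimics a 0.01-ppm binning of the 0.4–4.4 ppm region.
#' Identical spec and seed regenerate bit-identical data; the caller's RNG
#' state is left untouched.
#'
#' @param nFeatures number of features (default 400).
#' @param m1,m2 case and control group sizes (default 10 and 10).
#' @param planted integer indices of planted features (`NULL` for none), or
#'   a data.frame with columns `index`, `shift`, `direction` for full
#'   control.
#' @param shift effect size in noise-sd units (recycled over `planted`).
#' @param direction +1 or -1 per planted feature (recycled; default +1).
#' @param noiseSdRange,baselineRange uniform draw ranges for the
#'   per-feature noise sd and baseline intensity; the defaults give
#'   coefficients of variation of roughly 2–20%, typical of binned plasma
#'   spectra.
#' @param seed integer seed.
#' @param distribution `"normal"` (zero-truncated, default: shifts stay
#'   interpretable in sd units) or `"lognormal"` (multiplicative noise, for
#'   realism checks).
#' @return List with `dataset` (a [GroupedDataset-class]) and `truth`
#'   (list: `planted` indices, `shift`, `direction`, `baseline`, `noiseSd`,
#'   per-group true means `meanCase`/`meanControl`, and the `seed`).
#' @export
syntheticProfiles <- function(nFeatures = 400L, m1 = 10L, m2 = 10L,
                              planted = NULL, shift = 4,
                              direction = 1,
                              noiseSdRange = c(2, 10),
                              baselineRange = c(50, 150),
                              seed = 1L,
                              distribution = c("normal", "lognormal")) {
    distribution <- match.arg(distribution)
    if (m1 < 2L || m2 < 2L) stop("'m1' and 'm2' must be >= 2")
    if (baselineRange[1L] <= 0) stop("baselines must be positive")
    if (is.data.frame(planted)) {
        idx <- as.integer(planted$index)
        shift <- planted$shift
        direction <- planted$direction
    } else idx <- as.integer(planted)
    if (anyDuplicated(idx) || any(idx < 1L | idx > nFeatures))
        stop("planted indices must be distinct and within 1..nFeatures")
    shift <- rep_len(shift, length(idx))
    direction <- rep_len(direction, length(idx))
    if (any(!direction %in% c(-1, 1)))
        stop("'direction' entries must be +1 or -1")

    old <- .saveRNG(); on.exit(.restoreRNG(old))
    set.seed(seed)
    b <- runif(nFeatures, baselineRange[1L], baselineRange[2L])
    sigma <- runif(nFeatures, noiseSdRange[1L], noiseSdRange[2L])
    muCase <- b
    muCase[idx] <- b[idx] + shift * sigma[idx] * direction
    draw <- function(m, mu) {
        raw <- matrix(rnorm(m * nFeatures), m, nFeatures)
        if (distribution == "normal")
            pmax(sweep(sweep(raw, 2L, sigma, "*"), 2L, mu, "+"), 0)
        else
            exp(sweep(sweep(raw, 2L, sigma / mu, "*"), 2L, log(mu), "+"))
    }
    Tm <- draw(m1, muCase)
    Fm <- draw(m2, b)
    fid <- sprintf("bin%04d", seq_len(nFeatures))
    rownames(Tm) <- sprintf("case%02d", seq_len(m1))
    rownames(Fm) <- sprintf("ctrl%02d", seq_len(m2))
    colnames(Tm) <- colnames(Fm) <- fid
    ppmAxis <- seq(0.405, by = 0.01, length.out = nFeatures)
    list(dataset = GroupedDataset(Tm, Fm, fid, ppm = ppmAxis),
         truth = list(planted = idx, shift = shift, direction = direction,
                      baseline = b, noiseSd = sigma,
                      meanCase = muCase, meanControl = b,
                      seed = seed, distribution = distribution))
}

#' Null synthetic profiles (no planted biomarkers)
#'
#' Convenience wrapper of [syntheticProfiles()] with an empty planted set:
#' case and control are exchangeable, the calibration dataset for
#' false-positive behavior.
#'
#' @inheritParams syntheticProfiles
#' @return As [syntheticProfiles()]; `truth$planted` is empty.
#' @export
syntheticNull <- function(nFeatures = 400L, m1 = 10L, m2 = 10L,
                          noiseSdRange = c(2, 10),
                          baselineRange = c(50, 150), seed = 1L,
                          distribution = c("normal", "lognormal")) {
    syntheticProfiles(nFeatures = nFeatures, m1 = m1, m2 = m2,
                      planted = NULL, noiseSdRange = noiseSdRange,
                      baselineRange = baselineRange, seed = seed,
                      distribution = distribution)
}

#' Convert a GroupedDataset back to a labeled ProfileMatrix
#'
#' Inverse of [splitGroups()]; useful for writing simulated data to disk in
#' the same table conventions as real input.
#'
#' @param ds a [GroupedDataset-class].
#' @return List with `profile` (a [ProfileMatrix-class]) and `labels`
#'   (named character vector).
#' @export
groupedToProfile <- function(ds) {
    m <- rbind(ds@caseMatrix, ds@controlMatrix)
    if (is.null(rownames(m)))
        rownames(m) <- c(sprintf("case%02d", seq_len(nrow(ds@caseMatrix))),
                         sprintf("ctrl%02d", seq_len(nrow(ds@controlMatrix))))
    colnames(m) <- ds@featureIds
    labels <- setNames(rep(c("case", "control"),
                           c(nrow(ds@caseMatrix), nrow(ds@controlMatrix))),
                       rownames(m))
    list(profile = ProfileMatrix(m, ppm = ppm(ds)), labels = labels)
}

.saveRNG <- function() {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv())
    else NULL
}

.restoreRNG <- function(old) {
    if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
}
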