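#' Solve the LP relaxation of an LPFS problem
#'
#' Minimizes `sum(x) + lambda * sum(y)` subject to
#' `G %*% x + y >= delta`, `0 <= x <= xUpper`, `y >= 0` with a dense
#' bounded-variable primal simplex (the constraint system provides the
#' feasible start `x = 0, y = delta`, so no phase-1 is required).  The
#' fractional scores `x` are the LPFS scores; their strictly positive
#' support is the selected feature set.
#'
#' A constraint counts as correctly classified when its tolerable error is
#' below `tolCorrect` (a small multiple of `delta`, on the scale of solver
#' feasibility tolerances).
#'
#' @param problem an [LPFSProblem-class].
#' @param selectTol scores above this are considered selected (numerical
#'   zero threshold, not a magnitude cutoff).
#' @param tolCorrect tolerable-error threshold for counting a constraint
#'   as satisfied.
#' @return An [LPFSSolution-class].  Non-optimal solver terminations are
#'   surfaced in the `status` slot, never silently.
#' @examples
#' G <- rbind(c(2, -1), c(2, 0), c(-1, 2), c(0, 2))
#' pr <- new("LPFSProblem", G = G, delta = 1, lambda = 10, xUpper = Inf,
#'           rowScale = rep(1, 4), validation = "resubstitution",
#'           featureIds = c("f1", "f2"),
#'           sampleInfo = data.frame(group = rep("case", 4), index = 1:4))
#' sol <- solveLP(pr)
#' sol@objective   # 2: both features active, no tolerable error
#' @export
solveLP <- function(problem, selectTol = 1e-8,
                    tolCorrect = 1e-6 * problem@delta) {
    res <- .lpfsSimplex(problem@G, problem@delta, problem@lambda,
                        problem@xUpper)
    .asSolution(res, problem, selectTol, tolCorrect,
                solver = "bounded-variable primal simplex (dense)")
}

.asSolution <- function(res, problem, selectTol, tolCorrect, solver) {
    L <- nrow(problem@G)
    if (res$status != "optimal") {
        return(new("LPFSSolution", x = res$x, y = res$y,
                   objective = res$objective, selected = integer(0),
                   nCorrect = 0L, nWrong = L, accuracy = NA_real_,
                   status = res$status, featureIds = problem@featureIds,
                   lambda = problem@lambda, delta = problem@delta,
                   solver = solver))
    }
    sel <- .orderedSupport(res$x, selectTol)
    nc <- sum(res$y <= tolCorrect)
    new("LPFSSolution", x = res$x, y = res$y, objective = res$objective,
        selected = sel, nCorrect = as.integer(nc),
        nWrong = as.integer(L - nc), accuracy = nc / L,
        status = "optimal", featureIds = problem@featureIds,
        lambda = problem@lambda, delta = problem@delta, solver = solver)
}

.orderedSupport <- function(x, tol) {
    idx <- which(x > tol)
    idx[order(-x[idx], idx)]
}

#' Exact exhaustive solve of the integer LPFS problem
#'
#' Enumerates all `2^n` binary selections.  For a fixed binary `x` the
#' optimal tolerable errors are available in closed form,
#' `y_l = max(0, delta - G[l, ] %*% x)`, so each assignment is scored
#' directly and the global integer optimum is exact.  Serves as the oracle
#' the LP relaxation is tested against; refuses more than `maxN` features.
#'
#' @param problem an [LPFSProblem-class] with `ncol(G) <= maxN`.
#' @param maxN enumeration cap (default 20).
#' @param selectTol,tolCorrect as in [solveLP()].
#' @return An [LPFSSolution-class] with binary scores.  Among optima of
#'   equal objective the lexicographically first assignment (in order of
#'   enumeration `0, 1, ..., 2^n - 1` over feature bitmasks) is returned.
#' @export
solveILPExhaustive <- function(problem, maxN = 20L, selectTol = 1e-8,
                               tolCorrect = 1e-6 * problem@delta) {
    n <- ncol(problem@G)
    if (n > maxN)
        stop("refusing exhaustive enumeration for n = ", n, " > maxN = ",
             maxN, " features")
    G <- problem@G; delta <- problem@delta; lambda <- problem@lambda
    total <- 2^n
    bestObj <- Inf; bestMask <- 0
    chunk <- 2^min(n, 14L)
    for (start in seq(0, total - 1, by = chunk)) {
        ids <- start + seq_len(min(chunk, total - start)) - 1
        X <- vapply(seq_len(n) - 1L,
                    function(b) ids %/% 2^b %% 2, numeric(length(ids)))
        if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
        Yslack <- delta - X %*% t(G)
        Yslack[Yslack < 0] <- 0
        obj <- rowSums(X) + lambda * rowSums(Yslack)
        i <- which.min(obj)
        if (obj[i] < bestObj - 1e-12) {
            bestObj <- obj[i]; bestMask <- ids[i]
        }
    }
    x <- as.numeric(bestMask %/% 2^(seq_len(n) - 1L) %% 2)
    y <- pmax(0, delta - as.vector(G %*% x))
    res <- list(status = "optimal", x = x, y = y,
                objective = sum(x) + lambda * sum(y))
    .asSolution(res, problem, selectTol, tolCorrect,
                solver = "exhaustive enumeration (closed-form errors)")
}

#' Selected feature set of a solution
#'
#' Indices whose score exceeds `tol` — the strictly-positive-support
#' reading of the LPFS score — ordered by decreasing score (ties by
#' index).
#'
#' @param sol an [LPFSSolution-class].
#' @param tol numerical zero threshold on the scores.
#' @return Integer index vector.
#' @export
selectFeatures <- function(sol, tol = 1e-8) {
    if (sol@status != "optimal")
        stop("solution status is '", sol@status, "', not optimal")
    .orderedSupport(sol@x, tol)
}

#' Accuracy implied by the tolerable-error variables
#'
#' `N1 = #{l : y_l <= tolCorrect}` constraints are counted correct;
#' accuracy is `N1 / L`.  This is the optimization-internal accuracy; the
#' headline accuracy of a selected set is [posthocLooAccuracy()].
#'
#' @param sol an [LPFSSolution-class].
#' @param tolCorrect nonnegative threshold under which an error counts as
#'   zero.
#' @return Accuracy in `[0, 1]`.
#' @export
accuracyFromErrors <- function(sol, tolCorrect = 1e-6 * sol@delta) {
    mean(sol@y <= tolCorrect)
}

#' Default lambda grid
#'
#' Log-spaced trade-off values spanning the empty-selection regime to the
#' fully separable regime on row-normalized problems.
#'
#' @param from,to grid end points.
#' @param length number of grid points.
#' @return Numeric vector.
#' @export
lambdaGrid <- function(from = 1e-2, to = 1e3, length = 25L) {
    10^seq(log10(from), log10(to), length.out = length)
}

#' Solve the LPFS problem along a lambda grid and choose the trade-off
#'
#' Solves the LP for every lambda on the grid and evaluates each selected
#' set with a plain leave-one-out nearest-centroid run
#' ([posthocLooAccuracy()]).  The chosen lambda maximizes that post-hoc
#' accuracy; ties are broken by fewest selected features, then by smallest
#' lambda.  Empty selections have no classifier and enter the choice with
#' accuracy `NA` (never chosen over any non-empty selection); solver
#' failures at single grid points are recorded in the summary, not fatal.
#'
#' @param ds a [GroupedDataset-class].
#' @param lambdas positive lambda grid (default [lambdaGrid()]).
#' @param delta positive margin.
#' @param validation `"loo"` (default) or `"resubstitution"` constraint
#'   structure.
#' @param rowNormalize,xUpper see [buildLooProblem()].
#' @param selectTol score support threshold.
#' @return An [LPFSPath-class].
#' @export
lambdaPath <- function(ds, lambdas = lambdaGrid(), delta = 1,
                       validation = c("loo", "resubstitution"),
                       rowNormalize = TRUE, xUpper = 1, selectTol = 1e-8) {
    validation <- match.arg(validation)
    if (!length(lambdas)) stop("'lambdas' must be non-empty")
    lambdas <- sort(as.numeric(lambdas))
    build <- if (validation == "loo") buildLooProblem else buildResubProblem
    problem <- build(ds, lambda = lambdas[1L], delta = delta,
                     rowNormalize = rowNormalize, xUpper = xUpper)
    solutions <- vector("list", length(lambdas))
    rows <- lapply(seq_along(lambdas), function(k) {
        problem@lambda <- lambdas[k]
        sol <- solveLP(problem, selectTol = selectTol)
        solutions[[k]] <<- sol
        nSel <- length(sol@selected)
        post <- if (sol@status == "optimal" && nSel > 0L)
            posthocLooAccuracy(ds, sol@selected) else NA_real_
        data.frame(lambda = lambdas[k], objective = sol@objective,
                   nSelected = nSel, errorAccuracy = sol@accuracy,
                   posthocAccuracy = post, status = sol@status)
    })
    summary <- do.call(rbind, rows)
    ok <- summary$status == "optimal"
    acc <- ifelse(ok & !is.na(summary$posthocAccuracy),
                  summary$posthocAccuracy, -Inf)
    ord <- order(-acc, summary$nSelected, summary$lambda)
    chosen <- ord[1L]
    if (all(acc == -Inf)) chosen <- which(ok)[1L]
    if (!length(chosen) || is.na(chosen))
        stop("no grid point solved to optimality")
    new("LPFSPath", summary = summary, solutions = solutions,
        chosen = as.integer(chosen), validation = validation)
}

#' @rdname LPFS-accessors
#' @export
setMethod("lpfsScores", "LPFSSolution", function(x) {
    s <- x@x
    if (length(x@featureIds)) names(s) <- x@featureIds
    s
})

#' @rdname LPFS-accessors
#' @export
setMethod("tolerableErrors", "LPFSSolution", function(x) x@y)

#' @rdname LPFS-accessors
#' @export
setMethod("selectedFeatures", "LPFSSolution", function(x) {
    if (length(x@featureIds)) x@featureIds[x@selected] else x@selected
})

#' @rdname LPFS-accessors
#' @export
setMethod("selectedFeatures", "LPFSPath", function(x)
    selectedFeatures(x@solutions[[x@chosen]]))

#' Chosen-lambda solution of a path
#'
#' @param path an [LPFSPath-class].
#' @return The [LPFSSolution-class] at the chosen lambda.
#' @export
chosenSolution <- function(path) path@solutions[[path@chosen]]

#' Chosen lambda of a path
#'
#' @param path an [LPFSPath-class].
#' @return The chosen lambda value.
#' @export
chosenLambda <- function(path) path@summary$lambda[path@chosen]

#' Write a JSON run report for a lambda path
#'
#' Records the grid, per-lambda objective/selection/accuracies, the chosen
#' lambda, and solver metadata — enough to reproduce or audit a run.
#'
#' @param path an [LPFSPath-class].
#' @param file output JSON path.
#' @param seed optional seed to record.
#' @param extra optional named list merged into the report.
#' @return `file`, invisibly.
#' @export
writeLPFSReport <- function(path, file, seed = NULL, extra = list()) {
    sol <- chosenSolution(path)
    report <- c(list(
        validation = path@validation,
        grid = path@summary,
        chosenLambda = chosenLambda(path),
        selected = selectedFeatures(path),
        scores = unname(sol@x[sol@selected]),
        solver = sol@solver,
        tolerances = list(selectTol = 1e-8, feasibility = 1e-9),
        seed = seed), extra)
    jsonlite::write_json(report, file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(file)
}
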