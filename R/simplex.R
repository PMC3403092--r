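# Dense bounded-variable primal simplex, specialized to the LPFS structure
#
#   min  sum(x) + lambda * sum(y)
#   s.t. G x + y >= delta,  0 <= x <= xUpper,  y >= 0
#
# With surplus variables s the constraints become [G, I, -I] (x, y, s)' = delta,
# and the y columns form an identity with nonnegative basic values y = delta:
# a feasible starting basis is available by construction, so no phase 1 is
# needed.  Dantzig pricing with a switch to Bland's rule guards against
# cycling; the ratio test breaks ties on the smallest row index, so the
# returned vertex is deterministic.
#
# Problem sizes here are small (L = m1 + m2 constraint rows, a few hundred
# feature columns), so a dense tableau updated by rank-1 pivots is both
# simple and fast.

.lpfsSimplex <- function(G, delta, lambda, xUpper = 1,
                         tol = 1e-9, pivTol = 1e-11, maxIter = 20000L,
                         blandAfter = 2000L) {
    L <- nrow(G); n <- ncol(G)
    N <- n + 2L * L
    Tab <- cbind(G, diag(L), -diag(L))
    cc <- c(rep(1, n), rep(lambda, L), rep(0, L))
    up <- c(rep(xUpper, n), rep(Inf, 2L * L))
    bas <- n + seq_len(L)
    xB <- rep(delta, L)
    isBasic <- logical(N); isBasic[bas] <- TRUE
    atUpper <- logical(N)

    it <- 0L
    repeat {
        it <- it + 1L
        if (it > maxIter)
            return(list(status = "numeric_failure", x = rep(NA_real_, n),
                        y = rep(NA_real_, L), objective = NA_real_,
                        iterations = it))
        d <- cc - as.vector(crossprod(cc[bas], Tab))
        d[bas] <- 0
        lowerCand <- which(!isBasic & !atUpper & d < -tol)
        upperCand <- which(!isBasic & atUpper & d > tol)
        if (!length(lowerCand) && !length(upperCand)) break
        if (it > blandAfter) {                  # Bland: smallest index
            j <- min(c(lowerCand, upperCand))
            dirUp <- !atUpper[j]
        } else {                                # Dantzig: steepest rate
            j <- 0L; best <- -tol; dirUp <- TRUE
            if (length(lowerCand)) {
                k <- lowerCand[which.min(d[lowerCand])]
                if (d[k] < best) { best <- d[k]; j <- k; dirUp <- TRUE }
            }
            if (length(upperCand)) {
                k <- upperCand[which.max(d[upperCand])]
                if (-d[k] < best) { best <- -d[k]; j <- k; dirUp <- FALSE }
            }
        }
        col <- Tab[, j]
        sgn <- if (dirUp) 1 else -1
        # ratio test: entering moves by t >= 0, basics move by -sgn*t*col
        tmax <- up[j]                           # entering's own span
        r <- 0L; leaveAtUpper <- FALSE
        dec <- which(sgn * col > pivTol)        # basics decreasing toward 0
        if (length(dec)) {
            ratios <- xB[dec] / (sgn * col[dec])
            i <- which.min(ratios)
            if (ratios[i] < tmax) {
                tmax <- ratios[i]; r <- dec[i]; leaveAtUpper <- FALSE
            }
        }
        ubas <- up[bas]
        inc <- which(sgn * col < -pivTol & is.finite(ubas))
        if (length(inc)) {
            ratios <- (ubas[inc] - xB[inc]) / (-sgn * col[inc])
            i <- which.min(ratios)
            if (ratios[i] < tmax) {
                tmax <- ratios[i]; r <- inc[i]; leaveAtUpper <- TRUE
            }
        }
        if (!is.finite(tmax))
            return(list(status = "unbounded", x = rep(NA_real_, n),
                        y = rep(NA_real_, L), objective = -Inf,
                        iterations = it))
        if (r == 0L) {                          # bound flip, basis unchanged
            xB <- xB - sgn * tmax * col
            atUpper[j] <- dirUp
            next
        }
        lv <- bas[r]
        isBasic[lv] <- FALSE
        atUpper[lv] <- leaveAtUpper
        enterVal <- if (dirUp) tmax else up[j] - tmax
        xB <- xB - sgn * tmax * col
        xB[r] <- enterVal
        piv <- Tab[r, j]
        Tab[r, ] <- Tab[r, ] / piv
        colj <- Tab[, j]; colj[r] <- 0
        Tab <- Tab - outer(colj, Tab[r, ])
        bas[r] <- j
        isBasic[j] <- TRUE
        atUpper[j] <- FALSE
        xB[abs(xB) < 1e-12] <- 0
    }

    val <- ifelse(atUpper, up, 0)
    val[bas] <- xB
    x <- val[seq_len(n)]
    y <- val[n + seq_len(L)]
    x[x < 0 & x > -1e-9] <- 0
    y[y < 0 & y > -1e-9] <- 0
    list(status = "optimal", x = x, y = y,
         objective = sum(x) + lambda * sum(y), iterations = it)
}
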