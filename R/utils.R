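## Internal helpers shared across modules.

## Wrap angles (degrees) into [-180, 180).
wrapDegrees <- function(x) {
    ((x + 180) %% 360) - 180
}

## Derive a reproducible 32-bit sub-seed from a base seed and a stream label.
## Keeps derived seeds strictly below 2^31 so they remain valid R integers.
deriveSeed <- function(seed, stream) {
    h <- sum(utf8ToInt(as.character(stream)) *
             seq_along(utf8ToInt(as.character(stream))))
    as.integer((as.numeric(seed) * 48271 + h * 9973) %% 2147483647)
}

## Evaluate an expression with a temporary RNG state.
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(as.integer(seed))
    expr
}

## Column means / unbiased column variances for a trials x directions matrix.
colVarsUnbiased <- function(m) {
    n <- nrow(m)
    mu <- colMeans(m)
    colSums(sweep(m, 2L, mu)^2) / (n - 1)
}

## Centred running mean over k bins; returns a vector with (k-1)/2 NA at
## each edge (k odd).
runningMean <- function(x, k) {
    stopifnot(k %% 2 == 1)
    as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
}

## Two-sample Kolmogorov-Smirnov statistic (no p-value machinery needed).
ksStatistic <- function(x, y) {
    x <- sort(x); y <- sort(y)
    z <- c(x, y)
    cx <- ecdf(x)(z)
    cy <- ecdf(y)(z)
    max(abs(cx - cy))
}

## Symmetric positive-semidefinite repair by eigenvalue clipping. Eigenvalues
## below floor_frac * max(eigenvalue) are raised to that floor; errors if the
## repair moves the matrix by more than tol in relative Frobenius norm.
repairPSD <- function(sigma, floor_frac = 1e-10, tol = 1e-6) {
    sigma <- (sigma + t(sigma)) / 2
    ## fast path: already positive definite (the common case)
    ok <- tryCatch({ chol(sigma); TRUE }, error = function(e) FALSE)
    if (ok) return(sigma)
    e <- eigen(sigma, symmetric = TRUE)
    floorval <- floor_frac * max(e$values)
    if (all(e$values >= floorval)) return(sigma)
    vals <- pmax(e$values, floorval)
    repaired <- e$vectors %*% (vals * t(e$vectors))
    repaired <- (repaired + t(repaired)) / 2
    rel <- sqrt(sum((repaired - sigma)^2)) / max(sqrt(sum(sigma^2)), .Machine$double.eps)
    if (rel > tol)
        stop(sprintf(
            "covariance repair changed the matrix by %.3g relative Frobenius norm (tolerance %.3g)",
            rel, tol))
    repaired
}
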