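## Shared builders for the test suite. Everything is generated in code at
## test time; no stored fixtures.

## Flat tuning: every direction has expected count f (baseline f, amplitude 0
## would violate f > 0 nowhere, so use amplitude 0 with positive baseline).
flatTuning <- function(f, pref = 0) {
    TuningCurveFit(baseline = f, amplitude = 0, width = 2,
                   pref_direction = pref)
}

## Single-neuron gain-model config at the given directions.
gainConfig <- function(f, alpha, var_g, n_trials, dirs = 0, seed = 1L,
                       n_neurons = 1L, tuning = NULL, ...) {
    if (is.null(tuning))
        tuning <- replicate(n_neurons, flatTuning(f))
    SyntheticConfig(n_neurons, n_trials, dirs, GainModelParams(alpha, var_g),
                    tuning, seed = seed, ...)
}

## CountMatrix from a trials x directions matrix for one neuron.
cmFromMatrix <- function(m, dirs) {
    arr <- aperm(array(m, dim = c(nrow(m), ncol(m), 1L)), c(3L, 2L, 1L))
    CountMatrix(arr, dirs)
}

## CountMatrix for several neurons from a list of trials x directions
## matrices.
cmFromMatrices <- function(ms, dirs) {
    arr <- array(NA_real_, dim = c(length(ms), length(dirs), nrow(ms[[1L]])))
    for (i in seq_along(ms)) arr[i, , ] <- t(ms[[i]])
    CountMatrix(arr, dirs)
}

## Exact MI (bits) for Poisson counts at the given rates, uniform prior.
exactPoissonMI <- function(rates, kmax = 200L) {
    pkt <- vapply(rates, function(r) dpois(0:kmax, r), numeric(kmax + 1L))
    pk <- rowMeans(pkt)
    sum(vapply(seq_along(rates), function(j) {
        p <- pkt[, j]
        sum(ifelse(p > 0, p * log2(p / pk), 0))
    }, numeric(1L))) / length(rates)
}

## directionStats-shaped data.frame from explicit per-neuron values.
statsFrame <- function(dirs, means, ffs) {
    n <- length(means)
    data.frame(neuron_id = rep(paste0("n", seq_len(n)), times = length(dirs)),
               direction_deg = rep(dirs, each = n),
               mean = rep(means, length(dirs)),
               var = rep(means * ffs, length(dirs)),
               ff = rep(ffs, length(dirs)))
}
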