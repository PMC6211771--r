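## FFT-based autocovariance of a trials x bins residual matrix, summed over
## trials; returns unnormalised autocovariance per lag 0..max_lag.
acovFFT <- function(resid, max_lag) {
    Tn <- ncol(resid)
    npad <- 2^ceiling(log2(2 * Tn))
    padded <- matrix(0, nrow = npad, ncol = nrow(resid))
    padded[seq_len(Tn), ] <- t(resid)
    F <- stats::mvfft(padded)
    S <- rowSums(Mod(F)^2)
    full <- Re(stats::fft(S, inverse = TRUE)) / npad
    lags <- 0:max_lag
    full[lags + 1L] / (nrow(resid) * (Tn - lags))
}

#' Spike-count autocorrelation of within-trial fluctuations
#'
#' Spikes are binned (the tensor's bin width, 2 ms by default in the
#' generator), the across-trial mean at each time bin (the PSTH) is
#' subtracted so only fluctuations about the stimulus-locked response
#' remain, each trial is smoothed with a centred running average of
#' \code{smooth_bins} bins, and the autocorrelation of the smoothed
#' residuals is computed, normalised by the variance so the value at lag 0
#' is exactly 1. Traces are averaged over trials within a neuron, then over
#' neurons (unweighted).
#'
#' @param bt a \code{BinnedSpikeTensor} (>= 2 trials).
#' @param smooth_bins running-average width in bins (odd, default 5).
#' @param max_lag_ms largest lag returned, ms (default 300).
#' @param epoch optional \code{c(start_ms, end_ms)} restricting the analysis
#'   to a stationary epoch (default: from the tensor's latency, if known, to
#'   the end of the trial).
#' @return list with \code{lags_ms}, \code{ac} (population-average
#'   normalised autocorrelation), \code{ac_sd} (SD across neurons) and
#'   \code{per_neuron} (neuron x lag matrix).
#' @export
spikeCountAutocorrelation <- function(bt, smooth_bins = 5L, max_lag_ms = 300,
                                      epoch = NULL) {
    d <- dim(bt@counts)
    if (d[3L] < 2L) stop("need >= 2 trials")
    if (is.null(epoch)) {
        start <- if (is.finite(bt@latency_ms)) bt@latency_ms else 0
        epoch <- c(start, d[4L] * bt@bin_ms)
    }
    bin_starts <- (seq_len(d[4L]) - 1L) * bt@bin_ms
    sel <- which(bin_starts >= epoch[1L] & bin_starts < epoch[2L])
    if (length(sel) < 4L * smooth_bins)
        stop("analysis epoch too short for the smoothing width")
    half <- (smooth_bins - 1L) %/% 2L
    max_lag <- min(floor(max_lag_ms / bt@bin_ms),
                   length(sel) - 2L * half - 2L)
    lags <- 0:max_lag
    kern <- rep(1 / smooth_bins, smooth_bins)
    per_neuron <- matrix(NA_real_, nrow = d[1L], ncol = max_lag + 1L)
    for (i in seq_len(d[1L])) {
        acov <- numeric(max_lag + 1L)
        nseries <- 0L
        for (j in seq_len(d[2L])) {
            m <- matrix(bt@counts[i, j, , sel, drop = FALSE], nrow = d[3L])
            resid <- sweep(m, 2L, colMeans(m))
            sm <- t(apply(resid, 1L, function(x)
                as.numeric(stats::filter(x, kern, sides = 2))))
            sm <- sm[, (half + 1L):(ncol(sm) - half), drop = FALSE]
            acov <- acov + acovFFT(sm, max_lag)
            nseries <- nseries + 1L
        }
        acov <- acov / nseries
        if (acov[1L] <= 0)
            stop("zero residual variance for neuron ", i,
                 " (identical trials?)")
        per_neuron[i, ] <- acov / acov[1L]
    }
    list(lags_ms = lags * bt@bin_ms,
         ac = colMeans(per_neuron),
         ac_sd = apply(per_neuron, 2L, sd),
         per_neuron = per_neuron,
         smooth_bins = smooth_bins, bin_ms = bt@bin_ms)
}

#' Fit an exponential decay to an autocorrelation trace
#'
#' Least-squares fit of \eqn{a \exp(-lag/\tau)} to the population
#' autocorrelation over a lag range that excludes lag 0 and the lags
#' dominated by the smoothing kernel (default start:
#' \code{smooth_bins * bin_ms}). Multi-start over
#' \eqn{\tau \in \{10, 50, 100, 300\}} ms. Fits with non-positive amplitude
#' or \eqn{\tau} outside [1, 10000] ms are flagged ill-defined.
#'
#' When the decay is fast relative to the default 300 ms window, most fitted
#' lags carry no signal and the nonlinear fit can wander; with
#' \code{refine = TRUE} (default) the window end is re-set to five fitted
#' time constants (never below 10 lags, never above the original end) and
#' the fit repeated once.
#'
#' @param ac result of \code{\link{spikeCountAutocorrelation}}.
#' @param lag_range \code{c(min_ms, max_ms)}; default
#'   \code{c(smooth_bins * bin_ms, 300)}.
#' @param refine adapt the window end to the fitted decay (default TRUE).
#' @return list with \code{tau_ms}, \code{amplitude}, \code{lag_range},
#'   \code{resid_norm} and logical \code{ill_defined} (non-positive
#'   amplitude, or a time constant at the search bounds of [1, 1e4] ms).
#' @export
fitExponentialDecay <- function(ac, lag_range = NULL, refine = TRUE) {
    if (is.null(lag_range))
        lag_range <- c(ac$smooth_bins * ac$bin_ms, 300)
    fitOnce <- function(lr) {
        sel <- ac$lags_ms >= lr[1L] & ac$lags_ms <= lr[2L]
        if (sum(sel) < 4L) stop("lag range contains too few points")
        dat <- data.frame(lag = ac$lags_ms[sel], y = ac$ac[sel])
        best <- NULL
        for (tau0 in c(10, 50, 100, 300)) {
            fit <- tryCatch(
                minpack.lm::nlsLM(y ~ a * exp(-lag / tau), data = dat,
                                  start = list(a = max(dat$y[1L], 1e-4),
                                               tau = tau0),
                                  lower = c(0, 1), upper = c(Inf, 1e4),
                                  control = minpack.lm::nls.lm.control(
                                      maxiter = 200)),
                error = function(e) NULL)
            if (is.null(fit)) next
            rss <- sum(residuals(fit)^2)
            if (is.null(best) || rss < best$rss)
                best <- list(rss = rss, par = coef(fit))
        }
        best
    }
    best <- fitOnce(lag_range)
    used_range <- lag_range
    if (!is.null(best) && refine) {
        tau1 <- best$par[["tau"]]
        end <- min(lag_range[2L],
                   max(5 * tau1, lag_range[1L] + 10 * ac$bin_ms))
        if (end < lag_range[2L]) {
            refit <- fitOnce(c(lag_range[1L], end))
            if (!is.null(refit)) {
                best <- refit
                used_range <- c(lag_range[1L], end)
            }
        }
    }
    if (is.null(best))
        return(list(tau_ms = NA_real_, amplitude = NA_real_,
                    lag_range = lag_range, resid_norm = NA_real_,
                    ill_defined = TRUE))
    a <- best$par[["a"]]; tau <- best$par[["tau"]]
    list(tau_ms = tau, amplitude = a, lag_range = used_range,
         resid_norm = sqrt(best$rss),
         ill_defined = (a <= 1e-12 || tau <= 1 || tau >= 1e4 - 1))
}

#' Bagged exponential-decay fit
#'
#' The exponential least-squares fit is an unstable functional of a noisy
#' autocorrelation trace: at low signal-to-noise the objective has nearly
#' flat directions and single fits occasionally escape to very small or
#' very large time constants. Bootstrap aggregation over neurons tames
#' this: the per-neuron traces are resampled with replacement \code{B}
#' times, the population average re-formed and re-fit, and the median
#' fitted time constant reported. Ill-defined fits are dropped.
#'
#' @param ac result of \code{\link{spikeCountAutocorrelation}}.
#' @param B bootstrap replicates (default 15).
#' @param seed integer seed for the resampling.
#' @param lag_range,refine passed to \code{\link{fitExponentialDecay}}.
#' @return list with \code{tau_ms} (median over replicates), \code{tau_b}
#'   (the replicate values) and \code{n_ill} (replicates dropped).
#' @export
fitDecayBagged <- function(ac, B = 15L, seed = 1L, lag_range = NULL,
                           refine = TRUE) {
    n <- nrow(ac$per_neuron)
    taus <- withSeed(deriveSeed(seed, "bag"), vapply(seq_len(B), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        ac_b <- ac
        ac_b$ac <- colMeans(ac$per_neuron[idx, , drop = FALSE])
        fit <- fitExponentialDecay(ac_b, lag_range = lag_range,
                                   refine = refine)
        if (isTRUE(fit$ill_defined)) NA_real_ else fit$tau_ms
    }, numeric(1L)))
    list(tau_ms = median(taus, na.rm = TRUE), tau_b = taus,
         n_ill = sum(is.na(taus)))
}

#' Write autocorrelation outputs
#'
#' CSV with header \code{lag_ms,ac_mean,ac_sd}; fit JSON with
#' \code{tau_ms}, \code{amplitude}, \code{lag_range}.
#'
#' @param ac autocorrelation result.
#' @param fit exponential-decay fit.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAutocorrCSV <- function(ac, path) {
    utils::write.csv(data.frame(lag_ms = ac$lags_ms, ac_mean = ac$ac,
                                ac_sd = ac$ac_sd),
                     path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeAutocorrCSV
#' @export
writeAutocorrFitJSON <- function(fit, path) {
    jsonlite::write_json(fit[c("tau_ms", "amplitude", "lag_range")], path,
                         auto_unbox = TRUE, digits = NA)
    invisible(path)
}
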