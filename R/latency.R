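#' Estimate response latency from a PSTH
#'
#' Automated onset detection: the latency is the first time after motion
#' onset at which the trial-averaged rate exceeds the baseline mean by
#' \code{k} baseline standard deviations for \code{m} consecutive bins.
#' Baseline statistics come from the pre-onset epoch, which must be present.
#'
#' @param psth trial-averaged rate per time bin (any consistent unit).
#' @param times_ms bin start times in ms, same length as \code{psth};
#'   negative times are the baseline epoch.
#' @param onset_ms motion-onset time (default 0).
#' @param k baseline SD multiplier (default 3).
#' @param m required consecutive supra-threshold bins (default 5).
#' @return Latency in ms relative to onset, or \code{NA} with attribute
#'   \code{no_latency = TRUE} when the criterion is never met.
#' @export
estimateLatency <- function(psth, times_ms, onset_ms = 0, k = 3, m = 5) {
    if (length(psth) != length(times_ms))
        stop("'psth' and 'times_ms' must have equal length")
    base <- psth[times_ms < onset_ms]
    if (!length(base)) stop("no pre-onset baseline epoch in 'times_ms'")
    thr <- mean(base) + k * sd(base)
    if (is.na(thr)) thr <- mean(base)  # single baseline bin
    post <- which(times_ms >= onset_ms)
    above <- psth[post] > thr
    run <- 0L
    for (j in seq_along(above)) {
        run <- if (above[j]) run + 1L else 0L
        if (run >= m) {
            lat <- times_ms[post[j - m + 1L]] - onset_ms
            return(lat)
        }
    }
    structure(NA_real_, no_latency = TRUE)
}

#' Trial-averaged PSTH from binned trains
#'
#' @param bt a \code{BinnedSpikeTensor}.
#' @param neuron neuron index.
#' @param direction direction index (default 1).
#' @return list with \code{rate} (spikes/s per bin) and \code{times_ms}
#'   (bin start times).
#' @export
psthFromTensor <- function(bt, neuron = 1L, direction = 1L) {
    d <- dim(bt@counts)
    m <- matrix(bt@counts[neuron, direction, , , drop = FALSE], nrow = d[3L])
    list(rate = colMeans(m) / bt@bin_ms * 1000,
         times_ms = (seq_len(d[4L]) - 1L) * bt@bin_ms)
}

#' Fano factors over expanding counting windows
#'
#' Counts spikes in windows \code{[0, duration)} expanding from motion onset
#' (or from response onset, shifting by per-neuron latency) and computes the
#' Fano factor per neuron and direction at each duration, plus the
#' population mean and SD. Entries with zero mean count are undefined and
#' excluded from the population summary.
#'
#' @param bt a \code{BinnedSpikeTensor}.
#' @param durations_ms increasing window durations, ms.
#' @param alignment "stimulus_onset" or "response_onset".
#' @param latency_ms per-neuron latencies for response-onset alignment.
#' @return list with \code{ff} (neuron x direction x duration array),
#'   \code{summary} (data.frame: duration, population mean FF, SD, number of
#'   undefined entries excluded).
#' @export
ffExpandingWindows <- function(bt, durations_ms,
                               alignment = "stimulus_onset",
                               latency_ms = NULL) {
    if (is.unsorted(durations_ms, strictly = TRUE))
        stop("'durations_ms' must be strictly increasing")
    d <- dim(bt@counts)
    ff <- array(NA_real_, dim = c(d[1L], d[2L], length(durations_ms)))
    summ <- data.frame(duration_ms = durations_ms, ff_mean = NA_real_,
                       ff_sd = NA_real_, n_undefined = NA_integer_)
    for (k in seq_along(durations_ms)) {
        cm <- countInWindow(bt, c(0, durations_ms[k]), alignment = alignment,
                            latency_ms = latency_ms)
        st <- directionStats(cm)
        ff[, , k] <- matrix(st$ff, nrow = d[1L])
        summ$ff_mean[k] <- mean(st$ff, na.rm = TRUE)
        summ$ff_sd[k] <- sd(st$ff, na.rm = TRUE)
        summ$n_undefined[k] <- sum(is.na(st$ff))
    }
    list(ff = ff, summary = summ)
}
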