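#' Generate binned spike trains with a temporally correlated gain
#'
#' Per-bin counts are Poisson with rate
#' \eqn{f(\theta)\, g_t\, (bin\_ms / window\_ms)}, zero before the response
#' latency. The per-bin gain \eqn{g_t} follows a stationary first-order
#' autoregressive process (a discretised Ornstein-Uhlenbeck process) with
#' mean 1, variance \code{var_g} and lag-\eqn{k} correlation
#' \eqn{\exp(-k\, bin\_ms / tau\_gain\_ms)}, initialised from its stationary
#' distribution and clipped at zero before use as a rate. With
#' \code{tau_gain_ms = 0} the gain is white (independent across bins); with
#' \code{var_g = 0} it is constantly 1 and the trains are homogeneous
#' Poisson.
#'
#' The spike-count autocorrelation of the output therefore decays with time
#' constant approximately \code{tau_gain_ms}, which is what
#' \code{\link{spikeCountAutocorrelation}} and
#' \code{\link{fitExponentialDecay}} recover.
#'
#' @param config a \code{\link{SyntheticConfig}}; \code{tau_gain_ms},
#'   \code{bin_ms}, \code{trial_duration_ms} and \code{latency_ms} control
#'   the temporal structure.
#' @return A \code{BinnedSpikeTensor}.
#' @export
generateTemporalTrains <- function(config) {
    validObject(config)
    if (config@tau_gain_ms > 0 && config@gain_params@var_g == 0)
        warning("tau_gain_ms > 0 with var_g = 0: gain process degenerates ",
                "to a constant")
    nN <- config@n_neurons
    nD <- length(config@direction_grid)
    nT <- config@n_trials
    nB <- as.integer(config@trial_duration_ms / config@bin_ms)
    var_g <- config@gain_params@var_g
    fmat <- vapply(config@tuning, tuningValue,
                   numeric(nD), theta = config@direction_grid)  # nD x nN
    base <- t(fmat) * config@bin_ms / config@window_ms           # nN x nD
    bin_starts <- (seq_len(nB) - 1L) * config@bin_ms
    active <- bin_starts >= config@latency_ms
    counts <- withSeed(deriveSeed(config@seed, "trains"), {
        M <- nN * nD * nT
        g <- matrix(1, nrow = nB, ncol = M)
        if (var_g > 0) {
            s <- sqrt(var_g)
            if (config@tau_gain_ms > 0) {
                phi <- exp(-config@bin_ms / config@tau_gain_ms)
                z <- matrix(0, nrow = nB, ncol = M)
                z[1L, ] <- rnorm(M, 0, s)
                innov_sd <- s * sqrt(1 - phi^2)
                for (t in 2:nB)
                    z[t, ] <- phi * z[t - 1L, ] + rnorm(M, 0, innov_sd)
                g <- 1 + z
            } else {
                g <- 1 + matrix(rnorm(nB * M, 0, s), nrow = nB)
            }
            g <- pmax(g, 0)
        }
        ## rate[t, m]: column m runs over neuron fastest, then direction,
        ## then trial, matching array(dim = c(nN, nD, nT, nB)) after aperm.
        base_cols <- rep(as.vector(base), times = nT)  # length nN*nD*nT
        rate <- g * rep(base_cols, each = nB)
        rate[!active, ] <- 0
        x <- rpois(nB * M, lambda = as.vector(rate))
        aperm(array(x, dim = c(nB, nN, nD, nT)), c(2L, 3L, 4L, 1L))
    })
    dimnames(counts)[[1L]] <- paste0("n", seq_len(nN))
    new("BinnedSpikeTensor", counts = counts,
        directions = config@direction_grid, bin_ms = config@bin_ms,
        window_ms = config@window_ms, latency_ms = config@latency_ms)
}

#' Write / read binned trains CSV
#'
#' Long format with header
#' \code{neuron_id,direction_deg,trial,bin_start_ms,count}.
#'
#' @param bt a \code{BinnedSpikeTensor}.
#' @param path file path.
#' @return \code{readTrainsCSV} returns a \code{BinnedSpikeTensor};
#'   \code{writeTrainsCSV} returns \code{path} invisibly.
#' @export
writeTrainsCSV <- function(bt, path) {
    d <- dim(bt@counts)
    bin_starts <- (seq_len(d[4L]) - 1L) * bt@bin_ms
    df <- data.frame(
        neuron_id = rep(dimnames(bt@counts)[[1L]], times = prod(d[2:4])),
        direction_deg = rep(rep(bt@directions, each = d[1L]),
                            times = d[3L] * d[4L]),
        trial = rep(rep(seq_len(d[3L]), each = d[1L] * d[2L]), times = d[4L]),
        bin_start_ms = rep(bin_starts, each = prod(d[1:3])),
        count = as.vector(bt@counts))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @param window_ms,latency_ms metadata for the returned object.
#' @rdname writeTrainsCSV
#' @export
readTrainsCSV <- function(path, window_ms = 250, latency_ms = NA_real_) {
    df <- utils::read.csv(path)
    need <- c("neuron_id", "direction_deg", "trial", "bin_start_ms", "count")
    if (!all(need %in% names(df)))
        stop("trains CSV must have columns ", paste(need, collapse = ", "))
    neurons <- unique(df$neuron_id)
    dirs <- sort(unique(df$direction_deg))
    trials <- sort(unique(df$trial))
    bins <- sort(unique(df$bin_start_ms))
    bin_ms <- if (length(bins) > 1L) min(diff(bins)) else NA_real_
    arr <- array(NA_real_, dim = c(length(neurons), length(dirs),
                                   length(trials), length(bins)),
                 dimnames = list(neurons, NULL, NULL, NULL))
    idx <- cbind(match(df$neuron_id, neurons), match(df$direction_deg, dirs),
                 match(df$trial, trials), match(df$bin_start_ms, bins))
    arr[idx] <- df$count
    if (anyNA(arr))
        stop("trains CSV is not a balanced design")
    new("BinnedSpikeTensor", counts = arr, directions = dirs,
        bin_ms = bin_ms, window_ms = window_ms, latency_ms = latency_ms)
}
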