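#' Count events in a half-open window
#'
#' Counting windows are half-open intervals \code{[start, end)}: an event
#' exactly at the window end is excluded. For binned trains the window is
#' applied to bin start times and per-bin counts are summed, yielding a
#' \code{\link{CountMatrix}}. With \code{alignment = "response_onset"} the
#' window is shifted by each neuron's latency before counting.
#'
#' @param x numeric spike times (ms) for one trial, or a
#'   \code{BinnedSpikeTensor}.
#' @param window \code{c(start_ms, end_ms)}.
#' @param alignment "stimulus_onset" (default) or "response_onset".
#' @param latency_ms per-neuron latency estimates, required for
#'   response-onset alignment of a tensor.
#' @return Integer count (numeric input) or a \code{\link{CountMatrix}}.
#' @examples
#' countInWindow(c(10, 100, 249, 250), c(0, 250))  # 3: 250 ms is excluded
#' @export
setGeneric("countInWindow",
    function(x, window, alignment = "stimulus_onset", latency_ms = NULL)
        standardGeneric("countInWindow"))

#' @rdname countInWindow
#' @export
setMethod("countInWindow", "numeric",
    function(x, window, alignment = "stimulus_onset", latency_ms = NULL) {
        if (diff(window) <= 0) stop("window end must exceed start")
        if (identical(alignment, "response_onset")) {
            if (is.null(latency_ms)) stop("response-onset alignment needs a latency")
            window <- window + latency_ms
        }
        sum(x >= window[1L] & x < window[2L])
    })

#' @rdname countInWindow
#' @export
setMethod("countInWindow", "BinnedSpikeTensor",
    function(x, window, alignment = "stimulus_onset", latency_ms = NULL) {
        if (diff(window) <= 0) stop("window end must exceed start")
        d <- dim(x@counts)
        if (prod(d[1:3]) == 0L) stop("empty trial set")
        bin_starts <- (seq_len(d[4L]) - 1L) * x@bin_ms
        span <- d[4L] * x@bin_ms
        offsets <- if (identical(alignment, "response_onset")) {
            if (is.null(latency_ms))
                stop("response-onset alignment needs per-neuron latencies")
            rep(latency_ms, length.out = d[1L])
        } else rep(0, d[1L])
        if (any(window[1L] + offsets < 0) || any(window[2L] + offsets > span))
            stop("window extends outside the recorded span")
        out <- array(0, dim = d[1:3], dimnames = dimnames(x@counts)[1:3])
        for (i in seq_len(d[1L])) {
            sel <- bin_starts >= window[1L] + offsets[i] &
                   bin_starts < window[2L] + offsets[i]
            out[i, , ] <- apply(x@counts[i, , , sel, drop = FALSE], c(2L, 3L), sum)
        }
        CountMatrix(out, x@directions, window = window, alignment = alignment)
    })

#' Per-direction response statistics
#'
#' Mean count, unbiased (n-1) variance and Fano factor (variance/mean) for
#' every neuron and direction. The Fano factor is flagged \code{NA} where
#' the mean count is zero.
#'
#' @param cm a \code{\link{CountMatrix}} (>= 2 trials per direction).
#' @return data.frame with columns \code{neuron_id}, \code{direction_deg},
#'   \code{mean}, \code{var}, \code{ff}.
#' @export
directionStats <- function(cm) {
    d <- dim(cm@counts)
    if (d[3L] < 2L) stop("need >= 2 trials per (neuron, direction)")
    mu <- apply(cm@counts, c(1L, 2L), mean)
    vv <- apply(cm@counts, c(1L, 2L), var)  # stats::var is unbiased
    ff <- ifelse(mu > 0, vv / mu, NA_real_)
    data.frame(
        neuron_id = rep(dimnames(cm@counts)[[1L]], times = d[2L]),
        direction_deg = rep(cm@directions, each = d[1L]),
        mean = as.vector(mu), var = as.vector(vv), ff = as.vector(ff))
}

## Index of the sampled direction nearest to a target angle.
nearestDirIndex <- function(grid, target) {
    which.min(abs(wrapDegrees(grid - target)))
}

#' Tuning indices for rate, variance and Fano factor
#'
#' For each neuron, computes the direction index
#' \eqn{DI = (r_{pref} - r_{orth}) / (r_{pref} + r_{orth})}, the analogous
#' variance tuning index VTI, the Fano factor tuning index
#' \eqn{FFTI = (FF_{orth} - FF_{pref}) / (FF_{orth} + FF_{pref})}, and the
#' raw difference \eqn{\Delta FF = FF_{orth} - FF_{pref}}. Positive FFTI
#' means U-shaped variability tuning (a dip at the preferred direction).
#'
#' The preferred direction is taken from a parametric tuning fit by default
#' (less noise-prone than the raw argmax; "argmax" and "zero" modes are
#' available -- "zero" assumes pre-aligned data). Orthogonal statistics
#' average the nearest sampled directions at +90 and -90 degrees when both
#' exist ("average", default), or pool the trials of the two orthogonal
#' directions before computing a single statistic ("pool"). Neurons with no
#' spikes at the orthogonal directions have undefined FF_orth and are
#' excluded from FFTI with a logged reason.
#'
#' @param cm a \code{\link{CountMatrix}}.
#' @param pref_method "fit" (default), "argmax" or "zero".
#' @param orth_mode "average" (default) or "pool".
#' @param fit_shape tuning shape used when \code{pref_method = "fit"}.
#' @return data.frame with one row per neuron: preferred direction, the
#'   constituent statistics, \code{DI}, \code{VTI}, \code{FFTI},
#'   \code{delta_FF} and \code{excluded_reason} (empty when included).
#' @export
tuningIndices <- function(cm, pref_method = c("fit", "argmax", "zero"),
                          orth_mode = c("average", "pool"),
                          fit_shape = "gaussian") {
    pref_method <- match.arg(pref_method)
    orth_mode <- match.arg(orth_mode)
    d <- dim(cm@counts)
    dirs <- cm@directions
    rows <- vector("list", d[1L])
    for (i in seq_len(d[1L])) {
        m <- t(matrix(cm@counts[i, , , drop = FALSE], nrow = d[2L]))  # trials x dirs
        mu <- colMeans(m)
        vv <- colVarsUnbiased(m)
        pref <- switch(pref_method,
            zero = 0,
            argmax = dirs[which.max(mu)],
            fit = tryCatch(
                fitTuningCurve(mu, dirs, shape = fit_shape)@pref_direction,
                error = function(e) dirs[which.max(mu)]))
        ip <- nearestDirIndex(dirs, pref)
        io <- unique(c(nearestDirIndex(dirs, pref + 90),
                       nearestDirIndex(dirs, pref - 90)))
        io <- setdiff(io, ip)
        if (!length(io))
            stop("no sampled direction orthogonal to the preferred direction")
        r_pref <- mu[ip]; v_pref <- vv[ip]
        ff_pref <- if (r_pref > 0) v_pref / r_pref else NA_real_
        if (orth_mode == "pool" && length(io) > 1L) {
            pooled <- as.vector(m[, io])
            r_orth <- mean(pooled)
            v_orth <- var(pooled)
            ff_orth <- if (r_orth > 0) v_orth / r_orth else NA_real_
        } else {
            r_orth <- mean(mu[io])
            v_orth <- mean(vv[io])
            ffs <- ifelse(mu[io] > 0, vv[io] / mu[io], NA_real_)
            ff_orth <- if (all(is.na(ffs))) NA_real_ else mean(ffs, na.rm = TRUE)
        }
        reason <- ""
        if (is.na(ff_orth))
            reason <- "no spikes at the orthogonal directions; FF_orth undefined"
        else if (is.na(ff_pref))
            reason <- "no spikes at the preferred direction; FF_pref undefined"
        di <- if (r_pref + r_orth > 0) (r_pref - r_orth) / (r_pref + r_orth)
              else NA_real_
        vti <- if (v_pref + v_orth > 0) (v_pref - v_orth) / (v_pref + v_orth)
               else NA_real_
        ffti <- if (reason == "" && ff_pref + ff_orth > 0)
            (ff_orth - ff_pref) / (ff_orth + ff_pref) else NA_real_
        rows[[i]] <- data.frame(
            neuron_id = dimnames(cm@counts)[[1L]][i], pref_direction = pref,
            r_pref = r_pref, r_orth = r_orth, var_pref = v_pref,
            var_orth = v_orth, FF_pref = ff_pref, FF_orth = ff_orth,
            DI = di, VTI = vti, FFTI = ffti,
            delta_FF = ff_orth - ff_pref, excluded_reason = reason)
    }
    do.call(rbind, rows)
}

#' Write per-neuron statistics and indices CSVs
#'
#' \code{writeStatsCSV} writes the \code{\link{directionStats}} table with
#' header \code{neuron_id,direction_deg,mean,var,ff};
#' \code{writeIndicesCSV} writes the \code{\link{tuningIndices}} columns
#' \code{neuron_id,DI,VTI,FFTI,delta_FF,excluded_reason}.
#'
#' @param x the corresponding data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeStatsCSV <- function(x, path) {
    utils::write.csv(x[, c("neuron_id", "direction_deg", "mean", "var", "ff")],
                     path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeStatsCSV
#' @export
writeIndicesCSV <- function(x, path) {
    utils::write.csv(
        x[, c("neuron_id", "DI", "VTI", "FFTI", "delta_FF", "excluded_reason")],
        path, row.names = FALSE, quote = TRUE)
    invisible(path)
}
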