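#' @import methods
NULL

## ---------------------------------------------------------------------------
## Gain model parameters
## ---------------------------------------------------------------------------

#' Multiplicative-gain variance model parameters
#'
#' The doubly-stochastic count model scales a neuron's expected count by a
#' trial-wise gain \eqn{g} drawn from a Gamma distribution with mean 1 and
#' variance \code{var_g}, and draws the count from a normal law with mean
#' \eqn{\mu = f(\theta) g} and variance \eqn{\mu^\alpha}. \code{alpha}
#' controls how intrinsic count variance scales with rate; \code{var_g}
#' controls the strength of shared excitability fluctuations.
#'
#' @slot alpha variance exponent, dimensionless, in \code{[0, 2]}.
#' @slot var_g variance of the mean-1 trial gain, dimensionless, \eqn{\ge 0}.
#' @export
setClass("GainModelParams",
    representation(alpha = "numeric", var_g = "numeric"),
    prototype(alpha = 1, var_g = 0))

setValidity("GainModelParams", function(object) {
    msg <- character()
    if (length(object@alpha) != 1L || !is.finite(object@alpha))
        msg <- c(msg, "'alpha' must be a single finite number")
    else if (object@alpha < 0 || object@alpha > 2)
        msg <- c(msg, "'alpha' must lie in [0, 2]")
    if (length(object@var_g) != 1L || !is.finite(object@var_g) ||
        object@var_g < 0)
        msg <- c(msg, "'var_g' must be a single finite number >= 0")
    if (length(msg)) msg else TRUE
})

#' @param alpha variance exponent in \code{[0, 2]}.
#' @param var_g gain variance, \eqn{\ge 0}.
#' @return A \code{GainModelParams} object.
#' @examples
#' GainModelParams(alpha = 0.74, var_g = 0.0732)
#' @rdname GainModelParams-class
#' @export
GainModelParams <- function(alpha = 1, var_g = 0) {
    new("GainModelParams", alpha = as.numeric(alpha), var_g = as.numeric(var_g))
}

## ---------------------------------------------------------------------------
## Tuning curves
## ---------------------------------------------------------------------------

#' Parametric direction tuning curve
#'
#' Either a von Mises curve
#' \deqn{f(\theta) = b + A \frac{e^{\kappa(\cos(\theta-\theta_p)+1)} - 1}{
#'   e^{2\kappa} - 1}}
#' (360-degree periodic, equal to \eqn{b + A} at the preferred direction and
#' to \eqn{b} at the anti-preferred direction), or a Gaussian curve
#' \eqn{f(\theta) = b + A \exp(-(\theta-\theta_p)^2 / 2\sigma^2)} with the
#' width \eqn{\sigma} in degrees.
#'
#' @slot baseline background expected count per counting window (>= 0).
#' @slot amplitude peak expected count above baseline (>= 0).
#' @slot width von Mises concentration \eqn{\kappa} (dimensionless) or
#'   Gaussian \eqn{\sigma} (degrees), > 0.
#' @slot pref_direction preferred direction in degrees, in [-180, 180).
#' @slot shape "von_mises" or "gaussian".
#' @slot rss residual sum of squares when the object results from a fit,
#'   otherwise \code{NA}.
#' @export
setClass("TuningCurveFit",
    representation(baseline = "numeric", amplitude = "numeric",
                   width = "numeric", pref_direction = "numeric",
                   shape = "character", rss = "numeric"),
    prototype(baseline = 0, amplitude = 1, width = 2, pref_direction = 0,
              shape = "von_mises", rss = NA_real_))

setValidity("TuningCurveFit", function(object) {
    msg <- character()
    num1 <- function(x) length(x) == 1L && is.finite(x)
    if (!num1(object@baseline) || object@baseline < 0)
        msg <- c(msg, "'baseline' must be a single number >= 0")
    if (!num1(object@amplitude) || object@amplitude < 0)
        msg <- c(msg, "'amplitude' must be a single number >= 0")
    if (!num1(object@width) || object@width <= 0)
        msg <- c(msg, "'width' must be a single number > 0")
    if (!num1(object@pref_direction) ||
        object@pref_direction < -180 || object@pref_direction >= 180)
        msg <- c(msg, "'pref_direction' must be in [-180, 180)")
    if (!(object@shape %in% c("von_mises", "gaussian")))
        msg <- c(msg, "'shape' must be 'von_mises' or 'gaussian'")
    if (length(msg)) msg else TRUE
})

#' @param baseline,amplitude,width,pref_direction,shape,rss see slots.
#' @return A \code{TuningCurveFit} object.
#' @examples
#' tc <- TuningCurveFit(baseline = 10, amplitude = 60, width = 2)
#' tuningValue(tc, c(0, 90, 180))
#' @rdname TuningCurveFit-class
#' @export
TuningCurveFit <- function(baseline = 0, amplitude = 1, width = 2,
                           pref_direction = 0, shape = "von_mises",
                           rss = NA_real_) {
    new("TuningCurveFit", baseline = as.numeric(baseline),
        amplitude = as.numeric(amplitude), width = as.numeric(width),
        pref_direction = as.numeric(wrapDegrees(pref_direction)),
        shape = shape, rss = as.numeric(rss))
}

## ---------------------------------------------------------------------------
## Synthetic generator configuration
## ---------------------------------------------------------------------------

#' Configuration of the synthetic spike-count generator
#'
#' Bundles everything needed to generate trial counts and binned trains:
#' population size, trial numbers, the direction grid, the gain model, one
#' tuning curve per neuron, response latency, and the temporal-gain process.
#'
#' @slot n_neurons,n_trials positive integers (trials are per direction).
#' @slot direction_grid distinct motion directions in degrees.
#' @slot gain_params a \code{\link{GainModelParams}}.
#' @slot tuning list of \code{\link{TuningCurveFit}}, one per neuron.
#' @slot latency_ms response onset delay, >= 0.
#' @slot bin_ms temporal bin width for binned trains (default 2 ms).
#' @slot tau_gain_ms exponential correlation time of the within-trial gain;
#'   0 means trial-constant gain for counts and white gain for trains.
#' @slot trial_duration_ms total simulated trial duration.
#' @slot window_ms spike-counting window over which tuning-curve values are
#'   expressed as expected counts.
#' @slot count_mode "continuous" (default; clipped at 0) or "rounded".
#' @slot seed integer seed.
#' @export
setClass("SyntheticConfig",
    representation(n_neurons = "integer", n_trials = "integer",
                   direction_grid = "numeric", gain_params = "GainModelParams",
                   tuning = "list", latency_ms = "numeric", bin_ms = "numeric",
                   tau_gain_ms = "numeric", trial_duration_ms = "numeric",
                   window_ms = "numeric", count_mode = "character",
                   seed = "integer"))

setValidity("SyntheticConfig", function(object) {
    msg <- character()
    if (object@n_neurons < 1L) msg <- c(msg, "'n_neurons' must be >= 1")
    if (object@n_trials < 2L) msg <- c(msg, "'n_trials' must be >= 2")
    if (anyDuplicated(object@direction_grid))
        msg <- c(msg, "'direction_grid' entries must be unique")
    if (length(object@tuning) != object@n_neurons)
        msg <- c(msg, "need one tuning curve per neuron")
    else if (!all(vapply(object@tuning, is, logical(1), "TuningCurveFit")))
        msg <- c(msg, "'tuning' must be a list of TuningCurveFit objects")
    if (object@latency_ms < 0) msg <- c(msg, "'latency_ms' must be >= 0")
    if (object@bin_ms <= 0) msg <- c(msg, "'bin_ms' must be > 0")
    if (object@tau_gain_ms < 0) msg <- c(msg, "'tau_gain_ms' must be >= 0")
    if (object@trial_duration_ms <= 0)
        msg <- c(msg, "'trial_duration_ms' must be > 0")
    if (object@trial_duration_ms %% object@bin_ms != 0)
        msg <- c(msg, "'bin_ms' must divide 'trial_duration_ms'")
    if (!(object@count_mode %in% c("continuous", "rounded")))
        msg <- c(msg, "'count_mode' must be 'continuous' or 'rounded'")
    if (length(msg)) msg else TRUE
})

#' @param n_neurons,n_trials,direction_grid,gain_params,tuning,latency_ms
#'   see slots.
#' @param bin_ms,tau_gain_ms,trial_duration_ms,window_ms,count_mode,seed
#'   see slots.
#' @return A validated \code{SyntheticConfig}.
#' @examples
#' cfg <- SyntheticConfig(
#'     n_neurons = 2, n_trials = 50,
#'     direction_grid = seq(-90, 90, by = 15),
#'     gain_params = GainModelParams(0.74, 0.0732),
#'     tuning = replicate(2, TuningCurveFit(3, 12, 40, shape = "gaussian")),
#'     seed = 1)
#' @rdname SyntheticConfig-class
#' @export
SyntheticConfig <- function(n_neurons, n_trials, direction_grid, gain_params,
                            tuning, latency_ms = 0, bin_ms = 2,
                            tau_gain_ms = 0, trial_duration_ms = 500,
                            window_ms = 250, count_mode = "continuous",
                            seed = 1L) {
    if (!is.list(tuning)) tuning <- as.list(tuning)
    new("SyntheticConfig", n_neurons = as.integer(n_neurons),
        n_trials = as.integer(n_trials),
        direction_grid = as.numeric(direction_grid), gain_params = gain_params,
        tuning = tuning, latency_ms = as.numeric(latency_ms),
        bin_ms = as.numeric(bin_ms), tau_gain_ms = as.numeric(tau_gain_ms),
        trial_duration_ms = as.numeric(trial_duration_ms),
        window_ms = as.numeric(window_ms), count_mode = count_mode,
        seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## Count containers
## ---------------------------------------------------------------------------

#' Trial-resolved spike counts
#'
#' A neuron x direction x trial array of spike counts together with the
#' counting-window metadata. Counts may be non-integer when produced by the
#' continuous-mode synthetic generator.
#'
#' @slot counts 3-D numeric array \code{[neuron, direction, trial]}, >= 0.
#' @slot directions direction labels in degrees (one per array column).
#' @slot window counting window \code{c(start_ms, end_ms)} relative to the
#'   alignment event.
#' @slot alignment "stimulus_onset" or "response_onset".
#' @export
setClass("CountMatrix",
    representation(counts = "array", directions = "numeric",
                   window = "numeric", alignment = "character"))

setValidity("CountMatrix", function(object) {
    msg <- character()
    d <- dim(object@counts)
    if (length(d) != 3L)
        msg <- c(msg, "'counts' must be a 3-D array [neuron, direction, trial]")
    else {
        if (length(object@directions) != d[2L])
            msg <- c(msg, "'directions' must match dim(counts)[2]")
        if (d[3L] < 2L)
            msg <- c(msg, "need >= 2 trials per (neuron, direction)")
    }
    if (any(object@counts < 0, na.rm = TRUE))
        msg <- c(msg, "counts must be >= 0")
    if (length(object@window) != 2L || diff(object@window) <= 0)
        msg <- c(msg, "'window' must be c(start_ms, end_ms) with end > start")
    if (!(object@alignment %in% c("stimulus_onset", "response_onset")))
        msg <- c(msg, "'alignment' must be 'stimulus_onset' or 'response_onset'")
    if (length(msg)) msg else TRUE
})

#' @param counts,directions,window,alignment see slots.
#' @return A \code{CountMatrix}.
#' @rdname CountMatrix-class
#' @export
CountMatrix <- function(counts, directions, window = c(0, 250),
                        alignment = "stimulus_onset") {
    if (is.null(dimnames(counts)[[1L]]))
        dimnames(counts)[[1L]] <- paste0("n", seq_len(dim(counts)[1L]))
    new("CountMatrix", counts = counts, directions = as.numeric(directions),
        window = as.numeric(window), alignment = alignment)
}

#' Binned spike trains
#'
#' A neuron x direction x trial x time-bin array of per-bin spike counts.
#'
#' @slot counts 4-D integer-valued array \code{[neuron, direction, trial, bin]}.
#' @slot directions direction labels in degrees.
#' @slot bin_ms bin width in ms.
#' @slot window_ms counting window used to express tuning values as counts.
#' @slot latency_ms generative response latency (ms) when known, else NA.
#' @export
setClass("BinnedSpikeTensor",
    representation(counts = "array", directions = "numeric",
                   bin_ms = "numeric", window_ms = "numeric",
                   latency_ms = "numeric"))

setValidity("BinnedSpikeTensor", function(object) {
    msg <- character()
    if (length(dim(object@counts)) != 4L)
        msg <- c(msg, "'counts' must be 4-D [neuron, direction, trial, bin]")
    else if (length(object@directions) != dim(object@counts)[2L])
        msg <- c(msg, "'directions' must match dim(counts)[2]")
    if (object@bin_ms <= 0) msg <- c(msg, "'bin_ms' must be > 0")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Population decoding model
## ---------------------------------------------------------------------------

#' Pairwise-correlation kernel
#'
#' Noise correlation between two neurons as a von Mises function of the
#' difference \eqn{d} between their preferred directions:
#' \deqn{c(d) = c_{max} \frac{e^{\kappa(\cos d + 1)} - 1}{e^{2\kappa} - 1}.}
#' Equal to \code{c_max} at \eqn{d = 0} and exactly 0 at \eqn{d = 180}.
#'
#' @slot c_max peak pairwise correlation in [0, 1].
#' @slot kappa kernel width parameter, > 0.
#' @export
setClass("CorrelationKernel",
    representation(c_max = "numeric", kappa = "numeric"),
    prototype(c_max = 0.1, kappa = 1))

setValidity("CorrelationKernel", function(object) {
    msg <- character()
    if (object@c_max < 0 || object@c_max > 1)
        msg <- c(msg, "'c_max' must be in [0, 1]")
    if (object@kappa <= 0) msg <- c(msg, "'kappa' must be > 0")
    if (length(msg)) msg else TRUE
})

#' @param c_max,kappa see slots.
#' @return A \code{CorrelationKernel}.
#' @examples
#' k <- CorrelationKernel(c_max = 0.1, kappa = 1)
#' corrKernelValue(c(0, 64, 180), k)
#' @rdname CorrelationKernel-class
#' @export
CorrelationKernel <- function(c_max = 0.1, kappa = 1) {
    new("CorrelationKernel", c_max = as.numeric(c_max),
        kappa = as.numeric(kappa))
}

#' Imposed Fano-factor tuning
#'
#' A von Mises-shaped modulation of the Fano factor around each neuron's
#' preferred direction, constrained so the average FF across the direction
#' grid is exactly 1. The "positive" sign dips at the preferred direction
#' (U-shaped, FFTI > 0); "negative" is its mirror image about FF = 1;
#' "flat" is FF = 1 everywhere.
#'
#' @slot sign "positive", "flat" or "negative".
#' @slot amplitude peak-to-trough FF modulation depth (>= 0).
#' @slot kappa von Mises width of the FF tuning, > 0.
#' @slot grid direction grid (degrees) over which the mean-1 constraint is
#'   enforced.
#' @export
setClass("FFTuningSpec",
    representation(sign = "character", amplitude = "numeric",
                   kappa = "numeric", grid = "numeric"),
    prototype(sign = "flat", amplitude = 0.3, kappa = 2,
              grid = seq(-180, 165, by = 15)))

setValidity("FFTuningSpec", function(object) {
    msg <- character()
    if (!(object@sign %in% c("positive", "flat", "negative")))
        msg <- c(msg, "'sign' must be 'positive', 'flat' or 'negative'")
    if (object@amplitude < 0) msg <- c(msg, "'amplitude' must be >= 0")
    if (object@kappa <= 0) msg <- c(msg, "'kappa' must be > 0")
    if (length(object@grid) < 2L) msg <- c(msg, "'grid' needs >= 2 directions")
    if (length(msg)) msg else TRUE
})

#' @param sign,amplitude,kappa,grid see slots.
#' @return An \code{FFTuningSpec}.
#' @rdname FFTuningSpec-class
#' @export
FFTuningSpec <- function(sign = "flat", amplitude = 0.3, kappa = 2,
                         grid = seq(-180, 165, by = 15)) {
    new("FFTuningSpec", sign = sign, amplitude = as.numeric(amplitude),
        kappa = as.numeric(kappa), grid = as.numeric(grid))
}

#' Model population for Fisher-information decoding
#'
#' Combines a set of tuning curves (preferred directions tiling the circle),
#' an imposed Fano-factor tuning, a pairwise-correlation kernel, and the
#' information-limiting strength \eqn{\epsilon} (squared degrees).
#'
#' @slot tuning list of \code{\link{TuningCurveFit}}.
#' @slot ff_spec an \code{\link{FFTuningSpec}}.
#' @slot kernel a \code{\link{CorrelationKernel}}.
#' @slot epsilon information-limiting strength in deg^2, >= 0.
#' @slot direction_grid evaluation directions in degrees.
#' @slot kind "homogeneous" or "heterogeneous".
#' @export
setClass("PopulationModel",
    representation(tuning = "list", ff_spec = "FFTuningSpec",
                   kernel = "CorrelationKernel", epsilon = "numeric",
                   direction_grid = "numeric", kind = "character"))

setValidity("PopulationModel", function(object) {
    msg <- character()
    if (length(object@tuning) < 2L)
        msg <- c(msg, "need >= 2 neurons")
    else if (!all(vapply(object@tuning, is, logical(1), "TuningCurveFit")))
        msg <- c(msg, "'tuning' must be a list of TuningCurveFit objects")
    if (object@epsilon < 0) msg <- c(msg, "'epsilon' must be >= 0")
    if (!(object@kind %in% c("homogeneous", "heterogeneous")))
        msg <- c(msg, "'kind' must be 'homogeneous' or 'heterogeneous'")
    if (length(msg)) msg else TRUE
})

#' Linear Fisher-information decoding result
#'
#' @slot J0 linear Fisher information without information-limiting
#'   correlations, per deg^2 (possibly a vector over directions).
#' @slot J_eps information-limited Fisher information, per deg^2.
#' @slot cr_bound_deg square root of the Cramer-Rao bound, degrees.
#' @slot theta evaluation directions, degrees.
#' @slot extras list of auxiliary results (threshold crossings, curves).
#' @export
setClass("DecodingResult",
    representation(J0 = "numeric", J_eps = "numeric",
                   cr_bound_deg = "numeric", theta = "numeric",
                   extras = "list"),
    prototype(extras = list()))

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "GainModelParams", function(object) {
    cat(sprintf("GainModelParams: alpha = %.4g, var(g) = %.4g\n",
                object@alpha, object@var_g))
})

setMethod("show", "TuningCurveFit", function(object) {
    cat(sprintf(
        "TuningCurveFit (%s): b = %.3g, A = %.3g, width = %.3g, pref = %.1f deg%s\n",
        object@shape, object@baseline, object@amplitude, object@width,
        object@pref_direction,
        if (is.na(object@rss)) "" else sprintf(", rss = %.3g", object@rss)))
})

setMethod("show", "CountMatrix", function(object) {
    d <- dim(object@counts)
    cat(sprintf(
        "CountMatrix: %d neurons x %d directions x %d trials, window [%g, %g) ms (%s)\n",
        d[1L], d[2L], d[3L], object@window[1L], object@window[2L],
        object@alignment))
})

setMethod("show", "BinnedSpikeTensor", function(object) {
    d <- dim(object@counts)
    cat(sprintf(
        "BinnedSpikeTensor: %d neurons x %d directions x %d trials x %d bins (%g ms bins)\n",
        d[1L], d[2L], d[3L], d[4L], object@bin_ms))
})

setMethod("show", "PopulationModel", function(object) {
    cat(sprintf(
        "PopulationModel (%s): N = %d, FF tuning '%s' (amp %.2f), c_max = %.3g, epsilon = %.3g deg^2\n",
        object@kind, length(object@tuning), object@ff_spec@sign,
        object@ff_spec@amplitude, object@kernel@c_max, object@epsilon))
})

setMethod("show", "DecodingResult", function(object) {
    cat(sprintf(
        "DecodingResult: mean J0 = %.4g /deg^2, mean J_eps = %.4g /deg^2, mean CR bound = %.4g deg\n",
        mean(object@J0), mean(object@J_eps), mean(object@cr_bound_deg)))
})
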