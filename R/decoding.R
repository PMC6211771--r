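#' Pairwise-correlation kernel value
#'
#' Evaluates
#' \deqn{c(d) = c_{max} \frac{e^{\kappa(\cos d + 1)} - 1}{e^{2\kappa} - 1}}
#' for preferred-direction differences \code{d} in degrees. The kernel is
#' even, 360-degree periodic, equals \code{c_max} at \eqn{d = 0} and is
#' exactly zero at \eqn{d = 180}. With \eqn{\kappa = 1} its half-width at
#' half-maximum is 64 degrees (see \code{\link{corrKernelHWHM}}).
#'
#' @param d preferred-direction difference(s) in degrees.
#' @param kernel a \code{\link{CorrelationKernel}}.
#' @return Correlation values in \code{[0, c_max]}.
#' @export
corrKernelValue <- function(d, kernel) {
    kernel@c_max * (exp(kernel@kappa * (cos(d * pi / 180) + 1)) - 1) /
        (exp(2 * kernel@kappa) - 1)
}

#' Half-width at half-maximum of the correlation kernel
#'
#' Root-solves \eqn{c(d) = c_{max}/2} for \eqn{d \in (0, 180)} degrees.
#' Independent of \code{c_max}.
#'
#' @param kernel a \code{\link{CorrelationKernel}}.
#' @return HWHM in degrees.
#' @examples
#' corrKernelHWHM(CorrelationKernel(kappa = 1))  # ~64 degrees
#' @export
corrKernelHWHM <- function(kernel) {
    f <- function(d) corrKernelValue(d, kernel) - kernel@c_max / 2
    uniroot(f, c(1e-6, 180 - 1e-6), tol = 1e-10)$root
}

#' Imposed Fano-factor tuning value
#'
#' The FF tuning is a von Mises-shaped modulation around each neuron's
#' preferred direction, centred so that the average FF across the
#' specification's direction grid is exactly 1 and scaled so the
#' peak-to-trough modulation equals \code{amplitude}. "positive" dips at the
#' preferred direction (U-shaped variability tuning, FFTI > 0); "negative"
#' is the reflection about FF = 1; "flat" returns 1 everywhere.
#'
#' @param spec an \code{\link{FFTuningSpec}}.
#' @param d direction relative to the neuron's preferred direction, degrees.
#' @return Fano factors at \code{d}.
#' @export
ffTuningValue <- function(spec, d) {
    if (spec@sign == "flat") return(rep(1, length(d)))
    shape <- function(x) exp(spec@kappa * (cos(x * pi / 180) - 1))
    wg <- shape(spec@grid)
    s <- (shape(d) - mean(wg)) / (max(wg) - min(wg))
    if (spec@sign == "positive") 1 - spec@amplitude * s
    else 1 + spec@amplitude * s
}

#' Build a homogeneous model population
#'
#' \code{n} copies of one tuning curve with preferred directions spaced
#' evenly over the circle.
#'
#' @param n population size (>= 2).
#' @param curve a \code{\link{TuningCurveFit}} (its preferred direction is
#'   ignored; the copies tile the circle).
#' @param ff_spec an \code{\link{FFTuningSpec}}.
#' @param kernel a \code{\link{CorrelationKernel}}.
#' @param epsilon information-limiting strength, deg^2.
#' @param direction_grid evaluation directions, degrees.
#' @return A \code{\link{PopulationModel}}.
#' @export
homogeneousPopulation <- function(n, curve, ff_spec = FFTuningSpec(),
                                  kernel = CorrelationKernel(), epsilon = 4,
                                  direction_grid = seq(-180, 165, by = 15)) {
    prefs <- wrapDegrees(seq(0, 360, length.out = n + 1L)[seq_len(n)])
    tuning <- lapply(prefs, function(p)
        TuningCurveFit(curve@baseline, curve@amplitude, curve@width,
                       pref_direction = p, shape = curve@shape))
    new("PopulationModel", tuning = tuning, ff_spec = ff_spec,
        kernel = kernel, epsilon = as.numeric(epsilon),
        direction_grid = as.numeric(direction_grid), kind = "homogeneous")
}

#' Build a heterogeneous model population from a tuning pool
#'
#' Samples \code{n} curves from \code{pool} (with replacement by default)
#' and reassigns preferred directions, either spaced evenly over the circle
#' (default) or drawn uniformly.
#'
#' @param pool list of \code{\link{TuningCurveFit}} to sample from.
#' @param n population size.
#' @param seed integer seed (sampling is reproducible).
#' @param replace sample with replacement (default TRUE).
#' @param prefs "even" or "uniform".
#' @inheritParams homogeneousPopulation
#' @return A \code{\link{PopulationModel}} of kind "heterogeneous".
#' @export
heterogeneousPopulation <- function(pool, n, seed = 1L, replace = TRUE,
                                    prefs = c("even", "uniform"),
                                    ff_spec = FFTuningSpec(),
                                    kernel = CorrelationKernel(), epsilon = 4,
                                    direction_grid = seq(-180, 165, by = 15)) {
    prefs <- match.arg(prefs)
    if (!length(pool)) stop("'pool' must not be empty")
    withSeed(deriveSeed(seed, "hetpop"), {
        picks <- sample.int(length(pool), n, replace = replace)
        pd <- if (prefs == "even")
            wrapDegrees(seq(0, 360, length.out = n + 1L)[seq_len(n)])
        else runif(n, -180, 180)
        tuning <- lapply(seq_len(n), function(i) {
            tc <- pool[[picks[i]]]
            TuningCurveFit(tc@baseline, tc@amplitude, tc@width,
                           pref_direction = pd[i], shape = tc@shape)
        })
        new("PopulationModel", tuning = tuning, ff_spec = ff_spec,
            kernel = kernel, epsilon = as.numeric(epsilon),
            direction_grid = as.numeric(direction_grid),
            kind = "heterogeneous")
    })
}

#' Assemble population covariance matrices at one direction
#'
#' The diagonal of \eqn{\Sigma_0} holds each neuron's variance
#' \eqn{FF_i(\theta) f_i(\theta)}; off-diagonals are
#' \eqn{c(d_{ij})\sqrt{var_i\, var_j}} from the correlation kernel.
#' Information-limiting correlations add the rank-one term:
#' \eqn{\Sigma_\epsilon = \Sigma_0 + \epsilon f'(\theta) f'(\theta)^T}
#' with \eqn{f'} in counts per degree. Both matrices are verified (and if
#' needed minimally repaired) to be positive semidefinite.
#'
#' @param pop a \code{\link{PopulationModel}}.
#' @param theta a single direction in degrees.
#' @return list with \code{Sigma0}, \code{SigmaEps}, \code{f},
#'   \code{fprime}, \code{ff} (per-neuron FF at theta), \code{var}.
#' @export
buildCovariance <- function(pop, theta) {
    stopifnot(length(theta) == 1L)
    f <- vapply(pop@tuning, tuningValue, numeric(1L), theta = theta)
    fprime <- vapply(pop@tuning, tuningDerivative, numeric(1L), theta = theta)
    prefs <- vapply(pop@tuning, function(tc) tc@pref_direction, numeric(1L))
    ff <- ffTuningValue(pop@ff_spec, wrapDegrees(theta - prefs))
    v <- ff * f
    if (any(v <= 0))
        stop("zero or negative variance at theta = ", theta,
             "; check tuning curves and FF amplitude")
    dmat <- wrapDegrees(outer(prefs, prefs, "-"))
    C <- corrKernelValue(dmat, pop@kernel)
    diag(C) <- 1
    sd <- sqrt(v)
    Sigma0 <- C * (sd %o% sd)
    Sigma0 <- repairPSD(Sigma0)
    SigmaEps <- Sigma0 + pop@epsilon * (fprime %o% fprime)
    list(Sigma0 = Sigma0, SigmaEps = SigmaEps, f = f, fprime = fprime,
         ff = ff, var = v)
}

## Solve Sigma x = b with a logged ridge fallback for near-singular Sigma.
solveCov <- function(Sigma, b) {
    tryCatch(solve(Sigma, b), error = function(e) {
        ridge <- 1e-10 * mean(diag(Sigma))
        message("covariance solve failed; retrying with ridge ", ridge)
        solve(Sigma + diag(ridge, nrow(Sigma)), b)
    })
}

#' Linear Fisher information and the Cramer-Rao bound
#'
#' At each requested direction computes the linear Fisher information
#' \eqn{J_0 = f'^T \Sigma_0^{-1} f'} (covariance-derivative terms are
#' ignored), the information-limited value both directly,
#' \eqn{f'^T \Sigma_\epsilon^{-1} f'}, and through the rank-one identity
#' \eqn{J_\epsilon = J_0 / (1 + \epsilon J_0)} -- the two must agree to
#' \eqn{10^{-6}} relative or an error is raised -- and the discrimination
#' bound \eqn{\sqrt{1/J_0 + \epsilon}} in degrees, the lower bound on the
#' standard deviation of an unbiased direction estimator.
#'
#' @param pop a \code{\link{PopulationModel}}.
#' @param theta evaluation directions in degrees (defaults to the model's
#'   direction grid).
#' @return A \code{\link{DecodingResult}}.
#' @examples
#' pop <- homogeneousPopulation(24, TuningCurveFit(5, 25, 2), epsilon = 4)
#' linearFisher(pop)
#' @export
linearFisher <- function(pop, theta = pop@direction_grid) {
    J0 <- Jeps <- numeric(length(theta))
    for (i in seq_along(theta)) {
        cv <- buildCovariance(pop, theta[i])
        J0[i] <- drop(crossprod(cv$fprime, solveCov(cv$Sigma0, cv$fprime)))
        jd <- drop(crossprod(cv$fprime, solveCov(cv$SigmaEps, cv$fprime)))
        jf <- J0[i] / (1 + pop@epsilon * J0[i])
        if (pop@epsilon > 0 || jd > 0) {
            rel <- abs(jd - jf) / max(jf, .Machine$double.eps)
            if (rel > 1e-6)
                stop(sprintf(
                    "rank-one consistency check failed at theta = %g (rel. %.3g)",
                    theta[i], rel))
        }
        Jeps[i] <- jf
    }
    new("DecodingResult", J0 = J0, J_eps = Jeps,
        cr_bound_deg = sqrt(1 / J0 + pop@epsilon), theta = as.numeric(theta),
        extras = list(epsilon = pop@epsilon))
}

#' Cramer-Rao bound from Fisher information
#'
#' \eqn{\sqrt{1/J_0 + \epsilon}}: the lower bound, in degrees, on the
#' standard deviation of an unbiased direction estimator given linear
#' Fisher information \code{J0} (per deg^2) and information-limiting
#' strength \code{epsilon} (deg^2). As \code{J0} grows the bound tends to
#' the information-limiting floor \eqn{\sqrt{\epsilon}}.
#'
#' @param J0 Fisher information per deg^2 (> 0), vectorised.
#' @param epsilon information-limiting strength in deg^2.
#' @return Bound in degrees.
#' @examples
#' crBoundFromInfo(1, 4)     # sqrt(5)
#' crBoundFromInfo(1e6, 4)   # ~2
#' @export
crBoundFromInfo <- function(J0, epsilon) {
    stopifnot(all(J0 > 0), epsilon >= 0)
    sqrt(1 / J0 + epsilon)
}

#' Population size needed to reach a discrimination threshold
#'
#' Walks a monotone grid of population sizes, evaluating the mean Cramer-Rao
#' bound over the evaluation grid, and returns the smallest size whose bound
#' is at or below \code{threshold_deg} (refined by bisection between grid
#' points). If the threshold lies below the information-limiting floor
#' \eqn{\sqrt{\epsilon}} the target is unreachable and reported as such.
#'
#' @param popBuilder function(N) returning a \code{\link{PopulationModel}}.
#' @param threshold_deg behavioural discrimination criterion in degrees.
#' @param N_max largest population size to consider.
#' @param N_grid optional explicit grid of sizes (default: powers of 2 up to
#'   \code{N_max}).
#' @return list with \code{min_N} (NA if never crossed), \code{unreachable}
#'   (TRUE when threshold < sqrt(epsilon)), and \code{curve}, a data.frame of
#'   evaluated sizes and bounds.
#' @export
neuronsToThreshold <- function(popBuilder, threshold_deg, N_max = 2048,
                               N_grid = NULL) {
    probe <- popBuilder(2L)
    if (threshold_deg < sqrt(probe@epsilon))
        return(list(min_N = NA_integer_, unreachable = TRUE,
                    curve = data.frame(N = integer(), bound = numeric())))
    boundAt <- function(N) mean(crBound(linearFisher(popBuilder(N))))
    if (is.null(N_grid))
        N_grid <- unique(pmin(2^(1:30), N_max))
    N_grid <- sort(unique(as.integer(N_grid[N_grid <= N_max])))
    bounds <- vapply(N_grid, boundAt, numeric(1L))
    if (any(diff(bounds) > 1e-9))
        warning("Cramer-Rao bound is not monotone non-increasing over the ",
                "searched population sizes; bisection may be unreliable")
    curve <- data.frame(N = N_grid, bound = bounds)
    hit <- which(bounds <= threshold_deg)
    if (!length(hit))
        return(list(min_N = NA_integer_, unreachable = FALSE, curve = curve))
    hi <- N_grid[hit[1L]]
    lo <- if (hit[1L] > 1L) N_grid[hit[1L] - 1L] else 1L
    while (hi - lo > 1L) {
        mid <- as.integer((hi + lo) %/% 2)
        b <- boundAt(mid)
        curve <- rbind(curve, data.frame(N = mid, bound = b))
        if (b <= threshold_deg) hi <- mid else lo <- mid
    }
    list(min_N = hi, unreachable = FALSE, curve = curve[order(curve$N), ])
}

#' Time needed to reach a discrimination threshold
#'
#' Evaluates the mean Cramer-Rao bound for populations whose tuning
#' amplitudes reflect the expected cumulative count up to each time
#' \code{T}, and returns the earliest \code{T} at which the bound is at or
#' below the threshold. Times at which the population carries no signal
#' (e.g. before response latency) give an infinite bound.
#'
#' @param popBuilder function(T_ms) returning a \code{\link{PopulationModel}}
#'   (see \code{\link{rampTuning}} for the cumulative-count tuning model).
#' @param times_ms increasing grid of times after motion onset, ms.
#' @param threshold_deg criterion in degrees.
#' @return list with \code{min_T} (NA if never crossed within the grid) and
#'   \code{curve} (data.frame of times and bounds).
#' @export
timeToThreshold <- function(popBuilder, times_ms, threshold_deg) {
    bounds <- vapply(times_ms, function(T) {
        tryCatch(mean(crBound(linearFisher(popBuilder(T)))),
                 error = function(e) Inf)
    }, numeric(1L))
    curve <- data.frame(T_ms = times_ms, bound = bounds)
    hit <- which(bounds <= threshold_deg)
    list(min_T = if (length(hit)) times_ms[hit[1L]] else NA_real_,
         curve = curve)
}

#' Cumulative-count tuning curve at time T
#'
#' Simple latency-plus-ramp surrogate for tuning curves fit to cumulative
#' spike counts: expected count up to time \code{T} is
#' \eqn{rate \cdot \max(0, T - latency)/1000}, applied to both the baseline
#' and amplitude rates of a von Mises curve.
#'
#' @param T_ms time after motion onset, ms.
#' @param baseline_rate,amplitude_rate rates in spikes/s.
#' @param latency_ms response latency, ms.
#' @param kappa von Mises tuning width.
#' @return A \code{\link{TuningCurveFit}} (amplitude 0 before latency).
#' @export
rampTuning <- function(T_ms, baseline_rate, amplitude_rate, latency_ms,
                       kappa = 2) {
    scale <- max(0, T_ms - latency_ms) / 1000
    TuningCurveFit(baseline = baseline_rate * scale,
                   amplitude = amplitude_rate * scale, width = kappa)
}
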