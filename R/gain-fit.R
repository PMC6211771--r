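#' Predicted count variance under the multiplicative-gain model
#'
#' Approximate mode uses
#' \eqn{var(x|\theta) \approx f^\alpha + f^2 var(g)} (valid because the
#' mean-1 gain has \eqn{\langle g^\alpha\rangle \approx 1} for small
#' \code{var_g}); exact mode evaluates
#' \eqn{f^\alpha \langle g^\alpha\rangle + f^2 var(g)} with the Gamma moment
#' from \code{\link{gainMoment}}.
#'
#' @param f_value expected count(s), > 0.
#' @param params a \code{\link{GainModelParams}}.
#' @param exact use the exact Gamma-moment form (default FALSE).
#' @return Predicted variance(s).
#' @examples
#' predictVariance(50, GainModelParams(0.74, 0.0732))  # ~201.1
#' @export
predictVariance <- function(f_value, params, exact = FALSE) {
    if (any(f_value <= 0)) stop("'f_value' must be > 0")
    moment <- if (exact) gainMoment(params@alpha, params@var_g) else 1
    f_value^params@alpha * moment + f_value^2 * params@var_g
}

#' Model Fano factor across directions
#'
#' \eqn{FF(\theta) = f(\theta)^{\alpha-1} + f(\theta)\, var(g)} (approximate
#' variance law divided by the mean). Decreasing in \eqn{f} when
#' \code{var_g} is small and \eqn{\alpha < 1} (U-shaped FF tuning, FFTI >
#' 0); increasing in \eqn{f} when the gain term dominates (FFTI <= 0).
#'
#' @inheritParams predictVariance
#' @export
predictFF <- function(f_value, params, exact = FALSE) {
    predictVariance(f_value, params, exact) / f_value
}

## FFTI of one simulated neuron: counts matrix trials x directions.
simulatedFFTI <- function(f, dirs, alpha, var_g, n_trials, pref) {
    g <- rGain(n_trials * length(f), var_g)
    mu <- rep(f, each = n_trials) * g
    x <- pmax(rnorm(length(mu), mu, sqrt(mu^alpha)), 0)
    m <- matrix(x, nrow = n_trials)
    mus <- colMeans(m)
    ffs <- colVarsUnbiased(m) / mus
    ip <- nearestDirIndex(dirs, pref)
    io <- setdiff(unique(c(nearestDirIndex(dirs, pref + 90),
                           nearestDirIndex(dirs, pref - 90))), ip)
    ff_orth <- mean(ffs[io])
    ff_pref <- ffs[ip]
    if (!is.finite(ff_orth) || !is.finite(ff_pref) ||
        ff_orth + ff_pref <= 0) return(NA_real_)
    (ff_orth - ff_pref) / (ff_orth + ff_pref)
}

#' Simulate the model's FFTI distribution
#'
#' For every tuning curve, simulates spike counts under the gain model and
#' computes the Fano-factor tuning index, repeated \code{n_reps} times;
#' returns the pooled model FFTI sample. A warning is raised if any neuron
#' yields an undefined FFTI in more than half its repetitions.
#'
#' @param tuning_set list of \code{\link{TuningCurveFit}}.
#' @param params a \code{\link{GainModelParams}}.
#' @param n_trials simulated trials per direction.
#' @param n_reps repetitions per neuron.
#' @param seed integer seed.
#' @param direction_grid directions simulated (degrees).
#' @return Numeric vector of length up to
#'   \code{length(tuning_set) * n_reps} (NAs from undefined FFTIs removed).
#' @export
predictFFTIDistribution <- function(tuning_set, params, n_trials = 100L,
                                    n_reps = 1L, seed = 1L,
                                    direction_grid = seq(-90, 90, by = 15)) {
    withSeed(deriveSeed(seed, "fftidist"), {
        out <- matrix(NA_real_, nrow = n_reps, ncol = length(tuning_set))
        for (i in seq_along(tuning_set)) {
            tc <- tuning_set[[i]]
            f <- tuningValue(tc, direction_grid)
            if (any(f <= 0))
                stop("tuning curve ", i, " non-positive on the grid")
            for (r in seq_len(n_reps))
                out[r, i] <- simulatedFFTI(f, direction_grid, params@alpha,
                                           params@var_g, n_trials,
                                           tc@pref_direction)
        }
        bad <- colMeans(is.na(out))
        if (any(bad > 0.5))
            warning(sum(bad > 0.5),
                    " neuron(s) had undefined FFTI in > 50% of repetitions")
        as.vector(out[!is.na(out)])
    })
}

#' Fit population gain-model parameters by Kolmogorov-Smirnov distance
#'
#' Grid search over \eqn{(\alpha, var(g))}: at each grid point a model FFTI
#' sample is simulated from the tuning set (same seed at every point, so the
#' objective surface is smooth) and compared with the observed FFTI sample
#' by the two-sample KS statistic. Returns the argmin, the full objective
#' surface, and the model FFTI distribution at the optimum. A warning is
#' raised when the optimum sits on the grid boundary.
#'
#' @param observed_ffti observed FFTI sample (>= 10 values).
#' @param tuning_set list of \code{\link{TuningCurveFit}}.
#' @param grid_alpha,grid_var_g parameter grids.
#' @param n_trials simulated trials per direction (default: typical
#'   experimental scale, 100).
#' @param n_reps repetitions per neuron per grid point; default sized so
#'   the model sample is about 20x the observed sample.
#' @param seed integer seed.
#' @param direction_grid simulated directions.
#' @return list with \code{variant}, \code{alpha}, \code{var_g},
#'   \code{objective} (KS statistic at the optimum), \code{surface}
#'   (data.frame \code{alpha,var_g,ks_stat}), \code{model_ffti},
#'   \code{on_boundary}.
#' @export
fitPopulationKS <- function(observed_ffti, tuning_set,
                            grid_alpha = seq(0, 1.5, by = 0.1),
                            grid_var_g = c(0, 0.001, 0.0025, 0.005, 0.01,
                                           0.025, 0.05, 0.075, 0.1, 0.15, 0.2),
                            n_trials = 100L, n_reps = NULL, seed = 1L,
                            direction_grid = seq(-90, 90, by = 15)) {
    observed_ffti <- observed_ffti[is.finite(observed_ffti)]
    if (length(observed_ffti) < 10L)
        stop("need >= 10 observed FFTI values")
    if (is.null(n_reps))
        n_reps <- max(1L, ceiling(20 * length(observed_ffti) /
                                  length(tuning_set)))
    surface <- expand.grid(alpha = grid_alpha, var_g = grid_var_g)
    surface$ks_stat <- NA_real_
    samples_at <- function(a, v)
        predictFFTIDistribution(tuning_set, GainModelParams(a, v),
                                n_trials = n_trials, n_reps = n_reps,
                                seed = seed, direction_grid = direction_grid)
    for (k in seq_len(nrow(surface)))
        surface$ks_stat[k] <- ksStatistic(
            samples_at(surface$alpha[k], surface$var_g[k]), observed_ffti)
    best <- which.min(surface$ks_stat)
    a <- surface$alpha[best]; v <- surface$var_g[best]
    on_boundary <- a %in% range(grid_alpha) || v %in% range(grid_var_g)
    if (on_boundary)
        warning("KS optimum on the grid boundary; consider extending the grid")
    list(variant = "population_ks", alpha = a, var_g = v,
         objective = surface$ks_stat[best], surface = surface,
         model_ffti = samples_at(a, v), on_boundary = on_boundary)
}

#' Fit two states under a shared-parameter constraint
#'
#' Jointly fits two behavioural states with either a common \eqn{\alpha}
#' (\code{"shared_alpha"}) or a common \eqn{var(g)}
#' (\code{"shared_var_g"}): the shared parameter minimises the sum of
#' squared per-state KS statistics, with the free parameter optimised
#' separately per state at each candidate value.
#'
#' @param observed_a,observed_b observed FFTI samples for the two states.
#' @param tuning_a,tuning_b tuning sets for the two states.
#' @param constraint "shared_alpha" or "shared_var_g".
#' @inheritParams fitPopulationKS
#' @return list with \code{variant}, \code{shared} (name and value),
#'   \code{state_a}, \code{state_b} (free parameter and KS statistic each),
#'   and \code{objective} (sum of squared KS statistics).
#' @export
fitConstrained <- function(observed_a, observed_b, tuning_a, tuning_b,
                           constraint = c("shared_alpha", "shared_var_g"),
                           grid_alpha = seq(0, 1.5, by = 0.1),
                           grid_var_g = c(0, 0.001, 0.0025, 0.005, 0.01,
                                          0.025, 0.05, 0.075, 0.1, 0.15, 0.2),
                           n_trials = 100L, n_reps = NULL, seed = 1L,
                           direction_grid = seq(-90, 90, by = 15)) {
    constraint <- match.arg(constraint)
    surf <- function(obs, tun)
        fitPopulationKS(obs, tun, grid_alpha, grid_var_g,
                        n_trials = n_trials, n_reps = n_reps, seed = seed,
                        direction_grid = direction_grid)$surface
    sa <- surf(observed_a, tuning_a)
    sb <- surf(observed_b, tuning_b)
    shared_name <- if (constraint == "shared_alpha") "alpha" else "var_g"
    free_name <- if (constraint == "shared_alpha") "var_g" else "alpha"
    shared_grid <- if (constraint == "shared_alpha") grid_alpha else grid_var_g
    best <- NULL
    for (s in shared_grid) {
        ra <- sa[sa[[shared_name]] == s, ]
        rb <- sb[sb[[shared_name]] == s, ]
        ia <- which.min(ra$ks_stat); ib <- which.min(rb$ks_stat)
        obj <- ra$ks_stat[ia]^2 + rb$ks_stat[ib]^2
        if (is.null(best) || obj < best$objective)
            best <- list(shared = s, objective = obj,
                         free_a = ra[[free_name]][ia], ks_a = ra$ks_stat[ia],
                         free_b = rb[[free_name]][ib], ks_b = rb$ks_stat[ib])
    }
    list(variant = constraint,
         shared = setNames(best$shared, shared_name),
         state_a = setNames(c(best$free_a, best$ks_a),
                            c(free_name, "ks_stat")),
         state_b = setNames(c(best$free_b, best$ks_b),
                            c(free_name, "ks_stat")),
         objective = best$objective)
}

#' Per-neuron least-squares gain-model fit
#'
#' Minimises the squared error between an observed Fano-factor tuning curve
#' and the model prediction
#' \eqn{FF(\theta) = f(\theta)^{\alpha-1} + f(\theta)\, var(g)} over
#' \eqn{(\alpha, var(g) \ge 0)}. For fixed \eqn{\alpha} the optimal
#' \eqn{var(g)} is available in closed form (linear least squares truncated
#' at zero), so the search profiles \eqn{var(g)} out and optimises
#' \eqn{\alpha} over a dense one-dimensional grid with local refinement.
#'
#' @param ff observed Fano factors by direction (NAs allowed, dropped).
#' @param f expected counts at the same directions (mean tuning; > 0).
#' @param alpha_range search interval for alpha (default \code{c(0, 1.5)}).
#' @param alpha_step coarse grid step (default 0.01).
#' @return list with \code{alpha}, \code{var_g}, \code{rss},
#'   \code{converged}.
#' @export
fitNeuronLSQ <- function(ff, f, alpha_range = c(0, 1.5), alpha_step = 0.01) {
    ok <- is.finite(ff) & is.finite(f) & f > 0
    ff <- ff[ok]; f <- f[ok]
    if (length(ff) < 5L)
        stop("need >= 5 directions with defined Fano factors")
    vAt <- function(a) {
        resid <- ff - f^(a - 1)
        max(0, sum(f * resid) / sum(f^2))
    }
    rssAt <- function(a) {
        v <- vAt(a)
        sum((ff - f^(a - 1) - f * v)^2)
    }
    grid <- seq(alpha_range[1L], alpha_range[2L], by = alpha_step)
    rss <- vapply(grid, rssAt, numeric(1L))
    i <- which.min(rss)
    lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
    opt <- optimize(rssAt, c(lo, hi), tol = 1e-8)
    a <- opt$minimum
    if (rssAt(grid[i]) < opt$objective) { a <- grid[i] }
    list(alpha = a, var_g = vAt(a), rss = rssAt(a),
         converged = is.finite(rssAt(a)))
}

#' Write a gain-model fit to JSON and its objective surface to CSV
#'
#' @param fit result of \code{\link{fitPopulationKS}} or
#'   \code{\link{fitConstrained}}.
#' @param json_path,surface_path output paths (\code{surface_path} only for
#'   grid variants; header \code{alpha,var_g,ks_stat}).
#' @return \code{json_path}, invisibly.
#' @export
writeGainFit <- function(fit, json_path, surface_path = NULL) {
    keep <- setdiff(names(fit), c("surface", "model_ffti"))
    jsonlite::write_json(fit[keep], json_path, auto_unbox = TRUE, digits = NA)
    if (!is.null(surface_path) && !is.null(fit$surface))
        utils::write.csv(fit$surface, surface_path, row.names = FALSE,
                         quote = FALSE)
    invisible(json_path)
}
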