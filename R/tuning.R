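#' Evaluate a tuning curve
#'
#' @param fit a \code{\link{TuningCurveFit}}.
#' @param theta stimulus directions in degrees (vectorised).
#' @return Expected spike counts per counting window at \code{theta}.
#' @examples
#' tc <- TuningCurveFit(baseline = 10, amplitude = 60, width = 2)
#' tuningValue(tc, c(0, 90, 180))  # 70, ~17.15, 10
#' @export
tuningValue <- function(fit, theta) {
    d <- wrapDegrees(theta - fit@pref_direction)
    if (fit@shape == "von_mises") {
        k <- fit@width
        fit@baseline + fit@amplitude *
            (exp(k * (cos(d * pi / 180) + 1)) - 1) / (exp(2 * k) - 1)
    } else {
        fit@baseline + fit@amplitude * exp(-d^2 / (2 * fit@width^2))
    }
}

#' Analytic derivative of a tuning curve
#'
#' Derivative of the expected count with respect to direction, in counts per
#' degree. Used for linear Fisher information; a finite-difference mode is
#' available for cross-checking.
#'
#' @param fit a \code{\link{TuningCurveFit}}.
#' @param theta directions in degrees.
#' @param method "analytic" (default) or "fd" (central finite difference).
#' @param h finite-difference step in degrees.
#' @return df/dtheta in counts per degree.
#' @export
tuningDerivative <- function(fit, theta, method = c("analytic", "fd"),
                             h = 1e-4) {
    method <- match.arg(method)
    if (method == "fd")
        return((tuningValue(fit, theta + h) - tuningValue(fit, theta - h)) /
               (2 * h))
    d <- wrapDegrees(theta - fit@pref_direction)
    if (fit@shape == "von_mises") {
        k <- fit@width
        -fit@amplitude * k * sin(d * pi / 180) *
            exp(k * (cos(d * pi / 180) + 1)) / (exp(2 * k) - 1) * (pi / 180)
    } else {
        -fit@amplitude * d / fit@width^2 * exp(-d^2 / (2 * fit@width^2))
    }
}

#' Fit a parametric tuning curve to mean counts
#'
#' Nonlinear least squares (Levenberg-Marquardt, multi-start over width
#' initialisations) of a von Mises or Gaussian curve to per-direction mean
#' counts. The Gaussian tuning width is the fitted standard deviation in
#' degrees; the von Mises width is the concentration parameter.
#'
#' @param means per-direction mean counts.
#' @param dirs directions in degrees (>= 4 distinct values).
#' @param shape "von_mises" or "gaussian".
#' @return A \code{\link{TuningCurveFit}} with the residual sum of squares in
#'   its \code{rss} slot. A fitted amplitude near zero means the preferred
#'   direction is unconstrained (flat input).
#' @export
fitTuningCurve <- function(means, dirs, shape = c("von_mises", "gaussian")) {
    shape <- match.arg(shape)
    if (length(unique(dirs)) < 4L)
        stop("need >= 4 distinct directions to fit a tuning curve")
    if (length(means) != length(dirs))
        stop("'means' and 'dirs' must have equal length")
    b0 <- max(min(means), 0)
    a0 <- max(max(means) - min(means), 1e-6)
    ## start slightly off the argmax: at an exactly symmetric start the
    ## gradient w.r.t. the preferred direction vanishes (singular gradient)
    p0 <- dirs[which.max(means)] + 1
    width_starts <- if (shape == "von_mises") c(0.5, 1, 2, 4) else c(20, 40, 80)
    dat <- data.frame(y = means, th = dirs)
    form <- if (shape == "von_mises")
        y ~ b + A * (exp(w * (cos((th - p) * pi / 180) + 1)) - 1) /
            (exp(2 * w) - 1)
    else
        y ~ b + A * exp(-(((th - p + 180) %% 360) - 180)^2 / (2 * w^2))
    best <- NULL
    for (w0 in width_starts) {
        fit <- tryCatch(
            minpack.lm::nlsLM(
                form, data = dat,
                start = list(b = b0, A = a0, w = w0, p = p0),
                lower = c(0, 0, 1e-3, -360), upper = c(Inf, Inf, Inf, 360),
                control = minpack.lm::nls.lm.control(maxiter = 200)),
            error = function(e) NULL)
        if (is.null(fit)) next
        rss <- sum(residuals(fit)^2)
        if (is.null(best) || rss < best$rss)
            best <- list(rss = rss, par = coef(fit))
    }
    if (is.null(best)) {
        ## flat input: amplitude pinned to 0, preferred direction
        ## unconstrained (gradient vanishes, so the solver cannot move)
        if (sd(means) <= 1e-8 * max(abs(means), 1))
            return(TuningCurveFit(baseline = mean(means), amplitude = 0,
                                  width = width_starts[1L],
                                  pref_direction = 0, shape = shape,
                                  rss = sum((means - mean(means))^2)))
        stop("tuning-curve fit did not converge from any start")
    }
    p <- best$par
    TuningCurveFit(baseline = p[["b"]], amplitude = p[["A"]],
                   width = p[["w"]], pref_direction = wrapDegrees(p[["p"]]),
                   shape = shape, rss = best$rss)
}

#' Draw a set of tuning curves for a synthetic population
#'
#' Each parameter is drawn uniformly from its stated range; degenerate ranges
#' (min == max) give fixed values, so a single call covers both "fixed" and
#' "sampled" tuning rules.
#'
#' @param n number of neurons.
#' @param baseline,amplitude,width length-2 ranges (or single values).
#' @param pref_directions preferred directions; default all 0 (aligned data).
#' @param shape curve shape for all neurons.
#' @param seed integer seed.
#' @return list of \code{\link{TuningCurveFit}}.
#' @export
sampleTuningSet <- function(n, baseline = c(3, 3), amplitude = c(12, 12),
                            width = c(40, 40), pref_directions = rep(0, n),
                            shape = "gaussian", seed = 1L) {
    rng <- function(r) {
        r <- rep(r, length.out = 2L)
        if (r[1L] == r[2L]) rep(r[1L], n) else runif(n, r[1L], r[2L])
    }
    withSeed(seed, {
        b <- rng(baseline); a <- rng(amplitude); w <- rng(width)
        lapply(seq_len(n), function(i)
            TuningCurveFit(baseline = b[i], amplitude = a[i], width = w[i],
                           pref_direction = pref_directions[i], shape = shape))
    })
}
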