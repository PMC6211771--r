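#' Sample correlated population responses
#'
#' Draws trial-by-neuron responses from a multivariate normal law with the
#' model mean vector \eqn{f(\theta)} and covariance \eqn{\Sigma_\epsilon}
#' (information-limiting correlations included), at a single stimulus
#' direction. The generating covariance is returned alongside the samples so
#' downstream checks can compare empirical and generating moments directly.
#'
#' @param pop a \code{\link{PopulationModel}}.
#' @param n_trials number of trials to draw.
#' @param seed integer seed.
#' @param theta stimulus direction in degrees (default 0).
#' @return list with \code{counts} (n_trials x n_neurons matrix),
#'   \code{mean} (generating mean vector) and \code{covariance}
#'   (generating \eqn{\Sigma_\epsilon}).
#' @export
generatePopulationSample <- function(pop, n_trials, seed = 1L, theta = 0) {
    cv <- buildCovariance(pop, theta)
    counts <- withSeed(deriveSeed(seed, "popsample"),
        MASS::mvrnorm(n = n_trials, mu = cv$f, Sigma = cv$SigmaEps))
    if (n_trials == 1L) counts <- matrix(counts, nrow = 1L)
    colnames(counts) <- paste0("n", seq_along(cv$f))
    list(counts = counts, mean = cv$f, covariance = cv$SigmaEps)
}
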