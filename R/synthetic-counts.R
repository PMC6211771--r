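#' Gamma moments of the mean-1 trial gain
#'
#' For the unique mean-1 Gamma distribution with variance \code{var_g}
#' (shape \code{1/var_g}, scale \code{var_g}),
#' \deqn{\langle g^\alpha \rangle = var_g^\alpha \,
#'   \Gamma(1/var_g + \alpha) / \Gamma(1/var_g).}
#' Returns 1 when \code{var_g = 0} (degenerate gain).
#'
#' @param alpha exponent.
#' @param var_g gain variance >= 0.
#' @return \eqn{E[g^\alpha]}.
#' @examples
#' gainMoment(0.74, 0.0732)  # ~0.99, validating the <g^alpha> ~ 1 approximation
#' @export
gainMoment <- function(alpha, var_g) {
    if (var_g == 0) return(1)
    s <- 1 / var_g
    exp(alpha * log(var_g) + lgamma(s + alpha) - lgamma(s))
}

## Draw n mean-1 Gamma gains with variance var_g (all 1 when var_g = 0).
rGain <- function(n, var_g) {
    if (var_g == 0) rep(1, n)
    else rgamma(n, shape = 1 / var_g, scale = var_g)
}

#' Generate trial-resolved spike counts from the gain model
#'
#' For each neuron, direction and trial: draw a gain \eqn{g} from the mean-1
#' Gamma law with variance \code{var_g}; form the trial rate
#' \eqn{\mu = f(\theta) g}; draw the count from a normal law with mean
#' \eqn{\mu} and variance \eqn{\mu^\alpha}, clipped below at zero
#' (\code{count_mode = "continuous"}) or additionally rounded to integers
#' (\code{"rounded"}, which biases Fano factors at low rates).
#'
#' As the number of trials grows, the per-direction empirical mean converges
#' to \eqn{f(\theta)} and the empirical variance to
#' \eqn{f^\alpha \langle g^\alpha \rangle + f^2 var_g}
#' (see \code{\link{predictVariance}}).
#'
#' @param config a \code{\link{SyntheticConfig}}.
#' @return A \code{\link{CountMatrix}}. Identical configs (including seed)
#'   give identical output.
#' @examples
#' cfg <- SyntheticConfig(1, 200, seq(-90, 90, 15),
#'     GainModelParams(0.74, 0.0732),
#'     list(TuningCurveFit(3, 12, 40, shape = "gaussian")), seed = 7)
#' cm <- generateTrialCounts(cfg)
#' @export
generateTrialCounts <- function(config) {
    validObject(config)
    nN <- config@n_neurons
    nD <- length(config@direction_grid)
    nT <- config@n_trials
    alpha <- config@gain_params@alpha
    var_g <- config@gain_params@var_g
    fmat <- vapply(config@tuning, tuningValue,
                   numeric(nD), theta = config@direction_grid)  # nD x nN
    if (any(fmat <= 0))
        stop("tuning curves must be strictly positive at every direction ",
             "(mu^alpha is not defined for non-positive means)")
    counts <- withSeed(config@seed, {
        ntot <- nN * nD * nT
        f <- array(rep(t(fmat), times = nT), dim = c(nN, nD, nT))
        g <- array(rGain(ntot, var_g), dim = c(nN, nD, nT))
        mu <- f * g
        x <- rnorm(ntot, mean = mu, sd = sqrt(mu^alpha))
        x <- pmax(x, 0)
        if (config@count_mode == "rounded") x <- round(x)
        array(x, dim = c(nN, nD, nT))
    })
    CountMatrix(counts, config@direction_grid,
                window = c(0, config@window_ms))
}

#' Write / read the counts CSV interchange format
#'
#' Long format with header \code{neuron_id,direction_deg,trial,count}.
#' \code{readCountsCSV} requires a balanced design (equal trials per neuron
#' and direction), matching the synthetic generator's output.
#'
#' @param cm a \code{\link{CountMatrix}}.
#' @param path file path.
#' @return \code{readCountsCSV} returns a \code{\link{CountMatrix}};
#'   \code{writeCountsCSV} returns \code{path} invisibly.
#' @export
writeCountsCSV <- function(cm, path) {
    d <- dim(cm@counts)
    df <- data.frame(
        neuron_id = rep(dimnames(cm@counts)[[1L]], times = d[2L] * d[3L]),
        direction_deg = rep(rep(cm@directions, each = d[1L]), times = d[3L]),
        trial = rep(seq_len(d[3L]), each = d[1L] * d[2L]),
        count = as.vector(cm@counts))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @param window,alignment counting-window metadata for the returned object.
#' @rdname writeCountsCSV
#' @export
readCountsCSV <- function(path, window = c(0, 250),
                          alignment = "stimulus_onset") {
    df <- utils::read.csv(path)
    need <- c("neuron_id", "direction_deg", "trial", "count")
    if (!all(need %in% names(df)))
        stop("counts CSV must have columns ", paste(need, collapse = ", "))
    neurons <- unique(df$neuron_id)
    dirs <- sort(unique(df$direction_deg))
    trials <- sort(unique(df$trial))
    arr <- array(NA_real_,
                 dim = c(length(neurons), length(dirs), length(trials)),
                 dimnames = list(neurons, NULL, NULL))
    idx <- cbind(match(df$neuron_id, neurons),
                 match(df$direction_deg, dirs),
                 match(df$trial, trials))
    arr[idx] <- df$count
    if (anyNA(arr))
        stop("counts CSV is not a balanced neuron x direction x trial design")
    CountMatrix(arr, dirs, window = window, alignment = alignment)
}

#' Write a generation manifest
#'
#' Serialises every field of a \code{\link{SyntheticConfig}} (including the
#' seed) to JSON so a dataset can be regenerated exactly.
#'
#' @param config a \code{\link{SyntheticConfig}}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeGenerationManifest <- function(config, path) {
    tun <- lapply(config@tuning, function(tc) list(
        baseline = tc@baseline, amplitude = tc@amplitude, width = tc@width,
        pref_direction = tc@pref_direction, shape = tc@shape))
    manifest <- list(
        n_neurons = config@n_neurons, n_trials = config@n_trials,
        direction_grid = config@direction_grid,
        gain_params = list(alpha = config@gain_params@alpha,
                           var_g = config@gain_params@var_g),
        tuning = tun, latency_ms = config@latency_ms, bin_ms = config@bin_ms,
        tau_gain_ms = config@tau_gain_ms,
        trial_duration_ms = config@trial_duration_ms,
        window_ms = config@window_ms, count_mode = config@count_mode,
        seed = config@seed)
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}
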