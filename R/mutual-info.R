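## Plugin mutual information (bits) between integer counts and direction for
## a trials x directions matrix; uniform stimulus prior over columns.
pluginMI <- function(m) {
    if (ncol(m) < 2L) stop("mutual information needs >= 2 directions")
    m <- round(m)
    D <- ncol(m)
    nT <- nrow(m)
    ks <- sort(unique(as.vector(m)))
    ## p(k|theta): categories x directions
    pkt <- matrix(vapply(seq_len(D), function(j)
        tabulate(match(m[, j], ks), length(ks)) / nT, numeric(length(ks))),
        nrow = length(ks))
    pk <- rowMeans(pkt)  # uniform p(theta) = 1/D
    ratio <- sweep(pkt, 1L, pk, "/")
    terms <- pkt * log2(ifelse(pkt > 0, ratio, 1))
    sum(terms) / D
}

#' Plugin mutual information between spike count and direction
#'
#' Empirical (plugin) estimate of
#' \deqn{I(k;\theta) = \sum_\theta p(\theta) \sum_k p(k|\theta)
#'   \log_2 \frac{p(k|\theta)}{p(k)}}
#' with a uniform prior over the presented directions and raw integer counts
#' as categories (continuous counts are rounded). Bounded by 0 and
#' \eqn{\log_2} of the number of directions.
#'
#' @param cm a \code{\link{CountMatrix}}.
#' @return data.frame with \code{neuron_id} and \code{plugin_bits}.
#' @export
mutualInformationPlugin <- function(cm) {
    d <- dim(cm@counts)
    if (d[2L] < 2L) stop("mutual information needs >= 2 directions")
    bits <- vapply(seq_len(d[1L]), function(i)
        pluginMI(t(matrix(cm@counts[i, , , drop = FALSE], nrow = d[2L]))),
        numeric(1L))
    data.frame(neuron_id = dimnames(cm@counts)[[1L]], plugin_bits = bits)
}

## Quadratic-extrapolation correction for one trials x directions matrix.
correctedMIMatrix <- function(m, fractions, n_boot, rng_warn = 0.5) {
    nT <- nrow(m)
    N <- nT * ncol(m)
    if (floor(min(fractions) * nT) < 10L)
        stop("smallest fraction leaves fewer than 10 trials per direction")
    xs <- mi_means <- numeric(length(fractions) + 1L)
    for (q in seq_along(fractions)) {
        f <- fractions[q]
        nsub <- floor(f * nT)
        vals <- vapply(seq_len(n_boot), function(b) {
            sub <- m[sample.int(nT, nsub), , drop = FALSE]
            pluginMI(sub)
        }, numeric(1L))
        mi_means[q] <- mean(vals)
        xs[q] <- 1 / (f * N)
    }
    mi_means[length(mi_means)] <- pluginMI(m)
    xs[length(xs)] <- 1 / N
    fit <- lm(mi_means ~ xs + I(xs^2))
    spread <- max(mi_means) - min(mi_means)
    r2 <- summary(fit)$r.squared
    if (spread > 0.02 && !is.nan(r2) && r2 < rng_warn)
        warning(sprintf(
            "scattered subsample means (R^2 = %.2f); extrapolation may be unreliable",
            r2))
    list(plugin = mi_means[length(mi_means)],
         corrected = unname(coef(fit)[1L]), coef = coef(fit), x = xs,
         means = mi_means)
}

#' Bias-corrected mutual information by quadratic extrapolation
#'
#' Finite-sample (limited-sampling) bias in the plugin estimator is removed
#' by computing the plugin MI on random subsamples at fractions of the data,
#' regressing the mean subsample MI on the inverse effective sample size
#' \eqn{1/(fN)} with a quadratic polynomial, and reporting the intercept
#' (the extrapolation to infinite data). The full-data plugin value is
#' included as the \eqn{f = 1} point.
#'
#' @param cm a \code{\link{CountMatrix}}.
#' @param fractions subsampling fractions (default 0.5--0.95); the smallest
#'   must leave at least 10 trials per direction.
#' @param n_boot subsamples per fraction (default 50).
#' @param seed integer seed.
#' @param normalized also report the corrected MI divided by the plugin
#'   response entropy \eqn{H(k)} (default off).
#' @return data.frame with \code{neuron_id}, \code{plugin_bits},
#'   \code{corrected_bits} (and \code{normalized_bits} when requested).
#' @export
biasCorrectedMI <- function(cm, fractions = c(0.5, 0.6, 0.7, 0.8, 0.9, 0.95),
                            n_boot = 50L, seed = 1L, normalized = FALSE) {
    d <- dim(cm@counts)
    withSeed(deriveSeed(seed, "mi"), {
        res <- lapply(seq_len(d[1L]), function(i) {
            m <- t(matrix(cm@counts[i, , , drop = FALSE], nrow = d[2L]))
            cc <- correctedMIMatrix(m, fractions, n_boot)
            out <- data.frame(neuron_id = dimnames(cm@counts)[[1L]][i],
                              plugin_bits = cc$plugin,
                              corrected_bits = cc$corrected)
            if (normalized) {
                pk <- table(round(as.vector(m))) / length(m)
                H <- -sum(pk * log2(pk))
                out$normalized_bits <- if (H > 0) cc$corrected / H else NA_real_
            }
            out
        })
        do.call(rbind, res)
    })
}

#' Mutual-information time course from cumulative counts
#'
#' Applies the bias-corrected MI to cumulative spike counts in expanding
#' windows \code{[0, t)} for each requested time, per neuron.
#'
#' @param bt a \code{BinnedSpikeTensor}.
#' @param times_ms increasing evaluation times after motion onset, ms.
#' @inheritParams biasCorrectedMI
#' @return data.frame with \code{neuron_id}, \code{time_ms},
#'   \code{plugin_bits}, \code{corrected_bits}.
#' @export
miTimecourse <- function(bt, times_ms,
                         fractions = c(0.5, 0.6, 0.7, 0.8, 0.9, 0.95),
                         n_boot = 50L, seed = 1L) {
    out <- lapply(times_ms, function(t) {
        cm <- countInWindow(bt, c(0, t))
        mi <- biasCorrectedMI(cm, fractions = fractions, n_boot = n_boot,
                              seed = deriveSeed(seed, paste0("t", t)))
        mi$time_ms <- t
        mi
    })
    res <- do.call(rbind, out)
    res[, c("neuron_id", "time_ms", "plugin_bits", "corrected_bits")]
}

#' Write the MI CSV
#'
#' Header \code{neuron_id,time_ms,plugin_bits,corrected_bits}; a single
#' -1 is written for \code{time_ms} when the input has no time dimension.
#'
#' @param mi data.frame from \code{\link{biasCorrectedMI}} or
#'   \code{\link{miTimecourse}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMICSV <- function(mi, path) {
    if (!("time_ms" %in% names(mi))) mi$time_ms <- -1
    utils::write.csv(
        mi[, c("neuron_id", "time_ms", "plugin_bits", "corrected_bits")],
        path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
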