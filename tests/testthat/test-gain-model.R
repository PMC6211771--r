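test_that("predicted variance follows the approximate and exact laws", {
    expect_equal(predictVariance(7, GainModelParams(1, 0)), 7)   # FF = 1
    expect_equal(predictVariance(50, GainModelParams(0.74, 0.0732)),
                 201.1, tolerance = 1e-3)
    ## exact mode differs from the approximation by the Gamma moment only
    p <- GainModelParams(0.74, 0.0732)
    expect_equal(predictVariance(50, p, exact = TRUE) -
                 50^2 * 0.0732, 50^0.74 * gainMoment(0.74, 0.0732))
    expect_lt(abs(gainMoment(0.74, 0.0732) - 1), 0.02)
    expect_error(predictVariance(-1, p), "f_value")
})

test_that("model FF tuning flips sign with the gain-variance regime", {
    dirs <- seq(-90, 90, 15)
    tun <- replicate(6, TuningCurveFit(3, 12, 40, shape = "gaussian"))
    ## alpha = 1, var_g = 0: Poisson-like, FFTI centred at 0
    s0 <- predictFFTIDistribution(tun, GainModelParams(1, 0),
                                  n_trials = 2000, n_reps = 8, seed = 1,
                                  direction_grid = dirs)
    expect_lt(abs(mean(s0)), 0.05)
    ## alpha = 0.5, var_g = 0: FF decreases with rate, all FFTI > 0
    s1 <- predictFFTIDistribution(tun, GainModelParams(0.5, 0),
                                  n_trials = 2000, n_reps = 5, seed = 2,
                                  direction_grid = dirs)
    expect_true(all(s1 > 0))
    ## gain term dominating: FF grows with rate, FFTI < 0
    s2 <- predictFFTIDistribution(tun, GainModelParams(0.5, 0.3),
                                  n_trials = 2000, n_reps = 5, seed = 3,
                                  direction_grid = dirs)
    expect_true(all(s2 < 0))
})

test_that("expected FFTI decreases as gain variance grows", {
    dirs <- seq(-90, 90, 15)
    tun <- replicate(4, TuningCurveFit(3, 12, 40, shape = "gaussian"))
    means <- vapply(c(0, 0.01, 0.05, 0.2), function(v)
        mean(predictFFTIDistribution(tun, GainModelParams(0.5, v),
                                     n_trials = 800, n_reps = 5, seed = 4,
                                     direction_grid = dirs)),
        numeric(1L))
    expect_true(all(diff(means) < 0))
})

test_that("model FF is monotone in rate in the two regimes", {
    f <- seq(2, 30, by = 2)
    ## var_g = 0, alpha < 1: FF strictly decreasing in f
    expect_true(all(diff(predictFF(f, GainModelParams(0.5, 0))) < 0))
    ## strong gain: FF increasing where the second term dominates
    expect_true(all(diff(predictFF(f, GainModelParams(0.5, 0.5))) > 0))
})

test_that("the KS objective behaves at its degenerate extremes", {
    x <- rnorm(50)
    expect_equal(fanotune:::ksStatistic(x, x), 0)
    expect_equal(fanotune:::ksStatistic(rnorm(40, 10), rnorm(40, -10)), 1)
})

test_that("population KS fitting recovers generating parameters", {
    dirs <- seq(-90, 90, 15)
    tun <- replicate(8, TuningCurveFit(3, 12, 40, shape = "gaussian"))
    truth <- GainModelParams(0.7, 0.05)
    observed <- predictFFTIDistribution(tun, truth, n_trials = 150,
                                        n_reps = 15, seed = 10,
                                        direction_grid = dirs)
    grid_a <- c(0.3, 0.5, 0.7, 0.9, 1.1)
    grid_v <- c(0, 0.01, 0.05, 0.1)
    fit <- fitPopulationKS(observed, tun, grid_alpha = grid_a,
                           grid_var_g = grid_v, n_trials = 150,
                           n_reps = 15, seed = 11, direction_grid = dirs)
    expect_lte(abs(fit$alpha - 0.7), 0.2)            # at or adjacent
    expect_true(fit$var_g %in% c(0.01, 0.05, 0.1))
    expect_equal(nrow(fit$surface), length(grid_a) * length(grid_v))
    expect_true(all(fit$surface$ks_stat >= 0))
})

test_that("constrained two-state fits expose the shared-parameter asymmetry", {
    dirs <- seq(-90, 90, 15)
    tun <- replicate(6, TuningCurveFit(3, 12, 40, shape = "gaussian"))
    ## two states differing only in var_g (the central mechanism)
    obs_a <- predictFFTIDistribution(tun, GainModelParams(0.5, 0.005),
                                     n_trials = 150, n_reps = 15, seed = 20,
                                     direction_grid = dirs)
    obs_b <- predictFFTIDistribution(tun, GainModelParams(0.5, 0.1),
                                     n_trials = 150, n_reps = 15, seed = 21,
                                     direction_grid = dirs)
    grid_a <- c(0.3, 0.5, 0.7)
    grid_v <- c(0, 0.005, 0.02, 0.1, 0.2)
    fa <- fitConstrained(obs_a, obs_b, tun, tun, "shared_alpha",
                         grid_alpha = grid_a, grid_var_g = grid_v,
                         n_trials = 150, n_reps = 15, seed = 22,
                         direction_grid = dirs)
    ## shared-alpha fit recovers the two gain variances within the grid
    expect_lt(fa$state_a[["var_g"]], fa$state_b[["var_g"]])
    expect_lte(abs(fa$state_b[["var_g"]] - 0.1), 0.1)
    fv <- fitConstrained(obs_a, obs_b, tun, tun, "shared_var_g",
                         grid_alpha = grid_a, grid_var_g = grid_v,
                         n_trials = 150, n_reps = 15, seed = 22,
                         direction_grid = dirs)
    ## forcing a common var_g cannot explain states that differ only in
    ## var_g: the objective is strictly worse than under shared alpha
    expect_gt(fv$objective, fa$objective)
})

test_that("per-neuron least squares solves noiseless and degenerate cases", {
    f <- tuningValue(TuningCurveFit(3, 12, 40, shape = "gaussian"),
                     seq(-90, 90, 15))
    ## exact recovery from a noiseless model curve
    ff <- f^(0.74 - 1) + f * 0.0732
    fit <- fitNeuronLSQ(ff, f)
    expect_equal(fit$alpha, 0.74, tolerance = 1e-4)
    expect_equal(fit$var_g, 0.0732, tolerance = 1e-4)
    expect_lt(fit$rss, 1e-10)
    ## flat FF = 1 with varying f: unique exact solution alpha = 1, v = 0
    fit1 <- fitNeuronLSQ(rep(1, length(f)), f)
    expect_equal(fit1$alpha, 1, tolerance = 1e-4)
    expect_equal(fit1$var_g, 0, tolerance = 1e-6)
    expect_error(fitNeuronLSQ(c(1, 1), c(5, 6)), "5 directions")
})

test_that("high-FF positive-FFTI tuning is the documented failure mode", {
    f <- tuningValue(TuningCurveFit(3, 12, 40, shape = "gaussian"),
                     seq(-90, 90, 15))
    ## model-compatible curve fits essentially perfectly
    good <- f^(0.6 - 1) + f * 0.02
    ## large FF everywhere AND decreasing in f (positive FFTI): the model
    ## can only raise FF by raising alpha or var_g, which pushes FFTI the
    ## other way, so the fit misses badly
    bad <- 3 - 1.5 * (f - min(f)) / (max(f) - min(f))
    rss_good <- fitNeuronLSQ(good, f)$rss
    rss_bad <- fitNeuronLSQ(bad, f)$rss
    expect_lt(rss_good, 1e-8)
    expect_gt(rss_bad, 0.1)
})

test_that("gain-model fits serialise to JSON and CSV", {
    dirs <- seq(-90, 90, 15)
    tun <- replicate(4, TuningCurveFit(3, 12, 40, shape = "gaussian"))
    obs <- predictFFTIDistribution(tun, GainModelParams(0.6, 0.02),
                                   n_trials = 100, n_reps = 5, seed = 31,
                                   direction_grid = dirs)
    fit <- suppressWarnings(  # tiny demo grid may put the optimum on an edge
        fitPopulationKS(obs, tun, grid_alpha = c(0.4, 0.6, 0.8),
                        grid_var_g = c(0.005, 0.02, 0.08),
                        n_trials = 100, n_reps = 5, seed = 32,
                        direction_grid = dirs))
    fj <- withr::local_tempfile(fileext = ".json")
    fs <- withr::local_tempfile(fileext = ".csv")
    writeGainFit(fit, fj, fs)
    js <- jsonlite::read_json(fj)
    expect_equal(js$variant, "population_ks")
    expect_identical(names(read.csv(fs)), c("alpha", "var_g", "ks_stat"))
})
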