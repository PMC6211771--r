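test_that("the correlation kernel matches its closed-form anchors", {
    k <- CorrelationKernel(c_max = 0.1, kappa = 1)
    expect_equal(corrKernelValue(0, k), 0.1)
    expect_equal(corrKernelValue(180, k), 0, tolerance = 1e-15)
    ## even and periodic
    d <- seq(-180, 180, 10)
    expect_equal(corrKernelValue(d, k), corrKernelValue(-d, k))
    expect_equal(corrKernelValue(d, k), corrKernelValue(d + 360, k))
    expect_true(all(corrKernelValue(d, k) >= 0 &
                    corrKernelValue(d, k) <= 0.1))
    ## half-width at half-max is independent of c_max
    expect_equal(corrKernelHWHM(CorrelationKernel(0.05, 1)),
                 corrKernelHWHM(CorrelationKernel(0.9, 1)))
})

test_that("imposed FF tunings average to 1 and mirror about 1", {
    grid <- seq(-180, 165, 15)
    pos <- FFTuningSpec("positive", amplitude = 0.3, grid = grid)
    neg <- FFTuningSpec("negative", amplitude = 0.3, grid = grid)
    flat <- FFTuningSpec("flat")
    expect_equal(mean(ffTuningValue(pos, grid)), 1, tolerance = 1e-10)
    expect_equal(mean(ffTuningValue(neg, grid)), 1, tolerance = 1e-10)
    expect_equal(ffTuningValue(pos, grid) + ffTuningValue(neg, grid),
                 rep(2, length(grid)), tolerance = 1e-12)
    expect_equal(ffTuningValue(flat, grid), rep(1, length(grid)))
    ## positive sign dips at the preferred direction
    expect_lt(ffTuningValue(pos, 0), ffTuningValue(pos, 90))
    ## peak-to-trough modulation equals the amplitude
    vals <- ffTuningValue(pos, grid)
    expect_equal(max(vals) - min(vals), 0.3, tolerance = 1e-12)
})

test_that("covariance assembly matches hand arithmetic", {
    ## two neurons with equal preferred directions: c(0) = c_max = 0.05;
    ## variances 4 and 9 give off-diagonal 0.05 * sqrt(36) = 0.3
    pop <- new("PopulationModel",
               tuning = list(flatTuning(4, 0), flatTuning(9, 0)),
               ff_spec = FFTuningSpec("flat"),
               kernel = CorrelationKernel(0.05, 1), epsilon = 0,
               direction_grid = 0, kind = "homogeneous")
    cv <- buildCovariance(pop, 0)
    expect_equal(diag(cv$Sigma0), c(4, 9))
    expect_equal(cv$Sigma0[1, 2], 0.3)
    ## epsilon adds the rank-one outer product of the derivative
    pop2 <- pop; pop2@epsilon <- 1
    cv2 <- buildCovariance(pop2, 0)
    expect_equal(cv2$SigmaEps - cv2$Sigma0,
                 cv2$fprime %o% cv2$fprime, tolerance = 1e-12)
    ## c_max = 0 gives a diagonal covariance
    pop3 <- homogeneousPopulation(6, TuningCurveFit(5, 25, 2),
                                  kernel = CorrelationKernel(0, 1))
    s <- buildCovariance(pop3, 10)$Sigma0
    expect_true(all(s[upper.tri(s)] == 0))
})

test_that("analytic tuning derivatives agree with finite differences", {
    for (tc in list(TuningCurveFit(5, 25, 2, pref_direction = 30),
                    TuningCurveFit(3, 12, 40, pref_direction = -45,
                                   shape = "gaussian"))) {
        th <- seq(-170, 170, 20)
        expect_equal(tuningDerivative(tc, th),
                     tuningDerivative(tc, th, method = "fd"),
                     tolerance = 1e-6)
    }
})

test_that("linear Fisher information is additive for independent neurons", {
    pop <- homogeneousPopulation(24, TuningCurveFit(5, 25, 2),
                                 kernel = CorrelationKernel(0, 1),
                                 epsilon = 0, direction_grid = c(0, 45))
    res <- linearFisher(pop)
    for (i in seq_along(res@theta)) {
        cv <- buildCovariance(pop, res@theta[i])
        expect_equal(res@J0[i], sum(cv$fprime^2 / cv$var), tolerance = 1e-9)
    }
    ## epsilon = 0: J_eps equals J0 and the bound is 1/sqrt(J0)
    expect_equal(res@J_eps, res@J0)
    expect_equal(crBound(res), sqrt(1 / res@J0))
})

test_that("the rank-one information-limiting identity holds", {
    ## hand case: J0 = 1, epsilon = 4 gives J_eps = 0.2, bound sqrt(5)
    expect_equal(crBoundFromInfo(1, 4), sqrt(5))
    expect_equal(1 / (1 + 4 * 1), 0.2)
    ## random populations: direct inverse vs Eq-7 consistency is enforced
    ## inside linearFisher (errors beyond 1e-6 relative); J_eps < 1/eps
    withr::with_seed(121, {
        for (r in 1:5) {
            pool <- sampleTuningSet(10, baseline = c(2, 6),
                                    amplitude = c(10, 40), width = c(1, 3),
                                    shape = "von_mises", seed = 130 + r)
            pop <- heterogeneousPopulation(pool, 20, seed = 140 + r,
                                           kernel = CorrelationKernel(0.1, 1),
                                           epsilon = 4,
                                           direction_grid = c(0, 30, 77))
            res <- linearFisher(pop)
            expect_true(all(res@J_eps <= res@J0))
            expect_true(all(res@J_eps < 1 / 4))
            expect_true(all(crBound(res) > 2))
        }
    })
})

test_that("the bound approaches the information-limiting floor", {
    ## independent-neuron information grows linearly, so the floor is
    ## approached as N grows: evaluate the analytic large-N limit
    pop <- homogeneousPopulation(100, TuningCurveFit(5, 25, 2),
                                 kernel = CorrelationKernel(0, 1),
                                 epsilon = 4, direction_grid = 0)
    j1 <- linearFisher(pop)@J0 / 100          # per-neuron information
    J0_large <- j1 * 1e4
    expect_lt(crBoundFromInfo(J0_large, 4) - 2, 0.01 * 2)
    expect_gt(crBoundFromInfo(J0_large, 4), 2) # strictly above the floor
})

test_that("population-size search honours floors and closed forms", {
    curve <- TuningCurveFit(5, 25, 2)
    mk <- function(N) homogeneousPopulation(N, curve,
            kernel = CorrelationKernel(0, 1), epsilon = 4,
            direction_grid = seq(-180, 135, 45))
    ## threshold below the sqrt(epsilon) floor is unreachable
    un <- neuronsToThreshold(mk, 1.9)
    expect_true(un$unreachable)
    expect_true(is.na(un$min_N))
    ## closed form for independent homogeneous populations:
    ## 1/(j1 N) <= threshold^2 - epsilon
    res <- neuronsToThreshold(mk, 3, N_max = 512)
    j1 <- mean(linearFisher(mk(48))@J0) / 48
    expect_lte(abs(res$min_N - ceiling(1 / (j1 * 5))), 2)
    ## the evaluated curve is monotone non-increasing in N
    curve_df <- res$curve[order(res$curve$N), ]
    expect_true(all(diff(curve_df$bound) <= 1e-9))
})

test_that("time-to-threshold reflects latency and the scaling law", {
    grid8 <- seq(-180, 135, 45)
    mkT <- function(T, amp = 120) homogeneousPopulation(
        100, rampTuning(T, 20, amp, 56, 2),
        kernel = CorrelationKernel(0, 1), epsilon = 0,
        direction_grid = grid8)
    ## before latency there is no signal: bound infinite
    tt <- timeToThreshold(function(T) mkT(T), c(25, 50, 150, 250), 1.0)
    expect_true(all(!is.finite(tt$curve$bound[tt$curve$T_ms <= 56])))
    expect_true(all(is.finite(tt$curve$bound[tt$curve$T_ms > 56])))
    expect_true(all(diff(tt$curve$bound[tt$curve$T_ms > 56]) < 0))
    ## doubling all rates doubles J0, shrinking the bound by sqrt(2)
    popA <- homogeneousPopulation(100, rampTuning(250, 20, 120, 56, 2),
                                  kernel = CorrelationKernel(0, 1),
                                  epsilon = 0, direction_grid = grid8)
    popB <- homogeneousPopulation(100, rampTuning(250, 40, 240, 56, 2),
                                  kernel = CorrelationKernel(0, 1),
                                  epsilon = 0, direction_grid = grid8)
    rA <- linearFisher(popA); rB <- linearFisher(popB)
    expect_equal(rB@J0, 2 * rA@J0, tolerance = 1e-9)
    expect_equal(mean(crBound(rB)), mean(crBound(rA)) / sqrt(2),
                 tolerance = 1e-9)
})

test_that("heterogeneous population construction is seeded and tiled", {
    pool <- sampleTuningSet(5, baseline = c(2, 6), amplitude = c(10, 40),
                            width = c(1, 3), shape = "von_mises", seed = 8)
    ## pool of one curve reduces to a homogeneous population
    p1 <- heterogeneousPopulation(pool[1], 12, seed = 3)
    amps <- vapply(p1@tuning, function(tc) tc@amplitude, numeric(1))
    expect_true(all(amps == pool[[1]]@amplitude))
    prefs <- vapply(p1@tuning, function(tc) tc@pref_direction, numeric(1))
    expect_equal(sort(prefs), sort(fanotune:::wrapDegrees(seq(0, 330, 30))))
    ## sampling without replacement with N = pool size is a permutation
    p2 <- heterogeneousPopulation(pool, 5, seed = 4, replace = FALSE)
    a2 <- sort(vapply(p2@tuning, function(tc) tc@amplitude, numeric(1)))
    expect_equal(a2, sort(vapply(pool, function(tc) tc@amplitude,
                                 numeric(1))))
    ## reproducible under the same seed
    p3 <- heterogeneousPopulation(pool, 8, seed = 5)
    p4 <- heterogeneousPopulation(pool, 8, seed = 5)
    expect_identical(vapply(p3@tuning, function(tc) tc@amplitude, numeric(1)),
                     vapply(p4@tuning, function(tc) tc@amplitude, numeric(1)))
})
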