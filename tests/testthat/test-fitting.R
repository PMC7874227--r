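test_that("initial guesses implement the median head/tail rules", {
    ## 8 spatial bins whose rows are constant 1..8 -> row means 1..8;
    ## first three {1,2,3} -> nugget 2; last five {4,...,8} -> sill 6
    g <- matrix(rep(1:8, times = 13), 8, 13)
    np <- matrix(10, 8, 13)
    emp <- makeEmpirical(g, np, dist = seq(0, 30, length.out = 8),
                         edges = c(0, seq(2, 30, length.out = 7), 31),
                         lags = 0:12)
    init <- initialGuesses(emp)
    expect_equal(init@nugget, 2)
    expect_equal(init@sill, 6)
    expect_equal(init@rangeS, 10)    # max binned distance 30 / 3
    expect_equal(init@rangeT, 12)    # the maximum temporal lag
})

test_that("anisotropy is recovered from matched marginal levels", {
    ## metric truth with kappa = 2: marginals have identical shape with the
    ## spatial axis exactly 2x the temporal axis
    truth <- stModel("metric",
                     joint = variogramComponent("exponential", 0, 1, 20),
                     stAni = 2)
    dists <- seq(0, 60, length.out = 25)
    emp <- modelSurface(truth, dists, 0:20)
    expect_equal(estimateSTAnisotropy(emp), 2, tolerance = 0.05)
})

test_that("flat temporal marginals fall back to the range-guess ratio", {
    g <- matrix(rep(seq(0, 2, length.out = 10), times = 6), 10, 6)
    emp <- makeEmpirical(g, matrix(5, 10, 6), dist = seq(0, 45, length.out = 10),
                         edges = c(0, seq(5, 46, length.out = 10)), lags = 0:5)
    ## temporal marginal (row 1) is constant 0 -> flat -> fallback
    expect_equal(estimateSTAnisotropy(emp), (45 / 3) / 5)
})

test_that("anisotropy is recovered within 30% on a simulated metric field", {
    truth <- stModel("metric",
                     joint = variogramComponent("exponential", 0.05, 1, 25),
                     stAni = 5)
    net <- generateNetwork(18, seed = 14)
    panel <- simulateField(net, 40, truth, seed = 15)
    emp <- empiricalSTVariogram(panel)
    k <- estimateSTAnisotropy(emp)
    expect_gt(k, 5 * 0.7)
    expect_lt(k, 5 * 1.3)
})

test_that("fitting a noise-free model surface recovers it", {
    truth <- stModel("metric",
                     joint = variogramComponent("exponential", 0.2, 1.2, 18),
                     stAni = 3)
    emp <- modelSurface(truth, seq(0, 60, length.out = 16), 0:12)
    init <- initialGuesses(emp)
    fit <- fitSTModel(emp, "metric", c(joint = "exponential"), init)
    expect_true(fit@converged)
    expect_lt(fit@wmse, 1e-6)
    expect_equal(fit@model@joint@range, 18, tolerance = 1e-2)
    expect_equal(fit@model@joint@nugget, 0.2, tolerance = 1e-2)
    expect_equal(fit@model@stAni, 3, tolerance = 1e-2)
})

test_that("perturbing the start point barely moves the fitted range", {
    truth <- stModel("metric",
                     joint = variogramComponent("exponential", 0.2, 1.2, 18),
                     stAni = 3)
    emp <- modelSurface(truth, seq(0, 60, length.out = 16), 0:12)
    init <- initialGuesses(emp)
    ranges <- sapply(c(0.8, 1.0, 1.2), function(f) {
        ini <- new("STInitialValues", nugget = init@nugget * f,
                   sill = init@sill * f, nuggetT = init@nuggetT * f,
                   sillT = init@sillT * f, rangeS = init@rangeS * f,
                   rangeT = init@rangeT * f, stAni = init@stAni * f)
        fitSTModel(emp, "metric", c(joint = "exponential"), ini)@model@joint@range
    })
    expect_lt(max(abs(ranges / ranges[2] - 1)), 0.05)
})

test_that("an all-zero surface yields a degenerate zero-sill fit", {
    emp <- makeEmpirical(matrix(0, 6, 5), matrix(8, 6, 5),
                         dist = seq(0, 25, length.out = 6),
                         edges = c(0, seq(5, 26, length.out = 6)), lags = 0:4)
    fit <- fitSTModel(emp, "metric", c(joint = "spherical"))
    expect_lt(fit@wmse, 1e-12)
    expect_lt(totalSill(fit@model), 1e-6)
})

test_that("wmse weighting is scale invariant and bounds are enforced", {
    truth <- recoveryTruth()
    net <- generateNetwork(10, seed = 2)
    panel <- simulateField(net, 30, truth, seed = 3)
    emp <- empiricalSTVariogram(panel)
    fit <- fitSTModel(emp, "productSum",
                      c(spatial = "exponential", temporal = "spherical"))
    m <- fit@model
    for (cm in list(m@spatial, m@temporal)) {
        expect_gte(cm@nugget, 0)
        expect_gte(cm@sill, cm@nugget)
        expect_gt(cm@range, 0)
    }
    expect_gt(m@k, 0)
    ## wmse is invariant to uniform weight rescaling
    emp10 <- makeEmpirical(emp@gamma, emp@npairs * 10, emp@dist,
                           emp@binEdges, emp@temporalLags)
    expect_equal(wmse(m, emp), wmse(m, emp10))
})

test_that("the grid search enumerates all 75 candidates with a minimal winner", {
    truth <- recoveryTruth()
    net <- generateNetwork(8, seed = 4)
    panel <- simulateField(net, 25, truth, seed = 5)
    emp <- empiricalSTVariogram(panel, maxTemporalLag = 6)
    gs <- modelGridSearch(emp, maxit = 60)
    lb <- gs$leaderboard
    expect_equal(nrow(lb), 75)
    expect_equal(as.integer(table(lb$structure)[c(
        "metric", "separable", "productSum", "sumMetric", "simpleSumMetric")]),
        c(3L, 9L, 9L, 27L, 27L))
    expect_false(anyDuplicated(lb$candidate) > 0)
    ok <- is.finite(lb$wmse)
    expect_equal(gs$winner@wmse, min(lb$wmse[ok]))
    expect_true(all(gs$winner@wmse <= lb$wmse[ok]))
    ## the winner never fits worse than the true (separable) structure
    expect_lte(gs$winner@wmse,
               min(lb$wmse[ok & lb$structure == "separable"]))
})
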