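mkAll5 <- function() {
    sp <- variogramComponent("exponential", 0.1, 1, 20)
    tm <- variogramComponent("spherical", 0.05, 0.8, 10)
    j0 <- variogramComponent("gaussian", 0, 0.5, 15)
    list(
        separable = stModel("separable", spatial = sp, temporal = tm,
                            sill = 1.3),
        productSum = stModel("productSum", spatial = sp, temporal = tm,
                             k = 0.7),
        metric = stModel("metric", joint = j0, stAni = 2.5),
        sumMetric = stModel("sumMetric", spatial = sp, temporal = tm,
                            joint = j0, stAni = 2.5),
        simpleSumMetric = stModel("simpleSumMetric",
            spatial = variogramComponent("exponential", 0, 1, 20),
            temporal = variogramComponent("spherical", 0, 0.8, 10),
            joint = j0, stAni = 2.5, nugget = 0.3))
}

test_that("gamma(0,0) = 0 for every structure", {
    for (m in mkAll5())
        expect_identical(evalSTVariogram(m, 0, 0), 0)
})

test_that("metric structure evaluates the joint model at sqrt(h^2+(kappa*u)^2)", {
    j <- variogramComponent("spherical", 0, 1, 10)
    m <- stModel("metric", joint = j, stAni = 1)
    expect_equal(evalSTVariogram(m, 3, 4), evalComponent(j, 5))
    m2 <- stModel("metric", joint = j, stAni = 2)
    expect_equal(evalSTVariogram(m2, 0, 3), evalComponent(j, 6))
})

test_that("separable saturates at the overall sill", {
    sp <- variogramComponent("exponential", 0, 1, 5)
    tm <- variogramComponent("exponential", 0, 1, 5)
    m <- stModel("separable", spatial = sp, temporal = tm, sill = 2)
    expect_equal(evalSTVariogram(m, 1e6, 1e6), 2, tolerance = 1e-9)
    ## the constructor standardizes unstandardized components
    m2 <- stModel("separable",
                  spatial = variogramComponent("exponential", 0.2, 2, 5),
                  temporal = variogramComponent("exponential", 0, 0.5, 5))
    expect_equal(m2@spatial@sill, 1)
    expect_equal(m2@spatial@nugget, 0.1)
    expect_equal(m2@sill, 1)   # 2 * 0.5
})

test_that("simpleSumMetric applies its single nugget off the origin", {
    z <- function(r) variogramComponent("exponential", 0, 1e-12, r)
    m <- stModel("simpleSumMetric", spatial = z(1), temporal = z(1),
                 joint = z(1), stAni = 1, nugget = 0.3)
    expect_equal(evalSTVariogram(m, 0.5, 0), 0.3, tolerance = 1e-9)
    expect_equal(evalSTVariogram(m, 0, 2), 0.3, tolerance = 1e-9)
    expect_identical(evalSTVariogram(m, 0, 0), 0)
})

test_that("product-sum sill identity holds and is reached asymptotically", {
    expect_identical(productSumSill(2, 1, 0.5), 2.5)
    expect_identical(productSumSill(1e-12, 1, 1), 2 + 1e-12)
    expect_identical(productSumSill(1, 0, 3), 3)
    expect_error(productSumSill(0, 1, 1), "k must be > 0")
    expect_error(productSumSill(-1, 1, 1), "k must be > 0")
    m <- mkAll5()$productSum
    expect_equal(evalSTVariogram(m, 1e7, 1e7),
                 productSumSill(m@k, m@spatial@sill, m@temporal@sill),
                 tolerance = 1e-6)
})

test_that("sumMetric with a null joint component reduces to gamma_s + gamma_t", {
    sp <- variogramComponent("exponential", 0.1, 1, 20)
    tm <- variogramComponent("spherical", 0.05, 0.8, 10)
    zj <- variogramComponent("gaussian", 0, 1e-300, 5)
    m <- stModel("sumMetric", spatial = sp, temporal = tm, joint = zj,
                 stAni = 3)
    h <- c(0, 1, 7, 30); u <- c(0, 2, 5, 9)
    expect_equal(evalSTVariogram(m, h, u),
                 evalComponent(sp, h) + evalComponent(tm, u),
                 tolerance = 1e-12)
})

test_that("every structure is monotone along both axes", {
    h <- seq(0, 120, length.out = 60)
    u <- seq(0, 40, length.out = 60)
    for (m in mkAll5()) {
        gh <- evalSTVariogram(m, h, rep(3, 60))
        gu <- evalSTVariogram(m, rep(10, 60), u)
        expect_true(all(diff(gh[-1]) >= -1e-9))   # skip the origin jump
        expect_true(all(diff(gu[-1]) >= -1e-9))
    }
})

test_that("totalSill matches the asymptotic surface value", {
    for (m in mkAll5())
        expect_equal(evalSTVariogram(m, 1e7, 1e7), totalSill(m),
                     tolerance = 1e-6)
})

test_that("models survive a flat key-value round trip", {
    for (m in mkAll5()) {
        m2 <- stModelFromList(stModelToList(m))
        expect_equal(m2, m)
    }
})

test_that("structurally invalid compositions are rejected", {
    sp <- variogramComponent("exponential", 0.1, 1, 20)
    expect_error(stModel("metric", spatial = sp, stAni = 1), "joint")
    expect_error(stModel("productSum", spatial = sp,
                         temporal = sp, k = -1), "k > 0")
    expect_error(stModel("sumMetric", spatial = sp, temporal = sp,
                         joint = sp), "stAni")
    expect_error(stModel("simpleSumMetric", spatial = sp, temporal = sp,
                         joint = sp, stAni = 1, nugget = 0.1),
                 "zero nugget")
    expect_error(evalSTVariogram(mkAll5()$metric, -1, 0), "non-negative")
})
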