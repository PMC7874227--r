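test_that("station distances are haversine on a 6371 km sphere", {
    expect_equal(stationDistanceKm(c(0, 0), c(0, 0)), 0)
    expect_equal(stationDistanceKm(c(0, 0), c(1, 0)), 6371 * pi / 180,
                 tolerance = 1e-6)
    set.seed(21)
    for (i in 1:5) {
        a <- c(runif(1, -180, 180), runif(1, -60, 60))
        b <- c(runif(1, -180, 180), runif(1, -60, 60))
        expect_equal(stationDistanceKm(a, b), stationDistanceKm(b, a))
        expect_equal(stationDistanceKm(a, b),
                     havKm(a[1], a[2], b[1], b[2]), tolerance = 1e-9)
    }
    expect_error(stationDistanceKm(c(0, 95), c(0, 0)), "invalid")
})

test_that("worked examples match hand-computed semivariances", {
    ## three collinear stations at 0, 1, 2 km; single week of values 0, 1, 3
    st <- collinearStations()
    panel <- WeeklyPanel(matrix(c(0, 1, 3), 3, 1), st, as.Date("2012-01-02"))
    emp <- empiricalSTVariogram(panel, spatialBins = c(0, 0.5, 1.5, 2.5),
                                maxTemporalLag = 0)
    ## bin (0.5, 1.5]: pairs AB (diff 1) and BC (diff 2) -> (1+4)/(2*2)
    expect_equal(unname(emp@gamma[3, 1]), 1.25)
    expect_equal(unname(emp@npairs[3, 1]), 2)
    ## one station, two weeks 2 and 4 at lag 1 -> (4-2)^2 / 2
    p1 <- WeeklyPanel(matrix(c(2, 4), 1, 2),
                      data.frame(code = "A", lon = 0, lat = 0),
                      as.Date("2012-01-02") + c(0, 7))
    e1 <- empiricalSTVariogram(p1, spatialBins = c(0, 1), maxTemporalLag = 1)
    expect_equal(unname(e1@gamma[1, 2]), 2)
    expect_equal(unname(e1@npairs[1, 2]), 1)
})

test_that("a constant panel gives zero semivariance with positive pair counts", {
    st <- collinearStations()
    panel <- WeeklyPanel(matrix(7, 3, 5), st, as.Date("2012-01-02") + 7 * 0:4)
    emp <- empiricalSTVariogram(panel)
    expect_true(all(emp@gamma[emp@npairs > 0] == 0))
    expect_gt(sum(emp@npairs), 0)
})

test_that("estimates agree exactly with the brute-force all-pairs oracle", {
    set.seed(33)
    for (rep in 1:12) {
        n <- sample(2:6, 1); T <- sample(2:10, 1)
        st <- data.frame(code = sprintf("S%d", 1:n),
                         lon = runif(n, -99.4, -98.9),
                         lat = runif(n, 19.0, 19.6))
        Z <- matrix(rnorm(n * T), n, T)
        Z[runif(n * T) < 0.25] <- NA
        if (all(is.na(Z))) next
        maxLag <- sample(1:(T - 1), 1)
        dmax <- max(havKm(rep(st$lon, each = n), rep(st$lat, each = n),
                          st$lon, st$lat))
        edges <- seq(0, dmax * 1.0001, length.out = sample(3:6, 1))
        panel <- WeeklyPanel(Z, st, as.Date("2012-01-02") + 7 * (0:(T - 1)))
        emp <- empiricalSTVariogram(panel, spatialBins = edges,
                                    maxTemporalLag = maxLag)
        oracle <- bruteVariogram(Z, st, edges, maxLag)
        expect_equal(emp@npairs, oracle$npairs, ignore_attr = TRUE)
        has <- oracle$npairs > 0
        expect_equal(emp@gamma[has], oracle$gamma[has], tolerance = 1e-12)
    }
})

test_that("the grid is invariant to station relabeling", {
    set.seed(7)
    n <- 5; T <- 8
    st <- data.frame(code = sprintf("S%d", 1:n),
                     lon = runif(n, -99.4, -98.9), lat = runif(n, 19, 19.6))
    Z <- matrix(rnorm(n * T), n, T)
    panel <- WeeklyPanel(Z, st, as.Date("2012-01-02") + 7 * (0:(T - 1)))
    perm <- sample(n)
    panel2 <- WeeklyPanel(Z[perm, ], st[perm, ],
                          as.Date("2012-01-02") + 7 * (0:(T - 1)))
    e1 <- empiricalSTVariogram(panel, spatialBins = c(0, 20, 40, 80),
                               maxTemporalLag = 3)
    e2 <- empiricalSTVariogram(panel2, spatialBins = c(0, 20, 40, 80),
                               maxTemporalLag = 3)
    expect_equal(e1@gamma, e2@gamma)
    expect_equal(e1@npairs, e2@npairs)
})

test_that("removing a station never increases any pair count", {
    set.seed(8)
    n <- 6; T <- 6
    st <- data.frame(code = sprintf("S%d", 1:n),
                     lon = runif(n, -99.4, -98.9), lat = runif(n, 19, 19.6))
    Z <- matrix(rnorm(n * T), n, T)
    wk <- as.Date("2012-01-02") + 7 * (0:(T - 1))
    bins <- c(0, 20, 40, 80)
    full <- empiricalSTVariogram(WeeklyPanel(Z, st, wk), spatialBins = bins,
                                 maxTemporalLag = 3)
    drop <- empiricalSTVariogram(WeeklyPanel(Z[-2, ], st[-2, ], wk),
                                 spatialBins = bins, maxTemporalLag = 3)
    expect_true(all(drop@npairs <= full@npairs))
})

test_that("an all-missing panel raises an estimation error", {
    st <- collinearStations()
    panel <- WeeklyPanel(matrix(NA_real_, 3, 4), st,
                         as.Date("2012-01-02") + 7 * 0:3)
    expect_error(empiricalSTVariogram(panel), "no valid")
})

test_that("long-format serialization preserves every cell", {
    st <- collinearStations()
    panel <- WeeklyPanel(matrix(rnorm(12), 3, 4), st,
                         as.Date("2012-01-02") + 7 * 0:3)
    emp <- empiricalSTVariogram(panel, maxTemporalLag = 2)
    p <- withr::local_tempfile(fileext = ".csv")
    writeEmpiricalVariogram(emp, p)
    back <- read.csv(p)
    expect_equal(nrow(back), length(emp@gamma))
    expect_equal(sum(back$npairs), sum(emp@npairs))
    has <- !is.na(back$gamma)
    expect_equal(back$gamma[has], as.vector(emp@gamma)[!is.na(emp@gamma)])
})
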