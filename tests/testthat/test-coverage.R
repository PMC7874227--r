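## analytic area of the union of two equal circles at centre distance d
twoCircleUnion <- function(r, d) {
    if (d >= 2 * r) return(2 * pi * r^2)
    lens <- 2 * r^2 * acos(d / (2 * r)) - (d / 2) * sqrt(4 * r^2 - d^2)
    2 * pi * r^2 - lens
}

## place two stations d km apart along a parallel
twoStations <- function(d, lat = 19.3, lon = -99.1) {
    data.frame(code = c("A", "B"),
               lon = c(lon, lon + d / kmPerDegLon(lat)), lat = lat)
}

test_that("single- and two-circle areas match closed forms", {
    one <- bufferUnion(data.frame(code = "A", lon = -99.1, lat = 19.3), 5)
    expect_equal(one@coveredAreaKm2, pi * 25, tolerance = 1e-6)
    expect_equal(length(one@rings), 1)

    apart <- bufferUnion(twoStations(20), 5)
    expect_equal(apart@coveredAreaKm2, 2 * pi * 25, tolerance = 1e-6)
    expect_equal(length(apart@rings), 2)

    near <- bufferUnion(twoStations(6), 5)
    d <- stationDistanceKm(c(-99.1, 19.3),
                           c(-99.1 + 6 / kmPerDegLon(19.3), 19.3))
    expect_equal(near@coveredAreaKm2, twoCircleUnion(5, d),
                 tolerance = 0.005)
    expect_equal(length(near@rings), 1)
})

test_that("union area is subadditive with equality only for disjoint circles", {
    set.seed(40)
    for (rep in 1:4) {
        n <- sample(3:10, 1)
        st <- data.frame(code = sprintf("S%d", 1:n),
                         lon = runif(n, -99.3, -99.0),
                         lat = runif(n, 19.2, 19.5))
        r <- runif(1, 2, 12)
        u <- bufferUnion(st, r)
        expect_lte(u@coveredAreaKm2, n * pi * r^2 + 1e-9)
        D <- sapply(1:n, function(i) sapply(1:n, function(j)
            havKm(st$lon[i], st$lat[i], st$lon[j], st$lat[j])))
        disjoint <- all(D[upper.tri(D)] >= 2 * r)
        if (disjoint)
            expect_equal(u@coveredAreaKm2, n * pi * r^2, tolerance = 1e-6)
        else
            expect_lt(u@coveredAreaKm2, n * pi * r^2 - 1e-6)
    }
})

test_that("boundary rings enclose the exact union area", {
    net <- generateNetwork(12, seed = 3)
    u <- bufferUnion(net, 10)
    ringArea <- function(rg) {
        x <- rg[, "x"]; y <- rg[, "y"]
        sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
    }
    polyArea <- sum(vapply(u@rings, ringArea, numeric(1)))
    expect_equal(polyArea, u@coveredAreaKm2, tolerance = 0.005)
})

test_that("region fraction saturates, and is monotone in the radius", {
    reg <- squareRegion(-99.1, 19.3, 10)
    st <- data.frame(code = "A", lon = -99.1, lat = 19.3)
    expect_equal(bufferUnion(st, 50, region = reg)@regionFraction, 1.0)
    radii <- c(2, 4, 6, 9, 14)
    fr <- vapply(radii, function(r)
        bufferUnion(st, r, region = reg)@regionFraction, numeric(1))
    expect_true(all(diff(fr) >= 0))
    ## a 2 km circle covers pi*4/400 of the 20x20 km square
    expect_equal(fr[1], pi * 4 / 400, tolerance = 0.02)
})

test_that("active stations are counted from non-missing weekly cells", {
    net <- generateNetwork(3, seed = 6)
    wk <- seq(as.Date("2011-01-03"), by = 7, length.out = 105)
    vals <- matrix(1, 3, 105)
    panel <- WeeklyPanel(vals, net, wk)
    panel <- applyMissingness(panel,
                              activation = c(S02 = 60),   # mid-2012 start
                              shutdown = c(S03 = 52))     # stops end-2011
    expect_setequal(activeStations(panel, 2011), c("S01", "S03"))
    expect_setequal(activeStations(panel, 2012), c("S01", "S02"))
    expect_true("S02" %in% activeStations(panel, 2012, minWeeks = 10))
    expect_error(activeStations(panel, 2031), "span")
})

test_that("yearly coverage grows with network activations", {
    net <- generateNetwork(10, seed = 9)
    wk <- seq(as.Date("2011-01-03"), by = 7, length.out = 104)
    panel <- WeeklyPanel(matrix(1, 10, 104), net, wk)
    ## two stations only activate in year 2
    panel <- applyMissingness(panel, activation = c(S01 = 60, S02 = 60))
    reg <- squareRegion(mean(net$lon), mean(net$lat), 25)
    tl <- coverageTimeline(panel, radiusKm = 6, region = reg,
                           pollutant = "NO2")
    expect_named(tl, c("2011", "2012"))
    expect_gte(tl[["2012"]]@coveredAreaKm2, tl[["2011"]]@coveredAreaKm2)
    expect_gte(tl[["2012"]]@regionFraction, tl[["2011"]]@regionFraction)
    expect_equal(length(tl[["2011"]]@stationCodes), 8)
    expect_equal(length(tl[["2012"]]@stationCodes), 10)
    summ <- coverageSummary(tl)
    expect_equal(summ$n_active, c(8, 10))
    expect_equal(summ$radius_km, c(6, 6))
})

test_that("GeoJSON region and coverage round-trip through files", {
    p <- withr::local_tempfile(fileext = ".geojson")
    writeSquareRegionGeoJSON(p, -99.1, 19.3, 15)
    reg <- readRegionGeoJSON(p)
    expect_equal(length(reg), 1)
    expect_equal(nrow(reg[[1]]), 5)
    u <- bufferUnion(twoStations(6), 5, region = reg, pollutant = "CO",
                     year = 2015)
    out <- withr::local_tempfile(fileext = ".geojson")
    writeCoverageGeoJSON(u, out)
    gj <- jsonlite::fromJSON(out, simplifyVector = FALSE)
    expect_equal(gj$type, "FeatureCollection")
    ft <- gj$features[[1]]
    expect_equal(ft$geometry$type, "MultiPolygon")
    expect_equal(ft$properties$pollutant, "CO")
    expect_equal(ft$properties$year, 2015)
    expect_equal(ft$properties$covered_area_km2, u@coveredAreaKm2)
    ## ring coordinates are lon/lat near the stations
    ring <- ft$geometry$coordinates[[1]][[1]]
    lons <- vapply(ring, function(pt) pt[[1]], numeric(1))
    expect_true(all(abs(lons + 99.1) < 1))
})

test_that("degenerate coverage inputs are handled", {
    expect_error(bufferUnion(twoStations(5), 0), "radiusKm")
    empty <- bufferUnion(data.frame(code = character(0), lon = numeric(0),
                                    lat = numeric(0)), 5)
    expect_equal(empty@coveredAreaKm2, 0)
    expect_equal(length(empty@rings), 0)
    ## co-located stations collapse to a single circle
    co <- bufferUnion(data.frame(code = c("A", "B"), lon = -99.1, lat = 19.3), 4)
    expect_equal(co@coveredAreaKm2, pi * 16, tolerance = 1e-6)
})
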