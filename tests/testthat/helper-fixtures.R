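## Independent oracles and fixture builders shared across the suite.
## The oracles here deliberately use their own arithmetic (no calls into the
## code paths they check).

## plain haversine, Earth radius 6371 km
havKm <- function(lon1, lat1, lon2, lat2) {
    rad <- pi / 180
    dlat <- (lat2 - lat1) * rad / 2
    dlon <- (lon2 - lon1) * rad / 2
    a <- sin(dlat)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon)^2
    2 * 6371 * asin(pmin(1, sqrt(a)))
}

## O(n^2 T^2) brute-force space-time semivariogram: unordered station pairs,
## ordered time pairs (both orientations for u > 0, once for u = 0), the
## zero-distance bin first, half-open bins (e_{j-1}, e_j] beyond it
bruteVariogram <- function(Z, coords, edges, maxLag) {
    n <- nrow(Z); T <- ncol(Z)
    nb <- length(edges) - 1L
    ss <- np <- matrix(0, nb + 1L, maxLag + 1L)
    for (a in seq_len(n)) for (b in a:n) {
        d <- havKm(coords$lon[a], coords$lat[a], coords$lon[b], coords$lat[b])
        if (d == 0) bin <- 1L
        else {
            j <- which(d > edges[-length(edges)] & d <= edges[-1])
            if (!length(j)) next
            bin <- j + 1L
        }
        for (u in 0:maxLag) {
            if (u > T - 1L) next
            for (t in seq_len(T - u)) {
                orientations <- if (a == b) {
                    if (u == 0) list() else list(c(a, t, b, t + u))
                } else if (u == 0) list(c(a, t, b, t)) else
                    list(c(a, t, b, t + u), c(b, t, a, t + u))
                for (o in orientations) {
                    z1 <- Z[o[1], o[2]]; z2 <- Z[o[3], o[4]]
                    if (is.na(z1) || is.na(z2)) next
                    ss[bin, u + 1L] <- ss[bin, u + 1L] + (z1 - z2)^2
                    np[bin, u + 1L] <- np[bin, u + 1L] + 1
                }
            }
        }
    }
    list(gamma = ifelse(np > 0, ss / (2 * np), NaN), npairs = np)
}

## hand-built empirical variogram object (for fitting unit tests)
makeEmpirical <- function(gamma, npairs, dist, edges, lags) {
    new("EmpiricalSTVariogram", gamma = gamma, npairs = npairs,
        dist = dist, binEdges = edges, temporalLags = as.integer(lags))
}

## empirical object whose surface is exactly a model evaluation on a grid
modelSurface <- function(model, dists, lags, npairs = 100) {
    g <- outer(dists, lags, function(h, u) evalSTVariogram(model, h, u))
    edges <- c(0, dists + min(diff(c(0, dists))) / 2)
    makeEmpirical(g, matrix(npairs, length(dists), length(lags)),
                  dists, edges, lags)
}

## square region (side 2*halfKm) centred at (lonc, latc), as rings + GeoJSON
kmPerDegLon <- function(lat) 111.19493 * cos(lat * pi / 180)
squareRegion <- function(lonc, latc, halfKm) {
    dlat <- halfKm / 111.19493
    dlon <- halfKm / kmPerDegLon(latc)
    ring <- cbind(lon = lonc + c(-dlon, dlon, dlon, -dlon, -dlon),
                  lat = latc + c(-dlat, -dlat, dlat, dlat, -dlat))
    list(ring)
}
writeSquareRegionGeoJSON <- function(path, lonc, latc, halfKm) {
    ring <- squareRegion(lonc, latc, halfKm)[[1]]
    coords <- lapply(seq_len(nrow(ring)),
                     function(i) c(ring[i, "lon"], ring[i, "lat"]))
    gj <- list(type = "Feature", properties = list(name = "synthetic-square"),
               geometry = list(type = "Polygon", coordinates = list(coords)))
    writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = NA), path)
    path
}

## long hourly CSV from records; returns the path
writeHourlyCSV <- function(path, station, timestamp, pollutant, value) {
    write.csv(data.frame(station = station, timestamp = timestamp,
                         pollutant = pollutant, value = value),
              path, row.names = FALSE)
    path
}

## hourly timestamps covering `hours` hours of day `day` (ISO date string)
hoursOf <- function(day, hours) {
    sprintf("%sT%02d:00:00", day, hours)
}

## the parameter-recovery truth: separable exponential field
recoveryTruth <- function() {
    stModel("separable",
            spatial = variogramComponent("exponential", 0.1, 1, 40),
            temporal = variogramComponent("exponential", 0.1, 1, 8),
            sill = 1)
}

## collinear three-station catalogue at 0, 1, 2 km along the equator
collinearStations <- function() {
    data.frame(code = c("A", "B", "C"),
               lon = c(0, 1, 2) / 111.19493, lat = c(0, 0, 0))
}
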