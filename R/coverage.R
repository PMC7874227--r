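## Planar geometry for coverage maps.  Work happens in a local azimuthal
## equidistant projection (km) centred on the station centroid; the union of
## equal circles is computed exactly by arc decomposition + Green's theorem,
## so no polygon-clipping library is needed.

## ---- azimuthal equidistant projection -------------------------------------

.aeqdForward <- function(lonlat, center) {
    lonlat <- matrix(as.numeric(lonlat), ncol = 2)
    d <- geosphere::distHaversine(center, lonlat,
                                  r = .EARTH_RADIUS_KM * 1000) / 1000
    az <- geosphere::bearing(center, lonlat) * pi / 180
    az[is.na(az)] <- 0     # point coincides with the centre
    cbind(x = d * sin(az), y = d * cos(az))
}

.aeqdInverse <- function(xy, center) {
    xy <- matrix(as.numeric(xy), ncol = 2)
    d <- sqrt(rowSums(xy^2))
    az <- atan2(xy[, 1], xy[, 2]) * 180 / pi
    p <- geosphere::destPoint(center, az, d * 1000,
                              r = .EARTH_RADIUS_KM * 1000)
    colnames(p) <- c("lon", "lat")
    p
}

## ---- region polygons -------------------------------------------------------

#' Read a study-region polygon from GeoJSON
#'
#' Accepts a FeatureCollection, Feature or bare geometry containing a
#' Polygon or MultiPolygon in WGS84 lon/lat.
#'
#' @param path GeoJSON file.
#' @return a region object: list of rings, each a two-column lon/lat matrix
#'   (outer rings and holes; point-in-region uses the even-odd rule).
#' @export
readRegionGeoJSON <- function(path) {
    if (!file.exists(path)) stop("region file not found: ", path)
    g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (identical(g$type, "FeatureCollection")) g <- g$features[[1]]
    if (identical(g$type, "Feature")) g <- g$geometry
    ringMat <- function(ring)
        do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    rings <- switch(g$type,
        Polygon = lapply(g$coordinates, ringMat),
        MultiPolygon = unlist(lapply(g$coordinates, function(poly)
            lapply(poly, ringMat)), recursive = FALSE),
        stop("region must be a Polygon or MultiPolygon, got ", g$type))
    rings <- lapply(rings, function(m) {
        colnames(m) <- c("lon", "lat")
        m
    })
    if (any(vapply(rings, nrow, 1L) < 4L))
        stop("invalid region polygon: ring with fewer than 4 points")
    rings
}

## even-odd point-in-polygon over a list of rings (planar coordinates)
.pointsInRings <- function(pts, rings) {
    inside <- rep(FALSE, nrow(pts))
    for (ring in rings) {
        x <- ring[, 1]; y <- ring[, 2]
        n <- length(x)
        j <- c(n, seq_len(n - 1L))
        for (k in seq_len(n)) {
            xi <- x[k]; yi <- y[k]; xj <- x[j[k]]; yj <- y[j[k]]
            cross <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
                (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi) + xi)
            inside <- xor(inside, cross & !is.na(cross))
        }
    }
    inside
}

## ---- exact union of equal circles -----------------------------------------

## merge angular intervals (matrix th1, th2 within [0, 2pi] after splitting)
.mergeIntervals <- function(iv) {
    if (nrow(iv) == 0L) return(iv)
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    out <- iv[1, , drop = FALSE]
    for (i in seq_len(nrow(iv))[-1]) {
        if (iv[i, 1] <= out[nrow(out), 2] + 1e-12) {
            out[nrow(out), 2] <- max(out[nrow(out), 2], iv[i, 2])
        } else out <- rbind(out, iv[i, ])
    }
    out
}

## uncovered boundary arcs of each disk + exact union area (Green's theorem)
.diskUnion <- function(centers, r) {
    n <- nrow(centers)
    D <- as.matrix(dist(centers))
    arcs <- list()
    area <- 0
    for (i in seq_len(n)) {
        contained <- FALSE
        iv <- matrix(numeric(0), 0, 2)
        for (j in seq_len(n)) {
            if (j == i) next
            d <- D[i, j]
            if (d + 1e-12 >= 2 * r) next                    # disjoint
            if (d <= 1e-12) { if (j < i) { contained <- TRUE; break }; next }
            ## equal radii: neither disk contains the other when d > 0
            alpha <- atan2(centers[j, 2] - centers[i, 2],
                           centers[j, 1] - centers[i, 1])
            beta <- acos(pmin(1, pmax(-1, d / (2 * r))))
            th1 <- alpha - beta; th2 <- alpha + beta
            ## normalize into [0, 2pi), splitting wrap-around intervals
            th1 <- th1 %% (2 * pi); th2 <- th1 + 2 * beta
            if (th2 > 2 * pi) {
                iv <- rbind(iv, c(th1, 2 * pi), c(0, th2 - 2 * pi))
            } else iv <- rbind(iv, c(th1, th2))
        }
        if (contained) next
        iv <- .mergeIntervals(iv)
        ## complement of covered intervals
        free <- if (nrow(iv) == 0L) matrix(c(0, 2 * pi), 1) else {
            brk <- c(0, t(iv), 2 * pi)
            m <- matrix(brk, ncol = 2, byrow = TRUE)
            m[m[, 2] - m[, 1] > 1e-12, , drop = FALSE]
        }
        for (k in seq_len(nrow(free))) {
            th1 <- free[k, 1]; th2 <- free[k, 2]
            cx <- centers[i, 1]; cy <- centers[i, 2]
            area <- area + 0.5 * (r^2 * (th2 - th1) +
                r * (cx * (sin(th2) - sin(th1)) - cy * (cos(th2) - cos(th1))))
            arcs[[length(arcs) + 1L]] <- list(i = i, th1 = th1, th2 = th2)
        }
    }
    list(area = unname(area), arcs = arcs)
}

## chain uncovered arcs into closed rings (planar polylines)
.chainArcs <- function(arcs, centers, r, segPerQuadrant = 64) {
    if (!length(arcs)) return(list())
    pt <- function(a, th) centers[a$i, ] + r * c(cos(th), sin(th))
    starts <- t(vapply(arcs, function(a) pt(a, a$th1), numeric(2)))
    ends <- t(vapply(arcs, function(a) pt(a, a$th2), numeric(2)))
    used <- rep(FALSE, length(arcs))
    tol <- max(1e-9, 1e-7 * r)
    discretize <- function(a) {
        nseg <- max(2L, ceiling((a$th2 - a$th1) / (pi / 2) * segPerQuadrant))
        th <- seq(a$th1, a$th2, length.out = nseg + 1L)
        cbind(centers[a$i, 1] + r * cos(th), centers[a$i, 2] + r * sin(th))
    }
    rings <- list()
    repeat {
        i0 <- which(!used)[1]
        if (is.na(i0)) break
        used[i0] <- TRUE
        ring <- discretize(arcs[[i0]])
        closed <- sum((ends[i0, ] - starts[i0, ])^2) < tol^2
        cur <- i0
        while (!closed) {
            cand <- which(!used)
            if (!length(cand)) break
            d2 <- rowSums((starts[cand, , drop = FALSE] -
                           matrix(ends[cur, ], length(cand), 2,
                                  byrow = TRUE))^2)
            nxt <- cand[which.min(d2)]
            if (min(d2) > (10 * tol)^2) break    # open chain: give up cleanly
            used[nxt] <- TRUE
            ring <- rbind(ring, discretize(arcs[[nxt]])[-1, , drop = FALSE])
            cur <- nxt
            closed <- sum((ends[cur, ] - starts[i0, ])^2) < tol^2
        }
        ring <- rbind(ring, ring[1, ])
        rings[[length(rings) + 1L]] <- ring
    }
    rings
}

## ---- user-facing operations ------------------------------------------------

#' Stations active in a calendar year
#'
#' @param panel a [WeeklyPanel-class].
#' @param year ISO week-based calendar year.
#' @param minWeeks minimum non-missing weekly values required (default 1).
#' @return character vector of station codes.
#' @export
activeStations <- function(panel, year, minWeeks = 1) {
    yrs <- SummarizedExperiment::colData(panel)$year
    if (!year %in% yrs) stop("year ", year, " outside the panel span")
    v <- panelValues(panel)[, yrs == year, drop = FALSE]
    rownames(v)[rowSums(!is.na(v)) >= minWeeks]
}

#' Union-of-circles coverage map
#'
#' Places a circle of radius \code{radiusKm} (the fitted spatial correlation
#' range) around every station and forms their geometric union in a local
#' azimuthal equidistant plane.  The union area is exact (arc decomposition,
#' Green's theorem); the fraction of the study region covered is evaluated on
#' a deterministic grid of cell centres inside the region polygon.
#'
#' @param stations data.frame with \code{code}, \code{lon}, \code{lat}.
#' @param radiusKm circle radius in km, > 0.
#' @param region optional region rings from [readRegionGeoJSON()]; without it
#'   \code{regionFraction} is \code{NA}.
#' @param pollutant,year metadata stored in the result.
#' @param projCenter optional lon/lat projection centre (defaults to the
#'   station centroid); pass a fixed centre when comparing maps across years.
#' @param gridN region-fraction grid resolution per axis (default 200).
#' @return a [CoverageMap-class].
#' @export
bufferUnion <- function(stations, radiusKm, region = NULL, pollutant = "",
                        year = NA_integer_, projCenter = NULL, gridN = 200) {
    if (radiusKm <= 0) stop("radiusKm must be > 0")
    if (nrow(stations) == 0L) {
        return(new("CoverageMap", pollutant = pollutant,
                   year = as.integer(year), radiusKm = radiusKm,
                   stationCodes = character(0),
                   centers = matrix(numeric(0), 0, 2), rings = list(),
                   coveredAreaKm2 = 0,
                   regionFraction = if (is.null(region)) NA_real_ else 0,
                   projCenter = c(NA_real_, NA_real_)))
    }
    if (is.null(projCenter))
        projCenter <- c(mean(stations$lon), mean(stations$lat))
    ctr <- .aeqdForward(cbind(stations$lon, stations$lat), projCenter)
    un <- .diskUnion(ctr, radiusKm)
    rings <- .chainArcs(un$arcs, ctr, radiusKm)
    rings <- lapply(rings, function(rg) {
        ll <- .aeqdInverse(rg, projCenter)
        cbind(x = rg[, 1], y = rg[, 2], lon = ll[, 1], lat = ll[, 2])
    })
    frac <- NA_real_
    if (!is.null(region)) {
        regXY <- lapply(region, function(rg)
            .aeqdForward(rg[, c("lon", "lat")], projCenter))
        allXY <- do.call(rbind, regXY)
        gx <- seq(min(allXY[, 1]), max(allXY[, 1]), length.out = gridN)
        gy <- seq(min(allXY[, 2]), max(allXY[, 2]), length.out = gridN)
        pts <- cbind(rep(gx, times = gridN), rep(gy, each = gridN))
        inReg <- .pointsInRings(pts, regXY)
        pts <- pts[inReg, , drop = FALSE]
        if (nrow(pts) == 0L) stop("degenerate region polygon")
        inUnion <- rep(FALSE, nrow(pts))
        for (i in seq_len(nrow(ctr)))
            inUnion <- inUnion |
                ((pts[, 1] - ctr[i, 1])^2 + (pts[, 2] - ctr[i, 2])^2 <=
                 radiusKm^2)
        frac <- mean(inUnion)
    }
    new("CoverageMap", pollutant = pollutant, year = as.integer(year),
        radiusKm = radiusKm, stationCodes = as.character(stations$code),
        centers = cbind(lon = stations$lon, lat = stations$lat),
        rings = rings, coveredAreaKm2 = un$area, regionFraction = frac,
        projCenter = projCenter)
}

#' Yearly coverage timeline
#'
#' One [CoverageMap-class] per requested year, each using the stations active
#' that year and the single whole-period fitted radius.  All maps share one
#' projection centre (the full-network centroid) so areas are comparable.
#'
#' @param panel a [WeeklyPanel-class].
#' @param radiusKm fitted spatial range in km.
#' @param region optional region rings from [readRegionGeoJSON()].
#' @param years integer years; default all years in the panel.
#' @param minWeeks activity threshold passed to [activeStations()].
#' @param pollutant metadata label.
#' @return a named list of [CoverageMap-class], one per year.
#' @export
coverageTimeline <- function(panel, radiusKm, region = NULL, years = NULL,
                             minWeeks = 1, pollutant = "") {
    if (is.null(years))
        years <- sort(unique(SummarizedExperiment::colData(panel)$year))
    st <- panelStations(panel)
    center <- c(mean(st$lon), mean(st$lat))
    maps <- lapply(years, function(y) {
        act <- activeStations(panel, y, minWeeks)
        bufferUnion(st[st$code %in% act, , drop = FALSE], radiusKm, region,
                    pollutant = pollutant, year = y, projCenter = center)
    })
    names(maps) <- years
    maps
}

#' Coverage summary table
#'
#' @param maps list of [CoverageMap-class] (e.g. from [coverageTimeline()]).
#' @return data.frame with columns \code{pollutant}, \code{year},
#'   \code{n_active}, \code{radius_km}, \code{covered_area_km2},
#'   \code{region_fraction}.
#' @export
coverageSummary <- function(maps) {
    do.call(rbind, lapply(maps, function(m) data.frame(
        pollutant = m@pollutant, year = m@year,
        n_active = length(m@stationCodes), radius_km = m@radiusKm,
        covered_area_km2 = m@coveredAreaKm2,
        region_fraction = m@regionFraction)))
}

#' Write a coverage map as GeoJSON
#'
#' Rings with positive signed area become outer boundaries; negative rings
#' are emitted as holes of the outer ring containing them.  Coordinates are
#' WGS84 lon/lat.
#'
#' @param map a [CoverageMap-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeCoverageGeoJSON <- function(map, path) {
    ringArea <- function(rg) {
        x <- rg[, "x"]; y <- rg[, "y"]
        sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
    }
    sgn <- vapply(map@rings, ringArea, numeric(1))
    outers <- which(sgn >= 0); holes <- which(sgn < 0)
    coords <- lapply(outers, function(i) {
        shell <- map@rings[[i]][, c("lon", "lat"), drop = FALSE]
        polys <- list(lapply(seq_len(nrow(shell)),
                             function(k) as.numeric(shell[k, ])))
        for (hidx in holes) {
            p <- map@rings[[hidx]][1, c("x", "y"), drop = FALSE]
            if (.pointsInRings(p, list(map@rings[[i]][, c("x", "y")]))) {
                hring <- map@rings[[hidx]][, c("lon", "lat"), drop = FALSE]
                polys[[length(polys) + 1L]] <- lapply(
                    seq_len(nrow(hring)), function(k) as.numeric(hring[k, ]))
            }
        }
        polys
    })
    feature <- list(type = "Feature",
                    properties = list(pollutant = map@pollutant,
                                      year = map@year,
                                      radius_km = map@radiusKm,
                                      n_active = length(map@stationCodes),
                                      covered_area_km2 = map@coveredAreaKm2,
                                      region_fraction = map@regionFraction),
                    geometry = list(type = "MultiPolygon",
                                    coordinates = coords))
    gj <- list(type = "FeatureCollection", features = list(feature))
    writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = NA,
                                null = "null"), path)
    invisible(path)
}

setMethod("show", "CoverageMap", function(object) {
    cat(sprintf(
        "coverage map%s%s: %d stations, radius %.2f km, area %.1f km^2%s\n",
        if (nzchar(object@pollutant)) paste0(" ", object@pollutant) else "",
        if (is.na(object@year)) "" else paste0(" ", object@year),
        length(object@stationCodes), object@radiusKm, object@coveredAreaKm2,
        if (is.na(object@regionFraction)) "" else
            sprintf(", region fraction %.3f", object@regionFraction)))
})
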