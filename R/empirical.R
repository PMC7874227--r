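#' Great-circle distance between stations
#'
#' Haversine distance on a sphere of radius 6371 km.  Inputs may be
#' single-row data.frames (with \code{lon}, \code{lat}) or length-2 numeric
#' vectors \code{c(lon, lat)}.
#'
#' @param a,b station coordinates.
#' @return distance in km.
#' @examples
#' stationDistanceKm(c(0, 0), c(1, 0))  # ~111.195
#' @export
stationDistanceKm <- function(a, b) {
    xy <- function(p) {
        if (is.data.frame(p)) p <- c(p$lon[1], p$lat[1])
        p
    }
    a <- xy(a); b <- xy(b)
    if (any(abs(c(a[2], b[2])) > 90) || any(abs(c(a[1], b[1])) > 180))
        stop("invalid coordinates")
    geosphere::distHaversine(a, b, r = .EARTH_RADIUS_KM * 1000) / 1000
}

## full pairwise haversine matrix (km) for a station catalogue
.distMatrixKm <- function(stations) {
    p <- cbind(stations$lon, stations$lat)
    m <- geosphere::distm(p, fun = geosphere::distHaversine) / 1000 *
        (.EARTH_RADIUS_KM / 6378.137)
    dimnames(m) <- list(stations$code, stations$code)
    m
}

#' Empirical space-time semivariogram
#'
#' Estimates \eqn{\hat\gamma(h, u) = \frac{1}{2N(h,u)} \sum
#' [Z(s_a, t) - Z(s_b, t+u)]^2} over all station pairs whose great-circle
#' distance falls in spatial bin \eqn{h} and all week pairs at integer lag
#' \eqn{u \ge 0}; pairs with a missing value on either side are excluded.
#' Station pairs are counted once (unordered) per ordered time pair; the
#' zero-distance bin holds same-station (purely temporal) comparisons.
#'
#' @param panel a [WeeklyPanel-class].
#' @param stations optional station catalogue overriding the panel's
#'   coordinates.
#' @param spatialBins increasing vector of bin edges in km starting at 0;
#'   default 15 equal-width bins up to the maximum inter-station distance.
#' @param maxTemporalLag largest lag in weeks (default one third of the panel
#'   length).
#' @return an [EmpiricalSTVariogram-class].
#' @export
empiricalSTVariogram <- function(panel, stations = NULL, spatialBins = NULL,
                                 maxTemporalLag = NULL) {
    Z <- panelValues(panel)
    if (!is.null(stations)) {
        m <- match(rownames(Z), stations$code)
        if (anyNA(m)) stop("panel stations missing from catalogue")
        coords <- stations[m, , drop = FALSE]
    } else coords <- panelStations(panel)
    n <- nrow(Z); T <- ncol(Z)
    if (n < 1L || T < 1L) stop("empty panel")
    D <- .distMatrixKm(coords)
    if (is.null(maxTemporalLag))
        maxTemporalLag <- max(1L, floor(T / 3))
    maxTemporalLag <- min(maxTemporalLag, T - 1L)
    if (is.null(spatialBins)) {
        dmax <- max(D)
        if (dmax <= 0) dmax <- 1
        spatialBins <- seq(0, dmax, length.out = 16L)
    }
    if (any(diff(spatialBins) <= 0) || spatialBins[1] != 0)
        stop("spatialBins must be strictly increasing from 0")
    edges <- spatialBins
    nb <- length(edges) - 1L
    ## bin index: 1 = zero-distance, 1+j = (edges[j], edges[j+1]]
    bin <- matrix(1L, n, n)
    pos <- D > 0
    bi <- findInterval(D[pos], edges, left.open = TRUE, rightmost.closed = TRUE)
    bi[D[pos] > edges[nb + 1L]] <- NA  # beyond the last edge: excluded
    bin[pos] <- bi + 1L

    W <- !is.na(Z)
    Z0 <- ifelse(W, Z, 0)
    lags <- 0:maxTemporalLag
    nbins <- nb + 1L
    SS <- matrix(0, nbins, length(lags))
    NP <- matrix(0, nbins, length(lags))
    distSum <- numeric(nbins)
    distN <- numeric(nbins)

    for (li in seq_along(lags)) {
        u <- lags[li]
        A <- Z0[, seq_len(T - u), drop = FALSE]
        B <- Z0[, (u + 1L):T, drop = FALSE]
        Wa <- W[, seq_len(T - u), drop = FALSE] + 0
        Wb <- W[, (u + 1L):T, drop = FALSE] + 0
        ## M[a,b] = sum_t (Z[a,t] - Z[b,t+u])^2 over valid pairs
        M <- (A^2 %*% t(Wb)) + (Wa %*% t(B^2)) - 2 * (A %*% t(B))
        Np <- Wa %*% t(Wb)
        ## unordered station pair, ordered time pair: for u > 0 the two
        ## orientations (a at t, b at t+u) and (b at t, a at t+u) are
        ## distinct pairs; at u = 0 they coincide and count once
        if (u == 0L) {
            ssM <- M; npM <- Np
            ## (a,t) with itself is a degenerate pair: drop the diagonal
            diag(ssM) <- 0; diag(npM) <- 0
        } else {
            ssM <- M + t(M); npM <- Np + t(Np)
            diag(ssM) <- diag(M); diag(npM) <- diag(Np)
        }
        keep <- upper.tri(ssM, diag = TRUE) & !is.na(bin)
        b <- bin[keep]
        SS[, li] <- SS[, li] + as.numeric(
            tapply(ssM[keep], factor(b, levels = seq_len(nbins)), sum,
                   default = 0))
        NP[, li] <- NP[, li] + as.numeric(
            tapply(npM[keep], factor(b, levels = seq_len(nbins)), sum,
                   default = 0))
        wsum <- tapply(npM[keep] * D[keep],
                       factor(b, levels = seq_len(nbins)), sum, default = 0)
        distSum <- distSum + as.numeric(wsum)
    }
    distN <- rowSums(NP)
    if (sum(NP) == 0) stop("no valid station/time pairs anywhere")

    gamma <- ifelse(NP > 0, SS / (2 * NP), NaN)
    gamma[gamma < 0] <- 0   # guard against tiny negative round-off
    mids <- (edges[-1] + edges[-(nb + 1L)]) / 2
    dist <- ifelse(distN > 0, distSum / distN, c(0, mids))
    dist[1] <- 0
    dimnames(gamma) <- dimnames(NP) <-
        list(sprintf("%.3f", dist), paste0("lag", lags))
    new("EmpiricalSTVariogram", gamma = gamma, npairs = NP, dist = dist,
        binEdges = edges, temporalLags = as.integer(lags))
}

#' Long-format view of an empirical variogram
#'
#' @param x an [EmpiricalSTVariogram-class].
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with columns \code{dist_km}, \code{lag_weeks},
#'   \code{gamma}, \code{npairs}, one row per grid cell.
#' @export
as.data.frame.EmpiricalSTVariogram <- function(x, row.names = NULL,
                                               optional = FALSE, ...) {
    data.frame(dist_km = rep(x@dist, times = ncol(x@gamma)),
               lag_weeks = rep(x@temporalLags, each = nrow(x@gamma)),
               gamma = as.vector(x@gamma),
               npairs = as.vector(x@npairs))
}

#' Write an empirical variogram as long-format CSV
#'
#' @param emp an [EmpiricalSTVariogram-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeEmpiricalVariogram <- function(emp, path) {
    write.csv(as.data.frame(emp), path, row.names = FALSE)
    invisible(path)
}

setMethod("show", "EmpiricalSTVariogram", function(object) {
    cat(sprintf(
        "empirical space-time semivariogram: %d spatial bins (0-%.1f km) x %d lags, %d pairs\n",
        nrow(object@gamma), max(object@binEdges),
        length(object@temporalLags), sum(object@npairs)))
})

#' Plot an empirical space-time variogram surface
#'
#' @param x an [EmpiricalSTVariogram-class].
#' @param y ignored.
#' @param ... passed to [graphics::image()].
#' @return invisibly, \code{NULL}.
#' @export
setMethod("plot", signature(x = "EmpiricalSTVariogram", y = "missing"),
          function(x, y, ...) {
    graphics::image(x = x@dist, y = x@temporalLags, z = x@gamma,
                    xlab = "distance (km)", ylab = "lag (weeks)",
                    col = grDevices::hcl.colors(32, "viridis"), ...)
    invisible(NULL)
})
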