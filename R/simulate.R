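## Seeded synthetic data: station networks and Gaussian random fields with a
## prescribed space-time semivariogram, plus the structured missingness seen
## in real monitoring records (late activation, outages, shutdown, dropout).

## evaluate expr with a local, restored RNG state
.withSeed <- function(seed, expr) {
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = env) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = env)
        else if (exists(".Random.seed", envir = env, inherits = FALSE))
            rm(".Random.seed", envir = env)
    })
    set.seed(seed)
    expr
}

## default study region: a roughly 60 x 60 km box at Mexico City's latitude
.DEFAULT_BBOX <- c(lonMin = -99.44, lonMax = -98.86,
                   latMin = 19.05, latMax = 19.59)

#' Generate a synthetic monitoring network
#'
#' Uniform station locations inside a bounding box (optionally rejected into
#' a region polygon), with unique three-letter-style codes.  Deterministic
#' under \code{seed}.
#'
#' @param nStations number of stations (>= 2).
#' @param seed RNG seed.
#' @param bbox named vector \code{lonMin, lonMax, latMin, latMax}; the
#'   default spans a ~60 x 60 km metropolitan box.
#' @param region optional region rings ([readRegionGeoJSON()]); stations are
#'   rejection-sampled to fall inside.
#' @return data.frame with \code{code}, \code{lon}, \code{lat}.
#' @export
generateNetwork <- function(nStations, seed = 1, bbox = .DEFAULT_BBOX,
                            region = NULL) {
    stopifnot(nStations >= 2)
    if (bbox[["lonMax"]] <= bbox[["lonMin"]] ||
        bbox[["latMax"]] <= bbox[["latMin"]])
        stop("degenerate bounding box")
    .withSeed(seed, {
        pts <- matrix(numeric(0), 0, 2)
        tries <- 0L
        while (nrow(pts) < nStations) {
            m <- 4L * nStations
            cand <- cbind(runif(m, bbox[["lonMin"]], bbox[["lonMax"]]),
                          runif(m, bbox[["latMin"]], bbox[["latMax"]]))
            if (!is.null(region))
                cand <- cand[.pointsInRings(cand, region), , drop = FALSE]
            pts <- rbind(pts, cand)
            tries <- tries + 1L
            if (tries > 100L) stop("degenerate region: rejection sampling failed")
        }
        pts <- pts[seq_len(nStations), , drop = FALSE]
        data.frame(code = sprintf("S%02d", seq_len(nStations)),
                   lon = pts[, 1], lat = pts[, 2], stringsAsFactors = FALSE)
    })
}

.cholWithJitter <- function(C, scale, what) {
    for (jit in c(0, 1e-12, 1e-10, 1e-8) * scale) {
        R <- tryCatch(chol(C + diag(jit, nrow(C))), error = function(e) NULL)
        if (!is.null(R)) return(R)
    }
    stop("covariance of ", what,
         " is not positive semi-definite (jitter up to 1e-8 * sill failed)")
}

#' Simulate a weekly Gaussian random field
#'
#' Draws one zero-mean Gaussian realization on the station x week grid whose
#' space-time semivariogram is \code{truth}: the dense covariance
#' \eqn{C(h, u) = sill_{total} - \gamma(h, u)} is assembled over all cell
#' pairs and factorized (Cholesky, with diagonal jitter up to
#' \eqn{10^{-8} \times} sill).  For the separable structure the covariance is
#' a Kronecker product and is factorized per axis, which keeps large grids
#' cheap.  Optional white measurement noise adds an extra nugget.
#'
#' @param stations station catalogue (\code{code}, \code{lon}, \code{lat}).
#' @param nWeeks number of consecutive weeks (>= 2).
#' @param truth an [STVariogramModel-class].
#' @param seed RNG seed.
#' @param noiseVar extra nugget variance of independent measurement noise.
#' @param startWeek Date of the first week's Monday.
#' @return a [WeeklyPanel-class] with a complete (no-missing) value grid.
#' @export
simulateField <- function(stations, nWeeks, truth, seed = 1, noiseVar = 0,
                          startWeek = as.Date("2009-01-05")) {
    stopifnot(nWeeks >= 2, noiseVar >= 0)
    n <- nrow(stations)
    N <- n * nWeeks
    D <- .distMatrixKm(stations)
    sill <- totalSill(truth)
    if (sill <= 0 && noiseVar == 0)    # degenerate: constant (zero) field
        return(WeeklyPanel(matrix(0, n, nWeeks), stations,
                           seq(startWeek, by = 7L, length.out = nWeeks)))
    vals <- .withSeed(seed, {
        if (truth@structure == "separable") {
            gs <- evalComponent(truth@spatial, D)
            Cs <- truth@sill * (1 - matrix(gs, n, n))
            U <- abs(outer(seq_len(nWeeks), seq_len(nWeeks), "-"))
            Ct <- 1 - matrix(evalComponent(truth@temporal, U),
                             nWeeks, nWeeks)
            Ls <- t(.cholWithJitter(Cs, truth@sill, "the spatial factor"))
            Rt <- .cholWithJitter(Ct, 1, "the temporal factor")
            Z <- matrix(rnorm(N), n, nWeeks)
            Ls %*% Z %*% Rt
        } else {
            if (N > 20000L)
                stop("grid too large for dense covariance simulation (",
                     N, " cells > 20000)")
            ## cell order: station fastest, week slowest
            si <- rep(seq_len(n), times = nWeeks)
            ti <- rep(seq_len(nWeeks), each = n)
            H <- D[cbind(rep(si, times = N), rep(si, each = N))]
            Uu <- abs(ti[rep(seq_len(N), times = N)] -
                      ti[rep(seq_len(N), each = N)])
            C <- matrix(sill - evalSTVariogram(truth, H, Uu), N, N)
            R <- .cholWithJitter(C, sill,
                                 paste0("structure '", truth@structure, "'"))
            matrix(t(R) %*% rnorm(N), n, nWeeks)
        }
    })
    if (noiseVar > 0)
        vals <- vals + .withSeed(seed + 1L,
            matrix(rnorm(N, sd = sqrt(noiseVar)), n, nWeeks))
    WeeklyPanel(vals, stations, seq(startWeek, by = 7L,
                                    length.out = nWeeks))
}

#' Impose structured missingness on a panel
#'
#' Reproduces the gap patterns of real monitoring records: cells before a
#' station's activation week, after its shutdown week, inside outage blocks,
#' or hit by seeded random dropout become missing; everything else is
#' unchanged.
#'
#' @param panel a [WeeklyPanel-class].
#' @param activation named integer vector: first active week index per
#'   station (stations not named are active from week 1).
#' @param shutdown named integer vector: last active week index per station.
#' @param outages data.frame with \code{station}, \code{start}, \code{end}
#'   week indices (inclusive).
#' @param dropout random cell dropout rate in [0, 1).
#' @param seed RNG seed for the dropout draw.
#' @return a [WeeklyPanel-class] with the same grid and added missingness.
#' @export
applyMissingness <- function(panel, activation = NULL, shutdown = NULL,
                             outages = NULL, dropout = 0, seed = 1) {
    stopifnot(dropout >= 0, dropout < 1)
    v <- panelValues(panel)
    codes <- rownames(v); T <- ncol(v)
    badIdx <- function(stn, wk) {
        i <- match(stn, codes)
        if (anyNA(i)) stop("missingness spec names unknown station")
        if (any(wk < 1 | wk > T)) stop("missingness spec week out of range")
        cbind(i, wk)
    }
    for (s in names(activation)) {
        a <- activation[[s]]
        if (a > 1) v[badIdx(s, seq_len(min(a - 1, T)))] <- NA
    }
    for (s in names(shutdown)) {
        d <- shutdown[[s]]
        if (d < T) v[badIdx(s, (d + 1):T)] <- NA
    }
    if (!is.null(outages))
        for (r in seq_len(nrow(outages)))
            v[badIdx(outages$station[r],
                     outages$start[r]:outages$end[r])] <- NA
    if (dropout > 0)
        v[.withSeed(seed, runif(length(v)) < dropout)] <- NA
    WeeklyPanel(v, panelStations(panel), panelWeeks(panel))
}

#' Write a panel as a synthetic hourly measurement CSV
#'
#' Expands every non-missing station-week into a full week of hourly records
#' (7 days x 24 h, all equal to the weekly value), in the same long CSV
#' dialect [readMeasurements()] reads, so the real I/O and aggregation path
#' can be exercised end-to-end: re-aggregating the file reproduces the panel
#' exactly.
#'
#' @param panel a [WeeklyPanel-class].
#' @param path output CSV.
#' @param pollutant pollutant name written in the \code{pollutant} column.
#' @return \code{path}, invisibly.
#' @export
writeSyntheticMeasurements <- function(panel, path, pollutant = "NO2") {
    v <- panelValues(panel)
    weeks <- panelWeeks(panel)
    recs <- list()
    for (i in seq_len(nrow(v))) {
        for (j in which(!is.na(v[i, ]))) {
            ts <- seq(as.POSIXct(paste(weeks[j], "00:00:00"), tz = "UTC"),
                      by = 3600, length.out = 168)
            recs[[length(recs) + 1L]] <- data.frame(
                station = rownames(v)[i], timestamp = format(ts, "%Y-%m-%dT%H:%M:%S"),
                pollutant = pollutant, value = v[i, j])
        }
    }
    df <- if (length(recs)) do.call(rbind, recs) else
        data.frame(station = character(0), timestamp = character(0),
                   pollutant = character(0), value = numeric(0))
    write.csv(df, path, row.names = FALSE)
    invisible(path)
}
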