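## Hourly tables are plain data.frames with columns
## station (character), timestamp (POSIXct, strictly on the hour) and
## value (numeric, NA = missing), plus a "pollutant" attribute.

.isoWeekStart <- function(ts) {
    d <- as.Date(ts, tz = "UTC")
    d - (as.integer(format(d, "%u")) - 1L)
}

## ISO-8601 week-based year of a week given its Monday (year of the Thursday)
.isoWeekYear <- function(weekStart) as.integer(format(weekStart + 3L, "%Y"))

#' Read hourly measurements for one pollutant
#'
#' Parses a long-format CSV with columns \code{station}, \code{timestamp}
#' (ISO-8601, hourly resolution), \code{pollutant} and \code{value}, and
#' returns the records for the requested pollutant.  Empty cells, \code{"NA"},
#' unparseable values and negative values (network exports use negative
#' sentinels such as \code{-99}) become missing.
#'
#' @param path path to the CSV file.
#' @param pollutant pollutant name to extract.
#' @return a data.frame with columns \code{station}, \code{timestamp},
#'   \code{value} (the hourly table), with the pollutant name attached as
#'   attribute \code{"pollutant"}.
#' @seealso [aggregateWeekly()], [completenessMatrix()]
#' @export
readMeasurements <- function(path, pollutant) {
    if (!file.exists(path))
        stop("measurement file not found: ", path)
    raw <- read.csv(path, stringsAsFactors = FALSE,
                    colClasses = "character")
    need <- c("station", "timestamp", "value")
    if (!all(need %in% names(raw)))
        stop("measurement CSV must have columns station, timestamp, value")
    if (!"pollutant" %in% names(raw))
        stop("measurement CSV has no 'pollutant' column")
    raw <- raw[raw$pollutant == pollutant, , drop = FALSE]
    ts <- as.POSIXct(raw$timestamp, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                    "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                                    "%Y-%m-%d"))
    if (nrow(raw) && anyNA(ts))
        stop("unparseable timestamps in ", path)
    if (nrow(raw) && any(as.integer(format(ts, "%M")) != 0L |
                         as.integer(format(ts, "%S")) != 0L))
        stop("timestamps must be at hourly resolution")
    val <- suppressWarnings(as.numeric(raw$value))
    val[!is.na(val) & val < 0] <- NA_real_
    out <- data.frame(station = raw$station, timestamp = ts, value = val,
                      stringsAsFactors = FALSE)
    if (anyDuplicated(out[c("station", "timestamp")]))
        stop("duplicate (station, timestamp) records for pollutant ",
             pollutant)
    attr(out, "pollutant") <- pollutant
    out
}

#' Read a station catalogue
#'
#' @param path CSV with columns \code{code}, \code{lon}, \code{lat}.
#' @return a data.frame of stations, one row per unique code.
#' @export
readStations <- function(path) {
    if (!file.exists(path)) stop("station catalogue not found: ", path)
    st <- read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("code", "lon", "lat") %in% names(st)))
        stop("station catalogue must have columns code, lon, lat")
    if (anyDuplicated(st$code)) stop("duplicate station codes in catalogue")
    if (any(st$lon < -180 | st$lon > 180, na.rm = TRUE) ||
        any(st$lat < -90 | st$lat > 90, na.rm = TRUE))
        stop("station coordinates out of range")
    st
}

#' Construct a weekly station panel
#'
#' @param values station x week matrix of weekly mean concentrations
#'   (\code{NA} = missing); rownames are station codes.
#' @param stations data.frame with \code{code}, \code{lon}, \code{lat}
#'   matching the rows of \code{values}.
#' @param weekStart \code{Date} vector of week Mondays, one per column.
#' @return a [WeeklyPanel-class] object.
#' @export
WeeklyPanel <- function(values, stations, weekStart) {
    stopifnot(nrow(values) == nrow(stations),
              ncol(values) == length(weekStart))
    rownames(values) <- stations$code
    colnames(values) <- format(weekStart, "%G-W%V")
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(conc = values),
        rowData = S4Vectors::DataFrame(
            code = stations$code, lon = stations$lon, lat = stations$lat),
        colData = S4Vectors::DataFrame(
            weekStart = weekStart,
            year = .isoWeekYear(weekStart),
            row.names = colnames(values)))
    new("WeeklyPanel", se)
}

#' Station coordinates of a panel
#'
#' @param panel a [WeeklyPanel-class].
#' @return data.frame with \code{code}, \code{lon}, \code{lat}.
#' @export
panelStations <- function(panel) {
    rd <- SummarizedExperiment::rowData(panel)
    data.frame(code = rd$code, lon = rd$lon, lat = rd$lat,
               stringsAsFactors = FALSE)
}

#' Week start dates of a panel
#'
#' @param panel a [WeeklyPanel-class].
#' @return \code{Date} vector of ISO-week Mondays.
#' @export
panelWeeks <- function(panel) SummarizedExperiment::colData(panel)$weekStart

#' Concentration matrix of a panel
#'
#' @param panel a [WeeklyPanel-class].
#' @return the station x week matrix of weekly means.
#' @export
panelValues <- function(panel) SummarizedExperiment::assay(panel, "conc")

#' Aggregate hourly records into a weekly panel
#'
#' Hourly values are summarized by their arithmetic mean on an ISO-8601
#' calendar-week basis (Monday to Sunday).  A station's week is retained only
#' if at least \code{minDaysPerWeek} calendar days of that week each contain
#' at least \code{minHoursPerDay} non-missing hourly records (the network
#' completeness rule: more than 5 days with 17-hour records or more);
#' otherwise the cell is missing.  The mean uses all non-missing hourly
#' values of the week, not only those of qualifying days.
#'
#' @param table hourly table from [readMeasurements()].
#' @param minHoursPerDay minimum non-missing hourly records for a day to
#'   qualify (default 17).
#' @param minDaysPerWeek minimum qualifying days for a week to be retained
#'   (default 6).
#' @param stations optional station catalogue (\code{code}, \code{lon},
#'   \code{lat}); stations without records get all-missing rows, stations
#'   absent from the catalogue get \code{NA} coordinates.
#' @return a [WeeklyPanel-class] spanning the consecutive calendar weeks of
#'   the data.
#' @export
aggregateWeekly <- function(table, minHoursPerDay = 17, minDaysPerWeek = 6,
                            stations = NULL) {
    stopifnot(minHoursPerDay > 0, minDaysPerWeek > 0)
    if (nrow(table) == 0L)
        stop("cannot aggregate an empty hourly table")
    ok <- !is.na(table$value)
    day <- as.Date(table$timestamp, tz = "UTC")
    weekStart <- day - (as.integer(format(day, "%u")) - 1L)
    weeks <- seq(min(weekStart), max(weekStart), by = 7L)
    codes <- sort(unique(table$station))
    if (!is.null(stations)) codes <- union(stations$code, codes)

    si <- match(table$station, codes)
    wi <- match(weekStart, weeks)

    ## qualifying days: >= minHoursPerDay non-missing records per calendar day
    dkey <- paste(si, as.integer(day))
    perDay <- tapply(ok, dkey, sum)
    qual <- perDay >= minHoursPerDay
    dayWeek <- tapply(wi, dkey, `[`, 1L)    # week index of each station-day
    daySt <- tapply(si, dkey, `[`, 1L)
    wkey <- paste(daySt, dayWeek)
    qualDays <- tapply(qual, wkey, sum)

    ## weekly means over all non-missing hourly values
    cellKey <- paste(si, wi)
    sums <- tapply(ifelse(ok, table$value, 0), cellKey, sum)
    cnts <- tapply(ok, cellKey, sum)
    means <- ifelse(cnts > 0, sums / cnts, NA_real_)

    values <- matrix(NA_real_, length(codes), length(weeks))
    keep <- names(qualDays)[qualDays >= minDaysPerWeek]
    keep <- intersect(keep, names(means)[!is.na(means)])
    idx <- do.call(rbind, lapply(strsplit(keep, " "), as.integer))
    if (length(keep)) values[idx] <- means[keep]

    if (is.null(stations)) {
        stations <- data.frame(code = codes, lon = NA_real_, lat = NA_real_)
    } else {
        m <- match(codes, stations$code)
        stations <- data.frame(code = codes, lon = stations$lon[m],
                               lat = stations$lat[m])
    }
    WeeklyPanel(values, stations, weeks)
}

#' Weekly data-completeness grid
#'
#' Fraction of each station-week's 168 possible hourly records that are
#' present (non-missing), as displayed in network completeness tile plots.
#'
#' @param table hourly table from [readMeasurements()].
#' @return a station x week matrix of fractions in [0, 1], with week labels
#'   \code{"YYYY-Www"} as column names.
#' @export
completenessMatrix <- function(table) {
    if (nrow(table) == 0L)
        return(matrix(numeric(0), 0, 0))
    ok <- !is.na(table$value)
    weekStart <- .isoWeekStart(table$timestamp)
    weeks <- seq(min(weekStart), max(weekStart), by = 7L)
    codes <- sort(unique(table$station))
    counts <- matrix(0, length(codes), length(weeks),
                     dimnames = list(codes, format(weeks, "%G-W%V")))
    key <- paste(match(table$station, codes), match(weekStart, weeks))
    cnt <- tapply(ok, key, sum)
    ij <- do.call(rbind, lapply(strsplit(names(cnt), " "), as.integer))
    counts[ij] <- cnt
    counts / 168
}

#' Write a weekly panel as wide CSV
#'
#' Rows are weeks (first column \code{week} with the ISO label, second
#' \code{weekStart}), remaining columns one per station.
#'
#' @param panel a [WeeklyPanel-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeWeeklyPanel <- function(panel, path) {
    vals <- t(panelValues(panel))
    df <- data.frame(week = rownames(vals),
                     weekStart = format(panelWeeks(panel)),
                     vals, check.names = FALSE)
    write.csv(df, path, row.names = FALSE, na = "")
    invisible(path)
}

setMethod("show", "WeeklyPanel", function(object) {
    v <- panelValues(object)
    cat(sprintf(
        "WeeklyPanel: %d stations x %d weeks (%s to %s), %.1f%% cells present\n",
        nrow(v), ncol(v), format(min(panelWeeks(object))),
        format(max(panelWeeks(object))), 100 * mean(!is.na(v))))
})
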