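#' Run the full representativeness pipeline
#'
#' Orchestrates ingest, weekly aggregation, empirical variogram estimation,
#' the 75-candidate model grid search and yearly coverage mapping for each
#' requested pollutant, writing every artifact under \code{outdir} and
#' returning (and writing) a machine-readable run report.  A failure in one
#' pollutant is recorded in the report and does not stop the others.
#'
#' @param config a named list, or the path of a YAML file, with entries:
#'   \describe{
#'     \item{measurements}{long CSV of hourly records
#'       (\code{station,timestamp,pollutant,value}).}
#'     \item{stations}{station catalogue CSV (\code{code,lon,lat}).}
#'     \item{region}{optional region GeoJSON for coverage fractions.}
#'     \item{pollutants}{character vector of pollutants to process.}
#'     \item{outdir}{output directory (created if absent).}
#'     \item{years}{optional integer years for coverage maps (default: all).}
#'     \item{minHoursPerDay, minDaysPerWeek}{weekly completeness rule
#'       (defaults 17 and 6).}
#'     \item{spatialBins, maxTemporalLag}{binning overrides for
#'       [empiricalSTVariogram()].}
#'     \item{minWeeksActive}{activity threshold for [activeStations()]
#'       (default 1).}
#'   }
#' @param verbose log stage progress via [message()].
#' @return the run report: a list with one entry per pollutant holding the
#'   artifact paths, the winner candidate and its spatial/temporal ranges;
#'   also written as \code{report.json} in \code{outdir}.
#' @export
runPipeline <- function(config, verbose = TRUE) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    stopifnot(!is.null(config$measurements), !is.null(config$stations),
              !is.null(config$outdir))
    outdir <- config$outdir
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    stations <- readStations(config$stations)
    region <- if (!is.null(config$region)) readRegionGeoJSON(config$region)
    pollutants <- config$pollutants
    say <- function(...) if (verbose) message(sprintf(...))

    report <- list(pollutants = list())
    for (p in if (is.null(pollutants)) character(0) else pollutants) {
        res <- tryCatch({
            say("[%s] reading measurements", p)
            tab <- readMeasurements(config$measurements, p)
            if (nrow(tab) == 0L) stop("no records for pollutant ", p)
            say("[%s] weekly aggregation", p)
            panel <- aggregateWeekly(
                tab,
                minHoursPerDay = config$minHoursPerDay %||% 17,
                minDaysPerWeek = config$minDaysPerWeek %||% 6,
                stations = stations)
            comp <- completenessMatrix(tab)
            pfx <- file.path(outdir, p)
            writeWeeklyPanel(panel, paste0(pfx, "_weekly_panel.csv"))
            write.csv(data.frame(station = rownames(comp), comp,
                                 check.names = FALSE),
                      paste0(pfx, "_completeness.csv"), row.names = FALSE)
            say("[%s] empirical space-time variogram", p)
            emp <- empiricalSTVariogram(
                panel, stations = stations,
                spatialBins = config$spatialBins,
                maxTemporalLag = config$maxTemporalLag)
            writeEmpiricalVariogram(emp, paste0(pfx, "_empirical_variogram.csv"))
            say("[%s] grid search over 75 candidate models", p)
            gs <- modelGridSearch(emp, verbose = verbose)
            write.csv(gs$leaderboard, paste0(pfx, "_leaderboard.csv"),
                      row.names = FALSE)
            win <- gs$winner
            yaml::write_yaml(stModelToList(win@model),
                             paste0(pfx, "_winner_model.yaml"))
            radius <- effectiveSpatialRange(win@model, hMax = max(emp@dist))
            say("[%s] winner %s (wmse %.5g), spatial range %.2f km",
                p, win@candidateId, win@wmse, radius)
            years <- config$years %||%
                sort(unique(SummarizedExperiment::colData(panel)$year))
            maps <- coverageTimeline(panel, radius, region,
                                     years = years,
                                     minWeeks = config$minWeeksActive %||% 1,
                                     pollutant = p)
            for (y in names(maps))
                writeCoverageGeoJSON(maps[[y]],
                                     sprintf("%s_coverage_%s.geojson", pfx, y))
            summ <- coverageSummary(maps)
            write.csv(summ, paste0(pfx, "_coverage_summary.csv"),
                      row.names = FALSE)
            wrow <- gs$leaderboard[which.min(gs$leaderboard$wmse), ]
            list(status = "ok",
                 winner = win@candidateId, wmse = win@wmse,
                 spatial_range_km = radius,
                 spatial_component_range_km = wrow$spatial_range,
                 temporal_component_range_weeks = wrow$temporal_range,
                 coverage = summ,
                 artifacts = list.files(outdir, pattern = paste0("^", p, "_"),
                                        full.names = TRUE))
        }, error = function(e) {
            say("[%s] FAILED: %s", p, conditionMessage(e))
            list(status = "failed", error = conditionMessage(e))
        })
        report$pollutants[[p]] <- res
    }
    report$n_failed <- sum(vapply(report$pollutants,
                                  function(x) x$status == "failed", logical(1)))
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         null = "null", na = "null")
    invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
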