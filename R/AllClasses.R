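#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats median optim quantile rnorm runif sd approx setNames uniroot dist
#' @importFrom graphics plot image
#' @importFrom utils read.csv write.csv
NULL

.VGM_FAMILIES <- c("exponential", "spherical", "gaussian")
.ST_STRUCTURES <- c("separable", "productSum", "metric", "sumMetric",
                    "simpleSumMetric")

## practical-range scale constant: makes the nominal range of the
## exponential/Gaussian families coincide with the 95%-of-sill distance
.RANGE_A <- 1 / 3

.EARTH_RADIUS_KM <- 6371

#' Component semivariogram model
#'
#' A single bounded semivariogram component from one of the three classical
#' families (exponential, spherical, Gaussian), parameterised by nugget
#' \eqn{n}, sill \eqn{s} and range \eqn{r}.  The exponential and Gaussian
#' families use the practical-range convention with scale constant
#' \eqn{a = 1/3}, so that the semivariance first reaches 95\% of the sill at
#' \eqn{h = r}; the spherical family attains the sill exactly at \eqn{r}.
#'
#' @slot family one of \code{"exponential"}, \code{"spherical"},
#'   \code{"gaussian"}.
#' @slot nugget nugget \eqn{n \ge 0} (semivariance units).
#' @slot sill sill \eqn{s \ge n}, the limiting semivariance.
#' @slot range range \eqn{r > 0} (lag units).
#' @seealso [variogramComponent()], [evalComponent()]
#' @exportClass VariogramComponent
setClass("VariogramComponent",
         representation(family = "character", nugget = "numeric",
                        sill = "numeric", range = "numeric"))

setValidity("VariogramComponent", function(object) {
    msg <- NULL
    if (length(object@family) != 1L || !object@family %in% .VGM_FAMILIES)
        msg <- c(msg, sprintf("family must be one of %s",
                              paste(.VGM_FAMILIES, collapse = ", ")))
    for (s in c("nugget", "sill", "range")) {
        v <- slot(object, s)
        if (length(v) != 1L || !is.finite(v))
            msg <- c(msg, sprintf("%s must be a finite scalar", s))
    }
    if (is.null(msg)) {
        if (object@nugget < 0) msg <- c(msg, "nugget must be >= 0")
        if (object@sill < object@nugget) msg <- c(msg, "sill must be >= nugget")
        if (object@range <= 0) msg <- c(msg, "range must be > 0")
    }
    if (is.null(msg)) TRUE else msg
})

setClassUnion("VariogramComponentOrNULL", c("VariogramComponent", "NULL"))

#' Space-time semivariogram model
#'
#' One of the five standard space-time covariance structures, composed of
#' component semivariograms:
#' \describe{
#'   \item{separable}{\eqn{\gamma(h,u) = sill\,(\bar\gamma_s(h) +
#'     \bar\gamma_t(u) - \bar\gamma_s(h)\bar\gamma_t(u))} with components
#'     standardized to sill 1.}
#'   \item{productSum}{\eqn{(k\,sill_t + 1)\gamma_s(h) +
#'     (k\,sill_s + 1)\gamma_t(u) - k\,\gamma_s(h)\gamma_t(u)}, whose overall
#'     sill obeys \eqn{sill_{st} = k\,sill_s sill_t + sill_s + sill_t}.}
#'   \item{metric}{\eqn{\gamma_{joint}(\sqrt{h^2 + (\kappa u)^2})} with
#'     spatio-temporal anisotropy \eqn{\kappa} (space units per time unit).}
#'   \item{sumMetric}{\eqn{\gamma_s(h) + \gamma_t(u) +
#'     \gamma_{joint}(\sqrt{h^2 + (\kappa u)^2})}.}
#'   \item{simpleSumMetric}{sumMetric with all component nuggets zero and a
#'     single overall nugget \eqn{n} applied for \eqn{(h,u) \neq (0,0)}.}
#' }
#'
#' @slot structure structure name.
#' @slot spatial,temporal,joint [VariogramComponent-class] components, or
#'   \code{NULL} where the structure does not use them.
#' @slot sill overall sill (separable only; \code{NA} otherwise).
#' @slot k positive product-sum coupling (productSum only; \code{NA} otherwise).
#' @slot stAni spatio-temporal anisotropy \eqn{\kappa} in space units per time
#'   unit (metric-type structures; \code{NA} otherwise).
#' @slot nugget single overall nugget (simpleSumMetric only; \code{NA}
#'   otherwise).
#' @seealso [stModel()], [evalSTVariogram()], [totalSill()]
#' @exportClass STVariogramModel
setClass("STVariogramModel",
         representation(structure = "character",
                        spatial = "VariogramComponentOrNULL",
                        temporal = "VariogramComponentOrNULL",
                        joint = "VariogramComponentOrNULL",
                        sill = "numeric", k = "numeric",
                        stAni = "numeric", nugget = "numeric"))

setValidity("STVariogramModel", function(object) {
    st <- object@structure
    if (length(st) != 1L || !st %in% .ST_STRUCTURES)
        return(sprintf("structure must be one of %s",
                       paste(.ST_STRUCTURES, collapse = ", ")))
    msg <- NULL
    need <- function(comp, name) {
        if (is.null(slot(object, comp)))
            msg <<- c(msg, sprintf("%s structure requires a %s component",
                                   st, name))
    }
    absent <- function(comp) is.null(slot(object, comp))
    pos <- function(x) length(x) == 1L && is.finite(x) && x > 0
    switch(st,
        separable = {
            need("spatial", "spatial"); need("temporal", "temporal")
            if (!absent("joint")) msg <- c(msg, "separable has no joint component")
            if (!pos(object@sill)) msg <- c(msg, "separable requires sill > 0")
            for (comp in c("spatial", "temporal")) {
                cm <- slot(object, comp)
                if (!is.null(cm) && abs(cm@sill - 1) > 1e-8)
                    msg <- c(msg, sprintf(
                        "separable %s component must be standardized (sill 1)",
                        comp))
            }
        },
        productSum = {
            need("spatial", "spatial"); need("temporal", "temporal")
            if (!absent("joint")) msg <- c(msg, "productSum has no joint component")
            if (!pos(object@k)) msg <- c(msg, "productSum requires k > 0")
        },
        metric = {
            need("joint", "joint")
            if (!absent("spatial") || !absent("temporal"))
                msg <- c(msg, "metric uses only the joint component")
            if (!pos(object@stAni)) msg <- c(msg, "metric requires stAni > 0")
        },
        sumMetric = {
            need("spatial", "spatial"); need("temporal", "temporal")
            need("joint", "joint")
            if (!pos(object@stAni)) msg <- c(msg, "sumMetric requires stAni > 0")
        },
        simpleSumMetric = {
            need("spatial", "spatial"); need("temporal", "temporal")
            need("joint", "joint")
            if (!pos(object@stAni))
                msg <- c(msg, "simpleSumMetric requires stAni > 0")
            if (length(object@nugget) != 1L || !is.finite(object@nugget) ||
                object@nugget < 0)
                msg <- c(msg, "simpleSumMetric requires nugget >= 0")
            for (comp in c("spatial", "temporal", "joint")) {
                cm <- slot(object, comp)
                if (!is.null(cm) && cm@nugget != 0)
                    msg <- c(msg, sprintf(
                        "simpleSumMetric %s component must have zero nugget",
                        comp))
            }
        })
    if (is.null(msg)) TRUE else msg
})

#' Binned empirical space-time semivariogram
#'
#' Semivariance estimates on a spatial-bin by temporal-lag grid, together with
#' the number of station/time pairs behind each cell.  Row 1 is the
#' zero-distance bin holding same-station (purely temporal) pairs; subsequent
#' rows are half-open distance bins \eqn{(e_{j-1}, e_j]} in km.
#'
#' @slot gamma spatial-bin x temporal-lag matrix of semivariance estimates
#'   (\code{NaN} where no pairs fall in a cell).
#' @slot npairs matrix of pair counts \eqn{N(h,u)}, same shape.
#' @slot dist representative (pair-weighted mean) distance per bin, km.
#' @slot binEdges spatial bin edges in km, starting at 0.
#' @slot temporalLags integer lags in weeks, starting at 0.
#' @seealso [empiricalSTVariogram()]
#' @exportClass EmpiricalSTVariogram
setClass("EmpiricalSTVariogram",
         representation(gamma = "matrix", npairs = "matrix",
                        dist = "numeric", binEdges = "numeric",
                        temporalLags = "integer"))

setValidity("EmpiricalSTVariogram", function(object) {
    msg <- NULL
    if (!all(dim(object@gamma) == dim(object@npairs)))
        msg <- c(msg, "gamma and npairs must have identical dimensions")
    if (nrow(object@gamma) != length(object@dist))
        msg <- c(msg, "dist length must equal the number of spatial bins")
    if (ncol(object@gamma) != length(object@temporalLags))
        msg <- c(msg, "temporalLags length must equal the number of columns")
    if (any(object@npairs < 0) || any(object@npairs != round(object@npairs)))
        msg <- c(msg, "npairs must be non-negative integers")
    has <- object@npairs > 0
    if (any(!is.finite(object@gamma[has])) || any(object@gamma[has] < -1e-12))
        msg <- c(msg, "gamma must be finite and >= 0 wherever npairs > 0")
    if (is.null(msg)) TRUE else msg
})

#' Weekly station panel
#'
#' A \linkS4class{SummarizedExperiment} with one assay \code{"conc"}
#' (stations in rows, consecutive calendar weeks in columns), station
#' coordinates in \code{rowData} (\code{lon}, \code{lat}) and the Monday of
#' each ISO week in \code{colData$weekStart}.  A cell is non-missing only if
#' its source week passed the day/hour completeness rule of
#' [aggregateWeekly()] (or was simulated).
#'
#' @seealso [WeeklyPanel()], [aggregateWeekly()], [simulateField()]
#' @exportClass WeeklyPanel
setClass("WeeklyPanel", contains = "SummarizedExperiment")

setValidity("WeeklyPanel", function(object) {
    msg <- NULL
    if (!"conc" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "WeeklyPanel requires an assay named 'conc'")
    rd <- SummarizedExperiment::rowData(object)
    if (!all(c("lon", "lat") %in% colnames(rd))) {
        msg <- c(msg, "rowData must contain 'lon' and 'lat'")
    } else {
        lon <- rd$lon; lat <- rd$lat
        ok <- is.na(lon) | (lon >= -180 & lon <= 180)
        ok2 <- is.na(lat) | (lat >= -90 & lat <= 90)
        if (!all(ok)) msg <- c(msg, "lon must lie in [-180, 180]")
        if (!all(ok2)) msg <- c(msg, "lat must lie in [-90, 90]")
    }
    cd <- SummarizedExperiment::colData(object)
    if (!"weekStart" %in% colnames(cd))
        msg <- c(msg, "colData must contain 'weekStart'")
    if (is.null(msg)) TRUE else msg
})

#' Fit of one space-time model candidate
#'
#' @slot model the fitted [STVariogramModel-class].
#' @slot wmse achieved weighted mean squared error (pair-count weights).
#' @slot converged optimizer convergence flag.
#' @slot candidateId identifier \code{"structure/spatial+temporal+joint"}.
#' @seealso [fitSTModel()], [modelGridSearch()]
#' @exportClass STFitResult
setClass("STFitResult",
         representation(model = "STVariogramModel", wmse = "numeric",
                        converged = "logical", candidateId = "character"))

setValidity("STFitResult", function(object) {
    if (length(object@wmse) != 1L || is.na(object@wmse) || object@wmse < 0)
        return("wmse must be a single non-negative number")
    TRUE
})

#' Coverage map for one pollutant-year
#'
#' The union of circles of radius equal to the fitted spatial correlation
#' range, centred on the stations active in the given year, with exact area
#' statistics and the fraction of the study-region polygon covered.
#'
#' @slot pollutant pollutant name.
#' @slot year calendar year.
#' @slot radiusKm circle radius = fitted spatial range, km.
#' @slot stationCodes codes of the active stations (circle centres).
#' @slot centers matrix of active-station \code{lon}/\code{lat}.
#' @slot rings list of boundary rings; each a matrix with columns
#'   \code{x}, \code{y} (km, azimuthal-equidistant plane), \code{lon},
#'   \code{lat}.  Positive signed area = outer ring, negative = hole.
#' @slot coveredAreaKm2 exact union-of-circles area, km^2.
#' @slot regionFraction fraction of the study polygon covered, in [0, 1].
#' @slot projCenter lon/lat of the projection centre.
#' @seealso [bufferUnion()], [coverageTimeline()]
#' @exportClass CoverageMap
setClass("CoverageMap",
         representation(pollutant = "character", year = "integer",
                        radiusKm = "numeric", stationCodes = "character",
                        centers = "matrix", rings = "list",
                        coveredAreaKm2 = "numeric",
                        regionFraction = "numeric", projCenter = "numeric"))

setValidity("CoverageMap", function(object) {
    msg <- NULL
    if (object@coveredAreaKm2 < 0) msg <- c(msg, "coveredAreaKm2 must be >= 0")
    if (!is.na(object@regionFraction) &&
        (object@regionFraction < 0 || object@regionFraction > 1))
        msg <- c(msg, "regionFraction must lie in [0, 1]")
    if (length(object@stationCodes) >= 1L && length(object@rings) == 0L)
        msg <- c(msg, "polygon must be non-empty when stations are active")
    if (is.null(msg)) TRUE else msg
})
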