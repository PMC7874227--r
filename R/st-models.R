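#' Construct a space-time semivariogram model
#'
#' Composes component semivariograms into one of the five space-time
#' structures (see [STVariogramModel-class]).  For the \code{separable}
#' structure arbitrary components may be supplied: they are rescaled to sill 1
#' (nugget divided by the component sill) and the component sill is absorbed
#' into \code{sill} if that is missing.
#'
#' @param structure one of \code{"separable"}, \code{"productSum"},
#'   \code{"metric"}, \code{"sumMetric"}, \code{"simpleSumMetric"}.
#' @param spatial,temporal,joint [VariogramComponent-class] components as the
#'   structure requires.
#' @param sill overall sill (separable only).  Defaults to the product of the
#'   unstandardized component sills.
#' @param k positive product-sum coupling (productSum only).
#' @param stAni spatio-temporal anisotropy \eqn{\kappa} in km per week
#'   (metric-type structures).
#' @param nugget single overall nugget (simpleSumMetric only).
#' @return an [STVariogramModel-class] object.
#' @examples
#' sp <- variogramComponent("exponential", 0.1, 1, 40)
#' tm <- variogramComponent("exponential", 0.1, 1, 8)
#' stModel("separable", spatial = sp, temporal = tm, sill = 1)
#' @export
stModel <- function(structure, spatial = NULL, temporal = NULL, joint = NULL,
                    sill = NA_real_, k = NA_real_, stAni = NA_real_,
                    nugget = NA_real_) {
    structure <- match.arg(structure, .ST_STRUCTURES)
    if (structure == "separable") {
        std <- function(cm) {
            if (is.null(cm)) return(NULL)
            if (cm@sill <= 0) stop("separable component sill must be > 0")
            variogramComponent(cm@family, nugget = cm@nugget / cm@sill,
                               sill = 1, range = cm@range)
        }
        if (is.na(sill)) {
            ss <- if (is.null(spatial)) 1 else spatial@sill
            st <- if (is.null(temporal)) 1 else temporal@sill
            sill <- ss * st
        }
        spatial <- std(spatial); temporal <- std(temporal)
    }
    new("STVariogramModel", structure = structure, spatial = spatial,
        temporal = temporal, joint = joint, sill = as.numeric(sill),
        k = as.numeric(k), stAni = as.numeric(stAni),
        nugget = as.numeric(nugget))
}

#' Product-sum sill identity
#'
#' The overall sill of the product-sum structure in terms of its component
#' sills and coupling: \eqn{sill_{st} = k\,sill_s\,sill_t + sill_s + sill_t}.
#'
#' @param k positive coupling parameter.
#' @param sillS,sillT spatial and temporal component sills.
#' @return the overall space-time sill.
#' @examples
#' productSumSill(2, 1, 0.5)  # 2.5
#' @export
productSumSill <- function(k, sillS, sillT) {
    if (any(k <= 0)) stop("k must be > 0")
    k * sillS * sillT + sillS + sillT
}

#' Evaluate a space-time semivariogram
#'
#' Computes \eqn{\gamma(h, u)} for any of the five structures.  \code{h} and
#' \code{u} are recycled to a common length.  All metric-type structures use
#' the joint lag \eqn{\sqrt{h^2 + (\kappa u)^2}}.
#'
#' @param model an [STVariogramModel-class].
#' @param h spatial lag(s) in km, non-negative.
#' @param u temporal lag(s) in weeks, non-negative.
#' @return numeric vector of semivariances.
#' @examples
#' j <- variogramComponent("spherical", 0, 1, 10)
#' m <- stModel("metric", joint = j, stAni = 1)
#' evalSTVariogram(m, h = 3, u = 4)  # gamma_joint(5)
#' @export
setGeneric("evalSTVariogram",
           function(model, h, u) standardGeneric("evalSTVariogram"))

#' @rdname evalSTVariogram
#' @export
setMethod("evalSTVariogram", "STVariogramModel", function(model, h, u) {
    if (any(h < 0, na.rm = TRUE) || any(u < 0, na.rm = TRUE))
        stop("lags h and u must be non-negative")
    nn <- max(length(h), length(u))
    h <- rep_len(h, nn); u <- rep_len(u, nn)
    gs <- function() evalComponent(model@spatial, h)
    gt <- function() evalComponent(model@temporal, u)
    gj <- function() evalComponent(model@joint,
                                   sqrt(h^2 + (model@stAni * u)^2))
    switch(model@structure,
        separable = {
            a <- gs(); b <- gt()
            model@sill * (a + b - a * b)
        },
        productSum = {
            a <- gs(); b <- gt()
            ss <- model@spatial@sill; st <- model@temporal@sill
            (model@k * st + 1) * a + (model@k * ss + 1) * b -
                model@k * a * b
        },
        metric = gj(),
        sumMetric = gs() + gt() + gj(),
        simpleSumMetric =
            model@nugget * as.numeric(h > 0 | u > 0) + gs() + gt() + gj())
})

#' Overall sill of a space-time model
#'
#' The limiting semivariance \eqn{\gamma(h \to \infty, u \to \infty)}: the
#' overall sill for separable, the product-sum identity
#' ([productSumSill()]) for productSum, the joint sill for metric, and the sum
#' of component sills (plus the single nugget for simpleSumMetric) for the
#' sum-metric structures.
#'
#' @param model an [STVariogramModel-class].
#' @return the total sill (a scalar).
#' @export
setGeneric("totalSill", function(model) standardGeneric("totalSill"))

#' @rdname totalSill
#' @export
setMethod("totalSill", "STVariogramModel", function(model) {
    switch(model@structure,
        separable = model@sill,
        productSum = productSumSill(model@k, model@spatial@sill,
                                    model@temporal@sill),
        metric = model@joint@sill,
        sumMetric = model@spatial@sill + model@temporal@sill +
            model@joint@sill,
        simpleSumMetric = model@nugget + model@spatial@sill +
            model@temporal@sill + model@joint@sill)
})

#' Effective spatial practical range
#'
#' The smallest spatial lag \eqn{h} at which the purely spatial marginal
#' \eqn{\gamma(h, 0)} first reaches 95\% of the semivariance it attains at
#' \code{hMax}.  This generalizes the per-component range parameter to any of
#' the five structures (whose winners on a given data set may split spatial
#' structure between the spatial and joint components), using the
#' 95\%-of-sill practical-range convention of the component families.
#' \code{hMax} should be the largest distance the empirical variogram
#' observed: a fitted surface is not informative beyond it, so the range is
#' taken relative to the sill reached within the data domain.
#'
#' @param model an [STVariogramModel-class].
#' @param hMax upper bound in km; the level is referenced to
#'   \eqn{\gamma(hMax, 0)}.
#' @return the effective range in km.
#' @export
effectiveSpatialRange <- function(model, hMax = 1000) {
    lim <- evalSTVariogram(model, hMax, 0)
    if (lim <= 0) return(0)
    target <- 0.95 * lim
    f <- function(h) evalSTVariogram(model, h, 0) - target
    stats::uniroot(f, c(1e-9, hMax), tol = 1e-8)$root
}

#' Flatten a space-time model to a key-value list
#'
#' Serializes the structure name and every parameter in use to a flat named
#' list suitable for YAML/JSON config blocks; [stModelFromList()] inverts it.
#'
#' @param model an [STVariogramModel-class].
#' @return a named list of scalars.
#' @export
stModelToList <- function(model) {
    out <- list(structure = model@structure)
    for (comp in c("spatial", "temporal", "joint")) {
        cm <- slot(model, comp)
        if (is.null(cm)) next
        out[[paste0(comp, "_family")]] <- cm@family
        out[[paste0(comp, "_nugget")]] <- cm@nugget
        out[[paste0(comp, "_sill")]] <- cm@sill
        out[[paste0(comp, "_range")]] <- cm@range
    }
    for (s in c("sill", "k", "stAni", "nugget"))
        if (!is.na(slot(model, s))) out[[s]] <- slot(model, s)
    out
}

#' @rdname stModelToList
#' @param x a named list as produced by [stModelToList()].
#' @export
stModelFromList <- function(x) {
    comp <- function(p) {
        fam <- x[[paste0(p, "_family")]]
        if (is.null(fam)) return(NULL)
        variogramComponent(fam, x[[paste0(p, "_nugget")]],
                           x[[paste0(p, "_sill")]], x[[paste0(p, "_range")]])
    }
    g <- function(s) if (is.null(x[[s]])) NA_real_ else as.numeric(x[[s]])
    stModel(x$structure, spatial = comp("spatial"), temporal = comp("temporal"),
            joint = comp("joint"), sill = g("sill"), k = g("k"),
            stAni = g("stAni"), nugget = g("nugget"))
}

setMethod("show", "STVariogramModel", function(object) {
    cat(sprintf("space-time semivariogram model: %s (total sill %.4g)\n",
                object@structure, totalSill(object)))
    for (comp in c("spatial", "temporal", "joint")) {
        cm <- slot(object, comp)
        if (!is.null(cm))
            cat(sprintf("  %-8s %-11s nugget %.4g sill %.4g range %.4g\n",
                        comp, cm@family, cm@nugget, cm@sill, cm@range))
    }
    if (!is.na(object@sill)) cat(sprintf("  sill  %.4g\n", object@sill))
    if (!is.na(object@k)) cat(sprintf("  k     %.4g\n", object@k))
    if (!is.na(object@stAni)) cat(sprintf("  stAni %.4g km/week\n", object@stAni))
    if (!is.na(object@nugget)) cat(sprintf("  nugget %.4g\n", object@nugget))
})
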