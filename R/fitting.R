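#' Initial parameter values for space-time model fitting
#'
#' Rule-based starting values read off the empirical variogram matrix:
#' the nugget guess is the median of the means of the first three spatial
#' rows (resp. temporal columns), the sill guess the median of the means of
#' the last five; the spatial range guess is one third of the maximum binned
#' distance and the temporal range guess the maximum temporal lag.  When
#' fewer than three rows (five columns) carry data, all available ones are
#' used.  The anisotropy guess comes from [estimateSTAnisotropy()].
#'
#' @slot nugget,sill spatial-axis nugget and sill guesses.
#' @slot nuggetT,sillT temporal-axis counterparts.
#' @slot rangeS spatial range guess, km.
#' @slot rangeT temporal range guess, weeks.
#' @slot stAni anisotropy guess, km/week.
#' @exportClass STInitialValues
setClass("STInitialValues",
         representation(nugget = "numeric", sill = "numeric",
                        nuggetT = "numeric", sillT = "numeric",
                        rangeS = "numeric", rangeT = "numeric",
                        stAni = "numeric"))

setMethod("show", "STInitialValues", function(object) {
    cat(sprintf(
        "initial values: nugget %.4g/%.4g, sill %.4g/%.4g (spatial/temporal),\n  rangeS %.4g km, rangeT %.4g weeks, stAni %.4g km/week\n",
        object@nugget, object@nuggetT, object@sill, object@sillT,
        object@rangeS, object@rangeT, object@stAni))
})

.marginalMeans <- function(emp, margin) {
    g <- emp@gamma; np <- emp@npairs
    vapply(seq_len(dim(g)[margin]), function(i) {
        v <- if (margin == 1) g[i, ] else g[, i]
        w <- if (margin == 1) np[i, ] else np[, i]
        v <- v[w > 0]
        if (length(v)) mean(v) else NA_real_
    }, numeric(1))
}

.medianHeadTail <- function(x, k, tail = FALSE) {
    x <- x[is.finite(x)]
    if (!length(x)) return(NA_real_)
    k <- min(k, length(x))
    if (tail) median(x[(length(x) - k + 1):length(x)]) else median(x[1:k])
}

#' Initial guesses from an empirical variogram
#'
#' See [STInitialValues-class] for the rules.
#'
#' @param emp an [EmpiricalSTVariogram-class].
#' @return an [STInitialValues-class] object.
#' @export
setGeneric("initialGuesses", function(emp) standardGeneric("initialGuesses"))

#' @rdname initialGuesses
#' @export
setMethod("initialGuesses", "EmpiricalSTVariogram", function(emp) {
    if (sum(emp@npairs) == 0) stop("empty empirical variogram")
    rowM <- .marginalMeans(emp, 1)   # one mean per spatial bin
    colM <- .marginalMeans(emp, 2)   # one mean per temporal lag
    nugget <- .medianHeadTail(rowM, 3)
    sill <- .medianHeadTail(rowM, 5, tail = TRUE)
    nuggetT <- .medianHeadTail(colM, 3)
    sillT <- .medianHeadTail(colM, 5, tail = TRUE)
    rangeS <- max(emp@dist) / 3
    rangeT <- max(emp@temporalLags)
    if (rangeT <= 0) rangeT <- 1
    init <- new("STInitialValues", nugget = nugget, sill = sill,
                nuggetT = nuggetT, sillT = sillT, rangeS = rangeS,
                rangeT = max(rangeT, 1e-6), stAni = rangeS / max(rangeT, 1))
    init@stAni <- tryCatch(estimateSTAnisotropy(emp),
                           error = function(e) init@stAni)
    init
})

## first lag at which the curve (xs increasing, ys semivariance) reaches
## `level`, by linear interpolation; NA if never reached
.firstReach <- function(xs, ys, level) {
    ok <- is.finite(xs) & is.finite(ys)
    xs <- xs[ok]; ys <- ys[ok]
    if (length(xs) < 2L) return(NA_real_)
    i <- which(ys >= level)[1]
    if (is.na(i)) return(NA_real_)
    if (i == 1L) return(xs[1])
    x0 <- xs[i - 1L]; y0 <- ys[i - 1L]
    if (ys[i] == y0) return(xs[i])
    x0 + (level - y0) / (ys[i] - y0) * (xs[i] - x0)
}

#' Spatio-temporal anisotropy estimate
#'
#' Estimates the anisotropy \eqn{\kappa} (km per week) that makes one
#' temporal lag unit equivalent to \eqn{\kappa} spatial km, by matching the
#' levels at which the two marginal empirical variograms (the purely spatial
#' lag-0 column and the purely temporal zero-distance row) first reach a
#' common set of semivariance quantiles, and fitting a least-squares line
#' through the origin of the matched (temporal, spatial) lag pairs.  Flat or
#' degenerate marginals fall back to the ratio of the spatial and temporal
#' range guesses.
#'
#' @param emp an [EmpiricalSTVariogram-class].
#' @param nLevels number of matched semivariance levels.
#' @return \eqn{\kappa > 0} in km/week.
#' @export
estimateSTAnisotropy <- function(emp, nLevels = 10) {
    lag0 <- which(emp@temporalLags == 0L)[1]
    sOK <- emp@npairs[, lag0] > 0
    sX <- emp@dist[sOK]; sY <- emp@gamma[sOK, lag0]
    tOK <- emp@npairs[1, ] > 0
    tX <- as.numeric(emp@temporalLags[tOK]); tY <- emp@gamma[1, tOK]
    fallback <- (max(emp@dist) / 3) / max(max(emp@temporalLags), 1)
    flat <- function(y) length(y) < 2L || !is.finite(diff(range(y))) ||
        diff(range(y)) <= 1e-12
    if (flat(sY) || flat(tY)) return(fallback)
    lo <- max(min(sY), min(tY)); hi <- min(max(sY), max(tY))
    if (!(hi > lo)) return(fallback)
    levels <- quantile(seq(lo, hi, length.out = 101),
                       probs = seq(0.1, 0.9, length.out = nLevels))
    h <- vapply(levels, function(l) .firstReach(sX, sY, l), numeric(1))
    u <- vapply(levels, function(l) .firstReach(tX, tY, l), numeric(1))
    ok <- is.finite(h) & is.finite(u) & u > 0
    if (sum(ok) < 2L || sum(u[ok]^2) <= 0) return(fallback)
    kappa <- sum(h[ok] * u[ok]) / sum(u[ok]^2)
    if (!is.finite(kappa) || kappa <= 0) fallback else kappa
}

## ---- candidate parameterisation -------------------------------------------
## Components are parameterised by (nugget, partial sill, range) so that the
## constraint sill >= nugget becomes a box constraint psill >= 0.
## Each candidate also carries a closure-based `gamma(p, h, u)` evaluating the
## surface straight from the parameter vector, so the optimizer's objective
## avoids S4 construction; the closed forms are identical to
## evalComponent()/evalSTVariogram() and tested against them.

## family closure: gamma(h; nugget, sill, range), vectorized, h >= 0
.gfam <- function(family) {
    a <- .RANGE_A
    switch(family,
        exponential = function(h, n, s, r) {
            g <- (s - n) * (1 - exp(-h / (r * a))) + n
            g[h == 0] <- 0; g
        },
        gaussian = function(h, n, s, r) {
            g <- (s - n) * (1 - exp(-h^2 / (r^2 * a))) + n
            g[h == 0] <- 0; g
        },
        spherical = function(h, n, s, r) {
            hb <- pmin(h, r)
            g <- (s - n) * (3 * hb / (2 * r) - hb^3 / (2 * r^3)) + n
            g[h == 0] <- 0; g
        })
}

.candidateSpec <- function(structure, families, init) {
    gS <- if ("spatial" %in% names(families)) .gfam(families[["spatial"]])
    gT <- if ("temporal" %in% names(families)) .gfam(families[["temporal"]])
    gJ <- if ("joint" %in% names(families)) .gfam(families[["joint"]])
    S <- max(init@sill, 1e-8)
    St <- max(init@sillT, 1e-8)
    nug <- min(init@nugget, 0.9 * S)
    nugT <- min(init@nuggetT, 0.9 * St)
    rS <- max(init@rangeS, 1e-3); rT <- max(init@rangeT, 1e-3)
    kap <- max(init@stAni, 1e-6)
    lowR <- 1e-3
    switch(structure,
        separable = list(
            par = c(sill = S, nugS = min(nug / S, 1), rS = rS,
                    nugT = min(nugT / St, 1), rT = rT),
            lower = c(1e-12, 0, lowR, 0, lowR),
            upper = c(Inf, 1, Inf, 1, Inf),
            gamma = function(p, h, u) {
                gs <- gS(h, p[2], 1, p[3]); gt <- gT(u, p[4], 1, p[5])
                p[1] * (gs + gt - gs * gt)
            },
            build = function(p, fam) stModel("separable",
                spatial = variogramComponent(fam[["spatial"]], p[2], 1, p[3]),
                temporal = variogramComponent(fam[["temporal"]], p[4], 1, p[5]),
                sill = p[1])),
        productSum = {
            s0 <- sqrt(1 + S) - 1    # component sills solving Eq. 7 at k = 1
            n0 <- min(nug / 2, 0.9 * s0); n0t <- min(nugT / 2, 0.9 * s0)
            list(
                par = c(nugS = n0, psS = s0 - n0, rS = rS,
                        nugT = n0t, psT = s0 - n0t, rT = rT, k = 1),
                lower = c(0, 1e-12, lowR, 0, 1e-12, lowR, 1e-6),
                upper = rep(Inf, 7),
                gamma = function(p, h, u) {
                    sS <- p[1] + p[2]; sT <- p[4] + p[5]
                    gs <- gS(h, p[1], sS, p[3]); gt <- gT(u, p[4], sT, p[6])
                    (p[7] * sT + 1) * gs + (p[7] * sS + 1) * gt -
                        p[7] * gs * gt
                },
                build = function(p, fam) stModel("productSum",
                    spatial = variogramComponent(fam[["spatial"]], p[1],
                                                 p[1] + p[2], p[3]),
                    temporal = variogramComponent(fam[["temporal"]], p[4],
                                                  p[4] + p[5], p[6]),
                    k = p[7]))
        },
        metric = list(
            par = c(nugJ = nug, psJ = max(S - nug, 0.1 * S), rJ = rS,
                    kappa = kap),
            lower = c(0, 1e-12, lowR, 1e-6),
            upper = rep(Inf, 4),
            gamma = function(p, h, u)
                gJ(sqrt(h^2 + (p[4] * u)^2), p[1], p[1] + p[2], p[3]),
            build = function(p, fam) stModel("metric",
                joint = variogramComponent(fam[["joint"]], p[1], p[1] + p[2],
                                           p[3]),
                stAni = p[4])),
        sumMetric = list(
            par = c(nugS = nug / 3, psS = max((S - nug) / 3, 1e-3 * S),
                    rS = rS,
                    nugT = nugT / 3, psT = max((St - nugT) / 3, 1e-3 * St),
                    rT = rT,
                    nugJ = nug / 3, psJ = max((S - nug) / 3, 1e-3 * S),
                    rJ = rS, kappa = kap),
            lower = c(0, 0, lowR, 0, 0, lowR, 0, 0, lowR, 1e-6),
            upper = rep(Inf, 10),
            gamma = function(p, h, u)
                gS(h, p[1], p[1] + p[2], p[3]) +
                gT(u, p[4], p[4] + p[5], p[6]) +
                gJ(sqrt(h^2 + (p[10] * u)^2), p[7], p[7] + p[8], p[9]),
            build = function(p, fam) stModel("sumMetric",
                spatial = variogramComponent(fam[["spatial"]], p[1],
                                             p[1] + p[2], p[3]),
                temporal = variogramComponent(fam[["temporal"]], p[4],
                                              p[4] + p[5], p[6]),
                joint = variogramComponent(fam[["joint"]], p[7], p[7] + p[8],
                                           p[9]),
                stAni = p[10])),
        simpleSumMetric = list(
            par = c(n = nug, psS = max((S - nug) / 3, 1e-3 * S), rS = rS,
                    psT = max((St - nugT) / 3, 1e-3 * St), rT = rT,
                    psJ = max((S - nug) / 3, 1e-3 * S), rJ = rS,
                    kappa = kap),
            lower = c(0, 0, lowR, 0, lowR, 0, lowR, 1e-6),
            upper = rep(Inf, 8),
            gamma = function(p, h, u)
                p[1] * as.numeric(h > 0 | u > 0) +
                gS(h, 0, p[2], p[3]) + gT(u, 0, p[4], p[5]) +
                gJ(sqrt(h^2 + (p[8] * u)^2), 0, p[6], p[7]),
            build = function(p, fam) stModel("simpleSumMetric",
                spatial = variogramComponent(fam[["spatial"]], 0, p[2], p[3]),
                temporal = variogramComponent(fam[["temporal"]], 0, p[4],
                                              p[5]),
                joint = variogramComponent(fam[["joint"]], 0, p[6], p[7]),
                stAni = p[8], nugget = p[1])))
}

.familiesNeeded <- function(structure) {
    switch(structure,
           separable = c("spatial", "temporal"),
           productSum = c("spatial", "temporal"),
           metric = "joint",
           sumMetric = c("spatial", "temporal", "joint"),
           simpleSumMetric = c("spatial", "temporal", "joint"))
}

#' Weighted mean squared error of a model against an empirical variogram
#'
#' \eqn{WMSE = \sum_c w_c (\hat\gamma_c - \gamma_{model}(h_c, u_c))^2 /
#' \sum_c w_c} over all non-empty cells, with pair-count weights
#' \eqn{w_c = N(h_c, u_c)}.
#'
#' @param model an [STVariogramModel-class].
#' @param emp an [EmpiricalSTVariogram-class].
#' @return the WMSE (scalar).
#' @export
wmse <- function(model, emp) {
    has <- emp@npairs > 0
    hh <- rep(emp@dist, times = ncol(emp@gamma))[has]
    uu <- rep(as.numeric(emp@temporalLags), each = nrow(emp@gamma))[has]
    w <- emp@npairs[has]
    g <- emp@gamma[has]
    gm <- evalSTVariogram(model, hh, uu)
    sum(w * (g - gm)^2) / sum(w)
}

#' Fit one space-time model candidate by weighted least squares
#'
#' Minimizes the pair-count-weighted mean squared error between the model
#' surface and the empirical semivariogram, by bound-constrained
#' quasi-Newton (L-BFGS-B) from the rule-based starting point.  Component
#' sills are parameterised as nugget + partial sill so that all constraints
#' (nugget \eqn{\ge} 0, sill \eqn{\ge} nugget, range > 0, \eqn{k, \kappa} >
#' 0) are box constraints.
#'
#' @param emp an [EmpiricalSTVariogram-class].
#' @param structure structure name (see [stModel()]).
#' @param families named character vector assigning a component family to
#'   each component the structure uses (\code{spatial}, \code{temporal},
#'   \code{joint}); a single unnamed value is recycled.
#' @param init an [STInitialValues-class]; default [initialGuesses()].
#' @param maxit maximum optimizer iterations.
#' @return an [STFitResult-class]; if the optimizer signals non-convergence
#'   the best iterate is still returned with \code{converged = FALSE}.
#' @export
fitSTModel <- function(emp, structure, families, init = NULL, maxit = 500) {
    structure <- match.arg(structure, .ST_STRUCTURES)
    need <- .familiesNeeded(structure)
    if (is.null(names(families)) && length(families) == 1L)
        families <- setNames(rep(families, length(need)), need)
    if (is.null(names(families)) && length(families) == length(need))
        names(families) <- need
    if (!all(need %in% names(families)))
        stop("families must name components: ", paste(need, collapse = ", "))
    families <- vapply(families[need], function(f)
        match.arg(tolower(f), .VGM_FAMILIES), character(1))
    if (is.null(init)) init <- initialGuesses(emp)

    has <- emp@npairs > 0
    hh <- rep(emp@dist, times = ncol(emp@gamma))[has]
    uu <- rep(as.numeric(emp@temporalLags), each = nrow(emp@gamma))[has]
    w <- emp@npairs[has]; w <- w / sum(w)
    g <- emp@gamma[has]

    spec <- .candidateSpec(structure, families, init)
    fn <- function(p) {
        v <- sum(w * (g - spec$gamma(p, hh, uu))^2)
        if (!is.finite(v)) 1e12 else v
    }
    opt <- tryCatch(
        optim(spec$par, fn, method = "L-BFGS-B", lower = spec$lower,
              upper = spec$upper,
              control = list(maxit = maxit, factr = 1e7,
                             parscale = pmax(abs(spec$par), 1e-6))),
        error = function(e) list(par = spec$par, value = fn(spec$par),
                                 convergence = 51L, message = conditionMessage(e)))
    model <- spec$build(opt$par, families)
    fam3 <- vapply(c("spatial", "temporal", "joint"), function(cc)
        if (cc %in% names(families)) families[[cc]] else "-", character(1))
    new("STFitResult", model = model, wmse = opt$value,
        converged = opt$convergence == 0L,
        candidateId = sprintf("%s/%s+%s+%s", structure,
                              fam3[1], fam3[2], fam3[3]))
}

## parameter columns of one fit for the leaderboard
.fitRow <- function(fit, err = NA_character_) {
    m <- fit@model
    comp <- function(cc, what) {
        cm <- slot(m, cc)
        if (is.null(cm)) NA_real_ else slot(cm, what)
    }
    fam <- function(cc) {
        cm <- slot(m, cc)
        if (is.null(cm)) NA_character_ else cm@family
    }
    data.frame(structure = m@structure,
               spatial_family = fam("spatial"),
               temporal_family = fam("temporal"),
               joint_family = fam("joint"),
               wmse = fit@wmse, converged = fit@converged,
               spatial_nugget = comp("spatial", "nugget"),
               spatial_sill = comp("spatial", "sill"),
               spatial_range = comp("spatial", "range"),
               temporal_nugget = comp("temporal", "nugget"),
               temporal_sill = comp("temporal", "sill"),
               temporal_range = comp("temporal", "range"),
               joint_nugget = comp("joint", "nugget"),
               joint_sill = comp("joint", "sill"),
               joint_range = comp("joint", "range"),
               sill = m@sill, k = m@k, stAni = m@stAni, nugget = m@nugget,
               total_sill = totalSill(m),
               error = err, stringsAsFactors = FALSE)
}

#' Exhaustive structure-by-family model search
#'
#' Fits every combination of the five space-time structures with every
#' assignment of the three component families to the components each
#' structure uses: 9 separable + 9 productSum + 3 metric + 27 sumMetric +
#' 27 simpleSumMetric = 75 candidates.  The winner minimizes the pair-count
#' weighted mean squared error; ties go to the first candidate in the
#' deterministic enumeration order (structures in the order above, families
#' cycling exponential, spherical, Gaussian with the last component
#' fastest).
#'
#' @param emp an [EmpiricalSTVariogram-class].
#' @param init starting values; default [initialGuesses()].
#' @param maxit per-candidate optimizer iteration cap.
#' @param verbose log candidate progress via [message()].
#' @return a list with elements \code{winner} (an [STFitResult-class]),
#'   \code{leaderboard} (a 75-row data.frame sorted by the enumeration
#'   order) and \code{fits} (all [STFitResult-class] objects).
#' @export
modelGridSearch <- function(emp, init = NULL, maxit = 500, verbose = FALSE) {
    if (is.null(init)) init <- initialGuesses(emp)
    fams <- .VGM_FAMILIES
    rows <- list(); fits <- list(); ids <- character(0)
    for (structure in .ST_STRUCTURES) {
        need <- .familiesNeeded(structure)
        ## expand.grid varies its first factor fastest; list components
        ## reversed so the last one cycles fastest, then restore the order
        og <- do.call(expand.grid, c(
            setNames(rep(list(fams), length(need)), rev(need)),
            list(stringsAsFactors = FALSE)))
        grid <- og[, need, drop = FALSE]
        for (i in seq_len(nrow(grid))) {
            fm <- unlist(grid[i, , drop = FALSE])
            fit <- tryCatch(fitSTModel(emp, structure, fm, init, maxit),
                            error = function(e) e)
            if (inherits(fit, "error")) {
                id <- sprintf("%s/%s", structure, paste(fm, collapse = "+"))
                rows[[length(rows) + 1L]] <- data.frame(
                    structure = structure,
                    spatial_family = if ("spatial" %in% need) fm[["spatial"]] else NA,
                    temporal_family = if ("temporal" %in% need) fm[["temporal"]] else NA,
                    joint_family = if ("joint" %in% need) fm[["joint"]] else NA,
                    wmse = NA_real_, converged = FALSE,
                    spatial_nugget = NA_real_, spatial_sill = NA_real_,
                    spatial_range = NA_real_, temporal_nugget = NA_real_,
                    temporal_sill = NA_real_, temporal_range = NA_real_,
                    joint_nugget = NA_real_, joint_sill = NA_real_,
                    joint_range = NA_real_, sill = NA_real_, k = NA_real_,
                    stAni = NA_real_, nugget = NA_real_,
                    total_sill = NA_real_,
                    error = conditionMessage(fit), stringsAsFactors = FALSE)
                fits <- c(fits, list(NULL))
                ids <- c(ids, id)
            } else {
                rows[[length(rows) + 1L]] <- .fitRow(fit)
                fits[[length(fits) + 1L]] <- fit
                ids <- c(ids, fit@candidateId)
                if (verbose)
                    message(sprintf("  [%2d/75] %-40s wmse %.6g",
                                    length(rows), fit@candidateId, fit@wmse))
            }
        }
    }
    leaderboard <- do.call(rbind, rows)
    leaderboard$candidate <- ids
    okW <- which(is.finite(leaderboard$wmse))
    if (!length(okW))
        stop("all candidates failed: ",
             paste(unique(leaderboard$error), collapse = "; "))
    winner <- fits[[okW[which.min(leaderboard$wmse[okW])]]]
    list(winner = winner, leaderboard = leaderboard, fits = fits)
}

setMethod("show", "STFitResult", function(object) {
    cat(sprintf("fit %s: wmse %.6g, converged %s\n", object@candidateId,
                object@wmse, object@converged))
    show(object@model)
})
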