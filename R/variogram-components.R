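#' Construct a component semivariogram model
#'
#' @param family \code{"exponential"}, \code{"spherical"} or
#'   \code{"gaussian"} (case-insensitive, partial matching allowed).
#' @param nugget nugget \eqn{n \ge 0}.
#' @param sill sill \eqn{s \ge n}.
#' @param range range \eqn{r > 0}; for the exponential and Gaussian families
#'   this is the practical range at which 95\% of the sill is first reached
#'   (scale constant \eqn{a = 1/3}), for the spherical family the lag at which
#'   the sill is attained exactly.
#' @return a [VariogramComponent-class] object.
#' @examples
#' variogramComponent("exponential", nugget = 0.1, sill = 1, range = 40)
#' @export
variogramComponent <- function(family, nugget = 0, sill = 1, range = 1) {
    family <- match.arg(tolower(family), .VGM_FAMILIES)
    new("VariogramComponent", family = family, nugget = as.numeric(nugget),
        sill = as.numeric(sill), range = as.numeric(range))
}

#' Evaluate a component semivariogram
#'
#' Computes \eqn{\gamma(h)} for an exponential, spherical or Gaussian
#' component.  All three families use the Heaviside convention
#' \eqn{\gamma(0) = 0}, with right-limit \eqn{n} at \eqn{0^+}:
#' \deqn{\gamma_{exp}(h) = (s-n)(1 - e^{-h/(ra)}) + n\,H_{(0,\infty)}(h)}
#' \deqn{\gamma_{sph}(h) = (s-n)\left[\left(\tfrac{3h}{2r} -
#'   \tfrac{h^3}{2r^3}\right)H_{(0,r)}(h) + H_{[r,\infty)}(h)\right] +
#'   n\,H_{(0,\infty)}(h)}
#' \deqn{\gamma_{gau}(h) = (s-n)(1 - e^{-h^2/(r^2 a)}) + n\,H_{(0,\infty)}(h)}
#' with \eqn{a = 1/3}, so the exponential and Gaussian families reach
#' \eqn{n + 0.950213\,(s - n)} at \eqn{h = r}.
#'
#' @param object a [VariogramComponent-class].
#' @param h numeric vector of non-negative lags.
#' @return numeric vector of semivariances, same length as \code{h}.
#' @examples
#' m <- variogramComponent("exponential", 0, 1, 10)
#' evalComponent(m, 10)   # 1 - exp(-3)
#' @export
setGeneric("evalComponent", function(object, h) standardGeneric("evalComponent"))

#' @rdname evalComponent
#' @export
setMethod("evalComponent", "VariogramComponent", function(object, h) {
    if (any(h < 0, na.rm = TRUE))
        stop("lag h must be non-negative")
    n <- object@nugget; s <- object@sill; r <- object@range
    a <- .RANGE_A
    g <- switch(object@family,
        exponential = (s - n) * (1 - exp(-h / (r * a))),
        gaussian    = (s - n) * (1 - exp(-h^2 / (r^2 * a))),
        spherical   = {
            hb <- pmin(h, r)
            (s - n) * (3 * hb / (2 * r) - hb^3 / (2 * r^3))
        })
    g <- g + n
    g[h == 0] <- 0
    g
})

setMethod("show", "VariogramComponent", function(object) {
    cat(sprintf("%s variogram component: nugget %.4g, sill %.4g, range %.4g\n",
                object@family, object@nugget, object@sill, object@range))
})
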