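#' Convert between tumour diameter and volume
#'
#' Tumours are modelled as spheres, so a diameter \eqn{d} mm corresponds
#' to a volume \eqn{v = (\pi/6) d^3} mm^3.
#'
#' @param x positive numeric vector of diameters (mm) or volumes (mm^3).
#' @param from `"diameter"` to convert mm to mm^3, `"volume"` for the
#'   reverse.
#' @return Numeric vector of the converted sizes.
#' @examples
#' size_convert(20, "diameter")          # volume of a 20 mm tumour
#' size_convert(pi / 6, "volume")        # 1 mm
#' @export
size_convert <- function(x, from = c("diameter", "volume")) {
  from <- match.arg(from)
  if (any(x <= 0)) stop("sizes must be strictly positive")
  if (from == "diameter") pi / 6 * x^3 else (6 * x / pi)^(1 / 3)
}

#' Tumour volume at a time since onset
#'
#' Exponential growth from the onset volume:
#' \eqn{V(t) = V_0 \exp(t/r)}, where \eqn{r} is the woman's inverse
#' growth rate (years).
#'
#' @param t years since onset (nonnegative).
#' @param r inverse growth rate(s), years.
#' @param p a [growth_params()] object.
#' @return Tumour volume(s) in mm^3.
#' @export
volume_at <- function(t, r, p) {
  stopifnot(inherits(p, "growth_params"))
  if (any(t < 0)) stop("time since onset must be nonnegative")
  if (any(r <= 0)) stop("inverse growth rate must be positive")
  p$v0 * exp(t / r)
}

#' Cumulative hazard of symptomatic detection
#'
#' The symptomatic-detection hazard is proportional to the concurrent
#' tumour volume, \eqn{\lambda(u) = \eta V(u)}, so the cumulative hazard
#' has the closed form
#' \eqn{\Lambda(t) = \eta V_0 r (\exp(t/r) - 1)}.
#'
#' @inheritParams volume_at
#' @return Dimensionless cumulative hazard.
#' @export
sympt_cum_hazard <- function(t, r, p) {
  stopifnot(inherits(p, "growth_params"))
  if (any(t < 0)) stop("time since onset must be nonnegative")
  p$eta * p$v0 * r * expm1(t / r)
}

#' Sample inverse growth rates
#'
#' @param n number of draws (ignored when `u` is supplied).
#' @param p a [growth_params()] object.
#' @param u optional uniform(0,1) draws.
#' @return Gamma-distributed inverse growth rates (years), all positive.
#' @export
sample_inv_growth_rate <- function(n, p, u = NULL) {
  stopifnot(inherits(p, "growth_params"))
  if (is.null(u)) stats::rgamma(n, shape = p$shape, rate = p$rate)
  else stats::qgamma(u, shape = p$shape, rate = p$rate)
}

#' Sample the time from onset to symptomatic detection
#'
#' Inverse-transform sampling of the nonhomogeneous detection hazard:
#' with \eqn{E \sim \mathrm{Exp}(1)},
#' \eqn{t = r \log(1 + E / (\eta V_0 r))} satisfies
#' \eqn{\Lambda(t) = E} exactly.
#'
#' @param r inverse growth rate(s), years.
#' @param p a [growth_params()] object.
#' @param E optional standard-exponential draws (one per element of
#'   `r`); drawn internally when `NULL`.
#' @return Years from onset to symptomatic detection.
#' @export
sample_sympt_interval <- function(r, p, E = NULL) {
  stopifnot(inherits(p, "growth_params"))
  if (any(r <= 0)) stop("inverse growth rate must be positive")
  if (is.null(E)) E <- stats::rexp(length(r))
  r * log1p(E / (p$eta * p$v0 * r))
}
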