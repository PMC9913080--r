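# Two-stage clonal expansion (MVK) age-at-onset model.
#
# Initiated-cell clones follow a linear birth-death-mutation process
# (birth alpha, death beta, malignant mutation mu); initiation is Poisson
# with rate nu.  Writing r1 < r2 for the roots of
#   alpha z^2 - (alpha + beta + mu) z + beta = 0,
# and A = r2 - 1 > 0, B = 1 - r1 > 0, g = alpha (A + B), the probability
# that a clone initiated a time u ago has not yet produced a malignant
# cell is Q(u), with
#   1 - Q(u) = (mu/alpha) (1 - e^{-gu}) / (A + B e^{-gu}),
# giving closed forms for the onset hazard h(t) = nu (1 - Q(t)) and its
# integral (the identities mu = alpha A B and g = alpha (A + B) collapse
# the partial fractions):
#   H(t) = nu [ (mu/(alpha A)) t - (1/alpha) log((A+B)/(A + B e^{-gt})) ].

tsce_aux <- function(p) {
  s <- p$alpha + p$beta + p$mu
  g <- sqrt(s^2 - 4 * p$alpha * p$beta)   # always real: s^2-4ab = (a-b+m)^2+4bm
  r2 <- (s + g) / (2 * p$alpha)
  r1 <- (s - g) / (2 * p$alpha)
  list(g = g, A = r2 - 1, B = 1 - r1)
}

#' Onset hazard, cumulative hazard and CDF
#'
#' Closed-form hazard \eqn{h(t)}, cumulative hazard \eqn{H(t)} and CDF
#' \eqn{F(t) = 1 - e^{-H(t)}} of the age at tumour onset under the
#' two-stage clonal expansion model.
#'
#' @param age vector of ages in years (nonnegative).
#' @param p an [onset_params()] object.
#' @return Numeric vector the length of `age`.
#' @examples
#' p <- onset_params(nu = 0.04, alpha = 1, beta = 0.9, mu = 1e-4)
#' onset_cdf(c(40, 60, 80), p)
#' @export
onset_hazard <- function(age, p) {
  stopifnot(inherits(p, "onset_params"))
  if (any(age < 0)) stop("age must be nonnegative")
  k <- tsce_aux(p)
  e <- exp(-k$g * age)
  p$nu * (p$mu / p$alpha) * (1 - e) / (k$A + k$B * e)
}

#' @rdname onset_hazard
#' @export
onset_cumhaz <- function(age, p) {
  stopifnot(inherits(p, "onset_params"))
  if (any(age < 0)) stop("age must be nonnegative")
  k <- tsce_aux(p)
  e <- exp(-k$g * age)
  p$nu * (p$mu / (p$alpha * k$A) * age -
            log((k$A + k$B) / (k$A + k$B * e)) / p$alpha)
}

#' @rdname onset_hazard
#' @export
onset_cdf <- function(age, p) {
  -expm1(-onset_cumhaz(age, p))
}

# Cached evaluation grid for inverse sampling: F on ages 0..max_age in
# steps of `step` years; F is strictly increasing for age > 0, so linear
# interpolation of the inverse is well defined.
onset_grid <- function(p, max_age = 120, step = 0.05) {
  ages <- seq(0, max_age, by = step)
  list(ages = ages, F = onset_cdf(ages, p))
}

#' Sample ages at tumour onset
#'
#' Inverse-CDF sampling on a cached age grid (0 to `max_age` years in
#' steps of `step`).  A uniform draw exceeding the CDF at `max_age`
#' means the woman never develops a tumour; her onset age is `Inf`.
#'
#' @param n number of draws (ignored when `u` is supplied).
#' @param p an [onset_params()] object.
#' @param u optional uniform(0,1) draws, for coupling across scenarios.
#' @param max_age,step grid extent and resolution in years.
#' @return Numeric vector of onset ages; `Inf` for women with no onset
#'   by `max_age`.
#' @export
sample_onset_age <- function(n, p, u = NULL, max_age = 120, step = 0.05) {
  if (is.null(u)) u <- stats::runif(n)
  gr <- onset_grid(p, max_age = max_age, step = step)
  out <- stats::approx(gr$F, gr$ages, xout = u, ties = "ordered")$y
  out[u > gr$F[length(gr$F)]] <- Inf
  out[u <= 0] <- 0
  out
}
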