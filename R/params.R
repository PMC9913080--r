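#' Parameters of the tumour-onset model
#'
#' The age at tumour onset (the age at which a tumour reaches 0.5 mm in
#' diameter) follows the two-stage clonal expansion (Moolgavkar--Venzon--
#' Knudson) carcinogenesis model: susceptible cells acquire a first
#' (initiating) event as a Poisson process of rate `nu`; initiated cells
#' divide at rate `alpha`, die or differentiate at rate `beta`, and acquire
#' the second (malignant) event at rate `mu` per cell-year.  Onset is the
#' appearance of the first malignant cell.
#'
#' @param nu initiation rate (events per year; the number of susceptible
#'   cells is folded into this rate).
#' @param alpha division rate of initiated cells (per cell-year).
#' @param beta death/differentiation rate of initiated cells (per
#'   cell-year).
#' @param mu malignant transformation rate of initiated cells (per
#'   cell-year).
#' @return An object of class `onset_params`.
#' @seealso [onset_cdf()], [sample_onset_age()]
#' @export
onset_params <- function(nu, alpha, beta, mu) {
  stopifnot(is.numeric(nu), is.numeric(alpha), is.numeric(beta),
            is.numeric(mu), length(nu) == 1L, length(alpha) == 1L,
            length(beta) == 1L, length(mu) == 1L)
  if (any(c(nu, alpha, beta, mu) <= 0))
    stop("all onset rate parameters must be strictly positive")
  structure(list(nu = nu, alpha = alpha, beta = beta, mu = mu),
            class = "onset_params")
}

#' Parameters of tumour growth and symptomatic detection
#'
#' Tumour volume grows exponentially from the onset volume:
#' \eqn{V(t) = V_0 \exp(t/r)}, where the inverse growth rate \eqn{r}
#' (years; the time for volume to grow by a factor \eqn{e}) is a gamma
#' random effect.  The hazard of symptomatic detection at time \eqn{t}
#' after onset is proportional to the concurrent tumour volume,
#' \eqn{\lambda(t) = \eta V(t)}.  Tumours are spherical, so onset volume
#' is \eqn{V_0 = (\pi/6) d_0^3} with \eqn{d_0 = 0.5} mm.
#'
#' @param shape,rate shape and rate of the gamma distribution of the
#'   inverse growth rate (rate in 1/years).
#' @param eta symptomatic-detection hazard coefficient (per mm^3 per
#'   year).
#' @param d0 onset diameter in mm; fixed at 0.5 by the model definition.
#' @return An object of class `growth_params` with derived field `v0`
#'   (onset volume, mm^3).
#' @export
growth_params <- function(shape, rate, eta, d0 = 0.5) {
  stopifnot(length(shape) == 1L, length(rate) == 1L, length(eta) == 1L)
  if (shape <= 0 || rate <= 0) stop("gamma parameters must be positive")
  if (eta <= 0) stop("eta must be positive")
  if (!isTRUE(all.equal(d0, 0.5)))
    stop("d0 is fixed at 0.5 mm by the model definition")
  structure(list(d0 = d0, v0 = pi / 6 * d0^3, shape = shape, rate = rate,
                 eta = eta),
            class = "growth_params")
}

#' Parameters of lymph-node involvement at diagnosis
#'
#' Conditional on the tumour volume \eqn{v} at detection, the number of
#' affected lymph nodes follows a negative binomial distribution with
#' dispersion `size` and mean \eqn{m(v) = c\, v^{\omega}} — a mean that is
#' nonnegative and nondecreasing in tumour volume, reflecting a spread
#' process whose accumulated rate grows with the tumour.
#'
#' @param size negative-binomial dispersion (the `size` argument of
#'   [stats::rnbinom()]); smaller values give more overdispersion.
#' @param coef multiplier \eqn{c} of the mean function (nodes per
#'   mm^(3*power)).
#' @param power exponent \eqn{\omega} of tumour volume in the mean
#'   function.
#' @return An object of class `nodal_params`.
#' @export
nodal_params <- function(size, coef, power) {
  stopifnot(length(size) == 1L, length(coef) == 1L, length(power) == 1L)
  if (size <= 0) stop("dispersion must be positive")
  if (coef < 0 || power < 0) stop("mean-function parameters must be nonnegative")
  structure(list(size = size, coef = coef, power = power),
            class = "nodal_params")
}

#' Parameters of mammographic screening sensitivity
#'
#' The probability that a screen detects an existing tumour is a logistic
#' function of the latent tumour diameter \eqn{d} (mm):
#' \eqn{s(d) = \mathrm{expit}(\beta_0 + \beta_1 d)}.
#'
#' @param intercept logistic intercept \eqn{\beta_0}.
#' @param slope logistic slope \eqn{\beta_1} (per mm); must be positive
#'   so that larger tumours are more detectable.
#' @return An object of class `sensitivity_params`.
#' @export
sensitivity_params <- function(intercept, slope) {
  stopifnot(length(intercept) == 1L, length(slope) == 1L)
  if (slope <= 0) stop("sensitivity slope must be positive (larger tumours more detectable)")
  structure(list(intercept = intercept, slope = slope),
            class = "sensitivity_params")
}

#' Parameters of post-diagnosis breast-cancer-specific survival
#'
#' A mixture-cure model conditional on the prognostic features at
#' detection (tumour diameter in mm and number of positive nodes):
#' a woman is cured with probability
#' \eqn{\pi(d,n) = \mathrm{expit}(c_0 + c_d d + c_n n)}, and otherwise
#' her time from detection to breast-cancer death is Weibull with shape
#' `surv_shape` and scale \eqn{\exp(s_0 + s_d d + s_n n)} years.  The
#' mode of detection influences survival only through the size and nodal
#' status at detection, which is precisely the stage-shift mechanism by
#' which earlier detection improves prognosis.
#'
#' @param cure_intercept,cure_size,cure_slope_nodes coefficients
#'   \eqn{c_0, c_d, c_n} of the logistic cure probability; the size and
#'   node coefficients should be negative (worse prognosis for larger,
#'   node-positive tumours).
#' @param surv_shape Weibull shape of the uncured survival time.
#' @param surv_log_scale,surv_size,surv_slope_nodes coefficients
#'   \eqn{s_0, s_d, s_n} of the log Weibull scale (years).
#' @return An object of class `bc_survival_params`.
#' @export
bc_survival_params <- function(cure_intercept, cure_size, cure_slope_nodes,
                               surv_shape, surv_log_scale, surv_size,
                               surv_slope_nodes) {
  vals <- c(cure_intercept, cure_size, cure_slope_nodes, surv_shape,
            surv_log_scale, surv_size, surv_slope_nodes)
  stopifnot(is.numeric(vals), length(vals) == 7L, all(is.finite(vals)))
  if (surv_shape <= 0) stop("Weibull shape must be positive")
  structure(list(cure_intercept = cure_intercept, cure_size = cure_size,
                 cure_slope_nodes = cure_slope_nodes,
                 surv_shape = surv_shape, surv_log_scale = surv_log_scale,
                 surv_size = surv_size, surv_slope_nodes = surv_slope_nodes),
            class = "bc_survival_params")
}

#' Bundle of all natural-history parameters
#'
#' Collects the five submodels (onset, growth/symptomatic detection,
#' nodal spread, screening sensitivity, post-diagnosis survival) into one
#' object consumed by the simulation engine.
#'
#' @param onset an [onset_params()] object.
#' @param growth a [growth_params()] object.
#' @param nodal a [nodal_params()] object.
#' @param sensitivity a [sensitivity_params()] object.
#' @param survival a [bc_survival_params()] object.
#' @return An object of class `nh_params`.
#' @export
nh_params <- function(onset, growth, nodal, sensitivity, survival) {
  stopifnot(inherits(onset, "onset_params"),
            inherits(growth, "growth_params"),
            inherits(nodal, "nodal_params"),
            inherits(sensitivity, "sensitivity_params"),
            inherits(survival, "bc_survival_params"))
  structure(list(onset = onset, growth = growth, nodal = nodal,
                 sensitivity = sensitivity, survival = survival),
            class = "nh_params")
}

#' Default parameter sets
#'
#' `"synthetic"` is the package's default parameterisation: a synthetic
#' set calibrated once so that the no-screening pipeline reproduces
#' summary features of breast-cancer epidemiology in a Northern-European
#' screening setting (lifetime risk of invasive breast cancer around
#' 15\%, typical symptomatic tumour diameters of 20--25 mm, screening
#' sensitivity around 80\% at 20 mm, roughly a quarter of cases
#' ultimately fatal).  `"toy"` is a small deliberately fast-progressing
#' set for unit tests.
#'
#' @param set `"synthetic"` (default) or `"toy"`.
#' @return An `nh_params` object.
#' @export
default_nh_params <- function(set = c("synthetic", "toy")) {
  set <- match.arg(set)
  if (set == "synthetic") {
    nh_params(
      onset = onset_params(nu = 0.051, alpha = 1, beta = 0.902, mu = 1.1e-4),
      growth = growth_params(shape = 1.4, rate = 2.0, eta = 2.6e-4),
      nodal = nodal_params(size = 0.32, coef = 0.008, power = 0.5),
      sensitivity = sensitivity_params(intercept = -4.0, slope = 0.5),
      survival = bc_survival_params(
        cure_intercept = 2.7, cure_size = -0.06, cure_slope_nodes = -0.30,
        surv_shape = 1.2, surv_log_scale = 2.0, surv_size = -0.015,
        surv_slope_nodes = -0.08)
    )
  } else {
    nh_params(
      onset = onset_params(nu = 0.3, alpha = 1, beta = 0.8, mu = 5e-4),
      growth = growth_params(shape = 2, rate = 4, eta = 1e-3),
      nodal = nodal_params(size = 0.5, coef = 0.03, power = 0.5),
      sensitivity = sensitivity_params(intercept = -3, slope = 0.4),
      survival = bc_survival_params(
        cure_intercept = 1.5, cure_size = -0.05, cure_slope_nodes = -0.2,
        surv_shape = 1.1, surv_log_scale = 1.8, surv_size = -0.01,
        surv_slope_nodes = -0.05)
    )
  }
}

#' Read / write a natural-history parameter file
#'
#' Parameters are stored as JSON mirroring the constructor arguments
#' field-for-field, under top-level keys `onset`, `growth`, `nodal`,
#' `sensitivity`, `survival`.  The reader refuses partially-specified
#' sets and re-runs all constructor validation (positivity etc.).
#'
#' @param path file path of the JSON parameter file.
#' @return `read_nh_params()` returns an `nh_params` object;
#'   `write_nh_params()` returns `path` invisibly.
#' @export
read_nh_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("onset", "growth", "nodal", "sensitivity", "survival")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("parameter file is missing submodel(s): ", paste(miss, collapse = ", "))
  nh_params(
    onset = do.call(onset_params, as.list(x$onset)),
    growth = do.call(growth_params,
                     as.list(x$growth[setdiff(names(x$growth), "v0")])),
    nodal = do.call(nodal_params, as.list(x$nodal)),
    sensitivity = do.call(sensitivity_params, as.list(x$sensitivity)),
    survival = do.call(bc_survival_params, as.list(x$survival))
  )
}

#' @rdname read_nh_params
#' @param params an `nh_params` object to serialise.
#' @export
write_nh_params <- function(params, path) {
  stopifnot(inherits(params, "nh_params"))
  jsonlite::write_json(lapply(unclass(params), unclass), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.nh_params <- function(x, ...) {
  cat("Breast-cancer natural-history parameters\n")
  cat(sprintf("  onset (two-stage clonal expansion): nu=%.4g alpha=%.4g beta=%.4g mu=%.4g\n",
              x$onset$nu, x$onset$alpha, x$onset$beta, x$onset$mu))
  cat(sprintf("  growth: inverse growth rate ~ Gamma(shape=%.3g, rate=%.3g /yr); eta=%.3g /mm^3/yr\n",
              x$growth$shape, x$growth$rate, x$growth$eta))
  cat(sprintf("  nodal: NB(size=%.3g), mean = %.3g * v^%.3g\n",
              x$nodal$size, x$nodal$coef, x$nodal$power))
  cat(sprintf("  sensitivity: expit(%.3g + %.3g * d[mm])\n",
              x$sensitivity$intercept, x$sensitivity$slope))
  cat(sprintf("  survival: cure expit(%.3g %+.3g*d %+.3g*n); Weibull(shape=%.3g, scale=exp(%.3g %+.3g*d %+.3g*n))\n",
              x$survival$cure_intercept, x$survival$cure_size,
              x$survival$cure_slope_nodes, x$survival$surv_shape,
              x$survival$surv_log_scale, x$survival$surv_size,
              x$survival$surv_slope_nodes))
  invisible(x)
}
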