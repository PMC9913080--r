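#' Breast-cancer-specific survival function after diagnosis
#'
#' Mixture-cure survival conditional on prognostic features at
#' detection: \eqn{S(t \mid d, n) = \pi(d,n) + (1-\pi(d,n))
#' S_W(t \mid d, n)} with a logistic cure probability \eqn{\pi} and a
#' Weibull survival \eqn{S_W} for the uncured (see
#' [bc_survival_params()]).
#'
#' @param t years since detection (nonnegative).
#' @param diameter tumour diameter at detection, mm.
#' @param nodes number of positive nodes at detection.
#' @param p a [bc_survival_params()] object.
#' @return Survival probabilities, nonincreasing in `t` from 1.
#' @export
bc_survival_fn <- function(t, diameter, nodes, p) {
  stopifnot(inherits(p, "bc_survival_params"))
  if (any(t < 0)) stop("time since detection must be nonnegative")
  cure <- stats::plogis(p$cure_intercept + p$cure_size * diameter +
                          p$cure_slope_nodes * nodes)
  scale <- exp(p$surv_log_scale + p$surv_size * diameter +
                 p$surv_slope_nodes * nodes)
  cure + (1 - cure) * stats::pweibull(t, shape = p$surv_shape,
                                      scale = scale, lower.tail = FALSE)
}

#' Sample times from detection to breast-cancer death
#'
#' Inverse-CDF draws from [bc_survival_fn()]: cured women (probability
#' \eqn{\pi(d,n)}) never die of breast cancer and return `Inf`.  Using
#' a shared uniform vector couples draws monotonically across
#' counterfactual detection scenarios.
#'
#' @param diameter,nodes prognostic features at detection (vectors).
#' @param p a [bc_survival_params()] object.
#' @param u optional uniform(0,1) draws.
#' @return Years from detection to breast-cancer death; `Inf` if cured.
#' @export
sample_bc_survival <- function(diameter, nodes, p, u = NULL) {
  stopifnot(inherits(p, "bc_survival_params"))
  n <- length(diameter)
  if (is.null(u)) u <- stats::runif(n)
  cure <- stats::plogis(p$cure_intercept + p$cure_size * diameter +
                          p$cure_slope_nodes * nodes)
  scale <- exp(p$surv_log_scale + p$surv_size * diameter +
                 p$surv_slope_nodes * nodes)
  out <- rep(Inf, n)
  fatal <- u > cure                     # S(t) = u has a finite solution
  out[fatal] <- stats::qweibull((u[fatal] - cure[fatal]) / (1 - cure[fatal]),
                                shape = p$surv_shape, scale = scale[fatal],
                                lower.tail = FALSE)
  out
}

#' Resolve competing events into one observed outcome
#'
#' The realised mode of detection is whichever comes first: screen
#' detection, symptomatic detection, or death from other causes before
#' any diagnosis.  Two counterfactual all-cause death ages are computed
#' for every woman — one as if detection had been symptomatic, one as if
#' it had been at the (possibly absent) screen — sharing the other-cause
#' death age.  Death ages are truncated at the life-table terminal age.
#'
#' @param sympt_age,screen_age detection ages under each scenario
#'   (years; `Inf` when the scenario has no detection).
#' @param bc_surv_sympt,bc_surv_screen sampled times from detection to
#'   breast-cancer death under each scenario (years; `Inf` if cured).
#' @param other_cause_age age at death from other causes (years).
#' @param terminal_age upper truncation for death ages.
#' @return A data frame with columns `mode` (`"screen"`,
#'   `"symptomatic"`, `"none"`), `detection_age`, `death_age`,
#'   `death_cause` (`"breast cancer"` or `"other"`), and the
#'   counterfactual all-cause death ages `sympt_death_age`,
#'   `screen_death_age` (the latter `NA` when there is no screen
#'   detection).
#' @export
resolve_outcome <- function(sympt_age, screen_age, bc_surv_sympt,
                            bc_surv_screen, other_cause_age,
                            terminal_age = 111) {
  n <- length(sympt_age)
  stopifnot(length(screen_age) == n, length(other_cause_age) == n)
  sympt_death <- pmin(sympt_age + bc_surv_sympt, other_cause_age, terminal_age)
  screen_death <- pmin(screen_age + bc_surv_screen, other_cause_age, terminal_age)
  screen_death[!is.finite(screen_age)] <- NA_real_

  mode <- rep("none", n)
  mode[sympt_age < other_cause_age] <- "symptomatic"
  mode[is.finite(screen_age) & screen_age < other_cause_age &
         screen_age < sympt_age] <- "screen"

  detection_age <- ifelse(mode == "screen", screen_age,
                          ifelse(mode == "symptomatic", sympt_age, Inf))
  death_age <- ifelse(mode == "screen", screen_death,
                      ifelse(mode == "symptomatic", sympt_death,
                             pmin(other_cause_age, terminal_age)))
  bc_death_age <- ifelse(mode == "screen", screen_age + bc_surv_screen,
                         ifelse(mode == "symptomatic",
                                sympt_age + bc_surv_sympt, Inf))
  death_cause <- ifelse(mode != "none" & bc_death_age < other_cause_age &
                          bc_death_age <= terminal_age,
                        "breast cancer", "other")
  data.frame(mode = mode, detection_age = detection_age,
             death_age = death_age, death_cause = death_cause,
             sympt_death_age = sympt_death, screen_death_age = screen_death)
}
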