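#' Tumour stage categories
#'
#' Ordinal T (size) and N (nodal) categories used to define stage
#' shift: T boundaries at 20 and 50 mm, N boundaries at 0, 3 and 9
#' nodes.  A value exactly on a boundary belongs to the lower category.
#'
#' @param value tumour diameter in mm (`kind = "T"`) or node count
#'   (`kind = "N"`); nonnegative.
#' @param kind `"T"` or `"N"`.
#' @return Integer categories 0--3 (`T` of any detected tumour is at
#'   least 1).
#' @examples
#' stage_category(15, "T")   # 1
#' stage_category(5, "N")    # 2
#' @export
stage_category <- function(value, kind = c("T", "N")) {
  kind <- match.arg(kind)
  if (any(value < 0, na.rm = TRUE)) stop("stage value must be nonnegative")
  if (kind == "T") {
    ifelse(value <= 20, 1L, ifelse(value <= 50, 2L, 3L))
  } else {
    ifelse(value == 0, 0L, ifelse(value <= 3, 1L, ifelse(value <= 9, 2L, 3L)))
  }
}

case_levels <- c("overdiagnosed", "n_shifted", "t_shifted",
                 "other_screen", "symptomatic")

#' Classify breast-cancer cases
#'
#' Assigns each case one of five mutually exclusive categories with the
#' precedence overdiagnosed > N-shifted > T-shifted > other
#' screen-detected; non-screen-detected cases are symptomatic/interval.
#' Overdiagnosed means screen-detected with death from other causes
#' before the would-be symptomatic detection age; a shift means the
#' screen-detection stage category is below the would-be symptomatic
#' one (the N-shifted category absorbs cases that are also T-shifted).
#'
#' @param records a `cohort_records` data frame (rows with
#'   `mode == "none"` are not cases and return `NA`).
#' @return Factor with levels `overdiagnosed`, `n_shifted`,
#'   `t_shifted`, `other_screen`, `symptomatic`.
#' @export
classify_case <- function(records) {
  out <- rep(NA_character_, nrow(records))
  out[records$mode == "symptomatic"] <- "symptomatic"
  sc <- records$mode == "screen"
  if (any(sc)) {
    over <- sc & records$ocd_age < records$sympt_age
    nsh <- sc & !over &
      stage_category(records$screen_nodes, "N") <
        stage_category(records$sympt_nodes, "N")
    tsh <- sc & !over & !nsh &
      stage_category(records$screen_diameter, "T") <
        stage_category(records$sympt_diameter, "T")
    out[over] <- "overdiagnosed"
    out[nsh] <- "n_shifted"
    out[tsh] <- "t_shifted"
    out[sc & !over & !nsh & !tsh] <- "other_screen"
  }
  factor(out, levels = case_levels)
}

#' Lead time of screen-detected cases
#'
#' Time gained between screen detection and the would-be symptomatic
#' detection of the same tumour; `NA` for cases not detected by
#' screening (they are excluded from averages).
#'
#' @param records a `cohort_records` data frame.
#' @return Numeric vector of years, nonnegative where defined.
#' @export
lead_time <- function(records) {
  ifelse(records$mode == "screen",
         records$sympt_age - records$screen_age, NA_real_)
}

#' All-cause survival difference attributable to screen detection
#'
#' Difference between the all-cause death age under screen detection
#' and under would-be symptomatic detection (equivalently, both
#' survivals counted from the would-be symptomatic detection age, which
#' removes lead-time bias).  Exactly zero for all cases that are not
#' screen-detected; can be negative for individual women because the
#' two breast-cancer survival draws are independent.
#'
#' @param records a `cohort_records` data frame.
#' @return Numeric vector of years.
#' @export
survival_difference <- function(records) {
  ifelse(records$mode == "screen",
         records$screen_death_age - records$sympt_death_age, 0)
}

#' Aggregate programme-level outcomes
#'
#' Tallies the headline outcomes of a simulated programme: mammograms,
#' case counts by category, breast-cancer deaths (normalised per
#' `per` women), and average lead time and survival difference over all
#' screen-detected cases (overdiagnosed cases included).
#'
#' @param records a `cohort_records` data frame.
#' @param per normalising population size (default one million women).
#' @return An object of class `programme_tally`.
#' @export
tally_programme <- function(records, per = 1e6) {
  n <- nrow(records)
  scale <- per / n
  cat_ <- classify_case(records)
  counts <- table(cat_)
  sc <- records$mode == "screen"
  structure(list(
    programme = attr(records, "programme"),
    n_women = n, per = per,
    mammograms_k = count_mammograms(records) * scale / 1000,
    total_cases = sum(records$mode != "none") * scale,
    symptomatic = counts[["symptomatic"]] * scale,
    overdiagnosed = counts[["overdiagnosed"]] * scale,
    n_shifted = counts[["n_shifted"]] * scale,
    t_shifted = counts[["t_shifted"]] * scale,
    other_screen = counts[["other_screen"]] * scale,
    screen_detected = sum(sc) * scale,
    bc_deaths = sum(records$death_cause == "breast cancer" &
                      records$mode != "none") * scale,
    avg_lead_time = if (any(sc)) mean(lead_time(records)[sc]) else 0,
    avg_surv_diff = if (any(sc)) mean(survival_difference(records)[sc]) else 0
  ), class = "programme_tally")
}

#' @export
print.programme_tally <- function(x, ...) {
  cat(sprintf("Programme tally: %s (per %s women)\n", x$programme,
              format(x$per, big.mark = ",")))
  f <- function(lbl, v, d = 0) cat(sprintf("  %-22s %s\n", lbl,
                                           formatC(v, format = "f",
                                                   digits = d, big.mark = ",")))
  f("Mammograms (k)", x$mammograms_k)
  f("Total cases", x$total_cases)
  f("Symptomatic/Interval", x$symptomatic)
  f("Overdiagnosed", x$overdiagnosed)
  f("N-shifted", x$n_shifted)
  f("T-shifted", x$t_shifted)
  f("Other screen-detected", x$other_screen)
  f("Breast cancer deaths", x$bc_deaths)
  f("Avg. lead time (yrs)", x$avg_lead_time, 2)
  f("Avg. surv. diff. (yrs)", x$avg_surv_diff, 2)
  invisible(x)
}

#' Per-round breakdown of detected cases
#'
#' For each screening round: the number of mammograms performed, the
#' screen-detected cases by category, and the interval cancers
#' attributed to the preceding round (symptomatic cases after at least
#' one attended screen and before the end of the screening window).
#' Counts are also given per 100,000 mammograms at that round.
#'
#' @param records a `cohort_records` data frame from a screened run.
#' @param prog the [screening_programme()] used.
#' @return A data frame with one row per round.
#' @export
per_round_breakdown <- function(records, prog) {
  stopifnot(inherits(prog, "screening_programme"), length(prog$ages) > 0)
  ages <- prog$ages
  k <- length(ages)
  exit <- pmin(records$detection_age, records$death_age)
  mam <- vapply(seq_len(k), function(j)
    sum(ages[j] < exit) + sum(records$screen_round == j, na.rm = TRUE),
    numeric(1))
  cat_ <- classify_case(records)
  by_round <- function(lev) vapply(seq_len(k), function(j)
    sum(records$screen_round == j & cat_ == lev, na.rm = TRUE), numeric(1))
  interval_len <- if (k > 1) stats::median(diff(ages)) else 2
  idx <- findInterval(records$sympt_age, ages)
  is_interval <- records$mode == "symptomatic" & idx >= 1 &
    records$sympt_age < ages[k] + interval_len & records$mammograms >= 1
  intv <- vapply(seq_len(k), function(j)
    sum(is_interval & idx == j), numeric(1))
  out <- data.frame(round = seq_len(k), age = ages, mammograms = mam,
                    screen_detected = by_round("overdiagnosed") +
                      by_round("n_shifted") + by_round("t_shifted") +
                      by_round("other_screen"),
                    overdiagnosed = by_round("overdiagnosed"),
                    n_shifted = by_round("n_shifted"),
                    t_shifted = by_round("t_shifted"),
                    other_screen = by_round("other_screen"),
                    interval_cancers = intv)
  for (cc in c("screen_detected", "overdiagnosed", "n_shifted", "t_shifted",
               "other_screen", "interval_cancers"))
    out[[paste0(cc, "_per_100k")]] <- 1e5 * out[[cc]] / out$mammograms
  out
}

#' Life-expectancy gain per mammogram
#'
#' For each round, the sum of all (nonzero) survival differences of
#' cases screen-detected at that round divided by the mammograms
#' performed at that round, in days; and its reciprocal, the number of
#' mammograms per life-year gained.  The programme totals give the
#' expected life-expectancy change per woman (days) over the whole
#' programme and the overall mammograms per life-year.
#'
#' @inheritParams per_round_breakdown
#' @return A list with elements `per_round` (data frame: `round`,
#'   `age`, `mammograms`, `days_per_mammogram`,
#'   `mammograms_per_life_year`) and scalars `total_days_per_woman`,
#'   `total_mammograms_per_life_year`.
#' @export
life_expectancy_metrics <- function(records, prog) {
  stopifnot(inherits(prog, "screening_programme"), length(prog$ages) > 0)
  br <- per_round_breakdown(records, prog)
  sd_all <- survival_difference(records)
  gain <- vapply(seq_along(prog$ages), function(j)
    sum(sd_all[records$screen_round == j & !is.na(records$screen_round)]),
    numeric(1))
  days <- ifelse(br$mammograms > 0, 365.25 * gain / br$mammograms, NA_real_)
  per_round <- data.frame(round = br$round, age = br$age,
                          mammograms = br$mammograms,
                          days_per_mammogram = days,
                          mammograms_per_life_year =
                            ifelse(gain > 0, br$mammograms / gain, NA_real_))
  list(per_round = per_round,
       total_days_per_woman = 365.25 * sum(gain) / nrow(records),
       total_mammograms_per_life_year = sum(br$mammograms) / sum(gain))
}

#' Compare two programme tallies
#'
#' Percent changes of each count/average in `b` relative to `a`.
#'
#' @param a,b `programme_tally` objects on the same population size.
#' @return Data frame with columns `metric`, `a`, `b`,
#'   `change_pct` (NA where `a` is zero).
#' @export
compare_programmes <- function(a, b) {
  stopifnot(inherits(a, "programme_tally"), inherits(b, "programme_tally"),
            a$per == b$per)
  metrics <- c("mammograms_k", "total_cases", "symptomatic", "overdiagnosed",
               "n_shifted", "t_shifted", "other_screen", "screen_detected",
               "bc_deaths", "avg_lead_time", "avg_surv_diff")
  va <- unlist(a[metrics]); vb <- unlist(b[metrics])
  data.frame(metric = metrics, a = va, b = vb,
             change_pct = ifelse(va != 0, 100 * (vb - va) / va, NA_real_),
             row.names = NULL)
}

#' Sample parameter vectors for uncertainty propagation
#'
#' Multivariate-normal draws around the point estimate with the
#' supplied covariance (in practice the inverse of minus the Hessian of
#' the log-likelihood).  Draws violating positivity constraints are
#' rejected and redrawn; the number rejected is recorded in the
#' `"rejected"` attribute.
#'
#' @param theta_hat named numeric vector of point estimates.
#' @param covariance covariance matrix (symmetric positive
#'   semi-definite).
#' @param n_draws number of vectors to return.
#' @param positive logical vector marking components that must stay
#'   strictly positive (default: all).
#' @return `n_draws` x `length(theta_hat)` matrix with an attribute
#'   `rejected`.
#' @export
sample_parameter_vectors <- function(theta_hat, covariance, n_draws,
                                     positive = rep(TRUE, length(theta_hat))) {
  p <- length(theta_hat)
  covariance <- as.matrix(covariance)
  if (!isTRUE(all.equal(covariance, t(covariance))))
    stop("covariance must be symmetric")
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("covariance must be positive semi-definite")
  draws <- matrix(NA_real_, n_draws, p,
                  dimnames = list(NULL, names(theta_hat)))
  rejected <- 0L
  need <- seq_len(n_draws)
  while (length(need)) {
    cand <- MASS::mvrnorm(length(need), mu = theta_hat, Sigma = covariance)
    cand <- matrix(cand, ncol = p)
    ok <- apply(cand, 1, function(z) all(z[positive] > 0))
    rejected <- rejected + sum(!ok)
    take <- min(sum(ok), length(need))
    if (take) {
      draws[need[seq_len(take)], ] <- cand[which(ok)[seq_len(take)], , drop = FALSE]
      need <- need[-seq_len(take)]
    }
  }
  attr(draws, "rejected") <- rejected
  draws
}

#' Percentile confidence interval across runs
#'
#' @param x per-run statistics (at least two).
#' @param level interval coverage (default 0.90: the 5th and 95th
#'   percentiles).
#' @return Named vector `c(lo, hi)`.
#' @export
ci_from_runs <- function(x, level = 0.90) {
  if (length(x) < 2) stop("need at least two runs for an interval")
  q <- stats::quantile(x, probs = c((1 - level) / 2, (1 + level) / 2),
                       names = FALSE)
  c(lo = q[1], hi = q[2])
}
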