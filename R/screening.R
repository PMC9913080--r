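#' Define a screening programme
#'
#' A programme is an ordered list of ages at which women are invited to
#' mammography.  `screening_programme()` takes explicit ages;
#' `make_programme()` builds the arithmetic sequence
#' `start, start + interval, ..., <= end`.  An empty age vector means
#' no screening.
#'
#' @param ages strictly increasing numeric vector of round ages (years);
#'   may be empty.
#' @param name label for printing.
#' @return An object of class `screening_programme`.
#' @examples
#' make_programme(40, 74, 2)   # the current Swedish programme, 18 rounds
#' make_programme(40, 80, 2)   # extension to age 80, 21 rounds
#' @export
screening_programme <- function(ages, name = "custom") {
  ages <- as.numeric(ages)
  if (length(ages) && (any(!is.finite(ages)) || any(diff(ages) <= 0)))
    stop("round ages must be finite and strictly increasing")
  structure(list(name = name, ages = ages), class = "screening_programme")
}

#' @rdname screening_programme
#' @param start_age,end_age first round age and upper age limit (years).
#' @param interval_years years between rounds.
#' @export
make_programme <- function(start_age, end_age, interval_years,
                           name = sprintf("biennial %g-%g", start_age, end_age)) {
  if (start_age > end_age) stop("start_age must not exceed end_age")
  if (interval_years <= 0) stop("interval must be positive")
  screening_programme(seq(start_age, end_age, by = interval_years), name)
}

#' @rdname screening_programme
#' @export
programme_none <- function() screening_programme(numeric(0), "no screening")

#' @rdname screening_programme
#' @export
programme_current <- function() make_programme(40, 74, 2, "current (40-74 biennial)")

#' @rdname screening_programme
#' @export
programme_extended <- function() make_programme(40, 80, 2, "extended (40-80 biennial)")

#' @export
print.screening_programme <- function(x, ...) {
  if (!length(x$ages)) cat(sprintf("Screening programme '%s': no rounds\n", x$name))
  else cat(sprintf("Screening programme '%s': %d rounds at ages %s\n",
                   x$name, length(x$ages),
                   paste(x$ages, collapse = ", ")))
  invisible(x)
}

#' Mammographic test sensitivity
#'
#' Probability that a screen detects a tumour of latent diameter `d`:
#' \eqn{\mathrm{expit}(\beta_0 + \beta_1 d)}, strictly increasing in
#' `d`.
#'
#' @param d tumour diameter(s), mm (nonnegative).
#' @param p a [sensitivity_params()] object.
#' @return Detection probabilities in (0, 1).
#' @export
screen_sensitivity <- function(d, p) {
  stopifnot(inherits(p, "sensitivity_params"))
  if (any(d < 0)) stop("diameter must be nonnegative")
  stats::plogis(p$intercept + p$slope * d)
}

#' Superimpose a screening programme on latent histories
#'
#' Iterates over the programme's rounds; at each round a woman is
#' screened if her tumour has already reached onset and she has not yet
#' been detected symptomatically (a round at exactly the symptomatic
#' detection age is pre-empted by symptomatic detection).  The tumour
#' diameter presented to the test is the latent growth curve evaluated
#' at the round age — no extra size noise — and detection occurs at the
#' first positive screen.  Other-cause death is not considered here;
#' competing events are resolved later by [resolve_outcome()].
#'
#' @param onset_age,r vectors of onset ages (years, `Inf` allowed) and
#'   inverse growth rates.
#' @param sympt_age vector of symptomatic detection ages (years).
#' @param prog a [screening_programme()] object.
#' @param params an [nh_params()] object (uses `growth`, `sensitivity`,
#'   `nodal`).
#' @param U optional matrix of uniform draws, one row per woman, one
#'   column per round, for common-random-number comparisons across
#'   programmes; drawn internally when `NULL`.
#' @param u_nodes optional uniform draws for the node count at screen
#'   detection.
#' @param attendance probability of attending any given round
#'   (default 1).
#' @param u_attend optional uniform matrix like `U` for attendance.
#' @return A data frame with one row per woman: `detected`, `age`
#'   (`Inf` if never screen-detected), `diameter` (mm, `NA` if not
#'   detected), `nodes`, `round` (index of the detecting round, `NA` if
#'   none).
#' @export
simulate_screen_detection <- function(onset_age, r, sympt_age, prog, params,
                                      U = NULL, u_nodes = NULL,
                                      attendance = 1, u_attend = NULL) {
  stopifnot(inherits(prog, "screening_programme"),
            inherits(params, "nh_params"))
  n <- length(onset_age)
  k <- length(prog$ages)
  age <- rep(Inf, n); diam <- rep(NA_real_, n)
  nodes <- rep(NA_integer_, n); round_idx <- rep(NA_integer_, n)
  if (k > 0L && n > 0L) {
    if (is.null(U)) U <- matrix(stats::runif(n * k), n, k)
    if (attendance < 1 && is.null(u_attend))
      u_attend <- matrix(stats::runif(n * k), n, k)
    if (is.null(u_nodes)) u_nodes <- stats::runif(n)
    undetected <- rep(TRUE, n)
    for (j in seq_len(k)) {
      a <- prog$ages[j]
      present <- undetected & onset_age < a & a < sympt_age
      if (attendance < 1) present <- present & (u_attend[, j] < attendance)
      if (!any(present)) next
      d <- size_convert(volume_at(a - onset_age[present], r[present],
                                  params$growth), "volume")
      hit <- U[present, j] < screen_sensitivity(d, params$sensitivity)
      if (any(hit)) {
        who <- which(present)[hit]
        age[who] <- a
        diam[who] <- d[hit]
        round_idx[who] <- j
        undetected[who] <- FALSE
      }
    }
    det <- is.finite(age)
    if (any(det))
      nodes[det] <- sample_positive_nodes(size_convert(diam[det], "diameter"),
                                          params$nodal, u = u_nodes[det])
  }
  data.frame(detected = is.finite(age), age = age, diameter = diam,
             nodes = nodes, round = round_idx)
}
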