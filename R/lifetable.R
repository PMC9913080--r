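#' Life tables of other-cause mortality
#'
#' A life table is a data frame with one row per integer age from 0 to a
#' terminal age, columns `age` and `rate` (deaths per person-year, the
#' constant hazard on the interval `[age, age + 1)`).  Any woman still
#' alive at the end of the last interval dies there: the terminal
#' boundary `max(age) + 1` forces death.
#'
#' @param age integer ages 0, 1, ..., terminal age.
#' @param rate nonnegative mortality rates, one per age.
#' @param provenance `"real"` or `"synthetic"`.
#' @return An object of classes `life_table` and `data.frame`.
#' @export
life_table <- function(age, rate, provenance = c("synthetic", "real")) {
  provenance <- match.arg(provenance)
  age <- as.integer(age)
  if (length(age) != length(rate)) stop("age and rate lengths differ")
  if (any(duplicated(age))) stop("duplicate ages in life table")
  o <- order(age)
  age <- age[o]; rate <- as.numeric(rate)[o]
  if (age[1] != 0L || !identical(age, seq(0L, age[length(age)])))
    stop("life table must cover every integer age from 0; missing age ",
         setdiff(seq(0L, max(age)), age)[1])
  if (any(!is.finite(rate)) || any(rate < 0))
    stop("mortality rates must be finite and nonnegative")
  structure(data.frame(age = age, rate = rate),
            provenance = provenance, class = c("life_table", "data.frame"))
}

#' Read / write a life table CSV
#'
#' The file format is a plain CSV with columns `age` and `rate`
#' (per person-year), one row per integer age starting at 0.
#'
#' @param path CSV file path.
#' @param provenance provenance tag attached on read.
#' @return `read_life_table()` returns a `life_table`;
#'   `write_life_table()` returns `path` invisibly.
#' @export
read_life_table <- function(path, provenance = c("synthetic", "real")) {
  x <- utils::read.csv(path)
  if (!all(c("age", "rate") %in% names(x)))
    stop("life table CSV must have columns 'age' and 'rate'")
  life_table(x$age, x$rate, match.arg(provenance))
}

#' @rdname read_life_table
#' @param lt a `life_table` object.
#' @export
write_life_table <- function(lt, path) {
  stopifnot(inherits(lt, "life_table"))
  utils::write.csv(as.data.frame(lt), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Other-cause mortality by subtraction
#'
#' Subtracts cause-specific (here: breast-cancer) mortality rates from
#' all-cause rates on the same age grid, flooring at zero (with a
#' warning when a cause-specific rate exceeds the all-cause rate).
#'
#' @param all_cause,bc_specific `life_table` objects on identical age
#'   grids.
#' @return A `life_table` of other-cause mortality.
#' @export
derive_other_cause_table <- function(all_cause, bc_specific) {
  stopifnot(inherits(all_cause, "life_table"), inherits(bc_specific, "life_table"))
  if (!identical(all_cause$age, bc_specific$age))
    stop("life tables are on different age grids")
  d <- all_cause$rate - bc_specific$rate
  if (any(d < 0)) {
    warning("cause-specific rate exceeds all-cause rate at ",
            sum(d < 0), " age(s); floored at 0")
    d <- pmax(d, 0)
  }
  life_table(all_cause$age, d, attr(all_cause, "provenance"))
}

#' Synthetic Gompertz--Makeham life table
#'
#' Generates an other-cause mortality table of the same CSV shape as a
#' real national table, with hazard
#' \eqn{\lambda(x) = c + a e^{bx}}: a Makeham constant `makeham` plus a
#' Gompertz term rising exponentially with age.  The defaults are shaped
#' to resemble a modern high-income female population (life expectancy
#' at birth about 84 years).
#'
#' @param makeham age-independent hazard component (per year).
#' @param a,b Gompertz level (per year) and slope (per year of age).
#' @param terminal_age last tabulated age.
#' @return A `life_table` with provenance `"synthetic"`.
#' @export
synthetic_life_table <- function(makeham = 3e-4, a = 8e-6, b = 0.105,
                                 terminal_age = 110) {
  if (makeham < 0 || a < 0 || b < 0) stop("life-table parameters must be nonnegative")
  ages <- seq(0L, as.integer(terminal_age))
  life_table(ages, makeham + a * exp(b * ages), "synthetic")
}

#' Sample ages at death from other causes
#'
#' Inverse-transform sampling under the piecewise-constant hazard of the
#' life table; any survivor of the last interval dies at its end
#' (`max(age) + 1`).
#'
#' @param n number of draws (ignored when `u` is supplied).
#' @param lt a `life_table`.
#' @param u optional uniform(0,1) draws.
#' @return Ages at death (years), at most `max(lt$age) + 1`.
#' @export
sample_other_cause_death_age <- function(n, lt, u = NULL) {
  stopifnot(inherits(lt, "life_table"))
  if (is.null(u)) u <- stats::runif(n)
  E <- -log1p(-u)                       # Exp(1)
  Hcum <- c(0, cumsum(lt$rate))         # cumulative hazard at ages 0,1,...
  k <- findInterval(E, Hcum, rightmost.closed = FALSE)  # interval index
  terminal <- max(lt$age) + 1
  out <- rep(terminal, length(E))
  inside <- k <= nrow(lt) & lt$rate[pmin(k, nrow(lt))] > 0
  ki <- k[inside]
  out[inside] <- lt$age[ki] + (E[inside] - Hcum[ki]) / lt$rate[ki]
  pmin(out, terminal)
}

#' Life expectancy implied by a life table
#'
#' Exact expectation under the piecewise-constant-hazard model,
#' accounting for the forced death at the terminal boundary.
#'
#' @param lt a `life_table`.
#' @return Life expectancy at birth, years.
#' @export
life_expectancy <- function(lt) {
  stopifnot(inherits(lt, "life_table"))
  r <- lt$rate
  Scum <- exp(-c(0, cumsum(r)))         # survival at ages 0,1,...
  contrib <- ifelse(r > 0, (1 - exp(-r)) / r, 1)
  sum(Scum[-length(Scum)] * contrib)
}
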