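# Shared fixtures: fast-progressing toy parameter set, small life
# tables, and a hand-crafted record builder for the metrics tests.

toy_params <- function() default_nh_params("toy")

# life table with a single flat hazard up to the terminal age
flat_life_table <- function(rate, terminal_age = 110) {
  life_table(seq(0L, terminal_age), rep(rate, terminal_age + 1L))
}

# zero other-cause mortality before the terminal boundary
immortal_life_table <- function(terminal_age = 110) {
  flat_life_table(0, terminal_age)
}

# minimal cohort_records data frame for metric-level tests
make_records <- function(mode, sympt_age = 70, sympt_diameter = 25,
                         sympt_nodes = 2L, screen_age = NA_real_,
                         screen_diameter = NA_real_,
                         screen_nodes = NA_integer_,
                         screen_round = NA_integer_, ocd_age = 90,
                         death_age = 90, death_cause = "other",
                         sympt_death_age = 90, screen_death_age = NA_real_,
                         mammograms = 0L) {
  n <- length(mode)
  rec <- data.frame(
    id = seq_len(n), onset_age = 50, r = 1,
    sympt_age = rep_len(sympt_age, n),
    sympt_diameter = rep_len(sympt_diameter, n),
    sympt_nodes = rep_len(sympt_nodes, n),
    screen_age = rep_len(screen_age, n),
    screen_diameter = rep_len(screen_diameter, n),
    screen_nodes = rep_len(screen_nodes, n),
    screen_round = rep_len(screen_round, n),
    mode = mode,
    detection_age = ifelse(mode == "screen", rep_len(screen_age, n),
                           ifelse(mode == "symptomatic",
                                  rep_len(sympt_age, n), Inf)),
    death_age = rep_len(death_age, n),
    death_cause = rep_len(death_cause, n),
    ocd_age = rep_len(ocd_age, n),
    sympt_death_age = rep_len(sympt_death_age, n),
    screen_death_age = rep_len(screen_death_age, n),
    mammograms = rep_len(mammograms, n))
  structure(rec, class = c("cohort_records", "data.frame"),
            programme = "crafted", n = n, seed = 0L)
}

# Kolmogorov distance between draws (possibly containing Inf) and a CDF
ks_distance <- function(draws, cdf_fun) {
  n <- length(draws)
  x <- sort(draws[is.finite(draws)])
  Fx <- cdf_fun(x)
  i <- seq_along(x)
  max(abs(i / n - Fx), abs((i - 1) / n - Fx))
}
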