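# Cohort engine: per-woman latent history -> screen detection ->
# survival draws -> resolved outcome, vectorised and chunked.
#
# Randomness: a master seed spawns one sub-seed per chunk; within a
# chunk all uniforms are drawn up front in a fixed order, so a run is
# deterministic given (seed, n, chunk_size) and all programmes passed in
# one call share the same latent histories and per-round detection
# uniforms (common random numbers).

draw_chunk_uniforms <- function(n, k_union, attendance) {
  list(u_onset = stats::runif(n),
       u_r = stats::runif(n),
       E_sympt = stats::rexp(n),
       u_nodes_s = stats::runif(n),
       u_ocd = stats::runif(n),
       u_surv_s = stats::runif(n),
       u_surv_scr = stats::runif(n),
       U_screen = if (k_union) matrix(stats::runif(n * k_union), n, k_union),
       u_nodes_scr = stats::runif(n),
       u_attend = if (attendance < 1 && k_union)
         matrix(stats::runif(n * k_union), n, k_union))
}

#' Simulate a cohort of women under one or more screening programmes
#'
#' Every woman is simulated from birth: age at onset and inverse growth
#' rate are sampled first; from these, the age, size and nodal status at
#' (would-be) symptomatic detection; a screening programme is then
#' superimposed, breast-cancer survival is drawn for both detection
#' scenarios, and the observed outcome is resolved against death from
#' other causes.  When `programme` is a list, all programmes are
#' evaluated on identical latent histories and shared per-round
#' detection draws, so differences between their outputs are due to
#' policy alone.
#'
#' @param params an [nh_params()] object.
#' @param lt a [life_table()] of other-cause mortality.
#' @param programme a [screening_programme()] or a (possibly named)
#'   list of them.
#' @param n number of women.
#' @param seed master seed (integer).
#' @param chunk_size women per block; results are identical only for
#'   identical `chunk_size`.
#' @param attendance probability of attending each round (default 1).
#' @return A `cohort_records` data frame (one row per woman), or a
#'   named list of them when `programme` is a list.  Columns: ids,
#'   latent fields (`onset_age`, `r`, `sympt_age`, `sympt_diameter`,
#'   `sympt_nodes`), screen-detection fields, realised `mode`,
#'   `detection_age`, `death_age`, `death_cause`, `ocd_age`, both
#'   counterfactual all-cause death ages, and the `mammograms`
#'   attended before exit (the detection-round mammogram is counted: it
#'   is a performed examination).
#' @export
simulate_cohort <- function(params, lt, programme, n, seed,
                            chunk_size = 1e5, attendance = 1) {
  stopifnot(inherits(params, "nh_params"), inherits(lt, "life_table"),
            n >= 1)
  single <- inherits(programme, "screening_programme")
  progs <- if (single) list(programme) else programme
  stopifnot(all(vapply(progs, inherits, TRUE, "screening_programme")))
  if (is.null(names(progs)))
    names(progs) <- vapply(progs, `[[`, "", "name")

  union_ages <- sort(unique(unlist(lapply(progs, `[[`, "ages"))))
  terminal <- max(lt$age) + 1
  n_chunks <- ceiling(n / chunk_size)
  set.seed(seed)
  chunk_seeds <- sample.int(.Machine$integer.max - 1L, n_chunks)

  pieces <- vector("list", n_chunks)
  for (ch in seq_len(n_chunks)) {
    m <- if (ch < n_chunks) chunk_size else n - chunk_size * (n_chunks - 1)
    set.seed(chunk_seeds[ch])
    d <- draw_chunk_uniforms(m, length(union_ages), attendance)
    ids <- (ch - 1L) * chunk_size + seq_len(m)
    pieces[[ch]] <- simulate_chunk(ids, d, params, lt, progs, union_ages,
                                   terminal, attendance)
  }
  out <- lapply(seq_along(progs), function(i) {
    rec <- do.call(rbind, lapply(pieces, `[[`, i))
    structure(rec, class = c("cohort_records", "data.frame"),
              programme = progs[[i]]$name, n = n, seed = seed)
  })
  names(out) <- names(progs)
  if (single) out[[1]] else out
}

simulate_chunk <- function(ids, d, params, lt, progs, union_ages,
                           terminal, attendance) {
  m <- length(ids)
  onset <- sample_onset_age(m, params$onset, u = d$u_onset)
  r <- sample_inv_growth_rate(m, params$growth, u = d$u_r)
  dt_sympt <- sample_sympt_interval(r, params$growth, E = d$E_sympt)
  sympt_age <- onset + dt_sympt
  has_onset <- is.finite(onset)
  sympt_diam <- rep(NA_real_, m)
  sympt_vol <- volume_at(ifelse(has_onset, dt_sympt, 0), r, params$growth)
  sympt_diam[has_onset] <- size_convert(sympt_vol[has_onset], "volume")
  sympt_nodes <- rep(NA_integer_, m)
  sympt_nodes[has_onset] <- sample_positive_nodes(
    sympt_vol[has_onset], params$nodal, u = d$u_nodes_s[has_onset])
  ocd <- sample_other_cause_death_age(m, lt, u = d$u_ocd)
  surv_s <- rep(Inf, m)
  surv_s[has_onset] <- sample_bc_survival(
    sympt_diam[has_onset], sympt_nodes[has_onset], params$survival,
    u = d$u_surv_s[has_onset])

  lapply(progs, function(pr) {
    cols <- match(pr$ages, union_ages)
    det <- simulate_screen_detection(
      onset, r, sympt_age, pr, params,
      U = if (length(cols)) d$U_screen[, cols, drop = FALSE],
      u_nodes = d$u_nodes_scr, attendance = attendance,
      u_attend = if (!is.null(d$u_attend)) d$u_attend[, cols, drop = FALSE])
    surv_scr <- rep(Inf, m)
    sd <- det$detected
    if (any(sd))
      surv_scr[sd] <- sample_bc_survival(det$diameter[sd], det$nodes[sd],
                                         params$survival,
                                         u = d$u_surv_scr[sd])
    res <- resolve_outcome(sympt_age, det$age, surv_s, surv_scr, ocd,
                           terminal_age = terminal)
    exit <- pmin(res$detection_age, res$death_age)
    mam <- integer(m)
    if (length(pr$ages)) {
      att <- outer(rep(1, m), pr$ages) < exit       # rounds strictly before exit
      if (!is.null(d$u_attend))
        att <- att & (d$u_attend[, match(pr$ages, union_ages), drop = FALSE] <
                        attendance)
      mam <- rowSums(att) + (res$mode == "screen")  # detection round included
    }
    data.frame(id = ids, onset_age = onset, r = r, sympt_age = sympt_age,
               sympt_diameter = sympt_diam, sympt_nodes = sympt_nodes,
               screen_age = det$age, screen_diameter = det$diameter,
               screen_nodes = det$nodes, screen_round = det$round,
               mode = res$mode, detection_age = res$detection_age,
               death_age = res$death_age, death_cause = res$death_cause,
               ocd_age = ocd, sympt_death_age = res$sympt_death_age,
               screen_death_age = res$screen_death_age, mammograms = mam)
  })
}

#' Total number of mammograms performed
#'
#' @param records a `cohort_records` data frame.
#' @return Total count of attended screening examinations, including
#'   the examination at which a cancer is screen-detected.
#' @export
count_mammograms <- function(records) {
  sum(records$mammograms)
}

#' @export
print.cohort_records <- function(x, ...) {
  cat(sprintf("Cohort of %d women under programme '%s' (seed %s)\n",
              attr(x, "n"), attr(x, "programme"),
              format(attr(x, "seed"))))
  tab <- table(factor(x$mode, c("screen", "symptomatic", "none")))
  cat(sprintf("  screen-detected: %d, symptomatic: %d, no breast cancer: %d\n",
              tab[["screen"]], tab[["symptomatic"]], tab[["none"]]))
  invisible(x)
}
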