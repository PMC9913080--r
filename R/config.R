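#' Flatten natural-history parameters to a named vector (and back)
#'
#' Used for parameter-uncertainty propagation: the point estimate is
#' flattened, perturbed with [sample_parameter_vectors()], and rebuilt.
#' Names follow `submodel.field` (e.g. `onset.nu`, `growth.eta`).
#'
#' @param params an [nh_params()] object.
#' @return `nh_params_to_vector()` returns a named numeric vector;
#'   `nh_params_from_vector()` returns an `nh_params` object.
#' @export
nh_params_to_vector <- function(params) {
  stopifnot(inherits(params, "nh_params"))
  drop <- c("growth.d0", "growth.v0")
  v <- unlist(lapply(unclass(params), unclass))
  v[setdiff(names(v), drop)]
}

#' @rdname nh_params_to_vector
#' @param v a named vector as produced by `nh_params_to_vector()`.
#' @export
nh_params_from_vector <- function(v) {
  pick <- function(prefix) {
    x <- v[startsWith(names(v), paste0(prefix, "."))]
    names(x) <- sub(paste0("^", prefix, "\\."), "", names(x))
    as.list(x)
  }
  nh_params(
    onset = do.call(onset_params, pick("onset")),
    growth = do.call(growth_params, pick("growth")),
    nodal = do.call(nodal_params, pick("nodal")),
    sensitivity = do.call(sensitivity_params, pick("sensitivity")),
    survival = do.call(bc_survival_params, pick("survival"))
  )
}

#' Which flattened parameters must be strictly positive
#'
#' Companion to [sample_parameter_vectors()]: rate, shape, scale and
#' dispersion parameters are constrained positive; logistic and
#' log-scale regression coefficients are unconstrained.
#'
#' @param v a named vector from [nh_params_to_vector()].
#' @return Logical vector aligned with `v`.
#' @export
nh_params_positive <- function(v) {
  stats::setNames(names(v) %in% c("onset.nu", "onset.alpha", "onset.beta", "onset.mu",
                  "growth.shape", "growth.rate", "growth.eta",
                  "nodal.size", "nodal.coef", "nodal.power",
                  "sensitivity.slope", "survival.surv_shape"), names(v))
}

#' Load a run configuration
#'
#' Reads a YAML (or JSON) file describing a simulation run.  Recognised
#' keys: `programme` (`"none"`, `"current"`, `"extended"`, or a mapping
#' with either `ages` or `start_age`/`end_age`/`interval_years`), `n`
#' (women per run, default 1e6), `runs` (default 10), `seed` (default
#' 1), `params` (path to a parameter JSON; default the built-in
#' synthetic set), `lifetable` (path to a life-table CSV; default the
#' synthetic Gompertz--Makeham table).  Unknown keys trigger a warning.
#'
#' @param path configuration file path.
#' @return An object of class `run_config`: a list with elements
#'   `programme` (a [screening_programme()]), `n`, `runs`, `seed`,
#'   `params` (an `nh_params`), `lifetable` (a `life_table`).
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare key `n` as the boolean FALSE; map it back
  names(cfg)[names(cfg) == "FALSE"] <- "n"
  known <- c("programme", "n", "runs", "seed", "params", "lifetable")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    warning("ignoring unknown configuration key(s): ",
            paste(extra, collapse = ", "))
  prog <- cfg$programme
  programme <-
    if (is.null(prog) || identical(prog, "current")) programme_current()
    else if (identical(prog, "none")) programme_none()
    else if (identical(prog, "extended")) programme_extended()
    else if (is.list(prog) && !is.null(prog$ages))
      screening_programme(prog$ages, prog$name %||% "custom")
    else if (is.list(prog))
      make_programme(prog$start_age, prog$end_age, prog$interval_years,
                     prog$name %||% "custom")
    else stop("unrecognised programme specification")
  structure(list(
    programme = programme,
    n = as.integer(cfg$n %||% 1e6),
    runs = as.integer(cfg$runs %||% 10),
    seed = as.integer(cfg$seed %||% 1),
    params = if (is.null(cfg$params)) default_nh_params()
             else read_nh_params(cfg$params),
    lifetable = if (is.null(cfg$lifetable)) synthetic_life_table()
                else read_life_table(cfg$lifetable)
  ), class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a configured multi-run study
#'
#' Simulates `cfg$runs` independent cohorts of `cfg$n` women (run `i`
#' uses master seed `cfg$seed + i - 1`) and tallies each.
#'
#' @param cfg a `run_config` from [load_config()] (or built by hand).
#' @param chunk_size forwarded to [simulate_cohort()].
#' @return List of `programme_tally` objects, one per run.
#' @export
run_study <- function(cfg, chunk_size = 1e5) {
  stopifnot(inherits(cfg, "run_config"))
  lapply(seq_len(cfg$runs), function(i) {
    rec <- simulate_cohort(cfg$params, cfg$lifetable, cfg$programme,
                           n = cfg$n, seed = cfg$seed + i - 1L,
                           chunk_size = chunk_size)
    tally_programme(rec)
  })
}
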