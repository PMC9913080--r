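#' Mean number of positive lymph nodes at a given tumour volume
#'
#' @param v tumour volume(s), mm^3.
#' @param p a [nodal_params()] object.
#' @return Expected number of affected nodes, nondecreasing in `v`.
#' @export
nodal_mean <- function(v, p) {
  stopifnot(inherits(p, "nodal_params"))
  p$coef * v^p$power
}

#' Sample the number of affected lymph nodes at detection
#'
#' Conditional on the tumour volume at detection, the node count is
#' negative binomial with the size-dependent mean of [nodal_mean()] and
#' dispersion `p$size`.
#'
#' @param v tumour volume(s) at detection, mm^3; must be at least the
#'   onset volume \eqn{(\pi/6) 0.5^3}.
#' @param p a [nodal_params()] object.
#' @param u optional uniform(0,1) draws for quantile coupling.
#' @return Nonnegative integer node counts.
#' @export
sample_positive_nodes <- function(v, p, u = NULL) {
  stopifnot(inherits(p, "nodal_params"))
  v0 <- pi / 6 * 0.5^3
  if (any(v < v0 - 1e-12)) stop("tumour volume below the onset volume")
  m <- nodal_mean(v, p)
  if (is.null(u)) stats::rnbinom(length(v), size = p$size, mu = m)
  else stats::qnbinom(u, size = p$size, mu = m)
}
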