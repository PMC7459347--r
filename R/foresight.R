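# Foresight versus directed innovation.
#
# Standing variation maintained with foresight carries mean benefit f_sv
# after the shift; an innovation invented in direct response to the shift
# carries benefit f_dn. Foresight is assumed never to beat directed
# innovation, so only the triangle f_sv <= f_dn is meaningful. The
# quantity of interest is the signed difference in sweep probability
# delta = pi_SV(f_sv) - pi_DN(f_dn).

#' Difference in sweep probability: standing variation vs directed innovation
#'
#' Computes `pi_SV(f_sv) - pi_DN(f_dn)`, where `pi_SV` uses the chosen
#' pre-shift regime and a post-shift payoff kernel with benefit `f_sv`,
#' and `pi_DN` uses a post-shift payoff kernel with benefit `f_dn`.
#' Positive values mean the frequency advantage of standing variation
#' outweighs the benefit advantage of directed innovation.
#'
#' @param N Population size.
#' @param f_sv Mean benefit of the variant held in standing variation
#'   (foresight); must not exceed `f_dn`.
#' @param f_dn Mean benefit of a directed de novo innovation.
#' @param g Baseline payoff of the ancestral variant (default 1).
#' @param pre_regime Pre-shift transmission regime shaping the standing
#'   frequency distribution: `"unbiased"` (default, as in the core
#'   construction) or `"conformity"`.
#' @param theta Conformity exponent, used when
#'   `pre_regime = "conformity"`.
#' @return The signed difference (a single number).
#' @examples
#' delta_pi(100, f_sv = 1.02, f_dn = 1.02)  # diagonal: >= 0
#' delta_pi(100, f_sv = 1.00, f_dn = 2.00)  # poor foresight: < 0
#' @export
delta_pi <- function(N, f_sv, f_dn, g = 1,
                     pre_regime = c("unbiased", "conformity"), theta = 0.5) {
  pre_regime <- match.arg(pre_regime)
  check_scalar_number(f_sv, "f_sv", lower = 0, strict_lower = TRUE)
  check_scalar_number(f_dn, "f_dn", lower = 0, strict_lower = TRUE)
  if (f_sv > f_dn)
    stop("constraint violation: foresight cannot exceed directed innovation ",
         "(f_sv = ", f_sv, " > f_dn = ", f_dn, ")", call. = FALSE)
  pre <- switch(pre_regime,
                unbiased = make_unbiased_kernel(N),
                conformity = make_conformity_kernel(N, theta))
  sv <- fixation_from_standing_variation(pre, make_payoff_kernel(N, f_sv, g))
  dn <- fixation_from_de_novo(make_payoff_kernel(N, f_dn, g))
  sv$pi_sv - dn
}

#' Grid of sweep-probability differences over the foresight triangle
#'
#' Evaluates [delta_pi()] on the Cartesian grid `f_sv_values` x
#' `f_dn_values`, masking cells with `f_sv > f_dn` (kept as `NA` rather
#' than errors so rectangular output files stay aligned). Also locates,
#' for each `f_dn`, the smallest `f_sv` at which standing variation
#' catches up (`delta >= 0`), i.e. the sign boundary.
#'
#' @param N Population size.
#' @param f_sv_values Ascending axis of foresight benefits.
#' @param f_dn_values Ascending axis of directed-innovation benefits.
#' @inheritParams delta_pi
#' @return A `foresight_grid`: list with the axes, the `delta` matrix
#'   (rows = `f_sv`, columns = `f_dn`), the logical `mask` of valid
#'   cells, and `boundary`, a data frame giving per `f_dn` the smallest
#'   `f_sv` with `delta >= 0` (`NA` when none on the grid).
#' @examples
#' g <- delta_grid(100, seq(1, 1.5, by = 0.1), seq(1, 1.5, by = 0.1))
#' head(as.data.frame(g))
#' @export
delta_grid <- function(N, f_sv_values, f_dn_values, g = 1,
                       pre_regime = c("unbiased", "conformity"), theta = 0.5) {
  pre_regime <- match.arg(pre_regime)
  if (!length(f_sv_values) || !length(f_dn_values))
    stop("axes must be non-empty", call. = FALSE)
  if (is.unsorted(f_sv_values, strictly = TRUE) ||
      is.unsorted(f_dn_values, strictly = TRUE))
    stop("axes must be strictly ascending", call. = FALSE)
  pre <- switch(pre_regime,
                unbiased = make_unbiased_kernel(N),
                conformity = make_conformity_kernel(N, theta))
  occ <- sojourn_times(pre)$occupancy  # shared across the whole grid
  pi_sv <- vapply(f_sv_values, function(f) {
    sum(occ * fixation_all_states(make_payoff_kernel(N, f, g)))
  }, numeric(1))
  pi_dn <- vapply(f_dn_values, function(f) {
    fixation_from_de_novo(make_payoff_kernel(N, f, g))
  }, numeric(1))
  delta <- outer(pi_sv, pi_dn, `-`)
  mask <- outer(f_sv_values, f_dn_values, `<=`)
  delta[!mask] <- NA_real_
  boundary <- data.frame(
    f_dn = f_dn_values,
    f_sv_zero_crossing = vapply(seq_along(f_dn_values), function(cix) {
      ok <- which(mask[, cix] & delta[, cix] >= 0)
      if (length(ok)) f_sv_values[min(ok)] else NA_real_
    }, numeric(1))
  )
  structure(
    list(N = N, g = g, pre_regime = pre_regime,
         theta = if (pre_regime == "conformity") theta else NA_real_,
         f_sv_values = f_sv_values, f_dn_values = f_dn_values,
         delta = delta, mask = mask, boundary = boundary),
    class = "foresight_grid"
  )
}

#' @export
print.foresight_grid <- function(x, ...) {
  cat("<foresight_grid> N =", x$N, " pre-shift regime:", x$pre_regime, "\n")
  cat("  ", length(x$f_sv_values), "x", length(x$f_dn_values),
      "grid;", sum(x$mask), "cells on the triangle\n")
  invisible(x)
}

#' @export
as.data.frame.foresight_grid <- function(x, ...) {
  d <- expand.grid(f_sv = x$f_sv_values, f_dn = x$f_dn_values,
                   KEEP.OUT.ATTRS = FALSE)
  d$delta_pi <- as.vector(x$delta)
  d$on_triangle <- as.vector(x$mask)
  d
}
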