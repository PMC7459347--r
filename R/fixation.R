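# Exact absorption quantities of the variant-count chain: fixation
# probabilities, sojourn times, occupancy distributions, and the trait
# frequency spectrum.
#
# Numerical strategy: every product of step ratios prod_k beta_k/alpha_k
# is accumulated as a cumulative sum of logs, and sums of such products
# use max-shifted exponentiation (logsumexp). For N in the thousands and
# f/g around 2 the raw products underflow double precision, so the log
# route is the default general path. Kernels with a constant step ratio
# rho = beta_i/alpha_i (payoff kernels, and any neutral kernel, which
# reports rho = 1) additionally admit the geometric closed form
# pi_j = (1 - rho^j)/(1 - rho^N), used as an O(1) fast path.

# cumulative log step ratios log(beta_k/alpha_k), k = 1..N-1
cum_log_ratio <- function(kernel) cumsum(log(kernel$beta) - log(kernel$alpha))

# fixation probabilities for all interior starts via the closed form
pi_closed_form <- function(N, rho, j = seq_len(N - 1L)) {
  if (abs(rho - 1) < 1e-12) return(j / N)
  lr <- log(rho)
  if (rho < 1) {
    (1 - exp(j * lr)) / (1 - exp(N * lr))
  } else {
    # rewrite with negative exponents so nothing overflows for rho > 1
    exp((j - N) * lr) * (-expm1(-j * lr)) / (-expm1(-N * lr))
  }
}

# fixation probabilities for all interior starts via the log-space path:
# pi_j = (1 + sum_{l<j} P_l) / (1 + sum_{l<N} P_l), P_l = prod_{k<=l} beta_k/alpha_k
pi_log_space <- function(kernel, j = NULL) {
  N <- kernel$N
  cl <- cum_log_ratio(kernel)
  # running logsumexp of {0, cl_1, ..., cl_{l}} gives the numerators
  lse <- numeric(N - 1L)
  acc <- 0  # log(1)
  lse[1L] <- acc
  for (l in seq_len(N - 2L)) {
    acc <- logaddexp(acc, cl[l])
    lse[l + 1L] <- acc
  }
  denom <- logaddexp(acc, cl[N - 1L])
  pij <- exp(lse - denom)
  if (is.null(j)) pij else pij[j]
}

resolve_method <- function(kernel, method) {
  method <- match.arg(method, c("auto", "closed-form", "log-space"))
  if (method == "closed-form" && is.na(kernel$ratio))
    stop("closed form requires a kernel with constant beta/alpha ratio",
         call. = FALSE)
  if (method == "auto")
    method <- if (!is.na(kernel$ratio)) "closed-form" else "log-space"
  method
}

#' Fixation probability of a de novo innovation
#'
#' Probability that variant a, arising in a single individual (count 1)
#' after the environmental shift, reaches fixation (count `N`) rather
#' than loss under the dynamics of `post_kernel`:
#' `pi_1 = 1 / (1 + sum_{l=1}^{N-1} prod_{k=1}^{l} beta_k/alpha_k)`.
#'
#' @param post_kernel A `transition_kernel` describing transmission after
#'   the shift (typically a payoff kernel).
#' @param method `"auto"` (default) uses the geometric closed form when
#'   the kernel has a constant step ratio and the stable log-space
#'   evaluation otherwise; `"closed-form"` and `"log-space"` force a
#'   path (useful for cross-checking).
#' @return A single probability in (0, 1).
#' @examples
#' fixation_from_de_novo(make_payoff_kernel(50, f = 1))   # neutral: 1/50
#' fixation_from_de_novo(make_payoff_kernel(100, f = 2))  # ~ 0.5
#' @export
fixation_from_de_novo <- function(post_kernel, method = "auto") {
  fixation_from_state(post_kernel, 1L, method = method)
}

#' Fixation probability from an arbitrary starting count
#'
#' Generalises [fixation_from_de_novo()] to a variant already at count
#' `j`: `pi_j = pi_1 * (1 + sum_{l=1}^{j-1} prod_{k=1}^{l} beta_k/alpha_k)`.
#' Under neutrality this reduces to `j/N`.
#'
#' @inheritParams fixation_from_de_novo
#' @param j Starting count, an integer in `1..N-1` (vectorised).
#' @return Fixation probabilities, one per element of `j`.
#' @examples
#' fixation_from_state(make_payoff_kernel(100, f = 2), 10)  # ~ 0.999
#' @export
fixation_from_state <- function(post_kernel, j, method = "auto") {
  stopifnot(inherits(post_kernel, "transition_kernel"))
  N <- post_kernel$N
  if (any(j < 1 | j > N - 1 | j != round(j)))
    stop("'j' must be an interior state in 1..N-1", call. = FALSE)
  j <- as.integer(j)
  method <- resolve_method(post_kernel, method)
  if (method == "closed-form")
    pi_closed_form(N, post_kernel$ratio, j)
  else
    pi_log_space(post_kernel, j)
}

# all interior fixation probabilities at once
fixation_all_states <- function(post_kernel, method = "auto") {
  method <- resolve_method(post_kernel, method)
  if (method == "closed-form")
    pi_closed_form(post_kernel$N, post_kernel$ratio)
  else
    pi_log_space(post_kernel)
}

#' Sojourn times and occupancy distribution before absorption
#'
#' For a chain started at count 1, `t1j[j]` is the expected number of
#' timesteps (self-loop holds included) spent at interior count `j`
#' before absorption at 0 or `N`. With step ratios
#' `rho_k = prod_{m=1}^{k} beta_m/alpha_m` (`rho_0 = 1`) it equals
#' `t1j = D_j / (S_N * alpha_j)`, where
#' `S_N = sum_{k=0}^{N-1} rho_k` (so `1/S_N` is the fixation
#' probability from count 1) and
#' `D_j = sum_{k=j}^{N-1} prod_{m=j+1}^{k} beta_m/alpha_m`.
#' Both sums are accumulated in log space with max-shifted
#' exponentiation. `t1 = sum_j t1j` is the total expected persistence
#' time of the variant, and `occupancy = t1j / t1` is the probability
#' that a still-segregating variant sits at count `j` -- the weighting
#' used for standing variation. Under the unbiased kernel every ratio
#' is 1, so `D_j = N - j`, `S_N = N`, giving `t1j = N/j` and
#' `t1 = N * (1 + sum_{k=2}^{N-1} 1/k)`.
#'
#' @param pre_kernel A `transition_kernel` describing transmission before
#'   the environmental shift.
#' @return A `sojourn_profile`: list with `N`, `t1j`, `t1`, `occupancy`
#'   and the kernel's regime `label`.
#' @examples
#' p <- sojourn_times(make_unbiased_kernel(10))
#' p$t1j[5]  # 2, i.e. N/j
#' @export
sojourn_times <- function(pre_kernel) {
  stopifnot(inherits(pre_kernel, "transition_kernel"))
  N <- pre_kernel$N
  j <- seq_len(N - 1L)
  # c[k] = log rho_k = sum of log step ratios, with c[0] = 0 prepended
  cl <- c(0, cum_log_ratio(pre_kernel))
  log_SN <- logsumexp(cl)
  # suffix logsumexp of cl over k = j..N-1 in one backward pass:
  # log D_j = logsumexp(cl[j..N-1]) - cl[j], indices shifted by the
  # prepended zero (cl[j + 1] is log rho_j)
  suffix <- numeric(N)
  suffix[N] <- cl[N]
  for (k in (N - 1L):1L) suffix[k] <- logaddexp(cl[k], suffix[k + 1L])
  log_Dj <- suffix[j + 1L] - cl[j + 1L]
  log_t1j <- log_Dj - log_SN - log(pre_kernel$alpha)
  t1j <- exp(log_t1j)
  t1 <- sum(t1j)
  structure(
    list(N = N, t1j = t1j, t1 = t1, occupancy = t1j / t1,
         label = pre_kernel$label),
    class = "sojourn_profile"
  )
}

#' @export
print.sojourn_profile <- function(x, ...) {
  cat("<sojourn_profile> regime:", x$label, " N =", x$N, "\n")
  cat("  mean persistence time t1 =", format(x$t1), "timesteps\n")
  invisible(x)
}

#' Fixation probability from standing cultural variation
#'
#' A variant segregating when the environment shifts has frequency
#' distribution given by the occupancy of the pre-shift chain
#' (conditioned on not yet being fixed or lost). The sweep probability
#' is the occupancy-weighted average of the post-shift fixation
#' probabilities: `pi_SV = sum_j (t1j/t1) * pi_j`.
#'
#' @param pre_kernel Kernel of the pre-shift transmission regime
#'   (determines the standing frequency distribution).
#' @param post_kernel Kernel of the post-shift regime (determines the
#'   fixation probabilities `pi_j`); must share `N` with `pre_kernel`.
#' @inheritParams fixation_from_de_novo
#' @return A `fixation_result`: list with `pi_dn` (fixation from count
#'   1), `pi_j` (all interior starts), `pi_sv`, `N`, and the
#'   `sojourn_profile` used for the weighting.
#' @examples
#' # worked small case: N = 3, neutral before and after the shift
#' r <- fixation_from_standing_variation(make_unbiased_kernel(3),
#'                                       make_payoff_kernel(3, f = 1))
#' r$pi_sv  # 4/9
#' @export
fixation_from_standing_variation <- function(pre_kernel, post_kernel,
                                             method = "auto") {
  stopifnot(inherits(pre_kernel, "transition_kernel"),
            inherits(post_kernel, "transition_kernel"))
  if (pre_kernel$N != post_kernel$N)
    stop("pre- and post-shift kernels must share the same N (",
         pre_kernel$N, " vs ", post_kernel$N, ")", call. = FALSE)
  prof <- sojourn_times(pre_kernel)
  pij <- fixation_all_states(post_kernel, method = method)
  structure(
    list(pi_dn = pij[1L], pi_j = pij,
         pi_sv = sum(prof$occupancy * pij),
         N = post_kernel$N, sojourn = prof),
    class = "fixation_result"
  )
}

#' @export
print.fixation_result <- function(x, ...) {
  cat("<fixation_result> N =", x$N, "\n")
  cat("  pi_DN (de novo, start 1)   =", format(x$pi_dn), "\n")
  cat("  pi_SV (standing variation) =", format(x$pi_sv), "\n")
  invisible(x)
}

#' Trait frequency spectrum under an infinite-sites innovation process
#'
#' With independent innovations entering at per-capita rate `mu` and
#' each variant's lifetime governed by the pre-shift chain, the expected
#' number of variants segregating at count `j` is `S_Nj = t1j * mu`; the
#' total expected number of segregating variants is `S_N = mu * t1`.
#' Under unbiased transmission the spectrum has the classic `1/j` shape,
#' `S_Nj = mu * N / j`.
#'
#' @param profile A `sojourn_profile` from [sojourn_times()].
#' @param mu Per-capita innovation rate per timestep (positive).
#' @return A `trait_spectrum`: list with `mu`, `j`, `s_nj`, `s_n`.
#' @examples
#' sp <- trait_frequency_spectrum(sojourn_times(make_unbiased_kernel(10)), 0.01)
#' sp$s_nj[1]  # 0.1
#' @export
trait_frequency_spectrum <- function(profile, mu) {
  stopifnot(inherits(profile, "sojourn_profile"))
  check_scalar_number(mu, "mu", lower = 0, strict_lower = TRUE)
  structure(
    list(mu = mu, j = seq_len(profile$N - 1L),
         s_nj = profile$t1j * mu, s_n = mu * profile$t1, N = profile$N),
    class = "trait_spectrum"
  )
}

#' @export
print.trait_spectrum <- function(x, ...) {
  cat("<trait_spectrum> N =", x$N, " mu =", format(x$mu), "\n")
  cat("  expected segregating variants S_N =", format(x$s_n), "\n")
  invisible(x)
}
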