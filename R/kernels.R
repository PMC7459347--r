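# Transition kernels for the two-variant cultural Moran chain.
#
# Interior states are indexed i = 1..N-1 and the stored vectors use that
# offset directly: alpha[i] is the probability that the count of variant a
# moves i -> i+1 in one timestep, beta[i] the probability of i -> i-1, and
# 1 - alpha[i] - beta[i] the probability of staying. States 0 and N are
# absorbing and carry no entries. Kernels are treated as immutable after
# construction; the analytic and Monte-Carlo code paths share them.

new_kernel <- function(N, alpha, beta, label, params, ratio = NA_real_) {
  stopifnot(length(alpha) == N - 1L, length(beta) == N - 1L)
  if (any(alpha <= 0) || any(beta <= 0))
    stop("invalid kernel: all interior alpha_i and beta_i must be positive",
         call. = FALSE)
  if (any(alpha + beta > 1 + 1e-12))
    stop("invalid kernel: alpha_i + beta_i must not exceed 1", call. = FALSE)
  structure(
    list(N = as.integer(N), alpha = alpha, beta = beta,
         label = label, ratio = ratio, params = params),
    class = "transition_kernel"
  )
}

check_N <- function(N) {
  if (!is.numeric(N) || length(N) != 1L || !is.finite(N) || N < 2 ||
      N != round(N))
    stop("'N' must be an integer >= 2", call. = FALSE)
  as.integer(N)
}

#' Unbiased-transmission kernel
#'
#' Transition probabilities of the variant-count chain when a newborn
#' copies a uniformly chosen role model: `alpha_i = beta_i = i(N-i)/N^2`.
#' This is the neutral (drift-only) regime that governs the trait before
#' an environmental shift.
#'
#' @param N Population size (integer, at least 2).
#' @return A `transition_kernel`: a list with elements `N`, `alpha`,
#'   `beta` (each of length `N - 1`, indexed by the interior state
#'   `i = 1..N-1`), a regime `label`, and `ratio`, the constant value of
#'   `beta_i / alpha_i` when one exists (`NA` otherwise), which enables
#'   geometric closed forms downstream.
#' @examples
#' k <- make_unbiased_kernel(10)
#' k$alpha[5]  # 0.25 at the symmetric midpoint
#' @seealso [make_payoff_kernel()], [make_conformity_kernel()]
#' @export
make_unbiased_kernel <- function(N) {
  N <- check_N(N)
  i <- seq_len(N - 1L)
  a <- (i / N) * ((N - i) / N)
  new_kernel(N, a, a, "unbiased", list(N = N), ratio = 1)
}

#' Payoff-biased transmission kernel
#'
#' After an environmental shift, variant a confers benefit `f` and the
#' ancestral variant A benefit `g`; a newborn picks its role model with
#' probability proportional to these payoffs. The resulting step
#' probabilities are
#' `alpha_i = fi/(fi + g(N-i)) * (N-i)/N` and
#' `beta_i  = g(N-i)/(fi + g(N-i)) * i/N`,
#' so `beta_i / alpha_i = g/f` for every interior state. With `f == g`
#' the kernel is identical (value for value) to the unbiased kernel.
#'
#' @param N Population size (integer, at least 2).
#' @param f Payoff of variant a (positive).
#' @param g Payoff of variant A (positive; defaults to 1, the baseline
#'   against which `f` is read as a transmission advantage).
#' @return A `transition_kernel`; see [make_unbiased_kernel()].
#' @examples
#' k <- make_payoff_kernel(4, f = 2)
#' k$alpha[2]  # 1/3
#' k$beta[2]   # 1/6
#' @export
make_payoff_kernel <- function(N, f, g = 1) {
  N <- check_N(N)
  check_scalar_number(f, "f", lower = 0, strict_lower = TRUE)
  check_scalar_number(g, "g", lower = 0, strict_lower = TRUE)
  i <- seq_len(N - 1L)
  wa <- f * i
  wA <- g * (N - i)
  tot <- wa + wA
  a <- (wa / tot) * ((N - i) / N)
  b <- (wA / tot) * (i / N)
  new_kernel(N, a, b, "payoff", list(N = N, f = f, g = g), ratio = g / f)
}

#' Conformist / anti-conformist transmission kernel
#'
#' Frequency-dependent copying in which a variant at relative frequency
#' `x = i/N` is adopted with weight `x^(1+theta)`. Positive `theta`
#' models conformity (common variants are copied disproportionately
#' often), negative `theta` anti-conformity (rare variants are favoured),
#' and `theta = 0` recovers unbiased transmission exactly. The exponent
#' `1 + theta` must stay positive, hence `theta > -1`.
#'
#' @param N Population size (integer, at least 2).
#' @param theta Conformity exponent, a real number greater than -1.
#' @return A `transition_kernel`; see [make_unbiased_kernel()].
#' @examples
#' k <- make_conformity_kernel(10, theta = 0.5)
#' k$alpha[1] < make_unbiased_kernel(10)$alpha[1]  # rare variant suppressed
#' @export
make_conformity_kernel <- function(N, theta) {
  N <- check_N(N)
  check_scalar_number(theta, "theta", lower = -1, strict_lower = TRUE)
  if (theta == 0) {
    k <- make_unbiased_kernel(N)
    k$label <- "frequency_dependent"
    k$params <- list(N = N, theta = 0)
    return(k)
  }
  i <- seq_len(N - 1L)
  x <- i / N
  y <- (N - i) / N
  wa <- x^(1 + theta)
  wA <- y^(1 + theta)
  tot <- wa + wA
  a <- (wa / tot) * y
  b <- (wA / tot) * x
  new_kernel(N, a, b, "frequency_dependent", list(N = N, theta = theta))
}

#' Build a kernel from a regime name
#'
#' Convenience dispatcher used by the CLI and config loader.
#'
#' @param regime One of `"unbiased"`, `"payoff"`, `"conformity"`.
#' @param N Population size.
#' @param f,g Payoffs (payoff regime only).
#' @param theta Conformity exponent (conformity regime only).
#' @return A `transition_kernel`.
#' @export
make_kernel <- function(regime = c("unbiased", "payoff", "conformity"),
                        N, f = 1, g = 1, theta = 0) {
  regime <- match.arg(regime)
  switch(regime,
         unbiased   = make_unbiased_kernel(N),
         payoff     = make_payoff_kernel(N, f = f, g = g),
         conformity = make_conformity_kernel(N, theta = theta))
}

#' @export
print.transition_kernel <- function(x, ...) {
  cat("<transition_kernel> regime:", x$label, " N =", x$N, "\n")
  extra <- x$params[setdiff(names(x$params), "N")]
  if (length(extra))
    cat("  params:", paste(names(extra), unlist(extra), sep = " = ",
                           collapse = ", "), "\n")
  if (!is.na(x$ratio))
    cat("  constant step ratio beta/alpha =", format(x$ratio), "\n")
  invisible(x)
}
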