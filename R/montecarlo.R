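# Stochastic simulation of the fixed-N variant-count chain. Serves as the
# empirical check on every analytic quantity (fixation probabilities,
# sojourn times, occupancy distributions).
#
# Two engines share the same per-chain law:
#  * simulate_chain(): a literal per-timestep loop (move up with alpha_i,
#    down with beta_i, otherwise stay), the reference implementation.
#  * simulate_chain_batch(): advances many chains in lockstep over the
#    embedded jump chain -- the time spent at a state before leaving is
#    geometric with success probability alpha_i + beta_i, and the exit
#    direction is up with probability alpha_i/(alpha_i + beta_i). Visit
#    counts and absorption times have exactly the distribution of the
#    per-timestep walk, but self-loops are drawn in one geometric block,
#    which makes large ensembles feasible in pure R.
# The two engines consume random numbers differently, so agreement is
# asserted statistically (matched ensembles), not draw for draw.

#' Simulate one realisation of the variant-count chain
#'
#' Runs the chain from an interior starting count until absorption at 0
#' (loss) or `N` (fixation), one timestep at a time.
#'
#' @param kernel A `transition_kernel`.
#' @param start Interior starting count in `1..N-1`.
#' @param seed Optional integer seed for reproducibility.
#' @return A `chain_run`: list with `absorbed_at` (0 or `N`),
#'   `absorption_time` (timesteps until absorption, self-loops counted)
#'   and `visits` (length `N - 1`; timesteps spent at each interior
#'   count, summing to `absorption_time`).
#' @examples
#' simulate_chain(make_unbiased_kernel(10), start = 1, seed = 1)
#' @export
simulate_chain <- function(kernel, start, seed = NULL) {
  stopifnot(inherits(kernel, "transition_kernel"))
  N <- kernel$N
  if (start < 1 || start > N - 1 || start != round(start))
    stop("'start' must be an interior state in 1..N-1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  s <- as.integer(start)
  visits <- integer(N - 1L)
  steps <- 0L
  repeat {
    visits[s] <- visits[s] + 1L
    steps <- steps + 1L
    u <- runif(1)
    if (u < kernel$alpha[s]) s <- s + 1L
    else if (u < kernel$alpha[s] + kernel$beta[s]) s <- s - 1L
    if (s == 0L || s == N) break
  }
  structure(list(absorbed_at = as.integer(s), absorption_time = steps,
                 visits = visits),
            class = "chain_run")
}

#' Simulate an ensemble of chains in lockstep
#'
#' Vectorised batch runner over the embedded jump chain (see the file
#' header for why this preserves the per-chain law). Used by
#' [estimate_fixation()] and [estimate_occupancy()].
#'
#' @inheritParams simulate_chain
#' @param reps Number of independent chains.
#' @param track_visits If `TRUE`, also accumulate per-state visit counts
#'   (needed for occupancy; costs memory `reps * (N-1)`).
#' @return List with vectors `absorbed_at` and `absorption_time` (length
#'   `reps`) and, if tracked, the `visits` matrix (`reps` x `N-1`).
#' @export
simulate_chain_batch <- function(kernel, start, reps, seed = NULL,
                                 track_visits = FALSE) {
  stopifnot(inherits(kernel, "transition_kernel"))
  N <- kernel$N
  if (start < 1 || start > N - 1 || start != round(start))
    stop("'start' must be an interior state in 1..N-1", call. = FALSE)
  if (reps < 1) stop("'reps' must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  reps <- as.integer(reps)
  state <- rep(as.integer(start), reps)
  time <- numeric(reps)
  visits <- if (track_visits) matrix(0, reps, N - 1L) else NULL
  alive <- seq_len(reps)
  while (length(alive)) {
    s <- state[alive]
    a <- kernel$alpha[s]
    b <- kernel$beta[s]
    pm <- a + b
    hold <- rgeom(length(alive), pm) + 1
    time[alive] <- time[alive] + hold
    if (track_visits)
      visits[cbind(alive, s)] <- visits[cbind(alive, s)] + hold
    up <- runif(length(alive)) < a / pm
    s <- s + ifelse(up, 1L, -1L)
    state[alive] <- s
    alive <- alive[s != 0L & s != N]
  }
  out <- list(absorbed_at = state, absorption_time = time)
  if (track_visits) out$visits <- visits
  out
}

#' Monte-Carlo estimate of a fixation probability
#'
#' Binomial point estimate of the probability that the chain absorbs at
#' `N`, with its exact-binomial standard error. Deterministic given
#' `seed`.
#'
#' @inheritParams simulate_chain_batch
#' @return List with `estimate`, `se`, and `reps`.
#' @examples
#' estimate_fixation(make_payoff_kernel(100, f = 2), start = 1,
#'                   reps = 1000, seed = 7)
#' @export
estimate_fixation <- function(kernel, start, reps, seed = NULL) {
  if (reps < 100) stop("'reps' must be at least 100", call. = FALSE)
  runs <- simulate_chain_batch(kernel, start, reps, seed = seed)
  p <- mean(runs$absorbed_at == kernel$N)
  list(estimate = p, se = sqrt(p * (1 - p) / reps), reps = as.integer(reps))
}

#' Monte-Carlo estimate of the occupancy distribution
#'
#' Starting every chain at count 1 (the conditioning used for standing
#' variation), estimates the fraction of pre-absorption time spent at
#' each interior count as mean visits divided by mean absorption time.
#' Per-state standard errors come from the delta method for the ratio
#' estimator.
#'
#' @inheritParams simulate_chain_batch
#' @return List with `occupancy` and `se` (length `N - 1`),
#'   `mean_absorption_time`, and `reps`.
#' @export
estimate_occupancy <- function(kernel, reps, seed = NULL) {
  if (reps < 100) stop("'reps' must be at least 100", call. = FALSE)
  runs <- simulate_chain_batch(kernel, start = 1L, reps = reps, seed = seed,
                               track_visits = TRUE)
  tbar <- mean(runs$absorption_time)
  vbar <- colMeans(runs$visits)
  occ <- vbar / tbar
  # delta-method SE of mean(v_j)/mean(T)
  se <- vapply(seq_along(occ), function(j2) {
    resid <- runs$visits[, j2] - occ[j2] * runs$absorption_time
    sqrt(mean(resid^2) / reps) / tbar
  }, numeric(1))
  list(occupancy = occ, se = se, mean_absorption_time = tbar,
       reps = as.integer(reps))
}

#' Analytic-versus-empirical validation table
#'
#' Convenience wrapper comparing Monte-Carlo fixation and occupancy
#' estimates against the exact values for one kernel. Used by the
#' `validate` CLI subcommand.
#'
#' @inheritParams simulate_chain_batch
#' @return A data frame with columns `quantity`, `state`, `analytic`,
#'   `estimate`, `se`, `z` (standardised discrepancy).
#' @export
validate_kernel <- function(kernel, reps = 10000, seed = NULL) {
  fx <- estimate_fixation(kernel, start = 1L, reps = reps, seed = seed)
  pi1 <- fixation_from_de_novo(kernel, method = if (is.na(kernel$ratio))
    "log-space" else "closed-form")
  occ_hat <- estimate_occupancy(kernel, reps = reps)
  prof <- sojourn_times(kernel)
  pick <- unique(pmin(kernel$N - 1L, c(1L, 2L, 5L, kernel$N %/% 2L,
                                       kernel$N - 1L)))
  data.frame(
    quantity = c("pi_dn", rep("occupancy", length(pick))),
    state = c(1L, pick),
    analytic = c(pi1, prof$occupancy[pick]),
    estimate = c(fx$estimate, occ_hat$occupancy[pick]),
    se = c(fx$se, occ_hat$se[pick]),
    z = c((fx$estimate - pi1) / max(fx$se, .Machine$double.eps),
          (occ_hat$occupancy[pick] - prof$occupancy[pick]) /
            pmax(occ_hat$se[pick], .Machine$double.eps))
  )
}
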