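# Cultural evolutionary rescue: a birth-death model with variable
# population size. After a catastrophic environmental shift at t = 0,
# every individual carrying the ancestral variant A dies with per-capita
# probability (1 + r)/N_t per timestep, while carriers of the beneficial
# innovation a die with probability (1 - q)/N_t. One naive individual is
# then born and adopts variant a from a payoff-weighted role model with
# probability p_a = f*i_t / (f*i_t + g*(N_t - i_t)).
#
# Event order within a timestep (the model is agnostic, so this is fixed
# by convention): the reproduction probability is computed from
# start-of-step counts, deaths are applied as independent per-individual
# draws (one binomial per variant class), then the single newborn is
# added -- unless nobody survived the death phase, in which case the
# population is extinct. This order reproduces the expected per-step
# change E{dN} = (i/N)(q + r) - r exactly.
#
# Rescue criterion. N_t is a near-critical random walk (per-step noise of
# order 1 against drift of order r), so "first time N_t exceeds N0" taken
# literally is hit by demographic noise within a few steps for most
# replicates, independent of q and f. A replicate therefore counts as
# rescued only when N_t > N0 at a moment when the variant's frequency
# makes the expected per-step change positive, i_t/N_t > r/(q + r): the
# recovery is driven by the spread of the adaptation, not by noise. With
# i0 = 0 (or q = r = 0) this condition is unsatisfiable and a declining
# population always collapses. The first return of N_t to N0 after a dip
# is recorded separately as `return_time`.

#' Parameters of the cultural rescue model
#'
#' Validates and bundles the model parameters.
#'
#' @param N0 Initial population size (integer >= 2).
#' @param q Survival benefit of variant a, in `[0, 1)`.
#' @param r Excess mortality of the ancestral variant A, in `[0, 1)`;
#'   also the initial level of maladaptation.
#' @param i0 Initial count of variant a carriers (default 1: adaptation
#'   from a de novo innovation at the moment of the shift).
#' @param f,g Post-shift transmission payoffs of a and A (defaults 1:
#'   unbiased transmission).
#' @param extinction_threshold Population size at or below which the
#'   population is declared collapsed (default 5).
#' @param max_steps Hard cap on simulated timesteps; defaults to
#'   `ceiling(10 * N0 / max(r, 1e-6))`, ten times the no-variant
#'   collapse horizon.
#' @param reps Ensemble size for [run_rescue_ensemble()] (default 500).
#' @return A validated `rescue_params` list.
#' @export
rescue_params <- function(N0, q, r, i0 = 1, f = 1, g = 1,
                          extinction_threshold = 5, max_steps = NULL,
                          reps = 500) {
  N0 <- check_N(N0)
  check_scalar_number(q, "q", lower = 0, upper = 1, strict_upper = TRUE)
  check_scalar_number(r, "r", lower = 0, upper = 1, strict_upper = TRUE)
  check_scalar_number(f, "f", lower = 0, strict_lower = TRUE)
  check_scalar_number(g, "g", lower = 0, strict_lower = TRUE)
  if (i0 < 0 || i0 > N0 || i0 != round(i0))
    stop("'i0' must be an integer in 0..N0", call. = FALSE)
  if (extinction_threshold < 0 || extinction_threshold >= N0)
    stop("'extinction_threshold' must be in [0, N0)", call. = FALSE)
  if (is.null(max_steps)) max_steps <- ceiling(10 * N0 / max(r, 1e-6))
  if (max_steps < 1) stop("'max_steps' must be at least 1", call. = FALSE)
  if (reps < 1) stop("'reps' must be at least 1", call. = FALSE)
  structure(
    list(N0 = N0, i0 = as.integer(i0), q = q, r = r, f = f, g = g,
         extinction_threshold = extinction_threshold,
         max_steps = as.numeric(max_steps), reps = as.integer(reps)),
    class = "rescue_params"
  )
}

#' @export
print.rescue_params <- function(x, ...) {
  cat("<rescue_params> N0 =", x$N0, " i0 =", x$i0,
      " q =", x$q, " r =", x$r, " f =", x$f, " g =", x$g, "\n")
  cat("  extinction threshold =", x$extinction_threshold,
      " max steps =", format(x$max_steps), " reps =", x$reps, "\n")
  invisible(x)
}

# vectorised one-step update over parallel replicates; returns list(N, i)
rescue_advance <- function(Nv, iv, params) {
  n <- length(Nv)
  live <- Nv > 0
  pa <- numeric(n)
  wa <- params$f * iv[live]
  wA <- params$g * (Nv[live] - iv[live])
  pa[live] <- ifelse(wa + wA > 0, wa / (wa + wA), 0)
  # death probabilities clamped to [0, 1]; the clamp only matters for
  # pathological parameters or N_t = 1
  pda <- pmin(1, pmax(0, (1 - params$q) / Nv))
  pdA <- pmin(1, pmax(0, (1 + params$r) / Nv))
  da <- dA <- numeric(n)
  da[live] <- rbinom(sum(live), iv[live], pda[live])
  dA[live] <- rbinom(sum(live), Nv[live] - iv[live], pdA[live])
  surv <- Nv - da - dA
  isurv <- iv - da
  born_a <- runif(n) < pa
  newN <- ifelse(surv > 0, surv + 1, 0)
  newi <- ifelse(surv > 0, isurv + born_a, 0)
  list(N = newN, i = newi)
}

#' Advance the rescue model by one timestep
#'
#' Single stochastic step from state `(N_t, i_t)`. Reproduction uses the
#' start-of-step counts; if no individual survives the death phase the
#' population is extinct and no birth occurs.
#'
#' @param N_t Current population size.
#' @param i_t Current count of variant a carriers (`0 <= i_t <= N_t`).
#' @param params A `rescue_params` object.
#' @return A list with the new `N` and `i`.
#' @examples
#' p <- rescue_params(N0 = 100, q = 0.01, r = 0.01)
#' rescue_step(100, 1, p)
#' @export
rescue_step <- function(N_t, i_t, params) {
  stopifnot(inherits(params, "rescue_params"))
  if (i_t > N_t || i_t < 0 || N_t < 0)
    stop("invalid state: need 0 <= i_t <= N_t", call. = FALSE)
  out <- rescue_advance(as.numeric(N_t), as.numeric(i_t), params)
  list(N = out$N, i = out$i)
}

# is state (N, i) a cultural rescue? N above N0 with adaptation-driven
# positive expected growth: i/N > r/(q + r) (unsatisfiable when q + r = 0)
is_rescued_state <- function(Nv, iv, params) {
  Nv > params$N0 & (params$q + params$r) > 0 &
    iv * (params$q + params$r) > params$r * Nv
}

#' Simulate one rescue trajectory
#'
#' Iterates the model until the population is culturally rescued
#' (`rescued`: `N_t > N0` while `i_t/N_t > r/(q+r)`, so the expected
#' growth is positive and the recovery is attributable to the variant --
#' see Details), falls to or below the extinction threshold
#' (`collapsed`), or hits `max_steps` (`censored`).
#'
#' @details The population size performs a near-critical random walk
#'   (per-step noise of order one against drift of order `r`), so a bare
#'   first-crossing rule "`N_t > N0`" would be triggered by demographic
#'   noise within a few timesteps for most replicates. Requiring the
#'   variant's frequency to exceed the growth threshold `r/(q+r)` at the
#'   crossing restricts the label to recoveries the cultural adaptation
#'   actually drives; with `i0 = 0` the population then always collapses
#'   (in roughly `N0/r` timesteps on average).
#'
#' @param params A `rescue_params` object.
#' @param seed Optional integer seed.
#' @param record If `TRUE` (default) keep the full `(N_t, i_t)` path;
#'   set `FALSE` for long runs where only the summary statistics matter.
#' @return A `rescue_trajectory`: list with `pop_sizes`, `counts_a`
#'   (`NULL` when not recorded; element 1 is the state at t = 0),
#'   `outcome`, `rescue_time` (first t satisfying the rescue
#'   criterion), `return_time`
#'   (first t back at `N_t >= N0` after dipping below), `bottleneck`
#'   (minimum population size), `collapse_time`, `peak_freq_a`
#'   (maximum of `i_t/N_t`), and `steps`.
#' @examples
#' p <- rescue_params(N0 = 50, q = 0.2, r = 0.05, f = 2, max_steps = 5000)
#' simulate_rescue(p, seed = 1)$outcome
#' @export
simulate_rescue <- function(params, seed = NULL, record = TRUE) {
  stopifnot(inherits(params, "rescue_params"))
  if (!is.null(seed)) set.seed(seed)
  N <- as.numeric(params$N0)
  i <- as.numeric(params$i0)
  bottleneck <- N
  peak <- if (N > 0) i / N else 0
  dipped <- FALSE
  rescue_time <- return_time <- collapse_time <- NA_real_
  outcome <- "censored"
  if (record) {
    cap <- 65536L
    Ns <- numeric(cap); is <- numeric(cap)
    Ns[1L] <- N; is[1L] <- i
  }
  t <- 0
  while (t < params$max_steps) {
    t <- t + 1
    st <- rescue_advance(N, i, params)
    N <- st$N; i <- st$i
    if (record) {
      if (t + 1L > cap) {
        cap <- cap * 2L
        Ns <- c(Ns, numeric(cap / 2L)); is <- c(is, numeric(cap / 2L))
      }
      Ns[t + 1L] <- N; is[t + 1L] <- i
    }
    bottleneck <- min(bottleneck, N)
    if (N > 0) peak <- max(peak, i / N)
    if (!dipped && N < params$N0) dipped <- TRUE
    if (is.na(return_time) && dipped && N >= params$N0) return_time <- t
    if (is_rescued_state(N, i, params)) {
      outcome <- "rescued"; rescue_time <- t; break
    }
    if (N <= params$extinction_threshold) {
      outcome <- "collapsed"; collapse_time <- t; break
    }
  }
  structure(
    list(pop_sizes = if (record) Ns[seq_len(t + 1L)] else NULL,
         counts_a = if (record) is[seq_len(t + 1L)] else NULL,
         outcome = outcome, rescue_time = rescue_time,
         return_time = return_time, bottleneck = bottleneck,
         collapse_time = collapse_time, peak_freq_a = peak, steps = t),
    class = "rescue_trajectory"
  )
}

#' @export
print.rescue_trajectory <- function(x, ...) {
  cat("<rescue_trajectory>", x$outcome, "after", x$steps, "timesteps;",
      "bottleneck =", x$bottleneck, "\n")
  invisible(x)
}

#' Run an ensemble of rescue trajectories
#'
#' Advances `params$reps` independent replicates in lockstep (vectorised
#' over replicates; each replicate obeys the single-trajectory law,
#' including the adaptation-driven rescue criterion of
#' [simulate_rescue()]) and aggregates outcome statistics. Results are reproducible for a fixed
#' `(seed, reps)` pair: the replicates share one RNG stream, consumed
#' jointly step by step.
#'
#' @param params A `rescue_params` object.
#' @param seed Optional integer seed.
#' @param record_horizon If positive, also record each replicate's
#'   `N_t` and `i_t` for `t <= record_horizon` (finished replicates
#'   carry their terminal value forward), and return ensemble means --
#'   used for comparison with [rescue_mean_field()].
#' @return A `rescue_summary`: list with `rescue_probability`,
#'   conditional means `mean_rescue_time`, `mean_bottleneck` (over
#'   rescued replicates), `mean_collapse_time` (over collapsed ones; all
#'   `NA` when no replicate qualifies), `reps_used`, a per-replicate
#'   data frame `replicates`, ensemble means `mean_N`/`mean_i` and the
#'   underlying `N_paths`/`i_paths` matrices (when recorded; column 1 is
#'   t = 0, finished replicates carry their terminal value forward), and
#'   `params`.
#' @examples
#' p <- rescue_params(N0 = 50, q = 0.2, r = 0.05, f = 2, reps = 50,
#'                    max_steps = 5000)
#' run_rescue_ensemble(p, seed = 1)$rescue_probability
#' @export
run_rescue_ensemble <- function(params, seed = NULL, record_horizon = 0L) {
  stopifnot(inherits(params, "rescue_params"))
  if (!is.null(seed)) set.seed(seed)
  reps <- params$reps
  N0 <- as.numeric(params$N0)
  q <- params$q; r <- params$r; f <- params$f; g <- params$g
  thr <- params$extinction_threshold
  qr <- q + r
  # final per-replicate statistics
  fin_N <- rep(N0, reps); fin_i <- rep(as.numeric(params$i0), reps)
  bottleneck <- rep(N0, reps)
  peak <- fin_i / N0
  rescue_time <- return_time <- collapse_time <- rep(NA_real_, reps)
  outcome <- rep("censored", reps)
  rec <- record_horizon > 0L
  if (rec) {
    Nrec <- matrix(NA_real_, reps, record_horizon + 1L)
    irec <- matrix(NA_real_, reps, record_horizon + 1L)
    Nrec[, 1L] <- fin_N; irec[, 1L] <- fin_i
  }
  # hot loop works on compacted vectors of live replicates only
  id <- seq_len(reps)
  Nl <- fin_N; il <- fin_i
  bot <- bottleneck; pk <- peak
  dip <- rep(FALSE, reps); ret <- rep(NA_real_, reps)
  t <- 0
  while (length(id) && t < params$max_steps) {
    t <- t + 1
    m <- length(id)
    pa <- f * il / (f * il + g * (Nl - il))
    da <- rbinom(m, il, pmin(1, (1 - q) / Nl))
    dA <- rbinom(m, Nl - il, pmin(1, (1 + r) / Nl))
    surv <- Nl - da - dA
    pos <- surv > 0
    Nl <- (surv + 1) * pos
    il <- (il - da + (runif(m) < pa)) * pos
    bot <- pmin(bot, Nl)
    pk <- pmax(pk, il / pmax(Nl, 1))  # il = 0 whenever Nl = 0
    back <- dip & is.na(ret) & Nl >= N0
    if (any(back)) ret[back] <- t
    dip <- dip | Nl < N0
    done <- (qr > 0 & Nl > N0 & il * qr > r * Nl) | Nl <= thr
    if (rec && t <= record_horizon) {
      Nrec[id, t + 1L] <- Nl; irec[id, t + 1L] <- il
      if (length(id) < reps && t <= record_horizon) {
        gone <- setdiff(seq_len(reps), id)
        Nrec[gone, t + 1L] <- fin_N[gone]; irec[gone, t + 1L] <- fin_i[gone]
      }
    }
    if (any(done)) {
      dx <- id[done]
      resc <- done & Nl > N0
      outcome[id[resc]] <- "rescued"; rescue_time[id[resc]] <- t
      outcome[id[done & !resc]] <- "collapsed"
      collapse_time[id[done & !resc]] <- t
      fin_N[dx] <- Nl[done]; fin_i[dx] <- il[done]
      bottleneck[dx] <- bot[done]; peak[dx] <- pk[done]
      return_time[dx] <- ret[done]
      keep <- !done
      id <- id[keep]; Nl <- Nl[keep]; il <- il[keep]
      bot <- bot[keep]; pk <- pk[keep]; dip <- dip[keep]; ret <- ret[keep]
    }
  }
  # censored replicates keep their running statistics
  fin_N[id] <- Nl; fin_i[id] <- il
  bottleneck[id] <- bot; peak[id] <- pk; return_time[id] <- ret
  rescued <- outcome == "rescued"
  collapsed <- outcome == "collapsed"
  cond_mean <- function(x, sel) if (any(sel)) mean(x[sel]) else NA_real_
  structure(
    list(rescue_probability = mean(rescued),
         mean_rescue_time = cond_mean(rescue_time, rescued),
         mean_bottleneck = cond_mean(bottleneck, rescued),
         mean_collapse_time = cond_mean(collapse_time, collapsed),
         reps_used = reps,
         replicates = data.frame(
           rep = seq_len(reps), outcome = outcome,
           rescue_time = rescue_time, return_time = return_time,
           collapse_time = collapse_time, bottleneck = bottleneck,
           peak_freq_a = peak),
         mean_N = if (rec) colMeans(Nrec) else NULL,
         mean_i = if (rec) colMeans(irec) else NULL,
         N_paths = if (rec) Nrec else NULL,
         i_paths = if (rec) irec else NULL,
         params = params),
    class = "rescue_summary"
  )
}

#' @export
print.rescue_summary <- function(x, ...) {
  cat("<rescue_summary>", x$reps_used, "replicates\n")
  cat("  P(rescue) =", format(x$rescue_probability), "\n")
  cat("  mean rescue time  (rescued)  =", format(x$mean_rescue_time), "\n")
  cat("  mean bottleneck   (rescued)  =", format(x$mean_bottleneck), "\n")
  cat("  mean collapse time (collapsed) =", format(x$mean_collapse_time), "\n")
  invisible(x)
}

#' Mean-field recursion for the rescue model
#'
#' Iterates the expected-value recursions, treating the expectations as
#' state (a mean-field approximation that ignores the covariance of
#' `N_t` and `i_t`):
#' `E{N_{t+1}} = N - r + (i/N)(q + r)` and
#' `E{i_{t+1}} = i + p_a - i (1 - q)/N` with
#' `p_a = f i / (f i + g (N - i))`. With `i0 = 0` this gives the linear
#' decline `N_t = N0 - r t`, hence collapse after about `N0 / r`
#' timesteps. Iteration stops early if the expected population reaches
#' zero.
#'
#' @param params A `rescue_params` object.
#' @param steps Number of timesteps to iterate (at least 1).
#' @return A data frame with columns `t` (0-based), `N`, `i`.
#' @examples
#' p <- rescue_params(N0 = 1000, q = 0.005, r = 0.003)
#' head(rescue_mean_field(p, steps = 5))
#' @export
rescue_mean_field <- function(params, steps) {
  stopifnot(inherits(params, "rescue_params"))
  if (steps < 1) stop("'steps' must be at least 1", call. = FALSE)
  steps <- as.integer(steps)
  N <- numeric(steps + 1L); i <- numeric(steps + 1L)
  N[1L] <- params$N0; i[1L] <- params$i0
  q <- params$q; r <- params$r; f <- params$f; g <- params$g
  used <- steps
  for (t in seq_len(steps)) {
    Nc <- N[t]; ic <- i[t]
    if (Nc <= 0) { used <- t - 1L; break }
    pa <- if (f * ic + g * (Nc - ic) > 0) f * ic / (f * ic + g * (Nc - ic)) else 0
    N[t + 1L] <- Nc - r + (ic / Nc) * (q + r)
    i[t + 1L] <- min(ic + pa - ic * (1 - q) / Nc, N[t + 1L])
  }
  data.frame(t = 0:used, N = N[seq_len(used + 1L)], i = i[seq_len(used + 1L)])
}

#' Classify a point of the (q, f) plane into a rescue domain
#'
#' Estimates the rescue probability with the focal transmission
#' advantage `f` and with the neutral baseline `f = g`, then labels the
#' point by a documented heuristic with threshold `p_min`:
#' \describe{
#'   \item{iv}{rescue is likely even without a transmission advantage
#'     (`P(q, g) >= p_min`);}
#'   \item{i}{the transmission bias makes the rescue possible
#'     (`P(q, f) >= p_min > P(q, g)`);}
#'   \item{iii}{rescue unlikely even with the bias (`P(q, f) < p_min`);}
#'   \item{ii}{reserved for grid-level use: a region where rescue
#'     succeeds for every tested `f` (reported by callers sweeping `f`,
#'     not by this pointwise rule).}
#' }
#'
#' @param q Survival benefit to classify.
#' @param f Transmission advantage to classify.
#' @param params_template A `rescue_params` object supplying everything
#'   except `q` and `f`.
#' @param baseline_f Baseline payoff for the no-advantage comparison
#'   (defaults to the template's `g`).
#' @param p_min Probability threshold (default 0.5).
#' @param seed Optional integer seed.
#' @return List with `domain` (`"i"`, `"iii"` or `"iv"`), `p_focal`,
#'   `p_baseline`.
#' @export
classify_rescue_domain <- function(q, f, params_template,
                                   baseline_f = params_template$g,
                                   p_min = 0.5, seed = NULL) {
  stopifnot(inherits(params_template, "rescue_params"))
  if (!is.null(seed)) set.seed(seed)
  mk <- function(fv) {
    p <- params_template
    p$q <- check_scalar_number(q, "q", lower = 0, upper = 1,
                               strict_upper = TRUE)
    p$f <- fv
    p
  }
  p_focal <- run_rescue_ensemble(mk(f))$rescue_probability
  p_base <- run_rescue_ensemble(mk(baseline_f))$rescue_probability
  domain <- if (p_base >= p_min) "iv"
            else if (p_focal >= p_min) "i"
            else "iii"
  list(domain = domain, p_focal = p_focal, p_baseline = p_base)
}
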