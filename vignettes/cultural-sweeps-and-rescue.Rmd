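---
title: "Cultural selective sweeps, standing variation and evolutionary rescue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cultural selective sweeps, standing variation and evolutionary rescue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(culturesweep)
```

## The model

A population of fixed size $N$ carries a two-variant cultural trait:
ancestral $A$ and innovation $a$. Each timestep one newborn adopts a
variant from a role model and replaces a uniformly chosen individual
(overlapping generations, Moran-type dynamics). The count of $a$-carriers
is a birth--death Markov chain on $\{0, 1, \dots, N\}$ with absorbing
boundaries, fully described by the interior step-up and step-down
probabilities $\alpha_i$ and $\beta_i$. Three transmission regimes are
implemented:

* **unbiased** -- the role model is uniform:
  $\alpha_i = \beta_i = i(N-i)/N^2$;
* **payoff-biased** -- role models are weighted by the variant benefits
  $f$ (for $a$) and $g$ (for $A$, default 1), giving the constant step
  ratio $\beta_i/\alpha_i = g/f$;
* **conformist / anti-conformist** -- a variant at frequency $x$ is
  copied with weight $x^{1+\theta}$; $\theta > 0$ favours the common
  variant, $\theta < 0$ the rare one, and $\theta = 0$ recovers the
  unbiased kernel exactly ($\theta > -1$ keeps the exponent positive).

An environmental shift at $T_0$ makes $a$ beneficial: transmission
after the shift is payoff-biased with $f > g$. Two adaptation routes
are compared. A *de novo* innovation starts at count 1 after the shift
and fixes with probability
$$\pi_1 = \Big(1 + \sum_{l=1}^{N-1}\prod_{k=1}^{l}\tfrac{\beta_k}{\alpha_k}\Big)^{-1},
\qquad
\pi_j = \pi_1\Big(1 + \sum_{l=1}^{j-1}\prod_{k=1}^{l}\tfrac{\beta_k}{\alpha_k}\Big).$$
*Standing variation* is a variant already segregating at $T_0$; its
frequency distribution is the occupancy of the pre-shift chain started
from one copy, $t_{1j}/t_1$, where $t_{1j}$ is the expected time spent
at count $j$ before absorption and $t_1 = \sum_j t_{1j}$, so
$$\pi_{SV} = \sum_{j=1}^{N-1} \frac{t_{1j}}{t_1}\,\pi_j .$$

### Sojourn times

For a general birth--death kernel, writing
$\rho_k = \prod_{m \le k} \beta_m/\alpha_m$ ($\rho_0 = 1$), the sojourn
times from a single starting copy are
$$t_{1j} = \frac{D_j}{S_N\,\alpha_j}, \qquad
  S_N = \sum_{k=0}^{N-1} \rho_k, \qquad
  D_j = \sum_{k=j}^{N-1} \prod_{m=j+1}^{k}\frac{\beta_m}{\alpha_m},$$
which follows from the excursion decomposition of the chain (reach
count $j$ with probability $1/\sum_{k<j}\rho_k$, then make a geometric
number of returns). Under unbiased transmission every ratio is 1, so
$D_j = N - j$, $S_N = N$, and the familiar neutral results
$t_{1j} = N/j$ and $t_1 = N(1 + \sum_{k=2}^{N-1} 1/k)$ drop out. The
package validates this form, for all three regimes, against dense
fundamental-matrix solves of the full $(N+1)$-state chain (relative
error below $10^{-8}$ for $N \le 50$) and against Monte-Carlo visit
counts; a two-product expression without the inner sums that circulates
for this quantity reproduces only the unbiased special case and fails
the oracle for biased kernels, which is why the package uses the form
above.

Timesteps are counted *including* self-loop holds, so at $N = 2$ the
single interior state has escape probability $1/2$ and $t_1 = 2$; this
is also how a fundamental matrix counts, which keeps the analytic and
oracle conventions aligned.

### Numerical choices

Products $\prod \beta_k/\alpha_k$ underflow double precision
catastrophically for large $N$ (at $N = 1000$, $f/g = 2$ the raw
product is $\sim 10^{-300}$), so every product is a cumulative sum of
logs and every sum of products uses max-shifted exponentiation. Kernels
that know their constant step ratio $\rho = g/f$ (payoff kernels, and
any neutral kernel, which reports $\rho = 1$) use the geometric closed
form $\pi_j = (1-\rho^j)/(1-\rho^N)$ as an $O(1)$ fast path, rewritten
with negative exponents when $\rho > 1$ so nothing overflows, and
falling back to the $j/N$ limit when $|1-\rho| < 10^{-12}$. Both paths
are exposed (`method = "log-space"` / `"closed-form"`) and tested to
agree to $10^{-12}$ relative error up to $N = 10^4$.

### An ordering the package does not reproduce

Anti-conformist pre-shift transmission raises $\pi_{SV}$ relative to
unbiased transmission (it parks variants at intermediate frequencies),
and standing variation always beats de novo innovation at matched
benefit. Conformist pre-shift transmission, however, *lowers*
$\pi_{SV}$ below the unbiased value for every $N$ and $f$ we examined,
even though it has been claimed to raise it: with the chain started
from a single copy, $\theta > 0$ suppresses the rare variant, so the
occupancy distribution is stochastically dominated by the unbiased one
while $\pi_j$ increases in $j$ -- the weighted average can only drop.
The corresponding occupancy shapes (less mass at high frequencies under
conformity, more at intermediate frequencies under anti-conformity) are
exactly what the same sources show, so we assert the mechanism and
report the ordering our computation yields; the acceptance suite keeps
the published ordering as a failing expectation rather than silently
inverting it.

## Foresight versus directed innovation

Cognition can raise the mean benefit of variants held *before* a shift
(foresight, $f_{SV}$) or invented *in response* to it (directed
innovation, $f_{DN}$), with $f_{SV} \le f_{DN}$: foresight should not
beat innovation under full information. `delta_pi()` and `delta_grid()`
evaluate $\Delta\pi = \pi_{SV}(f_{SV}) - \pi_{DN}(f_{DN})$ over the
lower triangle; cells above it are masked `NA` rather than errors so
rectangular CSV output stays aligned. On the diagonal $\Delta\pi \ge 0$
(the frequency advantage of standing variation), and for $f_{SV}$ near
$g$ with large $f_{DN}$ the sign flips: directed innovation can only
compensate for starting from one copy when foresight buys little. The
default pre-shift regime is unbiased transmission, with conformity as an
option; the grid resolution and $N$ are user choices (no canonical
values exist), and the reported zero-crossing per $f_{DN}$ column makes
the sign boundary explicit.

## Cultural evolutionary rescue

After a catastrophic shift the population is no longer buffered:
$A$-carriers die with per-capita probability $(1+r)/N_t$ per step and
$a$-carriers with $(1-q)/N_t$ ($0 \le q, r < 1$); one newborn is added
per step, adopting $a$ with the payoff-weighted probability
$p_a = f i_t / (f i_t + g(N_t - i_t))$. Within a timestep the order is:
compute $p_a$ from start-of-step counts, apply deaths as two
independent binomial draws (one per variant class -- the marginal rates
are fixed by the model, independence is the minimal joint assumption),
then add the newborn unless nobody survived. This order reproduces the
expected change $\mathbf{E}\{\Delta N_t\} = (i_t/N_t)(q+r) - r$
exactly, so the population grows on average once $i_t/N_t$ exceeds
$r/(q+r)$ (the zero of the drift; a threshold sometimes misquoted as
$r/(q-r)$, which is not the zero of the printed drift and is not used
here). The matching mean-field recursions
$$\mathbf{E}\{N_{t+1}\} = N - r + \tfrac{i}{N}(q+r), \qquad
  \mathbf{E}\{i_{t+1}\} = i + p_a - i\,\tfrac{1-q}{N}$$
are iterated by `rescue_mean_field()`; with $i_0 = 0$ they give the
linear decline $N_t = N_0 - rt$ and collapse after about $N_0/r$ steps.
The pre-shift phase is never simulated: all analyses start at $T_0 = 0$
with the innovation present as a single copy ($i_0 = 1$) unless stated.

**What counts as a rescue.** $N_t$ is a near-critical random walk: its
per-step standard deviation is of order one while the drift is of order
$r \ll 1$, so the first time $N_t$ exceeds $N_0$ is reached by
demographic noise within a few steps for most replicates, at every
parameter set we examined -- a bare first-crossing rule would declare
"rescue" with probability near one independently of $q$ and $f$, and
conditioning on it biases collapse times. A replicate is therefore
labelled *rescued* at the first $t$ with $N_t > N_0$ **and**
$i_t/N_t > r/(q+r)$: the population is above its initial size at a
moment when the cultural adaptation makes the expected change positive,
so the recovery is attributable to the variant rather than to noise.
Consequences that match the model's logic: with $i_0 = 0$ or
$q = r = 0$ the condition is unsatisfiable, so a variant-free declining
population always collapses (in $\approx N_0/r$ steps) and a zero-drift
population is only censored or collapsed. The first return of $N_t$ to
$N_0$ after a dip is recorded separately (`return_time`) since both
notions of "reaching its initial size again" are of interest. Death
probabilities are clamped to $[0,1]$; with the default extinction
threshold of 5 individuals and $r < 1$ the clamp never binds, it only
guards pathological parameters.

`run_rescue_ensemble()` advances all replicates in lockstep (vectorised
over replicates, each obeying the single-trajectory law), which is what
makes ensembles of $10^5$-step trajectories feasible in pure R; a run
is reproducible for a fixed `(seed, reps)` pair, with the replicates
consuming one common RNG stream. `simulate_rescue()` is the scalar
reference implementation and accepts its own seed.

## What the simulations emulate -- and what they do not

The generator's defaults are the study conditions used throughout:
weak-benefit rescue at $N_0 = 1000$, $q = 0.005$, $r = 0.003$, $f = g = 1$,
$i_0 = 1$ (decline to a bottleneck of a few hundred with rescue
probability around 1%, 500 replicates); the variant-free collapse law at
$N_0 = 200$, $r = 0.05$; and, for the qualitative response surfaces, a
scaled-down grid at $N_0 = 300$, $r = 0.05$, $q \in \{0, 0.05, 0.25\}$,
$f \in \{1, 2, 4\}$ with 800 replicates per cell, sizes chosen so the
whole suite runs in minutes on one CPU while keeping Monte-Carlo
standard errors well below the effect sizes being asserted. These are
models of a single well-mixed population with one dichotomous trait,
no age structure, no innovation during the rescue phase and no
gene--culture coupling; passing tests show internal consistency of the
mathematics and simulator, not that any real population behaves this
way.

## Tunable parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `N` | population size (individuals) | -- | $\ge 2$ |
| `f`, `g` | transmission payoffs of $a$, $A$ | `g = 1` | positive; $f/g$ is the bias |
| `theta` | conformity exponent | 0 | $> -1$; $\pm 0.5$, $\pm 0.05$ typical |
| `mu` | per-capita innovation rate (per timestep) | -- | spectrum only |
| `q`, `r` | survival benefit / excess mortality | -- | in $[0, 1)$ |
| `extinction_threshold` | collapse size (individuals) | 5 | below $N_0$ |
| `max_steps` | step cap | $10 N_0 / \max(r, 10^{-6})$ | ten collapse horizons |

## Known limitations

* Occupancy conditioning is fixed at a chain started from one copy, the
  stated construction for "standing variation that has not yet fixed";
  no stationary-innovation alternative is offered.
* The rescue domain labels (i)--(iv) rest on a documented heuristic
  threshold `p_min` (default 0.5) applied to Monte-Carlo estimates;
  near the threshold the label is noisy.
* The `n`-variant accumulation model, time-varying environments with
  repeated shifts, and gene--culture co-evolutionary rescue are out of
  scope.
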