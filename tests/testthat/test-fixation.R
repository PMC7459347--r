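# Fixation probabilities, sojourn times and the trait frequency spectrum.

test_that("de novo fixation matches frozen hand/oracle values", {
  # neutral: 1/N
  expect_equal(fixation_from_de_novo(make_payoff_kernel(50, 1)), 1 / 50,
               tolerance = 1e-14)
  # constant-ratio geometric value (1 - 0.5)/(1 - 0.5^100)
  expect_equal(fixation_from_de_novo(make_payoff_kernel(100, 2)),
               0.5 / (1 - 0.5^100), tolerance = 1e-12)
  # 4-state chain, absorption-probability solve froze 0.3655589...
  k3 <- make_payoff_kernel(3, f = 1.1)
  expect_equal(fixation_from_de_novo(k3),
               dense_chain_solve(k3)$pi_j[1], tolerance = 1e-12)
  expect_equal(fixation_from_de_novo(k3), 0.36556, tolerance = 1e-4)
})

test_that("log-space and closed-form evaluations agree, including f < g", {
  for (N in c(10L, 100L, 1000L)) for (f in c(0.5, 1.001, 1.1, 2)) {
    k <- make_payoff_kernel(N, f)
    expect_equal(fixation_from_de_novo(k, method = "log-space"),
                 fixation_from_de_novo(k, method = "closed-form"),
                 tolerance = 1e-12)
    j <- c(1L, N %/% 2L, N - 1L)
    expect_equal(fixation_from_state(k, j, method = "log-space"),
                 fixation_from_state(k, j, method = "closed-form"),
                 tolerance = 1e-12)
  }
})

test_that("fixation from state j is j/N when neutral and monotone in j and f", {
  for (N in c(10L, 500L)) {
    k <- make_payoff_kernel(N, 1)
    expect_equal(fixation_from_state(k, seq_len(N - 1L)),
                 seq_len(N - 1L) / N, tolerance = 1e-14)
  }
  k <- make_payoff_kernel(100, 2)
  pij <- fixation_from_state(k, 1:99)
  # strictly increasing until 1 - (g/f)^j saturates double precision
  expect_true(all(diff(pij[1:50]) > 0))
  expect_true(all(diff(pij) >= 0))
  expect_lte(pij[99], 1)
  expect_equal(fixation_from_state(k, 10),
               (1 - 0.5^10) / (1 - 0.5^100), tolerance = 1e-12)
  expect_equal(fixation_from_state(k, 1), fixation_from_de_novo(k))
  # strictly increasing in f at fixed N
  for (N in c(100L, 500L)) {
    pis <- vapply(c(1.001, 1.01, 1.1, 1.5, 2), function(f)
      fixation_from_de_novo(make_payoff_kernel(N, f)), numeric(1))
    expect_true(all(diff(pis) > 0))
  }
  expect_error(fixation_from_state(k, 0), "interior")
  expect_error(fixation_from_state(k, 100), "interior")
})

test_that("sojourn times reduce to N/j under unbiased transmission", {
  for (N in c(10L, 100L, 1000L)) {
    p <- sojourn_times(make_unbiased_kernel(N))
    j <- seq_len(N - 1L)
    expect_lt(max(abs(p$t1j * j / N - 1)), 1e-10)
    expect_equal(p$t1, N * (1 + sum(1 / (2:(N - 1)))), tolerance = 1e-10)
    expect_equal(sum(p$occupancy), 1, tolerance = 1e-12)
  }
  # single interior state: geometric holding with escape probability 1/2
  expect_equal(sojourn_times(make_unbiased_kernel(2))$t1, 2, tolerance = 1e-12)
})

test_that("analytic quantities match dense fundamental-matrix solves for all regimes", {
  kernels <- c(
    lapply(c(11L, 30L), make_unbiased_kernel),
    lapply(c(1.02, 1.5, 3), function(f) make_payoff_kernel(31, f)),
    lapply(c(-0.5, -0.05, 0.05, 0.5), function(th)
      make_conformity_kernel(29, th))
  )
  for (k in kernels) {
    d <- dense_chain_solve(k)
    p <- sojourn_times(k)
    expect_equal(p$t1j, d$t1j, tolerance = 1e-8)
    expect_equal(p$t1, d$t1, tolerance = 1e-10)
    expect_equal(fixation_from_state(k, seq_len(k$N - 1L),
                                     method = "log-space"),
                 d$pi_j, tolerance = 1e-10)
  }
})

test_that("standing variation: worked N = 3 value and kernel checks", {
  r <- fixation_from_standing_variation(make_unbiased_kernel(3),
                                        make_payoff_kernel(3, 1))
  expect_equal(r$sojourn$t1j, c(3, 1.5), tolerance = 1e-12)
  expect_equal(r$sojourn$t1, 4.5, tolerance = 1e-12)
  expect_equal(r$pi_j, c(1 / 3, 2 / 3), tolerance = 1e-14)
  expect_equal(r$pi_sv, 4 / 9, tolerance = 1e-14)
  # N = 2: the only standing frequency is 1, so pi_SV = pi_DN exactly
  r2 <- fixation_from_standing_variation(make_unbiased_kernel(2),
                                         make_payoff_kernel(2, 1.3))
  expect_equal(r2$pi_sv, r2$pi_dn, tolerance = 1e-15)
  expect_error(
    fixation_from_standing_variation(make_unbiased_kernel(10),
                                     make_payoff_kernel(11, 2)),
    "same N")
})

test_that("standing variation beats de novo innovation; pi_SV increases with f", {
  for (N in c(100L, 1000L)) {
    sv <- vapply(c(1.001, 1.01, 1.05), function(f)
      fixation_from_standing_variation(make_unbiased_kernel(N),
                                       make_payoff_kernel(N, f))$pi_sv,
      numeric(1))
    dn <- vapply(c(1.001, 1.01, 1.05), function(f)
      fixation_from_de_novo(make_payoff_kernel(N, f)), numeric(1))
    expect_true(all(sv > dn))
    expect_true(all(diff(sv) > 0))
  }
})

test_that("occupancy shapes: conformity thins high frequencies, anti-conformity fattens the middle", {
  N <- 50L
  occ_u <- sojourn_times(make_unbiased_kernel(N))$occupancy
  occ_c <- sojourn_times(make_conformity_kernel(N, 0.05))$occupancy
  occ_a <- sojourn_times(make_conformity_kernel(N, -0.05))$occupancy
  high <- (N - 5L):(N - 1L)
  mid <- 20L:30L
  expect_true(all(occ_c[high] < occ_u[high]))
  expect_true(all(occ_a[mid] > occ_u[mid]))
})

test_that("trait frequency spectrum follows S_Nj = mu * t1j", {
  prof <- sojourn_times(make_unbiased_kernel(10))
  sp <- trait_frequency_spectrum(prof, mu = 0.01)
  expect_equal(sp$s_nj[1], 0.1, tolerance = 1e-12)
  # neutral 1/j shape: S_Nj * j constant
  expect_equal(sp$s_nj * sp$j, rep(0.1, 9), tolerance = 1e-10)
  expect_equal(sp$s_n, 0.01 * prof$t1, tolerance = 1e-14)
  # identity holds for a biased kernel too
  prof_b <- sojourn_times(make_conformity_kernel(20, -0.3))
  sp_b <- trait_frequency_spectrum(prof_b, mu = 0.05)
  expect_equal(sum(sp_b$s_nj), 0.05 * prof_b$t1, tolerance = 1e-12)
  expect_error(trait_frequency_spectrum(prof, mu = 0), "mu")
})
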