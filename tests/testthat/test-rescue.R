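# The cultural evolutionary-rescue birth-death model.

test_that("rescue parameters are validated", {
  expect_error(rescue_params(100, q = 1.2, r = 0.01), "q")
  expect_error(rescue_params(100, q = 0.1, r = 1), "r")
  expect_error(rescue_params(100, q = 0.1, r = 0.1, i0 = 101), "i0")
  expect_error(rescue_params(100, q = 0.1, r = 0.1,
                             extinction_threshold = 100), "extinction")
  p <- rescue_params(100, q = 0.1, r = 0.05)
  expect_identical(p$i0, 1L)
  expect_identical(p$extinction_threshold, 5)
  expect_equal(p$max_steps, ceiling(10 * 100 / 0.05))
})

test_that("one-step expectations match the model's drift", {
  adv <- culturesweep:::rescue_advance
  n <- 30000
  # all adapted, q = 0: one expected death, one birth -> E{dN} = 0
  set.seed(1)
  p <- rescue_params(100, q = 0, r = 0.3)
  st <- adv(rep(100, n), rep(100, n), p)
  dN <- st$N - 100
  expect_lt(abs(mean(dN)) / (sd(dN) / sqrt(n)), 3)
  # no adapted individuals: newborn is always ancestral, E{dN} = -r
  set.seed(2)
  p <- rescue_params(100, q = 0.4, r = 0.2)
  st <- adv(rep(100, n), rep(0, n), p)
  expect_true(all(st$i == 0))
  dN <- st$N - 100
  expect_lt(abs(mean(dN) + 0.2) / (sd(dN) / sqrt(n)), 3)
  # general state: E{dN} = (i/N)(q + r) - r
  set.seed(3)
  p <- rescue_params(200, q = 0.01, r = 0.02)
  st <- adv(rep(200, n), rep(50, n), p)
  dN <- st$N - 200
  expected <- (50 / 200) * (0.01 + 0.02) - 0.02
  expect_lt(abs(mean(dN) - expected) / (sd(dN) / sqrt(n)), 3)
  expect_error(rescue_step(10, 11, p), "state")
})

test_that("zero-drift runs never count as rescued and conserve i <= N", {
  p <- rescue_params(50, q = 0, r = 0, f = 1, g = 1, i0 = 10,
                     max_steps = 2000)
  tr <- simulate_rescue(p, seed = 4)
  expect_true(tr$outcome %in% c("censored", "collapsed"))
  expect_true(all(tr$counts_a <= tr$pop_sizes))
  expect_lte(tr$bottleneck, 50)
  expect_length(tr$pop_sizes, tr$steps + 1)
})

test_that("a single-replicate ensemble reproduces the single trajectory", {
  p <- rescue_params(80, q = 0.1, r = 0.05, f = 2, reps = 1,
                     max_steps = 20000)
  tr <- simulate_rescue(p, seed = 7, record = FALSE)
  en <- run_rescue_ensemble(p, seed = 7)
  expect_identical(en$replicates$outcome, tr$outcome)
  expect_equal(en$replicates$bottleneck, tr$bottleneck)
  expect_equal(en$replicates$rescue_time, tr$rescue_time)
  expect_equal(en$replicates$peak_freq_a, tr$peak_freq_a)
})

test_that("without the variant the population collapses in about N0/r steps", {
  p <- rescue_params(100, q = 0, r = 0.05, i0 = 0, reps = 200)
  s <- run_rescue_ensemble(p, seed = 5)
  expect_true(all(s$replicates$outcome == "collapsed"))
  expect_true(is.na(s$mean_rescue_time))
  ratio <- s$mean_collapse_time / (100 / 0.05)
  expect_gt(ratio, 0.9)
  expect_lt(ratio, 1.1)
})

test_that("neutral variant count is a martingale under q = r = 0, f = g", {
  p <- rescue_params(100, q = 0, r = 0, f = 1, g = 1, i0 = 20,
                     reps = 2000, max_steps = 200)
  s <- run_rescue_ensemble(p, seed = 6, record_horizon = 200)
  i_final <- s$i_paths[, 201]
  se <- sd(i_final) / sqrt(length(i_final))
  expect_lt(abs(mean(i_final) - 20) / se, 3)
  # conservation across the whole recorded window
  expect_true(all(s$i_paths <= s$N_paths))
})

test_that("mean-field recursion has the right limits and turning point", {
  # no variant: linear decline N0 - r t, collapse around N0/r
  p0 <- rescue_params(200, q = 0.1, r = 0.004, i0 = 0)
  mf <- rescue_mean_field(p0, steps = 1000)
  expect_equal(mf$N, 200 - 0.004 * mf$t, tolerance = 1e-12)
  # fully adapted with q = 0: constant size
  p1 <- rescue_params(200, q = 0, r = 0.3, i0 = 200)
  mf1 <- rescue_mean_field(p1, steps = 500)
  expect_equal(mf1$N, rep(200, 501), tolerance = 1e-9)
  # decline-then-recovery: minimum where i/N crosses r/(q+r)
  p2 <- rescue_params(200, q = 0.005, r = 0.003, f = 1, g = 1)
  mf2 <- rescue_mean_field(p2, steps = 120000)
  imin <- which.min(mf2$N)
  expect_lt(mf2$N[imin], 200)
  expect_gt(mf2$N[nrow(mf2)], 200)
  expect_equal(mf2$i[imin] / mf2$N[imin], 0.003 / (0.005 + 0.003),
               tolerance = 0.01)
})

test_that("rescue domains classify the canonical cases", {
  tpl <- rescue_params(300, q = 0, r = 0.05, f = 1, reps = 300)
  expect_identical(classify_rescue_domain(0, 1, tpl, seed = 1)$domain, "iii")
  expect_identical(classify_rescue_domain(0.6, 1, tpl, seed = 2)$domain, "iv")
  expect_identical(classify_rescue_domain(0.15, 3, tpl, seed = 3)$domain, "i")
})
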