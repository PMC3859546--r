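test_that("observed mismatch histograms match hand cases and theta_pi", {
  same <- setNames(rep("ACGTAC", 4), paste0("s", 1:4))
  ob <- observed_mismatch(same)
  expect_equal(ob$freq, 1)           # all mass at j = 0
  expect_equal(ob$mean, 0)

  pair <- c(a = "AAAAAA", b = "TTTAAA")
  ob <- observed_mismatch(pair)
  expect_equal(ob$freq, c(0, 0, 0, 1))
  expect_equal(ob$mean, 3)

  ## mean mismatch == mean pairwise differences (exact identity)
  seqs <- gen_coalescent(15, L = 300, theta0 = 6, seed = 23)
  ob <- observed_mismatch(seqs)
  expect_equal(ob$mean, fus_fs(seqs, p_value = FALSE)$theta_pi,
               tolerance = 1e-10)
  expect_equal(sum(ob$freq), 1, tolerance = 1e-12)
  expect_error(observed_mismatch(pair[1]), "n >= 2")
})

test_that("expected mismatch reduces to the geometric equilibrium in both limits", {
  fhat <- function(theta, j) theta^j / (1 + theta)^(j + 1)
  j <- 0:40
  ## at tau = 0 the pre-expansion equilibrium (theta0) is still in force
  e0 <- expected_mismatch(0, 1, 100, 40)
  expect_equal(e0, fhat(1, j) / sum(fhat(1, j)), tolerance = 1e-10)
  ## theta0 = theta1: no size change, equilibrium at any tau
  for (tau in c(0, 2, 9)) {
    ee <- expected_mismatch(tau, 3, 3, 40)
    expect_equal(ee, fhat(3, j) / sum(fhat(3, j)), tolerance = 1e-10)
  }
  ## large tau converges to the post-expansion equilibrium (theta1)
  el <- expected_mismatch(60, 1, 8, 60)
  expect_equal(el, fhat(8, 0:60) / sum(fhat(8, 0:60)), tolerance = 1e-3)
  expect_error(expected_mismatch(NA, 1, 1, 10), "non-finite")
})

test_that("expected mismatch sums to one over a parameter grid", {
  for (tau in c(0, 1, 4, 20)) for (t0 in c(0.1, 1, 5))
    for (t1 in c(5, 100, 1000)) {
      f <- expected_mismatch(tau, t0, t1, 80)
      expect_equal(sum(f), 1, tolerance = 1e-9)
      expect_true(all(f >= 0))
    }
})

test_that("the transient solution matches the coalescent simulator (TV oracle)", {
  ## guards against mis-transcribing the sudden-expansion formula
  set.seed(29)
  hist <- numeric(200)
  for (r in 1:2000) {
    M <- ovismthap:::sim_coal_M(50, theta0 = 1, theta1 = 100, tau = 4,
                                model = "sudden_expansion")
    d <- ovismthap:::M_pairwise(M)
    hist <- hist + tabulate(d[upper.tri(d)] + 1L, nbins = 200)
  }
  emp <- hist / sum(hist)
  theo <- expected_mismatch(4, 1, 100, 199)
  expect_lt(0.5 * sum(abs(emp - theo)), 0.03)
})

test_that("fitting recovers parameters from a model-exact distribution", {
  obs <- expected_mismatch(4, 1, 100, 40)
  fit <- fit_expansion(obs)
  expect_lt(fit$ssd, 1e-8)
  expect_lt(abs(fit$tau - 4), 0.05)
  expect_true(fit$theta0 <= fit$theta1)
})

test_that("degenerate input hits the tau = 0 boundary with a warning", {
  same <- setNames(rep("ACGTACGT", 5), paste0("s", 1:5))
  expect_warning(fit <- fit_expansion(observed_mismatch(same)),
                 "degenerate")
  expect_equal(fit$tau, 0)
})

test_that("tau is recovered from single expansion replicates", {
  ## band established from pilot oracle runs: tau-hat in [1, 8] for >= 90%
  set.seed(83)
  taus <- vapply(1:100, function(i) {
    M <- ovismthap:::sim_coal_M(50, theta0 = 1, theta1 = 100, tau = 4,
                                model = "sudden_expansion")
    obs <- ovismthap:::mismatch_from_d(ovismthap:::M_pairwise(M))
    suppressWarnings(fit_expansion(obs))$tau
  }, numeric(1))
  expect_gte(mean(taus >= 1 & taus <= 8), 0.90)
})

test_that("the seeded SSD test is bit-reproducible and bounded", {
  seqs <- gen_coalescent(25, L = 2000, theta0 = 1, theta1 = 60, tau = 4,
                         model = "sudden_expansion", seed = 31)
  obs <- observed_mismatch(seqs)
  fit <- fit_expansion(obs)
  t1 <- ssd_test(25, fit, n_boot = 100, seed = 7)
  t2 <- ssd_test(25, fit, n_boot = 100, seed = 7)
  expect_identical(t1$p_ssd, t2$p_ssd)
  expect_gte(t1$p_ssd, 0)
  expect_lte(t1$p_ssd, 1)
  expect_error(ssd_test(25, fit, n_boot = 50, seed = 1), "unstable")
})

test_that("constant-size data are rejected more often than the calibrated rate", {
  ## directional power check: ragged equilibrium mismatch vs the smooth
  ## expansion wave
  ps <- vapply(1:25, function(i) {
    old <- ovismthap:::.int_seed(900 + i)
    M <- ovismthap:::sim_coal_M(40, theta0 = 15)
    ovismthap:::.restore_seed(old)
    obs <- ovismthap:::mismatch_from_d(ovismthap:::M_pairwise(M))
    fit <- suppressWarnings(fit_expansion(obs))
    ssd_test(40, fit, n_boot = 100, seed = 300 + i)$p_ssd
  }, numeric(1))
  expect_gt(mean(ps < 0.05), 0.05)
})
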