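test_that("generators are pure functions of parameters and seed", {
  p1 <- gen_haplogroup_panel(n = 20, seed = 5)
  p2 <- gen_haplogroup_panel(n = 20, seed = 5)
  expect_identical(p1, p2)

  c1 <- gen_coalescent(10, L = 300, theta0 = 3, seed = 9)
  c2 <- gen_coalescent(10, L = 300, theta0 = 3, seed = 9)
  expect_identical(c1, c2)

  s1 <- gen_spatial_panel(n_flocks = 5, flock_size = 4, seed = 2)
  s2 <- gen_spatial_panel(n_flocks = 5, flock_size = 4, seed = 2)
  expect_identical(s1, s2)

  ## and the RNG state of the caller is left untouched
  set.seed(123); before <- .Random.seed
  invisible(gen_coalescent(5, theta0 = 2, seed = 77))
  expect_identical(.Random.seed, before)
})

test_that("panel sequences carry their spec's diagnostic bases and repeat lengths", {
  specs <- default_haplogroup_specs()
  panel <- gen_haplogroup_panel(specs["C"], n = 8, private_mut_rate = 1,
                                seed = 12)
  ref <- panel$ref
  for (id in names(panel$seqs)) {
    map <- anchor_to_reference(panel$seqs[[id]], ref$seq,
                               ref_start = ref$ref_start)
    pr <- suppressWarnings(parse_repeats(panel$seqs[[id]], map))
    expect_equal(pr$unit_lengths[1], 75)
    expect_true(all(pr$unit_lengths[-1] == 76))  # HPG C: 76 bp cluster
    expect_true(pr$n_units >= 3 && pr$n_units <= 5)
  }
})

test_that("duplicate diagnostic signatures are rejected", {
  specs <- default_haplogroup_specs()
  specs$Z <- specs$A
  specs$Z$name <- "Z"
  expect_error(gen_haplogroup_panel(specs, n = 5, seed = 1),
               "identical diagnostic signature")
})

test_that("coalescent sample matches closed-form coalescent moments", {
  ## E(pi) = theta; E(S/a1) = theta; Var(S) = a1 theta + a2 theta^2
  n <- 50; theta <- 5; reps <- 1500
  set.seed(404)
  pis <- numeric(reps); Ss <- numeric(reps)
  for (r in seq_len(reps)) {
    M <- ovismthap:::sim_coal_M(n, theta)
    pis[r] <- ovismthap:::M_theta_pi(M)
    Ss[r] <- nrow(M)
  }
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  se_pi <- sd(pis) / sqrt(reps)
  expect_lt(abs(mean(pis) - theta), 3 * se_pi)
  se_w <- sd(Ss / a1) / sqrt(reps)
  expect_lt(abs(mean(Ss) / a1 - theta), 3 * se_w)
  expect_lt(abs(var(Ss) - (a1 * theta + a2 * theta^2)),
            0.15 * (a1 * theta + a2 * theta^2))
})

test_that("coalescent sequences respect L and infinite sites", {
  seqs <- gen_coalescent(12, L = 400, theta0 = 4, seed = 6)
  expect_true(all(nchar(seqs) == 400))
  M <- attr(seqs, "M")
  mat <- do.call(rbind, strsplit(unname(seqs), ""))
  poly <- sum(apply(mat, 2, function(col) length(unique(col)) > 1))
  ## infinite sites: every mutation hits its own column, none with > 2 states
  expect_equal(poly, nrow(M))
  expect_true(all(apply(mat, 2, function(col) length(unique(col))) <= 2))
  expect_error(gen_coalescent(30, L = 2, theta0 = 50, seed = 1),
               "increase L")
})

test_that("flat cline gives location-independent haplogroup frequencies", {
  ## chi-square of haplogroup x west/east half, 100 seeds, alpha = 0.01
  pvals <- vapply(1:100, function(i) {
    pan <- gen_spatial_panel(n_flocks = 10, flock_size = 10,
                             cline = list(haplogroup = "B", delta = 0),
                             seed = 800 + i)
    half <- pan$meta$x_km > 750
    suppressWarnings(chisq.test(table(pan$meta$hpg, half))$p.value)
  }, numeric(1))
  expect_gte(mean(pvals >= 0.01), 0.95)
})

test_that("strong cline produces detectable short-range autocorrelation", {
  pan <- gen_spatial_panel(n_flocks = 15, flock_size = 12,
                           cline = list(haplogroup = "B", delta = 0.7),
                           seed = 3)
  d2 <- genetic_distance_matrix(pan$meta$hpg)
  kept <- attr(d2, "kept")
  ac <- autocorrelogram(d2, as.matrix(pan$meta[kept, c("x_km", "y_km")]),
                        metric = "planar", n_perm = 199, n_boot = 100,
                        seed = 4)
  expect_gt(ac$r[1], ac$belt_hi[1])
})

test_that("spatial panel rejects degenerate extents", {
  expect_error(gen_spatial_panel(n_flocks = 3, extent_km = 0, seed = 1),
               "degenerate extent")
})
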