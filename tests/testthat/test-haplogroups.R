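test_that("diagnostic signatures call the published haplogroups", {
  tab <- default_diagnostic_table()
  mk <- function(...) {
    obs <- c(`15459` = ".", `15476` = ".", `15484` = ".", `15509` = ".",
             `15512` = ".")
    v <- c(...)
    obs[names(v)] <- v
    obs
  }
  expect_equal(ovismthap:::match_haplogroup(
    mk(`15459` = "T", `15484` = "A"), tab)$haplogroup, "A")
  expect_equal(ovismthap:::match_haplogroup(mk(), tab)$haplogroup, "B")
  expect_equal(ovismthap:::match_haplogroup(
    mk(`15509` = "G"), tab)$haplogroup, "C")
  expect_equal(ovismthap:::match_haplogroup(
    mk(`15476` = "C", `15509` = "G"), tab)$haplogroup, "E")
  ## a signature matching no rule falls to unassigned, never nearest-match
  expect_equal(ovismthap:::match_haplogroup(
    mk(`15459` = "G"), tab)$haplogroup, "unassigned")
  ## partial possession of a signature is not a match
  expect_equal(ovismthap:::match_haplogroup(
    mk(`15459` = "T"), tab)$haplogroup, "unassigned")
  ## unreadable sites beyond max_missing -> unassigned with n_missing set
  obs <- mk(); obs["15509"] <- NA
  m <- ovismthap:::match_haplogroup(obs, tab, max_missing = 0)
  expect_equal(m$haplogroup, "unassigned")
  expect_equal(m$n_missing, 1)
})

test_that("classification of the ancient genotype table reproduces every published call", {
  g <- oylum_genotypes()
  expect_equal(nrow(g), 33)
  calls <- classify_genotypes(g)
  expect_identical(calls$haplogroup, g$published_hpg)
  tab <- table(calls$haplogroup)
  expect_equal(as.integer(tab[c("A", "B", "C", "E")]), c(16, 14, 2, 1))
})

test_that("era-stratified counts match the published strata", {
  g <- oylum_genotypes()
  calls <- classify_genotypes(g)
  strat <- era_stratum(g$date_from_bce, g$date_to_bce)
  expect_equal(sum(is.na(strat)), 1)   # the 330-30 BCE sample joins neither
  ft <- frequency_table(calls, strat)
  getn <- function(s, h) ft$count[ft$stratum == s & ft$haplogroup == h]
  expect_equal(getn("1800-1200 BCE", "A"), 8)
  expect_equal(getn("1200-330 BCE", "A"), 8)
  expect_equal(getn("1800-1200 BCE", "B"), 7)
  expect_equal(getn("1200-330 BCE", "B"), 6)
  expect_equal(getn("1800-1200 BCE", "C"), 1)
  expect_equal(getn("1200-330 BCE", "C"), 1)
  expect_equal(sum(ft$count[ft$stratum == "1800-1200 BCE"]), 16)
  expect_equal(sum(ft$count[ft$stratum == "1200-330 BCE"]), 16)
})

test_that("frequency_table percentages behave", {
  calls <- data.frame(id = "x", haplogroup = "A")
  ft <- frequency_table(calls)
  expect_equal(ft$pct, 100)
  expect_error(frequency_table(calls[0, ]), "no calls")
  g <- oylum_genotypes()
  ft <- frequency_table(classify_genotypes(g))
  expect_equal(sum(ft$pct), 100, tolerance = 1e-9)
  expect_equal(sum(ft$count), 33)
})

test_that("classifier round-trips synthetic panels perfectly", {
  for (seed in c(11, 12)) {
    panel <- gen_haplogroup_panel(n = 60, private_mut_rate = 2, seed = seed)
    calls <- classify_panel(panel$seqs, panel$ref$seq,
                            ref_start = panel$ref$ref_start)
    expect_identical(calls$haplogroup, panel$meta$true_hpg)
  }
})

test_that("diagnostic_table rejects duplicated signatures and sorts positions", {
  expect_error(diagnostic_table(list(A = c(`15509` = "G"),
                                     C = c(`15509` = "G"))),
               "identical signature")
  tab <- diagnostic_table(list(A = c(`15484` = "A", `15459` = "T")))
  expect_identical(names(tab$rules$A), c("15459", "15484"))
})

test_that("repeat parsing resolves unit number, lengths and cluster", {
  ref <- synthetic_reference()
  panelA <- gen_haplogroup_panel(default_haplogroup_specs()["A"], n = 6,
                                 private_mut_rate = 1, seed = 21)
  for (id in names(panelA$seqs)) {
    map <- anchor_to_reference(panelA$seqs[[id]], ref$seq,
                               ref_start = ref$ref_start)
    pr <- suppressWarnings(parse_repeats(panelA$seqs[[id]], map))
    expect_true(all(pr$unit_lengths == 75))
    expect_equal(pr$cluster, "i")
    expect_equal(pr$n_units, length(pr$unit_lengths))
  }
  ## a 5-unit 76 bp array lands in cluster ii
  unit75 <- ref$repeat_unit
  unit76 <- paste0(substr(unit75, 1, 37), "T", substr(unit75, 38, 75))
  syn <- paste0(strrep("ACGT", 20), unit75, strrep(unit76, 4),
                strrep("TTAC", 20))
  pr <- parse_repeats(syn, start_col = 81)
  expect_equal(pr$n_units, 5)
  expect_identical(pr$unit_lengths, c(75L, 76L, 76L, 76L, 76L))
  expect_equal(pr$cluster, "ii")
})

test_that("sequences without a repeat array are reported, not guessed", {
  set.seed(99)
  plain <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                 collapse = "")
  expect_error(parse_repeats(plain, start_col = 100),
               "repeat region not found")
})

test_that("repeat cluster is consistent with haplogroup cluster membership", {
  panel <- gen_haplogroup_panel(n = 40, private_mut_rate = 1, seed = 33)
  ref <- panel$ref
  for (i in seq_along(panel$seqs)) {
    map <- anchor_to_reference(panel$seqs[[i]], ref$seq,
                               ref_start = ref$ref_start)
    pr <- suppressWarnings(parse_repeats(panel$seqs[[i]], map))
    expected <- if (panel$meta$true_hpg[i] %in% c("A", "B", "D")) "i" else "ii"
    expect_equal(pr$cluster, expected)
  }
})
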