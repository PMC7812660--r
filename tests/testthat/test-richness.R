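test_that("frequency tallies count singletons and doubletons exactly", {
  fr <- tally_frequencies(c("a", "a", "b", "c"))
  expect_equal(unname(fr$counts[c("a", "b", "c")]), c(2L, 1L, 1L))
  expect_equal(fr$S_obs, 3L)
  expect_equal(fr$f1, 2L)
  expect_equal(fr$f2, 1L)
  empty <- tally_frequencies(character(0))
  expect_equal(empty$S_obs, 0L)
  expect_equal(empty$f1 + empty$f2, 0L)
})

test_that("tallies on simulated data match an independent recount", {
  pool <- sample_species_pool(S = 50, seed = 11)
  rec <- simulate_survey(pool, survey_design(), seed = 12)
  fr <- tally_frequencies(rec)
  # brute-force recount by looping species by species
  for (sp in sample(names(fr$counts), 10)) {
    expect_equal(unname(fr$counts[sp]), sum(rec$species_id == sp))
  }
  oracle <- vapply(split(rec$species_id, rec$species_id), length,
                   integer(1))
  expect_equal(fr$f1, sum(oracle == 1))
  expect_equal(fr$f2, sum(oracle == 2))
})

test_that("Chao1 reproduces hand-computed estimates", {
  expect_equal(chao1(221, 17, 6), 221 + 17^2 / 12, tolerance = 1e-12)
  expect_equal(round(chao1(221, 17, 6), 2), 245.08)
  expect_equal(chao1(10, 4, 2), 14)
  expect_equal(chao1(50, 0, 3), 50)       # no singletons add nothing
  expect_equal(chao1(10, 4, 0), 10 + 4 * 3 / 2)  # f2 = 0 fallback
  expect_equal(chao1(221, 17, 6, "bias_corrected"),
               221 + 17 * 16 / (2 * 7), tolerance = 1e-12)
  expect_error(chao1(-1, 0, 0), "non-negative")
  expect_error(chao1(3, 2, 2), "exceed")
})

test_that("Chao1 agrees with an independent implementation", {
  set.seed(21)
  counts <- c(rpois(40, 3) + 1, rep(1, 6), rep(2, 3))
  comm <- matrix(counts, nrow = 1)
  ref <- vegan::estimateR(comm)["S.chao1", 1]
  fr <- tally_frequencies(rep(paste0("s", seq_along(counts)), counts))
  expect_equal(chao1(fr$S_obs, fr$f1, fr$f2, "bias_corrected"),
               unname(ref), tolerance = 1e-8)
})

test_that("Chao1 is monotone in singletons and doubletons", {
  for (f1 in 0:10) for (f2 in 1:5) {
    s <- 20
    expect_gte(chao1(s, min(f1 + 1, s - f2), f2), chao1(s, f1, f2))
    expect_lte(chao1(s, f1, f2 + 1), chao1(s, f1, f2))
  }
})

test_that("ledger application reconciles, conserves and reports", {
  base <- paste0("sp", 1:20)
  led <- data.frame(
    name = c("sp1", "sp2", "sp3", "novel"),
    action = c("merge_into", "exclude_unsupported",
               "exclude_misidentified", "add_new"),
    target = c("sp4", "", "", ""),
    stringsAsFactors = FALSE)
  res <- apply_ledger(base, led)
  expect_length(res$accepted, 20 - 3 + 1)
  expect_false(any(c("sp1", "sp2", "sp3") %in% res$accepted))
  expect_true("novel" %in% res$accepted)
  expect_true(all(res$report$applied))
  # identity and error contracts
  expect_equal(apply_ledger(base, NULL)$accepted, sort(base))
  expect_error(apply_ledger(base, data.frame(name = "sp1",
                                             action = "add_new")),
               "existing")
  expect_error(apply_ledger(base, data.frame(name = "ghost",
                                             action = "merge_into",
                                             target = "sp1")),
               "unknown")
  expect_error(apply_ledger(base, data.frame(name = "sp1",
                                             action = "merge_into",
                                             target = "ghost")),
               "merge target")  # targets must exist among accepted names
})

test_that("re-applying an applied ledger changes nothing (non-strict)", {
  base <- paste0("sp", 1:15)
  led <- data.frame(name = c("sp1", "sp2", "new1"),
                    action = c("merge_into", "exclude_misidentified",
                               "add_new"),
                    target = c("sp3", "", ""), stringsAsFactors = FALSE)
  once <- apply_ledger(base, led)
  twice <- apply_ledger(once$accepted, led, strict = FALSE)
  expect_equal(twice$accepted, once$accepted)
})

test_that("the regional-extinction rule uses a strict 50-year gap", {
  last <- c(a = 1965, b = 1975, c = 1969)
  flagged <- flag_regionally_extinct(last, current_year = 2019)
  expect_equal(flagged, "a")       # gap 54 flagged
  expect_false("b" %in% flagged)   # gap 44
  expect_false("c" %in% flagged)   # gap exactly 50: not flagged
  # larger horizons never flag more species
  for (h in c(10, 30, 50, 80)) {
    f1 <- flag_regionally_extinct(last, 2019, h)
    f2 <- flag_regionally_extinct(last, 2019, h + 10)
    expect_true(all(f2 %in% f1))
  }
})

test_that("species with no record after the cutoff are found", {
  rec <- make_records(c("a", "a", "b"), year = c(1990, 2010, 1990))
  expect_equal(records_since(rec, 2004), "b")
  pool <- sample_species_pool(S = 40, seed = 13)
  sim <- simulate_survey(pool, survey_design(years = 1995:2019), seed = 14)
  got <- records_since(sim, 2004)
  oracle <- sort(names(which(
    vapply(split(sim$year, sim$species_id), max, numeric(1)) <= 2004)))
  expect_equal(got, oracle)
})

test_that("turnover percentages follow the symmetric formula", {
  old <- paste0("s", 1:200)
  new <- c(setdiff(old, paste0("s", 1:4)), paste0("g", 1:4))
  tr <- turnover(old, new)
  expect_equal(tr$turnover_pct, 2.0)
  expect_length(intersect(tr$losses, tr$gains), 0)
  expect_equal(turnover(old, old)$turnover_pct, 0)
  old2 <- paste0("s", 1:221)
  new2 <- c(setdiff(old2, paste0("s", 1:10)), paste0("g", 1:10))
  tr2 <- turnover(old2, new2)
  expect_equal(tr2$turnover_pct, 100 * 20 / (2 * 221), tolerance = 1e-12)
  expect_gte(tr2$turnover_pct, 3); expect_lte(tr2$turnover_pct, 5)
})
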