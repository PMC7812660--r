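test_that("association tables count exactly and keep totals of all records", {
  rec <- make_records(c("sp1", "sp1", "sp1", "sp1", "sp2"),
                      host = c("Picea abies", "Picea abies", "Picea abies",
                               "Betula spp.", NA))
  tab <- build_association_table(rec, "host_taxon")
  expect_equal(tab$counts["sp1", "Picea abies"], 3L)
  expect_equal(tab$counts["sp1", "Betula spp."], 1L)
  # the record with missing host stays in the species total only
  expect_equal(unname(tab$species_totals["sp2"]), 1L)
  expect_equal(sum(tab$counts["sp2", ]), 0L)
  expect_equal(tab$n_missing_axis, 1L)
  expect_equal(colnames(tab$counts), sort(colnames(tab$counts)))
  expect_error(build_association_table(make_records("a"), "host_taxon"),
               "missing from every record")
})

test_that("association tables on simulated data match a group-by oracle", {
  pool <- sample_species_pool(S = 40, seed = 15)
  rec <- simulate_survey(pool, survey_design(), seed = 16)
  tab <- build_association_table(rec, "substrate_fraction")
  oracle <- with(rec[!is.na(rec$substrate_fraction), ],
                 tapply(species_id, list(species_id, substrate_fraction),
                        length))
  oracle[is.na(oracle)] <- 0
  common <- rownames(oracle)
  expect_equal(unname(tab$counts[common, colnames(oracle)]),
               unname(oracle))
  # per-category species counts equal species with at least one record
  expect_equal(unname(colSums(tab$counts > 0)),
               vapply(colnames(tab$counts), function(cat)
                 length(unique(rec$species_id[
                   !is.na(rec$substrate_fraction) &
                     rec$substrate_fraction == cat])), integer(1),
                 USE.NAMES = FALSE))
})

test_that("the regular rules evaluate as an OR with reporting precedence", {
  r <- classify_regular(10, 100, 5000)
  expect_true(r$regular); expect_equal(r$rule, "a_share5_total40")
  r <- classify_regular(2, 30, 5000)
  expect_true(r$regular); expect_equal(r$rule, "b_gt1_total_lt40")
  # 1.5% of the species' records but 7.5% of the category: rule c only
  r <- classify_regular(3, 200, 40)
  expect_true(r$regular); expect_equal(r$rule, "c_cat_share5")
  r <- classify_regular(1, 100, 5000)
  expect_false(r$regular); expect_equal(r$rule, "none")
  # an empty category skips rule c without erroring
  expect_false(classify_regular(0, 50, 0)$regular)
})

test_that("the specialist rules require concentration or completeness", {
  expect_true(classify_specialist(5, 5, TRUE))    # all records, total 3-9
  expect_true(classify_specialist(36, 40, TRUE))  # exactly 90%
  expect_false(classify_specialist(2, 2, TRUE))   # needs > 2 records
  expect_false(classify_specialist(35, 40, TRUE)) # 87.5% and total > 9
  # total 9 with 8 records (88.9%) fails both clauses by design
  expect_false(classify_specialist(8, 9, TRUE))
  expect_false(classify_specialist(10, 10, FALSE)) # never without regular
})

test_that("scaling all counts by 10 changes only rule-b outcomes", {
  grid <- expand.grid(n_cat = 0:30, n_total = 0:30)
  grid <- grid[grid$n_cat <= grid$n_total & grid$n_total > 0, ]
  base <- classify_regular(grid$n_cat, grid$n_total, 500)
  scaled <- classify_regular(grid$n_cat * 10, grid$n_total * 10, 5000)
  changed <- base$regular != scaled$regular
  # rules a and c are ratio-based; only the small-total regime that rule b
  # (and the 40-record gate of rule a) governs can flip under scaling
  expect_true(all(grid$n_total[changed] < 40))
  # shares are unchanged, so rule a decisions agree where totals allow
  both_a_scale <- grid$n_total >= 40
  expect_equal(base$regular[both_a_scale], scaled$regular[both_a_scale])
})

test_that("host ranges are summarised for species recorded more than 10 times", {
  rec <- rbind(
    make_records(rep("wide", 12),
                 host = rep(c("Picea abies", "Pinus sylvestris",
                              "Betula spp.", "Populus tremula",
                              "Quercus robur", "Salix spp.",
                              "Alnus incana", "Tilia cordata"),
                            length.out = 12)),
    make_records(rep("narrow", 15), host = "Picea abies"),
    make_records(rep("edge", 10), host = "Picea abies"))
  tab <- build_association_table(rec, "host_taxon")
  hr <- host_range_summary(tab)
  expect_equal(hr$host_class[hr$species_id == "narrow"], "1-2")
  expect_equal(hr$host_class[hr$species_id == "wide"], ">=8")
  # exactly 10 records: excluded by the strict threshold
  expect_false("edge" %in% hr$species_id)
})

test_that("regular host-species pairs feed the similarity matrix", {
  rec <- make_records(
    rep(c("s1", "s2"), times = c(100, 10)),
    host = c(rep("h1", 6), rep("h2", 94), rep("h1", 1), rep("h2", 9)))
  tab <- build_association_table(rec, "host_taxon")
  pa <- host_similarity_input(tab)
  expect_equal(pa["s1", "h1"], 1L)  # 6% of the species' records
  expect_equal(pa["s2", "h1"], 1L)  # 1 of 7 host records is over 5%
  # 1 record of 100 for the species and under 5% of a large host: out
  rec2 <- make_records(rep(c("s1", "s2"), times = c(100, 100)),
                       host = c(rep("h1", 1), rep("h2", 99),
                                rep("h1", 100)))
  pa2 <- host_similarity_input(build_association_table(rec2, "host_taxon"))
  expect_equal(pa2["s1", "h1"], 0L)
})

test_that("host clustering needs 3 informative hosts and drops empty ones", {
  pa <- matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 1, 0, 0, 0), 3, 4,
               dimnames = list(paste0("s", 1:3), paste0("h", 1:4)))
  expect_warning(dend <- cluster_hosts(pa), "no present species")
  expect_length(dend$labels, 3)
  # two hosts with identical species sets merge at height 0
  expect_equal(min(dend$merges$height), 0)
  first <- dend$merges[1, ]  # leaves carry negative indices in hclust merges
  expect_setequal(dend$labels[c(-first$left, -first$right)], c("h1", "h2"))
  expect_error(cluster_hosts(pa[, 1:2]), "at least 3")
})
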