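test_that("a single-histone proteome reproduces the closed-form copy number", {
  # copies = ploidy * 3.25 pg * N_A / MW = 6.5e-12 * 6.022e23 / 14000 ~ 2.80e8
  x <- matrix(c(2e6, 5e6), 1, 2, dimnames = list("h1", NULL))
  pm <- proteome_matrix(x, mol_mass = 14000, col_stage = c("A", "B"),
                        col_replicate = c(1L, 1L))
  res <- estimate_copy_numbers(pm, "h1", ruler_settings(ploidy = 2))
  expect_equal(unname(res$copies["h1", ]), rep(2.796e8, 2), tolerance = 1e-3)
  # intensity cancels entirely: both samples give identical copies
  expect_equal(res$copies[1, 1], res$copies[1, 2])
})

test_that("copies are invariant under per-sample intensity rescaling", {
  sim <- generate_proteome(synth_config(n_proteins = 250, seed = 73))
  pm <- filter_completeness(sim$matrix, 1, 1L)
  res <- estimate_copy_numbers(pm, intersect(sim$truth$histone_ids,
                                             rownames(pm$intensity)))
  pm_scaled <- pm
  pm_scaled$intensity <- sweep(pm$intensity, 2,
                               seq(0.5, 4, length.out = ncol(pm$intensity)),
                               "*")
  res_scaled <- estimate_copy_numbers(pm_scaled,
                                      intersect(sim$truth$histone_ids,
                                                rownames(pm$intensity)))
  expect_equal(res$copies, res_scaled$copies, tolerance = 1e-12)
})

test_that("planted copy numbers round-trip through the ruler within 1%", {
  # histone content constant across stages: the ruler premise holds exactly
  cfg <- synth_config(n_proteins = 300, noise_cv = 0, dropout_midpoint = NA,
                      histone_decline = 1, seed = 79)
  sim <- generate_proteome(cfg)
  res <- estimate_copy_numbers(sim$matrix, sim$truth$histone_ids)
  truth_cols <- sim$truth$copies[, sim$matrix$col_stage]
  rel_err <- abs(res$copies / truth_cols - 1)
  expect_lt(max(rel_err), 0.01)
})

test_that("total mass scales with ploidy and volume times concentration is mass", {
  sim <- generate_proteome(synth_config(n_proteins = 200, seed = 83))
  pm <- filter_completeness(sim$matrix, 1, 1L)
  hist <- intersect(sim$truth$histone_ids, rownames(pm$intensity))
  r2 <- estimate_copy_numbers(pm, hist, ruler_settings(ploidy = 2))
  r4 <- estimate_copy_numbers(pm, hist, ruler_settings(ploidy = 4))
  expect_equal(r4$total_mass_pg, 2 * r2$total_mass_pg, tolerance = 1e-12)
  expect_equal(r2$cell_volume_fl * 200 * 1e-3, r2$total_mass_pg,
               tolerance = 1e-12)
  # total mass recomputes from copies x MW / N_A
  mw <- pm$mol_mass[rownames(r2$copies)]
  expect_equal(unname(colSums(r2$copies * mw, na.rm = TRUE) / 6.02214076e23 *
                        1e12),
               unname(r2$total_mass_pg), tolerance = 1e-6)
})

test_that("ruler input contracts are enforced", {
  x <- matrix(c(1e6, 2e6), 1, 2, dimnames = list("p1", NULL))
  pm <- proteome_matrix(x, 30000, c("A", "B"), c(1L, 1L))
  expect_error(estimate_copy_numbers(pm, character(0)), "non-empty")
  expect_error(estimate_copy_numbers(pm, "ghost"), "absent")
  expect_error(ruler_settings(ploidy = 0), "ploidy")
  expect_error(ruler_settings(total_protein_concentration = -1),
               "concentration")
})

test_that("copy-number summaries behave like order statistics", {
  sim <- generate_proteome(synth_config(n_proteins = 300, seed = 89))
  pm <- filter_completeness(sim$matrix, 1, 1L)
  hist <- intersect(sim$truth$histone_ids, rownames(pm$intensity))
  res <- estimate_copy_numbers(pm, hist)
  ids <- rownames(res$copies)
  # single-protein set: summary equals that protein's own values
  solo <- ids[rowSums(is.na(res$copies)) == 0][1]
  one <- summarize_copies(res, list(solo = solo))
  first_stage_cols <- which(res$col_stage == res$stages[1])
  expect_equal(one$median_copies[one$stage == res$stages[1]],
               mean(res$copies[solo, first_stage_cols]))
  # a partition's overall median lies between the two set medians
  half <- list(a = ids[seq_len(150)], b = ids[-seq_len(150)],
               all = ids)
  s <- summarize_copies(res, half)
  for (st in res$stages) {
    rows <- s[s$stage == st, ]
    expect_gte(rows$median_copies[rows$set == "all"],
               min(rows$median_copies[rows$set %in% c("a", "b")]))
    expect_lte(rows$median_copies[rows$set == "all"],
               max(rows$median_copies[rows$set %in% c("a", "b")]))
  }
  expect_warning(summarize_copies(res, list(empty = "nope")), "no proteins")
})

test_that("histone ground truth declines across stages as generated", {
  sim <- generate_proteome(synth_config(n_proteins = 300,
                                        histone_decline = 0.85, seed = 97))
  hist_copies <- sim$truth$copies[sim$truth$histone_ids, ]
  expect_true(all(diff(apply(hist_copies, 2, median)) < 0))
  # ruler output, by construction, renormalizes each sample to the DNA
  # anchor, so estimated histone totals stay ~flat even when true histone
  # content declines: the decline must be read from the ground truth
  pm <- filter_completeness(sim$matrix, 1, 1L)
  hist <- intersect(sim$truth$histone_ids, rownames(pm$intensity))
  res <- estimate_copy_numbers(pm, hist)
  est_total_mass <- colSums(res$copies[hist, , drop = FALSE] *
                              pm$mol_mass[hist], na.rm = TRUE)
  expect_lt(stats::sd(est_total_mass) / mean(est_total_mass), 0.05)
})
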