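# observation-count toy from first principles: 3 proteins, 2 stages x 4 reps,
# observed replicate counts {4,0}, {3,4}, {2,2}
.toy_completeness <- function() {
  x <- matrix(1000, 3, 8)
  x[1, 5:8] <- NA                 # p01: 4/4 in S1, 0/4 in S2
  x[2, 4] <- NA                   # p02: 3/4 in S1, 4/4 in S2
  x[3, c(1, 2, 5, 6)] <- NA       # p03: 2/4 in S1, 2/4 in S2
  toy_pm(x)
}

test_that("completeness filter keeps proteins complete in enough stages", {
  pm <- .toy_completeness()
  # 3-of-4 rule in >= 1 stage: p01 (4/4) and p02 (3/4 and 4/4) survive
  kept <- filter_completeness(pm, 0.75, 1L)
  expect_identical(rownames(kept$intensity), c("p01", "p02"))
  # 100% completeness in at least one stage: p01 and p02 both qualify
  kept_full <- filter_completeness(pm, 1, 1L)
  expect_identical(rownames(kept_full$intensity), c("p01", "p02"))
  # requiring two complete stages leaves only p02
  expect_identical(rownames(filter_completeness(pm, 0.75, 2L)$intensity), "p02")
  # a fully observed matrix is untouched by any threshold
  full <- toy_pm(matrix(seq(100, 1600, by = 100), 4, 4), n_stages = 2)
  expect_identical(filter_completeness(full, 1, 2L)$intensity, full$intensity)
  expect_error(filter_completeness(pm, 0), "min_fraction_per_stage")
})

test_that("imputed draws follow the downshifted column distribution", {
  # one column whose observed values have exactly mean 20, sd 2
  obs <- as.numeric(scale(seq_len(100))) * 2 + 20
  col <- c(obs, rep(NA_real_, 10000))
  m <- matrix(col, ncol = 1, dimnames = list(NULL, "s1"))
  out <- impute_missing(m, width = 0.3, downshift = 1.8, seed = 11)
  expect_false(anyNA(out))
  imp <- out[-seq_len(100), 1]
  expect_lt(abs(mean(imp) - (20 - 1.8 * 2)), 0.05)   # 16.4
  expect_lt(abs(sd(imp) - 0.3 * 2), 0.05)            # 0.6
  # observed cells untouched, reproducible under the seed
  expect_identical(out[seq_len(100), 1], obs)
  expect_identical(out, impute_missing(m, 0.3, 1.8, seed = 11))
  expect_false(identical(imp, impute_missing(m, 0.3, 1.8, seed = 12)[-(1:100), 1]))
})

test_that("imputation leaves complete matrices alone and rejects sd-less columns", {
  m <- matrix(rnorm(20, 20), 5, 4)
  expect_identical(impute_missing(m), m)
  bad <- matrix(c(20, NA, NA, NA), 4, 1)
  expect_error(impute_missing(bad), "fewer than 2 observed")
})

test_that("filtering then imputing never alters observed cells", {
  sim <- generate_proteome(synth_config(n_proteins = 500, seed = 21))
  f <- filter_completeness(sim$matrix)
  l2 <- log2_matrix(f)
  imp <- impute_missing(l2, seed = 3)
  obs <- !is.na(l2)
  expect_identical(imp[obs], l2[obs])
})

test_that("the stage F statistic matches hand and lm() computations", {
  # two stages reduce to the squared two-sample t: {1,2,3} vs {4,5,6} -> 13.5
  m <- matrix(c(1, 2, 3, 4, 5, 6), 1, 6)
  g <- rep(c("A", "B"), each = 3)
  expect_equal(erydecon:::.row_anova_f(m, g, s0 = 0)$f, 13.5)
  # dual route on random data: vectorized F vs stats::lm per protein at s0 = 0
  set.seed(31)
  x <- matrix(rnorm(40 * 12, sd = 1.3), 40, 12)
  g5 <- rep(c("a", "b", "c"), each = 4)
  f_vec <- erydecon:::.row_anova_f(x, g5, s0 = 0)$f
  f_lm <- apply(x, 1, function(row)
    anova(lm(row ~ factor(g5)))[1, "F value"])
  expect_equal(f_vec, f_lm, tolerance = 1e-10)
  # s0 damps but never increases the statistic
  f_s0 <- erydecon:::.row_anova_f(x, g5, s0 = 0.1)$f
  expect_true(all(f_s0 < f_vec))
})

test_that("degenerate zero-variance proteins get F = 0 and q = 1", {
  x <- rbind(rep(5, 8), rnorm(8, 5, 1) + rep(c(0, 3), each = 4))
  rownames(x) <- c("flat", "real")
  st <- suppressWarnings(anova_stage_test(x, rep(c("A", "B"), each = 4),
                                          n_permutations = 100L, s0 = 0))
  expect_equal(st$F[st$protein_id == "flat"], 0)
  expect_equal(st$q[st$protein_id == "flat"], 1)
  expect_lt(st$q[st$protein_id == "real"], st$q[st$protein_id == "flat"])
})

test_that("permutation q-values control the FDR under the global null", {
  set.seed(17)
  x <- matrix(rnorm(300 * 16), 300, 16,
              dimnames = list(sprintf("p%03d", 1:300), NULL))
  g <- rep(paste0("S", 1:4), each = 4)
  st <- anova_stage_test(x, g, n_permutations = 150L, s0 = 0.1, seed = 19)
  expect_true(all(st$q >= 0 & st$q <= 1))
  expect_lte(mean(st$q < 0.05), 0.06)   # null discoveries within MC error
  # q-values non-decreasing in p-value rank (step-up monotonicity)
  o <- order(st$F, decreasing = TRUE)
  expect_true(all(diff(st$q[o]) >= -1e-12))
  # null q-value behavior is stable under relabeling of the same null data
  st2 <- anova_stage_test(x, sample(g), n_permutations = 150L, s0 = 0.1,
                          seed = 19)
  expect_lte(mean(st2$q < 0.05), 0.06)
})

test_that("anova input contracts are enforced", {
  x <- matrix(rnorm(40), 5, 8)
  expect_error(anova_stage_test(x, rep("A", 8)), "at least 2 stages")
  x[1, 1] <- NA
  expect_error(anova_stage_test(x, rep(c("A", "B"), each = 4)), "missing values")
})

test_that("z-scored stage profiles have mean 0 and sd 1 per protein", {
  sim <- generate_proteome(synth_config(n_proteins = 300, seed = 23))
  f <- filter_completeness(sim$matrix)
  z <- stage_z_profiles(impute_missing(log2_matrix(f), seed = 1),
                        f$col_stage, f$stages)
  expect_equal(unname(rowMeans(z)), rep(0, nrow(z)), tolerance = 1e-9)
  expect_equal(unname(apply(z, 1, sd)), rep(1, nrow(z)), tolerance = 1e-9)
})

test_that("clustering recovers a planted archetype partition at zero noise", {
  cfg <- synth_config(n_proteins = 240, noise_cv = 0, dropout_midpoint = NA,
                      n_histones = 0, marker_spec = NULL, seed = 13)
  sim <- generate_proteome(cfg)
  z <- stage_z_profiles(log2_matrix(sim$matrix), sim$matrix$col_stage,
                        sim$matrix$stages)
  cl <- cluster_profiles(z, k = 6)
  # partition equality up to label permutation: 1:1 archetype/cluster table
  tab <- table(sim$truth$archetype, cl)
  expect_identical(sum(tab > 0), 6L)
  expect_true(all(colSums(tab > 0) == 1) && all(rowSums(tab > 0) == 1))
})

test_that("clustering edge cases behave as contracts say", {
  z <- matrix(rnorm(50), 10, 5, dimnames = list(letters[1:10], NULL))
  expect_identical(unname(cluster_profiles(z, k = 1)), rep(1L, 10))
  z2 <- rbind(z, dup = z["a", ])
  cl <- cluster_profiles(z2, k = 3)
  expect_identical(unname(cl["a"]), unname(cl["dup"]))  # zero distance
  expect_error(cluster_profiles(z[1:2, ], k = 6), "fewer proteins")
})
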