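test_that("signature entries average the designated replicates' linear intensities", {
  x <- matrix(1e5, 2, 8)
  x[1, ] <- c(100, 100, 300, 100,   500, 200, 700, 200)  # reps 1..4 per stage
  pm <- toy_pm(x)
  sig <- build_signature(pm, c("p01", "p02"), signature_replicates = c(2, 4))
  expect_equal(unname(sig["p01", ]), c(mean(c(100, 100)), mean(c(200, 200))))
  # replicate values 100 and 300 average to 200
  sig13 <- suppressWarnings(
    synthesize_mixtures(pm, matrix(c(1, 0), 1, 2), mixture_replicates = c(1, 3)))
  expect_equal(unname(sig13$stage_profile["p01", "S1"]), 200)
  # markers unobserved in every designated replicate of a stage are dropped
  x2 <- x
  x2[2, c(2, 4)] <- NA
  expect_warning(sig2 <- build_signature(toy_pm(x2), c("p01", "p02"),
                                         c(2, 4)),
                 "unobserved")
  expect_identical(rownames(sig2), "p01")
})

test_that("log-scale input is rejected when building signatures", {
  x <- matrix(runif(16, 10, 30), 2, 8)   # everything < 64: log-like
  expect_error(build_signature(toy_pm(x), c("p01", "p02")), "log-transformed")
  expect_error(build_signature(toy_pm(matrix(1e5, 2, 8)), character(0)),
               "empty")
})

test_that("random ratios live on the simplex and are exchangeable", {
  r <- generate_ratios(500, 5, seed = 1)
  expect_identical(dim(r), c(500L, 5L))
  expect_true(all(r >= 0))
  expect_lt(max(abs(rowSums(r) - 1)), 1e-12)
  expect_identical(r, generate_ratios(500, 5, seed = 1))
  # degenerate single-stage case is forced to 1
  expect_identical(generate_ratios(10, 1, seed = 1), matrix(1, 10, 1))
  # flat-Dirichlet symmetry: each coordinate has mean 1/5
  big <- generate_ratios(100000, 5, seed = 2)
  expect_lt(max(abs(colMeans(big) - 0.2)), 0.005)
})

test_that("mixtures are the ratio-weighted sums of stage profiles", {
  x <- matrix(0, 1, 8)
  x[1, ] <- c(10, 9999, 10, 9999,  30, 9999, 30, 9999)  # reps 2,4 unused
  pm <- toy_pm(x)
  # profile over 2 stages is (10, 30); a = (0.5, 0.5) -> 20
  ms <- synthesize_mixtures(pm, matrix(c(0.5, 0.5), 1, 2))
  expect_equal(unname(ms$intensity[1, 1]), 20)
  # one-hot ratio returns the pure stage profile
  one_hot <- synthesize_mixtures(pm, diag(2))
  expect_equal(unname(one_hot$intensity[1, ]), c(10, 30))
  # linearity: mixing ratios (0.25, 0.75) = average of (0, 1) and (0.5, 0.5)
  r3 <- synthesize_mixtures(pm, rbind(c(0.25, 0.75), c(0, 1), c(0.5, 0.5)))
  expect_equal(r3$intensity[1, 1], mean(r3$intensity[1, 2:3]))
  # overlapping replicate split is refused unless explicitly allowed
  expect_error(synthesize_mixtures(pm, diag(2), mixture_replicates = c(2, 3)),
               "overlap")
  expect_warning(synthesize_mixtures(pm, diag(2), mixture_replicates = c(2, 3),
                                     allow_overlap = TRUE), "overlap")
})

test_that("noiseless mixtures of the signature's own columns are recovered exactly", {
  sig <- toy_signature(5, 2, contrast = 1e6, baseline = 1e4)
  a <- c(0.1, 0.2, 0.3, 0.2, 0.2)
  fe <- estimate_fractions(sig, as.numeric(sig %*% a))
  expect_equal(unname(fe$fractions), a, tolerance = 1e-6)
  expect_lt(fe$residual_norm["iteration2"], 1e-6 * sqrt(sum((sig %*% a)^2)))
})

test_that("the 2-stage toy system matches the brute-force grid oracle", {
  sig <- matrix(c(1, 0, 1, 0, 1, 1), 3, 2,
                dimnames = list(c("m1", "m2", "m3"), c("S1", "S2")))
  y <- c(0.3, 0.7, 1.0)
  fe <- estimate_fractions(sig, setNames(y, rownames(sig)))
  expect_equal(unname(fe$fractions), c(0.3, 0.7), tolerance = 1e-9)
  oracle <- grid_search_fractions(sig, y, step = 1e-4)
  expect_equal(unname(oracle$fractions), c(0.3, 0.7), tolerance = 1e-4 + 1e-12)
})

test_that("NNLS agrees with exhaustive simplex search on small noiseless systems", {
  set.seed(41)
  for (k in 2:3) {
    for (rep in 1:4) {
      sig <- matrix(10^runif(8 * k, 2, 5), 8, k,
                    dimnames = list(sprintf("m%d", 1:8), paste0("S", 1:k)))
      a <- as.numeric(rand_simplex(1, k))
      fe <- estimate_fractions(sig, as.numeric(sig %*% a))
      oracle <- grid_search_fractions(sig, as.numeric(sig %*% a), step = 1e-3)
      expect_lt(max(abs(fe$fractions - oracle$fractions)), 2e-3)
    }
  }
})

test_that("exactly the best-fitting 90% of markers survive to the refit", {
  set.seed(43)
  sig <- matrix(10^runif(100 * 5, 3, 6), 100, 5,
                dimnames = list(sprintf("m%03d", 1:100), paste0("S", 1:5)))
  a <- c(0.3, 0.1, 0.2, 0.25, 0.15)
  y <- as.numeric(sig %*% a) * exp(rnorm(100, 0, 0.1))
  fe <- estimate_fractions(sig, setNames(y, rownames(sig)),
                           retain_fraction = 0.90)
  expect_length(fe$retained_ids, 90L)
  # retained markers are the 90 with the smallest scaled residuals
  score <- abs(fe$residuals$iteration1) / sqrt(rowSums(sig^2))
  expect_setequal(fe$retained_ids, names(sort(score))[1:90])
  # refit can only improve the fit on the retained system
  r1_restricted <- sqrt(sum(fe$residuals$iteration1[fe$retained_ids]^2))
  expect_lte(fe$residual_norm["iteration2"], r1_restricted + 1e-12)
  # never fewer retained markers than stages
  fe_small <- estimate_fractions(sig[1:6, ], setNames(y[1:6], rownames(sig)[1:6]),
                                 retain_fraction = 0.5)
  expect_length(fe_small$retained_ids, 5L)
})

test_that("estimates are scale invariant and L1-normalized", {
  set.seed(47)
  sig <- matrix(10^runif(40 * 5, 3, 6), 40, 5,
                dimnames = list(sprintf("m%02d", 1:40), paste0("S", 1:5)))
  y <- as.numeric(sig %*% rand_simplex(1, 5)[1, ]) * exp(rnorm(40, 0, 0.2))
  names(y) <- rownames(sig)
  fe <- estimate_fractions(sig, y)
  expect_true(all(fe$fractions >= 0))
  expect_equal(sum(fe$fractions), 1, tolerance = 1e-9)
  fe_scaled <- estimate_fractions(sig * 1e3, y * 1e3)
  expect_equal(fe$fractions, fe_scaled$fractions, tolerance = 1e-12)
  expect_identical(fe$retained_ids, fe_scaled$retained_ids)
})

test_that("degenerate mixtures are rejected", {
  sig <- toy_signature(3, 2)
  expect_error(estimate_fractions(sig, rep(0, 6)), "all-zero")
  expect_error(estimate_fractions(sig[1:2, ], c(1, 2)), "fewer markers")
})

test_that("the active-set solver agrees with an independent NNLS implementation", {
  set.seed(59)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    m <- k + sample(3:10, 1)
    C <- matrix(10^runif(m * k, 1, 4), m, k)
    d <- as.numeric(C %*% runif(k)) * exp(rnorm(m, 0, 0.3))
    mine <- erydecon:::.nnls(C, d)
    ref <- pracma::lsqnonneg(C, d)
    expect_true(all(mine >= 0))
    # identical objective value and (for these well-conditioned cases) solution
    expect_equal(sum((C %*% mine - d)^2), ref$resid.norm, tolerance = 1e-9)
    expect_equal(mine, ref$x, tolerance = 1e-7)
  }
})
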