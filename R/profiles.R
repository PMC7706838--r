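#' Filter proteins by per-stage data completeness
#'
#' Keeps proteins quantified in at least `min_fraction_per_stage` of the
#' replicates in at least `n_stages_required` stages. With four replicates the
#' default 0.75 corresponds to requiring all biological triplicates of at
#' least one differentiation stage; `min_fraction_per_stage = 1` gives the
#' stricter 100%-completeness-in-one-stage variant used before copy-number
#' estimation.
#'
#' @param pm a [proteome_matrix()].
#' @param min_fraction_per_stage fraction of a stage's replicates that must be
#'   observed (0 < f <= 1).
#' @param n_stages_required number of stages that must individually meet
#'   `min_fraction_per_stage`.
#' @return the filtered `proteome_matrix` (columns unchanged).
#' @export
filter_completeness <- function(pm, min_fraction_per_stage = 0.75,
                                n_stages_required = 1L) {
  stopifnot(inherits(pm, "proteome_matrix"))
  if (!(min_fraction_per_stage > 0 && min_fraction_per_stage <= 1))
    stop("min_fraction_per_stage must be in (0, 1]")
  obs <- !is.na(pm$intensity)
  frac <- vapply(pm$stages, function(s) {
    cols <- .stage_cols(pm, s)
    rowMeans(obs[, cols, drop = FALSE])
  }, numeric(nrow(obs)))
  # frac: proteins x stages; count stages meeting the completeness bar
  ok_stages <- rowSums(frac >= min_fraction_per_stage - 1e-12)
  keep <- ok_stages >= n_stages_required
  if (!any(keep))
    message("filter_completeness: no proteins pass the completeness filter")
  subset_proteins(pm, which(keep))
}

#' Impute missing log2 intensities from a downshifted normal distribution
#'
#' Left-censored (missing-not-at-random) imputation as used for MS intensity
#' matrices: missing cells of each sample column are replaced by draws from
#' `Normal(mean_col - downshift * sd_col, (width * sd_col)^2)`, where mean and
#' sd are computed from that column's observed values. Observed cells are
#' never altered.
#'
#' @param log2_mat numeric matrix on the log2 scale, `NA` for missing.
#' @param width imputation sd as a fraction of the column sd (default 0.3).
#' @param downshift center shift in column sds (default 1.8).
#' @param seed integer seed; fixing it makes imputation reproducible.
#' @return the matrix with all `NA` cells imputed.
#' @export
impute_missing <- function(log2_mat, width = 0.3, downshift = 1.8,
                           seed = 1L) {
  stopifnot(is.matrix(log2_mat))
  if (!anyNA(log2_mat)) return(log2_mat)
  set.seed(as.integer(seed))
  out <- log2_mat
  for (j in seq_len(ncol(out))) {
    obs <- out[, j][!is.na(out[, j])]
    miss <- which(is.na(out[, j]))
    if (!length(miss)) next
    if (length(obs) < 2L)
      stop(sprintf("column %d has fewer than 2 observed values; sd undefined", j))
    mu <- mean(obs)
    s <- stats::sd(obs)
    out[miss, j] <- stats::rnorm(length(miss), mu - downshift * s, width * s)
  }
  out
}

# vectorized one-way ANOVA F over matrix rows; s0 is added to the pooled
# within-group sd before squaring (damps significance of tiny effects)
.row_anova_f <- function(x, g, s0 = 0) {
  g <- as.factor(g)
  n <- ncol(x)
  k <- nlevels(g)
  counts <- as.numeric(table(g))
  M <- stats::model.matrix(~ g - 1)          # n x k indicator
  group_sum <- x %*% M
  group_mean <- sweep(group_sum, 2, counts, "/")
  grand <- rowMeans(x)
  ssb <- as.numeric(sweep(group_mean, 1, grand, "-")^2 %*% counts)
  sst <- rowSums(sweep(x, 1, grand, "-")^2)
  ssw <- pmax(sst - ssb, 0)
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  f <- msb / (sqrt(msw) + s0)^2
  f[!is.finite(f)] <- 0   # zero-variance rows: 0/0 -> no evidence
  list(f = f, df1 = k - 1, df2 = n - k)
}

#' Multi-stage differential test with permutation-based FDR
#'
#' One-way ANOVA across the ordered stages for every protein, with an
#' S0-regularized F statistic (the constant `s0` is added to the pooled
#' within-stage standard deviation, damping proteins whose significance rests
#' on minuscule variance) and a permutation-estimated q-value: stage labels
#' are permuted across samples, permuted statistics are pooled over all
#' proteins, and the FDR at each observed statistic is the ratio of expected
#' to observed discoveries, monotonized step-up.
#'
#' @param log2_mat complete (imputed) numeric matrix, proteins x samples.
#' @param stage_labels character/factor of length `ncol(log2_mat)` assigning
#'   each sample to a stage.
#' @param n_permutations number of label permutations (>= 100 recommended).
#' @param s0 regularization constant on the pooled sd scale (default 0.1).
#' @param seed integer seed for the permutations.
#' @return a `stage_stats` data.frame with columns `protein_id`, `F`, `p`
#'   (parametric, reference only), `q` (permutation FDR), and `cluster`
#'   (`NA` until [cluster_profiles()] is run).
#' @export
anova_stage_test <- function(log2_mat, stage_labels, n_permutations = 250L,
                             s0 = 0.1, seed = 1L) {
  stopifnot(is.matrix(log2_mat))
  if (anyNA(log2_mat))
    stop("log2_mat contains missing values; run impute_missing() first")
  g <- as.factor(stage_labels)
  if (nlevels(g) < 2L) stop("need at least 2 stages")
  if (min(table(g)) < 2L) stop("need at least 2 replicates per stage")
  if (n_permutations < 100L)
    warning("fewer than 100 permutations gives coarse q-value estimates")

  obs <- .row_anova_f(log2_mat, g, s0)
  f_obs <- obs$f
  n_prot <- nrow(log2_mat)

  set.seed(as.integer(seed))
  perm_f <- matrix(0, n_prot, n_permutations)
  for (b in seq_len(n_permutations)) {
    gp <- sample(g)
    perm_f[, b] <- .row_anova_f(log2_mat, gp, s0)$f
  }

  # FDR(t) = mean permuted count >= t over observed count >= t, at t = each
  # observed F; suffix-minimum over decreasing F monotonizes (step-up)
  ord <- order(f_obs, decreasing = TRUE)
  f_sorted <- f_obs[ord]
  pooled <- sort(as.numeric(perm_f))
  n_pool_ge <- length(pooled) -
    findInterval(f_sorted, pooled, left.open = TRUE)
  exp_fp <- n_pool_ge / n_permutations
  n_obs_ge <- seq_along(f_sorted)
  fdr <- pmin(exp_fp / n_obs_ge, 1)
  q_sorted <- rev(cummin(rev(fdr)))
  q <- numeric(n_prot)
  q[ord] <- q_sorted
  q[f_obs == 0] <- 1

  p <- stats::pf(f_obs, obs$df1, obs$df2, lower.tail = FALSE)
  res <- data.frame(protein_id = rownames(log2_mat), F = f_obs, p = p, q = q,
                    cluster = NA_integer_, stringsAsFactors = FALSE)
  class(res) <- c("stage_stats", "data.frame")
  res
}

#' Per-protein z-scored stage profiles
#'
#' Collapses replicates to per-stage medians of log2 intensities, then
#' z-scores each protein's profile (mean 0, sd 1 across stages).
#'
#' @param log2_mat complete numeric matrix, proteins x samples.
#' @param stage_labels stage of each column.
#' @param stages stage order for the output columns.
#' @return numeric matrix, proteins x stages, of z-scored stage medians.
#'   Proteins with zero across-stage variance get an all-zero profile.
#' @export
stage_z_profiles <- function(log2_mat, stage_labels,
                             stages = unique(as.character(stage_labels))) {
  med <- vapply(stages, function(s) {
    apply(log2_mat[, stage_labels == s, drop = FALSE], 1, stats::median)
  }, numeric(nrow(log2_mat)))
  mu <- rowMeans(med)
  sd <- apply(med, 1, stats::sd)
  z <- (med - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  z
}

#' Cluster temporal profiles into k groups
#'
#' Hierarchical clustering of z-scored stage profiles with Euclidean distance,
#' cut into `k` clusters. Deterministic given the input order. Ward linkage
#' (`ward.D2`) is the default: on noisy z-profiles, average linkage tends to
#' split off single outlier proteins as their own clusters, leaving fewer than
#' `k` usable temporal profiles, whereas Ward minimizes within-cluster
#' variance and yields balanced profile groups.
#'
#' @param z_profiles numeric matrix, proteins x stages (complete).
#' @param k number of clusters (default 6, the number of temporal archetypes
#'   typically resolved across erythroid maturation).
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return integer vector of cluster labels (1..k), named by protein id.
#' @export
cluster_profiles <- function(z_profiles, k = 6L, linkage = "ward.D2") {
  stopifnot(is.matrix(z_profiles))
  if (anyNA(z_profiles)) stop("z_profiles must be complete")
  if (nrow(z_profiles) < k)
    stop("fewer proteins than clusters requested")
  if (k < 1L) stop("k must be >= 1")
  if (k == 1L)
    return(stats::setNames(rep(1L, nrow(z_profiles)), rownames(z_profiles)))
  hc <- stats::hclust(stats::dist(z_profiles, method = "euclidean"),
                      method = linkage)
  stats::cutree(hc, k = k)
}
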