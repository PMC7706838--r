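#' Build a signature matrix for a marker panel
#'
#' The signature matrix holds, for every marker protein (rows) and every
#' stage (columns), the arithmetic mean of the *linear* (non-logged)
#' intensities over the designated signature replicates. By default
#' replicates 2 and 4 are reserved for the signature, leaving replicates 1
#' and 3 to build independent in silico mixtures.
#'
#' @param pm a [proteome_matrix()] of linear intensities.
#' @param panel a [marker_panel()] (or character vector of protein ids).
#' @param signature_replicates replicate indices used for the signature
#'   (default `c(2, 4)`).
#' @return numeric matrix, markers x stages (class `signature_matrix`).
#'   Markers missing in all designated replicates of any stage are dropped
#'   with a warning.
#' @export
build_signature <- function(pm, panel, signature_replicates = c(2L, 4L)) {
  stopifnot(inherits(pm, "proteome_matrix"))
  ids <- if (inherits(panel, "marker_panel")) panel$protein_ids
         else as.character(panel)
  if (!length(ids)) stop("empty marker panel")
  missing <- setdiff(ids, rownames(pm$intensity))
  if (length(missing)) {
    warning(sprintf("dropping %d marker(s) absent from the matrix",
                    length(missing)))
    ids <- setdiff(ids, missing)
  }
  obs_max <- suppressWarnings(max(pm$intensity, na.rm = TRUE))
  if (is.finite(obs_max) && obs_max < 64)
    stop("intensities look log-transformed (all < 64); the signature needs linear values")
  for (s in pm$stages)
    if (!length(.stage_cols(pm, s, signature_replicates)))
      stop(sprintf("no designated signature replicate exists for stage %s", s))

  sig <- vapply(pm$stages, function(s) {
    cols <- .stage_cols(pm, s, signature_replicates)
    rowMeans(pm$intensity[ids, cols, drop = FALSE], na.rm = TRUE)
  }, numeric(length(ids)))
  sig <- matrix(sig, nrow = length(ids),
                dimnames = list(ids, pm$stages))
  complete <- rowSums(is.na(sig)) == 0
  if (!all(complete)) {
    warning(sprintf(
      "dropping %d marker(s) unobserved in all signature replicates of some stage",
      sum(!complete)))
    sig <- sig[complete, , drop = FALSE]
  }
  if (!nrow(sig)) stop("empty signature: no marker is observed in every stage")
  class(sig) <- c("signature_matrix", class(sig))
  sig
}

#' Draw random stage-fraction vectors on the simplex
#'
#' Generates `n_mixtures` compositions of `n_stages` non-negative values that
#' add up to 1, drawn from the flat (symmetric, concentration 1) Dirichlet
#' distribution, which is exchangeable across stages.
#'
#' @param n_mixtures number of composition vectors (default 500).
#' @param n_stages number of stages (default 5).
#' @param seed integer seed.
#' @return numeric matrix `n_mixtures x n_stages`; every row sums to 1.
#' @export
generate_ratios <- function(n_mixtures = 500L, n_stages = 5L, seed = 1L) {
  if (n_mixtures < 1L) stop("n_mixtures must be >= 1")
  if (n_stages < 1L) stop("n_stages must be >= 1")
  set.seed(as.integer(seed))
  if (n_stages == 1L) return(matrix(1, n_mixtures, 1))
  g <- matrix(stats::rgamma(n_mixtures * n_stages, shape = 1, rate = 1),
              n_mixtures, n_stages)
  g / rowSums(g)
}

#' Synthesize in silico mixtures from pure-stage profiles
#'
#' Builds each mixture's protein intensity vector as the ratio-weighted sum
#' of the pure-stage profiles, where a stage's profile averages the
#' designated mixture replicates (disjoint from the signature replicates):
#' `I_mix[k] = sum_i a_i * Ibar[k, i]`.
#'
#' @param pm a [proteome_matrix()].
#' @param ratios a ratio matrix from [generate_ratios()] (mixtures x stages).
#' @param mixture_replicates replicate indices used for the mixtures
#'   (default `c(1, 3)`).
#' @param signature_replicates the replicates reserved for the signature;
#'   used to verify the split is disjoint.
#' @param allow_overlap set `TRUE` to downgrade an overlapping
#'   replicate split from an error to a warning.
#' @return a `mixture_set` list: `intensity` (proteins x mixtures; `NA` where
#'   the protein is unobserved in a needed stage), `ratios`, `stage_profile`
#'   (proteins x stages averaged mixture-replicate intensities).
#' @export
synthesize_mixtures <- function(pm, ratios, mixture_replicates = c(1L, 3L),
                                signature_replicates = c(2L, 4L),
                                allow_overlap = FALSE) {
  stopifnot(inherits(pm, "proteome_matrix"), is.matrix(ratios))
  if (ncol(ratios) != length(pm$stages))
    stop("ratio matrix columns must match the number of stages")
  overlap <- intersect(mixture_replicates, signature_replicates)
  if (length(overlap)) {
    msg <- sprintf("mixture and signature replicates overlap (%s)",
                   paste(overlap, collapse = ", "))
    if (allow_overlap) warning(msg) else stop(msg)
  }
  prof <- vapply(pm$stages, function(s) {
    cols <- .stage_cols(pm, s, mixture_replicates)
    if (!length(cols))
      stop(sprintf("no designated mixture replicate exists for stage %s", s))
    rowMeans(pm$intensity[, cols, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(pm$intensity)))
  prof[is.nan(prof)] <- NA_real_
  mix <- prof %*% t(ratios)   # NA propagates: protein needs all stages
  structure(list(intensity = mix, ratios = ratios, stage_profile = prof),
            class = "mixture_set")
}

# Lawson-Hanson active-set non-negative least squares:
# min ||C x - d||_2 subject to x >= 0. At convergence the KKT conditions
# hold: x[P] > 0 with zero gradient on P, and gradient <= tol elsewhere.
# Written here because available implementations cap the cumulative inner
# iteration count so low that realistically ill-conditioned signature
# matrices abort mid-solve.
.nnls <- function(C, d, itmax = 50 * (ncol(C) + 1)) {
  n <- ncol(C)
  tol <- 10 * .Machine$double.eps * norm(C, "2") * (max(dim(C)) + 1)
  solve_passive <- function(P) {
    z <- rep(0, n)
    z[P] <- tryCatch(qr.solve(C[, P, drop = FALSE], d),
                     error = function(e)
                       drop(pracma::pinv(C[, P, drop = FALSE]) %*% d))
    z
  }
  x <- rep(0, n)
  P <- logical(n)
  w <- drop(crossprod(C, d - C %*% x))
  iter <- 0
  while (any(!P) && any(w[!P] > tol)) {
    cand <- which(!P)
    P[cand[which.max(w[cand])]] <- TRUE
    z <- solve_passive(P)
    while (any(z[P] <= 0)) {
      iter <- iter + 1
      if (iter > itmax) {
        warning("NNLS iteration limit reached; returning best feasible point")
        x[x < 0] <- 0
        return(x)
      }
      Q <- P & (z <= 0)
      alpha <- min(x[Q] / (x[Q] - z[Q]))
      x <- x + alpha * (z - x)
      P <- P & (x > tol)
      z <- solve_passive(P)
    }
    x <- z
    w <- drop(crossprod(C, d - C %*% x))
  }
  x
}

# n markers kept for the refit: best retain_fraction of m, never fewer than
# the number of stages (epsilon guards 0.9 * 100 -> 90 exactly)
.n_retained <- function(m, n_stages, retain_fraction) {
  max(n_stages, as.integer(ceiling(m * retain_fraction - 1e-9)))
}

#' Estimate stage fractions by iterative non-negative least squares
#'
#' Solves the linear mixture model `i_mix = I %*% a` for the stage-fraction
#' vector `a` with zero lower bounds (Lawson-Hanson active-set NNLS). After
#' the initial fit, markers are ranked by how well the model reproduces them
#' (absolute residual scaled by the marker's signature row norm) and only the
#' best-fitting `retain_fraction` of markers are kept for a second, refitted
#' solve; the refit's solution is finally normalized by its Manhattan (L1)
#' norm so the estimated fractions lie on the simplex.
#'
#' @param signature a `signature_matrix` (markers x stages).
#' @param mixture numeric vector of mixture intensities, named by protein id
#'   (or aligned to the signature rows); `NA` entries are dropped from the
#'   system rather than zero-filled.
#' @param retain_fraction fraction of markers kept for the second iteration
#'   (default 0.90: the worst-fitting 10% are discarded as outliers).
#' @return a `fraction_estimate` list: `fractions` (named, non-negative,
#'   summing to 1), `raw` (unnormalized refit solution), `retained_ids`,
#'   `residual_norm` (L2, per iteration, each over its own marker set), and
#'   `residuals` (named per-marker residual vectors for both iterations).
#' @export
estimate_fractions <- function(signature, mixture, retain_fraction = 0.90) {
  stopifnot(is.matrix(signature))
  if (!is.null(names(mixture))) {
    common <- intersect(rownames(signature), names(mixture))
    sig <- signature[common, , drop = FALSE]
    y <- mixture[common]
  } else {
    if (length(mixture) != nrow(signature))
      stop("unnamed mixture vector must align with the signature rows")
    sig <- signature
    y <- stats::setNames(as.numeric(mixture), rownames(signature))
  }
  keep <- !is.na(y) & rowSums(is.na(sig)) == 0
  sig <- sig[keep, , drop = FALSE]
  y <- y[keep]
  n_stages <- ncol(sig)
  if (nrow(sig) < n_stages)
    stop("signature and mixture share fewer markers than stages")
  if (all(y == 0)) stop("all-zero mixture vector")
  if (qr(sig)$rank < n_stages)
    warning("signature matrix is column-rank deficient; estimates may be unstable")

  x1 <- .nnls(sig, as.numeric(y))
  resid1 <- as.numeric(sig %*% x1) - y
  row_norm <- sqrt(rowSums(sig^2))
  score <- abs(resid1) / ifelse(row_norm > 0, row_norm, 1)

  n_keep <- .n_retained(nrow(sig), n_stages, retain_fraction)
  retained <- names(sort(score))[seq_len(n_keep)]
  sig2 <- sig[retained, , drop = FALSE]
  x2 <- .nnls(sig2, as.numeric(y[retained]))
  resid2 <- as.numeric(sig2 %*% x2) - y[retained]

  total <- sum(abs(x2))
  if (total == 0) stop("degenerate fit: estimated fractions sum to zero")
  structure(
    list(fractions = stats::setNames(x2 / total, colnames(sig)),
         raw = stats::setNames(x2, colnames(sig)),
         retained_ids = retained,
         residual_norm = c(iteration1 = sqrt(sum(resid1^2)),
                           iteration2 = sqrt(sum(resid2^2))),
         residuals = list(iteration1 = stats::setNames(resid1, rownames(sig)),
                          iteration2 = stats::setNames(resid2, retained))),
    class = "fraction_estimate")
}

#' Exhaustive simplex grid search for the mixture fractions
#'
#' Brute-force reference estimator: enumerates all compositions on the
#' `n_stages`-simplex at resolution `step` and returns the one minimizing the
#' least-squares residual to the mixture vector. Exponential in the number of
#' stages; intended for 2-3 stage verification problems only.
#'
#' @param signature markers x stages matrix.
#' @param mixture numeric vector of length `nrow(signature)`.
#' @param step grid resolution on each coordinate (default 1e-3).
#' @return list `fractions` (grid minimizer) and `objective` (residual L2
#'   norm at the minimizer).
#' @export
grid_search_fractions <- function(signature, mixture, step = 1e-3) {
  stopifnot(is.matrix(signature))
  k <- ncol(signature)
  if (k > 3L) stop("grid search supported for up to 3 stages")
  n <- round(1 / step)
  if (k == 1L) {
    a <- matrix(1, 1, 1)
  } else if (k == 2L) {
    a1 <- seq(0, n) / n
    a <- cbind(a1, 1 - a1)
  } else {
    i <- rep(0:n, times = n + 1)
    j <- rep(0:n, each = n + 1)
    ok <- i + j <= n
    a <- cbind(i[ok], j[ok], n - i[ok] - j[ok]) / n
  }
  pred <- signature %*% t(a)                      # markers x grid
  obj <- sqrt(colSums((pred - mixture)^2))
  best <- which.min(obj)
  list(fractions = stats::setNames(a[best, ], colnames(signature)),
       objective = obj[best])
}
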