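#' Distance-weighted error between true and estimated stage fractions
#'
#' The 1-D earth-mover (Wasserstein-1) distance between two compositions
#' over the ordered maturation stages with unit spacing:
#' `sum_k |C_k(true) - C_k(est)|` over the cumulative sums `C_k` of the first
#' `K - 1` stages. Misassigning mass to a neighboring stage therefore costs
#' the amount moved, while misassigning it across the full series costs
#' `(K - 1)` times as much; the score is zero iff the compositions are equal,
#' symmetric, and satisfies the triangle inequality.
#'
#' @param true_fractions,est_fractions numeric vectors on the simplex, in
#'   stage order.
#' @param spacing optional positive stage spacings (length `K - 1`) for
#'   non-uniform developmental distances; default unit spacing.
#' @param tol off-simplex tolerance (default 1e-6).
#' @return non-negative numeric score.
#' @export
weighted_error <- function(true_fractions, est_fractions, spacing = NULL,
                           tol = 1e-6) {
  a <- as.numeric(true_fractions)
  b <- as.numeric(est_fractions)
  if (length(a) != length(b)) stop("fraction vectors differ in length")
  for (v in list(a, b))
    if (any(v < -tol) || abs(sum(v) - 1) > tol)
      stop("fraction vector is off the simplex beyond tolerance")
  k <- length(a)
  if (is.null(spacing)) spacing <- rep(1, k - 1)
  if (length(spacing) != k - 1 || any(spacing <= 0))
    stop("spacing must be ", k - 1, " positive distances")
  d <- cumsum(a - b)[seq_len(k - 1)]
  sum(abs(d) * spacing)
}

#' Baseline control estimators for the mixture benchmark
#'
#' Three references that ignore the data: `uniform` assigns every stage the
#' same fraction `1/K`; `center` puts all mass on the middle stage
#' (`ceiling(K / 2)`), i.e. assumes every cell is of the central type; and
#' `random` draws a fresh composition from the flat Dirichlet.
#'
#' @param kind one of `"random"`, `"uniform"`, `"center"`.
#' @param n_stages number of stages (>= 2).
#' @param seed integer seed (used by `random` only).
#' @return numeric fraction vector of length `n_stages`.
#' @export
control_estimate <- function(kind = c("random", "uniform", "center"),
                             n_stages = 5L, seed = 1L) {
  kind <- match.arg(kind)
  if (n_stages < 2L) stop("n_stages must be >= 2")
  switch(kind,
         uniform = rep(1 / n_stages, n_stages),
         center = {
           v <- rep(0, n_stages)
           v[ceiling(n_stages / 2)] <- 1
           v
         },
         random = as.numeric(generate_ratios(1L, n_stages, seed = seed)))
}

.summary_row <- function(errors) {
  q <- stats::quantile(errors, c(0.25, 0.5, 0.75), names = FALSE)
  data.frame(n = length(errors), min = min(errors), q1 = q[1], median = q[2],
             mean = mean(errors), q3 = q[3], max = max(errors))
}

#' Run the full panel-comparison benchmark
#'
#' For every marker panel: builds the signature matrix from the signature
#' replicates, deconvolves every in silico mixture (built from the disjoint
#' mixture replicates) by iterative non-negative least squares, and scores the
#' estimate against the known true fractions with [weighted_error()]. The
#' three baseline controls are scored against the same truths, with the
#' `random` control re-drawn independently per mixture.
#'
#' @param pm a [proteome_matrix()].
#' @param panels named list of [marker_panel()] objects.
#' @param ratios true mixing fractions (mixtures x stages), shared across all
#'   panels so comparisons are paired.
#' @param signature_replicates,mixture_replicates the disjoint replicate
#'   split (defaults 2,4 and 1,3).
#' @param retain_fraction marker retention for the refit (default 0.90).
#' @param seed integer seed for the `random` control.
#' @param spacing optional stage spacings for [weighted_error()].
#' @return an `evaluation_report` list: `errors` (data.frame `panel`,
#'   `mixture`, `error`, `retained`), `summary` (per panel/control: n, min,
#'   q1, median, mean, q3, max), `estimates` (list of mixtures x stages
#'   matrices), `ratios`.
#' @export
evaluate_panels <- function(pm, panels, ratios,
                            signature_replicates = c(2L, 4L),
                            mixture_replicates = c(1L, 3L),
                            retain_fraction = 0.90, seed = 1L,
                            spacing = NULL) {
  stopifnot(inherits(pm, "proteome_matrix"), is.matrix(ratios))
  n_stages <- length(pm$stages)
  n_mix <- nrow(ratios)
  mixset <- synthesize_mixtures(pm, ratios, mixture_replicates,
                                signature_replicates)

  rows <- list()
  estimates <- list()
  for (pname in names(panels)) {
    sig <- tryCatch(build_signature(pm, panels[[pname]], signature_replicates),
                    error = function(e) {
                      warning(sprintf("panel '%s' skipped: %s", pname,
                                      conditionMessage(e)))
                      NULL
                    })
    if (is.null(sig)) next
    # mixture-side missingness is shared across mixtures (it depends only on
    # the stage profile), so restrict the signature to usable markers once
    usable <- rownames(sig)[rowSums(is.na(
      mixset$stage_profile[rownames(sig), , drop = FALSE])) == 0]
    if (length(usable) < n_stages) {
      warning(sprintf(
        "panel '%s' skipped: only %d marker(s) usable in the mixtures",
        pname, length(usable)))
      next
    }
    sig <- sig[usable, , drop = FALSE]
    if (qr(sig)$rank < n_stages) {
      warning(sprintf("panel '%s' skipped: signature rank < number of stages",
                      pname))
      next
    }
    est <- matrix(NA_real_, n_mix, n_stages,
                  dimnames = list(NULL, pm$stages))
    err <- numeric(n_mix)
    ret <- integer(n_mix)
    for (m in seq_len(n_mix)) {
      fe <- estimate_fractions(sig, mixset$intensity[, m], retain_fraction)
      est[m, ] <- fe$fractions
      err[m] <- weighted_error(ratios[m, ], fe$fractions, spacing)
      ret[m] <- length(fe$retained_ids)
    }
    rows[[pname]] <- data.frame(panel = pname, mixture = seq_len(n_mix),
                                error = err, retained = ret)
    estimates[[pname]] <- est
  }

  # controls: scored against the same truths; 'random' redrawn per mixture
  rand_est <- generate_ratios(n_mix, n_stages, seed = seed)
  ctrl <- list(
    uniform = matrix(rep(control_estimate("uniform", n_stages), each = n_mix),
                     n_mix, n_stages),
    center = matrix(rep(control_estimate("center", n_stages), each = n_mix),
                    n_mix, n_stages),
    random = rand_est)
  for (cname in names(ctrl)) {
    err <- vapply(seq_len(n_mix), function(m)
      weighted_error(ratios[m, ], ctrl[[cname]][m, ], spacing), 0)
    rows[[paste0("control_", cname)]] <-
      data.frame(panel = paste0("control_", cname), mixture = seq_len(n_mix),
                 error = err, retained = NA_integer_)
    estimates[[paste0("control_", cname)]] <- ctrl[[cname]]
  }

  errors <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  summary <- do.call(rbind, lapply(split(errors$error, errors$panel),
                                   .summary_row))
  summary <- data.frame(panel = rownames(summary), summary,
                        row.names = NULL)
  structure(list(errors = errors, summary = summary, estimates = estimates,
                 ratios = ratios),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: %d panels/controls x %d mixtures\n",
              length(unique(x$errors$panel)), nrow(x$ratios)))
  print(x$summary[order(x$summary$mean), ], digits = 4, row.names = FALSE)
  invisible(x)
}

#' Write the per-mixture and summary error tables
#'
#' @param report an `evaluation_report`.
#' @param errors_path,summary_path output TSV paths.
#' @return invisibly, the two paths.
#' @export
write_report_tsv <- function(report, errors_path, summary_path) {
  utils::write.table(report$errors, errors_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(report$summary, summary_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(errors_path, summary_path))
}
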