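#' Settings for the histone proteomic ruler
#'
#' The ruler converts MS intensities to copies per cell by anchoring the
#' summed histone intensity to the cell's DNA mass, exploiting the
#' near-fixed histone:DNA mass stoichiometry of chromatin. The defaults are
#' the standard settings for a diploid human cell: ploidy 2, total cellular
#' protein concentration 200 g/l, haploid genome DNA mass 3.25 pg
#' (~3.1e9 bp), average molecular masses.
#'
#' @param ploidy genome copies per cell (>= 1).
#' @param total_protein_concentration g protein per liter cell volume
#'   (> 0); used only for the cell-volume estimate.
#' @param dna_mass_pg_haploid DNA mass of one haploid genome, picograms.
#' @param averaging_mode `"per-column"` computes copies from each sample
#'   column separately; `"pooled"` averages the columns of each stage first.
#' @return an object of class `ruler_settings`.
#' @export
ruler_settings <- function(ploidy = 2, total_protein_concentration = 200,
                           dna_mass_pg_haploid = 3.25,
                           averaging_mode = c("per-column", "pooled")) {
  if (ploidy < 1) stop("ploidy must be >= 1")
  if (total_protein_concentration <= 0)
    stop("total_protein_concentration must be > 0")
  if (dna_mass_pg_haploid <= 0) stop("dna_mass_pg_haploid must be > 0")
  structure(list(ploidy = ploidy,
                 total_protein_concentration = total_protein_concentration,
                 dna_mass_pg_haploid = dna_mass_pg_haploid,
                 averaging_mode = match.arg(averaging_mode)),
            class = "ruler_settings")
}

#' Estimate per-cell protein copy numbers with the histone ruler
#'
#' For each sample (column), protein copies are
#' `copies_p = I_p * m_DNA * N_A / (sum_h I_h * MW_p)` where the sum runs
#' over the histone intensities of that sample and `m_DNA = ploidy x haploid
#' DNA mass`. The method assumes MS intensity is proportional to protein
#' mass, so copies scale as intensity over molecular mass; any global
#' per-sample intensity rescaling cancels. Per-sample totals follow:
#' total protein mass (pg) is `sum_p copies_p * MW_p / N_A` and cell volume
#' (fl) is mass over the assumed protein concentration.
#'
#' @param pm a [proteome_matrix()] (filter for completeness first if the
#'   downstream summaries require it).
#' @param histone_ids character vector of histone protein ids present in the
#'   matrix.
#' @param settings a [ruler_settings()].
#' @return a `ruler_result` list: `copies` (proteins x samples; `NA` where
#'   intensity is missing), `total_mass_pg`, `cell_volume_fl` (per sample),
#'   `histone_ids`, `settings`, plus the column metadata of `pm`.
#' @export
estimate_copy_numbers <- function(pm, histone_ids,
                                  settings = ruler_settings()) {
  stopifnot(inherits(pm, "proteome_matrix"),
            inherits(settings, "ruler_settings"))
  if (!length(histone_ids)) stop("histone_ids must be non-empty")
  absent <- setdiff(histone_ids, rownames(pm$intensity))
  if (length(absent))
    stop("histone ids absent from the matrix: ",
         paste(utils::head(absent, 5), collapse = ", "))

  intens <- pm$intensity
  if (settings$averaging_mode == "pooled") {
    pooled <- vapply(pm$stages, function(s)
      rowMeans(intens[, .stage_cols(pm, s), drop = FALSE], na.rm = TRUE),
      numeric(nrow(intens)))
    pooled[is.nan(pooled)] <- NA_real_
    intens <- pooled
    col_stage <- pm$stages
    col_rep <- rep(NA_integer_, length(pm$stages))
  } else {
    col_stage <- pm$col_stage
    col_rep <- pm$col_replicate
  }

  mw <- pm$mol_mass
  no_mw <- !is.finite(mw) | mw <= 0
  if (any(no_mw)) {
    warning(sprintf("skipping %d protein(s) without a valid molecular mass",
                    sum(no_mw)))
    intens <- intens[!no_mw, , drop = FALSE]
    mw <- mw[!no_mw]
    histone_ids <- setdiff(histone_ids, names(pm$mol_mass)[no_mw])
    if (!length(histone_ids)) stop("no histone with a valid molecular mass")
  }

  m_dna_da <- settings$ploidy * settings$dna_mass_pg_haploid * 1e-12 *
    .AVOGADRO  # DNA mass per cell in Daltons
  hist_sum <- colSums(intens[histone_ids, , drop = FALSE], na.rm = TRUE)
  bad <- !is.finite(hist_sum) | hist_sum <= 0
  if (any(bad))
    stop("histone intensity sum is zero in sample(s): ",
         paste(colnames(intens)[bad], collapse = ", "))

  copies <- sweep(intens, 2, m_dna_da / hist_sum, "*") / mw
  total_mass_pg <- colSums(copies * mw, na.rm = TRUE) / .AVOGADRO * 1e12
  volume_fl <- total_mass_pg / (settings$total_protein_concentration * 1e-3)

  structure(list(copies = copies, total_mass_pg = total_mass_pg,
                 cell_volume_fl = volume_fl, histone_ids = histone_ids,
                 settings = settings, col_stage = col_stage,
                 col_replicate = col_rep, stages = pm$stages),
            class = "ruler_result")
}

#' @export
print.ruler_result <- function(x, ...) {
  cat(sprintf("ruler_result: %d proteins x %d samples; %d histones\n",
              nrow(x$copies), ncol(x$copies), length(x$histone_ids)))
  cat(sprintf("  total protein mass: %.1f-%.1f pg; cell volume: %.0f-%.0f fl\n",
              min(x$total_mass_pg), max(x$total_mass_pg),
              min(x$cell_volume_fl), max(x$cell_volume_fl)))
  invisible(x)
}

#' Summarize copy numbers per stage for named protein sets
#'
#' For each protein set and stage: the median and mean copies over the set
#' are computed within every replicate, then averaged across replicates with
#' a standard error (mean +/- SEM), plus the summed copies of the set.
#'
#' @param result a `ruler_result` (per-column averaging mode).
#' @param protein_sets named list of character vectors of protein ids.
#' @return data.frame with columns `set`, `stage`, `median_copies`,
#'   `median_sem`, `mean_copies`, `mean_sem`, `total_copies`, `n_proteins`.
#' @export
summarize_copies <- function(result, protein_sets) {
  stopifnot(inherits(result, "ruler_result"), is.list(protein_sets))
  out <- list()
  for (set_name in names(protein_sets)) {
    ids <- intersect(protein_sets[[set_name]], rownames(result$copies))
    if (!length(ids)) {
      warning(sprintf("set '%s' resolves to no proteins; skipped", set_name))
      next
    }
    for (s in result$stages) {
      cols <- which(result$col_stage == s)
      med <- vapply(cols, function(j)
        stats::median(result$copies[ids, j], na.rm = TRUE), 0)
      mn <- vapply(cols, function(j)
        mean(result$copies[ids, j], na.rm = TRUE), 0)
      tot <- vapply(cols, function(j)
        sum(result$copies[ids, j], na.rm = TRUE), 0)
      sem <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                         else NA_real_
      out[[paste(set_name, s)]] <- data.frame(
        set = set_name, stage = s,
        median_copies = mean(med), median_sem = sem(med),
        mean_copies = mean(mn), mean_sem = sem(mn),
        total_copies = mean(tot), n_proteins = length(ids))
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Write per-protein copy numbers as TSV
#'
#' @param result a `ruler_result`.
#' @param path output path (columns: protein_id, then one column per sample).
#' @return `path`, invisibly.
#' @export
write_copies_tsv <- function(result, path) {
  df <- data.frame(protein_id = rownames(result$copies), result$copies,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
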