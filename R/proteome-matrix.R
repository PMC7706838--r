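#' Stage-resolved proteome intensity matrix
#'
#' Lightweight container for a wide protein-intensity matrix: rows are protein
#' groups, columns are (stage, replicate) samples. Intensities are on the
#' linear scale, strictly positive where observed, `NA` where the protein
#' dropped out of quantification. The stage factor is ordered: stage 1 is the
#' least mature population and the last stage the most mature, which is what
#' the ordinal error metric and the mixture benchmark rely on.
#'
#' @param intensity numeric matrix, proteins x samples, linear scale, `NA`
#'   allowed. Must have rownames (protein ids).
#' @param mol_mass numeric vector of average molecular masses in Daltons, one
#'   per protein, in row order.
#' @param col_stage character vector mapping each column to a stage label.
#' @param col_replicate integer vector mapping each column to a replicate
#'   index within its stage.
#' @param stages character vector giving the stage order; defaults to the
#'   order of first appearance in `col_stage`.
#'
#' @return An object of class `proteome_matrix`: a list with elements
#'   `intensity`, `mol_mass`, `col_stage`, `col_replicate`, `stages`.
#' @export
proteome_matrix <- function(intensity, mol_mass, col_stage, col_replicate,
                            stages = unique(col_stage)) {
  if (!is.matrix(intensity) || is.null(rownames(intensity)))
    stop("'intensity' must be a matrix with protein ids as rownames")
  if (length(mol_mass) != nrow(intensity))
    stop("'mol_mass' must have one entry per protein row")
  if (length(col_stage) != ncol(intensity) ||
      length(col_replicate) != ncol(intensity))
    stop("column metadata must match the number of columns")
  if (!all(col_stage %in% stages))
    stop("every column stage must appear in 'stages'")
  key <- paste(col_stage, col_replicate)
  if (anyDuplicated(key))
    stop("every column must map to exactly one (stage, replicate)")
  obs <- intensity[!is.na(intensity)]
  if (length(obs) && any(obs <= 0))
    stop("observed linear intensities must be strictly positive")
  colnames(intensity) <- paste0(col_stage, "_r", col_replicate)
  structure(
    list(intensity = intensity,
         mol_mass = stats::setNames(as.numeric(mol_mass), rownames(intensity)),
         col_stage = col_stage,
         col_replicate = as.integer(col_replicate),
         stages = stages),
    class = "proteome_matrix")
}

#' @export
print.proteome_matrix <- function(x, ...) {
  cat(sprintf("proteome_matrix: %d proteins x %d samples (%d stages x %s replicates)\n",
              nrow(x$intensity), ncol(x$intensity), length(x$stages),
              paste(range(table(x$col_stage)), collapse = "-")))
  cat(sprintf("  stages: %s\n", paste(x$stages, collapse = " > ")))
  cat(sprintf("  missing: %.1f%% of cells\n",
              100 * mean(is.na(x$intensity))))
  invisible(x)
}

#' @export
dim.proteome_matrix <- function(x) dim(x$intensity)

#' Subset a proteome matrix to a set of proteins
#'
#' @param pm a `proteome_matrix`.
#' @param ids protein ids (or logical/integer row index) to keep, in the
#'   requested order.
#' @return a `proteome_matrix` with the selected rows.
#' @export
subset_proteins <- function(pm, ids) {
  stopifnot(inherits(pm, "proteome_matrix"))
  if (is.character(ids)) {
    missing <- setdiff(ids, rownames(pm$intensity))
    if (length(missing))
      stop("unknown protein ids: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  proteome_matrix(pm$intensity[ids, , drop = FALSE],
                  pm$mol_mass[ids],
                  pm$col_stage, pm$col_replicate, pm$stages)
}

#' Log2-transform the observed intensities
#'
#' @param pm a `proteome_matrix`.
#' @return numeric matrix of log2 intensities (`NA` preserved).
#' @export
log2_matrix <- function(pm) {
  stopifnot(inherits(pm, "proteome_matrix"))
  log2(pm$intensity)
}

#' Write / read the wide TSV interchange format
#'
#' Column 1 is `protein_id`, column 2 `mol_mass_avg_Da`, remaining columns are
#' named `<stage>_r<replicate>`; missing values are written as empty fields.
#'
#' @param pm a `proteome_matrix`.
#' @param path output file path.
#' @return `write_proteome_tsv` returns `path` invisibly; `read_proteome_tsv`
#'   returns a `proteome_matrix`.
#' @export
write_proteome_tsv <- function(pm, path) {
  stopifnot(inherits(pm, "proteome_matrix"))
  df <- data.frame(protein_id = rownames(pm$intensity),
                   mol_mass_avg_Da = pm$mol_mass,
                   pm$intensity, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_proteome_tsv
#' @param stages stage order for the read matrix; default: order of first
#'   appearance among the column names.
#' @export
read_proteome_tsv <- function(path, stages = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = c("", "NA"))
  if (!identical(colnames(df)[1:2], c("protein_id", "mol_mass_avg_Da")))
    stop("malformed proteome TSV: expected protein_id, mol_mass_avg_Da columns")
  sample_cols <- colnames(df)[-(1:2)]
  m <- regmatches(sample_cols, regexec("^(.*)_r(\\d+)$", sample_cols))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("malformed sample column names: ",
         paste(sample_cols[bad], collapse = ", "))
  col_stage <- vapply(m, `[`, "", 2L)
  col_rep <- as.integer(vapply(m, `[`, "", 3L))
  intensity <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(intensity) <- df$protein_id
  proteome_matrix(intensity, df$mol_mass_avg_Da, col_stage, col_rep,
                  stages = if (is.null(stages)) unique(col_stage) else stages)
}

# columns belonging to (stage, replicate in reps); reps = NULL keeps all
.stage_cols <- function(pm, stage, reps = NULL) {
  sel <- pm$col_stage == stage
  if (!is.null(reps)) sel <- sel & pm$col_replicate %in% reps
  which(sel)
}
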