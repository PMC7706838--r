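#' Construct a marker panel
#'
#' A marker panel is a named, ordered set of unique protein ids with a
#' provenance note per protein (how the protein entered the panel).
#'
#' @param name panel name (e.g. `sorting`, `known`, `cluster_top3`, `slc`,
#'   `combined`, `any20`).
#' @param protein_ids character vector of protein ids.
#' @param provenance character vector (recycled) noting each id's origin.
#' @return an object of class `marker_panel`.
#' @export
marker_panel <- function(name, protein_ids, provenance = name) {
  protein_ids <- as.character(protein_ids)
  if (anyDuplicated(protein_ids)) {
    keep <- !duplicated(protein_ids)
    provenance <- rep_len(provenance, length(protein_ids))[keep]
    protein_ids <- protein_ids[keep]
  } else {
    provenance <- rep_len(provenance, length(protein_ids))
  }
  structure(list(name = name, protein_ids = protein_ids,
                 provenance = provenance),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("marker_panel '%s': %d proteins\n", x$name,
              length(x$protein_ids)))
  invisible(x)
}

#' @export
length.marker_panel <- function(x) length(x$protein_ids)

# deterministic significance order: smallest q, ties by larger F, then id
.order_by_significance <- function(stats) {
  order(stats$q, -stats$F, stats$protein_id)
}

#' Select the top markers of each temporal cluster
#'
#' For every non-empty cluster, takes the `per_cluster` most significant
#' proteins (smallest ANOVA q-value; ties broken by larger F, then
#' lexicographic id). With six clusters and the default of three per cluster
#' this yields the 18-protein cluster-Top3 panel.
#'
#' @param stats a `stage_stats` data.frame with `cluster` labels assigned.
#' @param per_cluster markers to take per cluster (default 3).
#' @param q_threshold only proteins with `q < q_threshold` are eligible
#'   (default 0.01).
#' @return a `marker_panel` named `cluster_top3`.
#' @export
panel_cluster_top3 <- function(stats, per_cluster = 3L, q_threshold = 0.01) {
  if (all(is.na(stats$cluster)))
    stop("no cluster labels present; run cluster_profiles() first")
  pool <- stats[!is.na(stats$cluster) & stats$q < q_threshold, , drop = FALSE]
  pool <- pool[.order_by_significance(pool), , drop = FALSE]
  ids <- character(0)
  prov <- character(0)
  for (cl in sort(unique(pool$cluster))) {
    members <- pool[pool$cluster == cl, , drop = FALSE]
    if (nrow(members) < per_cluster)
      message(sprintf("cluster %s has only %d eligible proteins (< %d)",
                      cl, nrow(members), per_cluster))
    take <- utils::head(members$protein_id, per_cluster)
    ids <- c(ids, take)
    prov <- c(prov, rep(sprintf("cluster %s top%d", cl, per_cluster),
                        length(take)))
  }
  marker_panel("cluster_top3", ids, prov)
}

#' Assemble the full set of marker panels
#'
#' Builds the six panels compared in the mixture benchmark: the curated
#' `sorting`, `known` and `slc` panels (each restricted to proteins present in
#' the matrix and significant at `q < q_threshold`), the data-driven
#' `cluster_top3` panel, their deduplicated union `combined`, and the `any20`
#' negative control of randomly picked proteins from the unfiltered list,
#' excluding proteins in any other panel.
#'
#' @param stats a `stage_stats` data.frame (with cluster labels for the
#'   cluster panel).
#' @param curated named list of character vectors with elements `sorting`,
#'   `known`, `slc` (curated protein-id lists).
#' @param universe character vector of all protein ids eligible for `any20`
#'   (the unfiltered protein list); defaults to `stats$protein_id`.
#' @param q_threshold ANOVA q-value cutoff applied to every panel except
#'   `any20` (default 0.01).
#' @param per_cluster markers per cluster for the cluster panel.
#' @param any20_size size of the random control panel (default 20).
#' @param seed integer seed for the `any20` draw.
#' @return named list of `marker_panel` objects:
#'   `sorting`, `known`, `cluster_top3`, `slc`, `combined`, `any20`.
#' @export
assemble_panels <- function(stats, curated, universe = stats$protein_id,
                            q_threshold = 0.01, per_cluster = 3L,
                            any20_size = 20L, seed = 1L) {
  stopifnot(is.list(curated),
            all(c("sorting", "known", "slc") %in% names(curated)))
  qmap <- stats::setNames(stats$q, stats$protein_id)

  curate <- function(name) {
    ids <- as.character(curated[[name]])
    unknown <- setdiff(ids, names(qmap))
    if (length(unknown)) {
      warning(sprintf("panel '%s': dropping %d id(s) absent from the matrix",
                      name, length(unknown)))
      ids <- setdiff(ids, unknown)
    }
    ids <- ids[qmap[ids] < q_threshold]
    marker_panel(name, ids, paste0("curated ", name))
  }

  panels <- list(
    sorting = curate("sorting"),
    known = curate("known"),
    cluster_top3 = panel_cluster_top3(stats, per_cluster, q_threshold),
    slc = curate("slc"))

  union_ids <- character(0)
  union_prov <- character(0)
  for (p in panels) {
    new <- !(p$protein_ids %in% union_ids)
    union_ids <- c(union_ids, p$protein_ids[new])
    union_prov <- c(union_prov, paste0("from ", p$name)[rep(1, sum(new))])
  }
  panels$combined <- marker_panel("combined", union_ids, union_prov)

  pool <- setdiff(universe, union_ids)
  if (length(pool) < any20_size)
    stop(sprintf("any20 pool has only %d proteins (< %d)", length(pool),
                 any20_size))
  set.seed(as.integer(seed))
  panels$any20 <- marker_panel("any20", sort(sample(pool, any20_size)),
                               "random control")
  panels
}

#' Serialize a list of panels to a two-column TSV
#'
#' @param panels named list of `marker_panel` objects.
#' @param path output file path (columns `panel_name`, `protein_id`).
#' @return `path`, invisibly.
#' @export
write_panels_tsv <- function(panels, path) {
  df <- do.call(rbind, lapply(panels, function(p)
    data.frame(panel_name = p$name, protein_id = p$protein_ids)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read curated marker lists (one protein id per line)
#'
#' @param paths named character vector/list of file paths.
#' @return named list of character vectors.
#' @export
read_marker_lists <- function(paths) {
  lapply(paths, function(p) {
    ids <- readLines(p)
    ids <- trimws(ids)
    ids[nzchar(ids) & !startsWith(ids, "#")]
  })
}
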