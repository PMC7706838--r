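# Stage 3: multi-stage differential test and temporal clustering.
#
# S0-regularized one-way ANOVA across the five stages with a
# permutation-based FDR (stage labels permuted, statistics pooled), then
# Ward clustering of the z-scored per-stage median profiles of the
# significant proteins into six temporal clusters.

source("analysis/00_config.R")

pm <- read_proteome_tsv(out_path("proteome_matrix.tsv"))
filtered <- filter_completeness(pm, CFG$min_fraction_per_stage,
                                CFG$n_stages_required)
imp <- as.matrix(read.delim(out_path("log2_imputed.tsv"), row.names = 1,
                            check.names = FALSE))

stats <- anova_stage_test(imp, filtered$col_stage,
                          n_permutations = CFG$n_permutations, s0 = CFG$s0,
                          seed = child_seed("anova"))
sig_ids <- stats$protein_id[stats$q < CFG$q_threshold]
cat(sprintf("ANOVA (S0 = %.1f, %d permutations): %d of %d proteins at q < %g\n",
            CFG$s0, CFG$n_permutations, length(sig_ids), nrow(imp),
            CFG$q_threshold))

z <- stage_z_profiles(imp, filtered$col_stage, filtered$stages)
cl <- cluster_profiles(z[sig_ids, , drop = FALSE], k = CFG$n_clusters)
stats$cluster[match(names(cl), stats$protein_id)] <- cl
cat("cluster sizes:", paste(table(cl), collapse = " "), "\n")

# how well do the six clusters recover the generating archetypes?
truth <- read.delim(out_path("ground_truth.tsv"))
arch <- truth$archetype[match(names(cl), truth$protein_id)]
agreement <- table(arch, cl)
cat("dominant archetype per cluster:",
    paste(rownames(agreement)[apply(agreement, 2, which.max)],
          collapse = ", "), "\n")

write.table(stats, out_path("stage_stats.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote", out_path("stage_stats.tsv"), "\n")
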