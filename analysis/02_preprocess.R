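# Stage 2: completeness filter and downshifted-normal imputation.
#
# Keeps proteins quantified in >= 3 of 4 replicates of at least one stage
# (the completeness rule used for intensity matrices of this design), then
# replaces remaining missing log2 values per sample column with draws from
# Normal(mean - 1.8 sd, (0.3 sd)^2) - the left-censored imputation standard
# for MS intensities.

source("analysis/00_config.R")

pm <- read_proteome_tsv(out_path("proteome_matrix.tsv"))
filtered <- filter_completeness(pm, CFG$min_fraction_per_stage,
                                CFG$n_stages_required)
cat(sprintf("completeness filter: %d of %d proteins retained (%.1f%% cells missing before, %.1f%% after)\n",
            nrow(filtered$intensity), nrow(pm$intensity),
            100 * mean(is.na(pm$intensity)),
            100 * mean(is.na(filtered$intensity))))

log2_imp <- impute_missing(log2_matrix(filtered), CFG$impute_width,
                           CFG$impute_downshift, seed = child_seed("impute"))
stopifnot(!anyNA(log2_imp))

imp_tab <- data.frame(protein_id = rownames(log2_imp), log2_imp,
                      check.names = FALSE)
write.table(imp_tab, out_path("log2_imputed.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote", out_path("log2_imputed.tsv"), "\n")
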