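# Stage 6: histone proteomic-ruler copy numbers.
#
# Proteins 100% complete in at least one stage are converted to copies per
# cell by anchoring each sample's summed histone intensity to the DNA mass
# of a diploid genome (2 x 3.25 pg), with per-sample totals giving protein
# mass (pg) and cell volume (fl, at 200 g/l). Note the estimator
# renormalizes every sample to the DNA anchor, so the planted histone
# decline must be read from the ground truth, not from ruler output.

source("analysis/00_config.R")

pm <- read_proteome_tsv(out_path("proteome_matrix.tsv"))
truth <- read.delim(out_path("ground_truth.tsv"))
histones <- truth$protein_id[truth$is_histone]

ruler_input <- filter_completeness(pm, 1, 1L)
histones <- intersect(histones, rownames(ruler_input$intensity))
res <- estimate_copy_numbers(ruler_input, histones, CFG$ruler)
print(res)

summary <- summarize_copies(res, list(histones = histones,
                                      all = rownames(res$copies)))
print(summary, digits = 4)

truth_hist <- as.matrix(truth[truth$is_histone,
                              grep("^copies_", colnames(truth))])
cat(sprintf("planted histone median copies, first -> last stage: %.3g -> %.3g\n",
            median(truth_hist[, 1]), median(truth_hist[, ncol(truth_hist)])))

write_copies_tsv(res, out_path("copy_numbers.tsv"))
write.table(summary, out_path("copy_number_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote", out_path("copy_numbers.tsv"), "and copy_number_summary.tsv\n")
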