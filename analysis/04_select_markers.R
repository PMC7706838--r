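# Stage 4: assemble the six marker panels.
#
# Curated sorting/known/SLC lists (here: the generator's planted panels,
# standing in for curated tables), the data-driven cluster-Top3 panel
# (3 smallest-q proteins per temporal cluster), their deduplicated union
# ("combined"), and the any20 random control drawn from the unfiltered
# protein list excluding all other panels. All panels except any20 are
# restricted to ANOVA q < 0.01.

source("analysis/00_config.R")

stats <- read.delim(out_path("stage_stats.tsv"))
class(stats) <- c("stage_stats", "data.frame")
truth <- read.delim(out_path("ground_truth.tsv"))
curated <- split(truth$protein_id[!is.na(truth$marker_panel)],
                 truth$marker_panel[!is.na(truth$marker_panel)])

panels <- assemble_panels(stats, curated,
                          q_threshold = CFG$q_threshold,
                          per_cluster = CFG$per_cluster,
                          any20_size = CFG$any20_size,
                          seed = child_seed("panels"))
for (p in panels)
  cat(sprintf("%-12s %3d proteins\n", p$name, length(p)))

write_panels_tsv(panels, out_path("marker_panels.tsv"))
cat("wrote", out_path("marker_panels.tsv"), "\n")
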