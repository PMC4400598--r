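#!/usr/bin/env Rscript
# Stage 5 — fertility summaries.
#
# Summarises litters per pair and litter size by group (mean +/- s.d.) and
# compares each group with the control by a two-tailed Welch t-test. Writes
# fertility_summary.csv.
#
# Usage: Rscript analysis/05_fertility.R [control_group]

library(gcorient)

args <- commandArgs(trailingOnly = TRUE)
control <- if (length(args) >= 1L) args[[1L]] else "wild_type_like"
run_dir <- file.path("results", "run")

records <- read_fertility(file.path(run_dir, "fertility.csv"))
summary <- summarize_fertility(records, control = control)
write.csv(summary, file.path(run_dir, "fertility_summary.csv"), row.names = FALSE)

for (i in seq_len(nrow(summary))) {
  message(sprintf(
    "%s (n = %d pairs): %.1f +/- %.1f litters; litter size %.2f +/- %.2f%s",
    summary$group[i], summary$n_pairs[i], summary$mean_litters[i],
    summary$sd_litters[i], summary$mean_litter_size[i], summary$sd_litter_size[i],
    if (is.na(summary$p_size_vs_control[i])) " (control)" else
      sprintf("; p vs control: litters %.3g, size %.3g",
              summary$p_litters_vs_control[i], summary$p_size_vs_control[i])))
}

write_manifest(
  file.path(run_dir, "manifest_fertility.json"), "fertility",
  inputs = file.path(run_dir, "fertility.csv"),
  counts = list(pairs = nrow(records), groups = length(unique(records$group)))
)
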