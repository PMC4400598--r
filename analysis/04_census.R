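#!/usr/bin/env Rscript
# Stage 4 — follicle census.
#
# Classifies every observed follicle on the one-in-five sampled sections into
# its maturation stage (Pedersen-Peters mapping), counts stages per ovary,
# and compares the two groups per stage with Welch t-tests. Writes
# census.json.
#
# Usage: Rscript analysis/04_census.R

library(gcorient)

run_dir <- file.path("results", "run")
obs <- read_census_csv(file.path(run_dir, "census.csv"))

group_of <- sub("_ov[0-9]+$", "", obs$ovary_id)
gnames <- unique(group_of)
per_ovary <- lapply(gnames, function(g) {
  census_from_sections(obs[group_of == g, ], sampling_fraction = 1 / 5)
})
names(per_ovary) <- gnames

comparison <- NULL
if (length(gnames) >= 2L) {
  comparison <- compare_census(per_ovary[[1L]], per_ovary[[2L]], labels = gnames[1:2])
  for (i in seq_len(nrow(comparison))) {
    message(sprintf("%-12s %6.1f +/- %5.1f  vs %6.1f +/- %5.1f   Welch p = %.3g",
                    comparison$stage[i], comparison$mean_1[i], comparison$sd_1[i],
                    comparison$mean_2[i], comparison$sd_2[i], comparison$p_welch[i]))
  }
}

jsonlite::write_json(
  list(per_ovary = per_ovary, comparison = comparison),
  file.path(run_dir, "census.json"),
  auto_unbox = TRUE, digits = 12, dataframe = "columns", pretty = TRUE
)
write_manifest(
  file.path(run_dir, "manifest_census.json"), "census",
  inputs = file.path(run_dir, "census.csv"),
  counts = list(observations = nrow(obs),
                ovaries = length(unique(obs$ovary_id)))
)
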