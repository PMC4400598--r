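#!/usr/bin/env Rscript
# Stage 2 — score division angles from the annotation file.
#
# Reads results/run/annotations.csv, builds per cell the oocyte-basal-membrane
# axis and the phase-appropriate spindle axis, and writes one theta per
# mitotic cell to results/run/angles.csv. Degenerate cells are skipped and
# counted in the manifest, never silently dropped.
#
# Usage: Rscript analysis/02_angles.R

library(gcorient)

run_dir <- file.path("results", "run")
sections <- read_annotations(file.path(run_dir, "annotations.csv"))
angles <- angles_for_sections(sections)
skipped <- attr(angles, "skipped")
write_angles(angles, file.path(run_dir, "angles.csv"))

write_manifest(
  file.path(run_dir, "manifest_angles.json"), "angles",
  inputs = file.path(run_dir, "annotations.csv"),
  counts = list(
    cells_in = sum(vapply(sections, function(s) length(s$cells), integer(1))),
    angles_out = nrow(angles),
    skipped = nrow(skipped)
  )
)

message(sprintf("Scored %d mitotic cells from %d follicle sections (%d skipped).",
                nrow(angles), length(sections), nrow(skipped)))
message(sprintf("Overall median theta = %.1f deg.", median(angles$theta_deg)))
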