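# Human-readable run report assembled from a completed run directory.

#' Render a Markdown summary of a pipeline run
#'
#' Reads whatever stages a run directory contains — `angles.csv`,
#' `stats.json`, `census.json`, `fertility_summary.csv`, and any
#' `manifest_*.json` — and writes `report.md`: per-group angle summaries and
#' KS blocks, the pairwise rank comparison, census tables, fertility
#' summaries, and the embedded manifests. Missing stages are noted, not
#' fabricated. Input digests recorded in the manifests are re-checked and a
#' warning line is emitted for any file that changed since its stage ran.
#'
#' @param run_dir directory holding the run outputs.
#' @param out_path output Markdown path (default `report.md` inside `run_dir`).
#' @return The output path, invisibly.
#' @export
render_run_report <- function(run_dir, out_path = file.path(run_dir, "report.md")) {
  if (!dir.exists(run_dir)) gc_abort(sprintf("no run directory: %s", run_dir), "gcorient_io_error")
  has <- function(f) file.exists(file.path(run_dir, f))
  if (!has("stats.json") && !has("angles.csv")) {
    gc_abort("run directory holds neither angles.csv nor stats.json; nothing to report",
             "gcorient_io_error")
  }
  ln <- character()
  push <- function(...) ln <<- c(ln, sprintf(...))
  push("# Granulosa-cell division orientation: run report")
  push("")

  # digest verification across all manifests
  manifests <- sort(list.files(run_dir, pattern = "^manifest_.*\\.json$", full.names = TRUE))
  tampered <- character()
  for (mf in manifests) {
    m <- read_manifest(mf)
    tampered <- c(tampered, verify_manifest_digests(m, run_dir))
  }
  if (length(tampered)) {
    push("**WARNING: input digest mismatch** — file(s) changed since their stage ran: %s",
         paste(unique(tampered), collapse = ", "))
    push("")
  }

  if (has("angles.csv")) {
    ang <- read_angles(file.path(run_dir, "angles.csv"))
    push("## Division angles")
    push("")
    push("%d mitotic cells scored; overall median theta = %.1f deg.",
         nrow(ang), median(ang$theta_deg))
    push("")
  }

  if (has("stats.json")) {
    stats <- jsonlite::read_json(file.path(run_dir, "stats.json"))
    ks_blocks <- Filter(function(b) identical(b$type, "ks_vs_random"), stats)
    mw_blocks <- Filter(function(b) identical(b$type, "mann_whitney"), stats)
    if (length(ks_blocks)) {
      push("## Uniformity tests (KS vs random)")
      push("")
      for (b in ks_blocks) {
        push("- **%s** (n = %s, median %.1f deg): D = %.4f, p = %.4g [%s, %s]",
             b$label, b$n, as.numeric(b$median_deg), as.numeric(b$D),
             as.numeric(b$p), b$mode, b$method)
      }
      push("")
    }
    for (b in mw_blocks) {
      push("## Group comparison (%s vs %s)", b$labels[[1]], b$labels[[2]])
      push("")
      push("Mann-Whitney U = %s, p = %.4g (%s); medians %.1f vs %.1f deg;",
           b$U, as.numeric(b$p_mw), b$method, as.numeric(b$median_1),
           as.numeric(b$median_2))
      push("Hodges-Lehmann shift %.1f deg [%d%% CI %.1f, %.1f].",
           as.numeric(b$hl_shift), round(100 * as.numeric(b$confidence)),
           as.numeric(b$ci_low), as.numeric(b$ci_high))
      push("")
    }
  }

  push("## Follicle census")
  push("")
  if (has("census.json")) {
    cs <- jsonlite::read_json(file.path(run_dir, "census.json"))
    for (gname in names(cs$per_ovary)) {
      push("### %s", gname)
      push("")
      tab <- cs$per_ovary[[gname]]
      push("| ovary | %s |", paste(FOLLICLE_STAGES, collapse = " | "))
      push("|%s", paste(rep("---|", length(FOLLICLE_STAGES) + 1L), collapse = ""))
      for (i in seq_along(tab$ovary_id)) {
        push("| %s | %s |", tab$ovary_id[[i]],
             paste(vapply(FOLLICLE_STAGES, function(st) as.character(tab[[st]][[i]]),
                          character(1)), collapse = " | "))
      }
      push("")
    }
    if (!is.null(cs$comparison)) {
      push("Per-stage Welch p-values: %s.",
           paste(sprintf("%s %.3g", vapply(cs$comparison$stage, identity, character(1)),
                         vapply(cs$comparison$p_welch, as.numeric, numeric(1))),
                 collapse = "; "))
      push("")
    }
  } else {
    push("Census stage not run; section omitted.")
    push("")
  }

  if (has("fertility_summary.csv")) {
    fs <- read.csv(file.path(run_dir, "fertility_summary.csv"), stringsAsFactors = FALSE)
    push("## Fertility")
    push("")
    for (i in seq_len(nrow(fs))) {
      push("- **%s** (n = %d pairs): %.1f +/- %.1f litters; litter size %.1f +/- %.1f%s",
           fs$group[i], fs$n_pairs[i], fs$mean_litters[i], fs$sd_litters[i],
           fs$mean_litter_size[i], fs$sd_litter_size[i],
           if (is.na(fs$p_size_vs_control[i])) " (control)" else
             sprintf("; p vs control: litters %.3g, size %.3g",
                     fs$p_litters_vs_control[i], fs$p_size_vs_control[i]))
    }
    push("")
  }

  if (length(manifests)) {
    push("## Manifests")
    push("")
    for (mf in manifests) {
      push("### %s", basename(mf))
      push("")
      push("```json")
      ln <- c(ln, readLines(mf))
      push("```")
      push("")
    }
  }

  writeLines(ln, out_path)
  invisible(out_path)
}
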