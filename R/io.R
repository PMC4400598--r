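# File dialects: annotation CSV, angle CSV, census CSV, fertility CSV,
# stats JSON/TSV.

ANNOTATION_ROLES <- c("oocyte_centre", "lamina_vertex", "cell_centre", "landmark")

#' Write follicle sections to the annotation CSV dialect
#'
#' Columns: `follicle_id, cell_id, role, phase, x, y, group`, with `role` in
#' `oocyte_centre, lamina_vertex, cell_centre, landmark` and `group` in
#' `a, b, ""` (anaphase chromatid groups). One file may hold many follicles.
#' The dialect carries no oocyte radius or layer count; those live with the
#' generator's truth output.
#'
#' @param sections list of `gc_section` objects.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_annotations <- function(sections, path) {
  rows <- list()
  add <- function(fid, cid, role, phase, x, y, group) {
    rows[[length(rows) + 1L]] <<- data.frame(
      follicle_id = fid, cell_id = cid, role = role, phase = phase,
      x = x, y = y, group = group, stringsAsFactors = FALSE
    )
  }
  for (sec in sections) {
    fid <- sec$follicle_id
    add(fid, "", "oocyte_centre", "", sec$oocyte_centre[1L], sec$oocyte_centre[2L], "")
    add(fid, "", "lamina_vertex", "", sec$basal_lamina[, 1L], sec$basal_lamina[, 2L], "")
    for (cell in sec$cells) {
      add(fid, cell$cell_id, "cell_centre", cell$phase,
          cell$centre[1L], cell$centre[2L], "")
      if (cell$phase == "metaphase") {
        add(fid, cell$cell_id, "landmark", cell$phase,
            cell$landmarks[, 1L], cell$landmarks[, 2L], "")
      } else {
        add(fid, cell$cell_id, "landmark", cell$phase,
            cell$landmarks_a[, 1L], cell$landmarks_a[, 2L], "a")
        add(fid, cell$cell_id, "landmark", cell$phase,
            cell$landmarks_b[, 1L], cell$landmarks_b[, 2L], "b")
      }
    }
  }
  out <- do.call(rbind, rows)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read follicle sections from the annotation CSV dialect
#'
#' Validates the schema (required columns, known `role` and `phase` values,
#' finite coordinates) with row numbers in every error message, then
#' assembles one `gc_section` per follicle. The dialect does not carry the
#' oocyte radius, so sections are built with `oocyte_radius = NA` (the
#' disc-exclusion check is skipped) and `layer_count = 1`.
#'
#' @param path annotation CSV file.
#' @param validate run section validation on assembly.
#' @return Named list of `gc_section` objects.
#' @export
read_annotations <- function(path, validate = TRUE) {
  if (!file.exists(path)) gc_abort(sprintf("file not found: %s", path), "gcorient_io_error")
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("follicle_id", "cell_id", "role", "phase", "x", "y", "group")
  for (col in setdiff(need, c("x", "y"))) {
    if (col %in% names(df)) df[[col]] <- as.character(df[[col]])
  }
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    validation_error(sprintf("annotation file misses column(s): %s",
                             paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) == 0L) return(list())
  df$group[is.na(df$group)] <- ""
  df$phase[is.na(df$phase)] <- ""
  bad_role <- which(!df$role %in% ANNOTATION_ROLES)
  if (length(bad_role)) {
    validation_error(sprintf("unknown role '%s' at row %d", df$role[bad_role[1L]],
                             bad_role[1L] + 1L))  # +1: header line
  }
  bad_xy <- which(!is.finite(df$x) | !is.finite(df$y))
  if (length(bad_xy)) {
    validation_error(sprintf("non-finite coordinates at row %d", bad_xy[1L] + 1L))
  }
  cellish <- df$role %in% c("cell_centre", "landmark")
  bad_phase <- which(cellish & !df$phase %in% PHASES)
  if (length(bad_phase)) {
    validation_error(sprintf("unknown phase '%s' at row %d", df$phase[bad_phase[1L]],
                             bad_phase[1L] + 1L))
  }
  sections <- list()
  for (fid in unique(df$follicle_id)) {
    fd <- df[df$follicle_id == fid, , drop = FALSE]
    oc <- fd[fd$role == "oocyte_centre", , drop = FALSE]
    if (nrow(oc) != 1L) {
      validation_error(sprintf("follicle '%s': expected exactly one oocyte_centre row", fid))
    }
    lam <- fd[fd$role == "lamina_vertex", , drop = FALSE]
    cells <- list()
    for (cid in unique(fd$cell_id[fd$role == "cell_centre"])) {
      cd <- fd[fd$cell_id == cid & fd$cell_id != "", , drop = FALSE]
      cc <- cd[cd$role == "cell_centre", , drop = FALSE]
      lmk <- cd[cd$role == "landmark", , drop = FALSE]
      phase <- cc$phase[1L]
      if (phase == "metaphase") {
        cells[[cid]] <- mitotic_cell(cid, c(cc$x[1L], cc$y[1L]), phase,
                                     landmarks = cbind(lmk$x, lmk$y))
      } else {
        la <- lmk[lmk$group == "a", , drop = FALSE]
        lb <- lmk[lmk$group == "b", , drop = FALSE]
        if (nrow(la) == 0L || nrow(lb) == 0L) {
          validation_error(sprintf(
            "follicle '%s', cell '%s': anaphase needs landmark groups a and b", fid, cid))
        }
        cells[[cid]] <- mitotic_cell(cid, c(cc$x[1L], cc$y[1L]), phase,
                                     landmarks_a = cbind(la$x, la$y),
                                     landmarks_b = cbind(lb$x, lb$y))
      }
    }
    sections[[fid]] <- follicle_section(
      fid, c(oc$x[1L], oc$y[1L]), cbind(lam$x, lam$y), cells,
      oocyte_radius = NA_real_, layer_count = 1L, validate = validate
    )
  }
  sections
}

#' Write scored angles to CSV
#'
#' Columns: `follicle_id, cell_id, phase, theta_deg`.
#' @param angles data frame from [angles_for_sections()].
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_angles <- function(angles, path) {
  write.csv(angles[, c("follicle_id", "cell_id", "phase", "theta_deg")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read scored angles from CSV
#' @param path angle CSV file.
#' @return Data frame `follicle_id, cell_id, phase, theta_deg`.
#' @export
read_angles <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Read census observations from CSV
#'
#' Expects columns `ovary_id, section_index, follicle_id, layer_count,
#' gc_morphology, antral_cavities, oocyte_diameter_um`.
#' @param path census CSV file.
#' @return Data frame of follicle observations.
#' @export
read_census_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("ovary_id", "section_index", "follicle_id", "layer_count",
            "gc_morphology", "antral_cavities", "oocyte_diameter_um")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    validation_error(sprintf("census file misses column(s): %s",
                             paste(missing_cols, collapse = ", ")))
  }
  df
}

#' Read fertility records from CSV
#' @param path fertility CSV with columns `group, pair_id, litters, litter_size`.
#' @return Data frame of per-pair records.
#' @export
read_fertility <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write a stats report as JSON plus a flat TSV
#'
#' @param comparisons list of comparison blocks (each a named list with the
#'   KS/Mann-Whitney fields).
#' @param json_path,tsv_path output files (either may be NULL to skip).
#' @return Invisibly, the comparisons list.
#' @export
write_stats_report <- function(comparisons, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(comparisons, json_path, auto_unbox = TRUE, digits = 12,
                         pretty = TRUE)
  }
  if (!is.null(tsv_path)) {
    flat <- lapply(comparisons, function(b) {
      as.data.frame(lapply(b, function(v) {
        if (length(v) > 1L) paste(v, collapse = ";") else if (is.null(v)) NA else v
      }), stringsAsFactors = FALSE)
    })
    all_names <- unique(unlist(lapply(flat, names)))
    flat <- lapply(flat, function(d) { d[setdiff(all_names, names(d))] <- NA; d[all_names] })
    tab <- do.call(rbind, flat)
    write.table(tab, tsv_path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(comparisons)
}
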