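# Follicle-section containers and the per-section angle pass.

PHASES <- c("metaphase", "anaphase")

#' Annotate one mitotic granulosa cell
#'
#' @param cell_id identifier.
#' @param centre cell centre point.
#' @param phase `"metaphase"` or `"anaphase"`.
#' @param landmarks metaphase: >= 2 points along the metaphase plate
#'   (2-column matrix or list of points). Ignored for anaphase.
#' @param landmarks_a,landmarks_b anaphase only: the two non-empty point
#'   groups, one per segregating chromatid mass.
#' @return An object of class `gc_cell`.
#' @export
mitotic_cell <- function(cell_id, centre, phase,
                         landmarks = NULL, landmarks_a = NULL, landmarks_b = NULL) {
  if (!phase %in% PHASES) {
    validation_error(sprintf("phase must be one of %s", paste(PHASES, collapse = ", ")))
  }
  if (phase == "metaphase") {
    if (is.null(landmarks) || nrow(as_point_matrix(landmarks)) < 2L) {
      validation_error(sprintf("cell '%s': metaphase requires >= 2 plate landmarks", cell_id))
    }
  } else {
    if (is.null(landmarks_a) || is.null(landmarks_b)) {
      validation_error(sprintf("cell '%s': anaphase requires two landmark groups", cell_id))
    }
  }
  structure(
    list(
      cell_id = as.character(cell_id),
      centre = as.numeric(centre)[1:2],
      phase = phase,
      landmarks = if (!is.null(landmarks)) as_point_matrix(landmarks),
      landmarks_a = if (!is.null(landmarks_a)) as_point_matrix(landmarks_a),
      landmarks_b = if (!is.null(landmarks_b)) as_point_matrix(landmarks_b)
    ),
    class = "gc_cell"
  )
}

#' Assemble one annotated follicle section
#'
#' @param follicle_id identifier.
#' @param oocyte_centre oocyte centre point.
#' @param basal_lamina closed polygon outlining the follicle (>= 3 vertices;
#'   do not repeat the first vertex).
#' @param cells list of [mitotic_cell()] annotations.
#' @param oocyte_radius oocyte radius (> 0), or `NA` when the annotation
#'   source does not record it (the cell-outside-oocyte check is then skipped).
#' @param layer_count number of granulosa layers (1 or 2 for angle analysis).
#' @param validate run [validate_section()] on construction.
#' @return An object of class `gc_section`.
#' @export
follicle_section <- function(follicle_id, oocyte_centre, basal_lamina,
                             cells = list(), oocyte_radius = NA_real_,
                             layer_count = 1L, validate = TRUE) {
  sec <- structure(
    list(
      follicle_id = as.character(follicle_id),
      oocyte_centre = as.numeric(oocyte_centre)[1:2],
      oocyte_radius = as.numeric(oocyte_radius),
      basal_lamina = as_point_matrix(basal_lamina),
      layer_count = as.integer(layer_count),
      cells = cells
    ),
    class = "gc_section"
  )
  if (validate) validate_section(sec)
  sec
}

#' @noRd
inside_polygon <- function(pts, poly) {
  pts <- as_point_matrix(pts)
  pracma::inpolygon(pts[, 1L], pts[, 2L], poly[, 1L], poly[, 2L],
                    boundary = FALSE)
}

#' Validate a follicle section's geometric invariants
#'
#' Checks: basal lamina has >= 3 vertices; oocyte centre strictly inside it;
#' oocyte radius (when known) positive; every cell centre inside the lamina
#' and (when the radius is known) outside the oocyte disc; layer_count 1 or 2.
#'
#' @param section a `gc_section`.
#' @return The section, invisibly; signals a validation error otherwise.
#' @export
validate_section <- function(section) {
  fid <- section$follicle_id
  if (nrow(section$basal_lamina) < 3L) {
    validation_error(sprintf("follicle '%s': basal lamina needs >= 3 vertices", fid))
  }
  if (!section$layer_count %in% c(1L, 2L)) {
    validation_error(sprintf("follicle '%s': layer_count must be 1 or 2 for angle analysis", fid))
  }
  if (!inside_polygon(section$oocyte_centre, section$basal_lamina)) {
    validation_error(sprintf("follicle '%s': oocyte centre not strictly inside basal lamina", fid))
  }
  r <- section$oocyte_radius
  if (!is.na(r) && r <= 0) {
    validation_error(sprintf("follicle '%s': oocyte radius must be > 0", fid))
  }
  for (cell in section$cells) {
    if (!inside_polygon(cell$centre, section$basal_lamina)) {
      validation_error(sprintf(
        "follicle '%s': centre of cell '%s' outside basal lamina", fid, cell$cell_id
      ))
    }
    if (!is.na(r)) {
      d <- sqrt(sum((cell$centre - section$oocyte_centre)^2))
      if (d <= r) {
        validation_error(sprintf(
          "follicle '%s': centre of cell '%s' inside the oocyte disc", fid, cell$cell_id
        ))
      }
    }
  }
  invisible(section)
}

#' Score the division angle of every mitotic cell in a section
#'
#' For each cell the oocyte-basal-membrane axis (oocyte centre -> cell centre)
#' and the phase-appropriate spindle axis are built and theta is computed.
#' Cells with degenerate geometry are skipped, counted and reported in the
#' `"skipped"` attribute — never silently dropped. Section-level invariant
#' violations abort before any angle is computed.
#'
#' @param section a `gc_section`.
#' @return A data frame with columns `follicle_id, cell_id, phase, theta_deg`
#'   (one row per successfully scored cell), with attribute `skipped`: a data
#'   frame `follicle_id, cell_id, reason` of cells that could not be scored.
#' @export
angles_for_section <- function(section) {
  validate_section(section)
  rows <- vector("list", length(section$cells))
  skipped <- list()
  for (i in seq_along(section$cells)) {
    cell <- section$cells[[i]]
    res <- tryCatch(
      {
        ob <- oocyte_basal_axis(section$oocyte_centre, cell$centre, cell$cell_id)
        sp <- spindle_axis_for_cell(cell)
        division_angle(ob, sp)
      },
      gcorient_degenerate_geometry = function(e) e
    )
    if (inherits(res, "condition")) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        follicle_id = section$follicle_id,
        cell_id = cell$cell_id,
        reason = conditionMessage(res),
        stringsAsFactors = FALSE
      )
    } else {
      rows[[i]] <- data.frame(
        follicle_id = section$follicle_id,
        cell_id = cell$cell_id,
        phase = cell$phase,
        theta_deg = res,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, c(rows, list(data.frame(
    follicle_id = character(), cell_id = character(),
    phase = character(), theta_deg = numeric(), stringsAsFactors = FALSE
  ))))
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) {
    do.call(rbind, skipped)
  } else {
    data.frame(follicle_id = character(), cell_id = character(),
               reason = character(), stringsAsFactors = FALSE)
  }
  out
}

#' Score division angles for a list of sections
#'
#' @param sections list of `gc_section` objects.
#' @return As [angles_for_section()], rows concatenated across sections.
#' @export
angles_for_sections <- function(sections) {
  parts <- lapply(sections, angles_for_section)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  attr(out, "skipped") <- do.call(rbind, lapply(parts, attr, "skipped"))
  out
}
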