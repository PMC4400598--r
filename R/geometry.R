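# Geometry engine: axes from point annotations and the division angle theta.
# Coordinates are unit-agnostic (pixels or micrometres); angles are degrees.
# Coincidence threshold 1e-9 coordinate units; unit-vector norm tolerance 1e-12.

.COINCIDENCE_TOL <- 1e-9

#' Construct a 2-D point
#'
#' @param x,y finite real coordinates (pixels or micrometres).
#' @return A length-2 named numeric vector `c(x, y)`.
#' @export
point2d <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != 1L || length(y) != 1L ||
      !is.finite(x) || !is.finite(y)) {
    validation_error("point2d() requires finite scalar coordinates")
  }
  c(x = x, y = y)
}

# coerce a list of points / 2-column matrix to an n x 2 matrix
as_point_matrix <- function(pts) {
  if (is.matrix(pts)) {
    m <- pts
  } else if (is.list(pts)) {
    m <- do.call(rbind, lapply(pts, function(p) as.numeric(p)[1:2]))
  } else if (is.numeric(pts) && length(pts) == 2L) {
    m <- matrix(pts, nrow = 1L)
  } else {
    validation_error("points must be a 2-column matrix, a list of points, or a single point")
  }
  if (ncol(m) != 2L || !all(is.finite(m))) {
    validation_error("points must be finite 2-D coordinates")
  }
  colnames(m) <- c("x", "y")
  m
}

#' Construct an undirected 2-D axis
#'
#' An axis is a line through `origin` with unit `direction`; an axis and its
#' reversal (direction negated) are equivalent, which is why [division_angle()]
#' folds with the absolute dot product.
#'
#' @param origin a point (see [point2d()]).
#' @param direction a 2-D vector; it is normalised to unit length.
#' @return An object of class `gc_axis` with fields `origin` and `direction`
#'   (unit norm within 1e-12).
#' @export
axis2d <- function(origin, direction) {
  direction <- as.numeric(direction)[1:2]
  nrm <- sqrt(sum(direction^2))
  if (!is.finite(nrm) || nrm < .COINCIDENCE_TOL) {
    degenerate_geometry_error("axis direction has (near-)zero length")
  }
  d <- direction / nrm
  # one more normalisation pass keeps |d| within 1e-12 even for extreme inputs
  d <- d / sqrt(sum(d^2))
  structure(
    list(origin = as.numeric(origin)[1:2], direction = d),
    class = "gc_axis"
  )
}

#' Oocyte-basal-membrane axis
#'
#' The line dissecting the oocyte centre, the centre of the mitotic granulosa
#' cell and (extended) the basal lamina. Mathematically the axis is fixed by
#' the two centres; the basal lamina enters only through the section
#' containment checks.
#'
#' @param oocyte_centre,cell_centre distinct points.
#' @param cell_id optional identifier used in error messages.
#' @return A `gc_axis` with direction `cell_centre - oocyte_centre` normalised.
#' @export
oocyte_basal_axis <- function(oocyte_centre, cell_centre, cell_id = NULL) {
  o <- as.numeric(oocyte_centre)[1:2]
  p <- as.numeric(cell_centre)[1:2]
  v <- p - o
  if (sqrt(sum(v^2)) <= .COINCIDENCE_TOL) {
    degenerate_geometry_error(sprintf(
      "oocyte centre and cell centre coincide%s",
      if (is.null(cell_id)) "" else sprintf(" (cell '%s')", cell_id)
    ))
  }
  axis2d(o, v)
}

#' Spindle axis of an anaphase cell
#'
#' The spindle axis is the line parallel to the direction of the separating
#' chromosomes: the segment joining the centroids of the two chromatid-mass
#' landmark groups.
#'
#' @param group_a,group_b non-empty point sets (lists or 2-column matrices),
#'   one per segregating chromatid mass.
#' @return A `gc_axis` through the midpoint of the two centroids.
#' @export
spindle_axis_anaphase <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    degenerate_geometry_error("anaphase requires two non-empty chromatid groups")
  }
  a <- as_point_matrix(group_a)
  b <- as_point_matrix(group_b)
  ca <- colMeans(a)
  cb <- colMeans(b)
  v <- cb - ca
  if (sqrt(sum(v^2)) <= .COINCIDENCE_TOL) {
    degenerate_geometry_error("anaphase chromatid-group centroids coincide")
  }
  axis2d((ca + cb) / 2, v)
}

#' Spindle axis of a metaphase cell
#'
#' A line along the metaphase plate is fitted through the plate landmarks
#' (two points: exactly through both; more: first principal axis by orthogonal
#' total-least-squares regression, appropriate because the plate is a
#' chromatin band rather than a two-ended segment). The spindle axis is the
#' perpendicular to that line through the plate centroid.
#'
#' @param plate_points >= 2 landmark points along the metaphase plate.
#' @return A `gc_axis` perpendicular to the fitted plate line.
#' @export
spindle_axis_metaphase <- function(plate_points) {
  m <- as_point_matrix(plate_points)
  if (nrow(m) < 2L) {
    degenerate_geometry_error("metaphase requires at least 2 plate points")
  }
  ctr <- colMeans(m)
  if (nrow(m) == 2L) {
    plate_dir <- m[2L, ] - m[1L, ]
    if (sqrt(sum(plate_dir^2)) <= .COINCIDENCE_TOL) {
      degenerate_geometry_error("metaphase plate points coincide")
    }
  } else {
    cen <- sweep(m, 2L, ctr)
    s <- crossprod(cen)   # 2x2 scatter matrix
    if (max(abs(s)) <= .COINCIDENCE_TOL^2) {
      degenerate_geometry_error("metaphase plate points all coincide")
    }
    plate_dir <- eigen(s, symmetric = TRUE)$vectors[, 1L]
  }
  axis2d(ctr, c(-plate_dir[2L], plate_dir[1L]))
}

#' Division angle theta between two axes
#'
#' theta = arccos(|d1 . d2|) in degrees, folded into \[0, 90\] because an axis
#' has no sign. Symmetric in its arguments and invariant under reversal of
#' either direction.
#'
#' @param axis_ob,axis_spindle `gc_axis` objects (or raw 2-D direction vectors).
#' @return Angle in degrees in \[0, 90\].
#' @export
division_angle <- function(axis_ob, axis_spindle) {
  d1 <- if (inherits(axis_ob, "gc_axis")) axis_ob$direction else axis2d(c(0, 0), axis_ob)$direction
  d2 <- if (inherits(axis_spindle, "gc_axis")) axis_spindle$direction else axis2d(c(0, 0), axis_spindle)$direction
  cosang <- abs(sum(d1 * d2))
  acos(min(max(cosang, 0), 1)) * 180 / pi
}

#' @noRd
spindle_axis_for_cell <- function(cell) {
  switch(cell$phase,
    metaphase = spindle_axis_metaphase(cell$landmarks),
    anaphase = spindle_axis_anaphase(cell$landmarks_a, cell$landmarks_b),
    validation_error(sprintf("unknown phase '%s' for cell '%s'", cell$phase, cell$cell_id))
  )
}
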