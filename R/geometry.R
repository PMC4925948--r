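# Cone-beam C-arm projection geometry. World frame: isocenter at the origin,
# patient axes x = left, y = posterior, z = superior. At zero gantry angles
# the source sits posterior to the patient at (0, sod, 0), the beam travels
# along -y, and the detector plane lies at distance SID from the source with
# in-plane axes u0 = +x (image columns grow toward patient left) and
# r0 = -z (image rows grow toward the feet). The gantry rotation is the
# primary (LAO positive) rotation about +z composed with the secondary
# (cranial positive) rotation about +x, applied in that order to the
# baseline frame.

rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}
rot_x <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
}

#' Cone-beam projection geometry of one angiographic view
#'
#' @param sid source-to-intensifier (detector) distance in mm.
#' @param pixel_size_mm detector pixel size in mm/px.
#' @param primary_deg gantry primary angle in degrees (LAO positive,
#'   RAO negative).
#' @param secondary_deg gantry secondary angle in degrees (cranial positive,
#'   caudal negative).
#' @param sod source-to-isocenter distance in mm; defaults to `sid / 2`.
#' @param image_size `c(rows, cols)` of the detector raster; the principal
#'   point is its centre.
#' @param translation optional world-frame translation (mm) applied to the
#'   whole view (table motion between acquisitions).
#' @return a `projection_geometry` object with derived fields: `source`
#'   (3D source position), `det_origin` (detector centre), `axis_row`,
#'   `axis_col` (detector in-plane unit axes) and `beam` (unit beam
#'   direction, source toward detector).
#' @export
projection_geometry <- function(sid, pixel_size_mm, primary_deg = 0,
                                secondary_deg = 0, sod = sid / 2,
                                image_size = c(512, 512),
                                translation = c(0, 0, 0)) {
  if (sid <= 0) stop("`sid` must be positive")
  if (pixel_size_mm <= 0) stop("`pixel_size_mm` must be positive")
  if (sod <= 0 || sod >= sid) stop("`sod` must lie strictly between 0 and `sid`")
  R <- rot_z(primary_deg * pi / 180) %*% rot_x(secondary_deg * pi / 180)
  source <- as.vector(R %*% c(0, sod, 0)) + translation
  beam <- as.vector(R %*% c(0, -1, 0))
  det_origin <- source + sid * beam
  axis_col <- as.vector(R %*% c(1, 0, 0))
  axis_row <- as.vector(R %*% c(0, 0, -1))
  structure(list(sid = sid, pixel_size_mm = pixel_size_mm,
                 primary_deg = primary_deg, secondary_deg = secondary_deg,
                 sod = sod, image_size = as.integer(image_size),
                 translation = translation,
                 source = source, beam = beam, det_origin = det_origin,
                 axis_row = axis_row, axis_col = axis_col),
            class = "projection_geometry")
}

#' @export
print.projection_geometry <- function(x, ...) {
  cat(sprintf("projection_geometry: SID %.0f mm, SOD %.0f mm, %.3g mm/px, primary %+.1f deg, secondary %+.1f deg\n",
              x$sid, x$sod, x$pixel_size_mm, x$primary_deg, x$secondary_deg))
  invisible(x)
}

#' Read a projection geometry from a JSON block
#'
#' The JSON object carries the acquisition parameters normally found in the
#' DICOM header: `sid`, `pixel_size_mm`, `primary_deg`, `secondary_deg`, and
#' optionally `sod`, `image_size`, `translation`.
#'
#' @param x path to a JSON file, a JSON string, or an already-parsed list.
#' @return a [projection_geometry()].
#' @export
geometry_from_json <- function(x) {
  if (is.character(x)) x <- jsonlite::fromJSON(x)
  do.call(projection_geometry, x[intersect(names(x),
    names(formals(projection_geometry)))])
}

#' Project a 3D point into a view
#'
#' Perspective projection along the ray from the source through `X3` onto the
#' detector plane, returned in pixel coordinates `(row, col)`.
#'
#' @param geom a [projection_geometry()].
#' @param X3 3D point (mm) or n x 3 matrix of points.
#' @return `(row, col)` vector, or n x 2 matrix for matrix input.
#' @export
project_point <- function(geom, X3) {
  X <- if (is.matrix(X3)) X3 else matrix(X3, 1, 3)
  dvec <- X - matrix(geom$source, nrow(X), 3, byrow = TRUE)
  depth <- dvec %*% geom$beam
  if (any(abs(depth) < 1e-12)) stop("ray parallel to the detector plane")
  if (any(depth < 0)) stop("point lies behind the source")
  t <- geom$sid / depth
  P <- matrix(geom$source, nrow(X), 3, byrow = TRUE) + dvec * as.vector(t)
  rel <- P - matrix(geom$det_origin, nrow(X), 3, byrow = TRUE)
  out <- cbind(row = as.vector(rel %*% geom$axis_row) / geom$pixel_size_mm +
                 (geom$image_size[1] + 1) / 2,
               col = as.vector(rel %*% geom$axis_col) / geom$pixel_size_mm +
                 (geom$image_size[2] + 1) / 2)
  if (is.matrix(X3)) out else out[1, ]
}

# Unit direction of the back-projection ray of pixel(s) (row, col).
backproject_ray <- function(geom, px) {
  P <- if (is.matrix(px)) px else matrix(px, 1, 2)
  rel_r <- (P[, 1] - (geom$image_size[1] + 1) / 2) * geom$pixel_size_mm
  rel_c <- (P[, 2] - (geom$image_size[2] + 1) / 2) * geom$pixel_size_mm
  pts <- matrix(geom$det_origin, nrow(P), 3, byrow = TRUE) +
    outer(rel_r, geom$axis_row) + outer(rel_c, geom$axis_col)
  d <- pts - matrix(geom$source, nrow(P), 3, byrow = TRUE)
  d / sqrt(rowSums(d^2))
}

#' Triangulate a 3D point from two views
#'
#' Back-projects the two pixel observations into rays and returns the
#' midpoint of their common perpendicular, with half its length as the
#' reconstruction residual (0 mm for exact correspondences).
#'
#' @param geomA,geomB the two [projection_geometry()] objects.
#' @param pA,pB `(row, col)` pixel coordinates of the same 3D point in each
#'   view.
#' @return list with `point` (3D mm) and `residual` (mm).
#' @export
triangulate <- function(geomA, geomB, pA, pB) {
  dA <- as.vector(backproject_ray(geomA, pA))
  dB <- as.vector(backproject_ray(geomB, pB))
  cr <- c(dA[2] * dB[3] - dA[3] * dB[2],
          dA[3] * dB[1] - dA[1] * dB[3],
          dA[1] * dB[2] - dA[2] * dB[1])
  sin_angle <- sqrt(sum(cr^2))
  if (sin_angle < 1e-6)
    stop("degenerate geometry: back-projected rays are (near) parallel")
  SA <- geomA$source; SB <- geomB$source
  w <- SB - SA
  a <- sum(dA * dA); b <- sum(dA * dB); c2 <- sum(dB * dB)
  d <- sum(dA * w); e <- sum(dB * w)
  den <- a * c2 - b * b
  tA <- (c2 * d - b * e) / den
  tB <- (b * d - a * e) / den
  PA <- SA + tA * dA
  PB <- SB + tB * dB
  list(point = (PA + PB) / 2, residual = sqrt(sum((PA - PB)^2)) / 2)
}

# 2D epipolar line in view B of pixel pA observed in view A, as a point on
# the line and a unit direction (pixel coordinates of view B).
epipolar_line <- function(geomA, geomB, pA, depth_frac = c(0.4, 0.9)) {
  dA <- as.vector(backproject_ray(geomA, pA))
  X1 <- geomA$source + depth_frac[1] * geomA$sid * dA
  X2 <- geomA$source + depth_frac[2] * geomA$sid * dA
  p1 <- project_point(geomB, X1)
  p2 <- project_point(geomB, X2)
  dir <- p2 - p1
  list(origin = p1, dir = dir / sqrt(sum(dir^2)))
}
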