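# Centreline extraction between user-selected points: snapping to the
# skeleton, weighted shortest path along skeleton pixels, and sub-pixel spline
# smoothing that excludes bifurcation pixels from the support.

#' Snap a point to the nearest skeleton pixel
#'
#' Returns the skeleton pixel minimizing the Euclidean distance to the query;
#' ties are broken toward the smallest `(row, col)` lexicographically.
#'
#' @param point numeric `(row, col)` query.
#' @param skel a `skeleton_map` (from [skeletonize_and_label()]) or a logical
#'   skeleton matrix.
#' @return integer `(row, col)` of the nearest skeleton pixel.
#' @export
snap_to_skeleton <- function(point, skel) {
  sk <- if (inherits(skel, "skeleton_map")) skel$skeleton else skel
  px <- which(sk, arr.ind = TRUE)
  if (nrow(px) == 0) stop("skeleton is empty")
  d2 <- (px[, 1] - point[1])^2 + (px[, 2] - point[2])^2
  ord <- order(d2, px[, 1], px[, 2])
  as.integer(px[ord[1], 1:2])
}

#' Shortest skeleton path between two skeleton pixels
#'
#' Computes the shortest 8-connected path along skeleton pixels from `start`
#' to `end`, with axial steps costing 1 and diagonal steps costing
#' \eqn{\sqrt 2}.
#'
#' @param skel a `skeleton_map` or logical matrix.
#' @param start,end integer `(row, col)` pixels; must lie on the skeleton.
#' @return integer matrix of `(row, col)` path pixels ordered start to end.
#' @export
extract_path <- function(skel, start, end) {
  sk <- if (inherits(skel, "skeleton_map")) skel$skeleton else skel
  nr <- nrow(sk)
  vid <- matrix(0L, nr, ncol(sk))
  idx <- which(sk)
  vid[idx] <- seq_along(idx)
  s <- vid[start[1], start[2]]; e <- vid[end[1], end[2]]
  if (s == 0 || e == 0) stop("start and end must lie on the skeleton")
  if (s == e) return(matrix(as.integer(start), 1, 2))
  g <- pixel_graph(sk)
  sp <- suppressWarnings(
    igraph::shortest_paths(g, from = s, to = e, mode = "all",
                           output = "vpath"))$vpath[[1]]
  if (length(sp) == 0)
    stop(sprintf("no skeleton path between (%d, %d) and (%d, %d)",
                 start[1], start[2], end[1], end[2]))
  v <- as.integer(sp)
  cbind(row = ((idx[v] - 1L) %% nr) + 1L,
        col = ((idx[v] - 1L) %/% nr) + 1L)
}

#' Smooth a pixel path into a sub-pixel centreline curve
#'
#' Fits cubic smoothing splines to the path coordinates as functions of the
#' cumulative chord length, excluding pixels within `bif_radius` of any
#' bifurcation point (thinning places branch-point pixels off the true vessel
#' axis), then resamples the curve at a uniform arc-length step. If fewer than
#' 4 support points remain after exclusion, all points are used with a
#' warning.
#'
#' @param path integer matrix of `(row, col)` pixels (from [extract_path()]).
#' @param skel optional `skeleton_map` supplying bifurcation points.
#' @param sample_step resampling step in pixels (default 1).
#' @param bif_radius exclusion radius around bifurcation points in pixels.
#' @param df equivalent degrees of freedom of the smoothing splines; `NULL`
#'   (default) uses a light smoothing heuristic of one df per 3 support
#'   points (at least 4): close to interpolation but damping single-pixel
#'   staircase noise.
#' @param pixel_spacing_mm pixel spacing used for the mm arc length.
#' @return an object of class `centreline_curve`: list with `points` (n x 2
#'   sub-pixel `(row, col)`), `arc_length` (px, strictly increasing from 0),
#'   `arc_length_mm`, `bifurcations_on_path` and `pixel_spacing_mm`.
#' @export
smooth_centreline <- function(path, skel = NULL, sample_step = 1,
                              bif_radius = 2, df = NULL,
                              pixel_spacing_mm = 1) {
  path <- as.matrix(path)
  if (nrow(path) < 4) stop("path must contain at least 4 pixels")
  bifs <- if (inherits(skel, "skeleton_map")) skel$bifurcation_points
          else matrix(numeric(0), 0, 2)
  on_path <- matrix(numeric(0), 0, 2)
  keep <- rep(TRUE, nrow(path))
  if (nrow(bifs) > 0) {
    for (i in seq_len(nrow(bifs))) {
      d <- sqrt((path[, 1] - bifs[i, 1])^2 + (path[, 2] - bifs[i, 2])^2)
      if (any(d <= bif_radius)) {
        on_path <- rbind(on_path, bifs[i, , drop = FALSE])
        keep <- keep & d > bif_radius
      }
    }
  }
  keep[c(1, nrow(path))] <- TRUE   # endpoints anchor the fit
  if (sum(keep) < 4) {
    warning("fewer than 4 support points after bifurcation exclusion; using all points")
    keep <- rep(TRUE, nrow(path))
  }
  sup <- path[keep, , drop = FALSE]
  u <- c(0, cumsum(sqrt(rowSums(diff(sup)^2))))
  n <- nrow(sup)
  if (is.null(df)) df <- max(4, ceiling(n / 3))
  df <- min(df, n)
  fit_coord <- function(y) {
    if (df >= n) stats::splinefun(u, y, method = "natural")
    else {
      f <- stats::smooth.spline(u, y, df = df)
      function(x) stats::predict(f, x)$y
    }
  }
  fr <- fit_coord(sup[, 1]); fc <- fit_coord(sup[, 2])
  # dense evaluation, then uniform arc-length resampling
  ud <- seq(0, max(u), by = max(u) / max(200L, 20L * n))
  dense <- cbind(fr(ud), fc(ud))
  al <- c(0, cumsum(sqrt(rowSums(diff(dense)^2))))
  total <- al[length(al)]
  targets <- seq(0, total, by = sample_step)
  if (targets[length(targets)] < total - 1e-9) targets <- c(targets, total)
  pts <- cbind(stats::approx(al, dense[, 1], xout = targets)$y,
               stats::approx(al, dense[, 2], xout = targets)$y)
  centreline_curve(pts, bifurcations_on_path = on_path,
                   pixel_spacing_mm = pixel_spacing_mm)
}

#' Construct a centreline curve object
#'
#' @param points n x 2 matrix of sub-pixel `(row, col)` coordinates, n >= 4.
#' @param bifurcations_on_path optional `(row, col)` matrix of bifurcation
#'   points encountered along the path (kept as 3D-correspondence anchors).
#' @param pixel_spacing_mm pixel spacing (mm/px), scalar or `c(row, col)`.
#' @return `centreline_curve` object.
#' @export
centreline_curve <- function(points, bifurcations_on_path = NULL,
                             pixel_spacing_mm = 1) {
  points <- as.matrix(points)
  if (nrow(points) < 4) stop("a centreline needs at least 4 points")
  if (any(!is.finite(points))) stop("non-finite centreline coordinates")
  seg <- sqrt(rowSums(diff(points)^2))
  if (any(seg <= 0)) stop("repeated consecutive centreline points")
  spacing <- rep_len(as.numeric(pixel_spacing_mm), 2L)
  al <- c(0, cumsum(seg))
  structure(list(points = unname(points),
                 arc_length = al,
                 arc_length_mm = al * mean(spacing),
                 bifurcations_on_path =
                   if (is.null(bifurcations_on_path))
                     matrix(numeric(0), 0, 2)
                   else unname(as.matrix(bifurcations_on_path)),
                 pixel_spacing_mm = spacing),
            class = "centreline_curve")
}

#' @export
print.centreline_curve <- function(x, ...) {
  cat(sprintf("centreline_curve: %d points, length %.2f px (%.2f mm), %d bifurcation(s) on path\n",
              nrow(x$points), max(x$arc_length), max(x$arc_length_mm),
              nrow(x$bifurcations_on_path)))
  invisible(x)
}

#' Sub-pixel ridge refinement of a centreline
#'
#' The thinning-based centreline inherits half-pixel staircase bias from the
#' binary skeleton. This refinement moves every centreline point to the local
#' maximum of the vesselness map along its normal: the map is sampled at
#' sub-pixel offsets on the normal and the maximum is localized by a
#' three-point parabola fit (standard sub-pixel ridge localization). The
#' shifted points are then re-fit and resampled by [smooth_centreline()].
#'
#' @param centreline a [centreline_curve()].
#' @param vesselness the vesselness map ([angio_image] or matrix) the
#'   skeleton was derived from.
#' @param max_shift largest allowed displacement in px (default 2).
#' @param step offset sampling step along the normal in px (default 0.5).
#' @return refined [centreline_curve()] (bifurcation anchors preserved).
#' @export
refine_centreline_ridge <- function(centreline, vesselness, max_shift = 2,
                                    step = 0.5) {
  stopifnot(inherits(centreline, "centreline_curve"))
  vmap <- as_pixel_matrix(vesselness)
  P <- centreline$points
  n <- nrow(P)
  tg <- rbind(P[2, ] - P[1, ],
              (P[3:n, , drop = FALSE] - P[1:(n - 2), , drop = FALSE]) / 2,
              P[n, ] - P[n - 1, ])
  tg <- tg / sqrt(rowSums(tg^2))
  nrm <- cbind(-tg[, 2], tg[, 1])
  offs <- seq(-max_shift, max_shift, by = step)
  V <- vapply(offs, function(o)
    as.vector(bilinear(vmap, P[, 1] + o * nrm[, 1], P[, 2] + o * nrm[, 2])),
    numeric(n))
  shift <- numeric(n)
  for (i in seq_len(n)) {
    j <- which.max(V[i, ])
    s <- offs[j]
    if (j > 1 && j < length(offs)) {    # parabolic sub-sample interpolation
      y0 <- V[i, j - 1]; y1 <- V[i, j]; y2 <- V[i, j + 1]
      den <- y0 - 2 * y1 + y2
      if (abs(den) > 1e-12) s <- s + 0.5 * (y0 - y2) / den * step
    }
    shift[i] <- min(max(s, -max_shift), max_shift)
  }
  out <- smooth_centreline(P + shift * nrm, skel = NULL,
                           pixel_spacing_mm = centreline$pixel_spacing_mm[1])
  out$bifurcations_on_path <- centreline$bifurcations_on_path
  out
}

# Linear interpolation of a curve at arbitrary arc lengths (px).
curve_at <- function(curve, s) {
  cbind(stats::approx(curve$arc_length, curve$points[, 1], xout = s, rule = 2)$y,
        stats::approx(curve$arc_length, curve$points[, 2], xout = s, rule = 2)$y)
}
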