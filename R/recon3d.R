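# Two-view 3D centreline reconstruction with iterative foreshortening
# correction, radius estimation from the delineated wall curves, and
# Frenet-frame computation along the reconstructed curve.

# Signed perpendicular offset of points from a 2D line (origin + unit dir).
line_offset <- function(pts, line) {
  (pts[, 1] - line$origin[1]) * line$dir[2] -
    (pts[, 2] - line$origin[2]) * line$dir[1]
}

# Arc-length positions where a polyline crosses a 2D line; `al` are the
# cumulative arc lengths of `pts`.
polyline_line_crossings <- function(pts, al, line) {
  s <- line_offset(pts, line)
  n <- length(s)
  hit <- which(s[-n] * s[-1] <= 0 & (s[-n] != 0 | s[-1] != 0))
  if (length(hit) == 0) return(numeric(0))
  f <- s[hit] / (s[hit] - s[hit + 1])
  f[!is.finite(f)] <- 0
  al[hit] + f * (al[hit + 1] - al[hit])
}

#' Reconstruct a 3D centreline from two projections
#'
#' Establishes point correspondences between the two 2D centrelines with the
#' epipolar constraint and triangulates them, then iterates to remove
#' foreshortening: the 3D curve is resampled to uniform 3D arc length,
#' re-projected into view A, re-matched to the measured curves by arc length,
#' and re-triangulated, until the largest 3D point displacement falls below
#' `tol` or `max_iter` is reached. Matching is monotone (order preserving);
#' bifurcation points stored on both curves are used as hard correspondence
#' anchors for the initial parameter map. If the second curve is traversed in
#' the opposite direction, it is automatically re-oriented using endpoint
#' epipolar consistency.
#'
#' @param centrelineA,centrelineB [centreline_curve()]s in the two views
#'   (sub-pixel `(row, col)` coordinates).
#' @param geomA,geomB the corresponding [projection_geometry()]s.
#' @param n_points number of reconstructed samples (default: points of A).
#' @param tol convergence tolerance on the 3D update, mm (default 1e-3).
#' @param max_iter maximum number of foreshortening iterations (default 20).
#' @return a `vessel_model_3d` with fields `centreline3d` (n x 3 mm),
#'   `residual_mm` (per-point triangulation residuals), `u_A`, `u_B`
#'   (matched arc-length parameters on each 2D curve, px), `iterations`,
#'   `update_norms` (per-iteration max 3D displacement), plus the inputs
#'   needed downstream (`centrelineA`, `centrelineB`, `geomA`, `geomB`).
#' @export
correspond_and_reconstruct <- function(centrelineA, centrelineB, geomA, geomB,
                                       n_points = NULL, tol = 1e-3,
                                       max_iter = 20) {
  stopifnot(inherits(centrelineA, "centreline_curve"),
            inherits(centrelineB, "centreline_curve"))
  if (is.null(n_points)) n_points <- nrow(centrelineA$points)

  # dense sampling of curve B for epipolar intersection
  lenB <- max(centrelineB$arc_length)
  sB <- seq(0, lenB, by = 0.25)
  endsA <- centrelineA$points[c(1, nrow(centrelineA$points)), , drop = FALSE]

  # orientation: endpoints of A must pair with like-ordered endpoints of B
  ep1 <- epipolar_line(geomA, geomB, endsA[1, ])
  ep2 <- epipolar_line(geomA, geomB, endsA[2, ])
  endsB <- centrelineB$points[c(1, nrow(centrelineB$points)), , drop = FALSE]
  d_same <- abs(line_offset(endsB[1, , drop = FALSE], ep1)) +
            abs(line_offset(endsB[2, , drop = FALSE], ep2))
  d_flip <- abs(line_offset(endsB[2, , drop = FALSE], ep1)) +
            abs(line_offset(endsB[1, , drop = FALSE], ep2))
  flipped <- d_flip < d_same
  if (flipped) {
    centrelineB <- centreline_curve(
      centrelineB$points[rev(seq_len(nrow(centrelineB$points))), ],
      bifurcations_on_path = centrelineB$bifurcations_on_path,
      pixel_spacing_mm = centrelineB$pixel_spacing_mm)
  }
  ptsB <- curve_at(centrelineB, sB)

  lenA <- max(centrelineA$arc_length)
  uA <- seq(0, lenA, length.out = n_points)

  # initial monotone parameter map A -> B, anchored at shared bifurcations
  anchorA <- anchor_params(centrelineA)
  anchorB <- anchor_params(centrelineB)
  if (length(anchorA) == length(anchorB) && length(anchorA) > 0) {
    mapx <- c(0, sort(anchorA), lenA); mapy <- c(0, sort(anchorB), lenB)
  } else {
    mapx <- c(0, lenA); mapy <- c(0, lenB)
  }
  uB <- stats::approx(mapx, mapy, xout = uA, rule = 2)$y

  X <- NULL
  update_norms <- numeric(0)
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    ptsA <- curve_at(centrelineA, uA)
    match <- epipolar_match(ptsA, ptsB, sB, uB, geomA, geomB)
    uB <- match$uB
    pairB <- curve_at(centrelineB, uB)
    Xn <- matrix(0, n_points, 3)
    res <- numeric(n_points)
    for (i in seq_len(n_points)) {
      tr <- triangulate(geomA, geomB, ptsA[i, ], pairB[i, ])
      Xn[i, ] <- tr$point; res[i] <- tr$residual
    }
    if (!is.null(X)) {
      upd <- max(sqrt(rowSums((Xn - X)^2)))
      update_norms <- c(update_norms, upd)
      if (upd < tol) { X <- Xn; break }
    }
    X <- Xn
    # foreshortening removal: uniform 3D arc-length resampling, re-matching
    X <- resample_polyline3d(X, n_points)
    projA <- project_point(geomA, X)
    uA <- snap_params(projA, centrelineA)
    projB <- project_point(geomB, X)
    uB <- snap_params(projB, centrelineB)
  }
  structure(list(centreline3d = X, residual_mm = res,
                 u_A = uA, u_B = uB,
                 iterations = iterations, update_norms = update_norms,
                 flipped_B = flipped,
                 centrelineA = centrelineA, centrelineB = centrelineB,
                 geomA = geomA, geomB = geomB),
            class = "vessel_model_3d")
}

# Arc-length parameters of a curve's stored bifurcation points.
anchor_params <- function(curve) {
  b <- curve$bifurcations_on_path
  if (is.null(b) || nrow(b) == 0) return(numeric(0))
  vapply(seq_len(nrow(b)), function(i) {
    d2 <- (curve$points[, 1] - b[i, 1])^2 + (curve$points[, 2] - b[i, 2])^2
    curve$arc_length[which.min(d2)]
  }, numeric(1))
}

# For each point of ptsA, intersect its epipolar line with curve B (dense
# samples ptsB at arc lengths sB); choose the crossing nearest the current
# estimate, then enforce monotonicity. Missing crossings are interpolated.
epipolar_match <- function(ptsA, ptsB, sB, uB_init, geomA, geomB) {
  n <- nrow(ptsA)
  alB <- sB
  uB <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ln <- epipolar_line(geomA, geomB, ptsA[i, ])
    cross <- polyline_line_crossings(ptsB, alB, ln)
    if (length(cross) > 0)
      uB[i] <- cross[which.min(abs(cross - uB_init[i]))]
  }
  miss <- is.na(uB)
  if (mean(miss) > 0.2)
    stop(sprintf("epipolar lines miss the second curve for %.0f%% of points; check view labelling/geometry",
                 100 * mean(miss)))
  if (any(miss)) {
    ok <- which(!miss)
    uB[miss] <- stats::approx(ok, uB[ok], xout = which(miss), rule = 2)$y
  }
  uB <- cummax(uB)                      # order-preserving matching
  list(uB = uB, missing = miss)
}

# Snap projected points onto a measured 2D curve: continuous arc-length
# parameter of the orthogonal projection onto the nearest polyline segment,
# made monotone.
snap_params <- function(proj, curve) {
  P <- curve$points
  al <- curve$arc_length
  A <- P[-nrow(P), , drop = FALSE]
  D <- P[-1, , drop = FALSE] - A
  len2 <- rowSums(D^2)
  u <- vapply(seq_len(nrow(proj)), function(i) {
    tt <- ((proj[i, 1] - A[, 1]) * D[, 1] + (proj[i, 2] - A[, 2]) * D[, 2]) / len2
    tt <- pmin(pmax(tt, 0), 1)
    fr <- A[, 1] + tt * D[, 1] - proj[i, 1]
    fc <- A[, 2] + tt * D[, 2] - proj[i, 2]
    j <- which.min(fr^2 + fc^2)
    al[j] + tt[j] * (al[j + 1] - al[j])
  }, numeric(1))
  cummax(u)
}

resample_polyline3d <- function(X, n) {
  seg <- sqrt(rowSums(diff(X)^2))
  al <- c(0, cumsum(seg))
  s <- seq(0, al[length(al)], length.out = n)
  cbind(stats::approx(al, X[, 1], xout = s)$y,
        stats::approx(al, X[, 2], xout = s)$y,
        stats::approx(al, X[, 3], xout = s)$y)
}

#' Estimate per-point vessel radii from the wall curves
#'
#' Each wall point corresponding to a reconstructed centreline sample is
#' back-projected into 3D at the beam-axis depth of that centreline point;
#' the radius is the mean of the (up to four: two walls in each of two
#' views) Euclidean distances from the 3D centreline point to these
#' back-projected wall points. The circular cross-section assumption of
#' two-view reconstruction makes this mean the lumen radius estimate.
#'
#' @param model a `vessel_model_3d` from [correspond_and_reconstruct()].
#' @param wallsA,wallsB lists with `left`/`right` `wall_curve`s delineated in
#'   view A and B (indexed like the respective 2D centrelines).
#' @param min_mm distances at or below this are treated as degenerate and
#'   excluded (warned); points with no usable wall distance are interpolated
#'   from their neighbours.
#' @return the model with fields `radii_mm` (per-point radius) added.
#' @export
estimate_radii <- function(model, wallsA, wallsB = NULL, min_mm = 1e-6) {
  stopifnot(inherits(model, "vessel_model_3d"))
  n <- nrow(model$centreline3d)
  dists <- matrix(NA_real_, n, 4)
  sets <- list(list(walls = wallsA, curve = model$centrelineA,
                    geom = model$geomA, u = model$u_A),
               list(walls = wallsB, curve = model$centrelineB,
                    geom = model$geomB, u = model$u_B))
  col <- 0L
  for (s in sets) {
    if (is.null(s$walls)) { col <- col + 2L; next }
    # fractional wall index matched to each centreline sample
    idx <- stats::approx(s$curve$arc_length,
                         seq_along(s$curve$arc_length),
                         xout = pmin(pmax(s$u, 0), max(s$curve$arc_length)),
                         rule = 2)$y
    for (side in c("left", "right")) {
      col <- col + 1L
      w <- s$walls[[side]]
      if (is.null(w)) next
      wp <- cbind(stats::approx(seq_len(nrow(w$points)), w$points[, 1],
                                xout = idx, rule = 2)$y,
                  stats::approx(seq_len(nrow(w$points)), w$points[, 2],
                                xout = idx, rule = 2)$y)
      dirs <- backproject_ray(s$geom, wp)
      depth <- (model$centreline3d -
                  matrix(s$geom$source, n, 3, byrow = TRUE)) %*% s$geom$beam
      tt <- as.vector(depth) / as.vector(dirs %*% s$geom$beam)
      W <- matrix(s$geom$source, n, 3, byrow = TRUE) + dirs * tt
      dists[, col] <- sqrt(rowSums((W - model$centreline3d)^2))
    }
  }
  bad <- !is.na(dists) & dists <= min_mm
  if (any(bad)) {
    warning(sprintf("%d degenerate wall distance(s) excluded", sum(bad)))
    dists[bad] <- NA
  }
  r <- rowMeans(dists, na.rm = TRUE)
  if (any(!is.finite(r))) {
    ok <- which(is.finite(r))
    if (length(ok) == 0) stop("no usable wall distances at any point")
    r[!is.finite(r)] <- stats::approx(ok, r[ok], xout = which(!is.finite(r)),
                                      rule = 2)$y
  }
  model$radii_mm <- as.vector(r)
  model
}

#' @export
print.vessel_model_3d <- function(x, ...) {
  cat(sprintf("vessel_model_3d: %d centreline points, length %.1f mm",
              nrow(x$centreline3d),
              sum(sqrt(rowSums(diff(x$centreline3d)^2)))))
  if (!is.null(x$radii_mm))
    cat(sprintf(", radii %.2f-%.2f mm", min(x$radii_mm), max(x$radii_mm)))
  if (!is.null(x$mesh)) cat(sprintf(", mesh %d faces", nrow(x$mesh$faces)))
  cat("\n")
  invisible(x)
}

# Central-difference derivative of columns of P with respect to arc
# parameter s (forward/backward at the ends).
fd_deriv <- function(P, s) {
  n <- nrow(P)
  out <- P
  out[1, ] <- (P[2, ] - P[1, ]) / (s[2] - s[1])
  out[n, ] <- (P[n, ] - P[n - 1, ]) / (s[n] - s[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    out[i, ] <- (P[i + 1, , drop = FALSE] - P[i - 1, , drop = FALSE]) /
      (s[i + 1] - s[i - 1])
  }
  out
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Frenet frames, curvature and torsion along a 3D curve
#'
#' Derivatives use central differences at interior points and
#' forward/backward differences at the ends. Curvature
#' \eqn{\kappa = |r' \times r''| / |r'|^3} and torsion
#' \eqn{\tau = (r' \times r'') \cdot r''' / |r' \times r''|^2}. The normal is
#' taken from the tangent derivative where curvature is meaningful
#' (\eqn{\kappa > 10^{-8}}); along straight runs it is continued by parallel
#' transport of the previous frame (rotation-minimizing fallback) so frames
#' never flip. Frames are re-orthonormalized, right-handed by construction
#' (\eqn{B = T \times N}).
#'
#' @param centreline3d n x 3 matrix of curve points (n >= 4, no repeated
#'   consecutive points).
#' @return list with `T`, `N`, `B` (n x 3 unit-vector matrices), `kappa`,
#'   `tau` (per point).
#' @export
frenet_frames <- function(centreline3d) {
  P <- as.matrix(centreline3d)
  n <- nrow(P)
  if (n < 4) stop("at least 4 points are required")
  seg <- sqrt(rowSums(diff(P)^2))
  if (any(seg == 0)) stop("repeated consecutive points")
  s <- c(0, cumsum(seg))
  d1 <- fd_deriv(P, s)
  d2 <- fd_deriv(d1, s)
  d3 <- fd_deriv(d2, s)
  sp <- sqrt(rowSums(d1^2))
  Tv <- d1 / sp
  cr <- cross3(d1, d2)
  crn <- sqrt(rowSums(cr^2))
  kappa <- crn / sp^3
  tau <- ifelse(crn > 1e-12, rowSums(cr * d3) / crn^2, 0)

  Nv <- matrix(0, n, 3)
  dT <- fd_deriv(Tv, s)
  prevN <- NULL
  for (i in seq_len(n)) {
    if (kappa[i] > 1e-8 && sqrt(sum(dT[i, ]^2)) > 1e-12) {
      cand <- dT[i, ] - sum(dT[i, ] * Tv[i, ]) * Tv[i, ]
      if (sqrt(sum(cand^2)) > 1e-12) {
        Nv[i, ] <- cand / sqrt(sum(cand^2))
        prevN <- Nv[i, ]
        next
      }
    }
    if (is.null(prevN)) {               # straight start: any perpendicular
      ref <- if (abs(Tv[i, 3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      cand <- ref - sum(ref * Tv[i, ]) * Tv[i, ]
    } else {                            # parallel transport of previous N
      cand <- prevN - sum(prevN * Tv[i, ]) * Tv[i, ]
    }
    Nv[i, ] <- cand / sqrt(sum(cand^2))
    prevN <- Nv[i, ]
  }
  # keep N continuous (Frenet N can flip sign through inflections)
  for (i in 2:n) if (sum(Nv[i, ] * Nv[i - 1, ]) < 0) Nv[i, ] <- -Nv[i, ]
  Bv <- cross3(Tv, Nv)
  Bv <- Bv / sqrt(rowSums(Bv^2))
  Nv <- cross3(Bv, Tv)                  # exact right-handed orthonormal triad
  list(T = Tv, N = Nv, B = Bv, kappa = kappa, tau = tau)
}

#' Add Frenet frames (and optional smoothing) to a vessel model
#'
#' Optionally smooths the reconstructed centreline with coordinate-wise
#' cubic smoothing splines against arc length before differentiating —
#' curvature and torsion are second/third-derivative quantities and amplify
#' sub-pixel reconstruction noise.
#'
#' @param model a `vessel_model_3d` (or bare n x 3 matrix).
#' @param smooth logical; estimate the derivatives on a spline-smoothed copy
#'   of the centreline (default TRUE). The model's `centreline3d` itself is
#'   left untouched — smoothing only stabilizes the second/third-derivative
#'   quantities.
#' @param df degrees of freedom per coordinate for the smoothing spline;
#'   `NULL` picks one df per ~7 mm of arc length (at least 8), i.e. enough
#'   flexibility to resolve curvature at the typical coronary bending scale
#'   while suppressing sub-millimetre reconstruction noise that third
#'   derivatives would otherwise amplify.
#' @return the model with `frames`, `kappa`, `tau` set.
#' @export
add_frenet_frames <- function(model, smooth = TRUE, df = NULL) {
  X <- model$centreline3d
  if (smooth) X <- smooth_centreline3d(X, df = df)
  fr <- frenet_frames(X)
  model$frames <- fr[c("T", "N", "B")]
  model$kappa <- fr$kappa
  model$tau <- fr$tau
  model
}

smooth_centreline3d <- function(X, df = NULL) {
  seg <- sqrt(rowSums(diff(X)^2))
  s <- c(0, cumsum(seg))
  if (is.null(df)) df <- max(8, ceiling(s[length(s)] / 7))
  df <- min(df, nrow(X) - 1)
  sm <- function(y) stats::predict(stats::smooth.spline(s, y, df = df), s)$y
  cbind(sm(X[, 1]), sm(X[, 2]), sm(X[, 3]))
}
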