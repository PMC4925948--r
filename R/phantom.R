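# Synthetic vascular phantoms with full ground truth: parametric 3D
# centrelines (line / arc / helix / branched), a radius profile with optional
# stenosis, and cone-beam rendering of projection pairs (dark vessel on
# bright background, chord-length attenuation, Gaussian read noise).

#' Create a parametric vessel phantom
#'
#' The phantom is a 3D parametric curve `centre(t)`, `t` in \[0, 1\], centred
#' near the isocenter, with radius profile
#' \eqn{r(t) = r_0 (1 - \mathrm{severity} \cdot
#' \exp(-(t - t_0)^2 / 2 w^2))}: a Gaussian-shaped stenosis whose minimum
#' radius is exactly `(1 - severity) * r0` at `t = t0`.
#'
#' @param kind `"line"`, `"arc"`, `"helix"`, or `"branched"` (a line with an
#'   oblique straight branch; the branch point is recorded as ground truth).
#' @param length_mm overall extent of the phantom (line/branched), mm.
#' @param arc_radius_mm,arc_span_deg circle radius and swept angle (arc).
#' @param helix_a,helix_b,helix_turns helix \eqn{(a\cos t, a\sin t, b t)}
#'   parameters (mm; closed-form curvature \eqn{a/(a^2+b^2)} and torsion
#'   \eqn{b/(a^2+b^2)} are stored).
#' @param r0_mm baseline lumen radius in mm (default 1.5, a typical proximal
#'   coronary calibre).
#' @param stenosis optional list `list(location =, severity =, width =)`
#'   with `location` in \[0,1\], `severity` in \[0, 0.9\], `width` the
#'   Gaussian sigma in `t` units (default 0.08).
#' @param branch_angle_deg,branch_t branched phantom: take-off angle and
#'   branch-point parameter.
#' @return a `vessel_phantom`: list with `centre(t)` (function returning an
#'   n x 3 matrix), `radius(t)`, `kind`, `kappa`, `tau` (closed form where
#'   applicable, else NA), `branch_point` (3D, branched only).
#' @export
make_phantom <- function(kind = c("line", "arc", "helix", "branched"),
                         length_mm = 60, arc_radius_mm = 30, arc_span_deg = 120,
                         helix_a = 10, helix_b = 6, helix_turns = 0.75,
                         r0_mm = 1.5, stenosis = NULL,
                         branch_angle_deg = 45, branch_t = 0.5) {
  kind <- match.arg(kind)
  if (r0_mm <= 0) stop("`r0_mm` must be positive")
  if (!is.null(stenosis)) {
    if (is.null(stenosis$width)) stenosis$width <- 0.08
    if (stenosis$severity < 0 || stenosis$severity > 0.9)
      stop("stenosis severity must lie in [0, 0.9]")
    if ((1 - stenosis$severity) * r0_mm <= 0) stop("stenosis closes the lumen")
  }
  kappa <- NA_real_; tau <- NA_real_
  branch <- NULL
  centre <- switch(kind,
    line = {
      kappa <- 0; tau <- 0
      function(t) cbind(length_mm * (t - 0.5), 0.2 * length_mm * (t - 0.5),
                        0.1 * length_mm * (t - 0.5))
    },
    arc = {
      # arc in the x-z plane, swept so z is monotone along the curve: views
      # separated by a primary (about-z) rotation then meet every epipolar
      # line in a single point
      span <- arc_span_deg * pi / 180
      kappa <- 1 / arc_radius_mm; tau <- 0
      function(t) {
        a <- span * (t - 0.5)
        cbind(arc_radius_mm * (cos(a) - 1), 0, arc_radius_mm * sin(a))
      }
    },
    helix = {
      # axis along z: the epipolar coordinate of primary-rotated view pairs
      # grows monotonically along the vessel (well-posed two-view matching);
      # the default pitch is high enough that neither projection's bend is
      # tighter than the lumen half-width (no self-overlap in the images)
      kappa <- helix_a / (helix_a^2 + helix_b^2)
      tau <- helix_b / (helix_a^2 + helix_b^2)
      tmax <- 2 * pi * helix_turns
      function(t) {
        a <- tmax * (t - 0.5)
        cbind(helix_a * cos(a), helix_a * sin(a), helix_b * a)
      }
    },
    branched = {
      kappa <- 0; tau <- 0
      function(t) cbind(length_mm * (t - 0.5), 0,
                        0.15 * length_mm * (t - 0.5))
    })
  if (kind == "branched") {
    bp <- centre(branch_t)[1, ]
    ang <- branch_angle_deg * pi / 180
    main_dir <- centre(branch_t + 1e-4)[1, ] - centre(branch_t - 1e-4)[1, ]
    main_dir <- main_dir / sqrt(sum(main_dir^2))
    perp <- c(-main_dir[3], 0, main_dir[1])
    bdir <- cos(ang) * main_dir + sin(ang) * perp
    blen <- 0.35 * length_mm
    branch <- list(point = bp, t = branch_t,
                   centre = function(t) {
                     t <- pmin(pmax(t, 0), 1)
                     matrix(bp, length(t), 3, byrow = TRUE) + outer(t * blen, bdir)
                   })
  }
  radius <- function(t) {
    r <- rep(r0_mm, length(t))
    if (!is.null(stenosis))
      r <- r0_mm * (1 - stenosis$severity *
                      exp(-(t - stenosis$location)^2 / (2 * stenosis$width^2)))
    r
  }
  structure(list(centre = centre, radius = radius, kind = kind,
                 r0_mm = r0_mm, stenosis = stenosis,
                 kappa = kappa, tau = tau, branch = branch),
            class = "vessel_phantom")
}

#' @export
print.vessel_phantom <- function(x, ...) {
  cat(sprintf("vessel_phantom: %s, r0 %.2f mm%s\n", x$kind, x$r0_mm,
              if (!is.null(x$stenosis))
                sprintf(", stenosis %.0f%% at t=%.2f",
                        100 * x$stenosis$severity, x$stenosis$location)
              else ""))
  invisible(x)
}

# Project a 3D polyline and its radii into one view: returns 2D points and
# the projected radius in px at each sample.
project_curve <- function(geom, X, r_mm) {
  p <- project_point(geom, X)
  depth <- as.vector((X - matrix(geom$source, nrow(X), 3, byrow = TRUE)) %*%
                       geom$beam)
  mag <- geom$sid / depth
  list(points = p, radius_px = r_mm * mag / geom$pixel_size_mm)
}

# Offset silhouette curves of a projected tube: centreline2d +/- R_px along
# the 2D normal.
silhouette_curves <- function(p2, R_px) {
  n <- nrow(p2)
  tg <- rbind(p2[2, ] - p2[1, ],
              (p2[3:n, , drop = FALSE] - p2[1:(n - 2), , drop = FALSE]) / 2,
              p2[n, ] - p2[n - 1, ])
  tg <- tg / sqrt(rowSums(tg^2))
  nr <- cbind(-tg[, 2], tg[, 1])
  list(left = p2 + nr * R_px, right = p2 - nr * R_px)
}

#' Render a phantom into a pair of projection images
#'
#' Simulates cone-beam attenuation of a circular-cross-section tube: per
#' pixel the intensity is the bright background minus a term proportional to
#' the X-ray chord length through the tube (computed from the distance to the
#' projected centreline and the locally projected radius), plus Gaussian read
#' noise. All randomness is behind `seed`; the same seed gives bit-identical
#' images.
#'
#' @param phantom a [make_phantom()] object.
#' @param geomA,geomB the two view [projection_geometry()]s.
#' @param seed RNG seed for the noise.
#' @param noise_sd Gaussian noise standard deviation (intensity units;
#'   default 0.02, moderate fluoroscopic noise).
#' @param background background intensity (default 0.9).
#' @param contrast peak attenuation depth of the unstenosed vessel
#'   (default 0.5).
#' @param n_samples centreline samples used for rendering and ground truth.
#' @return list with `imageA`, `imageB` ([angio_image]s) and `truth`: 3D
#'   centreline samples and radii, per-view projected centrelines (matrices
#'   and [centreline_curve()]s), projected radii, silhouette wall curves, and
#'   the branch point where applicable.
#' @export
render_views <- function(phantom, geomA, geomB, seed = 1, noise_sd = 0.02,
                         background = 0.9, contrast = 0.5, n_samples = 600) {
  stopifnot(inherits(phantom, "vessel_phantom"))
  t <- seq(0, 1, length.out = n_samples)
  X <- phantom$centre(t)
  r <- phantom$radius(t)
  views <- list(A = geomA, B = geomB)
  imgs <- list(); truth_views <- list()
  for (nm in names(views)) {
    g <- views[[nm]]
    pc <- project_curve(g, X, r)
    if (any(pc$points[, 1] < 2 | pc$points[, 1] > g$image_size[1] - 1 |
            pc$points[, 2] < 2 | pc$points[, 2] > g$image_size[2] - 1))
      stop("phantom outside the view frustum of view ", nm)
    canvas <- render_tube(g$image_size, pc$points, pc$radius_px)
    if (!is.null(phantom$branch)) {
      bt <- seq(0, 1, length.out = ceiling(n_samples / 2))
      bX <- phantom$branch$centre(bt)
      bpc <- project_curve(g, bX, phantom$radius(bt) * 0.7)
      canvas <- pmax(canvas, render_tube(g$image_size, bpc$points, bpc$radius_px))
    }
    img <- background - contrast * canvas
    sil <- silhouette_curves(pc$points, pc$radius_px)
    truth_views[[nm]] <- list(
      centreline2d = pc$points,
      centreline_curve = centreline_curve(
        resample_polyline2d(pc$points, 1),
        pixel_spacing_mm = g$pixel_size_mm),
      radius_px = pc$radius_px,
      walls = sil)
    imgs[[nm]] <- img
  }
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    for (nm in names(imgs))
      imgs[[nm]] <- imgs[[nm]] +
        matrix(stats::rnorm(length(imgs[[nm]]), sd = noise_sd),
               nrow(imgs[[nm]]))
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  list(imageA = angio_image(pmin(pmax(imgs$A, 0), 1),
                            pixel_spacing_mm = geomA$pixel_size_mm,
                            normalize = FALSE),
       imageB = angio_image(pmin(pmax(imgs$B, 0), 1),
                            pixel_spacing_mm = geomB$pixel_size_mm,
                            normalize = FALSE),
       truth = list(t = t, centreline3d = X, radii_mm = r,
                    kappa = phantom$kappa, tau = phantom$tau,
                    branch_point = if (!is.null(phantom$branch)) phantom$branch$point,
                    views = truth_views))
}

# Normalized chord-length canvas of a projected tube: value 1 on the thickest
# chord, 0 outside the silhouette. Distances to the projected centreline are
# computed against dense samples in pixel chunks to bound memory.
render_tube <- function(image_size, p2, R_px) {
  nr <- image_size[1]; nc <- image_size[2]
  # densify the projected centreline to 0.25 px steps
  al <- c(0, cumsum(sqrt(rowSums(diff(p2)^2))))
  s <- seq(0, al[length(al)], by = 0.25)
  pr <- stats::approx(al, p2[, 1], xout = s)$y
  pc <- stats::approx(al, p2[, 2], xout = s)$y
  pR <- stats::approx(al, R_px, xout = s)$y
  canvas <- matrix(0, nr, nc)
  maxR <- max(pR)
  rmin <- max(1L, floor(min(pr) - maxR - 2)); rmax <- min(nr, ceiling(max(pr) + maxR + 2))
  cmin <- max(1L, floor(min(pc) - maxR - 2)); cmax <- min(nc, ceiling(max(pc) + maxR + 2))
  rows <- rmin:rmax; cols <- cmin:cmax
  grid_r <- rep(rows, times = length(cols))
  grid_c <- rep(cols, each = length(rows))
  npix <- length(grid_r)
  chunk <- max(1L, floor(2e6 / length(pr)))
  vals <- numeric(npix)
  for (start in seq(1L, npix, by = chunk)) {
    ix <- start:min(start + chunk - 1L, npix)
    D2 <- outer(grid_r[ix]^2 + grid_c[ix]^2, pr^2 + pc^2, "+") -
      2 * (outer(grid_r[ix], pr) + outer(grid_c[ix], pc))
    j <- max.col(-D2, ties.method = "first")
    d2 <- D2[cbind(seq_along(ix), j)]
    R <- pR[j]
    vals[ix] <- sqrt(pmax(R^2 - pmax(d2, 0), 0)) / maxR
  }
  canvas[cbind(grid_r, grid_c)] <- vals
  canvas
}
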