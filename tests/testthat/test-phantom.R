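# synthetic phantom construction and cone-beam rendering

test_that("make_phantom exposes analytic geometry and radii", {
  ph <- make_phantom("helix", helix_a = 10, helix_b = 3)
  expect_equal(ph$kappa, 10 / 109)
  expect_equal(ph$tau, 3 / 109)
  # stenosis: minimum radius is exactly (1 - severity) * r0 at the apex
  st <- make_phantom("line", r0_mm = 2,
                     stenosis = list(location = 0.4, severity = 0.5))
  t <- seq(0, 1, length.out = 2001)
  expect_equal(min(st$radius(t)), 1, tolerance = 1e-6)
  expect_equal(st$radius(0.4), 1)
  expect_error(make_phantom("line", stenosis = list(location = 0.5, severity = 1)),
               "severity")
  expect_error(make_phantom("line", r0_mm = 0), "positive")
  # branched phantom records the take-off point
  br <- make_phantom("branched", branch_t = 0.3)
  expect_equal(br$branch$point, br$centre(0.3)[1, ])
  # arc curvature closed form
  arc <- make_phantom("arc", arc_radius_mm = 25)
  expect_equal(arc$kappa, 1 / 25)
})

test_that("rendering is deterministic for a fixed seed", {
  ph <- make_phantom("line", length_mm = 40, r0_mm = 1.2)
  r1 <- render_views(ph, std_geom(0), std_geom(30), seed = 3)
  r2 <- render_views(ph, std_geom(0), std_geom(30), seed = 3)
  expect_identical(r1$imageA$pixels, r2$imageA$pixels)
  expect_identical(r1$imageB$pixels, r2$imageB$pixels)
  r3 <- render_views(ph, std_geom(0), std_geom(30), seed = 4)
  expect_false(identical(r1$imageA$pixels, r3$imageA$pixels))
})

test_that("noise-free straight tube renders symmetrically about its axis", {
  # vertical vessel through the isocenter projects to the centre column
  ph <- structure(list(centre = function(t) cbind(0, 0, 30 * (t - 0.5)),
                       radius = function(t) rep(1.5, length(t)),
                       kind = "line", r0_mm = 1.5, stenosis = NULL,
                       kappa = 0, tau = 0, branch = NULL),
                  class = "vessel_phantom")
  g <- projection_geometry(1000, 0.4, primary_deg = 0, sod = 750,
                           image_size = c(121, 121))
  rv <- render_views(ph, g, std_geom(30), seed = 1, noise_sd = 0)
  img <- rv$imageA$pixels
  c0 <- 61                                 # centre column
  for (k in 1:20)
    expect_equal(img[30:90, c0 - k], img[30:90, c0 + k], tolerance = 1e-6)
})

test_that("ground-truth projected centreline agrees with project_point", {
  hp <- helix_phantom_views()
  gt <- hp$rv$truth
  again <- project_point(std_geom(0), gt$centreline3d)
  expect_equal(gt$views$A$centreline2d, again, tolerance = 1e-12,
               ignore_attr = TRUE)
})

closest_sample <- function(tv, p) {
  which.min((tv$centreline2d[, 1] - p[1])^2 + (tv$centreline2d[, 2] - p[2])^2)
}

test_that("silhouette walls match a dense surface-projection oracle", {
  ph <- make_phantom("line", length_mm = 40, r0_mm = 1.5)
  gA <- std_geom(0)
  rv <- render_views(ph, gA, std_geom(30), seed = 2, noise_sd = 0)
  tv <- rv$truth$views$A
  # oracle: project dense rings of true tube surface points; the silhouette
  # offset at a station is the extreme signed distance from the projected
  # centreline among surface points projecting nearby
  t <- seq(0.3, 0.7, length.out = 9)
  X <- ph$centre(t); r <- ph$radius(t)
  fr <- frenet_frames(ph$centre(seq(0, 1, length.out = 201)))
  # tube axis direction is constant for a line phantom
  axis <- (X[2, ] - X[1, ]) / sqrt(sum((X[2, ] - X[1, ])^2))
  ref <- c(axis[2], -axis[1], 0); ref <- ref / sqrt(sum(ref^2))
  ref2 <- c(axis[2] * ref[3] - axis[3] * ref[2],
            axis[3] * ref[1] - axis[1] * ref[3],
            axis[1] * ref[2] - axis[2] * ref[1])
  theta <- seq(0, 2 * pi, length.out = 721)[-721]
  P2 <- tv$centreline2d
  al <- c(0, cumsum(sqrt(rowSums(diff(P2)^2))))
  for (i in seq_along(t)) {
    ring <- matrix(X[i, ], length(theta), 3, byrow = TRUE) +
      r[i] * (outer(cos(theta), ref) + outer(sin(theta), ref2))
    proj <- project_point(gA, ring)
    # signed offsets of projected ring points from the projected centreline
    jn <- vapply(seq_len(nrow(proj)), function(k)
      which.min((P2[, 1] - proj[k, 1])^2 + (P2[, 2] - proj[k, 2])^2),
      integer(1))
    n_idx <- pmin(pmax(jn, 2), nrow(P2) - 1)
    tg <- (P2[n_idx + 1, ] - P2[n_idx - 1, ])
    tg <- tg / sqrt(rowSums(tg^2))
    off <- (proj[, 1] - P2[jn, 1]) * (-tg[, 2]) + (proj[, 2] - P2[jn, 2]) * tg[, 1]
    # the stored silhouette offset at the matching station
    station <- closest_sample(tv, project_point(gA, X[i, ]))
    expect_lt(abs(max(off) - tv$radius_px[station]), 0.25)
    expect_lt(abs(-min(off) - tv$radius_px[station]), 0.25)
  }
})

test_that("phantom outside the frustum errors", {
  ph <- make_phantom("line", length_mm = 400, r0_mm = 1.5)
  expect_error(render_views(ph, std_geom(0), std_geom(30), seed = 1),
               "frustum")
})
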