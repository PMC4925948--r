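# 3D centreline reconstruction, radius estimation, Frenet frames, tube mesh

gt_curves <- function(rv) list(A = rv$truth$views$A$centreline_curve,
                               B = rv$truth$views$B$centreline_curve)

test_that("noise-free reconstruction from exact 2D curves is sub-0.1 mm", {
  hp <- helix_phantom_views()
  cv <- gt_curves(hp$rv)
  m <- correspond_and_reconstruct(cv$A, cv$B, std_geom(0), std_geom(30))
  expect_s3_class(m, "vessel_model_3d")
  rms <- angiorecon:::centreline_rms(m$centreline3d, hp$rv$truth$centreline3d)
  expect_lt(rms, 0.1)
  expect_lte(m$iterations, 20)
})

test_that("straight vessel converges with shrinking update norms", {
  lp <- line_phantom_views()
  cv <- gt_curves(lp$rv)
  m <- correspond_and_reconstruct(cv$A, cv$B, std_geom(0), std_geom(30))
  expect_lt(m$iterations, 20)
  u <- m$update_norms
  if (length(u) > 1) expect_lt(u[length(u)], u[1])
  rms <- angiorecon:::centreline_rms(m$centreline3d, lp$rv$truth$centreline3d)
  expect_lt(rms, 0.1)
})

test_that("a reversed second curve is auto-reoriented", {
  hp <- helix_phantom_views()
  cv <- gt_curves(hp$rv)
  revB <- centreline_curve(cv$B$points[rev(seq_len(nrow(cv$B$points))), ],
                           pixel_spacing_mm = cv$B$pixel_spacing_mm)
  m <- correspond_and_reconstruct(cv$A, revB, std_geom(0), std_geom(30))
  expect_true(m$flipped_B)
  rms <- angiorecon:::centreline_rms(m$centreline3d, hp$rv$truth$centreline3d)
  expect_lt(rms, 0.1)
})

test_that("an unrelated second curve raises a matching error", {
  hp <- helix_phantom_views()
  cv <- gt_curves(hp$rv)
  far <- centreline_curve(cbind(seq(2, 6, length.out = 10), seq(2, 6, length.out = 10)))
  expect_error(correspond_and_reconstruct(cv$A, far, std_geom(0), std_geom(30)),
               "epipolar")
})

test_that("radius from symmetric walls follows the magnification closed form", {
  # straight 3D segment at the isocenter plane, walls exactly +/- d px
  gA <- std_geom(0); gB <- std_geom(30)
  # sloped in z so the epipolar coordinate varies along the segment; the
  # whole segment stays in the y = 0 plane, so depth (and magnification)
  # is constant
  X <- cbind(seq(-10, 10, length.out = 30), 0, seq(-8, 8, length.out = 30))
  mk_view <- function(g) {
    p2 <- project_point(g, X)
    cl <- centreline_curve(p2, pixel_spacing_mm = g$pixel_size_mm)
    n <- nrow(p2)
    tg <- rbind(p2[2, ] - p2[1, ],
                (p2[3:n, ] - p2[1:(n - 2), ]) / 2, p2[n, ] - p2[n - 1, ])
    tg <- tg / sqrt(rowSums(tg^2))
    nr <- cbind(-tg[, 2], tg[, 1])
    d <- 5
    list(cl = cl,
         walls = list(
           left = structure(list(points = p2 + d * nr, offsets = rep(5L, n),
                                 objective = 0, side = "left"), class = "wall_curve"),
           right = structure(list(points = p2 - d * nr, offsets = rep(5L, n),
                                  objective = 0, side = "right"), class = "wall_curve")))
  }
  vA <- mk_view(gA); vB <- mk_view(gB)
  m <- correspond_and_reconstruct(vA$cl, vB$cl, gA, gB)
  m <- estimate_radii(m, vA$walls, vB$walls)
  # depth of the isocenter = sod, magnification M = sid/sod = 4/3
  M <- gA$sid / gA$sod
  expected <- 5 * gA$pixel_size_mm / M
  interior <- 3:(length(m$radii_mm) - 2)
  expect_equal(mean(m$radii_mm[interior]), expected, tolerance = 1e-4)
})

test_that("frenet frames reproduce closed forms", {
  # planar circle
  t <- seq(0, 2 * pi, length.out = 101)[-101]
  R <- 20
  circ <- cbind(R * cos(t), R * sin(t), 0)
  fr <- frenet_frames(circ)
  int <- 5:95
  expect_lt(max(abs(fr$kappa[int] - 1 / R) / (1 / R)), 0.01)
  expect_lt(max(abs(fr$tau[int])), 1e-3)
  # helix
  a <- 10; b <- 3
  th <- seq(0, 4 * pi, length.out = 200)
  hel <- cbind(a * cos(th), a * sin(th), b * th)
  frh <- frenet_frames(hel)
  ka <- a / (a^2 + b^2); ta <- b / (a^2 + b^2)
  int <- 10:190
  expect_lt(max(abs(frh$kappa[int] - ka) / ka), 0.01)
  expect_lt(max(abs(frh$tau[int] - ta) / ta), 0.01)
  # straight line: zero curvature/torsion and a stable transported frame
  line <- cbind(seq(0, 9), 0, 0)
  frl <- frenet_frames(line)
  expect_equal(max(frl$kappa), 0)
  expect_equal(max(abs(frl$tau)), 0)
  expect_equal(frl$T, matrix(rep(c(1, 0, 0), each = 10), 10, 3))
  expect_lt(max(abs(diff(frl$N))), 1e-12)        # no frame flips
  expect_error(frenet_frames(line[1:3, ]), "4 points")
  expect_error(frenet_frames(rbind(line, line[10, ])), "repeated")
})

test_that("frames are right-handed orthonormal everywhere", {
  th <- seq(0, 3 * pi, length.out = 80)
  crv <- cbind(8 * cos(th), 6 * sin(th), th^1.3)
  fr <- frenet_frames(crv)
  for (i in seq_along(th)) {
    M <- rbind(fr$T[i, ], fr$N[i, ], fr$B[i, ])
    expect_lt(max(abs(M %*% t(M) - diag(3))), 1e-9)
    expect_equal(det(M), 1, tolerance = 1e-9)
  }
})

test_that("build_tube places ring vertices exactly at radius r", {
  th <- seq(0, 2 * pi, length.out = 40)
  model <- list(centreline3d = cbind(10 * cos(th), 10 * sin(th), th),
                radii_mm = 1.2 + 0.3 * sin(3 * th))
  fr <- frenet_frames(model$centreline3d)
  model$frames <- fr[c("T", "N", "B")]
  mesh <- build_tube(model, s = 12, cap = FALSE)
  n <- nrow(model$centreline3d); s <- 12
  expect_equal(nrow(mesh$vertices), n * s)
  expect_equal(nrow(mesh$faces), 2 * s * (n - 1))
  for (i in seq_len(n)) {
    ring <- mesh$vertices[(i - 1) * s + seq_len(s), ]
    d <- sqrt(rowSums((ring - matrix(model$centreline3d[i, ], s, 3,
                                     byrow = TRUE))^2))
    expect_lt(max(abs(d - model$radii_mm[i])), 1e-9)
  }
})

test_that("two rings with s = 4 give 8 vertices and 8 side triangles", {
  model <- list(centreline3d = cbind(c(0, 1, 2, 3), 0, 0),
                radii_mm = rep(1, 4))
  fr <- frenet_frames(model$centreline3d)
  model$frames <- fr[c("T", "N", "B")]
  mesh <- build_tube(model, s = 4, cap = FALSE)
  # 4 points, but the combinatorial claim is per ring pair:
  expect_equal(nrow(mesh$vertices), 16)
  expect_equal(nrow(mesh$faces), 8 * 3)
  sub <- build_tube(list(centreline3d = model$centreline3d[1:2, ] + 0,
                         radii_mm = c(1, 1),
                         frames = lapply(fr[c("T", "N", "B")],
                                         function(m) m[1:2, , drop = FALSE])),
                    s = 4, cap = FALSE)
  expect_equal(nrow(sub$vertices), 8)
  expect_equal(nrow(sub$faces), 8)
  expect_error(build_tube(model, s = 2), "at least 3")
})

test_that("capped tubes are watertight and edge-manifold", {
  th <- seq(0, pi, length.out = 25)
  model <- list(centreline3d = cbind(15 * cos(th), 15 * sin(th), 2 * th),
                radii_mm = rep(1.4, 25))
  fr <- frenet_frames(model$centreline3d)
  model$frames <- fr[c("T", "N", "B")]
  mesh <- build_tube(model, s = 10, cap = TRUE)
  use <- angiorecon:::mesh_edge_use(mesh)
  expect_true(all(use == 2))             # every edge shared by exactly 2 faces
})

test_that("STL and OBJ export round-trip", {
  model <- list(centreline3d = cbind(seq(0, 5), 0, 0), radii_mm = rep(1, 6))
  fr <- frenet_frames(model$centreline3d)
  model$frames <- fr[c("T", "N", "B")]
  mesh <- build_tube(model, s = 8, cap = TRUE)
  fs <- tempfile(fileext = ".stl"); fo <- tempfile(fileext = ".obj")
  export_mesh(mesh, fs)
  export_mesh(mesh, fo)
  stl <- import_mesh(fs)
  expect_equal(nrow(stl$faces), nrow(mesh$faces))  # facet count preserved
  obj <- import_mesh(fo)
  expect_equal(nrow(obj$vertices), nrow(mesh$vertices))
  expect_equal(obj$vertices, mesh$vertices, tolerance = 1e-6)
  expect_equal(obj$faces, mesh$faces, ignore_attr = TRUE)
  # empty mesh: error, no file written
  bad <- tempfile(fileext = ".stl")
  expect_error(export_mesh(structure(list(vertices = matrix(0, 0, 3),
                                          faces = matrix(0L, 0, 3)),
                                     class = "tri_mesh"), bad), "empty")
  expect_false(file.exists(bad))
  expect_error(export_mesh(mesh, tempfile(fileext = ".ply")), "unknown")
})
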