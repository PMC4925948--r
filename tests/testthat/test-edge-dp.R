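# transition scoring and the dynamic-programming wall optimizer

test_that("transition_score matches independent arithmetic", {
  p <- dp_params(beta = 0.75, epsilon = 1e-6)
  prev <- list(e_m = 0.8, e_gm = 0.8, e_hm = 0.1, e_gd = 0)
  cur <- list(e_m = 0.6, e_gm = 0.6, e_hm = 0.2, e_gd = pi / 4)
  expect_equal(transition_score(prev, cur, p),
               score_oracle(0.8, 0.1, 0, 0.6, 0.2, pi / 4, 0.6, 0.75, 1e-6))
  # identical features: penalties vanish, score is the node reward
  expect_equal(transition_score(prev, prev, p), prev$e_m)
  # beta = 1 removes the direction term entirely
  p1 <- dp_params(beta = 1)
  cur2 <- modifyList(cur, list(e_gd = 2.9))
  expect_equal(transition_score(prev, cur, p1), transition_score(prev, cur2, p1))
  # direction differences live modulo pi: orientations pi - x and x are close
  p0 <- dp_params(beta = 0)
  a <- list(e_m = 0, e_gm = 1, e_hm = 1, e_gd = 0.05)
  b <- list(e_m = 0, e_gm = 1, e_hm = 1, e_gd = pi - 0.05)
  expect_equal(transition_score(a, b, p0), -(0.1)^2, tolerance = 1e-12)
})

test_that("dp_params validates its domain", {
  expect_error(dp_params(beta = 1.2), "beta")
  expect_error(dp_params(beta = -0.1), "beta")
  expect_error(dp_params(epsilon = 0), "epsilon")
})

test_that("dp_optimal_path equals exhaustive enumeration on random grids", {
  set.seed(123)
  for (trial in 1:25) {
    n <- sample(3:7, 1); k <- sample(2:5, 1)
    beta <- sample(c(0, 0.5, 0.75, 1), 1)
    g <- random_grid(n, k)
    p <- dp_params(beta = beta, epsilon = 0.5)
    got <- dp_optimal_path(g, p)
    want <- dp_oracle(g, beta, 0.5)
    expect_equal(got$objective, want$objective, tolerance = 1e-10)
    expect_equal(got$offsets, unname(want$path))
  }
})

test_that("single-node stages force the path; objective is the summed score", {
  g <- normal_grid(e_m = matrix(c(0.5, 0.2, 0.9), 3, 1),
                   e_gm = matrix(1, 3, 1), e_hm = matrix(1, 3, 1),
                   e_gd = matrix(0, 3, 1))
  w <- dp_optimal_path(g, dp_params(0.75, 0.5))
  expect_equal(w$offsets, c(1L, 1L, 1L))
  expect_equal(w$objective, 0.5 + 0.2 + 0.9)   # penalties vanish
  expect_error(dp_optimal_path(g, dp_params()) , NA)
  g1 <- normal_grid(e_m = matrix(1, 1, 2), e_gm = matrix(1, 1, 2),
                    e_hm = matrix(1, 1, 2), e_gd = matrix(0, 1, 2))
  expect_error(dp_optimal_path(g1), "2 stages")
})

test_that("objective increases by exactly delta when e_m is raised on the path", {
  set.seed(9)
  g <- random_grid(6, 4)
  p <- dp_params(0.5, 0.5)
  w <- dp_optimal_path(g, p)
  i <- 3
  g2 <- g
  g2$e_m[i, w$offsets[i]] <- g2$e_m[i, w$offsets[i]] + 0.25
  w2 <- dp_optimal_path(g2, p)
  expect_equal(w2$objective, w$objective + 0.25, tolerance = 1e-12)
  expect_equal(w2$offsets, w$offsets)
})

test_that("ties break toward the smaller offset index", {
  # two identical columns of features: every path has the same objective
  g <- normal_grid(e_m = matrix(0.5, 4, 3), e_gm = matrix(0.7, 4, 3),
                   e_hm = matrix(0.3, 4, 3), e_gd = matrix(1, 4, 3))
  w <- dp_optimal_path(g, dp_params())
  expect_equal(w$offsets, rep(1L, 4))
})

test_that("DP runtime for N = 500, K = 10 stays under a second", {
  set.seed(4)
  g <- random_grid(500, 10)
  t0 <- Sys.time()
  w <- dp_optimal_path(g, dp_params())
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 1)
  expect_length(w$offsets, 500)
})

test_that("build_normal_grid geometry and degenerate features", {
  img <- angio_image(matrix(0.5, 64, 64), normalize = FALSE)
  cl <- centreline_curve(cbind(rep(32, 20), seq(20, 39)))
  grids <- build_normal_grid(img, cl, half_width = 5, spacing = 1)
  # straight horizontal centreline: normals are vertical, so left nodes sit
  # at decreasing/increasing rows with constant columns
  expect_equal(grids$left$pos_c[3, ], rep(cl$points[3, 2], 5))
  expect_equal(abs(grids$left$pos_r[3, ] - 32), 1:5)
  # constant image: zero gradient and curvature features (numerically)
  expect_lt(max(grids$left$e_gm), 1e-12)
  expect_lt(max(grids$left$e_hm), 1e-12)
  expect_error(build_normal_grid(img, cl, spacing = -1), "positive")
  # grid pushed fully outside the image errors
  cl_out <- centreline_curve(cbind(rep(2, 20), seq(20, 39)))
  expect_error(build_normal_grid(img, cl_out, half_width = 80, spacing = 10),
               "outside")
})

test_that("normal grids cover the true wall offset of a rendered vessel", {
  lp <- line_phantom_views()
  tv <- lp$rv$truth$views$A
  grids <- build_normal_grid(lp$rv$imageA, tv$centreline_curve)
  # true projected half-width ~4 px lies within the K = 10 offsets
  expect_true(all(tv$radius_px < 10 * grids$left$spacing))
  expect_true(all(tv$radius_px > grids$left$spacing))
})

test_that("walls of a rendered straight vessel are recovered accurately", {
  lp <- line_phantom_views()
  tv <- lp$rv$truth$views$A
  walls <- extract_vessel_walls(lp$rv$imageA, tv$centreline_curve)
  for (side in c("left", "right")) {
    d <- curve_dist(walls[[side]]$points, tv$walls[[side]])
    expect_lt(mean(d), 1)
    expect_lt(compare_walls(walls[[side]],
              angiorecon:::crop_reference_to_span(tv$walls[[side]],
                                                  walls[[side]]))$px, 2)
  }
})

test_that("feature rescaling invariance: scaling e_gm, e_hm, e_m and epsilon", {
  set.seed(31)
  g <- random_grid(5, 4)
  p <- dp_params(0.6, 0.3)
  w1 <- dp_optimal_path(g, p)
  s <- 3.7
  g2 <- g
  g2$e_gm <- g$e_gm * s; g2$e_hm <- g$e_hm * s; g2$e_m <- g$e_m
  w2 <- dp_optimal_path(g2, dp_params(0.6, 0.3 * s))
  expect_equal(w2$offsets, w1$offsets)
  expect_equal(w2$objective, w1$objective, tolerance = 1e-10)
})
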