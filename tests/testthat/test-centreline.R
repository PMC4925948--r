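# snapping, skeleton path extraction, spline smoothing

toy_skeleton <- function() {
  m <- matrix(FALSE, 20, 20)
  m[10, 3:17] <- TRUE
  structure(list(skeleton = m,
                 bifurcation_points = matrix(numeric(0), 0, 2),
                 end_points = rbind(c(10, 3), c(10, 17))),
            class = "skeleton_map")
}

test_that("snap_to_skeleton matches a brute-force scan and breaks ties", {
  sk <- toy_skeleton()
  expect_equal(snap_to_skeleton(c(10, 5), sk), c(10L, 5L))  # already on it
  # equidistant pixels: lexicographically smaller (row, col) wins
  m <- matrix(FALSE, 20, 20)
  m[4, 6] <- TRUE; m[6, 4] <- TRUE   # both sqrt(2)/... from (5, 5)
  expect_equal(snap_to_skeleton(c(5, 5), m), c(4L, 6L))
  # random queries vs exhaustive scan on a larger skeleton
  set.seed(7)
  big <- matrix(runif(40 * 40) < 0.12, 40, 40)
  big[1, 1] <- TRUE
  px <- which(big, arr.ind = TRUE)
  for (i in 1:20) {
    q <- runif(2, 1, 40)
    d <- sqrt((px[, 1] - q[1])^2 + (px[, 2] - q[2])^2)
    ord <- order(d, px[, 1], px[, 2])
    expect_equal(snap_to_skeleton(q, big), unname(as.integer(px[ord[1], ])))
  }
  expect_error(snap_to_skeleton(c(1, 1), matrix(FALSE, 5, 5)), "empty")
})

test_that("extract_path returns ordered weighted-shortest skeleton paths", {
  sk <- toy_skeleton()
  expect_equal(extract_path(sk, c(10, 3), c(10, 3)),
               matrix(c(10L, 3L), 1, 2, dimnames = list(NULL, c("row", "col"))),
               ignore_attr = TRUE)
  p <- extract_path(sk, c(10, 5), c(10, 14))
  expect_equal(p[, 1], rep(10L, 10))
  expect_equal(p[, 2], 5:14)
  expect_error(extract_path(sk, c(10, 3), c(1, 1)), "skeleton")
  # disconnected components
  m <- matrix(FALSE, 10, 10); m[2, 2:4] <- TRUE; m[8, 6:8] <- TRUE
  expect_error(extract_path(m, c(2, 2), c(8, 8)),
               "no skeleton path between \\(2, 2\\) and \\(8, 8\\)")
})

test_that("extract_path picks the cheaper arm of a loop (Dijkstra oracle)", {
  # loop: short arm along a row (straight), long arm with a detour
  m <- matrix(FALSE, 12, 12)
  m[6, 2:10] <- TRUE                       # straight arm, cost 8
  m[5, 3] <- m[4, 4:8] <- m[5, 9] <- TRUE  # detour arm via row 4
  p <- extract_path(m, c(6, 2), c(6, 10))
  expect_equal(p[, 1], rep(6L, 9))
  # independent Dijkstra on the pixel graph
  px <- which(m, arr.ind = TRUE)
  n <- nrow(px)
  dist <- rep(Inf, n); done <- rep(FALSE, n)
  id <- function(rc) which(px[, 1] == rc[1] & px[, 2] == rc[2])
  dist[id(c(6, 2))] <- 0
  repeat {
    u <- which(!done & dist == min(dist[!done]))[1]
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    for (v in seq_len(n)) {
      dr <- abs(px[v, 1] - px[u, 1]); dc <- abs(px[v, 2] - px[u, 2])
      if (!done[v] && dr <= 1 && dc <= 1 && (dr + dc) > 0) {
        w <- if (dr + dc == 2) sqrt(2) else 1
        if (dist[u] + w < dist[v]) dist[v] <- dist[u] + w
      }
    }
    if (all(done | !is.finite(dist))) break
  }
  path_cost <- sum(sqrt(rowSums(diff(p)^2)))
  expect_equal(path_cost, dist[id(c(6, 10))], tolerance = 1e-12)
})

test_that("smooth_centreline reproduces straight paths and resamples evenly", {
  path <- cbind(rep(5, 50), seq(3, 52))
  cl <- smooth_centreline(path, sample_step = 1, pixel_spacing_mm = 0.5)
  expect_s3_class(cl, "centreline_curve")
  expect_lt(max(abs(cl$points[, 1] - 5)), 1e-8)      # stays on the line
  spacing <- diff(cl$arc_length)
  expect_true(all(abs(spacing[-length(spacing)] - 1) < 0.05))
  expect_true(all(diff(cl$arc_length) > 0))
  expect_equal(cl$arc_length_mm, cl$arc_length * 0.5)
  # endpoints preserved within 0.5 px
  expect_lt(sqrt(sum((cl$points[1, ] - path[1, ])^2)), 0.5)
  expect_lt(sqrt(sum((cl$points[nrow(cl$points), ] - path[nrow(path), ])^2)), 0.5)
})

test_that("bifurcation pixels are excluded from the spline support", {
  path <- cbind(rep(5, 30), 1:30)
  path[15, 1] <- 6                      # branch-point pixel off the axis
  sk <- structure(list(skeleton = NULL,
                       bifurcation_points = matrix(c(6, 15), 1, 2),
                       end_points = matrix(numeric(0), 0, 2)),
                  class = "skeleton_map")
  cl <- smooth_centreline(path, sk, sample_step = 1)
  expect_equal(nrow(cl$bifurcations_on_path), 1L)
  # the displaced pixel must not be interpolated exactly
  d <- min(sqrt((cl$points[, 1] - 6)^2 + (cl$points[, 2] - 15)^2))
  expect_gt(d, 0.5)
  # smoothed curve stays close to the true axis row 5 near the bifurcation
  near <- abs(cl$points[, 2] - 15) < 2
  expect_lt(max(abs(cl$points[near, 1] - 5)), 0.3)
})

test_that("insufficient support after exclusion falls back with a warning", {
  path <- cbind(rep(5, 6), 1:6)
  sk <- structure(list(skeleton = NULL,
                       bifurcation_points = matrix(c(5, 3), 1, 2),
                       end_points = matrix(numeric(0), 0, 2)),
                  class = "skeleton_map")
  expect_warning(smooth_centreline(path, sk, bif_radius = 3), "support")
  expect_error(smooth_centreline(path[1:3, ]), "at least 4")
})

test_that("smoothed curve stays within 2 px Hausdorff of the raw path", {
  lp <- line_phantom_views()
  st <- angiorecon:::enhance_stage(lp$rv$imageA, default_config()$enhancement)
  p <- lp$rv$truth$views$A$centreline2d
  s <- snap_to_skeleton(p[1, ], st$skeleton)
  e <- snap_to_skeleton(p[nrow(p), ], st$skeleton)
  path <- extract_path(st$skeleton, s, e)
  cl <- smooth_centreline(path, st$skeleton)
  expect_lt(hausdorff_distance(cl$points, path), 2)
})

test_that("ridge refinement moves a biased centreline onto the ridge", {
  # vesselness-like map with a ridge at row 20.4; centreline guessed at row 21
  n <- 48
  vmap <- matrix(0, n, n)
  for (r in 1:n) vmap[r, ] <- exp(-((r - 20.4)^2) / (2 * 2^2))
  cl <- centreline_curve(cbind(rep(21, 30), seq(5, 34)))
  ref <- refine_centreline_ridge(cl, vmap)
  int <- ref$points[, 2] > 7 & ref$points[, 2] < 32   # spline ends are looser
  expect_lt(max(abs(ref$points[int, 1] - 20.4)), 0.25)
  expect_lt(max(abs(ref$points[, 1] - 20.4)), 0.35)
})
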