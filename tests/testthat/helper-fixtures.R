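# Shared fixtures: standard two-view C-arm geometry and phantom renderings.
# Rendering is the slow step, so renders used by several tests are memoized
# per test run.

std_geom <- function(primary_deg = 0, image_size = c(256, 256)) {
  projection_geometry(sid = 1000, pixel_size_mm = 0.4,
                      primary_deg = primary_deg, sod = 750,
                      image_size = image_size)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# straight vessel whose projected half-width is ~4 px in view A
line_phantom_views <- function() cached("line", {
  ph <- make_phantom("line", length_mm = 50, r0_mm = 1.2)
  list(phantom = ph,
       rv = render_views(ph, std_geom(0), std_geom(30), seed = 11,
                         noise_sd = 0.02))
})

helix_phantom_views <- function() cached("helix", {
  ph <- make_phantom("helix", r0_mm = 1.5,
                     stenosis = list(location = 0.5, severity = 0.5,
                                     width = 0.08))
  list(phantom = ph,
       rv = render_views(ph, std_geom(0), std_geom(30), seed = 5,
                         noise_sd = 0.02))
})

branched_phantom_views <- function() cached("branched", {
  ph <- make_phantom("branched", length_mm = 50, r0_mm = 1.2,
                     branch_angle_deg = 90, branch_t = 0.5)
  list(phantom = ph,
       rv = render_views(ph, std_geom(0), std_geom(30), seed = 13,
                         noise_sd = 0.02))
})

# mean/max nearest-point distance from each row of `pts` to polyline `ref`
curve_dist <- function(pts, ref, step = 0.1) {
  R <- angiorecon:::resample_polyline2d(ref, step)
  vapply(seq_len(nrow(pts)), function(i)
    sqrt(min((R[, 1] - pts[i, 1])^2 + (R[, 2] - pts[i, 2])^2)), numeric(1))
}

# independent brute-force Hausdorff (double loop)
hausdorff_bf <- function(X, Y) {
  dxy <- apply(X, 1, function(x) min(apply(Y, 1, function(y) sqrt(sum((x - y)^2)))))
  dyx <- apply(Y, 1, function(y) min(apply(X, 1, function(x) sqrt(sum((x - y)^2)))))
  max(max(dxy), max(dyx))
}

# independent transition-score arithmetic (kept deliberately separate from
# the package implementation)
score_oracle <- function(gm0, hm0, gd0, gm1, hm1, gd1, em1, beta, eps) {
  r0 <- gm0 / (hm0 + eps)
  r1 <- gm1 / (hm1 + eps)
  dd <- gd1 - gd0
  dd <- dd - pi * round(dd / pi)
  em1 - beta * abs(r1 - r0) - (1 - beta) * dd^2
}

# exhaustive DP oracle: enumerate all paths with pinned endpoints
dp_oracle <- function(g, beta, eps) {
  n <- nrow(g$e_m); k <- ncol(g$e_m)
  first <- which.max(g$e_gm[1, ])
  last <- which.max(g$e_gm[n, ])
  mids <- if (n > 2) as.matrix(expand.grid(rep(list(seq_len(k)), n - 2)))
          else matrix(integer(0), 1, 0)
  npaths <- nrow(mids)
  obj <- rep(g$e_m[1, first], npaths)
  prev <- rep(first, npaths)
  for (i in 2:n) {
    cur <- if (i < n) mids[, i - 1] else rep(last, npaths)
    obj <- obj + score_oracle(
      g$e_gm[cbind(i - 1, prev)], g$e_hm[cbind(i - 1, prev)],
      g$e_gd[cbind(i - 1, prev)],
      g$e_gm[cbind(i, cur)], g$e_hm[cbind(i, cur)], g$e_gd[cbind(i, cur)],
      g$e_m[cbind(i, cur)], beta, eps)
    prev <- cur
  }
  best <- which.max(obj)
  list(objective = obj[best],
       path = c(first, if (n > 2) mids[best, ] else integer(0), last))
}

random_grid <- function(n, k) {
  normal_grid(e_m = matrix(runif(n * k), n, k),
              e_gm = matrix(runif(n * k), n, k),
              e_hm = matrix(runif(n * k), n, k),
              e_gd = matrix(runif(n * k, 0, pi), n, k))
}
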