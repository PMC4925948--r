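# End-to-end orchestration: enhancement -> centreline -> wall delineation ->
# 3D reconstruction -> tube mesh, driven by a JSON config, with a run
# manifest capturing every parameter for reproducibility.

#' Default pipeline configuration
#'
#' Returns the full default parameter set; user configs override fields
#' selectively (recursively merged).
#'
#' @return nested list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1,
    segment_name = "vessel",
    enhancement = list(scales = c(1, 2, 3, 5, 8), polarity = "dark",
                       hysteresis_quantiles = c(0.80, 0.95),
                       low = NULL, high = NULL,
                       min_object_px = 30, closing = TRUE),
    centreline = list(sample_step = 1, bif_radius = 2, ridge_refine = TRUE),
    edge = list(beta = 0.75, epsilon = 0.5, half_width = 10,
                spacing = 1, sigma = 1),
    recon = list(tol = 1e-3, max_iter = 20, smooth = TRUE),
    mesh = list(subdivisions = 16, cap = TRUE, format = "stl")
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read and validate a run configuration
#'
#' @param config path to a JSON config file or an already-built list. The
#'   config must name two `views`, each with an `image` (file path),
#'   `geometry` block (see [geometry_from_json()]), `pixel_spacing_mm`, and
#'   `points` (`start`/`end` `(row, col)` pairs); phantom-driven configs give
#'   a `phantom` block instead of image paths.
#' @return validated config list with defaults filled in.
#' @export
read_config <- function(config) {
  if (is.character(config)) config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  cfg <- merge_config(default_config(), config)
  if (is.null(cfg$phantom)) {
    if (is.null(cfg$views) || length(cfg$views) != 2)
      stop("config must define exactly 2 views")
    for (i in 1:2) {
      v <- cfg$views[[i]]
      if (is.null(v$image)) stop(sprintf("view %d: missing image path", i))
      if (!file.exists(v$image)) stop(sprintf("view %d: image not found: %s", i, v$image))
      if (is.null(v$geometry)) stop(sprintf("view %d: missing geometry block", i))
      if (is.null(v$points$start) || is.null(v$points$end))
        stop(sprintf("view %d: missing start/end points", i))
    }
  }
  cfg
}

# Enhancement + skeletonization of one image under the config block.
enhance_stage <- function(image, enh) {
  v <- vesselness_filter(image, scales = enh$scales, polarity = enh$polarity)
  mask <- if (!is.null(enh$low) && !is.null(enh$high))
    hysteresis_threshold(v, low = enh$low, high = enh$high)
  else
    hysteresis_threshold(v, quantiles = enh$hysteresis_quantiles)
  if (isTRUE(enh$closing)) mask <- binary_close(mask)
  if (!is.null(enh$min_object_px) && enh$min_object_px > 0)
    mask <- remove_small_objects(mask, enh$min_object_px)
  list(vesselness = v, mask = mask, skeleton = skeletonize_and_label(mask))
}

# Centreline between user points on one view (optionally ridge-refined
# against the vesselness map).
centreline_stage <- function(skel, start, end, cfg, pixel_spacing_mm,
                             vesselness = NULL) {
  s <- snap_to_skeleton(start, skel)
  e <- snap_to_skeleton(end, skel)
  path <- extract_path(skel, s, e)
  cl <- smooth_centreline(path, skel,
                          sample_step = cfg$centreline$sample_step,
                          bif_radius = cfg$centreline$bif_radius,
                          pixel_spacing_mm = pixel_spacing_mm)
  if (isTRUE(cfg$centreline$ridge_refine) && !is.null(vesselness))
    cl <- refine_centreline_ridge(cl, vesselness)
  cl
}

#' Run the full reconstruction pipeline
#'
#' Executes the four stages on both views and writes, per segment: the tube
#' mesh (STL/OBJ), a CSV of the 3D centreline with per-point radius,
#' curvature and torsion, and a JSON manifest with every parameter of the
#' run. With a `phantom` config block the projection pair is generated
#' internally and a validation report (Hausdorff discrepancies of the
#' extracted walls and centreline against ground truth) is added.
#'
#' @param config path to a JSON config or a config list (see [read_config()]).
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the stage outputs (`model`, `walls`,
#'   `centrelines`, `files`, and `validation` when ground truth is known).
#' @export
run_pipeline <- function(config, outdir = tempfile("angiorecon_run_")) {
  cfg <- read_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  truth <- NULL
  if (!is.null(cfg$phantom)) {
    ph_args <- cfg$phantom[setdiff(names(cfg$phantom), c("geometryA", "geometryB",
                                                         "noise_sd", "points"))]
    phantom <- do.call(make_phantom, ph_args)
    gA <- geometry_from_json(cfg$phantom$geometryA)
    gB <- geometry_from_json(cfg$phantom$geometryB)
    noise <- if (is.null(cfg$phantom$noise_sd)) 0.02 else cfg$phantom$noise_sd
    rv <- render_views(phantom, gA, gB, seed = cfg$seed, noise_sd = noise)
    imgs <- list(rv$imageA, rv$imageB)
    geoms <- list(gA, gB)
    truth <- rv$truth
    pts <- lapply(rv$truth$views, function(tv) {
      p <- tv$centreline_curve$points
      list(start = p[1, ], end = p[nrow(p), ])
    })
  } else {
    imgs <- list(); geoms <- list(); pts <- list()
    for (i in 1:2) {
      v <- cfg$views[[i]]
      sp <- if (is.null(v$pixel_spacing_mm)) 1 else v$pixel_spacing_mm
      imgs[[i]] <- read_angio_image(v$image, pixel_spacing_mm = sp)
      geoms[[i]] <- geometry_from_json(v$geometry)
      pts[[i]] <- v$points
    }
  }

  enh <- lapply(imgs, enhance_stage, enh = cfg$enhancement)
  cls <- vector("list", 2)
  for (i in 1:2)
    cls[[i]] <- centreline_stage(enh[[i]]$skeleton,
                                 pts[[i]]$start, pts[[i]]$end, cfg,
                                 imgs[[i]]$pixel_spacing_mm[1],
                                 vesselness = enh[[i]]$vesselness)
  dpp <- dp_params(beta = cfg$edge$beta, epsilon = cfg$edge$epsilon)
  walls <- lapply(1:2, function(i)
    extract_vessel_walls(imgs[[i]], cls[[i]], params = dpp,
                         half_width = cfg$edge$half_width,
                         spacing = cfg$edge$spacing, sigma = cfg$edge$sigma))

  model <- correspond_and_reconstruct(cls[[1]], cls[[2]], geoms[[1]], geoms[[2]],
                                      tol = cfg$recon$tol,
                                      max_iter = cfg$recon$max_iter)
  model <- estimate_radii(model, walls[[1]], walls[[2]])
  model <- add_frenet_frames(model, smooth = isTRUE(cfg$recon$smooth))
  model <- build_tube(model, s = cfg$mesh$subdivisions, cap = isTRUE(cfg$mesh$cap))

  base <- file.path(outdir, cfg$segment_name)
  mesh_file <- paste0(base, ".", cfg$mesh$format)
  export_mesh(model$mesh, mesh_file, format = cfg$mesh$format)
  csv_file <- paste0(base, "_centreline.csv")
  utils::write.csv(data.frame(x_mm = model$centreline3d[, 1],
                              y_mm = model$centreline3d[, 2],
                              z_mm = model$centreline3d[, 3],
                              radius_mm = model$radii_mm,
                              kappa = model$kappa, tau = model$tau),
                   csv_file, row.names = FALSE)

  validation <- NULL
  if (!is.null(truth)) {
    validation <- list(
      centreline_rms_mm = centreline_rms(model$centreline3d, truth$centreline3d),
      walls_hausdorff_px = lapply(1:2, function(i) {
        tv <- truth$views[[i]]
        list(left = compare_walls(walls[[i]]$left,
               crop_reference_to_span(tv$walls$left, walls[[i]]$left))$px,
             right = compare_walls(walls[[i]]$right,
               crop_reference_to_span(tv$walls$right, walls[[i]]$right))$px)
      }))
    val_file <- paste0(base, "_validation.json")
    jsonlite::write_json(validation, val_file, auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(package_version = as.character(utils::packageVersion("angiorecon")),
                   config = cfg[setdiff(names(cfg), "views")],
                   beta = cfg$edge$beta, epsilon = cfg$edge$epsilon,
                   subdivisions = cfg$mesh$subdivisions,
                   recon_tol = cfg$recon$tol, recon_max_iter = cfg$recon$max_iter,
                   iterations = model$iterations,
                   outputs = c(mesh_file, csv_file))
  manifest_file <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)

  invisible(list(model = model, walls = walls, centrelines = cls,
                 enhancement = enh, validation = validation,
                 files = list(mesh = mesh_file, csv = csv_file,
                              manifest = manifest_file),
                 outdir = outdir))
}

# RMS of nearest-point distances from a reconstructed to a reference
# polyline (reference densified for a fair point-to-curve distance).
centreline_rms <- function(X, ref) {
  seg <- sqrt(rowSums(diff(ref)^2))
  al <- c(0, cumsum(seg))
  s <- seq(0, al[length(al)], length.out = 8 * nrow(ref))
  dense <- cbind(stats::approx(al, ref[, 1], xout = s)$y,
                 stats::approx(al, ref[, 2], xout = s)$y,
                 stats::approx(al, ref[, 3], xout = s)$y)
  d2 <- vapply(seq_len(nrow(X)), function(i)
    min((dense[, 1] - X[i, 1])^2 + (dense[, 2] - X[i, 2])^2 +
          (dense[, 3] - X[i, 3])^2), numeric(1))
  sqrt(mean(d2))
}
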