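# Frenet-frame tube meshing and STL/OBJ export. Ring vertices follow
# X + r (N cos(theta) + B sin(theta)) with s equally spaced angles of step
# 2*pi/s over [0, 2*pi) — no duplicated seam vertex.

#' Build the triangulated tube surface of a vessel model
#'
#' Places a ring of `s` vertices around every centreline point in its
#' normal/binormal plane at the local radius and stitches consecutive rings
#' with `2s` triangles. With `cap = TRUE` both ends are closed with a
#' triangle fan around the centreline end point, yielding a watertight mesh.
#'
#' @param model a `vessel_model_3d` with `frames` and `radii_mm` set, or a
#'   list with `centreline3d`, `frames`, `radii_mm`.
#' @param s number of angular subdivisions per ring (>= 3, default 16).
#' @param cap close the tube ends (default TRUE).
#' @return for a model input, the model with `$mesh` set; the mesh itself is
#'   a `tri_mesh`: list with `vertices` (V x 3) and `faces` (F x 3, 1-based).
#' @export
build_tube <- function(model, s = 16, cap = TRUE) {
  if (s < 3) stop("`s` must be at least 3")
  X <- model$centreline3d
  fr <- model$frames
  r <- model$radii_mm
  if (is.null(fr) || is.null(r))
    stop("model needs Frenet frames and radii; see add_frenet_frames() and estimate_radii()")
  if (any(r <= 0)) stop("radii must be positive")
  n <- nrow(X)
  theta <- 2 * pi * (seq_len(s) - 1) / s
  verts <- matrix(0, n * s, 3)
  for (i in seq_len(n)) {
    ring <- matrix(X[i, ], s, 3, byrow = TRUE) +
      r[i] * (outer(cos(theta), fr$N[i, ]) + outer(sin(theta), fr$B[i, ]))
    verts[(i - 1) * s + seq_len(s), ] <- ring
  }
  faces <- matrix(0L, 0, 3)
  for (i in seq_len(n - 1)) {
    a <- (i - 1) * s + seq_len(s)
    nxt <- c(a[-1], a[1])               # next vertex around the ring
    a2 <- a + s; nxt2 <- nxt + s
    faces <- rbind(faces,
                   cbind(a, nxt, a2),
                   cbind(nxt, nxt2, a2))
  }
  if (cap) {
    c1 <- nrow(verts) + 1L; c2 <- nrow(verts) + 2L
    verts <- rbind(verts, X[1, ], X[n, ])
    ring1 <- seq_len(s)
    ringN <- (n - 1) * s + seq_len(s)
    faces <- rbind(faces,
                   cbind(c1, c(ring1[-1], ring1[1]), ring1),
                   cbind(c2, ringN, c(ringN[-1], ringN[1])))
  }
  mesh <- structure(list(vertices = verts, faces = faces), class = "tri_mesh")
  if (inherits(model, "vessel_model_3d")) { model$mesh <- mesh; model }
  else mesh
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Export a triangle mesh as STL or OBJ
#'
#' @param mesh a `tri_mesh` (or `vessel_model_3d` with `$mesh`).
#' @param path output file path.
#' @param format `"stl"` (ASCII) or `"obj"`; default from the file extension.
#' @return `path`, invisibly.
#' @export
export_mesh <- function(mesh, path, format = NULL) {
  if (inherits(mesh, "vessel_model_3d")) mesh <- mesh$mesh
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  if (!format %in% c("stl", "obj")) stop("unknown mesh format: ", format)
  if (is.null(mesh) || nrow(mesh$faces) == 0 || nrow(mesh$vertices) == 0)
    stop("empty mesh; nothing written")
  v <- mesh$vertices; f <- mesh$faces
  if (max(f) > nrow(v) || min(f) < 1) stop("faces reference invalid vertices")
  if (format == "obj") {
    lines <- c(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
               sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]))
    writeLines(lines, path)
  } else {
    e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    nrm <- cross3(e1, e2)
    len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
    nrm <- nrm / len
    tri <- function(i) {
      p <- v[f[i, ], , drop = FALSE]
      c(sprintf("  facet normal %.9g %.9g %.9g", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
        "    outer loop",
        sprintf("      vertex %.9g %.9g %.9g", p[, 1], p[, 2], p[, 3]),
        "    endloop",
        "  endfacet")
    }
    writeLines(c("solid vessel",
                 unlist(lapply(seq_len(nrow(f)), tri)),
                 "endsolid vessel"), path)
  }
  invisible(path)
}

#' Import a mesh written by [export_mesh()]
#'
#' OBJ meshes round-trip vertices and faces; ASCII STL is read back as one
#' vertex triple per facet (`faces` regenerated consecutively).
#'
#' @param path mesh file (`.stl` or `.obj`).
#' @return a `tri_mesh`.
#' @export
import_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path, warn = FALSE)
  if (ext == "obj") {
    vl <- grep("^v ", lines, value = TRUE)
    fl <- grep("^f ", lines, value = TRUE)
    v <- do.call(rbind, lapply(strsplit(vl, "\\s+"),
                               function(x) as.numeric(x[2:4])))
    f <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x)
      as.integer(sub("/.*", "", x[2:4]))))
  } else if (ext == "stl") {
    vl <- grep("^\\s*vertex ", lines, value = TRUE)
    v <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                               function(x) as.numeric(x[2:4])))
    f <- matrix(seq_len(nrow(v)), ncol = 3, byrow = TRUE)
  } else stop("unknown mesh format: ", ext)
  structure(list(vertices = v, faces = f), class = "tri_mesh")
}

# Edge-manifold check: each undirected edge is used by at most two faces,
# and (watertight) exactly two.
mesh_edge_use <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  table(key)
}
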