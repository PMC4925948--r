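#' Grayscale angiogram image
#'
#' Construct an `angio_image` object: a 2D matrix of intensities normalized to
#' \[0, 1\] with physical pixel spacing. The coordinate convention throughout
#' the package is row-major `(row, col)`, 1-based (R convention), with row 1 at
#' the top of the image.
#'
#' @param pixels numeric matrix of intensities. Rescaled to \[0, 1\] when
#'   `normalize = TRUE` (the default) unless already within range.
#' @param pixel_spacing_mm physical size of one pixel in mm, either a single
#'   value or `c(row, col)` spacings.
#' @param normalize logical; rescale intensities to span \[0, 1\].
#' @return an object of class `angio_image` with fields `pixels` and
#'   `pixel_spacing_mm`.
#' @examples
#' img <- angio_image(matrix(runif(32 * 32), 32), pixel_spacing_mm = 0.3)
#' dim(img$pixels)
#' @export
angio_image <- function(pixels, pixel_spacing_mm = 1, normalize = TRUE) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (any(!is.finite(pixels)))
    stop("image contains non-finite pixels")
  if (nrow(pixels) < 16 || ncol(pixels) < 16)
    stop("image dimensions must both be >= 16")
  if (any(pixel_spacing_mm <= 0))
    stop("`pixel_spacing_mm` must be positive")
  pixel_spacing_mm <- rep_len(as.numeric(pixel_spacing_mm), 2L)
  rng <- range(pixels)
  if (normalize && (rng[1] < 0 || rng[2] > 1)) {
    if (diff(rng) > 0) pixels <- (pixels - rng[1]) / diff(rng)
    else pixels <- matrix(0, nrow(pixels), ncol(pixels))
  }
  structure(list(pixels = pixels, pixel_spacing_mm = pixel_spacing_mm),
            class = "angio_image")
}

#' @export
print.angio_image <- function(x, ...) {
  cat(sprintf("angio_image: %d x %d px, spacing %.4g x %.4g mm/px, range [%.3g, %.3g]\n",
              nrow(x$pixels), ncol(x$pixels),
              x$pixel_spacing_mm[1], x$pixel_spacing_mm[2],
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

as_pixel_matrix <- function(image) {
  if (inherits(image, "angio_image")) image$pixels
  else if (is.matrix(image) && is.numeric(image)) image
  else stop("expected an `angio_image` or a numeric matrix")
}

#' Read a grayscale image
#'
#' Reads PNG (via the \pkg{png} package; RGB(A) images are converted to
#' luminance), ASCII PGM (`P2`), or a plain CSV matrix of intensities.
#' Format is chosen by file extension.
#'
#' @param path file path (`.png`, `.pgm`, `.csv`).
#' @param pixel_spacing_mm physical pixel spacing (mm/px); images carry no
#'   spacing metadata in these formats, so it must be supplied.
#' @return an [angio_image].
#' @export
read_angio_image <- function(path, pixel_spacing_mm = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = {
      a <- png::readPNG(path)
      if (length(dim(a)) == 3L)  # luminance from RGB(A)
        a <- 0.2126 * a[, , 1] + 0.7152 * a[, , 2] + 0.0722 * a[, , 3]
      a
    },
    pgm = read_pgm(path),
    csv = as.matrix(utils::read.csv(path, header = FALSE)),
    stop("unsupported image format: .", ext)
  )
  storage.mode(px) <- "double"
  dimnames(px) <- NULL
  angio_image(px, pixel_spacing_mm = pixel_spacing_mm)
}

#' Write a grayscale image
#'
#' @param image an [angio_image] or numeric matrix in \[0,1\].
#' @param path output path; `.png` or `.pgm` (ASCII, 16-bit).
#' @return `path`, invisibly.
#' @export
write_angio_image <- function(image, path) {
  px <- as_pixel_matrix(image)
  px <- pmin(pmax(px, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(px, path)
  else if (ext == "pgm") write_pgm(px, path)
  else stop("unsupported image format: .", ext)
  invisible(path)
}

# Minimal ASCII PGM (P2) reader; comments and arbitrary whitespace permitted.
read_pgm <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- sub("#.*$", "", txt)
  tok <- scan(text = paste(txt, collapse = " "), what = character(),
              quiet = TRUE)
  if (length(tok) < 4 || tok[1] != "P2") stop("not an ASCII PGM (P2) file")
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  maxv <- as.numeric(tok[4])
  vals <- as.numeric(tok[-(1:4)])
  if (length(vals) != w * h) stop("PGM pixel count mismatch")
  matrix(vals / maxv, nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(px, path, maxval = 65535L) {
  q <- round(px * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(px), nrow(px)), as.character(maxval)), con)
  apply(q, 1L, function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}
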