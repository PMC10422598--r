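# Internal helpers shared across modules. Images are plain numeric arrays
# (height x width x 3) on the 0..255 scale; pixel coordinates are (x, y) =
# (column, row), 0-based, with rectangles closed on both ends.

clip255 <- function(x) pmin(pmax(x, 0), 255)

assert_rgb <- function(image, arg = "image") {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L) {
    abort(sprintf("`%s` must be a height x width x 3 array", arg))
  }
  invisible(image)
}

# Bilinear resize of an RGB array, delegated to EBImage. EBImage stores
# images with the x (width) dimension first, so transpose in and out.
# Resizing to the native size is an exact passthrough.
resize_rgb <- function(image, width, height) {
  d <- dim(image)
  if (d[1] == height && d[2] == width) {
    return(image)
  }
  eb <- EBImage::Image(aperm(image, c(2L, 1L, 3L)), colormode = EBImage::Color)
  out <- EBImage::resize(eb, w = width, h = height, filter = "bilinear")
  aperm(EBImage::imageData(out), c(2L, 1L, 3L))
}

#' Read a field image
#'
#' Reads a PNG or JPEG nadir field photograph into the array representation
#' used throughout the package: height x width x 3, values 0..255. Grayscale
#' input is replicated across channels; an alpha channel is dropped.
#'
#' @param path Path to a PNG or JPEG file.
#' @return A numeric array (height x width x 3) with attribute `source`.
#' @export
read_field_image <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such image file: %s", path))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    px <- png::readPNG(path)
  } else {
    px <- EBImage::imageData(EBImage::readImage(path))
    px <- if (length(dim(px)) == 2L) t(px) else aperm(px, c(2L, 1L, 3L))
  }
  if (length(dim(px)) == 2L) px <- array(px, c(dim(px), 1L))
  if (dim(px)[3] == 1L) px <- px[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE]
  out <- round(px * 255)
  attr(out, "source") <- path
  out
}

#' Write a field image as PNG
#'
#' @param image Height x width x 3 array, values 0..255.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_field_image <- function(image, path) {
  assert_rgb(image)
  png::writePNG(clip255(image) / 255, path)
  invisible(path)
}

# Stage code helpers: stages are encoded 0 (VE), 1 (VC), 2 (V1) throughout.
stage_levels <- function() c("VE", "VC", "V1")

stage_name <- function(code) stage_levels()[code + 1L]

# Deterministic sub-seed derivation so that independent parts of a scene
# (layout, stages, plant rendering, distractors, illumination, noise) draw
# from independent streams: adding distractors must not perturb the plants.
sub_seed <- function(seed, offset) {
  (as.integer(seed) * 31L + offset * 7919L) %% 2147483562L + 1L
}
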