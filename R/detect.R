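# Seedling emergence detection: vegetation-index grayscale conversion,
# Otsu adaptive thresholding, strict binarisation, colour re-masking,
# connected-component analysis (8-connectivity by default), area filtering,
# minimum bounding rectangles, and an annotated overlay.

#' Convert an RGB field image to grayscale
#'
#' The default rule is the excess-green index 2G - R - B (clipped to
#' 0..255), which separates green vegetation from brown soil and from bright
#' but green-poor distractors such as dry stalks. `"luminance"`
#' (0.299R + 0.587G + 0.114B) and `"green"` (the raw G channel) are also
#' available.
#'
#' @param image Height x width x 3 array, 0..255.
#' @param rule One of `"exg"`, `"luminance"`, `"green"`.
#' @return A height x width numeric matrix, 0..255.
#' @export
to_gray <- function(image, rule = c("exg", "luminance", "green")) {
  assert_rgb(image)
  rule <- match.arg(rule)
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  switch(rule,
         exg = clip255(2 * g - r - b),
         luminance = 0.299 * r + 0.587 * g + 0.114 * b,
         green = g * 1)
}

#' Otsu threshold of an 8-bit grayscale raster
#'
#' Exhaustively scans all 256 candidate thresholds k and picks the one
#' maximising the between-class variance
#' \deqn{\sigma^2(k) = w_0(\mu - \mu_0)^2 + w_1(\mu - \mu_1)^2,}
#' where class 0 ("target") is the pixels with grey value strictly above k
#' and class 1 ("background") the rest; \eqn{w_0, w_1} are the class
#' probabilities and \eqn{\mu, \mu_0, \mu_1} the overall and class means.
#' Ties are broken towards the smallest k. A constant image has
#' \eqn{\sigma^2 = 0} everywhere and is flagged degenerate, with k set to the
#' constant grey value.
#'
#' @param gray Numeric matrix; values are rounded and clipped to 0..255 for
#'   the histogram.
#' @return An `otsu_result`: list with `k`, `sigma2`, `w0`, `w1`, `mu`,
#'   `mu0`, `mu1`, `histogram` (256 counts) and `degenerate`.
#' @export
otsu_threshold <- function(gray) {
  if (length(gray) == 0) abort("`gray` must be a nonempty raster")
  v <- pmin(pmax(round(as.vector(gray)), 0), 255)
  h <- tabulate(v + 1L, nbins = 256L)
  n <- sum(h)
  lev <- 0:255
  p <- h / n
  cw1 <- cumsum(p)                 # P(value <= k), the background class
  cm1 <- cumsum(p * lev)
  mu <- cm1[256]
  w1 <- cw1
  w0 <- 1 - cw1                    # target: value > k
  mu1 <- ifelse(w1 > 0, cm1 / w1, 0)
  mu0 <- ifelse(w0 > 0, (mu - cm1) / w0, 0)
  sigma2 <- w0 * (mu - mu0)^2 + w1 * (mu - mu1)^2
  if (max(sigma2) <= 0) {
    k <- lev[which.max(h)]         # the constant value
    i <- k + 1L
    return(structure(list(k = k, sigma2 = 0, w0 = w0[i], w1 = w1[i], mu = mu,
                          mu0 = mu0[i], mu1 = mu1[i], histogram = h,
                          degenerate = TRUE),
                     class = "otsu_result"))
  }
  i <- which.max(sigma2)           # first maximum = smallest k
  structure(list(k = lev[i], sigma2 = sigma2[i], w0 = w0[i], w1 = w1[i],
                 mu = mu, mu0 = mu0[i], mu1 = mu1[i], histogram = h,
                 degenerate = FALSE),
            class = "otsu_result")
}

#' @export
print.otsu_result <- function(x, ...) {
  cat(sprintf(
    "Otsu threshold: k = %d (sigma^2 = %.3f, w0 = %.3f, w1 = %.3f%s)\n",
    x$k, x$sigma2, x$w0, x$w1, if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Binarise a grayscale raster at an Otsu threshold
#'
#' A pixel is foreground iff its (rounded) grey value is strictly greater
#' than k.
#'
#' @param gray Numeric matrix.
#' @param otsu An `otsu_result` or a plain threshold value.
#' @return A logical matrix of the same shape.
#' @export
binarize <- function(gray, otsu) {
  k <- if (inherits(otsu, "otsu_result")) otsu$k else otsu
  m <- pmin(pmax(round(gray), 0), 255) > k
  dim(m) <- dim(gray)
  m
}

#' Re-mask an RGB image with a binary vegetation mask
#'
#' Keeps the original colour where the mask is true and black elsewhere.
#' Component analysis downstream treats any non-black pixel of this masked
#' colour image as foreground.
#'
#' @param image Height x width x 3 array.
#' @param mask Logical matrix of matching height/width.
#' @return The masked colour image.
#' @export
mask_to_color <- function(image, mask) {
  assert_rgb(image)
  if (!all(dim(mask) == dim(image)[1:2])) {
    abort("`mask` dimensions must match the image")
  }
  image * as.numeric(mask)
}

#' Label connected components of a binary mask
#'
#' Maximal connected sets of true pixels under the chosen adjacency:
#' 8-connectivity (the default) joins horizontal, vertical and diagonal
#' neighbours; 4-connectivity only horizontal and vertical. Components are
#' numbered in raster-scan order (top-to-bottom, left-to-right) of their
#' first pixel.
#'
#' @param mask Logical matrix.
#' @param connectivity 8 or 4.
#' @return A tibble with one row per component: `label`, `area`, the minimum
#'   bounding rectangle (`x_min`, `y_min`, `width`, `height`; 0-based, closed
#'   on both ends) and `pixels` (list column of (x, y) coordinate matrices).
#' @export
label_components <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) abort("`connectivity` must be 4 or 8")
  storage.mode(mask) <- "logical"
  lab <- cpp_label_components(mask, as.integer(connectivity))
  idx <- which(lab > 0L)
  if (length(idx) == 0L) {
    return(tibble(label = integer(), area = integer(),
                  x_min = integer(), y_min = integer(),
                  width = integer(), height = integer(), pixels = list()))
  }
  H <- nrow(mask)
  lv <- lab[idx]
  x <- (idx - 1L) %/% H
  y <- (idx - 1L) %% H
  ord <- order(lv)
  lv <- lv[ord]; x <- x[ord]; y <- y[ord]
  split_at <- c(which(diff(lv) != 0L), length(lv))
  start <- c(1L, head(split_at, -1L) + 1L)
  tibble(
    label = lv[split_at],
    area = split_at - start + 1L,
    x_min = as.integer(vapply(seq_along(start), function(i)
      min(x[start[i]:split_at[i]]), numeric(1))),
    y_min = as.integer(vapply(seq_along(start), function(i)
      min(y[start[i]:split_at[i]]), numeric(1))),
    width = as.integer(vapply(seq_along(start), function(i)
      max(x[start[i]:split_at[i]]) - min(x[start[i]:split_at[i]]) + 1,
      numeric(1))),
    height = as.integer(vapply(seq_along(start), function(i)
      max(y[start[i]:split_at[i]]) - min(y[start[i]:split_at[i]]) + 1,
      numeric(1))),
    pixels = lapply(seq_along(start), function(i)
      cbind(x = x[start[i]:split_at[i]], y = y[start[i]:split_at[i]]))
  )
}

#' Filter components by area
#'
#' Small components are noise speckle and weed fragments; an optional upper
#' bound removes merged canopy. Order is preserved.
#'
#' @param components Component tibble from [label_components()].
#' @param min_area Minimum pixel area (>= 1).
#' @param max_area Maximum pixel area, or `Inf`.
#' @return The surviving components.
#' @export
filter_components <- function(components, min_area = 25, max_area = Inf) {
  if (min_area < 1) abort("`min_area` must be >= 1")
  if (min_area > max_area) abort("`min_area` must not exceed `max_area`")
  dplyr::filter(components, .data$area >= min_area, .data$area <= max_area)
}

#' Minimum bounding rectangle of a pixel set
#'
#' @param pixels A two-column (x, y) coordinate matrix, or a one-row
#'   component tibble.
#' @return Named vector `x_min`, `y_min`, `width`, `height` (0-based, closed;
#'   width = x_max - x_min + 1).
#' @export
min_bounding_rect <- function(pixels) {
  if (is.data.frame(pixels)) pixels <- pixels$pixels[[1]]
  if (is.null(dim(pixels)) || nrow(pixels) == 0) {
    abort("empty component has no bounding rectangle")
  }
  c(x_min = min(pixels[, 1]), y_min = min(pixels[, 2]),
    width = max(pixels[, 1]) - min(pixels[, 1]) + 1,
    height = max(pixels[, 2]) - min(pixels[, 2]) + 1)
}

#' Detection parameters
#'
#' @param gray_rule Grayscale rule for [to_gray()].
#' @param min_area,max_area Component area bounds in pixels. The default
#'   minimum of 25 px corresponds to a 1 cm^2 footprint at 2 mm/px.
#' @param connectivity Component adjacency (8 per the method; 4 available).
#' @param max_veg_fraction Segmentation sanity cap: adaptive thresholding
#'   needs a real vegetation class to anchor on, and on a frame with (next
#'   to) no vegetation it ends up splitting the soil noise, flooding the
#'   mask. A foreground fraction above this cap (default 0.25 -- far above
#'   any seedling-stage canopy cover) is treated as a degenerate
#'   segmentation and reported as zero detections.
#' @return A list of class `detect_params`.
#' @export
detect_params <- function(gray_rule = "exg", min_area = 25, max_area = Inf,
                          connectivity = 8, max_veg_fraction = 0.25) {
  structure(list(gray_rule = gray_rule, min_area = min_area,
                 max_area = max_area, connectivity = connectivity,
                 max_veg_fraction = max_veg_fraction),
            class = "detect_params")
}

#' Detect and count emerged seedlings in a field image
#'
#' Runs the full detection chain: grayscale conversion, Otsu thresholding,
#' strict binarisation, colour re-masking, connected-component labelling of
#' the non-black pixels, area filtering, and minimum-bounding-rectangle
#' extraction. Each surviving component is counted as exactly one seedling.
#'
#' @param image Height x width x 3 array, 0..255.
#' @param params A [detect_params()].
#' @return A `seedling_detections` object: list with `detections` (tibble:
#'   `index`, `area`, `x_min`, `y_min`, `width`, `height`, `pixels`),
#'   `count`, `otsu`, `mask`, and `params`.
#' @export
detect_seedlings <- function(image, params = detect_params()) {
  assert_rgb(image)
  gray <- to_gray(image, params$gray_rule)
  ot <- otsu_threshold(gray)
  mask <- binarize(gray, ot)
  degenerate <- ot$degenerate ||
    mean(mask) > (params$max_veg_fraction %||% 0.25)
  if (degenerate) mask[] <- FALSE
  masked <- mask_to_color(image, mask)
  fg <- masked[, , 1] > 0 | masked[, , 2] > 0 | masked[, , 3] > 0
  comps <- label_components(fg, params$connectivity)
  comps <- filter_components(comps, params$min_area, params$max_area)
  det <- dplyr::mutate(comps, index = dplyr::row_number(),
                       .before = 1)
  det$label <- NULL
  structure(list(detections = det, count = nrow(det), otsu = ot,
                 degenerate = degenerate,
                 mask = mask, dim = dim(image)[1:2], params = params),
            class = "seedling_detections")
}

#' @export
print.seedling_detections <- function(x, ...) {
  cat(sprintf("%d seedling(s) detected (Otsu k = %d, min area = %g px)\n",
              x$count, x$otsu$k, x$params$min_area))
  invisible(x)
}

#' @rdname tidy.stagenet_fit
#' @export
tidy.seedling_detections <- function(x, ...) {
  dplyr::select(x$detections, -"pixels")
}

#' @rdname tidy.stagenet_fit
#' @export
glance.seedling_detections <- function(x, ...) {
  tibble(count = x$count, otsu_k = x$otsu$k,
         otsu_sigma2 = x$otsu$sigma2, degenerate = x$degenerate)
}

# 3x5 digit glyphs for annotation indices (no graphics device needed).
.digit_font <- list(
  "0" = c(1,1,1, 1,0,1, 1,0,1, 1,0,1, 1,1,1),
  "1" = c(0,1,0, 1,1,0, 0,1,0, 0,1,0, 1,1,1),
  "2" = c(1,1,1, 0,0,1, 1,1,1, 1,0,0, 1,1,1),
  "3" = c(1,1,1, 0,0,1, 0,1,1, 0,0,1, 1,1,1),
  "4" = c(1,0,1, 1,0,1, 1,1,1, 0,0,1, 0,0,1),
  "5" = c(1,1,1, 1,0,0, 1,1,1, 0,0,1, 1,1,1),
  "6" = c(1,1,1, 1,0,0, 1,1,1, 1,0,1, 1,1,1),
  "7" = c(1,1,1, 0,0,1, 0,1,0, 0,1,0, 0,1,0),
  "8" = c(1,1,1, 1,0,1, 1,1,1, 1,0,1, 1,1,1),
  "9" = c(1,1,1, 1,0,1, 1,1,1, 0,0,1, 1,1,1))

draw_rect_border <- function(image, x_min, y_min, width, height, rgb) {
  H <- dim(image)[1]; W <- dim(image)[2]
  x0 <- max(x_min, 0); x1 <- min(x_min + width - 1, W - 1)
  y0 <- max(y_min, 0); y1 <- min(y_min + height - 1, H - 1)
  xs <- x0:x1; ys <- y0:y1
  for (ch in 1:3) {
    image[cbind(y0 + 1, xs + 1, ch)] <- rgb[ch]
    image[cbind(y1 + 1, xs + 1, ch)] <- rgb[ch]
    image[cbind(ys + 1, x0 + 1, ch)] <- rgb[ch]
    image[cbind(ys + 1, x1 + 1, ch)] <- rgb[ch]
  }
  image
}

draw_number <- function(image, number, x, y, rgb) {
  H <- dim(image)[1]; W <- dim(image)[2]
  digits <- strsplit(as.character(number), "")[[1]]
  for (i in seq_along(digits)) {
    glyph <- matrix(.digit_font[[digits[i]]], 5, 3, byrow = TRUE)
    px <- which(glyph == 1, arr.ind = TRUE)
    xs <- x + (i - 1) * 4 + px[, 2] - 1
    ys <- y + px[, 1] - 1
    keep <- xs >= 0 & xs < W & ys >= 0 & ys < H
    for (ch in 1:3) {
      image[cbind(ys[keep] + 1, xs[keep] + 1, ch)] <- rgb[ch]
    }
  }
  image
}

#' Annotate detections on the source image
#'
#' Draws each detection's minimum bounding rectangle in red and its 1-based
#' index in blue next to the rectangle, leaving all other pixels untouched.
#' The positions of the rendered indices are recorded in the `annotations`
#' attribute so the overlay can be audited without OCR.
#'
#' @param image The source image array.
#' @param detections A `seedling_detections` object or its detections tibble.
#' @return The annotated image, with attribute `annotations` (tibble:
#'   `index`, `text_x`, `text_y`).
#' @export
annotate_detections <- function(image, detections) {
  assert_rgb(image)
  det <- if (inherits(detections, "seedling_detections"))
    detections$detections else detections
  out <- image
  ann <- vector("list", nrow(det))
  if (nrow(det)) {
    for (i in seq_len(nrow(det))) {
      out <- draw_rect_border(out, det$x_min[i], det$y_min[i],
                              det$width[i], det$height[i], c(255, 0, 0))
      tx <- det$x_min[i]
      ty <- max(det$y_min[i] - 7, 0)
      out <- draw_number(out, det$index[i], tx, ty, c(0, 0, 255))
      ann[[i]] <- tibble(index = det$index[i], text_x = tx, text_y = ty)
    }
  }
  attr(out, "annotations") <- dplyr::bind_rows(ann)
  out
}

#' Write detections to JSON and CSV
#'
#' @param detections A `seedling_detections` object.
#' @param json_path,csv_path Output paths (either may be `NULL`).
#' @param image_name Identifier recorded in the files.
#' @return The detections, invisibly.
#' @export
write_detections <- function(detections, json_path = NULL, csv_path = NULL,
                             image_name = "image") {
  det <- tidy(detections)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(image = image_name, count = detections$count,
           detections = det),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    write.csv(tibble(image = image_name, predicted_count = detections$count),
              csv_path, row.names = FALSE)
  }
  invisible(detections)
}
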