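# Automatic cutting of detections into labelled 255 x 255 x 3 crops, the
# five augmentation operators (brightness, horizontal flip, saturation,
# random crop, scale), class balancing by augmentation multiplicity, and the
# stratified 3:1 train/test split.

CROP_SIZE <- 255L

#' Construct a labelled seedling crop
#'
#' @param pixels 255 x 255 x 3 array, 0..255.
#' @param label Stage code: 0 (VE), 1 (VC) or 2 (V1).
#' @param provenance List recording `source`, `index` and `augmentation`.
#' @return A `seedling_crop` object.
#' @export
seedling_crop <- function(pixels, label, provenance = list()) {
  d <- dim(pixels)
  if (is.null(d) || length(d) != 3L ||
      !all(d == c(CROP_SIZE, CROP_SIZE, 3L))) {
    abort("crop pixels must be exactly 255 x 255 x 3")
  }
  if (!label %in% 0:2 && !isTRUE(provenance$free_label)) {
    abort("crop label must be 0 (VE), 1 (VC) or 2 (V1)")
  }
  structure(list(pixels = pixels, label = as.integer(label),
                 provenance = provenance),
            class = "seedling_crop")
}

#' @export
print.seedling_crop <- function(x, ...) {
  cat(sprintf("seedling crop, stage %s (%d), augmentation: %s\n",
              stage_name(x$label), x$label,
              x$provenance$augmentation %||% "none"))
  invisible(x)
}

#' Cut a detection into a classifier-ready crop
#'
#' Expands the detection's bounding rectangle by a margin, clamps the window
#' to the image, extracts it and resizes to 255 x 255 with bilinear
#' interpolation (an exact passthrough when the window is already
#' 255 x 255).
#'
#' @param image The source image array.
#' @param detection One row of a detections tibble (or a list with `x_min`,
#'   `y_min`, `width`, `height`).
#' @param margin Margin in pixels added on every side; the default `NULL`
#'   uses 10% of the larger rectangle side.
#' @param label Stage label to attach (from ground truth or a classifier);
#'   `NA` when not yet known.
#' @return A [seedling_crop()].
#' @export
cut_crop <- function(image, detection, margin = NULL, label = NA) {
  assert_rgb(image)
  H <- dim(image)[1]; W <- dim(image)[2]
  if (is.data.frame(detection)) detection <- as.list(detection[1, ])
  if (is.null(margin)) {
    margin <- round(0.1 * max(detection$width, detection$height))
  }
  x0 <- max(detection$x_min - margin, 0)
  y0 <- max(detection$y_min - margin, 0)
  x1 <- min(detection$x_min + detection$width - 1 + margin, W - 1)
  y1 <- min(detection$y_min + detection$height - 1 + margin, H - 1)
  if (x1 < x0 || y1 < y0) abort("detection window has empty intersection with the image")
  win <- image[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), , drop = FALSE]
  px <- resize_rgb(win, CROP_SIZE, CROP_SIZE)
  px <- array(clip255(px), c(CROP_SIZE, CROP_SIZE, 3L))
  seedling_crop(px, if (is.na(label)) 0L else label,
                provenance = list(source = attr(image, "source") %||% "image",
                                  index = detection$index %||% NA_integer_,
                                  augmentation = "none",
                                  free_label = is.na(label)))
}

#' Augment a seedling crop
#'
#' The five augmentation operators. All preserve the label and the
#' 255 x 255 x 3 shape, and are deterministic for a fixed seed:
#' * `brightness`: multiply by a gain (default drawn from 0.7..1.3);
#' * `hflip`: horizontal mirror (an involution);
#' * `saturation`: blend towards the per-pixel luminance by a gain in
#'   0.7..1.3 (gain > 1 increases colourfulness);
#' * `random_crop`: keep a random window of at least 80% area, resized back;
#' * `scale`: zoom by a factor in 0.8..1.2 (centre-crop when zooming in,
#'   edge-replicating pad when zooming out).
#'
#' @param crop A [seedling_crop()].
#' @param op One of `"brightness"`, `"hflip"`, `"saturation"`,
#'   `"random_crop"`, `"scale"`.
#' @param params Optional list of fixed parameters (`gain`, `min_frac`,
#'   `factor`); anything unset is drawn from the documented range.
#' @param seed Integer seed for the drawn parameters.
#' @return The augmented crop.
#' @export
augment_crop <- function(crop, op, params = list(), seed = 1L) {
  if (!inherits(crop, "seedling_crop")) abort("`crop` must be a seedling_crop")
  ops <- c("brightness", "hflip", "saturation", "random_crop", "scale")
  if (!op %in% ops) abort(sprintf("unknown augmentation op: %s", op))
  px <- crop$pixels
  px <- withr::with_seed(as.integer(seed), {
    switch(op,
      brightness = {
        gain <- params$gain %||% runif(1, 0.7, 1.3)
        if (gain < 0) abort("brightness gain must be non-negative")
        clip255(px * gain)
      },
      hflip = px[, CROP_SIZE:1, , drop = FALSE],
      saturation = {
        gain <- params$gain %||% runif(1, 0.7, 1.3)
        if (gain < 0) abort("saturation gain must be non-negative")
        lum <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
        out <- px
        for (ch in 1:3) out[, , ch] <- lum + gain * (px[, , ch] - lum)
        clip255(out)
      },
      random_crop = {
        min_frac <- params$min_frac %||% 0.8
        if (min_frac <= 0 || min_frac > 1) abort("`min_frac` must be in (0, 1]")
        side <- round(CROP_SIZE * sqrt(runif(1, min_frac, 1)))
        x0 <- sample.int(CROP_SIZE - side + 1L, 1L) - 1L
        y0 <- sample.int(CROP_SIZE - side + 1L, 1L) - 1L
        win <- px[(y0 + 1):(y0 + side), (x0 + 1):(x0 + side), , drop = FALSE]
        clip255(resize_rgb(win, CROP_SIZE, CROP_SIZE))
      },
      scale = {
        factor <- params$factor %||% runif(1, 0.8, 1.2)
        if (factor <= 0) abort("scale factor must be positive")
        side <- max(round(CROP_SIZE * factor), 8L)
        z <- resize_rgb(px, side, side)
        if (side >= CROP_SIZE) {
          o <- (side - CROP_SIZE) %/% 2
          z[(o + 1):(o + CROP_SIZE), (o + 1):(o + CROP_SIZE), , drop = FALSE]
        } else {
          o <- (CROP_SIZE - side) %/% 2
          ridx <- pmin(pmax(seq_len(CROP_SIZE) - o, 1L), side)
          z[ridx, ridx, , drop = FALSE]   # edge-replicating pad
        }
      })
  })
  out <- crop
  out$pixels <- array(clip255(px), c(CROP_SIZE, CROP_SIZE, 3L))
  out$provenance$augmentation <- op
  out
}

as_crop_table <- function(crops) {
  if (is.data.frame(crops)) {
    if (!"label" %in% names(crops)) abort("crop table needs a `label` column")
    return(crops)
  }
  if (is.list(crops) && length(crops) &&
      all(vapply(crops, inherits, logical(1), "seedling_crop"))) {
    return(tibble(crop = crops,
                  label = vapply(crops, function(cr) cr$label, integer(1))))
  }
  abort("`crops` must be a list of seedling_crop objects or a tibble with a `label` column")
}

#' Build a balanced, augmented, stratified dataset manifest
#'
#' Each original crop spawns `n_aug` augmented copies (so the default 2
#' turns 1000 originals per class into 3000), classes are balanced to equal
#' counts by giving under-represented classes extra augmented copies, and a
#' seeded stratified split assigns `train`/`test` at the requested ratio
#' within every class, rounding the test side down.
#'
#' Augmented entries are *planned*, not materialised: each manifest row
#' records its source crop, operator and seed, and [realise_crop()]
#' regenerates the pixels on demand. This keeps memory flat while the split
#' and counts stay exactly reproducible.
#'
#' @param crops A list of [seedling_crop()] objects, or a tibble with a
#'   `label` column (and optionally a `crop` list column; omit it to plan a
#'   manifest without pixel data).
#' @param n_aug Augmented copies per original.
#' @param split Train:test ratio as a length-2 vector (default `c(3, 1)`).
#' @param seed Integer seed for operator draws and the shuffle.
#' @return A `dataset_manifest` tibble: `id`, `label`, `split`, `augmented`,
#'   `op`, `aug_seed`, `source_id`, with per-class counts in the
#'   `class_counts` attribute.
#' @export
build_dataset <- function(crops, n_aug = 2L, split = c(3L, 1L), seed = 1L) {
  tab <- as_crop_table(crops)
  labels <- tab$label
  if (length(labels) == 0L) abort("at least one crop per class is required")
  classes <- sort(unique(labels))
  per_class <- table(factor(labels, levels = classes))
  if (any(per_class == 0)) abort("at least one crop per class is required")
  if (length(split) != 2L || any(split <= 0)) {
    abort("`split` must be two positive numbers (train:test)")
  }
  ops <- c("brightness", "hflip", "saturation", "random_crop", "scale")
  target <- (1L + as.integer(n_aug)) * max(per_class)

  withr::with_seed(as.integer(seed), {
    rows <- list()
    for (cl in classes) {
      src <- which(labels == cl)
      rows[[length(rows) + 1L]] <- tibble(
        label = cl, augmented = FALSE, op = NA_character_,
        aug_seed = NA_integer_, source_id = src)
      n_extra <- target - length(src)
      if (n_extra > 0) {
        reps <- rep_len(src, n_extra)   # cycle originals
        rows[[length(rows) + 1L]] <- tibble(
          label = cl, augmented = TRUE,
          op = sample(ops, n_extra, replace = TRUE),
          aug_seed = sample.int(2147483647L, n_extra),
          source_id = reps)
      }
    }
    manifest <- dplyr::bind_rows(rows)
    manifest$id <- seq_len(nrow(manifest))
    manifest$split <- NA_character_
    for (cl in classes) {
      idx <- which(manifest$label == cl)
      idx <- idx[sample.int(length(idx))]
      n_test <- floor(length(idx) * split[2] / sum(split))
      test_idx <- idx[seq_len(n_test)]
      manifest$split[test_idx] <- "test"
      manifest$split[setdiff(idx, test_idx)] <- "train"
    }
    manifest <- dplyr::select(manifest, "id", "label", "split", "augmented",
                              "op", "aug_seed", "source_id")
    attr(manifest, "class_counts") <-
      table(manifest$label, manifest$split)
    class(manifest) <- c("dataset_manifest", class(manifest))
    manifest
  })
}

#' Materialise one manifest entry
#'
#' @param manifest A `dataset_manifest`.
#' @param i Row number.
#' @param crops The original crops the manifest was built from.
#' @return The [seedling_crop()] for that entry (augmented on the fly when
#'   the entry is an augmentation plan).
#' @export
realise_crop <- function(manifest, i, crops) {
  tab <- as_crop_table(crops)
  if (!"crop" %in% names(tab)) abort("`crops` carries no pixel data")
  row <- manifest[i, ]
  base <- tab$crop[[row$source_id]]
  if (!row$augmented) return(base)
  augment_crop(base, row$op, seed = row$aug_seed)
}

#' Write dataset crops and manifest to disk
#'
#' Crops are written as PNG under per-class directories (`class_0`,
#' `class_1`, ...), the manifest as CSV (`path`, `label`, `split`,
#' `augmented`).
#'
#' @param manifest A `dataset_manifest`.
#' @param crops The original crops.
#' @param out_dir Output directory.
#' @return The manifest with a `path` column, invisibly.
#' @export
write_crop_dataset <- function(manifest, crops, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    cl_dir <- file.path(out_dir, sprintf("class_%d", manifest$label[i]))
    dir.create(cl_dir, showWarnings = FALSE)
    paths[i] <- file.path(cl_dir, sprintf("crop_%05d.png", manifest$id[i]))
    write_field_image(realise_crop(manifest, i, crops)$pixels, paths[i])
  }
  out <- dplyr::mutate(manifest, path = paths)
  write.csv(dplyr::select(out, "path", "label", "split", "augmented"),
            file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(out)
}
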