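# Synthetic field scenes with exact ground truth.
#
# The generator emulates the acquisition conditions of low-altitude nadir RGB
# imagery over ridge-planted soybean: parallel rows 22.5 cm apart, plants
# ~7.1 cm apart along the row, green seedlings on brown soil, stage-dependent
# morphology (VE: one compact blob; VC: two opposed cotyledon lobes; V1:
# cotyledons plus a node/leaf cluster), illumination gain and gradient,
# optional plant overlap, and bright low-green stalk distractors. Every
# rendered plant and distractor is recorded in a ground-truth table, so the
# detection, cutting, classification and reporting stages can all be checked
# against known answers.

#' Scene configuration for the synthetic field generator
#'
#' Physical quantities are in millimetres and converted to pixels through
#' `ground_sampling` (mm per pixel; the default 2 mm/px mimics a 3-5 m
#' flight, making a 71 mm plant spacing about 35 px).
#'
#' @param image_size Width and height in pixels.
#' @param ground_sampling Ground sampling distance, mm per pixel.
#' @param row_spacing Distance between planted rows, mm.
#' @param plant_spacing_mean,plant_spacing_jitter Along-row plant spacing
#'   mean and jitter (standard deviation), mm. Spacing draws are truncated
#'   below at 80% of the mean so that non-overlapping scenes stay
#'   non-overlapping.
#' @param n_rows Number of planted rows.
#' @param n_plants Total number of plants to place.
#' @param stage_mix Probability triple over the stages (VE, VC, V1); must sum
#'   to 1.
#' @param overlap_prob Probability that a plant is shifted onto its along-row
#'   neighbour so their footprints touch.
#' @param distractor_density Number of bright stalk-like distractors per
#'   image.
#' @param illumination List with `gain` (global multiplicative gain) and
#'   `gradient` (maximum relative linear shading across the frame).
#' @param noise_sd Per-channel Gaussian sensor noise, grey levels.
#' @param seed Integer seed; fixes every stochastic draw.
#' @return A `scene_config` list.
#' @export
scene_config <- function(image_size = c(640L, 520L),
                         ground_sampling = 2,
                         row_spacing = 225,
                         plant_spacing_mean = 71,
                         plant_spacing_jitter = 6,
                         n_rows = 4L,
                         n_plants = 24L,
                         stage_mix = c(1 / 3, 1 / 3, 1 / 3),
                         overlap_prob = 0,
                         distractor_density = 0,
                         illumination = list(gain = 1, gradient = 0.15),
                         noise_sd = 6,
                         seed = 1L) {
  if (abs(sum(stage_mix) - 1) > 1e-9) {
    abort("`stage_mix` must sum to 1")
  }
  if (any(stage_mix < 0)) abort("`stage_mix` components must be non-negative")
  if (any(image_size <= 0)) abort("`image_size` must be positive")
  vals <- c(ground_sampling, row_spacing, plant_spacing_mean,
            plant_spacing_jitter, overlap_prob, distractor_density, noise_sd)
  if (any(vals < 0)) abort("spacings, densities and noise must be non-negative")
  structure(
    list(image_size = as.integer(image_size),
         ground_sampling = ground_sampling,
         row_spacing = row_spacing,
         plant_spacing_mean = plant_spacing_mean,
         plant_spacing_jitter = plant_spacing_jitter,
         n_rows = as.integer(n_rows),
         n_plants = as.integer(n_plants),
         stage_mix = stage_mix,
         overlap_prob = overlap_prob,
         distractor_density = distractor_density,
         illumination = illumination,
         noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "scene_config")
}

# Reference colours (0..255). Plants are green-dominant, soil brown-dominant,
# distractors bright but with a small excess-green value (2G - R - B ~ 30),
# which is what lets threshold-based vegetation segmentation reject them.
.soil_rgb <- c(120, 92, 62)
.plant_rgb <- c(58, 150, 56)
.distractor_rgb <- c(205, 205, 172)

# A plant is a composite of elliptical lobes; each lobe is
# (dx, dy, a, b, theta) relative to the plant centre, in pixels.
plant_lobes <- function(stage, scale = 1) {
  if (stage == 0L) {            # VE: single compact blob
    lobes <- list(c(0, 0, runif(1, 4.0, 5.0), runif(1, 2.9, 3.8),
                    runif(1, 0, pi)))
  } else if (stage == 1L) {     # VC: two opposed cotyledon lobes on a stem
    th <- runif(1, 0, pi)
    d <- runif(1, 4.5, 5.5)
    a <- runif(1, 4.0, 4.8)
    b <- runif(1, 2.8, 3.6)
    lobes <- list(c(d * cos(th), d * sin(th), a, b, th),
                  c(-d * cos(th), -d * sin(th), a, b, th),
                  c(0, 0, d, 1.8, th))   # hypocotyl joining the lobes
  } else {                      # V1: larger cotyledons plus a node cluster
    th <- runif(1, 0, pi)
    d <- runif(1, 5.0, 6.0)
    a <- runif(1, 4.5, 5.2)
    b <- runif(1, 3.2, 4.0)
    lobes <- list(c(d * cos(th), d * sin(th), a, b, th),
                  c(-d * cos(th), -d * sin(th), a, b, th),
                  c(0, 0, d, 1.8, th))
    ph <- th + pi / 2
    for (j in c(-1, 0, 1)) {
      off <- runif(1, 1.5, 2.8)          # stays attached to the hypocotyl
      cxj <- off * cos(ph) + 2.2 * j * cos(th)
      cyj <- off * sin(ph) + 2.2 * j * sin(th)
      lobes <- c(lobes, list(c(cxj, cyj,
                               runif(1, 2.2, 3.0), runif(1, 2.2, 3.0), 0)))
    }
  }
  lapply(lobes, function(l) c(l[1:4] * scale, l[5]))
}

# Logical mask of a lobe composite on an integer offset grid.
lobes_mask <- function(lobes) {
  R <- ceiling(max(vapply(lobes, function(l) {
    sqrt(l[1]^2 + l[2]^2) + max(l[3], l[4])
  }, numeric(1)))) + 1L
  n <- 2L * R + 1L
  dx <- matrix(rep(-R:R, each = n), n, n)   # columns = x offsets
  dy <- matrix(rep(-R:R, n), n, n)
  inside <- matrix(FALSE, n, n)
  for (l in lobes) {
    u <- (dx - l[1]) * cos(l[5]) + (dy - l[2]) * sin(l[5])
    v <- -(dx - l[1]) * sin(l[5]) + (dy - l[2]) * cos(l[5])
    inside <- inside | ((u / l[3])^2 + (v / l[4])^2 <= 1)
  }
  list(mask = inside, R = R)
}

# Rotated-rectangle mask for a stalk distractor.
stalk_mask <- function(len, wid, theta) {
  R <- ceiling(len / 2 + wid) + 1L
  n <- 2L * R + 1L
  dx <- matrix(rep(-R:R, each = n), n, n)
  dy <- matrix(rep(-R:R, n), n, n)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  list(mask = abs(u) <= len / 2 & abs(v) <= wid / 2, R = R)
}

# Paint a footprint onto the canvas with a jittered base colour; returns the
# canvas and the (x, y) coordinates painted (0-based).
paint_mask <- function(canvas, cx, cy, mk, base_rgb, pixel_sd = 5) {
  H <- dim(canvas)[1]; W <- dim(canvas)[2]
  off <- which(mk$mask, arr.ind = TRUE)      # row = dy index, col = dx index
  xs <- round(cx) + (off[, 2] - mk$R - 1L)
  ys <- round(cy) + (off[, 1] - mk$R - 1L)
  keep <- xs >= 0 & xs < W & ys >= 0 & ys < H
  xs <- xs[keep]; ys <- ys[keep]
  npx <- length(xs)
  for (ch in 1:3) {
    canvas[cbind(ys + 1L, xs + 1L, ch)] <-
      base_rgb[ch] + rnorm(npx, 0, pixel_sd)
  }
  list(canvas = canvas, coords = cbind(x = xs, y = ys))
}

#' Generate a synthetic field scene with ground truth
#'
#' Renders a nadir view of row-planted seedlings on soil and returns both the
#' image and an exact record of what was drawn. The generator is fully
#' deterministic for a fixed config (the seed lives in the config), and the
#' separate parts of the scene (layout, stage assignment, plant rendering,
#' distractors, illumination, sensor noise) draw from independent seeded
#' streams, so switching distractors on or off leaves the plants untouched --
#' which is what makes paired distractor experiments possible.
#'
#' @param config A [scene_config()].
#' @return A `field_scene`: list with `image` (height x width x 3 integer
#'   array, 0..255), `truth` (list with `plants` and `distractors` tibbles)
#'   and `config`.
#' @export
generate_scene <- function(config) {
  if (!inherits(config, "scene_config")) abort("`config` must be a scene_config")
  W <- config$image_size[1]; H <- config$image_size[2]
  gsd <- config$ground_sampling
  seed <- config$seed

  # ---- layout ------------------------------------------------------------
  margin <- 18L
  row_pitch <- config$row_spacing / gsd
  sp_mean <- config$plant_spacing_mean / gsd
  sp_sd <- config$plant_spacing_jitter / gsd
  slots <- withr::with_seed(sub_seed(seed, 1L), {
    y0 <- (H - (config$n_rows - 1) * row_pitch) / 2
    if (y0 < margin) abort("rows do not fit the requested image height")
    out <- list()
    for (r in seq_len(config$n_rows)) {
      yr <- y0 + (r - 1) * row_pitch
      xs <- margin + runif(1, 0, sp_mean)
      while (TRUE) {
        nx <- xs[length(xs)] + max(0.8 * sp_mean, rnorm(1, sp_mean, sp_sd))
        if (nx > W - margin) break
        xs <- c(xs, nx)
      }
      out[[r]] <- tibble(row = r, slot = seq_along(xs), x = xs, y = yr)
    }
    slots <- dplyr::bind_rows(out)
    if (config$n_plants > nrow(slots)) {
      abort(sprintf(
        "requested %d plants but the layout only fits %d at this density",
        config$n_plants, nrow(slots)))
    }
    slots[sort(sample.int(nrow(slots), config$n_plants)), ]
  })

  stages <- withr::with_seed(sub_seed(seed, 2L),
    sample(0:2, config$n_plants, replace = TRUE, prob = config$stage_mix))

  # ---- plants ------------------------------------------------------------
  canvas <- array(rep(.soil_rgb, each = H * W), c(H, W, 3))
  plants <- withr::with_seed(sub_seed(seed, 3L), {
    acc <- vector("list", config$n_plants)
    prev_row <- -1L; prev_x <- NA_real_; prev_R <- 0
    for (i in seq_len(config$n_plants)) {
      cx <- slots$x[i]; cy <- slots$y[i]
      lob <- plant_lobes(stages[i])
      mk <- lobes_mask(lob)
      if (slots$row[i] == prev_row && !is.na(prev_x) &&
          runif(1) < config$overlap_prob) {
        # pull this plant onto its neighbour so the footprints touch
        cx <- prev_x + (prev_R + mk$R) * runif(1, 0.55, 0.85)
      }
      cy <- min(max(cy, margin), H - margin - 1)
      cx <- min(max(cx, margin), W - margin - 1)
      col <- .plant_rgb + rnorm(3, 0, 8)
      p <- paint_mask(canvas, cx, cy, mk, col)
      canvas <- p$canvas
      acc[[i]] <- tibble(x = cx, y = cy, stage = stages[i],
                         area = nrow(p$coords), footprint = list(p$coords))
      prev_row <- slots$row[i]; prev_x <- cx; prev_R <- mk$R
    }
    if (length(acc)) {
      dplyr::bind_rows(acc)
    } else {
      tibble(x = numeric(), y = numeric(), stage = integer(),
             area = integer(), footprint = list())
    }
  })

  # ---- distractors -------------------------------------------------------
  n_distract <- as.integer(round(config$distractor_density))
  distractors <- tibble(x = numeric(), y = numeric(),
                        footprint = list())
  if (n_distract > 0) {
    occupied <- matrix(FALSE, H, W)
    for (fp in plants$footprint) occupied[fp[, c("y", "x")] + 1L] <- TRUE
    res <- withr::with_seed(sub_seed(seed, 4L), {
      acc <- list()
      for (i in seq_len(n_distract)) {
        for (try in 1:60) {
          mk <- stalk_mask(runif(1, 30, 70), runif(1, 2, 3.5), runif(1, 0, pi))
          cx <- runif(1, mk$R + 2, W - mk$R - 3)
          cy <- runif(1, mk$R + 2, H - mk$R - 3)
          off <- which(mk$mask, arr.ind = TRUE)
          xs <- round(cx) + (off[, 2] - mk$R - 1L)
          ys <- round(cy) + (off[, 1] - mk$R - 1L)
          # keep a 2 px guard band away from any plant footprint
          clear <- TRUE
          for (dx in -2:2) for (dy in -2:2) {
            xx <- pmin(pmax(xs + dx, 0L), W - 1L)
            yy <- pmin(pmax(ys + dy, 0L), H - 1L)
            if (any(occupied[cbind(yy + 1L, xx + 1L)])) { clear <- FALSE; break }
          }
          if (!clear) next
          col <- .distractor_rgb + rnorm(3, 0, 8)
          p <- paint_mask(canvas, cx, cy, mk, col)
          canvas <- p$canvas
          acc[[length(acc) + 1L]] <-
            tibble(x = cx, y = cy, footprint = list(p$coords))
          break
        }
      }
      dplyr::bind_rows(acc)
    })
    if (nrow(res)) distractors <- res
  }

  # ---- illumination and sensor noise ------------------------------------
  canvas <- withr::with_seed(sub_seed(seed, 5L), {
    grad <- config$illumination$gradient %||% 0
    gxy <- runif(2, -grad, grad)
    gx <- gxy[1]; gy <- gxy[2]
    shade <- config$illumination$gain *
      (1 + outer((seq_len(H) - 1) / (H - 1) - 0.5,
                 (seq_len(W) - 1) / (W - 1) - 0.5,
                 function(yn, xn) gy * yn + gx * xn))
    canvas * as.vector(shade)   # recycles over channels
  })
  canvas <- withr::with_seed(sub_seed(seed, 6L),
    canvas + rnorm(length(canvas), 0, config$noise_sd))
  img <- array(as.integer(round(clip255(canvas))), c(H, W, 3))

  structure(list(image = img,
                 truth = list(plants = plants, distractors = distractors),
                 config = config),
            class = "field_scene")
}

#' Per-stage ground-truth counts of a synthetic scene
#'
#' @param truth A `field_scene` or its `truth` element.
#' @return A [stage_counts()] object: per-stage counts and their total.
#' @export
scene_to_count_truth <- function(truth) {
  if (inherits(truth, "field_scene")) truth <- truth$truth
  st <- truth$plants$stage
  n <- tabulate(st + 1L, nbins = 3L)
  stage_counts(n[1], n[2], n[3])
}

#' Render a set of synthetic labelled seedling crops
#'
#' Produces classifier-ready 255 x 255 x 3 crops, one centred plant per
#' crop, rendered with the same stage morphologies as [generate_scene()]
#' but zoomed the way [cut_crop()] output is: the detection rectangle is
#' resized to fill the crop, so each plant spans 55-80% of the frame
#' regardless of its size in the field. The stage signal is morphological:
#' a VE blob fills its window as one compact mass, VC shows the two-lobed
#' cotyledon dumbbell, V1 the dumbbell plus the node/leaf cluster.
#'
#' @param n_per_class Crops per stage.
#' @param seed Integer seed.
#' @param stages Stage codes to render (default 0:2).
#' @return A tibble with columns `crop` (list of [seedling_crop()] objects)
#'   and `label`.
#' @export
synthetic_crop_set <- function(n_per_class, seed = 1L, stages = 0:2) {
  withr::with_seed(as.integer(seed), {
    rows <- list()
    for (st in stages) {
      for (i in seq_len(n_per_class)) {
        canvas <- array(rep(.soil_rgb, each = 255L * 255L), c(255L, 255L, 3L))
        lob1 <- plant_lobes(st, scale = 1)
        ext <- max(vapply(lob1, function(l)
          sqrt(l[1]^2 + l[2]^2) + max(l[3], l[4]), numeric(1)))
        zoom <- runif(1, 0.55, 0.8) * 127 / ext
        lob <- lapply(lob1, function(l) c(l[1:4] * zoom, l[5]))
        mk <- lobes_mask(lob)
        cx <- 127 + runif(1, -12, 12)
        cy <- 127 + runif(1, -12, 12)
        col <- .plant_rgb + rnorm(3, 0, 8)
        canvas <- paint_mask(canvas, cx, cy, mk, col)$canvas
        canvas <- canvas * runif(1, 0.85, 1.15) +
          rnorm(length(canvas), 0, 6)
        px <- array(as.integer(round(clip255(canvas))), c(255L, 255L, 3L))
        rows[[length(rows) + 1L]] <- tibble(
          crop = list(seedling_crop(px, st,
                                    provenance = list(source = "synthetic",
                                                      index = i,
                                                      augmentation = "none"))),
          label = st)
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Write a batch of synthetic scenes to disk
#'
#' Each scene is written as a PNG with a JSON ground-truth sidecar
#' (`{plants: [{x, y, stage, area}], distractors: [...]}`), plus one manifest
#' CSV (`image_path`, `truth_path`, `seed`) covering the batch.
#'
#' @param n_images Number of scenes.
#' @param out_dir Output directory (created if needed).
#' @param config Base [scene_config()]; scene i uses seed `seed + i - 1`.
#' @return The manifest tibble, invisibly.
#' @export
write_scene_batch <- function(n_images, out_dir, config = scene_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    sc <- generate_scene(cfg)
    img_path <- file.path(out_dir, sprintf("scene_%03d.png", i))
    truth_path <- file.path(out_dir, sprintf("scene_%03d_truth.json", i))
    write_field_image(sc$image, img_path)
    truth <- list(
      plants = dplyr::select(sc$truth$plants, "x", "y", "stage", "area"),
      distractors = if (nrow(sc$truth$distractors))
        dplyr::select(sc$truth$distractors, "x", "y") else list())
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
    rows[[i]] <- tibble(image_path = img_path, truth_path = truth_path,
                        seed = cfg$seed)
  }
  manifest <- dplyr::bind_rows(rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
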