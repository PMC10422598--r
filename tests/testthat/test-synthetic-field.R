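# The scene generator must be exactly reproducible, honour its layout
# contract (requested plant count, disjoint footprints without overlap,
# degenerate stage mixes), and render plants/distractors whose colour
# statistics make the downstream segmentation contracts testable.

test_that("identical config and seed give bit-identical scenes", {
  cfg <- scene_config(seed = 42L, distractor_density = 3)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
})

test_that("a no-overlap scene places exactly the requested plants with disjoint footprints", {
  sc <- generate_scene(scene_config(n_plants = 25L, seed = 3L,
                                    overlap_prob = 0, distractor_density = 0))
  expect_equal(nrow(sc$truth$plants), 25L)
  H <- dim(sc$image)[1]
  ids <- unlist(lapply(sc$truth$plants$footprint,
                       function(m) m[, "x"] * H + m[, "y"]))
  expect_equal(anyDuplicated(ids), 0L)
  # all footprints inside the image
  for (m in sc$truth$plants$footprint) {
    expect_true(all(m[, "x"] >= 0 & m[, "x"] < dim(sc$image)[2]))
    expect_true(all(m[, "y"] >= 0 & m[, "y"] < H))
  }
})

test_that("degenerate stage mix labels every plant VE", {
  sc <- generate_scene(scene_config(stage_mix = c(1, 0, 0), seed = 9L))
  expect_true(all(sc$truth$plants$stage == 0L))
})

test_that("invalid configurations are rejected", {
  expect_error(scene_config(stage_mix = c(0.5, 0.2, 0.2)), "sum to 1")
  expect_error(scene_config(plant_spacing_mean = -1), "non-negative")
  expect_error(generate_scene(scene_config(n_plants = 10000L)), "only fits")
})

test_that("ground-truth counts mirror the plant table", {
  sc <- generate_scene(scene_config(n_plants = 25L, seed = 3L,
                                    stage_mix = c(1, 0, 0)))
  ct <- scene_to_count_truth(sc)
  expect_equal(unname(ct$TP), c(25, 0, 0))
  expect_equal(ct$ST, 25)

  empty <- scene_to_count_truth(list(plants = tibble::tibble(stage = integer())))
  expect_equal(unname(empty$TP), c(0, 0, 0))
  expect_equal(empty$ST, 0)

  mixed <- list(plants = tibble::tibble(stage = c(rep(0L, 10), rep(1L, 8),
                                                  rep(2L, 7))))
  expect_equal(unname(scene_to_count_truth(mixed)$TP), c(10, 8, 7))
  expect_equal(scene_to_count_truth(mixed)$ST, 25)
})

test_that("plant footprints are green-separable from the soil", {
  sc <- generate_scene(scene_config(seed = 5L))
  g <- to_gray(sc$image, "exg")
  H <- dim(sc$image)[1]
  plant_px <- do.call(rbind, sc$truth$plants$footprint)
  plant_idx <- cbind(plant_px[, "y"] + 1, plant_px[, "x"] + 1)
  soil <- g
  soil[plant_idx] <- NA
  for (m in sc$truth$plants$footprint) {
    fp_mean <- mean(g[cbind(m[, "y"] + 1, m[, "x"] + 1)])
    expect_gt(fp_mean, mean(soil, na.rm = TRUE) + 60)
  }
})

test_that("distractors are bright but below the vegetation threshold", {
  sc <- generate_scene(scene_config(seed = 8L, distractor_density = 4))
  expect_gt(nrow(sc$truth$distractors), 0)
  lum <- to_gray(sc$image, "luminance")
  g <- to_gray(sc$image, "exg")
  k <- detect_seedlings(sc$image)$otsu$k
  for (m in sc$truth$distractors$footprint) {
    idx <- cbind(m[, "y"] + 1, m[, "x"] + 1)
    expect_gt(mean(lum[idx]), stats::median(lum))     # brighter than the scene
    expect_lt(mean(g[idx]), k)                        # but green-poor
  }
})

test_that("synthetic crops have the contracted shape, labels and zoom", {
  crops <- synthetic_crop_set(3, seed = 2L)
  expect_equal(nrow(crops), 9L)
  expect_setequal(unique(crops$label), 0:2)
  for (i in seq_len(nrow(crops))) {
    cr <- crops$crop[[i]]
    expect_s3_class(cr, "seedling_crop")
    expect_equal(dim(cr$pixels), c(255L, 255L, 3L))
    expect_equal(cr$label, crops$label[i])
  }
  # deterministic under seed
  again <- synthetic_crop_set(3, seed = 2L)
  expect_identical(crops$crop[[5]]$pixels, again$crop[[5]]$pixels)
})

test_that("scene batches are written with truth sidecars and a manifest", {
  out <- withr::local_tempdir()
  man <- write_scene_batch(2, out, scene_config(n_plants = 6L, seed = 21L))
  expect_true(all(file.exists(man$image_path)))
  expect_true(all(file.exists(man$truth_path)))
  expect_true(file.exists(file.path(out, "manifest.csv")))
  truth <- jsonlite::read_json(man$truth_path[1], simplifyVector = TRUE)
  expect_equal(nrow(truth$plants), 6L)
  img <- read_field_image(man$image_path[1])
  sc <- generate_scene(scene_config(n_plants = 6L, seed = 21L))
  expect_equal(img, sc$image, ignore_attr = TRUE)
})
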