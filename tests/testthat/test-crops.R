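# Cutting, augmentation and dataset assembly: shape contracts, the exact
# passthrough at native size, deterministic seeded augmentation, label
# preservation, class balancing and the stratified 3:1 split.

test_that("cut crops always come out 255 x 255 x 3", {
  sc <- generate_scene(scene_config(n_plants = 15L, seed = 19L))
  det <- detect_seedlings(sc$image)
  cr <- cut_crop(sc$image, det$detections[1, ], margin = 0)
  expect_equal(dim(cr$pixels), c(255L, 255L, 3L))
  # whole image as one detection
  whole <- list(x_min = 0, y_min = 0,
                width = dim(sc$image)[2], height = dim(sc$image)[1])
  expect_equal(dim(cut_crop(sc$image, whole, margin = 0)$pixels),
               c(255L, 255L, 3L))
})

test_that("a native 255 x 255 window is an exact passthrough", {
  withr::local_seed(5)
  img <- array(sample(0:255, 300 * 300 * 3, TRUE), c(300, 300, 3))
  cr <- cut_crop(img, list(x_min = 10, y_min = 20, width = 255, height = 255),
                 margin = 0)
  expect_equal(cr$pixels, img[21:275, 11:265, ] * 1)
})

test_that("corner detections with margins clamp to the image", {
  withr::local_seed(6)
  img <- array(sample(0:255, 100 * 120 * 3, TRUE), c(100, 120, 3))
  cr <- cut_crop(img, list(x_min = 0, y_min = 0, width = 12, height = 9),
                 margin = 20)
  expect_equal(dim(cr$pixels), c(255L, 255L, 3L))
  # clamped window is the top-left block; interpolation stays in its range
  expect_true(all(cr$pixels >= min(img[1:30, 1:33, ]) - 1e-6))
  expect_true(all(cr$pixels <= max(img[1:30, 1:33, ]) + 1e-6))
})

test_that("augmentation preserves labels and shape and honours its seed", {
  crops <- synthetic_crop_set(1, seed = 14L)
  cr <- crops$crop[[2]]
  for (op in c("brightness", "hflip", "saturation", "random_crop", "scale")) {
    a <- augment_crop(cr, op, seed = 99L)
    expect_equal(dim(a$pixels), c(255L, 255L, 3L))
    expect_equal(a$label, cr$label)
    expect_identical(a$pixels, augment_crop(cr, op, seed = 99L)$pixels)
  }
  expect_error(augment_crop(cr, "rotate"), "unknown")
})

test_that("horizontal flip is an involution and unit gains are identities", {
  crops <- synthetic_crop_set(1, seed = 15L)
  cr <- crops$crop[[1]]
  expect_equal(augment_crop(augment_crop(cr, "hflip"), "hflip")$pixels,
               cr$pixels, ignore_attr = TRUE)
  expect_equal(augment_crop(cr, "brightness", params = list(gain = 1))$pixels,
               cr$pixels)
  expect_equal(augment_crop(cr, "saturation", params = list(gain = 1))$pixels,
               cr$pixels, tolerance = 1e-12)
})

test_that("the enhanced-dataset layout splits 3:1 within every class", {
  # 1000 originals per stage, two augmented copies each -> 3000 per stage
  plan <- build_dataset(tibble::tibble(label = rep(0:2, each = 1000)),
                        n_aug = 2L, seed = 1L)
  counts <- table(plan$label, plan$split)
  expect_true(all(counts[, "train"] == 2250))
  expect_true(all(counts[, "test"] == 750))
  # original-only layout: 1000 per stage -> 750 / 250
  plan0 <- build_dataset(tibble::tibble(label = rep(0:2, each = 1000)),
                         n_aug = 0L, seed = 1L)
  counts0 <- table(plan0$label, plan0$split)
  expect_true(all(counts0[, "train"] == 750))
  expect_true(all(counts0[, "test"] == 250))
})

test_that("the split is a partition and balancing equalises classes", {
  plan <- build_dataset(tibble::tibble(label = c(rep(0, 40), rep(1, 25),
                                                 rep(2, 10))),
                        n_aug = 1L, seed = 7L)
  expect_setequal(unique(plan$split), c("train", "test"))
  expect_equal(anyDuplicated(plan$id), 0L)
  per_class <- table(plan$label)
  expect_true(all(per_class == max(per_class)))   # balanced to 80 each
  expect_true(all(!plan$augmented[plan$source_id == plan$id]))
  expect_error(build_dataset(tibble::tibble(label = integer())), "at least one")
})

test_that("a fixed seed reproduces the manifest exactly", {
  labs <- tibble::tibble(label = rep(0:2, each = 30))
  a <- build_dataset(labs, n_aug = 2L, seed = 123L)
  b <- build_dataset(labs, n_aug = 2L, seed = 123L)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("manifest entries realise deterministically from their plan", {
  crops <- synthetic_crop_set(4, seed = 31L)
  man <- build_dataset(crops$crop, n_aug = 1L, seed = 2L)
  i_aug <- which(man$augmented)[1]
  r1 <- realise_crop(man, i_aug, crops$crop)
  r2 <- realise_crop(man, i_aug, crops$crop)
  expect_identical(r1$pixels, r2$pixels)
  expect_equal(r1$label, man$label[i_aug])
  i_orig <- which(!man$augmented)[1]
  expect_identical(realise_crop(man, i_orig, crops$crop)$pixels,
                   crops$crop[[man$source_id[i_orig]]]$pixels)
})

test_that("crop datasets round-trip through disk", {
  out <- withr::local_tempdir()
  crops <- synthetic_crop_set(2, seed = 41L)
  man <- build_dataset(crops$crop, n_aug = 0L, seed = 2L)
  written <- write_crop_dataset(man, crops$crop, out)
  expect_true(all(file.exists(written$path)))
  back <- read_field_image(written$path[1])
  expect_equal(back, realise_crop(man, 1, crops$crop)$pixels,
               ignore_attr = TRUE)
})
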