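# Detection chain: grayscale rules, the Otsu scan (checked against an
# exhaustive independent oracle), strict binarisation, colour re-masking,
# connected components under both adjacencies (checked against a BFS flood
# fill), area filtering, bounding rectangles, whole-image detection and the
# annotation overlay.

test_that("grayscale rules follow their defining arithmetic", {
  px <- function(r, g, b) array(c(r, g, b), c(1, 1, 3))
  expect_equal(as.numeric(to_gray(px(0, 255, 0), "exg")), 255)      # clipped from 510
  expect_equal(as.numeric(to_gray(px(100, 100, 100), "exg")), 0)
  expect_equal(as.numeric(to_gray(px(50, 100, 30), "exg")), 120)
  expect_equal(as.numeric(to_gray(px(100, 100, 100), "luminance")), 100)
  expect_equal(as.numeric(to_gray(px(10, 42, 99), "green")), 42)
  expect_error(to_gray(px(1, 2, 3), "hue"), "arg")
})

test_that("Otsu picks the smallest maximising threshold on a bimodal image", {
  g <- matrix(c(rep(10, 50), rep(200, 50)), 10)
  scan <- oracle_otsu_scan(g)
  argmax_region <- (0:255)[scan == max(scan)]
  expect_equal(range(argmax_region), c(10, 199))
  ot <- otsu_threshold(g)
  expect_equal(ot$k, 10)
  expect_false(ot$degenerate)
})

test_that("a constant image is degenerate with k at the constant value", {
  ot <- otsu_threshold(matrix(128, 8, 8))
  expect_true(ot$degenerate)
  expect_equal(ot$k, 128)
  expect_equal(ot$sigma2, 0)
})

test_that("Otsu matches the exhaustive oracle and its internal identities", {
  withr::local_seed(101)
  for (rep in 1:20) {
    g <- matrix(sample(0:255, 64 * 64, replace = TRUE,
                       prob = runif(256)^2), 64)
    ot <- otsu_threshold(g)
    expect_identical(ot$k, oracle_otsu_k(g))
    # class probabilities and means recombine to the image mean
    expect_equal(ot$w0 + ot$w1, 1, tolerance = 1e-9)
    expect_equal(ot$w0 * ot$mu0 + ot$w1 * ot$mu1, ot$mu, tolerance = 1e-6)
    # printed between-class form equals the product form
    expect_equal(ot$sigma2, ot$w0 * ot$w1 * (ot$mu0 - ot$mu1)^2,
                 tolerance = 1e-6 * max(1, ot$sigma2))
  }
})

test_that("binarisation is strictly greater-than the threshold", {
  expect_equal(binarize(matrix(c(10, 200), 1), 10), matrix(c(FALSE, TRUE), 1))
  expect_true(all(!binarize(matrix(0, 4, 4), 0)))
  withr::local_seed(7)
  g <- matrix(sample(0:255, 900, replace = TRUE), 30)
  ot <- otsu_threshold(g)
  m <- binarize(g, ot)
  expect_identical(m, g > ot$k)
  # fraction of foreground pixels equals the target-class probability
  expect_equal(mean(m), ot$w0, tolerance = 1e-12)
})

test_that("colour re-masking keeps originals under the mask and blackens the rest", {
  withr::local_seed(8)
  img <- array(sample(1:255, 10 * 12 * 3, replace = TRUE), c(10, 12, 3))
  expect_identical(mask_to_color(img, matrix(TRUE, 10, 12)), img * 1)
  expect_true(all(mask_to_color(img, matrix(FALSE, 10, 12)) == 0))
  m <- matrix(runif(120) > 0.5, 10, 12)
  masked <- mask_to_color(img, m)
  fg <- masked[, , 1] > 0 | masked[, , 2] > 0 | masked[, , 3] > 0
  expect_equal(sum(fg), sum(m))
  expect_error(mask_to_color(img, matrix(TRUE, 3, 3)), "match")
})

test_that("diagonal pixels join under 8-connectivity and split under 4", {
  m <- matrix(FALSE, 5, 5)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE
  expect_equal(nrow(label_components(m, 8)), 1L)
  expect_equal(nrow(label_components(m, 4)), 2L)
})

test_that("component partitions match a BFS oracle on random masks", {
  withr::local_seed(33)
  for (rep in 1:8) {
    m <- matrix(runif(30 * 40) < 0.35, 30, 40)
    for (conn in c(4, 8)) {
      got <- component_pixel_sets(label_components(m, conn), nrow(m))
      want <- oracle_components(m, conn)
      expect_equal(got, want)
    }
    # merging property: 8-connectivity never has more components than 4
    expect_lte(nrow(label_components(m, 8)), nrow(label_components(m, 4)))
  }
})

test_that("components are labelled in raster-scan order of their first pixel", {
  withr::local_seed(12)
  m <- matrix(runif(25 * 25) < 0.2, 25, 25)
  comps <- label_components(m, 8)
  first_pos <- vapply(comps$pixels, function(px) {
    min(px[, "y"] * ncol(m) + px[, "x"])    # raster order: y major, x minor
  }, numeric(1))
  expect_equal(first_pos, sort(first_pos))
  expect_equal(comps$label, seq_len(nrow(comps)))
})

test_that("area filtering keeps bounds, preserves order, and is monotone", {
  m <- matrix(FALSE, 40, 80)
  m[2:4, 2] <- TRUE                    # area 3
  m[10:14, 10:19] <- TRUE              # area 50
  m[21:50 %% 40, 31:60] <- TRUE        # big block
  comps <- label_components(m, 8)
  kept <- filter_components(comps, min_area = 10)
  expect_true(all(kept$area >= 10))
  expect_equal(kept$area, sort(kept$area, decreasing = FALSE)[order(order(kept$area))]) # order preserved
  expect_identical(filter_components(comps, 1, Inf), comps)
  counts <- vapply(c(1, 5, 20, 60, 1000), function(a)
    nrow(filter_components(comps, a)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(filter_components(comps, 10, 5), "exceed")
  expect_error(filter_components(comps, 0), ">= 1")
})

test_that("minimum bounding rectangles equal the coordinate extremes", {
  expect_equal(min_bounding_rect(cbind(x = 5, y = 7)),
               c(x_min = 5, y_min = 7, width = 1, height = 1))
  expect_equal(min_bounding_rect(cbind(x = c(0, 3), y = c(0, 1))),
               c(x_min = 0, y_min = 0, width = 4, height = 2))
  withr::local_seed(4)
  px <- cbind(x = sample(0:50, 20, TRUE), y = sample(0:50, 20, TRUE))
  r <- min_bounding_rect(px)
  expect_equal(unname(r), c(min(px[, 1]), min(px[, 2]),
                            diff(range(px[, 1])) + 1, diff(range(px[, 2])) + 1))
  expect_error(min_bounding_rect(cbind(x = numeric(), y = numeric())), "empty")
})

test_that("detection recovers the planted count on clean synthetic scenes", {
  for (s in c(2L, 13L)) {
    sc <- generate_scene(scene_config(seed = s))
    det <- detect_seedlings(sc$image)
    expect_equal(det$count, nrow(sc$truth$plants))
    expect_equal(det$detections$index, seq_len(det$count))
  }
})

test_that("an all-soil scene yields zero detections", {
  sc <- generate_scene(scene_config(n_plants = 0L, seed = 6L))
  expect_equal(detect_seedlings(sc$image)$count, 0L)
})

test_that("sub-threshold stalk distractors leave the count unchanged", {
  for (s in c(4L, 9L)) {
    plain <- detect_seedlings(generate_scene(scene_config(seed = s))$image)
    withd <- detect_seedlings(
      generate_scene(scene_config(seed = s, distractor_density = 5))$image)
    expect_equal(withd$count, plain$count)
  }
})

test_that("annotation draws one red rectangle per detection and records indices", {
  sc <- generate_scene(scene_config(n_plants = 12L, seed = 17L))
  det <- detect_seedlings(sc$image)
  out <- annotate_detections(sc$image, det)
  ann <- attr(out, "annotations")
  expect_equal(ann$index, seq_len(det$count))
  d1 <- det$detections[1, ]
  top <- out[d1$y_min + 1, (d1$x_min:(d1$x_min + d1$width - 1)) + 1, ]
  expect_true(all(top[, 1] == 255 & top[, 2] == 0 & top[, 3] == 0))
  # identity with no detections
  none <- detect_seedlings(generate_scene(scene_config(n_plants = 0L,
                                                       seed = 6L))$image)
  blank <- generate_scene(scene_config(n_plants = 0L, seed = 6L))$image
  out0 <- annotate_detections(blank, none)
  expect_equal(unname(out0), unname(blank), ignore_attr = TRUE)
})
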