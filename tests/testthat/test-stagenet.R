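# Classifier module: architecture description (5 conv / 3 pool / 3 FC),
# parameter accounting, exactness of the backpropagated gradients against
# central differences (double precision), the averaged metrics, evaluation
# identities, inference contracts, and a short training smoke run.

test_that("the model description always has 5 conv, 3 pool and 3 fc layers", {
  for (cfg in list(net_config(), desk_net_config(),
                   net_config(conv_channels = c(2L, 2L, 2L, 2L, 2L),
                              fc_sizes = c(16L, 8L), lrn = FALSE))) {
    m <- build_model(cfg)
    expect_equal(sum(m$layers$type == "conv"), 5L)
    expect_equal(sum(m$layers$type == "pool"), 3L)
    expect_equal(sum(m$layers$type == "fc"), 3L)
  }
})

test_that("overlapping pooling arithmetic matches (n - 3) / 2 + 1", {
  expect_equal(soyemerge:::pool_out_size(15L), 7L)
  expect_equal(soyemerge:::pool_out_size(255L), 127L)
  expect_equal(soyemerge:::pool_out_size(127L), 63L)
  # spatial underflow is rejected
  expect_error(build_model(net_config(input_shape = c(4L, 4L, 3L))),
               "underflow")
})

test_that("the parameter count equals the hand-summed layer arithmetic", {
  cfg <- net_config(input_shape = c(63L, 63L, 3L),
                    conv_channels = c(1L, 1L, 1L, 1L, 1L),
                    fc_sizes = c(4L, 3L), n_classes = 2L)
  m <- build_model(cfg)
  # conv params k^2 * Cin * Cout + Cout; feature map 63 -> 31 -> 15 -> 7
  hand <- (7 * 7 * 3 * 1 + 1) + (5 * 5 * 1 * 1 + 1) + 3 * (3 * 3 * 1 * 1 + 1) +
    (7 * 7 * 1 * 4 + 4) + (4 * 3 + 3) + (3 * 2 + 2)
  expect_equal(m$n_params, hand)
})

test_that("backpropagated gradients match central differences", {
  set.seed(42)
  cfg <- net_config(input_shape = c(16L, 16L, 3L),
                    conv_channels = c(2L, 3L, 3L, 3L, 2L),
                    fc_sizes = c(8L, 6L), n_classes = 3L, dropout = 0)
  ccfg <- soyemerge:::cpp_config(cfg)
  ptr <- soyemerge:::cpp_net_create(ccfg, "double")
  w <- soyemerge:::init_weights(cfg)
  soyemerge:::cpp_net_set_weights(ptr, "double", w)
  img <- as.numeric(array(runif(16 * 16 * 3), c(16, 16, 3)))
  dims <- cfg$input_shape
  soyemerge:::cpp_net_zero_grads(ptr, "double")
  soyemerge:::cpp_net_train_step(ptr, "double", img, dims, 1L, 1L)
  g <- soyemerge:::cpp_net_get_grads(ptr, "double")
  h <- 1e-6
  for (nm in names(w)) {
    for (rep in 1:3) {
      i <- sample(length(w[[nm]]), 1)
      wp <- w; wp[[nm]][i] <- wp[[nm]][i] + h
      soyemerge:::cpp_net_set_weights(ptr, "double", wp)
      lp <- soyemerge:::cpp_net_train_step(ptr, "double", img, dims, 1L, 1L)
      wm <- w; wm[[nm]][i] <- wm[[nm]][i] - h
      soyemerge:::cpp_net_set_weights(ptr, "double", wm)
      lm <- soyemerge:::cpp_net_train_step(ptr, "double", img, dims, 1L, 1L)
      numeric_grad <- (lp - lm) / (2 * h)
      expect_equal(g[[nm]][i], numeric_grad,
                   tolerance = 1e-4,
                   label = sprintf("analytic grad %s[%d]", nm, i))
    }
  }
})

test_that("averaged metrics follow the epoch-sum definitions", {
  h <- tibble::tibble(epoch = 1:2, loss = c(1.0, 0.5), accuracy = c(0.9, 1.0))
  m <- average_metrics(h)
  expect_equal(m$AL, 0.75)
  expect_equal(m$AA, 95)
  single <- average_metrics(tibble::tibble(epoch = 1, loss = 0.42,
                                           accuracy = 0.87))
  expect_equal(single$AL, 0.42)
  expect_equal(single$AA, 87)
  withr::local_seed(3)
  r <- tibble::tibble(epoch = 1:37, loss = rexp(37), accuracy = runif(37))
  m2 <- average_metrics(r)
  expect_equal(m2$AL, sum(r$loss) / 37, tolerance = 1e-12)
  expect_equal(m2$AA, sum(r$accuracy) / 37 * 100, tolerance = 1e-12)
  expect_error(average_metrics(r[0, ]), "empty")
})

test_that("a short smoke run trains, logs history, and is seed-reproducible", {
  crops <- synthetic_crop_set(10, seed = 51L)
  man <- build_dataset(crops$crop, n_aug = 0L, seed = 4L)
  m <- build_model(net_config(conv_channels = c(2L, 3L, 3L, 3L, 2L),
                              fc_sizes = c(32L, 16L)))
  cfg <- train_config(epochs = 2L, seed = 77L)
  fit <- train_stagenet(m, man, crops$crop, cfg)
  expect_equal(nrow(fit$history), 2L)
  expect_true(all(is.finite(fit$history$loss)))
  expect_true(all(fit$history$accuracy >= 0 & fit$history$accuracy <= 1))
  expect_equal(fit$e_L, sum(fit$history$loss), tolerance = 1e-9)
  # same seed, same first-epoch loss
  fit2 <- train_stagenet(m, man, crops$crop, cfg)
  expect_identical(fit$history$loss[1], fit2$history$loss[1])
  # tidy/glance accessors
  expect_identical(tidy(fit), fit$history)
  expect_equal(glance(fit)$AL, average_metrics(fit)$AL)

  # inference contracts
  labs <- classify_crops(fit, crops$crop[1:5])
  expect_length(labs, 5)
  expect_true(all(labs %in% 0:2))
  expect_identical(labs[1], classify_crops(fit, crops$crop[[1]]))
  probs <- classify_crops(fit, crops$crop[1:5], type = "prob")
  expect_equal(rowSums(probs), rep(1, 5), tolerance = 1e-5)

  # evaluation identities: A = N_C / N_T = trace / total of the confusion
  ev <- evaluate_model(fit, man, crops$crop)
  expect_equal(ev$A, ev$N_C / ev$N_T)
  expect_equal(ev$A, sum(diag(ev$confusion)) / sum(ev$confusion))
  expect_equal(unname(rowSums(ev$confusion)),
               as.vector(table(man$label[man$split == "test"])))
  expect_equal(glance(ev)$A, ev$A)
})

test_that("training errors are raised for unusable manifests", {
  crops <- synthetic_crop_set(2, seed = 52L)
  man <- build_dataset(crops$crop, n_aug = 0L, seed = 4L)
  man$split <- "train"
  m <- build_model(net_config(conv_channels = c(2L, 2L, 2L, 2L, 2L),
                              fc_sizes = c(8L, 4L)))
  expect_error(train_stagenet(m, man, crops$crop, train_config(epochs = 1L)),
               "train and test")
})

test_that("trivially separable two-class crops reach perfect test accuracy", {
  set.seed(2)
  crops <- c(lapply(1:10, function(i) make_solid_crop(c(200, 40, 40), 0L)),
             lapply(1:10, function(i) make_solid_crop(c(40, 40, 200), 1L)))
  man <- build_dataset(crops, n_aug = 0L, seed = 1L)
  cfg <- net_config(conv_channels = c(4L, 6L, 8L, 8L, 6L), n_classes = 2L)
  fit <- train_stagenet(build_model(cfg), man, crops,
                        train_config(epochs = 20L, seed = 7L))
  expect_equal(fit$history$accuracy[20], 1.0)
})
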