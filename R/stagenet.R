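# Growth-stage classifier: a compact AlexNet-style network with five
# stride-1 convolutions whose kernels shrink 7 -> 5 -> 3 -> 3 -> 3, local
# response normalisation after the first two, overlapping max pooling
# (window 3, stride 2) halving the feature maps at layers 1, 2 and 5, and a
# reduced fully connected head 1024 -> 256 -> classes with dropout 0.6 on
# both hidden FC layers. Trained with Adam at learning rate 1e-4, batch
# size 32, categorical cross-entropy. The numerical engine lives in
# src/stagenet.cpp; this file owns configuration, initialisation, the
# training loop, metrics and the tidy/glance/autoplot interface.

#' Network configuration
#'
#' Defaults follow the reference architecture; `conv_channels` is the one
#' knob without a published value, so it is configurable, with
#' `c(32, 64, 96, 96, 64)` as the full-size default and
#' [desk_net_config()] providing a reduced-channel variant that trains in
#' minutes on a single CPU.
#'
#' @param input_shape Height, width, channels of the input crops.
#' @param conv_kernels Five odd kernel sizes.
#' @param conv_channels Five output-channel counts.
#' @param pool_layers Which conv layers are followed by overlapping max
#'   pooling (window `pool_win`, stride `pool_stride`).
#' @param pool_win,pool_stride Pooling window and stride; window > stride
#'   makes the pooling overlapping.
#' @param fc_sizes Two hidden fully connected sizes.
#' @param n_classes Number of output classes.
#' @param dropout Dropout rate on both hidden FC layers, in [0, 1).
#' @param lrn Use local response normalisation after conv layers 1 and 2.
#' @param lrn_n,lrn_alpha,lrn_beta,lrn_k LRN constants (classic values).
#' @return A `net_config` list.
#' @export
net_config <- function(input_shape = c(255L, 255L, 3L),
                       conv_kernels = c(7L, 5L, 3L, 3L, 3L),
                       conv_channels = c(32L, 64L, 96L, 96L, 64L),
                       pool_layers = c(1L, 2L, 5L),
                       pool_win = 3L, pool_stride = 2L,
                       fc_sizes = c(1024L, 256L),
                       n_classes = 3L,
                       dropout = 0.6,
                       lrn = TRUE,
                       lrn_n = 5L, lrn_alpha = 1e-4, lrn_beta = 0.75,
                       lrn_k = 2) {
  if (length(conv_kernels) != 5L || length(conv_channels) != 5L) {
    abort("exactly 5 conv kernel sizes and channel counts are required")
  }
  if (length(fc_sizes) != 2L) abort("`fc_sizes` must have 2 entries")
  if (dropout < 0 || dropout >= 1) abort("`dropout` must be in [0, 1)")
  structure(list(input_shape = as.integer(input_shape),
                 conv_kernels = as.integer(conv_kernels),
                 conv_channels = as.integer(conv_channels),
                 pool_layers = as.integer(pool_layers),
                 pool_win = as.integer(pool_win),
                 pool_stride = as.integer(pool_stride),
                 fc_sizes = as.integer(fc_sizes),
                 n_classes = as.integer(n_classes),
                 dropout = dropout, lrn = lrn,
                 lrn_n = as.integer(lrn_n), lrn_alpha = lrn_alpha,
                 lrn_beta = lrn_beta, lrn_k = lrn_k),
            class = "net_config")
}

#' Reduced-channel configuration for single-CPU training
#'
#' Same architecture, conv channels `c(8, 12, 16, 16, 12)`.
#'
#' @param ... Overrides passed on to [net_config()].
#' @export
desk_net_config <- function(...) {
  net_config(conv_channels = c(8L, 12L, 16L, 16L, 12L), ...)
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate (reference value 1e-4).
#' @param batch_size Minibatch size (reference value 32).
#' @param epochs Number of epochs; the reference schedule is 150, scaled
#'   down to 20 for desk-scale runs.
#' @param seed Integer seed driving initialisation, shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 32L,
                         epochs = 20L, seed = 1L) {
  if (learning_rate <= 0) abort("`learning_rate` must be positive")
  if (batch_size < 1 || epochs < 1) abort("`batch_size` and `epochs` must be positive")
  structure(list(optimizer = "adam", learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "train_config")
}

pool_out_size <- function(n, win = 3L, stride = 2L) (n - win) %/% stride + 1L

# Spatial sizes entering each conv layer and after its (optional) pooling.
net_spatial <- function(config) {
  h <- config$input_shape[1]; w <- config$input_shape[2]
  out <- vector("list", 5L)
  for (i in 1:5) {
    if (i %in% config$pool_layers) {
      if (h < config$pool_win || w < config$pool_win) {
        abort(sprintf("spatial size underflow at pooling layer %d", i))
      }
      h2 <- pool_out_size(h, config$pool_win, config$pool_stride)
      w2 <- pool_out_size(w, config$pool_win, config$pool_stride)
    } else {
      h2 <- h; w2 <- w
    }
    out[[i]] <- c(in_h = h, in_w = w, out_h = h2, out_w = w2)
    h <- h2; w <- w2
  }
  out
}

#' Build the model description
#'
#' Lays the configuration out as an explicit layer table (5 conv, 3 pool,
#' 3 FC) with output shapes and trainable parameter counts, verifying that
#' the spatial sizes survive the pooling schedule.
#'
#' @param config A [net_config()].
#' @return A `stagenet_model`: list with `config`, `layers` (tibble) and
#'   `n_params`.
#' @export
build_model <- function(config = net_config()) {
  if (!inherits(config, "net_config")) abort("`config` must be a net_config")
  sp <- net_spatial(config)
  rows <- list()
  cin <- config$input_shape[3]
  for (i in 1:5) {
    k <- config$conv_kernels[i]; cout <- config$conv_channels[i]
    rows[[length(rows) + 1L]] <- tibble(
      layer = sprintf("conv%d", i), type = "conv",
      kernel = k, units = cout,
      out_shape = sprintf("%dx%dx%d", sp[[i]]["in_h"], sp[[i]]["in_w"], cout),
      n_params = k * k * cin * cout + cout)
    if (config$lrn && i %in% c(1L, 2L)) {
      rows[[length(rows) + 1L]] <- tibble(
        layer = sprintf("lrn%d", i), type = "lrn", kernel = NA_integer_,
        units = cout,
        out_shape = sprintf("%dx%dx%d", sp[[i]]["in_h"], sp[[i]]["in_w"], cout),
        n_params = 0)
    }
    if (i %in% config$pool_layers) {
      rows[[length(rows) + 1L]] <- tibble(
        layer = sprintf("pool%d", i), type = "pool",
        kernel = config$pool_win, units = cout,
        out_shape = sprintf("%dx%dx%d", sp[[i]]["out_h"], sp[[i]]["out_w"], cout),
        n_params = 0)
    }
    cin <- cout
  }
  feat <- sp[[5]]["out_h"] * sp[[5]]["out_w"] * config$conv_channels[5]
  fdims <- c(feat, config$fc_sizes, config$n_classes)
  fnames <- c("fc1", "fc2", "out")
  for (i in 1:3) {
    rows[[length(rows) + 1L]] <- tibble(
      layer = fnames[i], type = "fc", kernel = NA_integer_,
      units = fdims[i + 1],
      out_shape = as.character(fdims[i + 1]),
      n_params = fdims[i] * fdims[i + 1] + fdims[i + 1])
  }
  layers <- dplyr::bind_rows(rows)
  structure(list(config = config, layers = layers,
                 n_params = sum(layers$n_params)),
            class = "stagenet_model")
}

#' @export
print.stagenet_model <- function(x, ...) {
  cat(sprintf("stage classifier: %d conv / %d pool / %d fc layers, %s trainable parameters\n",
              sum(x$layers$type == "conv"), sum(x$layers$type == "pool"),
              sum(x$layers$type == "fc"),
              format(x$n_params, big.mark = ",")))
  print(dplyr::select(x$layers, -"kernel"))
  invisible(x)
}

# Configuration list handed to the C++ engine.
cpp_config <- function(config) {
  list(input = config$input_shape[c(1, 2, 3)],
       kernels = config$conv_kernels,
       channels = config$conv_channels,
       pool_layers = config$pool_layers,
       pool_win = config$pool_win, pool_stride = config$pool_stride,
       lrn_layers = if (config$lrn) c(1L, 2L) else integer(0),
       lrn_n = config$lrn_n, lrn_alpha = config$lrn_alpha,
       lrn_beta = config$lrn_beta, lrn_k = config$lrn_k,
       fc_sizes = config$fc_sizes, n_classes = config$n_classes,
       dropout = config$dropout)
}

# He-normal initial weights, deterministic under the current RNG state.
init_weights <- function(config) {
  sp <- net_spatial(config)
  w <- list()
  cin <- config$input_shape[3]
  for (i in 1:5) {
    k <- config$conv_kernels[i]; cout <- config$conv_channels[i]
    fan_in <- k * k * cin
    w[[sprintf("conv%d_W", i)]] <-
      matrix(rnorm(fan_in * cout, 0, sqrt(2 / fan_in)), fan_in, cout)
    w[[sprintf("conv%d_b", i)]] <- numeric(cout)
    cin <- cout
  }
  feat <- sp[[5]]["out_h"] * sp[[5]]["out_w"] * config$conv_channels[5]
  fdims <- c(feat, config$fc_sizes, config$n_classes)
  fnames <- c("fc1", "fc2", "out")
  for (i in 1:3) {
    w[[sprintf("%s_W", fnames[i])]] <-
      matrix(rnorm(fdims[i] * fdims[i + 1], 0, sqrt(2 / fdims[i])),
             fdims[i + 1], fdims[i])
    w[[sprintf("%s_b", fnames[i])]] <- numeric(fdims[i + 1])
  }
  w
}

# Build (or rebuild) the C++ engine for a model/fit and cache the pointer.
engine_of <- function(fit, precision = "float") {
  env <- fit$engine
  if (is.null(env$ptr) || !identical(env$precision, precision)) {
    env$ptr <- cpp_net_create(cpp_config(fit$model$config), precision)
    env$precision <- precision
    cpp_net_set_weights(env$ptr, precision, fit$weights)
    env$weights_version <- fit$weights_version %||% 0L
  }
  env
}

# Raw pixel array of a crop; scaling to 0..1 happens inside the engine.
crop_pixels <- function(crop) {
  if (inherits(crop, "seedling_crop")) crop$pixels else crop
}

#' Train the stage classifier
#'
#' Minimises categorical cross-entropy with Adam, evaluating loss and
#' accuracy on the test split after every epoch. All stochastic draws
#' (weight initialisation, epoch shuffles, dropout masks) derive from the
#' training seed, so a fixed seed reproduces the run exactly.
#'
#' @param model A [build_model()] description.
#' @param manifest A `dataset_manifest` with both `train` and `test` rows.
#' @param crops The original crops backing the manifest.
#' @param config A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return A `stagenet_fit`: the model plus trained `weights`, the per-epoch
#'   `history` tibble (`epoch`, `train_loss`, `loss`, `accuracy` -- loss and
#'   accuracy are measured on the test split), and the epoch sums `e_L`,
#'   `e_A` behind the averaged metrics.
#' @export
train_stagenet <- function(model, manifest, crops, config = train_config(),
                           verbose = FALSE) {
  if (!inherits(model, "stagenet_model")) model <- build_model(model)
  tr_rows <- which(manifest$split == "train")
  te_rows <- which(manifest$split == "test")
  if (!length(tr_rows) || !length(te_rows)) {
    abort("manifest must contain both train and test entries")
  }
  ncfg <- model$config
  dims <- ncfg$input_shape
  tab <- as_crop_table(crops)

  set.seed(config$seed)
  weights <- init_weights(ncfg)
  ptr <- cpp_net_create(cpp_config(ncfg), "float")
  cpp_net_set_weights(ptr, "float", weights)

  # plain vectors for fast per-entry access inside the hot loop; augmented
  # entries are regenerated on demand from their recorded op and seed
  if (!"crop" %in% names(tab)) abort("`crops` carries no pixel data")
  crop_list <- tab$crop
  m_aug <- manifest$augmented; m_op <- manifest$op
  m_seed <- manifest$aug_seed; m_src <- manifest$source_id
  fetch_px <- function(i) {
    if (!m_aug[i]) return(crop_pixels(crop_list[[m_src[i]]]))
    crop_pixels(augment_crop(crop_list[[m_src[i]]], m_op[i],
                             seed = m_seed[i]))
  }
  test_px <- lapply(te_rows, fetch_px)
  test_lab <- manifest$label[te_rows]
  class_codes <- sort(unique(manifest$label))
  code_of <- match(manifest$label, class_codes) - 1L   # 0-based class index

  history <- vector("list", config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- tr_rows[sample.int(length(tr_rows))]
    losses <- numeric(0)
    for (b0 in seq(1, length(ord), by = config$batch_size)) {
      batch <- ord[b0:min(b0 + config$batch_size - 1, length(ord))]
      cpp_net_zero_grads(ptr, "float")
      bl <- numeric(length(batch))
      drop_seeds <- sample.int(2147483647L, length(batch))
      for (j in seq_along(batch)) {
        i <- batch[j]
        bl[j] <- cpp_net_train_step(ptr, "float", fetch_px(i), dims,
                                    code_of[i], drop_seeds[j])
      }
      if (any(!is.finite(bl))) {
        abort(sprintf("non-finite loss at epoch %d; try a smaller learning rate", ep))
      }
      losses <- c(losses, bl)
      # fused Adam update inside the engine (beta1 0.9, beta2 0.999)
      cpp_net_adam_step(ptr, "float", config$learning_rate,
                        0.9, 0.999, 1e-8, length(batch))
    }
    # per-epoch evaluation on the test split
    te_loss <- numeric(length(test_px))
    te_correct <- logical(length(test_px))
    for (j in seq_along(test_px)) {
      probs <- cpp_net_predict(ptr, "float", test_px[[j]], dims)
      te_loss[j] <- -log(max(probs[match(test_lab[j], class_codes)], 1e-12))
      te_correct[j] <- class_codes[which.max(probs)] == test_lab[j]
    }
    history[[ep]] <- tibble(epoch = ep, train_loss = mean(losses),
                            loss = mean(te_loss),
                            accuracy = mean(te_correct))
    if (verbose) {
      cat(sprintf("epoch %3d  train loss %.4f  test loss %.4f  test acc %.4f\n",
                  ep, mean(losses), mean(te_loss), mean(te_correct)))
    }
  }
  history <- dplyr::bind_rows(history)
  weights <- cpp_net_get_weights(ptr, "float")
  structure(list(model = model, weights = weights, train_config = config,
                 classes = class_codes,
                 history = history, e = nrow(history),
                 e_L = sum(history$loss), e_A = sum(history$accuracy),
                 engine = new.env(parent = emptyenv())),
            class = "stagenet_fit")
}

#' @export
print.stagenet_fit <- function(x, ...) {
  m <- average_metrics(x)
  cat(sprintf("stage classifier fit: %d epochs, AL = %.4f, AA = %.2f%%, final test accuracy %.4f\n",
              x$e, m$AL, m$AA, x$history$accuracy[x$e]))
  invisible(x)
}

#' Averaged training metrics
#'
#' The average loss AL = e_L / e and average accuracy AA = (e_A / e) x 100%,
#' where e_L and e_A are the sums of the per-epoch (test-split) loss and
#' accuracy and e is the number of epochs.
#'
#' @param history A `stagenet_fit` or its history tibble.
#' @return List with `AL` and `AA` (AA in percent).
#' @export
average_metrics <- function(history) {
  if (inherits(history, "stagenet_fit")) history <- history$history
  if (!nrow(history)) abort("empty training history")
  list(AL = sum(history$loss) / nrow(history),
       AA = sum(history$accuracy) / nrow(history) * 100)
}

#' Classify seedling crops
#'
#' Runs the trained network in inference mode (dropout disabled) and returns
#' the argmax class per crop; ties break towards the lowest class index.
#'
#' @param fit A `stagenet_fit`.
#' @param crops A list of crops/arrays, a tibble with a `crop` column, or a
#'   single crop.
#' @param type `"class"` for labels, `"prob"` for the softmax matrix.
#' @return Integer labels, or a crops x classes probability matrix.
#' @export
classify_crops <- function(fit, crops, type = c("class", "prob")) {
  type <- match.arg(type)
  if (inherits(crops, "seedling_crop") ||
      (is.array(crops) && length(dim(crops)) == 3L)) {
    crops <- list(crops)
  }
  if (is.data.frame(crops)) crops <- crops$crop
  dims <- fit$model$config$input_shape
  eng <- engine_of(fit)
  probs <- matrix(NA_real_, length(crops), fit$model$config$n_classes)
  for (j in seq_along(crops)) {
    px <- crop_pixels(crops[[j]])
    if (length(px) != prod(dims)) abort("crop has the wrong shape for this model")
    probs[j, ] <- cpp_net_predict(eng$ptr, eng$precision, px, dims)
  }
  if (type == "prob") return(probs)
  fit$classes[apply(probs, 1, which.max)]
}

#' Evaluate a trained classifier on a split
#'
#' @param fit A `stagenet_fit`.
#' @param manifest The dataset manifest.
#' @param crops The original crops.
#' @param split Which split to evaluate (default `"test"`).
#' @return A `stagenet_eval`: accuracy A = N_C / N_T, the correct/total
#'   counts, per-class accuracies and the confusion matrix (rows = truth).
#' @export
evaluate_model <- function(fit, manifest, crops, split = "test") {
  rows <- which(manifest$split == split)
  if (!length(rows)) abort(sprintf("no entries in split '%s'", split))
  tab <- as_crop_table(crops)
  truth <- manifest$label[rows]
  pred <- vapply(rows, function(i)
    classify_crops(fit, list(realise_crop(manifest, i, tab))), numeric(1))
  classes <- fit$classes
  conf <- table(factor(truth, levels = classes),
                factor(pred, levels = classes))
  n_c <- sum(diag(conf)); n_t <- length(rows)
  per_class <- diag(conf) / pmax(rowSums(conf), 1)
  structure(list(A = n_c / n_t, N_C = n_c, N_T = n_t,
                 per_class = tibble(stage = stage_name(as.numeric(classes)),
                                    label = as.numeric(classes),
                                    accuracy = as.numeric(per_class)),
                 confusion = unclass(conf)),
            class = "stagenet_eval")
}

#' @export
print.stagenet_eval <- function(x, ...) {
  cat(sprintf("accuracy A = %.4f (%d / %d correct)\n", x$A, x$N_C, x$N_T))
  print(x$confusion)
  invisible(x)
}

#' Tidy and glance methods
#'
#' Broom-style accessors: `tidy()` returns the per-epoch history of a fit,
#' the long confusion table of an evaluation, the detection table of a
#' `seedling_detections`, or the per-stage rows of an `emergence_report`;
#' `glance()` returns their one-row summaries.
#'
#' @param x The object.
#' @param ... Unused.
#' @name tidy.stagenet_fit
#' @export
tidy.stagenet_fit <- function(x, ...) x$history

#' @rdname tidy.stagenet_fit
#' @export
glance.stagenet_fit <- function(x, ...) {
  m <- average_metrics(x)
  tibble(epochs = x$e, AL = m$AL, AA = m$AA,
         final_accuracy = x$history$accuracy[x$e],
         n_params = x$model$n_params)
}

#' @rdname tidy.stagenet_fit
#' @export
tidy.stagenet_eval <- function(x, ...) {
  as_tibble(as.data.frame(as.table(x$confusion))) |>
    setNames(c("truth", "predicted", "n"))
}

#' @rdname tidy.stagenet_fit
#' @export
glance.stagenet_eval <- function(x, ...) {
  tibble(A = x$A, N_C = x$N_C, N_T = x$N_T)
}

#' Plot the training history
#'
#' @param object A `stagenet_fit`.
#' @param ... Unused.
#' @return A ggplot of test loss and accuracy per epoch.
#' @export
autoplot.stagenet_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, c("loss", "accuracy"),
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "Stage classifier test loss and accuracy")
}
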