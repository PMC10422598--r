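# End-to-end orchestration: detect -> cut -> classify -> report over a batch
# of images, with every artifact written under one run directory, and an
# evaluation step comparing predicted counts against manual ground truth.
# Reports contain no timestamps, so a rerun with identical inputs, config
# and seed reproduces them byte for byte; wall-clock logging goes to
# log.txt only.

pipeline_images <- function(images) {
  if (is.character(images) && length(images) == 1L && dir.exists(images)) {
    images <- list.files(images, pattern = "\\.(png|jpg|jpeg)$",
                         ignore.case = TRUE, full.names = TRUE)
    images <- images[!grepl("annotated", basename(images))]
  }
  if (is.character(images)) {
    if (!length(images)) abort("no input images found")
    return(setNames(lapply(images, read_field_image),
                    sub("\\.[^.]+$", "", basename(images))))
  }
  if (inherits(images, "field_scene")) images <- list(images)
  if (is.list(images) && length(images)) {
    imgs <- lapply(images, function(x) {
      if (inherits(x, "field_scene")) x$image else x
    })
    if (is.null(names(imgs))) {
      names(imgs) <- sprintf("image_%03d", seq_along(imgs))
    }
    return(imgs)
  }
  abort("no input images found")
}

apply_classifier <- function(classifier, crops, detections) {
  if (inherits(classifier, "stagenet_fit")) {
    return(classify_crops(classifier, crops))
  }
  if (is.function(classifier)) {
    if (length(formals(classifier)) >= 2L) {
      return(classifier(crops, detections))
    }
    return(classifier(crops))
  }
  abort("`classifier` must be a stagenet_fit or a function over crops")
}

#' Run the full emergence pipeline
#'
#' For every input image: detect and count seedlings, cut each detection
#' into a 255 x 255 crop, classify the crops into growth stages, and build
#' the per-image emergence report with a uniformity verdict. All artifacts
#' (detections JSON, labels CSV, per-image and combined report JSON, the
#' resolved configuration snapshot and a log) are written under `out_dir`.
#'
#' @param images A directory, a vector of image paths, or a list of image
#'   arrays / `field_scene` objects.
#' @param classifier A trained [train_stagenet()] fit, or a function
#'   `f(crops)` (or `f(crops, detections)`) returning stage labels 0/1/2 --
#'   the latter supports oracle classifiers in validation studies.
#' @param out_dir Run directory (created; default a fresh directory under
#'   `tempdir()`).
#' @param detect A [detect_params()].
#' @param margin Crop margin passed to [cut_crop()].
#' @param rules A [uniformity_rules()].
#' @param expected_count Expected seedlings per image for the low-emergence
#'   rule (optional).
#' @param date_label Optional observation-date label stamped into reports.
#' @param seed Integer seed (recorded; the detection chain itself is
#'   deterministic).
#' @param write_annotated Also write annotated overlay PNGs.
#' @return A `pipeline_run`: list with `run_dir`, `summary` (one tibble row
#'   per image: counts, proportions, verdict), `reports`, `detections`.
#' @export
run_pipeline <- function(images, classifier,
                         out_dir = file.path(tempdir(), paste0("run-", format(Sys.time(), "%Y%m%d-%H%M%S"))),
                         detect = detect_params(), margin = NULL,
                         rules = uniformity_rules(), expected_count = NULL,
                         date_label = NULL, seed = 1L,
                         write_annotated = FALSE) {
  imgs <- pipeline_images(images)   # fails cleanly before any artifact is written
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  log_line <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), sprintf(...), "\n",
        sep = "", file = log_path, append = TRUE)
  }
  log_line("pipeline start: %d image(s)", length(imgs))

  snapshot <- list(seed = as.integer(seed),
                   detect = unclass(detect),
                   margin = margin, rules = unclass(rules),
                   expected_count = expected_count,
                   date_label = date_label,
                   images = names(imgs))
  yaml::write_yaml(snapshot, file.path(out_dir, "config.yaml"))

  reports <- list(); detections <- list(); labels_rows <- list()
  summary_rows <- list()
  for (nm in names(imgs)) {
    img <- imgs[[nm]]
    det <- tryCatch(detect_seedlings(img, detect), error = function(e) {
      abort(sprintf("stage 'detect' failed on input '%s': %s", nm,
                    conditionMessage(e)))
    })
    log_line("detect %s: %d seedling(s)", nm, det$count)
    crops <- lapply(seq_len(det$count), function(i)
      cut_crop(img, det$detections[i, ], margin = margin))
    stages <- if (det$count > 0) {
      tryCatch(apply_classifier(classifier, crops, det),
               error = function(e) {
                 abort(sprintf("stage 'classify' failed on input '%s': %s",
                               nm, conditionMessage(e)))
               })
    } else {
      integer(0)
    }
    log_line("classify %s: %s", nm,
             paste(table(factor(stages, levels = 0:2)), collapse = "/"))
    cn <- tabulate(stages + 1L, nbins = 3L)
    report <- emergence_proportion(stage_counts(cn[1], cn[2], cn[3]),
                                   date = date_label)
    report <- uniformity_verdict(report, rules, expected_count)

    write_detections(det,
                     json_path = file.path(out_dir, paste0(nm, "_detections.json")),
                     image_name = nm)
    jsonlite::write_json(
      list(image = nm, date = date_label,
           counts = as.list(report$counts$TP), ST = report$counts$ST,
           EP = if (report$empty) NULL else as.list(report$EP),
           uniformity = report$uniformity),
      file.path(out_dir, paste0(nm, "_report.json")),
      auto_unbox = TRUE, digits = NA)
    if (write_annotated) {
      write_field_image(annotate_detections(img, det),
                        file.path(out_dir, paste0(nm, "_annotated.png")))
    }
    if (det$count > 0) {
      labels_rows[[nm]] <- tibble(image = nm,
                                  index = det$detections$index,
                                  stage = stages)
    }
    reports[[nm]] <- report
    detections[[nm]] <- det
    summary_rows[[nm]] <- tibble(
      image = nm, count = det$count,
      TP_VE = cn[1], TP_VC = cn[2], TP_V1 = cn[3],
      EP_VE = if (report$empty) NA_real_ else report$EP[[1]],
      EP_VC = if (report$empty) NA_real_ else report$EP[[2]],
      EP_V1 = if (report$empty) NA_real_ else report$EP[[3]],
      uniform = report$uniformity$uniform)
  }
  labels <- dplyr::bind_rows(labels_rows)
  write.csv(labels, file.path(out_dir, "labels.csv"), row.names = FALSE)
  summary <- dplyr::bind_rows(summary_rows)
  write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
  log_line("pipeline done")
  structure(list(run_dir = out_dir, summary = summary,
                 reports = reports, detections = detections,
                 labels = labels),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("pipeline run over %d image(s) in %s\n",
              nrow(x$summary), x$run_dir))
  print(x$summary)
  invisible(x)
}

#' Evaluate a pipeline run against manual counts
#'
#' Joins the run's predicted counts with a ground-truth count table and
#' computes the count-agreement statistics. Truth rows without a matching
#' image (or images without truth) are listed, excluded and warned about.
#'
#' @param run A `pipeline_run` (or its summary tibble).
#' @param truth A data frame with columns `image` and `count`, or a CSV path.
#' @return List with `per_image` (image, real, predicted, abs_error) and
#'   `metrics` (the [count_metrics()] row).
#' @export
evaluate_run <- function(run, truth) {
  summary <- if (inherits(run, "pipeline_run")) run$summary else run
  if (is.character(truth)) truth <- read.csv(truth)
  if (!all(c("image", "count") %in% names(truth))) {
    abort("`truth` needs columns image and count")
  }
  joined <- dplyr::inner_join(
    dplyr::select(summary, "image", predicted = "count"),
    dplyr::select(truth, "image", real = "count"), by = "image")
  missing_truth <- setdiff(summary$image, truth$image)
  missing_pred <- setdiff(truth$image, summary$image)
  if (length(missing_truth)) {
    warn(sprintf("no truth for: %s (excluded)",
                 paste(missing_truth, collapse = ", ")))
  }
  if (length(missing_pred)) {
    warn(sprintf("truth without predictions for: %s (excluded)",
                 paste(missing_pred, collapse = ", ")))
  }
  per_image <- dplyr::mutate(joined,
                             abs_error = abs(.data$predicted - .data$real))
  list(per_image = per_image,
       metrics = count_metrics(per_image$real, per_image$predicted))
}
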