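# Emergence reporting: per-stage counts, emergence proportions
# EP_i = TP_i / ST, proportion-error comparisons against reference
# observations, the emergence-uniformity verdict, and the count-agreement
# statistics (R^2, RMSE, MAE, average accuracy) used to compare predicted
# with manually counted seedlings.

#' Per-stage seedling counts
#'
#' @param ve,vc,v1 Seedling counts at the VE, VC and V1 stages.
#' @return A `stage_counts` object with `TP` (named triple) and total `ST`.
#' @export
stage_counts <- function(ve = 0, vc = 0, v1 = 0) {
  tp <- c(VE = ve, VC = vc, V1 = v1)
  if (any(tp < 0)) abort("stage counts must be non-negative")
  structure(list(TP = tp, ST = sum(tp)), class = "stage_counts")
}

#' @export
print.stage_counts <- function(x, ...) {
  cat(sprintf("stage counts: VE %g, VC %g, V1 %g (total %g)\n",
              x$TP[1], x$TP[2], x$TP[3], x$ST))
  invisible(x)
}

#' Emergence proportion per growth stage
#'
#' EP_i = TP_i / ST for each stage i in (VE, VC, V1); the proportions sum to
#' 1 whenever any seedling emerged. A field with no emerged seedlings yields
#' a defined empty report with no proportions.
#'
#' @param counts A [stage_counts()] (or numeric triple).
#' @param date Optional observation-date label.
#' @return An `emergence_report`: `counts`, `EP` (named triple, or `NULL`
#'   when empty), `date`, `empty`.
#' @export
emergence_proportion <- function(counts, date = NULL) {
  if (is.numeric(counts) && length(counts) == 3L) {
    counts <- stage_counts(counts[1], counts[2], counts[3])
  }
  if (!inherits(counts, "stage_counts")) {
    abort("`counts` must be a stage_counts or numeric triple")
  }
  ep <- if (counts$ST > 0) counts$TP / counts$ST else NULL
  structure(list(counts = counts, EP = ep, date = date,
                 empty = counts$ST == 0, uniformity = NULL),
            class = "emergence_report")
}

#' @export
print.emergence_report <- function(x, ...) {
  if (x$empty) {
    cat("emergence report: no seedlings emerged\n")
  } else {
    cat(sprintf("emergence report%s: EP(VE) = %.4f, EP(VC) = %.4f, EP(V1) = %.4f (ST = %g)\n",
                if (!is.null(x$date)) paste0(" [", x$date, "]") else "",
                x$EP[1], x$EP[2], x$EP[3], x$counts$ST))
  }
  if (!is.null(x$uniformity)) {
    cat(sprintf("  emergence %s%s\n",
                if (x$uniformity$uniform) "uniform" else "non-uniform",
                if (length(x$uniformity$reasons))
                  paste0(" (", paste(x$uniformity$reasons, collapse = "; "), ")")
                else ""))
  }
  invisible(x)
}

#' @rdname tidy.stagenet_fit
#' @export
tidy.emergence_report <- function(x, ...) {
  tibble(stage = stage_levels(), label = 0:2,
         count = as.numeric(x$counts$TP),
         proportion = if (x$empty) NA_real_ else as.numeric(x$EP))
}

#' @rdname tidy.stagenet_fit
#' @export
glance.emergence_report <- function(x, ...) {
  tibble(ST = x$counts$ST,
         dominant_stage = if (x$empty) NA_character_
           else stage_levels()[which.max(x$EP)],
         uniform = if (is.null(x$uniformity)) NA else x$uniformity$uniform)
}

#' Plot per-stage emergence proportions
#'
#' @param object An `emergence_report`.
#' @param ... Unused.
#' @export
autoplot.emergence_report <- function(object, ...) {
  d <- tidy(object)
  d$stage <- factor(d$stage, levels = stage_levels())
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stage, y = .data$proportion)) +
    ggplot2::geom_col() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "emergence proportion")
}

#' Absolute per-stage proportion errors
#'
#' @param predicted,real Emergence-proportion triples (named or not), or
#'   `emergence_report`s.
#' @return Named numeric triple of absolute errors |predicted - real|.
#' @export
proportion_error <- function(predicted, real) {
  as_ep <- function(x) {
    if (inherits(x, "emergence_report")) x <- x$EP
    if (is.null(x) || length(x) != 3L) abort("a proportion triple is required")
    setNames(as.numeric(x), stage_levels())
  }
  abs(as_ep(predicted) - as_ep(real))
}

#' Proportion-error table over a series of observations
#'
#' Computes the per-cell absolute error between predicted and real
#' emergence proportions over a long-format observation table and the
#' table-wide extremes.
#'
#' @param observations Tibble with columns `date`, `stage`, `predicted`,
#'   `real` (one row per date x stage cell).
#' @return List with `table` (the observations plus an `error` column),
#'   `max_error` and `min_error`.
#' @export
proportion_error_table <- function(observations) {
  need <- c("date", "stage", "predicted", "real")
  if (!all(need %in% names(observations))) {
    abort("`observations` needs columns date, stage, predicted, real")
  }
  tab <- dplyr::mutate(observations,
                       error = abs(.data$predicted - .data$real))
  list(table = tab, max_error = max(tab$error), min_error = min(tab$error))
}

#' Example field observations of emergence proportions
#'
#' A six-date observation series from a row-planted soybean emergence trial:
#' model-predicted and manually recorded per-stage emergence proportions for
#' each observation date in late May, in long format. Useful for
#' demonstrating [proportion_error_table()].
#'
#' @return Tibble with columns `date`, `stage`, `predicted`, `real`.
#' @export
example_emergence_observations <- function() {
  tribble(
    ~date,  ~stage, ~predicted, ~real,
    "5.19", "VE",   0.9380,     0.9830,
    "5.19", "VC",   0.0261,     0.0170,
    "5.19", "V1",   0.0359,     0,
    "5.20", "VE",   0.9440,     0.9568,
    "5.20", "VC",   0.0339,     0.0432,
    "5.20", "V1",   0.0221,     0,
    "5.22", "VE",   0.7960,     0.8548,
    "5.22", "VC",   0.1524,     0.1126,
    "5.22", "V1",   0.0516,     0.0326,
    "5.23", "VE",   0.5948,     0.6723,
    "5.23", "VC",   0.3015,     0.2659,
    "5.23", "V1",   0.1037,     0.0618,
    "5.25", "VE",   0.4495,     0.4892,
    "5.25", "VC",   0.4054,     0.4163,
    "5.25", "V1",   0.1451,     0.0945,
    "5.26", "VE",   0.2830,     0.3275,
    "5.26", "VC",   0.5487,     0.5547,
    "5.26", "V1",   0.1683,     0.1178)
}

#' Uniformity decision rules
#'
#' Emergence is judged uniform when one stage clearly dominates and nothing
#' flags a problem: substantial coexistence of all three stages, or an
#' emerged count well below the expected planting density, marks the stand
#' non-uniform.
#'
#' @param theta_dom Minimum dominant-stage proportion for a uniform verdict.
#' @param theta_coexist Proportion above which a stage counts as
#'   substantially present; all three above it flags multi-stage
#'   coexistence.
#' @param theta_density Fraction of the expected count below which emergence
#'   is flagged low.
#' @return A `uniformity_rules` list.
#' @export
uniformity_rules <- function(theta_dom = 0.90, theta_coexist = 0.05,
                             theta_density = 0.5) {
  structure(list(theta_dom = theta_dom, theta_coexist = theta_coexist,
                 theta_density = theta_density),
            class = "uniformity_rules")
}

#' Judge emergence uniformity
#'
#' @param report An [emergence_proportion()] report.
#' @param rules A [uniformity_rules()].
#' @param expected_count Expected number of seedlings (e.g. seeds sown);
#'   enables the low-emergence rule.
#' @return The report with a `uniformity` element: `uniform` (logical) and
#'   `reasons` (character, empty when uniform).
#' @export
uniformity_verdict <- function(report, rules = uniformity_rules(),
                               expected_count = NULL) {
  if (!inherits(report, "emergence_report")) {
    abort("`report` must be an emergence_report")
  }
  if (!inherits(rules, "uniformity_rules")) {
    abort("`rules` must be a uniformity_rules object")
  }
  reasons <- character()
  if (report$empty) {
    reasons <- "no seedlings emerged"
  } else {
    if (all(report$EP >= rules$theta_coexist)) {
      reasons <- c(reasons, "multi-stage coexistence")
    }
    if (max(report$EP) < rules$theta_dom) {
      reasons <- c(reasons, "no dominant stage")
    }
  }
  if (!is.null(expected_count) && expected_count > 0 &&
      report$counts$ST < rules$theta_density * expected_count) {
    reasons <- c(reasons, "low emergence")
  }
  report$uniformity <- list(uniform = length(reasons) == 0L,
                            reasons = reasons)
  report
}

#' Count-agreement statistics between predicted and real counts
#'
#' For sites i with real counts y_i and predicted counts yhat_i:
#' \deqn{R^2 = 1 - \sum_i (y_i - \hat y_i)^2 / \sum_i (y_i - \bar y)^2}
#' \deqn{RMSE = \sqrt{\sum_i (\hat y_i - y_i)^2 / N}, \quad
#'       MAE = \sum_i |\hat y_i - y_i| / N}
#' and the average accuracy is the mean over sites of
#' (1 - |yhat_i - y_i| / y_i) x 100%, with y_i = 0 sites excluded from that
#' mean (and counted separately).
#'
#' @param real,predicted Count vectors, or a data frame in `real` with
#'   columns `real` and `predicted`.
#' @return One-row tibble: `r_squared`, `rmse`, `mae`, `average_accuracy`,
#'   `n`, `n_zero_excluded`. `r_squared` is `NA` (with a warning) when the
#'   real counts have no variance.
#' @export
count_metrics <- function(real, predicted = NULL) {
  if (is.data.frame(real)) {
    predicted <- real$predicted
    real <- real$real
  }
  if (length(real) != length(predicted)) {
    abort("`real` and `predicted` must have the same length")
  }
  n <- length(real)
  if (n < 2) abort("at least two sites are required")
  if (any(real < 0 | predicted < 0)) abort("counts must be non-negative")
  ss_res <- sum((real - predicted)^2)
  ss_tot <- sum((real - mean(real))^2)
  r2 <- if (ss_tot == 0) {
    warn("real counts have zero variance; R^2 is undefined")
    NA_real_
  } else {
    1 - ss_res / ss_tot
  }
  pos <- real > 0
  avg_acc <- if (any(pos)) {
    mean((1 - abs(predicted[pos] - real[pos]) / real[pos])) * 100
  } else {
    NA_real_
  }
  tibble(r_squared = r2,
         rmse = sqrt(sum((predicted - real)^2) / n),
         mae = sum(abs(predicted - real)) / n,
         average_accuracy = avg_acc,
         n = n, n_zero_excluded = sum(!pos))
}
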