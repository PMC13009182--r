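check_same_geometry <- function(a, b) {
  da <- dim(a$labels); db <- dim(b$labels)
  if (!identical(da, db) || max(abs(a$affine - b$affine)) > 1e-6)
    abort("label maps do not share geometry (dim/affine mismatch)")
}

#' Dice similarity coefficient for one label
#'
#' `2|A n B| / (|A| + |B|)`. Defined as 1 when the label is empty in both
#' maps (nothing to disagree about) and 0 when it is empty in exactly one.
#'
#' @param map_a,map_b [label_map()]s sharing geometry (reference and
#'   prediction).
#' @param label Marker label 1..5.
#' @return A proportion in `[0, 1]`.
#' @export
dice <- function(map_a, map_b, label) {
  check_same_geometry(map_a, map_b)
  a <- map_a$labels == label
  b <- map_b$labels == label
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

#' Intersection over union (Jaccard index) for one label
#'
#' `|A n B| / |A u B|`; same empty-mask conventions as [dice()]. Related by
#' the identity `IoU = DSC / (2 - DSC)`.
#'
#' @inheritParams dice
#' @return A proportion in `[0, 1]`.
#' @export
iou <- function(map_a, map_b, label) {
  check_same_geometry(map_a, map_b)
  a <- map_a$labels == label
  b <- map_b$labels == label
  un <- sum(a | b)
  if (un == 0) return(1)
  sum(a & b) / un
}

#' Per-label overlap scores between two label maps
#'
#' @inheritParams dice
#' @return A tibble with one row per label 1..5: `label`, `name`,
#'   `n_voxels_a`, `n_voxels_b`, `dsc`, `iou`.
#' @export
overlap_scores <- function(map_a, map_b) {
  check_same_geometry(map_a, map_b)
  purrr::map_dfr(1:5, function(l) {
    tibble::tibble(label = l, name = marker_names()[[as.character(l)]],
                   n_voxels_a = sum(map_a$labels == l),
                   n_voxels_b = sum(map_b$labels == l),
                   dsc = dice(map_a, map_b, l),
                   iou = iou(map_a, map_b, l))
  })
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact interval from beta quantiles: lower bound
#' `qbeta(alpha/2, k, n - k + 1)` (0 when `k = 0`), upper bound
#' `qbeta(1 - alpha/2, k + 1, n - k)` (1 when `k = n`).
#'
#' @param k Number of successes, `0 <= k <= n` (vectorized).
#' @param n Number of trials, `>= 1`.
#' @param level Confidence level in (0, 1), default 0.95.
#' @return A tibble with `k`, `n`, `estimate`, `lower`, `upper`.
#' @examples
#' clopper_pearson(72, 75)   # the exact-or-adjacent accuracy interval
#' @export
clopper_pearson <- function(k, n, level = 0.95) {
  if (any(!is.finite(k)) || any(!is.finite(n)) || any(k != round(k)) ||
      any(n != round(n)) || any(n < 1) || any(k < 0) || any(k > n))
    abort("need integer 0 <= k <= n with n >= 1")
  if (!is.finite(level) || level <= 0 || level >= 1)
    abort("`level` must be in (0, 1)")
  alpha <- 1 - level
  lower <- ifelse(k == 0, 0, qbeta(alpha / 2, k, n - k + 1))
  upper <- ifelse(k == n, 1, qbeta(1 - alpha / 2, k + 1, n - k))
  tibble::tibble(k = as.integer(k), n = as.integer(n),
                 estimate = k / n, lower = lower, upper = upper)
}

#' Format a proportion the way the clinical report prints it
#'
#' Percentage rounded to one decimal place, with a trailing ".0" dropped
#' (so 72/75 prints as "96%", 73/75 as "97.3%").
#'
#' @param k,n Successes and trials.
#' @return `format_proportion()`: character; `proportion_percent()`: the
#'   rounded numeric percentage (1 decimal place).
#' @export
format_proportion <- function(k, n) {
  paste0(sub("\\.0$", "", sprintf("%.1f", proportion_percent(k, n))), "%")
}

#' @rdname format_proportion
#' @export
proportion_percent <- function(k, n) {
  round(100 * k / n, 1)
}

#' Confusion matrix over settings, keeping undeterminable cases aside
#'
#' @param truth Integer settings 1..8.
#' @param pred Integer settings 1..8, with `NA` for undeterminable cases
#'   (these are excluded from the matrix but counted).
#' @return A list of class `setting_confusion`: `matrix` (8x8 integer, rows =
#'   true setting, cols = predicted), `n_undeterminable`, `n_total`.
#' @export
confusion_matrix <- function(truth, pred) {
  if (length(truth) != length(pred))
    abort("`truth` and `pred` must have equal length")
  truth <- check_setting(truth)
  det <- !is.na(pred)
  if (any(det)) check_setting(pred[det])
  m <- matrix(0L, 8, 8, dimnames = list(true = 1:8, predicted = 1:8))
  for (i in which(det)) m[truth[i], pred[i]] <- m[truth[i], pred[i]] + 1L
  structure(list(matrix = m, n_undeterminable = sum(!det),
                 n_total = length(truth)),
            class = "setting_confusion")
}

#' @export
print.setting_confusion <- function(x, ...) {
  cat("<setting_confusion> ", x$n_total, " cases (",
      x$n_undeterminable, " undeterminable)\n", sep = "")
  print(x$matrix)
  invisible(x)
}

#' Per-setting summary of measured angles
#'
#' For each setting present in the data: sample mean and SD (n-1 denominator;
#' SD is reported as `NA` for a single sample, not 0) of the measured angle,
#' the expected zone-center angle, and a flag for settings whose expected
#' angle lies outside mean +/- 2 SD — the layout used to judge whether the
#' measured dial angles track the nominal zones.
#'
#' @param records A data frame with columns `truth_setting` and `angle_deg`
#'   (undeterminable rows, `NA` angle, are dropped).
#' @return A tibble per setting: `setting`, `n`, `mean_angle`, `sd_angle`,
#'   `expected_angle`, `expected_outside_2sd`.
#' @export
angle_summary <- function(records) {
  stopifnot(all(c("truth_setting", "angle_deg") %in% names(records)))
  records |>
    dplyr::filter(!is.na(.data$angle_deg)) |>
    dplyr::group_by(setting = check_setting(.data$truth_setting)) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_angle = mean(.data$angle_deg),
                     sd_angle = if (dplyr::n() > 1) sd(.data$angle_deg) else NA_real_,
                     .groups = "drop") |>
    dplyr::mutate(expected_angle = setting_to_expected_angle(.data$setting),
                  expected_outside_2sd = !is.na(.data$sd_angle) &
                    abs(.data$expected_angle - .data$mean_angle) > 2 * .data$sd_angle)
}

#' Evaluate setting predictions against ground truth
#'
#' Computes the full evaluation report: determinable rate, exact accuracy and
#' adjacent-setting accuracy — all with the total case count as denominator,
#' so an undeterminable case counts as incorrect — each with a
#' Clopper-Pearson exact confidence interval, plus the confusion matrix and
#' the per-setting angle summary.
#'
#' @param records A data frame with columns `truth_setting`, `setting`
#'   (predicted, `NA` when undeterminable) and optionally `angle_deg`.
#' @param circular Adjacency mode for the adjacent accuracy (default
#'   non-circular; see [settings_adjacent()]).
#' @param level Confidence level for the intervals (default 0.95).
#' @return An object of class `eval_report` with fields `n_total`,
#'   `accuracy` (tibble of the three rates with CIs), `confusion`
#'   ([confusion_matrix()]), `angles` ([angle_summary()] or `NULL`),
#'   `circular`, `level`.
#' @export
evaluate_predictions <- function(records, circular = FALSE, level = 0.95) {
  stopifnot(all(c("truth_setting", "setting") %in% names(records)))
  truth <- check_setting(records$truth_setting)
  pred <- records$setting
  n <- length(truth)
  det <- !is.na(pred)
  exact <- det & pred == truth
  adjacent <- det
  adjacent[det] <- settings_adjacent(truth[det], pred[det], circular = circular)
  counts <- c(determinable = sum(det), exact = sum(exact),
              adjacent = sum(adjacent))
  acc <- clopper_pearson(unname(counts), n, level)
  acc <- dplyr::mutate(acc, metric = names(counts),
                       percent = proportion_percent(.data$k, .data$n),
                       formatted = format_proportion(.data$k, .data$n),
                       .before = 1)
  structure(list(n_total = n,
                 accuracy = acc,
                 confusion = confusion_matrix(truth, pred),
                 angles = if ("angle_deg" %in% names(records))
                   angle_summary(records) else NULL,
                 circular = circular, level = level),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> ", x$n_total, " cases, ",
      round(100 * x$level), "% Clopper-Pearson CIs\n", sep = "")
  for (i in seq_len(nrow(x$accuracy))) {
    r <- x$accuracy[i, ]
    cat(sprintf("  %-12s %s (CI: %s - %s)\n", r$metric, r$formatted,
                format_proportion(round(r$lower * r$n), r$n),
                format_proportion(round(r$upper * r$n), r$n)))
  }
  cat("  undeterminable: ", x$confusion$n_undeterminable, "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return One row per metric: `metric`, `k`, `n`, `estimate`, `lower`,
#'   `upper`, `percent`.
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) {
  dplyr::select(x$accuracy, "metric", "k", "n", "estimate", "lower", "upper",
                "percent")
}

#' @rdname tidy.eval_report
#' @return `glance()`: a one-row tibble with the headline rates and CI bounds.
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  wide <- tidy.eval_report(x) |>
    tidyr::pivot_wider(names_from = "metric",
                       values_from = c("estimate", "lower", "upper"),
                       id_cols = c())
  dplyr::bind_cols(tibble::tibble(n_total = x$n_total,
                                  n_undeterminable = x$confusion$n_undeterminable),
                   wide)
}

#' Serialize an evaluation report
#'
#' Writes the report as JSON (accuracies, confusion counts, angle summary)
#' and the confusion matrix as CSV.
#'
#' @param report An `eval_report`.
#' @param json_path,confusion_csv_path Output paths (`NULL` to skip either).
#' @return `report`, invisibly.
#' @export
write_eval_report <- function(report, json_path = NULL,
                              confusion_csv_path = NULL) {
  if (!is.null(json_path)) {
    payload <- list(
      n_total = report$n_total,
      level = report$level,
      circular_adjacency = report$circular,
      accuracy = report$accuracy,
      n_undeterminable = report$confusion$n_undeterminable,
      confusion = as.data.frame(as.table(report$confusion$matrix)),
      angles = report$angles)
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "rows")
  }
  if (!is.null(confusion_csv_path))
    utils::write.csv(report$confusion$matrix, confusion_csv_path)
  invisible(report)
}
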