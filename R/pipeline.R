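#' Predict the valve setting from a label map or CT volume
#'
#' Runs the measurement chain: marker centroids -> valve frame -> signed
#' indicator angle -> setting zone. Given an intensity volume instead of a
#' label map, the threshold segmenter ([segment_markers()]) produces the
#' label map first. A missing marker is a reported outcome
#' (`status = "undeterminable"` with the missing markers named), not an
#' error: clinically these cases are flagged for manual verification.
#'
#' @param x A [label_map()] or [voxel_grid()].
#' @param params [seg_params()] used when `x` is an intensity volume.
#' @return A one-row tibble: `status` (`"ok"` or `"undeterminable"`),
#'   `angle_deg`, `setting`, `zone_lo`, `zone_hi`, `missing_markers`
#'   (list-column of character vectors) and `reason`.
#' @examples
#' ph <- make_phantom(phantom_spec(setting = 6, seed = 42))
#' predict_setting(ph$labels)
#' @export
predict_setting <- function(x, params = seg_params()) {
  if (inherits(x, "voxel_grid")) {
    x <- tryCatch(segment_markers(x, params),
                  certasdial_no_markers = function(e) e)
    if (inherits(x, "error"))
      return(undeterminable_row(.MARKERS, conditionMessage(x)))
  }
  stopifnot(inherits(x, "label_map"))
  mk <- marker_centroids(x)
  res <- tryCatch(indicator_angle(mk),
                  certasdial_missing_marker = function(e) e,
                  certasdial_degenerate = function(e) e)
  if (inherits(res, "error")) {
    missing <- res$missing_markers %||% character(0)
    return(undeterminable_row(missing, conditionMessage(res)))
  }
  s <- angle_to_setting(res$angle_deg)
  tibble::tibble(status = "ok", angle_deg = res$angle_deg,
                 setting = s$setting, zone_lo = s$zone_lo, zone_hi = s$zone_hi,
                 missing_markers = list(character(0)), reason = NA_character_)
}

undeterminable_row <- function(missing, reason) {
  tibble::tibble(status = "undeterminable", angle_deg = NA_real_,
                 setting = NA_integer_, zone_lo = NA_real_, zone_hi = NA_real_,
                 missing_markers = list(missing), reason = reason)
}

#' Run the full pipeline over a synthetic cohort
#'
#' Materializes each phantom in turn (volumes are generated on demand, never
#' held together in memory), optionally segments it from intensities, and
#' predicts the setting. With `from = "labels"` the ground-truth label map is
#' used, isolating the geometry from segmentation quality; with
#' `from = "volume"` the end-to-end chain
#' segment -> centroids -> angle -> setting is exercised.
#'
#' @param cohort A [make_cohort()] result.
#' @param from `"volume"` (default, end-to-end) or `"labels"`.
#' @param params [seg_params()] for the end-to-end route.
#' @param progress Log per-case progress to stderr.
#' @return The cohort manifest joined with per-case prediction columns
#'   (`status`, `angle_deg`, `setting`, ...) and `angle_error_deg`, the
#'   measured-minus-truth angle wrapped into (-180, 180].
#' @export
run_cohort <- function(cohort, from = c("volume", "labels"),
                       params = seg_params(), progress = FALSE) {
  stopifnot(inherits(cohort, "valve_cohort"))
  from <- match.arg(from)
  preds <- purrr::map(seq_along(cohort$specs), function(i) {
    ph <- make_phantom(cohort$specs[[i]])
    if (progress)
      message("case ", cohort$manifest$case_id[i], " (", i, "/",
              length(cohort$specs), ")")
    predict_setting(if (from == "volume") ph$volume else ph$labels, params)
  })
  out <- dplyr::bind_cols(cohort$manifest, dplyr::bind_rows(preds))
  out$angle_error_deg <- wrap_pm180(out$angle_deg - out$truth_angle_deg)
  out
}

# wrap into (-180, 180]
wrap_pm180 <- function(x) -((-x + 180) %% 360 - 180)

#' Grouped train/test split
#'
#' Splits a manifest into train and test partitions by a grouping key
#' (patient), so no group spans both partitions — the precaution that
#' prevents leakage when scans of one patient resemble each other.
#'
#' @param manifest A data frame with one row per case.
#' @param group Column name holding the grouping key (default
#'   `"patient_id"`).
#' @param train_fraction Target fraction of cases in the train split
#'   (default 0.8); realized fractions differ by at most one group.
#' @param seed Integer seed for the group shuffle.
#' @return The manifest with a `split` column (`"train"`/`"test"`).
#' @export
split_cohort <- function(manifest, group = "patient_id", train_fraction = 0.8,
                         seed = 1L) {
  if (!is.data.frame(manifest) || !group %in% names(manifest))
    abort("`manifest` must contain the grouping column `", group, "`")
  if (train_fraction <= 0 || train_fraction >= 1)
    abort("`train_fraction` must be in (0, 1)")
  groups <- unique(manifest[[group]])
  withr::with_seed(as.integer(seed), groups <- sample(groups))
  sizes <- table(manifest[[group]])[groups]
  cum <- cumsum(as.integer(sizes))
  n_train_groups <- which.min(abs(cum - train_fraction * nrow(manifest)))
  train_groups <- groups[seq_len(n_train_groups)]
  manifest$split <- ifelse(manifest[[group]] %in% train_groups, "train", "test")
  manifest
}
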