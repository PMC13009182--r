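#' Convert indicator angles to Certas Plus settings
#'
#' The eight settings occupy consecutive 45-degree zones increasing clockwise
#' around the full 360-degree dial. An angle of 0 degrees — indicator
#' superimposed on the RC-to-RHS reference axis — is the cutoff between
#' settings 2 and 3; zones are half-open and lower-inclusive, so 0 maps to
#' setting 3. Setting `s` covers `[(s-3)*45, (s-2)*45)` on the reporting range
#' `[-90, 270)`; any real input is first normalized into that range, so the
#' map is invariant to adding multiples of 360.
#'
#' @param angle_deg Numeric vector of finite angles in degrees.
#' @return A tibble with columns `setting` (1..8), `angle_deg` (normalized),
#'   `zone_lo`, `zone_hi`.
#' @examples
#' angle_to_setting(c(0, 54.5, -67.5, 315))
#' @export
angle_to_setting <- function(angle_deg) {
  if (!is.numeric(angle_deg) || any(!is.finite(angle_deg)))
    abort("`angle_deg` must be finite")
  a <- normalize_angle(angle_deg)
  s <- as.integer(floor(a / 45)) + 3L
  s <- pmin(pmax(s, 1L), 8L)   # guards the a == 270 - eps float edge
  tibble::tibble(setting = s, angle_deg = a,
                 zone_lo = (s - 3) * 45, zone_hi = (s - 2) * 45)
}

check_setting <- function(setting) {
  if (!is.numeric(setting) || any(!is.finite(setting)) ||
      any(setting != round(setting)) || any(setting < 1) || any(setting > 8))
    abort("`setting` must be integers in 1..8")
  as.integer(setting)
}

#' Expected indicator angle for a setting
#'
#' The center of the setting's 45-degree zone: `(setting - 2.5) * 45` degrees,
#' i.e. -67.5 for setting 1 through 247.5 for setting 8.
#'
#' @param setting Integer vector in 1..8.
#' @return Numeric vector of zone-center angles in degrees.
#' @export
setting_to_expected_angle <- function(setting) {
  (check_setting(setting) - 2.5) * 45
}

#' Zone bounds for a setting
#'
#' @inheritParams setting_to_expected_angle
#' @return A tibble with `setting`, `zone_lo`, `zone_hi` (degrees, half-open
#'   lower-inclusive).
#' @export
zone_bounds <- function(setting) {
  s <- check_setting(setting)
  tibble::tibble(setting = s, zone_lo = (s - 3) * 45, zone_hi = (s - 2) * 45)
}

#' Full setting/zone table
#'
#' @return A tibble over settings 1..8 with zone bounds and expected angles;
#'   exportable as CSV.
#' @export
zone_table <- function() {
  dplyr::mutate(zone_bounds(1:8), expected_angle = setting_to_expected_angle(.data$setting))
}

#' Are two settings adjacent?
#'
#' Non-circular (default) adjacency is clinical pressure adjacency,
#' `|a - b| <= 1`. Circular adjacency additionally treats settings 1 and 8 as
#' neighbours on the dial; the distinction matters because 1 (very low outflow
#' resistance) and 8 (functionally closed) are clinically opposite despite
#' being geometrically adjacent.
#'
#' @param a,b Integer vectors of settings in 1..8 (recycled).
#' @param circular Use circular dial adjacency (default `FALSE`).
#' @return Logical vector; exact matches count as adjacent.
#' @export
settings_adjacent <- function(a, b, circular = FALSE) {
  a <- check_setting(a); b <- check_setting(b)
  d <- abs(a - b)
  if (circular) d <- pmin(d, 8L - d)
  d <= 1L
}
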