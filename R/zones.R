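# AU zone displacement and intensity calibration.
#
# The activation of an action unit is read off the Euclidean displacement of
# its zone's landmarks between a neutral reference frame and an activated
# frame, both in canonical (interocular-unit) coordinates. Displacements are
# mapped linearly to the 0-5 FACS intensity scale by a per-AU calibration.

#' Euclidean landmark displacement
#'
#' Distance between corresponding neutral and activated landmark points,
#' `sqrt((x2 - x1)^2 + (y2 - y1)^2)`. By default the distance is planar
#' (z ignored); set `use_z = TRUE` for the 3-D distance. Vectorized over
#' rows.
#'
#' @param p_neutral,p_active Data frames (or named numeric vectors) with
#'   `x`, `y` and optionally `z`, in the same canonical frame.
#' @param use_z Include the depth coordinate in the distance.
#' @return Non-negative numeric vector of displacements.
#' @export
#' @examples
#' displacement(c(x = 1, y = 2), c(x = 4, y = 6))  # 5
displacement <- function(p_neutral, p_active, use_z = FALSE) {
  pn <- as_point_df(p_neutral)
  pa <- as_point_df(p_active)
  if (nrow(pn) != nrow(pa)) stop_invalid("point sets differ in length")
  d2 <- (pa$x - pn$x)^2 + (pa$y - pn$y)^2
  if (use_z) d2 <- d2 + (pa$z - pn$z)^2
  if (any(!is.finite(d2))) stop_invalid("non-finite coordinates")
  sqrt(d2)
}

as_point_df <- function(p) {
  if (is.numeric(p) && is.null(dim(p))) {
    nm <- names(p)
    p <- if (is.null(nm)) {
      as.list(c(p, 0)[1:3]) |> setNames(c("x", "y", "z"))
    } else {
      as.list(p)
    }
    p <- as.data.frame(p)
  }
  p <- as.data.frame(p)
  if (is.null(p$z)) p$z <- 0
  if (!all(c("x", "y") %in% names(p))) stop_invalid("points need x and y")
  p
}

#' Per-point displacements within one AU zone
#'
#' @param neutral,active Canonical `landmark_set`s sharing a mesh size.
#' @param zone Either an AU id present in `config`, a zone definition list
#'   with an `indices` field, or an integer vector of 0-based indices.
#' @param config A `zone_config` used to resolve AU ids.
#' @param use_z Include depth in the distance.
#' @return Numeric vector, one displacement per zone index (order preserved).
#' @export
zone_displacements <- function(neutral, active, zone,
                               config = default_zone_config(), use_z = FALSE) {
  idx <- if (is.character(zone)) {
    z <- config$zones[[zone]]
    if (is.null(z)) stop_config(paste0("zone not configured: ", zone))
    z$indices
  } else if (is.list(zone)) {
    zone$indices
  } else {
    as.integer(zone)
  }
  if (nrow(neutral) != nrow(active)) stop_schema("frames differ in mesh size")
  rows <- match(idx, neutral$point)
  if (anyNA(rows)) stop_schema("zone index outside the landmark set")
  displacement(neutral[rows, , drop = FALSE], active[rows, , drop = FALSE],
               use_z = use_z)
}

#' Map a displacement to the 0-5 intensity scale
#'
#' Linear calibration with saturation: `min(5 * d / d_max, 5)`, where
#' `d_max` is the canonical-unit displacement corresponding to a maximal
#' (intensity 5) activation. Non-decreasing in `d` and invariant to joint
#' rescaling of `(d, d_max)`.
#'
#' @param d Non-negative displacement(s), canonical units.
#' @param d_max Positive displacement mapped to intensity 5.
#' @return Intensity value(s) in \[0, 5\].
#' @export
#' @examples
#' calibrate_intensity(c(0, 0.125, 0.25, 1), d_max = 0.25)
calibrate_intensity <- function(d, d_max) {
  if (length(d_max) != 1 || !is.finite(d_max) || d_max <= 0) {
    stop_invalid("d_max must be a single positive number")
  }
  if (any(!is.finite(d)) || any(d < 0)) stop_invalid("d must be non-negative")
  pmin(5 * d / d_max, 5)
}

#' Per-point AU intensities for every configured zone
#'
#' Runs [zone_displacements()] then [calibrate_intensity()] for each zone in
#' the configuration. AU43 (eye closure) is binarized per point: 1 when the
#' displacement reaches its `binary_threshold`, else 0. Because displacements
#' are computed in canonical coordinates the result is invariant under any
#' common similarity transform of both frames.
#'
#' @inheritParams zone_displacements
#' @param calibration Calibration tibble, see [default_calibration()].
#' @return Tibble with columns `au_id`, `point`, `displacement`, `intensity`
#'   (intensity in \[0, 5\]; AU43 rows are 0/1).
#' @export
compute_zone_intensities <- function(neutral, active,
                                     config = default_zone_config(),
                                     calibration = default_calibration(config),
                                     use_z = FALSE) {
  purrr::map_dfr(names(config$zones), function(au) {
    ci <- match(au, calibration$au_id)
    if (is.na(ci)) stop_config(paste0("no calibration entry for ", au))
    d <- zone_displacements(neutral, active, au, config = config, use_z = use_z)
    intensity <- if (au == "AU43") {
      thr <- calibration$binary_threshold[ci]
      if (!is.finite(thr) || thr <= 0) stop_config("AU43 needs a positive binary_threshold")
      as.numeric(d >= thr)
    } else {
      calibrate_intensity(d, calibration$d_max[ci])
    }
    tibble(au_id = au, point = as.integer(config$zones[[au]]$indices),
           displacement = d, intensity = intensity)
  })
}

#' Reduce per-point zone intensities to one scalar per AU
#'
#' @param zi Zone intensity tibble from [compute_zone_intensities()]
#'   (columns `au_id`, `intensity`).
#' @param mode `"max"` (default; the strongest activation represents the
#'   zone) or `"mean"`.
#' @return Tibble with columns `au_id`, `intensity`.
#' @export
reduce_to_vector <- function(zi, mode = c("max", "mean")) {
  mode <- match.arg(mode)
  if (!all(c("au_id", "intensity") %in% names(zi))) {
    stop_schema("zone intensities need au_id and intensity columns")
  }
  if (nrow(zi) == 0) stop_schema("empty zone intensity table")
  f <- if (mode == "max") max else mean
  zi |>
    dplyr::group_by(.data$au_id) |>
    dplyr::summarise(intensity = f(.data$intensity), .groups = "drop")
}

au_vector <- function(au_tbl) {
  if (is.numeric(au_tbl) && !is.null(names(au_tbl))) return(au_tbl)
  if (!all(c("au_id", "intensity") %in% names(au_tbl))) {
    stop_schema("AU intensities need au_id and intensity columns")
  }
  setNames(au_tbl$intensity, au_tbl$au_id)
}
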