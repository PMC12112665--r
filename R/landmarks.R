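# Landmark sets: reading, writing and canonical alignment.
#
# A landmark set is a tibble with columns `point` (0-based mesh index),
# `x`, `y`, `z`, ordered by `point`, plus attributes `frame_id`,
# `canonical` and `scale_ref`. Input coordinates are image-normalized
# (x, y in [0, 1], origin top-left, y down); displacement math happens in
# canonical interocular-unit coordinates after align_landmarks().

#' Construct a landmark set
#'
#' @param points A matrix or data frame of coordinates: columns `x`, `y`
#'   and optionally `z` (relative depth, 0 when absent). Rows are taken in
#'   mesh-index order 0, 1, 2, ...
#' @param frame_id Identifier of the source frame.
#' @return A `landmark_set`: a tibble with columns `point`, `x`, `y`, `z`.
#' @export
#' @examples
#' landmark_set(cbind(x = c(0, 1, 0.5), y = c(0, 0, 1)), frame_id = "f1")
landmark_set <- function(points, frame_id = "frame") {
  pts <- as.data.frame(points)
  if (is.null(colnames(points))) {
    names(pts) <- c("x", "y", "z")[seq_len(ncol(pts))]
  }
  if (!all(c("x", "y") %in% names(pts))) {
    stop_schema("points must have x and y columns")
  }
  if (is.null(pts$z)) pts$z <- 0
  lm <- tibble(point = seq_len(nrow(pts)) - 1L,
               x = as.numeric(pts$x), y = as.numeric(pts$y),
               z = as.numeric(pts$z))
  if (any(!is.finite(lm$x)) || any(!is.finite(lm$y)) || any(!is.finite(lm$z))) {
    stop_invalid("landmark coordinates must be finite")
  }
  new_landmark_set(lm, frame_id = frame_id, canonical = FALSE, scale_ref = NA_real_)
}

new_landmark_set <- function(tbl, frame_id, canonical, scale_ref) {
  structure(tbl,
            frame_id = frame_id, canonical = canonical, scale_ref = scale_ref,
            class = c("landmark_set", class(tibble())))
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> frame '%s', %d points%s\n",
              frame_id(x), nrow(x),
              if (isTRUE(attr(x, "canonical")))
                sprintf(", canonical (scale_ref = %.4g)", attr(x, "scale_ref"))
              else ""))
  NextMethod()
}

#' Landmark set attributes
#'
#' @param lm A `landmark_set`.
#' @return `frame_id()`: the frame identifier; `is_canonical()`: whether the
#'   set has been canonically aligned; `scale_ref()`: the source frame's
#'   interocular distance recorded at alignment (NA before alignment).
#' @export
frame_id <- function(lm) attr(lm, "frame_id") %||% "frame"

#' @rdname frame_id
#' @export
is_canonical <- function(lm) isTRUE(attr(lm, "canonical"))

#' @rdname frame_id
#' @export
scale_ref <- function(lm) attr(lm, "scale_ref") %||% NA_real_

lm_matrix <- function(lm) cbind(x = lm$x, y = lm$y, z = lm$z)

#' Load landmarks from JSON or CSV
#'
#' JSON: `{"frame_id": str, "points": [[x, y, z], ...]}`.
#' CSV: columns `idx, x, y, z` (idx 0-based; rows sorted by idx on load).
#'
#' @param path File path; format inferred from the extension unless given.
#' @param format `"json"` or `"csv"`.
#' @param n_points Expected point count (e.g. the configured mesh size);
#'   a mismatch raises a schema error. `NULL` skips the check.
#' @param frame_id Frame id for CSV input (JSON carries its own).
#' @return A `landmark_set`.
#' @export
load_landmarks <- function(path, format = c("auto", "json", "csv"),
                           n_points = NULL, frame_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_parse(paste0("landmark file not found: ", path))
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     json = "json", csv = "csv",
                     stop_parse("cannot infer landmark format from extension"))
  }
  lm <- if (format == "json") {
    doc <- tryCatch(jsonlite::fromJSON(path, simplifyMatrix = TRUE),
                    error = function(e) stop_parse(paste0("malformed JSON: ", conditionMessage(e))))
    if (is.null(doc$points)) stop_parse("landmark JSON must have a 'points' field")
    pts <- doc$points
    if (is.list(pts)) pts <- do.call(rbind, pts)
    pts <- as.matrix(pts)
    if (ncol(pts) == 2) pts <- cbind(pts, 0)
    if (ncol(pts) != 3) stop_parse("each point must be [x, y] or [x, y, z]")
    colnames(pts) <- c("x", "y", "z")
    landmark_set(pts, frame_id = doc$frame_id %||% frame_id %||% "frame")
  } else {
    df <- tryCatch(
      as.data.frame(readr::read_csv(path, show_col_types = FALSE, progress = FALSE)),
      error = function(e) stop_parse(paste0("malformed CSV: ", conditionMessage(e))))
    if (!all(c("idx", "x", "y") %in% names(df))) {
      stop_parse("landmark CSV must have columns idx, x, y (and optionally z)")
    }
    df <- df[order(df$idx), , drop = FALSE]
    if (!identical(as.integer(df$idx), seq_len(nrow(df)) - 1L)) {
      stop_schema("landmark CSV idx must be the contiguous 0-based mesh indices")
    }
    if (is.null(df$z)) df$z <- 0
    landmark_set(df[, c("x", "y", "z")],
                 frame_id = frame_id %||% tools::file_path_sans_ext(basename(path)))
  }
  if (!is.null(n_points) && nrow(lm) != n_points) {
    stop_schema(sprintf("expected %d landmarks, found %d", n_points, nrow(lm)))
  }
  lm
}

#' Write landmarks to JSON or CSV
#'
#' @param lm A `landmark_set`.
#' @inheritParams load_landmarks
#' @return The path, invisibly.
#' @export
write_landmarks <- function(lm, path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     json = "json", csv = "csv",
                     stop_parse("cannot infer landmark format from extension"))
  }
  if (format == "json") {
    doc <- list(frame_id = frame_id(lm),
                points = unname(lapply(seq_len(nrow(lm)),
                                       function(i) c(lm$x[i], lm$y[i], lm$z[i]))))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  } else {
    readr::write_csv(tibble(idx = lm$point, x = lm$x, y = lm$y, z = lm$z), path,
                     progress = FALSE)
  }
  invisible(path)
}

#' Canonically align a landmark set
#'
#' Applies the similarity transform (rotation, uniform scale, translation)
#' that places the two eye-anchor landmarks on a horizontal line, exactly
#' one unit apart, centered at the origin. All displacement computation is
#' done in this canonical frame so that intensities are comparable across
#' faces, head poses and image scales. `scale_ref` records the source
#' frame's interocular distance (in input units) before normalization; z is
#' rescaled by the same factor but not rotated (it is a relative depth).
#'
#' The operation is idempotent and invariant under any in-plane similarity
#' transform of the input.
#'
#' @param lm A `landmark_set`.
#' @param left_eye_idx,right_eye_idx 0-based mesh indices of the eye
#'   anchors; defaults follow `config`.
#' @param config A `zone_config` supplying default anchors.
#' @return A canonical `landmark_set` (attribute `canonical = TRUE`).
#' @export
#' @examples
#' lm <- landmark_set(cbind(x = c(0.3, 0.7, 0.5), y = c(0.4, 0.4, 0.8)))
#' align_landmarks(lm, left_eye_idx = 0, right_eye_idx = 1)
align_landmarks <- function(lm, left_eye_idx = NULL, right_eye_idx = NULL,
                            config = NULL) {
  if (is.null(left_eye_idx) || is.null(right_eye_idx)) {
    config <- config %||% default_zone_config()
    left_eye_idx  <- left_eye_idx  %||% config$left_eye
    right_eye_idx <- right_eye_idx %||% config$right_eye
  }
  if (left_eye_idx == right_eye_idx) {
    stop_degenerate("eye anchor indices coincide")
  }
  il <- match(left_eye_idx, lm$point)
  ir <- match(right_eye_idx, lm$point)
  if (is.na(il) || is.na(ir)) stop_schema("eye anchor index outside the landmark set")
  L <- c(lm$x[il], lm$y[il]); R <- c(lm$x[ir], lm$y[ir])
  v <- R - L
  d <- sqrt(sum(v^2))
  if (!is.finite(d) || d < 1e-300) {
    stop_degenerate("eye anchor landmarks coincide; cannot define the interocular axis")
  }
  ctr <- (L + R) / 2
  cs <- v[1] / d; sn <- v[2] / d
  dx <- lm$x - ctr[1]; dy <- lm$y - ctr[2]
  out <- tibble(point = lm$point,
                x = ( cs * dx + sn * dy) / d,
                y = (-sn * dx + cs * dy) / d,
                z = lm$z / d)
  prev <- scale_ref(lm)
  new_landmark_set(out, frame_id = frame_id(lm), canonical = TRUE,
                   scale_ref = if (is.na(prev)) d else prev * d)
}
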