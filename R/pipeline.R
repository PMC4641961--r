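#' Run the full border-irregularity pipeline
#'
#' Executes the stages in order: preprocessing (frame removal, hair
#' removal), healthy-skin region growing and lesion extraction, rotation
#' of the lesion so its major axis is horizontal, borderline function
#' construction, Gaussian smoothing, and turning-point detection.
#' Irregularity calls are reported both in the rotated frame and mapped
#' back to raw input-image coordinates.
#'
#' @param image Path to a PNG/JPEG image, or an `H x W x 3` array with
#'   channels on the `[0, 255]` scale.
#' @param config Pipeline configuration, see [border_config()].
#' @param abcd Optional named list/vector with `A`, `C`, `D` component
#'   scores; when supplied, the TDS is computed with the pipeline's B
#'   score.
#' @return An object of class `border_assessment`: list with `calls`
#'   (tibble: `index`, `row`, `col`, `row_rotated`, `col_rotated`,
#'   `prominence`, `segment`, `octant`), `n_irregularities`, `b_score`,
#'   `signal` (smoothed `borderline_signal`), `signal_raw`, `mask`,
#'   `mask_rotated`, `rotation`, `crop`, `hair_mask`, `tds` (or `NULL`),
#'   `config`.
#' @export
run_pipeline <- function(image, config = border_config(), abcd = NULL) {
  if (is.character(image)) image <- read_rgb(image)
  pre <- preprocess_image(image, config)
  mask <- segment_lesion(pre$gray, config)
  rec <- make_rotation(mask)
  mask_rot <- rotate_raster(mask, rec)
  mask_rot <- fill_holes4(mask_rot)  # nearest-neighbour resampling pinholes
  sig <- borderline_function(mask_rot)
  sm <- gaussian_smooth(sig, size = config$smooth_size,
                        sigma = config$smooth_sigma)
  calls <- detect_turning_points(sm, min_prominence = config$min_prominence)
  if (config$count_minima) {
    neg <- sm; neg$value <- -neg$value
    valleys <- detect_turning_points(neg,
                                     min_prominence = config$min_prominence)
    valleys$value <- -valleys$value
    calls <- dplyr::arrange(dplyr::bind_rows(calls, valleys), .data$index)
  }
  orig <- map_to_original(calls[, c("row", "col")], rec, pre$crop)
  calls$row_rotated <- calls$row
  calls$col_rotated <- calls$col
  calls$row <- orig$row
  calls$col <- orig$col
  n <- nrow(sm)
  calls$octant <- if (nrow(calls) > 0)
    pmin(floor((calls$index - 1L) * 8 / n), 7) + 1L else integer(0)
  b <- border_score(calls, n)
  tds <- if (!is.null(abcd)) {
    tds_score(A = abcd[["A"]], B = b, C = abcd[["C"]], D = abcd[["D"]])
  } else NULL
  structure(list(
    calls = calls[, c("index", "row", "col", "row_rotated", "col_rotated",
                      "value", "prominence", "segment", "octant")],
    n_irregularities = nrow(calls), b_score = b,
    signal = sm, signal_raw = sig,
    mask = mask, mask_rotated = mask_rot,
    rotation = rec, crop = pre$crop, hair_mask = pre$hair_mask,
    tds = tds, config = config
  ), class = "border_assessment")
}

#' @export
print.border_assessment <- function(x, ...) {
  cat("Border irregularity assessment\n")
  cat("  lesion area:        ", sum(x$mask), "px\n")
  cat("  rotation angle:     ", format(x$rotation$theta * 180 / pi,
                                       digits = 3), "deg\n")
  cat("  irregularities:     ", x$n_irregularities, "\n")
  cat("  border score (B):   ", x$b_score, "/ 8\n")
  if (!is.null(x$tds)) {
    cat("  TDS:                ", format(x$tds$tds, digits = 3),
        "->", as.character(x$tds$classification), "\n")
  }
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `border_assessment`.
#' @param ... Unused.
#' @export
tidy.border_assessment <- function(x, ...) {
  x$calls
}

#' @rdname run_pipeline
#' @export
glance.border_assessment <- function(x, ...) {
  tibble::tibble(
    n_irregularities = x$n_irregularities,
    b_score = x$b_score,
    lesion_area = sum(x$mask),
    signal_length = nrow(x$signal),
    rotation_deg = x$rotation$theta * 180 / pi,
    closure_gap = attr(x$signal, "closure_gap"),
    overhang = attr(x$signal, "overhang"),
    tds = if (!is.null(x$tds)) x$tds$tds else NA_real_,
    classification = if (!is.null(x$tds))
      as.character(x$tds$classification) else NA_character_
  )
}

#' @rdname run_pipeline
#' @param object A `border_assessment`.
#' @export
autoplot.border_assessment <- function(object, ...) {
  autoplot(object$signal) +
    ggplot2::geom_point(data = object$calls,
                        ggplot2::aes(x = .data$index, y = .data$value),
                        colour = "red", shape = 25, fill = "red", size = 2) +
    ggplot2::labs(title = paste0("Smoothed borderline function, ",
                                 object$n_irregularities,
                                 " irregularities, B = ", object$b_score))
}

#' Serializable result record
#'
#' Plain-list result record (JSON schema version 1) with per-call
#' positions, counts, the B score, rotation and crop provenance, and the
#' run-length-encoded lesion mask, for writing with
#' [jsonlite::write_json()].
#'
#' @param x A `border_assessment`.
#' @param include_mask Include the RLE lesion mask (default `TRUE`).
#' @return A list.
#' @export
result_record <- function(x, include_mask = TRUE) {
  rec <- list(
    schema_version = 1L,
    n_irregularities = x$n_irregularities,
    b_score = x$b_score,
    calls = as.data.frame(x$calls),
    rotation = list(theta = x$rotation$theta,
                    center = as.numeric(x$rotation$center),
                    out_dim = as.integer(x$rotation$out_dim)),
    crop = as.data.frame(x$crop),
    signal_length = nrow(x$signal),
    junctions = as.integer(attr(x$signal, "junctions")),
    closure_gap = attr(x$signal, "closure_gap"),
    overhang = attr(x$signal, "overhang"),
    config = unclass(x$config)
  )
  if (!is.null(x$tds)) rec$tds <- as.data.frame(x$tds)
  if (include_mask) rec$lesion_mask_rle <- mask_to_rle(x$mask)
  rec
}

#' Assess a rendered phantom with the borderline method or the baseline
#'
#' Convenience wrappers used by the validation suite: run the full
#' pipeline (or the radial-distance baseline on the segmented mask) on a
#' rendered phantom and score the calls against the phantom's ground
#' truth by circular arc-length matching on the true contour.
#'
#' @param ph A rendered phantom from [render_phantom()].
#' @param config Pipeline configuration.
#' @return One-row tibble as [evaluate_detection()], plus `n_calls` and
#'   (borderline method only) attribute `assessment`.
#' @export
assess_phantom <- function(ph, config = border_config()) {
  res <- run_pipeline(ph$image, config)
  out <- evaluate_detection(res$calls[, c("row", "col")],
                            ph$truth[, c("row", "col")],
                            ph$contour, tol_frac = config$match_tol_frac)
  attr(out, "assessment") <- res
  out
}

#' @rdname assess_phantom
#' @export
assess_phantom_radial <- function(ph, config = border_config()) {
  pre <- preprocess_image(ph$image, config)
  mask <- segment_lesion(pre$gray, config)
  calls <- detect_irregularities_radial(mask, config)
  coords <- tibble::tibble(
    row = calls$row + pre$crop$rows_removed_top,
    col = calls$col + pre$crop$cols_removed_left
  )
  evaluate_detection(coords, ph$truth[, c("row", "col")],
                     ph$contour, tol_frac = config$match_tol_frac)
}
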