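#' Pipeline configuration
#'
#' Collects every tunable of the border-irregularity pipeline with its
#' default, validated against per-field ranges. Defaults follow the
#' method's reference settings: black pixels are lightness below 15, a
#' frame row is 50 % black, 10 extra rows are removed per qualifying
#' side, the hair top-hat uses a disc of radius 5, the smoothing filter
#' has size 15.
#'
#' @param frame_lightness_thresh Lightness below which a pixel is black
#'   (`[0, 255]`).
#' @param frame_black_fraction Black-pixel fraction for a frame row
#'   (`(0, 1]`).
#' @param frame_extra_rows Extra rows removed past the frame band.
#' @param tophat_radius Disc radius of the black top-hat structuring
#'   element (px).
#' @param hair_binarize_thresh Threshold on the top-hat response
#'   (`[0,255]` scale, or `"otsu"`).
#' @param hair_min_elongation Minimum major/minor axis ratio of a hair.
#' @param hair_min_length Minimum hair major-axis length (px).
#' @param inpaint_radius Inpainting neighbourhood disc radius (px).
#' @param grow_tolerance Region-growing tolerance (intensity units), or
#'   `"auto"` for 0.1 x image intensity range.
#' @param grow_presmooth_sigma Optional Gaussian pre-smoothing before
#'   growing (px, 0 = off).
#' @param smooth_size Gaussian smoothing kernel size (odd, samples).
#' @param smooth_sigma Gaussian smoothing standard deviation (samples).
#' @param min_prominence Minimum turning-point prominence (px); 0 gives
#'   strict sign-change detection.
#' @param count_minima Also count concave notches (minima) as
#'   irregularities (off by default; the method counts maxima only).
#' @param radial_samples Angular samples of the radial baseline curve.
#' @param match_tol_frac Call-to-truth matching tolerance as a fraction
#'   of boundary length.
#' @return A validated list of class `border_config`.
#' @export
border_config <- function(frame_lightness_thresh = 15,
                          frame_black_fraction = 0.5,
                          frame_extra_rows = 10,
                          tophat_radius = 5,
                          hair_binarize_thresh = 20,
                          hair_min_elongation = 4,
                          hair_min_length = 30,
                          inpaint_radius = 5,
                          grow_tolerance = "auto",
                          grow_presmooth_sigma = 0,
                          smooth_size = 15,
                          smooth_sigma = 2.5,
                          min_prominence = 2,
                          count_minima = FALSE,
                          radial_samples = 360,
                          match_tol_frac = 0.02) {
  cfg <- list(frame_lightness_thresh = frame_lightness_thresh,
              frame_black_fraction = frame_black_fraction,
              frame_extra_rows = frame_extra_rows,
              tophat_radius = tophat_radius,
              hair_binarize_thresh = hair_binarize_thresh,
              hair_min_elongation = hair_min_elongation,
              hair_min_length = hair_min_length,
              inpaint_radius = inpaint_radius,
              grow_tolerance = grow_tolerance,
              grow_presmooth_sigma = grow_presmooth_sigma,
              smooth_size = smooth_size,
              smooth_sigma = smooth_sigma,
              min_prominence = min_prominence,
              count_minima = isTRUE(count_minima),
              radial_samples = radial_samples,
              match_tol_frac = match_tol_frac)
  validate_config(cfg)
  structure(cfg, class = "border_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid configuration: ", msg)
  chk(cfg$frame_lightness_thresh >= 0 && cfg$frame_lightness_thresh <= 255,
      "frame_lightness_thresh must be in [0, 255]")
  chk(cfg$frame_black_fraction > 0 && cfg$frame_black_fraction <= 1,
      "frame_black_fraction must be in (0, 1]")
  chk(cfg$frame_extra_rows >= 0, "frame_extra_rows must be >= 0")
  chk(cfg$tophat_radius >= 1, "tophat_radius must be >= 1")
  chk(identical(cfg$hair_binarize_thresh, "otsu") ||
        cfg$hair_binarize_thresh > 0, "hair_binarize_thresh must be > 0")
  chk(cfg$hair_min_elongation > 0, "hair_min_elongation must be > 0")
  chk(cfg$hair_min_length > 0, "hair_min_length must be > 0")
  chk(cfg$inpaint_radius >= 1, "inpaint_radius must be >= 1")
  chk(identical(cfg$grow_tolerance, "auto") ||
        (is.numeric(cfg$grow_tolerance) && cfg$grow_tolerance > 0),
      "grow_tolerance must be positive or \"auto\"")
  chk(cfg$grow_presmooth_sigma >= 0, "grow_presmooth_sigma must be >= 0")
  chk(cfg$smooth_size >= 3 && cfg$smooth_size %% 2 == 1,
      "smooth_size must be odd and >= 3")
  chk(cfg$smooth_sigma > 0, "smooth_sigma must be > 0")
  chk(cfg$min_prominence >= 0, "min_prominence must be >= 0")
  chk(cfg$radial_samples >= 8, "radial_samples must be >= 8")
  chk(cfg$match_tol_frac > 0 && cfg$match_tol_frac < 0.5,
      "match_tol_frac must be in (0, 0.5)")
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys in the file override the built-in defaults; explicit `...`
#' arguments override the file (defaults < file < call), mirroring the
#' command-line precedence.
#'
#' @param path YAML file of `key: value` pairs (keys as in
#'   [border_config()]).
#' @param ... Further overrides.
#' @return A validated `border_config`.
#' @export
border_config_from_yaml <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  dots <- list(...)
  vals[names(dots)] <- dots
  unknown <- setdiff(names(vals), names(formals(border_config)))
  if (length(unknown) > 0)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  do.call(border_config, vals)
}
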