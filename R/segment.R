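#' Seeded region growing of the healthy skin
#'
#' Best-first region growing from a single seed: a frontier of 4-connected
#' neighbours of the current region is maintained and the frontier pixel
#' whose intensity is closest to the running region mean is admitted,
#' updating the mean, while that difference does not exceed `tolerance`.
#' Ties are broken by row-major scan order, so the result is deterministic.
#' The grower is intended to flood the homogeneous healthy skin starting
#' from a corner seed; the lesion is whatever remains unallocated.
#'
#' @param gray `H x W` numeric matrix (hair-free grayscale image).
#' @param seed Integer `(row, col)` seed, 1-based. Default `c(1, 1)`, the
#'   upper-left corner.
#' @param tolerance Maximum allowed absolute difference between a pixel's
#'   intensity and the region mean. `NULL` (default) uses
#'   `0.1 * diff(range(gray))`.
#' @param presmooth_sigma Optional Gaussian pre-smoothing of the intensity
#'   image before growing (standard deviation in pixels); `NULL` or 0
#'   disables it (the default).
#' @return Logical `H x W` mask of the grown (healthy-skin) region.
#' @export
region_grow <- function(gray, seed = c(1L, 1L), tolerance = NULL,
                        presmooth_sigma = NULL) {
  stopifnot(is.matrix(gray))
  seed <- as.integer(seed)
  if (seed[1] < 1L || seed[1] > nrow(gray) ||
      seed[2] < 1L || seed[2] > ncol(gray))
    stop("seed outside image")
  if (is.null(tolerance)) tolerance <- 0.1 * diff(range(gray))
  stopifnot(tolerance >= 0)
  if (!is.null(presmooth_sigma) && presmooth_sigma > 0) {
    gray <- EBImage::gblur(gray, sigma = presmooth_sigma)
  }
  rg_grow_cpp(gray, seed[1] - 1L, seed[2] - 1L, tolerance)
}

#' Extract the lesion mask from the healthy-skin mask
#'
#' The lesion candidate is the complement of the healthy-skin region.
#' The largest 4-connected component is kept, interior holes (background
#' components not reaching the image border, 4-connectivity) are filled,
#' and a warning is emitted if the lesion touches the image edge, since
#' the borderline construction assumes the lesion lies fully inside the
#' image.
#'
#' @param healthy Logical `H x W` healthy-skin mask.
#' @return Logical `H x W` lesion mask with attributes `area` and
#'   `centroid` (`(row, col)`, 1-based, real-valued).
#' @export
extract_lesion <- function(healthy) {
  stopifnot(is.matrix(healthy))
  if (!any(healthy) || all(healthy))
    stop("healthy-skin mask must be non-empty and not cover the image")
  cand <- !healthy
  lab <- cc_label_cpp(cand, 4L)
  sizes <- tabulate(lab[lab > 0L])
  if (length(sizes) == 0L) stop("no lesion found: complement is empty")
  lesion <- lab == which.max(sizes)
  lesion <- fill_holes4(lesion)
  if (any(lesion[1, ]) || any(lesion[nrow(lesion), ]) ||
      any(lesion[, 1]) || any(lesion[, ncol(lesion)]))
    warning("lesion touches the image boundary; ",
            "border assessment assumes an interior lesion")
  attr(lesion, "area") <- sum(lesion)
  attr(lesion, "centroid") <- mask_centroid(lesion)
  lesion
}

# Fill interior holes: background components (4-connectivity) that do not
# touch the image border become foreground.
fill_holes4 <- function(mask) {
  bg <- !mask
  lab <- cc_label_cpp(bg, 4L)
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ],
                            lab[, 1], lab[, ncol(lab)]))
  border_labels <- border_labels[border_labels > 0L]
  mask | (lab > 0L & !(lab %in% border_labels))
}

#' Centroid of a binary mask
#'
#' @param mask Logical matrix.
#' @return Numeric `(row, col)`, 1-based.
#' @export
mask_centroid <- function(mask) {
  idx <- which(mask)
  r <- (idx - 1L) %% nrow(mask) + 1L
  c <- (idx - 1L) %/% nrow(mask) + 1L
  c(mean(r), mean(c))
}

#' Segment the lesion from a preprocessed grayscale image
#'
#' Grows the healthy skin from the upper-left corner seed (sliding along
#' the top row to the first artifact-free pixel if the corner still shows
#' a strong top-hat response) and extracts the lesion as the complement.
#'
#' @param gray `H x W` hair-free grayscale image on the `[0, 255]` scale.
#' @param config Pipeline configuration, see [border_config()].
#' @return Logical lesion mask (see [extract_lesion()]) with attribute
#'   `healthy`, the grown healthy-skin mask.
#' @export
segment_lesion <- function(gray, config = border_config()) {
  tol <- config$grow_tolerance
  if (is.character(tol) && tol == "auto") tol <- NULL
  tol_eff <- if (is.null(tol)) 0.1 * diff(range(gray)) else tol
  # upper-left corner seed, slid along the top row past residual
  # artifacts (top-hat response) or single-pixel noise outliers (far
  # from the top-row median), so growth starts on representative skin
  th <- black_tophat(gray, selem_radius = config$tophat_radius)
  med_top <- stats::median(gray[1, ])
  clean <- th[1, ] <= (if (identical(config$hair_binarize_thresh, "otsu"))
    20 else config$hair_binarize_thresh) &
    abs(gray[1, ] - med_top) <= tol_eff / 2
  seed <- c(1L, if (any(clean)) which(clean)[1] else 1L)
  healthy <- region_grow(gray, seed = seed, tolerance = tol,
                         presmooth_sigma = config$grow_presmooth_sigma)
  lesion <- extract_lesion(healthy)
  attr(lesion, "healthy") <- healthy
  lesion
}

#' Jaccard index between two masks
#'
#' Intersection over union of two binary masks of equal shape.
#'
#' @param a,b Logical matrices.
#' @return A number in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
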