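#' HSL lightness of an RGB image
#'
#' Computes the lightness component of the HSL colour space,
#' `L = (max(R, G, B) + min(R, G, B)) / 2`, used to decide which pixels
#' count as "black" when locating the digitization frame.
#'
#' @param img `H x W x 3` array with channels in `[0, 255]`.
#' @return `H x W` numeric matrix in `[0, 255]`.
#' @export
compute_lightness <- function(img) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  (pmax(img[, , 1], img[, , 2], img[, , 3]) +
     pmin(img[, , 1], img[, , 2], img[, , 3])) / 2
}

#' NTSC 1953 grayscale conversion
#'
#' Luma conversion `0.299 R + 0.587 G + 0.114 B` used before hair
#' detection and segmentation.
#'
#' @inheritParams compute_lightness
#' @return `H x W` numeric matrix in `[0, 255]`.
#' @export
to_grayscale_ntsc <- function(img) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Remove the black digitization frame
#'
#' Some dermatoscopes introduce a black frame around the image. Scanning
#' inward from each of the four sides, consecutive rows (columns for the
#' left/right sides) whose fraction of black pixels (HSL lightness below
#' `lightness_thresh`) is at least `black_row_fraction` are labelled as
#' frame. Each qualifying side's frame band, plus `extra_rows` additional
#' rows/columns covering the lighter inner rim of the frame, is removed.
#' Sides with no qualifying edge row are left untouched. Interior dark
#' rows are never removed: scanning stops at the first non-qualifying
#' row/column.
#'
#' @param img `H x W x 3` array with channels in `[0, 255]`.
#' @param lightness_thresh Lightness below which a pixel is black
#'   (default 15 on the `[0, 255]` scale).
#' @param black_row_fraction Minimum fraction of black pixels for a
#'   row/column to be part of the frame (default 0.5).
#' @param extra_rows Additional rows/columns removed past the detected
#'   band on each qualifying side (default 10).
#' @return A list with `image` (cropped array) and `crop`, a one-row
#'   tibble with `rows_removed_top`, `rows_removed_bottom`,
#'   `cols_removed_left`, `cols_removed_right`.
#' @export
remove_black_frame <- function(img, lightness_thresh = 15,
                               black_row_fraction = 0.5, extra_rows = 10) {
  L <- compute_lightness(img)
  black <- L < lightness_thresh
  H <- nrow(black); W <- ncol(black)

  scan_band <- function(fracs) {
    n <- 0L
    for (f in fracs) {
      if (f >= black_row_fraction) n <- n + 1L else break
    }
    if (n > 0L) n + as.integer(extra_rows) else 0L
  }
  row_frac <- rowMeans(black)
  col_frac <- colMeans(black)
  top <- scan_band(row_frac)
  bottom <- scan_band(rev(row_frac))
  left <- scan_band(col_frac)
  right <- scan_band(rev(col_frac))

  if (top + bottom >= H || left + right >= W)
    stop("frame removal would leave an empty image ",
         "(all-black or frame-dominated input)")
  crop <- tibble::tibble(
    rows_removed_top = top, rows_removed_bottom = bottom,
    cols_removed_left = left, cols_removed_right = right
  )
  out <- img[(top + 1L):(H - bottom), (left + 1L):(W - right), , drop = FALSE]
  list(image = out, crop = crop)
}

#' Black top-hat transform
#'
#' Morphological closing with a disc structuring element minus the input:
#' responds strongly to dark structures thinner than the disc, such as
#' thick hairs, and is zero on locally flat or wide regions.
#'
#' @param gray `H x W` matrix on the `[0, 255]` scale.
#' @param selem_radius Disc radius in pixels (default 5).
#' @return `H x W` non-negative matrix.
#' @export
black_tophat <- function(gray, selem_radius = 5) {
  stopifnot(selem_radius >= 1)
  kern <- EBImage::makeBrush(2L * as.integer(selem_radius) + 1L, "disc")
  # EBImage grayscale morphology clips to [0, 1]; work on the unit scale
  closed <- EBImage::closing(gray / 255, kern) * 255
  out <- closed - gray
  out[out < 0] <- 0  # guard against numeric fuzz; closing is extensive
  out
}

#' Detect dark thick hairs from a top-hat response
#'
#' Binarizes the black top-hat response, labels connected components and
#' keeps only elongated ones: a component is a hair iff its moment-derived
#' major axis is at least `min_length` pixels and the major/minor axis
#' ratio is at least `min_elongation`. This discriminates hairs from
#' compact dark structures (dots, globules). Component perimeters are
#' measured and attached as an attribute for diagnostics but play no role
#' in the decision.
#'
#' @param tophat Non-negative `H x W` matrix (output of [black_tophat()]).
#' @param binarize_thresh Absolute threshold on the `[0, 255]` scale
#'   (default 20), or `"otsu"` for Otsu's threshold on the response.
#' @param min_elongation Minimum major/minor axis ratio (default 4).
#' @param min_length Minimum major axis length in pixels (default 30).
#' @return Logical `H x W` hair mask with attribute `components`, a tibble
#'   of per-component shape measurements.
#' @export
detect_hairs <- function(tophat, binarize_thresh = 20, min_elongation = 4,
                         min_length = 30) {
  thr <- if (identical(binarize_thresh, "otsu")) {
    EBImage::otsu(EBImage::Image(tophat / 255), range = c(0, 1)) * 255
  } else {
    binarize_thresh
  }
  stopifnot(thr > 0, min_elongation > 0, min_length > 0)
  bin <- tophat > thr
  mask <- matrix(FALSE, nrow(tophat), ncol(tophat))
  if (!any(bin)) {
    attr(mask, "components") <- component_shapes(matrix(0L, 1, 1))[0, ]
    return(mask)
  }
  lab <- cc_label_cpp(bin, 8L)
  comp <- component_shapes(lab)
  comp$is_hair <- comp$elongation >= min_elongation &
    comp$major_axis >= min_length
  keep <- comp$label[comp$is_hair]
  mask <- matrix(lab %in% keep, nrow(lab), ncol(lab))
  attr(mask, "components") <- comp
  mask
}

# Moment-based shape measurements per labelled component. Axis lengths use
# the uniform-ellipse convention (axis = 4 * sqrt(eigenvalue of the pixel
# covariance)), so a disc of radius r measures major ~ minor ~ 2r and a
# thin stroke of length l measures major ~ 1.15 l.
component_shapes <- function(lab) {
  idx <- which(lab > 0L)
  if (length(idx) == 0L) {
    return(tibble::tibble(label = integer(), area = integer(),
                          major_axis = numeric(), minor_axis = numeric(),
                          elongation = numeric(), perimeter = integer()))
  }
  l <- lab[idx]
  r <- (idx - 1L) %% nrow(lab)
  c <- (idx - 1L) %/% nrow(lab)
  n <- as.vector(rowsum(rep(1, length(l)), l))
  labs <- sort(unique(l))
  mr <- as.vector(rowsum(r, l)) / n
  mc <- as.vector(rowsum(c, l)) / n
  key <- match(l, labs)
  vr <- as.vector(rowsum((r - mr[key])^2, l)) / n
  vc <- as.vector(rowsum((c - mc[key])^2, l)) / n
  vrc <- as.vector(rowsum((r - mr[key]) * (c - mc[key]), l)) / n
  tr <- vr + vc
  det <- vr * vc - vrc^2
  disc <- pmax(tr^2 / 4 - det, 0)
  lam1 <- tr / 2 + sqrt(disc)
  lam2 <- pmax(tr / 2 - sqrt(disc), 0)
  major <- 4 * sqrt(lam1)
  minor <- 4 * sqrt(lam2)
  # 4-connected boundary pixel count, a cheap perimeter proxy (diagnostic)
  fg <- lab > 0L
  pad <- rbind(FALSE, cbind(FALSE, fg, FALSE), FALSE)
  hpad <- nrow(pad)
  inner <- pad[2:(hpad - 1), 2:(ncol(pad) - 1)]
  bnd <- inner & !(pad[1:(hpad - 2), 2:(ncol(pad) - 1)] &
                     pad[3:hpad, 2:(ncol(pad) - 1)] &
                     pad[2:(hpad - 1), 1:(ncol(pad) - 2)] &
                     pad[2:(hpad - 1), 3:ncol(pad)])
  per <- as.vector(rowsum(as.numeric(bnd[idx]), l))
  tibble::tibble(label = labs, area = as.integer(n), major_axis = major,
                 minor_axis = minor,
                 elongation = major / pmax(minor, 1),
                 perimeter = as.integer(per))
}

#' Inpaint hair pixels by neighbourhood averaging
#'
#' Every masked pixel is replaced, per channel, by the mean of non-hair
#' pixels within a disc of radius `neighborhood_radius`. Pixels deep
#' inside a thick hair that have no clean neighbour in the first pass are
#' filled iteratively from the mask boundary inward, so the operation is
#' total for any mask that does not cover the whole image. Pixels outside
#' the mask are returned bit-identical.
#'
#' @param img `H x W x 3` array (or `H x W` matrix) on the `[0, 255]` scale.
#' @param hairs Logical `H x W` hair mask.
#' @param neighborhood_radius Disc radius in pixels (default 5).
#' @return Array/matrix of the same shape as `img`.
#' @export
inpaint_hairs <- function(img, hairs, neighborhood_radius = 5) {
  is_rgb <- length(dim(img)) == 3L
  dims <- if (is_rgb) dim(img)[1:2] else dim(img)
  stopifnot(all(dims == dim(hairs)))
  if (!any(hairs)) return(img)
  if (all(hairs)) stop("hair mask covers the entire image: no donor pixels")
  kern <- EBImage::makeBrush(2L * as.integer(neighborhood_radius) + 1L, "disc")
  out <- if (is_rgb) img else array(img, c(dims, 1L))
  out <- out * 1.0
  remaining <- hairs
  while (any(remaining)) {
    clean <- !remaining
    cnt <- EBImage::filter2(matrix(as.numeric(clean), dims[1], dims[2]),
                            kern, boundary = 0)
    fillable <- remaining & (cnt > 1e-6)
    if (!any(fillable)) stop("inpainting cannot progress")  # unreachable
    for (ch in seq_len(dim(out)[3])) {
      plane <- out[, , ch]
      plane[remaining] <- 0
      s <- EBImage::filter2(plane, kern, boundary = 0)
      vals <- s[fillable] / cnt[fillable]
      plane <- out[, , ch]
      plane[fillable] <- vals
      out[, , ch] <- plane
    }
    remaining <- remaining & !fillable
  }
  if (!is_rgb) out <- out[, , 1]
  # untouched pixels must be exactly the input
  if (is_rgb) out[!array(hairs, dim(out) ) ] <- img[!array(hairs, dim(out))]
  else out[!hairs] <- img[!hairs]
  out
}

#' Full preprocessing stage
#'
#' Removes the black digitization frame, then detects and inpaints dark
#' thick hairs, producing an artifact-free image for segmentation.
#'
#' @param img `H x W x 3` array with channels in `[0, 255]`.
#' @param config Pipeline configuration, see [border_config()].
#' @return A list with `image` (cleaned RGB array), `gray` (NTSC grayscale
#'   of the cleaned image), `crop` (frame crop record) and `hair_mask`.
#' @export
preprocess_image <- function(img, config = border_config()) {
  fr <- remove_black_frame(img,
                           lightness_thresh = config$frame_lightness_thresh,
                           black_row_fraction = config$frame_black_fraction,
                           extra_rows = config$frame_extra_rows)
  gray <- to_grayscale_ntsc(fr$image)
  th <- black_tophat(gray, selem_radius = config$tophat_radius)
  hairs <- detect_hairs(th,
                        binarize_thresh = config$hair_binarize_thresh,
                        min_elongation = config$hair_min_elongation,
                        min_length = config$hair_min_length)
  clean <- if (any(hairs)) {
    inpaint_hairs(fr$image, hairs,
                  neighborhood_radius = config$inpaint_radius)
  } else {
    fr$image
  }
  list(image = clean, gray = to_grayscale_ntsc(clean),
       crop = fr$crop, hair_mask = hairs)
}
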