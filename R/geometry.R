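# Raster convention used throughout: x = column (right), y = row (down),
# origin top-left, 1-based pixel centres. A rotation by theta acts on
# (x, y) with the matrix [cos -sin; sin cos], i.e. positive theta turns
# +x toward +y (clockwise on screen).

#' Principal-axis angle of a lesion mask
#'
#' Computes the orientation of the mask's major axis from central second
#' moments and returns the rotation angle that makes the major axis
#' horizontal. With `mu_pq` the central moments in (x, y) = (col, row)
#' coordinates, the axis orientation is
#' `alpha = atan2(2 mu11, mu20 - mu02) / 2` and the returned rotation is
#' `theta = -alpha`, normalised into `(-pi/2, pi/2]`. A mask whose two
#' axes are equal within tolerance (e.g. a disc) returns 0.
#'
#' @param mask Logical matrix with at least 3 foreground pixels.
#' @return Angle in radians in `(-pi/2, pi/2]`.
#' @export
principal_axis_angle <- function(mask) {
  idx <- which(mask)
  if (length(idx) < 3L) stop("mask area must be at least 3 pixels")
  y <- (idx - 1L) %% nrow(mask)
  x <- (idx - 1L) %/% nrow(mask)
  mu20 <- mean((x - mean(x))^2)
  mu02 <- mean((y - mean(y))^2)
  mu11 <- mean((x - mean(x)) * (y - mean(y)))
  if (abs(mu11) < 1e-6 && abs(mu20 - mu02) < 1e-6) return(0)
  if (mu20 < 1e-12 && mu02 < 1e-12) stop("degenerate mask: zero second moments")
  alpha <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  theta <- -alpha
  if (theta <= -pi / 2) theta <- theta + pi
  if (theta > pi / 2) theta <- theta - pi
  theta
}

#' Build a rotation record for a lesion
#'
#' Describes the rotation that aligns the lesion's major axis with the
#' horizontal: angle, rotation centre (the lesion centroid, so the lesion
#' stays inside the enlarged canvas), and an output canvas expanded to
#' contain the fully rotated input with no clipping. The record carries
#' everything needed to map coordinates between the two frames.
#'
#' @param mask Logical lesion mask.
#' @param angle Rotation angle in radians; `NULL` (default) uses
#'   [principal_axis_angle()] of `mask`.
#' @return An object of class `rotation_record`: list with `theta`,
#'   `center` (row, col), `qmin` (canvas origin offsets), `in_dim`,
#'   `out_dim`.
#' @export
make_rotation <- function(mask, angle = NULL) {
  if (is.null(angle)) angle <- principal_axis_angle(mask)
  ctr <- mask_centroid(mask)  # (row, col)
  H <- nrow(mask); W <- ncol(mask)
  cx <- ctr[2]; cy <- ctr[1]
  corners_x <- c(1, W, 1, W) - cx
  corners_y <- c(1, 1, H, H) - cy
  qx <- cos(angle) * corners_x - sin(angle) * corners_y
  qy <- sin(angle) * corners_x + cos(angle) * corners_y
  qxmin <- floor(min(qx)); qxmax <- ceiling(max(qx))
  qymin <- floor(min(qy)); qymax <- ceiling(max(qy))
  structure(list(theta = angle, center = ctr,
                 qmin = c(qymin, qxmin),
                 in_dim = c(H, W),
                 out_dim = c(qymax - qymin + 1L, qxmax - qxmin + 1L)),
            class = "rotation_record")
}

#' Rotate a raster into the aligned frame
#'
#' Resamples a grayscale image, RGB image or binary mask into the rotated
#' canvas described by a [make_rotation()] record. Continuous rasters use
#' bilinear interpolation (each output pixel is the weighted average of
#' the nearest 2 x 2 source pixels) with border replication outside the
#' source; binary masks use nearest-neighbour sampling and are filled with
#' background (healthy skin) outside the source.
#'
#' @param x `H x W` matrix, `H x W x 3` array, or logical matrix.
#' @param rec A `rotation_record`.
#' @param interpolation `"bilinear"` (default for numeric rasters) or
#'   `"nearest"` (always used for logical masks).
#' @return Rotated raster of dimension `rec$out_dim`.
#' @export
rotate_raster <- function(x, rec, interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  is_mask <- is.logical(x)
  if (is_mask) interpolation <- "nearest"
  if (length(dim(x)) == 3L) {
    out <- array(0, c(rec$out_dim, dim(x)[3]))
    for (ch in seq_len(dim(x)[3]))
      out[, , ch] <- rotate_raster(x[, , ch], rec, interpolation)
    return(out)
  }
  Ho <- rec$out_dim[1]; Wo <- rec$out_dim[2]
  H <- rec$in_dim[1]; W <- rec$in_dim[2]
  qx <- matrix(rep(seq_len(Wo) - 1 + rec$qmin[2], each = Ho), Ho, Wo)
  qy <- matrix(rep(seq_len(Ho) - 1 + rec$qmin[1], times = Wo), Ho, Wo)
  th <- -rec$theta  # inverse rotation
  px <- cos(th) * qx - sin(th) * qy + rec$center[2]
  py <- sin(th) * qx + cos(th) * qy + rec$center[1]
  if (interpolation == "nearest") {
    ir <- round(py); ic <- round(px)
    inside <- ir >= 1 & ir <= H & ic >= 1 & ic <= W
    out <- matrix(if (is_mask) FALSE else 0, Ho, Wo)
    vals <- x[cbind(pmin(pmax(ir[inside], 1), H),
                    pmin(pmax(ic[inside], 1), W))]
    out[inside] <- vals
    if (!is_mask) {
      # border replication for continuous rasters sampled outside
      out[!inside] <- x[cbind(pmin(pmax(ir[!inside], 1), H),
                              pmin(pmax(ic[!inside], 1), W))]
    }
    return(out)
  }
  x0 <- floor(px); y0 <- floor(py)
  fx <- px - x0; fy <- py - y0
  cx0 <- pmin(pmax(x0, 1), W); cx1 <- pmin(pmax(x0 + 1, 1), W)
  cy0 <- pmin(pmax(y0, 1), H); cy1 <- pmin(pmax(y0 + 1, 1), H)
  g <- function(rr, cc) matrix(x[cbind(as.vector(rr), as.vector(cc))], Ho, Wo)
  (1 - fx) * (1 - fy) * g(cy0, cx0) + fx * (1 - fy) * g(cy0, cx1) +
    (1 - fx) * fy * g(cy1, cx0) + fx * fy * g(cy1, cx1)
}

#' Map rotated-frame coordinates back to the raw input image
#'
#' Applies the inverse rotation and then the frame-crop offsets, giving
#' real-valued coordinates in the original (uncropped) image.
#'
#' @param coords Two-column matrix or data frame of `(row, col)` in the
#'   rotated frame (1-based).
#' @param rec A `rotation_record`.
#' @param crop Optional crop record (one-row data frame from
#'   [remove_black_frame()]); `NULL` means no crop offset.
#' @return Tibble with real-valued `row`, `col` in the raw image frame.
#' @export
map_to_original <- function(coords, rec, crop = NULL) {
  coords <- as.matrix(coords)
  qy <- coords[, 1] - 1 + rec$qmin[1]
  qx <- coords[, 2] - 1 + rec$qmin[2]
  th <- -rec$theta
  px <- cos(th) * qx - sin(th) * qy + rec$center[2]
  py <- sin(th) * qx + cos(th) * qy + rec$center[1]
  off_r <- if (is.null(crop)) 0 else crop$rows_removed_top
  off_c <- if (is.null(crop)) 0 else crop$cols_removed_left
  tibble::tibble(row = py + off_r, col = px + off_c)
}

#' Map original-frame coordinates into the rotated frame
#'
#' Forward companion of [map_to_original()].
#'
#' @inheritParams map_to_original
#' @param coords Two-column matrix or data frame of `(row, col)` in the
#'   raw image frame.
#' @return Tibble with real-valued `row`, `col` in the rotated frame.
#' @export
map_from_original <- function(coords, rec, crop = NULL) {
  coords <- as.matrix(coords)
  off_r <- if (is.null(crop)) 0 else crop$rows_removed_top
  off_c <- if (is.null(crop)) 0 else crop$cols_removed_left
  x <- coords[, 2] - off_c - rec$center[2]
  y <- coords[, 1] - off_r - rec$center[1]
  qx <- cos(rec$theta) * x - sin(rec$theta) * y
  qy <- sin(rec$theta) * x + cos(rec$theta) * y
  tibble::tibble(row = qy - rec$qmin[1] + 1, col = qx - rec$qmin[2] + 1)
}
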