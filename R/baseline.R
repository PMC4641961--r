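#' Radial (centroid) distance curve
#'
#' The classical baseline contour signature: for uniformly spaced angles,
#' the distance from the lesion centroid to the outermost boundary
#' crossing along the ray at that angle. For non-round lesions a ray may
#' cross the boundary several times; the per-angle crossing count is
#' reported alongside, surfacing the known failure mode of this
#' signature (everything radially inside the outermost crossing is
#' invisible to it).
#'
#' @param mask Logical lesion mask; the centroid must lie inside it.
#' @param n_samples Number of uniformly spaced angles (default 360).
#' @return Tibble with `angle` (radians, screen convention: x right,
#'   y down), `distance` (pixels), `crossings` (number of inside-to-
#'   outside transitions along the ray) and `row`, `col` of the outermost
#'   crossing point.
#' @export
radial_distance_curve <- function(mask, n_samples = 360) {
  ctr <- mask_centroid(mask)
  if (!mask[round(ctr[1]), round(ctr[2])])
    stop("centroid lies outside the mask")
  H <- nrow(mask); W <- ncol(mask)
  angles <- (seq_len(n_samples) - 1L) / n_samples * 2 * pi
  rmax <- sqrt(H^2 + W^2)
  rs <- seq(0, rmax, by = 0.5)
  co <- cos(angles); si <- sin(angles)
  # n_samples x length(rs) grids of sample coordinates
  X <- outer(co, rs) + ctr[2]
  Y <- outer(si, rs) + ctr[1]
  ir <- round(Y); ic <- round(X)
  ok <- ir >= 1 & ir <= H & ic >= 1 & ic <= W
  inside <- matrix(FALSE, n_samples, length(rs))
  inside[ok] <- mask[cbind(ir[ok], ic[ok])]
  out_step <- inside[, -ncol(inside), drop = FALSE] &
    !inside[, -1, drop = FALSE]
  dist <- numeric(n_samples); ncross <- integer(n_samples)
  rowi <- numeric(n_samples); coli <- numeric(n_samples)
  mid <- (rs[-length(rs)] + rs[-1]) / 2
  for (i in seq_len(n_samples)) {
    w <- which(out_step[i, ])
    ncross[i] <- length(w)
    d <- if (length(w) > 0) mid[max(w)] else 0
    dist[i] <- d
    rowi[i] <- ctr[1] + d * si[i]
    coli[i] <- ctr[2] + d * co[i]
  }
  tibble::tibble(angle = angles, distance = dist, crossings = ncross,
                 row = rowi, col = coli)
}

#' Detect irregularities on the radial distance curve
#'
#' Baseline detector: smooths the (periodic) radial distance curve with
#' the same Gaussian filter used for the borderline function and calls
#' turning points with circular boundary handling. Calls carry the image
#' coordinates of the outermost boundary crossing at their angle.
#'
#' @param mask Logical lesion mask.
#' @param config Pipeline configuration, see [border_config()].
#' @return Tibble of calls with `index`, `angle`, `value`, `prominence`,
#'   `row`, `col`; attribute `curve` holds the full radial curve.
#' @export
detect_irregularities_radial <- function(mask, config = border_config()) {
  curve <- radial_distance_curve(mask, n_samples = config$radial_samples)
  sm <- gaussian_smooth(curve$distance, size = config$smooth_size,
                        sigma = config$smooth_sigma, circular = TRUE)
  calls <- detect_turning_points(sm, min_prominence = config$min_prominence,
                                 circular = TRUE)
  calls$angle <- curve$angle[calls$index]
  calls$row <- curve$row[calls$index]
  calls$col <- curve$col[calls$index]
  attr(calls, "curve") <- curve
  calls
}
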