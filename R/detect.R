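#' Sampled normalized Gaussian kernel
#'
#' Discrete 1-D Gaussian `exp(-x^2 / (2 sigma^2))` sampled at integer
#' offsets and renormalized to sum exactly to 1.
#'
#' @param size Odd kernel length, at least 3 (default 15).
#' @param sigma Standard deviation in samples (default 2.5).
#' @return Numeric vector of length `size` summing to 1.
#' @export
gaussian_kernel <- function(size = 15, sigma = 2.5) {
  size <- as.integer(size)
  stopifnot(size >= 3L, size %% 2L == 1L, sigma > 0)
  m <- (size - 1L) %/% 2L
  x <- (-m):m
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

#' Gaussian smoothing of a 1-D signal
#'
#' Convolves the signal with the sampled, renormalized Gaussian kernel.
#' Boundaries are handled by edge replication for open signals and by
#' circular (periodic) padding when `circular = TRUE` (used for the
#' radial distance curve, which is periodic in angle). For a
#' `borderline_signal` the junction indices and other attributes are
#' carried over.
#'
#' @param x Numeric vector or `borderline_signal`.
#' @param size,sigma Kernel parameters, see [gaussian_kernel()].
#' @param circular Treat the signal as periodic (default `FALSE`).
#' @return Same type as `x`.
#' @export
gaussian_smooth <- function(x, size = 15, sigma = 2.5, circular = FALSE) {
  UseMethod("gaussian_smooth")
}

#' @export
gaussian_smooth.default <- function(x, size = 15, sigma = 2.5,
                                    circular = FALSE) {
  w <- gaussian_kernel(size, sigma)
  m <- (length(w) - 1L) %/% 2L
  n <- length(x)
  if (n < length(w))
    stop("signal shorter than the smoothing kernel (", n, " < ", size, ")")
  pad <- if (circular) {
    c(x[(n - m + 1L):n], x, x[1:m])
  } else {
    c(rep(x[1], m), x, rep(x[n], m))
  }
  out <- numeric(n)
  for (j in seq_along(w)) out <- out + w[j] * pad[j:(j + n - 1L)]
  out
}

#' @export
gaussian_smooth.borderline_signal <- function(x, size = 15, sigma = 2.5,
                                              circular = FALSE) {
  x$value <- gaussian_smooth(x$value, size = size, sigma = sigma,
                             circular = circular)
  attr(x, "smoothed") <- c(size = size, sigma = sigma)
  x
}

# Prominence of a peak: height above the higher of the two lowest points
# separating it from higher terrain (or the signal ends).
peak_prominence <- function(v, i) {
  n <- length(v)
  lo_l <- v[i]; j <- i - 1L
  while (j >= 1L && v[j] <= v[i]) { if (v[j] < lo_l) lo_l <- v[j]; j <- j - 1L }
  lo_r <- v[i]; j <- i + 1L
  while (j <= n && v[j] <= v[i]) { if (v[j] < lo_r) lo_r <- v[j]; j <- j + 1L }
  v[i] - max(lo_l, lo_r)
}

#' Detect turning points (border irregularities) in a signal
#'
#' A turning point is an index where the discrete derivative changes sign
#' from positive to negative: `d[i-1] > 0` and `d[i] < 0` with
#' `d[i] = v[i+1] - v[i]`. Plateaus (runs of zero derivative bounded by a
#' positive then a negative step) yield a single call at the plateau
#' midpoint (floor). Calls whose prominence falls below `min_prominence`
#' are discarded; set `min_prominence = 0` for the strict
#' sign-change-only behaviour. Endpoints are never called. With
#' `circular = TRUE` the signal is treated as periodic (the index of the
#' global minimum anchors the cut, so no peak is lost at the wrap).
#'
#' @param x Numeric vector or `borderline_signal` (already smoothed).
#' @param min_prominence Minimum peak prominence in signal units
#'   (default 2).
#' @param circular Treat the signal as periodic (default `FALSE`).
#' @return Tibble with `index`, `value`, `prominence`; for a
#'   `borderline_signal` input also `row`, `col`, `segment`.
#' @export
detect_turning_points <- function(x, min_prominence = 2, circular = FALSE) {
  UseMethod("detect_turning_points")
}

#' @export
detect_turning_points.default <- function(x, min_prominence = 2,
                                          circular = FALSE) {
  v <- as.numeric(x)
  n <- length(v)
  if (circular && n >= 3L) {
    s <- which.min(v)
    w <- v[c(s:n, seq_len(s - 1L))]
    calls <- detect_turning_points.default(w, min_prominence, circular = FALSE)
    calls$index <- (calls$index + s - 2L) %% n + 1L
    calls <- calls[order(calls$index), , drop = FALSE]
    rownames(calls) <- NULL
    return(calls)
  }
  empty <- tibble::tibble(index = integer(), value = numeric(),
                          prominence = numeric())
  if (n < 3L) return(empty)
  d <- diff(v)
  nz <- which(d != 0)
  if (length(nz) < 2L) return(empty)
  idx <- integer(0)
  for (t in seq_len(length(nz) - 1L)) {
    p <- nz[t]; q <- nz[t + 1L]
    if (d[p] > 0 && d[q] < 0) idx <- c(idx, (p + 1L + q) %/% 2L)
  }
  if (length(idx) == 0L) return(empty)
  prom <- vapply(idx, function(i) peak_prominence(v, i), numeric(1))
  keep <- prom >= min_prominence
  tibble::tibble(index = idx[keep], value = v[idx[keep]],
                 prominence = prom[keep])
}

#' @export
detect_turning_points.borderline_signal <- function(x, min_prominence = 2,
                                                    circular = FALSE) {
  calls <- detect_turning_points.default(x$value, min_prominence, circular)
  calls$row <- x$row[calls$index]
  calls$col <- x$col[calls$index]
  calls$segment <- x$segment[calls$index]
  calls
}

#' ABCD border score from irregularity calls
#'
#' Divides the borderline signal domain into 8 equal-length octants and
#' counts those containing at least one irregularity call, giving the
#' border component B (0-8) of the ABCD rule.
#'
#' @param calls Tibble of calls with an `index` column (or an integer
#'   vector of call indices).
#' @param signal_length Length of the borderline signal.
#' @return Integer in `0:8`.
#' @export
border_score <- function(calls, signal_length) {
  idx <- if (is.data.frame(calls)) calls$index else as.integer(calls)
  stopifnot(signal_length >= 1L)
  if (length(idx) == 0L) return(0L)
  oct <- pmin(floor((idx - 1L) * 8 / signal_length), 7)
  min(length(unique(oct)), 8L)
}

#' Total dermoscopy score (TDS) and classification
#'
#' ABCD rule arithmetic: `TDS = 1.3 A + 0.1 B + 0.5 C + 0.5 D` with
#' asymmetry A in 0-2, border B in 0-8, colours C in 1-6 and differential
#' structures D in 1-5. A TDS below 4.75 indicates a benign melanocytic
#' lesion, values above 5.45 are highly suspicious, and everything in
#' between (including the 4.75-4.8 band the thresholds leave unnamed) is
#' classified as suspicious.
#'
#' @param A,B,C,D Integer component scores (vectors recycle).
#' @return Tibble with `A`, `B`, `C`, `D`, `tds`, `classification`
#'   (factor: benign, suspicious, highly_suspicious).
#' @export
tds_score <- function(A, B, C, D) {
  if (any(A != round(A)) || any(A < 0) || any(A > 2))
    stop("A (asymmetry) must be an integer in 0..2")
  if (any(B != round(B)) || any(B < 0) || any(B > 8))
    stop("B (border) must be an integer in 0..8")
  if (any(C != round(C)) || any(C < 1) || any(C > 6))
    stop("C (colour) must be an integer in 1..6")
  if (any(D != round(D)) || any(D < 1) || any(D > 5))
    stop("D (differential structures) must be an integer in 1..5")
  tds <- 1.3 * A + 0.1 * B + 0.5 * C + 0.5 * D
  cls <- ifelse(tds < 4.75, "benign",
                ifelse(tds > 5.45, "highly_suspicious", "suspicious"))
  tibble::tibble(A = as.integer(A), B = as.integer(B), C = as.integer(C),
                 D = as.integer(D), tds = tds,
                 classification = factor(cls, levels = c(
                   "benign", "suspicious", "highly_suspicious")))
}

#' @rdname tds_score
#' @export
classify_tds <- function(A, B, C, D) {
  as.character(tds_score(A, B, C, D)$classification)
}
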