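# Small raster fixtures built in code, shared across test files.

disc_mask <- function(r, pad = 6L) {
  n <- 2L * (r + pad) + 1L
  ctr <- r + pad + 1L
  dx <- matrix(rep(seq_len(n) - ctr, each = n), n, n)
  dy <- matrix(seq_len(n) - ctr, n, n)
  dx^2 + dy^2 <= r^2
}

ellipse_mask <- function(a, b, phi = 0, pad = 8L) {
  n <- 2L * (max(a, b) + pad) + 1L
  ctr <- max(a, b) + pad + 1L
  dx <- matrix(rep(seq_len(n) - ctr, each = n), n, n)
  dy <- matrix(seq_len(n) - ctr, n, n)
  u <- dx * cos(phi) + dy * sin(phi)
  v <- -dx * sin(phi) + dy * cos(phi)
  (u / a)^2 + (v / b)^2 <= 1
}

square_mask <- function(side, pad = 6L) {
  n <- side + 2L * pad
  m <- matrix(FALSE, n, n)
  m[(pad + 1L):(pad + side), (pad + 1L):(pad + side)] <- TRUE
  m
}

gray_rgb <- function(mat) {
  arr <- array(0, c(dim(mat), 3L))
  arr[, , 1] <- mat; arr[, , 2] <- mat; arr[, , 3] <- mat
  arr
}

# Independent brute-force turning-point oracle: for every interior index,
# test the sign pattern of the derivative around the plateau containing it
# (rising immediately before, falling immediately after, call at the
# plateau midpoint). Deliberately structured differently from the
# diff-based detector it checks.
oracle_turning_points <- function(v) {
  n <- length(v)
  out <- integer(0)
  for (i in 2:(n - 1L)) {
    p <- i
    while (p > 1L && v[p - 1L] == v[i]) p <- p - 1L
    q <- i
    while (q < n && v[q + 1L] == v[i]) q <- q + 1L
    if (p == 1L || q == n) next
    if (v[p - 1L] < v[i] && v[q + 1L] < v[i] && i == (p + q) %/% 2L)
      out <- c(out, i)
  }
  out
}

# Independent ABCD/TDS oracle (thresholds applied in a different order
# than the implementation; note TDS is always a multiple of 0.1, so the
# threshold values themselves are never attained).
oracle_tds_class <- function(A, B, C, D) {
  tds <- sum(c(A, B, C, D) * c(1.3, 0.1, 0.5, 0.5))
  cls <- "suspicious"
  if (tds < 4.75) cls <- "benign"
  if (tds > 5.45) cls <- "highly_suspicious"
  cls
}
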