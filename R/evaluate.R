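#' Match detected calls to ground-truth irregularities
#'
#' Greedy one-to-one matching by increasing distance along the boundary:
#' all detection-truth pairs within `tol` (circular arc distance when a
#' `circumference` is given) are considered in order of increasing
#' distance and matched greedily. Matched pairs are true positives,
#' unmatched detections false positives, unmatched truths false
#' negatives. True negatives are undefined for this task and deliberately
#' absent.
#'
#' @param detected Numeric vector of detected arc-length positions.
#' @param truth Numeric vector of ground-truth arc-length positions.
#' @param tol Matching tolerance in arc-length pixels (> 0).
#' @param circumference Total boundary length for circular distance;
#'   `NULL` treats positions as linear.
#' @return One-row tibble with `tp`, `fp`, `fn`.
#' @export
match_calls <- function(detected, truth, tol, circumference = NULL) {
  stopifnot(tol > 0)
  nd <- length(detected); nt <- length(truth)
  if (nd == 0L || nt == 0L)
    return(tibble::tibble(tp = 0L, fp = nd, fn = nt))
  d <- abs(outer(detected, truth, `-`))
  if (!is.null(circumference)) d <- pmin(d, circumference - d)
  pairs <- which(d <= tol, arr.ind = TRUE)
  tp <- 0L
  if (nrow(pairs) > 0L) {
    ord <- order(d[pairs])
    used_d <- logical(nd); used_t <- logical(nt)
    for (k in ord) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      if (!used_d[i] && !used_t[j]) {
        used_d[i] <- TRUE; used_t[j] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  tibble::tibble(tp = tp, fp = nd - tp, fn = nt - tp)
}

#' Sensitivity (recall) of detection counts
#'
#' `TP / (TP + FN)`: the proportion of true irregularities that were
#' detected. Undefined (NA with a warning) when there are no positives.
#'
#' @param counts Data frame with `tp`, `fp`, `fn` (rows are summed).
#' @return A number in `[0, 1]`, or `NA` if undefined.
#' @export
sensitivity <- function(counts) {
  tp <- sum(counts$tp); fn <- sum(counts$fn)
  if (tp + fn == 0) {
    warning("sensitivity undefined: no condition positives")
    return(NA_real_)
  }
  tp / (tp + fn)
}

#' Precision (positive predictive value) of detection counts
#'
#' `TP / (TP + FP)`: the proportion of detections that are true.
#' Undefined (NA with a warning) when there are no detections.
#'
#' @inheritParams sensitivity
#' @return A number in `[0, 1]`, or `NA` if undefined.
#' @export
precision <- function(counts) {
  tp <- sum(counts$tp); fp <- sum(counts$fp)
  if (tp + fp == 0) {
    warning("precision undefined: no detections")
    return(NA_real_)
  }
  tp / (tp + fp)
}

#' Arc-length positions along a closed contour
#'
#' Cumulative arc length of each vertex of a closed polygonal contour
#' (boundary trace), starting at 0 for the first vertex.
#'
#' @param contour Data frame with `row`, `col` vertices in order.
#' @return Numeric vector of positions; attribute `perimeter` holds the
#'   closed total length.
#' @export
contour_arc_positions <- function(contour) {
  r <- contour$row; c <- contour$col
  n <- length(r)
  seg <- sqrt(diff(r)^2 + diff(c)^2)
  close_seg <- sqrt((r[1] - r[n])^2 + (c[1] - c[n])^2)
  pos <- c(0, cumsum(seg))
  attr(pos, "perimeter") <- sum(seg) + close_seg
  pos
}

#' Project image points onto a contour
#'
#' Maps each `(row, col)` point to the arc-length position of its nearest
#' contour vertex. Used to express detected calls and ground-truth apexes
#' in a common circular coordinate before matching.
#'
#' @param points Data frame or matrix with `row`, `col` (real-valued).
#' @param contour Closed boundary trace with `row`, `col`.
#' @return Numeric vector of arc positions; attribute `perimeter` as in
#'   [contour_arc_positions()].
#' @export
project_to_contour <- function(points, contour) {
  pos <- contour_arc_positions(contour)
  pts <- as.data.frame(points)
  if (nrow(pts) == 0L) {
    out <- numeric(0)
    attr(out, "perimeter") <- attr(pos, "perimeter")
    return(out)
  }
  out <- vapply(seq_len(nrow(pts)), function(i) {
    d2 <- (contour$row - pts$row[i])^2 + (contour$col - pts$col[i])^2
    pos[which.min(d2)]
  }, numeric(1))
  attr(out, "perimeter") <- attr(pos, "perimeter")
  out
}

#' Evaluate detections against ground truth on a contour
#'
#' Projects detected calls and ground-truth apexes onto the ground-truth
#' contour and matches them with a circular arc-length tolerance given as
#' a fraction of the perimeter.
#'
#' @param calls Data frame with `row`, `col` of detections (raw-image
#'   frame).
#' @param truth Data frame with `row`, `col` of true irregularities.
#' @param contour Ground-truth boundary trace (`row`, `col`).
#' @param tol_frac Tolerance as a fraction of the perimeter
#'   (default 0.02).
#' @return One-row tibble with `tp`, `fp`, `fn`, `n_truth`, `n_detected`,
#'   `sensitivity`, `precision`.
#' @export
evaluate_detection <- function(calls, truth, contour, tol_frac = 0.02) {
  dp <- project_to_contour(calls, contour)
  tp_ <- project_to_contour(truth, contour)
  perim <- attr(tp_, "perimeter")
  counts <- match_calls(dp, tp_, tol = tol_frac * perim,
                        circumference = perim)
  counts$n_truth <- length(tp_)
  counts$n_detected <- length(dp)
  counts$sensitivity <- if (counts$tp + counts$fn > 0)
    counts$tp / (counts$tp + counts$fn) else NA_real_
  counts$precision <- if (counts$tp + counts$fp > 0)
    counts$tp / (counts$tp + counts$fp) else NA_real_
  counts
}

#' Mean boundary distance between two masks
#'
#' Symmetric mean distance between the traced boundaries of two masks:
#' the average, over the boundary pixels of each mask, of the distance to
#' the nearest boundary pixel of the other, averaged over both
#' directions. Used to quantify segmentation border error in pixels.
#'
#' @param a,b Logical masks of equal shape.
#' @return Mean boundary distance in pixels.
#' @export
boundary_distance <- function(a, b) {
  ta <- trace_boundary(a); tb <- trace_boundary(b)
  dmap <- function(tr, dims) {
    m <- matrix(1, dims[1], dims[2])
    m[cbind(tr$row, tr$col)] <- 0
    EBImage::distmap(m)
  }
  da <- dmap(ta, dim(a)); db <- dmap(tb, dim(b))
  (mean(db[cbind(ta$row, ta$col)]) + mean(da[cbind(tb$row, tb$col)])) / 2
}
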