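#' Trace the exterior boundary of a lesion mask
#'
#' Moore-neighbour boundary tracing with a fixed start (the topmost, then
#' leftmost foreground pixel) and clockwise traversal in raster
#' convention. The returned trace is closed: the last point is 8-adjacent
#' to the first.
#'
#' @param mask Logical matrix with a single connected foreground.
#' @return Tibble with `row`, `col` of ordered boundary pixels and
#'   attribute `closed = TRUE`.
#' @export
trace_boundary <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0L) stop("empty mask: nothing to trace")
  H <- nrow(mask); W <- ncol(mask)
  r <- (idx - 1L) %% H + 1L
  c <- (idx - 1L) %/% H + 1L
  o <- order(r, c)
  sr <- r[o[1]]; sc <- c[o[1]]
  # clockwise Moore ring starting west: W NW N NE E SE S SW
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  fg <- function(rr, cc) rr >= 1L && rr <= H && cc >= 1L && cc <= W &&
    mask[rr, cc]
  rows <- integer(0); cols <- integer(0)
  rows[1] <- sr; cols[1] <- sc
  cur <- c(sr, sc); bt <- c(sr, sc - 1L)  # west of start is background
  n <- 1L
  max_steps <- 8L * length(idx) + 16L
  for (step in seq_len(max_steps)) {
    b <- which(dr == bt[1] - cur[1] & dc == bt[2] - cur[2])
    nxt <- NULL
    prev <- bt
    for (k in seq_len(8L)) {
      d <- (b + k - 1L) %% 8L + 1L
      cand <- c(cur[1] + dr[d], cur[2] + dc[d])
      if (fg(cand[1], cand[2])) { nxt <- cand; break }
      prev <- cand
    }
    if (is.null(nxt)) break  # isolated single pixel
    # Jacob's stopping criterion: entering the start pixel again with the
    # same backtrack as the initial state means the boundary is closed
    if (nxt[1] == sr && nxt[2] == sc &&
        prev[1] == sr && prev[2] == sc - 1L) break
    if (nxt[1] == sr && nxt[2] == sc && n >= 2L * length(idx)) break
    n <- n + 1L
    rows[n] <- nxt[1]; cols[n] <- nxt[2]
    bt <- prev
    cur <- nxt
  }
  out <- tibble::tibble(row = rows[seq_len(n)], col = cols[seq_len(n)])
  attr(out, "closed") <- TRUE
  out
}

#' Split a boundary trace into four quadrant segments
#'
#' Computes the bounding box and centroid of the mask, casts rays from the
#' centroid to each bounding-box vertex, and takes as split points the
#' trace pixels closest (in perpendicular distance) to each ray on the
#' vertex's side; among near-ties the crossing farthest from the centroid
#' is chosen, matching the exterior boundary. The four split points cut
#' the closed trace into the ordered segments top, right, bottom, left,
#' which partition the trace exactly.
#'
#' @param trace Boundary trace from [trace_boundary()].
#' @param mask The lesion mask the trace came from.
#' @return An object of class `quadrant_split`: list with `segments`
#'   (named list of integer index vectors into the trace), `split_indices`
#'   (named, upper-left/upper-right/lower-right/lower-left), `bbox`
#'   (rmin, rmax, cmin, cmax) and `centroid` (row, col).
#' @export
split_quadrants <- function(trace, mask) {
  n <- nrow(trace)
  if (n < 4L) stop("trace too short to split")
  ctr <- mask_centroid(mask)
  if (!mask[round(ctr[1]), round(ctr[2])])
    stop("centroid lies outside the mask (strongly concave lesion); ",
         "the borderline construction assumes an interior centroid")
  idxm <- which(mask)
  rr <- (idxm - 1L) %% nrow(mask) + 1L
  cc <- (idxm - 1L) %/% nrow(mask) + 1L
  bbox <- c(rmin = min(rr), rmax = max(rr), cmin = min(cc), cmax = max(cc))
  corners <- rbind(
    `upper-left`  = c(bbox["rmin"], bbox["cmin"]),
    `upper-right` = c(bbox["rmin"], bbox["cmax"]),
    `lower-right` = c(bbox["rmax"], bbox["cmax"]),
    `lower-left`  = c(bbox["rmax"], bbox["cmin"])
  )
  vy <- trace$row - ctr[1]
  vx <- trace$col - ctr[2]
  split_idx <- integer(4)
  for (i in 1:4) {
    dy <- corners[i, 1] - ctr[1]
    dx <- corners[i, 2] - ctr[2]
    len <- sqrt(dx^2 + dy^2)
    proj <- (vx * dx + vy * dy) / len
    perp <- abs(vx * dy - vy * dx) / len
    cand <- proj > 0
    if (!any(cand)) stop("no trace points on the side of a bounding-box ray")
    mind <- min(perp[cand])
    sel <- which(cand & perp <= mind + 0.5)
    split_idx[i] <- sel[which.max(proj[sel])]
  }
  names(split_idx) <- rownames(corners)
  if (anyDuplicated(split_idx))
    stop("degenerate quadrant split: coincident split points")
  # segments are half-open circular ranges between consecutive split points
  circ_range <- function(from, to) {
    if (from < to) from:(to - 1L) else c(from:n, seq_len(to - 1L))
  }
  segs <- list(
    top    = circ_range(split_idx[["upper-left"]], split_idx[["upper-right"]]),
    right  = circ_range(split_idx[["upper-right"]], split_idx[["lower-right"]]),
    bottom = circ_range(split_idx[["lower-right"]], split_idx[["lower-left"]]),
    left   = circ_range(split_idx[["lower-left"]], split_idx[["upper-left"]])
  )
  rel <- (split_idx - split_idx[["upper-left"]]) %% n
  if (is.unsorted(rel))
    stop("split points are not in clockwise order along the trace")
  structure(list(segments = segs, split_indices = split_idx,
                 bbox = bbox, centroid = ctr, trace_length = n),
            class = "quadrant_split")
}

#' Distance-to-edge profile of one boundary segment
#'
#' Converts a quadrant segment of the boundary into a single-valued 1-D
#' profile: for the top segment, one sample per column touched by the
#' segment (left to right), taking the outermost (minimum-row) pixel per
#' column; analogously for the other sides, with traversal orders chosen
#' so the concatenation of the four profiles walks the boundary clockwise.
#' Values are sign-adjusted outward extents, i.e. the raw distance from
#' the corresponding canvas edge negated and offset so lesion protrusions
#' are local maxima on every side (turning-point detection looks for
#' maxima only; assembly later removes all constant offsets). Columns
#' (rows) where the segment has several pixels — overhangs — contribute
#' only their outermost pixel; the number of such columns is recorded in
#' the `overhang` attribute.
#'
#' @param segment Tibble/data frame with `row`, `col` of the segment's
#'   trace pixels (in trace order).
#' @param side One of `"top"`, `"right"`, `"bottom"`, `"left"`.
#' @param canvas `(H, W)` of the rotated canvas (used only to relate the
#'   outward extent to distance-from-edge; values differ by a constant).
#' @return Tibble with `pos`, `value`, `row`, `col`, `side`; attribute
#'   `overhang` counts multi-valued columns/rows.
#' @export
segment_profile <- function(segment, side = c("top", "right", "bottom", "left"),
                            canvas = NULL) {
  side <- match.arg(side)
  stopifnot(nrow(segment) >= 1L)
  r <- segment$row; c <- segment$col
  if (side %in% c("top", "bottom")) {
    keys <- sort(unique(c), decreasing = (side == "bottom"))
    f <- if (side == "top") min else max
    vrow <- vapply(keys, function(k) f(r[c == k]), numeric(1))
    value <- if (side == "top") -vrow else vrow
    out <- tibble::tibble(pos = seq_along(keys), value = value,
                          row = vrow, col = keys, side = side)
    attr(out, "overhang") <- length(c) - length(keys)
  } else {
    keys <- sort(unique(r), decreasing = (side == "left"))
    f <- if (side == "right") max else min
    vcol <- vapply(keys, function(k) f(c[r == k]), numeric(1))
    value <- if (side == "right") vcol else -vcol
    out <- tibble::tibble(pos = seq_along(keys), value = value,
                          row = keys, col = vcol, side = side)
    attr(out, "overhang") <- length(r) - length(keys)
  }
  out
}

#' Assemble the borderline function from four segment profiles
#'
#' Concatenates the top, right, bottom and left profiles in clockwise
#' order and subtracts, at each junction, the constant gap between the
#' incoming segment's first value and the previous segment's last value,
#' applied cumulatively left to right. The assembled signal is therefore
#' exactly continuous at the three interior junctions; the residual
#' closure gap between the end of the left segment and the start of the
#' top segment is recorded but not corrected (the borderline function is
#' an open curve).
#'
#' @param profiles List of four profile tibbles in order top, right,
#'   bottom, left (from [segment_profile()]).
#' @return An object of class `borderline_signal`: tibble with `index`,
#'   `value`, `segment`, `row`, `col`; attributes `junctions` (three
#'   interior indices, the first sample of segments 2-4), `closure_gap`,
#'   and `overhang` (total multi-valued columns/rows).
#' @export
assemble_borderline <- function(profiles) {
  stopifnot(length(profiles) == 4L)
  sides <- vapply(profiles, function(p) p$side[1], character(1))
  stopifnot(identical(sides, c("top", "right", "bottom", "left")))
  shift <- 0
  values <- list(); lens <- integer(4)
  for (i in 1:4) {
    v <- profiles[[i]]$value
    if (i > 1L) {
      gap <- v[1] - values[[i - 1L]][lens[i - 1L]]
      shift <- gap  # offset for this segment relative to already-shifted prev
      v <- v - gap
    }
    values[[i]] <- v
    lens[i] <- length(v)
  }
  value <- unlist(values, use.names = FALSE)
  out <- tibble::tibble(
    index = seq_along(value),
    value = value,
    segment = rep(sides, lens),
    row = unlist(lapply(profiles, `[[`, "row"), use.names = FALSE),
    col = unlist(lapply(profiles, `[[`, "col"), use.names = FALSE)
  )
  attr(out, "junctions") <- cumsum(lens)[1:3] + 1L
  attr(out, "closure_gap") <- value[length(value)] - value[1]
  attr(out, "overhang") <- sum(vapply(profiles, function(p) {
    ov <- attr(p, "overhang")
    if (is.null(ov)) 0 else as.numeric(ov)
  }, numeric(1)))
  class(out) <- c("borderline_signal", class(out))
  out
}

#' Borderline function of a lesion mask
#'
#' Full construction of the 1-D borderline signal for an aligned lesion
#' mask: boundary tracing, quadrant split at the centroid-to-vertex rays,
#' per-segment distance-to-edge profiles, and junction gap subtraction.
#'
#' @param mask Logical lesion mask (typically already rotated so the
#'   major axis is horizontal).
#' @return A `borderline_signal` (see [assemble_borderline()]) with
#'   additional attributes `trace` and `split`.
#' @export
borderline_function <- function(mask) {
  tr <- trace_boundary(mask)
  sp <- split_quadrants(tr, mask)
  profs <- lapply(names(sp$segments), function(s) {
    segment_profile(tr[sp$segments[[s]], , drop = FALSE], side = s,
                    canvas = dim(mask))
  })
  sig <- assemble_borderline(profs)
  attr(sig, "trace") <- tr
  attr(sig, "split") <- sp
  sig
}

# keep borderline_signal class through dplyr-style subsetting of attrs
#' @export
print.borderline_signal <- function(x, ...) {
  cat("<borderline_signal> length", nrow(x),
      "| junctions at", paste(attr(x, "junctions"), collapse = ", "),
      "| closure gap", format(attr(x, "closure_gap"), digits = 3), "\n")
  NextMethod()
}

#' @rdname borderline_function
#' @param object A `borderline_signal`.
#' @param ... Unused.
#' @export
autoplot.borderline_signal <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$index, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_vline(xintercept = attr(object, "junctions"),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "arc position (samples)", y = "borderline height (px)",
                  title = "Borderline function") +
    ggplot2::theme_minimal()
}
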