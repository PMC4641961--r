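test_that("Moore tracing is closed, clockwise, with the fixed start", {
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_equal(nrow(trace_boundary(one)), 1L)

  sq <- matrix(FALSE, 5, 5); sq[2:4, 2:4] <- TRUE
  tr <- trace_boundary(sq)
  expect_equal(nrow(tr), 8L)
  expect_equal(tr$row, c(2, 2, 2, 3, 4, 4, 4, 3))
  expect_equal(tr$col, c(2, 3, 4, 4, 4, 3, 2, 2))

  d <- disc_mask(50)
  tr2 <- trace_boundary(d)
  # consecutive points 8-adjacent, closed, no repeats except closure
  steps <- cbind(diff(c(tr2$row, tr2$row[1])), diff(c(tr2$col, tr2$col[1])))
  expect_true(all(pmax(abs(steps[, 1]), abs(steps[, 2])) == 1))
  expect_equal(anyDuplicated(paste(tr2$row, tr2$col)), 0L)
  # length close to the independent boundary-pixel count of the digital disc
  inner <- d[2:(nrow(d) - 1), 2:(ncol(d) - 1)]
  nbnd <- sum(inner & !(d[1:(nrow(d) - 2), 2:(ncol(d) - 1)] &
                          d[3:nrow(d), 2:(ncol(d) - 1)] &
                          d[2:(nrow(d) - 1), 1:(ncol(d) - 2)] &
                          d[2:(nrow(d) - 1), 3:ncol(d)]))
  expect_lt(abs(nrow(tr2) - nbnd) / nbnd, 0.05)
  expect_error(trace_boundary(matrix(FALSE, 4, 4)), "empty")
})

test_that("quadrant split cuts the trace at the bounding-box vertex rays", {
  sq <- square_mask(21, 10)
  tr <- trace_boundary(sq)
  sp <- split_quadrants(tr, sq)
  corners <- tr[sp$split_indices, ]
  expect_setequal(paste(corners$row, corners$col),
                  c("11 11", "11 31", "31 31", "31 11"))
  # exact partition: segment lengths sum to the trace length
  expect_equal(sum(lengths(sp$segments)), nrow(tr))
  expect_equal(sort(unname(unlist(sp$segments))), seq_len(nrow(tr)))

  # disc: each segment covers about a quarter of the boundary
  d <- disc_mask(40)
  spd <- split_quadrants(trace_boundary(d), d)
  ctr <- mask_centroid(d)
  for (seg in spd$segments) {
    pts <- trace_boundary(d)[seg, ]
    ang <- atan2(pts$row - ctr[1], pts$col - ctr[2])
    arc <- diff(range(((ang - ang[1]) + pi) %% (2 * pi)))
    expect_equal(arc * 180 / pi, 90, tolerance = 4)
  }

  # 2:1 horizontal ellipse: top/bottom segments longer than left/right
  e <- ellipse_mask(60, 30, 0)
  spe <- split_quadrants(trace_boundary(e), e)
  expect_gt(length(spe$segments$top), length(spe$segments$right))
  expect_gt(length(spe$segments$bottom), length(spe$segments$left))
})

test_that("segment profiles are single-valued with protrusions as maxima", {
  sq <- square_mask(21, 10)
  tr <- trace_boundary(sq)
  sp <- split_quadrants(tr, sq)
  topp <- segment_profile(tr[sp$segments$top, ], "top")
  expect_true(all(topp$value == topp$value[1]))

  # single-column spike 8 px above a straight top edge (square top row 15)
  m <- square_mask(31, 14)
  m[7:14, 22] <- TRUE  # spike protruding 8 px at col 22
  trm <- trace_boundary(m)
  spm <- split_quadrants(trm, m)
  pr <- segment_profile(trm[spm$segments$top, ], "top")
  pk <- which.max(pr$value)
  expect_equal(pr$col[pk], 22)
  expect_equal(pr$value[pk] - min(pr$value), 8)
  calls <- detect_turning_points(gaussian_smooth(pr$value, 5, 1),
                                 min_prominence = 2)
  expect_equal(nrow(calls), 1L)

  # disc segment: concave-down arc with one interior maximum
  d <- disc_mask(40)
  spd <- split_quadrants(trace_boundary(d), d)
  prd <- segment_profile(trace_boundary(d)[spd$segments$top, ], "top")
  expect_equal(nrow(detect_turning_points(prd$value, min_prominence = 0)), 1L)
})

test_that("assembly removes junction gaps and preserves lengths", {
  mk <- function(v, side, n = 25) tibble::tibble(
    pos = seq_len(n), value = rep(v, n), row = 1, col = 1, side = side)
  sig <- assemble_borderline(list(mk(10, "top"), mk(40, "right"),
                                  mk(25, "bottom"), mk(90, "left")))
  expect_equal(sig$value, rep(10, 100))
  expect_equal(attr(sig, "junctions"), c(26L, 51L, 76L))
  expect_equal(nrow(sig), 100L)
  # junction discontinuity is zero by construction
  j <- attr(sig, "junctions")
  expect_equal(sig$value[j] - sig$value[j - 1L], rep(0, 3))

  # disc: four interior maxima before smoothing (one arc per segment)
  d <- disc_mask(45)
  sigd <- borderline_function(d)
  expect_equal(nrow(detect_turning_points(sigd$value, min_prominence = 2)), 4L)
  # signal length equals the sum of profile lengths / partitions preserved
  spd <- attr(sigd, "split")
  expect_equal(sum(lengths(spd$segments)), nrow(attr(sigd, "trace")))
})

test_that("bump count is recovered within one for moderate bump densities", {
  # beyond k ~ 10 bumps aligned with the bounding-box corner rays fall
  # into overhang folds invisible to the extremal profiles (see the
  # methods vignette), so the exact-count property is asserted where the
  # construction supports it
  for (k in c(5, 8, 10)) {
    ph <- render_phantom(phantom_spec("clean", k = k, seed = 40 + k))
    sig <- borderline_function(ph$mask)
    sm <- gaussian_smooth(sig, 15, 2.5)
    calls <- detect_turning_points(sm, min_prominence = 2)
    expect_gte(nrow(calls), k - 1)
    expect_lte(nrow(calls), k + 1)
  }
})

test_that("centroid outside the mask is rejected with a diagnostic", {
  horseshoe <- matrix(FALSE, 40, 40)
  horseshoe[10:30, 10:14] <- TRUE
  horseshoe[10:14, 10:30] <- TRUE
  horseshoe[26:30, 10:30] <- TRUE
  ctr <- mask_centroid(horseshoe)
  expect_false(horseshoe[round(ctr[1]), round(ctr[2])])
  expect_error(split_quadrants(trace_boundary(horseshoe), horseshoe),
               "centroid")
})
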