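test_that("radial distance curve reflects radius and crossing counts", {
  d <- disc_mask(30, 8)
  cv <- radial_distance_curve(d, 180)
  expect_true(all(abs(cv$distance - 30) <= 1))
  expect_true(all(cv$crossings == 1))

  e <- ellipse_mask(50, 25, 0)
  cve <- radial_distance_curve(e, 360)
  expect_equal(max(cve$distance) / min(cve$distance), 2, tolerance = 0.05)

  # canopy phantom: some rays cross the boundary three or more times
  ph <- render_phantom(lobed_phantom_spec(seed = 2))
  cvl <- radial_distance_curve(ph$mask, 360)
  expect_gte(max(cvl$crossings), 3)
  expect_error(radial_distance_curve({
    m <- matrix(FALSE, 40, 40); m[10:30, 10:12] <- TRUE
    m[10:12, 10:30] <- TRUE; m[28:30, 10:30] <- TRUE; m
  }), "centroid")
})

test_that("greedy call-to-truth matching reproduces hand-worked counts", {
  ex <- match_calls(c(100, 300, 500), c(100, 300, 500), tol = 5)
  expect_equal(unlist(ex), c(tp = 3L, fp = 0L, fn = 0L))
  none <- match_calls(numeric(0), c(1, 2, 3, 4, 5), tol = 5)
  expect_equal(unlist(none), c(tp = 0L, fp = 0L, fn = 5L))
  mixed <- match_calls(c(104, 290, 800), c(100, 300, 500), tol = 15)
  expect_equal(unlist(mixed), c(tp = 2L, fp = 1L, fn = 1L))
  # circular distance wraps
  wrap <- match_calls(995, 5, tol = 15, circumference = 1000)
  expect_equal(wrap$tp, 1L)
  expect_error(match_calls(1, 1, tol = 0))
})

test_that("sensitivity and precision follow their defining ratios", {
  expect_equal(sensitivity(tibble::tibble(tp = 10, fp = 0, fn = 0)), 1.0)
  expect_equal(precision(tibble::tibble(tp = 9, fp = 1, fn = 0)), 0.9)
  expect_warning(s <- sensitivity(tibble::tibble(tp = 0, fp = 0, fn = 0)),
                 "undefined")
  expect_true(is.na(s))
  expect_warning(p <- precision(tibble::tibble(tp = 0, fp = 0, fn = 3)),
                 "undefined")
  expect_true(is.na(p))
  # sensitivity is non-decreasing in the matching tolerance
  set.seed(17)
  truth <- sort(runif(10, 0, 1000))
  det <- truth + rnorm(10, 0, 20)
  sens <- vapply(c(5, 10, 20, 40, 80), function(tol) {
    sensitivity(match_calls(det, truth, tol, circumference = 1000))
  }, numeric(1))
  expect_true(all(diff(sens) >= 0))
})

test_that("contour projection places points at their nearest arc position", {
  d <- disc_mask(30, 8)
  tr <- trace_boundary(d)
  pos <- contour_arc_positions(tr)
  expect_equal(pos[1], 0)
  expect_true(all(diff(pos) > 0))
  p <- project_to_contour(tr[c(1, 50, 100), ], tr)
  expect_equal(unclass(p), pos[c(1, 50, 100)], ignore_attr = TRUE)
  perim <- attr(p, "perimeter")
  expect_equal(perim, max(pos) + sqrt(sum((tr[1, ] - tr[nrow(tr), ])^2)),
               tolerance = 1e-9)
})
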