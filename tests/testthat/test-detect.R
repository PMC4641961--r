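test_that("Gaussian kernel and smoothing match direct convolution", {
  w <- gaussian_kernel(15, 2.5)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(w, rev(w))
  expect_error(gaussian_kernel(14, 2.5))
  expect_error(gaussian_kernel(15, 0))

  expect_equal(gaussian_smooth(rep(3.7, 60), 15, 2.5), rep(3.7, 60))
  imp <- c(rep(0, 30), 1, rep(0, 30))
  out <- gaussian_smooth(imp, 15, 2.5)
  expect_equal(out[31 + (-7:7)], w, tolerance = 1e-12)
  expect_equal(which.max(out), 31)

  # oracle: direct double-loop convolution with edge replication
  direct <- function(x, size, sigma) {
    ww <- gaussian_kernel(size, sigma)
    m <- (size - 1) %/% 2
    vapply(seq_along(x), function(i) {
      s <- 0
      for (j in -m:m) s <- s + ww[j + m + 1] * x[min(max(i + j, 1), length(x))]
      s
    }, numeric(1))
  }
  set.seed(7)
  for (rep in 1:10) {
    x <- rnorm(80)
    expect_equal(gaussian_smooth(x, 15, 2.5), direct(x, 15, 2.5),
                 tolerance = 1e-10)
  }
  # smoothing is a contraction of the range
  x <- rnorm(200)
  sm <- gaussian_smooth(x, 15, 2.5)
  expect_lte(max(sm), max(x))
  expect_gte(min(sm), min(x))
  expect_error(gaussian_smooth(rnorm(10), 15, 2.5), "shorter")
})

test_that("turning-point detection matches the brute-force sign-pattern scan", {
  expect_equal(nrow(detect_turning_points(1:50, min_prominence = 0)), 0L)
  tri <- c(1:20, 19:1)
  expect_equal(detect_turning_points(tri, min_prominence = 0)$index, 20L)
  # plateau: one call at the floor midpoint
  plat <- c(1:10, rep(10, 4), 9:1)
  expect_equal(detect_turning_points(plat, min_prominence = 0)$index,
               oracle_turning_points(plat))
  # sine with 7 full periods: 7 calls, equal to the brute-force scan
  s7 <- sin(2 * pi * 7 * (0:499) / 500)
  got <- detect_turning_points(s7, min_prominence = 0)$index
  expect_equal(length(got), 7L)
  expect_equal(got, oracle_turning_points(s7))
  # random signals: exact agreement
  set.seed(13)
  for (rep in 1:200) {
    v <- runif(300)
    expect_identical(detect_turning_points(v, min_prominence = 0)$index,
                     oracle_turning_points(v))
  }
})

test_that("prominence filtering and circular detection behave as documented", {
  base <- sin(2 * pi * 3 * (0:299) / 300) * 10
  rippled <- base + sin(2 * pi * 40 * (0:299) / 300) * 0.4
  expect_gt(nrow(detect_turning_points(rippled, min_prominence = 0)), 3)
  expect_equal(nrow(detect_turning_points(rippled, min_prominence = 2)), 3L)

  # circular signal: peak at the wrap position is found once
  ang <- 2 * pi * (0:359) / 360
  circ <- cos(ang) * 5  # single maximum at index 1 boundary
  calls <- detect_turning_points(circ, min_prominence = 1, circular = TRUE)
  expect_equal(nrow(calls), 1L)
  expect_true(calls$index %in% c(1L, 360L))

  # smoothing more never increases the number of detected calls
  ph <- render_phantom(phantom_spec("clean", k = 10, seed = 55))
  sig <- borderline_function(ph$mask)
  counts <- vapply(c(1.5, 2.5, 4, 6), function(sg) {
    nrow(detect_turning_points(gaussian_smooth(sig$value, 15, sg),
                               min_prominence = 2))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("border octant score counts occupied octants", {
  expect_equal(border_score(integer(0), 400), 0L)
  centers <- floor((0:7) * 50 + 25)
  expect_equal(border_score(centers, 400), 8L)
  expect_equal(border_score(c(10, 20, 30, 40, 49), 400), 1L)
  expect_equal(border_score(tibble::tibble(index = c(10, 60)), 400), 2L)
})

test_that("TDS arithmetic and classification match the clinical rule", {
  expect_equal(tds_score(0, 0, 1, 1)$tds, 1.0)
  expect_equal(as.character(tds_score(0, 0, 1, 1)$classification), "benign")
  expect_equal(tds_score(2, 8, 6, 5)$tds, 8.9)
  expect_equal(as.character(tds_score(2, 8, 6, 5)$classification),
               "highly_suspicious")
  expect_equal(tds_score(1, 8, 4, 3)$tds, 5.6)
  expect_equal(classify_tds(1, 8, 4, 3), "highly_suspicious")
  expect_error(tds_score(3, 0, 1, 1), "A ")
  expect_error(tds_score(0, 9, 1, 1), "B ")
  expect_error(tds_score(0, 0, 0, 1), "C ")
  expect_error(tds_score(0, 0, 1, 6), "D ")

  # TDS is monotone non-decreasing in each component
  base <- tds_score(1, 4, 3, 2)$tds
  expect_gte(tds_score(2, 4, 3, 2)$tds, base)
  expect_gte(tds_score(1, 5, 3, 2)$tds, base)
  expect_gte(tds_score(1, 4, 4, 2)$tds, base)
  expect_gte(tds_score(1, 4, 3, 3)$tds, base)
})
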