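test_that("principal-axis angle recovers known orientations", {
  expect_equal(principal_axis_angle(ellipse_mask(40, 20, 0)), 0, tolerance = 1e-3)
  vert <- principal_axis_angle(ellipse_mask(40, 20, pi / 2))
  expect_equal(abs(vert), pi / 2, tolerance = 1e-2)
  expect_equal(principal_axis_angle(disc_mask(25)), 0)
  for (deg in c(30, -20, 60)) {
    m <- ellipse_mask(50, 25, deg * pi / 180)
    got <- principal_axis_angle(m)
    expect_equal(got, -deg * pi / 180, tolerance = 1 * pi / 180)
    rot <- rotate_raster(m, make_rotation(m))
    expect_lt(abs(principal_axis_angle(rot)), 1 * pi / 180)
  }
  expect_error(principal_axis_angle(matrix(FALSE, 5, 5)), "3 pixels")
})

test_that("rotation resampling preserves content and area", {
  m <- ellipse_mask(40, 22, 0.4)
  rec <- make_rotation(m)
  rot <- rotate_raster(m, rec)
  # area conserved within 2 % under nearest-neighbour resampling
  expect_lt(abs(sum(rot) - sum(m)) / sum(m), 0.02)
  # round trip: rotate by theta then -theta
  rec2 <- make_rotation(rot, angle = -rec$theta)
  back <- rotate_raster(rot, rec2)
  # compare on centred crops via centroids
  c1 <- mask_centroid(m); c2 <- mask_centroid(back)
  sh <- round(c2 - c1)
  idx <- which(m, arr.ind = TRUE)
  idx2 <- cbind(idx[, 1] + sh[1], idx[, 2] + sh[2])
  ok <- idx2[, 1] >= 1 & idx2[, 1] <= nrow(back) &
    idx2[, 2] >= 1 & idx2[, 2] <= ncol(back)
  inter <- sum(back[idx2[ok, , drop = FALSE]])
  uni <- sum(m) + sum(back) - inter
  expect_gte(inter / uni, 0.98)

  # identity rotation is identity up to canvas padding
  rec0 <- make_rotation(m, angle = 0)
  rot0 <- rotate_raster(m, rec0)
  expect_equal(sum(rot0), sum(m))

  # bilinear rotation of a constant image is constant (weights sum to 1)
  cst <- matrix(42, 50, 60)
  blob <- matrix(FALSE, 50, 60); blob[15:35, 20:40] <- TRUE
  recc <- make_rotation(blob, angle = 0.5)
  expect_equal(range(rotate_raster(cst, recc)), c(42, 42))
})

test_that("coordinate maps between frames compose to identity", {
  m <- ellipse_mask(35, 20, 0.6)
  rec <- make_rotation(m)
  crop <- tibble::tibble(rows_removed_top = 12L, rows_removed_bottom = 0L,
                         cols_removed_left = 7L, cols_removed_right = 0L)
  pts <- data.frame(row = c(30.5, 44, 61.2), col = c(28, 52.7, 40))
  fwd <- map_from_original(pts, rec, crop)
  back <- map_to_original(fwd, rec, crop)
  expect_lt(max(abs(back$row - pts$row)), 0.5)
  expect_lt(max(abs(back$col - pts$col)), 0.5)

  # identity records leave coordinates unchanged
  rec0 <- make_rotation(m, angle = 0)
  out <- map_to_original(map_from_original(pts, rec0), rec0)
  expect_equal(out$row, pts$row, tolerance = 1e-9)
  expect_equal(out$col, pts$col, tolerance = 1e-9)
})
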