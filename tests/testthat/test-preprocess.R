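test_that("HSL lightness and NTSC grayscale follow their formulas", {
  px <- array(0, c(2, 2, 3))
  px[1, 1, ] <- c(0, 0, 0)
  px[1, 2, ] <- c(255, 255, 255)
  px[2, 1, ] <- c(200, 50, 100)
  px[2, 2, ] <- c(255, 0, 0)
  L <- compute_lightness(px)
  expect_equal(L[1, 1], 0)
  expect_equal(L[1, 2], 255)
  expect_equal(L[2, 1], (200 + 50) / 2)
  g <- to_grayscale_ntsc(px)
  expect_equal(g[1, 1], 0)
  expect_equal(g[1, 2], 255)
  expect_equal(g[2, 2], 0.299 * 255)
  # outputs bounded on [0, 255] for random valid input
  set.seed(1)
  r <- array(sample(0:255, 300, TRUE), c(10, 10, 3))
  expect_true(all(compute_lightness(r) >= 0 & compute_lightness(r) <= 255))
  expect_true(all(to_grayscale_ntsc(r) >= 0 & to_grayscale_ntsc(r) <= 255))
})

test_that("black frame removal counts bands, adds extra rows, and is idempotent", {
  img <- gray_rgb(matrix(128, 80, 90))
  out <- remove_black_frame(img)
  expect_equal(unlist(out$crop), c(rows_removed_top = 0, rows_removed_bottom = 0,
                                   cols_removed_left = 0, cols_removed_right = 0))
  expect_identical(out$image, img)

  img2 <- gray_rgb(matrix(180, 100, 90))
  img2[1:20, , ] <- 0  # 20-pixel black band at the top
  out2 <- remove_black_frame(img2)
  expect_equal(out2$crop$rows_removed_top, 30L)  # band + 10 extra
  expect_equal(out2$crop$rows_removed_bottom, 0L)
  expect_equal(nrow(out2$image), 70L)

  expect_error(remove_black_frame(gray_rgb(matrix(0, 50, 50))), "empty")

  # idempotence: a second pass removes nothing
  ph <- render_phantom(phantom_spec("standard", k = 6, seed = 21))
  once <- remove_black_frame(ph$image)
  twice <- remove_black_frame(once$image)
  expect_equal(sum(unlist(twice$crop)), 0L)
  expect_identical(twice$image, once$image)
})

test_that("black top-hat responds to thin dark lines, not wide or flat regions", {
  expect_true(all(black_tophat(matrix(90, 40, 40), 5) == 0))
  m <- matrix(200, 60, 60)
  m[30, ] <- 50  # 1-px-wide dark line
  th <- black_tophat(m, 5)
  expect_equal(th[30, 30], 150, tolerance = 1e-8)
  expect_equal(th[10, 30], 0, tolerance = 1e-8)
  d10 <- disc_mask(10, 20)  # disc wider than the structuring element
  wide <- matrix(200, nrow(d10), ncol(d10))
  wide[d10] <- 50
  thw <- black_tophat(wide, 5)
  ctr <- (nrow(d10) + 1) / 2
  expect_equal(thw[ctr, ctr], 0, tolerance = 1e-8)  # interior survives closing
  set.seed(2)
  noisy <- matrix(runif(900, 0, 255), 30, 30)
  expect_true(all(black_tophat(noisy, 3) >= 0))
})

test_that("hair discrimination keeps elongated components and rejects globules", {
  empty <- detect_hairs(matrix(0, 30, 30))
  expect_false(any(empty))
  resp <- matrix(0, 100, 120)
  resp[50, 20:99] <- 80        # straight line, 80 px long
  resp[51, 20:99] <- 80        # 2 px wide
  d <- disc_mask(6, 8)          # globule mimic, radius 6
  resp2 <- matrix(0, 100, 120)
  resp2[1:nrow(d), 1:ncol(d)] <- d * 80
  hm <- detect_hairs(resp)
  expect_true(all(hm[50, 30:90]))
  comp <- attr(hm, "components")
  expect_gt(comp$elongation[comp$is_hair][1], 30)
  hm2 <- detect_hairs(resp2)
  expect_false(any(hm2))
  comp2 <- attr(hm2, "components")
  expect_lt(max(comp2$elongation), 1.5)
})

test_that("inpainting replaces only masked pixels by neighbourhood means", {
  img <- gray_rgb(matrix(120, 30, 30))
  mask <- matrix(FALSE, 30, 30); mask[10:12, 5:25] <- TRUE
  expect_identical(inpaint_hairs(img, matrix(FALSE, 30, 30)), img)
  out <- inpaint_hairs(img, mask)
  expect_equal(out, img, tolerance = 1e-12)  # mean of constants

  # single masked pixel surrounded by a known constant becomes that mean
  img2 <- array(0, c(15, 15, 3))
  img2[, , 1] <- 100; img2[, , 2] <- 60; img2[, , 3] <- 30
  m2 <- matrix(FALSE, 15, 15); m2[8, 8] <- TRUE
  img2[8, 8, ] <- c(0, 255, 7)
  out2 <- inpaint_hairs(img2, m2, neighborhood_radius = 1)
  expect_equal(out2[8, 8, ], c(100, 60, 30), tolerance = 1e-10)

  # pixels outside the mask are bit-identical
  set.seed(3)
  img3 <- array(sample(0:255, 20 * 20 * 3, TRUE), c(20, 20, 3))
  m3 <- matrix(runif(400) < 0.2, 20, 20)
  out3 <- inpaint_hairs(img3, m3)
  expect_identical(out3[!array(m3, dim(img3))], as.numeric(img3[!array(m3, dim(img3))]))

  expect_error(inpaint_hairs(img, matrix(TRUE, 30, 30)), "donor")
})
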