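test_that("gray-world balance fixes uniform gray and equalizes channel means", {
  gray <- flat_image(128, 128, 128)
  out <- gray_world_balance(gray)
  expect_equal(out$image, gray)
  expect_equal(unlist(out$gains[, c("s_r", "s_g", "s_b")]),
               c(s_r = 1, s_g = 1, s_b = 1))

  img <- flat_image(100, 50, 150)
  out2 <- gray_world_balance(img)
  expect_equal(out2$gains$a_gray, 100)
  expect_equal(unlist(out2$gains[, c("s_r", "s_g", "s_b")]),
               c(s_r = 1, s_g = 2, s_b = 2 / 3), tolerance = 1e-12)
  # gains algebra: s_c * a_c = a_gray exactly, so pre-clipping means equalize
  expect_equal(out2$gains$s_r * out2$gains$a_r, out2$gains$a_gray)
  expect_equal(out2$gains$s_b * out2$gains$a_b, out2$gains$a_gray)

  # on a generic image the post-balance 8-bit means agree within a unit
  withr::with_seed(5, {
    noisy <- array(runif(12 * 12 * 3, 40, 220), c(12, 12, 3))
  })
  bal <- gray_world_balance(noisy)$image
  means <- apply(bal, 3, mean)
  expect_lt(max(means) - min(means), 1)
  expect_error(gray_world_balance(flat_image(0, 10, 10)),
               class = "ripecast_zero_channel")
})

test_that("white balance is idempotent up to rounding", {
  withr::with_seed(6, {
    img <- array(runif(16 * 16 * 3, 30, 230), c(16, 16, 3))
  })
  once <- gray_world_balance(img)$image
  again <- gray_world_balance(once)
  # a balanced image already has equal means: gains ~ 1
  expect_equal(unlist(again$gains[, c("s_r", "s_g", "s_b")]),
               c(s_r = 1, s_g = 1, s_b = 1), tolerance = 5e-3)
})

test_that("a* extraction matches reference colorimetry", {
  mask <- matrix(TRUE, 4, 4)
  # achromatic pixels sit exactly on the gray axis
  for (v in c(0, 64, 128, 255)) {
    a <- rgb_to_a(flat_image(v, v, v, 4, 4), mask)
    expect_equal(a$a_mean, 0, tolerance = 1e-6)
  }
  # a_mean = 0 -> a_norm = 128/255
  expect_equal(rgb_to_a(flat_image(90, 90, 90, 4, 4), mask)$a_norm, 128 / 255,
               tolerance = 1e-6)

  # pure sRGB red against the published value and an independent oracle
  red <- rgb_to_a(flat_image(255, 0, 0, 4, 4), mask)
  expect_equal(red$a_mean, 80.1, tolerance = 0.1)
  ref <- grDevices::convertColor(matrix(c(1, 0, 0), 1), "sRGB", "Lab")[2]
  expect_equal(red$a_mean, ref, tolerance = 0.2)

  # several random colors against convertColor (slightly different matrix)
  withr::with_seed(21, {
    for (i in 1:25) {
      rgb <- runif(3)
      ours <- rgb_to_a(flat_image(rgb[1] * 255, rgb[2] * 255, rgb[3] * 255,
                                  2, 2), matrix(TRUE, 2, 2))$a_mean
      ref <- grDevices::convertColor(matrix(rgb, 1), "sRGB", "Lab")[2]
      expect_equal(ours, ref, tolerance = 0.35)
    }
  })
  expect_error(rgb_to_a(flat_image(1, 1, 1), matrix(FALSE, 8, 8)),
               class = "ripecast_empty_mask")
})

test_that("a* increases strictly with the red channel at fixed green and blue", {
  mask <- matrix(TRUE, 2, 2)
  for (gb in list(c(50, 50), c(120, 80), c(200, 30))) {
    a_vals <- vapply(seq(10, 250, by = 40), function(r) {
      rgb_to_a(flat_image(r, gb[1], gb[2], 2, 2), mask)$a_mean
    }, numeric(1))
    expect_true(all(diff(a_vals) > 0))
  }
})

test_that("color ratios count hue classes and redistribute unclassified pixels", {
  red_disc <- render_fruit_image(1, 0, 0, size = 48, seed = 1)
  cr <- color_ratios(red_disc$image, red_disc$mask)
  expect_equal(c(cr$red, cr$yellow, cr$green), c(1, 0, 0))

  # synthetic half/half and thirds by direct pixel painting (no jitter)
  img <- flat_image(200, 40, 40, 10, 10)
  img[, 6:10, 1] <- 60; img[, 6:10, 2] <- 170; img[, 6:10, 3] <- 60
  cr2 <- color_ratios(img, matrix(TRUE, 10, 10))
  expect_equal(c(cr2$red, cr2$green), c(0.5, 0.5), tolerance = 1e-6)

  img3 <- flat_image(200, 40, 40, 9, 9)
  img3[, 4:6, 1] <- 235; img3[, 4:6, 2] <- 200; img3[, 4:6, 3] <- 40
  img3[, 7:9, 1] <- 60; img3[, 7:9, 2] <- 170; img3[, 7:9, 3] <- 60
  cr3 <- color_ratios(img3, matrix(TRUE, 9, 9))
  expect_equal(c(cr3$red, cr3$yellow, cr3$green), rep(1 / 3, 3),
               tolerance = 1e-6)
  # fractions always sum to one
  expect_equal(cr3$red + cr3$yellow + cr3$green, 1, tolerance = 1e-9)
})

test_that("color ratios are invariant to mask-preserving translation", {
  fr <- render_fruit_image(0.4, 0.2, 0.4, size = 40, seed = 3)
  cr <- color_ratios(fr$image, fr$mask)
  # translate image and mask by 3 pixels (content shifts together)
  shift <- function(m, by) rbind(m[(by + 1):nrow(m), ], m[1:by, ])
  img2 <- fr$image
  for (ch in 1:3) img2[, , ch] <- shift(fr$image[, , ch], 3)
  mask2 <- shift(fr$mask, 3)
  cr2 <- color_ratios(img2, mask2)
  expect_equal(cr[, 1:3], cr2[, 1:3], tolerance = 1e-12)
})

test_that("maturity grading follows the red-coverage bands and is monotone", {
  expect_equal(grade_maturity(0.05, 0.03), 2L)
  expect_equal(grade_maturity(0.50), 4L)
  expect_equal(grade_maturity(0.90), 5L)
  expect_equal(grade_maturity(0, 0), 1L)
  expect_equal(grade_maturity(0.005, 0.002), 1L)
  expect_equal(grade_maturity(c(0.10, 0.40, 0.70)), c(3L, 4L, 5L))
  grid <- seq(0, 1, by = 0.005)
  expect_true(all(diff(grade_maturity(grid, 0.0)) >= 0))
})

test_that("polygon masks rasterize inclusively and match a ray-casting oracle", {
  ann <- list(shapes = list(list(label = "fruit",
                                 points = list(list(0, 0), list(10, 0),
                                               list(10, 10), list(0, 10)))))
  mask <- read_polygon_mask(ann, 20, 20)
  expect_equal(sum(mask), 121L)

  tri <- list(shapes = list(list(label = "fruit",
                                 points = list(list(1, 1), list(12, 2),
                                               list(5, 11)))))
  mask_tri <- read_polygon_mask(tri, 16, 16)
  vx <- c(1, 12, 5); vy <- c(1, 2, 11)
  for (r in seq_len(16)) {
    for (cc in seq_len(16)) {
      expect_identical(mask_tri[r, cc],
                       oracle_in_polygon(cc - 1, r - 1, vx, vy))
    }
  }

  degenerate <- list(shapes = list(list(points = list(list(0, 0), list(5, 5),
                                                      list(10, 10)))))
  expect_error(read_polygon_mask(degenerate, 12, 12),
               class = "ripecast_bad_annotation")

  two <- list(shapes = list(
    list(points = list(list(0, 0), list(3, 0), list(3, 3), list(0, 3))),
    list(points = list(list(8, 8), list(11, 8), list(11, 11), list(8, 11)))))
  m2 <- read_polygon_mask(two, 14, 14)
  expect_equal(sum(m2), 32L) # two disjoint 4x4 inclusive squares
})

test_that("polygon mask files round-trip through LabelMe JSON", {
  ann <- list(version = "5.0.1",
              shapes = list(list(label = "fruit",
                                 points = list(list(2, 2), list(9, 2),
                                               list(9, 9), list(2, 9)))))
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(ann, path, auto_unbox = TRUE)
  mask <- read_polygon_mask(path, 12, 12)
  expect_equal(sum(mask), 64L)
})

test_that("PNG image IO round-trips 8-bit values", {
  withr::with_seed(4, {
    img <- array(sample(0:255, 6 * 5 * 3, TRUE), c(6, 5, 3))
  })
  path <- withr::local_tempfile(fileext = ".png")
  write_rgb_image(img, path)
  expect_equal(read_rgb_image(path), img)
})

test_that("measure_fruit_images produces one graded observation per image", {
  fr1 <- render_fruit_image(0.8, 0.1, 0.1, size = 40, seed = 2)
  fr2 <- render_fruit_image(0.02, 0.02, 0.96, size = 40, seed = 3)
  obs <- measure_fruit_images(list(fr1$image, fr2$image),
                              list(fr1$mask, fr2$mask), ids = c("a", "b"))
  expect_equal(nrow(obs), 2L)
  expect_equal(obs$maturity_level, c(5L, grade_maturity(obs$red[2], obs$yellow[2])))
  expect_true(all(obs$a_norm >= 0 & obs$a_norm <= 1))
  expect_gt(obs$a_mean[1], obs$a_mean[2]) # redder fruit has larger a*
})
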