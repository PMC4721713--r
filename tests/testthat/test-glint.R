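test_that("find_regions boxes saturated squares with row-major ids", {
  m <- matrix(100, 60, 80)
  # four 5x5 saturated squares in reading order
  put <- function(r, c) m[r:(r + 4), c:(c + 4)] <<- 250
  put(10, 10); put(10, 50); put(40, 12); put(40, 52)
  regs <- find_regions(gray_image(m))
  expect_length(regs, 4)
  expect_equal(vapply(regs, function(r) r$id, numeric(1)), 1:4)
  expect_equal(vapply(regs, function(r) r$box[["y_min"]], numeric(1)),
               c(9, 9, 39, 39))
  expect_equal(vapply(regs, function(r) r$box[["x_min"]], numeric(1)),
               c(9, 49, 11, 51))

  # ids follow whole-pixel translation
  m2 <- matrix(100, 60, 80)
  m2[(10:14) + 3, (10:14) + 5] <- 250
  m2[(40:44) + 3, (52:56) + 5] <- 250
  regs2 <- find_regions(gray_image(m2))
  expect_equal(vapply(regs2, function(r) r$id, numeric(1)), 1:2)
  expect_equal(regs2[[1]]$box[["x_min"]], 9 + 5)
})

test_that("find_regions filters specks and oversized components", {
  m <- matrix(50, 40, 40)
  m[20, 20] <- 255  # single pixel: killed by the 2x2 opening
  expect_length(find_regions(gray_image(m)), 0)
  m2 <- matrix(50, 40, 40)
  m2[5:35, 5:35] <- 255  # area 961 > max_area
  expect_length(find_regions(gray_image(m2)), 0)
  expect_length(find_regions(gray_image(m2), max_area = 2000), 1)
})

test_that("gaussian_fit is exact on a noise-free sampled Gaussian", {
  m <- gaussian_patch(15, 15, 10.3, 7.6, 2.0, 3.0, 220)
  region <- list(id = 1L, box = c(x_min = 4L, y_min = 1L, x_max = 14L, y_max = 13L),
                 area = 100L)
  fit <- gaussian_fit(region, gray_image(m))
  expect_lt(abs(fit$center[["x"]] - 10.3), 1e-6)
  expect_lt(abs(fit$center[["y"]] - 7.6), 1e-6)
  expect_equal(unname(fit$sigma), c(2.0, 3.0), tolerance = 1e-6)
  expect_equal(fit$amplitude, 220, tolerance = 1e-4)
})

test_that("gaussian_fit handles quantization and saturation", {
  # 8-bit quantized: center within 0.2 px (20 jittered cases; the full
  # 100-seed sweep runs in the acceptance suite)
  set.seed(51)
  for (i in 1:20) {
    xg <- 7 + runif(1); yg <- 7 + runif(1)
    m <- gaussian_patch(15, 15, xg, yg, runif(1, 1.8, 2.6), runif(1, 1.8, 2.6),
                        240, quantize = TRUE)
    region <- list(id = 1L, box = c(x_min = 3L, y_min = 3L, x_max = 12L,
                                    y_max = 12L), area = 80L)
    fit <- gaussian_fit(region, gray_image(m))
    expect_lt(abs(fit$center[["x"]] - xg), 0.2)
    expect_lt(abs(fit$center[["y"]] - yg), 0.2)
  }
  # clipped top: exactly-255 plateau pixels are excluded, center still < 0.5
  m <- gaussian_patch(17, 17, 8.4, 8.2, 2.5, 2.5, 320, quantize = TRUE)
  expect_gte(sum(m == 255), 4)
  region <- list(id = 1L, box = c(x_min = 4L, y_min = 4L, x_max = 13L,
                                  y_max = 13L), area = 80L)
  fit <- gaussian_fit(region, gray_image(m))
  expect_lt(abs(fit$center[["x"]] - 8.4), 0.5)
  expect_lt(abs(fit$center[["y"]] - 8.2), 0.5)
})

test_that("gaussian_fit rejects non-Gaussian and tiny regions", {
  m <- matrix(250, 20, 20)  # flat: paraboloid not downward
  region <- list(id = 1L, box = c(x_min = 5L, y_min = 5L, x_max = 14L,
                                  y_max = 14L), area = 100L)
  expect_null(gaussian_fit(region, gray_image(m)))
  m2 <- matrix(0, 20, 20); m2[10, 10] <- 250
  region2 <- list(id = 1L, box = c(x_min = 9L, y_min = 9L, x_max = 9L,
                                   y_max = 9L), area = 1L)
  expect_null(gaussian_fit(region2, gray_image(m2)))
})

test_that("glint centers are invariant to intensity rescaling", {
  base <- gaussian_patch(15, 15, 7.3, 6.8, 2.2, 2.0, 250)
  region <- list(id = 1L, box = c(x_min = 3L, y_min = 3L, x_max = 12L,
                                  y_max = 12L), area = 80L)
  f1 <- gaussian_fit(region, gray_image(base))
  for (k in c(0.6, 0.8)) {
    fk <- gaussian_fit(region, gray_image(base * k))
    expect_equal(unname(fk$center), unname(f1$center), tolerance = 1e-6)
    expect_equal(fk$amplitude, k * f1$amplitude, tolerance = 1e-4)
  }
})

test_that("detect_glints finds a rendered 2x2 LED grid accurately", {
  glints <- list(
    list(center = c(260, 200), sigma = c(2.2, 2.0), H = 250),
    list(center = c(380, 202), sigma = c(2.0, 2.4), H = 248),
    list(center = c(262, 280), sigma = c(2.5, 2.2), H = 252),
    list(center = c(378, 278), sigma = c(2.1, 2.1), H = 246))
  tr <- scene_truth(glints = glints, noise_sd = 0, blur_sd = 0.8)
  fits <- detect_glints(render_eye(tr))
  expect_length(fits, 4)
  errs <- vapply(glints, function(g) {
    min(vapply(fits, function(f)
      sqrt(sum((f$center - g$center)^2)), numeric(1)))
  }, numeric(1))
  expect_lt(mean(errs), 0.3)
  # pupil-only image: no saturation anywhere -> empty list
  tr0 <- scene_truth(noise_sd = 0, blur_sd = 0.8)
  expect_length(detect_glints(render_eye(tr0)), 0)
})
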