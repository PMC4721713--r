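test_that("gradient amplitude is zero on constants and 4h at a sharp step", {
  f <- gradient_field(gray_image(matrix(120, 12, 12)))
  expect_equal(max(f$amplitude), 0)

  # vertical step 0 -> 100 between columns 6 and 7: unnormalized Sobel gives
  # amplitude 4h = 400 at the two adjacent columns, gx > 0 left-to-right
  m <- matrix(0, 10, 12)
  m[, 7:12] <- 100
  f2 <- gradient_field(gray_image(m))
  expect_equal(f2$amplitude[5, 6], 400)
  expect_equal(f2$amplitude[5, 7], 400)
  expect_gt(f2$gx[5, 6], 0)
  expect_equal(f2$amplitude[5, 3], 0)

  # smooth ramp of slope s per px gives amplitude 8s in the interior
  ramp <- matrix(rep(seq(0, 2 * 19, by = 2), each = 10), 10, 20)
  f3 <- gradient_field(gray_image(ramp))
  expect_equal(f3$amplitude[5, 10], 16)
})

test_that("gradient amplitude is near-isotropic on a 45-degree smooth edge", {
  # blurred step along x vs the same rotated 45 degrees; compare peak
  # amplitudes (sampled in the interior, away from borders)
  w <- 41; h <- 41
  X <- matrix(rep(0:(w - 1), each = h), h, w)
  Y <- matrix(rep(0:(h - 1), times = w), h, w)
  edge <- function(d) 100 * pnorm(d / 1.5)  # smooth step profile
  ax <- edge(X - 20)
  di <- (X - 20 + Y - 20) / sqrt(2)
  rot <- edge(di)
  fa <- gradient_field(gray_image(ax))
  fr <- gradient_field(gray_image(rot))
  pa <- max(fa$amplitude[10:30, 10:30])
  pr <- max(fr$amplitude[10:30, 10:30])
  expect_lt(abs(pa - pr) / pa, 0.03)
})

test_that("cast_rays geometry, clipping, and sample counts", {
  rough <- structure(list(center = c(x = 100, y = 100), radius = 20),
                     class = "rough_pupil")
  params <- crrl_params()
  rays <- cast_rays(rough, params, c(640, 480))
  expect_length(rays, 36)
  expect_equal(rays[[1]]$angle, 0)
  expect_equal(range(rays[[1]]$x), c(110, 130))
  expect_equal(unique(round(rays[[1]]$y, 12)), 100)
  # ray 9 (index 9 -> 90 degrees) points straight down in image coords
  expect_equal(unique(round(rays[[10]]$x, 12)), 100)
  # sample count per ray: ceil((r_out - r_in)/step + 1)
  for (r in rays[c(1, 5, 13)]) {
    expect_length(r$radii, ceiling((30 - 10) / params$step + 1))
  }
  # center near a corner: rays clipped but still 36 entries
  rough2 <- structure(list(center = c(x = 4, y = 4), radius = 20),
                      class = "rough_pupil")
  rays2 <- cast_rays(rough2, params, c(640, 480))
  expect_length(rays2, 36)
  expect_true(any(vapply(rays2, function(r) length(r$x), numeric(1)) <
                    length(rays[[1]]$x)))
  expect_true(all(unlist(lapply(rays2, function(r) r$x >= 0 & r$y >= 0))))
})

test_that("detect_on_ray clusters supra-threshold samples and counts edges", {
  # synthetic amplitude field: a vertical edge band at x ~ 60 and a glint
  # rim band at x ~ 70, flat elsewhere
  w <- 120; h <- 120
  X <- matrix(rep(0:(w - 1), each = h), h, w)
  amp <- 200 * exp(-(X - 60)^2 / 2) + 180 * exp(-(X - 70)^2 / 2)
  field <- list(amplitude = amp)
  rough <- structure(list(center = c(x = 40, y = 60), radius = 25),
                     class = "rough_pupil")
  params <- crrl_params()
  rays <- cast_rays(rough, params, c(w, h))
  # ray 0 crosses both bands: 2 clusters; delta = 100 -> threshold 140
  r0 <- detect_on_ray(rays[[1]], field, delta = 100, params)
  expect_equal(r0$n_clusters, 2)
  # ray 18 (180 deg) goes away from both bands: flat, 0 clusters
  r18 <- detect_on_ray(rays[[19]], field, delta = 100, params)
  expect_equal(r18$n_clusters, 0)
  # with only the first band present: exactly 1 cluster at the edge
  field1 <- list(amplitude = 200 * exp(-(X - 60)^2 / 2))
  r0b <- detect_on_ray(rays[[1]], field1, delta = 100, params)
  expect_equal(r0b$n_clusters, 1)
  peak_x <- rays[[1]]$x[r0b$candidates[1]]
  expect_lt(abs(peak_x - 60), 0.5)
})

test_that("eliminate_interference keeps only single-cluster rays", {
  mk <- function(n) list(candidates = seq_len(n), n_clusters = n)
  per_ray <- c(rep(list(mk(1)), 30), rep(list(mk(2)), 6))
  keep <- eliminate_interference(per_ray)
  expect_equal(sum(!is.na(keep)), 30)
  expect_true(all(is.na(keep[31:36])))
  expect_error(eliminate_interference(rep(list(mk(0)), 36)),
               class = "pupilglint_detection_error")
  expect_error(eliminate_interference(c(rep(list(mk(1)), 5), rep(list(mk(3)), 31))),
               class = "pupilglint_detection_error")
})

test_that("subpixel refinement recovers an off-grid peak to < 0.1 px", {
  # amplitude profile peaked at radius 20.3 px, sampled every 0.5 px
  ray <- list(index = 0L, angle = 0,
              radii = seq(10, 30, by = 0.5))
  ray$x <- 50 + ray$radii
  ray$y <- rep(40, length(ray$radii))
  prof <- function(r) exp(-(r - 20.3)^2 / (2 * 1.2^2))
  amp <- prof(ray$radii)
  cand <- which.max(amp)
  ref <- subpixel_refine(cand, ray, amp)
  expect_true(ref$refined)
  # dense-sampling oracle for the spline-free truth
  expect_lt(abs(ref$radius - 20.3), 0.1)
  expect_equal(ref$y, 40)
  expect_lt(abs(ref$x - 70.3), 0.1)

  # peak exactly on a sample with a symmetric profile: unchanged
  amp2 <- exp(-(ray$radii - 20)^2 / (2 * 1.2^2))
  ref2 <- subpixel_refine(which.max(amp2), ray, amp2)
  expect_equal(ref2$radius, 20, tolerance = 1e-6)

  # monotone ramp: no interior max, clamped and flagged
  amp3 <- ray$radii
  ref3 <- subpixel_refine(21L, ray, amp3)
  expect_false(ref3$refined)
  expect_equal(ref3$radius, ray$radii[21])
})

test_that("collect_boundary returns near-contour points on rendered scenes", {
  tr <- scene_truth(pupil = list(center = c(300, 240), axes = c(55, 45),
                                 angle = 0.3, gray = 18),
                    iris = list(radius = 130, gray = 118),
                    background_gray = 205,
                    noise_sd = 0, blur_sd = 1)
  img <- render_eye(tr)
  res <- detect(img)
  pts <- res$diagnostics$boundary_points
  expect_gte(nrow(pts), 30)
  d <- contour_distance(pts$x, pts$y, tr$pupil$center, tr$pupil$axes,
                        tr$pupil$angle)
  expect_lt(max(abs(d)), 1)
  # every point's distance from the rough center lies inside the annulus
  rough <- res$diagnostics$rough_pupil
  rr <- sqrt((pts$x - rough$center[["x"]])^2 + (pts$y - rough$center[["y"]])^2)
  expect_true(all(rr >= 0.5 * rough$radius - 0.5))
  expect_true(all(rr <= 1.5 * rough$radius + 0.5))
  expect_error(detect(gray_image(matrix(0, 64, 64)))$pupil_center, NA)
})

test_that("rotating the scene by 90 degrees rotates the boundary points", {
  tr <- scene_truth(pupil = list(center = c(200, 160), axes = c(40, 30),
                                 angle = 0.2, gray = 20),
                    iris = list(radius = 100, gray = 120),
                    background_gray = 200, noise_sd = 0, blur_sd = 1,
                    size = c(400L, 400L))
  img <- render_eye(tr)
  m <- unclass(img)
  # rotate 90 degrees clockwise: (x, y) -> (W - 1 - y, x) for W x W
  mr <- t(m[nrow(m):1, ])
  res1 <- detect(img)
  th <- res1$diagnostics$thresholds
  rough1 <- res1$diagnostics$rough_pupil
  # map the rough seed exactly (the box-derived op' carries a half-pixel
  # convention that flips under rotation; CRRL equivariance is tested with
  # an identical seed)
  rough2 <- structure(list(
    center = c(x = 400 - 1 - rough1$center[["y"]], y = rough1$center[["x"]]),
    radius = rough1$radius), class = "rough_pupil")
  p1 <- collect_boundary(img, rough1, th, crrl_params())
  p2 <- collect_boundary(gray_image(mr), rough2, th, crrl_params())
  mapped <- data.frame(x = 400 - 1 - p1$y, y = p1$x,
                       ray = (p1$ray_index + 9) %% 36)
  # match by nearest neighbor; interpolation tolerance 0.2 px; ray indices
  # permute by a quarter turn (9 rays)
  worst <- 0
  for (i in seq_len(nrow(mapped))) {
    d <- sqrt((p2$x - mapped$x[i])^2 + (p2$y - mapped$y[i])^2)
    j <- which.min(d)
    worst <- max(worst, d[j])
    expect_equal(p2$ray_index[j], mapped$ray[i])
  }
  expect_lt(worst, 0.2)
})
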