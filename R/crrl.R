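#' CRRL parameters
#'
#' Parameters of the circular ring rays location (CRRL) boundary detector:
#' `n_rays` rays at equal angular spacing are cast across an annulus
#' `[inner * rp', outer * rp']` around the rough pupil center, and samples
#' whose gradient amplitude reaches `delta_coeff * delta`
#' (`delta = T2 - T1`) are recorded as boundary candidates.
#'
#' @param n_rays number of rays (default 36, i.e. 10 degree spacing).
#' @param inner,outer annulus radii as factors of the rough radius `rp'`.
#' @param delta_coeff gradient threshold coefficient in `[1.3, 1.5]`.
#' @param step ray sampling step in pixels.
#' @param band if `TRUE`, accept amplitudes inside the band
#'   `[1.3 delta, 1.5 delta]` instead of at/above `delta_coeff * delta`
#'   (the literal band reading; default `FALSE`).
#' @return An object of class `crrl_params`.
#' @export
crrl_params <- function(n_rays = 36L, inner = 0.5, outer = 1.5,
                        delta_coeff = 1.4, step = 0.5, band = FALSE) {
  stopifnot(n_rays >= 4L, inner > 0, inner < outer,
            delta_coeff >= 1.3, delta_coeff <= 1.5, step > 0)
  structure(list(n_rays = as.integer(n_rays), inner = inner, outer = outer,
                 delta_coeff = delta_coeff, step = step, band = isTRUE(band)),
            class = "crrl_params")
}

#' Image gradient field
#'
#' Partial derivatives `gx`, `gy` by the conventional (unnormalized) 3x3
#' Sobel kernels, and the gradient amplitude `M = sqrt(gx^2 + gy^2)`.
#' A sharp intensity step of height `h` yields amplitude `4h` at the two
#' columns adjacent to the step; a smooth ramp of slope `s` per pixel yields
#' `8s`. This scaling is what makes the boundary threshold
#' `delta_coeff * (T2 - T1)` operable: typical NIR pupil/iris contrasts
#' produce edge amplitudes of several hundred against a threshold of ~140.
#' Borders use edge replication.
#'
#' @param image a [gray_image()].
#' @return An object of class `gradient_field`: list with matrices `gx`,
#'   `gy`, `amplitude`.
#' @export
gradient_field <- function(image) {
  m <- unclass(as_gray_image(image))
  # column/row differences with replication
  dx <- shift_replicate(m, 0L, -1L) - shift_replicate(m, 0L, 1L)  # f(x+1)-f(x-1)
  dy <- shift_replicate(m, -1L, 0L) - shift_replicate(m, 1L, 0L)
  gx <- shift_replicate(dx, 1L, 0L) + 2 * dx + shift_replicate(dx, -1L, 0L)
  gy <- shift_replicate(dy, 0L, 1L) + 2 * dy + shift_replicate(dy, 0L, -1L)
  structure(list(gx = gx, gy = gy, amplitude = sqrt(gx^2 + gy^2)),
            class = "gradient_field")
}

#' Cast CRRL rays across the pupil annulus
#'
#' Builds `n_rays` rays at angles `k * 360 / n_rays` degrees (0-based index
#' `k`), each sampled from radius `inner * rp'` to `outer * rp'` around the
#' rough center at spacing `step` (the outer endpoint is always included).
#' Samples falling outside the image are dropped.
#'
#' @param rough a [rough_pupil()].
#' @param params a [crrl_params()].
#' @param image_bounds `c(width, height)` in pixels.
#' @return List of rays; each ray is a list with `index` (0-based), `angle`
#'   (degrees), `radii`, `x`, `y` (0-based subpixel sample positions).
#' @export
cast_rays <- function(rough, params, image_bounds) {
  stopifnot(inherits(rough, "rough_pupil"), inherits(params, "crrl_params"))
  w <- image_bounds[[1]]; h <- image_bounds[[2]]
  r_in <- params$inner * rough$radius
  r_out <- params$outer * rough$radius
  cx <- rough$center[["x"]]; cy <- rough$center[["y"]]
  inside <- function(x, y) x >= 0 & x <= w - 1 & y >= 0 & y <= h - 1
  n_inside <- 0L
  rays <- vector("list", params$n_rays)
  for (k in seq_len(params$n_rays) - 1L) {
    ang <- k * 360 / params$n_rays
    th <- ang * pi / 180
    base <- seq(r_in, r_out - 1e-9, by = params$step)
    radii <- c(base, r_out)
    x <- cx + radii * cos(th)
    y <- cy + radii * sin(th)
    keep <- inside(x, y)
    n_inside <- n_inside + sum(keep)
    rays[[k + 1L]] <- list(index = k, angle = ang,
                           radii = radii[keep], x = x[keep], y = y[keep])
  }
  if (n_inside == 0L) {
    stop_detection("pupil annulus lies entirely outside the image", "cast_rays")
  }
  rays
}

#' Detect boundary candidates on one ray
#'
#' Samples the gradient amplitude along the ray by bilinear interpolation,
#' marks samples at/above the threshold `delta_coeff * delta` (or inside the
#' `[1.3, 1.5] delta` band when `params$band`), and merges marked samples
#' separated by at most one unmarked sample into clusters. Each cluster is
#' represented by its maximum-amplitude sample. A clean pupil-edge crossing
#' yields one cluster; a glint rim inside the annulus adds more.
#'
#' @param ray one ray from [cast_rays()].
#' @param field a [gradient_field()].
#' @param delta `T2 - T1` from the threshold pair.
#' @param params a [crrl_params()].
#' @return List with `candidates` (integer sample indices of cluster
#'   representatives), `amplitudes` (full amplitude profile), and
#'   `n_clusters`.
#' @export
detect_on_ray <- function(ray, field, delta, params) {
  stopifnot(delta > 0)
  if (length(ray$x) == 0L) {
    return(list(candidates = integer(0), amplitudes = numeric(0), n_clusters = 0L))
  }
  amp <- interp_bilinear(field$amplitude, ray$x, ray$y)
  marked <- if (params$band) {
    amp >= 1.3 * delta & amp <= 1.5 * delta
  } else {
    amp >= params$delta_coeff * delta
  }
  idx <- which(marked)
  if (length(idx) == 0L) {
    return(list(candidates = integer(0), amplitudes = amp, n_clusters = 0L))
  }
  # split where the index gap exceeds 2 (i.e. more than one unmarked sample)
  brk <- c(0L, which(diff(idx) > 2L), length(idx))
  reps <- integer(length(brk) - 1L)
  for (j in seq_len(length(brk) - 1L)) {
    members <- idx[(brk[j] + 1L):brk[j + 1L]]
    reps[j] <- members[which.max(amp[members])]
  }
  list(candidates = reps, amplitudes = amp, n_clusters = length(reps))
}

#' Interference elimination across rays
#'
#' Rays whose candidate count differs from exactly one are discarded
#' wholesale: multiple gradient clusters on a ray indicate a glint rim or
#' reflection near the pupil contour, and a ray with none saw no edge.
#'
#' @param per_ray list of [detect_on_ray()] results, one per ray.
#' @param min_points minimum surviving points required (an ellipse has 5 free
#'   coefficients; default 6).
#' @return Integer vector: for each ray, the surviving candidate sample
#'   index, or `NA` for eliminated rays.
#' @export
eliminate_interference <- function(per_ray, min_points = 6L) {
  keep <- vapply(per_ray, function(r) {
    if (r$n_clusters == 1L) r$candidates[1L] else NA_integer_
  }, integer(1))
  if (sum(!is.na(keep)) < min_points) {
    stop_detection(sprintf(
      "insufficient boundary points: %d surviving rays (need >= %d)",
      sum(!is.na(keep)), min_points), "eliminate_interference")
  }
  keep
}

#' Subpixel refinement of a boundary candidate
#'
#' Fits a cubic spline to the gradient-amplitude profile over the candidate
#' +/- 2 samples along its ray and moves the point to the spline's argmax
#' within that window. Candidates with fewer than two neighbors on either
#' side, or whose argmax clamps to a window end (monotone profile), are
#' returned unrefined and flagged.
#'
#' @param cand_idx candidate sample index on the ray.
#' @param ray the ray (from [cast_rays()]).
#' @param amplitudes amplitude profile along the ray (from [detect_on_ray()]).
#' @return List with `x`, `y` (0-based subpixel), `radius`, `refined`
#'   (logical), `amplitude_at_peak`.
#' @export
subpixel_refine <- function(cand_idx, ray, amplitudes) {
  n <- length(ray$radii)
  i <- cand_idx
  if (i < 3L || i > n - 2L) {
    return(list(x = ray$x[i], y = ray$y[i], radius = ray$radii[i],
                refined = FALSE, amplitude_at_peak = amplitudes[i]))
  }
  win <- (i - 2L):(i + 2L)
  sf <- stats::splinefun(ray$radii[win], amplitudes[win], method = "fmm")
  tt <- seq(ray$radii[i - 2L], ray$radii[i + 2L], length.out = 201L)
  vals <- sf(tt)
  jbest <- which.max(vals)
  clamped <- jbest == 1L || jbest == length(tt)
  r_star <- if (clamped) ray$radii[i] else tt[jbest]
  th <- ray$angle * pi / 180
  # rays are straight lines from the rough center; reconstruct from radius
  cx <- ray$x[1L] - ray$radii[1L] * cos(th)
  cy <- ray$y[1L] - ray$radii[1L] * sin(th)
  list(x = cx + r_star * cos(th), y = cy + r_star * sin(th),
       radius = r_star, refined = !clamped,
       amplitude_at_peak = if (clamped) amplitudes[i] else vals[jbest])
}

#' Collect subpixel pupil boundary points
#'
#' Full CRRL composition: build the annulus, cast rays, detect candidates by
#' gradient amplitude, eliminate interference rays, refine survivors to
#' subpixel. Deterministic for fixed inputs.
#'
#' @param image a [gray_image()] (gradients are computed on this image).
#' @param rough a [rough_pupil()].
#' @param thresholds a `threshold_pair` from [solve_thresholds()] (supplies
#'   `delta`).
#' @param params a [crrl_params()].
#' @param min_points minimum surviving boundary points.
#' @return A data.frame with columns `x`, `y`, `ray_index`, `amplitude`,
#'   `refined`; attribute `n_rays_surviving`.
#' @export
collect_boundary <- function(image, rough, thresholds, params = crrl_params(),
                             min_points = 6L) {
  field <- gradient_field(image)
  sz <- image_size(as_gray_image(image))
  rays <- cast_rays(rough, params, c(sz[["width"]], sz[["height"]]))
  per_ray <- lapply(rays, detect_on_ray, field = field,
                    delta = thresholds$delta, params = params)
  keep <- eliminate_interference(per_ray, min_points = min_points)
  rows <- lapply(which(!is.na(keep)), function(k) {
    ref <- subpixel_refine(keep[k], rays[[k]], per_ray[[k]]$amplitudes)
    data.frame(x = ref$x, y = ref$y, ray_index = rays[[k]]$index,
               amplitude = ref$amplitude_at_peak, refined = ref$refined)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_rays_surviving") <- nrow(out)
  out
}
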