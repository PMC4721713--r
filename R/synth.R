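# Seeded renderer of NIR-like eye images with exact ground truth. The scene
# emulates what a close-range 640x480 NIR eye camera sees: a dark elliptical
# pupil inside a mid-gray iris disk on bright skin/sclera, a 2x2 grid of
# near-saturated Gaussian glints, optional eyelash strokes, optical blur and
# sensor noise. Every structural parameter is recorded in the truth object,
# so detector output can be scored against exact values.

#' Scene ground truth
#'
#' Constructor for the synthetic scene description consumed by [render_eye()].
#' Defaults describe a "typical" clean scene; [sample_scene()] draws
#' randomized scenes from documented ranges.
#'
#' @param pupil list: `center` (x, y), `axes` (a, b semi-axes, px), `angle`
#'   (tilt, radians), `gray`.
#' @param iris list: `radius` (px), `gray`.
#' @param background_gray skin/sclera gray level.
#' @param glints list of lists: `center` (x, y), `sigma` (x, y), `H`
#'   (additive peak amplitude, `>= 245`).
#' @param lashes list of eyelash strokes, each a list with `from`, `to`
#'   (x, y endpoints), `width` (1 or 2 px), `gray`.
#' @param noise_sd additive Gaussian noise, gray levels.
#' @param blur_sd Gaussian blur, px.
#' @param seed integer seed making the render deterministic.
#' @param size `c(W, H)` image size in px.
#' @return An object of class `scene_truth`.
#' @export
scene_truth <- function(pupil = list(center = c(320, 240), axes = c(45, 38),
                                     angle = 0, gray = 20),
                        iris = list(radius = 120, gray = 120),
                        background_gray = 200,
                        glints = list(),
                        lashes = list(),
                        noise_sd = 2, blur_sd = 1,
                        seed = 1L, size = c(640L, 480L)) {
  stopifnot(pupil$gray < iris$gray, iris$gray < background_gray)
  for (g in glints) stopifnot(g$H >= 245)
  w <- size[[1]]; h <- size[[2]]
  within <- function(x, y, margin = 0) {
    x - margin >= 0 && x + margin <= w - 1 && y - margin >= 0 && y + margin <= h - 1
  }
  if (!within(pupil$center[[1]], pupil$center[[2]], max(pupil$axes))) {
    stop("pupil ellipse outside image bounds", call. = FALSE)
  }
  for (g in glints) {
    if (!within(g$center[[1]], g$center[[2]], 2 * max(g$sigma))) {
      stop("glint outside image bounds", call. = FALSE)
    }
  }
  structure(list(pupil = pupil, iris = iris,
                 background_gray = background_gray, glints = glints,
                 lashes = lashes, noise_sd = noise_sd, blur_sd = blur_sd,
                 seed = as.integer(seed), size = as.integer(size)),
            class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf(
    "<scene_truth %dx%d: pupil (%.1f, %.1f) a=%.1f b=%.1f tilt %.1f deg, %d glint(s), %d lash(es), seed %d>\n",
    x$size[1], x$size[2], x$pupil$center[[1]], x$pupil$center[[2]],
    x$pupil$axes[[1]], x$pupil$axes[[2]], x$pupil$angle * 180 / pi,
    length(x$glints), length(x$lashes), x$seed))
  invisible(x)
}

# signed-distance approximation to the pupil ellipse: the implicit value
# rho = sqrt((u/a)^2 + (v/b)^2) rescaled by its gradient magnitude, accurate
# near the contour, which is all the anti-aliasing band needs
ellipse_distance <- function(X, Y, center, axes, angle) {
  u <- (X - center[[1]]) * cos(angle) + (Y - center[[2]]) * sin(angle)
  v <- -(X - center[[1]]) * sin(angle) + (Y - center[[2]]) * cos(angle)
  a <- axes[[1]]; b <- axes[[2]]
  rho <- sqrt((u / a)^2 + (v / b)^2)
  gr <- sqrt((u / a^2)^2 + (v / b^2)^2)
  near <- (rho - 1) * rho / pmax(gr, 1e-12)
  # the gradient rescaling degenerates far from the contour (rho -> 0 gives
  # distance 0 at the center); only the +/- few px band matters, so fall
  # back to a crude but sign-correct distance elsewhere
  ifelse(rho > 0.7 & rho < 1.3, near, (rho - 1) * min(a, b))
}

# separable Gaussian blur with edge replication; kernel radius 3 sd
blur_gaussian <- function(m, sd) {
  if (sd <= 0) return(m)
  r <- max(1L, ceiling(3 * sd))
  k <- dnorm(-r:r, sd = sd)
  k <- k / sum(k)
  acc_r <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) acc_r <- acc_r + k[i] * shift_replicate(m, (-r:r)[i], 0L)
  acc <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) acc <- acc + k[i] * shift_replicate(acc_r, 0L, (-r:r)[i])
  acc
}

#' Render a synthetic eye image
#'
#' Paints background, iris disk and anti-aliased pupil ellipse (coverage
#' shading over a 2-px band), draws eyelash strokes, adds Gaussian glints
#' (clipped at 255), applies Gaussian blur and additive Gaussian noise, and
#' quantizes to 8 bits. Deterministic for a fixed `truth$seed`; the caller's
#' RNG state is left untouched.
#'
#' @param truth a [scene_truth()].
#' @return A [gray_image()].
#' @export
render_eye <- function(truth) {
  stopifnot(inherits(truth, "scene_truth"))
  w <- truth$size[1]; h <- truth$size[2]
  X <- matrix(rep(0:(w - 1), each = h), h, w)   # x = column coordinate
  Y <- matrix(rep(0:(h - 1), times = w), h, w)

  m <- matrix(truth$background_gray, h, w)
  # iris disk
  d_iris <- sqrt((X - truth$pupil$center[[1]])^2 + (Y - truth$pupil$center[[2]])^2) -
    truth$iris$radius
  cov_iris <- pmin(pmax(0.5 - d_iris / 2, 0), 1)  # 2-px soft rim
  m <- m * (1 - cov_iris) + truth$iris$gray * cov_iris
  # pupil ellipse, anti-aliased over a 2-px band
  d_pup <- ellipse_distance(X, Y, truth$pupil$center, truth$pupil$axes,
                            truth$pupil$angle)
  cov_pup <- pmin(pmax(0.5 - d_pup / 2, 0), 1)
  m <- m * (1 - cov_pup) + truth$pupil$gray * cov_pup
  # eyelash strokes: dark polyline segments of width 1-2 px
  for (ls in truth$lashes) {
    n <- ceiling(2 * sqrt(sum((ls$to - ls$from)^2))) + 1L
    tseq <- seq(0, 1, length.out = n)
    px <- ls$from[[1]] + tseq * (ls$to[[1]] - ls$from[[1]])
    py <- ls$from[[2]] + tseq * (ls$to[[2]] - ls$from[[2]])
    half <- (ls$width - 1) / 2
    for (dx in seq(-half, half, by = 1)) for (dy in seq(-half, half, by = 1)) {
      jj <- round(px + dx) + 1L; ii <- round(py + dy) + 1L
      ok <- jj >= 1L & jj <= w & ii >= 1L & ii <= h
      m[cbind(ii[ok], jj[ok])] <- ls$gray
    }
  }
  # glints: additive Gaussians on local patches
  for (g in truth$glints) {
    sx <- g$sigma[[1]]; sy <- g$sigma[[2]]
    rx <- ceiling(4 * sx); ry <- ceiling(4 * sy)
    jj <- max(0, floor(g$center[[1]]) - rx):min(w - 1, ceiling(g$center[[1]]) + rx)
    ii <- max(0, floor(g$center[[2]]) - ry):min(h - 1, ceiling(g$center[[2]]) + ry)
    gx <- exp(-(jj - g$center[[1]])^2 / (2 * sx^2))
    gy <- exp(-(ii - g$center[[2]])^2 / (2 * sy^2))
    m[ii + 1L, jj + 1L] <- m[ii + 1L, jj + 1L] + g$H * (gy %o% gx)
  }
  m <- pmin(m, 255)
  m <- blur_gaussian(m, truth$blur_sd)
  if (truth$noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old_seed, globalenv())
      }
    })
    set.seed(truth$seed)
    m <- m + matrix(rnorm(h * w, 0, truth$noise_sd), h, w)
  }
  gray_image(pmin(pmax(round_half_up(m), 0), 255))
}

#' Sample a randomized scene
#'
#' Draws a [scene_truth()] from documented ranges: pupil semi-axes in
#' `[25, 70]` px with tilt up to ~30 degrees, pupil gray 10-30, iris gray
#' 100-140, background 180-230, four glints with `H` in `[245, 255]` and
#' spreads in `[1.8, 3.0]` px arranged in a 2x2 rectangular grid (wider than
#' tall) around the pupil on the iris. Difficulty levels:
#' \describe{
#'   \item{`clean`}{no occluders; all glint centers at least 4 px from the
#'     pupil contour.}
#'   \item{`occluded`}{5-15 dark eyelash strokes crossing the upper pupil
#'     region.}
#'   \item{`contour_glint`}{glint 1 is moved onto the pupil contour (within
#'     2 px) -- the hard interference case.}
#' }
#'
#' @param seed integer RNG seed; scenes are reproducible.
#' @param difficulty `"clean"`, `"occluded"`, or `"contour_glint"`.
#' @param size image size `c(W, H)`.
#' @param noise_sd,blur_sd noise and blur levels (defaults 2 and 1).
#' @return A [scene_truth()].
#' @export
sample_scene <- function(seed, difficulty = c("clean", "occluded", "contour_glint"),
                         size = c(640L, 480L), noise_sd = 2, blur_sd = 1) {
  difficulty <- match.arg(difficulty)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, globalenv())
    }
  })
  set.seed(as.integer(seed))

  w <- size[[1]]; h <- size[[2]]
  a <- runif(1, 25, 70)
  b <- runif(1, 25, 70)
  if (b > a) { tmp <- a; a <- b; b <- tmp }  # a = major semi-axis
  angle <- runif(1, -pi / 6, pi / 6)
  iris_r <- runif(1, 2.2, 2.6) * a
  margin <- iris_r + 6
  cx <- runif(1, margin, w - 1 - margin)
  cy <- runif(1, min(margin, (h - 1) / 2), max(h - 1 - margin, (h - 1) / 2))
  pupil_gray <- runif(1, 10, 30)
  iris_gray <- runif(1, 100, 140)
  bg_gray <- runif(1, 180, 230)

  # contour radius of the pupil ellipse in direction theta (from center)
  r_contour <- function(theta) {
    ct <- cos(theta - angle); st <- sin(theta - angle)
    1 / sqrt((ct / a)^2 + (st / b)^2)
  }

  # 2x2 glint grid, wider than tall, centered near the pupil center;
  # each glint is pushed radially onto the iris, clear of the contour
  gdx <- runif(1, 0.55, 0.75)   # half-spacings as fractions of the axes
  gdy <- runif(1, 0.35, 0.5)
  glints <- list()
  k <- 0L
  for (sy in c(-1, 1)) for (sx in c(-1, 1)) {
    k <- k + 1L
    sig <- c(runif(1, 1.8, 3.0), runif(1, 1.8, 3.0))
    theta <- atan2(sy * gdy * b, sx * gdx * a)
    rad <- r_contour(theta) + runif(1, 6, 14)  # on the iris, >= ~4 px out
    glints[[k]] <- list(center = c(cx + rad * cos(theta), cy + rad * sin(theta)),
                        sigma = sig, H = runif(1, 245, 255))
  }
  if (difficulty == "contour_glint") {
    theta <- runif(1, 0, 2 * pi)
    rad <- r_contour(theta) + runif(1, -1.5, 1.5)  # within ~2 px of contour
    glints[[1]]$center <- c(cx + rad * cos(theta), cy + rad * sin(theta))
  }

  lashes <- list()
  if (difficulty == "occluded") {
    n_lash <- sample(5:15, 1)
    for (j in seq_len(n_lash)) {
      x0 <- cx + runif(1, -1.2, 1.2) * a
      y0 <- cy - b - runif(1, 10, 40)
      x1 <- x0 + runif(1, -25, 25)
      y1 <- cy - runif(1, 0.2, 0.8) * b
      lashes[[j]] <- list(from = c(x0, y0), to = c(x1, y1),
                          width = sample(1:2, 1),
                          gray = runif(1, 25, 60))
    }
  }

  scene_truth(
    pupil = list(center = c(cx, cy), axes = c(a, b), angle = angle,
                 gray = pupil_gray),
    iris = list(radius = iris_r, gray = iris_gray),
    background_gray = bg_gray,
    glints = glints, lashes = lashes,
    noise_sd = noise_sd, blur_sd = blur_sd,
    seed = as.integer(seed) + 1000000L, size = size
  )
}
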