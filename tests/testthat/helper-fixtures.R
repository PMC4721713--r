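# Shared fixture builders. Everything is generated in code at test time;
# no binary fixtures are stored.

# n points on the ellipse with center (cx, cy), semi-axes (a, b), tilt theta
ellipse_points <- function(n, cx, cy, a, b, theta = 0, t = NULL) {
  if (is.null(t)) t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  data.frame(
    x = cx + a * cos(t) * cos(theta) - b * sin(t) * sin(theta),
    y = cy + a * cos(t) * sin(theta) + b * sin(t) * cos(theta)
  )
}

# true conic coefficients of that ellipse, normalized to A + C = 1
ellipse_conic <- function(cx, cy, a, b, theta = 0) {
  A <- sin(theta)^2 / b^2 + cos(theta)^2 / a^2
  B <- 2 * sin(theta) * cos(theta) * (1 / a^2 - 1 / b^2)
  C <- cos(theta)^2 / b^2 + sin(theta)^2 / a^2
  D <- -2 * A * cx - B * cy
  E <- -B * cx - 2 * C * cy
  F <- A * cx^2 + B * cx * cy + C * cy^2 - 1
  s <- 1 / (A + C)
  c(A = s * A, B = s * B, C = s * C, D = s * D, E = s * E, F = s * F)
}

# approximate signed distance from (x, y) to the ellipse contour (>0 outside)
contour_distance <- function(x, y, center, axes, angle) {
  u <- (x - center[[1]]) * cos(angle) + (y - center[[2]]) * sin(angle)
  v <- -(x - center[[1]]) * sin(angle) + (y - center[[2]]) * cos(angle)
  rho <- sqrt((u / axes[[1]])^2 + (v / axes[[2]])^2)
  gr <- sqrt((u / axes[[1]]^2)^2 + (v / axes[[2]]^2)^2)
  (rho - 1) * rho / pmax(gr, 1e-12)
}

# small synthetic gray matrix with a filled disk of foreground
disk_binary <- function(w, h, cx, cy, r) {
  X <- matrix(rep(0:(w - 1), each = h), h, w)
  Y <- matrix(rep(0:(h - 1), times = w), h, w)
  binary_image(((X - cx)^2 + (Y - cy)^2 <= r^2) * 1)
}

# pure Gaussian intensity patch (no background), exact model class
gaussian_patch <- function(w, h, xg, yg, sx, sy, H, quantize = FALSE) {
  X <- matrix(rep(0:(w - 1), each = h), h, w)
  Y <- matrix(rep(0:(h - 1), times = w), h, w)
  m <- H * exp(-((X - xg)^2 / (2 * sx^2) + (Y - yg)^2 / (2 * sy^2)))
  if (quantize) m <- pmin(pmax(round(m), 0), 255)
  m
}

# histogram object built directly from probabilities (for threshold tests)
hist_from_probs <- function(p, n = 10000L) {
  counts <- round(p / sum(p) * n)
  structure(list(counts = counts, p = counts / sum(counts), n = sum(counts)),
            class = "gray_histogram")
}

# random trimodal histogram: three Gaussian-ish bumps at draws from the
# pupil/iris/skin gray ranges (the structure the threshold stage assumes)
random_trimodal_hist <- function() {
  lev <- 0:255
  mu <- c(runif(1, 10, 30), runif(1, 100, 140), runif(1, 180, 230))
  sd <- runif(3, 4, 12)
  wt <- runif(3, 0.15, 0.6)
  wt <- wt / sum(wt)
  p <- wt[1] * dnorm(lev, mu[1], sd[1]) + wt[2] * dnorm(lev, mu[2], sd[2]) +
    wt[3] * dnorm(lev, mu[3], sd[3]) + 1e-6
  hist_from_probs(p, n = 100000L)
}

# independent brute-force between-class criterion (direct class sums; the
# oracle deliberately avoids the implementation's prefix-sum path)
oracle_criterion_g <- function(hist, T1, T2) {
  p <- hist$p
  lev <- 0:255
  h <- sum(lev * p)
  g <- 0
  for (rng in list(0:T1, (T1 + 1):T2, (T2 + 1):255)) {
    w <- sum(p[rng + 1])
    if (w > 0) {
      hk <- sum(lev[rng + 1] * p[rng + 1]) / w
      g <- g + w * (hk - h)^2
    }
  }
  g
}

oracle_grid_argmax <- function(hist, t1_range = c(1L, 50L), t2_max = 150L) {
  best <- c(-Inf, NA, NA)
  for (T1 in t1_range[1]:t1_range[2]) for (T2 in (T1 + 1):t2_max) {
    g <- oracle_criterion_g(hist, T1, T2)
    if (g > best[1]) best <- c(g, T1, T2)
  }
  list(g = best[1], T1 = best[2], T2 = best[3])
}
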