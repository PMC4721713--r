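#' 3x3 mean smoothing
#'
#' Replaces every pixel by the arithmetic mean of its 3x3 neighborhood
#' (edge pixels use edge replication), rounded to the nearest integer
#' (half up). This is the pre-smoothing applied before histogramming so
#' that the gray-level histogram of an eye image shows clean pupil / iris /
#' skin modes.
#'
#' @param image a [gray_image()].
#' @return A smoothed [gray_image()].
#' @export
smooth_3x3 <- function(image) {
  m <- unclass(as_gray_image(image))
  acc <- matrix(0, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) acc <- acc + shift_replicate(m, dr, dc)
  gray_image(round_half_up(acc / 9))
}

#' Gray-level histogram
#'
#' Exact 256-bin histogram of an 8-bit image: counts `n_i`, probabilities
#' `p_i = n_i / N`, and total pixel count `N`. Fractional intensities are
#' binned by rounding (half up).
#'
#' @param image a [gray_image()].
#' @return An object of class `gray_histogram`: list with `counts` (length
#'   256, bins 0..255), `p` (probabilities), `n` (total pixels).
#' @export
gray_histogram <- function(image) {
  m <- round_half_up(unclass(as_gray_image(image)))
  counts <- tabulate(as.integer(m) + 1L, nbins = 256L)
  structure(list(counts = counts, p = counts / sum(counts), n = sum(counts)),
            class = "gray_histogram")
}

#' @export
print.gray_histogram <- function(x, ...) {
  nz <- which(x$counts > 0) - 1L
  cat(sprintf("<gray_histogram: N = %d, occupied levels %d..%d (%d bins)>\n",
              x$n, min(nz), max(nz), length(nz)))
  invisible(x)
}

# Per-class statistics for the three-class split G0 = {0..T1},
# G1 = {T1+1..T2}, G2 = {T2+1..255}. An empty class gets mean = midpoint of
# its range and variance 0 (and is flagged), which keeps both the
# within-class variance and the between-class criterion finite: an
# omega = 0 class contributes nothing to either, so the law-of-total-variance
# identity sigma_W^2 + g = total variance is preserved.

#' Three-class statistics at a threshold pair
#'
#' Computes class probabilities `omega`, class means `h`, class variances
#' `sigma2`, the within-class variance `sigma_W2`, and the between-class
#' criterion `criterion_g` (the objective maximized by
#' [solve_thresholds()]) for the split of gray levels into
#' `{0..T1}`, `{T1+1..T2}`, `{T2+1..255}`.
#'
#' @param hist a `gray_histogram` from [gray_histogram()].
#' @param T1,T2 integer thresholds with `0 < T1 < T2 < 255`.
#' @return List with `omega` (length 3), `h` (class means), `h_global`,
#'   `sigma2` (class variances), `sigma_W2`, `criterion_g`,
#'   `empty_classes` (logical length 3).
#' @export
class_stats <- function(hist, T1, T2) {
  stopifnot(inherits(hist, "gray_histogram"))
  T1 <- as.integer(T1); T2 <- as.integer(T2)
  if (!(T1 > 0L && T1 < T2 && T2 < 255L)) {
    stop("require 0 < T1 < T2 < 255", call. = FALSE)
  }
  p <- hist$p
  lev <- 0:255
  ranges <- list(0:T1, (T1 + 1L):T2, (T2 + 1L):255)
  omega <- h <- s2 <- numeric(3)
  empty <- logical(3)
  for (k in 1:3) {
    idx <- ranges[[k]] + 1L
    omega[k] <- sum(p[idx])
    if (omega[k] > 0) {
      h[k] <- sum(lev[idx] * p[idx]) / omega[k]
      s2[k] <- sum((lev[idx] - h[k])^2 * p[idx]) / omega[k]
    } else {
      empty[k] <- TRUE
      h[k] <- mean(range(ranges[[k]]))  # midpoint convention
      s2[k] <- 0
    }
  }
  hg <- sum(lev * p)
  list(omega = omega, h = h, h_global = hg, sigma2 = s2,
       sigma_W2 = sum(omega * s2),
       criterion_g = sum(omega * (h - hg)^2),
       empty_classes = empty)
}

#' Solve optimal three-class thresholds
#'
#' Exhaustively maximizes the between-class criterion over the constrained
#' grid `T1 in t1_range`, `T2 in (T1+1)..t2_max` (defaults `[1, 50]` and 150,
#' reflecting where the pupil/iris and iris/skin boundaries fall in NIR eye
#' images). Prefix sums of `p_i`, `i p_i`, `i^2 p_i` make each evaluation
#' O(1), so the full grid costs ~7.5k constant-time evaluations. Ties are
#' broken by smallest `T1`, then smallest `T2`.
#'
#' The stationarity residuals `|2 T1 - h0 - h1|` and `|2 T2 - h1 - h2|` of the
#' continuous-approximation optimality conditions are reported as diagnostics
#' only; they are not used for solving.
#'
#' @param hist a `gray_histogram`, normally of a [smooth_3x3()]-smoothed image.
#' @param t1_range integer length-2, inclusive search range for `T1`.
#' @param t2_max maximum `T2` searched.
#' @return An object of class `threshold_pair`: list with `T1`, `T2`, `delta`
#'   (`T2 - T1`), plus the [class_stats()] fields at the optimum, the
#'   stationarity residuals, and a `degenerate` flag (TRUE if any class is
#'   empty at the optimum).
#' @export
solve_thresholds <- function(hist, t1_range = c(1L, 50L), t2_max = 150L) {
  stopifnot(inherits(hist, "gray_histogram"))
  t1_range <- as.integer(t1_range); t2_max <- as.integer(t2_max)
  stopifnot(length(t1_range) == 2L, t1_range[1] >= 1L,
            t1_range[2] < t2_max, t2_max <= 254L)
  p <- hist$p
  lev <- 0:255
  P <- cumsum(p)            # P[t+1]  = sum_{i<=t} p_i
  S1 <- cumsum(lev * p)
  S2 <- cumsum(lev^2 * p)
  hg <- S1[256L]

  t1s <- t1_range[1]:t1_range[2]
  best <- list(g = -Inf, T1 = NA_integer_, T2 = NA_integer_)
  for (T1 in t1s) {
    T2s <- (T1 + 1L):t2_max
    w0 <- P[T1 + 1L]
    m0 <- S1[T1 + 1L]
    w1 <- P[T2s + 1L] - w0
    m1 <- S1[T2s + 1L] - m0
    w2 <- 1 - w0 - w1
    m2 <- hg - m0 - m1
    # between-class criterion: sum_k w_k (h_k - h)^2 = sum_k m_k^2 / w_k - h^2
    term <- function(m, w) ifelse(w > 0, m^2 / w, 0)
    g <- term(m0, w0) + term(m1, w1) + term(m2, w2) - hg^2
    jmax <- which.max(g)    # first max: smallest T2 for this T1
    if (g[jmax] > best$g) { # strict: keeps smallest T1 on ties
      best <- list(g = g[jmax], T1 = T1, T2 = T2s[jmax])
    }
  }
  st <- class_stats(hist, best$T1, best$T2)
  structure(list(
    T1 = best$T1, T2 = best$T2, delta = best$T2 - best$T1,
    omega = st$omega, h = st$h, h_global = st$h_global,
    sigma2 = st$sigma2, sigma_W2 = st$sigma_W2, criterion_g = st$criterion_g,
    stationarity = c(t1 = abs(2 * best$T1 - st$h[1] - st$h[2]),
                     t2 = abs(2 * best$T2 - st$h[2] - st$h[3])),
    degenerate = any(st$empty_classes),
    t1_range = t1_range, t2_max = t2_max
  ), class = "threshold_pair")
}

#' @export
print.threshold_pair <- function(x, ...) {
  cat(sprintf("<threshold_pair T1 = %d, T2 = %d (delta = %d), g = %.3f%s>\n",
              x$T1, x$T2, x$delta, x$criterion_g,
              if (isTRUE(x$degenerate)) ", degenerate" else ""))
  invisible(x)
}

#' Binarize an image at a threshold
#'
#' @param image a [gray_image()].
#' @param T threshold gray level in `[0, 255]`.
#' @param foreground `"below"` maps pixels `<= T` to 1 (pupil extraction);
#'   `"above"` maps pixels `>= T` to 1 (glint extraction).
#' @return A [binary_image()].
#' @export
binarize <- function(image, T, foreground = c("below", "above")) {
  foreground <- match.arg(foreground)
  stopifnot(T >= 0, T <= 255)
  m <- unclass(as_gray_image(image))
  b <- if (foreground == "below") (m <= T) else (m >= T)
  binary_image(b * 1, foreground_meaning = foreground)
}
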