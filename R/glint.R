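# Glint (corneal reflection) detection. Glints are small near-saturated
# blobs whose intensity profile is modeled as a 2-D Gaussian
#   I(x, y) = H exp(-[(x - xg)^2 / (2 sx^2) + (y - yg)^2 / (2 sy^2)]) ,
# so ln I is a downward paraboloid z = a x^2 + b y^2 + c x + d y + e with
#   a = -1/(2 sx^2), b = -1/(2 sy^2), c = xg/sx^2, d = yg/sy^2 ,
# and the center is (xg, yg) = (-c/2a, -d/2b). The linear model is solved by
# the same deflated-TLS machinery as the ellipse fit.

#' Rough glint regions
#'
#' Binarizes at a fixed high threshold (default 240), filters with a 2x2
#' open-close, labels 8-connected components, and keeps components with area
#' in `[min_area, max_area]`. Regions are numbered 1..K in row-major order
#' of their bounding-box top-left corners.
#'
#' @param image a [gray_image()].
#' @param threshold binarization threshold (foreground = intensity `>=`).
#' @param min_area,max_area component area bounds in pixels.
#' @return List of `glint_region` objects: `id`, `box`
#'   (`c(x_min, y_min, x_max, y_max)`, 0-based, inclusive), `pixels`
#'   (data.frame `x`, `y`, `intensity` of member pixels), `area`.
#' @export
find_regions <- function(image, threshold = 240, min_area = 4L, max_area = 400L) {
  img <- as_gray_image(image)
  b <- binarize(img, threshold, "above")
  b <- open_close(b, 2L, 2L)
  lab <- label_components(unclass(b))
  if (lab$n == 0L) return(list())
  m <- unclass(img)
  regions <- list()
  for (k in seq_len(lab$n)) {
    idx <- which(lab$labels == k)
    if (length(idx) < min_area || length(idx) > max_area) next
    rr <- ((idx - 1L) %% nrow(m)) + 1L
    cc <- ((idx - 1L) %/% nrow(m)) + 1L
    regions[[length(regions) + 1L]] <- list(
      box = c(x_min = min(cc) - 1L, y_min = min(rr) - 1L,
              x_max = max(cc) - 1L, y_max = max(rr) - 1L),
      pixels = data.frame(x = cc - 1L, y = rr - 1L, intensity = m[idx]),
      area = length(idx))
  }
  if (length(regions) == 0L) return(list())
  ord <- order(vapply(regions, function(r) r$box[["y_min"]], numeric(1)),
               vapply(regions, function(r) r$box[["x_min"]], numeric(1)))
  regions <- regions[ord]
  for (k in seq_along(regions)) {
    regions[[k]]$id <- k
    class(regions[[k]]) <- "glint_region"
  }
  regions
}

# 8-connected component labeling of a 0/1 matrix by BFS over the foreground
# pixel set (glint foregrounds are small, so this stays cheap).
label_components <- function(b) {
  h <- nrow(b); w <- ncol(b)
  fg <- which(b > 0)
  labels <- integer(h * w)
  if (length(fg) == 0L) return(list(labels = labels, n = 0L))
  in_fg <- logical(h * w); in_fg[fg] <- TRUE
  nbr_off <- c(-1L, 1L, -h, h, -h - 1L, -h + 1L, h - 1L, h + 1L)
  n <- 0L
  for (seed in fg) {
    if (labels[seed] != 0L) next
    n <- n + 1L
    queue <- seed; labels[seed] <- n
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((cur - 1L) %% h) + 1L
      for (o in nbr_off) {
        nb <- cur + o
        if (nb < 1L || nb > h * w) next
        # column-major neighbors: guard row wrap-around
        nr <- ((nb - 1L) %% h) + 1L
        if (abs(nr - r) > 1L) next
        if (in_fg[nb] && labels[nb] == 0L) {
          labels[nb] <- n
          queue <- c(queue, nb)
        }
      }
    }
  }
  list(labels = labels, n = n)
}

#' Fit a 2-D Gaussian to a glint region
#'
#' Takes the pixels inside the region's bounding box (expanded by 1 px) whose
#' intensity is at least `max(1, support_frac * region max)` -- excluding
#' exactly saturated (255) pixels, whose clipped values would bias the
#' log-paraboloid -- and fits `ln I` by the deflated TLS solver in
#' region-local coordinates. Regions whose fitted paraboloid is not downward
#' (`a >= 0` or `b >= 0`), with fewer than 6 usable pixels, or whose center
#' falls outside the box dilated by 1 px are rejected (`NULL` with a
#' `reason` attribute).
#'
#' @param region a `glint_region` from [find_regions()].
#' @param image the [gray_image()] the region came from.
#' @param support_frac fraction of the region maximum defining the fit
#'   support (default 0.2).
#' @return A `glint_fit` object (list with `id`, `center` (`x`, `y`,
#'   0-based subpixel), `sigma` (`x`, `y`), `amplitude` (`H`), `coeffs`
#'   (`a`..`e`, region-local), `box`, `n_pixels`) or `NULL` if rejected.
#' @export
gaussian_fit <- function(region, image, support_frac = 0.2) {
  img <- as_gray_image(image)
  m <- unclass(img)
  box <- region$box
  x_lo <- max(box[["x_min"]] - 1L, 0L); x_hi <- min(box[["x_max"]] + 1L, ncol(m) - 1L)
  y_lo <- max(box[["y_min"]] - 1L, 0L); y_hi <- min(box[["y_max"]] + 1L, nrow(m) - 1L)
  sub <- m[(y_lo:y_hi) + 1L, (x_lo:x_hi) + 1L, drop = FALSE]
  xs <- rep(x_lo:x_hi, each = nrow(sub))
  ys <- rep(y_lo:y_hi, times = ncol(sub))
  inten <- as.vector(sub)
  floor_v <- max(1, support_frac * max(inten))
  usable <- inten >= floor_v & inten < 255
  if (sum(usable) < 6L) return(reject_glint(region, "fewer than 6 usable pixels"))
  xl <- xs[usable] - x_lo  # region-local coordinates
  yl <- ys[usable] - y_lo
  z <- log(inten[usable])
  A <- cbind(x2 = xl^2, y2 = yl^2, x = xl, y = yl)
  if (qr(A - rep(1, length(xl)) %o% colMeans(A))$rank < 4L) {
    return(reject_glint(region, "degenerate pixel configuration"))
  }
  sol <- tls_core(A, z)
  a <- sol$tau[[1]]; bq <- sol$tau[[2]]; cq <- sol$tau[[3]]; dq <- sol$tau[[4]]
  e <- sol$intercept
  if (!is.finite(a) || !is.finite(bq) || a >= 0 || bq >= 0) {
    return(reject_glint(region, "not Gaussian-shaped (paraboloid opens upward)"))
  }
  xg_l <- -cq / (2 * a); yg_l <- -dq / (2 * bq)
  xg <- xg_l + x_lo; yg <- yg_l + y_lo
  if (xg < box[["x_min"]] - 1 || xg > box[["x_max"]] + 1 ||
      yg < box[["y_min"]] - 1 || yg > box[["y_max"]] + 1) {
    return(reject_glint(region, "fitted center outside dilated box"))
  }
  H <- exp(a * xg_l^2 + bq * yg_l^2 + cq * xg_l + dq * yg_l + e)
  structure(list(
    id = region$id,
    center = c(x = xg, y = yg),
    sigma = c(x = sqrt(-1 / (2 * a)), y = sqrt(-1 / (2 * bq))),
    amplitude = H,
    coeffs = c(a = a, b = bq, c = cq, d = dq, e = e),
    box = box, n_pixels = sum(usable)
  ), class = "glint_fit")
}

reject_glint <- function(region, reason) {
  # rejected regions contribute nothing; reason surfaces only in diagnostics
  NULL
}

# shared centered linear TLS solve: design columns A (uncentered), response z
tls_core <- function(A, z) {
  alpha_bar <- colMeans(A)
  beta_bar <- mean(z)
  X <- sweep(A, 2L, alpha_bar)
  Z <- z - beta_bar
  ev <- jacobi_eigen(crossprod(cbind(-Z, X)))
  gamma2 <- max(min(ev$values), 0)
  p <- ncol(A)
  M <- crossprod(X) - gamma2 * diag(p)
  tau <- tryCatch(solve(M, crossprod(X, Z)), error = function(e) NULL)
  if (is.null(tau)) {
    tau <- solve(crossprod(X) + 1e-10 * sum(diag(crossprod(X))) / p * diag(p),
                 crossprod(X, Z))
  }
  tau <- drop(tau)
  list(tau = tau, intercept = beta_bar - sum(alpha_bar * tau),
       gamma_min = sqrt(gamma2))
}

#' @export
print.glint_fit <- function(x, ...) {
  cat(sprintf("<glint_fit #%d: center (%.2f, %.2f), sigma (%.2f, %.2f), H = %.1f>\n",
              x$id, x$center[["x"]], x$center[["y"]],
              x$sigma[["x"]], x$sigma[["y"]], x$amplitude))
  invisible(x)
}

#' Detect all glints in an image
#'
#' [find_regions()] followed by [gaussian_fit()] on each region; rejected
#' regions are dropped. Deterministic.
#'
#' @param image a [gray_image()].
#' @param threshold,min_area,max_area passed to [find_regions()].
#' @param support_frac passed to [gaussian_fit()].
#' @return List of `glint_fit` objects (possibly empty).
#' @export
detect_glints <- function(image, threshold = 240, min_area = 4L,
                          max_area = 400L, support_frac = 0.2) {
  regions <- find_regions(image, threshold = threshold,
                          min_area = min_area, max_area = max_area)
  fits <- lapply(regions, gaussian_fit, image = image,
                 support_frac = support_frac)
  Filter(Negate(is.null), fits)
}
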