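#' Default pipeline configuration
#'
#' Nested list of all stage parameters with their defaults. Any subset can
#' be overridden via [load_config()] or by passing a partially filled list
#' to [detect()]; unspecified entries keep their defaults.
#'
#' @return Nested named list; see the methods vignette for the meaning and
#'   units of every key.
#' @export
default_config <- function() {
  list(
    otsu = list(t1_range = c(1L, 50L), t2_max = 150L, smooth = TRUE),
    morph = list(open_factor = 0.3, close_factor = 0.7),
    crrl = list(n_rays = 36L, delta_coeff = 1.4, inner = 0.5, outer = 1.5,
                step = 0.5, band = FALSE, use_smoothed = FALSE),
    fit = list(min_points = 6L, cond_limit = 1e12),
    glint = list(threshold = 240, min_area = 4L, max_area = 400L,
                 expected_count = 4L, support_frac = 0.2),
    eval = list(success_radius = 5, glint_match_radius = 3)
  )
}

# recursive merge: entries of `over` override `base`
merge_config <- function(base, over) {
  for (k in names(over)) {
    if (is.list(over[[k]]) && is.list(base[[k]])) {
      base[[k]] <- merge_config(base[[k]], over[[k]])
    } else {
      base[[k]] <- over[[k]]
    }
  }
  base
}

#' Load a YAML configuration
#'
#' Reads a YAML file of overrides and merges it over [default_config()].
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Full configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) cfg <- merge_config(cfg, yaml::read_yaml(path))
  cfg
}

#' Detect pupil and glints in an eye image
#'
#' End-to-end detector: 3x3 smoothing, three-class threshold selection,
#' binarization at `T1` (pupil = below), opening-closing with
#' `0.3 T1` / `0.7 T1` elements, projection-based rough localization, CRRL
#' boundary collection, constrained TLS ellipse fit, and (independently, on
#' the unsmoothed image) glint detection. Any pupil-stage failure yields a
#' partial result naming the failing stage, with downstream fields `NULL`;
#' glint detection still runs.
#'
#' @param image a [gray_image()] (or matrix coercible to one).
#' @param config configuration list as from [default_config()]; partial
#'   lists are merged over the defaults.
#' @return An object of class `detection_result`: list with `pupil_center`
#'   (named `x`, `y`, or `NULL`), `pupil_ellipse` ([fit_ellipse()] result or
#'   `NULL`), `glints` (list of `glint_fit`), `failed_stage` (`NULL` on full
#'   success), and `diagnostics` (thresholds, rough pupil, boundary points,
#'   ray counts).
#' @export
detect <- function(image, config = default_config()) {
  config <- merge_config(default_config(), config)
  img <- as_gray_image(image)
  diagnostics <- list()
  failed <- NULL
  pupil_center <- NULL
  ellipse <- NULL

  res <- tryCatch({
    smoothed <- smooth_3x3(img)
    hist_img <- if (isTRUE(config$otsu$smooth)) smoothed else img
    th <- solve_thresholds(gray_histogram(hist_img),
                           t1_range = config$otsu$t1_range,
                           t2_max = config$otsu$t2_max)
    diagnostics$thresholds <- th
    bin <- binarize(hist_img, th$T1, "below")
    cleaned <- open_close(bin,
                          element_from_threshold(th$T1, config$morph$open_factor),
                          element_from_threshold(th$T1, config$morph$close_factor))
    proj <- project(cleaned)
    rough <- rough_pupil(proj$x_profile, proj$y_profile)
    diagnostics$rough_pupil <- rough
    params <- crrl_params(n_rays = config$crrl$n_rays,
                          inner = config$crrl$inner, outer = config$crrl$outer,
                          delta_coeff = config$crrl$delta_coeff,
                          step = config$crrl$step, band = config$crrl$band)
    grad_img <- if (isTRUE(config$crrl$use_smoothed)) smoothed else img
    pts <- collect_boundary(grad_img, rough, th, params,
                            min_points = config$fit$min_points)
    diagnostics$boundary_points <- pts
    diagnostics$n_rays_surviving <- attr(pts, "n_rays_surviving")
    fit_ellipse(pts, min_points = config$fit$min_points,
                cond_limit = config$fit$cond_limit)
  }, pupilglint_detection_error = function(e) e, error = function(e) e)

  if (inherits(res, "ellipse_fit")) {
    ellipse <- res
    pupil_center <- res$center
  } else {
    failed <- if (!is.null(res$stage)) res$stage else "fit_ellipse"
    diagnostics$failure_message <- conditionMessage(res)
  }

  glints <- detect_glints(img,
                          threshold = config$glint$threshold,
                          min_area = config$glint$min_area,
                          max_area = config$glint$max_area,
                          support_frac = config$glint$support_frac)

  structure(list(pupil_center = pupil_center, pupil_ellipse = ellipse,
                 glints = glints, failed_stage = failed,
                 diagnostics = diagnostics),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  if (is.null(x$pupil_center)) {
    cat(sprintf("<detection_result: pupil FAILED at stage '%s'", x$failed_stage))
  } else {
    cat(sprintf("<detection_result: pupil (%.2f, %.2f)",
                x$pupil_center[["x"]], x$pupil_center[["y"]]))
  }
  cat(sprintf(", %d glint(s)>\n", length(x$glints)))
  invisible(x)
}

## ---- result serialization --------------------------------------------------

result_to_list <- function(result) {
  gl <- lapply(result$glints, function(g) list(
    id = g$id, x = round(g$center[["x"]], 2), y = round(g$center[["y"]], 2),
    sigma_x = round(g$sigma[["x"]], 3), sigma_y = round(g$sigma[["y"]], 3),
    amplitude = round(g$amplitude, 1)))
  th <- result$diagnostics$thresholds
  list(
    pupil = if (is.null(result$pupil_center)) NULL else list(
      x = round(result$pupil_center[["x"]], 2),
      y = round(result$pupil_center[["y"]], 2),
      conic = lapply(result$pupil_ellipse[c("A", "B", "C", "D", "E", "F")],
                     signif, digits = 8)),
    glints = gl,
    failed_stage = result$failed_stage,
    diagnostics = list(
      T1 = if (is.null(th)) NULL else th$T1,
      T2 = if (is.null(th)) NULL else th$T2,
      delta = if (is.null(th)) NULL else th$delta,
      n_rays_surviving = result$diagnostics$n_rays_surviving)
  )
}

#' Write a detection result to JSON or CSV
#'
#' JSON keeps the nested structure (pupil center + conic, per-glint center,
#' spread and amplitude, diagnostics). CSV writes one flat row per result:
#' `image, pupil_x, pupil_y, glint1_x, glint1_y, ...` with all floats at
#' 2-decimal precision and `NA` markers for absent fields.
#'
#' @param result a `detection_result`, or a list of them (CSV only).
#' @param path output file path.
#' @param format `"json"` or `"csv"`.
#' @param image_names optional names for the CSV `image` column.
#' @param n_glints number of glint column pairs in CSV output.
#' @export
write_result <- function(result, path, format = c("json", "csv"),
                         image_names = NULL, n_glints = 4L) {
  format <- match.arg(format)
  if (format == "json") {
    stopifnot(inherits(result, "detection_result"))
    jsonlite::write_json(result_to_list(result), path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  } else {
    results <- if (inherits(result, "detection_result")) list(result) else result
    if (is.null(image_names)) image_names <- sprintf("image%03d", seq_along(results))
    rows <- mapply(function(res, nm) {
      fmt <- function(v) if (is.null(v) || !is.finite(v)) "NA" else sprintf("%.2f", v)
      gl <- character(2L * n_glints)
      for (k in seq_len(n_glints)) {
        g <- if (k <= length(res$glints)) res$glints[[k]] else NULL
        gl[2 * k - 1] <- fmt(if (is.null(g)) NULL else g$center[["x"]])
        gl[2 * k] <- fmt(if (is.null(g)) NULL else g$center[["y"]])
      }
      paste(c(nm, fmt(res$pupil_center[["x"]]), fmt(res$pupil_center[["y"]]), gl),
            collapse = ",")
    }, results, image_names)
    header <- paste(c("image", "pupil_x", "pupil_y",
                      paste0(rep(sprintf("glint%d", seq_len(n_glints)), each = 2),
                             c("_x", "_y"))), collapse = ",")
    writeLines(c(header, rows), path)
  }
  invisible(path)
}

#' Read back a JSON detection result
#'
#' @param path JSON file written by [write_result()].
#' @return The parsed list (not a full `detection_result`).
#' @export
read_result <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Render a detection overlay
#'
#' Draws the fitted pupil ellipse, its center, and glint crosses over the
#' input image and writes a PNG (RGB). Intended for visual inspection.
#'
#' @param image the input [gray_image()].
#' @param result the matching `detection_result`.
#' @param path output PNG path.
#' @export
write_overlay <- function(image, result, path) {
  m <- unclass(as_gray_image(image)) / 255
  rgb <- array(rep(m, 3L), c(nrow(m), ncol(m), 3L))
  put <- function(x, y, channel_rgb) {
    ok <- x >= 0 & x <= ncol(m) - 1 & y >= 0 & y <= nrow(m) - 1
    i <- round(y[ok]) + 1L; j <- round(x[ok]) + 1L
    for (ch in 1:3) rgb[cbind(i, j, ch)] <<- channel_rgb[ch]
  }
  if (!is.null(result$pupil_ellipse)) {
    e <- result$pupil_ellipse
    tt <- seq(0, 2 * pi, length.out = 720)
    # sample the conic by ray marching from the center
    ctr <- e$center
    conic <- function(x, y) e$A * x^2 + e$B * x * y + e$C * y^2 +
      e$D * x + e$E * y + e$F
    for (th in tt) {
      lo <- 0; hi <- max(dim(m))
      s0 <- sign(conic(ctr[["x"]], ctr[["y"]]))
      for (it in 1:40) {
        mid <- (lo + hi) / 2
        if (sign(conic(ctr[["x"]] + mid * cos(th),
                       ctr[["y"]] + mid * sin(th))) == s0) lo <- mid else hi <- mid
      }
      put(ctr[["x"]] + lo * cos(th), ctr[["y"]] + lo * sin(th), c(1, 0, 0))
    }
    put(ctr[["x"]] + (-2:2), rep(ctr[["y"]], 5), c(1, 0, 0))
    put(rep(ctr[["x"]], 5), ctr[["y"]] + (-2:2), c(1, 0, 0))
  }
  for (g in result$glints) {
    put(g$center[["x"]] + (-3:3), rep(g$center[["y"]], 7), c(0, 1, 0))
    put(rep(g$center[["x"]], 7), g$center[["y"]] + (-3:3), c(0, 1, 0))
  }
  png::writePNG(rgb, path)
  invisible(path)
}
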