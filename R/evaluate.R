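#' Score detections against ground truth
#'
#' Reproduces the stability / RMS-error evaluation semantics on synthetic
#' batches. A pupil detection counts as a success when the pipeline
#' completed and the center error is at most `success_radius` (default 5 px;
#' the success criterion has to be declared by the implementer). Stability
#' is the percentage of successes; RMS error is computed over successes
#' only. Each true glint is matched to the nearest detected glint within
#' `glint_match_radius` (one detection can serve only one truth); unmatched
#' truths count as glint failures.
#'
#' @param results list of `detection_result` objects from [detect()].
#' @param truths list of matching [scene_truth()] objects, same order.
#' @param success_radius pupil success radius, px.
#' @param glint_match_radius glint matching radius, px.
#' @return An object of class `eval_report`: list with `n_images`,
#'   `pupil_stability` (%), `pupil_rms_error` (px), `glint_stability` (%),
#'   `glint_rms_error` (px), and `per_image` (data.frame with per-image
#'   pupil error, success flag, glint match counts).
#' @export
score <- function(results, truths, success_radius = 5, glint_match_radius = 3) {
  if (length(results) != length(truths)) {
    stop("results and truths must have the same length", call. = FALSE)
  }
  n <- length(results)
  pupil_err <- rep(NA_real_, n)
  pupil_ok <- logical(n)
  glint_errs <- list()
  n_glints_true <- 0L
  n_glints_matched <- 0L
  per_image <- vector("list", n)

  for (i in seq_len(n)) {
    res <- results[[i]]; tr <- truths[[i]]
    if (!is.null(res$pupil_center)) {
      pc_true <- c(tr$pupil$center[[1]], tr$pupil$center[[2]])
      pupil_err[i] <- sqrt(sum((c(res$pupil_center[["x"]],
                                  res$pupil_center[["y"]]) - pc_true)^2))
      pupil_ok[i] <- pupil_err[i] <= success_radius
    }
    det <- do.call(rbind, lapply(res$glints, function(g)
      c(g$center[["x"]], g$center[["y"]])))
    avail <- rep(TRUE, NROW(det))
    matched_i <- 0L
    errs_i <- numeric(0)
    for (g in tr$glints) {
      n_glints_true <- n_glints_true + 1L
      if (is.null(det) || !any(avail)) next
      d <- sqrt((det[, 1] - g$center[[1]])^2 + (det[, 2] - g$center[[2]])^2)
      d[!avail] <- Inf
      j <- which.min(d)
      if (d[j] <= glint_match_radius) {
        avail[j] <- FALSE
        matched_i <- matched_i + 1L
        errs_i <- c(errs_i, d[j])
      }
    }
    n_glints_matched <- n_glints_matched + matched_i
    glint_errs[[i]] <- errs_i
    per_image[[i]] <- data.frame(
      image = i, pupil_error = pupil_err[i], pupil_success = pupil_ok[i],
      n_glints_true = length(tr$glints), n_glints_matched = matched_i,
      failed_stage = if (is.null(res$failed_stage)) NA_character_ else res$failed_stage)
  }

  ge <- unlist(glint_errs)
  structure(list(
    n_images = n,
    pupil_stability = 100 * mean(pupil_ok),
    pupil_rms_error = if (any(pupil_ok)) sqrt(mean(pupil_err[pupil_ok]^2)) else NA_real_,
    glint_stability = if (n_glints_true > 0) {
      100 * n_glints_matched / n_glints_true
    } else NA_real_,
    glint_rms_error = if (length(ge)) sqrt(mean(ge^2)) else NA_real_,
    per_image = do.call(rbind, per_image)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    paste0("<eval_report over %d image(s):\n",
           "  pupil: stability %.1f%%, RMS error %.3f px\n",
           "  glint: stability %.1f%%, RMS error %.3f px>\n"),
    x$n_images, x$pupil_stability, x$pupil_rms_error,
    x$glint_stability, x$glint_rms_error))
  invisible(x)
}
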