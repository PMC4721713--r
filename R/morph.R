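# Binary morphology with square structuring elements.
#
# Erosion/dilation are separable for squares: a running min (resp. max) over
# rows then over columns. Out-of-image pixels count as background (0), the
# convention stated for all stages. Offsets for a size-k element are
# lo..lo+k-1 with lo = -floor((k-1)/2): centered for odd k; for the even
# k = 2 glint element the anchor is the top-left pixel and dilation uses the
# reflected offsets, so that opening/closing remain proper morphological
# operations (adjunction holds for any k).

se_offsets <- function(k) {
  lo <- -((k - 1L) %/% 2L)
  lo:(lo + k - 1L)
}

# windowed sum over row offsets lo..hi per pixel, zero padding outside;
# one cumulative sum per column instead of k shifted copies
win_sum_rows <- function(m, lo, hi) {
  h <- nrow(m)
  cs0 <- rbind(0, apply(m, 2L, cumsum))
  top <- pmin(seq_len(h) + hi, h) + 1L
  bot <- pmax(seq_len(h) + lo - 1L, 0L) + 1L
  cs0[top, , drop = FALSE] - cs0[bot, , drop = FALSE]
}

win_sum_square <- function(b, lo, hi) {
  t(win_sum_rows(t(win_sum_rows(b, lo, hi)), lo, hi))
}

# binary erosion: every pixel of the k x k window is foreground
erode_square <- function(b, k) {
  offs <- se_offsets(k)
  (win_sum_square(b, offs[1L], offs[k]) == k * k) * 1
}

# binary dilation: any pixel of the reflected window is foreground
dilate_square <- function(b, k) {
  offs <- se_offsets(k)
  (win_sum_square(b, -offs[k], -offs[1L]) > 0) * 1
}

#' Morphological opening then closing
#'
#' Applies opening (erosion then dilation) with a square element of side
#' `open_size`, then closing (dilation then erosion) with side `close_size`.
#' Opening removes specks and thin strokes (eyelashes) smaller than the
#' element; closing fills holes (e.g. glints inside the pupil blob). Borders
#' are treated as background.
#'
#' @param binary a [binary_image()].
#' @param open_size,close_size square element side lengths in pixels.
#' @return A [binary_image()].
#' @export
open_close <- function(binary, open_size, close_size) {
  stopifnot(inherits(binary, "binary_image"))
  open_size <- as.integer(open_size); close_size <- as.integer(close_size)
  if (max(open_size, close_size) > min(dim(binary))) {
    stop("structuring element larger than image", call. = FALSE)
  }
  if (min(open_size, close_size) < 2L) {
    stop("structuring element must be at least 2 px", call. = FALSE)
  }
  m <- unclass(binary)
  m <- dilate_square(erode_square(m, open_size), open_size)   # opening
  m <- erode_square(dilate_square(m, close_size), close_size) # closing
  binary_image(m, foreground_meaning = attr(binary, "foreground_meaning"))
}

#' Structuring-element size from the pupil threshold
#'
#' The cleanup element sizes scale with the pupil threshold `T1`:
#' factor 0.3 for opening and 0.7 for closing. The product is rounded to the
#' nearest integer and then raised to the nearest odd integer `>= 3` so the
#' element has a center pixel.
#'
#' @param T1 pupil threshold (gray level, `>= 1`).
#' @param factor size factor, normally 0.3 (opening) or 0.7 (closing).
#' @return Odd integer element size `>= 3`.
#' @examples
#' element_from_threshold(13, 0.3)  # 5
#' element_from_threshold(13, 0.7)  # 9
#' @export
element_from_threshold <- function(T1, factor) {
  stopifnot(T1 >= 1)
  k <- as.integer(round_half_up(factor * T1))
  if (k %% 2L == 0L) k <- k + 1L
  max(k, 3L)
}

#' Foreground projections
#'
#' Column-wise and row-wise foreground pixel counts of a binary image -- the
#' x/y projections of the segmented pupil blob used for rough localization.
#'
#' @param binary a [binary_image()].
#' @return List with `x_profile` (length W, per-column counts) and
#'   `y_profile` (length H, per-row counts).
#' @export
project <- function(binary) {
  stopifnot(inherits(binary, "binary_image"))
  m <- unclass(binary)
  list(x_profile = colSums(m), y_profile = rowSums(m))
}

# longest contiguous run of TRUE; returns c(start_0based, length) or NULL
longest_run <- function(pos) {
  r <- rle(pos)
  if (!any(r$values)) return(NULL)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  c(start = starts[best] - 1L, length = r$lengths[best])
}

#' Rough pupil box, center and radius from projections
#'
#' The pupil box is the longest contiguous run of positive columns
#' (`l1` = first column, `l2` = run length) and rows (`l3`, `l4`), so a
#' surviving speck elsewhere cannot stretch the box. The rough center is
#' `op' = (l1 + l2/2, l3 + l4/2)` and the rough radius `rp' = (l2 + l4)/4`.
#'
#' @param x_profile,y_profile projections from [project()].
#' @return An object of class `rough_pupil`: list with `l1`, `l2`, `l3`, `l4`
#'   (0-based margins and box sizes), `center` (`op'`, 0-based x, y), and
#'   `radius` (`rp'`).
#' @export
rough_pupil <- function(x_profile, y_profile) {
  rx <- longest_run(x_profile > 0)
  ry <- longest_run(y_profile > 0)
  if (is.null(rx) || is.null(ry)) {
    stop_detection("no pupil candidate: empty projections", "rough_pupil")
  }
  l1 <- rx[["start"]]; l2 <- rx[["length"]]
  l3 <- ry[["start"]]; l4 <- ry[["length"]]
  structure(list(
    l1 = l1, l2 = l2, l3 = l3, l4 = l4,
    center = c(x = l1 + l2 / 2, y = l3 + l4 / 2),
    radius = (l2 + l4) / 4
  ), class = "rough_pupil")
}

#' @export
print.rough_pupil <- function(x, ...) {
  cat(sprintf("<rough_pupil center (%.1f, %.1f), radius %.1f, box %dx%d at (%d, %d)>\n",
              x$center[1], x$center[2], x$radius, x$l2, x$l4, x$l1, x$l3))
  invisible(x)
}

# detection-failure condition shared by all stages
stop_detection <- function(msg, stage) {
  stop(structure(class = c("pupilglint_detection_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), stage = stage)))
}
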