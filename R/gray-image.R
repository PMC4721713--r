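#' Grayscale image container
#'
#' A `gray_image` is a numeric matrix of 8-bit intensities in `[0, 255]`,
#' stored in raster order: rows are image rows, columns are image columns.
#'
#' @section Coordinate convention:
#' All coordinates reported or consumed by this package are **0-based**, with
#' `x` the column index and `y` the row index, and pixel centers at integer
#' coordinates. The pixel stored at matrix element `m[r, c]` (1-based R
#' indexing) has coordinates `(x = c - 1, y = r - 1)`. A subpixel position
#' `(x, y)` therefore interpolates between the four pixels whose integer
#' coordinates bracket it.
#'
#' @param pixels numeric matrix of intensities in `[0, 255]`.
#' @return An object of class `gray_image` (a matrix with a class attribute).
#' @examples
#' img <- gray_image(matrix(0, 16, 16))
#' image_size(img)
#' @export
gray_image <- function(pixels) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 8L || ncol(pixels) < 8L) {
    stop("image must be at least 8x8 pixels", call. = FALSE)
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop("intensities must lie in [0, 255] with no NA", call. = FALSE)
  }
  structure(unclass(pixels), class = "gray_image")
}

#' @rdname gray_image
#' @param x object to test or coerce.
#' @export
is_gray_image <- function(x) inherits(x, "gray_image")

#' @rdname gray_image
#' @export
as_gray_image <- function(x) {
  if (is_gray_image(x)) x else gray_image(as.matrix(x))
}

#' @rdname gray_image
#' @param img a `gray_image`.
#' @return `image_size()`: named vector `c(width =, height =)` in pixels.
#' @export
image_size <- function(img) {
  c(width = ncol(img), height = nrow(img))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d (W x H), range [%g, %g]>\n",
              ncol(x), nrow(x), min(x), max(x)))
  invisible(x)
}

# round half away from zero (all values here are >= 0, so this is
# round-half-up); base round() rounds half to even
round_half_up <- function(x) floor(x + 0.5)

#' Binary image
#'
#' A `{0,1}` matrix with the same layout as [gray_image()], carrying a label
#' stating what foreground (value 1) means (e.g. `"pupil"`, `"glint"`).
#'
#' @param pixels matrix of 0/1 values.
#' @param foreground_meaning character label for the foreground class.
#' @return An object of class `binary_image`.
#' @export
binary_image <- function(pixels, foreground_meaning = "foreground") {
  pixels <- as.matrix(pixels)
  if (anyNA(pixels) || !all(pixels %in% c(0, 1))) {
    stop("binary image values must be 0 or 1", call. = FALSE)
  }
  structure(unclass(pixels), class = "binary_image",
            foreground_meaning = foreground_meaning)
}

#' @export
print.binary_image <- function(x, ...) {
  cat(sprintf("<binary_image %d x %d, foreground = '%s', %d fg px>\n",
              ncol(x), nrow(x), attr(x, "foreground_meaning"), sum(x)))
  invisible(x)
}

## ---- file I/O --------------------------------------------------------------

# BT.601 luma from 0-255 channels, rounded half up
luma_601 <- function(r, g, b) round_half_up(0.299 * r + 0.587 * g + 0.114 * b)

#' Load an eye image from disk
#'
#' Reads PNG, JPEG, or PGM/PPM (plain `P2`/`P3` or raw `P5`/`P6`) files into a
#' [gray_image()]. Color images are converted to luma
#' (`0.299 R + 0.587 G + 0.114 B`, rounded half up); an alpha channel, if
#' present, is ignored.
#'
#' @param path path to the image file.
#' @return A [gray_image()].
#' @export
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L) {
    stop("`path` must be a single file path", call. = FALSE)
  }
  if (!file.exists(path)) {
    stop(sprintf("cannot read image: file '%s' does not exist", path),
         call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path) * 255,
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE)) {
        stop("reading JPEG requires the 'jpeg' package", call. = FALSE)
      }
      jpeg::readJPEG(path) * 255
    },
    pgm = ,
    ppm = ,
    pnm = read_pnm(path),
    stop(sprintf("unsupported image format '.%s' (supported: png, jpg, pgm, ppm)",
                 ext), call. = FALSE)
  )
  gray_from_array(arr)
}

# collapse a HxW or HxWxC numeric array (0-255 scale) to a gray_image
gray_from_array <- function(arr) {
  if (length(dim(arr)) == 2L) {
    m <- round_half_up(arr)
  } else if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3L]
    if (nc >= 3L) {
      m <- luma_601(arr[, , 1L], arr[, , 2L], arr[, , 3L])
    } else {
      m <- round_half_up(arr[, , 1L])
    }
  } else {
    stop("decoded image has unsupported dimensions", call. = FALSE)
  }
  gray_image(pmin(pmax(m, 0), 255))
}

# Minimal PNM (PGM/PPM) reader, plain and raw variants, maxval <= 255.
# No installed R package reads PNM; kept deliberately small.
read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  raw_all <- readBin(con, "raw", n = file.info(path)$size)
  # header tokens: magic, width, height, maxval -- with '#' comments
  txt_head <- rawToChar(raw_all[seq_len(min(length(raw_all), 4096L))])
  toks <- character(0); i <- 1L; nch <- nchar(txt_head); pos_after <- NA_integer_
  while (length(toks) < 4L && i <= nch) {
    ch <- substr(txt_head, i, i)
    if (ch == "#") {
      while (i <= nch && substr(txt_head, i, i) != "\n") i <- i + 1L
    } else if (grepl("[[:space:]]", ch)) {
      i <- i + 1L
    } else {
      j <- i
      while (j <= nch && !grepl("[[:space:]]", substr(txt_head, j, j))) j <- j + 1L
      toks <- c(toks, substr(txt_head, i, j - 1L))
      i <- j
    }
  }
  if (length(toks) < 4L) stop("malformed PNM header", call. = FALSE)
  magic <- toks[1L]
  w <- as.integer(toks[2L]); h <- as.integer(toks[3L]); maxv <- as.integer(toks[4L])
  if (is.na(w) || is.na(h) || w < 1L || h < 1L) {
    stop("malformed PNM dimensions", call. = FALSE)
  }
  if (maxv > 255L) stop("PNM maxval > 255 not supported", call. = FALSE)
  nchan <- if (magic %in% c("P3", "P6")) 3L else 1L
  nval <- w * h * nchan
  if (magic %in% c("P2", "P3")) {
    body <- rawToChar(raw_all)
    body <- gsub("#[^\n]*", " ", body)
    toks_all <- scan(text = body, what = character(), quiet = TRUE)
    vals <- as.integer(toks_all[-(1:4)])[seq_len(nval)]
  } else if (magic %in% c("P5", "P6")) {
    # binary data starts one whitespace byte after the maxval token
    pos_after <- i + 1L  # i is 1-based index of the whitespace after token 4
    vals <- as.integer(raw_all[seq(pos_after, length.out = nval)])
  } else {
    stop(sprintf("unsupported PNM magic '%s'", magic), call. = FALSE)
  }
  if (anyNA(vals) || length(vals) < nval) stop("truncated PNM data", call. = FALSE)
  vals <- vals * (255 / maxv)
  if (nchan == 1L) {
    matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  } else {
    a <- array(0, c(h, w, 3L))
    for (k in 1:3) a[, , k] <- matrix(vals[seq(k, nval, by = 3L)], h, w, byrow = TRUE)
    a
  }
}

#' Write an image to disk
#'
#' Writes a [gray_image()] or [binary_image()] as PNG or plain-text PGM (`P2`).
#' Format is chosen from the file extension.
#'
#' @param img image to write.
#' @param path output path ending in `.png` or `.pgm`.
#' @export
write_image <- function(img, path) {
  m <- unclass(img)
  if (inherits(img, "binary_image")) m <- m * 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(m / 255, path)
  } else if (ext == "pgm") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", sprintf("%d %d", ncol(m), nrow(m)), "255"), con)
    apply(m, 1L, function(row) writeLines(paste(as.integer(row), collapse = " "), con))
  } else {
    stop("write_image supports only .png and .pgm", call. = FALSE)
  }
  invisible(path)
}

## ---- small shared raster helpers ------------------------------------------

# shift matrix by (dr, dc) with edge replication: result[r, c] = m[r - dr, c - dc]
shift_replicate <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) - dr, 1L), h)
  ci <- pmin(pmax(seq_len(w) - dc, 1L), w)
  m[ri, ci, drop = FALSE]
}

# shift matrix by (dr, dc) with zero fill
shift_zero <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  rs <- max(1L, 1L + dr):min(h, h + dr)
  cs <- max(1L, 1L + dc):min(w, w + dc)
  if (length(rs) && length(cs)) out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

# bilinear interpolation of matrix m at 0-based subpixel coords (x, y);
# callers must keep x in [0, W-1], y in [0, H-1]
interp_bilinear <- function(m, x, y) {
  h <- nrow(m); w <- ncol(m)
  x0 <- pmin(floor(x), w - 2); y0 <- pmin(floor(y), h - 2)
  x0 <- pmax(x0, 0); y0 <- pmax(y0, 0)
  fx <- x - x0; fy <- y - y0
  i <- y0 + 1L; j <- x0 + 1L  # 1-based top-left
  idx <- function(ii, jj) m[cbind(ii, jj)]
  (1 - fy) * ((1 - fx) * idx(i, j) + fx * idx(i, j + 1L)) +
    fy * ((1 - fx) * idx(i + 1L, j) + fx * idx(i + 1L, j + 1L))
}
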