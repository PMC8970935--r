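#' @keywords internal
"_PACKAGE"

## Validation helpers -------------------------------------------------------

stop_invalid <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

assert_rgb_frame <- function(frame, arg = "frame") {
  if (!is.array(frame) || length(dim(frame)) != 3L || dim(frame)[3] != 3L)
    stop_invalid(arg, "must be a height x width x 3 array")
  if (anyNA(frame) || min(frame) < 0 || max(frame) > 1)
    stop_invalid(arg, "channel intensities must lie in [0, 1]")
  invisible(frame)
}

assert_gray_frame <- function(frame, arg = "frame") {
  if (!is.matrix(frame) || any(dim(frame) < 1L))
    stop_invalid(arg, "must be a non-empty numeric matrix")
  if (anyNA(frame)) stop_invalid(arg, "contains NA")
  invisible(frame)
}

## Reflect padding index map: -p .. n-1+p (0-based) -> 0 .. n-1,
## mirroring with edge duplication ( d c b a | a b c d | d c b a ).
reflect_index <- function(i, n) {
  i <- ifelse(i < 0L, -i - 1L, i)
  ifelse(i >= n, 2L * n - i - 1L, i)
}

## Bilinear interpolation of matrix `m` at real-valued (row, col), 0-based.
bilinear <- function(m, row, col) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- pmin(pmax(floor(row), 0), nr - 1L)
  c0 <- pmin(pmax(floor(col), 0), nc - 1L)
  r1 <- pmin(r0 + 1, nr - 1L)
  c1 <- pmin(c0 + 1, nc - 1L)
  fr <- row - r0; fc <- col - c0
  m[cbind(r0 + 1, c0 + 1)] * (1 - fr) * (1 - fc) +
    m[cbind(r1 + 1, c0 + 1)] * fr * (1 - fc) +
    m[cbind(r0 + 1, c1 + 1)] * (1 - fr) * fc +
    m[cbind(r1 + 1, c1 + 1)] * fr * fc
}

## Image I/O ---------------------------------------------------------------

#' Read an RGB frame from a PNG file
#'
#' Intensities are returned on the real \[0, 1\] scale; 8-bit files are
#' divided by 255 by the reader. Grayscale files are replicated to three
#' channels; an alpha channel, if present, is dropped.
#'
#' @param path path to a PNG file.
#' @return a height x width x 3 numeric array in \[0, 1\].
#' @export
read_frame <- function(path) {
  img <- png::readPNG(path)
  if (is.matrix(img)) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] >= 4L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write an RGB frame or grayscale matrix as PNG
#'
#' @param frame a height x width x 3 array or a matrix, values in \[0, 1\].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path) {
  png::writePNG(frame, path)
  invisible(path)
}

#' Read a lexicographically ordered directory of PNG frames
#'
#' @param dir directory containing `*.png` frames.
#' @return a list of RGB frame arrays, in lexicographic filename order.
#' @export
read_frame_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L) stop_invalid("dir", paste0("no PNG frames found in ", dir))
  lapply(files, read_frame)
}

## HSV helpers -------------------------------------------------------------

## Hue/saturation/value of an RGB frame, each as a matrix. Hue in [0, 1)
## (1 == 360 degrees); undefined hue (gray pixels) reported as 0 with s = 0.
frame_hsv <- function(frame) {
  d <- dim(frame)
  px <- rbind(as.vector(frame[, , 1]), as.vector(frame[, , 2]), as.vector(frame[, , 3]))
  hsv <- grDevices::rgb2hsv(px, maxColorValue = 1)
  list(h = matrix(hsv[1, ], d[1], d[2]),
       s = matrix(hsv[2, ], d[1], d[2]),
       v = matrix(hsv[3, ], d[1], d[2]))
}
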