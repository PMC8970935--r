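## Frame-level preprocessing and moment features.

#' Convert an RGB frame to grayscale
#'
#' Uses the luminance weighting `Gray = 0.299 R + 0.587 G + 0.114 B`; since
#' the weights sum to one the output stays in \[0, 1\] and equal-channel
#' (achromatic) pixels map to themselves.
#'
#' @param frame height x width x 3 array, channel intensities in \[0, 1\].
#' @return a grayscale matrix in \[0, 1\].
#' @examples
#' to_gray(array(c(1, 0, 0), c(1, 1, 3)))  # 0.299
#' @export
to_gray <- function(frame) {
  assert_rgb_frame(frame)
  0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
}

#' Separable low-pass filter kernel
#'
#' A one-dimensional tap vector defining, by outer product with itself, the
#' 2-D smoothing filter applied before moment extraction. The default taps
#' `c(1, 2, 1) / 4` are the normalized Haar-like scaling filter.
#'
#' @param taps numeric vector of odd length, finite.
#' @return an object of class `filter_kernel` with fields `taps_1d` and
#'   `normalization` (the tap sum).
#' @export
filter_kernel <- function(taps = c(1, 2, 1) / 4) {
  if (length(taps) < 1L || length(taps) %% 2L == 0L)
    stop_invalid("taps", "must have odd length >= 1")
  if (!all(is.finite(taps))) stop_invalid("taps", "must be finite")
  structure(list(taps_1d = as.numeric(taps), normalization = sum(taps)),
            class = "filter_kernel")
}

#' @export
print.filter_kernel <- function(x, ...) {
  cat("Separable filter kernel:", paste(signif(x$taps_1d, 4), collapse = " "),
      sprintf("(sum %.4g)\n", x$normalization))
  invisible(x)
}

## 1-D convolution of each column of `m` with `taps`, reflect padding.
conv_cols <- function(m, taps) {
  p <- (length(taps) - 1L) %/% 2L
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(taps)) {
    off <- j - 1L - p
    idx <- reflect_index(seq_len(n) - 1L + off, n) + 1L
    out <- out + taps[j] * m[idx, , drop = FALSE]
  }
  out
}

#' Smooth a grayscale frame with a separable kernel
#'
#' Convolves with the outer product of the kernel taps with themselves,
#' reflect-padding at the borders so the output has the source shape.
#'
#' @param frame grayscale matrix.
#' @param kernel a [filter_kernel()].
#' @return filtered matrix, same shape as `frame`.
#' @export
filter_frame <- function(frame, kernel = filter_kernel()) {
  assert_gray_frame(frame)
  if (!inherits(kernel, "filter_kernel")) kernel <- filter_kernel(kernel)
  t(conv_cols(t(conv_cols(frame, kernel$taps_1d)), kernel$taps_1d))
}

#' Central moments of a weight image
#'
#' Treats `weights` (a gray image or binary mask, non-negative) as a mass
#' distribution over the pixel grid and computes the mass `E_00`, the mass
#' centroid, and all central moments
#' `E_pq = sum (r - rbar)^p (c - cbar)^q D(r, c)` with `p + q <= max_order`.
#' `p` indexes rows and `q` columns; coordinates are 0-based.
#'
#' @param weights non-negative matrix with positive total mass.
#' @param max_order highest total order `p + q` computed (default 4).
#' @return object of class `central_moments`: fields `mass`, `centroid`
#'   (row, col) and `E`, a named list keyed `"p_q"`.
#' @export
central_moments <- function(weights, max_order = 4L) {
  assert_gray_frame(weights, "weights")
  if (min(weights) < 0) stop_invalid("weights", "must be non-negative")
  mass <- sum(weights)
  if (mass <= 0)
    stop("degenerate input: total mass is zero, centroid undefined", call. = FALSE)
  r <- row(weights) - 1
  c <- col(weights) - 1
  rbar <- sum(r * weights) / mass
  cbar <- sum(c * weights) / mass
  E <- list()
  for (p in 0:max_order) for (q in 0:(max_order - p)) {
    E[[sprintf("%d_%d", p, q)]] <- sum((r - rbar)^p * (c - cbar)^q * weights)
  }
  structure(list(mass = mass, centroid = c(rbar, cbar), E = E,
                 max_order = as.integer(max_order)),
            class = "central_moments")
}

#' @export
print.central_moments <- function(x, ...) {
  cat(sprintf("Central moments up to order %d: mass %.6g, centroid (%.3f, %.3f)\n",
              x$max_order, x$mass, x$centroid[1], x$centroid[2]))
  invisible(x)
}

#' Normalized central moments
#'
#' Scales each central moment by a power of the mass,
#' `eta_pq = E_pq / E_00^gamma` with `gamma = (p + q)/2 + 1`, for total
#' orders `p + q` in 2..4 — the normalization that makes the moments
#' approximately invariant to uniform scaling of a binary shape.
#'
#' @param m a [central_moments()] object with `max_order >= 2` and mass > 0.
#' @param orders total orders to normalize; only values in 2..4 are defined.
#' @return object of class `normalized_moments`: `eta` and `gamma`, named
#'   lists keyed `"p_q"`.
#' @export
normalized_moments <- function(m, orders = 2:4) {
  stopifnot(inherits(m, "central_moments"))
  if (m$mass <= 0) stop("degenerate input: E_00 must be positive", call. = FALSE)
  if (!all(orders %in% 2:4))
    stop_invalid("orders", "normalization exponent is defined for p+q in 2..4 only")
  orders <- orders[orders <= m$max_order]
  eta <- list(); gamma <- list()
  for (p in 0:max(orders)) for (q in 0:(max(orders) - p)) {
    if (!(p + q) %in% orders) next
    g <- (p + q) / 2 + 1
    key <- sprintf("%d_%d", p, q)
    eta[[key]] <- m$E[[key]] / m$mass^g
    gamma[[key]] <- g
  }
  structure(list(eta = eta, gamma = gamma), class = "normalized_moments")
}

#' @export
print.normalized_moments <- function(x, ...) {
  cat("Normalized moments eta_pq for", length(x$eta), "order pairs\n")
  invisible(x)
}
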