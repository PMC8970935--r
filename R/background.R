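## Per-pixel Gaussian-mixture background model on grayscale frames, with
## online updates (match at a fixed number of standard deviations, replace
## the weakest component on no-match) and foreground extraction by
## differencing against the reconstructed background image.

#' Initialize a per-pixel Gaussian mixture background model
#'
#' Component 1 of every pixel is centred on the first frame's value with
#' weight 1; the remaining `K - 1` components start empty (weight 0, mean 0,
#' variance at the floor).
#'
#' @param first_frame grayscale matrix in \[0, 1\].
#' @param K mixture components per pixel (>= 1, default 3).
#' @param learning_rate update rate alpha in (0, 1).
#' @param match_threshold match radius in standard deviations.
#' @param background_fraction fraction T of cumulative weight treated as
#'   background when ranking components.
#' @param var_init variance of the component seeded from the first frame.
#' @param var_replace (large) variance given to a component replaced on a
#'   no-match update.
#' @param var_floor lower bound kept on all variances.
#' @return an object of class `pixel_gmm` with per-pixel weight, mean and
#'   variance arrays (`height x width x K`).
#' @export
init_gmm <- function(first_frame, K = 3L, learning_rate = 0.05,
                     match_threshold = 2.5, background_fraction = 0.7,
                     var_init = 0.0025, var_replace = 0.01, var_floor = 1e-4) {
  assert_gray_frame(first_frame, "first_frame")
  if (K < 1) stop_invalid("K", "must be >= 1")
  if (learning_rate <= 0 || learning_rate >= 1)
    stop_invalid("learning_rate", "must be in (0, 1)")
  if (var_floor <= 0) stop_invalid("var_floor", "must be positive")
  h <- nrow(first_frame); w <- ncol(first_frame)
  wts <- array(0, c(h, w, K)); mu <- array(0, c(h, w, K))
  va <- array(var_floor, c(h, w, K))
  wts[, , 1] <- 1
  mu[, , 1] <- first_frame
  va[, , 1] <- max(var_init, var_floor)
  structure(list(weights = wts, means = mu, vars = va, K = as.integer(K),
                 learning_rate = learning_rate, match_threshold = match_threshold,
                 background_fraction = background_fraction,
                 var_init = max(var_init, var_floor),
                 var_replace = max(var_replace, var_floor), var_floor = var_floor,
                 n_updates = 0L),
            class = "pixel_gmm")
}

#' @export
print.pixel_gmm <- function(x, ...) {
  cat(sprintf("Per-pixel Gaussian mixture background model: %d x %d pixels, K = %d, alpha = %g, %d update(s)\n",
              dim(x$weights)[1], dim(x$weights)[2], x$K, x$learning_rate, x$n_updates))
  invisible(x)
}

#' Online update of the background mixture with one frame
#'
#' Per pixel: a component matches when `|x - mu| <= match_threshold * sigma`.
#' The best-ranked (highest weight/sigma) matching component is pulled
#' toward the pixel value with rate alpha for weight, mean and variance;
#' every other component's weight decays by `(1 - alpha)`. When no component
#' matches, the weakest component is replaced by (x, var_init, small
#' weight). Weights are renormalized to sum to one at every pixel.
#'
#' @param model a `pixel_gmm`.
#' @param frame grayscale matrix, shape matching the model.
#' @return the updated `pixel_gmm`.
#' @export
update_gmm <- function(model, frame) {
  stopifnot(inherits(model, "pixel_gmm"))
  assert_gray_frame(frame)
  dm <- dim(model$weights)
  if (!all(dim(frame) == dm[1:2])) stop_invalid("frame", "shape does not match model")
  K <- model$K; n <- dm[1] * dm[2]
  a <- model$learning_rate
  W <- matrix(model$weights, n, K)
  M <- matrix(model$means, n, K)
  V <- matrix(model$vars, n, K)
  x <- as.vector(frame)

  sd <- sqrt(V)
  match <- abs(x - M) <= model$match_threshold * sd
  rank_score <- W / sd
  score <- ifelse(match, rank_score, -Inf)
  best <- max.col(score, ties.method = "first")      # best matching component
  has_match <- match[cbind(seq_len(n), best)]

  ## decay all weights, then add alpha to the matched component
  W <- (1 - a) * W
  idx <- cbind(which(has_match), best[has_match])
  W[idx] <- W[idx] + a
  xm <- x[has_match]
  M[idx] <- (1 - a) * M[idx] + a * xm
  V[idx] <- (1 - a) * V[idx] + a * (xm - M[idx])^2

  ## replace the weakest component where nothing matched
  if (any(!has_match)) {
    weakest <- max.col(-W, ties.method = "first")
    ridx <- cbind(which(!has_match), weakest[!has_match])
    W[ridx] <- a
    M[ridx] <- x[!has_match]
    V[ridx] <- model$var_replace
  }
  V <- pmax(V, model$var_floor)
  W <- W / rowSums(W)

  model$weights <- array(W, dm); model$means <- array(M, dm); model$vars <- array(V, dm)
  model$n_updates <- model$n_updates + 1L
  model
}

#' Reconstructed background image
#'
#' Per pixel, the mean of the component ranked first by weight/sigma — the
#' head of the cumulative-weight ranking whose top `background_fraction` is
#' treated as background.
#'
#' @param model a `pixel_gmm`.
#' @return grayscale matrix of background means.
#' @export
background_image <- function(model) {
  stopifnot(inherits(model, "pixel_gmm"))
  dm <- dim(model$weights); n <- dm[1] * dm[2]
  W <- matrix(model$weights, n, model$K)
  V <- matrix(model$vars, n, model$K)
  M <- matrix(model$means, n, model$K)
  best <- max.col(W / sqrt(V), ties.method = "first")
  matrix(M[cbind(seq_len(n), best)], dm[1], dm[2])
}

#' Foreground mask by background differencing
#'
#' Thresholds the absolute difference between the frame and the
#' reconstructed background, then applies one morphological opening with a
#' 3 x 3 box element to suppress single-pixel noise.
#'
#' @param model a `pixel_gmm`.
#' @param frame grayscale matrix.
#' @param diff_threshold intensity difference above which a pixel is
#'   foreground (default 0.1).
#' @return an object of class `foreground_mask`: logical matrix `mask` plus
#'   `frame_index` (the model's update count when extracted).
#' @export
foreground_mask <- function(model, frame, diff_threshold = 0.1) {
  stopifnot(inherits(model, "pixel_gmm"))
  assert_gray_frame(frame)
  raw <- abs(frame - background_image(model)) > diff_threshold
  opened <- EBImage::opening(raw * 1, EBImage::makeBrush(3, "box"))
  structure(list(mask = matrix(as.logical(opened > 0.5), nrow(frame), ncol(frame)),
                 frame_index = model$n_updates),
            class = "foreground_mask")
}

#' @export
print.foreground_mask <- function(x, ...) {
  cat(sprintf("Foreground mask: %d x %d, %d foreground pixel(s), after %d update(s)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$frame_index))
  invisible(x)
}

#' Intersection-over-union of two binary masks
#'
#' @param a,b logical matrices of equal shape.
#' @return IoU in \[0, 1\]; 1 when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  if (inherits(a, "foreground_mask")) a <- a$mask
  if (inherits(b, "foreground_mask")) b <- b$mask
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
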