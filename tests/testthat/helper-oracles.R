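# Independent brute-force oracles. These deliberately re-derive results by
# direct summation / enumeration, never by calling the implementation path
# they check.

# Direct (non-separable) 2-D convolution with the outer-product kernel and
# reflect padding, one output pixel at a time.
oracle_conv2d <- function(frame, taps) {
  K <- outer(taps, taps)
  p <- (length(taps) - 1L) %/% 2L
  nr <- nrow(frame); nc <- ncol(frame)
  refl <- function(i, n) { i <- ifelse(i < 1L, 1L - i, i); ifelse(i > n, 2L * n + 1L - i, i) }
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    acc <- 0
    for (dr in -p:p) for (dc in -p:p)
      acc <- acc + K[dr + p + 1L, dc + p + 1L] * frame[refl(r + dr, nr), refl(c + dc, nc)]
    out[r, c] <- acc
  }
  out
}

# Scalar re-implementation of the per-pixel mixture update recursion for a
# single pixel: decay all weights, pull the best-ranked matching component
# (match within `thr` standard deviations, rank by weight/sigma) toward x
# with rate `a`, replace the weakest component on no-match, renormalize.
oracle_gmm_step <- function(state, x, a = 0.05, thr = 2.5,
                            var_replace = 0.01, var_floor = 1e-4) {
  w <- state$w; mu <- state$mu; v <- state$v
  match <- abs(x - mu) <= thr * sqrt(v)
  score <- ifelse(match, w / sqrt(v), -Inf)
  best <- which.max(score)
  has_match <- match[best]
  w <- (1 - a) * w
  if (has_match) {
    w[best] <- w[best] + a
    mu[best] <- (1 - a) * mu[best] + a * x
    v[best] <- (1 - a) * v[best] + a * (x - mu[best])^2
  } else {
    weakest <- which.min(w)
    w[weakest] <- a; mu[weakest] <- x; v[weakest] <- var_replace
  }
  v <- pmax(v, var_floor)
  list(w = w / sum(w), mu = mu, v = v)
}

# Brute-force pixel count inside an axis-aligned ellipse (point-in-ellipse
# test per pixel centre, 0-based grid).
oracle_ellipse_area <- function(height, width, center, axes) {
  n <- 0L
  for (r in 0:(height - 1)) for (c in 0:(width - 1))
    if (((r - center[1]) / axes[1])^2 + ((c - center[2]) / axes[2])^2 <= 1) n <- n + 1L
  n
}

# Brute-force nearest neighbour over a coefficient matrix (loop over pairs).
oracle_nn <- function(query, coefficients, labels) {
  best_d <- Inf; best_i <- NA_integer_
  for (i in seq_len(nrow(coefficients))) {
    d <- sqrt(sum((coefficients[i, ] - query)^2))
    if (d < best_d) { best_d <- d; best_i <- i }
  }
  list(label = labels[best_i], distance = best_d, index = best_i)
}

# Brute-force red-pixel count under the documented thresholds.
oracle_red_count <- function(frame, hue_tol = 15, sat_min = 0.5, val_min = 0.3) {
  n <- 0L
  for (r in seq_len(dim(frame)[1])) for (c in seq_len(dim(frame)[2])) {
    px <- frame[r, c, ]
    hsv <- grDevices::rgb2hsv(matrix(px, 3, 1), maxColorValue = 1)
    deg <- hsv[1] * 360
    if ((deg <= hue_tol || deg >= 360 - hue_tol) && hsv[2] >= sat_min && hsv[3] >= val_min)
      n <- n + 1L
  }
  n
}

# Frames for a teleporting small blob: first half from one scene, second
# half from another whose blob sits far away; returns frames + stitched
# ground-truth trajectory and the 0-based teleport frame index.
teleport_fixture <- function(seed = 3L) {
  small_blob <- function(start, vel, seed) {
    scene_config(
      height = 64, width = 64, n_frames = 40, background_texture = "noise",
      blobs = list(list(start_center = start, velocity = vel,
                        axes = c(5, 4), body_color = c(0.15, 0.25, 0.8))),
      markers = list(list(blob = 1L, offset = c(-3, 0), radius = 1.5,
                          color = c(1, 0.05, 0.05))),
      noise_sigma = 0.01, seed = seed)
  }
  a <- make_scene(small_blob(c(20, 12), c(0, 0.8), seed))
  b <- make_scene(small_blob(c(45, 50), c(0, 0.2), seed + 1L))
  list(frames = c(a$frames[1:20], b$frames[21:40]),
       trajectory = rbind(a$truth$trajectories[[1]][1:20, ],
                          b$truth$trajectories[[1]][21:40, ]),
       teleport_frame = 20L,
       init_window = search_window(c(20, 12), c(7, 6)))
}
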