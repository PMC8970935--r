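## Kernel-histogram target modelling, back-projection, CAMSHIFT window
## tracking, and red-marker detection used as colour feedback when the
## tracker's confidence collapses.

#' Rectangular search window
#'
#' @param center (row, col) centre in pixels, 0-based, real-valued.
#' @param half_extent (half_rows, half_cols) in pixels, each >= 1.
#' @return object of class `search_window`.
#' @export
search_window <- function(center, half_extent) {
  if (any(half_extent < 1)) stop_invalid("half_extent", "extents must be >= 1")
  structure(list(center = as.numeric(center), half_extent = as.numeric(half_extent)),
            class = "search_window")
}

#' @export
print.search_window <- function(x, ...) {
  cat(sprintf("Search window: centre (%.2f, %.2f), half-extent (%.2f, %.2f)\n",
              x$center[1], x$center[2], x$half_extent[1], x$half_extent[2]))
  invisible(x)
}

## Integer pixel grid covered by a window, clipped to the frame; 0-based.
window_pixels <- function(window, height, width) {
  r0 <- max(0L, ceiling(window$center[1] - window$half_extent[1]))
  r1 <- min(height - 1L, floor(window$center[1] + window$half_extent[1]))
  c0 <- max(0L, ceiling(window$center[2] - window$half_extent[2]))
  c1 <- min(width - 1L, floor(window$center[2] + window$half_extent[2]))
  if (r0 > r1 || c0 > c1) return(NULL)
  list(rows = r0:r1, cols = c0:c1)
}

## Colour bin index per pixel: hue quantized into n_bins plus one trailing
## achromatic bin for pixels with saturation below sat_min.
bin_image <- function(frame, n_bins, sat_min = 0.1) {
  hsv <- frame_hsv(frame)
  b <- pmin(floor(hsv$h * n_bins), n_bins - 1L) + 1L
  b[hsv$s < sat_min] <- n_bins + 1L
  b
}

#' Kernel-weighted colour histogram of a target window
#'
#' The target model `p_u = I_h * sum_i k(||(y - x_i)/h||^2) delta(b(x_i) - u)`
#' over the window pixels, with `y` the window centre, bandwidth `h` the
#' window half-diagonal, `b(x)` the hue-bin index (saturation below 0.1 maps
#' to a dedicated achromatic bin), Epanechnikov profile
#' `k(r) = max(0, 1 - r)`, and `I_h` the constant normalizing the histogram
#' to unit total mass.
#'
#' @param frame RGB frame array.
#' @param window a [search_window()] intersecting the frame.
#' @param n_bins number of hue bins (>= 2, default 16); the model carries
#'   `n_bins + 1` bins, the last being achromatic.
#' @param kernel kernel profile name; `"epanechnikov"` or `"uniform"`.
#' @return object of class `target_model` with fields `p` (normalized bin
#'   masses), `n_bins`, `bandwidth`, `kernel`, `I_h`.
#' @export
build_target_model <- function(frame, window, n_bins = 16L,
                               kernel = c("epanechnikov", "uniform")) {
  assert_rgb_frame(frame)
  kernel <- match.arg(kernel)
  if (n_bins < 2) stop_invalid("n_bins", "must be >= 2")
  d <- dim(frame)
  px <- window_pixels(window, d[1], d[2])
  if (is.null(px)) stop("degenerate input: window does not cover any pixel", call. = FALSE)
  h <- sqrt(sum(window$half_extent^2))
  bins <- bin_image(frame, n_bins)[px$rows + 1L, px$cols + 1L, drop = FALSE]
  r2 <- outer((px$rows - window$center[1])^2, (px$cols - window$center[2])^2, "+") / h^2
  kw <- if (kernel == "epanechnikov") pmax(0, 1 - r2) else (r2 <= 1) * 1
  tot <- sum(kw)
  if (tot <= 0) stop("degenerate input: zero kernel mass in window", call. = FALSE)
  p <- as.vector(tapply(kw, factor(bins, levels = seq_len(n_bins + 1L)), sum,
                        default = 0))
  structure(list(p = p / tot, n_bins = as.integer(n_bins), bandwidth = h,
                 kernel = kernel, I_h = 1 / tot),
            class = "target_model")
}

#' @export
print.target_model <- function(x, ...) {
  cat(sprintf("Target colour model: %d hue bins + achromatic, bandwidth %.2f px, %s profile\n",
              x$n_bins, x$bandwidth, x$kernel))
  invisible(x)
}

#' Histogram back-projection of a target model
#'
#' Replaces every pixel with the model probability `p_u` of its colour bin.
#'
#' @param frame RGB frame array.
#' @param model a [build_target_model()] result.
#' @return weight matrix in \[0, 1\].
#' @export
backproject <- function(frame, model) {
  assert_rgb_frame(frame)
  stopifnot(inherits(model, "target_model"))
  b <- bin_image(frame, model$n_bins)
  matrix(model$p[b], nrow(b), ncol(b))
}

#' One CAMSHIFT step: mean-shift recentre plus window resize
#'
#' Recentres the window on the weighted centroid of the back-projection
#' weights inside it, then rescales the half-extents proportionally to the
#' square root of the windowed zeroth moment with the aspect ratio
#' preserved. The constant follows standard CAMSHIFT practice (full extent
#' `2 * sqrt(M00)` for unit-scaled weights), which sizes the window from
#' the captured target mass rather than the previous window area — the
#' window always extends past a uniform target's boundary, keeping the
#' centroid responsive to target motion.
#' Extents are clamped to \[`min_extent`, frame size\]. A
#' window with zero captured mass is returned unchanged with `lost = TRUE`.
#'
#' @param weights back-projection weight matrix.
#' @param window a [search_window()].
#' @param resize apply the size adaptation (default TRUE).
#' @param min_extent smallest allowed half-extent in px.
#' @return a `search_window` with attributes `m00` (windowed zeroth moment)
#'   and `lost`.
#' @export
camshift_step <- function(weights, window, resize = TRUE, min_extent = 4) {
  assert_gray_frame(weights, "weights")
  px <- window_pixels(window, nrow(weights), ncol(weights))
  if (is.null(px)) {
    attr(window, "m00") <- 0; attr(window, "lost") <- TRUE
    return(window)
  }
  w <- weights[px$rows + 1L, px$cols + 1L, drop = FALSE]
  m00 <- sum(w)
  if (m00 <= 0) {
    attr(window, "m00") <- 0; attr(window, "lost") <- TRUE
    return(window)
  }
  new_center <- c(sum(px$rows * rowSums(w)), sum(px$cols * colSums(w))) / m00
  he <- window$half_extent
  if (resize) {
    rho <- he[1] / he[2]
    he <- sqrt(m00) * c(sqrt(rho), 1 / sqrt(rho))
    he <- pmin(pmax(he, min_extent), c(nrow(weights), ncol(weights)) / 2)
  }
  out <- search_window(new_center, he)
  attr(out, "m00") <- m00; attr(out, "lost") <- FALSE
  out
}

## Mean-shift recentring iterations at fixed size; a move is accepted only
## if the captured mass does not decrease, so the windowed zeroth moment is
## non-decreasing across iterations. Resize applied once at the end.
camshift_converge <- function(weights, window, max_iter = 20L, tol = 0.5,
                              min_extent = 4) {
  cur <- window
  m00 <- attr(camshift_step(weights, cur, resize = FALSE), "m00")
  lost <- m00 <= 0
  if (!lost) {
    for (it in seq_len(max_iter)) {
      nxt <- camshift_step(weights, cur, resize = FALSE)
      m00_new <- attr(camshift_step(weights, nxt, resize = FALSE), "m00")
      if (m00_new < m00 - 1e-12) break   # would descend: stop at current window
      shift <- sqrt(sum((nxt$center - cur$center)^2))
      cur <- nxt; m00 <- m00_new
      if (shift < tol) break
    }
    cur <- camshift_step(weights, cur, resize = TRUE, min_extent = min_extent)
    lost <- isTRUE(attr(cur, "lost"))
  }
  attr(cur, "m00") <- m00; attr(cur, "lost") <- lost
  cur
}

#' Detect saturated-red marker regions
#'
#' Thresholds pixels whose hue lies within `hue_tol` degrees of 0/360 with
#' saturation >= `sat_min` and value >= `val_min`, groups them by
#' 8-connected component labelling, and returns components of at least
#' `min_area` pixels, sorted by area (largest first).
#'
#' @param frame RGB frame array.
#' @param hue_tol hue tolerance around red, degrees (default 15).
#' @param sat_min minimum saturation (default 0.5).
#' @param val_min minimum value (default 0.3).
#' @param min_area minimum component area in pixels (default 3).
#' @return list of detections, each with `centroid` (row, col), `contour`
#'   (boundary pixels ordered by angle about the centroid), and `area`.
#' @export
detect_red_markers <- function(frame, hue_tol = 15, sat_min = 0.5,
                               val_min = 0.3, min_area = 3L) {
  assert_rgb_frame(frame)
  hsv <- frame_hsv(frame)
  deg <- hsv$h * 360
  mask <- (deg <= hue_tol | deg >= 360 - hue_tol) & hsv$s >= sat_min & hsv$v >= val_min
  lab <- label_components(mask)
  if (max(lab) == 0L) return(list())
  dets <- lapply(seq_len(max(lab)), function(k) {
    idx <- which(lab == k, arr.ind = TRUE) - 1L   # 0-based (row, col)
    if (nrow(idx) < min_area) return(NULL)
    centroid <- colMeans(idx)
    ## boundary: component pixels with a 4-neighbour outside the component
    on <- matrix(FALSE, nrow(mask), ncol(mask))
    on[idx + 1L] <- TRUE
    bd <- idx[apply(idx, 1L, function(p) {
      r <- p[1] + 1L; c <- p[2] + 1L
      r == 1L || c == 1L || r == nrow(on) || c == ncol(on) ||
        !(on[r - 1L, c] && on[r + 1L, c] && on[r, c - 1L] && on[r, c + 1L])
    }), , drop = FALSE]
    ang <- atan2(bd[, 1] - centroid[1], bd[, 2] - centroid[2])
    list(centroid = unname(centroid), contour = unname(bd[order(ang), , drop = FALSE]),
         area = nrow(idx))
  })
  dets <- Filter(Negate(is.null), dets)
  dets[order(vapply(dets, `[[`, numeric(1), "area"), decreasing = TRUE)]
}

## 8-connected component labelling of a logical matrix (two-pass scan with
## union-find); returns an integer label matrix, 0 = background.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nxt <- 0L
  for (c in seq_len(nc)) for (r in seq_len(nr)) {
    if (!mask[r, c]) next
    nb <- integer(0)
    for (d in list(c(-1L, 0L), c(0L, -1L), c(-1L, -1L), c(1L, -1L))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc && lab[rr, cc] > 0L)
        nb <- c(nb, lab[rr, cc])
    }
    if (length(nb) == 0L) {
      nxt <- nxt + 1L; parent[nxt] <- nxt; lab[r, c] <- nxt
    } else {
      roots <- vapply(unique(nb), find, integer(1))
      keep <- min(roots)
      lab[r, c] <- keep
      for (rt in roots) parent[rt] <- keep
    }
  }
  if (nxt == 0L) return(lab)
  remap <- vapply(seq_len(nxt), find, integer(1))
  remap <- match(remap, sort(unique(remap)))
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}

#' Track a target through a frame sequence
#'
#' Builds a kernel colour histogram of the initial window on the first
#' frame, then per frame back-projects the model (with the achromatic bin
#' zeroed — low-saturation pixels carry no colour evidence and must not
#' attract the window — and scaled by the maximum remaining bin mass,
#' standard CAMSHIFT practice), runs mean-shift recentring to
#' convergence (centre shift below 0.5 px or `max_iter` iterations) and one
#' window resize. Confidence is the mean scaled back-projection weight
#' inside the window; when it drops below `feedback_fraction` of its
#' initial value the window is re-centred on the nearest detected red
#' marker (distance to the last good centre, ties broken by larger area),
#' restored to its initial size, and the event recorded.
#'
#' @param frames a `frame_sequence` from [make_scene()] or a plain list of
#'   RGB frame arrays.
#' @param init_window a [search_window()] valid on the first frame.
#' @param n_bins hue bins for the target model.
#' @param max_iter mean-shift iteration cap per frame.
#' @param feedback_fraction confidence fraction triggering marker feedback.
#' @param marker_params list of arguments passed to [detect_red_markers()].
#' @return object of class `mofex_track`: data frame `windows` with columns
#'   frame, row, col, half_rows, half_cols, confidence, reinit; plus
#'   `reinit_events` (frame indices) and the `target_model`.
#' @export
track <- function(frames, init_window, n_bins = 16L, max_iter = 20L,
                  feedback_fraction = 0.3, marker_params = list()) {
  if (inherits(frames, "frame_sequence")) frames <- frames$frames
  if (length(frames) == 0L) stop_invalid("frames", "sequence is empty")
  model <- build_target_model(frames[[1]], init_window, n_bins = n_bins)
  bp_model <- model
  bp_model$p[model$n_bins + 1L] <- 0   # achromatic pixels do not pull the window
  scale <- max(bp_model$p)
  if (scale <= 0) stop("degenerate input: initial window has no chromatic mass", call. = FALSE)
  window <- init_window
  init_he <- init_window$half_extent
  init_conf <- NA_real_
  rows <- vector("list", length(frames))
  reinit_events <- integer(0)
  for (t in seq_along(frames)) {
    weights <- backproject(frames[[t]], bp_model) / scale
    window <- camshift_converge(weights, window, max_iter = max_iter)
    conf <- window_confidence(weights, window)
    reinit <- 0L
    if (t == 1L) init_conf <- conf
    if (conf < feedback_fraction * init_conf || isTRUE(attr(window, "lost"))) {
      dets <- do.call(detect_red_markers, c(list(frames[[t]]), marker_params))
      if (length(dets) > 0L) {
        last <- window$center
        d2 <- vapply(dets, function(m) sum((m$centroid - last)^2), numeric(1))
        ar <- vapply(dets, `[[`, numeric(1), "area")
        pick <- order(d2, -ar)[1]
        window <- search_window(dets[[pick]]$centroid, init_he)
        window <- camshift_converge(weights, window, max_iter = max_iter)
        conf <- window_confidence(weights, window)
        reinit <- 1L
        reinit_events <- c(reinit_events, t)
      }
    }
    rows[[t]] <- data.frame(frame = t - 1L, row = window$center[1],
                            col = window$center[2],
                            half_rows = window$half_extent[1],
                            half_cols = window$half_extent[2],
                            confidence = conf, reinit = reinit)
  }
  structure(list(windows = do.call(rbind, rows), reinit_events = reinit_events,
                 target_model = model),
            class = "mofex_track")
}

## Mean back-projection weight inside the window (density in [0, 1] for
## max-scaled weights); 0 when the window captures nothing.
window_confidence <- function(weights, window) {
  px <- window_pixels(window, nrow(weights), ncol(weights))
  if (is.null(px)) return(0)
  mean(weights[px$rows + 1L, px$cols + 1L])
}

#' @export
print.mofex_track <- function(x, ...) {
  cat(sprintf("Track over %d frame(s), %d feedback re-initialization(s)\n",
              nrow(x$windows), length(x$reinit_events)))
  invisible(x)
}

#' Write a track as CSV
#'
#' Columns: frame, row, col, half_rows, half_cols, confidence, reinit.
#'
#' @param x a `mofex_track`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_track_csv <- function(x, path) {
  stopifnot(inherits(x, "mofex_track"))
  utils::write.csv(x$windows, path, row.names = FALSE)
  invisible(path)
}

#' Root-mean-square tracking error against a ground-truth trajectory
#'
#' @param x a `mofex_track`.
#' @param trajectory matrix with columns row, col (one row per frame).
#' @return RMSE of the window centre in pixels.
#' @export
track_rmse <- function(x, trajectory) {
  stopifnot(inherits(x, "mofex_track"), nrow(trajectory) == nrow(x$windows))
  sqrt(mean((x$windows$row - trajectory[, 1])^2 + (x$windows$col - trajectory[, 2])^2))
}
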