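## Seeded synthetic scenes with full ground truth: a static (optionally
## textured) background plus moving elliptical "person" blobs carrying small
## saturated-red marker patches. Coordinates are (row, col), 0-based, origin
## top-left; intensities are real-valued in [0, 1].

#' Configuration of a synthetic scene
#'
#' @param height,width frame size in pixels (>= 32).
#' @param n_frames number of frames (>= 2).
#' @param background_texture `"flat"` for a uniform background or `"noise"`
#'   for a static speckle texture (fixed across frames, drawn once from the
#'   seed with standard deviation `texture_sigma`).
#' @param background_value base background intensity (gray level).
#' @param blobs list of blobs; each a list with `start_center` (row, col),
#'   `velocity` (d_row, d_col) in px/frame, `axes` (semi-axes a, b in px,
#'   a along rows), and `body_color` (RGB in \[0, 1\]).
#' @param markers list of markers; each a list with `blob` (index of the
#'   carrying blob), `offset` (row, col) from the blob centre, `radius` in
#'   px, and `color` (RGB, saturated red by default).
#' @param noise_sigma standard deviation of the per-frame additive Gaussian
#'   noise (intensity units); added after rendering and clipped to \[0, 1\].
#' @param texture_sigma standard deviation of the static background texture.
#' @param seed integer seed; equal seeds give bit-identical scenes.
#' @return a validated object of class `scene_config`.
#' @seealso [make_scene()], [default_scene_config()]
#' @export
scene_config <- function(height, width, n_frames,
                         background_texture = c("flat", "noise"),
                         background_value = 0.5,
                         blobs = list(), markers = list(),
                         noise_sigma = 0, texture_sigma = 0.05, seed = 1L) {
  background_texture <- match.arg(background_texture)
  if (height < 32 || width < 32) stop_invalid("height/width", "must be >= 32")
  if (n_frames < 2) stop_invalid("n_frames", "must be >= 2")
  if (noise_sigma < 0) stop_invalid("noise_sigma", "must be >= 0")
  if (background_value < 0 || background_value > 1)
    stop_invalid("background_value", "must be in [0, 1]")
  for (i in seq_along(blobs)) {
    b <- blobs[[i]]
    need <- c("start_center", "velocity", "axes", "body_color")
    if (!all(need %in% names(b)))
      stop_invalid(sprintf("blobs[[%d]]", i),
                   paste("needs fields", paste(need, collapse = ", ")))
    if (any(b$axes <= 0)) stop_invalid(sprintf("blobs[[%d]]$axes", i), "must be positive")
    if (any(b$body_color < 0 | b$body_color > 1))
      stop_invalid(sprintf("blobs[[%d]]$body_color", i), "must be in [0, 1]")
    ## trajectory must stay at least one semi-axis inside the frame
    t <- 0:(n_frames - 1)
    rows <- b$start_center[1] + t * b$velocity[1]
    cols <- b$start_center[2] + t * b$velocity[2]
    if (min(rows) < b$axes[1] || max(rows) > height - 1 - b$axes[1] ||
        min(cols) < b$axes[2] || max(cols) > width - 1 - b$axes[2])
      stop_invalid(sprintf("blobs[[%d]]", i),
                   "trajectory leaves the one-semi-axis interior margin")
  }
  for (i in seq_along(markers)) {
    m <- markers[[i]]
    if (is.null(m$blob) || m$blob < 1 || m$blob > length(blobs))
      stop_invalid(sprintf("markers[[%d]]$blob", i), "must index an existing blob")
    if (m$radius <= 0) stop_invalid(sprintf("markers[[%d]]$radius", i), "must be positive")
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_frames = as.integer(n_frames),
                 background_texture = background_texture,
                 background_value = background_value,
                 blobs = blobs, markers = markers,
                 noise_sigma = noise_sigma, texture_sigma = texture_sigma,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Default synthetic scene: one moving blob with a red marker
#'
#' A 64 x 64, 40-frame scene: textured static background, one elliptical
#' blob (semi-axes 10 x 7 px, uniform blue body) translating 1 px/frame
#' along the columns, carrying a saturated-red marker disc of radius 2 px
#' near its top, with additive frame noise of sigma 0.01.
#'
#' @param seed integer seed.
#' @param noise_sigma per-frame noise level.
#' @return a `scene_config`.
#' @export
default_scene_config <- function(seed = 1L, noise_sigma = 0.01) {
  scene_config(
    height = 64, width = 64, n_frames = 40,
    background_texture = "noise", background_value = 0.5,
    blobs = list(list(start_center = c(32, 14), velocity = c(0, 1),
                      axes = c(10, 7), body_color = c(0.15, 0.25, 0.8))),
    markers = list(list(blob = 1L, offset = c(-6, 0), radius = 2,
                        color = c(1, 0.05, 0.05))),
    noise_sigma = noise_sigma, seed = seed)
}

## Pixel-centre point-in-ellipse mask on the (0-based) grid.
ellipse_mask <- function(height, width, center, axes) {
  r <- matrix(0:(height - 1), height, width)
  c <- matrix(0:(width - 1), height, width, byrow = TRUE)
  ((r - center[1]) / axes[1])^2 + ((c - center[2]) / axes[2])^2 <= 1
}

disc_mask <- function(height, width, center, radius) {
  ellipse_mask(height, width, center, c(radius, radius))
}

#' Render a synthetic scene with ground truth
#'
#' Renders each frame as background + blobs + markers (draw order: later
#' element wins), then adds i.i.d. Gaussian noise clipped to \[0, 1\].
#' Ground truth is computed on the noise-free render: per-frame binary
#' foreground masks, real-valued per-blob trajectories, and per-marker
#' centroids.
#'
#' @param config a [scene_config()].
#' @return a list of class `frame_sequence` with `frames` (list of RGB
#'   arrays) and `truth` (fields `masks`, `trajectories`, `marker_centroids`,
#'   plus `background`, the noise-free background RGB array).
#' @export
make_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  h <- config$height; w <- config$width; nf <- config$n_frames
  withr::with_seed(config$seed, {
    bg_gray <- matrix(config$background_value, h, w)
    if (config$background_texture == "noise")
      bg_gray <- pmin(pmax(bg_gray + matrix(stats::rnorm(h * w, 0, config$texture_sigma), h, w), 0), 1)
    background <- array(rep(bg_gray, 3L), c(h, w, 3L))

    nb <- length(config$blobs)
    trajectories <- lapply(config$blobs, function(b) {
      t <- 0:(nf - 1)
      cbind(row = b$start_center[1] + t * b$velocity[1],
            col = b$start_center[2] + t * b$velocity[2])
    })
    marker_centroids <- lapply(config$markers, function(m) {
      tr <- trajectories[[m$blob]]
      cbind(row = tr[, "row"] + m$offset[1], col = tr[, "col"] + m$offset[2])
    })

    frames <- vector("list", nf)
    masks <- vector("list", nf)
    for (t in seq_len(nf)) {
      clean <- background
      mask <- matrix(FALSE, h, w)
      for (i in seq_len(nb)) {
        b <- config$blobs[[i]]
        em <- ellipse_mask(h, w, trajectories[[i]][t, ], b$axes)
        for (ch in 1:3) {
          plane <- clean[, , ch]; plane[em] <- b$body_color[ch]; clean[, , ch] <- plane
        }
        mask <- mask | em
      }
      for (i in seq_along(config$markers)) {
        m <- config$markers[[i]]
        dm <- disc_mask(h, w, marker_centroids[[i]][t, ], m$radius)
        col <- if (is.null(m$color)) c(1, 0.05, 0.05) else m$color
        for (ch in 1:3) {
          plane <- clean[, , ch]; plane[dm] <- col[ch]; clean[, , ch] <- plane
        }
        mask <- mask | dm
      }
      noisy <- clean
      if (config$noise_sigma > 0)
        noisy <- pmin(pmax(clean + array(stats::rnorm(h * w * 3, 0, config$noise_sigma),
                                         c(h, w, 3L)), 0), 1)
      frames[[t]] <- noisy
      masks[[t]] <- mask
    }
    structure(list(frames = frames,
                   truth = list(masks = masks, trajectories = trajectories,
                                marker_centroids = marker_centroids,
                                background = background),
                   config = config),
              class = "frame_sequence")
  })
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("Synthetic frame sequence: %d frames of %d x %d, %d blob(s), %d marker(s)\n",
              length(x$frames), x$config$height, x$config$width,
              length(x$config$blobs), length(x$config$markers)))
  invisible(x)
}

#' Write a scene to disk
#'
#' Frames go to `dir/frame_0000.png`, ..., ground-truth masks to
#' `dir/mask_0000.png` and trajectories to `dir/truth.csv`
#' (frame, blob_id, row, col).
#'
#' @param scene a `frame_sequence` from [make_scene()].
#' @param dir output directory (created if missing).
#' @return the paths written, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "frame_sequence"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (t in seq_along(scene$frames)) {
    fp <- file.path(dir, sprintf("frame_%04d.png", t - 1L))
    mp <- file.path(dir, sprintf("mask_%04d.png", t - 1L))
    write_frame(scene$frames[[t]], fp)
    write_frame(scene$truth$masks[[t]] * 1, mp)
    paths <- c(paths, fp, mp)
  }
  tr <- do.call(rbind, lapply(seq_along(scene$truth$trajectories), function(i) {
    m <- scene$truth$trajectories[[i]]
    data.frame(frame = seq_len(nrow(m)) - 1L, blob_id = i, row = m[, "row"], col = m[, "col"])
  }))
  csv <- file.path(dir, "truth.csv")
  utils::write.csv(tr, csv, row.names = FALSE)
  invisible(c(paths, csv))
}

#' Labelled gallery of synthetic injury-feature images
#'
#' Each class is a fixed template — a dark body silhouette band with a
#' bright circular "damage" blob at a class-specific joint position (hip,
#' knee, ankle positions for the first three classes) — plus i.i.d.
#' Gaussian pixel noise, clipped to \[0, 1\].
#'
#' @param n_classes number of classes (>= 2).
#' @param n_per_class samples per class (>= 2).
#' @param image_shape (rows, cols) of each sample.
#' @param class_separation amplitude of the class-specific blob above the
#'   body intensity; 0 makes all templates identical.
#' @param noise_sigma pixel noise standard deviation; 0 makes within-class
#'   samples bit-identical.
#' @param seed integer seed.
#' @return list of class `damage_gallery`: `samples` (list of matrices),
#'   `labels` (integer vector), `templates` (one matrix per class).
#' @export
make_damage_gallery <- function(n_classes = 3L, n_per_class = 10L,
                                image_shape = c(24L, 24L),
                                class_separation = 0.25, noise_sigma = 0.05,
                                seed = 1L) {
  if (n_classes < 2) stop_invalid("n_classes", "must be >= 2")
  if (n_per_class < 2) stop_invalid("n_per_class", "must be >= 2")
  h <- image_shape[1]; w <- image_shape[2]
  ## joint positions along the body axis: hip, knee, ankle, then evenly spaced
  fracs <- c(0.30, 0.58, 0.85, seq(0.15, 0.95, length.out = max(n_classes, 4)))[seq_len(n_classes)]
  base <- matrix(0.1, h, w)
  band <- (col(base) - 1 >= w * 0.35) & (col(base) - 1 <= w * 0.65)
  base[band] <- 0.3  # body silhouette band
  templates <- lapply(fracs, function(f) {
    tm <- base
    dm <- disc_mask(h, w, c(round(h * f), round(w / 2)), radius = max(2, round(min(h, w) / 8)))
    tm[dm] <- pmin(tm[dm] + class_separation, 1)
    tm
  })
  withr::with_seed(seed, {
    samples <- list(); labels <- integer(0)
    for (k in seq_len(n_classes)) for (j in seq_len(n_per_class)) {
      s <- templates[[k]]
      if (noise_sigma > 0)
        s <- pmin(pmax(s + matrix(stats::rnorm(h * w, 0, noise_sigma), h, w), 0), 1)
      samples[[length(samples) + 1L]] <- s
      labels <- c(labels, k)
    }
    structure(list(samples = samples, labels = labels, templates = templates),
              class = "damage_gallery")
  })
}

#' Random graph fixture over detection-like nodes
#'
#' Erdos-Renyi style symmetric adjacency with i.i.d. standard-normal node
#' features; deterministic given the seed.
#'
#' @param n_nodes number of nodes (>= 1).
#' @param edge_prob probability of each undirected edge.
#' @param feature_dim feature dimension.
#' @param seed integer seed.
#' @return a [detection_graph()].
#' @export
make_graph_fixture <- function(n_nodes, edge_prob = 0.3, feature_dim = 4L, seed = 1L) {
  if (n_nodes < 1) stop_invalid("n_nodes", "must be >= 1")
  if (edge_prob < 0 || edge_prob > 1) stop_invalid("edge_prob", "must be in [0, 1]")
  withr::with_seed(seed, {
    A <- matrix(0, n_nodes, n_nodes)
    if (n_nodes > 1) {
      up <- upper.tri(A)
      A[up] <- as.numeric(stats::runif(sum(up)) < edge_prob)
      A <- A + t(A)
    }
    H <- matrix(stats::rnorm(n_nodes * feature_dim), n_nodes, feature_dim)
    detection_graph(A, H,
                    node_meta = data.frame(track = rep(1L, n_nodes),
                                           frame = seq_len(n_nodes) - 1L))
  })
}
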