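## Injury-region localization by greedy snake-energy descent and
## eigen-subspace nearest-neighbour classification of damage-feature images.

#' Closed active contour (snake)
#'
#' @param points n x 2 matrix of ordered (row, col) vertices, n >= 4, read
#'   as a closed polygon; consecutive duplicates are rejected.
#' @param a internal (smoothness) energy weight. The internal term is
#'   measured in squared pixels (order 10 per vertex for typical spacings)
#'   while the external term is an intensity gradient (order 0.1 on
#'   \[0, 1\]-scaled images), so the default balancing weight is small.
#' @param beta external (edge-attraction) energy weight.
#' @return object of class `contour_model`.
#' @export
contour_model <- function(points, a = 0.001, beta = 1) {
  points <- as.matrix(points)
  if (nrow(points) < 4L) stop_invalid("points", "need at least 4 contour points")
  nxt <- rbind(points[-1, , drop = FALSE], points[1, , drop = FALSE])
  if (any(rowSums((points - nxt)^2) == 0))
    stop_invalid("points", "consecutive duplicate points")
  structure(list(points = unname(points), a = a, beta = beta),
            class = "contour_model")
}

#' @export
print.contour_model <- function(x, ...) {
  cat(sprintf("Closed contour: %d points, a = %g, beta = %g\n",
              nrow(x$points), x$a, x$beta))
  invisible(x)
}

#' Evenly spaced circular contour
#'
#' @param center (row, col) centre.
#' @param radius radius in px.
#' @param n number of vertices.
#' @param ... passed to [contour_model()].
#' @return a `contour_model`.
#' @export
circle_contour <- function(center, radius, n = 32L, ...) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  contour_model(cbind(center[1] + radius * sin(th), center[2] + radius * cos(th)), ...)
}

## Gradient-magnitude field of a gray image by central differences
## (one-sided at the borders).
gradient_magnitude <- function(gray) {
  nr <- nrow(gray); nc <- ncol(gray)
  up <- gray[reflect_index(0:(nr - 1) - 1L, nr) + 1L, , drop = FALSE]
  dn <- gray[reflect_index(0:(nr - 1) + 1L, nr) + 1L, , drop = FALSE]
  lf <- gray[, reflect_index(0:(nc - 1) - 1L, nc) + 1L, drop = FALSE]
  rt <- gray[, reflect_index(0:(nc - 1) + 1L, nc) + 1L, drop = FALSE]
  sqrt(((dn - up) / 2)^2 + ((rt - lf) / 2)^2)
}

#' Snake energy of a contour on a gray image
#'
#' `E = a * E_in + beta * E_es` where the internal term sums squared
#' first differences (membrane) and squared second differences (curvature)
#' over the closed vertex sequence, and the external term is the negative
#' sum of the image's gradient magnitude sampled at the vertices by
#' bilinear interpolation — so contours lying on strong edges have lower
#' energy.
#'
#' @param contour a [contour_model()] whose points lie inside the frame.
#' @param gray grayscale matrix.
#' @param grad optional precomputed gradient-magnitude field.
#' @return scalar energy.
#' @export
snake_energy <- function(contour, gray, grad = NULL) {
  stopifnot(inherits(contour, "contour_model"))
  assert_gray_frame(gray, "gray")
  p <- contour$points
  if (min(p) < 0 || max(p[, 1]) > nrow(gray) - 1 || max(p[, 2]) > ncol(gray) - 1)
    stop_invalid("contour", "points must lie inside the frame")
  if (contour$a == 0 && contour$beta == 0) return(0)
  nxt <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE])
  prv <- rbind(p[nrow(p), , drop = FALSE], p[-nrow(p), , drop = FALSE])
  e_in <- sum((nxt - p)^2) + sum((nxt - 2 * p + prv)^2)
  if (is.null(grad)) grad <- gradient_magnitude(gray)
  e_es <- -sum(bilinear(grad, p[, 1], p[, 2]))
  contour$a * e_in + contour$beta * e_es
}

#' Localize a damage region by greedy snake descent
#'
#' One pass moves each vertex in turn to the lowest-energy position among
#' its 3 x 3 neighbourhood at spacing `step` (staying inside the frame);
#' passes repeat until no vertex moves or `max_iter` passes. Energy never
#' increases.
#'
#' @param gray grayscale matrix.
#' @param init initial [contour_model()].
#' @param max_iter maximum full passes (default 100).
#' @param step neighbourhood spacing in px (default 1).
#' @return the converged `contour_model`, with attributes `energy` (final
#'   energy) and `iterations` (passes used).
#' @export
localize_damage <- function(gray, init, max_iter = 100L, step = 1) {
  stopifnot(inherits(init, "contour_model"))
  assert_gray_frame(gray, "gray")
  grad <- gradient_magnitude(gray)
  cur <- init
  energy <- snake_energy(cur, gray, grad)
  offsets <- expand.grid(dr = c(-step, 0, step), dc = c(-step, 0, step))
  iters <- 0L
  for (pass in seq_len(max_iter)) {
    moved <- FALSE
    for (i in seq_len(nrow(cur$points))) {
      best_e <- energy; best_p <- cur$points[i, ]
      for (k in seq_len(nrow(offsets))) {
        if (offsets$dr[k] == 0 && offsets$dc[k] == 0) next
        cand <- cur$points[i, ] + c(offsets$dr[k], offsets$dc[k])
        if (cand[1] < 0 || cand[2] < 0 ||
            cand[1] > nrow(gray) - 1 || cand[2] > ncol(gray) - 1) next
        trial <- cur
        trial$points[i, ] <- cand
        e <- snake_energy(trial, gray, grad)
        if (e < best_e) { best_e <- e; best_p <- cand }
      }
      if (best_e < energy) {
        cur$points[i, ] <- best_p
        energy <- best_e
        moved <- TRUE
      }
    }
    iters <- pass
    if (!moved) break
  }
  attr(cur, "energy") <- energy
  attr(cur, "iterations") <- iters
  cur
}

#' Fit an eigen-subspace to a gallery of gray images
#'
#' Flattens the samples to vectors, subtracts the sample mean, and
#' eigendecomposes the sample covariance (1/(m-1) normalization; via the
#' small m x m Gram matrix when the pixel dimension exceeds the sample
#' count). Eigenpairs are sorted by decreasing eigenvalue, numerically zero
#' eigenvalues are dropped, and the smallest leading set whose cumulative
#' eigenvalue mass reaches `retention` of the total is kept (default 60%).
#'
#' @param samples list of at least two gray matrices of equal shape (or an
#'   m x d matrix of already-flattened samples).
#' @param retention fraction of total eigenvalue mass to retain, in (0, 1\].
#' @return object of class `eigen_subspace`: `mean`, `values` (retained
#'   eigenvalues, descending), `vectors` (d x k orthonormal columns),
#'   `retention`, `all_values`, `image_shape`.
#' @export
fit_subspace <- function(samples, retention = 0.6) {
  if (retention <= 0 || retention > 1) stop_invalid("retention", "must be in (0, 1]")
  if (is.list(samples)) {
    if (length(samples) < 2L) stop_invalid("samples", "need at least 2 samples")
    shp <- dim(samples[[1]])
    X <- t(vapply(samples, function(s) {
      if (!all(dim(s) == shp)) stop_invalid("samples", "unequal image shapes")
      as.vector(s)
    }, numeric(prod(shp))))
  } else {
    X <- as.matrix(samples); shp <- NULL
    if (nrow(X) < 2L) stop_invalid("samples", "need at least 2 samples")
  }
  m <- nrow(X); d <- ncol(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  if (d > m) {
    ## Gram trick: eigenvectors of Xc Xc^T / (m-1) lifted to pixel space
    G <- Xc %*% t(Xc) / (m - 1)
    eg <- eigen(G, symmetric = TRUE)
    lam <- eg$values
    keep <- lam > max(lam, 0) * 1e-10 & lam > 0
    U <- if (any(keep))
      sweep(t(Xc) %*% eg$vectors[, keep, drop = FALSE], 2L,
            sqrt((m - 1) * lam[keep]), "/")
    else matrix(0, d, 0)
    lam <- lam[keep]
  } else {
    S <- stats::cov(X)
    eg <- eigen(S, symmetric = TRUE)
    lam <- eg$values
    keep <- lam > max(lam, 0) * 1e-10 & lam > 0
    U <- eg$vectors[, keep, drop = FALSE]
    lam <- lam[keep]
  }
  if (length(lam) == 0L) {
    warning("all samples identical: empty eigen-subspace", call. = FALSE)
    k <- 0L
  } else {
    k <- which(cumsum(lam) >= retention * sum(lam))[1]
  }
  structure(list(mean = mu, values = lam[seq_len(k)],
                 vectors = U[, seq_len(k), drop = FALSE],
                 retention = retention, all_values = lam, image_shape = shp),
            class = "eigen_subspace")
}

#' @export
print.eigen_subspace <- function(x, ...) {
  cat(sprintf("Eigen-subspace: %d retained component(s) of %d nonzero (%.0f%% eigenvalue mass target)\n",
              length(x$values), length(x$all_values), 100 * x$retention))
  invisible(x)
}

#' Project a sample into an eigen-subspace
#'
#' `y = U^T (x - mean)`: the coefficient vector of the mean-centred sample
#' on the retained eigenvectors.
#'
#' @param sample gray matrix (training shape) or flattened numeric vector.
#' @param subspace an [fit_subspace()] result.
#' @return numeric coefficient vector of length = retained components.
#' @export
project <- function(sample, subspace) {
  stopifnot(inherits(subspace, "eigen_subspace"))
  x <- if (is.matrix(sample)) {
    if (!is.null(subspace$image_shape) && !all(dim(sample) == subspace$image_shape))
      stop_invalid("sample", "shape does not match the training samples")
    as.vector(sample)
  } else as.numeric(sample)
  if (length(x) != length(subspace$mean))
    stop_invalid("sample", "dimension does not match the training samples")
  as.vector(crossprod(subspace$vectors, x - subspace$mean))
}

#' Build a projected gallery from labelled training samples
#'
#' @param samples list of gray matrices.
#' @param labels class label per sample.
#' @param subspace an [fit_subspace()] result (fitted on `samples` when
#'   omitted).
#' @param retention passed to [fit_subspace()] when fitting here.
#' @return object of class `damage_gallery_model`: `coefficients` (one row
#'   per sample), `labels`, `subspace`.
#' @export
build_gallery <- function(samples, labels, subspace = NULL, retention = 0.6) {
  if (length(samples) != length(labels))
    stop_invalid("labels", "one label per sample required")
  if (is.null(subspace)) subspace <- fit_subspace(samples, retention = retention)
  Y <- t(vapply(samples, project, numeric(length(subspace$values)),
                subspace = subspace))
  if (length(subspace$values) == 1L) Y <- matrix(as.vector(Y), ncol = 1L)
  structure(list(coefficients = Y, labels = labels, subspace = subspace),
            class = "damage_gallery_model")
}

#' @export
print.damage_gallery_model <- function(x, ...) {
  cat(sprintf("Projected gallery: %d sample(s), %d class(es), %d coefficient(s) per sample\n",
              nrow(x$coefficients), length(unique(x$labels)), ncol(x$coefficients)))
  invisible(x)
}

#' Nearest-neighbour classification in coefficient space
#'
#' Returns the label of the gallery entry at minimum Euclidean distance
#' from the query coefficients; ties go to the lowest gallery index.
#'
#' @param query coefficient vector (from [project()]).
#' @param gallery a [build_gallery()] result.
#' @return list with `label`, `distance`, and `index` of the matched entry.
#' @export
classify_nn <- function(query, gallery) {
  stopifnot(inherits(gallery, "damage_gallery_model"))
  if (nrow(gallery$coefficients) == 0L)
    stop_invalid("gallery", "gallery is empty")
  if (length(query) != ncol(gallery$coefficients))
    stop_invalid("query", "dimension does not match the gallery")
  d <- sqrt(colSums((t(gallery$coefficients) - query)^2))
  i <- which.min(d)
  list(label = gallery$labels[i], distance = d[i], index = i)
}

#' Classify gray images end-to-end against a projected gallery
#'
#' @param samples list of gray matrices.
#' @param gallery a [build_gallery()] result.
#' @return data frame with columns label, distance, index (one row per
#'   sample).
#' @export
classify_images <- function(samples, gallery) {
  res <- lapply(samples, function(s) classify_nn(project(s, gallery$subspace), gallery))
  data.frame(label = vapply(res, `[[`, numeric(1), "label"),
             distance = vapply(res, `[[`, numeric(1), "distance"),
             index = vapply(res, `[[`, numeric(1), "index"))
}
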