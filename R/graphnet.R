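## Graph construction over tracked detections and graph-convolutional
## feature propagation with the renormalized adjacency
## D^{-1/2} (A + I) D^{-1/2}, plus the equivalent spectral-filter view.

#' Detection graph
#'
#' @param adjacency symmetric n x n non-negative matrix with zero diagonal.
#' @param features n x d feature matrix (the layer-0 node features).
#' @param node_meta data frame with one row per node; columns `track` and
#'   `frame`.
#' @return object of class `detection_graph`.
#' @export
detection_graph <- function(adjacency, features, node_meta = NULL) {
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (n < 1L) stop_invalid("adjacency", "need at least one node")
  if (!isSymmetric(unname(adjacency), tol = 1e-12))
    stop_invalid("adjacency", "must be symmetric")
  if (min(adjacency) < 0) stop_invalid("adjacency", "must be non-negative")
  if (any(diag(adjacency) != 0))
    stop_invalid("adjacency", "diagonal must be zero before self-loop augmentation")
  features <- as.matrix(features)
  if (nrow(features) != n) stop_invalid("features", "one feature row per node required")
  if (is.null(node_meta))
    node_meta <- data.frame(track = rep(1L, n), frame = seq_len(n) - 1L)
  structure(list(adjacency = unname(adjacency), features = unname(features),
                 node_meta = node_meta),
            class = "detection_graph")
}

#' @export
print.detection_graph <- function(x, ...) {
  cat(sprintf("Detection graph: %d node(s), %d undirected edge(s), %d feature dim(s)\n",
              nrow(x$adjacency), sum(x$adjacency > 0) / 2, ncol(x$features)))
  invisible(x)
}

#' Build a detection graph from tracks
#'
#' One node per (track, frame) detection. Edges connect consecutive frames
#' of the same track (temporal links) and detections of different tracks in
#' the same frame whose window centres lie within `radius` pixels (spatial
#' links). The adjacency is binary and symmetric.
#'
#' @param tracks list of `mofex_track` objects.
#' @param features matrix with one row per detection, ordered track by
#'   track then frame; defaults to (row, col, confidence) of each window.
#' @param radius spatial linking radius in pixels.
#' @return a [detection_graph()].
#' @export
build_detection_graph <- function(tracks, features = NULL, radius = 10) {
  if (length(tracks) == 0L) stop_invalid("tracks", "need at least one track")
  meta <- do.call(rbind, lapply(seq_along(tracks), function(i) {
    w <- tracks[[i]]$windows
    data.frame(track = i, frame = w$frame, row = w$row, col = w$col,
               confidence = w$confidence)
  }))
  n <- nrow(meta)
  if (is.null(features)) features <- as.matrix(meta[, c("row", "col", "confidence")])
  features <- as.matrix(features)
  if (nrow(features) != n) stop_invalid("features", "one feature row per detection required")
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    same_track <- meta$track[i] == meta$track[j]
    if (same_track && abs(meta$frame[i] - meta$frame[j]) == 1L) A[i, j] <- 1
    if (!same_track && meta$frame[i] == meta$frame[j] &&
        (meta$row[i] - meta$row[j])^2 + (meta$col[i] - meta$col[j])^2 <= radius^2)
      A[i, j] <- 1
  }
  A <- A + t(A)
  detection_graph(A, features, node_meta = meta[, c("track", "frame")])
}

#' Renormalized propagation matrix
#'
#' Adds self-loops, `Ahat = A + I`, and returns the symmetric propagation
#' operator `D^{-1/2} Ahat D^{-1/2}` with `D = diag(rowSums(Ahat))`. Its
#' eigenvalues lie in \[-1, 1\].
#'
#' @param A symmetric non-negative adjacency matrix (zero diagonal).
#' @return symmetric propagation matrix of the same size.
#' @export
normalized_adjacency <- function(A) {
  if (inherits(A, "detection_graph")) A <- A$adjacency
  A <- as.matrix(A)
  if (!isSymmetric(unname(A), tol = 1e-12)) stop_invalid("A", "must be symmetric")
  if (min(A) < 0) stop_invalid("A", "must be non-negative")
  Ahat <- A + diag(nrow(A))
  d <- rowSums(Ahat)
  dis <- ifelse(d > 0, 1 / sqrt(d), 0)   # zero-degree guard (cannot fire after self-loops)
  Ahat * outer(dis, dis)
}

#' One graph-convolution layer
#'
#' Computes `sigma(P %*% H %*% W)` for a propagation matrix `P`, feature
#' matrix `H` and layer weights `W`.
#'
#' @param H n x d_in feature matrix.
#' @param P n x n propagation matrix (see [normalized_adjacency()]).
#' @param W d_in x d_out weight matrix.
#' @param activation `"identity"` (default) or `"relu"`.
#' @return n x d_out feature matrix.
#' @export
gcn_layer <- function(H, P, W, activation = c("identity", "relu")) {
  activation <- match.arg(activation)
  H <- as.matrix(H); P <- as.matrix(P); W <- as.matrix(W)
  if (!all(is.finite(W))) stop_invalid("W", "must be finite")
  if (ncol(P) != nrow(H)) stop_invalid("P", "propagation/feature dimensions do not conform")
  if (ncol(H) != nrow(W)) stop_invalid("W", "feature/weight dimensions do not conform")
  Z <- P %*% H %*% W
  if (activation == "relu") Z <- pmax(Z, 0)
  Z
}

#' Spectral graph filtering of a node signal
#'
#' Filters `x` in the eigenbasis of the symmetric normalized Laplacian of
#' the self-loop graph, `L = I - D^{-1/2}(A + I)D^{-1/2} = U Lambda U^T`,
#' returning `U g(Lambda) U^T x`. With `g(lambda) = 1 - lambda` this equals
#' multiplication by the renormalized propagation matrix.
#'
#' @param x numeric node signal of length n.
#' @param A symmetric non-negative adjacency (zero diagonal).
#' @param g vectorized gain function of the eigenvalues.
#' @return filtered signal of length n.
#' @export
spectral_filter <- function(x, A, g) {
  if (inherits(A, "detection_graph")) A <- A$adjacency
  A <- as.matrix(A)
  if (!isSymmetric(unname(A), tol = 1e-12)) stop_invalid("A", "must be symmetric")
  if (length(x) != nrow(A)) stop_invalid("x", "signal length must equal node count")
  L <- diag(nrow(A)) - normalized_adjacency(A)
  eg <- eigen(L, symmetric = TRUE)
  as.vector(eg$vectors %*% (g(eg$values) * crossprod(eg$vectors, x)))
}

#' Layer parameters for graph-convolutional propagation
#'
#' @param W d_in x d_out weight matrix.
#' @param activation `"identity"` or `"relu"`.
#' @return object of class `gcn_layer_params`.
#' @export
gcn_layer_params <- function(W, activation = c("identity", "relu")) {
  activation <- match.arg(activation)
  W <- as.matrix(W)
  if (!all(is.finite(W))) stop_invalid("W", "must be finite")
  structure(list(W = W, activation = activation), class = "gcn_layer_params")
}

#' Seeded random layer weights
#'
#' @param d_in,d_out layer dimensions.
#' @param seed integer seed.
#' @param activation passed to [gcn_layer_params()].
#' @return a `gcn_layer_params` with N(0, 1/d_in) entries.
#' @export
random_gcn_layer <- function(d_in, d_out, seed = 1L, activation = "identity") {
  withr::with_seed(seed, gcn_layer_params(
    matrix(stats::rnorm(d_in * d_out, sd = 1 / sqrt(d_in)), d_in, d_out),
    activation = activation))
}

#' Propagate detection features through graph-convolution layers
#'
#' Applies the layers sequentially with the fixed renormalized propagation
#' matrix of the graph, then mean-pools the final embeddings per track.
#'
#' @param graph a [detection_graph()].
#' @param layers list of [gcn_layer_params()] (at least one).
#' @return list with `embeddings` (n x d_out) and `track_embeddings` (one
#'   pooled row per track, rownames = track id).
#' @export
manage_features <- function(graph, layers) {
  stopifnot(inherits(graph, "detection_graph"))
  if (length(layers) < 1L) stop_invalid("layers", "need at least one layer")
  P <- normalized_adjacency(graph$adjacency)
  H <- graph$features
  for (ly in layers) {
    stopifnot(inherits(ly, "gcn_layer_params"))
    H <- gcn_layer(H, P, ly$W, activation = ly$activation)
  }
  tracks <- sort(unique(graph$node_meta$track))
  pooled <- do.call(rbind, lapply(tracks, function(tr)
    colMeans(H[graph$node_meta$track == tr, , drop = FALSE])))
  rownames(pooled) <- tracks
  list(embeddings = H, track_embeddings = pooled)
}
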