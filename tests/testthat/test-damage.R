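# Synthetic gray disc: bright disc of given radius on a dark field.
disc_image <- function(n, center, radius, lo = 0.1, hi = 0.9) {
  r <- matrix(0:(n - 1), n, n); c <- t(r)
  img <- matrix(lo, n, n)
  img[(r - center[1])^2 + (c - center[2])^2 <= radius^2] <- hi
  img
}

test_that("snake energy: zero weights, hand-summed membrane term, edge preference", {
  gray <- matrix(0.5, 20, 20)
  sq <- contour_model(rbind(c(5, 5), c(5, 10), c(10, 10), c(10, 5)), a = 0, beta = 0)
  expect_equal(snake_energy(sq, gray), 0)

  # evenly spaced points on a straight segment, constant image:
  # curvature term vanishes except at the closing turn-around; check the
  # full internal sum term by term against a hand summation
  pts <- cbind(5, seq(2, 14, by = 3))   # 5 points, spacing 3 along a row
  cm <- contour_model(pts, a = 1, beta = 0)
  nxt <- rbind(pts[-1, ], pts[1, ]); prv <- rbind(pts[nrow(pts), ], pts[-nrow(pts), ])
  hand <- sum((nxt - pts)^2) + sum((nxt - 2 * pts + prv)^2)
  expect_equal(snake_energy(cm, gray), hand)

  # a contour on a step edge has lower energy than on a flat region
  step <- matrix(0.2, 30, 30); step[, 16:30] <- 0.8
  on_edge <- circle_contour(c(15, 15), 6, n = 16, a = 0, beta = 1)
  on_flat <- circle_contour(c(15, 7), 6, n = 16, a = 0, beta = 1)
  expect_lt(snake_energy(on_edge, step), snake_energy(on_flat, step))
  expect_error(snake_energy(circle_contour(c(2, 2), 5), gray), "contour")
})

test_that("greedy snake descent never increases energy and respects fixed points", {
  img <- disc_image(40, c(20, 20), 10)
  # track energy across passes by running one pass at a time
  cur <- circle_contour(c(20, 20), 14, n = 24)
  e_prev <- snake_energy(cur, img)
  for (pass in 1:10) {
    cur2 <- localize_damage(img, cur, max_iter = 1)
    e <- attr(cur2, "energy")
    expect_lte(e, e_prev + 1e-12)
    e_prev <- e
    cur <- contour_model(cur2$points, a = cur2$a, beta = cur2$beta)
  }
  # a converged contour is a fixed point of a further pass
  conv <- localize_damage(img, circle_contour(c(20, 20), 13, n = 24), max_iter = 100)
  again <- localize_damage(img, contour_model(conv$points, a = conv$a, beta = conv$beta),
                           max_iter = 1)
  expect_equal(again$points, conv$points)
})

test_that("a circle initialized 3 px outside a disc converges onto its boundary", {
  # smoothing the image first extends the edge's capture range, as usual
  # for gradient-driven active contours
  k5 <- filter_kernel(c(1, 4, 6, 4, 1) / 16)
  img <- filter_frame(filter_frame(disc_image(48, c(24, 24), 10), k5), k5)
  init <- circle_contour(c(24, 24), 13, n = 28)
  fit <- localize_damage(img, init, max_iter = 60)
  radial <- sqrt(rowSums(sweep(fit$points, 2, c(24, 24))^2))
  expect_lte(mean(abs(radial - 10)), 1)
})

test_that("subspace fitting: retention rule, rank-1 recovery, degenerate gallery", {
  expect_equal(formals(fit_subspace)$retention, 0.6)

  # samples varying along one direction: a single eigenpair, parallel to it
  withr::with_seed(4, {
    dir <- rnorm(50); dir <- dir / sqrt(sum(dir^2))
    mu <- runif(50)
    X <- t(sapply(seq(-2, 2, length.out = 9), function(s) mu + s * dir))
    sub <- fit_subspace(X)
    expect_length(sub$values, 1)
    expect_gte(abs(sum(sub$vectors[, 1] * dir)), 0.999)
    expect_lt(max(abs(crossprod(sub$vectors) - diag(ncol(sub$vectors)))), 1e-8)
  })

  # identical samples: empty subspace with a warning
  same <- replicate(3, matrix(0.3, 4, 4), simplify = FALSE)
  expect_warning(empty <- fit_subspace(same), "identical")
  expect_length(empty$values, 0)
  expect_error(fit_subspace(list(matrix(0, 2, 2))), "samples")
})

test_that("retention truncates at cumulative eigenvalue mass, exactly on a constructed spectrum", {
  # orthogonal +/- pairs give sample covariance eigenvalues proportional to
  # 5 : 3 : 2 -> cumulative mass 0.5, 0.8, 1.0, so 60% retention keeps 2
  d <- 12
  amps <- sqrt(c(5, 3, 2))
  X <- do.call(rbind, lapply(1:3, function(i) {
    e <- numeric(d); e[i] <- 1
    rbind(amps[i] * e, -amps[i] * e)
  }))
  sub <- fit_subspace(X, retention = 0.6)
  expect_length(sub$values, 2)
  expect_equal(sub$values[1] / sub$values[2], 5 / 3, tolerance = 1e-9)
  expect_length(fit_subspace(X, retention = 0.5)$values, 1)
  expect_length(fit_subspace(X, retention = 0.81)$values, 3)
})

test_that("projection is centred, orthonormal, and obeys the Bessel bound", {
  withr::with_seed(6, {
    samples <- replicate(8, matrix(runif(36), 6, 6), simplify = FALSE)
    sub <- fit_subspace(samples, retention = 0.9)
    expect_equal(project(matrix(sub$mean, 6, 6), sub), rep(0, length(sub$values)))
    v1 <- sub$mean + sub$vectors[, 1]
    y <- project(matrix(v1, 6, 6), sub)
    expect_equal(y, c(1, rep(0, length(sub$values) - 1)), tolerance = 1e-8)
    for (i in 1:20) {
      x <- runif(36)
      expect_lte(sqrt(sum(project(x, sub)^2)), sqrt(sum((x - sub$mean)^2)) + 1e-12)
    }
    expect_error(project(matrix(0, 3, 3), sub), "sample")
  })
})

test_that("nearest-neighbour classification agrees exactly with the brute-force oracle", {
  withr::with_seed(9, {
    gal <- make_damage_gallery(n_classes = 3, n_per_class = 6, seed = 2)
    gallery <- build_gallery(gal$samples, gal$labels)
    expect_lte(length(gallery$subspace$values), length(gal$samples))
    for (i in 1:100) {
      q <- rnorm(ncol(gallery$coefficients), sd = 2)
      got <- classify_nn(q, gallery)
      want <- oracle_nn(q, gallery$coefficients, gallery$labels)
      expect_identical(got$index, want$index)
      expect_identical(got$label, want$label)
      expect_equal(got$distance, want$distance)
    }
    # exact gallery entry comes back with distance zero
    hit <- classify_nn(gallery$coefficients[7, ], gallery)
    expect_equal(hit$index, 7)
    expect_equal(hit$distance, 0)
  })
  # documented tie-break: two equidistant entries -> lower index
  tie <- structure(list(coefficients = rbind(c(1, 0), c(-1, 0)),
                        labels = c(10L, 20L), subspace = NULL),
                   class = "damage_gallery_model")
  expect_equal(classify_nn(c(0, 5), tie)$label, 10L)
})

test_that("held-out classification on the synthetic gallery reaches 90% accuracy", {
  gal <- make_damage_gallery(n_classes = 3, n_per_class = 15,
                             class_separation = 0.25, noise_sigma = 0.05, seed = 5)
  is_test <- rep(seq_len(15) > 10, times = 3)
  gallery <- build_gallery(gal$samples[!is_test], gal$labels[!is_test])
  res <- classify_images(gal$samples[is_test], gallery)
  expect_gte(mean(res$label == gal$labels[is_test]), 0.9)
})

test_that("reconstruction error is non-increasing in retention on the same gallery", {
  withr::with_seed(12, {
    samples <- replicate(10, matrix(runif(25), 5, 5), simplify = FALSE)
    x <- runif(25)
    errs <- sapply(c(0.3, 0.6, 0.9, 1.0), function(ret) {
      sub <- fit_subspace(samples, retention = ret)
      y <- project(x, sub)
      sqrt(sum((x - sub$mean - as.vector(sub$vectors %*% y))^2))
    })
    expect_true(all(diff(errs) <= 1e-10))
  })
})
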