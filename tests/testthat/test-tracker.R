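# Single-colour test frame with an optional rectangle of another colour.
solid_frame <- function(h, w, color, patch = NULL, patch_color = NULL) {
  f <- array(rep(color, each = h * w), c(h, w, 3))
  if (!is.null(patch)) {
    for (ch in 1:3) {
      plane <- f[, , ch]
      plane[patch$rows, patch$cols] <- patch_color[ch]
      f[, , ch] <- plane
    }
  }
  f
}

test_that("target models are normalized histograms with sensible bin placement", {
  blue <- solid_frame(20, 20, c(0.1, 0.2, 0.9))
  win <- search_window(c(9.5, 9.5), c(5, 5))
  tm <- build_target_model(blue, win)
  expect_equal(sum(tm$p), 1, tolerance = 1e-9)
  expect_true(all(tm$p >= 0))
  expect_equal(max(tm$p), 1)   # single colour: all mass in one bin
  gray <- solid_frame(20, 20, c(0.5, 0.5, 0.5))
  tg <- build_target_model(gray, win)
  expect_equal(tg$p[tg$n_bins + 1], 1)  # achromatic bin
  expect_error(build_target_model(blue, win, n_bins = 1), "n_bins")
})

test_that("Epanechnikov weighting matches direct summation and zeroes r >= 1 pixels", {
  withr::with_seed(21, {
    f <- array(runif(21 * 21 * 3), c(21, 21, 3))
    win <- search_window(c(10, 10), c(4, 4))
    tm <- build_target_model(f, win, n_bins = 8)
    h <- sqrt(2) * 4
    # direct per-pixel summation over the window grid, unvectorized
    p_direct <- numeric(9)
    for (r in 6:14) for (c in 6:14) {
      r2 <- ((r - 10)^2 + (c - 10)^2) / h^2
      kw <- max(0, 1 - r2)                     # exactly 0 once r2 >= 1
      hsv <- grDevices::rgb2hsv(matrix(f[r + 1, c + 1, ], 3, 1), maxColorValue = 1)
      b <- if (hsv[2] < 0.1) 9 else min(floor(hsv[1] * 8), 7) + 1
      p_direct[b] <- p_direct[b] + kw
    }
    expect_equal(tm$p, p_direct / sum(p_direct), tolerance = 1e-12)
    expect_equal(tm$I_h, 1 / sum(p_direct))
  })
  # a uniform-profile model weights all window pixels equally
  blue <- solid_frame(21, 21, c(0.1, 0.2, 0.9))
  tu <- build_target_model(blue, search_window(c(10, 10), c(4, 4)), kernel = "uniform")
  expect_equal(max(tu$p), 1)
})

test_that("backprojection looks up bin masses and matches brute-force summation", {
  withr::with_seed(5, {
    f <- array(runif(12 * 12 * 3), c(12, 12, 3))
    win <- search_window(c(5.5, 5.5), c(4, 4))
    tm <- build_target_model(f, win)
    wts <- backproject(f, tm)
    expect_true(all(wts >= 0 & wts <= 1))
    # brute force: per-pixel hue binning and lookup
    acc <- 0
    for (r in 1:12) for (c in 1:12) {
      hsv <- grDevices::rgb2hsv(matrix(f[r, c, ], 3, 1), maxColorValue = 1)
      b <- if (hsv[2] < 0.1) tm$n_bins + 1 else min(floor(hsv[1] * tm$n_bins), tm$n_bins - 1) + 1
      acc <- acc + tm$p[b]
      expect_equal(wts[r, c], tm$p[b])
    }
    expect_equal(sum(wts), acc)
  })
  blue <- solid_frame(10, 10, c(0.1, 0.2, 0.9))
  tm <- build_target_model(blue, search_window(c(4.5, 4.5), c(3, 3)))
  expect_equal(backproject(blue, tm), matrix(1, 10, 10))       # dominant colour
  red <- solid_frame(10, 10, c(1, 0, 0))
  expect_equal(backproject(red, tm), matrix(0, 10, 10))        # absent colour
})

test_that("camshift steps: symmetric fields do not move, Gaussian blobs are found, zero mass flags lost", {
  sym <- matrix(0, 21, 21)
  sym[9:13, 9:13] <- outer(c(1, 2, 3, 2, 1), c(1, 2, 3, 2, 1))
  w0 <- search_window(c(10, 10), c(6, 6))
  stepped <- camshift_step(sym, w0, resize = FALSE)
  expect_equal(stepped$center, w0$center)

  # off-centre Gaussian: converged centre within 1 px of the analytic centroid
  r <- matrix(0:30, 31, 31); c <- t(r)
  blob <- exp(-((r - 19.3)^2 + (c - 12.7)^2) / (2 * 2.5^2))
  win <- search_window(c(14, 14), c(8, 8))
  for (i in 1:10) win <- camshift_step(blob, win, resize = FALSE)
  expect_lt(sqrt(sum((win$center - c(19.3, 12.7))^2)), 1)

  lost <- camshift_step(matrix(0, 15, 15), w0)
  expect_true(attr(lost, "lost"))
  expect_equal(lost$center, w0$center)
  expect_equal(attr(lost, "m00"), 0)
})

test_that("red marker detection finds discs, orders by area, and matches pixel counts", {
  f <- solid_frame(30, 30, c(0.5, 0.5, 0.5))
  red <- c(1, 0.05, 0.05)
  for (p in list(list(rows = 5:11, cols = 5:11), list(rows = 20:23, cols = 18:21)))
    for (ch in 1:3) {
      plane <- f[, , ch]; plane[p$rows, p$cols] <- red[ch]; f[, , ch] <- plane
    }
  dets <- detect_red_markers(f)
  expect_length(dets, 2)
  expect_equal(dets[[1]]$area, 49)
  expect_equal(dets[[2]]$area, 16)
  expect_equal(dets[[1]]$centroid, c(7, 7))
  expect_equal(dets[[2]]$centroid, c(20.5, 18.5))
  expect_equal(dets[[1]]$area + dets[[2]]$area, oracle_red_count(f))
  expect_length(detect_red_markers(solid_frame(10, 10, c(0.2, 0.8, 0.2))), 0)
})

test_that("single red disc on gray: one detection with centroid within 1 px", {
  sc <- scene_config(height = 32, width = 32, n_frames = 2, background_texture = "flat",
                     blobs = list(list(start_center = c(16, 16), velocity = c(0, 0),
                                       axes = c(3, 3), body_color = c(1, 0.05, 0.05))),
                     noise_sigma = 0, seed = 1)
  f <- make_scene(sc)$frames[[1]]
  dets <- detect_red_markers(f)
  expect_length(dets, 1)
  expect_lt(sqrt(sum((dets[[1]]$centroid - c(16, 16))^2)), 1)
  expect_gt(nrow(dets[[1]]$contour), 4)
})

test_that("a static target is held within 1 px for the whole sequence", {
  cfg <- scene_config(
    height = 48, width = 48, n_frames = 10, background_texture = "flat",
    blobs = list(list(start_center = c(24, 24), velocity = c(0, 0),
                      axes = c(8, 6), body_color = c(0.15, 0.25, 0.8))),
    noise_sigma = 0, seed = 1)
  sc <- make_scene(cfg)
  tk <- track(sc, search_window(c(24, 24), c(10, 8)))
  expect_true(all(sqrt((tk$windows$row - 24)^2 + (tk$windows$col - 24)^2) < 1))
})

test_that("the windowed mass is non-decreasing across mean-shift iterations", {
  r <- matrix(0:40, 41, 41); c <- t(r)
  blob <- exp(-((r - 25)^2 + (c - 28)^2) / (2 * 4^2))
  win <- search_window(c(15, 15), c(9, 9))
  m_prev <- -Inf
  for (i in 1:15) {
    win <- camshift_step(blob, win, resize = FALSE)
    m <- attr(win, "m00")
    expect_gte(m, m_prev - 1e-9)
    m_prev <- m
  }
})

test_that("moving blob with red marker is tracked to within 3 px RMSE", {
  sc <- make_scene(default_scene_config(seed = 1))
  tk <- track(sc, search_window(c(32, 14), c(12, 9)))
  expect_lte(track_rmse(tk, sc$truth$trajectories[[1]]), 3)
})

test_that("a teleporting target triggers marker feedback and is re-acquired within 5 frames", {
  fx <- teleport_fixture(seed = 3)
  tk <- track(fx$frames, fx$init_window)
  expect_gte(length(tk$reinit_events), 1)
  after <- fx$teleport_frame + (1:5)
  err <- sqrt((tk$windows$row[after + 1] - fx$trajectory[after + 1, 1])^2 +
              (tk$windows$col[after + 1] - fx$trajectory[after + 1, 2])^2)
  expect_lt(min(err), 3)
  expect_error(track(list(), search_window(c(1, 1), c(2, 2))), "frames")
})
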