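## Batch orchestration: configuration validation and the end-to-end run
## (scene/frames -> background -> moments -> tracking -> damage -> graph),
## writing CSV/JSON/PNG outputs and a run report.

pipeline_defaults <- function() list(
  frames_dir = NULL, out_dir = "mofex_out",
  stages = c("background", "moments", "tracking", "damage", "graph"),
  seed = 1L, noise_sigma = 0.01,
  K = 3L, learning_rate = 0.05, match_threshold = 2.5,
  background_fraction = 0.7, diff_threshold = 0.1, warmup = 30L,
  n_bins = 16L, feedback_fraction = 0.3, init_window = NULL,
  retention = 0.6, n_classes = 3L, n_train = 10L, n_test = 5L,
  radius = 10, gcn_dims = c(3L, 3L)
)

param_ranges <- list(
  K = c(1, 10), learning_rate = c(1e-6, 1 - 1e-6), match_threshold = c(0.1, 10),
  background_fraction = c(0, 1), diff_threshold = c(0, 1), warmup = c(1, 10000),
  n_bins = c(2, 256), feedback_fraction = c(0, 1), retention = c(1e-6, 1),
  n_classes = c(2, 26), n_train = c(2, 1000), n_test = c(1, 1000),
  radius = c(0, 10000), noise_sigma = c(0, 0.5), seed = c(-2^31, 2^31)
)

#' Validate a raw pipeline configuration
#'
#' Merges the supplied named list over the documented defaults, checks
#' every parameter against its documented range, and rejects unknown keys.
#' All violations are collected, not just the first.
#'
#' @param raw named list (e.g. parsed from a YAML file).
#' @return a typed `pipeline_config` when valid, otherwise a character
#'   vector of violations with class `config_violations`.
#' @export
validate_config <- function(raw = list()) {
  defaults <- pipeline_defaults()
  violations <- character(0)
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0)
    violations <- c(violations, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, raw[names(raw) %in% names(defaults)])
  for (nm in names(param_ranges)) {
    v <- cfg[[nm]]; rg <- param_ranges[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < rg[1] || v > rg[2])
      violations <- c(violations,
                      sprintf("`%s` must be a number in [%g, %g] (got %s)",
                              nm, rg[1], rg[2], paste(format(v), collapse = ",")))
  }
  bad_stage <- setdiff(cfg$stages, pipeline_defaults()$stages)
  if (length(bad_stage) > 0)
    violations <- c(violations, paste0("unknown stage(s): ", paste(bad_stage, collapse = ", ")))
  if (!is.null(cfg$init_window) && length(cfg$init_window) != 4L)
    violations <- c(violations, "`init_window` must be c(row, col, half_rows, half_cols)")
  if (length(violations) > 0) return(structure(violations, class = "config_violations"))
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration, stages:", paste(x$stages, collapse = " > "), "\n")
  invisible(x)
}

#' @export
print.config_violations <- function(x, ...) {
  cat("Configuration violations:\n")
  for (v in x) cat(" -", v, "\n")
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order on either a directory of PNG frames
#' (`frames_dir`) or, when none is given, the default synthetic scene
#' rendered from the configured seed. Outputs (per-frame foreground mask
#' PNGs, a moments JSON, the track CSV, a classification JSON, an
#' embeddings CSV) and a run report JSON are written under `out_dir`. The
#' whole run is deterministic given the configuration.
#'
#' @param config a `pipeline_config` from [validate_config()] (a raw list
#'   is validated first; violations raise an error).
#' @return the run report, an object of class `run_report`, invisibly
#'   written to `out_dir/report.json`.
#' @export
run_pipeline <- function(config = list()) {
  if (!inherits(config, "pipeline_config")) {
    config <- validate_config(config)
    if (inherits(config, "config_violations"))
      stop(paste(c("invalid configuration:", config), collapse = "\n  "), call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(package_version = as.character(utils::packageVersion("mofex")),
                 parameters = config[setdiff(names(config), "stages")],
                 stages = list(), manifest = character(0), failed_stage = NULL)
  t_all <- proc.time()["elapsed"]

  ## --- inputs --------------------------------------------------------------
  truth <- NULL
  if (!is.null(config$frames_dir)) {
    if (!dir.exists(config$frames_dir))
      stop(sprintf("missing input: frames directory `%s` does not exist", config$frames_dir),
           call. = FALSE)
    frames <- read_frame_dir(config$frames_dir)
    init_window <- if (!is.null(config$init_window))
      search_window(config$init_window[1:2], config$init_window[3:4]) else NULL
  } else {
    scfg <- default_scene_config(seed = config$seed, noise_sigma = config$noise_sigma)
    scene <- make_scene(scfg)
    frames <- scene$frames
    truth <- scene$truth
    b <- scfg$blobs[[1]]
    init_window <- if (!is.null(config$init_window))
      search_window(config$init_window[1:2], config$init_window[3:4])
    else search_window(b$start_center, b$axes + 2)
  }
  grays <- lapply(frames, to_gray)
  n_frames <- length(frames)

  stage_on <- function(s) s %in% config$stages
  run_stage <- function(name, fun) {
    if (!is.null(report$failed_stage)) return(invisible(NULL))
    t0 <- proc.time()["elapsed"]
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      report$failed_stage <<- list(stage = name, message = conditionMessage(res))
      warning(sprintf("stage `%s` failed: %s", name, conditionMessage(res)), call. = FALSE)
      return(invisible(NULL))
    }
    res$seconds <- round(unname(proc.time()["elapsed"] - t0), 3)
    report$stages[[name]] <<- res
    invisible(NULL)
  }
  add_manifest <- function(paths) report$manifest <<- c(report$manifest, paths)

  masks <- NULL; trk <- NULL

  if (stage_on("background")) run_stage("background", function() {
    gmm <- init_gmm(grays[[1]], K = config$K, learning_rate = config$learning_rate,
                    match_threshold = config$match_threshold,
                    background_fraction = config$background_fraction)
    warm <- min(config$warmup, n_frames)
    for (t in 2:warm) gmm <- update_gmm(gmm, grays[[t]])
    out <- list(); paths <- character(0)
    for (t in seq_len(n_frames)) {
      if (t > warm) gmm <- update_gmm(gmm, grays[[t]])
      fm <- foreground_mask(gmm, grays[[t]], diff_threshold = config$diff_threshold)
      out[[t]] <- fm$mask
      p <- file.path(config$out_dir, sprintf("mask_%04d.png", t - 1L))
      write_frame(fm$mask * 1, p)
      paths <- c(paths, p)
    }
    masks <<- out
    add_manifest(paths)
    list(frames = n_frames, warmup_frames = warm,
         foreground_pixels = sum(vapply(out, sum, numeric(1))))
  })

  if (stage_on("moments")) run_stage("moments", function() {
    src <- if (!is.null(masks)) lapply(masks, function(m) m * 1) else grays
    per_frame <- lapply(seq_along(src), function(t) {
      if (sum(src[[t]]) <= 0) return(NULL)
      m <- central_moments(src[[t]], max_order = 4L)
      list(frame = t - 1L, mass = m$mass, centroid = m$centroid,
           E = m$E, eta = normalized_moments(m)$eta)
    })
    per_frame <- Filter(Negate(is.null), per_frame)
    p <- file.path(config$out_dir, "moments.json")
    jsonlite::write_json(per_frame, p, auto_unbox = TRUE, digits = 10)
    add_manifest(p)
    list(frames_with_mass = length(per_frame))
  })

  if (stage_on("tracking")) run_stage("tracking", function() {
    if (is.null(init_window))
      stop("tracking requires `init_window` when frames are read from disk")
    tk <- track(frames, init_window, n_bins = config$n_bins,
                feedback_fraction = config$feedback_fraction)
    trk <<- tk
    p <- file.path(config$out_dir, "track.csv")
    write_track_csv(tk, p)
    add_manifest(p)
    res <- list(frames = nrow(tk$windows), reinit_events = length(tk$reinit_events))
    if (!is.null(truth))
      res$rmse_px <- track_rmse(tk, truth$trajectories[[1]])
    res
  })

  if (stage_on("damage")) run_stage("damage", function() {
    gal <- make_damage_gallery(n_classes = config$n_classes,
                               n_per_class = config$n_train + config$n_test,
                               seed = config$seed)
    is_test <- rep(seq_len(config$n_train + config$n_test) > config$n_train,
                   times = config$n_classes)
    gallery <- build_gallery(gal$samples[!is_test], gal$labels[!is_test],
                             retention = config$retention)
    queries <- gal$samples[is_test]
    res <- classify_images(queries, gallery)
    margins <- vapply(seq_along(queries), function(i) {
      q <- project(queries[[i]], gallery$subspace)
      d <- sort(sqrt(colSums((t(gallery$coefficients) - q)^2)))
      if (length(d) > 1) d[2] - d[1] else NA_real_
    }, numeric(1))
    out <- lapply(seq_len(nrow(res)), function(i)
      list(query = i - 1L, label = res$label[i], true_label = gal$labels[is_test][i],
           distance = res$distance[i], runner_up_margin = margins[i]))
    p <- file.path(config$out_dir, "classification.json")
    jsonlite::write_json(out, p, auto_unbox = TRUE, digits = 10)
    add_manifest(p)
    list(queries = nrow(res),
         accuracy = mean(res$label == gal$labels[is_test]),
         retained_components = length(gallery$subspace$values))
  })

  if (stage_on("graph")) run_stage("graph", function() {
    if (is.null(trk))
      return(list(skipped = "tracking stage produced no track"))
    g <- build_detection_graph(list(trk), radius = config$radius)
    d_in <- ncol(g$features)
    dims <- c(d_in, config$gcn_dims)
    layers <- lapply(seq_along(config$gcn_dims), function(l)
      random_gcn_layer(dims[l], dims[l + 1], seed = config$seed + l))
    emb <- manage_features(g, layers)
    df <- cbind(g$node_meta, as.data.frame(emb$embeddings))
    p <- file.path(config$out_dir, "embeddings.csv")
    utils::write.csv(df, p, row.names = FALSE)
    add_manifest(p)
    list(nodes = nrow(g$adjacency), edges = sum(g$adjacency > 0) / 2,
         layers = length(layers))
  })

  report$seconds_total <- round(unname(proc.time()["elapsed"] - t_all), 3)
  rp <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report, rp, auto_unbox = TRUE, digits = 10, null = "null")
  report$manifest <- c(report$manifest, rp)
  class(report) <- "run_report"
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Pipeline run (mofex %s): %d stage(s), %.2f s\n",
              x$package_version, length(x$stages), x$seconds_total))
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    cat(sprintf("  %-10s %s\n", nm,
                paste(names(s), unlist(lapply(s, format)), sep = "=", collapse = " ")))
  }
  if (!is.null(x$failed_stage))
    cat("  FAILED at stage:", x$failed_stage$stage, "-", x$failed_stage$message, "\n")
  invisible(x)
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with top-level pipeline keys.
#' @return validated `pipeline_config` or `config_violations`.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("missing input: config file `%s` does not exist", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.null(raw$stages)) raw$stages <- unlist(raw$stages)
  if (!is.null(raw$init_window)) raw$init_window <- unlist(raw$init_window)
  if (!is.null(raw$gcn_dims)) raw$gcn_dims <- as.integer(unlist(raw$gcn_dims))
  validate_config(raw)
}
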