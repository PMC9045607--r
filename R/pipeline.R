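#' Session configuration
#'
#' Bundles every knob of an end-to-end run. In synthetic mode the session is
#' generated from scratch (design, dynamics, rendered frames); in video mode
#' tracking starts from frame directories on disk (one directory per trial,
#' since the interludes between exposure tests are not recorded).
#'
#' @param mode `"synthetic"` or `"video"`.
#' @param seed master seed; every random stage derives from it.
#' @param n_blocks permutation blocks in the generated design.
#' @param exposure_s exposure duration per trial, seconds.
#' @param params a [generator_params()] object.
#' @param tracker a [tracker_config()] object.
#' @param P resampled points per shape for the shape PCA.
#' @param n_starts multi-start count for the transient fits.
#' @param trial_dirs video mode: character vector of per-trial frame
#'   directories, in temporal order.
#' @param design video mode: the matching `exposure_design` (or CSV path).
#' @param frame_rate video mode: acquisition rate, Hz.
#' @param annotations optional manual-annotation data.frame or CSV path; when
#'   present the auto-vs-manual comparison stage runs.
#' @param out_dir if non-NULL, results are written here (CSV/JSON).
#' @return List of class `"session_config"`.
#' @export
session_config <- function(mode = c("synthetic", "video"), seed = 7,
                           n_blocks = 5, exposure_s = 180,
                           params = generator_params(),
                           tracker = tracker_config(), P = 100,
                           n_starts = 10, trial_dirs = NULL, design = NULL,
                           frame_rate = NULL, annotations = NULL,
                           out_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "video") {
    if (is.null(trial_dirs) || !all(dir.exists(trial_dirs)))
      stopf("video mode requires existing trial frame directories")
    if (is.null(design)) stopf("video mode requires a design")
  }
  structure(list(mode = mode, seed = seed, n_blocks = n_blocks,
                 exposure_s = exposure_s, params = params, tracker = tracker,
                 P = P, n_starts = n_starts, trial_dirs = trial_dirs,
                 design = design, frame_rate = frame_rate,
                 annotations = annotations, out_dir = out_dir),
            class = "session_config")
}

# render each sample of a simulated series and track it immediately, never
# materializing the whole frame stack; returns a tracked_series with shapes
track_rendered_series <- function(series, params, tracker, P) {
  canvas <- render_canvas(params)
  n <- length(series$theta)
  theta <- rep(NA_real_, n)
  gap <- broken <- curled <- logical(n)
  shapes <- matrix(NA_real_, n, 2L * P)
  for (i in seq_len(n)) {
    res <- tryCatch({
      fr <- render_filament_frame(series$theta[i], params, canvas, i - 1L)
      track_frame(fr$frame, tracker)
    }, error = function(e) NULL)
    if (is.null(res)) { gap[i] <- TRUE; next }
    theta[i] <- res$tip_angle
    broken[i] <- res$path$broken
    curled[i] <- res$path$curled
    shapes[i, ] <- tryCatch(
      resample_path(res$path, P, nominal_length_px = params$filament_length_px),
      error = function(e) rep(NA_real_, 2L * P))
  }
  if (all(gap)) stopf("empty series: no frame could be tracked")
  structure(list(times = series$times, theta = unwrap_angles(theta),
                 gap = gap, broken = broken, curled = curled,
                 frame_rate = series$frame_rate,
                 trial_boundaries = series$trial_boundaries,
                 paths = NULL, shapes = shapes),
            class = c("tracked_series", "angle_series"))
}

# initial angle of a trial: mean over the first second (a windowed estimate
# of the angle the filament had relaxed to when the exposure began)
initial_angle <- function(seg, window_s = 1) {
  y <- seg$theta[seg$times <= window_s]
  y <- y[is.finite(y)]
  if (!length(y)) y <- seg$theta[is.finite(seg$theta)][1L]
  mean(y)
}

# per-trial summary table: composition, initial angle, bending summaries and
# transient-fit parameters
trial_summary <- function(segments, design, fits) {
  fr <- design_fractions(design)
  do.call(rbind, lapply(seq_along(segments), function(i) {
    seg <- segments[[i]]
    f <- fits[[i]]
    t_max <- time_to_max_deflection(seg)
    data.frame(
      trial_index = i, solution_id = design$solution_id[i],
      f_acetone = fr$f_acetone[i], f_ethanol = fr$f_ethanol[i],
      f_water = fr$f_water[i],
      initial_angle = initial_angle(seg),
      delta_theta = delta_tip_angle(seg),
      t_max_s = as.numeric(t_max),
      a0 = f$a0, a1 = f$a1, a2 = f$a2, a3 = f$a3,
      lambda1 = f$lambda1, lambda2 = f$lambda2, lambda3 = f$lambda3,
      sse = f$sse, converged = f$converged)
  }))
}

#' Run an end-to-end session
#'
#' Synthetic mode chains every stage: exposure design, bending simulation,
#' frame rendering, midline tracking (streamed frame by frame), per-trial
#' splitting, triple-exponential transient fits, pooled shape PCA, forward
#' and inverse calibration models, and the hysteresis diagnostic. Video mode
#' starts at tracking from frame directories. Identical seeds produce
#' byte-identical output files.
#'
#' @param config a [session_config()] (or arguments passed on to it).
#' @param ... convenience: forwarded to [session_config()] when `config` is
#'   missing.
#' @return Object of class `"vocbend_session"` holding the design, simulated
#'   and tracked series, per-trial table, transient fits, shape modes,
#'   calibration models, hysteresis diagnostic, and (optionally) the manual
#'   comparison; `out_paths` lists written files.
#' @examples
#' \donttest{
#' res <- run_session(session_config(seed = 7, n_blocks = 1, exposure_s = 20,
#'   params = generator_params(frame_rate = 5)))
#' print(res)
#' }
#' @export
run_session <- function(config, ...) {
  if (missing(config)) config <- session_config(...)
  stopifnot(inherits(config, "session_config"))
  seed <- config$seed
  t0 <- Sys.time()
  log <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf("[%6.1fs] %s", as.numeric(Sys.time() - t0, units = "secs"),
                   sprintf(fmt, ...))
    log <<- c(log, msg)
  }

  if (config$mode == "synthetic") {
    design <- generate_exposure_design(config$n_blocks, seed = seed,
                                       exposure_s = config$exposure_s)
    say("design: %d trials", nrow(design))
    series <- simulate_session(design, config$params, seed = seed + 1L)
    say("simulated %d samples at %g Hz", length(series$theta),
        config$params$frame_rate)
    tracked <- track_rendered_series(series, config$params, config$tracker,
                                     config$P)
    say("rendered and tracked %d frames (%d gaps)", length(tracked$theta),
        sum(tracked$gap))
  } else {
    design <- config$design
    if (is.character(design)) design <- read_exposure_design(design)
    series <- NULL
    per_trial <- lapply(seq_along(config$trial_dirs), function(i) {
      fs <- read_frames(config$trial_dirs[i],
                        frame_rate = config$frame_rate %||% 30)
      track_sequence(fs, config$tracker, resample_P = config$P)
    })
    theta <- unlist(lapply(per_trial, `[[`, "theta"))
    nper <- vapply(per_trial, function(x) length(x$theta), integer(1))
    boundaries <- cumsum(c(1L, head(nper, -1L)))
    offs <- rep(cumsum(c(0, head(nper, -1L))) /
                  (config$frame_rate %||% 30), nper)
    tracked <- structure(list(
      times = unlist(lapply(per_trial, `[[`, "times")) + offs,
      theta = theta,
      gap = unlist(lapply(per_trial, `[[`, "gap")),
      broken = unlist(lapply(per_trial, `[[`, "broken")),
      curled = unlist(lapply(per_trial, `[[`, "curled")),
      frame_rate = config$frame_rate %||% 30,
      trial_boundaries = boundaries,
      shapes = do.call(rbind, lapply(per_trial, `[[`, "shapes"))),
      class = c("tracked_series", "angle_series"))
    say("tracked %d trial directories (%d frames)", length(per_trial),
        length(theta))
  }

  segments <- split_trials(tracked, design)
  fits <- lapply(segments, function(seg)
    fit_triple_exponential(seg, n_starts = config$n_starts,
                           seed = seed + 100L + seg$trial_index))
  say("fitted %d transients (%d converged)", length(fits),
      sum(vapply(fits, `[[`, logical(1), "converged")))

  trials <- trial_summary(segments, design, fits)
  modes <- shape_pca(tracked$shapes)
  say("shape PCA over %d shapes: PC1-2 %.1f%%, PC1-4 %.1f%%", modes$n_shapes,
      100 * cumulative_variance(modes, 2), 100 * cumulative_variance(modes, 4))

  stage <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      say("%s skipped: %s", label, conditionMessage(e))
      NULL
    })
  }
  forward <- stage("forward model", fit_forward_model(trials))
  inverse <- stage("inverse model",
                   fit_inverse_model(trials,
                                     trials[, c("f_acetone", "f_ethanol")]))
  hyst <- stage("hysteresis diagnostic",
                hysteresis_diagnostic(trials$initial_angle))
  if (!is.null(forward) && !is.null(inverse))
    say("forward R^2 %.3f; inverse R^2 acetone %.3f, ethanol %.3f",
        forward$r2[["delta_theta"]], inverse$r2[["f_acetone"]],
        inverse$r2[["f_ethanol"]])

  manual <- NULL
  if (!is.null(config$annotations)) {
    ann <- config$annotations
    if (is.character(ann)) ann <- read.csv(ann)
    manual <- compare_to_manual(tracked, ann, config$tracker)
    say("manual comparison R^2 %.3f over %d frames", manual$r_squared,
        length(manual$times))
  } else if (config$mode == "video") {
    say("no annotation file given: manual-comparison stage skipped")
  }

  res <- structure(list(config = config, design = design, series = series,
                        tracked = tracked, segments = segments, fits = fits,
                        trials = trials, shape_modes = modes,
                        forward_model = forward, inverse_model = inverse,
                        hysteresis = hyst, manual_comparison = manual,
                        log = log, out_paths = NULL),
                   class = "vocbend_session")
  if (!is.null(config$out_dir)) res$out_paths <- write_session(res, config$out_dir)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.vocbend_session <- function(x, ...) {
  cat("End-to-end bending-sensor session\n")
  cat(sprintf("  %d trials, %d tracked frames, seed %s\n", nrow(x$trials),
              length(x$tracked$theta), format(x$config$seed)))
  cat(sprintf("  shape PCA: PC1-2 %.1f%%, PC1-4 %.1f%% of variance\n",
              100 * cumulative_variance(x$shape_modes, 2),
              100 * cumulative_variance(x$shape_modes, 4)))
  if (!is.null(x$forward_model))
    cat(sprintf("  forward model R^2: %.3f\n",
                x$forward_model$r2[["delta_theta"]]))
  if (!is.null(x$inverse_model))
    cat(sprintf("  inverse model R^2: acetone %.3f, ethanol %.3f\n",
                x$inverse_model$r2[["f_acetone"]],
                x$inverse_model$r2[["f_ethanol"]]))
  if (!is.null(x$hysteresis))
    cat(sprintf("  hysteresis: drift %.3f deg/trial, lag-1 autocorr %s\n",
                x$hysteresis$drift_slope_deg_per_trial,
                if (isTRUE(x$hysteresis$undefined)) "undefined"
                else sprintf("%.3f", x$hysteresis$lag1_autocorrelation)))
  if (!is.null(x$manual_comparison))
    cat(sprintf("  auto-vs-manual cubic R^2: %.3f\n",
                x$manual_comparison$r_squared))
  invisible(x)
}

# write all session outputs; every file embeds the seed and config hash
write_session <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- res$config
  cfgjson <- jsonlite::toJSON(cfg[c("mode", "seed", "n_blocks", "exposure_s",
                                    "P", "n_starts")],
                              auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); writeLines(cfgjson, tf)
  hash <- unname(tools::md5sum(tf)); unlink(tf)
  hdr <- sprintf("# seed: %s | config: %s | angles deg, times s",
                 format(cfg$seed), hash)

  w_csv <- function(df, file) {
    path <- file.path(dir, file)
    con <- file(path, "w")
    writeLines(hdr, con)
    write.csv(df, con, row.names = FALSE)
    close(con)
    path
  }
  p1 <- w_csv(data.frame(time_s = res$tracked$times,
                         tip_angle_deg = res$tracked$theta,
                         gap = res$tracked$gap, broken = res$tracked$broken,
                         curled = res$tracked$curled), "angle_series.csv")
  p2 <- w_csv(res$trials, "trial_fits.csv")
  p3 <- file.path(dir, "shape_modes.json")
  jsonlite::write_json(list(
    seed = cfg$seed, config_hash = hash, P = res$shape_modes$P,
    n_shapes = res$shape_modes$n_shapes,
    explained_variance = res$shape_modes$explained_variance,
    mean_shape = res$shape_modes$mean_shape,
    components = lapply(seq_len(min(4L, ncol(res$shape_modes$components))),
                        function(k) res$shape_modes$components[, k])),
    p3, auto_unbox = TRUE, digits = NA)
  p4 <- file.path(dir, "models.json")
  model_json <- list(seed = cfg$seed, config_hash = hash)
  if (!is.null(res$forward_model))
    model_json$forward <- list(
      features = res$forward_model$feature_names,
      coefficients = res$forward_model$coefficients,
      r2 = as.list(res$forward_model$r2),
      n = res$forward_model$n_trials)
  if (!is.null(res$inverse_model))
    model_json$inverse <- list(
      features = res$inverse_model$feature_names,
      coefficients = res$inverse_model$coefficients,
      r2 = as.list(res$inverse_model$r2),
      r2_full_minus_reduced =
        as.list(res$inverse_model$r2_full_minus_reduced),
      n = res$inverse_model$n_trials)
  if (!is.null(res$hysteresis))
    model_json$hysteresis <- list(
      drift_slope_deg_per_trial = res$hysteresis$drift_slope_deg_per_trial,
      lag1_autocorrelation = res$hysteresis$lag1_autocorrelation)
  jsonlite::write_json(model_json, p4, auto_unbox = TRUE, digits = NA)
  p5 <- file.path(dir, "run_log.txt")
  writeLines(c(hdr, sprintf("# R %s, vocbend %s", getRversion(),
                            as.character(utils::packageVersion("vocbend"))),
               res$log), p5)
  c(angle_series = p1, trial_fits = p2, shape_modes = p3, models = p4,
    log = p5)
}
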