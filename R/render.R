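#' Constant-curvature filament midline
#'
#' Midline of a constant-curvature arc of fixed arc length, clamped at its
#' root with a fixed root tangent (plumb by default). The curvature is chosen
#' so that the *tip angle* — the direction of the last 25 percent of the arc,
#' which for a circular arc equals the tangent at the arc-length midpoint of
#' that segment — equals `tip_angle_deg`.
#'
#' @param tip_angle_deg target tip angle, degrees (plumb = -90).
#' @param length_px arc length in pixels.
#' @param root_xy pixel coordinates (x, y) of the root.
#' @param root_angle_deg root tangent direction, degrees.
#' @param tip_fraction fraction of arc length defining the tip segment.
#' @param step_px sampling step along the arc.
#' @return Matrix with columns `x`, `y` (pixel coordinates, y down), root
#'   first.
#' @export
arc_midline <- function(tip_angle_deg, length_px, root_xy,
                        root_angle_deg = -90, tip_fraction = 0.25,
                        step_px = 0.4) {
  # tangent angle varies linearly in arc length; the tip-segment PCA
  # direction equals the tangent at s = (1 - tip_fraction/2) * L
  s_ref <- (1 - tip_fraction / 2) * length_px
  kappa <- deg2rad(tip_angle_deg - root_angle_deg) / s_ref
  s <- seq(0, length_px, by = step_px)
  if (s[length(s)] < length_px) s <- c(s, length_px)
  phi <- deg2rad(root_angle_deg) + kappa * s
  if (abs(kappa) < 1e-12) {
    x <- root_xy[1] + cos(phi[1]) * s
    y <- root_xy[2] - sin(phi[1]) * s
  } else {
    # closed-form integral of (cos phi, sin phi) ds
    x <- root_xy[1] + (sin(phi) - sin(phi[1])) / kappa
    y <- root_xy[2] + (cos(phi) - cos(phi[1])) / kappa
  }
  cbind(x = x, y = y)
}

#' Rasterize a midline into a binary frame
#'
#' Stamps a disk of diameter `thickness_px` at each midline sample, producing
#' a logical matrix (TRUE = foreground filament pixel, image row = y).
#'
#' @param midline matrix with columns x, y in pixel coordinates.
#' @param thickness_px stroke width in pixels.
#' @param width,height canvas size in pixels.
#' @param frame_index used in error messages.
#' @return `height x width` logical matrix.
#' @export
render_midline <- function(midline, thickness_px, width, height,
                           frame_index = NA) {
  r <- thickness_px / 2
  if (any(midline[, "x"] < r + 1) || any(midline[, "x"] > width - r) ||
      any(midline[, "y"] < r + 1) || any(midline[, "y"] > height - r))
    stopf("frame %s: filament geometry exceeds the %dx%d canvas",
          as.character(frame_index), width, height)
  off <- expand.grid(di = -ceiling(r):ceiling(r), dj = -ceiling(r):ceiling(r))
  off <- off[off$di^2 + off$dj^2 <= r^2, ]
  rows <- round(rep(midline[, "y"], each = nrow(off))) + off$di
  cols <- round(rep(midline[, "x"], each = nrow(off))) + off$dj
  img <- matrix(FALSE, height, width)
  img[cbind(rows, cols)] <- TRUE
  img
}

# canvas geometry shared by the renderer and run_session
render_canvas <- function(params) {
  L <- params$filament_length_px
  tk <- params$thickness_px
  margin <- ceiling(tk) + 6
  list(width = 2L * ceiling(L + margin) + 1L,
       height = ceiling(L + 2 * margin),
       root = c(ceiling(L + margin) + 1, margin + 1))
}

# render one frame at a given tip angle; returns frame + true midline
render_filament_frame <- function(tip_angle_deg, params, canvas = NULL,
                                  frame_index = NA) {
  if (is.null(canvas)) canvas <- render_canvas(params)
  mid <- arc_midline(tip_angle_deg, params$filament_length_px, canvas$root)
  frame <- render_midline(mid, params$thickness_px, canvas$width,
                          canvas$height, frame_index)
  list(frame = frame, midline = mid, tip_angle = tip_angle_deg,
       frame_index = frame_index)
}

#' Render a tip-angle series as binary frames
#'
#' Renders each sample of an angle series as a constant-curvature filament
#' frame (black filament on white, returned as a logical foreground mask),
#' together with the ground-truth midline.
#'
#' @param series an `angle_series` (or a numeric vector of tip angles).
#' @param params a [generator_params()] object (render geometry).
#' @return List of class `"frame_sequence"`: `frames` (list of logical
#'   matrices), `midlines` (list of ground-truth midline matrices),
#'   `tip_angles`, `times`, `frame_rate`, `canvas`.
#' @export
render_frames <- function(series, params = generator_params()) {
  theta <- if (inherits(series, "angle_series")) series$theta else as.numeric(series)
  times <- if (inherits(series, "angle_series")) series$times
  else (seq_along(theta) - 1) / params$frame_rate
  canvas <- render_canvas(params)
  rendered <- lapply(seq_along(theta), function(i)
    render_filament_frame(theta[i], params, canvas, frame_index = i - 1L))
  structure(list(frames = lapply(rendered, `[[`, "frame"),
                 midlines = lapply(rendered, `[[`, "midline"),
                 tip_angles = theta, times = times,
                 frame_rate = params$frame_rate, canvas = canvas),
            class = "frame_sequence")
}

#' Write a frame sequence to disk
#'
#' Frames are written as zero-padded numbered PNG files (black filament on
#' white) plus a JSON sidecar holding the frame rate, times, ground-truth tip
#' angles and midlines.
#'
#' @param fs a `frame_sequence`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_frames <- function(fs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nd <- max(5L, nchar(as.character(length(fs$frames))))
  for (i in seq_along(fs$frames)) {
    img <- 1 - fs$frames[[i]] * 1  # foreground black
    png::writePNG(img, file.path(dir, sprintf("frame_%0*d.png", nd, i - 1L)))
  }
  side <- list(frame_rate = fs$frame_rate, times = fs$times,
               tip_angles = fs$tip_angles,
               midlines = lapply(fs$midlines, function(m)
                 list(x = unname(m[, "x"]), y = unname(m[, "y"]))))
  jsonlite::write_json(side, file.path(dir, "frames.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a directory of numbered image frames
#'
#' Reads PNG/TIFF frames (sorted by filename) into a `frame_sequence`;
#' grayscale conversion uses luminance. Foreground is not thresholded here —
#' use [binarize()].
#'
#' @param dir directory of frames.
#' @param frame_rate acquisition rate, Hz.
#' @return A `frame_sequence` whose `frames` are numeric luminance matrices.
#' @export
read_frames <- function(dir, frame_rate = 30) {
  files <- sort(list.files(dir, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (!length(files)) stopf("no PNG/TIFF frames found in %s", dir)
  frames <- lapply(files, function(f) {
    img <- if (grepl("png$", f, ignore.case = TRUE)) png::readPNG(f)
    else as.array(EBImage::readImage(f))
    if (length(dim(img)) == 3L)
      img <- 0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
    img
  })
  structure(list(frames = frames, midlines = NULL, tip_angles = NULL,
                 times = (seq_along(frames) - 1) / frame_rate,
                 frame_rate = frame_rate,
                 canvas = list(width = ncol(frames[[1]]),
                               height = nrow(frames[[1]]))),
            class = "frame_sequence")
}

# point on a polyline at arc length s (linear interpolation)
polyline_at <- function(pts, s) {
  cl <- c(0, cumsum(sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)))
  cbind(x = approx(cl, pts[, 1], xout = s, rule = 2)$y,
        y = approx(cl, pts[, 2], xout = s, rule = 2)$y)
}

polyline_length <- function(pts)
  sum(sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2))

#' Emulate manual annotation of filament frames
#'
#' Emulates a human annotator clicking `n_points` roughly equidistant points
#' along the filament, root to tip, on one displayed frame every `interval_s`
#' seconds: points are placed exactly equidistant in arc length on the true
#' midline, then isotropic Gaussian click noise of SD `click_sd_px` is added.
#'
#' @param fs a `frame_sequence` with ground-truth `midlines`.
#' @param interval_s seconds between annotated frames.
#' @param n_points clicked points per frame (>= 2; endpoints always included).
#' @param click_sd_px click noise SD in pixels.
#' @param seed integer seed.
#' @return data.frame with columns `frame_index`, `time_s`, `point_index`,
#'   `x_px`, `y_px`.
#' @export
emulate_manual_annotation <- function(fs, interval_s = 5, n_points = 7,
                                      click_sd_px = 2, seed = NULL) {
  if (is.null(fs$midlines)) stopf("frame sequence has no ground-truth midlines")
  if (n_points < 2) stopf("n_points must be >= 2")
  step <- max(1L, round(interval_s * fs$frame_rate))
  sel <- seq(1L, length(fs$midlines), by = step)
  ann <- do.call(rbind, lapply(sel, function(i) {
    m <- fs$midlines[[i]]
    L <- polyline_length(m)
    p <- polyline_at(m, seq(0, L, length.out = n_points))
    data.frame(frame_index = i - 1L, time_s = fs$times[i],
               point_index = seq_len(n_points),
               x_px = p[, "x"], y_px = p[, "y"])
  }))
  if (click_sd_px > 0) {
    noise <- with_seed(seed, rnorm(2L * nrow(ann), 0, click_sd_px))
    ann$x_px <- ann$x_px + noise[seq_len(nrow(ann))]
    ann$y_px <- ann$y_px + noise[nrow(ann) + seq_len(nrow(ann))]
  }
  ann
}
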