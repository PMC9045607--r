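#' Tracker configuration
#'
#' @param threshold_method `"otsu"` (default) or a fixed numeric threshold in
#'   `[0, 1]`; foreground is every pixel darker than the threshold.
#' @param tip_fraction fraction of total arc length defining the tip segment
#'   whose principal direction is the tip angle (default 0.25, the distal
#'   quarter).
#' @param min_cluster_px minimum pixel count for each of two row clusters to
#'   count as substantial; default `max(3, 0.5 * thickness)` with thickness
#'   estimated per frame.
#' @param cluster_sep_factor minimum separation between two row clusters, in
#'   units of filament thickness, for the two-cluster split to be accepted.
#' @param max_gap_factor gaps between consecutive path points larger than
#'   `max_gap_factor * thickness` truncate the path (broken flag).
#' @param refine apply the midline refinement pass (orthogonal re-centering of
#'   near-horizontal stretches, tangent extension of the distal end, light
#'   smoothing, end-cap trimming). Row scanning alone parameterizes the
#'   midline by the image row, which degrades where the filament runs nearly
#'   horizontally; the refinement restores sub-degree accuracy there.
#' @param smooth_window moving-average window (path points) of the
#'   refinement; default the odd-rounded filament thickness.
#' @param end_trim_factor arc length trimmed from each path end, in units of
#'   thickness (default 0.3), discounting the stroke's rounded end caps which
#'   carry no midline information.
#' @return List of class `"tracker_config"`.
#' @export
tracker_config <- function(threshold_method = "otsu", tip_fraction = 0.25,
                           min_cluster_px = NULL, cluster_sep_factor = 1.5,
                           max_gap_factor = 3, refine = TRUE,
                           smooth_window = NULL, end_trim_factor = 0.3) {
  if (tip_fraction <= 0 || tip_fraction >= 1)
    stopf("tip_fraction must be in (0, 1)")
  structure(list(threshold_method = threshold_method,
                 tip_fraction = tip_fraction,
                 min_cluster_px = min_cluster_px,
                 cluster_sep_factor = cluster_sep_factor,
                 max_gap_factor = max_gap_factor, refine = refine,
                 smooth_window = smooth_window,
                 end_trim_factor = end_trim_factor),
            class = "tracker_config")
}

#' Binarize a grayscale frame
#'
#' Converts a luminance frame to a logical foreground mask (TRUE = dark
#' filament pixel). The threshold is Otsu's by default. Logical input is
#' returned unchanged, so the operation is idempotent.
#'
#' @param gray_frame numeric matrix in `[0, 1]` (0 = black), an RGB array, or
#'   a logical foreground mask.
#' @param config a [tracker_config()].
#' @return Logical matrix, TRUE = foreground.
#' @export
binarize <- function(gray_frame, config = tracker_config()) {
  if (is.logical(gray_frame)) {
    fg <- gray_frame
  } else {
    if (length(dim(gray_frame)) == 3L)
      gray_frame <- 0.2126 * gray_frame[, , 1] + 0.7152 * gray_frame[, , 2] +
        0.0722 * gray_frame[, , 3]
    rng <- range(gray_frame)
    if (rng[2] > 1) gray_frame <- gray_frame / 255
    thr <- config$threshold_method
    if (identical(thr, "otsu")) {
      if (diff(range(gray_frame)) < .Machine$double.eps^0.5)
        stopf("empty frame: no foreground pixels after thresholding")
      thr <- EBImage::otsu(EBImage::Image(gray_frame))
    } else if (!is.numeric(thr)) {
      stopf("unknown threshold_method")
    }
    fg <- gray_frame < thr
  }
  if (!any(fg)) stopf("empty frame: no foreground pixels after thresholding")
  fg
}

#' Per-row midpoint candidates
#'
#' Scans each horizontal pixel line of a binary frame. A row's default
#' midpoint is the mean column of its foreground pixels. Rows whose foreground
#' is non-contiguous are tested with a two-cluster k-means split: if both
#' clusters are substantial (>= `min_cluster_px` pixels) and separated by at
#' least `cluster_sep_factor` times the typical filament thickness (median
#' foreground run length over contiguous rows), the row contributes two
#' midpoints — the filament crosses that line twice, once going down and once
#' coming back up after curling.
#'
#' @param frame logical foreground matrix (see [binarize()]).
#' @param config a [tracker_config()].
#' @return List with `candidates` (data.frame `y`, `x`, `n_px`, `paired`
#'   logical: row produced two midpoints) and `thickness` (px estimate).
#' @export
row_midpoints <- function(frame, config = tracker_config()) {
  idx <- which(frame)
  if (!length(idx)) stopf("empty frame: no foreground pixels")
  nr <- nrow(frame)
  ys <- (idx - 1L) %% nr + 1L
  xs <- (idx - 1L) %/% nr + 1L
  o <- order(ys, xs)
  ys <- ys[o]; xs <- xs[o]

  newrow <- c(TRUE, diff(ys) > 0L)
  grp <- cumsum(newrow)                      # row group id per pixel
  ur <- ys[newrow]                           # unique rows, ascending
  cnt <- tabulate(grp)
  sum_x <- as.vector(rowsum(xs, grp))
  # a row is contiguous iff max - min + 1 == count
  min_x <- xs[newrow]
  max_x <- xs[cumsum(cnt)]
  contiguous <- (max_x - min_x + 1L) == cnt

  thickness <- if (any(contiguous)) median(cnt[contiguous]) else median(cnt)
  min_cluster <- config$min_cluster_px
  if (is.null(min_cluster)) min_cluster <- max(3, 0.5 * thickness)

  cand_y <- ur[contiguous]
  cand_x <- sum_x[contiguous] / cnt[contiguous]
  cand_n <- cnt[contiguous]
  cand_p <- rep(FALSE, sum(contiguous))

  for (g in which(!contiguous)) {
    cols <- xs[grp == g]
    runs <- cumsum(c(1L, diff(cols) > 1L))
    centers <- matrix(c(mean(cols[runs == 1L]),
                        mean(cols[runs == max(runs)])), ncol = 1)
    km <- suppressWarnings(kmeans(cols, centers = centers))
    sizes <- km$size
    sep <- abs(diff(km$centers[, 1]))
    if (length(sizes) == 2L && all(sizes >= min_cluster) &&
        sep >= config$cluster_sep_factor * thickness) {
      cand_y <- c(cand_y, ur[g], ur[g])
      cand_x <- c(cand_x, km$centers[1, 1], km$centers[2, 1])
      cand_n <- c(cand_n, sizes)
      cand_p <- c(cand_p, TRUE, TRUE)
    } else {
      cand_y <- c(cand_y, ur[g])
      cand_x <- c(cand_x, mean(cols))
      cand_n <- c(cand_n, length(cols))
      cand_p <- c(cand_p, FALSE)
    }
  }
  o2 <- order(cand_y, cand_x)
  list(candidates = data.frame(y = cand_y[o2], x = cand_x[o2],
                               n_px = cand_n[o2], paired = cand_p[o2]),
       thickness = thickness)
}

#' Assemble per-row midpoints into a root-to-tip path
#'
#' Starting from the topmost (root) row, steps downward choosing the nearest
#' continuation candidate on each row. On rows with two accepted midpoints the
#' nearer one continues the descending branch and the other is stashed; after
#' the lowest row the stashed ascending-branch points are traversed bottom to
#' top, so a curled filament yields a single ordered root-to-tip path. A gap
#' between consecutive points exceeding `max_gap_factor * thickness` truncates
#' the path and sets the `broken` flag.
#'
#' @param mids result of [row_midpoints()].
#' @param config a [tracker_config()].
#' @return Object of class `"filament_path"`: list with `points` (matrix
#'   `x`, `y`, root first), `arc_length` (cumulative, px), `thickness`,
#'   `broken`, `curled`.
#' @export
assemble_path <- function(mids, config = tracker_config()) {
  cand <- mids$candidates
  thick <- mids$thickness
  rows <- unique(cand$y)
  if (length(rows) < 4L) stopf("too few usable rows (%d) to form a path",
                               length(rows))

  if (!any(cand$paired)) {
    px <- cand$x; py <- cand$y               # one candidate per row, sorted
    curled <- FALSE
  } else {
    px <- numeric(0); py <- numeric(0)
    stash_x <- numeric(0); stash_y <- numeric(0)
    x_cur <- NA_real_
    for (yy in rows) {
      xs_row <- cand$x[cand$y == yy]
      if (length(xs_row) == 1L) {
        x_cur <- xs_row
      } else {
        if (is.na(x_cur)) x_cur <- xs_row[1L]
        pick <- which.min(abs(xs_row - x_cur))
        x_cur <- xs_row[pick]
        stash_x <- c(stash_x, xs_row[-pick])
        stash_y <- c(stash_y, yy)
      }
      px <- c(px, x_cur); py <- c(py, yy)
    }
    if (length(stash_x)) {                   # ascending branch, bottom to top
      o <- order(stash_y, decreasing = TRUE)
      px <- c(px, stash_x[o]); py <- c(py, stash_y[o])
    }
    curled <- length(stash_x) > 0
  }

  seg <- sqrt(diff(px)^2 + diff(py)^2)
  broken <- FALSE
  bad <- which(seg > config$max_gap_factor * thick)
  if (length(bad)) {
    keep <- seq_len(bad[1L])
    px <- px[keep]; py <- py[keep]
    seg <- seg[seq_len(bad[1L] - 1L)]
    broken <- TRUE
    if (length(px) < 4L) stopf("too few usable rows after gap truncation")
  }
  structure(list(points = cbind(x = px, y = py),
                 arc_length = c(0, cumsum(seg)),
                 thickness = thick, broken = broken, curled = curled),
            class = "filament_path")
}

#' @export
print.filament_path <- function(x, ...) {
  cat(sprintf("Filament path: %d points, arc length %.1f px%s%s\n",
              nrow(x$points), max(x$arc_length),
              if (x$broken) ", BROKEN" else "",
              if (x$curled) ", curled" else ""))
  invisible(x)
}

#' Tip angle of a filament path
#'
#' The tip is the distal `tip_fraction` of the path's arc length. Its
#' direction is the first principal component of the tip-segment points,
#' sign-oriented along the chord from the segment's proximal end to the tip
#' endpoint, and reported in degrees counterclockwise from +x (image y down),
#' so a plumb filament reads -90.
#'
#' @param path a `"filament_path"` (or a plain matrix of x, y points ordered
#'   root to tip).
#' @param config a [tracker_config()].
#' @return Tip angle in degrees, in (-180, 180].
#' @export
tip_angle <- function(path, config = tracker_config()) {
  pts <- if (inherits(path, "filament_path")) path$points else as.matrix(path)
  s <- if (inherits(path, "filament_path")) path$arc_length
  else c(0, cumsum(sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)))
  S <- s[length(s)]
  sel <- s >= (1 - config$tip_fraction) * S
  if (sum(sel) < 2L) sel[length(sel) - 1L] <- TRUE
  p <- pts[sel, , drop = FALSE]
  ctr <- sweep(p, 2, colMeans(p))
  if (max(abs(ctr)) < .Machine$double.eps^0.5)
    stopf("degenerate tip: all tip-segment points coincide")
  v <- eigen(crossprod(ctr) / nrow(ctr), symmetric = TRUE)$vectors[, 1]
  chord <- p[nrow(p), ] - p[1, ]
  if (sum(v * chord) < 0) v <- -v
  px_angle(v[1], v[2])
}

# running mean with symmetric windows that shrink toward the ends
smooth_running_mean <- function(v, w) {
  n <- length(v)
  if (w < 3 || n < w) return(v)
  h <- w %/% 2
  cs <- cumsum(c(0, v))
  hw <- pmin(seq_len(n) - pmax(1, seq_len(n) - h),
             pmin(n, seq_len(n) + h) - seq_len(n))
  lo <- seq_len(n) - hw; hi <- seq_len(n) + hw
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# mean of foreground pixels on a thin slice orthogonal to direction (ux, uy)
# centered at (cx, cy); NULL when under-occupied
ortho_slice_mean <- function(frame, cx, cy, ux, uy, thickness) {
  hw <- ceiling(1.5 * thickness)
  rr <- max(1, round(cy) - hw):min(nrow(frame), round(cy) + hw)
  cc <- max(1, round(cx) - hw):min(ncol(frame), round(cx) + hw)
  sub <- frame[rr, cc, drop = FALSE]
  if (!any(sub)) return(NULL)
  id <- which(sub)
  yy <- rr[(id - 1L) %% nrow(sub) + 1L]
  xx <- cc[(id - 1L) %/% nrow(sub) + 1L]
  pu <- (xx - cx) * ux + (yy - cy) * uy
  pv <- -(xx - cx) * uy + (yy - cy) * ux
  k <- abs(pu) <= 1 & abs(pv) <= 0.75 * thickness
  if (sum(k) < 2L) return(NULL)
  c(mean(xx[k]), mean(yy[k]))
}

#' Refine a row-scanned filament path
#'
#' Post-processes the raw row-scan path against the binary frame it came
#' from: (1) re-centers points on near-horizontal stretches using column
#' means (row means cannot localize a horizontal midline); (2) extends the
#' distal end along its local tangent with orthogonal-slice means, capturing
#' tail geometry the row scan under-samples; (3) smooths both coordinates
#' with a running mean of about one thickness; (4) trims
#' `end_trim_factor * thickness` of arc length from each end, discarding the
#' stroke's end caps. Flags are inherited from the input path.
#'
#' @param path a `"filament_path"` from [assemble_path()].
#' @param frame the logical foreground frame the path was extracted from.
#' @param config a [tracker_config()].
#' @return A refined `"filament_path"`.
#' @export
refine_path <- function(path, frame, config = tracker_config()) {
  px <- path$points[, 1]; py <- path$points[, 2]
  tk <- path$thickness
  n <- length(px)
  if (n < 6L) return(path)

  # (1) orthogonal re-centering where the path runs flatter than 45 degrees
  dx <- c(px[2] - px[1], diff(px)); dy <- c(py[2] - py[1], diff(py))
  for (i in seq_len(n)) {
    if (abs(dx[i]) > abs(dy[i])) {
      ys <- which(frame[, round(px[i])])
      ys <- ys[abs(ys - py[i]) <= 1.5 * tk]
      if (length(ys)) py[i] <- mean(ys)
    }
  }

  # (2) tangent extension of the distal end
  i0 <- max(1L, n - round(tk))
  ux <- px[n] - px[i0]; uy <- py[n] - py[i0]
  nn <- sqrt(ux^2 + uy^2)
  if (nn > 0) {
    ux <- ux / nn; uy <- uy / nn
    d_last <- 0
    for (j in seq_len(ceiling(3 * tk))) {
      m <- ortho_slice_mean(frame, px[n] + j * ux, py[n] + j * uy, ux, uy, tk)
      if (is.null(m)) break
      d <- (m[1] - px[n]) * ux + (m[2] - py[n]) * uy
      if (d < d_last + 0.3) break
      d_last <- d
      px <- c(px, m[1]); py <- c(py, m[2])
    }
  }

  # (3) smoothing and (4) end-cap trimming
  w <- config$smooth_window
  if (is.null(w)) w <- max(3L, round(tk))
  if (w %% 2L == 0L) w <- w - 1L
  px <- smooth_running_mean(px, w)
  py <- smooth_running_mean(py, w)
  s <- c(0, cumsum(sqrt(diff(px)^2 + diff(py)^2)))
  S <- s[length(s)]
  keep <- s >= config$end_trim_factor * tk & s <= S - config$end_trim_factor * tk
  if (sum(keep) < 4L) keep <- rep(TRUE, length(px))
  px <- px[keep]; py <- py[keep]

  structure(list(points = cbind(x = px, y = py),
                 arc_length = c(0, cumsum(sqrt(diff(px)^2 + diff(py)^2))),
                 thickness = tk, broken = path$broken, curled = path$curled),
            class = "filament_path")
}

# track one binary or grayscale frame
track_frame <- function(frame, config = tracker_config()) {
  fg <- binarize(frame, config)
  path <- assemble_path(row_midpoints(fg, config), config)
  if (isTRUE(config$refine)) path <- refine_path(path, fg, config)
  list(path = path, tip_angle = tip_angle(path, config))
}

#' Track a frame sequence
#'
#' Runs the midline tracker over every frame: binarize, per-row midpoints,
#' root-to-tip path assembly, PCA tip angle. Frames on which any stage fails
#' are flagged as gaps (NA angle), never silently interpolated. Tip angles are
#' unwrapped across frames by nearest-branch continuation (successive angles
#' differ by at most 180 degrees).
#'
#' @param fs a `frame_sequence` (or plain list of frames).
#' @param config a [tracker_config()].
#' @param frame_rate used when `fs` carries no times.
#' @param keep_paths store per-frame `filament_path` objects (memory-heavy
#'   for long sequences).
#' @param resample_P if non-NULL, store each path resampled to `resample_P`
#'   arc-length points (see [resample_path()]) in a shape matrix.
#' @return Object of class `"tracked_series"`: `times`, `theta` (deg, NA at
#'   gaps), `gap`, `broken`, `curled` flags, `frame_rate`, optionally `paths`
#'   and `shapes` (n x 2P matrix).
#' @export
track_sequence <- function(fs, config = tracker_config(), frame_rate = NULL,
                           keep_paths = FALSE, resample_P = NULL) {
  frames <- if (inherits(fs, "frame_sequence")) fs$frames else fs
  if (!length(frames)) stopf("no frames to track")
  rate <- if (!is.null(frame_rate)) frame_rate
  else if (inherits(fs, "frame_sequence")) fs$frame_rate else 30
  times <- if (inherits(fs, "frame_sequence") && !is.null(fs$times)) fs$times
  else (seq_along(frames) - 1) / rate

  n <- length(frames)
  theta <- rep(NA_real_, n)
  gap <- broken <- curled <- logical(n)
  paths <- if (keep_paths) vector("list", n) else NULL
  shapes <- if (!is.null(resample_P)) matrix(NA_real_, n, 2L * resample_P) else NULL

  for (i in seq_len(n)) {
    res <- tryCatch(track_frame(frames[[i]], config), error = function(e) NULL)
    if (is.null(res)) { gap[i] <- TRUE; next }
    theta[i] <- res$tip_angle
    broken[i] <- res$path$broken
    curled[i] <- res$path$curled
    if (keep_paths) paths[[i]] <- res$path
    if (!is.null(shapes))
      shapes[i, ] <- tryCatch(resample_path(res$path, resample_P),
                              error = function(e) rep(NA_real_, 2L * resample_P))
  }
  if (all(gap)) stopf("empty series: no frame could be tracked")
  theta <- unwrap_angles(theta)
  structure(list(times = times, theta = theta, gap = gap, broken = broken,
                 curled = curled, frame_rate = rate, paths = paths,
                 shapes = shapes),
            class = c("tracked_series", "angle_series"))
}

# unwrap by nearest-branch continuation: adjust each angle by a multiple of
# 360 so that |delta| <= 180 relative to the previous tracked frame
unwrap_angles <- function(theta) {
  ok <- which(!is.na(theta))
  if (length(ok) < 2L) return(theta)
  for (j in seq_along(ok)[-1L]) {
    d <- theta[ok[j]] - theta[ok[j - 1L]]
    theta[ok[j]] <- theta[ok[j]] - 360 * round(d / 360)
  }
  theta
}

#' Compare automatic tracking with manual annotations
#'
#' Rebuilds the manual midline of each annotated frame by cubic-spline
#' interpolation through the clicked points (parameterized by cumulative
#' chord length), computes the manual tip angle with the same PCA tip-angle
#' operation used for automatic tracking, and fits a cubic polynomial
#' predicting the automatic tip angles from the manual ones at matched
#' timestamps. Agreement is summarized as the squared Pearson correlation
#' between prediction and automatic values.
#'
#' @param auto a `tracked_series` (or any `angle_series`).
#' @param annotations data.frame from [emulate_manual_annotation()] (columns
#'   `frame_index`, `time_s`, `point_index`, `x_px`, `y_px`).
#' @param config a [tracker_config()].
#' @param densify points per manual midline after spline interpolation.
#' @return List with `r_squared`, `coefficients` (cubic, increasing order),
#'   `times`, `manual_deg`, `auto_deg`.
#' @export
compare_to_manual <- function(auto, annotations, config = tracker_config(),
                              densify = 200) {
  frames <- unique(annotations$frame_index)
  if (length(frames) < 4L)
    stopf("need annotations on at least 4 distinct frames")
  manual <- vapply(frames, function(fi) {
    a <- annotations[annotations$frame_index == fi, ]
    a <- a[order(a$point_index), ]
    cl <- c(0, cumsum(sqrt(diff(a$x_px)^2 + diff(a$y_px)^2)))
    ss <- seq(0, max(cl), length.out = densify)
    mid <- cbind(x = spline(cl, a$x_px, xout = ss)$y,
                 y = spline(cl, a$y_px, xout = ss)$y)
    tip_angle(mid, config)
  }, numeric(1))
  t_manual <- vapply(frames, function(fi)
    annotations$time_s[annotations$frame_index == fi][1L], numeric(1))

  idx <- vapply(t_manual, function(t0) which.min(abs(auto$times - t0)),
                integer(1))
  ok <- abs(auto$times[idx] - t_manual) <= 0.5 / auto$frame_rate + 1e-9 &
    !is.na(auto$theta[idx])
  manual <- manual[ok]; idx <- idx[ok]
  if (length(idx) < 4L) stopf("fewer than 4 matched annotated frames")
  if (sd(manual) < .Machine$double.eps^0.5)
    stopf("undefined correlation: manual tip-angle series is constant")
  av <- auto$theta[idx]
  fit <- lm(av ~ manual + I(manual^2) + I(manual^3))
  pred <- fitted(fit)
  list(r_squared = cor(pred, av)^2,
       coefficients = unname(coef(fit)),
       times = t_manual[ok], manual_deg = manual, auto_deg = av)
}
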