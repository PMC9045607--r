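#' Resample a filament path to a fixed-length shape vector
#'
#' Places `P` points equally spaced in arc length from root to tip and
#' concatenates them (all x first, then all y) into a 2P shape vector, the
#' common representation required for a well-defined shape covariance.
#'
#' @param path a `"filament_path"` or matrix of x, y points ordered root to
#'   tip.
#' @param P number of resampled points (>= 2).
#' @param nominal_length_px if given and the path is broken and shorter than
#'   half this length, the shape is excluded (error of class
#'   `"vocbend_excluded"`), since a truncated path would distort the ensemble.
#' @return Numeric vector of length 2P.
#' @export
resample_path <- function(path, P = 100, nominal_length_px = NULL) {
  if (P < 2) stopf("P must be >= 2")
  pts <- if (inherits(path, "filament_path")) path$points else as.matrix(path)
  s <- if (inherits(path, "filament_path")) path$arc_length
  else c(0, cumsum(sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)))
  S <- s[length(s)]
  if (S <= 0) stopf("path has zero arc length")
  if (!is.null(nominal_length_px) && inherits(path, "filament_path") &&
      path$broken && S < 0.5 * nominal_length_px)
    stop(structure(class = c("vocbend_excluded", "error", "condition"),
                   list(message = sprintf(
                     "broken path (%.0f px) shorter than 50%% of nominal length (%.0f px); shape excluded",
                     S, nominal_length_px), call = NULL)))
  ss <- seq(0, S, length.out = P)
  c(approx(s, pts[, 1], xout = ss)$y, approx(s, pts[, 2], xout = ss)$y)
}

#' Principal component analysis of a shape ensemble
#'
#' Pools all shapes (rows) of the ensemble — across all frames and all
#' exposure conditions — and performs mean-centered PCA without per-coordinate
#' standardization (all coordinates share pixel units). The principal
#' components are the directions of highest shape variance; their eigenvalue
#' spectrum measures how many numbers suffice to describe the filament's
#' shape.
#'
#' @param shapes numeric matrix, one 2P shape vector per row (NA rows are
#'   dropped).
#' @return Object of class `"shape_modes"`: `mean_shape` (2P), `components`
#'   (2P x k orthonormal columns, decreasing variance), `explained_variance`
#'   (fractions summing to 1), `P`, `n_shapes`.
#' @export
shape_pca <- function(shapes) {
  shapes <- as.matrix(shapes)
  keep <- rowSums(is.na(shapes)) == 0L
  shapes <- shapes[keep, , drop = FALSE]
  if (nrow(shapes) < 2L) stopf("need at least 2 shapes")
  pc <- prcomp(shapes, center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  if (tot < .Machine$double.eps^0.5)
    stopf("zero-variance ensemble: all shapes are identical")
  structure(list(mean_shape = pc$center,
                 components = pc$rotation,
                 explained_variance = pc$sdev^2 / tot,
                 P = ncol(shapes) %/% 2L,
                 n_shapes = nrow(shapes)),
            class = "shape_modes")
}

#' @export
print.shape_modes <- function(x, ...) {
  cat(sprintf("Shape modes: %d shapes, P = %d points\n", x$n_shapes, x$P))
  k <- min(4L, length(x$explained_variance))
  cv <- cumsum(x$explained_variance)[seq_len(k)]
  cat("  cumulative variance:",
      paste(sprintf("PC1-%d %.1f%%", seq_len(k), 100 * cv), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
plot.shape_modes <- function(x, k = 10, ...) {
  k <- min(k, length(x$explained_variance))
  plot(seq_len(k), cumsum(x$explained_variance)[seq_len(k)], type = "b",
       xlab = "number of principal components",
       ylab = "cumulative variance explained", ylim = c(0, 1), ...)
  invisible(x)
}

#' Cumulative explained variance
#'
#' @param modes a `"shape_modes"` object.
#' @param k number of leading components (1 <= k <= number of components).
#' @return Fraction of total shape variance explained by the first `k`
#'   components.
#' @export
cumulative_variance <- function(modes, k) {
  nk <- length(modes$explained_variance)
  if (k < 1 || k > nk) stopf("k must be in 1..%d", nk)
  sum(modes$explained_variance[seq_len(k)])
}

#' Reconstruct a shape from mode coefficients
#'
#' Returns `mean_shape + sum(coefficients[i] * component[, i])`: the filament
#' shape represented as a linear combination of the leading principal
#' components plus the mean shape.
#'
#' @param modes a `"shape_modes"` object.
#' @param coefficients numeric vector of scores for the first
#'   `length(coefficients)` components.
#' @return Numeric 2P shape vector.
#' @export
reconstruct <- function(modes, coefficients) {
  k <- length(coefficients)
  if (k > ncol(modes$components))
    stopf("more coefficients (%d) than components (%d)", k,
          ncol(modes$components))
  out <- modes$mean_shape
  if (k > 0)
    out <- out + drop(modes$components[, seq_len(k), drop = FALSE] %*%
                        coefficients)
  out
}

#' Project a shape onto the leading components
#'
#' @param modes a `"shape_modes"` object.
#' @param shape a 2P shape vector.
#' @param k number of components (default all).
#' @return Numeric vector of `k` scores.
#' @export
project_shape <- function(modes, shape, k = ncol(modes$components)) {
  drop(crossprod(modes$components[, seq_len(k), drop = FALSE],
                 shape - modes$mean_shape))
}

# split a 2P shape vector back into an x,y matrix
shape_to_points <- function(shape) {
  P <- length(shape) %/% 2L
  cbind(x = shape[seq_len(P)], y = shape[P + seq_len(P)])
}
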