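#' Generator parameters for the synthetic bending model
#'
#' Parameters of the synthetic chemo-mechanical bending model. The film's tip
#' angle relaxes toward a deflected target during exposure and back toward its
#' rest angle during recovery; the response *rate* (not the steady state)
#' increases with the acetone fraction and, less strongly, the ethanol
#' fraction, while a slow hidden state driven by the water fraction shifts the
#' rest angle and produces hysteresis.
#'
#' @param theta_rest0 rest tip angle, degrees (plumb = -90).
#' @param A_deflect maximum deflection amplitude, degrees.
#' @param k0,k_acetone,k_ethanol base and per-unit-fraction response rates,
#'   1/s; `k_acetone > k_ethanol` encodes acetone-dominated response speed.
#' @param mode_ratios three multipliers giving the rates of the three
#'   exponential modes (`mode_ratios * k`).
#' @param mode_weights weights of the three modes; must sum to 1.
#' @param k_recover recovery relaxation rate, 1/s. The default 0.05 makes the
#'   60 s interlude achieve substantial (about 95 percent) recovery, as the
#'   interlude was designed to, while the remaining few percent plus the
#'   hidden slow state carry history between trials.
#' @param tau_h hysteresis time constant of the hidden water-driven state, s.
#' @param gamma_h baseline-drift gain, degrees per unit hidden state.
#' @param sigma_theta per-sample Gaussian angle noise SD, degrees.
#' @param filament_length_px,thickness_px render geometry, pixels.
#' @param frame_rate sampling/rendering rate, Hz.
#' @return A list of class `"generator_params"`.
#' @export
generator_params <- function(theta_rest0 = -90, A_deflect = 60,
                             k0 = 0.005, k_acetone = 0.15, k_ethanol = 0.03,
                             mode_ratios = c(1, 0.2, 0.05),
                             mode_weights = c(0.7, 0.2, 0.1),
                             k_recover = 0.05, tau_h = 600, gamma_h = 15,
                             sigma_theta = 1,
                             filament_length_px = 100, thickness_px = 5,
                             frame_rate = 30) {
  p <- list(theta_rest0 = theta_rest0, A_deflect = A_deflect, k0 = k0,
            k_acetone = k_acetone, k_ethanol = k_ethanol,
            mode_ratios = mode_ratios, mode_weights = mode_weights,
            k_recover = k_recover, tau_h = tau_h, gamma_h = gamma_h,
            sigma_theta = sigma_theta,
            filament_length_px = filament_length_px,
            thickness_px = thickness_px, frame_rate = frame_rate)
  if (!all(vapply(p, function(x) all(is.finite(x)), logical(1))))
    stopf("all generator parameters must be finite")
  if (any(c(k0, k_acetone, k_ethanol, k_recover, tau_h, frame_rate) <= 0))
    stopf("rates, tau_h and frame_rate must be positive")
  if (abs(sum(mode_weights) - 1) > 1e-9)
    stopf("mode_weights must sum to 1")
  if (length(mode_ratios) != 3L || length(mode_weights) != 3L)
    stopf("mode_ratios and mode_weights must have length 3")
  if (k_acetone <= k_ethanol)
    stopf("k_acetone must exceed k_ethanol (acetone-dominated response speed)")
  structure(p, class = "generator_params")
}

#' Simulate the tip-angle time series of one exposure session
#'
#' Integrates the synthetic bending model over every trial of an exposure
#' design. During a trial with composition (f_a, f_e, f_w) the drive rate is
#' `k = k0 + k_acetone*f_a + k_ethanol*f_e`; the deflection (rest angle minus
#' tip angle) relaxes toward an amplitude proportional to the total vapor
#' fraction as a weighted sum of three exponential modes with rates
#' `mode_ratios * k`. During the (unrecorded) recovery interval the deflection
#' decays at `k_recover`; recovery within the 60 s interlude is substantial
#' but not complete, so the next trial starts from a slightly
#' history-dependent angle. A hidden state `h`
#' relaxes toward `f_water` during exposure and toward 0 during recovery with
#' time constant `tau_h`, and shifts the rest angle by `gamma_h * h`
#' (hysteresis / slow baseline drift). Gaussian noise `sigma_theta` is added
#' per recorded sample.
#'
#' Only exposure phases are sampled (the interludes are not recorded); the
#' model state is still propagated through the interludes.
#'
#' @param design an [generate_exposure_design()] object.
#' @param params a [generator_params()] object.
#' @param seed integer seed; the series is deterministic given the seed.
#' @return An object of class `"angle_series"`: list with `times` (s, global
#'   session clock), `theta` (degrees), `trial_boundaries` (first sample index
#'   of each trial), `frame_rate`, `design`, plus the noiseless `theta_true`
#'   and per-sample `trial_index`.
#' @examples
#' d <- generate_exposure_design(1, seed = 2, exposure_s = 60)
#' s <- simulate_session(d, generator_params(frame_rate = 5), seed = 3)
#' range(s$theta)
#' @export
simulate_session <- function(design, params = generator_params(), seed = NULL) {
  stopifnot(inherits(design, "exposure_design"),
            inherits(params, "generator_params"))
  fr <- design_fractions(design)
  dt <- 1 / params$frame_rate

  # per-mode deflection state and hidden hysteresis state
  D <- c(0, 0, 0)
  h <- 0
  theta_rest <- function() params$theta_rest0 + params$gamma_h * h

  times <- numeric(0); theta <- numeric(0); trial_of <- integer(0)
  boundaries <- integer(0)
  clock <- 0

  for (i in seq_len(nrow(design))) {
    f <- fr[i, ]
    k <- params$k0 + params$k_acetone * f$f_acetone +
      params$k_ethanol * f$f_ethanol
    vapor <- f$f_acetone + f$f_ethanol + f$f_water
    A_eff <- params$A_deflect * vapor
    n <- max(2L, round(design$exposure_s[i] * params$frame_rate))

    th_i <- numeric(n)
    boundaries <- c(boundaries, length(theta) + 1L)
    for (j in seq_len(n)) {
      # exact one-step updates of the linear relaxations
      if (j > 1L) {
        D <- params$mode_weights * A_eff +
          (D - params$mode_weights * A_eff) * exp(-params$mode_ratios * k * dt)
        h <- f$f_water + (h - f$f_water) * exp(-dt / params$tau_h)
      }
      th_i[j] <- theta_rest() - sum(D)
    }
    times <- c(times, clock + (seq_len(n) - 1L) * dt)
    theta <- c(theta, th_i)
    trial_of <- c(trial_of, rep(i, n))
    clock <- clock + (n - 1L) * dt

    # unrecorded recovery interlude: single exact jump
    tr <- design$recovery_s[i]
    D <- D * exp(-params$k_recover * tr)
    h <- h * exp(-tr / params$tau_h)
    clock <- clock + tr
  }

  theta_true <- theta
  if (params$sigma_theta > 0 && length(theta) > 0) {
    noise <- with_seed(seed, rnorm(length(theta), 0, params$sigma_theta))
    theta <- theta + noise
  }

  structure(list(times = times, theta = theta, theta_true = theta_true,
                 trial_boundaries = boundaries, trial_index = trial_of,
                 frame_rate = params$frame_rate, design = design,
                 params = params, seed = seed),
            class = "angle_series")
}

#' @export
print.angle_series <- function(x, ...) {
  cat(sprintf("Tip-angle series: %d samples, %d trials, %.3g Hz\n",
              length(x$theta), length(x$trial_boundaries), x$frame_rate))
  if (length(x$theta))
    cat(sprintf("  angle range: [%.1f, %.1f] deg over %.0f s\n",
                min(x$theta), max(x$theta), max(x$times)))
  invisible(x)
}

#' @export
plot.angle_series <- function(x, ...) {
  plot(x$times, x$theta, type = "l", xlab = "time (s)",
       ylab = "tip angle (deg)", ...)
  abline(v = x$times[x$trial_boundaries], col = "grey70", lty = 3)
  invisible(x)
}

#' Split a session series into per-trial segments
#'
#' Returns one segment per design trial with the clock reset to zero at the
#' trial start. Recovery interludes carry no samples (they are unrecorded).
#'
#' @param series an `angle_series`.
#' @param design the matching `exposure_design`; defaults to the design
#'   embedded in the series.
#' @return List of segments; each has `times` (from 0), `theta`,
#'   `trial_index`, `solution_id`.
#' @export
split_trials <- function(series, design = series$design) {
  nb <- length(series$trial_boundaries)
  if (!is.null(design) && nrow(design) != nb)
    stopf("series has %d trials but design has %d", nb, nrow(design))
  ends <- c(series$trial_boundaries[-1L] - 1L, length(series$theta))
  lapply(seq_len(nb), function(i) {
    idx <- series$trial_boundaries[i]:ends[i]
    list(times = series$times[idx] - series$times[idx[1L]],
         theta = series$theta[idx],
         trial_index = i,
         solution_id = if (!is.null(design)) design$solution_id[i] else NA_integer_)
  })
}
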