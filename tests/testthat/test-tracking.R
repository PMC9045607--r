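test_that("binarization matches rendered foreground, is idempotent, rejects blanks", {
  p <- generator_params(sigma_theta = 0, frame_rate = 5)
  fr <- vocbend:::render_filament_frame(-100, p)$frame
  gray <- 1 - 0.9 * fr  # dark filament on light background
  fg <- binarize(gray)
  expect_lt(abs(sum(fg) - sum(fr)) / sum(fr), 0.01)
  expect_identical(binarize(fg), fg)
  expect_error(binarize(matrix(1, 20, 20)), "empty frame")
  expect_error(binarize(matrix(FALSE, 5, 5)), "empty frame")
})

test_that("row scanning finds the midpoint of a symmetric bar", {
  img <- matrix(FALSE, 40, 30)
  img[5:35, 8:12] <- TRUE
  mids <- row_midpoints(img)
  expect_true(all(mids$candidates$x == 10))
  expect_equal(mids$thickness, 5)
})

test_that("two nearby runs are merged rather than split", {
  img <- matrix(FALSE, 40, 30)
  img[5:35, 8:12] <- TRUE
  img[20, 10] <- FALSE       # one-pixel dropout: runs 8-9 and 11-12
  mids <- row_midpoints(img)
  row20 <- mids$candidates[mids$candidates$y == 20, ]
  expect_equal(nrow(row20), 1)
  expect_false(row20$paired)
})

test_that("a straight diagonal filament yields a collinear chord-length path", {
  mid <- cbind(x = 30 + seq(0, 80, by = 0.4) * cos(-60 * pi / 180),
               y = 15 - seq(0, 80, by = 0.4) * sin(-60 * pi / 180))
  img <- render_midline(mid, 5, 120, 120)
  path <- vocbend:::track_frame(img)$path
  pts <- path$points
  chord <- sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2))
  expect_lt(abs(max(path$arc_length) - chord) / chord, 0.02)
  # collinearity: residual of the 2d regression line is sub-pixel
  fit <- lm(pts[, 1] ~ pts[, 2])
  expect_lt(max(abs(residuals(fit))), 1)
})

test_that("large vertical gaps truncate the path and set the broken flag", {
  img <- matrix(FALSE, 100, 30)
  img[5:30, 8:12] <- TRUE
  img[81:95, 8:12] <- TRUE   # gap of 50 rows = 10x thickness
  path <- assemble_path(row_midpoints(img))
  expect_true(path$broken)
  expect_lte(max(path$points[, 2]), 30)
  tiny <- matrix(FALSE, 10, 10); tiny[4:5, 4:6] <- TRUE
  expect_error(assemble_path(row_midpoints(tiny)), "too few usable rows")
})

test_that("tip angle follows the analytic direction of straight paths", {
  down <- cbind(x = rep(5, 50), y = seq(1, 50))
  expect_equal(tip_angle(down), -90)
  up_right <- cbind(x = seq(0, 49), y = seq(50, 1))
  expect_equal(tip_angle(up_right), 45)
  expect_error(tip_angle(cbind(x = rep(1, 10), y = rep(1, 10))),
               "degenerate tip")
})

test_that("tip angle of a gentle arc matches the mean tangent over the tip", {
  # quarter-turn arc sampled densely; true mean tangent over the last 25%
  # equals the tangent at 87.5% of arc length
  mid <- arc_midline(-50, 200, c(250, 20))
  expect_lt(abs(tip_angle(mid) - (-50)), 3)
  mid2 <- arc_midline(-130, 200, c(250, 20))
  expect_lt(abs(tip_angle(mid2) - (-130)), 3)
})

test_that("tracking is translation invariant", {
  p <- generator_params(sigma_theta = 0, frame_rate = 5)
  fr <- vocbend:::render_filament_frame(-115, p)$frame
  a1 <- vocbend:::track_frame(fr)$tip_angle
  shifted <- matrix(FALSE, nrow(fr) + 10, ncol(fr) + 15)
  shifted[10 + seq_len(nrow(fr)), 15 + seq_len(ncol(fr))] <- fr
  a2 <- vocbend:::track_frame(shifted)$tip_angle
  expect_equal(a1, a2, tolerance = 1e-9)
})

test_that("rotating a straight filament rotates the tip angle with it", {
  angle_at <- function(phi) {
    s <- seq(0, 80, by = 0.4)
    mid <- cbind(x = 100 + s * cos(phi * pi / 180),
                 y = 15 - s * sin(phi * pi / 180))
    vocbend:::track_frame(render_midline(mid, 5, 200, 120))$tip_angle
  }
  base <- angle_at(-90)
  for (phi in c(-120, -70, -45)) {
    expect_lt(abs((angle_at(phi) - base) - (phi - (-90))), 1)
  }
})

test_that("track_sequence stamps timestamps and flags bad frames as gaps", {
  p <- generator_params(sigma_theta = 0, frame_rate = 30)
  fs <- render_frames(c(-90, -95, -100), p)
  fs$frames[[2]] <- matrix(FALSE, 5, 5)  # blank frame
  fs$times <- NULL
  tr <- track_sequence(fs, frame_rate = 30)
  expect_equal(tr$times, (0:2) / 30)
  expect_equal(tr$gap, c(FALSE, TRUE, FALSE))
  expect_true(is.na(tr$theta[2]))
  all_blank <- list(matrix(FALSE, 5, 5))
  expect_error(track_sequence(all_blank), "empty series")
})

test_that("angle unwrapping keeps consecutive frames on the nearest branch", {
  th <- c(-170, -179, 178, 170)   # crosses the -180/180 seam
  expect_equal(diff(vocbend:::unwrap_angles(th)),
               c(-9, -3, -8), tolerance = 1e-12)
})

test_that("manual annotations predict automatic angles (cubic model)", {
  p <- generator_params(sigma_theta = 0, frame_rate = 5)
  # one simulated pure-acetone trial: wide angle range for the comparison
  d <- generate_exposure_design(1, list(solution_composition(1)), seed = 3,
                                exposure_s = 120)
  s <- simulate_session(d, p)
  fs <- render_frames(s, p)
  tr <- track_sequence(fs)

  exact <- emulate_manual_annotation(fs, click_sd_px = 0)
  cmp0 <- compare_to_manual(tr, exact)
  expect_gt(cmp0$r_squared, 0.99)

  noisy <- emulate_manual_annotation(fs, click_sd_px = 2, seed = 5)
  cmp2 <- compare_to_manual(tr, noisy)
  expect_gt(cmp2$r_squared, 0.9)

  flat <- exact
  flat$x_px <- rep(exact$x_px[1:7], length.out = nrow(flat))
  flat$y_px <- rep(exact$y_px[1:7], length.out = nrow(flat))
  expect_error(compare_to_manual(tr, flat), "constant")
  expect_error(compare_to_manual(tr, exact[exact$frame_index == 0, ]),
               "4 distinct frames")
})
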