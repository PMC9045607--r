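test_that("a plumb filament renders as a vertically symmetric stroke", {
  p <- generator_params(sigma_theta = 0, frame_rate = 5)
  fr <- vocbend:::render_filament_frame(-90, p)
  mids <- row_midpoints(fr$frame)
  expect_true(all(!mids$candidates$paired))
  expect_equal(var(mids$candidates$x), 0)
})

test_that("rendered arcs round-trip through the tracker", {
  p <- generator_params(sigma_theta = 0, frame_rate = 5)
  for (th in c(-150, -90, -45, -20)) {
    fr <- vocbend:::render_filament_frame(th, p)
    tr <- vocbend:::track_frame(fr$frame)
    expect_lt(abs(tr$tip_angle - th), 2)
    expect_lt(abs(max(tr$path$arc_length) - p$filament_length_px) /
                p$filament_length_px, 0.05)
  }
})

test_that("strong curls produce doubly-crossed pixel rows", {
  p <- generator_params(sigma_theta = 0, frame_rate = 5)
  canvas <- vocbend:::render_canvas(p)
  # total tangent turn from -90 to beyond horizontal: > 90 degrees
  mid <- arc_midline(40, p$filament_length_px, canvas$root)
  fr <- render_midline(mid, p$thickness_px, canvas$width, canvas$height)
  mids <- row_midpoints(fr)
  expect_gt(sum(mids$candidates$paired), 0)
  paired_rows <- mids$candidates$y[mids$candidates$paired]
  expect_true(all(table(paired_rows) == 2))
  tr <- vocbend:::track_frame(fr)
  expect_true(tr$path$curled)
  expect_lt(abs(tr$tip_angle - 40), 4)
})

test_that("geometry exceeding the canvas raises a render error naming the frame", {
  mid <- arc_midline(-90, 500, c(50, 10))
  expect_error(render_midline(mid, 5, 100, 100, frame_index = 17),
               "frame 17.*canvas")
})

test_that("render_frames returns ground truth aligned with the series", {
  p <- generator_params(sigma_theta = 0, frame_rate = 5)
  fs <- render_frames(c(-90, -100, -110), p)
  expect_length(fs$frames, 3)
  expect_length(fs$midlines, 3)
  expect_equal(fs$tip_angles, c(-90, -100, -110))
  # ground-truth midline tip angle equals the requested angle
  expect_equal(tip_angle(fs$midlines[[2]]), -100, tolerance = 0.2)
})

test_that("emulated annotations sit on the midline when click noise is zero", {
  p <- generator_params(sigma_theta = 0, frame_rate = 5)
  fs <- render_frames(rep(-120, 51), p)  # 10 s at 5 Hz -> 3 annotated frames
  ann <- emulate_manual_annotation(fs, interval_s = 5, click_sd_px = 0)
  expect_equal(sort(unique(ann$frame_index)), c(0, 25, 50))
  a0 <- ann[ann$frame_index == 0, ]
  expect_equal(nrow(a0), 7)
  mid <- fs$midlines[[1]]
  for (i in seq_len(nrow(a0))) {
    dmin <- min(sqrt((mid[, 1] - a0$x_px[i])^2 + (mid[, 2] - a0$y_px[i])^2))
    expect_lt(dmin, 0.5)
  }
})

test_that("annotation spacing is uniform in arc length and endpoints-only works", {
  p <- generator_params(sigma_theta = 0, frame_rate = 5)
  fs <- render_frames(-70, p)
  ann <- emulate_manual_annotation(fs, click_sd_px = 0)
  seg <- sqrt(diff(ann$x_px)^2 + diff(ann$y_px)^2)
  expect_lt((max(seg) - min(seg)) / mean(seg), 0.1)
  two <- emulate_manual_annotation(fs, n_points = 2, click_sd_px = 0)
  mid <- fs$midlines[[1]]
  expect_equal(unlist(two[1, c("x_px", "y_px")], use.names = FALSE),
               unname(mid[1, ]), tolerance = 1e-6)
  expect_equal(unlist(two[2, c("x_px", "y_px")], use.names = FALSE),
               unname(mid[nrow(mid), ]), tolerance = 1e-6)
})

test_that("frames round-trip through PNG files", {
  p <- generator_params(sigma_theta = 0, frame_rate = 5)
  fs <- render_frames(c(-80, -95, -110), p)
  dir <- withr::local_tempdir()
  write_frames(fs, dir)
  expect_length(list.files(dir, pattern = "png$"), 3)
  fs2 <- read_frames(dir, frame_rate = 5)
  tr <- track_sequence(fs2)
  expect_equal(tr$theta, c(-80, -95, -110), tolerance = 2)
})
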