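test_that("video generation is deterministic with exact beat counts", {
  spec <- beating_video_spec(frames = 300, fps = 30, frame_size = 32,
                             base_frequency = 60, noise_level = 0)
  v <- generate_beating_video(spec)
  expect_identical(v, generate_beating_video(spec))
  # 60 bpm for 10 s at 30 fps: every pixel trace has exactly 10 maxima
  pk <- detect_peaks(v[5, 7, ], fps = 30)
  expect_equal(length(pk$index), 10)
  expect_equal(diff(pk$times), rep(1, 9), tolerance = 0.05)
  expect_error(beating_video_spec(fps = 1, base_frequency = 120),
               "sampling")
})

test_that("peak detection handles constant and noisy traces", {
  expect_length(detect_peaks(rep(1, 50))$index, 0)
  tt <- seq(0, 10, by = 1 / 30)
  clean <- sin(2 * pi * tt)
  expect_equal(length(detect_peaks(clean, fps = 30)$index), 10)
  # noisy generator traces: peak count within +-1 of the beat count
  for (sd in 1:10) {
    v <- generate_beating_video(beating_video_spec(
      frames = 300, fps = 30, frame_size = 16, base_frequency = 60,
      noise_level = 0.2, seed = sd))
    trace <- apply(v, 3, mean)
    npk <- length(detect_peaks(trace, fps = 30)$index)
    expect_lte(abs(npk - 10), 1)
  }
})

test_that("peak detection agrees with an independent reference detector", {
  skip_if_not_installed("pracma")
  v <- generate_beating_video(beating_video_spec(
    frames = 300, fps = 30, frame_size = 16, base_frequency = 90,
    noise_level = 0.1, seed = 3))
  trace <- apply(v, 3, mean)
  ours <- detect_peaks(trace, min_prominence = 0.2 * diff(range(trace)),
                       min_interval = 0.25, fps = 30)$index
  ref <- pracma::findpeaks(trace, minpeakdistance = 8,
                           minpeakheight = mean(trace))[, 2]
  expect_setequal(ours, sort(ref))
})

test_that("frequency maps recover the generator rate within 5%", {
  for (bpm in c(60, 120)) {
    v <- generate_beating_video(beating_video_spec(
      base_frequency = bpm, noise_level = 0.1, seed = 1))
    fm <- frequency_map(v)
    expect_true(all(fm$valid))
    expect_lt(abs(median(fm$frequency[fm$valid]) - bpm / 60) / (bpm / 60),
              0.05)
  }
  # noise-only stacks produce no valid blocks
  noise <- array(runif(32 * 32 * 240), c(32, 32, 240))
  attr(noise, "fps") <- 30
  expect_warning(fmn <- frequency_map(noise), "no valid blocks")
  expect_false(any(fmn$valid))
})

test_that("doubling the frame rate leaves the recovered frequency stable", {
  f1 <- frequency_map(generate_beating_video(beating_video_spec(
    frames = 300, fps = 30, base_frequency = 90, noise_level = 0.1,
    seed = 4)))
  f2 <- frequency_map(generate_beating_video(beating_video_spec(
    frames = 600, fps = 60, base_frequency = 90, noise_level = 0.1,
    seed = 4)))
  m1 <- median(f1$frequency[f1$valid]); m2 <- median(f2$frequency[f2$valid])
  expect_lt(abs(m1 - m2) / m1, 0.02)
})

test_that("phase maps are synchronised, referenced, and recover gradients", {
  # no phase gradient: all block phases within 5 degrees of zero
  v0 <- generate_beating_video(beating_video_spec(
    base_frequency = 60, phase_gradient = 0, noise_level = 0.05, seed = 2))
  p0 <- phase_map(v0)
  expect_lt(max(abs(p0$phase[p0$valid])), 5)
  # reference block has phase 0 by definition
  pb <- phase_map(v0, reference = "block", ref_block = c(2, 2))
  expect_lt(abs(pb$phase[2, 2]), 1e-9)
  # linear gradient: recovered slope within 10% of the specification
  v1 <- generate_beating_video(beating_video_spec(
    base_frequency = 60, phase_gradient = 1.5, noise_level = 0.1,
    seed = 6))
  p1 <- phase_map(v1)
  ok <- !is.na(p1$phase)
  xs <- rep(p1$block_x, times = ncol(p1$phase))
  slope <- stats::coef(stats::lm(as.vector(p1$phase)[ok] ~ xs[ok]))[2]
  expect_lt(abs(slope - 1.5) / 1.5, 0.1)
})

test_that("phase maps are invariant (mod 360) to a global temporal shift", {
  base <- beating_video_spec(base_frequency = 75, phase_gradient = 1,
                             noise_level = 0.05, seed = 8)
  shifted <- beating_video_spec(base_frequency = 75, phase_gradient = 1,
                                noise_level = 0.05, phase_offset = 133,
                                seed = 8)
  p1 <- phase_map(generate_beating_video(base))
  p2 <- phase_map(generate_beating_video(shifted))
  ok <- p1$valid & p2$valid
  d <- (p1$phase[ok] - p2$phase[ok] + 180) %% 360 - 180
  expect_lt(max(abs(d)), 5)
})

test_that("video TIFF round-trip preserves the stack", {
  v <- generate_beating_video(beating_video_spec(
    frames = 20, fps = 30, frame_size = 16, base_frequency = 120,
    noise_level = 0, seed = 1))
  tf <- tempfile(fileext = ".tif")
  write_video_tiff(v, tf)
  back <- read_video_tiff(tf, fps = 30)
  expect_equal(dim(back), dim(v))
  expect_lt(max(abs(back - unclass(v))), 1 / 65535 + 1e-6)
  expect_equal(attr(back, "fps"), 30)
  unlink(tf)
})
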