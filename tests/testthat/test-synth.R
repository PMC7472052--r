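test_that("rendering is deterministic given the seed", {
  cfg <- proto_cfg()
  sc <- small_scene(seed = 21)
  f1 <- render_frame(cfg, sc, 45)
  f2 <- render_frame(cfg, sc, 45)
  expect_identical(f1, f2)
  f3 <- render_frame(cfg, sc, 45, seed = 22)
  expect_false(identical(f1, f3))
  wf <- make_waveform("sine", duration_s = 0.5, frame_rate = 30)
  s1 <- render_sequence(cfg, sc, wf)
  s2 <- render_sequence(cfg, sc, wf)
  expect_identical(s1$frames, s2$frames)
  expect_identical(s1$truth, s2$truth)
})

test_that("the in-focus stripe sits at the depth-dependent column", {
  cfg <- proto_cfg()
  sc <- small_scene(noise_sigma = 0, baseline = baseline_poly(0))
  f <- render_frame(cfg, sc, 45)
  expect_equal(attr(f, "true_column"), 640)
  # column of maximum local variance of the profile (32 px window) is at
  # the true column
  p <- colMeans(f)
  win <- stats::filter(p^2, rep(1 / 32, 32), sides = 2)
  expect_lt(abs(which.max(win) - 1 - 640), 2 + sc$texture_period / 2)
  # near-full texture contrast at the stripe centre (pixel-centre sampling
  # keeps the maximum just below the nominal contrast)
  expect_gt(max(f), 0.9 * sc$texture_contrast)
  expect_lte(max(f), sc$texture_contrast)
})

test_that("frame spectral energy concentrates in the 20-300 px annulus", {
  cfg <- proto_cfg()
  sc <- scene_config(rows = 256, noise_sigma = 0, seed = 1)
  f <- render_frame(cfg, sc, 45)
  S <- Mod(stats::fft(f))^2
  n_r <- nrow(f); n_c <- ncol(f)
  fr <- pmin(0:(n_r - 1), n_r - 0:(n_r - 1))
  fc <- pmin(0:(n_c - 1), n_c - 0:(n_c - 1))
  R <- sqrt(outer(fr^2, fc^2, `+`))
  non_dc <- sum(S) - S[1, 1]
  expect_gt(sum(S[R >= 20 & R <= 300]) / non_dc, 0.8)
  # dominant non-DC energy at the grating radius n_c / texture_period = 160
  S[1, 1] <- 0
  peak_r <- R[which.max(S)]
  expect_equal(peak_r, n_c / sc$texture_period, tolerance = 0.02)
})

test_that("off-sensor positions yield a stripe-free frame with a warning", {
  cfg <- proto_cfg()
  sc <- small_scene(noise_sigma = 0, baseline = baseline_poly(0))
  expect_warning(f <- render_frame(cfg, sc, 41.0), "off sensor")
  expect_true(attr(f, "off_sensor"))
  # the texture is strongly attenuated everywhere on the sensor
  expect_lt(max(abs(f)), 0.05 * sc$texture_contrast)
})

test_that("waveform construction: sampling, Nyquist guard, component mix", {
  wf <- make_waveform("sine", duration_s = 2, frame_rate = 30, freq_hz = 1)
  expect_length(wf$times, 60)
  expect_equal(wf$x1_mm[1], wf$x1_mm[31], tolerance = 1e-9)  # period 30 samples
  expect_warning(make_waveform("sine", freq_hz = 20, frame_rate = 30),
                 "Nyquist")
  const <- make_waveform("constant", duration_s = 1, center_mm = 45)
  expect_true(all(const$x1_mm == 45))
  # respiratory + cardiac: peak-to-peak dominated by the slow large tone
  rc <- make_waveform("resp_plus_cardiac", duration_s = 10, amp_mm = 0.685,
                      freq_hz = 1, card_freq_hz = 7, amp_ratio = 100)
  pp <- diff(range(rc$x1_mm))
  expect_lt(abs(pp - 2 * 0.685) / (2 * 0.685), 0.02)
})

test_that("rendered sequences carry consistent ground truth", {
  cfg <- proto_cfg()
  sc <- small_scene(seed = 9)
  const <- make_waveform("constant", duration_s = 0.2, frame_rate = 30,
                         center_mm = 45)
  s <- render_sequence(cfg, sc, const)
  expect_true(all(s$truth$column_px == 640))
  expect_false(any(s$truth$off_sensor))
  # a sine spanning 290 columns peak-to-peak
  amp_mm <- 290 / 2 / abs(sensitivity(cfg, 45))
  wf <- make_waveform("sine", duration_s = 10, frame_rate = 30,
                      amp_mm = amp_mm, freq_hz = 1, phase = pi / 2)
  s2 <- render_sequence(cfg, sc, wf)
  expect_equal(nrow(s2$truth), 300)
  expect_equal(diff(range(s2$truth$column_px)), 290, tolerance = 0.01)
  # a waveform leaving the visible range flags off-sensor frames
  big <- make_waveform("sine", duration_s = 1, frame_rate = 30, amp_mm = 4)
  expect_warning(s3 <- render_sequence(cfg, sc, big), "off the sensor")
  expect_true(any(s3$truth$off_sensor))
})
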