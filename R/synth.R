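#' Baseline (illumination drift) models for the synthetic renderer
#'
#' The smooth baseline field is specified either as a low-order 2-D
#' polynomial in normalized coordinates `u = column fraction`,
#' `v = row fraction` (both in `[0, 1]`), or as a broad Gaussian blob.
#' Coefficients are in grey levels.
#'
#' @param offset Constant term, grey levels.
#' @param gx,gy Linear terms in `u` (columns) and `v` (rows).
#' @param gxx,gyy,gxy Quadratic terms.
#' @return A baseline model list consumed by [scene_config()].
#' @export
baseline_poly <- function(offset = 0, gx = 0, gy = 0,
                          gxx = 0, gyy = 0, gxy = 0) {
  list(kind = "poly", offset = offset, gx = gx, gy = gy,
       gxx = gxx, gyy = gyy, gxy = gxy)
}

#' @rdname baseline_poly
#' @param amp Peak amplitude of the Gaussian blob, grey levels.
#' @param center Blob centre `c(u, v)` in normalized coordinates.
#' @param sigma Blob width in normalized units.
#' @export
baseline_gaussian <- function(offset = 0, amp = 0, center = c(0.5, 0.5),
                              sigma = 0.5) {
  list(kind = "gaussian", offset = offset, amp = amp,
       center = center, sigma = sigma)
}

.baseline_field <- function(model, rows, cols) {
  u <- ((seq_len(cols) - 1) + 0.5) / cols
  v <- ((seq_len(rows) - 1) + 0.5) / rows
  if (is.null(model)) return(matrix(0, rows, cols))
  if (identical(model$kind, "poly")) {
    U <- matrix(u, rows, cols, byrow = TRUE)
    V <- matrix(v, rows, cols)
    model$offset + model$gx * U + model$gy * V +
      model$gxx * U^2 + model$gyy * V^2 + model$gxy * U * V
  } else if (identical(model$kind, "gaussian")) {
    U <- matrix(u, rows, cols, byrow = TRUE)
    V <- matrix(v, rows, cols)
    model$offset + model$amp *
      exp(-((U - model$center[1])^2 + (V - model$center[2])^2) /
            (2 * model$sigma^2))
  } else stop("unknown baseline model kind: ", model$kind, call. = FALSE)
}

#' Scene description for the synthetic frame renderer
#'
#' Controls the three components of a rendered frame: a periodic specimen
#' texture that is sharp inside the in-focus stripe and progressively
#' defocused away from it, a smooth illumination baseline, and additive
#' sensor noise.
#'
#' Defaults are chosen to emulate the prototype's functional-test images: a
#' texture period of 8 px puts the grating's spectral radius at
#' `1280 / 8 = 160` px, mid-way through the 20-300 px annulus where the
#' stripe energy of real captures concentrates; texture contrast of 80 grey
#' levels over a gentle baseline (offset 100, 10 grey-level ramp) mirrors
#' the strong fluctuation contrast between stripe and non-stripe regions;
#' Gaussian read noise of 2 grey levels is typical of an 8-bit CMOS sensor.
#'
#' @param texture_period Pixels per cycle of the specimen texture (>= 2).
#' @param texture_contrast Texture amplitude, grey levels (> 0).
#' @param blur_scale Defocus growth rate: blur sigma in pixels per pixel of
#'   column distance beyond the stripe core (>= 0).
#' @param stripe_core_px Half-width of a fully in-focus plateau, pixels.
#'   The default 0 makes the defocus envelope strictly peaked at the stripe
#'   centre, which keeps the per-row amplitude maximum unique; a positive
#'   plateau makes all texture peaks inside it equally sharp, so per-row
#'   peaks then scatter uniformly across the plateau.
#' @param baseline Baseline model from [baseline_poly()] or
#'   [baseline_gaussian()].
#' @param noise_sigma Additive Gaussian noise standard deviation, grey
#'   levels (>= 0).
#' @param noise_model `"gaussian"` (default) or `"poisson"` (shot noise on
#'   the clean frame; `noise_sigma` is then ignored).
#' @param rows Number of sensor rows per frame (columns come from the
#'   optical configuration).
#' @param seed Integer RNG seed making rendering reproducible.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(texture_period = 8, texture_contrast = 80,
                         blur_scale = 0.05, stripe_core_px = 0,
                         baseline = baseline_poly(offset = 100, gx = 10),
                         noise_sigma = 2,
                         noise_model = c("gaussian", "poisson"),
                         rows = 720L, seed = 7L) {
  stopifnot(is.numeric(texture_period), texture_period >= 2,
            is.numeric(texture_contrast), texture_contrast > 0,
            is.numeric(blur_scale), blur_scale >= 0,
            is.numeric(stripe_core_px), stripe_core_px >= 0,
            is.numeric(noise_sigma), noise_sigma >= 0)
  rows <- as.integer(rows)
  stopifnot(rows >= 1L)
  structure(list(texture_period = texture_period,
                 texture_contrast = texture_contrast,
                 blur_scale = blur_scale,
                 stripe_core_px = stripe_core_px,
                 baseline = baseline,
                 noise_sigma = noise_sigma,
                 noise_model = match.arg(noise_model),
                 rows = rows,
                 seed = as.integer(seed)),
            class = "scene_config")
}

# Evaluate expr with a temporary RNG seed, restoring global RNG state.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Render one synthetic tilted-sensor frame
#'
#' Produces a `rows x n_columns` matrix of grey values containing a cosine
#' grating of period `texture_period` centred (phase peak) on the stripe
#' column for specimen position `x1_mm`. Away from the stripe the grating
#' amplitude is attenuated by the modulation-transfer factor of a Gaussian
#' defocus blur whose sigma grows linearly with column distance beyond the
#' stripe core: `exp(-2 * pi^2 * sigma^2 / period^2)`. The baseline field
#' and seeded noise are then added. Values are unbounded floats; clipping
#' to `[0, 255]` happens only when writing 8-bit files.
#'
#' @param cfg An [optical_config()].
#' @param scene A [scene_config()].
#' @param x1_mm Specimen distance to lens I, mm.
#' @param seed RNG seed for the noise; defaults to `scene$seed`.
#' @return Numeric matrix with attributes `true_column` and `off_sensor`.
#' @export
render_frame <- function(cfg, scene, x1_mm, seed = scene$seed) {
  .assert_cfg(cfg)
  if (!inherits(scene, "scene_config"))
    stop("'scene' must be a 'scene_config'", call. = FALSE)
  cc <- stripe_column(cfg, x1_mm)
  off <- cc < 0 || cc > cfg$nc
  if (off)
    warning(sprintf("stripe off sensor at x1 = %g mm (column %.1f)",
                    x1_mm, cc))
  xcol <- (seq_len(cfg$nc) - 1) + 0.5
  dist <- pmax(0, abs(xcol - cc) - scene$stripe_core_px)
  sig <- scene$blur_scale * dist
  atten <- exp(-2 * pi^2 * sig^2 / scene$texture_period^2)
  profile <- scene$texture_contrast * atten *
    cos(2 * pi * (xcol - cc) / scene$texture_period)
  frame <- matrix(profile, scene$rows, cfg$nc, byrow = TRUE) +
    .baseline_field(scene$baseline, scene$rows, cfg$nc)
  frame <- .with_seed(seed, {
    if (scene$noise_model == "poisson") {
      matrix(stats::rpois(length(frame), pmax(frame, 0)),
             nrow(frame), ncol(frame))
    } else if (scene$noise_sigma > 0) {
      frame + matrix(stats::rnorm(length(frame), 0, scene$noise_sigma),
                     nrow(frame), ncol(frame))
    } else frame
  })
  attr(frame, "true_column") <- cc
  attr(frame, "off_sensor") <- off
  frame
}

#' Motion waveforms for synthetic sequences
#'
#' Samples a specimen-position waveform `x1(t)` at the sensor frame rate.
#' `"constant"` holds `center_mm`; `"sine"` is a single tone of amplitude
#' `amp_mm` (half peak-to-peak) about `center_mm`; `"resp_plus_cardiac"`
#' adds a small high-frequency tone to a large low-frequency one, emulating
#' respiratory motion (about 1-2 Hz in rodents) with a superimposed cardiac
#' component roughly 100 times smaller, as reported for abdominal organs.
#'
#' Default amplitude 0.685 mm gives a 1.37 mm peak-to-peak excursion,
#' matching the scale of rat liver motion; at the prototype sensitivity this
#' spans about 290 pixel columns.
#'
#' @param kind Waveform type.
#' @param duration_s Duration, seconds.
#' @param frame_rate Sampling rate, Hz (sensor frame rate; prototype 30).
#' @param center_mm Mean specimen position, mm.
#' @param amp_mm Amplitude (half peak-to-peak) of the main tone, mm.
#' @param freq_hz Frequency of the main tone, Hz.
#' @param card_freq_hz Cardiac tone frequency, Hz (resp_plus_cardiac only).
#' @param amp_ratio Respiratory-to-cardiac amplitude ratio (default 100).
#' @param phase Phase offset of the main tone, radians.
#' @return Object of class `motion_waveform`: list with `times`, `x1_mm`,
#'   `frame_rate`.
#' @export
make_waveform <- function(kind = c("constant", "sine", "resp_plus_cardiac"),
                          duration_s = 10, frame_rate = 30, center_mm = 45,
                          amp_mm = 0.685, freq_hz = 1, card_freq_hz = 7,
                          amp_ratio = 100, phase = 0) {
  kind <- match.arg(kind)
  stopifnot(duration_s > 0, frame_rate > 0)
  n <- max(1L, as.integer(round(duration_s * frame_rate)))
  times <- (seq_len(n) - 1) / frame_rate
  check_nyquist <- function(f, label) {
    if (f >= frame_rate / 2)
      warning(sprintf("%s frequency %g Hz is at or above the Nyquist limit %g Hz: the sampled waveform will alias",
                      label, f, frame_rate / 2))
  }
  x1 <- switch(kind,
    constant = rep(center_mm, n),
    sine = {
      check_nyquist(freq_hz, "sine")
      center_mm + amp_mm * sin(2 * pi * freq_hz * times + phase)
    },
    resp_plus_cardiac = {
      check_nyquist(freq_hz, "respiratory")
      check_nyquist(card_freq_hz, "cardiac")
      center_mm + amp_mm * sin(2 * pi * freq_hz * times + phase) +
        (amp_mm / amp_ratio) * sin(2 * pi * card_freq_hz * times)
    })
  structure(list(times = times, x1_mm = x1, frame_rate = frame_rate),
            class = "motion_waveform")
}

#' Render a synthetic frame sequence with ground truth
#'
#' Renders one frame per waveform sample. Each frame gets its own noise
#' seed (`base_seed + frame index`) so stacks are reproducible yet frames
#' are independent. Optionally writes the stack as an 8-bit multi-page TIFF
#' and the ground truth as CSV.
#'
#' @inheritParams render_frame
#' @param waveform A [make_waveform()] result.
#' @param out_tiff Optional path for an 8-bit multi-page TIFF of the stack.
#' @param truth_csv Optional path for the ground-truth CSV.
#' @param base_seed Base RNG seed; defaults to `scene$seed`.
#' @return List with `frames` (list of matrices) and `truth` (data frame
#'   with `frame_index`, `time_s`, `x1_mm`, `column_px`, `off_sensor`;
#'   frame indices are 0-based).
#' @export
render_sequence <- function(cfg, scene, waveform, out_tiff = NULL,
                            truth_csv = NULL, base_seed = scene$seed) {
  if (!inherits(waveform, "motion_waveform"))
    stop("'waveform' must be a 'motion_waveform'", call. = FALSE)
  n <- length(waveform$times)
  frames <- vector("list", n)
  cols <- numeric(n)
  off <- logical(n)
  for (i in seq_len(n)) {
    f <- withCallingHandlers(
      render_frame(cfg, scene, waveform$x1_mm[i], seed = base_seed + i - 1L),
      warning = function(w) {
        if (grepl("off sensor", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    cols[i] <- attr(f, "true_column")
    off[i] <- attr(f, "off_sensor")
    attributes(f) <- attributes(f)["dim"]
    frames[[i]] <- f
  }
  if (any(off))
    warning(sum(off), " of ", n, " frames have the stripe off the sensor")
  truth <- data.frame(frame_index = seq_len(n) - 1L,
                      time_s = waveform$times,
                      x1_mm = waveform$x1_mm,
                      column_px = cols,
                      off_sensor = off)
  if (!is.null(out_tiff)) write_stack(frames, out_tiff)
  if (!is.null(truth_csv)) write_table_csv(truth, truth_csv)
  list(frames = frames, truth = truth)
}
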