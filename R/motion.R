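#' Extract the analysis signal from a motion trace
#'
#' Traces carry the stripe column in pixels and, after calibration, a
#' displacement in mm. Analyses default to the displacement column when
#' present.
#' @noRd
.trace_signal <- function(trace, units = c("auto", "px", "mm")) {
  units <- match.arg(units)
  has_mm <- "displacement_mm" %in% names(trace)
  if (units == "mm" && !has_mm)
    stop("trace has no 'displacement_mm' column; run convert_trace() first",
         call. = FALSE)
  use_mm <- (units == "mm") || (units == "auto" && has_mm)
  list(values = if (use_mm) trace$displacement_mm else trace$column_px,
       units = if (use_mm) "mm" else "px")
}

#' Add world-coordinate displacements to a trace
#'
#' Applies [column_to_displacement()] to every tracked column, adding a
#' `displacement_mm` column.
#'
#' @param trace A motion trace from [track_stack()] (or any data frame with
#'   a `column_px` column).
#' @param fit A [fit_calibration()] result.
#' @return The trace with a `displacement_mm` column added.
#' @export
convert_trace <- function(trace, fit) {
  stopifnot("column_px" %in% names(trace))
  trace$displacement_mm <- column_to_displacement(fit, trace$column_px)
  trace
}

#' Peak-to-peak amplitude of a motion trace
#'
#' Span between the upper and lower `robust_quantile` quantiles of the
#' signal (default 0.01, trimming outliers); `robust_quantile = 0` gives
#' the strict max minus min. "Amplitude" here means the full peak-to-peak
#' excursion.
#'
#' @param trace A motion trace data frame.
#' @param robust_quantile Fraction trimmed at each end, in `[0, 0.5)`.
#' @param units `"auto"` (displacement if present, else pixels), `"px"`, or
#'   `"mm"`.
#' @return Peak-to-peak amplitude in the chosen units.
#' @export
trace_amplitude <- function(trace, robust_quantile = 0.01,
                            units = c("auto", "px", "mm")) {
  stopifnot(robust_quantile >= 0, robust_quantile < 0.5)
  sig <- .trace_signal(trace, units)
  x <- sig$values[!is.na(sig$values)]
  if (length(x) < 2L)
    stop("need at least 2 valid samples to compute an amplitude", call. = FALSE)
  q <- stats::quantile(x, c(robust_quantile, 1 - robust_quantile),
                       names = FALSE, type = 7)
  q[2] - q[1]
}

#' Dominant frequency of a motion trace
#'
#' Frequency of the largest non-DC periodogram peak. The trace is assumed
#' uniformly sampled at its frame rate; missing entries are linearly
#' interpolated first (with a message). The mean is subtracted before the
#' FFT; an optional Hann window is available for long traces.
#'
#' @param trace A motion trace data frame (with a `frame_rate` attribute or
#'   uniformly spaced `time_s`).
#' @param window `"none"` (default, suited to short physiological traces)
#'   or `"hann"`.
#' @param units Signal choice as in [trace_amplitude()].
#' @return List with `frequency_hz`, `resolution_hz` (one periodogram bin,
#'   `frame_rate / n`), and `n` (samples used).
#' @export
dominant_frequency <- function(trace, window = c("none", "hann"),
                               units = c("auto", "px", "mm")) {
  window <- match.arg(window)
  sig <- .trace_signal(trace, units)
  x <- sig$values
  n <- length(x)
  if (n < 8L) stop("trace too short for frequency analysis (need >= 8 samples)",
                   call. = FALSE)
  fs <- attr(trace, "frame_rate")
  if (is.null(fs)) {
    dt_mean <- (trace$time_s[n] - trace$time_s[1]) / (n - 1)
    dt <- diff(trace$time_s)
    if (dt_mean <= 0 || any(abs(dt - dt_mean) > 0.2 * dt_mean))
      stop("trace is not uniformly sampled and has no frame_rate attribute",
           call. = FALSE)
    fs <- 1 / dt_mean
  }
  if (anyNA(x)) {
    message("interpolating ", sum(is.na(x)), " missing samples before the periodogram")
    ok <- !is.na(x)
    if (sum(ok) < 8L) stop("too few valid samples", call. = FALSE)
    x <- stats::approx(which(ok), x[ok], xout = seq_len(n), rule = 2)$y
  }
  x <- x - mean(x)
  if (window == "hann")
    x <- x * (0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  spec <- Mod(stats::fft(x))^2
  k <- 2:(floor(n / 2) + 1)          # positive non-DC frequencies
  p <- spec[k]
  if (max(p) <= n * .Machine$double.eps * max(sum(p), 1) || sum(p) == 0)
    stop("no non-DC periodogram peak (constant trace?)", call. = FALSE)
  i <- which.max(p)
  list(frequency_hz = (i) * fs / n, resolution_hz = fs / n, n = n)
}

#' Summary report for a tracked motion trace
#'
#' Collects the trace-level quantities into a plain list suitable for JSON
#' export: sample counts, valid fraction, duration, peak-to-peak amplitude
#' in pixels (and mm when a calibration fit is supplied), and the dominant
#' frequency with its resolution. Degenerate traces (no valid samples)
#' yield a report with `valid_fraction = 0` and `NA` analysis fields rather
#' than an error.
#'
#' @param trace A motion trace data frame.
#' @param fit Optional [fit_calibration()] for pixel-to-mm conversion.
#' @param robust_quantile Passed to [trace_amplitude()].
#' @return A named list (the report).
#' @export
summarize_motion <- function(trace, fit = NULL, robust_quantile = 0.01) {
  n <- nrow(trace)
  valid <- if ("valid" %in% names(trace)) trace$valid else !is.na(trace$column_px)
  vf <- if (n > 0) mean(valid) else 0
  duration <- if (n > 1) trace$time_s[n] - trace$time_s[1] else 0
  rep0 <- list(n_frames = n, valid_fraction = vf, duration_s = duration,
               amplitude_px = NA_real_, amplitude_mm = NA_real_,
               dominant_freq_hz = NA_real_, freq_resolution_hz = NA_real_)
  if (sum(valid & !is.na(trace$column_px)) < 2L) return(rep0)
  rep0$amplitude_px <- trace_amplitude(trace, robust_quantile, units = "px")
  if (!is.null(fit))
    rep0$amplitude_mm <- abs(rep0$amplitude_px / fit$a)
  ff <- tryCatch(dominant_frequency(trace, units = "px"),
                 error = function(e) NULL)
  if (!is.null(ff)) {
    rep0$dominant_freq_hz <- ff$frequency_hz
    rep0$freq_resolution_hz <- ff$resolution_hz
  }
  rep0
}
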