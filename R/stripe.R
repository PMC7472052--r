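#' Row-quality thresholds for stripe estimation
#'
#' After bandpass filtering, each row contributes one peak to the stripe
#' position estimate. Rows whose peak amplitude falls below `amp_threshold`
#' (grey levels) are discarded — on frames that actually contain a stripe
#' the per-row peak amplitude is close to the texture contrast, far above
#' the filtered noise floor, so the default gate of 10 grey levels is inert
#' on clean frames while rejecting blank (noise-only) frames. An estimate
#' is flagged invalid when fewer than `min_rows` rows survive.
#'
#' @param amp_threshold Minimum per-row peak amplitude, grey levels.
#' @param min_rows Minimum number of surviving rows for a valid estimate.
#' @param baseline_stat Per-row baseline statistic subtracted before peak
#'   detection: `"mean"` (default) or `"median"`.
#' @return Object of class `quality_spec`.
#' @export
quality_spec <- function(amp_threshold = 10, min_rows = 50,
                         baseline_stat = c("mean", "median")) {
  stopifnot(is.numeric(amp_threshold), amp_threshold >= 0,
            is.numeric(min_rows), min_rows >= 1)
  structure(list(amp_threshold = amp_threshold,
                 min_rows = as.integer(min_rows),
                 baseline_stat = match.arg(baseline_stat)),
            class = "quality_spec")
}

#' Per-row baseline of a filtered row
#'
#' The statistic subtracted from each row before peak detection. Filtered
#' rows are already near zero-mean, so the arithmetic mean (default) is a
#' light-touch recentring; the median is available for heavy-tailed rows.
#'
#' @param row Numeric vector of grey values (nonempty).
#' @param stat `"mean"` or `"median"`.
#' @return The baseline grey value.
#' @export
row_baseline <- function(row, stat = c("mean", "median")) {
  if (length(row) == 0L) stop("empty row", call. = FALSE)
  stat <- match.arg(stat)
  if (stat == "mean") mean(row) else stats::median(row)
}

#' Peak of a baseline-subtracted row
#'
#' Locates the column of maximum absolute value. The bandpassed stripe
#' oscillates symmetrically about zero, so the magnitude — not the signed
#' value — carries the stripe position; ties are broken to the lowest
#' column index. Columns are 0-based (column 0 is the leftmost pixel).
#'
#' @param row Numeric vector, already baseline-subtracted.
#' @return List with `column` (0-based integer) and `amplitude` (>= 0).
#' @export
peak_per_row <- function(row) {
  if (length(row) == 0L) stop("empty row", call. = FALSE)
  a <- abs(row)
  i <- which.max(a)  # first maximum = lowest column on ties
  list(column = i - 1L, amplitude = a[i])
}

#' Estimate the stripe position in one frame
#'
#' The peak-value detection pipeline: bandpass filter the frame, subtract
#' each row's baseline, find the per-row peak column, drop rows whose peak
#' amplitude is below the quality gate, and average the surviving peak
#' columns. The average of integer per-row peaks yields a fractional-pixel
#' stripe position; its dispersion across rows is reported as a diagnostic.
#'
#' @param frame Numeric matrix of grey values.
#' @param mask A [build_mask()] result matching the frame shape.
#' @param quality A [quality_spec()].
#' @return Object of class `stripe_estimate`: list with `column_mean`,
#'   `column_sd`, `n_rows_used`, `valid`. When too few rows survive the
#'   gate, `valid` is `FALSE` and the estimates are `NA` (no error is
#'   raised).
#' @export
estimate_stripe <- function(frame, mask, quality = quality_spec()) {
  if (!inherits(quality, "quality_spec"))
    stop("'quality' must be a 'quality_spec'", call. = FALSE)
  filtered <- apply_bandpass(frame, mask)
  bl <- if (quality$baseline_stat == "mean") rowMeans(filtered)
        else apply(filtered, 1, stats::median)
  filtered <- filtered - bl
  a <- abs(filtered)
  peak_col <- max.col(a, ties.method = "first") - 1L   # 0-based
  peak_amp <- a[cbind(seq_len(nrow(a)), peak_col + 1L)]
  keep <- peak_amp >= quality$amp_threshold
  n_used <- sum(keep)
  if (n_used < quality$min_rows) {
    return(structure(list(column_mean = NA_real_, column_sd = NA_real_,
                          n_rows_used = n_used, valid = FALSE),
                     class = "stripe_estimate"))
  }
  cols <- peak_col[keep]
  structure(list(column_mean = mean(cols),
                 column_sd = if (n_used > 1L) stats::sd(cols) else 0,
                 n_rows_used = n_used, valid = TRUE),
            class = "stripe_estimate")
}

#' @export
print.stripe_estimate <- function(x, ...) {
  if (x$valid)
    cat(sprintf("stripe at column %.2f (sd %.2f px, %d rows)\n",
                x$column_mean, x$column_sd, x$n_rows_used))
  else
    cat(sprintf("no valid stripe (%d rows above threshold)\n", x$n_rows_used))
  invisible(x)
}

#' Track the stripe through a frame stack
#'
#' Runs [estimate_stripe()] on every frame and assembles a motion trace.
#' Frames with no valid stripe are recorded with `NA` columns, never
#' interpolated here (interpolation, when needed, happens in the frequency
#' analysis and is flagged there).
#'
#' @param frames List of numeric matrices with identical dimensions.
#' @param mask A [build_mask()] for that shape.
#' @param quality A [quality_spec()].
#' @param frame_rate Frames per second used to derive time stamps.
#' @return A data frame (motion trace) with columns `frame_index` (0-based),
#'   `time_s`, `column_px`, `column_sd_px`, `n_rows_used`, `valid`, plus a
#'   `frame_rate` attribute.
#' @export
track_stack <- function(frames, mask, quality = quality_spec(),
                        frame_rate = 30) {
  if (!is.list(frames) || length(frames) == 0L)
    stop("'frames' must be a nonempty list of matrices", call. = FALSE)
  d1 <- dim(frames[[1]])
  n <- length(frames)
  out <- data.frame(frame_index = seq_len(n) - 1L,
                    time_s = (seq_len(n) - 1) / frame_rate,
                    column_px = NA_real_, column_sd_px = NA_real_,
                    n_rows_used = NA_integer_, valid = FALSE)
  for (i in seq_len(n)) {
    f <- frames[[i]]
    if (!is.matrix(f) || !identical(dim(f), d1))
      stop("frame ", i - 1L, " is unreadable or has a different shape",
           call. = FALSE)
    est <- estimate_stripe(f, mask, quality)
    out$column_px[i] <- est$column_mean
    out$column_sd_px[i] <- est$column_sd
    out$n_rows_used[i] <- est$n_rows_used
    out$valid[i] <- est$valid
  }
  attr(out, "frame_rate") <- frame_rate
  out
}
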