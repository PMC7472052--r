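#' Calibration table: stage displacement vs measured stripe column
#'
#' @param displacement_mm Stage displacements, mm; strictly monotone,
#'   length >= 3 for a fit with uncertainties (2 points give an exact
#'   interpolating line with zero reported standard errors).
#' @param column_px Measured stripe columns, fractional pixels.
#' @param column_sd_px Optional per-point replicate standard deviations.
#' @return A data frame of class `calibration_table`.
#' @export
calibration_table <- function(displacement_mm, column_px, column_sd_px = NULL) {
  stopifnot(is.numeric(displacement_mm), is.numeric(column_px),
            length(displacement_mm) == length(column_px),
            length(displacement_mm) >= 2L)
  dd <- diff(displacement_mm)
  if (!(all(dd > 0) || all(dd < 0)))
    stop("'displacement_mm' must be strictly monotone", call. = FALSE)
  out <- data.frame(displacement_mm = displacement_mm, column_px = column_px)
  if (!is.null(column_sd_px)) {
    stopifnot(length(column_sd_px) == length(column_px))
    out$column_sd_px <- column_sd_px
  }
  class(out) <- c("calibration_table", "data.frame")
  out
}

#' Fit the linear column-displacement calibration
#'
#' Ordinary least squares of stripe column on stage displacement,
#' `column = a * displacement + b`. Reports the slope and intercept with
#' one standard error each, the Pearson correlation of the two variables,
#' and the maximum indication error: the worst-case difference between the
#' displacement recovered by inverting the fit, `(column - b)/a`, and the
#' true stage displacement, evaluated over the calibration points
#' themselves.
#'
#' @param table A [calibration_table()].
#' @return Object of class `calibration_fit` with fields `a` (slope, per
#'   mm), `b` (intercept, px), `se_a`, `se_b`, `pearson_r`,
#'   `max_indication_error_mm`, `n_points`.
#' @export
fit_calibration <- function(table) {
  if (!inherits(table, "calibration_table"))
    table <- calibration_table(table$displacement_mm, table$column_px,
                               table$column_sd_px)
  x <- table$displacement_mm
  y <- table$column_px
  if (stats::sd(x) == 0)
    stop("singular fit: all displacements are equal", call. = FALSE)
  fit <- stats::lm(y ~ x)
  a <- unname(stats::coef(fit)[2])
  b <- unname(stats::coef(fit)[1])
  if (stats::df.residual(fit) > 0) {
    # noiseless synthetic tables fit exactly; the "essentially perfect fit"
    # caution from summary.lm is expected there, not actionable
    se <- withCallingHandlers(
      sqrt(diag(stats::vcov(fit))),
      warning = function(w) {
        if (grepl("essentially perfect fit", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    se_a <- unname(se[2]); se_b <- unname(se[1])
  } else {
    warning("only 2 points: exact interpolating line, standard errors reported as 0")
    se_a <- 0; se_b <- 0
  }
  r <- stats::cor(x, y)
  pred_disp <- (y - b) / a
  structure(list(a = a, b = b, se_a = se_a, se_b = se_b,
                 pearson_r = r,
                 max_indication_error_mm = max(abs(pred_disp - x)),
                 n_points = length(x)),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("column = a * displacement + b\n"))
  cat(sprintf("  a = %.2f +/- %.2f per mm (1 SE)\n", x$a, x$se_a))
  cat(sprintf("  b = %.2f +/- %.2f px (1 SE)\n", x$b, x$se_b))
  cat(sprintf("  Pearson r = %.4f over %d points\n", x$pearson_r, x$n_points))
  cat(sprintf("  max indication error = %.1f um\n",
              1000 * x$max_indication_error_mm))
  invisible(x)
}

#' Convert stripe columns to displacements with a calibration fit
#'
#' Analytic inverse of the fitted line: `displacement = (column - b) / a`.
#'
#' @param fit A [fit_calibration()] result.
#' @param column_px Stripe column(s), fractional pixels.
#' @return Displacement(s), mm.
#' @export
column_to_displacement <- function(fit, column_px) {
  if (!inherits(fit, "calibration_fit"))
    stop("'fit' must be a 'calibration_fit'", call. = FALSE)
  if (fit$a == 0) stop("zero slope: calibration is not invertible", call. = FALSE)
  (column_px - fit$b) / fit$a
}

#' @rdname column_to_displacement
#' @param displacement_mm Displacement(s), mm (forward map).
#' @export
displacement_to_column <- function(fit, displacement_mm) {
  if (!inherits(fit, "calibration_fit"))
    stop("'fit' must be a 'calibration_fit'", call. = FALSE)
  fit$a * displacement_mm + fit$b
}

#' Simulate a staircase calibration run
#'
#' Emulates the bench calibration protocol: position the specimen so the
#' stripe sits near the right sensor edge, then step the stage in equal
#' increments (0.5 mm by default) while rendering a frame and estimating
#' the stripe column at each step, until the requested number of steps or
#' the stripe leaves the sensor. Steps whose true stripe column falls off
#' the sensor truncate the run with a warning.
#'
#' @param cfg An [optical_config()].
#' @param scene A [scene_config()].
#' @param n_steps Number of stage positions (default 13: a 6 mm staircase
#'   at 0.5 mm per step).
#' @param step_mm Stage increment, mm.
#' @param start_x1_mm Specimen position of the first step; default places
#'   the stripe 10 columns in from the right sensor edge.
#' @param mask Optional precomputed [build_mask()] for the frame shape.
#' @param quality A [quality_spec()].
#' @param seed Base RNG seed (per-step seeds are `seed + step`).
#' @return A [calibration_table()] of stage displacement vs estimated
#'   column, with attribute `true_column_px` holding the model truth.
#' @export
simulate_calibration_run <- function(cfg, scene, n_steps = 13, step_mm = 0.5,
                                     start_x1_mm = NULL, mask = NULL,
                                     quality = quality_spec(),
                                     seed = scene$seed) {
  .assert_cfg(cfg)
  if (is.null(start_x1_mm))
    start_x1_mm <- specimen_from_column(cfg, cfg$nc - 10)
  if (is.null(mask))
    mask <- build_mask(c(scene$rows, cfg$nc))
  disp <- numeric(0); cols <- numeric(0); truth <- numeric(0)
  for (i in seq_len(n_steps)) {
    s <- (i - 1) * step_mm
    x1 <- start_x1_mm + s
    cc <- stripe_column(cfg, x1)
    if (cc < 0 || cc > cfg$nc) {
      warning(sprintf("stripe left the sensor at step %d (column %.1f); run truncated",
                      i - 1L, cc))
      break
    }
    frame <- render_frame(cfg, scene, x1, seed = seed + i - 1L)
    est <- estimate_stripe(frame, mask, quality)
    if (!est$valid)
      stop("no valid stripe estimate at step ", i - 1L, call. = FALSE)
    disp <- c(disp, s); cols <- c(cols, est$column_mean); truth <- c(truth, cc)
  }
  if (length(disp) < 2L)
    stop("calibration run produced fewer than 2 usable steps", call. = FALSE)
  tab <- calibration_table(disp, cols)
  attr(tab, "true_column_px") <- truth
  tab
}
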