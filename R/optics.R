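#' Optical configuration of the tilted-sensor relay
#'
#' Describes the two-lens wide-field relay with an image sensor tilted
#' relative to the optical axis. Lens I (focal length `f1_mm`) faces the
#' specimen, lens II (`f2_mm`) faces the sensor, and the two lenses are
#' separated by `d_mm`. The sensor is referenced to the back focal point of
#' lens II and covers `sensor_width_mm` across `n_columns` pixel columns.
#' Defaults correspond to the laboratory prototype: 45 mm and 18 mm effective
#' focal lengths at the telecentric separation `d = f1 + f2 = 63` mm, a
#' 1.44 mm-wide sensor with 1280 columns, tilted 45 degrees.
#'
#' @param f1_mm Focal length of lens I (specimen side), mm. Must be > 0.
#' @param f2_mm Focal length of lens II (sensor side), mm. Must be > 0.
#' @param d_mm Separation between the two lenses, mm. Must be > 0.
#' @param sensor_width_mm Width of the sensor image area, mm.
#' @param n_columns Number of pixel columns across the sensor width.
#' @param tilt_deg Sensor tilt relative to the optical axis, degrees, in
#'   (0, 90). Only 45 degrees is validated against the prototype; other
#'   angles substitute `cos(tilt)` in the column mapping.
#' @return An object of class `optical_config`.
#' @examples
#' cfg <- optical_config()
#' stripe_column(cfg, 45)   # sensor centre: column 640
#' @export
optical_config <- function(f1_mm = 45, f2_mm = 18, d_mm = 63,
                           sensor_width_mm = 1.44, n_columns = 1280L,
                           tilt_deg = 45) {
  if (!is.numeric(f1_mm) || length(f1_mm) != 1L || !is.finite(f1_mm) || f1_mm <= 0)
    stop("'f1_mm' must be a single positive number", call. = FALSE)
  if (!is.numeric(f2_mm) || length(f2_mm) != 1L || !is.finite(f2_mm) || f2_mm <= 0)
    stop("'f2_mm' must be a single positive number", call. = FALSE)
  if (!is.numeric(d_mm) || length(d_mm) != 1L || !is.finite(d_mm) || d_mm <= 0)
    stop("'d_mm' must be a single positive number", call. = FALSE)
  if (!is.numeric(sensor_width_mm) || length(sensor_width_mm) != 1L ||
      !is.finite(sensor_width_mm) || sensor_width_mm <= 0)
    stop("'sensor_width_mm' must be a single positive number", call. = FALSE)
  n_columns <- as.integer(n_columns)
  if (is.na(n_columns) || n_columns < 2L)
    stop("'n_columns' must be an integer >= 2", call. = FALSE)
  if (!is.numeric(tilt_deg) || length(tilt_deg) != 1L || !is.finite(tilt_deg) ||
      tilt_deg <= 0 || tilt_deg >= 90)
    stop("'tilt_deg' must lie strictly between 0 and 90 degrees", call. = FALSE)
  structure(
    list(f1 = as.numeric(f1_mm), f2 = as.numeric(f2_mm), d = as.numeric(d_mm),
         w = as.numeric(sensor_width_mm), nc = n_columns,
         tilt_deg = as.numeric(tilt_deg)),
    class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat("Optical configuration (tilted-sensor relay)\n")
  cat(sprintf("  lens I focal length : %g mm\n", x$f1))
  cat(sprintf("  lens II focal length: %g mm\n", x$f2))
  cat(sprintf("  lens separation     : %g mm%s\n", x$d,
              if (isTRUE(all.equal(x$d, x$f1 + x$f2))) " (telecentric)" else ""))
  cat(sprintf("  sensor width        : %g mm over %d columns\n", x$w, x$nc))
  cat(sprintf("  sensor tilt         : %g deg\n", x$tilt_deg))
  invisible(x)
}

.assert_cfg <- function(cfg) {
  if (!inherits(cfg, "optical_config"))
    stop("'cfg' must be an 'optical_config' object", call. = FALSE)
  cfg
}

# Moebius (rational-linear) coefficients of the image-distance map
# x2 = (alpha*x1 + beta) / (gamma*x1 + delta).
.moebius <- function(cfg) {
  list(alpha = cfg$d * cfg$f2 - cfg$f1 * cfg$f2,
       beta  = -cfg$d * cfg$f1 * cfg$f2,
       gamma = cfg$d - cfg$f1 - cfg$f2,
       delta = cfg$f1 * cfg$f2 - cfg$d * cfg$f1)
}

#' Ray-transfer matrix of the complete relay
#'
#' Multiplies the five paraxial factors of the system — propagation over
#' `x1`, thin lens I, propagation over `d`, thin lens II, propagation over
#' `x2` — into the overall 2x2 ray-transfer (ABCD) matrix taking ray
#' height/angle at the specimen plane to the candidate image plane. The
#' matrix has unit determinant; the `B` element vanishes exactly when `x2`
#' satisfies the imaging condition (see [image_distance()]), and at that
#' point `A` is the transverse magnification.
#'
#' @param cfg An [optical_config()].
#' @param x1_mm Specimen distance to lens I, mm.
#' @param x2_mm Candidate image distance from lens II, mm.
#' @return Object of class `ray_transfer_matrix` with elements `A`, `B`,
#'   `C`, `D`.
#' @export
system_matrix <- function(cfg, x1_mm, x2_mm) {
  .assert_cfg(cfg)
  stopifnot(is.numeric(x1_mm), length(x1_mm) == 1L, is.finite(x1_mm),
            is.numeric(x2_mm), length(x2_mm) == 1L, is.finite(x2_mm))
  prop <- function(t) matrix(c(1, 0, t, 1), 2, 2)
  lens <- function(f) matrix(c(1, -1 / f, 0, 1), 2, 2)
  m <- prop(x2_mm) %*% lens(cfg$f2) %*% prop(cfg$d) %*% lens(cfg$f1) %*% prop(x1_mm)
  structure(list(A = m[1, 1], B = m[1, 2], C = m[2, 1], D = m[2, 2]),
            class = "ray_transfer_matrix")
}

#' @export
print.ray_transfer_matrix <- function(x, ...) {
  cat(sprintf("ABCD matrix: A=%.6g B=%.6g C=%.6g D=%.6g (det=%.6g)\n",
              x$A, x$B, x$C, x$D, x$A * x$D - x$B * x$C))
  invisible(x)
}

#' Image distance satisfying the imaging condition
#'
#' Solves `B = 0` for the image distance `x2` given the specimen distance
#' `x1`. The solution is the rational-linear (Moebius) map
#' `x2 = (alpha*x1 + beta)/(gamma*x1 + delta)` of the lens parameters; at
#' the telecentric separation `d = f1 + f2` it reduces to an affine map of
#' `x1`, which is what makes the depth-to-column response of the prototype
#' linear.
#'
#' @inheritParams system_matrix
#' @return Image distance from lens II, mm.
#' @seealso [magnification()], [stripe_column()]
#' @export
image_distance <- function(cfg, x1_mm) {
  .assert_cfg(cfg)
  stopifnot(is.numeric(x1_mm), length(x1_mm) == 1L, is.finite(x1_mm))
  mb <- .moebius(cfg)
  den <- mb$gamma * x1_mm + mb$delta
  scale <- max(abs(mb$gamma * x1_mm), abs(mb$delta), 1)
  if (abs(den) < 1e-12 * scale)
    stop("degenerate configuration: no finite image plane at x1 = ",
         format(x1_mm), " mm", call. = FALSE)
  (mb$alpha * x1_mm + mb$beta) / den
}

#' Transverse magnification at the in-focus plane
#'
#' Evaluates the `A` element of the system matrix at the image distance
#' solving the imaging condition. At the telecentric separation the result
#' is the constant `-f2/f1`, independent of specimen position; away from it
#' the magnification varies with `x1`.
#'
#' @inheritParams image_distance
#' @return Dimensionless (signed) magnification.
#' @export
magnification <- function(cfg, x1_mm) {
  x2 <- image_distance(cfg, x1_mm)
  system_matrix(cfg, x1_mm, x2)$A
}

#' Stripe column for a given specimen position
#'
#' Maps the specimen distance `x1` to the column coordinate of the in-focus
#' stripe on the tilted sensor. The image plane at distance `x2` from lens
#' II intersects the sensor (referenced to the back focal point of lens II,
#' tilted by `tilt_deg`) along a line whose column coordinate is
#' `c = ((x2 - f2)/cos(tilt) + w/2) * nc / w`.
#'
#' The column is a continuous coordinate: `c = 0` at the left sensor edge,
#' `c = nc` at the right edge, pixel `k` spanning `[k, k + 1)`. Values
#' outside `[0, nc]` are returned unchanged (off-sensor); they are flagged
#' by [optics_sweep()] rather than clamped.
#'
#' @inheritParams image_distance
#' @return Stripe column, fractional pixels.
#' @export
stripe_column <- function(cfg, x1_mm) {
  .assert_cfg(cfg)
  x2 <- image_distance(cfg, x1_mm)
  ct <- cospi(cfg$tilt_deg / 180)
  ((x2 - cfg$f2) / ct + cfg$w / 2) * cfg$nc / cfg$w
}

#' Depth sensitivity of the stripe column
#'
#' Derivative of the stripe column with respect to specimen position,
#' `dc/dx1`, in columns per mm. For the prototype (telecentric) geometry the
#' analytic value is `-(f2/f1)^2 * (nc/w) / cos(tilt)`, approximately
#' -201 per mm.
#'
#' @inheritParams image_distance
#' @param method `"analytic"` differentiates the closed-form Moebius map;
#'   `"fd"` uses a central finite difference with step `h_mm`.
#' @param h_mm Finite-difference step, mm (used when `method = "fd"`).
#' @return Sensitivity, per mm (columns of stripe motion per mm of specimen
#'   motion; negative for the prototype).
#' @export
sensitivity <- function(cfg, x1_mm, method = c("analytic", "fd"), h_mm = 1e-5) {
  .assert_cfg(cfg)
  method <- match.arg(method)
  if (method == "fd") {
    return((stripe_column(cfg, x1_mm + h_mm) -
            stripe_column(cfg, x1_mm - h_mm)) / (2 * h_mm))
  }
  mb <- .moebius(cfg)
  den <- mb$gamma * x1_mm + mb$delta
  scale <- max(abs(mb$gamma * x1_mm), abs(mb$delta), 1)
  if (abs(den) < 1e-12 * scale)
    stop("degenerate configuration: sensitivity undefined at x1 = ",
         format(x1_mm), " mm", call. = FALSE)
  dx2 <- (mb$alpha * mb$delta - mb$beta * mb$gamma) / den^2
  ct <- cospi(cfg$tilt_deg / 180)
  dx2 / ct * cfg$nc / cfg$w
}

#' Specimen position producing a given stripe column
#'
#' Inverse of [stripe_column()]: recovers `x1` from a column coordinate.
#' The column maps linearly to the image distance `x2`, and the imaging
#' condition is a rational-linear (Moebius) map of `x1`, so the inverse is
#' closed-form: `x1 = (delta*x2 - beta)/(alpha - gamma*x2)`.
#'
#' @inheritParams image_distance
#' @param column_px Stripe column, fractional pixels (may lie outside the
#'   sensor, which corresponds to a specimen position outside the visible
#'   range).
#' @return Specimen distance `x1`, mm.
#' @export
specimen_from_column <- function(cfg, column_px) {
  .assert_cfg(cfg)
  stopifnot(is.numeric(column_px), length(column_px) == 1L, is.finite(column_px))
  ct <- cospi(cfg$tilt_deg / 180)
  x2 <- cfg$f2 + ct * (column_px * cfg$w / cfg$nc - cfg$w / 2)
  mb <- .moebius(cfg)
  den <- mb$alpha - mb$gamma * x2
  scale <- max(abs(mb$alpha), abs(mb$gamma * x2), 1)
  if (abs(den) < 1e-12 * scale)
    stop("column ", format(column_px),
         " is unreachable for this configuration", call. = FALSE)
  (mb$delta * x2 - mb$beta) / den
}

#' Sweep the optical model over a grid of specimen positions
#'
#' Evaluates image distance, magnification, stripe column and sensitivity
#' on a grid of `x1` values. Points where the imaging condition is
#' degenerate yield `NA` entries rather than an error.
#'
#' @inheritParams image_distance
#' @param x1_grid_mm Numeric vector of specimen positions, mm (nonempty).
#' @return A data frame with columns `x1_mm`, `x2_mm`, `magnification`,
#'   `column_px`, `sensitivity_per_mm`, `off_sensor`.
#' @examples
#' sw <- optics_sweep(optical_config(), seq(41.8, 48.2, length.out = 5))
#' @export
optics_sweep <- function(cfg, x1_grid_mm) {
  .assert_cfg(cfg)
  stopifnot(is.numeric(x1_grid_mm), length(x1_grid_mm) >= 1L)
  one <- function(x1) {
    tryCatch({
      x2 <- image_distance(cfg, x1)
      cc <- stripe_column(cfg, x1)
      c(x2 = x2,
        magnification = system_matrix(cfg, x1, x2)$A,
        column = cc,
        sens = sensitivity(cfg, x1))
    }, error = function(e) c(x2 = NA_real_, magnification = NA_real_,
                             column = NA_real_, sens = NA_real_))
  }
  tol <- 1e-9 * cfg$nc   # guard against float noise at the exact edges
  vals <- t(vapply(x1_grid_mm, one, numeric(4)))
  data.frame(
    x1_mm = x1_grid_mm,
    x2_mm = vals[, "x2"],
    magnification = vals[, "magnification"],
    column_px = vals[, "column"],
    sensitivity_per_mm = vals[, "sens"],
    off_sensor = is.na(vals[, "column"]) |
      vals[, "column"] < -tol | vals[, "column"] > cfg$nc + tol)
}

#' Convert a column span to a world-coordinate span via the model
#'
#' Divides a span in pixels by the magnitude of the model sensitivity at
#' the sensor centre. This is the model-based (calibration-free) pixel to
#' mm conversion; for measured data prefer [column_to_displacement()] with
#' a fitted calibration.
#'
#' @inheritParams image_distance
#' @param span_px Span in pixel columns.
#' @return Span in mm.
#' @export
column_span_to_mm <- function(cfg, span_px) {
  .assert_cfg(cfg)
  x1_center <- specimen_from_column(cfg, cfg$nc / 2)
  span_px / abs(sensitivity(cfg, x1_center))
}
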