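#' Specification of the Gaussian annular bandpass filter
#'
#' Frames captured by the tilted-sensor system decompose into a sharp
#' high-spatial-frequency stripe, a smooth illumination baseline and sensor
#' noise. In the centred 2-D spectrum the baseline lives within a radius of
#' about 20 pixels and the stripe within about 300 pixels, so an annular
#' passband between those radii isolates the stripe. The mask is a product
#' of two radial Gaussian edges (see [build_mask()]); `rolloff` controls the
#' softness of each edge as a fraction of its radius.
#'
#' @param r_low Inner passband radius in pixels of the centred spectrum
#'   (default 20).
#' @param r_high Outer passband radius in pixels (default 300).
#' @param rolloff Gaussian transition softness as a fraction of each radius
#'   (default 0.1).
#' @return An object of class `bandpass_spec`.
#' @export
bandpass_spec <- function(r_low = 20, r_high = 300, rolloff = 0.1) {
  stopifnot(is.numeric(r_low), length(r_low) == 1L, r_low >= 0,
            is.numeric(r_high), length(r_high) == 1L, r_high > r_low,
            is.numeric(rolloff), length(rolloff) == 1L, rolloff >= 0)
  structure(list(r_low = as.numeric(r_low), r_high = as.numeric(r_high),
                 rolloff = as.numeric(rolloff)),
            class = "bandpass_spec")
}

# Radial transmission profile in [0, 1]: T(r) = G_hi(r) * (1 - G_lo(r)).
# G_lo is a Gaussian of sigma r_low*(1+rolloff) blocking the baseline and
# DC; G_hi is flat to r_high then falls off with sigma r_high*rolloff.
.mask_profile <- function(r, spec) {
  if (spec$r_low > 0) {
    s_lo <- spec$r_low * (1 + spec$rolloff)
    g_lo <- exp(-r^2 / (2 * s_lo^2))
  } else {
    g_lo <- as.numeric(r == 0)  # block DC only
  }
  if (spec$rolloff > 0) {
    s_hi <- spec$r_high * spec$rolloff
    g_hi <- ifelse(r <= spec$r_high, 1, exp(-(r - spec$r_high)^2 / (2 * s_hi^2)))
  } else {
    g_hi <- as.numeric(r <= spec$r_high)
  }
  g_hi * (1 - g_lo)
}

#' Build the frequency-domain transmission mask
#'
#' Evaluates the annular Gaussian profile on a centred frequency grid of the
#' given shape. Transmission is 1 = pass, 0 = block; the DC component (grid
#' centre, row `floor(rows/2)+1`, column `floor(cols/2)+1` in R's 1-based
#' indexing) is blocked. The mask is point-symmetric about the centre so
#' that filtering a real image yields a real image.
#'
#' @param shape Either an integer vector `c(rows, cols)` or a matrix whose
#'   dimensions are used.
#' @param spec A [bandpass_spec()].
#' @return A matrix of class `frequency_mask` with values in `[0, 1]`,
#'   zero-frequency at the centre.
#' @export
build_mask <- function(shape, spec = bandpass_spec()) {
  if (is.matrix(shape)) shape <- dim(shape)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L, all(shape >= 2L))
  if (!inherits(spec, "bandpass_spec"))
    stop("'spec' must be a 'bandpass_spec' object", call. = FALSE)
  rows <- shape[1]; cols <- shape[2]
  fr <- (seq_len(rows) - 1L) - floor(rows / 2)
  fc <- (seq_len(cols) - 1L) - floor(cols / 2)
  r <- sqrt(outer(fr^2, fc^2, `+`))
  m <- .mask_profile(r, spec)
  structure(m, class = c("frequency_mask", "matrix", "array"))
}

# Move a centred mask to FFT order (zero frequency at element [1, 1]).
.ifftshift <- function(m) {
  rows <- nrow(m); cols <- ncol(m)
  ri <- ((seq_len(rows) - 1L + floor(rows / 2)) %% rows) + 1L
  ci <- ((seq_len(cols) - 1L + floor(cols / 2)) %% cols) + 1L
  m[ri, ci, drop = FALSE]
}

#' Apply the bandpass filter to a frame
#'
#' Transforms the frame to the frequency domain with a 2-D FFT, multiplies
#' by the transmission mask, and transforms back. The operation is linear
#' in the frame and returns a real matrix (the imaginary residue of the
#' inverse transform is discarded after a sanity check).
#'
#' @param frame Numeric matrix (grey values; any real scale).
#' @param mask A [build_mask()] result with the same dimensions.
#' @return Filtered frame, a numeric matrix of the same shape.
#' @export
apply_bandpass <- function(frame, mask) {
  if (!is.matrix(frame) || !is.numeric(frame))
    stop("'frame' must be a numeric matrix", call. = FALSE)
  if (!inherits(mask, "frequency_mask"))
    stop("'mask' must be a 'frequency_mask' from build_mask()", call. = FALSE)
  if (!identical(dim(frame), dim(mask)))
    stop(sprintf("shape mismatch: frame is %dx%d but mask is %dx%d",
                 nrow(frame), ncol(frame), nrow(mask), ncol(mask)),
         call. = FALSE)
  spec_f <- stats::fft(frame) * .ifftshift(unclass(mask))
  out <- stats::fft(spec_f, inverse = TRUE) / length(frame)
  im <- max(abs(Im(out)))
  sig <- max(abs(Re(out)), .Machine$double.eps)
  if (im > 1e-8 * sig)
    warning("unexpected imaginary residue after inverse FFT (",
            format(im / sig), " of signal); mask may not be point-symmetric")
  Re(out)
}

#' Export / import a frequency mask as 32-bit float TIFF
#'
#' Convenience for visual inspection of the mask in external viewers.
#'
#' @param mask A `frequency_mask`.
#' @param path Destination TIFF path.
#' @return `write_mask()` returns `path` invisibly; `read_mask()` returns a
#'   `frequency_mask`.
#' @export
write_mask <- function(mask, path) {
  if (!inherits(mask, "frequency_mask"))
    stop("'mask' must be a 'frequency_mask'", call. = FALSE)
  tiff::writeTIFF(unclass(mask), path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  structure(m, class = c("frequency_mask", "matrix", "array"))
}
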