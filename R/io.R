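#' Read a frame stack from a multi-page TIFF or a frame directory
#'
#' Accepts a multi-page TIFF file or a directory of equally shaped
#' PNG/TIFF frames (taken in lexicographic order). Colour frames are
#' converted to single-channel luminance with the standard video weights
#' `0.299 R + 0.587 G + 0.114 B`. Pixel values are returned on the 0-255
#' grey-level scale.
#'
#' @param path Path to a TIFF file or a directory of frames.
#' @return List of numeric matrices (one per frame).
#' @export
read_stack <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L)
      stop("no PNG/TIFF frames found in directory ", path, call. = FALSE)
    frames <- lapply(files, .read_frame_file)
  } else if (file.exists(path)) {
    raw <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop("unreadable TIFF file ", path,
                                             ": ", conditionMessage(e),
                                             call. = FALSE))
    if (!is.list(raw)) raw <- list(raw)
    frames <- lapply(raw, .to_luminance)
  } else stop("no such file or directory: ", path, call. = FALSE)
  dims <- lapply(frames, dim)
  if (length(unique(dims)) != 1L)
    stop("mixed frame shapes in ", path, call. = FALSE)
  message(length(frames), " frame(s) of ", dims[[1]][1], "x", dims[[1]][2],
          " read from ", path)
  frames
}

.read_frame_file <- function(file) {
  img <- if (grepl("\\.png$", file, ignore.case = TRUE)) {
    tryCatch(png::readPNG(file),
             error = function(e) stop("unreadable PNG file ", file,
                                      call. = FALSE))
  } else {
    tryCatch(tiff::readTIFF(file),
             error = function(e) stop("unreadable TIFF file ", file,
                                      call. = FALSE))
  }
  .to_luminance(img)
}

# Collapse an array read by png/tiff to a 0-255 luminance matrix.
.to_luminance <- function(img) {
  if (length(dim(img)) == 3L) {
    ch <- dim(img)[3]
    img <- if (ch >= 3L)
      0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    else img[, , 1]
  }
  255 * img
}

#' Write a frame stack as an 8-bit multi-page TIFF
#'
#' Frames are clipped to `[0, 255]` and quantized to 8 bits on write;
#' in-memory frames stay unclipped floats.
#'
#' @param frames List of numeric matrices.
#' @param path Destination TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(frames, path) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  pages <- lapply(frames, function(f) pmin(pmax(f, 0), 255) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

# Format numeric data-frame columns at 6 significant digits for CSV output.
.signif_df <- function(df, digits = 6) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  df
}

#' Write / read pipeline CSV files
#'
#' All CSV output uses headers, 6-significant-digit floats and empty cells
#' (not zeros) for missing values. `write_trace()`/`read_trace()` handle
#' motion traces (`frame_index, time_s, column_px, column_sd_px,
#' n_rows_used, valid[, displacement_mm]`); `write_table_csv()` /
#' `read_table_csv()` handle generic tables such as calibration tables and
#' model sweeps.
#'
#' @param trace,table Data frame to write.
#' @param path CSV path.
#' @return Writers return `path` invisibly; readers return a data frame.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(.signif_df(as.data.frame(trace)), path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trace
#' @param frame_rate Frame rate attached to the trace on read, Hz.
#' @export
read_trace <- function(path, frame_rate = NULL) {
  tr <- utils::read.csv(path)
  if (is.null(frame_rate) && nrow(tr) > 1 && "time_s" %in% names(tr)) {
    # infer from the full span: robust to per-sample rounding in the CSV
    dt_mean <- (tr$time_s[nrow(tr)] - tr$time_s[1]) / (nrow(tr) - 1)
    dt <- diff(tr$time_s)
    if (dt_mean > 0 && all(abs(dt - dt_mean) <= 0.2 * dt_mean))
      frame_rate <- 1 / dt_mean
  }
  if (!is.null(frame_rate)) attr(tr, "frame_rate") <- frame_rate
  tr
}

#' @rdname write_trace
#' @export
write_table_csv <- function(table, path) {
  utils::write.csv(.signif_df(as.data.frame(table)), path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trace
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path)
}

#' Read a calibration table CSV
#'
#' Expects columns `displacement_mm`, `column_px` and optionally
#' `column_sd_px`.
#'
#' @param path CSV path.
#' @return A [calibration_table()].
#' @export
read_calibration_table <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("displacement_mm", "column_px") %in% names(df)))
    stop("calibration CSV must have columns 'displacement_mm' and 'column_px'",
         call. = FALSE)
  calibration_table(df$displacement_mm, df$column_px, df$column_sd_px)
}

#' Write / read JSON reports and calibration fits
#'
#' @param x Report list or `calibration_fit`.
#' @param path JSON path.
#' @return Writers return `path` invisibly; `read_report()` returns a list.
#' @export
write_report <- function(x, path) {
  jsonlite::write_json(lapply(unclass(x), function(v)
    if (is.numeric(v)) signif(v, 6) else v),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Read an optical/scene configuration from a YAML file
#'
#' Recognized keys (all optional, defaults from [optical_config()]):
#' `f1_mm`, `f2_mm`, `d_mm`, `sensor_width_mm`, `n_columns`, `tilt_deg`.
#'
#' @param path YAML file path.
#' @return An [optical_config()].
#' @export
read_optical_config <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- c("f1_mm", "f2_mm", "d_mm", "sensor_width_mm", "n_columns",
               "tilt_deg")
  bad <- setdiff(names(y), allowed)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(optical_config, y)
}
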