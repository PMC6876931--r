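#' Calibration scale
#'
#' Millivolts per vertical pixel and milliseconds per horizontal pixel,
#' plus the provenance of the measurement.
#'
#' @param mv_per_px,ms_per_px Strictly positive, finite conversion factors.
#' @param source `"auto"`, `"manual_crop"` or `"config"`.
#' @return An object of class `ecg_scale`.
#' @export
calibration_scale <- function(mv_per_px, ms_per_px, source = "config") {
  if (!is.finite(mv_per_px) || mv_per_px <= 0 ||
      !is.finite(ms_per_px) || ms_per_px <= 0)
    abort_ecg("ecg_calibration_error", "scale factors must be positive and finite")
  source <- match.arg(source, c("auto", "manual_crop", "config"))
  structure(list(mv_per_px = mv_per_px, ms_per_px = ms_per_px, source = source),
            class = "ecg_scale")
}

#' @export
print.ecg_scale <- function(x, ...) {
  cat(sprintf("<ecg_scale> %.5f mV/px, %.4f ms/px (%s)\n",
              x$mv_per_px, x$ms_per_px, x$source))
  invisible(x)
}

#' Locate the calibration-pulse search rectangle
#'
#' The reference pulse sits immediately to the left of the aVF lead (below
#' aVL) on the supported print layout. The search box has height equal to
#' 60% of the aVF region height, width equal to 75% of that height, is
#' vertically centered on the aVF box, and ends at the column just before
#' the aVF box starts.
#'
#' @param img An `ecg_raster` (full page).
#' @param avf_box The aVF lead's `ecg_box`.
#' @param height_frac,width_frac Geometry fractions (defaults 0.6 and 0.75).
#' @return An `ecg_box` delimiting the pulse search region.
#' @export
locate_scale_pulse <- function(img, avf_box, height_frac = 0.6, width_frac = 0.75) {
  h_box <- box_height(avf_box)
  ph <- round(height_frac * h_box)
  pw <- round(width_frac * ph)
  col_end <- avf_box$col_start - 1L
  col_start <- col_end - pw + 1L
  row_start <- avf_box$row_start + floor((h_box - ph) / 2)
  row_end <- row_start + ph - 1L
  if (col_start < 1L || col_end < 1L || row_start < 1L || row_end > nrow(img))
    abort_ecg("ecg_calibration_error",
              "calibration-pulse rectangle falls outside the image")
  bounding_box(row_start, row_end, col_start, col_end)
}

#' Measure the pixel scale from a calibration-pulse crop
#'
#' Binarizes the (non-inverted) pulse crop with the trace binarizer, cleans
#' small objects, and profiles the topmost foreground row per column. The
#' pulse height in px is the distance between the plateau level and the
#' baseline level; the plateau width in px is the number of columns above
#' half pulse height minus the stroke thickness (measured on the baseline),
#' which compensates for the vertical pulse edges. Physical meaning of the
#' pulse defaults to the standard ECG calibration mark: 1 mV, 200 ms.
#'
#' @param pulse_crop Numeric matrix containing a single rectangular step
#'   pulse (dark on light, as printed).
#' @param pulse_mv Pulse amplitude in millivolts (default 1.0).
#' @param pulse_ms Pulse duration in milliseconds (default 200).
#' @param otsu_scale,min_frac Binarization/cleaning parameters.
#' @param source Provenance recorded on the result (default `"auto"`).
#' @return An `ecg_scale`.
#' @export
measure_scale <- function(pulse_crop, pulse_mv = 1.0, pulse_ms = 200.0,
                          otsu_scale = 1.2, min_frac = 0.02, source = "auto") {
  m <- as_pixel_matrix(pulse_crop)
  mask <- tryCatch(binarize(1 - m, otsu_scale = otsu_scale),
                   ecg_degenerate_error = function(e)
                     abort_ecg("ecg_calibration_error",
                               "pulse crop is constant: no step structure"))
  mask <- suppressWarnings(remove_small_objects(mask, min_frac))
  if (!any(mask))
    abort_ecg("ecg_calibration_error", "no pulse found in the crop")
  # the pulse is a single connected object; profile only the largest
  # component so stray specks cannot fake a step
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  mask <- lab == which.max(sizes)
  top <- apply(mask, 2L, function(col) if (any(col)) which(col)[1L] else NA_real_)
  if (sum(!is.na(top)) < 2L || length(unique(stats::na.omit(top))) < 2L)
    abort_ecg("ecg_calibration_error",
              "fewer than 2 distinct row levels: no step structure detected")
  lo <- min(top, na.rm = TRUE)               # plateau (upper) level
  hi <- max(top, na.rm = TRUE)               # baseline (lower) level
  h <- hi - lo
  if (h < 2)
    abort_ecg("ecg_calibration_error", "pulse height below 2 px")
  mid <- (lo + hi) / 2
  n_above <- sum(top < mid, na.rm = TRUE)
  base_cols <- which(!is.na(top) & top >= mid)
  if (n_above < 2L || length(base_cols) < 2L)
    abort_ecg("ecg_calibration_error",
              "no plausible pulse: plateau and baseline must each span >= 2 columns")
  thick <- stats::median(colSums(mask[, base_cols, drop = FALSE]))
  w <- max(n_above - thick, 1)
  calibration_scale(mv_per_px = pulse_mv / h, ms_per_px = pulse_ms / w,
                    source = source)
}

#' Digitized ECG signal
#'
#' @param t Time in ms, uniformly spaced from 0, strictly increasing.
#' @param v Voltage in mV, same length as `t`.
#' @param lead Lead label.
#' @param fs Sampling rate in Hz; derived from `t` when omitted.
#' @return An object of class `ecg_signal`.
#' @export
ecg_signal <- function(t, v, lead = "II", fs = NULL) {
  if (length(t) != length(v) || length(t) < 2L)
    abort_ecg("ecg_param_error", "t and v must have equal length >= 2")
  if (any(diff(t) <= 0))
    abort_ecg("ecg_param_error", "t must be strictly increasing")
  if (is.null(fs)) fs <- 1000 / mean(diff(t))
  structure(list(t = as.numeric(t), v = as.numeric(v),
                 fs = fs, lead = lead), class = "ecg_signal")
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf("<ecg_signal> lead %s: %d samples, %.1f Hz, %.0f ms, [%.3f, %.3f] mV\n",
              x$lead, length(x$v), x$fs, max(x$t) - min(x$t), min(x$v), max(x$v)))
  invisible(x)
}

#' Convert a pixel trace into a calibrated signal
#'
#' Voltage grows upward while image rows grow downward, so
#' `v = (center_row - rows) * mv_per_px`; time is `(col - 1) * ms_per_px`
#' from the first crop column.
#'
#' @param trace An `ecg_trace` from [trace_path()] (optionally smoothed).
#' @param center_row Centerline row used as the 0 mV reference.
#' @param scale An `ecg_scale`.
#' @param lead Lead label carried on the output.
#' @return An `ecg_signal`.
#' @export
apply_scale <- function(trace, center_row, scale, lead = "II") {
  rows <- if (is.list(trace)) trace$rows else as.numeric(trace)
  n <- length(rows)
  ecg_signal(t = (seq_len(n) - 1L) * scale$ms_per_px,
             v = (center_row - rows) * scale$mv_per_px,
             lead = lead, fs = 1000 / scale$ms_per_px)
}
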