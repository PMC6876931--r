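#' Digitize a full ECG page
#'
#' The complete pipeline on an in-memory image: median prefilter, lead
#' bounding-box detection, per-lead trace extraction (invert, Otsu x
#' `otsu_scale`, small-object removal, Hough centerline, path growth,
#' peak-preserving smoothing), calibration via the reference pulse next to
#' aVF (or the configured fallback), and per-lead fiducials/intervals
#' where at least two beats are present.
#'
#' @param img An `ecg_raster` or a path to a PNG/JPEG file.
#' @param layout An [layout_config()].
#' @param config An [run_config()].
#' @return An object of class `ecg_digitization`: list with `boxes`
#'   (`ecg_boxset`), `scale` (`ecg_scale`), `leads` (named list; per lead:
#'   `signal`, `trace`, `center_row`, `box`, `fiducials`, `intervals` —
#'   the last two `NULL` when beat detection fails), and `notes`
#'   (character vector of per-lead warnings).
#' @export
digitize_page <- function(img, layout = layout_config(), config = run_config()) {
  if (is.character(img)) img <- load_image(img)
  if (!inherits(img, "ecg_raster")) img <- raster_image(img)
  work <- if (config$denoise) denoise(img) else img
  boxes <- detect_lead_boxes(work, layout,
                             window = config$window,
                             height_frac = config$height_frac,
                             min_dist_frac = config$min_dist_frac,
                             col_frac = config$col_frac,
                             edge_frac = config$edge_frac,
                             mode = config$profile_mode)
  notes <- character(0)

  scale <- digitize_scale(work, boxes, config,
                          note = function(msg) notes <<- c(notes, msg))

  leads <- list()
  for (i in seq_len(nrow(boxes))) {
    lead <- boxes$lead[i]
    box <- boxset_box(boxes, i)
    res <- tryCatch(
      extract_lead(work, box, scale, lead, config),
      ecg_error = function(e) {
        notes <<- c(notes, sprintf("%s: %s", lead, conditionMessage(e)))
        NULL
      })
    if (is.null(res)) next
    res$fiducials <- NULL
    res$intervals <- NULL
    fid_try <- tryCatch(suppressWarnings({
      qrs <- pan_tompkins_qrs(res$signal)
      fid <- locate_pt(res$signal, qrs, t_window_ms = config$t_window_ms)
      list(fiducials = fid, intervals = ecg_intervals(fid, res$signal))
    }), ecg_error = function(e) {
      notes <<- c(notes, sprintf("%s (fiducials): %s", lead, conditionMessage(e)))
      NULL
    })
    if (!is.null(fid_try)) {
      res$fiducials <- fid_try$fiducials
      res$intervals <- fid_try$intervals
    }
    leads[[lead]] <- res
  }
  if (length(leads) == 0L)
    abort_ecg("ecg_extraction_error", "no lead could be extracted")
  structure(list(boxes = boxes, scale = scale, leads = leads, notes = notes),
            class = "ecg_digitization")
}

# calibration stage with manual-crop and config fallbacks
digitize_scale <- function(work, boxes, config, note = function(msg) {}) {
  if (!is.null(config$pulse_crop)) {
    crop <- crop_box(work, config$pulse_crop)
    return(measure_scale(crop, config$pulse_mv, config$pulse_ms,
                         otsu_scale = config$otsu_scale,
                         min_frac = config$min_frac, source = "manual_crop"))
  }
  auto <- tryCatch({
    i_avf <- which(boxes$lead == "aVF")
    if (length(i_avf) != 1L)
      abort_ecg("ecg_calibration_error", "no aVF box: cannot auto-locate the pulse")
    pbox <- locate_scale_pulse(work, boxset_box(boxes, i_avf))
    measure_scale(crop_box(work, pbox), config$pulse_mv, config$pulse_ms,
                  otsu_scale = config$otsu_scale, min_frac = config$min_frac,
                  source = "auto")
  }, ecg_error = function(e) e)
  if (inherits(auto, "ecg_scale")) return(auto)
  if (!is.null(config$fallback_scale)) {
    note(sprintf("calibration fell back to configured scale: %s",
                 conditionMessage(auto)))
    fb <- config$fallback_scale
    return(calibration_scale(fb$mv_per_px, fb$ms_per_px, source = "config"))
  }
  stop(auto)
}

# one lead: crop -> invert -> binarize -> clean -> centerline -> path ->
# smooth -> calibrate
extract_lead <- function(work, box, scale, lead, config) {
  crop <- crop_box(work, box)
  mask <- binarize(1 - crop, otsu_scale = config$otsu_scale)
  mask <- suppressWarnings(remove_small_objects(mask, config$min_frac))
  ctr <- centerline(mask, angle_tol_deg = config$angle_tol_deg,
                    angle_step = config$angle_step,
                    accum_frac = config$accum_frac)
  trace <- trace_path(mask, ctr, max_iter = config$max_iter,
                      seed_band = config$seed_band)
  trace$rows <- smooth_trace(trace$rows, span = config$span,
                             peak_factor = config$peak_factor)
  signal <- apply_scale(trace, ctr, scale, lead = lead)
  list(signal = signal, trace = trace, center_row = ctr, box = box)
}

#' @export
print.ecg_digitization <- function(x, ...) {
  cat(sprintf("<ecg_digitization> %d lead(s), scale %.4f mV/px %.3f ms/px (%s)\n",
              length(x$leads), x$scale$mv_per_px, x$scale$ms_per_px,
              x$scale$source))
  for (nm in names(x$leads)) {
    iv <- x$leads[[nm]]$intervals
    cat(sprintf("  %-10s %5d samples%s\n", nm, length(x$leads[[nm]]$signal$v),
                if (!is.null(iv)) sprintf(
                  "  PR %.0f QRS %.0f QT %.0f RR %.0f ms (%.1f bpm)",
                  iv$pr_ms, iv$qrs_ms, iv$qt_ms, iv$rr_ms, iv$heart_rate_bpm)
                else ""))
  }
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}
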