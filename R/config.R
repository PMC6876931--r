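#' Pipeline run configuration
#'
#' Collects every tunable constant of the digitization pipeline with its
#' documented default. Values are range-checked on construction.
#'
#' @param window Std-dev mask size in px (odd, default 5).
#' @param height_frac Peak threshold as a fraction of the profile maximum.
#' @param min_dist_frac Minimum peak spacing as a fraction of profile length.
#' @param col_frac Fraction of columns scanned for the left margin.
#' @param edge_frac Profile fraction bounding the outermost lead boxes.
#' @param profile_mode `"pooled"` or `"mean_row_sd"` (see [row_std_profile()]).
#' @param otsu_scale Multiplier on the Otsu threshold (default 1.2).
#' @param min_frac Relative small-object cutoff (default 0.02).
#' @param angle_tol_deg,angle_step,accum_frac Hough centerline parameters.
#' @param max_iter Path-growth iteration cap (default 20).
#' @param seed_band Centerline seed band half-width in px (default 2).
#' @param span Smoothing span (odd, default 5).
#' @param peak_factor Smoothing peak-exclusion multiplier (default 5).
#' @param pulse_mv,pulse_ms Calibration-pulse physical constants.
#' @param t_window_ms T-wave search window after S (default 400).
#' @param resample_n Validation resampling length (default 1000).
#' @param denoise Apply the 3x3 median prefilter (default `TRUE`).
#' @param fallback_scale Optional `ecg_scale` used when automatic
#'   calibration fails (flagged `source = "config"`).
#' @param pulse_crop Optional `ecg_box`: manual calibration-pulse crop
#'   overriding automatic location.
#' @return An object of class `ecg_config` (a named list).
#' @export
run_config <- function(window = 5L, height_frac = 0.5, min_dist_frac = 0.05,
                       col_frac = 0.10, edge_frac = 0.10,
                       profile_mode = "pooled",
                       otsu_scale = 1.2, min_frac = 0.02,
                       angle_tol_deg = 5, angle_step = 0.5, accum_frac = 0.5,
                       max_iter = 20L, seed_band = 2,
                       span = 5L, peak_factor = 5,
                       pulse_mv = 1.0, pulse_ms = 200.0,
                       t_window_ms = 400, resample_n = 1000L,
                       denoise = TRUE, fallback_scale = NULL,
                       pulse_crop = NULL) {
  chk <- function(ok, what) if (!ok) abort_ecg("ecg_param_error", paste("invalid", what))
  chk(window >= 1 && window %% 2 == 1, "window (odd, >= 1)")
  chk(height_frac > 0 && height_frac <= 1, "height_frac in (0, 1]")
  chk(min_dist_frac >= 0 && min_dist_frac < 1, "min_dist_frac in [0, 1)")
  chk(col_frac > 0 && col_frac <= 0.5, "col_frac in (0, 0.5]")
  chk(edge_frac >= 0 && edge_frac < 1, "edge_frac in [0, 1)")
  chk(profile_mode %in% c("pooled", "mean_row_sd"), "profile_mode")
  chk(otsu_scale > 0, "otsu_scale (> 0)")
  chk(min_frac >= 0 && min_frac <= 1, "min_frac in [0, 1]")
  chk(angle_tol_deg > 0 && angle_tol_deg <= 45, "angle_tol_deg in (0, 45]")
  chk(max_iter >= 1, "max_iter (>= 1)")
  chk(seed_band >= 0, "seed_band (>= 0)")
  chk(span >= 1 && span %% 2 == 1, "span (odd, >= 1)")
  chk(peak_factor > 0, "peak_factor (> 0)")
  chk(pulse_mv > 0 && pulse_ms > 0, "pulse constants (> 0)")
  chk(t_window_ms > 0, "t_window_ms (> 0)")
  chk(resample_n >= 2, "resample_n (>= 2)")
  if (!is.null(fallback_scale) && !inherits(fallback_scale, "ecg_scale"))
    abort_ecg("ecg_param_error", "fallback_scale must be an ecg_scale")
  structure(list(window = as.integer(window), height_frac = height_frac,
                 min_dist_frac = min_dist_frac, col_frac = col_frac,
                 edge_frac = edge_frac, profile_mode = profile_mode,
                 otsu_scale = otsu_scale, min_frac = min_frac,
                 angle_tol_deg = angle_tol_deg, angle_step = angle_step,
                 accum_frac = accum_frac, max_iter = as.integer(max_iter),
                 seed_band = seed_band, span = as.integer(span),
                 peak_factor = peak_factor, pulse_mv = pulse_mv,
                 pulse_ms = pulse_ms, t_window_ms = t_window_ms,
                 resample_n = as.integer(resample_n), denoise = denoise,
                 fallback_scale = fallback_scale, pulse_crop = pulse_crop),
            class = "ecg_config")
}

#' Read a run configuration (and optional layout) from a JSON file
#'
#' Top-level keys matching [run_config()] arguments override defaults; an
#' optional `layout` object (`n_leads`, `leads_per_column`, `rhythm_lead`)
#' builds the [layout_config()].
#'
#' @param path Path to a JSON file.
#' @return List with elements `config` and `layout`.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    abort_ecg("ecg_input_error", sprintf("config file '%s' not found", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  layout <- if (!is.null(raw$layout)) do.call(layout_config, raw$layout)
            else layout_config()
  raw$layout <- NULL
  keep <- intersect(names(raw), names(formals(run_config)))
  cfg <- do.call(run_config, raw[keep])
  list(config = cfg, layout = layout)
}
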