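#' Synthetic printed-ECG specification
#'
#' Describes both the physiology (Gaussian-bump PQRST beat model) and the
#' print geometry (page size, grid, margins, pixel scale) of a rendered
#' ECG page. Defaults emulate a 200 dpi scan of a standard 25 mm/s,
#' 10 mm/mV record: 5 ms and 0.025 mV per pixel, a 1147 x 1638 px page,
#' and the textbook morphology PR 160 ms, QRS 90 ms, QT 380 ms.
#'
#' @param heart_rate_bpm Heart rate in `[30, 240]` (default 72).
#' @param n_beats Beats per standard lead (default 4; the rhythm strip
#'   carries as many beats as fit its width).
#' @param fs Synthesis sampling rate in Hz (default 500).
#' @param wave_params Data frame with columns `wave` (P,Q,R,S,T), `amp_mv`,
#'   `sigma_ms` (Gaussian width) and `offset_ms` (center relative to R).
#' @param lead_gains Named multiplicative per-lead amplitude variants
#'   (aVR is inverted, as on a real ECG).
#' @param page_px Page size `c(rows, cols)`; at least 600 x 800.
#' @param layout An [layout_config()].
#' @param ms_per_px,mv_per_px Rendering scale (ground truth).
#' @param margin_px Column where traces start (and, mirrored, end).
#' @param grid_spacing_px Background grid pitch (0 disables the grid).
#' @param grid_intensity Grid gray level (default 0.85).
#' @param trace_width_px Odd stroke width in px (default 3).
#' @param trace_intensity,paper_intensity Trace / paper gray levels.
#' @param tick_half_px Half-height of the lead-onset delimiter tick.
#' @param lead_in_ms,tail_ms Flat lead-in before the first R and tail after
#'   the last programmed T.
#' @param pulse_mv,pulse_ms Calibration-pulse physical constants.
#' @param pulse_tail_px,pulse_gap_px Baseline tails flanking the pulse and
#'   gap between pulse and trace onset.
#' @param noise_sd Gaussian pixel-noise SD (default 0.02).
#' @param n_glyphs Number of small stray dark glyphs scattered on the page.
#' @param jpeg_quality If non-`NULL`, round-trip the page through JPEG at
#'   this quality in `(0, 1]`.
#' @param seed Random seed controlling noise and glyph placement.
#' @return An object of class `ecg_synth_spec`.
#' @export
synthetic_spec <- function(heart_rate_bpm = 72, n_beats = 4L, fs = 500,
                           wave_params = default_wave_params(),
                           lead_gains = default_lead_gains(),
                           page_px = c(1147L, 1638L),
                           layout = layout_config(),
                           ms_per_px = 5, mv_per_px = 0.025,
                           margin_px = 110L,
                           grid_spacing_px = 8L, grid_intensity = 0.85,
                           trace_width_px = 3L, trace_intensity = 0.12,
                           paper_intensity = 0.98, tick_half_px = 15L,
                           lead_in_ms = 250, tail_ms = 500,
                           pulse_mv = 1.0, pulse_ms = 200,
                           pulse_tail_px = 10L, pulse_gap_px = 5L,
                           noise_sd = 0.02, n_glyphs = 6L,
                           jpeg_quality = NULL, seed = 1L) {
  if (heart_rate_bpm < 30 || heart_rate_bpm > 240)
    abort_ecg("ecg_spec_error", "heart_rate_bpm must lie in [30, 240]")
  if (page_px[1] < 600L || page_px[2] < 800L)
    abort_ecg("ecg_spec_error", "page must be at least 600 x 800 px")
  if (noise_sd < 0) abort_ecg("ecg_spec_error", "noise_sd must be >= 0")
  if (trace_width_px %% 2L == 0L)
    abort_ecg("ecg_spec_error", "trace_width_px must be odd")
  wp <- wave_params[match(c("P", "Q", "R", "S", "T"), wave_params$wave), ]
  if (anyNA(wp$wave) || any(diff(wp$offset_ms) <= 0))
    abort_ecg("ecg_spec_error",
              "wave offsets must be strictly ordered P < Q < R < S < T")
  structure(list(
    heart_rate_bpm = heart_rate_bpm, n_beats = as.integer(n_beats), fs = fs,
    wave_params = wp, lead_gains = lead_gains,
    page_px = as.integer(page_px), layout = layout,
    ms_per_px = ms_per_px, mv_per_px = mv_per_px,
    margin_px = as.integer(margin_px),
    grid_spacing_px = as.integer(grid_spacing_px),
    grid_intensity = grid_intensity,
    trace_width_px = as.integer(trace_width_px),
    trace_intensity = trace_intensity, paper_intensity = paper_intensity,
    tick_half_px = as.integer(tick_half_px),
    lead_in_ms = lead_in_ms, tail_ms = tail_ms,
    pulse_mv = pulse_mv, pulse_ms = pulse_ms,
    pulse_tail_px = as.integer(pulse_tail_px),
    pulse_gap_px = as.integer(pulse_gap_px),
    noise_sd = noise_sd, n_glyphs = as.integer(n_glyphs),
    jpeg_quality = jpeg_quality, seed = as.integer(seed)),
    class = "ecg_synth_spec")
}

#' @rdname synthetic_spec
#' @export
default_wave_params <- function() {
  data.frame(wave = c("P", "Q", "R", "S", "T"),
             amp_mv = c(0.15, -0.10, 1.00, -0.25, 0.35),
             sigma_ms = c(20, 8, 10, 8, 35),
             offset_ms = c(-205, -45, 0, 45, 335),
             stringsAsFactors = FALSE)
}

#' @rdname synthetic_spec
#' @export
default_lead_gains <- function() {
  c(I = 0.8, II = 1.0, III = 0.6, aVR = -0.7, aVL = 0.5, aVF = 0.9,
    V1 = 0.7, V2 = 0.9, V3 = 1.1, V4 = 1.2, V5 = 1.0, V6 = 0.85)
}

# Beat schedule and closed-form waveform evaluation (unit gain).
synth_wave_fun <- function(spec) {
  rr <- 60000 / spec$heart_rate_bpm
  wp <- spec$wave_params
  function(t_ms, n_beats) {
    r_centers <- spec$lead_in_ms + (seq_len(n_beats) - 1) * rr
    v <- numeric(length(t_ms))
    for (k in seq_len(n_beats)) {
      for (w in seq_len(nrow(wp))) {
        mu <- r_centers[k] + wp$offset_ms[w]
        v <- v + wp$amp_mv[w] * exp(-(t_ms - mu)^2 / (2 * wp$sigma_ms[w]^2))
      }
    }
    v
  }
}

synth_lead_names <- function(layout) {
  base <- c("I", "II", "III", "aVR", "aVL", "aVF",
            paste0("V", seq_len(layout$leads_per_column)))[
              c(seq_len(layout$leads_per_column),
                6L + seq_len(layout$leads_per_column))]
  if (layout$n_leads == 13L) c(base, paste0(layout$rhythm_lead, "-rhythm"))
  else base
}

#' Synthesize ground-truthed ECG signals
#'
#' Each beat is a sum of five Gaussian bumps (P, Q, R, S, T) on a zero
#' baseline, repeated at `60000 / heart_rate_bpm` ms; per-lead amplitudes
#' are scaled by `lead_gains` (the rhythm strip reuses its source lead's
#' gain and carries as many beats as fit the strip width). The fiducial
#' ground truth is the set of Gaussian centers.
#'
#' @param spec An [synthetic_spec()].
#' @return List with `leads` (named list of `ecg_signal` at `spec$fs`),
#'   `fiducials` (data.frame `lead`, `beat`, `p_ms` ... `t_ms`),
#'   `durations_ms`, and the beat spacing `rr_ms`.
#' @export
synthesize_ecg <- function(spec) {
  rr <- 60000 / spec$heart_rate_bpm
  wave <- synth_wave_fun(spec)
  names_all <- synth_lead_names(spec$layout)
  mid <- spec$page_px[2] %/% 2L
  trace_len <- trace_length_px(spec)
  dur_std <- trace_len * spec$ms_per_px
  rhythm_len <- (spec$page_px[2] - spec$margin_px) - spec$margin_px + 1L
  dur_rhythm <- rhythm_len * spec$ms_per_px
  wp <- spec$wave_params
  leads <- list()
  fid <- list()
  for (nm in names_all) {
    is_rhythm <- grepl("-rhythm$", nm)
    src <- sub("-rhythm$", "", nm)
    gain <- unname(spec$lead_gains[src])
    dur <- if (is_rhythm) dur_rhythm else dur_std
    nb <- if (is_rhythm)
      max(1L, floor((dur - spec$lead_in_ms - spec$tail_ms) / rr) + 1L)
    else spec$n_beats
    t_ms <- seq(0, dur, by = 1000 / spec$fs)
    leads[[nm]] <- ecg_signal(t = t_ms, v = gain * wave(t_ms, nb),
                              lead = nm, fs = spec$fs)
    r_centers <- spec$lead_in_ms + (seq_len(nb) - 1) * rr
    fid[[nm]] <- data.frame(
      lead = nm, beat = seq_len(nb),
      p_ms = r_centers + wp$offset_ms[1], q_ms = r_centers + wp$offset_ms[2],
      r_ms = r_centers, s_ms = r_centers + wp$offset_ms[4],
      t_ms = r_centers + wp$offset_ms[5], stringsAsFactors = FALSE)
  }
  list(leads = leads, fiducials = do.call(rbind, fid), rr_ms = rr,
       durations_ms = c(standard = dur_std, rhythm = dur_rhythm))
}

# usable trace length (px) of a standard (half-width) lead
trace_length_px <- function(spec) {
  mid <- spec$page_px[2] %/% 2L
  need <- ceiling((spec$lead_in_ms + (spec$n_beats - 1) * 60000 /
                     spec$heart_rate_bpm + spec$tail_ms) / spec$ms_per_px)
  avail <- mid - spec$margin_px - 9L
  if (need > avail)
    abort_ecg("ecg_spec_error", sprintf(
      "lead traces need %d px but only %d fit the half page", need, avail))
  need
}

# unrestricted square 8-neighborhood dilation
dilate8 <- function(sel) {
  nr <- nrow(sel); nc <- ncol(sel)
  up <- rbind(sel[-1L, , drop = FALSE], FALSE)
  down <- rbind(FALSE, sel[-nr, , drop = FALSE])
  vert <- sel | up | down
  left <- cbind(vert[, -1L, drop = FALSE], FALSE)
  right <- cbind(FALSE, vert[, -nc, drop = FALSE])
  vert | left | right
}

# draw a column-sampled curve into a logical stroke mask: each column is
# filled with the vertical run the continuous curve sweeps while crossing
# that column, i.e. from the left-boundary value through the column-center
# value to the right-boundary value (standard polyline rasterization;
# keeps the stroke 8-connected across columns)
draw_polyline <- function(stroke, cols, rows_center, rows_bound = NULL) {
  nr <- nrow(stroke)
  n <- length(cols)
  if (is.null(rows_bound)) # boundary j sits between columns j and j+1
    rows_bound <- (rows_center[-n] + rows_center[-1L]) / 2
  bl <- c(rows_center[1L], rows_bound)   # left boundary per column
  br <- c(rows_bound, rows_center[n])    # right boundary per column
  clamp <- function(r) pmin(pmax(round(r), 1L), nr)
  for (i in seq_len(n)) {
    lo <- clamp(min(bl[i], rows_center[i], br[i]))
    hi <- clamp(max(bl[i], rows_center[i], br[i]))
    stroke[lo:hi, cols[i]] <- TRUE
  }
  stroke
}

#' Render a synthetic printed-ECG page
#'
#' Draws the synthesized leads onto a light page in the two-column layout
#' (optional full-width rhythm strip at the bottom), with a faint
#' background grid, a lead-onset delimiter tick per row, the calibration
#' pulse left of the aVF lead, a few stray dark glyphs, Gaussian pixel
#' noise and an optional JPEG round trip. Every rendering parameter is
#' recorded in the returned ground truth.
#'
#' @param synth Output of [synthesize_ecg()] for the same `spec`.
#' @param spec The [synthetic_spec()].
#' @return List with `image` (an `ecg_raster`) and `truth`: `boxes`
#'   (data.frame of true band extents and trace column ranges per lead),
#'   `baselines`, `per_col` (named list of data.frames `col`, `t_ms`,
#'   `v_mv`, `row`), `scale` (the true `ecg_scale`), `fiducials`, `bpm`,
#'   `signals` (the synthesized `ecg_signal`s), and `spec`.
#' @export
render_page <- function(synth, spec) {
  nr <- spec$page_px[1]; nc <- spec$page_px[2]
  mid <- nc %/% 2L
  layout <- spec$layout
  n_bands <- layout$leads_per_column + (layout$n_leads == 13L)
  bh <- nr %/% n_bands
  hw <- (spec$trace_width_px - 1L) %/% 2L
  names_all <- synth_lead_names(layout)
  trace_len <- trace_length_px(spec)

  # deterministic rendering under the spec seed
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(spec$seed)

  canvas <- matrix(spec$paper_intensity, nr, nc)
  if (spec$grid_spacing_px > 0L) {
    gcols <- seq(1L, nc, by = spec$grid_spacing_px)
    grows <- seq(1L, nr, by = spec$grid_spacing_px)
    canvas[, gcols] <- pmin(canvas[, gcols], spec$grid_intensity)
    canvas[grows, ] <- pmin(canvas[grows, ], spec$grid_intensity)
  }

  stroke <- matrix(FALSE, nr, nc)
  boxes <- list(); baselines <- numeric(0); per_col <- list()
  for (i in seq_along(names_all)) {
    nm <- names_all[i]
    is_rhythm <- grepl("-rhythm$", nm)
    band <- if (is_rhythm) n_bands
            else if (i <= layout$leads_per_column) i
            else i - layout$leads_per_column
    half <- if (is_rhythm) "full" else if (i <= layout$leads_per_column) "left" else "right"
    band_top <- (band - 1L) * bh + 1L
    baseline <- band_top + round(0.5 * bh)
    col0 <- switch(half,
                   left = spec$margin_px,
                   right = mid + 31L,
                   full = spec$margin_px)
    len <- if (is_rhythm)
      (nc - spec$margin_px) - spec$margin_px + 1L else trace_len
    cols <- col0 + seq_len(len) - 1L
    if (max(cols) > nc || band_top + bh - 1L > nr)
      abort_ecg("ecg_spec_error", "lead boxes overflow the page")
    t_cols <- (seq_len(len) - 1L) * spec$ms_per_px
    sig <- synth$leads[[nm]]
    v_cols <- stats::approx(sig$t, sig$v, xout = t_cols, rule = 2)$y
    rows_real <- baseline - v_cols / spec$mv_per_px
    t_bound <- t_cols[-1L] - spec$ms_per_px / 2
    v_bound <- stats::approx(sig$t, sig$v, xout = t_bound, rule = 2)$y
    stroke <- draw_polyline(stroke, cols, rows_real,
                            rows_bound = baseline - v_bound / spec$mv_per_px)
    # lead-onset delimiter tick
    tick_rows <- max(1L, baseline - spec$tick_half_px):min(nr, baseline + spec$tick_half_px)
    stroke[tick_rows, col0:(col0 + 1L)] <- TRUE
    boxes[[nm]] <- data.frame(
      lead = nm, half = half, band = band,
      row_start = band_top, row_end = band_top + bh - 1L,
      col_start = cols[1L], col_end = cols[len],
      baseline_row = baseline, stringsAsFactors = FALSE)
    baselines[nm] <- baseline
    per_col[[nm]] <- data.frame(col = cols, t_ms = t_cols, v_mv = v_cols,
                                row = rows_real)
  }

  # calibration pulse left of aVF, plateau height pulse_mv, width pulse_ms
  avf_baseline <- baselines[["aVF"]]
  pw <- round(spec$pulse_ms / spec$ms_per_px)
  ph <- round(spec$pulse_mv / spec$mv_per_px)
  p_total <- pw + 2L * spec$pulse_tail_px
  p_start <- spec$margin_px - spec$pulse_gap_px - p_total
  if (p_start < 2L)
    abort_ecg("ecg_spec_error", "calibration pulse does not fit left of the traces")
  p_cols <- p_start + seq_len(p_total) - 1L
  p_rows <- rep(avf_baseline, p_total)
  plateau <- seq(spec$pulse_tail_px + 1L, spec$pulse_tail_px + pw)
  p_rows[plateau] <- avf_baseline - ph
  pulse_truth <- data.frame(col_start = p_cols[1L], col_end = p_cols[p_total],
                            row_top = avf_baseline - ph, row_bottom = avf_baseline,
                            height_px = ph, plateau_px = pw)
  # step semantics: the level changes exactly at the column boundary
  stroke <- draw_polyline(stroke, p_cols, p_rows,
                          rows_bound = p_rows[-length(p_rows)])

  if (hw > 0L) for (k in seq_len(hw)) stroke <- dilate8(stroke)

  # stray glyphs in the page margins (left strip and inter-column gap),
  # drawn at final size (after stroke dilation) so they stay small objects
  if (spec$n_glyphs > 0L) {
    avf_band <- boxes[["aVF"]]
    for (g in seq_len(spec$n_glyphs)) {
      gh <- sample(3:5, 1L); gw <- sample(4:7, 1L)
      strip <- sample(c("left", "gap"), 1L)
      gc <- if (strip == "left") sample(5:(p_start - gw - 3L), 1L)
            else sample((mid + 3L):(mid + 28L - gw), 1L)
      repeat {
        gr <- sample(5:(nr - gh - 4L), 1L)
        # keep left-strip glyphs clear of the calibration-pulse band
        if (strip == "gap" || gr > avf_band$row_end || gr + gh < avf_band$row_start) break
      }
      stroke[gr:(gr + gh), gc:(gc + gw)] <- TRUE
    }
  }

  canvas[stroke] <- spec$trace_intensity

  if (spec$noise_sd > 0) {
    canvas <- canvas + matrix(rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
    canvas <- pmin(pmax(canvas, 0), 1)
  }
  if (!is.null(spec$jpeg_quality)) {
    tf <- tempfile(fileext = ".jpg")
    on.exit(unlink(tf), add = TRUE)
    jpeg::writeJPEG(canvas, tf, quality = spec$jpeg_quality)
    canvas <- luminance(jpeg::readJPEG(tf))
  }

  truth <- list(
    boxes = do.call(rbind, boxes), baselines = baselines, per_col = per_col,
    scale = calibration_scale(spec$mv_per_px, spec$ms_per_px, source = "config"),
    pulse = pulse_truth,
    fiducials = synth$fiducials, bpm = spec$heart_rate_bpm,
    signals = synth$leads, rr_ms = synth$rr_ms, spec = spec)
  rownames(truth$boxes) <- NULL
  list(image = raster_image(canvas), truth = truth)
}

#' Synthesize and render in one call
#'
#' @param spec An [synthetic_spec()].
#' @return See [render_page()].
#' @export
render_ecg_page <- function(spec = synthetic_spec()) {
  render_page(synthesize_ecg(spec), spec)
}
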