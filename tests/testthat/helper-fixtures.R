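# Shared rendered-page fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture_page <- function() {
  if (is.null(.fixture_env$page))
    .fixture_env$page <- render_ecg_page(synthetic_spec(seed = 42L))
  .fixture_env$page
}

fixture_digitization <- function() {
  if (is.null(.fixture_env$digit))
    .fixture_env$digit <- digitize_page(fixture_page()$image)
  .fixture_env$digit
}

# per-lead round-trip correlation of a digitization against its page truth,
# both members resampled to n points over the overlapping columns
roundtrip_rhos <- function(digit, truth, n = 1000L) {
  sapply(names(digit$leads), function(nm) {
    ld <- digit$leads[[nm]]
    pc <- truth$per_col[[nm]]
    cols <- intersect(pc$col, ld$box$col_start:ld$box$col_end)
    v_true <- pc$v_mv[match(cols, pc$col)]
    v_rec <- ld$signal$v[cols - ld$box$col_start + 1L]
    t_axis <- (seq_along(cols) - 1L) * truth$scale$ms_per_px
    pearson(resample_signal(ecg_signal(t_axis, v_true, lead = nm), n),
            resample_signal(ecg_signal(t_axis, v_rec, lead = nm), n))
  })
}

# a small synthesized clean signal (no rendering) for fiducial tests
fixture_signal <- function(heart_rate = 60, fs = 500, n_beats = 4L,
                           lead = "II") {
  spec <- synthetic_spec(heart_rate_bpm = heart_rate, fs = fs,
                         n_beats = n_beats,
                         page_px = c(1147L, 2200L))  # room for slow rates
  synthesize_ecg(spec)$leads[[lead]]
}
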