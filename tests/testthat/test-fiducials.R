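test_that("pan_tompkins_qrs locates R peaks of a clean 60-bpm ECG", {
  sig <- fixture_signal(heart_rate = 60, fs = 500, n_beats = 4L)
  spec <- synthetic_spec(heart_rate_bpm = 60, fs = 500, n_beats = 4L,
                         page_px = c(1147L, 2200L))
  truth <- synthesize_ecg(spec)$fiducials
  truth <- truth[truth$lead == "II", ]
  qrs <- pan_tompkins_qrs(sig)
  expect_equal(nrow(qrs), 4L)
  # 1000 ms spacing at fs = 500: exactly 500 samples apart, +/- 1 sample
  expect_true(all(abs(diff(qrs$r_idx) - 500) <= 1))
  r_true <- round(truth$r_ms / 1000 * 500) + 1L
  expect_true(all(abs(qrs$r_idx - r_true) <= 1))
  # beat order q < r < s within each beat
  expect_true(all(qrs$q_idx < qrs$r_idx & qrs$r_idx < qrs$s_idx))
})

test_that("pan_tompkins_qrs errors on flat input and shifts with the signal", {
  flat <- ecg_signal(t = (0:999) * 2, v = rep(0, 1000))
  expect_error(pan_tompkins_qrs(flat), class = "ecg_fiducial_error")

  sig <- fixture_signal(heart_rate = 72, fs = 500)
  n_cut <- 50L   # keep the first beat inside the trimmed record
  shifted <- ecg_signal(t = sig$t[-(1:n_cut)] - sig$t[n_cut + 1],
                        v = sig$v[-(1:n_cut)], lead = sig$lead)
  r0 <- pan_tompkins_qrs(sig)$r_idx
  r1 <- pan_tompkins_qrs(shifted)$r_idx
  expect_equal(r1, r0[seq_along(r1)] - n_cut)
})

test_that("locate_pt finds P and T at the programmed offsets", {
  fs <- 500
  sig <- fixture_signal(heart_rate = 60, fs = fs)
  spec <- synthetic_spec(heart_rate_bpm = 60, fs = fs,
                         page_px = c(1147L, 2200L))
  truth <- synthesize_ecg(spec)$fiducials
  truth <- truth[truth$lead == "II", ]
  fid <- locate_pt(sig, pan_tompkins_qrs(sig))
  expect_s3_class(fid, "ecg_fiducials")
  expect_equal(nrow(fid$beats), 4L)
  expect_true(all(abs(fid$beats$p_idx - (round(truth$p_ms / 1000 * fs) + 1)) <= 2))
  expect_true(all(abs(fid$beats$t_idx - (round(truth$t_ms / 1000 * fs) + 1)) <= 2))
  # fiducial ordering invariant
  b <- fid$beats
  expect_true(all(b$p_idx < b$q_idx & b$q_idx < b$r_idx &
                  b$r_idx < b$s_idx & b$s_idx < b$t_idx))
})

test_that("locate_pt drops beats without T and errors when none remain", {
  # single bump train: no positive deflection after S
  t <- (0:2999) * 2
  v <- numeric(3000)
  for (ctr in c(500, 1500, 2500)) v <- v + exp(-((t - t[ctr])^2) / (2 * 15^2))
  sig <- ecg_signal(t, v)
  qrs <- pan_tompkins_qrs(sig)
  expect_warning(
    expect_error(locate_pt(sig, qrs), class = "ecg_fiducial_error"),
    class = "ecg_fiducial_warning")
})

test_that("locate_pt takes the higher T peak, the earlier on exact ties", {
  fs <- 500
  t <- (0:1999) * (1000 / fs)
  beat <- function(r_ms, t1_amp, t2_amp) {
    exp(-(t - r_ms)^2 / (2 * 10^2)) +
      t1_amp * exp(-(t - r_ms - 250)^2 / (2 * 25^2)) +
      t2_amp * exp(-(t - r_ms - 330)^2 / (2 * 25^2)) +
      0.1 * exp(-(t - r_ms + 160)^2 / (2 * 20^2))   # P
  }
  v <- beat(1000, 0.2, 0.3) + beat(2000, 0.2, 0.3)
  sig <- ecg_signal(t, v)
  fid <- locate_pt(sig, pan_tompkins_qrs(sig))
  # the higher (later) bump wins
  expect_true(all(abs(fid$beats$t_idx - (c(1330, 2330) / 2 + 1)) <= 3))

  # exact symmetric tie: earlier peak chosen
  v2 <- beat(1000, 0.25, 0.25) + beat(2000, 0.25, 0.25)
  fid2 <- locate_pt(ecg_signal(t, v2), pan_tompkins_qrs(ecg_signal(t, v2)))
  expect_true(all(abs(fid2$beats$t_idx - (c(1250, 2250) / 2 + 1)) <= 3))
})

test_that("ecg_intervals computes single-beat and per-beat values", {
  # arithmetic by construction: indices at a known sampling rate
  fid <- structure(list(
    beats = data.frame(p_idx = 21L, q_idx = 101L, r_idx = 126L,
                       s_idx = 151L, t_idx = 301L),
    all_r_idx = c(126L, 626L, 1126L), fs = 500, lead = "II"),
    class = "ecg_fiducials")
  iv <- ecg_intervals(fid)
  expect_equal(iv$qrs_ms, (151 - 101) * 2)      # 100 ms
  expect_equal(iv$qt_ms, (301 - 101) * 2)       # 400 ms
  expect_equal(iv$pr_ms, (101 - 21) * 2)        # 160 ms
  expect_equal(iv$rr_ms, 1000)
  expect_equal(iv$heart_rate_bpm, 60)
  expect_length(iv$per_beat$rr_ms, 2L)

  fid$all_r_idx <- 126L
  expect_error(ecg_intervals(fid), class = "ecg_fiducial_error")
})

test_that("programmed intervals are recovered from clean synthesis", {
  fs <- 500
  sig <- fixture_signal(heart_rate = 60, fs = fs)
  fid <- locate_pt(sig, pan_tompkins_qrs(sig))
  iv <- ecg_intervals(fid, sig)
  tol <- 2 * 1000 / fs   # +/- 2 samples
  expect_lte(abs(iv$pr_ms - 160), tol)
  expect_lte(abs(iv$qrs_ms - 90), tol)
  expect_lte(abs(iv$qt_ms - 380), tol)
  expect_equal(iv$rr_ms, 1000, tolerance = tol / 1000)
  # all interval outputs positive and bounded by the record duration
  dur <- max(sig$t)
  expect_true(all(unlist(iv$per_beat) > 0 & unlist(iv$per_beat) < dur))
})

test_that("fiducials are source-agnostic: truth vs digitized RR agree", {
  pg <- fixture_page()
  d <- fixture_digitization()
  for (nm in c("II", "V1")) {
    ref <- pg$truth$signals[[nm]]
    rr_ref <- ecg_intervals(locate_pt(ref, pan_tompkins_qrs(ref)), ref)
    rr_dig <- d$leads[[nm]]$intervals
    expect_equal(round(60000 / mean(rr_dig$per_beat$rr_ms)),
                 round(60000 / mean(rr_ref$per_beat$rr_ms)))
  }
  expect_equal(round(heart_rate(pg$truth$signals[["II"]])), 72)
})
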