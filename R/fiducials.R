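# Linear-phase band-pass FIR (Hamming-windowed sinc), applied centered so
# no group-delay compensation is needed. Edges are padded by replication.
fir_bandpass <- function(x, fs, low = 5, high = 15, taps = NULL) {
  if (is.null(taps)) taps <- 2L * floor(0.2 * fs) + 1L  # ~400 ms support
  m <- (taps - 1L) / 2L
  k <- seq(-m, m)
  sinc <- function(f) {
    out <- 2 * f / fs * rep(1, length(k))
    nz <- k != 0
    out[nz] <- sin(2 * pi * f * k[nz] / fs) / (pi * k[nz])
    out
  }
  h <- (sinc(high) - sinc(low)) * (0.54 + 0.46 * cos(pi * k / m))
  xp <- c(rep(x[1L], m), x, rep(x[length(x)], m))
  as.numeric(stats::filter(xp, h, sides = 2L))[(m + 1L):(m + length(x))]
}

#' Pan-Tompkins QRS detection
#'
#' The classic chain: 5-15 Hz band-pass, centered 5-point derivative,
#' squaring, 150 ms moving-window integration, then adaptive dual
#' thresholds (signal/noise estimates updated with factors 0.125/0.25) with
#' a 200 ms refractory period and a search-back pass at half threshold when
#' an RR gap exceeds 1.66 times the running average. Each detection is
#' refined to the largest absolute deflection of the original signal within
#' +/-75 ms; Q and S are the minima within 80 ms before/after R.
#'
#' @param sig An `ecg_signal` spanning at least 2 beats.
#' @param refine_ms Half-width of the R refinement window (default 75).
#' @param qs_ms Q/S search window in ms (default 80).
#' @return A data.frame with one row per beat: `q_idx`, `r_idx`, `s_idx`
#'   (1-based sample indices, ordered).
#' @export
pan_tompkins_qrs <- function(sig, refine_ms = 75, qs_ms = 80) {
  v <- sig$v
  fs <- sig$fs
  n <- length(v)
  bp <- fir_bandpass(v, fs)
  d <- c(0, 0, (2 * bp[-(1:2)][seq_len(n - 4L)] + bp[-(1:4)] -
                2 * bp[seq_len(n - 4L) + 1L] - bp[seq_len(n - 4L)]) / 8, 0, 0)
  sq <- d^2
  w <- max(1L, round(0.150 * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2L))
  mwi[is.na(mwi)] <- 0

  locmax <- which(diff(c(-Inf, mwi)) > 0 & diff(c(mwi, -Inf)) <= 0)
  locmax <- locmax[mwi[locmax] > 0]
  if (length(locmax) == 0L)
    abort_ecg("ecg_fiducial_error", "no activity found: cannot detect beats")

  # adaptive thresholds initialized from the first 2 s
  init <- mwi[seq_len(min(n, round(2 * fs)))]
  spki <- max(init) * 0.5
  npki <- mean(init) * 0.5
  refract <- round(0.2 * fs)
  peaks <- integer(0)
  for (i in locmax) {
    thr <- npki + 0.25 * (spki - npki)
    if (mwi[i] > thr && (length(peaks) == 0L || i - peaks[length(peaks)] > refract)) {
      peaks <- c(peaks, i)
      spki <- 0.125 * mwi[i] + 0.875 * spki
    } else {
      npki <- 0.125 * mwi[i] + 0.875 * npki
    }
  }
  # search-back over long RR gaps at half threshold
  if (length(peaks) >= 2L) {
    repeat {
      rr <- diff(peaks)
      avg <- mean(rr)
      gap <- which(rr > 1.66 * avg)
      added <- FALSE
      for (g in gap) {
        lo <- peaks[g] + refract
        hi <- peaks[g + 1L] - refract
        cand <- locmax[locmax > lo & locmax < hi]
        thr2 <- 0.5 * (npki + 0.25 * (spki - npki))
        cand <- cand[mwi[cand] > thr2]
        if (length(cand)) {
          peaks <- sort(c(peaks, cand[which.max(mwi[cand])]))
          added <- TRUE
          break
        }
      }
      if (!added) break
    }
  }
  if (length(peaks) < 2L)
    abort_ecg("ecg_fiducial_error", sprintf(
      "only %d R peak(s) found; at least 2 required", length(peaks)))

  # refine R on the original signal (largest absolute deflection)
  ctr <- stats::median(v)
  half <- as.integer(round(refine_ms / 1000 * fs))
  r_idx <- vapply(peaks, function(p) {
    lo <- max(1L, p - half); hi <- min(n, p + half)
    lo + which.max(abs(v[lo:hi] - ctr)) - 1L
  }, integer(1))
  r_idx <- sort(unique(r_idx))

  qs <- as.integer(round(qs_ms / 1000 * fs))
  q_idx <- vapply(r_idx, function(r) {
    lo <- max(1L, r - qs)
    if (lo >= r) return(NA_integer_)
    lo + which.min(v[lo:(r - 1L)]) - 1L
  }, integer(1))
  s_idx <- vapply(r_idx, function(r) {
    hi <- min(n, r + qs)
    if (hi <= r) return(NA_integer_)
    r + which.min(v[(r + 1L):hi])
  }, integer(1))
  ok <- !is.na(q_idx) & !is.na(s_idx)
  data.frame(q_idx = q_idx[ok], r_idx = r_idx[ok], s_idx = s_idx[ok])
}

# indices of local maxima, plateau-aware: a run of equal values counts as
# one maximum (its first index) when strictly above both neighbours
local_maxima <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  i <- 2:(k - 1L)
  hit <- r$values[i] > r$values[i - 1L] & r$values[i] > r$values[i + 1L]
  starts[i][hit]
}

#' Locate P and T waves around detected QRS complexes
#'
#' P is the local maximum nearest before Q (searched back to the previous
#' beat's T, or the start of the record); T is the highest local maximum
#' within `t_window_ms` after S (exact ties resolve to the earlier peak).
#' Beats missing either wave are dropped with a warning.
#'
#' @param sig An `ecg_signal`.
#' @param qrs Per-beat q/r/s indices from [pan_tompkins_qrs()].
#' @param t_window_ms T search window after S in ms (default 400).
#' @return An object of class `ecg_fiducials`: list with `beats` (data.frame
#'   of `p_idx`, `q_idx`, `r_idx`, `s_idx`, `t_idx`) and the signal's `fs`.
#' @export
locate_pt <- function(sig, qrs, t_window_ms = 400) {
  if (nrow(qrs) == 0L)
    abort_ecg("ecg_fiducial_error", "no beats supplied")
  v <- sig$v
  n <- length(v)
  fs <- sig$fs
  tw <- round(t_window_ms / 1000 * fs)
  peaks <- local_maxima(v)
  out <- vector("list", nrow(qrs))
  prev_t <- 0L
  for (b in seq_len(nrow(qrs))) {
    q <- qrs$q_idx[b]; r <- qrs$r_idx[b]; s <- qrs$s_idx[b]
    p_cand <- peaks[peaks > prev_t & peaks < q]
    p <- if (length(p_cand)) max(p_cand) else NA_integer_
    t_cand <- peaks[peaks > s & peaks <= min(n, s + tw)]
    t_pt <- if (length(t_cand)) {
      t_cand[which.max(v[t_cand])]   # which.max: earlier index on exact tie
    } else NA_integer_
    if (!is.na(t_pt)) prev_t <- t_pt else prev_t <- s
    out[[b]] <- data.frame(p_idx = p, q_idx = q, r_idx = r, s_idx = s, t_idx = t_pt)
  }
  beats <- do.call(rbind, out)
  complete <- stats::complete.cases(beats)
  if (any(!complete))
    warn_ecg("ecg_fiducial_warning", sprintf(
      "%d beat(s) dropped: missing P or T wave", sum(!complete)))
  all_r <- beats$r_idx
  beats <- beats[complete, , drop = FALSE]
  if (nrow(beats) == 0L)
    abort_ecg("ecg_fiducial_error", "every beat is missing a P or T wave")
  rownames(beats) <- NULL
  structure(list(beats = beats, all_r_idx = all_r, fs = fs, lead = sig$lead),
            class = "ecg_fiducials")
}

#' @export
print.ecg_fiducials <- function(x, ...) {
  cat(sprintf("<ecg_fiducials> lead %s: %d complete beat(s), %d R peak(s)\n",
              x$lead, nrow(x$beats), length(x$all_r_idx)))
  invisible(x)
}

#' PR, QRS, QT and RR intervals
#'
#' Per-beat intervals in ms (PR = Q - P, QRS = S - Q, QT = T - Q, RR =
#' successive R differences over all detected beats), plus single-beat
#' values taken from the first complete beat, following the single-beat
#' protocol used for validation.
#'
#' @param fid An `ecg_fiducials` from [locate_pt()].
#' @param sig The `ecg_signal` the fiducials came from (for its sampling).
#' @return List with scalars `pr_ms`, `qrs_ms`, `qt_ms`, `rr_ms`,
#'   `heart_rate_bpm`, and per-beat vectors under `per_beat`.
#' @export
ecg_intervals <- function(fid, sig = NULL) {
  fs <- if (!is.null(sig)) sig$fs else fid$fs
  msps <- 1000 / fs
  b <- fid$beats
  if (nrow(b) < 1L)
    abort_ecg("ecg_fiducial_error", "no complete beat: PR/QRS/QT undefined")
  if (length(fid$all_r_idx) < 2L)
    abort_ecg("ecg_fiducial_error", "fewer than 2 R peaks: RR undefined")
  pr <- (b$q_idx - b$p_idx) * msps
  qrs <- (b$s_idx - b$q_idx) * msps
  qt <- (b$t_idx - b$q_idx) * msps
  rr <- diff(fid$all_r_idx) * msps
  list(pr_ms = pr[1L], qrs_ms = qrs[1L], qt_ms = qt[1L], rr_ms = rr[1L],
       heart_rate_bpm = 60000 / mean(rr),
       per_beat = list(pr_ms = pr, qrs_ms = qrs, qt_ms = qt, rr_ms = rr))
}

#' Heart rate from an already-digitized signal
#'
#' Convenience wrapper: Pan-Tompkins R detection followed by
#' `60000 / mean(RR)`.
#'
#' @param sig An `ecg_signal` with at least 2 beats.
#' @return Heart rate in bpm.
#' @export
heart_rate <- function(sig) {
  qrs <- pan_tompkins_qrs(sig)
  rr <- diff(qrs$r_idx) * 1000 / sig$fs
  60000 / mean(rr)
}
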