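#' Sliding-window standard-deviation profile over rows
#'
#' Slides a mask of `window` rows (all columns wide) down the image and
#' records, for each center row, the standard deviation of all pixels under
#' the mask. Rows crossed by a printed trace mix dark and light pixels and
#' stand out as humps of the profile; one hump per printed signal row.
#'
#' The window is clipped (shrunk) at the first/last `floor(window/2)`
#' positions. `mode = "pooled"` (default) is the standard deviation over all
#' pixels in the window; `mode = "mean_row_sd"` averages the per-row
#' standard deviations instead.
#'
#' @param img An `ecg_raster` (or numeric matrix).
#' @param window Odd window size in rows (default 5).
#' @param mode `"pooled"` or `"mean_row_sd"`.
#' @return Numeric vector of length `nrow(img)` with attribute `axis = "rows"`.
#' @export
row_std_profile <- function(img, window = 5L, mode = c("pooled", "mean_row_sd")) {
  mode <- match.arg(mode)
  m <- as_pixel_matrix(img)
  check_window(window, nrow(m))
  n <- nrow(m)
  h <- window %/% 2L
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  if (mode == "pooled") {
    rs1 <- rowSums(m)
    rs2 <- rowSums(m^2)
    c1 <- cumsum(rs1); c2 <- cumsum(rs2)
    s1 <- c1[hi] - c(0, c1)[lo]
    s2 <- c2[hi] - c(0, c2)[lo]
    cnt <- (hi - lo + 1L) * ncol(m)
    # sample variance, guarded against tiny negative round-off
    v <- pmax((s2 - s1^2 / cnt) / (cnt - 1L), 0)
    out <- sqrt(v)
  } else {
    per_row <- apply(m, 1L, stats::sd)
    cp <- cumsum(per_row)
    out <- (cp[hi] - c(0, cp)[lo]) / (hi - lo + 1L)
  }
  structure(out, axis = "rows")
}

# shared window validation
check_window <- function(window, limit) {
  if (length(window) != 1L || is.na(window) || window %% 2L == 0L || window < 1L)
    abort_ecg("ecg_param_error", "window must be a positive odd integer")
  if (window > limit)
    abort_ecg("ecg_param_error", sprintf("window (%d) exceeds image extent (%d)", window, limit))
  invisible(TRUE)
}

#' Column-wise standard-deviation profile
#'
#' Same statistic as [row_std_profile()] with the mask slid along columns;
#' used to find where the traces begin at the left page margin.
#'
#' @inheritParams row_std_profile
#' @param cols Columns to scan (default: all).
#' @return Numeric vector (one value per scanned column), attribute `axis = "cols"`.
#' @export
col_std_profile <- function(img, window = 5L, cols = NULL,
                            mode = c("pooled", "mean_row_sd")) {
  m <- as_pixel_matrix(img)
  if (!is.null(cols)) m <- m[, cols, drop = FALSE]
  p <- row_std_profile(t(m), window = window, mode = match.arg(mode))
  structure(as.numeric(p), axis = "cols")
}

#' Detect peaks of a standard-deviation profile
#'
#' Keeps local maxima whose value is at least `height_frac` times the
#' profile maximum (half of the maximum by default) and enforces a minimum
#' peak-to-peak distance exceeding `min_dist_frac` of the profile length;
#' when two candidates are closer than that, the higher one is kept (ties:
#' the earlier one).
#'
#' @param profile Numeric vector (e.g. from [row_std_profile()]).
#' @param height_frac Fraction of the maximum a peak must reach (default 0.5).
#' @param min_dist_frac Minimum separation as a fraction of `length(profile)`.
#' @return Integer vector of peak positions, sorted ascending (possibly empty).
#' @export
detect_profile_peaks <- function(profile, height_frac = 0.5, min_dist_frac = 0.05) {
  p <- as.numeric(profile)
  n <- length(p)
  if (n == 0L) abort_ecg("ecg_param_error", "empty profile")
  mx <- max(p)
  if (mx <= 0) return(integer(0))
  # local maxima: strictly above the previous run, >= the next value;
  # plateaus resolve to their first position
  cand <- which(diff(c(-Inf, p)) > 0 & diff(c(p, -Inf)) <= 0)
  cand <- cand[p[cand] >= height_frac * mx & p[cand] > 0]
  if (length(cand) == 0L) return(integer(0))
  min_dist <- min_dist_frac * n
  # greedy suppression by height (ties: earlier index wins)
  ord <- cand[order(-p[cand], cand)]
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(kept - i) > min_dist)) kept <- c(kept, i)
  }
  sort(kept)
}

#' Locate the left margin of the traces
#'
#' Slides a `window`-column standard-deviation mask over the first
#' `col_frac` of the columns and returns the column with the maximum value,
#' which marks where the printed traces start. Ties resolve to the first
#' occurrence. A degenerate (all-zero) profile returns column 1 with a
#' warning.
#'
#' @inheritParams row_std_profile
#' @param col_frac Fraction of columns to scan from the left (default 0.10).
#' @return A single 1-based column index.
#' @export
left_margin <- function(img, window = 5L, col_frac = 0.10) {
  m <- as_pixel_matrix(img)
  n_scan <- floor(col_frac * ncol(m))
  if (n_scan < window)
    abort_ecg("ecg_param_error", sprintf(
      "scan region (%d cols) smaller than window (%d)", n_scan, window))
  prof <- col_std_profile(m, window = window, cols = seq_len(n_scan))
  if (max(prof) <= 0) {
    warn_ecg("ecg_degenerate_warning", "left-margin profile is all zero; returning column 1")
    return(1L)
  }
  which.max(prof)
}

#' Detect one bounding box per lead
#'
#' Runs the row-profile peak detection and left-margin scan on the left
#' half of the page, repeats the procedure on the horizontally mirrored
#' image for the right half (mapping columns back), and converts each row
#' peak into a box: vertical extent from the midpoint to the neighbouring
#' peaks (outermost boxes extend to where the profile falls below
#' `edge_frac` of its maximum), horizontal extent from the detected margin
#' to the page midline (left half) or from the midline to the mirrored
#' margin (right half). With a 13-lead layout the bottom row of both halves
#' is the rhythm strip and is merged into one full-width box.
#'
#' @param img An `ecg_raster` of a full ECG page.
#' @param layout An [layout_config()].
#' @param window Mask size in px (default 5).
#' @param height_frac,min_dist_frac Passed to [detect_profile_peaks()].
#' @param col_frac Passed to [left_margin()].
#' @param edge_frac Profile fraction bounding the outermost boxes (default 0.10).
#' @param mode Profile statistic, see [row_std_profile()].
#' @return An object of class `ecg_boxset`: a data.frame with columns
#'   `lead`, `half` (`"left"|"right"|"full"`), `row_start`, `row_end`,
#'   `col_start`, `col_end`.
#' @export
detect_lead_boxes <- function(img, layout = layout_config(), window = 5L,
                              height_frac = 0.5, min_dist_frac = 0.05,
                              col_frac = 0.10, edge_frac = 0.10,
                              mode = c("pooled", "mean_row_sd")) {
  mode <- match.arg(mode)
  m <- as_pixel_matrix(img)
  nr <- nrow(m); nc <- ncol(m)
  mid <- nc %/% 2L
  n_expect <- layout$leads_per_column + (layout$n_leads == 13L)

  half_boxes <- function(mm) {
    prof <- row_std_profile(mm[, seq_len(mid), drop = FALSE], window = window, mode = mode)
    peaks <- detect_profile_peaks(prof, height_frac, min_dist_frac)
    if (length(peaks) != n_expect)
      abort_ecg("ecg_detection_error", sprintf(
        "found %d signal rows, expected %d for the configured layout",
        length(peaks), n_expect))
    margin <- left_margin(mm, window = window, col_frac = col_frac)
    list(prof = prof, peaks = peaks, margin = margin)
  }

  left <- half_boxes(m)
  right <- half_boxes(m[, nc:1, drop = FALSE])

  row_extents <- function(prof, peaks) {
    k <- length(peaks)
    cutoff <- edge_frac * max(prof)
    starts <- ends <- integer(k)
    for (i in seq_len(k)) {
      starts[i] <- if (i == 1L) {
        below <- which(prof[seq_len(peaks[1L])] < cutoff)
        if (length(below)) max(below) + 1L else 1L
      } else floor((peaks[i - 1L] + peaks[i]) / 2) + 1L
      ends[i] <- if (i == k) {
        below <- which(prof[peaks[k]:length(prof)] < cutoff)
        if (length(below)) peaks[k] + min(below) - 2L else length(prof)
      } else floor((peaks[i] + peaks[i + 1L]) / 2)
    }
    cbind(start = pmax(starts, 1L), end = pmin(ends, length(prof)))
  }

  ext_l <- row_extents(left$prof, left$peaks)
  ext_r <- row_extents(right$prof, right$peaks)
  col_l <- c(left$margin, mid)
  col_r <- c(mid + 1L, nc - right$margin + 1L)

  left_labels <- c("I", "II", "III", "aVR", "aVL", "aVF")[seq_len(layout$leads_per_column)]
  right_labels <- paste0("V", seq_len(layout$leads_per_column))

  n_sig <- layout$leads_per_column
  df <- data.frame(
    lead = c(left_labels, right_labels),
    half = rep(c("left", "right"), each = n_sig),
    row_start = c(ext_l[seq_len(n_sig), "start"], ext_r[seq_len(n_sig), "start"]),
    row_end = c(ext_l[seq_len(n_sig), "end"], ext_r[seq_len(n_sig), "end"]),
    col_start = c(rep(col_l[1L], n_sig), rep(col_r[1L], n_sig)),
    col_end = c(rep(col_l[2L], n_sig), rep(col_r[2L], n_sig)),
    stringsAsFactors = FALSE)

  if (layout$n_leads == 13L) {
    df <- rbind(df, data.frame(
      lead = paste0(layout$rhythm_lead, "-rhythm"), half = "full",
      row_start = ext_l[n_expect, "start"], row_end = ext_l[n_expect, "end"],
      col_start = col_l[1L], col_end = col_r[2L], stringsAsFactors = FALSE))
  }
  rownames(df) <- NULL
  structure(df, class = c("ecg_boxset", "data.frame"),
            margins = c(left = left$margin, right_mapped = nc - right$margin + 1L),
            mid = mid)
}

#' @export
print.ecg_boxset <- function(x, ...) {
  cat(sprintf("<ecg_boxset> %d lead boxes (page midline at col %d)\n",
              nrow(x), attr(x, "mid")))
  print.data.frame(x, ...)
  invisible(x)
}

# Extract one row of an ecg_boxset as an ecg_box.
boxset_box <- function(boxes, i) {
  bounding_box(boxes$row_start[i], boxes$row_end[i],
               boxes$col_start[i], boxes$col_end[i])
}
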