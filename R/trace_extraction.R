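#' Otsu threshold of an intensity image
#'
#' Exhaustively searches the 256-bin intensity histogram for the threshold
#' maximizing the between-class variance. When several thresholds attain
#' the maximum (perfectly separable classes yield a plateau) the midpoint
#' of the plateau is returned.
#'
#' @param x Numeric vector or matrix of intensities in `[0, 1]`.
#' @return Threshold value in `[0, 1]` (bin value / 255).
#' @export
otsu_threshold <- function(x) {
  v <- as.numeric(x)
  if (max(v) - min(v) <= 0)
    abort_ecg("ecg_degenerate_error", "constant intensities: Otsu threshold undefined")
  bins <- pmin(floor(v * 256), 255)
  h <- tabulate(bins + 1L, nbins = 256L)
  n <- length(v)
  w0 <- cumsum(h) / n                         # class 0 = bins <= k
  mu <- cumsum(h * (0:255)) / n
  mu_t <- mu[256L]
  k <- 0:254
  w0k <- w0[k + 1L]
  valid <- w0k > 0 & w0k < 1
  sb <- rep(-Inf, 255L)
  sb[valid] <- (mu_t * w0k[valid] - mu[k + 1L][valid])^2 /
    (w0k[valid] * (1 - w0k[valid]))
  best <- which(sb >= max(sb) - 1e-12)        # plateau of maximizers
  k_star <- round(mean(range(best - 1L)))
  k_star / 255
}

#' Binarize an inverted lead crop
#'
#' Applies Otsu's threshold scaled by `otsu_scale` (1.2 by default, which
#' removes the faint background grid while keeping the dark trace, here
#' bright after color inversion). A pixel is set when its intensity exceeds
#' `min(1, otsu_scale * t*)`.
#'
#' @param crop Numeric matrix: the color-inverted lead region (signal bright).
#' @param otsu_scale Multiplier applied to the automatic threshold.
#' @return Logical matrix of the crop's shape.
#' @export
binarize <- function(crop, otsu_scale = 1.2) {
  m <- as_pixel_matrix(crop)
  t_star <- otsu_threshold(m)
  m > min(1, otsu_scale * t_star)
}

#' Label connected components of a binary mask
#'
#' 8-connected labeling; ids follow raster scan order of each component's
#' first pixel.
#'
#' @param mask Logical matrix.
#' @return Integer matrix of the same shape; 0 = background.
#' @export
label_components <- function(mask) {
  if (!is.logical(mask)) storage.mode(mask) <- "logical"
  .cpp_label_components(mask)
}

#' Remove small connected components
#'
#' Components (8-connectivity) whose pixel count falls below `min_frac`
#' times the size of the largest component are treated as noise (grid
#' remnants, stray glyphs) and cleared. The largest component always
#' survives.
#'
#' @param mask Logical matrix.
#' @param min_frac Relative size cutoff (default 0.02).
#' @return Cleaned logical matrix.
#' @export
remove_small_objects <- function(mask, min_frac = 0.02) {
  if (!is.logical(mask)) storage.mode(mask) <- "logical"
  if (!any(mask)) {
    warn_ecg("ecg_degenerate_warning", "mask has no foreground pixels; returned unchanged")
    return(mask)
  }
  lab <- .cpp_label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_frac * max(sizes))
  out <- matrix(lab %in% keep & mask, nrow(mask), ncol(mask))
  out
}

#' Estimate the isoelectric centerline of a lead crop
#'
#' A Hough transform restricted to almost-horizontal lines (within
#' `angle_tol_deg` of horizontal, scanned in `angle_step`-degree steps at
#' 1-px distance resolution) votes over the cleaned mask; every accumulator
#' cell reaching `accum_frac` of the strongest cell counts as a detected
#' line. The centerline is the median of the detected lines' row intercepts
#' evaluated at the crop's horizontal midpoint. If no usable line is found
#' the row with the most foreground pixels is returned instead.
#'
#' @param mask Logical matrix with at least one `TRUE` pixel.
#' @param angle_tol_deg Maximum deviation from horizontal, degrees (default 5).
#' @param angle_step Angular resolution in degrees (default 0.5).
#' @param accum_frac Accumulator fraction defining a detected line (default 0.5).
#' @return Real-valued row coordinate of the centerline.
#' @export
centerline <- function(mask, angle_tol_deg = 5, angle_step = 0.5, accum_frac = 0.5) {
  if (!is.logical(mask)) storage.mode(mask) <- "logical"
  idx <- which(mask)
  if (length(idx) == 0L)
    abort_ecg("ecg_extraction_error", "empty mask: no trace to locate")
  nr <- nrow(mask)
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  thetas <- seq(-angle_tol_deg, angle_tol_deg, by = angle_step) * pi / 180
  best <- -Inf
  cells <- list()
  for (i in seq_along(thetas)) {
    th <- thetas[i]
    rho <- round(cc * sin(th) + r * cos(th))   # 1-px distance resolution
    tab <- table(rho)
    cells[[i]] <- tab
    best <- max(best, max(tab))
  }
  if (best < 2) { # cannot define a line from a single vote
    counts <- tabulate(r, nbins = nr)
    return(which.max(counts))
  }
  x_mid <- (ncol(mask) + 1) / 2
  cand <- do.call(rbind, lapply(seq_along(thetas), function(i) {
    tab <- cells[[i]]
    hit <- tab >= accum_frac * best
    if (!any(hit)) return(NULL)
    rho <- as.numeric(names(tab)[hit])
    th <- thetas[i]
    cbind(votes = as.numeric(tab[hit]), theta = th,
          row = (rho - x_mid * sin(th)) / cos(th))
  }))
  # non-maximum suppression: neighbouring accumulator cells describe the
  # same physical line; keep the strongest cell per intercept cluster,
  # preferring the most horizontal on ties
  ord <- order(-cand[, "votes"], abs(cand[, "theta"]), cand[, "row"])
  rows <- numeric(0)
  for (i in ord) {
    if (all(abs(rows - cand[i, "row"]) > 1)) rows <- c(rows, cand[i, "row"])
  }
  stats::median(rows)
}

# 3x3 binary erosion; out-of-range neighbors count as foreground so the
# crop border does not erode structures touching it
erode3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up <- rbind(m[-1L, , drop = FALSE], TRUE)
  down <- rbind(TRUE, m[-nr, , drop = FALSE])
  vert <- m & up & down
  left <- cbind(vert[, -1L, drop = FALSE], TRUE)
  right <- cbind(TRUE, vert[, -nc, drop = FALSE])
  vert & left & right
}

#' Extract one trace row per crop column
#'
#' Starting from the pixels within `seed_band` of the centerline, grows the
#' selection to the connected points of the mask (geodesic reconstruction
#' by raster sweeps; `max_iter` caps the sweeps, which converge after a
#' handful on real traces). Per column, the center (median row) of the
#' selected ink run is taken after a 3x3 erosion compensating the stroke
#' width, i.e. the stroke midline (flag `"grown"`); columns whose
#' far-envelope deviation peaks locally (wave tips, where flank ink merges
#' and biases the midline) instead take the farthest selected pixel pulled
#' back by half the stroke thickness;
#' columns untouched by growth but holding foreground pixels take the
#' pixel farthest from the centerline, preserving the tips of wave peaks
#' that growth never reached (flag `"farthest"`; an exact above/below tie
#' picks the pixel vertically closer to the previous column's choice, or
#' the upper one at the first column). Columns with no foreground at all
#' are filled by linear interpolation between the nearest flanking
#' choices; leading/trailing gaps copy the nearest value (flag
#' `"interpolated"`).
#'
#' @param mask Logical matrix (cleaned binary crop, signal `TRUE`).
#' @param center_row Centerline row from [centerline()].
#' @param max_iter Cap on growth sweeps (default 20).
#' @param seed_band Half-width in px of the initial selection band (default 2).
#' @return An object of class `ecg_trace`: list with `rows` (numeric, one
#'   per column) and `flags` (character).
#' @export
trace_path <- function(mask, center_row, max_iter = 20L, seed_band = 2) {
  if (!is.logical(mask)) storage.mode(mask) <- "logical"
  nr <- nrow(mask); nc <- ncol(mask)
  if (!any(mask))
    abort_ecg("ecg_extraction_error", "empty mask: no trace to follow")
  if (center_row < 1 || center_row > nr)
    abort_ecg("ecg_param_error", "center_row outside the crop")
  dist <- abs(seq_len(nr) - center_row)
  seed <- mask & (dist <= seed_band)
  sel <- if (any(seed)) .cpp_grow_selection(mask, seed, as.integer(max_iter))
         else seed
  # stroke-width compensation: a 3x3 erosion strips one pixel of pen width
  # from each side, so the midline of what remains tracks the drawn curve
  # instead of the union of adjacent ink; thin (< 3 px) strokes erode away
  # and fall back to the uneroded run
  core <- erode3(sel)
  rows <- rep(NA_real_, nc)
  flags <- rep(NA_character_, nc)
  far_row <- rep(NA_real_, nc)                # farthest selected pixel
  run_len <- rep(NA_real_, nc)
  prev_choice <- NA_real_
  for (c in seq_len(nc)) {
    sc <- which(sel[, c])
    if (length(sc)) {
      ec <- which(core[, c])
      rows[c] <- stats::median(if (length(ec)) ec else sc)  # stroke midline
      far_row[c] <- sc[which.max(dist[sc])]
      run_len[c] <- length(sc)
      flags[c] <- "grown"
      prev_choice <- rows[c]
    } else {
      mc <- which(mask[, c])
      if (length(mc)) {
        d <- dist[mc]
        far <- mc[d == max(d)]
        if (length(far) > 1L) {
          far <- if (is.na(prev_choice)) min(far)  # first column: choose above
                 else far[which.min(abs(far - prev_choice))]
        }
        rows[c] <- far
        flags[c] <- "farthest"
        prev_choice <- rows[c]
      }
    }
  }
  # wave-tip correction: where the far-envelope deviation peaks locally
  # (the apex of a deflection), the run merges the ink of both flanks and
  # its midline underestimates the tip; take the farthest pixel pulled
  # back by half the stroke thickness instead. For runs of plain stroke
  # height this equals the midline, so flat regions are unaffected.
  grown_cols <- which(flags == "grown")
  if (length(grown_cols) >= 3L) {
    hw_est <- max(0, (stats::median(run_len[grown_cols]) - 1) / 2)
    fdev <- ifelse(is.na(far_row), -Inf, abs(far_row - center_row))
    r <- rle(fdev)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    k <- length(r$values)
    if (k >= 3L) {
      i <- 2:(k - 1L)
      tip_runs <- i[r$values[i] > r$values[i - 1L] & r$values[i] > r$values[i + 1L]]
      for (j in tip_runs) {
        c_tip <- floor((starts[j] + ends[j]) / 2)  # middle of a tip plateau
        if (!is.na(far_row[c_tip]) && flags[c_tip] == "grown")
          rows[c_tip] <- far_row[c_tip] + sign(center_row - far_row[c_tip]) * hw_est
      }
    }
  }
  empty <- is.na(rows)
  if (all(empty))
    abort_ecg("ecg_extraction_error", "no column holds a foreground pixel")
  if (any(empty)) {
    known <- which(!empty)
    filled <- stats::approx(known, rows[known], xout = which(empty),
                            method = "linear", rule = 2)$y
    rows[empty] <- filled
    flags[empty] <- "interpolated"
  }
  structure(list(rows = rows, flags = flags, center_row = center_row),
            class = "ecg_trace")
}

#' @export
print.ecg_trace <- function(x, ...) {
  cat(sprintf("<ecg_trace> %d columns (%s)\n", length(x$rows),
              paste(sprintf("%s: %d", names(table(x$flags)), table(x$flags)),
                    collapse = ", ")))
  invisible(x)
}

#' Peak-preserving moving-average smoothing
#'
#' Centered moving average with a symmetric window that shrinks near the
#' edges (positions 1, 2, ... use windows of 1, 3, ... values), except that
#' positions whose absolute deviation from the series median exceeds
#' `peak_factor` times the median absolute deviation are copied through
#' unchanged — the R (and other wave) peaks carry the diagnostic
#' information and must not be averaged away.
#'
#' @param values Numeric vector.
#' @param span Odd averaging span (default 5).
#' @param peak_factor Peak-exclusion multiplier (default 5).
#' @return Numeric vector of the same length.
#' @export
smooth_trace <- function(values, span = 5L, peak_factor = 5) {
  n <- length(values)
  if (n == 0L) abort_ecg("ecg_param_error", "empty input")
  if (span %% 2L == 0L || span < 1L)
    abort_ecg("ecg_param_error", "span must be odd and positive")
  h <- span %/% 2L
  baseline <- stats::median(values)
  dev <- abs(values - baseline)
  is_peak <- dev > peak_factor * stats::median(dev)
  cs <- cumsum(values)
  i <- seq_len(n)
  hw <- pmin(h, i - 1L, n - i)                # symmetric shrinking window
  lo <- i - hw; hi <- i + hw
  sm <- (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1L)
  ifelse(is_peak, values, sm)
}
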