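# Independent brute-force oracles used to freeze expected values. These are
# deliberately naive re-derivations, sharing no code with the package.

# sliding-window standard deviation over rows, pooled across all columns
brute_row_sd_profile <- function(m, window = 5L) {
  h <- window %/% 2L
  sapply(seq_len(nrow(m)), function(r) {
    rows <- max(1L, r - h):min(nrow(m), r + h)
    stats::sd(as.vector(m[rows, ]))
  })
}

# 3x3 median with edge replication, pixel by pixel
brute_median3x3 <- function(m) {
  out <- m
  for (r in seq_len(nrow(m))) for (c in seq_len(ncol(m))) {
    rr <- pmin(pmax(r + (-1:1), 1L), nrow(m))
    cc <- pmin(pmax(c + (-1:1), 1L), ncol(m))
    out[r, c] <- stats::median(as.vector(m[rr, cc]))
  }
  out
}

# queue-based 8-connected flood fill
brute_flood_fill <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nid <- 0L
  for (c0 in seq_len(ncol(mask))) for (r0 in seq_len(nrow(mask))) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    nid <- nid + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- nid
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1L] + dr; c <- p[2L] + dc
        if (r >= 1 && r <= nrow(mask) && c >= 1 && c <= ncol(mask) &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nid
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# two labelings describe the same partition of foreground pixels
same_partition <- function(a, b) {
  fg <- a > 0L
  if (!identical(fg, b > 0L)) return(FALSE)
  key <- paste(a[fg], b[fg])
  length(unique(key)) == length(unique(a[fg])) &&
    length(unique(key)) == length(unique(b[fg]))
}

# exhaustive between-class-variance scan over 8-bit histogram thresholds;
# returns the variance achieved at every candidate threshold bin k (class 0
# = bins <= k)
brute_otsu_variances <- function(v) {
  bins <- pmin(floor(v * 256), 255)
  sapply(0:254, function(k) {
    in0 <- bins <= k
    n0 <- sum(in0); n1 <- length(v) - n0
    if (n0 == 0L || n1 == 0L) return(-Inf)
    w0 <- n0 / length(v)
    (w0 * (1 - w0)) * (mean(bins[in0]) - mean(bins[!in0]))^2
  })
}

# greedy peak suppression: keep highest first, drop anything within min_dist
brute_peak_suppression <- function(p, height_frac = 0.5, min_dist_frac = 0.05) {
  cand <- integer(0)
  for (i in seq_along(p)) {
    left <- if (i == 1L) -Inf else p[i - 1L]
    right <- if (i == length(p)) -Inf else p[i + 1L]
    if (p[i] > left && p[i] >= right) cand <- c(cand, i)
  }
  cand <- cand[p[cand] >= height_frac * max(p) & p[cand] > 0]
  kept <- integer(0)
  for (i in cand[order(-p[cand], cand)])
    if (all(abs(kept - i) > min_dist_frac * length(p))) kept <- c(kept, i)
  sort(kept)
}

# textbook Pearson correlation written out by hand
hand_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my)) / (n - 1)
  sx <- sqrt(sum((x - mx)^2) / (n - 1))
  sy <- sqrt(sum((y - my)^2) / (n - 1))
  sxy / (sx * sy)
}
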