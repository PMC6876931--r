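#' Resample a signal to a fixed number of points
#'
#' Linear interpolation onto `n` uniformly spaced time points spanning the
#' signal's time range; the endpoints are preserved exactly. Both members
#' of a validation pair are brought to the same length (1000 points by
#' default) before correlating, which adjusts for the differing sampling
#' rates of the reference recording and the scanned image.
#'
#' @param sig An `ecg_signal` with at least 2 samples.
#' @param n Target length (default 1000).
#' @return A resampled `ecg_signal`.
#' @export
resample_signal <- function(sig, n = 1000L) {
  if (n < 2L) abort_ecg("ecg_param_error", "n must be at least 2")
  tt <- seq(sig$t[1L], sig$t[length(sig$t)], length.out = n)
  vv <- stats::approx(sig$t, sig$v, xout = tt, method = "linear")$y
  ecg_signal(t = tt, v = vv, lead = sig$lead)
}

#' Pearson correlation between two signals
#'
#' `rho = cov(sig1, sig2) / (sd(sig1) * sd(sig2))`, the agreement statistic
#' between an original and a digitized signal.
#'
#' @param sig1,sig2 Numeric vectors of equal length (>= 3) with nonzero
#'   variance, or `ecg_signal` objects (their voltages are used).
#' @return Correlation in `[-1, 1]`.
#' @export
pearson <- function(sig1, sig2) {
  x <- if (inherits(sig1, "ecg_signal")) sig1$v else as.numeric(sig1)
  y <- if (inherits(sig2, "ecg_signal")) sig2$v else as.numeric(sig2)
  if (length(x) != length(y) || length(x) < 3L)
    abort_ecg("ecg_param_error", "signals must have equal length >= 3")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0)
    abort_ecg("ecg_degenerate_error", "zero-variance input: correlation undefined")
  r <- stats::cov(x, y) / (sx * sy)
  min(1, max(-1, r))
}

# two-sided p-value of a correlation via the t transform
cor_p_value <- function(rho, n) {
  if (abs(rho) >= 1) return(0)
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Validate a batch of (reference, digitized) signal pairs
#'
#' Each pair is resampled to `n` points and correlated; the report carries
#' per-lead correlations with two-sided p-values, the batch mean/SD, and —
#' when at least 3 pairs yield complete fiducials — correlations of the
#' single-beat PR/QRS/QT/RR intervals computed identically on both members
#' of every pair. Pairs with undefined correlation are excluded from the
#' summaries and listed under `excluded`.
#'
#' @param pairs List of `list(reference =, digitized =, lead =)` entries;
#'   `reference` and `digitized` are `ecg_signal`s of the same lead.
#' @param n Resampling length (default 1000).
#' @return An object of class `ecg_validation`: list with `per_lead`
#'   (data.frame `lead`, `rho`, `p_value`), `mean_rho`, `sd_rho`,
#'   `interval_rho`, `interval_p`, `excluded`.
#' @export
validate_batch <- function(pairs, n = 1000L) {
  if (length(pairs) < 1L)
    abort_ecg("ecg_input_error", "at least one signal pair is required")
  leads <- character(length(pairs))
  rho <- rep(NA_real_, length(pairs))
  excluded <- character(0)
  iv_ref <- iv_dig <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    if (!identical(p$reference$lead, p$digitized$lead))
      abort_ecg("ecg_pairing_error", sprintf(
        "pair %d mixes leads '%s' and '%s'", i, p$reference$lead, p$digitized$lead))
    leads[i] <- if (!is.null(p$lead)) p$lead else p$reference$lead
    rho[i] <- tryCatch(
      pearson(resample_signal(p$reference, n), resample_signal(p$digitized, n)),
      ecg_error = function(e) {
        excluded <<- c(excluded, sprintf("%s: %s", leads[i], conditionMessage(e)))
        NA_real_
      })
    iv <- function(s) tryCatch(
      ecg_intervals(locate_pt(s, pan_tompkins_qrs(s)), s),
      ecg_error = function(e) NULL, ecg_warning = function(w) suppressWarnings(
        ecg_intervals(locate_pt(s, pan_tompkins_qrs(s)), s)))
    iv_ref[[i]] <- suppressWarnings(iv(p$reference))
    iv_dig[[i]] <- suppressWarnings(iv(p$digitized))
  }
  ok <- !is.na(rho)
  per_lead <- data.frame(lead = leads, rho = rho,
                         p_value = vapply(rho, function(r)
                           if (is.na(r)) NA_real_ else cor_p_value(r, n), numeric(1)))
  interval_rho <- interval_p <- c(pr = NA_real_, qrs = NA_real_,
                                  qt = NA_real_, rr = NA_real_)
  have <- !vapply(iv_ref, is.null, logical(1)) & !vapply(iv_dig, is.null, logical(1))
  if (sum(have) >= 3L) {
    for (key in c("pr", "qrs", "qt", "rr")) {
      a <- vapply(iv_ref[have], function(z) z[[paste0(key, "_ms")]], numeric(1))
      b <- vapply(iv_dig[have], function(z) z[[paste0(key, "_ms")]], numeric(1))
      r <- tryCatch(pearson_n3plus(a, b), ecg_error = function(e) NA_real_)
      interval_rho[key] <- r
      if (!is.na(r)) interval_p[key] <- cor_p_value(r, sum(have))
    }
  }
  structure(list(per_lead = per_lead,
                 mean_rho = mean(rho[ok]), sd_rho = stats::sd(rho[ok]),
                 interval_rho = interval_rho, interval_p = interval_p,
                 excluded = excluded, n_resample = n),
            class = "ecg_validation")
}

# pearson() for short interval vectors (still requires length >= 3)
pearson_n3plus <- function(a, b) pearson(a, b)

#' @export
print.ecg_validation <- function(x, ...) {
  cat(sprintf("<ecg_validation> %d pair(s): mean rho %.4f (SD %.4f)\n",
              nrow(x$per_lead), x$mean_rho, x$sd_rho))
  if (any(!is.na(x$interval_rho)))
    cat(sprintf("  interval rho: PR %.3f  QRS %.3f  QT %.3f  RR %.3f\n",
                x$interval_rho["pr"], x$interval_rho["qrs"],
                x$interval_rho["qt"], x$interval_rho["rr"]))
  if (length(x$excluded))
    cat("  excluded:", paste(x$excluded, collapse = "; "), "\n")
  invisible(x)
}
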