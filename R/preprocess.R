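# Quality control, normalization and methylation estimation for
# probe-level tiling-array data: the four QC rules, within-sample
# control-probe LOESS normalization, between-sample subset quantile
# normalization, and the M-value transform used for modeling.

#' Filter probes by quality score
#'
#' Discards probes whose quality score is strictly lower than the
#' threshold (default 80). Region membership is preserved for surviving
#' probes; regions left without any probe are dropped entirely.
#'
#' @param design Array design data.frame with a `quality` column.
#' @param quality_threshold Minimum quality score to retain a probe.
#' @return A list with `design` (the filtered design) and `report`, a
#'   data.frame of discarded probes with the triggering rule.
#' @export
qc_probes <- function(design, quality_threshold = 80) {
  if (is.null(design$quality)) stop("design carries no quality scores")
  drop <- design$quality < quality_threshold
  report <- data.frame(probe_id = design$probe_id[drop],
                       rule = rep("quality_below_threshold", sum(drop)),
                       value = design$quality[drop],
                       stringsAsFactors = FALSE)
  kept <- design[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  list(design = kept, report = report)
}

#' Sample-level quality control
#'
#' Applies the sample-level QC rules: (1) each sample must correlate well
#' with the rest of the cohort — a sample is flagged when its *median*
#' correlation with the other samples falls below `min_pairwise_corr`
#' (the median makes the rule robust: one corrupt sample depresses every
#' sample's minimum, but only its own median); (2) the difference
#' median(control probes) - median(non-control probes) must be negative
#' (control probes interrogate CpG-free, unmethylated regions); (3) when
#' two-channel intensities are supplied, the untreated-channel sd must not
#' be an outlier across samples (z-score above `untreated_sd_z`). The
#' minimum pairwise correlation is reported alongside as a metric.
#'
#' @param meth Probes x samples methylation matrix (proportions).
#' @param design Array design aligned to the matrix rows.
#' @param min_pairwise_corr Correlation threshold for rule 1.
#' @param untreated Optional untreated-channel intensity matrix for rule 3.
#' @param untreated_sd_z z-score cutoff across samples for rule 3.
#' @return A data.frame with one row per sample: the metrics, per-rule
#'   flags, and an overall `flagged` column.
#' @export
qc_samples <- function(meth, design, min_pairwise_corr = 0.8,
                       untreated = NULL, untreated_sd_z = 3) {
  stopifnot(nrow(meth) == nrow(design))
  n <- ncol(meth)
  if (n < 1L) stop("no samples")
  min_corr <- med_corr <- rep(NA_real_, n)
  if (n >= 2L) {
    cc <- stats::cor(meth, use = "pairwise.complete.obs")
    diag(cc) <- NA
    min_corr <- apply(cc, 2L, min, na.rm = TRUE)
    med_corr <- apply(cc, 2L, stats::median, na.rm = TRUE)
  } else {
    warning("single sample: correlation rule skipped")
  }
  med_diff <- apply(meth, 2L, function(x) {
    stats::median(x[design$is_control], na.rm = TRUE) -
      stats::median(x[!design$is_control], na.rm = TRUE)
  })
  usd <- rep(NA_real_, n)
  usd_flag <- rep(FALSE, n)
  if (!is.null(untreated)) {
    usd <- apply(log2(untreated), 2L, stats::sd, na.rm = TRUE)
    z <- (usd - mean(usd)) / stats::sd(usd)
    usd_flag <- !is.na(z) & z > untreated_sd_z
  }
  corr_flag <- !is.na(med_corr) & med_corr < min_pairwise_corr
  med_flag <- med_diff >= 0
  data.frame(sample_id = colnames(meth) %||% paste0("s", seq_len(n)),
             median_pairwise_corr = med_corr,
             min_pairwise_corr = min_corr,
             control_minus_noncontrol_median = med_diff,
             untreated_log_sd = usd,
             flag_low_correlation = corr_flag,
             flag_control_median = med_flag,
             flag_untreated_sd = usd_flag,
             flagged = corr_flag | med_flag | usd_flag,
             stringsAsFactors = FALSE)
}

#' Within-sample normalization against control probes
#'
#' For each sample, fits a smooth intensity-dependent baseline to the
#' control (CpG-free) probes — a robust local linear regression of the
#' log-ratio `log2(treated/untreated)` on the average log-intensity — and
#' subtracts the interpolated baseline from every probe's log-ratio. After
#' adjustment the control probes' mean log-ratio is exactly zero, i.e.
#' CpG-free regions anchor the unmethylated level.
#'
#' @param treated,untreated Positive intensity matrices (probes x samples).
#' @param design Array design marking control probes (>= 20 required).
#' @param span LOESS span for the control-probe baseline fit.
#' @return A list of adjusted `treated`/`untreated` matrices with the same
#'   average log-intensity per probe as the input.
#' @export
normalize_within_sample <- function(treated, untreated, design, span = 0.3) {
  stopifnot(nrow(treated) == nrow(design), all(dim(treated) == dim(untreated)))
  ctrl <- which(design$is_control)
  if (length(ctrl) < 20L) stop("at least 20 control probes are required")
  out_t <- treated
  out_u <- untreated
  for (s in seq_len(ncol(treated))) {
    L <- log2(treated[, s]) - log2(untreated[, s])
    A <- (log2(treated[, s]) + log2(untreated[, s])) / 2
    if (stats::sd(A[ctrl]) < 1e-12) {
      baseline <- rep(mean(L[ctrl]), length(L))
    } else {
      fit <- stats::lowess(A[ctrl], L[ctrl], f = span, iter = 2L)
      baseline <- stats::approx(fit$x, fit$y, xout = A, rule = 2L, ties = mean)$y
    }
    L_adj <- L - baseline
    L_adj <- L_adj - mean(L_adj[ctrl])  # pin control mean log-ratio at 0
    out_t[, s] <- 2^(A + L_adj / 2)
    out_u[, s] <- 2^(A - L_adj / 2)
  }
  list(treated = out_t, untreated = out_u)
}

#' Between-sample subset quantile normalization
#'
#' Normalizes samples to a common scale by anchoring the quantile map on
#' the control-probe subset: each sample's control-probe quantile curve
#' (evaluated on a fixed probability grid) is mapped onto the mean curve
#' across samples, the monotone map is linearly interpolated between grid
#' knots, and applied to all probes of the sample. Ranks within a sample
#' are preserved; applying the transform twice is a no-op.
#'
#' @param meth Probes x samples methylation matrix (proportions).
#' @param design Array design marking control probes.
#' @param n_grid Number of probability-grid points for the quantile curves.
#' @return The normalized matrix, clipped to \[0, 1\].
#' @export
normalize_between_samples <- function(meth, design, n_grid = 1000L) {
  stopifnot(nrow(meth) == nrow(design))
  if (ncol(meth) < 2L) stop("at least 2 samples are required")
  ctrl <- which(design$is_control)
  if (length(ctrl) < 2L) stop("too few control probes for quantile anchoring")
  # include the control order-statistic probabilities so every sample's
  # quantile curve is exactly linear within each grid segment (makes the
  # control quantile map exact, not just approximate)
  probs <- sort(unique(c(seq(0, 1, length.out = n_grid),
                         seq(0, 1, length.out = length(ctrl)))))
  curves <- apply(meth[ctrl, , drop = FALSE], 2L, stats::quantile,
                  probs = probs, names = FALSE, type = 7L)
  ref <- rowMeans(curves)
  out <- meth
  for (s in seq_len(ncol(meth))) {
    qs <- curves[, s]
    if (max(qs) - min(qs) < 1e-12) {
      warning("sample ", s, " has a degenerate control distribution; ",
              "mapped to the reference median")
      out[, s] <- stats::median(ref)
      next
    }
    # collapse ties in the source knots so approx() sees a function
    keep <- !duplicated(qs)
    x <- qs[keep]
    y <- ref[keep]
    v <- meth[, s]
    mapped <- stats::approx(x, y, xout = v, rule = 1L, ties = mean)$y
    # beyond the control-anchored range, extend the map with slope 1
    # (edge offset) so out-of-range probes are shifted, not collapsed
    lo <- v < x[1]
    hi <- v > x[length(x)]
    mapped[lo] <- v[lo] + (y[1] - x[1])
    mapped[hi] <- v[hi] + (y[length(y)] - x[length(x)])
    out[, s] <- mapped
  }
  clip01(out)
}

#' Estimate methylation proportions from two-channel intensities
#'
#' Under the stylized emission model the methylation-enriched channel
#' carries a `p` share of the total signal, so
#' `p = treated / (treated + untreated)`, clipped to \[0, 1\]. Probes with
#' zero total intensity are set missing.
#'
#' @param treated,untreated Adjusted intensity matrices.
#' @return A probes x samples methylation matrix; attribute `flagged`
#'   lists probes with zero total intensity.
#' @export
estimate_methylation <- function(treated, untreated) {
  stopifnot(all(dim(treated) == dim(untreated)))
  total <- treated + untreated
  p <- treated / total
  bad <- which(!(total > 0), arr.ind = TRUE)
  if (nrow(bad)) p[bad] <- NA_real_
  p <- clip01(p)
  attr(p, "flagged") <- unique(rownames(treated)[bad[, 1L]])
  p
}

#' M-value transform of methylation proportions
#'
#' `M = log2(p / (1 - p))` after clamping p into `[eps, 1 - eps]` so the
#' transform stays finite. Strictly monotone in p; variance-stabilizing
#' for linear modeling of methylation.
#'
#' @param p Proportions in \[0, 1\] (vector or matrix).
#' @param eps Clamp in (0, 0.5); default 0.01.
#' @return M-values with the shape of `p`.
#' @examples
#' m_transform(c(0.5, 0.8))  # 0 and 2
#' @export
m_transform <- function(p, eps = 0.01) {
  if (eps <= 0 || eps >= 0.5) stop("eps must lie in (0, 0.5)")
  q <- pmin(pmax(p, eps), 1 - eps)
  log2(q / (1 - q))
}

#' Inverse M-value transform
#'
#' @param m M-values.
#' @return Proportions `2^m / (1 + 2^m)`.
#' @export
m_inverse <- function(m) {
  1 / (1 + 2^(-m))
}
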