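# Probe-level paired linear modeling on M-values, coefficient smoothing,
# bump-hunting candidate discovery, and the three region statistics
# (avg, max, area_raw) computed on the proportion scale.

validate_cohort <- function(cohort, sample_ids = NULL) {
  need <- c("sample_id", "pair_id", "phenotype")
  if (!all(need %in% names(cohort))) {
    stop("cohort must have columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(cohort$sample_id)) stop("duplicate sample ids in cohort")
  tab <- table(cohort$pair_id, cohort$phenotype)
  bad <- rownames(tab)[tab[, "case", drop = TRUE] != 1L |
                         tab[, "control", drop = TRUE] != 1L]
  if (length(bad)) {
    stop("pair(s) without exactly one case and one control: ",
         paste(bad, collapse = ", "))
  }
  if ("batch" %in% names(cohort) && length(unique(cohort$batch)) > 1L) {
    stop("cohort mixes batches; analyze each batch separately")
  }
  if (!is.null(sample_ids) && !setequal(sample_ids, cohort$sample_id)) {
    stop("sample ids in the matrix and the cohort differ: missing in matrix [",
         paste(setdiff(cohort$sample_id, sample_ids), collapse = ", "),
         "], missing in cohort [",
         paste(setdiff(sample_ids, cohort$sample_id), collapse = ", "), "]")
  }
  invisible(cohort)
}

# Design matrix of the paired model: one indicator per pair, a case
# indicator, and optional cell-proportion covariates.
pair_design_matrix <- function(cohort, covariates = NULL) {
  pair <- factor(cohort$pair_id)
  X <- stats::model.matrix(~ 0 + pair)
  pheno <- as.numeric(cohort$phenotype == "case")
  X <- cbind(X, phenotype = pheno)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != nrow(cohort)) {
      stop("covariates must cover all samples")
    }
    colnames(covariates) <- colnames(covariates) %||%
      paste0("cov", seq_len(ncol(covariates)))
    X <- cbind(X, covariates)
  }
  rownames(X) <- cohort$sample_id
  X
}

#' Fit the paired probe-level linear model on M-values
#'
#' For every probe, ordinary least squares of the M-value on a pair
#' indicator block (one fixed effect per twin pair), a phenotype indicator,
#' and optionally three cell-proportion covariates (see
#' [proportion_covariates()]). The phenotype coefficient is the "logFC" on
#' the M scale; its two-sided t-test p-value and the residual matrix are
#' returned. Probes with any missing value across retained samples are
#' excluded from modeling.
#'
#' @param meth Probes x samples methylation matrix (proportions).
#' @param cohort Sample sheet with `sample_id`, `pair_id`, `phenotype`
#'   (`"case"`/`"control"`), all from one batch.
#' @param covariates Optional samples x k numeric matrix/data.frame of
#'   model covariates, rows aligned to `cohort$sample_id`.
#' @param eps Clamp for the M-value transform.
#' @return An object of class `probe_fit`: per-probe `coef`, `se`, `t`,
#'   `p`, the residual matrix on the M scale, degrees of freedom, and the
#'   model descriptor.
#' @export
fit_probe_model <- function(meth, cohort, covariates = NULL, eps = 0.01) {
  validate_cohort(cohort, colnames(meth))
  meth <- meth[, cohort$sample_id, drop = FALSE]
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (!is.null(rownames(covariates))) {
      covariates <- covariates[cohort$sample_id, , drop = FALSE]
    }
  }
  X <- pair_design_matrix(cohort, covariates)
  M <- m_transform(meth, eps)
  ok <- !apply(M, 1L, anyNA)
  qrx <- qr(X)
  pheno_col <- match("phenotype", colnames(X))
  dropped <- character(0)
  if (qrx$rank < ncol(X)) {
    # the phenotype effect is identifiable only if removing its column
    # lowers the rank; otherwise some covariate is confounded with it
    if (qr(X[, -pheno_col, drop = FALSE])$rank == qrx$rank) {
      stop("phenotype coefficient is not estimable (rank-deficient design; ",
           "check covariates for collinearity with the phenotype)")
    }
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    # a proportion triple sums to 1 and is collinear with the pair
    # intercepts; dropping the redundant column is routine, not an error
    if (!all(dropped %in% colnames(covariates))) {
      warning("rank-deficient design; dropped: ", paste(dropped, collapse = ", "))
    }
  }
  n <- nrow(X)
  df <- n - qrx$rank
  if (df < 1L) stop("no residual degrees of freedom")
  Y <- t(M[ok, , drop = FALSE])
  beta <- qr.coef(qrx, Y)
  res <- Y - X %*% ifelse(is.na(beta), 0, beta)
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qrx)[seq_len(qrx$rank), seq_len(qrx$rank)])
  unpiv <- order(qrx$pivot[seq_len(qrx$rank)])
  cpp <- XtXinv[unpiv, unpiv][pheno_col, pheno_col]
  npk <- nrow(meth)
  coef <- se <- tt <- pp <- rep(NA_real_, npk)
  names(coef) <- names(se) <- names(tt) <- names(pp) <- rownames(meth)
  coef[ok] <- beta[pheno_col, ]
  se[ok] <- sqrt(sigma2 * cpp)
  tt[ok] <- coef[ok] / se[ok]
  pp[ok] <- 2 * stats::pt(-abs(tt[ok]), df)
  residuals <- matrix(NA_real_, npk, n, dimnames = list(rownames(meth), cohort$sample_id))
  residuals[ok, ] <- t(res)
  structure(list(coef = coef, se = se, t = tt, p = pp,
                 residuals = residuals, df = df, retained = ok,
                 model = list(covariates = colnames(covariates),
                              dropped = dropped,
                              n_pairs = length(unique(cohort$pair_id)),
                              eps = eps)),
            class = "probe_fit")
}

#' Smooth probe coefficients along the genome within regions
#'
#' Within each design region, smooths the per-probe phenotype coefficients
#' over genomic position with a robust local linear regression; regions
#' with fewer than `min_probes_loess` probes use a centered running mean
#' instead. Smoothing never crosses region boundaries, and control probes
#' (no region membership) are left unsmoothed as `NA`.
#'
#' @param coef Named per-probe coefficient vector (names = probe ids).
#' @param design Array design aligned to the coefficients.
#' @param span LOESS span (fraction of region probes per local fit).
#' @param min_probes_loess Regions smaller than this use the running mean.
#' @param window Running-mean window (odd, default 3).
#' @return Named numeric vector of smoothed coefficients.
#' @export
smooth_coefficients <- function(coef, design, span = 0.75,
                                min_probes_loess = 4L, window = 3L) {
  stopifnot(length(coef) == nrow(design))
  smooth_grouped(coef, design, region_groups(design), span,
                 min_probes_loess, window)
}

# Probe indices per region, each sorted by genomic position. Precomputed
# once and reused across bootstrap iterations.
region_groups <- function(design) {
  idx <- seq_len(nrow(design))[!design$is_control]
  groups <- split(idx, design$region_id[idx])
  lapply(groups, function(g) g[order(design$pos[g])])
}

smooth_grouped <- function(coef, design, groups, span = 0.75,
                           min_probes_loess = 4L, window = 3L) {
  out <- rep(NA_real_, length(coef))
  names(out) <- design$probe_id
  pos_all <- design$pos
  for (idx in groups) {
    y <- coef[idx]
    obs <- !is.na(y)
    if (!any(obs)) next
    if (sum(obs) < min_probes_loess) {
      out[idx[obs]] <- running_mean(y[obs], window)
    } else {
      pos <- pos_all[idx][obs]
      sm <- stats::lowess(pos, y[obs], f = span, iter = 2L)
      out[idx[obs]] <- sm$y[match(pos, sm$x)]
    }
  }
  out
}

#' Region statistics for a probe set
#'
#' Per-probe difference = mean over case samples minus mean over control
#' samples, on the proportion scale. `avg` is the mean over probes, `max`
#' the signed difference of largest magnitude, and `area_raw` the probe
#' count times `avg`.
#'
#' @param probe_ids Probe ids of the candidate region.
#' @param meth Probes x samples methylation matrix (proportions).
#' @param cohort Sample sheet defining case/control columns.
#' @return Named numeric vector `c(avg, max, area_raw)`.
#' @export
compute_statistics <- function(probe_ids, meth, cohort) {
  idx <- match(probe_ids, rownames(meth))
  if (anyNA(idx)) stop("candidate probes absent from the matrix")
  d <- rowMeans(meth[idx, cohort$sample_id[cohort$phenotype == "case"], drop = FALSE]) -
    rowMeans(meth[idx, cohort$sample_id[cohort$phenotype == "control"], drop = FALSE])
  avg <- mean(d)
  mx <- d[which.max(abs(d))]
  c(avg = avg, max = unname(mx), area_raw = length(d) * avg)
}

#' Identify candidate DMRs by bump hunting
#'
#' Scans the smoothed coefficients for maximal runs of consecutive probes
#' (within one design region) whose smoothed coefficient exceeds the cutoff
#' in absolute value with a consistent sign, with inter-probe gaps at most
#' `max_gap` bp and at least `min_probes` probes. The cutoff is either
#' given in absolute terms or resolved as a quantile of the non-missing
#' |smoothed| values. The three region statistics are attached on the
#' proportion scale.
#'
#' @param smoothed Named per-probe smoothed coefficients.
#' @param design Array design aligned to the coefficients.
#' @param meth Probes x samples methylation matrix (proportions).
#' @param cohort Sample sheet defining case/control columns.
#' @param cutoff Absolute cutoff; overrides `cutoff_quantile` when given.
#' @param cutoff_quantile Quantile of |smoothed| defining the cutoff.
#' @param min_probes Minimum probes per candidate.
#' @param max_gap Maximum gap (bp) between consecutive candidate probes.
#' @param groups Precomputed per-region probe grouping (internal
#'   optimization for repeated calls on one design).
#' @return A data.frame of candidates (`dmr_id`, `chrom`, `start`, `end`
#'   1-based inclusive, `region_id`, `nprobes`, `avg`, `max`, `area_raw`,
#'   and a `probes` list-column), sorted by position, with the resolved
#'   cutoff in `attr(, "cutoff")`.
#' @export
find_candidates <- function(smoothed, design, meth, cohort,
                            cutoff = NULL, cutoff_quantile = 0.995,
                            min_probes = 3L, max_gap = 300L,
                            groups = region_groups(design)) {
  stopifnot(length(smoothed) == nrow(design))
  if (is.null(cutoff)) {
    cutoff <- stats::quantile(abs(smoothed), cutoff_quantile, na.rm = TRUE,
                              names = FALSE)
  }
  runs <- candidate_runs(smoothed, design, cutoff, min_probes, max_gap, groups)
  if (nrow(runs) == 0L) {
    out <- data.frame(dmr_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      region_id = character(), nprobes = integer(),
                      avg = numeric(), max = numeric(), area_raw = numeric(),
                      probes = I(list()), stringsAsFactors = FALSE)
    attr(out, "cutoff") <- cutoff
    return(out)
  }
  out <- runs[order(runs$chrom, runs$start), , drop = FALSE]
  stats_m <- t(vapply(out$probes, compute_statistics, numeric(3L),
                      meth = meth, cohort = cohort))
  out$avg <- stats_m[, "avg"]
  out$max <- stats_m[, "max"]
  out$area_raw <- stats_m[, "area_raw"]
  out$dmr_id <- sprintf("cDMR%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out <- out[, c("dmr_id", "chrom", "start", "end", "region_id", "nprobes",
                 "avg", "max", "area_raw", "probes")]
  attr(out, "cutoff") <- cutoff
  out
}

# Maximal same-sign runs of |smoothed| >= cutoff within regions, broken at
# sign changes and positional gaps > max_gap. Shared by the bump hunter
# and sorted-cell marker discovery.
candidate_runs <- function(smoothed, design, cutoff, min_probes, max_gap,
                           groups = region_groups(design)) {
  cands <- list()
  for (rid in names(groups)) {
    idx <- groups[[rid]]
    y <- smoothed[idx]
    pos <- design$pos[idx]
    hit <- !is.na(y) & abs(y) >= cutoff
    if (!any(hit)) next
    sgn <- sign(y)
    brk <- c(TRUE, !hit[-length(hit)] | sgn[-1] != sgn[-length(sgn)] |
               diff(pos) > max_gap)
    run_id <- cumsum(brk)
    for (r in unique(run_id[hit])) {
      sel <- idx[run_id == r & hit]
      if (length(sel) < min_probes) next
      cands[[length(cands) + 1L]] <- data.frame(
        chrom = design$chrom[sel[1]], start = min(design$pos[sel]),
        end = max(design$pos[sel]), region_id = rid,
        nprobes = length(sel), probes = I(list(design$probe_id[sel])),
        stringsAsFactors = FALSE)
    }
  }
  if (length(cands) == 0L) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      region_id = character(), nprobes = integer(),
                      stringsAsFactors = FALSE)
    out$probes <- I(list())
    return(out)
  }
  do.call(rbind, cands)
}

#' Benjamini-Hochberg q-values and single-probe discoveries
#'
#' Standard step-up BH adjustment of the probe-level p-values with
#' monotonicity enforcement, and the discovery set at a q threshold
#' (default 0.20).
#'
#' @param fit A `probe_fit` object or a numeric vector of p-values.
#' @param q Discovery threshold on the q-value.
#' @return A list with `qvalues` (aligned to the input) and `discoveries`
#'   (indices with q <= threshold).
#' @export
single_probe_fdr <- function(fit, q = 0.20) {
  p <- if (inherits(fit, "probe_fit")) fit$p else fit
  qv <- stats::p.adjust(p, method = "BH")
  list(qvalues = qv, discoveries = which(!is.na(qv) & qv <= q))
}
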