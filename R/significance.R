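# Region-level significance: within-pair sign-flip permutation p-values,
# the outlier-exclusion filter applied both at discovery and inside every
# resampling iteration, probe-count-stratified bootstrap FWER over the
# three region statistics, and the dual-criterion DMR call.

# Per-sample summary (mean or max methylation over the candidate probes)
# and per-pair case-minus-control differences of that summary.
pair_summary_differences <- function(probe_ids, meth, cohort,
                                     statistic = c("avg", "max")) {
  statistic <- match.arg(statistic)
  idx <- match(probe_ids, rownames(meth))
  if (length(idx) == 0L || anyNA(idx)) stop("candidate has no probes in the matrix")
  sub <- meth[idx, cohort$sample_id, drop = FALSE]
  summ <- if (statistic == "avg") colMeans(sub) else apply(sub, 2L, max)
  pairs <- unique(cohort$pair_id)
  vapply(pairs, function(pr) {
    summ[cohort$sample_id[cohort$pair_id == pr & cohort$phenotype == "case"]] -
      summ[cohort$sample_id[cohort$pair_id == pr & cohort$phenotype == "control"]]
  }, numeric(1L))
}

#' Within-pair sign-flip permutation p-value
#'
#' Builds the null by randomizing the case/control labels independently
#' within each twin pair, which flips the sign of that pair's
#' case-minus-control difference of the per-sample summary (mean or max of
#' methylation over the candidate probes). The test statistic is the mean
#' over pairs of those differences. All `2^n` sign assignments are
#' enumerated when `2^n <= cap`; otherwise `cap` Monte-Carlo assignments
#' are drawn. The two-sided p-value is the fraction of assignments
#' (identity included) whose |statistic| reaches the observed |statistic|.
#'
#' @param probe_ids Probe ids of the candidate region.
#' @param meth Probes x samples methylation matrix (proportions).
#' @param cohort Sample sheet defining pairs and phenotype.
#' @param statistic `"avg"` or `"max"` per-sample summary.
#' @param cap Enumeration cap; beyond it, Monte-Carlo with `seed`.
#' @param seed Seed for the Monte-Carlo branch.
#' @return A list with `p`, `observed`, `n_permutations`, `exhaustive`.
#' @export
within_pair_permutation_p <- function(probe_ids, meth, cohort,
                                      statistic = c("avg", "max"),
                                      cap = 4096L, seed = NULL) {
  statistic <- match.arg(statistic)
  d <- pair_summary_differences(probe_ids, meth, cohort, statistic)
  n <- length(d)
  if (n < 2L) stop("at least 2 pairs are required")
  obs <- mean(d)
  tol <- 1e-12
  if (2^n <= cap) {
    S <- sign_assignments(n)
    stats <- as.vector(S %*% d) / n
    p <- mean(abs(stats) >= abs(obs) - tol)
    list(p = p, observed = obs, n_permutations = 2L^n, exhaustive = TRUE)
  } else {
    stats <- with_seed(seed, {
      S <- matrix(sample(c(-1, 1), cap * n, replace = TRUE), nrow = cap)
      as.vector(S %*% d) / n
    })
    p <- (1 + sum(abs(stats) >= abs(obs) - tol)) / (cap + 1)
    list(p = p, observed = obs, n_permutations = as.integer(cap),
         exhaustive = FALSE)
  }
}

#' Permutation p-values (avg and max) for a table of candidates
#'
#' @param candidates Candidate data.frame with a `probes` list-column.
#' @param meth,cohort Data the permutation runs on.
#' @param cap,seed Passed to [within_pair_permutation_p()].
#' @return `candidates` with columns `p_avg`, `p_max`, `n_permutations`,
#'   `exhaustive` appended.
#' @export
attach_permutation_p <- function(candidates, meth, cohort,
                                 cap = 4096L, seed = NULL) {
  if (nrow(candidates) == 0L) {
    candidates$p_avg <- numeric(0)
    candidates$p_max <- numeric(0)
    candidates$n_permutations <- integer(0)
    candidates$exhaustive <- logical(0)
    return(candidates)
  }
  res <- lapply(seq_len(nrow(candidates)), function(i) {
    pa <- within_pair_permutation_p(candidates$probes[[i]], meth, cohort,
                                    "avg", cap, child_seed(seed, i))
    pm <- within_pair_permutation_p(candidates$probes[[i]], meth, cohort,
                                    "max", cap, child_seed(seed, i + 100000L))
    c(p_avg = pa$p, p_max = pm$p, n = pa$n_permutations, ex = pa$exhaustive)
  })
  res <- do.call(rbind, res)
  candidates$p_avg <- res[, "p_avg"]
  candidates$p_max <- res[, "p_max"]
  candidates$n_permutations <- as.integer(res[, "n"])
  candidates$exhaustive <- as.logical(res[, "ex"])
  candidates
}

#' Outlier-exclusion permutation filter
#'
#' Excludes a candidate iff its permuted p-value exceeds the threshold for
#' BOTH statistics (average and maximum). This discards candidates driven
#' by a single outlier pair — one extreme within-pair difference inflates
#' the region statistic but cannot produce a small sign-flip p-value. The
#' filter is applied at discovery and inside every bootstrap iteration.
#'
#' @param candidates Data.frame with `p_avg` and `p_max` columns.
#' @param threshold Exclusion threshold (default 0.1).
#' @return A list with `retained` and `excluded` (with a `reason` column).
#' @export
permutation_filter <- function(candidates, threshold = 0.1) {
  stopifnot(all(c("p_avg", "p_max") %in% names(candidates)))
  excl <- candidates$p_avg > threshold & candidates$p_max > threshold
  excluded <- candidates[excl, , drop = FALSE]
  if (nrow(excluded)) {
    excluded$reason <- sprintf("permuted p > %g for both statistics (avg=%g, max=%g)",
                               threshold, excluded$p_avg, excluded$p_max)
  } else {
    excluded$reason <- character(0)
  }
  list(retained = candidates[!excl, , drop = FALSE], excluded = excluded)
}

# One bootstrap/permutation pipeline pass: coefficients -> smoothing ->
# candidates at a fixed absolute cutoff -> permutation filter. Returns the
# surviving null candidates' statistics.
null_iteration_candidates <- function(M_null, design, cohort, X_qr, pheno_col,
                                      cutoff, span, min_probes, max_gap,
                                      perm_threshold, perm_cap, perm_seed,
                                      groups) {
  beta <- qr.coef(X_qr, t(M_null))
  coefs <- beta[pheno_col, ]
  names(coefs) <- rownames(M_null)
  sm <- smooth_grouped(coefs, design, groups, span = span)
  p_null <- m_inverse(M_null)
  cand <- find_candidates(sm, design, p_null, cohort, cutoff = cutoff,
                          min_probes = min_probes, max_gap = max_gap,
                          groups = groups)
  if (nrow(cand) == 0L) return(NULL)
  cand <- attach_permutation_p(cand, p_null, cohort, cap = perm_cap,
                               seed = perm_seed)
  cand$kept <- !(cand$p_avg > perm_threshold & cand$p_max > perm_threshold)
  cand[, c("nprobes", "avg", "max", "area_raw", "kept")]
}

#' Build the null statistics pool by resampling
#'
#' Re-runs the full candidate pipeline (probe model, smoothing, bump
#' hunting at the observed absolute cutoff, and the within-pair
#' permutation filter) on resampled null data `B` times, pooling the
#' surviving null candidates' statistics and probe counts per iteration.
#'
#' Two null schemes are available. `"residual-bootstrap"` (default) fits
#' the model without the phenotype term, resamples whole residual columns
#' (samples) with replacement on the M scale, and adds them back to the
#' null fitted values — preserving probe-wise correlation structure while
#' removing any phenotype effect. `"pair-label-permutation"` keeps the data
#' and randomly swaps the case/control labels within each pair.
#'
#' @param meth Probes x samples methylation matrix (proportions).
#' @param design Array design aligned to the matrix.
#' @param cohort Sample sheet.
#' @param covariates Optional model covariates (samples x k).
#' @param cutoff Absolute candidate cutoff (resolve it on the observed data
#'   first, e.g. `attr(find_candidates(...), "cutoff")`).
#' @param B Number of resampling iterations (>= 1).
#' @param scheme Null-generation scheme.
#' @param seed Integer seed; every iteration derives its own child seed.
#' @param span,min_probes,max_gap Candidate-finder settings (match the
#'   observed run).
#' @param perm_threshold,perm_cap Permutation-filter settings.
#' @param eps M-value clamp.
#' @return A data.frame pool with columns `iteration`, `nprobes`, `avg`,
#'   `max`, `area_raw`, `kept` (survived the filter), with attributes `B`
#'   and `scheme`.
#' @export
bootstrap_null <- function(meth, design, cohort, covariates = NULL,
                           cutoff, B = 2000L,
                           scheme = c("residual-bootstrap", "pair-label-permutation"),
                           seed = NULL, span = 0.75, min_probes = 3L,
                           max_gap = 300L, perm_threshold = 0.1,
                           perm_cap = 4096L, eps = 0.01) {
  scheme <- match.arg(scheme)
  if (B < 1L) stop("B must be >= 1")
  validate_cohort(cohort, colnames(meth))
  meth <- meth[, cohort$sample_id, drop = FALSE]
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (!is.null(rownames(covariates))) {
      covariates <- covariates[cohort$sample_id, , drop = FALSE]
    }
  }
  M <- m_transform(meth, eps)
  X <- pair_design_matrix(cohort, covariates)
  pheno_col <- match("phenotype", colnames(X))
  X_qr <- qr(X)
  n <- ncol(meth)
  groups <- region_groups(design)

  if (scheme == "residual-bootstrap") {
    X0 <- X[, -pheno_col, drop = FALSE]
    qr0 <- qr(X0)
    beta0 <- qr.coef(qr0, t(M))
    fitted0 <- t(X0 %*% ifelse(is.na(beta0), 0, beta0))
    res0 <- M - fitted0
  }

  pool <- vector("list", B)
  for (b in seq_len(B)) {
    sb <- child_seed(seed, b)
    it <- tryCatch({
      if (scheme == "residual-bootstrap") {
        idx <- with_seed(sb, sample.int(n, n, replace = TRUE))
        M_null <- fitted0 + res0[, idx, drop = FALSE]
        colnames(M_null) <- colnames(M)
        null_iteration_candidates(M_null, design, cohort, X_qr, pheno_col,
                                  cutoff, span, min_probes, max_gap,
                                  perm_threshold, perm_cap,
                                  child_seed(sb, 1L), groups)
      } else {
        flips <- with_seed(sb, sample(c(TRUE, FALSE),
                                      length(unique(cohort$pair_id)),
                                      replace = TRUE))
        coh_b <- cohort
        for (k in which(flips)) {
          pr <- unique(cohort$pair_id)[k]
          sel <- coh_b$pair_id == pr
          coh_b$phenotype[sel] <- rev(coh_b$phenotype[sel])
        }
        Xb <- pair_design_matrix(coh_b, covariates)
        null_iteration_candidates(M, design, coh_b, qr(Xb),
                                  match("phenotype", colnames(Xb)),
                                  cutoff, span, min_probes, max_gap,
                                  perm_threshold, perm_cap,
                                  child_seed(sb, 1L), groups)
      }
    }, error = function(e) {
      warning("null iteration ", b, " failed and was recorded empty: ",
              conditionMessage(e))
      NULL
    })
    if (!is.null(it) && nrow(it)) {
      it$iteration <- b
      pool[[b]] <- it
    }
  }
  pool <- do.call(rbind, pool)
  if (is.null(pool)) {
    pool <- data.frame(nprobes = integer(), avg = numeric(), max = numeric(),
                       area_raw = numeric(), kept = logical(),
                       iteration = integer())
  }
  pool <- pool[, c("iteration", "nprobes", "avg", "max", "area_raw", "kept")]
  attr(pool, "B") <- as.integer(B)
  attr(pool, "scheme") <- scheme
  pool
}

# Probe-count bins: quartile edges of the null candidates' probe counts,
# with under-populated bins merged into their nearest neighbor.
default_strata <- function(nprobes, min_per_stratum = 20L) {
  if (length(nprobes) == 0L) return(c(-Inf, Inf))
  edges <- unique(stats::quantile(nprobes, c(0.25, 0.5, 0.75), names = FALSE))
  edges <- sort(unique(c(-Inf, edges, Inf)))
  repeat {
    bins <- findInterval(nprobes, edges, left.open = TRUE)
    counts <- tabulate(bins, nbins = length(edges) - 1L)
    small <- which(counts < min_per_stratum)
    if (length(small) == 0L || length(edges) <= 2L) break
    # drop the interior edge adjacent to the emptiest bin
    k <- small[which.min(counts[small])]
    drop_edge <- if (k == 1L) 2L else k
    edges <- edges[-drop_edge]
  }
  edges
}

#' Probe-count-stratified family-wise error rate
#'
#' For each candidate DMR and each of the three region statistics, the
#' FWER is the fraction of resampling iterations whose maximum |statistic|
#' among filter-surviving null candidates *with a similar probe count*
#' (same stratum) reaches the candidate's |statistic|. Iterations with no
#' null candidate in the stratum contribute a maximum of 0. An estimate of
#' exactly 0 means "below 1/B" and is flagged.
#'
#' @param candidates Candidate data.frame with `nprobes`, `avg`, `max`,
#'   `area_raw`.
#' @param null_pool Pool from [bootstrap_null()].
#' @param strata Optional fixed bin edges for probe counts (default:
#'   quartile bins of the null candidates' probe counts, merged so every
#'   bin holds at least `min_per_stratum` null observations).
#' @param min_per_stratum Minimum null observations per bin before merging.
#' @param filtered Use only filter-surviving null candidates (default) or
#'   the full pool.
#' @return `candidates` with `stratum`, `fwer_avg`, `fwer_max`,
#'   `fwer_area`, and `fwer_floor` (= 1/B; FWER 0 means "< 1/B") appended.
#' @export
stratified_fwer <- function(candidates, null_pool, strata = NULL,
                            min_per_stratum = 20L, filtered = TRUE) {
  B <- attr(null_pool, "B")
  if (is.null(B)) stop("null_pool lacks a B attribute")
  pool <- if (filtered && "kept" %in% names(null_pool)) {
    null_pool[null_pool$kept, , drop = FALSE]
  } else {
    null_pool
  }
  edges <- strata %||% default_strata(pool$nprobes, min_per_stratum)
  if (!is.infinite(edges[1])) edges <- c(-Inf, edges)
  if (!is.infinite(edges[length(edges)])) edges <- c(edges, Inf)
  pool_bin <- findInterval(pool$nprobes, edges, left.open = TRUE)
  cand_bin <- findInterval(candidates$nprobes, edges, left.open = TRUE)
  fwer <- matrix(NA_real_, nrow(candidates), 3L,
                 dimnames = list(NULL, c("avg", "max", "area_raw")))
  for (s in c("avg", "max", "area_raw")) {
    for (i in seq_len(nrow(candidates))) {
      rows <- pool_bin == cand_bin[i]
      maxima <- rep(0, B)
      if (any(rows)) {
        mx <- tapply(abs(pool[[s]][rows]), pool$iteration[rows], max)
        maxima[as.integer(names(mx))] <- mx
      }
      fwer[i, s] <- mean(maxima >= abs(candidates[[s]][i]))
    }
  }
  candidates$stratum <- cand_bin
  candidates$fwer_avg <- fwer[, "avg"]
  candidates$fwer_max <- fwer[, "max"]
  candidates$fwer_area <- fwer[, "area_raw"]
  candidates$fwer_floor <- rep(1 / B, nrow(candidates))
  attr(candidates, "strata_edges") <- edges
  candidates
}

#' Call DMRs by the dual significance criterion
#'
#' A candidate passes iff (1) globally, the FWER of at least one of the
#' three statistics is at or below `fwer_threshold`, and (2) locally, the
#' smaller of its two within-pair permutation p-values is below
#' `perm_threshold`. Calls are sorted by best FWER, then genomic position.
#'
#' @param candidates Data.frame carrying `fwer_avg`, `fwer_max`,
#'   `fwer_area`, `p_avg`, `p_max`.
#' @param fwer_threshold Global threshold (default 0.10; a relaxed report
#'   threshold of 0.20 is conventional for review tables).
#' @param perm_threshold Local permutation threshold (default 0.1).
#' @return `candidates` with `best_fwer`, `pass`, and `reason` columns,
#'   sorted; passing rows first.
#' @export
call_dmrs <- function(candidates, fwer_threshold = 0.10, perm_threshold = 0.1) {
  need <- c("fwer_avg", "fwer_max", "fwer_area", "p_avg", "p_max")
  stopifnot(all(need %in% names(candidates)))
  if (nrow(candidates) == 0L) {
    candidates$best_fwer <- numeric(0)
    candidates$pass <- logical(0)
    candidates$reason <- character(0)
    return(candidates)
  }
  best <- pmin(candidates$fwer_avg, candidates$fwer_max, candidates$fwer_area)
  perm_ok <- pmin(candidates$p_avg, candidates$p_max) < perm_threshold
  fwer_ok <- best <= fwer_threshold
  candidates$best_fwer <- best
  candidates$pass <- fwer_ok & perm_ok
  candidates$reason <- ifelse(candidates$pass, "pass",
                              ifelse(!fwer_ok & !perm_ok, "fwer+perm",
                                     ifelse(!fwer_ok, "fwer", "perm")))
  ord <- order(!candidates$pass, best, candidates$chrom, candidates$start)
  out <- candidates[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
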