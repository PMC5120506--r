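# Cross-cohort projection of DMR intervals, directional-consistency
# checks, meta-analysis of replication data, and DMR-vs-covariate
# association tests.

#' Project DMR intervals onto another cohort
#'
#' Takes genomic intervals (e.g. DMRs called in one twin set) and computes
#' the within-pair sign-flip permutation p-values — for the average and
#' maximum statistics — on a *different* cohort's data. The projection is
#' asymmetric by construction: each direction is an independent
#' computation on its own data. Intervals overlapping no probe of the
#' target design are reported untestable.
#'
#' @param intervals Data.frame with `chrom`, `start`, `end` (1-based,
#'   inclusive).
#' @param target_meth Probes x samples matrix of the target cohort.
#' @param target_design Array design of the target cohort.
#' @param target_cohort Sample sheet of the target cohort.
#' @param cap,seed Passed to [within_pair_permutation_p()].
#' @return `intervals` with `p_avg`, `p_max`, `n_permutations`,
#'   `n_probes_overlapping`, `testable` appended.
#' @export
project_dmrs <- function(intervals, target_meth, target_design, target_cohort,
                         cap = 4096L, seed = NULL) {
  res <- lapply(seq_len(nrow(intervals)), function(i) {
    sel <- !target_design$is_control &
      target_design$chrom == intervals$chrom[i] &
      target_design$pos >= intervals$start[i] &
      target_design$pos <= intervals$end[i]
    pids <- target_design$probe_id[sel]
    if (length(pids) == 0L) {
      return(data.frame(p_avg = NA_real_, p_max = NA_real_,
                        n_permutations = NA_integer_,
                        n_probes_overlapping = 0L, testable = FALSE))
    }
    pa <- within_pair_permutation_p(pids, target_meth, target_cohort, "avg",
                                    cap, child_seed(seed, i))
    pm <- within_pair_permutation_p(pids, target_meth, target_cohort, "max",
                                    cap, child_seed(seed, i + 100000L))
    data.frame(p_avg = pa$p, p_max = pm$p,
               n_permutations = pa$n_permutations,
               n_probes_overlapping = length(pids), testable = TRUE)
  })
  cbind(intervals, do.call(rbind, res))
}

#' Directional consistency of two sets of signed differences
#'
#' The fraction of aligned difference pairs whose signs agree, among the
#' pairs where both differences are nonzero (zeros carry no direction and
#' are excluded from the denominator).
#'
#' @param delta_a,delta_b Aligned numeric vectors of signed differences.
#' @return A list with `ratio` (NA if no pair has two nonzero entries),
#'   `n_agree`, `n_compared`.
#' @export
directional_consistency <- function(delta_a, delta_b) {
  stopifnot(length(delta_a) == length(delta_b))
  both <- delta_a != 0 & delta_b != 0 & !is.na(delta_a) & !is.na(delta_b)
  n <- sum(both)
  if (n == 0L) {
    warning("no pair with two nonzero differences; ratio undefined")
    return(list(ratio = NA_real_, n_agree = 0L, n_compared = 0L))
  }
  agree <- sum(sign(delta_a[both]) == sign(delta_b[both]))
  list(ratio = agree / n, n_agree = agree, n_compared = n)
}

#' Combine p-values by the summation-of-p (Edgington) method
#'
#' The combined p-value is `P(U1 + ... + Uk <= S)` for independent
#' Uniform(0,1) variables, where S is the sum of the observed p-values —
#' the Irwin-Hall CDF, evaluated in its exact inclusion-exclusion form
#' `F(S) = (1/k!) * sum_{j=0}^{floor(S)} (-1)^j C(k,j) (S-j)^k`, valid for
#' any S in \[0, k\].
#'
#' @param p_values Numeric vector of p-values in (0, 1\].
#' @return The combined p-value.
#' @examples
#' meta_sum_p(c(0.1, 0.1))  # 0.02
#' @export
meta_sum_p <- function(p_values) {
  if (length(p_values) < 1L) stop("at least one p-value is required")
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  k <- length(p_values)
  S <- sum(p_values)
  if (S >= k) return(1)
  j <- 0:floor(S)
  val <- sum((-1)^j * choose(k, j) * (S - j)^k) / factorial(k)
  min(max(val, 0), 1)
}

#' Fixed-effect (inverse-variance) meta-analysis
#'
#' Combines per-study effect sizes with weights `1/se^2`. Reports the
#' combined effect, its standard error, z and two-sided p, and Cochran's Q
#' homogeneity statistic with its chi-square p-value on k - 1 degrees of
#' freedom.
#'
#' @param effects Per-study effect estimates (k >= 2).
#' @param ses Per-study standard errors (> 0).
#' @return A list with `effect`, `se`, `z`, `p`, `Q`, `Q_df`, `Q_p`,
#'   `weights` (normalized to sum to 1).
#' @export
meta_fixed_effect <- function(effects, ses) {
  k <- length(effects)
  if (k < 2L) stop("at least 2 studies are required")
  if (length(ses) != k) stop("effects and ses must align")
  if (any(is.na(ses)) || any(ses <= 0)) stop("standard errors must be > 0")
  w <- 1 / ses^2
  eff <- sum(w * effects) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- eff / se
  Q <- sum(w * (effects - eff)^2)
  list(effect = eff, se = se, z = z, p = 2 * stats::pnorm(-abs(z)),
       Q = Q, Q_df = k - 1L, Q_p = stats::pchisq(Q, k - 1L, lower.tail = FALSE),
       weights = w / sum(w))
}

#' Association between DMR methylation and a covariate
#'
#' Simple linear regression of per-sample (or per-pair difference) DMR
#' methylation summaries on a covariate; the null hypothesis is a zero
#' slope. Binary covariates are encoded 0/1.
#'
#' @param dmr_values Numeric response (n >= 3).
#' @param covariate Numeric, logical, or two-level factor/character.
#' @return A list with `slope` and `p` (two-sided t-test on the slope).
#' @export
covariate_association <- function(dmr_values, covariate) {
  if (is.character(covariate) || is.factor(covariate)) {
    lev <- unique(as.character(covariate))
    if (length(lev) != 2L) stop("non-numeric covariates must have 2 levels")
    covariate <- as.numeric(as.character(covariate) == lev[2L])
  }
  covariate <- as.numeric(covariate)
  if (length(dmr_values) < 3L) stop("at least 3 observations are required")
  if (stats::sd(covariate) < 1e-12) stop("covariate is constant")
  fit <- stats::lm(dmr_values ~ covariate)
  cf <- summary(fit)$coefficients
  list(slope = cf["covariate", "Estimate"],
       p = cf["covariate", "Pr(>|t|)"])
}

#' Kolmogorov-Smirnov comparison of two sets of differences
#'
#' Two-sample KS statistic (supremum distance between the empirical CDFs)
#' with the asymptotic p-value; used to compare the distributions of
#' within-pair methylation differences between strata (e.g. male vs
#' female pairs) at the top differentially methylated probes.
#'
#' @param diffs_a,diffs_b Non-empty numeric vectors.
#' @return A list with `statistic` and `p`.
#' @export
ks_compare_differences <- function(diffs_a, diffs_b) {
  if (length(diffs_a) == 0L || length(diffs_b) == 0L) {
    stop("both groups must be non-empty")
  }
  kt <- suppressWarnings(stats::ks.test(diffs_a, diffs_b, exact = FALSE))
  list(statistic = unname(kt$statistic), p = kt$p.value)
}
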