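# Shared fixtures and independent oracles. Oracles deliberately avoid the
# package's code paths: enumeration, brute-force recomputation, closed
# forms.

# A tiny design with `n_regions` regions of exactly `probes_per_region`
# probes, deterministic layout.
tiny_design <- function(n_regions = 5L, probes_per_region = 10L,
                        n_control = 30L, seed = 42L) {
  generate_array_design(n_regions,
                        c(probes_per_region, probes_per_region),
                        control_fraction = 0, n_control = n_control,
                        seed = seed)
}

# A cohort sheet of n complete pairs without simulating methylation.
tiny_cohort <- function(n_pairs) {
  pair <- sprintf("pair%02d", seq_len(n_pairs))
  data.frame(
    sample_id = as.vector(rbind(paste0(pair, "_case"), paste0(pair, "_ctrl"))),
    pair_id = rep(pair, each = 2L),
    phenotype = rep(c("case", "control"), n_pairs),
    batch = "B1", stringsAsFactors = FALSE)
}

# A methylation matrix with given per-pair, per-probe structure:
# base + case shift, columns ordered as tiny_cohort.
meth_from_pairs <- function(base, shift, cohort) {
  n <- length(base)
  m <- matrix(rep(base, nrow(cohort)), nrow = n)
  m[, cohort$phenotype == "case"] <- m[, cohort$phenotype == "case"] + shift
  rownames(m) <- names(base) %||% sprintf("p%03d", seq_len(n))
  colnames(m) <- cohort$sample_id
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Oracle: exhaustive sign-flip permutation p for pair differences d.
oracle_perm_p <- function(d) {
  S <- as.matrix(expand.grid(rep(list(c(-1, 1)), length(d))))
  stats <- as.vector(S %*% d) / length(d)
  mean(abs(stats) >= abs(mean(d)) - 1e-12)
}

# Oracle: brute-force BH step-up discoveries at level q.
oracle_bh_discoveries <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- which(ps <= q * seq_len(m) / m)
  if (length(k) == 0L) return(integer(0))
  sort(ord[seq_len(max(k))])
}

# Oracle: brute-force BH q-values (step-up with monotonicity).
oracle_bh_q <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# Oracle: simplex grid search at `step` for 3 cell types.
oracle_simplex_grid3 <- function(x, B, step = 0.001) {
  n <- round(1 / step)
  i <- rep(0:n, times = n + 1 - 0:n)
  j <- sequence(n + 1 - 0:n) - 1L
  W <- cbind(i, j, n - i - j) * step
  obj <- colSums((t(W %*% B) - x)^2)
  W[which.min(obj), ]
}

# Oracle: two-sample KS statistic by direct ECDF enumeration.
oracle_ks_stat <- function(a, b) {
  xs <- sort(unique(c(a, b)))
  max(abs(vapply(xs, function(x) mean(a <= x) - mean(b <= x), numeric(1))))
}

# Standard small simulated twin dataset used across tests.
sim_dataset <- function(n_regions = 100L, n_pairs = 5L, delta = 0.15,
                        planted_region = sprintf("r%05d", min(10L, n_regions)),
                        noise_sd = 0.05,
                        seed = 7L, share_pair_weights = FALSE,
                        probes_per_region = c(8L, 12L)) {
  design <- generate_array_design(n_regions, probes_per_region, 0.05,
                                  seed = seed)
  ref <- generate_cell_reference(design, n_marker_regions = max(5L, n_regions %/% 10L),
                                 seed = seed + 1L)
  planted <- if (!is.null(planted_region)) {
    data.frame(region_id = planted_region, delta = delta,
               stringsAsFactors = FALSE)
  }
  cfg <- simulation_config(n_pairs = n_pairs, planted_dmrs = planted,
                           noise_sd = noise_sd,
                           share_pair_weights = share_pair_weights,
                           seed = seed + 2L)
  sim <- simulate_twin_cohort(design, ref, cfg)
  c(sim, list(design = design, reference = ref, config = cfg))
}
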