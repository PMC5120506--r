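# Synthetic tiling-array data: CHARM-like designs, sorted-cell reference
# panels, and paired twin cohorts with planted DMRs and cell-mixture
# structure. Every generator returns full ground truth so downstream
# stages can be tested against known answers.

#' Generate a CHARM-like tiling array design
#'
#' Lays out `n_regions` genomic regions of densely tiled probes across
#' chromosomes, separated by at least 1 kb, plus a set of CpG-free control
#' probes placed in the gaps between regions. Within a region, probe
#' positions increase strictly with inter-probe gaps drawn uniformly from
#' `probe_gap` (at most 100 bp, mimicking tiling density). Each probe gets
#' a quality score drawn from `quality_range` so that quality filtering has
#' realistic work to do.
#'
#' @param n_regions Number of non-control regions (may be 0).
#' @param probes_per_region Integer range `c(min, max)` of probes per region.
#' @param control_fraction Fraction of all probes that are control probes.
#' @param seed Integer seed for reproducibility.
#' @param chroms Chromosome labels to cycle regions over.
#' @param region_gap Range of gaps (bp) between consecutive regions; the
#'   minimum must be >= 1000.
#' @param probe_gap Range of within-region inter-probe gaps (bp); max <= 100.
#' @param n_control Override for the number of control probes (default is
#'   derived from `control_fraction`).
#' @param quality_range Range of per-probe quality scores in \[0, 100\].
#' @return A data.frame with columns `probe_id`, `chrom`, `pos` (1-based),
#'   `region_id` (`NA` for controls), `is_control`, `quality`.
#' @examples
#' design <- generate_array_design(10, c(8, 12), 0.05, seed = 1)
#' table(design$is_control)
#' @export
generate_array_design <- function(n_regions,
                                  probes_per_region = c(8L, 12L),
                                  control_fraction = 0.02,
                                  seed = NULL,
                                  chroms = paste0("chr", 1:8),
                                  region_gap = c(1000L, 5000L),
                                  probe_gap = c(30L, 100L),
                                  n_control = NULL,
                                  quality_range = c(60, 100)) {
  if (length(probes_per_region) != 2L || probes_per_region[1] > probes_per_region[2]) {
    stop("probes_per_region must be c(min, max) with min <= max")
  }
  if (any(probes_per_region < 1L)) stop("probes_per_region bounds must be >= 1")
  if (n_regions < 0L) stop("n_regions must be >= 0")
  if (control_fraction < 0 || control_fraction >= 1) {
    stop("control_fraction must lie in [0, 1)")
  }
  if (region_gap[1] < 1000L) stop("regions must be separated by >= 1 kb")
  if (probe_gap[2] > 100L) stop("within-region probe gaps must be <= 100 bp")

  with_seed(seed, {
    rows <- list()
    gaps <- list()  # candidate intervals for control probes
    cursor <- stats::setNames(rep(1L, length(chroms)), chroms)
    probe_n <- 0L
    for (r in seq_len(n_regions)) {
      chrom <- chroms[((r - 1L) %% length(chroms)) + 1L]
      gap <- floor(stats::runif(1, region_gap[1], region_gap[2] + 1))
      gap_start <- cursor[[chrom]] + 100L
      start <- cursor[[chrom]] + as.integer(gap)
      if (gap_start < start - 100L) {
        gaps[[length(gaps) + 1L]] <-
          list(chrom = chrom, lo = gap_start, hi = start - 100L)
      }
      np <- if (probes_per_region[1] == probes_per_region[2]) {
        probes_per_region[1]
      } else {
        sample(probes_per_region[1]:probes_per_region[2], 1L)
      }
      steps <- floor(stats::runif(np - 1L, probe_gap[1], probe_gap[2] + 1))
      pos <- as.integer(start + cumsum(c(0L, steps)))
      rows[[r]] <- data.frame(
        probe_id = sprintf("p%07d", probe_n + seq_len(np)),
        chrom = chrom,
        pos = pos,
        region_id = sprintf("r%05d", r),
        is_control = FALSE,
        stringsAsFactors = FALSE
      )
      probe_n <- probe_n + np
      cursor[[chrom]] <- pos[np]
    }
    n_noncontrol <- probe_n
    if (is.null(n_control)) {
      n_control <- if (control_fraction == 0) {
        0L
      } else if (n_noncontrol > 0L) {
        as.integer(round(control_fraction / (1 - control_fraction) * n_noncontrol))
      } else {
        100L
      }
    }
    ctrl <- NULL
    if (n_control > 0L) {
      if (length(gaps) == 0L) {
        # no inter-region gaps (e.g. empty design): park controls on the
        # first chromosome beyond any region probes
        base <- max(c(1L, vapply(rows, function(d) max(d$pos), 1L)))
        ctrl <- data.frame(
          probe_id = sprintf("ctrl%05d", seq_len(n_control)),
          chrom = chroms[1], pos = base + 1000L + seq_len(n_control) * 50L,
          region_id = NA_character_, is_control = TRUE,
          stringsAsFactors = FALSE
        )
      } else {
        pick <- sample(length(gaps), n_control, replace = TRUE)
        ctrl <- data.frame(
          probe_id = sprintf("ctrl%05d", seq_len(n_control)),
          chrom = vapply(gaps[pick], `[[`, "", "chrom"),
          pos = vapply(gaps[pick], function(g) {
            as.integer(floor(stats::runif(1, g$lo, g$hi + 1)))
          }, 1L),
          region_id = NA_character_, is_control = TRUE,
          stringsAsFactors = FALSE
        )
      }
    }
    design <- rbind(do.call(rbind, rows), ctrl)
    if (is.null(design)) {
      design <- data.frame(probe_id = character(), chrom = character(),
                           pos = integer(), region_id = character(),
                           is_control = logical(), stringsAsFactors = FALSE)
    }
    design$quality <- stats::runif(nrow(design), quality_range[1], quality_range[2])
    rownames(design) <- NULL
    design
  })
}

#' Generate a sorted-cell reference panel
#'
#' Builds true cell-type-specific methylation profiles over an array design
#' and emits noisy replicate samples per cell type, emulating methylation
#' profiling of flow-sorted leukocyte populations. In each of
#' `n_marker_regions` randomly chosen marker regions, one designated cell
#' type is shifted away from the shared baseline by at least 0.2 on the
#' proportion scale; everywhere else all cell types share a common
#' baseline. Control probes sit near zero methylation for all cell types.
#'
#' @param design Array design from [generate_array_design()].
#' @param cell_types Character vector of at least two cell-type labels.
#' @param n_marker_regions Number of regions carrying a cell-type marker.
#' @param n_replicates Replicate samples per cell type.
#' @param noise_sd Gaussian noise sd added to replicates (proportion scale).
#' @param effect_range Range of the marker effect size (min >= 0.2).
#' @param baseline_range Range of the shared regional baseline.
#' @param seed Integer seed.
#' @return A list with elements `meth` (probes x samples matrix), `labels`
#'   (cell type of each column), `truth` (probes x cell-types matrix of
#'   true profiles), and `markers` (data.frame of marker regions with the
#'   designated cell type and signed effect).
#' @export
generate_cell_reference <- function(design,
                                    cell_types = c("neutrophil", "CD4T", "CD8T", "CD56NK"),
                                    n_marker_regions = 40L,
                                    n_replicates = 5L,
                                    noise_sd = 0.01,
                                    effect_range = c(0.2, 0.25),
                                    baseline_range = c(0.3, 0.7),
                                    seed = NULL) {
  if (length(cell_types) < 2L) stop("at least 2 cell types are required")
  regions <- unique(design$region_id[!design$is_control])
  if (n_marker_regions > length(regions)) {
    stop("n_marker_regions exceeds the number of regions in the design")
  }
  if (effect_range[1] < 0.2) stop("marker effect floor must be >= 0.2")
  K <- length(cell_types)
  with_seed(seed, {
    n <- nrow(design)
    base_region <- stats::setNames(
      stats::runif(length(regions), baseline_range[1], baseline_range[2]), regions)
    baseline <- numeric(n)
    nc <- !design$is_control
    baseline[nc] <- base_region[design$region_id[nc]] +
      stats::runif(sum(nc), -0.05, 0.05)
    baseline[!nc] <- stats::runif(sum(!nc), 0.01, 0.08)
    truth <- matrix(baseline, nrow = n, ncol = K,
                    dimnames = list(design$probe_id, cell_types))
    marker_regions <- sample(regions, n_marker_regions)
    designated <- sample(cell_types, n_marker_regions, replace = TRUE)
    effect <- stats::runif(n_marker_regions, effect_range[1], effect_range[2]) *
      sample(c(-1, 1), n_marker_regions, replace = TRUE)
    for (i in seq_len(n_marker_regions)) {
      idx <- which(!design$is_control & design$region_id == marker_regions[i])
      truth[idx, designated[i]] <- clip01(truth[idx, designated[i]] + effect[i])
    }
    labels <- rep(cell_types, each = n_replicates)
    meth <- truth[, labels, drop = FALSE]
    if (noise_sd > 0) {
      meth <- clip01(meth + matrix(stats::rnorm(length(meth), 0, noise_sd),
                                   nrow = n))
    }
    colnames(meth) <- paste0(labels, "_rep", rep(seq_len(n_replicates), K))
    rownames(meth) <- design$probe_id
    list(meth = meth, labels = labels, truth = truth,
         markers = data.frame(region_id = marker_regions,
                              cell_type = designated, effect = effect,
                              stringsAsFactors = FALSE))
  })
}

#' Simulation configuration for a twin cohort
#'
#' Collects and validates all knobs of the twin-cohort generator. The
#' defaults describe the study conditions the package is calibrated
#' against: five discordant monozygotic pairs, several hundred tiled
#' regions, four leukocyte types with a neutrophil-dominated Dirichlet
#' mixture, and proportion-scale Gaussian noise.
#'
#' @param n_pairs Number of twin pairs (one case + one control each).
#' @param cell_types Ordered cell-type labels matching the reference panel.
#' @param dirichlet_alpha Per-cell-type Dirichlet concentrations used to
#'   draw mixing proportions (strictly positive). The default
#'   `c(12, 4, 2, 2)` centers the mixture at roughly 60% neutrophils, 20%
#'   CD4 T, 10% CD8 T, 10% NK — typical for whole blood restricted to
#'   these four types.
#' @param planted_dmrs `NULL`, or a data.frame with columns `region_id` and
#'   `delta` (signed phenotype effect on the proportion scale, |delta| <= 0.5)
#'   marking regions where cases are shifted relative to their co-twin.
#' @param noise_sd Gaussian noise sd on the proportion scale.
#' @param proportion_shift Optional per-cell-type additive shift applied to
#'   case samples' mixing proportions (re-projected onto the simplex).
#' @param pair_baseline_sd SD of the pair-level baseline perturbation shared
#'   by both twins of a pair (removed by paired differencing).
#' @param share_pair_weights If `TRUE`, both twins of a pair share one
#'   mixing-proportion draw (isolates the phenotype effect).
#' @param batch Batch label stamped on all samples.
#' @param batch_effect Additive per-batch intercept on the proportion scale.
#' @param seed Integer seed.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_pairs = 5L,
                              cell_types = c("neutrophil", "CD4T", "CD8T", "CD56NK"),
                              dirichlet_alpha = c(12, 4, 2, 2),
                              planted_dmrs = NULL,
                              noise_sd = 0.05,
                              proportion_shift = NULL,
                              pair_baseline_sd = 0.02,
                              share_pair_weights = FALSE,
                              batch = "B1",
                              batch_effect = 0,
                              seed = NULL) {
  if (n_pairs < 1L) stop("n_pairs must be >= 1")
  if (length(dirichlet_alpha) != length(cell_types)) {
    stop("dirichlet_alpha must have one entry per cell type")
  }
  if (any(dirichlet_alpha <= 0)) stop("dirichlet_alpha must be strictly positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(planted_dmrs)) {
    stopifnot(is.data.frame(planted_dmrs),
              all(c("region_id", "delta") %in% names(planted_dmrs)))
    if (any(abs(planted_dmrs$delta) > 0.5)) stop("|delta| must be <= 0.5")
  }
  if (!is.null(proportion_shift) &&
      length(proportion_shift) != length(cell_types)) {
    stop("proportion_shift must have one entry per cell type")
  }
  structure(list(n_pairs = as.integer(n_pairs), cell_types = cell_types,
                 dirichlet_alpha = dirichlet_alpha, planted_dmrs = planted_dmrs,
                 noise_sd = noise_sd, proportion_shift = proportion_shift,
                 pair_baseline_sd = pair_baseline_sd,
                 share_pair_weights = share_pair_weights,
                 batch = batch, batch_effect = batch_effect, seed = seed),
            class = "simulation_config")
}

# Dirichlet draws via normalized gammas; rows are simplex vectors.
rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha, rate = 1),
              nrow = n, byrow = TRUE)
  x / rowSums(x)
}

#' Simulate a discordant twin cohort with known ground truth
#'
#' Each sample's proportion-scale methylation at probe j is the mixture
#' `sum_k w_k * mu_k(j)` over the reference profiles, plus a pair-level
#' baseline perturbation shared by both twins, plus `delta` at planted DMR
#' probes for case samples, plus Gaussian noise, clipped to \[0, 1\].
#'
#' @param design Array design covering all probes of `reference`.
#' @param reference True cell-type profiles: either the list returned by
#'   [generate_cell_reference()] or a probes x cell-types matrix.
#' @param config A [simulation_config()].
#' @return A list with `meth` (probes x samples), `cohort` (sample sheet
#'   data.frame), and `truth` (planted intervals, true mixing proportions,
#'   reference profiles, pair baselines).
#' @export
simulate_twin_cohort <- function(design, reference, config) {
  stopifnot(inherits(config, "simulation_config"))
  mu <- if (is.list(reference) && !is.data.frame(reference)) reference$truth else reference
  if (!all(design$probe_id %in% rownames(mu))) {
    stop("reference must cover all probes of the design")
  }
  mu <- mu[design$probe_id, config$cell_types, drop = FALSE]
  if (!is.null(config$planted_dmrs)) {
    missing <- setdiff(config$planted_dmrs$region_id,
                       design$region_id[!design$is_control])
    if (length(missing)) {
      stop("planted region id(s) absent from design: ",
           paste(missing, collapse = ", "))
    }
  }
  n_pairs <- config$n_pairs
  K <- length(config$cell_types)
  with_seed(config$seed, {
    pair_ids <- sprintf("pair%02d", seq_len(n_pairs))
    sample_ids <- as.vector(rbind(paste0(pair_ids, "_case"),
                                  paste0(pair_ids, "_ctrl")))
    phenotype <- rep(c("case", "control"), n_pairs)
    pair_of <- rep(pair_ids, each = 2L)

    W <- if (config$share_pair_weights) {
      wp <- rdirichlet(n_pairs, config$dirichlet_alpha)
      wp[rep(seq_len(n_pairs), each = 2L), , drop = FALSE]
    } else {
      rdirichlet(2L * n_pairs, config$dirichlet_alpha)
    }
    if (!is.null(config$proportion_shift)) {
      is_case <- phenotype == "case"
      shifted <- W[is_case, , drop = FALSE] +
        matrix(config$proportion_shift, sum(is_case), K, byrow = TRUE)
      shifted <- pmax(shifted, 0)
      W[is_case, ] <- shifted / rowSums(shifted)
    }
    dimnames(W) <- list(sample_ids, config$cell_types)

    meth <- mu %*% t(W)
    pair_baseline <- stats::rnorm(n_pairs, 0, config$pair_baseline_sd)
    meth <- meth + matrix(rep(pair_baseline, each = 2L),
                          nrow(meth), 2L * n_pairs, byrow = TRUE)
    planted <- NULL
    if (!is.null(config$planted_dmrs) && nrow(config$planted_dmrs) > 0L) {
      for (i in seq_len(nrow(config$planted_dmrs))) {
        rid <- config$planted_dmrs$region_id[i]
        idx <- which(!design$is_control & design$region_id == rid)
        meth[idx, phenotype == "case"] <-
          meth[idx, phenotype == "case"] + config$planted_dmrs$delta[i]
      }
      planted <- do.call(rbind, lapply(seq_len(nrow(config$planted_dmrs)), function(i) {
        rid <- config$planted_dmrs$region_id[i]
        idx <- which(!design$is_control & design$region_id == rid)
        data.frame(region_id = rid, chrom = design$chrom[idx[1]],
                   start = min(design$pos[idx]), end = max(design$pos[idx]),
                   delta = config$planted_dmrs$delta[i], stringsAsFactors = FALSE)
      }))
    }
    meth <- meth + config$batch_effect
    if (config$noise_sd > 0) {
      meth <- meth + matrix(stats::rnorm(length(meth), 0, config$noise_sd),
                            nrow(meth))
    }
    meth <- clip01(meth)
    dimnames(meth) <- list(design$probe_id, sample_ids)

    age <- rep(as.integer(round(stats::runif(n_pairs, 50, 80))), each = 2L)
    sex <- rep(sample(c("F", "M"), n_pairs, replace = TRUE), each = 2L)
    smoking <- stats::rbinom(2L * n_pairs, 1L, 0.35)
    hla_se <- rep(stats::rbinom(n_pairs, 1L, 0.5), each = 2L)
    cohort <- data.frame(sample_id = sample_ids, pair_id = pair_of,
                         phenotype = phenotype, batch = config$batch,
                         age = age, sex = sex, smoking = smoking,
                         hla_se = hla_se, stringsAsFactors = FALSE)
    list(meth = meth, cohort = cohort,
         truth = list(planted = planted, proportions = W, reference = mu,
                      pair_baseline = stats::setNames(pair_baseline, pair_ids)))
  })
}

#' Emit stylized two-channel intensities from a methylation matrix
#'
#' A stylized emission model for exercising the normalization code:
#' per-probe total intensity S is drawn log-normal, the methylation-enriched
#' (treated) channel carries `p * S` and the depleted (untreated) channel
#' `(1 - p) * S`, so `treated / (treated + untreated)` recovers p exactly.
#' This is not a model of array chemistry.
#'
#' @param meth Probes x samples methylation matrix (proportions).
#' @param meanlog,sdlog Log-normal parameters for the total intensity.
#' @param seed Integer seed.
#' @return A list with matrices `treated` and `untreated`.
#' @export
emit_two_channel <- function(meth, meanlog = log(1000), sdlog = 0.4, seed = NULL) {
  with_seed(seed, {
    p <- pmin(pmax(meth, 1e-6), 1 - 1e-6)
    S <- matrix(stats::rlnorm(length(meth), meanlog, sdlog), nrow(meth))
    dimnames(S) <- dimnames(meth)
    list(treated = p * S, untreated = (1 - p) * S)
  })
}
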