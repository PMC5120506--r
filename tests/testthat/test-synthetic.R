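# The synthetic tiling-array generator: layout invariants, planted
# effects, mixture structure, and reproducibility.

test_that("array design layout respects tiling constraints", {
  design <- generate_array_design(50, c(8, 12), 0.05, seed = 1)
  nc <- design[!design$is_control, ]
  expect_true(all(is.na(design$region_id[design$is_control])))
  expect_true(all(design$quality >= 0 & design$quality <= 100))
  expect_false(anyDuplicated(design$probe_id) > 0)
  for (rid in unique(nc$region_id)) {
    pos <- nc$pos[nc$region_id == rid]
    expect_true(all(diff(pos) > 0))
    expect_true(all(diff(pos) <= 100))
  }
  # regions on the same chromosome are >= 1 kb apart
  for (ch in unique(nc$chrom)) {
    sub <- nc[nc$chrom == ch, ]
    spans <- do.call(rbind, lapply(split(sub$pos, sub$region_id), range))
    spans <- spans[order(spans[, 1]), , drop = FALSE]
    if (nrow(spans) > 1) {
      expect_true(all(spans[-1, 1] - spans[-nrow(spans), 2] >= 1000))
    }
  }
})

test_that("design edge cases: empty, no controls, fixed region size", {
  empty <- generate_array_design(0, c(5, 5), 0.5, seed = 1)
  expect_true(all(empty$is_control))
  expect_gt(nrow(empty), 0)

  no_ctrl <- generate_array_design(100, c(8, 12), 0, seed = 2)
  expect_equal(sum(no_ctrl$is_control), 0)
  expect_true(nrow(no_ctrl) >= 800 && nrow(no_ctrl) <= 1200)

  fixed <- generate_array_design(50, c(10, 10), 0, seed = 1)
  expect_equal(sum(!fixed$is_control), 500)
  expect_true(all(table(fixed$region_id) == 10))

  expect_error(generate_array_design(10, c(12, 8)), "min <= max")
})

test_that("design generation is reproducible under a fixed seed", {
  a <- generate_array_design(20, c(8, 12), 0.05, seed = 9)
  b <- generate_array_design(20, c(8, 12), 0.05, seed = 9)
  expect_identical(a, b)
})

test_that("cell reference plants markers with the promised structure", {
  design <- tiny_design(40, 10)
  ref <- generate_cell_reference(design, n_marker_regions = 40,
                                 n_replicates = 1, noise_sd = 0, seed = 3)
  # zero-noise replicates equal the truth
  expect_equal(unname(ref$meth), unname(ref$truth[, ref$labels]),
               tolerance = 1e-12)
  # designated assignments cover all marker regions
  expect_equal(nrow(ref$markers), 40)
  expect_setequal(unique(ref$markers$cell_type),
                  intersect(c("neutrophil", "CD4T", "CD8T", "CD56NK"),
                            ref$markers$cell_type))
  # marker effect floor: outlier vs baseline >= 0.2 at every marker probe
  for (i in seq_len(nrow(ref$markers))) {
    idx <- which(!design$is_control &
                   design$region_id == ref$markers$region_id[i])
    ct <- ref$markers$cell_type[i]
    others <- setdiff(colnames(ref$truth), ct)
    gap <- abs(ref$truth[idx, ct] - rowMeans(ref$truth[idx, others]))
    expect_true(all(gap >= 0.2 - 1e-9))
  }
  expect_error(generate_cell_reference(design, cell_types = "only_one"),
               "2 cell types")
})

test_that("zero-noise cohort with shared weights gives identical twins", {
  design <- tiny_design(10, 10)
  ref <- generate_cell_reference(design, n_marker_regions = 2,
                                 noise_sd = 0, seed = 4)
  cfg <- simulation_config(n_pairs = 4, noise_sd = 0,
                           share_pair_weights = TRUE, seed = 5)
  sim <- simulate_twin_cohort(design, ref, cfg)
  for (pr in unique(sim$cohort$pair_id)) {
    cols <- sim$cohort$sample_id[sim$cohort$pair_id == pr]
    expect_equal(sim$meth[, cols[1]], sim$meth[, cols[2]])
  }
})

test_that("planted delta is recovered exactly in the noiseless cohort", {
  design <- tiny_design(10, 10)
  ref <- generate_cell_reference(design, n_marker_regions = 2,
                                 noise_sd = 0, seed = 4)
  cfg <- simulation_config(n_pairs = 4, noise_sd = 0,
                           share_pair_weights = TRUE,
                           planted_dmrs = data.frame(region_id = "r00003",
                                                     delta = 0.15),
                           seed = 6)
  sim <- simulate_twin_cohort(design, ref, cfg)
  idx <- which(!design$is_control & design$region_id == "r00003")
  d <- rowMeans(sim$meth[idx, sim$cohort$phenotype == "case"]) -
    rowMeans(sim$meth[idx, sim$cohort$phenotype == "control"])
  expect_equal(mean(d), 0.15, tolerance = 1e-12)
  # probes outside the planted region are untouched
  out <- setdiff(which(!design$is_control), idx)
  d_out <- sim$meth[out, sim$cohort$phenotype == "case"] -
    sim$meth[out, sim$cohort$phenotype == "control"]
  expect_equal(max(abs(d_out)), 0, tolerance = 1e-12)
})

test_that("mixing proportions follow the Dirichlet mean", {
  design <- tiny_design(5, 10)
  ref <- generate_cell_reference(design, n_marker_regions = 1,
                                 noise_sd = 0, seed = 4)
  alpha <- c(8, 5, 3, 2)
  cfg <- simulation_config(n_pairs = 20, dirichlet_alpha = alpha,
                           noise_sd = 0, seed = 3)
  sim <- simulate_twin_cohort(design, ref, cfg)
  W <- sim$truth$proportions
  expect_true(all(W >= 0))
  expect_equal(unname(rowSums(W)), rep(1, nrow(W)), tolerance = 1e-9)
  mean_target <- alpha / sum(alpha)
  # Dirichlet component sd / sqrt(n): 3 MC standard errors
  a0 <- sum(alpha)
  sds <- sqrt(alpha * (a0 - alpha) / (a0^2 * (a0 + 1))) / sqrt(nrow(W))
  expect_true(all(abs(colMeans(W) - mean_target) <= 3 * sds))
})

test_that("cohort values stay in [0,1] and bad planted regions are rejected", {
  sim <- sim_dataset(n_regions = 20, seed = 11)
  expect_true(all(sim$meth >= 0 & sim$meth <= 1))
  cfg_bad <- simulation_config(planted_dmrs = data.frame(region_id = "r99999",
                                                         delta = 0.1))
  expect_error(simulate_twin_cohort(sim$design, sim$reference, cfg_bad),
               "absent from design")
  expect_error(simulation_config(planted_dmrs = data.frame(region_id = "r00001",
                                                           delta = 0.7)),
               "<= 0.5")
  expect_error(simulation_config(dirichlet_alpha = c(1, 1, 0, 1)),
               "positive")
})

test_that("identical simulation configs give bitwise-identical cohorts", {
  a <- sim_dataset(n_regions = 10, seed = 21)
  b <- sim_dataset(n_regions = 10, seed = 21)
  expect_identical(a$meth, b$meth)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$truth, b$truth)
})

test_that("two-channel emission round-trips through estimate_methylation", {
  design <- tiny_design(5, 10)
  ref <- generate_cell_reference(design, n_marker_regions = 1,
                                 noise_sd = 0, seed = 4)
  cfg <- simulation_config(n_pairs = 3, noise_sd = 0, seed = 8)
  sim <- simulate_twin_cohort(design, ref, cfg)
  ch <- emit_two_channel(sim$meth, seed = 9)
  p <- estimate_methylation(ch$treated, ch$untreated)
  expect_lt(max(abs(p - sim$meth)), 1e-9)
})
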