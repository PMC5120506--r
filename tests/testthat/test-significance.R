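# Sign-flip permutation, the outlier filter, the resampled null pool,
# stratified FWER, and the dual-criterion call.

test_that("uniform pair differences give the two-boundary permutation p", {
  cohort <- tiny_cohort(5)
  meth <- meth_from_pairs(rep(0.4, 6), 0.1, cohort)
  r <- within_pair_permutation_p(rownames(meth), meth, cohort, "avg")
  expect_equal(r$n_permutations, 32L)
  expect_true(r$exhaustive)
  # only identity and the all-flipped assignment reach |0.1|
  expect_equal(r$p, 2 / 32)
  expect_equal(r$observed, 0.1, tolerance = 1e-12)
})

test_that("exhaustive permutation p matches the enumeration oracle", {
  set.seed(5)
  for (i in 1:30) {
    n <- sample(2:8, 1)
    cohort <- tiny_cohort(n)
    base <- runif(sample(1:6, 1), 0.2, 0.7)
    meth <- meth_from_pairs(base, 0, cohort)
    is_case <- cohort$phenotype == "case"
    meth[, is_case] <- meth[, is_case] +
      matrix(rnorm(length(base) * n, 0, 0.1), length(base))
    meth[] <- pmin(pmax(meth, 0), 1)
    for (stat in c("avg", "max")) {
      r <- within_pair_permutation_p(rownames(meth), meth, cohort, stat)
      d <- twindmr:::pair_summary_differences(rownames(meth), meth, cohort, stat)
      expect_identical(r$p, oracle_perm_p(d))
    }
  }
})

test_that("Monte-Carlo permutation agrees with the exhaustive value", {
  set.seed(6)
  cohort <- tiny_cohort(8)  # 2^8 = 256
  meth <- meth_from_pairs(runif(5, 0.3, 0.6), 0, cohort)
  is_case <- cohort$phenotype == "case"
  meth[, is_case] <- pmin(pmax(meth[, is_case] + rnorm(5 * 8, 0.03, 0.05), 0), 1)
  exact <- within_pair_permutation_p(rownames(meth), meth, cohort, "avg",
                                     cap = 4096)$p
  mc <- within_pair_permutation_p(rownames(meth), meth, cohort, "avg",
                                  cap = 255, seed = 1)
  expect_false(mc$exhaustive)
  se <- sqrt(exact * (1 - exact) / 255)
  expect_lt(abs(mc$p - exact), 3 * se + 1 / 255)
})

test_that("outlier-driven candidates get large permuted p and are excluded", {
  cohort <- tiny_cohort(5)
  meth <- meth_from_pairs(rep(0, 4), 0, cohort)
  meth[, cohort$sample_id[1]] <- 1  # one extreme pair, others identical
  r <- within_pair_permutation_p(rownames(meth), meth, cohort, "avg")
  d <- twindmr:::pair_summary_differences(rownames(meth), meth, cohort, "avg")
  expect_identical(r$p, oracle_perm_p(d))
  expect_gt(r$p, 0.1)  # flips of the null pairs never change |stat|
  cand <- data.frame(dmr_id = "x", p_avg = r$p, p_max = r$p)
  expect_equal(nrow(permutation_filter(cand, 0.1)$retained), 0)
})

test_that("the exclusion rule is a conjunction over both statistics", {
  cand <- data.frame(dmr_id = c("a", "b", "c"),
                     p_avg = c(0.05, 0.2, 0.5),
                     p_max = c(0.5, 0.2, 0.05))
  f <- permutation_filter(cand, 0.1)
  expect_equal(f$retained$dmr_id, c("a", "c"))
  expect_equal(f$excluded$dmr_id, "b")
  expect_match(f$excluded$reason, "both statistics")
})

test_that("the null pool is seed-reproducible and B is validated", {
  sim <- sim_dataset(n_regions = 30, seed = 71)
  fit <- fit_probe_model(sim$meth, sim$cohort)
  sm <- smooth_coefficients(fit$coef, sim$design)
  cand <- find_candidates(sm, sim$design, sim$meth, sim$cohort)
  cutoff <- attr(cand, "cutoff")
  p1 <- bootstrap_null(sim$meth, sim$design, sim$cohort, cutoff = cutoff,
                       B = 20, seed = 3)
  p2 <- bootstrap_null(sim$meth, sim$design, sim$cohort, cutoff = cutoff,
                       B = 20, seed = 3)
  expect_identical(p1, p2)
  expect_error(bootstrap_null(sim$meth, sim$design, sim$cohort,
                              cutoff = cutoff, B = 0), "B must be >= 1")
})

test_that("stratified FWER counts iteration maxima correctly", {
  # hand-built pool: 10 iterations with stratum maxima 0.1 ... 1.0
  pool <- data.frame(iteration = 1:10, nprobes = 5,
                     avg = seq(0.1, 1, by = 0.1),
                     max = seq(0.1, 1, by = 0.1),
                     area_raw = 5 * seq(0.1, 1, by = 0.1),
                     kept = TRUE)
  attr(pool, "B") <- 10L
  cand <- data.frame(dmr_id = "x", nprobes = 5, avg = 0.35, max = 0.35,
                     area_raw = 1.75)
  fw <- stratified_fwer(cand, pool, strata = c(-Inf, Inf))
  expect_equal(fw$fwer_avg, 7 / 10)   # maxima 0.4 ... 1.0
  expect_equal(fw$fwer_max, 7 / 10)

  # observed 0 -> every iteration max >= 0 -> FWER 1
  cand0 <- transform(cand, avg = 0, max = 0, area_raw = 0)
  expect_equal(stratified_fwer(cand0, pool, strata = c(-Inf, Inf))$fwer_avg, 1)

  # observed above all maxima -> 0, floored at 1/B
  cand_big <- transform(cand, avg = 2, max = 2, area_raw = 10)
  fw <- stratified_fwer(cand_big, pool, strata = c(-Inf, Inf))
  expect_equal(fw$fwer_avg, 0)
  expect_equal(fw$fwer_floor, 1 / 10)
})

test_that("FWER is monotone in |statistic| within a stratum", {
  sim <- sim_dataset(n_regions = 40, planted_region = NULL, seed = 81)
  fit <- fit_probe_model(sim$meth, sim$cohort)
  sm <- smooth_coefficients(fit$coef, sim$design)
  cand <- find_candidates(sm, sim$design, sim$meth, sim$cohort,
                          cutoff_quantile = 0.90)
  pool <- bootstrap_null(sim$meth, sim$design, sim$cohort,
                         cutoff = attr(cand, "cutoff"), B = 60, seed = 4)
  expect_gte(nrow(cand), 2)
  expect_gt(nrow(pool), 0)
  fw <- stratified_fwer(cand, pool, strata = c(-Inf, Inf))
  ord <- order(abs(fw$avg))
  expect_true(all(diff(fw$fwer_avg[ord]) <= 1e-12))
})

test_that("filtering the null pool never inflates FWER versus no filter", {
  sim <- sim_dataset(n_regions = 40, planted_region = NULL, seed = 91)
  fit <- fit_probe_model(sim$meth, sim$cohort)
  sm <- smooth_coefficients(fit$coef, sim$design)
  cand <- find_candidates(sm, sim$design, sim$meth, sim$cohort,
                          cutoff_quantile = 0.90)
  pool <- bootstrap_null(sim$meth, sim$design, sim$cohort,
                         cutoff = attr(cand, "cutoff"), B = 60, seed = 5)
  expect_gt(nrow(cand), 0)
  expect_gt(nrow(pool), 0)
  fw_filt <- stratified_fwer(cand, pool, strata = c(-Inf, Inf), filtered = TRUE)
  fw_all <- stratified_fwer(cand, pool, strata = c(-Inf, Inf), filtered = FALSE)
  expect_true(all(fw_filt$fwer_avg <= fw_all$fwer_avg + 1e-12))
  expect_true(all(fw_filt$fwer_max <= fw_all$fwer_max + 1e-12))
  expect_true(all(fw_filt$fwer_area <= fw_all$fwer_area + 1e-12))
})

test_that("the dual criterion requires one FWER hit and the permutation p", {
  cand <- data.frame(dmr_id = c("a", "b"), chrom = "chr1",
                     start = c(100L, 500L), end = c(200L, 600L),
                     nprobes = 5L,
                     fwer_avg = c(0.05, 0.15), fwer_max = c(0.5, 0.15),
                     fwer_area = c(0.5, 0.15),
                     p_avg = c(0.06, 0.06), p_max = c(0.5, 0.06))
  calls <- call_dmrs(cand, fwer_threshold = 0.10, perm_threshold = 0.1)
  expect_true(calls$pass[calls$dmr_id == "a"])
  expect_false(calls$pass[calls$dmr_id == "b"])
  expect_equal(calls$reason[calls$dmr_id == "b"], "fwer")
})
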