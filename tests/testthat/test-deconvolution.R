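# Marker discovery, reference building, informative-marker selection, the
# simplex-constrained least squares fit, and proportion comparisons.

make_panel <- function(n_regions = 40, n_markers = 20, noise_sd = 0,
                       seed = 101) {
  design <- tiny_design(n_regions, 10, seed = seed)
  ref <- generate_cell_reference(design, n_marker_regions = n_markers,
                                 n_replicates = 3, noise_sd = noise_sd,
                                 seed = seed + 1)
  list(design = design, ref = ref)
}

test_that("marker discovery recovers exactly the planted marker regions", {
  p <- make_panel()
  markers <- find_cell_type_dmrs(p$ref$meth, p$ref$labels, p$design)
  hit_regions <- unique(unlist(lapply(seq_len(nrow(markers)), function(i) {
    sel <- !p$design$is_control & p$design$chrom == markers$chrom[i] &
      p$design$pos >= markers$start[i] & p$design$pos <= markers$end[i]
    unique(p$design$region_id[sel])
  })))
  expect_setequal(hit_regions, p$ref$markers$region_id)
})

test_that("identical cell types yield zero markers", {
  p <- make_panel(n_markers = 0)
  markers <- find_cell_type_dmrs(p$ref$meth, p$ref$labels, p$design)
  expect_equal(nrow(markers), 0)
})

test_that("overlapping one-vs-rest candidates merge into one interval", {
  design <- tiny_design(1, 12)
  idx <- which(!design$is_control)
  types <- c("A", "B", "C")
  labels <- rep(types, each = 2)
  truth <- matrix(0.5, nrow(design), 3, dimnames = list(design$probe_id, types))
  truth[idx[1:8], "A"] <- 0.8    # A elevated over probes 1-8
  truth[idx[5:12], "B"] <- 0.2   # B depressed over probes 5-12
  meth <- truth[, labels]
  colnames(meth) <- paste0(labels, 1:2)
  markers <- find_cell_type_dmrs(meth, labels, design, cutoff = 0.1)
  expect_equal(nrow(markers), 1)
  expect_equal(markers$start, design$pos[idx[1]])
  expect_equal(markers$end, design$pos[idx[12]])
})

test_that("reference averaging follows its definition", {
  p <- make_panel()
  markers <- find_cell_type_dmrs(p$ref$meth, p$ref$labels, p$design)
  prof <- build_reference(p$ref$meth, markers, p$ref$labels)
  # zero-noise panel: B equals the true profile averaged over marker probes
  for (i in seq_len(nrow(prof$markers))) {
    pids <- prof$markers$probes[[i]]
    for (ct in prof$cell_types) {
      expect_equal(unname(prof$B[ct, i]),
                   mean(p$ref$truth[pids, ct]), tolerance = 1e-9)
    }
  }
  # two-probe arithmetic on a hand-built marker
  mini <- data.frame(marker_id = "m1", chrom = "chr1", start = 1L, end = 2L)
  mini$probes <- I(list(c("x", "y")))
  mm <- matrix(c(0.2, 0.4), 2, 1, dimnames = list(c("x", "y"), "s1"))
  pr <- build_reference(mm, mini, "A")
  expect_equal(unname(pr$B["A", "m1"]), 0.3)
})

test_that("informative-marker selection matches a brute-force ANOVA", {
  p <- make_panel(n_regions = 40, n_markers = 25, noise_sd = 0.02,
                  seed = 111)
  markers <- find_cell_type_dmrs(p$ref$meth, p$ref$labels, p$design)
  prof <- build_reference(p$ref$meth, markers, p$ref$labels)

  expect_equal(suppressWarnings(
    select_informative(prof, p$ref$meth, p$ref$labels,
                       k = nrow(prof$markers))$markers$marker_id),
    prof$markers$marker_id)

  top10 <- select_informative(prof, p$ref$meth, p$ref$labels, k = 10)
  # oracle: per-marker one-way ANOVA F via aov
  g <- factor(p$ref$labels)
  fstats <- vapply(seq_len(nrow(prof$markers)), function(i) {
    y <- colMeans(p$ref$meth[prof$markers$probes[[i]], , drop = FALSE])
    summary(aov(y ~ g))[[1]]$`F value`[1]
  }, numeric(1))
  oracle_top <- sort(order(-fstats)[1:10])
  expect_equal(top10$markers$marker_id, prof$markers$marker_id[oracle_top])
  expect_equal(top10$markers$score,
               fstats[oracle_top], tolerance = 1e-8)
})

test_that("a zero-variance marker ranks last", {
  B <- matrix(runif(12, 0.2, 0.8), 3, 4,
              dimnames = list(c("A", "B", "C"), paste0("m", 1:4)))
  labels <- rep(c("A", "B", "C"), each = 2)
  mk <- data.frame(marker_id = paste0("m", 1:4), chrom = "chr1",
                   start = 1:4 * 100L, end = 1:4 * 100L + 10L)
  pids <- paste0("p", 1:4)
  mk$probes <- I(as.list(pids))
  set.seed(2)
  meth <- matrix(runif(24, 0.2, 0.8), 4, 6, dimnames = list(pids, NULL))
  meth[2, ] <- 0.5  # flat across all cell types
  prof <- structure(list(B = B, markers = mk, cell_types = c("A", "B", "C")),
                    class = "cell_reference_profile")
  sel <- select_informative(prof, meth, labels, k = 3)
  expect_false("m2" %in% sel$markers$marker_id)
})

test_that("the simplex QP recovers exact and mixed profiles", {
  set.seed(9)
  B <- matrix(runif(4 * 30, 0.1, 0.9), 4, 30,
              dimnames = list(c("neutrophil", "CD4T", "CD8T", "CD56NK"), NULL))
  # pure profile -> unit vector
  r <- solve_simplex_lsq(B[2, ], B)
  expect_equal(unname(r$w), c(0, 1, 0, 0), tolerance = 1e-9)
  expect_lt(r$residual_norm, 1e-9)
  # two-component mixture
  x <- 0.6 * B[1, ] + 0.4 * B[2, ]
  r <- solve_simplex_lsq(x, B)
  expect_equal(unname(r$w), c(0.6, 0.4, 0, 0), tolerance = 1e-6)
  # underdetermined
  expect_error(solve_simplex_lsq(x[1:3], B[, 1:3]), "underdetermined")
})

test_that("QP output is optimal over random simplex directions", {
  set.seed(10)
  for (i in 1:10) {
    B <- matrix(runif(4 * 15, 0, 1), 4, 15)
    x <- runif(15)
    r <- solve_simplex_lsq(x, B)
    expect_equal(sum(r$w), 1, tolerance = 1e-8)
    expect_true(all(r$w >= -1e-9))
    obj <- function(w) sum((x - t(B) %*% w)^2)
    # no feasible perturbation reduces the objective
    for (j in 1:30) {
      v <- runif(4); v <- v / sum(v)
      for (step in c(1e-3, 1e-2)) {
        w2 <- (1 - step) * r$w + step * v
        expect_gte(obj(w2), r$objective - 1e-10)
      }
    }
  }
})

test_that("estimates are invariant to marker reordering", {
  p <- make_panel(seed = 121)
  markers <- find_cell_type_dmrs(p$ref$meth, p$ref$labels, p$design)
  prof <- build_reference(p$ref$meth, markers, p$ref$labels)
  cfg <- simulation_config(n_pairs = 2, noise_sd = 0.02, seed = 3)
  sim <- simulate_twin_cohort(p$design, p$ref, cfg)
  w1 <- estimate_proportions(sim$meth, prof)
  perm <- sample(nrow(prof$markers))
  prof2 <- prof
  prof2$markers <- prof$markers[perm, ]
  prof2$B <- prof$B[, perm]
  w2 <- estimate_proportions(sim$meth, prof2)
  expect_equal(w1, w2, tolerance = 1e-9)
})

test_that("covariate triple follows the neutrophil/NK/T mapping", {
  w <- data.frame(neutrophil = 0.5, CD4T = 0.2, CD8T = 0.2, CD56NK = 0.1)
  cov3 <- proportion_covariates(w)
  expect_equal(unname(cov3[1, ]), c(0.5, 0.1, 0.4))
  w2 <- data.frame(neutrophil = 1, CD4T = 0, CD8T = 0, CD56NK = 0)
  expect_equal(unname(proportion_covariates(w2)[1, ]), c(1, 0, 0))
  set.seed(4)
  W <- as.data.frame(twindmr:::rdirichlet(20, c(2, 2, 2, 2)))
  names(W) <- names(w)
  expect_equal(unname(rowSums(proportion_covariates(W))), rep(1, 20),
               tolerance = 1e-9)
  expect_error(proportion_covariates(data.frame(Xcell = 1)), "mapping")
})

test_that("paired proportion tests match the closed-form paired t", {
  cohort <- tiny_cohort(5)
  set.seed(12)
  w <- as.data.frame(twindmr:::rdirichlet(10, c(6, 3, 2, 2)))
  names(w) <- c("neutrophil", "CD4T", "CD8T", "CD56NK")
  rownames(w) <- cohort$sample_id
  # identical case/control -> zero-variance policy p = 1
  w_same <- w
  w_same[cohort$phenotype == "case", ] <- w_same[cohort$phenotype == "control", ]
  res <- compare_proportions(w_same, cohort)
  expect_true(all(res$tests$p == 1))

  # constant shift plus jitter: closed-form paired t
  w_shift <- w
  set.seed(13)
  w_shift$neutrophil[cohort$phenotype == "case"] <-
    w_shift$neutrophil[cohort$phenotype == "control"] + 0.1 + rnorm(5, 0, 1e-3)
  res <- compare_proportions(w_shift, cohort)
  d <- res$differences[, "neutrophil"]
  t_manual <- mean(d) / (sd(d) / sqrt(5))
  p_manual <- 2 * pt(-abs(t_manual), 4)
  row <- res$tests[res$tests$cell_type == "neutrophil", ]
  expect_equal(row$t, t_manual, tolerance = 1e-9)
  expect_equal(row$p, p_manual, tolerance = 1e-9)

  expect_error(compare_proportions(w[1:2, ], tiny_cohort(1)), "2 pairs")
})

test_that("paired t on null proportion differences is calibrated", {
  set.seed(14)
  nrep <- 1000
  rej <- 0
  cohort <- tiny_cohort(7)
  for (i in seq_len(nrep)) {
    w <- as.data.frame(matrix(runif(14, 0.1, 0.9), 14, 1))
    names(w) <- "neutrophil"
    w$CD4T <- 0; w$CD8T <- 0; w$CD56NK <- 1 - w$neutrophil
    rownames(w) <- cohort$sample_id
    p <- compare_proportions(w, cohort)$tests
    rej <- rej + (p$p[p$cell_type == "neutrophil"] < 0.05)
  }
  se <- sqrt(0.05 * 0.95 / nrep)
  expect_lt(abs(rej / nrep - 0.05), 3 * se)
})
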