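# Reference-based leukocyte deconvolution: one-vs-rest marker discovery on
# sorted-cell profiles, reference profile averaging, informative-marker
# selection by per-marker F-statistic, and a simplex-constrained least
# squares fit of each bulk sample's marker profile onto the reference.

#' Find cell-type marker DMRs from sorted-cell profiles
#'
#' For every cell type, computes the one-vs-rest per-probe mean methylation
#' difference (that cell type's replicates against all other sorted
#' samples), smooths it within regions, and extracts candidate runs with
#' the bump-hunting machinery at a fixed effect cutoff (default 0.1 on the
#' proportion scale, minimum 2 probes — sorted-cell contrasts are large).
#' Intervals pooled over cell types are merged wherever they overlap.
#'
#' @param sorted_meth Probes x samples matrix of sorted-cell methylation.
#' @param cell_labels Cell type of each column.
#' @param design Array design aligned to the rows.
#' @param cutoff Absolute effect cutoff on the smoothed difference.
#' @param min_probes Minimum probes per marker (>= 2).
#' @param max_gap Maximum gap (bp) within a marker run.
#' @param span Smoothing span.
#' @return A data.frame of deduplicated marker intervals (`marker_id`,
#'   `chrom`, `start`, `end`, `probes` list-column, `nprobes`).
#' @export
find_cell_type_dmrs <- function(sorted_meth, cell_labels, design,
                                cutoff = 0.1, min_probes = 2L,
                                max_gap = 300L, span = 0.75) {
  stopifnot(nrow(sorted_meth) == nrow(design))
  types <- unique(cell_labels)
  if (length(types) < 2L) stop("at least 2 cell types are required")
  if (!all(cell_labels %in% types)) stop("cell label missing from labels")
  reps <- table(cell_labels)
  if (any(reps < 2L)) {
    warning("fewer than 2 replicates for: ",
            paste(names(reps)[reps < 2L], collapse = ", "))
  }
  pieces <- list()
  for (ct in types) {
    d <- rowMeans(sorted_meth[, cell_labels == ct, drop = FALSE]) -
      rowMeans(sorted_meth[, cell_labels != ct, drop = FALSE])
    names(d) <- rownames(sorted_meth)
    sm <- smooth_coefficients(d, design, span = span)
    runs <- candidate_runs(sm, design, cutoff = cutoff,
                           min_probes = min_probes, max_gap = max_gap)
    if (nrow(runs)) pieces[[ct]] <- runs
  }
  if (length(pieces) == 0L) {
    return(data.frame(marker_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      probes = I(list()), nprobes = integer(),
                      stringsAsFactors = FALSE))
  }
  merged <- merge_intervals(do.call(rbind, pieces)[, c("chrom", "start", "end")])
  probes <- lapply(seq_len(nrow(merged)), function(i) {
    sel <- !design$is_control & design$chrom == merged$chrom[i] &
      design$pos >= merged$start[i] & design$pos <= merged$end[i]
    design$probe_id[sel]
  })
  out <- data.frame(marker_id = sprintf("marker%03d", seq_len(nrow(merged))),
                    chrom = merged$chrom, start = merged$start,
                    end = merged$end, stringsAsFactors = FALSE)
  out$probes <- I(probes)
  out$nprobes <- lengths(probes)
  out <- out[out$nprobes >= 2L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a cell-type reference profile over marker DMRs
#'
#' `B[k, m]` is the mean, over the replicates of cell type k, of the mean
#' methylation over the probes of marker m.
#'
#' @param sorted_meth Probes x samples sorted-cell methylation matrix.
#' @param markers Marker table from [find_cell_type_dmrs()].
#' @param cell_labels Cell type of each column.
#' @return A list of class `cell_reference_profile` with `B` (cell types x
#'   markers), `markers` (possibly reduced), `cell_types`.
#' @export
build_reference <- function(sorted_meth, markers, cell_labels) {
  if (nrow(markers) == 0L) stop("no markers supplied")
  types <- unique(cell_labels)
  marker_means <- marker_sample_means(sorted_meth, markers)
  ok <- !apply(marker_means, 1L, anyNA)
  if (!all(ok)) {
    warning(sum(!ok), " marker(s) without surviving probes dropped")
    markers <- markers[ok, , drop = FALSE]
    marker_means <- marker_means[ok, , drop = FALSE]
  }
  B <- matrix(NA_real_, length(types), nrow(markers),
              dimnames = list(types, markers$marker_id))
  for (ct in types) {
    B[ct, ] <- rowMeans(marker_means[, cell_labels == ct, drop = FALSE])
  }
  structure(list(B = B, markers = markers, cell_types = types),
            class = "cell_reference_profile")
}

# markers x samples matrix of per-sample mean methylation over each
# marker's probes (NA where no probe survives in the matrix).
marker_sample_means <- function(meth, markers) {
  out <- vapply(markers$probes, function(pids) {
    idx <- match(pids, rownames(meth))
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0L) return(rep(NA_real_, ncol(meth)))
    colMeans(meth[idx, , drop = FALSE])
  }, numeric(ncol(meth)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L)  # single sample
  out <- t(out)
  dimnames(out) <- list(markers$marker_id, colnames(meth))
  out
}

#' Select the most informative markers
#'
#' Scores each marker by the F-statistic of a one-way fit of its
#' sorted-cell marker means on the cell-type indicators and keeps the
#' top k, breaking ties by genomic order.
#'
#' @param reference A `cell_reference_profile`.
#' @param sorted_meth Probes x samples sorted-cell methylation matrix.
#' @param cell_labels Cell type of each column.
#' @param k Number of markers to keep (default 300; capped at the number
#'   available, with a warning).
#' @return A reduced `cell_reference_profile` with a `score` column on the
#'   markers.
#' @export
select_informative <- function(reference, sorted_meth, cell_labels, k = 300L) {
  stopifnot(inherits(reference, "cell_reference_profile"))
  markers <- reference$markers
  m <- nrow(markers)
  if (k > m) {
    warning("k exceeds the number of markers; keeping all ", m)
    k <- m
  }
  mm <- marker_sample_means(sorted_meth, markers)
  g <- factor(cell_labels)
  n <- ncol(mm)
  kg <- nlevels(g)
  group_means <- t(apply(mm, 1L, function(x) tapply(x, g, mean)))
  grand <- rowMeans(mm)
  n_per <- as.vector(table(g))
  ss_between <- colSums(t((group_means - grand)^2) * n_per)
  ss_within <- rowSums((mm - group_means[, as.integer(g), drop = FALSE])^2)
  f <- (ss_between / (kg - 1L)) / (ss_within / (n - kg))
  f[ss_within == 0 & ss_between > 0] <- Inf
  f[ss_between == 0] <- 0
  ord <- order(-f, markers$chrom, markers$start)
  keep <- sort(ord[seq_len(k)])
  out <- reference
  out$markers <- markers[keep, , drop = FALSE]
  out$markers$score <- f[keep]
  out$B <- reference$B[, keep, drop = FALSE]
  rownames(out$markers) <- NULL
  out
}

#' Simplex-constrained least squares (the deconvolution QP)
#'
#' Solves `argmin_w || x - t(B) w ||^2` subject to `w >= 0` and
#' `sum(w) = 1` exactly, by enumerating active sets: for every support the
#' equality-constrained least squares problem is solved via its KKT
#' system, and the feasible stationary point with the smallest objective
#' is returned. Deterministic, exact to solver tolerance, and practical
#' for reference panels of up to ~15 cell types.
#'
#' @param x Observed marker-mean vector (length = number of markers).
#' @param B Cell types x markers reference matrix.
#' @return A list with `w` (named simplex weights), `residual_norm`, and
#'   `objective`.
#' @export
solve_simplex_lsq <- function(x, B) {
  A <- t(B)                       # markers x cell types
  K <- ncol(A)
  ok <- !is.na(x)
  A <- A[ok, , drop = FALSE]
  x <- x[ok]
  if (nrow(A) < K) stop("fewer markers than cell types: underdetermined")
  AtA <- crossprod(A)
  Atx <- crossprod(A, x)
  best <- NULL
  for (size in seq_len(K)) {
    supports <- utils::combn(K, size, simplify = FALSE)
    for (S in supports) {
      k <- length(S)
      KKT <- rbind(cbind(2 * AtA[S, S, drop = FALSE], rep(1, k)),
                   c(rep(1, k), 0))
      sol <- tryCatch(solve(KKT, c(2 * Atx[S], 1)), error = function(e) NULL)
      if (is.null(sol)) next
      wS <- sol[seq_len(k)]
      if (any(wS < -1e-9)) next
      w <- numeric(K)
      w[S] <- pmax(wS, 0)
      w <- w / sum(w)
      obj <- sum((x - A %*% w)^2)
      if (is.null(best) || obj < best$objective - 1e-12) {
        best <- list(w = w, objective = obj)
      }
    }
  }
  if (is.null(best)) stop("no feasible solution found (singular reference?)")
  names(best$w) <- rownames(B)
  list(w = best$w, residual_norm = sqrt(best$objective),
       objective = best$objective)
}

#' Estimate cell-type proportions for bulk samples
#'
#' Computes each sample's marker-mean profile over the reference markers
#' and fits it onto the reference matrix under the simplex constraint
#' (proportions non-negative, summing to one). Markers without surviving
#' probes in the bulk matrix are dropped pairwise.
#'
#' @param meth Probes x samples bulk methylation matrix, or a precomputed
#'   markers x samples profile matrix (set `profile = TRUE`).
#' @param reference A `cell_reference_profile`.
#' @param profile Set `TRUE` when `meth` is already a marker-profile matrix.
#' @return A data.frame (class `proportion_estimate`): one row per sample
#'   with one column per cell type, plus `residual_norm`.
#' @export
estimate_proportions <- function(meth, reference, profile = FALSE) {
  stopifnot(inherits(reference, "cell_reference_profile"))
  X <- if (profile) meth else marker_sample_means(meth, reference$markers)
  res <- lapply(seq_len(ncol(X)), function(s) {
    fit <- solve_simplex_lsq(X[, s], reference$B)
    c(fit$w, residual_norm = fit$residual_norm)
  })
  out <- as.data.frame(do.call(rbind, res))
  rownames(out) <- colnames(X)
  class(out) <- c("proportion_estimate", "data.frame")
  out
}

#' Model covariates from estimated proportions
#'
#' Returns the three covariates entering the DMR model: the neutrophil
#' proportion, the NK proportion, and the summed CD4 + CD8 T-cell
#' proportion. Three of the four proportions are used to avoid
#' collinearity with the model intercept; the triple still sums to 1.
#'
#' @param w A `proportion_estimate` (or matrix/data.frame of proportions).
#' @param mapping Named list giving, for each covariate, the cell-type
#'   column(s) summed into it.
#' @return A samples x 3 matrix with columns `neutrophil`, `NK`, `T`.
#' @export
proportion_covariates <- function(w,
                                  mapping = list(neutrophil = "neutrophil",
                                                 NK = "CD56NK",
                                                 T = c("CD4T", "CD8T"))) {
  w <- as.data.frame(w)
  missing <- setdiff(unlist(mapping), names(w))
  if (length(missing)) {
    stop("cell type(s) not found in proportions: ",
         paste(missing, collapse = ", "),
         "; supply a mapping for nonstandard cell-type sets")
  }
  out <- vapply(mapping, function(cols) rowSums(w[, cols, drop = FALSE]),
                numeric(nrow(w)))
  if (nrow(w) == 1L) out <- matrix(out, nrow = 1L, dimnames = list(NULL, names(mapping)))
  rownames(out) <- rownames(w)
  out
}

#' Paired comparison of cell proportions between phenotypes
#'
#' Per cell type, computes the within-pair case-minus-control differences
#' of the estimated proportions and a two-sided paired t-test. Pairs with
#' identically zero differences across the board yield t = 0 and p = 1
#' (no evidence by convention).
#'
#' @param w Proportion estimates with one row per sample.
#' @param cohort Sample sheet with pairing and phenotype.
#' @return A list with `tests` (per cell type: mean difference, t, p) and
#'   `differences` (pairs x cell types matrix of within-pair differences).
#' @export
compare_proportions <- function(w, cohort) {
  validate_cohort(cohort)
  pairs <- unique(cohort$pair_id)
  if (length(pairs) < 2L) stop("at least 2 pairs are required")
  w <- as.data.frame(w)
  types <- setdiff(names(w), "residual_norm")
  dif <- vapply(types, function(ct) {
    vapply(pairs, function(pr) {
      w[cohort$sample_id[cohort$pair_id == pr & cohort$phenotype == "case"], ct] -
        w[cohort$sample_id[cohort$pair_id == pr & cohort$phenotype == "control"], ct]
    }, numeric(1L))
  }, numeric(length(pairs)))
  tests <- do.call(rbind, lapply(types, function(ct) {
    d <- dif[, ct]
    if (stats::sd(d) < 1e-12) {
      data.frame(cell_type = ct, mean_diff = mean(d), t = 0, p = 1,
                 stringsAsFactors = FALSE)
    } else {
      tt <- stats::t.test(d)
      data.frame(cell_type = ct, mean_diff = mean(d),
                 t = unname(tt$statistic), p = tt$p.value,
                 stringsAsFactors = FALSE)
    }
  }))
  list(tests = tests, differences = dif)
}
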