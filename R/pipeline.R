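# End-to-end orchestration: QC -> (optional deconvolution) -> paired
# probe model -> bump hunting -> permutation filter -> bootstrap FWER ->
# dual-criterion calls. One batch per run; batch separation is enforced
# structurally by the cohort validator.

#' Run the full twin DMR pipeline on one batch
#'
#' Executes the discovery pipeline on a methylation matrix: probe QC,
#' optional cell-proportion covariates (either given directly or estimated
#' from a sorted-cell reference), the paired probe-level model on
#' M-values, coefficient smoothing, bump-hunting candidate discovery,
#' within-pair permutation p-values and the outlier filter, the resampled
#' null pool, probe-count-stratified FWER, and the dual-criterion call.
#'
#' @param meth Probes x samples methylation matrix (proportions).
#' @param design Array design covering the matrix rows.
#' @param cohort Sample sheet (one batch; one case and one control per
#'   pair).
#' @param config A [run_config()].
#' @param covariates Optional samples x 3 cell-proportion covariates
#'   (e.g. from [proportion_covariates()]). Takes precedence over
#'   `reference`.
#' @param reference Optional `cell_reference_profile`; when given (and
#'   `covariates` is not), proportions are estimated from it and converted
#'   to model covariates.
#' @param out_dir Optional directory to write TSV/BED/JSON artifacts to.
#' @return A list bundle: `design` (post-QC), `qc`, `proportions`,
#'   `covariates`, `fit`, `smoothed`, `candidates` (with permutation and
#'   FWER columns), `excluded`, `null_pool`, `calls`, `config`.
#' @export
run_pipeline <- function(meth, design, cohort, config = run_config(),
                         covariates = NULL, reference = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  validate_cohort(cohort, colnames(meth))

  qc <- qc_probes(design, config$quality_threshold)
  design <- qc$design
  meth <- meth[design$probe_id, cohort$sample_id, drop = FALSE]
  sample_qc <- qc_samples(meth, design, config$min_pairwise_corr)

  proportions <- NULL
  if (is.null(covariates) && !is.null(reference)) {
    proportions <- estimate_proportions(meth, reference)
    covariates <- proportion_covariates(proportions)
  }

  fit <- fit_probe_model(meth, cohort, covariates, eps = config$eps)
  smoothed <- smooth_coefficients(fit$coef, design, span = config$span)
  candidates <- find_candidates(smoothed, design, meth, cohort,
                                cutoff_quantile = config$cutoff_quantile,
                                min_probes = config$min_probes,
                                max_gap = config$max_gap)
  cutoff <- attr(candidates, "cutoff")
  candidates <- attach_permutation_p(candidates, meth, cohort,
                                     cap = config$perm_cap,
                                     seed = child_seed(config$seed, 1L))
  filt <- permutation_filter(candidates, config$perm_threshold)

  pool <- bootstrap_null(meth, design, cohort, covariates,
                         cutoff = cutoff, B = config$B,
                         scheme = config$scheme,
                         seed = child_seed(config$seed, 2L),
                         span = config$span, min_probes = config$min_probes,
                         max_gap = config$max_gap,
                         perm_threshold = config$perm_threshold,
                         perm_cap = config$perm_cap, eps = config$eps)
  retained <- stratified_fwer(filt$retained, pool)
  calls <- call_dmrs(retained, fwer_threshold = config$fwer_threshold,
                     perm_threshold = config$perm_threshold)

  bundle <- list(design = design, qc = list(probes = qc$report,
                                            samples = sample_qc),
                 proportions = proportions, covariates = covariates,
                 fit = fit, smoothed = smoothed, cutoff = cutoff,
                 candidates = retained, excluded = filt$excluded,
                 null_pool = pool, calls = calls, config = config)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

# Persist the result bundle as plain-text artifacts.
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  calls_flat <- bundle$calls
  calls_flat$probes <- vapply(calls_flat$probes, paste, "", collapse = ",")
  write_tsv(calls_flat, file.path(out_dir, "calls.tsv"))
  write_bed(bundle$calls[bundle$calls$pass, , drop = FALSE],
            file.path(out_dir, "calls.bed"))
  if (!is.null(bundle$proportions)) {
    write_tsv(data.frame(sample_id = rownames(bundle$proportions),
                         bundle$proportions, stringsAsFactors = FALSE),
              file.path(out_dir, "proportions.tsv"))
  }
  jsonlite::write_json(
    list(config = unclass(bundle$config), cutoff = bundle$cutoff,
         n_candidates = nrow(bundle$candidates),
         n_calls = sum(bundle$calls$pass)),
    file.path(out_dir, "run_log.json"), auto_unbox = TRUE, null = "null")
  invisible(out_dir)
}
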