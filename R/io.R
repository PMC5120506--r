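# Readers and writers for the tabular and genomic formats: design,
# methylation matrix and sample-sheet TSVs, BED export of calls, and the
# serialized run configuration. TSVs are tab-separated UTF-8 with
# mandatory headers and "." for missing values; internal coordinates are
# 1-based inclusive, BED export is 0-based half-open.

#' Run configuration with the pipeline's default thresholds
#'
#' Collects every tunable of the analysis with its default: probe quality
#' threshold 80, probe-level FDR 0.20, candidate cutoff at the 0.995
#' quantile of |smoothed coefficient|, minimum 3 probes and maximum 300 bp
#' gap per candidate, permutation threshold 0.1, FWER threshold 0.10
#' (report column at 0.20), 2000 resampling iterations, 300 informative
#' markers, permutation enumeration cap 4096.
#'
#' @param ... Overrides for any default field.
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    quality_threshold = 80,
    min_pairwise_corr = 0.8,
    probe_fdr = 0.20,
    eps = 0.01,
    span = 0.75,
    cutoff_quantile = 0.995,
    min_probes = 3L,
    max_gap = 300L,
    perm_threshold = 0.1,
    perm_cap = 4096L,
    fwer_threshold = 0.10,
    report_fwer_threshold = 0.20,
    B = 2000L,
    scheme = "residual-bootstrap",
    k_markers = 300L,
    seed = NULL
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path File to write to / read from (YAML).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

write_tsv <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2)) if (is.numeric(df2[[j]])) df2[[j]] <- df2[[j]]
  utils::write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' Read an array design TSV
#'
#' Expects columns `probe_id`, `chrom`, `pos`, `region_id`, `is_control`,
#' `quality`; `.` marks missing region ids (control probes).
#'
#' @param path TSV path.
#' @return A validated design data.frame.
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = ".")
  need <- c("probe_id", "chrom", "pos", "region_id", "is_control", "quality")
  if (!all(need %in% names(d))) {
    stop("design file must have columns ", paste(need, collapse = ", "))
  }
  d$is_control <- as.logical(d$is_control)
  dup <- which(duplicated(d$probe_id))
  if (length(dup)) stop("duplicate probe id(s) at row(s) ", paste(dup, collapse = ", "))
  if (any(d$is_control & !is.na(d$region_id))) {
    stop("control probes must not carry a region id")
  }
  for (rid in unique(d$region_id[!d$is_control])) {
    pos <- d$pos[!d$is_control & d$region_id == rid]
    if (any(diff(pos) <= 0)) {
      stop("positions not strictly increasing within region ", rid)
    }
  }
  d
}

#' @rdname read_design
#' @param design Design data.frame to write.
#' @export
write_design <- function(design, path) write_tsv(design, path)

#' Read a methylation matrix TSV
#'
#' First column `probe_id`, remaining columns one per sample, proportions
#' in \[0, 1\]. Values outside the unit interval are rejected with their
#' coordinates; when a design is given, the probe sets must match and the
#' difference is spelled out otherwise.
#'
#' @param path TSV path.
#' @param design Optional design to validate the probe set against.
#' @return A probes x samples numeric matrix with probe-id rownames.
#' @export
read_matrix <- function(path, design = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = ".",
                         check.names = FALSE)
  if (names(d)[1] != "probe_id") stop("first column must be probe_id")
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$probe_id
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("value outside [0, 1] at probe ", rownames(m)[bad[1, 1]],
         ", sample ", colnames(m)[bad[1, 2]], " (", m[bad[1, , drop = FALSE]], ")")
  }
  if (!is.null(design) && !setequal(rownames(m), design$probe_id)) {
    stop("probe sets differ: in design only [",
         paste(utils::head(setdiff(design$probe_id, rownames(m)), 5), collapse = ", "),
         "], in matrix only [",
         paste(utils::head(setdiff(rownames(m), design$probe_id), 5), collapse = ", "), "]")
  }
  m
}

#' @rdname read_matrix
#' @param meth Matrix to write.
#' @export
write_matrix <- function(meth, path) {
  write_tsv(data.frame(probe_id = rownames(meth), meth,
                       check.names = FALSE, stringsAsFactors = FALSE), path)
}

#' Read a twin-cohort sample sheet TSV
#'
#' Expects `sample_id`, `pair_id`, `phenotype` (`case`/`control`),
#' `batch`, and covariate columns. Every pair must have exactly one case
#' and one control and the sheet must not mix batches.
#'
#' @param path TSV path.
#' @return A validated sample-sheet data.frame.
#' @export
read_samplesheet <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = ".")
  validate_cohort(d)
  d
}

#' @rdname read_samplesheet
#' @param cohort Sample sheet to write.
#' @export
write_samplesheet <- function(cohort, path) write_tsv(cohort, path)

#' Export DMR calls as BED
#'
#' Converts the internal 1-based inclusive coordinates to BED's 0-based
#' half-open convention (`start - 1`, `end`). The score column is
#' `-10 * log10(best FWER)`, with the FWER floored at 1/B so zero
#' estimates stay finite.
#'
#' @param calls Data.frame with `chrom`, `start`, `end`, `dmr_id`, and
#'   (optionally) `best_fwer` and `fwer_floor`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bed <- function(calls, path) {
  if (nrow(calls) == 0L) {
    writeLines("#chrom\tstart\tend\tname\tscore", path)
    return(invisible(path))
  }
  floor_ <- if ("fwer_floor" %in% names(calls)) calls$fwer_floor else 1e-4
  fw <- if ("best_fwer" %in% names(calls)) pmax(calls$best_fwer, floor_) else floor_
  score <- round(-10 * log10(fw), 4)
  lines <- sprintf("%s\t%d\t%d\t%s\t%s", calls$chrom, calls$start - 1L,
                   calls$end, calls$dmr_id, format(score, trim = TRUE))
  writeLines(c("#chrom\tstart\tend\tname\tscore", lines), path)
  invisible(path)
}

#' @rdname write_bed
#' @return For `read_bed`, a data.frame of intervals in internal 1-based
#'   inclusive coordinates.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      dmr_id = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  parts <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  data.frame(chrom = parts[, 1], start = as.integer(parts[, 2]) + 1L,
             end = as.integer(parts[, 3]), dmr_id = parts[, 4],
             score = as.numeric(parts[, 5]), stringsAsFactors = FALSE)
}
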