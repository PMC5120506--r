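# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's
#' RNG state afterwards, so seeded operations never perturb the global
#' random stream. A `NULL` seed evaluates `code` under the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-task child seed from a base seed; keeps values < 2^31.
# Double-precision arithmetic is exact here (products stay below 2^53).
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 69421 + as.numeric(k) * 2903) %% 2147483587)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Centered running mean that shrinks the window at region edges.
running_mean <- function(x, window = 3L) {
  n <- length(x)
  if (n == 0L) return(x)
  half <- (window - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    out[i] <- mean(x[lo:hi])
  }
  out
}

# Merge overlapping or bookended 1-based inclusive intervals per chromosome.
# `df` needs columns chrom/start/end; returns the union set, sorted.
merge_intervals <- function(df) {
  if (nrow(df) == 0L) return(df[, c("chrom", "start", "end")])
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  out <- list()
  cur <- NULL
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    if (is.null(cur) || row$chrom != cur$chrom || row$start > cur$end + 1L) {
      if (!is.null(cur)) out[[length(out) + 1L]] <- cur
      cur <- data.frame(chrom = row$chrom, start = row$start, end = row$end,
                        stringsAsFactors = FALSE)
    } else {
      cur$end <- max(cur$end, row$end)
    }
  }
  out[[length(out) + 1L]] <- cur
  do.call(rbind, out)
}

# All 2^n sign assignments as a (2^n x n) matrix of +/-1; row 1 is identity.
sign_assignments <- function(n) {
  stopifnot(n >= 1L, n <= 30L)
  m <- 2L^n
  out <- matrix(1, nrow = m, ncol = n)
  for (j in seq_len(n)) {
    out[, j] <- ifelse(bitwAnd(seq_len(m) - 1L, bitwShiftL(1L, j - 1L)) > 0L, -1, 1)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
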