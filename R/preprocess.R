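## Expression filtering, TMM normalization and the log-CPM transform that
## feeds the linear-model engine.

#' Filter features by expression
#'
#' Keeps a feature when (a) its counts-per-million reach the CPM equivalent
#' of \code{minCount} in the median library in at least
#' \code{ceiling(minProp * smallest group size)} samples, and (b) its total
#' count across all samples is at least \code{minTotal}. This fixed rule is
#' deliberately version-independent (the usual filtering helpers move their
#' cutoff formula between releases). Genes shrink to their surviving
#' features.
#'
#' @param x a \code{deju_counts}.
#' @param group factor of group memberships, one per sample (defaults to
#'   \code{x$samples$group}).
#' @param minCount per-sample-equivalent count threshold (default 10).
#' @param minTotal summed-count threshold (default 15).
#' @param minProp fraction of the smallest group (default 0.7).
#' @return the filtered \code{deju_counts}.
#' @export
filterCounts <- function(x, group = x$samples$group, minCount = 10,
                         minTotal = 15, minProp = 0.7) {
  if (is.null(group)) stop("no group factor available")
  if (ncol(x$counts) < 2L) stop("need at least 2 samples")
  lib <- x$samples$lib_size
  cpm <- t(t(x$counts) / lib * 1e6)
  cutoff <- minCount / stats::median(lib / 1e6)
  k <- ceiling(minProp * min(table(group)))
  keep <- rowSums(cpm >= cutoff) >= k & rowSums(x$counts) >= minTotal
  if (!any(keep))
    stop("no features pass the expression filter; relax minCount/minTotal")
  x$counts <- x$counts[keep, , drop = FALSE]
  x$features <- x$features[keep, , drop = FALSE]
  rownames(x$features) <- NULL
  x
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values scaling factors correcting composition bias
#' between libraries, computed with \code{edgeR::calcNormFactors}. The
#' reference sample is the one whose 75th-percentile CPM is closest to the
#' mean; 30\% of the most extreme log-ratios (M) and 5\% of the most
#' extreme log-abundances (A) are trimmed; the remaining M-values are
#' averaged with inverse asymptotic-variance weights. Factors are scaled so
#' their product is 1.
#'
#' @param x a \code{deju_counts}, or an integer count matrix.
#' @param lib.size library sizes (defaults to assigned totals for a
#'   \code{deju_counts}, column sums for a matrix).
#' @return numeric vector of normalization factors, one per sample.
#' @export
tmmNormFactors <- function(x, lib.size = NULL) {
  counts <- if (inherits(x, "deju_counts")) x$counts else x
  if (is.null(lib.size))
    lib.size <- if (inherits(x, "deju_counts")) x$samples$lib_size
                else colSums(counts)
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  if (any(colSums(counts) == 0)) stop("a sample has no positive counts")
  if (nrow(counts) < 10L) {
    warning("fewer than 10 features; returning unit normalization factors")
    return(rep(1, ncol(counts)))
  }
  f <- edgeR::calcNormFactors(counts, lib.size = lib.size, method = "TMM")
  as.numeric(f)
}

#' Log2 counts per million
#'
#' \code{log2((count + 0.5) / (lib_size * factor + 1) * 1e6)}.
#'
#' @param x a \code{deju_counts} or count matrix.
#' @param normFactors TMM factors from \code{\link{tmmNormFactors}}
#'   (default 1 for every sample).
#' @param lib.size library sizes (defaults as in
#'   \code{\link{tmmNormFactors}}).
#' @return numeric matrix of log2-CPM values.
#' @export
logCPM <- function(x, normFactors = NULL, lib.size = NULL) {
  counts <- if (inherits(x, "deju_counts")) x$counts else x
  if (is.null(lib.size))
    lib.size <- if (inherits(x, "deju_counts")) x$samples$lib_size
                else colSums(counts)
  if (is.null(normFactors)) normFactors <- rep(1, ncol(counts))
  eff <- lib.size * normFactors
  t(log2(t(counts + 0.5) / (eff + 1) * 1e6))
}

#' Normalization report
#'
#' @param x a \code{deju_counts}.
#' @param normFactors TMM factors.
#' @param path optional TSV output path.
#' @return data.frame with sample, library_size, tmm_factor and
#'   effective_library_size.
#' @export
normReport <- function(x, normFactors, path = NULL) {
  rep <- data.frame(sample = x$samples$sample_id,
                    library_size = x$samples$lib_size,
                    tmm_factor = normFactors,
                    effective_library_size = x$samples$lib_size * normFactors)
  if (!is.null(path))
    utils::write.table(rep, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  rep
}
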