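## Simulation benchmark: empirical FDR, per-pattern power and top-ranked
## false-discovery curves, averaged over independent simulation runs.

#' Evaluate detection against ground truth
#'
#' Detected genes are those with gene-level BH-adjusted p-values at or
#' below \code{alpha}. Empirical FDR is FP / max(1, detected); power per
#' splicing pattern is the fraction of genuine DEU genes of that pattern
#' that are detected.
#'
#' @param genes gene-level results (from a \code{deju_fit}'s \code{genes}
#'   element).
#' @param labels truth table with \code{gene_id}, \code{pattern},
#'   \code{is_true_deu}.
#' @param alpha nominal FDR (default 0.05).
#' @param test \code{"simes"} or \code{"F"}.
#' @return list with \code{fdr}, \code{power} (overall), \code{power_by}
#'   (named per pattern), \code{n_detected}, \code{tp}, \code{fp}.
#' @export
evaluateDetection <- function(genes, labels, alpha = 0.05,
                              test = c("simes", "F")) {
  test <- match.arg(test)
  fdr <- if (test == "simes") genes$fdr_simes else genes$fdr_F
  detected <- genes$gene_id[!is.na(fdr) & fdr <= alpha]
  truth <- labels$gene_id[labels$is_true_deu]
  tp <- sum(detected %in% truth)
  fp <- length(detected) - tp
  pats <- sort(unique(labels$pattern[labels$is_true_deu]))
  power_by <- vapply(pats, function(p) {
    tg <- labels$gene_id[labels$is_true_deu & labels$pattern == p]
    sum(tg %in% detected) / length(tg)
  }, 0)
  list(fdr = fp / max(1L, length(detected)),
       power = tp / max(1L, length(truth)),
       power_by = power_by,
       n_detected = length(detected), tp = tp, fp = fp)
}

#' False discoveries among top-ranked genes
#'
#' Genes are ranked by ascending gene-level p-value (ties by gene id;
#' untested genes last); for each N in the grid the number of non-true
#' genes among the top N is reported.
#'
#' @param genes gene-level results table.
#' @param labels truth table.
#' @param N integer grid of list sizes.
#' @param test \code{"simes"} or \code{"F"}.
#' @return data.frame with columns \code{N} and \code{fp}.
#' @export
falseDiscoveryCurve <- function(genes, labels, N = c(50, 100, 200, 500),
                                test = c("simes", "F")) {
  test <- match.arg(test)
  p <- if (test == "simes") genes$p_simes else genes$p_F
  o <- order(is.na(p), p, genes$gene_id)
  ranked <- genes$gene_id[o]
  truth <- labels$gene_id[labels$is_true_deu]
  if (any(N > length(ranked))) {
    warning("N larger than the number of tested genes; truncating")
    N <- pmin(N, length(ranked))
  }
  is_fp <- cumsum(!(ranked %in% truth))
  data.frame(N = N, fp = is_fp[N])
}

## one simulation run: transcriptome -> abundances -> streamed counting ->
## fit, for each requested counting mode
.benchmarkRun <- function(runSeed, nGenes, nTrueDEU, patterns, nPerGroup,
                          libSizes, depth, foldChange, bcv, nullMode,
                          transcriptsPerGene, modes, alpha,
                          minJunctionReads, zipf = 1) {
  set.seed(runSeed)
  sim <- simTranscriptome(nGenes = nGenes, nTrueDEU = nTrueDEU,
                          patterns = patterns,
                          transcriptsPerGene = transcriptsPerGene)
  design <- sampleDesign(nPerGroup, libSizes, depth)
  baseline <- baselineExpression(sim, zipf = zipf)
  ab <- sampleAbundances(sim, baseline, design, foldChange = foldChange,
                         bcv = bcv, nullMode = nullMode)
  counts <- simulateCounts(sim, ab, design, modes = modes,
                           minJunctionReads = minJunctionReads)
  fits <- lapply(counts, dejuFit)
  list(sim = sim, design = design, fits = fits)
}

#' Run the FDR/power simulation benchmark
#'
#' For every cell of the design grid (replicates per group x library-size
#' scenario) and every run, generates a transcriptome, simulates fragments,
#' quantifies them in the requested counting modes, fits the usage model
#' and evaluates detection against the ground truth. Per-run seeds are
#' derived from the master seed as \code{seed * 1000 + run}, so a cell's
#' runs are reproducible and cells share seeds (paired comparisons across
#' sample sizes use the same transcriptomes).
#'
#' Scaled defaults (500 genes, 124 genuine DEU genes, 5 million fragments
#' per sample) are a 1/10 linear scaling of the full study conditions that
#' preserves per-gene coverage.
#'
#' @param nRuns simulation runs per cell (default 3).
#' @param seed master seed.
#' @param nPerGroup vector of replicates per group to evaluate.
#' @param libSizes character vector, subset of balanced/unbalanced.
#' @param depth nominal fragments per sample.
#' @param nGenes,nTrueDEU,patterns,transcriptsPerGene transcriptome
#'   settings (see \code{\link{simTranscriptome}}).
#' @param foldChange,bcv,nullMode abundance settings (see
#'   \code{\link{sampleAbundances}}).
#' @param modes counting modes to benchmark.
#' @param tests gene-level tests to evaluate.
#' @param alpha nominal FDR.
#' @param minJunctionReads pooled junction support threshold.
#' @param fdN grid for the false-discovery curve.
#' @return An object of class \code{deju_benchmark}: list with \code{runs}
#'   (one row per run x cell x mode x test), \code{curves} (averaged
#'   false-discovery curves) and the configuration.
#' @export
runBenchmark <- function(nRuns = 3L, seed = 1L, nPerGroup = 3L,
                         libSizes = "balanced", depth = 5e6,
                         nGenes = 500L, nTrueDEU = 124L,
                         patterns = c("ES", "MXE", "ASS", "IR"),
                         transcriptsPerGene = 2L, foldChange = 3,
                         bcv = 0.2, nullMode = FALSE,
                         modes = c("DEJU", "DEU"),
                         tests = c("simes", "F"), alpha = 0.05,
                         minJunctionReads = 3L,
                         fdN = c(50, 100, 200)) {
  rows <- list()
  curves <- list()
  for (n in nPerGroup) for (ls in libSizes) {
    for (run in seq_len(nRuns)) {
      runSeed <- seed * 1000 + run
      res <- .benchmarkRun(runSeed, nGenes, nTrueDEU, patterns, n, ls,
                           depth, foldChange, bcv, nullMode,
                           transcriptsPerGene, modes, alpha,
                           minJunctionReads)
      for (m in modes) for (tst in tests) {
        ev <- evaluateDetection(res$fits[[m]]$genes, res$sim$labels,
                                alpha, tst)
        row <- data.frame(n_per_group = n, lib_sizes = ls, run = run,
                          seed = runSeed, mode = m, test = tst,
                          fdr = ev$fdr, power = ev$power,
                          n_detected = ev$n_detected, tp = ev$tp,
                          fp = ev$fp, stringsAsFactors = FALSE)
        for (p in names(ev$power_by))
          row[[paste0("power_", p)]] <- ev$power_by[[p]]
        rows[[length(rows) + 1L]] <- row
        fd <- falseDiscoveryCurve(res$fits[[m]]$genes, res$sim$labels,
                                  fdN, tst)
        fd$n_per_group <- n; fd$lib_sizes <- ls
        fd$mode <- m; fd$test <- tst; fd$run <- run
        curves[[length(curves) + 1L]] <- fd
      }
    }
  }
  runs <- do.call(rbind, rows)
  curves <- do.call(rbind, curves)
  avg_curve <- stats::aggregate(fp ~ N + n_per_group + lib_sizes + mode +
                                  test, data = curves, FUN = mean)
  structure(list(runs = runs, curves = avg_curve,
                 config = list(nRuns = nRuns, seed = seed,
                               nPerGroup = nPerGroup, libSizes = libSizes,
                               depth = depth, nGenes = nGenes,
                               nTrueDEU = nTrueDEU, patterns = patterns,
                               foldChange = foldChange, bcv = bcv,
                               nullMode = nullMode, alpha = alpha)),
            class = "deju_benchmark")
}

#' Summarise a benchmark: per-cell means and standard errors
#'
#' @param object a \code{deju_benchmark}.
#' @param ... unused.
#' @return data.frame with mean and standard error of FDR and power (per
#'   pattern) for every cell x mode x test.
#' @export
summary.deju_benchmark <- function(object, ...) {
  runs <- object$runs
  metrics <- c("fdr", "power",
               grep("^power_", names(runs), value = TRUE))
  key <- c("n_per_group", "lib_sizes", "mode", "test")
  agg <- stats::aggregate(runs[metrics], runs[key], FUN = mean)
  se <- stats::aggregate(runs[metrics], runs[key],
                         FUN = function(x) stats::sd(x) / sqrt(length(x)))
  names(se)[-seq_along(key)] <- paste0("se_", metrics)
  merge(agg, se, by = key)
}

#' @export
print.deju_benchmark <- function(x, ...) {
  cat("deju_benchmark:", nrow(x$runs), "evaluations (",
      x$config$nRuns, "runs/cell, alpha =", x$config$alpha, ")\n")
  s <- summary(x)
  show <- c("n_per_group", "lib_sizes", "mode", "test", "fdr", "power",
            grep("^power_[A-Z]", names(s), value = TRUE))
  print(format(s[show], digits = 3), row.names = FALSE)
  invisible(x)
}

#' Write the benchmark report
#'
#' @param x a \code{deju_benchmark}.
#' @param runsPath,summaryPath,curvesPath optional TSV output paths.
#' @return invisibly, the summary data.frame.
#' @export
writeBenchmark <- function(x, runsPath = NULL, summaryPath = NULL,
                           curvesPath = NULL) {
  s <- summary(x)
  if (!is.null(runsPath))
    utils::write.table(x$runs, runsPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(summaryPath))
    utils::write.table(s, summaryPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(curvesPath))
    utils::write.table(x$curves, curvesPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(s)
}
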