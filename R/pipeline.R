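## Thin pipeline layer: simulate -> quantify -> preprocess -> test, with
## every artifact written to disk and listed in a checksummed manifest.

#' Run the complete analysis pipeline on simulated data
#'
#' Executes the full workflow in order — transcriptome simulation,
#' abundance and fragment simulation, exon-junction quantification,
#' filtering/normalization and the usage test — writing all artifacts
#' (annotation as GTF/SAF/junction table, truth labels, count matrix,
#' normalization report, feature- and gene-level results) plus a manifest
#' with MD5 checksums, the seed and the configuration. Re-running with the
#' same configuration reproduces identical outputs.
#'
#' @param outDir output directory (created if missing).
#' @param seed master seed.
#' @param nGenes,nTrueDEU,patterns,transcriptsPerGene see
#'   \code{\link{simTranscriptome}}.
#' @param nPerGroup,libSizes,depth see \code{\link{sampleDesign}}.
#' @param foldChange,bcv,nullMode see \code{\link{sampleAbundances}}.
#' @param mode counting mode.
#' @param minJunctionReads pooled junction support threshold.
#' @return invisibly, a list with \code{sim}, \code{counts}, \code{fit} and
#'   the \code{manifest}.
#' @export
runPipeline <- function(outDir, seed = 1L, nGenes = 100L, nTrueDEU = 20L,
                        patterns = c("ES", "MXE", "ASS", "IR"),
                        transcriptsPerGene = 2L, nPerGroup = 3L,
                        libSizes = "balanced", depth = 2e5,
                        foldChange = 3, bcv = 0.2, nullMode = FALSE,
                        mode = "DEJU", minJunctionReads = 3L) {
  if (!dir.exists(outDir)) {
    ok <- dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(outDir)) stop("cannot create output dir: ", outDir)
  }
  if (file.access(outDir, 2L) != 0L) stop("output dir not writable: ", outDir)
  set.seed(seed)
  sim <- simTranscriptome(nGenes = nGenes, nTrueDEU = nTrueDEU,
                          patterns = patterns,
                          transcriptsPerGene = transcriptsPerGene)
  design <- sampleDesign(nPerGroup, libSizes, depth)
  baseline <- baselineExpression(sim)
  ab <- sampleAbundances(sim, baseline, design, foldChange = foldChange,
                         bcv = bcv, nullMode = nullMode)
  counts <- simulateCounts(sim, ab, design, modes = mode,
                           minJunctionReads = minJunctionReads)[[mode]]
  fit <- dejuFit(counts)

  path <- function(f) file.path(outDir, f)
  writeGTF(sim$annotation, path("annotation.gtf"))
  writeSAF(sim$annotation, path("annotation.saf"))
  writeJunctionTable(sim$annotation$junctions, path("junctions.tab"))
  writeTruthLabels(sim, path("truth.tsv"))
  writeCountMatrix(counts, path("counts.tsv"))
  normReport(counts, fit$normFactors, path("norm_report.tsv"))
  writeResults(fit, path("features.tsv"), path("genes.tsv"))

  files <- c("annotation.gtf", "annotation.saf", "junctions.tab",
             "truth.tsv", "counts.tsv", "norm_report.tsv", "features.tsv",
             "genes.tsv")
  manifest <- list(
    package_version = as.character(utils::packageVersion("deju")),
    seed = seed,
    config = list(nGenes = nGenes, nTrueDEU = nTrueDEU,
                  patterns = patterns,
                  transcriptsPerGene = transcriptsPerGene,
                  nPerGroup = nPerGroup, libSizes = libSizes,
                  depth = depth, foldChange = foldChange, bcv = bcv,
                  nullMode = nullMode, mode = mode,
                  minJunctionReads = minJunctionReads),
    files = lapply(files, function(f)
      list(name = f, md5 = unname(tools::md5sum(path(f))))))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(sim = sim, counts = counts, fit = fit,
                 manifest = manifest))
}
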