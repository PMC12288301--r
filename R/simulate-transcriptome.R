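## Synthetic multi-isoform transcriptome with injected splicing events.
##
## Each simulated gene starts from a "parent" exon chain. Isoform A and
## isoform B are derived from the parent by one of four alternative-splicing
## patterns (exon skipping ES, mutually exclusive exons MXE, alternative
## splice site ASS, intron retention IR). The counting reference for the
## gene is the parent chain itself: its flattened exons and its consecutive
## introns form the annotation and junction database. Event-specific
## junctions are therefore *novel* with respect to the reference, just as
## splice variants discovered by two-pass alignment are novel with respect
## to a genome annotation.

.pattern_min_exons <- c(ES = 3L, MXE = 4L, ASS = 3L, IR = 2L)

#' Inject an alternative-splicing event into an exon chain
#'
#' Given the parent exon chain of a gene, constructs the two isoforms that
#' differ by one splicing pattern:
#' \describe{
#'   \item{ES}{isoform A keeps the full chain, isoform B omits one randomly
#'     chosen internal exon.}
#'   \item{MXE}{a random adjacent internal exon pair (i, i+1): isoform A
#'     omits exon i+1, isoform B omits exon i.}
#'   \item{ASS}{isoform B moves one splice site of a random internal exon
#'     inward by \code{delta} bases, so the flattened exons of the gene are
#'     unchanged but one junction differs.}
#'   \item{IR}{isoform B replaces a random adjacent exon pair and the intron
#'     between them by one contiguous exon block (the intron is retained).}
#' }
#' Uses the current R random number generator state.
#'
#' @param exons data.frame of the parent chain with columns \code{start},
#'   \code{end}, sorted, non-overlapping.
#' @param pattern one of \code{"ES"}, \code{"MXE"}, \code{"ASS"}, \code{"IR"}.
#' @param assShiftRange integer range for the ASS splice-site shift in bp.
#' @return list with data.frames \code{A} and \code{B} (columns
#'   \code{start}, \code{end}) and a list \code{detail} recording the exon
#'   index/indices and shift used.
#' @export
injectEvent <- function(exons, pattern = c("ES", "MXE", "ASS", "IR"),
                        assShiftRange = c(30L, 100L)) {
  pattern <- match.arg(pattern)
  E <- nrow(exons)
  if (E < .pattern_min_exons[[pattern]])
    stop("pattern ", pattern, " needs >= ", .pattern_min_exons[[pattern]],
         " exons, gene has ", E)
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  rownames(exons) <- NULL
  A <- exons
  if (pattern == "ES") {
    k <- if (E == 3L) 2L else sample(2:(E - 1L), 1L)
    B <- exons[-k, , drop = FALSE]
    detail <- list(pattern = pattern, exon = k)
  } else if (pattern == "MXE") {
    i <- if (E == 4L) 2L else sample(2:(E - 2L), 1L)
    A <- exons[-(i + 1L), , drop = FALSE]
    B <- exons[-i, , drop = FALSE]
    detail <- list(pattern = pattern, exons = c(i, i + 1L))
  } else if (pattern == "ASS") {
    len <- exons$end - exons$start + 1L
    eligible <- setdiff(which(len >= assShiftRange[1] + 30L), c(1L, E))
    if (!length(eligible))
      stop("pattern ASS: no internal exon long enough for the splice-site shift")
    k <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
    dmax <- min(assShiftRange[2], len[k] - 30L)
    delta <- if (dmax == assShiftRange[1]) dmax else
      sample(assShiftRange[1]:dmax, 1L)
    side <- sample(c("start", "end"), 1L)
    B <- exons
    if (side == "start") B$start[k] <- B$start[k] + delta
    else B$end[k] <- B$end[k] - delta
    detail <- list(pattern = pattern, exon = k, side = side, delta = delta)
  } else { # IR
    i <- if (E == 2L) 1L else sample(1:(E - 1L), 1L)
    B <- exons
    B$end[i] <- B$end[i + 1L]
    B <- B[-(i + 1L), , drop = FALSE]
    detail <- list(pattern = pattern, exons = c(i, i + 1L))
  }
  rownames(A) <- rownames(B) <- NULL
  list(A = A, B = B, detail = detail)
}

## draw one parent exon chain; returns data.frame(start, end) at offset 1
.draw_chain <- function(nExons, exonLengthRange, intronLengthRange) {
  el <- sample(exonLengthRange[1]:exonLengthRange[2], nExons, replace = TRUE)
  il <- if (nExons > 1L)
    sample(intronLengthRange[1]:intronLengthRange[2], nExons - 1L, replace = TRUE)
  else integer(0)
  starts <- cumsum(c(1L, el[-nExons] + il))
  data.frame(start = as.integer(starts), end = as.integer(starts + el - 1L))
}

#' Simulate a splicing-event transcriptome
#'
#' Generates \code{nGenes} non-overlapping multi-exon genes on synthetic
#' chromosomes. Every gene carries two isoforms (A and B) differing by one
#' alternative-splicing pattern; \code{nTrueDEU} genes, chosen uniformly at
#' random and split equally over \code{patterns}, are labelled as genuine
#' differential-usage genes (their isoform usage will switch between groups
#' when abundances are simulated). The remaining genes keep the same
#' two-isoform structure but are labelled null, so the null set contains
#' structurally comparable multi-isoform genes.
#'
#' In five-transcript mode, three additional isoforms per gene are random
#' internal-exon-skipping variants that leave the labelled event's junctions
#' untouched; they later receive baseline (non-differential) abundance.
#'
#' @param nGenes number of genes (scaled default 500).
#' @param nTrueDEU number of genuine DEU genes; must be divisible by the
#'   number of patterns (scaled default 125, i.e. 25 per pattern, hence the
#'   mixed default uses 124; see Details).
#' @param patterns splicing patterns to simulate, a subset of
#'   ES/MXE/ASS/IR.
#' @param transcriptsPerGene 2 or 5.
#' @param exonCountRange,exonLengthRange,intronLengthRange,assShiftRange
#'   integer ranges for the gene structure draws (bp for lengths).
#' @param seed optional integer seed (\code{set.seed} is called when given).
#' @return An object of class \code{deju_sim}: a list with
#'   \code{annotation} (the reference \code{deju_annotation}, flattened with
#'   junction database), \code{iso_exons} (exon table of the simulated
#'   isoforms), \code{transcripts} (one row per isoform with cDNA length),
#'   \code{labels} (gene_id, pattern, is_true_deu) and \code{config}.
#' @details With the mixed four-pattern default, \code{nTrueDEU} must be a
#'   multiple of 4 (e.g. 124 or 1000); the scaled study condition uses
#'   500 genes with 124 true-DEU genes (31 per pattern) when 125 is not
#'   divisible by 4 — pass \code{nTrueDEU = 124}.
#' @export
simTranscriptome <- function(nGenes = 500L, nTrueDEU = 124L,
                             patterns = c("ES", "MXE", "ASS", "IR"),
                             transcriptsPerGene = 2L,
                             exonCountRange = c(4L, 12L),
                             exonLengthRange = c(80L, 300L),
                             intronLengthRange = c(200L, 2000L),
                             assShiftRange = c(30L, 100L),
                             seed = NULL) {
  patterns <- match.arg(patterns, c("ES", "MXE", "ASS", "IR"),
                        several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  if (nTrueDEU > nGenes)
    stop("nTrueDEU must not exceed nGenes")
  if (nTrueDEU %% length(patterns) != 0L)
    stop("nTrueDEU (", nTrueDEU, ") must be divisible by the number of ",
         "patterns (", length(patterns), ")")
  if (!transcriptsPerGene %in% c(2L, 5L))
    stop("transcriptsPerGene must be 2 or 5")
  if (assShiftRange[1] + 30L > exonLengthRange[2])
    stop("assShiftRange too large for exonLengthRange")

  gene_id <- sprintf("G%05d", seq_len(nGenes))
  ## pattern assignment: true-DEU genes equal split, nulls random pattern
  true_idx <- sort(sample(nGenes, nTrueDEU))
  pattern <- character(nGenes)
  pattern[true_idx] <- sample(rep(patterns, nTrueDEU / length(patterns)))
  null_idx <- setdiff(seq_len(nGenes), true_idx)
  pattern[null_idx] <- sample(patterns, length(null_idx), replace = TRUE)

  genes_per_chrom <- 50L
  gap <- 5000L

  iso_list <- vector("list", nGenes)
  ref_list <- vector("list", nGenes)
  for (g in seq_len(nGenes)) {
    pat <- pattern[g]
    minE <- max(exonCountRange[1], .pattern_min_exons[[pat]])
    if (minE > exonCountRange[2])
      stop("exonCountRange cannot host pattern ", pat)
    ev <- NULL
    for (try in 1:100) {
      nE <- sample(minE:exonCountRange[2], 1L)
      chain <- .draw_chain(nE, exonLengthRange, intronLengthRange)
      ev <- tryCatch(injectEvent(chain, pat, assShiftRange),
                     error = function(e) NULL)
      if (!is.null(ev)) break
    }
    if (is.null(ev))
      stop("could not host pattern ", pat, " in gene ", gene_id[g])
    isoforms <- list(A = ev$A, B = ev$B)
    if (transcriptsPerGene == 5L) {
      ## extra isoforms: drop one internal exon away from the event
      involved <- unlist(ev$detail[c("exon", "exons")], use.names = FALSE)
      touch <- unique(c(involved - 1L, involved, involved + 1L))
      spare <- setdiff(2:(nrow(chain) - 1L), touch)
      for (x in c("C", "D", "E")) {
        iso <- if (length(spare))
          chain[-sample(rep(spare, 2L), 1L), , drop = FALSE]
        else chain
        isoforms[[x]] <- iso
      }
    }
    chrom <- sprintf("chrS%d", (g - 1L) %/% genes_per_chrom + 1L)
    slot <- (g - 1L) %% genes_per_chrom
    strand <- sample(c("+", "-"), 1L)
    ## worst-case gene span: all exons + introns at their maxima
    span_max <- exonCountRange[2] * exonLengthRange[2] +
      (exonCountRange[2] - 1L) * intronLengthRange[2] + gap
    offset <- slot * span_max
    shift <- function(df) data.frame(start = df$start + offset,
                                     end = df$end + offset)
    iso_list[[g]] <- do.call(rbind, lapply(names(isoforms), function(nm) {
      df <- shift(isoforms[[nm]])
      data.frame(gene_id = gene_id[g],
                 transcript_id = paste0(gene_id[g], ".", nm),
                 isoform = nm, chrom = chrom,
                 start = as.integer(df$start), end = as.integer(df$end),
                 strand = strand, stringsAsFactors = FALSE)
    }))
    rchain <- shift(chain)
    ref_list[[g]] <- data.frame(
      gene_id = gene_id[g], transcript_id = paste0(gene_id[g], ".R"),
      chrom = chrom, start = as.integer(rchain$start),
      end = as.integer(rchain$end), strand = strand,
      stringsAsFactors = FALSE)
  }
  iso_exons <- do.call(rbind, iso_list)
  ref_exons <- do.call(rbind, ref_list)
  rownames(iso_exons) <- rownames(ref_exons) <- NULL

  annotation <- buildJunctionDatabase(flattenExons(newAnnotation(ref_exons)))

  len <- rowsum(iso_exons$end - iso_exons$start + 1L, iso_exons$transcript_id)
  nex <- rowsum(rep(1L, nrow(iso_exons)), iso_exons$transcript_id)
  tid <- rownames(len)
  transcripts <- data.frame(
    transcript_id = tid,
    gene_id = iso_exons$gene_id[match(tid, iso_exons$transcript_id)],
    isoform = iso_exons$isoform[match(tid, iso_exons$transcript_id)],
    length = as.integer(len[, 1]),
    n_exons = as.integer(nex[, 1]),
    stringsAsFactors = FALSE)
  rownames(transcripts) <- NULL

  labels <- data.frame(gene_id = gene_id, pattern = pattern,
                       is_true_deu = seq_len(nGenes) %in% true_idx,
                       stringsAsFactors = FALSE)
  structure(list(
    annotation = annotation,
    iso_exons = iso_exons,
    transcripts = transcripts,
    labels = labels,
    config = list(nGenes = nGenes, nTrueDEU = nTrueDEU, patterns = patterns,
                  transcriptsPerGene = transcriptsPerGene,
                  exonCountRange = exonCountRange,
                  exonLengthRange = exonLengthRange,
                  intronLengthRange = intronLengthRange,
                  assShiftRange = assShiftRange, seed = seed)),
    class = "deju_sim")
}

#' @export
print.deju_sim <- function(x, ...) {
  cat("deju_sim:", x$config$nGenes, "genes,",
      nrow(x$transcripts), "isoforms,",
      sum(x$labels$is_true_deu), "true-DEU genes (",
      paste(x$config$patterns, collapse = "/"), ")\n")
  invisible(x)
}

#' Write ground-truth splicing labels
#'
#' @param sim a \code{deju_sim}.
#' @param path output TSV path (columns gene_id, pattern, is_true_deu).
#' @return \code{path}, invisibly.
#' @export
writeTruthLabels <- function(sim, path) {
  utils::write.table(sim$labels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
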