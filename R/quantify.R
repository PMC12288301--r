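## Fragment-to-feature quantification.
##
## DEJU mode: a fragment with a junction-bridging mate is assigned to
## exactly one junction feature (longest minimum overhang, ties leftmost);
## a non-split fragment is assigned to the single flattened exon with the
## largest total overlap across both mates. Each fragment contributes 0 or
## 1 counts, so library sizes track true sequencing depth. Junctions are
## assigned to genes through the junction database (exact match) or, for
## novel junctions, by containment of both flanking bases in exactly one
## gene span; junctions with pooled support not exceeding the filtering
## threshold are dropped and their fragments left unassigned, emulating
## two-pass alignment junction filtering.
##
## DEU mode reproduces legacy exon-only counting: one count to every
## flattened exon either mate overlaps, so junction-spanning fragments are
## double-counted and junction features do not exist.

## candidate junction universe: consecutive-exon introns of the simulated
## isoform chains, with per-transcript gap -> global id mapping
.junctionUniverse <- function(sim, idx) {
  ex <- sim$iso_exons[order(match(sim$iso_exons$transcript_id,
                                  sim$transcripts$transcript_id),
                            sim$iso_exons$start), , drop = FALSE]
  n <- nrow(ex)
  same_tx <- ex$transcript_id[-n] == ex$transcript_id[-1]
  i <- which(same_tx)
  gaps <- data.frame(
    chrom = ex$chrom[i], intron_start = ex$end[i] + 1L,
    intron_end = ex$start[i + 1L] - 1L, strand = ex$strand[i],
    stringsAsFactors = FALSE)
  key <- paste(gaps$chrom, gaps$intron_start, gaps$intron_end, gaps$strand)
  uk <- !duplicated(key)
  jtab <- gaps[uk, , drop = FALSE]
  rownames(jtab) <- NULL
  jid_per_gap <- match(key, key[uk])
  ## jOffset: 0-based start of each transcript's gap ids
  nE <- idx$n_exons
  jOffset <- c(0L, cumsum(pmax(nE - 1L, 0L)))
  list(jtab = jtab, jid = jid_per_gap, jOffset = jOffset)
}

.flatIndex <- function(ann) {
  flat <- ann$flat
  if (is.null(flat)) stop("annotation lacks flattened exons")
  g <- match(flat$gene_id, ann$genes$gene_id)
  o <- order(g, flat$start)
  flat <- flat[o, , drop = FALSE]
  runs <- rle(match(flat$gene_id, ann$genes$gene_id))
  stopifnot(identical(runs$values, seq_len(nrow(ann$genes))))
  list(flat = flat, fgOffset = c(0L, cumsum(runs$lengths)))
}

#' Assign observed junctions to genes
#'
#' A junction that exactly matches an annotated junction database record
#' (chromosome, intron coordinates, strand) takes that record's gene. A
#' novel junction is assigned to a gene if and only if both its flanking
#' exonic bases (intron_start - 1 and intron_end + 1) fall within that
#' gene's genomic span and exactly one gene qualifies; otherwise the gene
#' is unknown (\code{NA}) and the junction is excluded from count matrices.
#'
#' @param junctions data.frame with columns \code{chrom},
#'   \code{intron_start}, \code{intron_end}, \code{strand}.
#' @param ann a \code{deju_annotation} with the junction database built.
#' @return \code{junctions} with added columns \code{gene_id} (or
#'   \code{NA}) and \code{annotated}.
#' @export
assignJunctionsToGenes <- function(junctions, ann) {
  db <- ann$junctions
  if (is.null(db)) stop("annotation lacks the junction database")
  key <- paste(junctions$chrom, junctions$intron_start,
               junctions$intron_end, junctions$strand)
  dbkey <- paste(db$chrom, db$intron_start, db$intron_end, db$strand)
  hit <- match(key, dbkey)
  gene_id <- db$gene_id[hit]
  annotated <- !is.na(hit)
  novel <- which(!annotated)
  if (length(novel)) {
    genes <- ann$genes
    for (i in novel) {
      lo <- junctions$intron_start[i] - 1L
      hi <- junctions$intron_end[i] + 1L
      cand <- which(genes$chrom == junctions$chrom[i] &
                    genes$start <= lo & genes$end >= hi)
      if (length(cand) == 1L) gene_id[i] <- genes$gene_id[cand]
    }
  }
  junctions$gene_id <- gene_id
  junctions$annotated <- annotated
  junctions
}

#' Reference fragment classifier (pure R)
#'
#' Applies the DEJU or DEU assignment rules fragment by fragment using
#' interval projection in R. This is the readable reference implementation
#' used to validate the compiled counting path; use
#' \code{\link{countFeatures}} for full-depth data.
#'
#' @param frags compact fragment table from \code{\link{simulateFragments}}.
#' @param sim the originating \code{deju_sim}.
#' @param mode \code{"DEJU"} or \code{"DEU"}.
#' @return For DEJU, a data.frame per fragment with \code{sample_id},
#'   \code{type} (junction/exon/unassigned), \code{gene_id}, \code{start},
#'   \code{end} (feature coordinates; intron first/last base for
#'   junctions). For DEU, the same but \code{features} is a
#'   semicolon-separated list of overlapped flat exons (possibly empty).
#' @export
classifyFragments <- function(frags, sim, mode = c("DEJU", "DEU")) {
  mode <- match.arg(mode)
  R <- attr(frags, "readLength")
  idx <- .txIndex(sim)
  fi <- .flatIndex(sim$annotation)
  n <- nrow(frags)
  type <- character(n); gene <- character(n)
  fs <- integer(n); fe <- integer(n); featlist <- character(n)
  for (i in seq_len(n)) {
    t <- frags$tx[i]
    lo <- idx$offset[t] + 1L; hi <- idx$offset[t + 1L]
    es <- idx$estart[lo:hi]; ee <- idx$eend[lo:hi]
    s <- frags$tstart[i]; L <- frags$flen[i]
    mates <- list(c(s, min(s + R - 1L, s + L - 1L)),
                  c(max(s, s + L - R), s + L - 1L))
    g <- idx$tx_gene[t]
    gene[i] <- sim$annotation$genes$gene_id[g]
    proj <- lapply(mates, function(m) .projectInterval(es, ee, m[1], m[2]))
    if (mode == "DEJU") {
      ## per-junction best (max over mates) minimum overhang
      cand <- list()
      for (p in seq_along(proj)) {
        jx <- proj[[p]]$junctions
        if (!nrow(jx)) next
        m <- mates[[p]]
        cum <- cumsum(ee - es + 1L)
        for (r in seq_len(nrow(jx))) {
          k <- match(jx[r, 1], ee + 1L)  # gap index by intron start
          C <- cum[k]
          over <- min(C - m[1] + 1L, m[2] - C)
          key <- paste(jx[r, 1], jx[r, 2])
          if (is.null(cand[[key]]) || over > cand[[key]]$over)
            cand[[key]] <- list(start = jx[r, 1], end = jx[r, 2], over = over)
        }
      }
      if (length(cand)) {
        overs <- vapply(cand, function(x) x$over, 0L)
        starts <- vapply(cand, function(x) x$start, 0L)
        best <- which(overs == max(overs))
        best <- best[which.min(starts[best])]
        type[i] <- "junction"
        fs[i] <- cand[[best]]$start; fe[i] <- cand[[best]]$end
        next
      }
    }
    ## exon overlap against the gene's flattened exons
    frange <- (fi$fgOffset[g] + 1L):fi$fgOffset[g + 1L]
    ov <- numeric(length(frange))
    for (p in seq_along(proj)) {
      bl <- proj[[p]]$blocks
      for (r in seq_len(nrow(bl))) {
        o <- pmax(0L, pmin(bl[r, 2], fi$flat$end[frange]) -
                        pmax(bl[r, 1], fi$flat$start[frange]) + 1L)
        ov <- ov + o
      }
    }
    if (mode == "DEU") {
      hitf <- frange[ov > 0]
      type[i] <- if (length(hitf)) "exon" else "unassigned"
      featlist[i] <- paste(sprintf("%d-%d", fi$flat$start[hitf],
                                   fi$flat$end[hitf]), collapse = ";")
      next
    }
    if (all(ov == 0)) { type[i] <- "unassigned"; next }
    best <- frange[which.max(ov)]  # which.max: leftmost tie
    type[i] <- "exon"
    fs[i] <- fi$flat$start[best]; fe[i] <- fi$flat$end[best]
  }
  out <- data.frame(sample_id = frags$sample_id, type = type,
                    gene_id = gene, start = fs, end = fe,
                    stringsAsFactors = FALSE)
  if (mode == "DEU") out$features <- featlist
  out
}

## bundle of index structures used by the counting paths
.quantIndices <- function(sim) {
  idx <- .txIndex(sim)
  fi <- .flatIndex(sim$annotation)
  ju <- .junctionUniverse(sim, idx)
  list(idx = idx, fi = fi, ju = ju)
}

## per-sample tabulation: DEJU returns exon/junction count vectors and the
## junction max overhangs; DEU returns the double-counted exon vector
.tabulateSample <- function(tx, tstart, flen, R, ind, mode) {
  if (mode == "DEU") {
    return(count_deu_cpp(tx, tstart, flen, R,
                         ind$idx$estart, ind$idx$eend, ind$idx$offset,
                         ind$idx$tx_gene, ind$fi$flat$start,
                         ind$fi$flat$end, ind$fi$fgOffset))
  }
  cl <- classify_deju_cpp(tx, tstart, flen, R,
                          ind$idx$estart, ind$idx$eend, ind$idx$offset,
                          ind$idx$tx_gene, ind$ju$jid, ind$ju$jOffset,
                          nrow(ind$ju$jtab), ind$fi$flat$start,
                          ind$fi$flat$end, ind$fi$fgOffset)
  a <- cl$assign
  list(ex = tabulate(a[a > 0L], nrow(ind$fi$flat)),
       jx = tabulate(-a[a < 0L], nrow(ind$ju$jtab)),
       maxover = cl$max_overhang)
}

.exonFeatureTable <- function(fi) {
  data.frame(
    feature_id = sprintf("%s:E:%d-%d", fi$flat$gene_id, fi$flat$start,
                         fi$flat$end),
    feature_type = "EXON", gene_id = fi$flat$gene_id,
    chrom = fi$flat$chrom, start = fi$flat$start, end = fi$flat$end,
    strand = fi$flat$strand, stringsAsFactors = FALSE)
}

## assemble a deju_counts object from accumulated per-sample tabulations
.assembleCounts <- function(sim, ind, mode, exCounts, jxCounts, maxOver,
                            simulated, sample_ids, design,
                            minJunctionReads) {
  fi <- ind$fi
  if (mode == "DEU") {
    features <- .exonFeatureTable(fi)
    counts <- exCounts
    dimnames(counts) <- list(features$feature_id, sample_ids)
    samples <- data.frame(sample_id = sample_ids,
                          simulated = as.integer(simulated),
                          lib_size = colSums(counts),
                          unassigned = NA_integer_,
                          stringsAsFactors = FALSE)
    if (!is.null(design))
      samples$group <- design$group[match(sample_ids, design$sample_id)]
    return(structure(list(counts = counts, features = features,
                          samples = samples, mode = mode,
                          junction_support = NULL),
                     class = "deju_counts"))
  }
  support <- rowSums(jxCounts)
  jassign <- assignJunctionsToGenes(ind$ju$jtab, sim$annotation)
  keep <- support > minJunctionReads & !is.na(jassign$gene_id)
  jfeat <- data.frame(
    feature_id = sprintf("%s:J:%d-%d", jassign$gene_id[keep],
                         jassign$intron_start[keep],
                         jassign$intron_end[keep]),
    feature_type = rep("JUNCTION", sum(keep)),
    gene_id = jassign$gene_id[keep],
    chrom = jassign$chrom[keep], start = jassign$intron_start[keep],
    end = jassign$intron_end[keep], strand = jassign$strand[keep],
    stringsAsFactors = FALSE)
  features <- rbind(.exonFeatureTable(fi), jfeat)
  counts <- rbind(exCounts, jxCounts[keep, , drop = FALSE])
  dimnames(counts) <- list(features$feature_id, sample_ids)
  o <- order(features$gene_id, features$feature_type, features$start)
  features <- features[o, , drop = FALSE]
  counts <- counts[o, , drop = FALSE]
  rownames(features) <- NULL
  samples <- data.frame(sample_id = sample_ids,
                        simulated = as.integer(simulated),
                        lib_size = colSums(counts),
                        stringsAsFactors = FALSE)
  samples$unassigned <- samples$simulated - samples$lib_size
  if (!is.null(design))
    samples$group <- design$group[match(sample_ids, design$sample_id)]
  jsupport <- cbind(jassign,
                    data.frame(n_unique = as.integer(support),
                               max_overhang = maxOver, kept = keep))
  structure(list(counts = counts, features = features, samples = samples,
                 mode = mode, minJunctionReads = minJunctionReads,
                 junction_support = jsupport),
            class = "deju_counts")
}

#' Build the exon-junction count matrix
#'
#' Converts simulated fragments into a feature-by-sample count matrix in
#' DEJU mode (flattened exons plus retained junction features, each
#' fragment counted at most once) or legacy DEU mode (flattened exons only,
#' with junction-spanning fragments double-counted).
#'
#' Junction features whose support summed across all samples does not
#' exceed \code{minJunctionReads} (strictly-greater rule), or which cannot
#' be assigned to a unique gene, are dropped; their fragments stay
#' unassigned.
#'
#' @param frags compact fragment table from \code{\link{simulateFragments}}
#'   (any number of samples).
#' @param sim the originating \code{deju_sim}.
#' @param design optional \code{\link{sampleDesign}}; when given, sample
#'   ordering and group labels are taken from it (samples absent from the
#'   design are an error).
#' @param mode \code{"DEJU"} or \code{"DEU"}.
#' @param minJunctionReads pooled-support filtering threshold (a junction
#'   is kept when support > this value; study condition 3).
#' @return An object of class \code{deju_counts}: list with \code{counts}
#'   (integer matrix), \code{features} (feature_id, feature_type, gene_id,
#'   chrom, start, end, strand), \code{samples} (sample_id, group,
#'   simulated, lib_size, unassigned), \code{mode}, and the junction
#'   support table \code{junction_support}.
#' @export
countFeatures <- function(frags, sim, design = NULL,
                          mode = c("DEJU", "DEU"), minJunctionReads = 3L) {
  mode <- match.arg(mode)
  R <- attr(frags, "readLength")
  if (is.null(R)) stop("fragment table lacks the readLength attribute")
  ind <- .quantIndices(sim)
  sample_ids <- unique(frags$sample_id)
  if (!is.null(design)) {
    if (!all(sample_ids %in% design$sample_id))
      stop("sample id(s) absent from design: ",
           paste(setdiff(sample_ids, design$sample_id), collapse = ", "))
    sample_ids <- design$sample_id[design$sample_id %in% sample_ids]
  }
  nS <- length(sample_ids)
  by_sample <- split(seq_len(nrow(frags)), factor(frags$sample_id, sample_ids))
  simulated <- lengths(by_sample)
  nFlat <- nrow(ind$fi$flat)
  nJ <- nrow(ind$ju$jtab)
  exCounts <- matrix(0L, nFlat, nS)
  jxCounts <- matrix(0L, nJ, nS)
  maxOver <- integer(nJ)
  for (s in seq_len(nS)) {
    ii <- by_sample[[s]]
    tab <- .tabulateSample(frags$tx[ii], frags$tstart[ii], frags$flen[ii],
                           R, ind, mode)
    if (mode == "DEU") {
      exCounts[, s] <- tab
    } else {
      exCounts[, s] <- tab$ex
      jxCounts[, s] <- tab$jx
      maxOver <- pmax(maxOver, tab$maxover)
    }
  }
  .assembleCounts(sim, ind, mode, exCounts, jxCounts, maxOver, simulated,
                  sample_ids, design, minJunctionReads)
}

#' Simulate and count fragments sample by sample
#'
#' Streaming equivalent of \code{\link{simulateFragments}} followed by
#' \code{\link{countFeatures}}: fragments of each sample are generated,
#' classified and discarded before the next sample is simulated, so
#' full-depth simulations never hold all fragments in memory. Both counting
#' modes can be produced from the identical fragment stream in one pass.
#' With the same RNG state this reproduces \code{countFeatures} on the
#' output of \code{simulateFragments} exactly.
#'
#' @param sim a \code{deju_sim}.
#' @param abundances matrix from \code{\link{sampleAbundances}}.
#' @param design a \code{\link{sampleDesign}} data.frame.
#' @param modes counting modes to produce (subset of DEJU/DEU).
#' @param minJunctionReads pooled junction support threshold.
#' @param readLength,fragLenMean,fragLenSd see
#'   \code{\link{simulateFragments}}.
#' @param seed optional seed.
#' @return a named list of \code{deju_counts}, one per requested mode.
#' @export
simulateCounts <- function(sim, abundances, design,
                           modes = c("DEJU", "DEU"), minJunctionReads = 3L,
                           readLength = 75L, fragLenMean = 250,
                           fragLenSd = 40, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  modes <- match.arg(modes, c("DEJU", "DEU"), several.ok = TRUE)
  ind <- .quantIndices(sim)
  sample_ids <- design$sample_id
  nS <- length(sample_ids)
  nFlat <- nrow(ind$fi$flat)
  nJ <- nrow(ind$ju$jtab)
  acc <- lapply(modes, function(m)
    list(ex = matrix(0L, nFlat, nS), jx = matrix(0L, nJ, nS),
         maxover = integer(nJ)))
  names(acc) <- modes
  simulated <- integer(nS)
  for (s in seq_len(nS)) {
    frags <- simulateFragments(sim, abundances, design,
                               readLength = readLength,
                               fragLenMean = fragLenMean,
                               fragLenSd = fragLenSd,
                               samples = sample_ids[s])
    simulated[s] <- nrow(frags)
    for (m in modes) {
      tab <- .tabulateSample(frags$tx, frags$tstart, frags$flen,
                             readLength, ind, m)
      if (m == "DEU") {
        acc[[m]]$ex[, s] <- tab
      } else {
        acc[[m]]$ex[, s] <- tab$ex
        acc[[m]]$jx[, s] <- tab$jx
        acc[[m]]$maxover <- pmax(acc[[m]]$maxover, tab$maxover)
      }
    }
  }
  out <- lapply(modes, function(m)
    .assembleCounts(sim, ind, m, acc[[m]]$ex, acc[[m]]$jx, acc[[m]]$maxover,
                    simulated, sample_ids, design, minJunctionReads))
  names(out) <- modes
  out
}

#' Assemble a count object from external tables
#'
#' Builds a \code{deju_counts} from a feature table and count matrix (for
#' example read back with \code{\link{readCountMatrix}}), so externally
#' produced exon-junction counts can enter \code{\link{dejuFit}}.
#'
#' @param counts integer matrix, features x samples.
#' @param features data.frame with feature_id, feature_type, gene_id,
#'   chrom, start, end, strand (rows aligned with \code{counts}).
#' @param group optional two-level factor of sample groups.
#' @param mode counting mode label (default DEJU).
#' @param lib.size library sizes (default column sums).
#' @return a \code{deju_counts}.
#' @export
newCounts <- function(counts, features, group = NULL, mode = "DEJU",
                      lib.size = colSums(counts)) {
  if (nrow(counts) != nrow(features))
    stop("counts and features disagree on the number of rows")
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  rownames(counts) <- features$feature_id
  samples <- data.frame(sample_id = colnames(counts),
                        simulated = NA_integer_,
                        lib_size = lib.size,
                        unassigned = NA_integer_, stringsAsFactors = FALSE)
  if (!is.null(group)) samples$group <- factor(group)
  structure(list(counts = counts, features = features, samples = samples,
                 mode = mode, junction_support = NULL),
            class = "deju_counts")
}

#' @export
print.deju_counts <- function(x, ...) {
  nj <- sum(x$features$feature_type == "JUNCTION")
  cat("deju_counts (", x$mode, " mode): ", nrow(x$counts), " features (",
      nrow(x$counts) - nj, " exons, ", nj, " junctions) x ",
      ncol(x$counts), " samples\n", sep = "")
  cat("  library sizes:", paste(format(x$samples$lib_size, big.mark = ","),
                                collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a count matrix as TSV
#'
#' Columns: feature_id, feature_type, gene_id, chrom, start, end, strand,
#' then one integer column per sample.
#'
#' @param x a \code{deju_counts}.
#' @param path file path.
#' @return \code{writeCountMatrix} returns \code{path} invisibly;
#'   \code{readCountMatrix} returns a list with \code{counts} and
#'   \code{features}.
#' @export
writeCountMatrix <- function(x, path) {
  tab <- cbind(x$features, as.data.frame(x$counts, check.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCountMatrix
#' @export
readCountMatrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- c("feature_id", "feature_type", "gene_id", "chrom", "start",
            "end", "strand")
  if (!all(meta %in% names(tab)))
    stop("count matrix file missing column(s): ",
         paste(setdiff(meta, names(tab)), collapse = ", "))
  counts <- as.matrix(tab[, setdiff(names(tab), meta), drop = FALSE])
  rownames(counts) <- tab$feature_id
  list(counts = counts, features = tab[, meta])
}
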