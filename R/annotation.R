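#' Gene annotation container
#'
#' A \code{deju_annotation} holds transcript-level exons for a set of genes,
#' the per-gene flattened (merged) exon bins used as counting features, and
#' the splice-junction database derived from transcript exon chains.
#' Coordinates are 1-based inclusive throughout; junctions are stored as the
#' first and last base of the intron (the SJ.out.tab convention).
#'
#' @param exons data.frame with columns \code{gene_id}, \code{transcript_id},
#'   \code{chrom}, \code{start}, \code{end}, \code{strand} (one row per exon).
#'   Exons of a transcript must be non-overlapping; all exons of a gene must
#'   share one chromosome and strand.
#' @return An object of class \code{deju_annotation}: a list with elements
#'   \code{exons}, \code{genes} (gene spans), and \code{flat} /
#'   \code{junctions} (populated by \code{\link{flattenExons}} and
#'   \code{\link{buildJunctionDatabase}}; \code{NULL} until then).
#' @seealso \code{\link{parseGTF}}, \code{\link{flattenExons}},
#'   \code{\link{buildJunctionDatabase}}
#' @export
newAnnotation <- function(exons) {
  required <- c("gene_id", "transcript_id", "chrom", "start", "end", "strand")
  missing <- setdiff(required, names(exons))
  if (length(missing))
    stop("exon table lacks column(s): ", paste(missing, collapse = ", "))
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (any(exons$start > exons$end))
    stop("exon with start > end")
  if (!all(exons$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  exons <- exons[order(exons$gene_id, exons$transcript_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  ## one chromosome and strand per gene
  by_gene <- split(seq_len(nrow(exons)), exons$gene_id)
  for (idx in by_gene) {
    if (length(unique(exons$chrom[idx])) > 1L ||
        length(unique(exons$strand[idx])) > 1L)
      stop("gene '", exons$gene_id[idx[1]],
           "' has exons on multiple chromosomes or strands")
  }
  genes <- data.frame(
    gene_id = names(by_gene),
    chrom = vapply(by_gene, function(i) exons$chrom[i[1]], ""),
    strand = vapply(by_gene, function(i) exons$strand[i[1]], ""),
    start = vapply(by_gene, function(i) min(exons$start[i]), 0L),
    end = vapply(by_gene, function(i) max(exons$end[i]), 0L),
    stringsAsFactors = FALSE
  )
  rownames(genes) <- NULL
  structure(list(exons = exons, genes = genes, flat = NULL, junctions = NULL),
            class = "deju_annotation")
}

#' @export
print.deju_annotation <- function(x, ...) {
  cat("deju_annotation:", nrow(x$genes), "genes,",
      length(unique(x$exons$transcript_id)), "transcripts,",
      nrow(x$exons), "exon records\n")
  if (!is.null(x$flat))
    cat("  flattened exon bins:", nrow(x$flat), "\n")
  if (!is.null(x$junctions))
    cat("  junction database:", nrow(x$junctions), "records\n")
  invisible(x)
}

#' Parse a GTF file into an annotation object
#'
#' Reads exon records from a standard 9-column GTF file and groups them into
#' transcripts and genes. Only records with feature type \code{exon} are
#' consumed; gene/transcript records are skipped. Flattened exons and the
#' junction database are not computed here (see \code{\link{flattenExons}}
#' and \code{\link{buildJunctionDatabase}}).
#'
#' @param path path to a GTF file.
#' @return A \code{deju_annotation}, or an empty list of genes for an empty
#'   file.
#' @export
parseGTF <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  if (!any(keep)) {
    ann <- structure(list(
      exons = data.frame(gene_id = character(), transcript_id = character(),
                         chrom = character(), start = integer(),
                         end = integer(), strand = character()),
      genes = data.frame(gene_id = character(), chrom = character(),
                         strand = character(), start = integer(),
                         end = integer()),
      flat = NULL, junctions = NULL), class = "deju_annotation")
    return(ann)
  }
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    stop("malformed GTF line ", lineno[which(nf != 9L)[1]],
         ": expected 9 tab-separated columns, found ", nf[nf != 9L][1])
  feat <- vapply(fields, `[`, "", 3L)
  is_exon <- feat == "exon"
  if (!any(is_exon))
    return(newAnnotation(data.frame(
      gene_id = character(), transcript_id = character(), chrom = character(),
      start = integer(), end = integer(), strand = character())))
  ex <- fields[is_exon]
  exln <- lineno[is_exon]
  attr_field <- vapply(ex, `[`, "", 9L)
  get_attr <- function(key) {
    m <- regmatches(attr_field,
                    regexpr(paste0(key, ' "([^"]*)"'), attr_field))
    out <- rep(NA_character_, length(attr_field))
    has <- grepl(paste0(key, ' "'), attr_field, fixed = TRUE)
    out[has] <- sub(paste0('.*', key, ' "([^"]*)".*'), "\\1",
                    attr_field[has])
    out
  }
  gene_id <- get_attr("gene_id")
  transcript_id <- get_attr("transcript_id")
  if (anyNA(gene_id))
    stop("GTF line ", exln[which(is.na(gene_id))[1]],
         ": exon record without gene_id attribute")
  if (anyNA(transcript_id))
    stop("GTF line ", exln[which(is.na(transcript_id))[1]],
         ": exon record without transcript_id attribute")
  start <- suppressWarnings(as.integer(vapply(ex, `[`, "", 4L)))
  end <- suppressWarnings(as.integer(vapply(ex, `[`, "", 5L)))
  if (anyNA(start) || anyNA(end))
    stop("malformed GTF line ", exln[which(is.na(start) | is.na(end))[1]],
         ": non-integer coordinates")
  newAnnotation(data.frame(
    gene_id = gene_id,
    transcript_id = transcript_id,
    chrom = vapply(ex, `[`, "", 1L),
    start = start, end = end,
    strand = vapply(ex, `[`, "", 7L),
    stringsAsFactors = FALSE))
}

#' Write an annotation as GTF
#'
#' Emits one \code{exon} record per transcript exon with \code{gene_id} and
#' \code{transcript_id} attributes.
#'
#' @param ann a \code{deju_annotation}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGTF <- function(ann, path) {
  ex <- ann$exons
  ex <- ex[order(ex$gene_id, ex$transcript_id, ex$start), , drop = FALSE]
  lines <- sprintf(
    '%s\tdeju\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    ex$chrom, ex$start, ex$end, ex$strand, ex$gene_id, ex$transcript_id)
  writeLines(lines, path)
  invisible(path)
}

## merge sorted intervals; bookended (gap 0) merged when mergeBookended
.merge_intervals <- function(start, end, mergeBookended = TRUE) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  gap <- if (mergeBookended) 1L else 0L
  out_s <- start[1]; out_e <- end[1]
  ms <- integer(0); me <- integer(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= out_e + gap) {
      if (end[i] > out_e) out_e <- end[i]
    } else {
      ms <- c(ms, out_s); me <- c(me, out_e)
      out_s <- start[i]; out_e <- end[i]
    }
  }
  list(start = c(ms, out_s), end = c(me, out_e))
}

#' Flatten per-gene exons into disjoint merged bins
#'
#' Computes, for every gene, the sorted union of all its transcripts' exon
#' intervals, merging overlapping and (by default) book-ended intervals.
#' These flattened exons are the exon-level counting bins.
#'
#' @param ann a \code{deju_annotation}.
#' @param mergeBookended merge intervals separated by a gap of 0 bases
#'   (default \code{TRUE}).
#' @return \code{ann} with \code{$flat} populated: a data.frame with columns
#'   \code{gene_id}, \code{chrom}, \code{start}, \code{end}, \code{strand}.
#' @export
flattenExons <- function(ann, mergeBookended = TRUE) {
  ex <- ann$exons
  if (nrow(ex) == 0L) {
    ann$flat <- data.frame(gene_id = character(), chrom = character(),
                           start = integer(), end = integer(),
                           strand = character())
    return(ann)
  }
  by_gene <- split(seq_len(nrow(ex)), ex$gene_id)
  res <- lapply(names(by_gene), function(g) {
    idx <- by_gene[[g]]
    m <- .merge_intervals(ex$start[idx], ex$end[idx], mergeBookended)
    data.frame(gene_id = g, chrom = ex$chrom[idx[1]],
               start = as.integer(m$start), end = as.integer(m$end),
               strand = ex$strand[idx[1]], stringsAsFactors = FALSE)
  })
  flat <- do.call(rbind, res)
  rownames(flat) <- NULL
  ann$flat <- flat
  ann
}

#' Build the splice-junction database from transcript exon chains
#'
#' Every pair of consecutive exons within a transcript defines one intron;
#' these introns form the annotated junction database. Duplicate junctions
#' (same chromosome, intron coordinates, strand and gene) are collapsed.
#'
#' @param ann a \code{deju_annotation}.
#' @return \code{ann} with \code{$junctions} populated: a data.frame with
#'   columns \code{chrom}, \code{intron_start}, \code{intron_end},
#'   \code{strand}, \code{gene_id}, \code{annotated}, sorted by
#'   (chrom, intron_start, intron_end).
#' @export
buildJunctionDatabase <- function(ann) {
  ex <- ann$exons
  if (nrow(ex) == 0L) {
    ann$junctions <- data.frame(
      chrom = character(), intron_start = integer(), intron_end = integer(),
      strand = character(), gene_id = character(), annotated = logical())
    return(ann)
  }
  ex <- ex[order(ex$transcript_id, ex$start), , drop = FALSE]
  n <- nrow(ex)
  same_tx <- ex$transcript_id[-n] == ex$transcript_id[-1]
  i <- which(same_tx)
  jx <- data.frame(
    chrom = ex$chrom[i],
    intron_start = ex$end[i] + 1L,
    intron_end = ex$start[i + 1L] - 1L,
    strand = ex$strand[i],
    gene_id = ex$gene_id[i],
    annotated = rep(TRUE, length(i)),
    stringsAsFactors = FALSE
  )
  if (any(jx$intron_start > jx$intron_end))
    stop("book-ended or overlapping consecutive exons within a transcript")
  jx <- unique(jx)
  jx <- jx[order(jx$chrom, jx$intron_start, jx$intron_end), , drop = FALSE]
  rownames(jx) <- NULL
  ann$junctions <- jx
  ann
}

#' Write / read flattened exons in SAF format
#'
#' SAF (simplified annotation format) is the tab-separated table with header
#' \code{GeneID, Chr, Start, End, Strand}, one row per flattened exon.
#'
#' @param ann a \code{deju_annotation} with flattened exons.
#' @param path file path.
#' @return \code{writeSAF} returns \code{path} invisibly; \code{readSAF}
#'   returns the feature table as a data.frame.
#' @export
writeSAF <- function(ann, path) {
  if (is.null(ann$flat)) stop("flattened exons not computed; run flattenExons()")
  saf <- data.frame(GeneID = ann$flat$gene_id, Chr = ann$flat$chrom,
                    Start = ann$flat$start, End = ann$flat$end,
                    Strand = ann$flat$strand)
  utils::write.table(saf, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSAF
#' @export
readSAF <- function(path) {
  saf <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("GeneID", "Chr", "Start", "End", "Strand")
  missing <- setdiff(required, names(saf))
  if (length(missing))
    stop("SAF file missing column(s): ", paste(missing, collapse = ", "))
  saf$Start <- as.integer(saf$Start)
  saf$End <- as.integer(saf$End)
  saf
}

#' Write / read a junction table in the SJ.out.tab dialect
#'
#' Columns: chromosome, intron first base, intron last base, strand coded
#' 1 (+) / 2 (-), motif (always 0 here), annotated 0/1, number of uniquely
#' mapping reads, number of multi-mapping reads (0), maximum overhang.
#'
#' @param junctions data.frame with columns \code{chrom}, \code{intron_start},
#'   \code{intron_end}, \code{strand}, \code{annotated}, and optionally
#'   \code{n_unique} and \code{max_overhang}.
#' @param path file path.
#' @return \code{writeJunctionTable} returns \code{path} invisibly;
#'   \code{readJunctionTable} returns a data.frame with the same columns.
#' @export
writeJunctionTable <- function(junctions, path) {
  n <- nrow(junctions)
  nu <- if ("n_unique" %in% names(junctions)) junctions$n_unique else rep(0L, n)
  oh <- if ("max_overhang" %in% names(junctions)) junctions$max_overhang else rep(0L, n)
  tab <- data.frame(
    chrom = junctions$chrom,
    intron_start = junctions$intron_start,
    intron_end = junctions$intron_end,
    strand = ifelse(junctions$strand == "+", 1L, 2L),
    motif = 0L,
    annotated = as.integer(junctions$annotated),
    n_unique = nu, n_multi = 0L, max_overhang = oh)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeJunctionTable
#' @export
readJunctionTable <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) != 9L)
    stop("junction table must have 9 columns, found ", ncol(tab))
  names(tab) <- c("chrom", "intron_start", "intron_end", "strand", "motif",
                  "annotated", "n_unique", "n_multi", "max_overhang")
  tab$strand <- ifelse(tab$strand == 1L, "+", "-")
  tab$annotated <- tab$annotated == 1L
  tab
}
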