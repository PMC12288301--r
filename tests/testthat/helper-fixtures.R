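# Fixture builders shared across test files. Everything is generated in
# code; no fixture files are stored.

# exon table for one or more transcripts: list(tx_id = matrix/df of start,end)
exon_table <- function(..., gene_id = "G1", chrom = "chr1", strand = "+") {
  txs <- list(...)
  do.call(rbind, lapply(names(txs), function(id) {
    m <- txs[[id]]
    data.frame(gene_id = gene_id, transcript_id = id, chrom = chrom,
               start = m[, 1], end = m[, 2], strand = strand,
               stringsAsFactors = FALSE)
  }))
}

# a three-exon single-transcript gene used throughout
toy_annotation <- function() {
  ex <- exon_table(T1 = cbind(c(100, 300, 500), c(200, 400, 600)))
  buildJunctionDatabase(flattenExons(newAnnotation(ex)))
}

# hand-build a deju_sim around explicit isoform exon sets so that fragment
# placement and counting can be asserted exactly. `isoforms` is a named
# list (names "A", "B", ...) of two-column start/end matrices; the
# reference chain is their interval union.
manual_sim <- function(isoforms, gene_id = "G1", chrom = "chr1",
                       strand = "+", pattern = "ES", is_true = TRUE,
                       parent = NULL) {
  iso_exons <- do.call(rbind, lapply(names(isoforms), function(nm) {
    m <- isoforms[[nm]]
    data.frame(gene_id = gene_id,
               transcript_id = paste0(gene_id, ".", nm), isoform = nm,
               chrom = chrom, start = as.integer(m[, 1]),
               end = as.integer(m[, 2]), strand = strand,
               stringsAsFactors = FALSE)
  }))
  ## reference = explicit parent chain, or the union of the isoforms
  u <- if (is.null(parent))
    deju:::.merge_intervals(iso_exons$start, iso_exons$end)
  else list(start = parent[, 1], end = parent[, 2])
  ref <- data.frame(gene_id = gene_id,
                    transcript_id = paste0(gene_id, ".R"), chrom = chrom,
                    start = as.integer(u$start), end = as.integer(u$end),
                    strand = strand, stringsAsFactors = FALSE)
  ann <- buildJunctionDatabase(flattenExons(newAnnotation(ref)))
  len <- vapply(names(isoforms), function(nm) {
    m <- isoforms[[nm]]
    sum(m[, 2] - m[, 1] + 1)
  }, 0)
  transcripts <- data.frame(
    transcript_id = paste0(gene_id, ".", names(isoforms)),
    gene_id = gene_id, isoform = names(isoforms),
    length = as.integer(len),
    n_exons = vapply(isoforms, nrow, 0L), stringsAsFactors = FALSE)
  labels <- data.frame(gene_id = gene_id, pattern = pattern,
                       is_true_deu = is_true, stringsAsFactors = FALSE)
  structure(list(annotation = ann, iso_exons = iso_exons,
                 transcripts = transcripts, labels = labels,
                 config = list(nGenes = 1L)), class = "deju_sim")
}

# compact fragment table (the simulateFragments format) built by hand;
# tx is the row index into sim$transcripts
manual_frags <- function(sample_id, tx, tstart, flen, readLength = 75L) {
  f <- data.frame(sample_id = sample_id, tx = as.integer(tx),
                  tstart = as.integer(tstart), flen = as.integer(flen),
                  stringsAsFactors = FALSE)
  attr(f, "readLength") <- as.integer(readLength)
  f
}

# minimal deju_counts for preprocess/engine tests
manual_counts <- function(counts, group = NULL, gene_id = NULL,
                          lib_size = colSums(counts)) {
  n <- nrow(counts)
  if (is.null(gene_id)) gene_id <- paste0("G", seq_len(n))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  features <- data.frame(
    feature_id = paste0("F", seq_len(n)), feature_type = "EXON",
    gene_id = gene_id, chrom = "chr1", start = seq_len(n) * 1000L,
    end = seq_len(n) * 1000L + 100L, strand = "+",
    stringsAsFactors = FALSE)
  rownames(counts) <- features$feature_id
  samples <- data.frame(sample_id = colnames(counts),
                        simulated = as.integer(colSums(counts)),
                        lib_size = lib_size,
                        unassigned = 0L, stringsAsFactors = FALSE)
  if (!is.null(group)) samples$group <- factor(group)
  structure(list(counts = counts, features = features, samples = samples,
                 mode = "DEJU", junction_support = NULL),
            class = "deju_counts")
}

# independent interval-union oracle: count covered bases by enumeration
covered_bases <- function(start, end) {
  length(unique(unlist(mapply(seq, start, end, SIMPLIFY = FALSE))))
}

# junction set of an exon chain (sorted start/end vectors)
chain_junctions <- function(m) {
  m <- m[order(m[, 1]), , drop = FALSE]
  if (nrow(m) < 2) return(character(0))
  paste(m[-nrow(m), 2] + 1, m[-1, 1] - 1, sep = "-")
}
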