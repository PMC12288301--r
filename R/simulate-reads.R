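## Per-sample transcript abundances and paired-end fragment simulation.
##
## Baseline transcript expression follows Zipf's law (weight of rank k
## proportional to k^-s). Genuine DEU genes switch isoform usage between the
## two groups by a multiplicative fold-change; biological variation between
## replicates is a mean-1 gamma multiplier per transcript per sample with
## coefficient of variation `bcv`. Fragments are drawn multinomially from
## the per-sample abundance column and placed uniformly on the transcript
## with truncated-normal fragment lengths, then projected through the exon
## chain to genomic blocks, recording every intron a mate bridges.

#' Two-group sample design
#'
#' @param nPerGroup replicates per group (study conditions: 3, 5 or 10).
#' @param libSizes \code{"balanced"} (every sample at \code{depth}),
#'   \code{"unbalanced"} (alternating \code{depth/2} and \code{2*depth}), or
#'   a numeric vector of per-sample fragment counts.
#' @param depth fragments per sample in the balanced scenario (scaled
#'   default 5e6, a 1/10 scaling of the 50 million read study condition).
#' @return data.frame with columns \code{sample_id}, \code{group} (factor
#'   "1"/"2") and \code{lib_size}.
#' @export
sampleDesign <- function(nPerGroup = 3L, libSizes = "balanced", depth = 5e6) {
  n <- 2L * nPerGroup
  sample_id <- sprintf("S%d_G%d", seq_len(n), rep(1:2, each = nPerGroup))
  if (is.character(libSizes)) {
    libSizes <- match.arg(libSizes, c("balanced", "unbalanced"))
    ls <- if (libSizes == "balanced") rep(depth, n)
          else rep(c(depth / 2, depth * 2), length.out = n)
  } else {
    if (length(libSizes) != n) stop("need one library size per sample")
    ls <- libSizes
  }
  if (any(ls <= 0)) stop("library sizes must be positive")
  data.frame(sample_id = sample_id,
             group = factor(rep(c("1", "2"), each = nPerGroup)),
             lib_size = ls, stringsAsFactors = FALSE)
}

#' Zipf baseline expression weights
#'
#' Transcripts are ranked by a uniform random permutation; the transcript of
#' rank k receives weight proportional to \eqn{k^{-s}}, normalised to sum
#' to one. \code{zipf = 0} gives uniform weights.
#'
#' @param sim a \code{deju_sim}.
#' @param zipf the Zipf exponent s (default 1).
#' @param seed optional seed.
#' @return named numeric vector of baseline proportions (one per transcript,
#'   in \code{sim$transcripts} order, summing to 1).
#' @export
baselineExpression <- function(sim, zipf = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nT <- nrow(sim$transcripts)
  rank <- sample(nT)
  w <- rank^(-zipf)
  w <- w / sum(w)
  names(w) <- sim$transcripts$transcript_id
  w
}

#' Per-sample transcript abundances
#'
#' Applies the group fold-change to the isoform pair of every genuine DEU
#' gene (isoform A multiplied in group 1, isoform B in group 2), multiplies
#' every transcript-by-sample cell by an independent mean-1
#' Gamma(shape = 1/bcv^2, scale = bcv^2) draw, and renormalises each column
#' to sum to one. In null mode the fold-change step is skipped, so the
#' underlying abundances are identical across all samples (up to the gamma
#' noise).
#'
#' @param sim a \code{deju_sim}.
#' @param baseline baseline weights from \code{\link{baselineExpression}}.
#' @param design a \code{\link{sampleDesign}} data.frame.
#' @param foldChange isoform switch fold-change (study condition: 3).
#' @param bcv biological coefficient of variation of the gamma noise
#'   (default 0.2); 0 disables noise.
#' @param nullMode skip the fold-change (type-I-error simulations).
#' @param seed optional seed.
#' @return numeric matrix, transcripts x samples, columns summing to 1.
#' @export
sampleAbundances <- function(sim, baseline, design, foldChange = 3,
                             bcv = 0.2, nullMode = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (foldChange < 1) stop("foldChange must be >= 1")
  tx <- sim$transcripts
  nT <- nrow(tx); nS <- nrow(design)
  expected <- matrix(baseline, nT, nS,
                     dimnames = list(tx$transcript_id, design$sample_id))
  if (!nullMode) {
    true_genes <- sim$labels$gene_id[sim$labels$is_true_deu]
    isA <- tx$gene_id %in% true_genes & tx$isoform == "A"
    isB <- tx$gene_id %in% true_genes & tx$isoform == "B"
    g1 <- design$group == "1"
    expected[isA, g1] <- expected[isA, g1] * foldChange
    expected[isB, !g1] <- expected[isB, !g1] * foldChange
  }
  if (bcv > 0) {
    noise <- matrix(stats::rgamma(nT * nS, shape = 1 / bcv^2, scale = bcv^2),
                    nT, nS)
    expected <- expected * noise
  }
  sweep(expected, 2L, colSums(expected), "/")
}

#' Simulate paired-end fragments
#'
#' Per sample, the number of fragments per transcript is multinomial with
#' the sample's library size and abundance column. Each fragment has a
#' length drawn from Normal(\code{fragLenMean}, \code{fragLenSd}) truncated
#' to [2 x read length, transcript length] (transcripts shorter than twice
#' the read length yield full-length fragments) and a uniform start.
#' Transcripts shorter than the read length are excluded from sampling with
#' a warning.
#'
#' The result is the compact fragment table used by
#' \code{\link{countFeatures}}; use \code{\link{fragmentRecords}} to expand
#' fragments to genomic block coordinates and spanned junctions.
#'
#' @param sim a \code{deju_sim}.
#' @param abundances matrix from \code{\link{sampleAbundances}}.
#' @param design a \code{\link{sampleDesign}} data.frame.
#' @param readLength read length in bp (study condition: 75).
#' @param fragLenMean,fragLenSd fragment length distribution in bp.
#' @param samples subset of sample ids to simulate (default all).
#' @param seed optional seed.
#' @return data.frame with columns \code{sample_id}, \code{tx} (integer row
#'   index into \code{sim$transcripts}), \code{tstart} and \code{flen}
#'   (transcript-coordinate start and fragment length), with the read
#'   length stored in attribute \code{"readLength"}.
#' @export
simulateFragments <- function(sim, abundances, design, readLength = 75L,
                              fragLenMean = 250, fragLenSd = 40,
                              samples = design$sample_id, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (readLength > fragLenMean)
    stop("readLength must not exceed fragLenMean")
  tlen <- sim$transcripts$length
  short <- tlen < readLength
  if (any(short))
    warning(sum(short), " transcript(s) shorter than the read length ",
            "excluded from sampling")
  out <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    s <- samples[i]
    col <- match(s, design$sample_id)
    if (is.na(col)) stop("sample '", s, "' not in design")
    p <- abundances[, match(s, colnames(abundances))]
    p[short] <- 0
    p <- p / sum(p)
    counts <- as.vector(stats::rmultinom(1L, design$lib_size[col], p))
    tx <- rep(seq_along(counts), counts)
    n <- length(tx)
    tl <- tlen[tx]
    flen <- as.integer(round(stats::rnorm(n, fragLenMean, fragLenSd)))
    flen <- pmin(pmax(flen, 2L * readLength), tl)
    tstart <- 1L + as.integer(floor(stats::runif(n) * (tl - flen + 1L)))
    out[[i]] <- data.frame(sample_id = s, tx = tx, tstart = tstart,
                           flen = flen, stringsAsFactors = FALSE)
  }
  frags <- do.call(rbind, out)
  rownames(frags) <- NULL
  attr(frags, "readLength") <- as.integer(readLength)
  frags
}

## per-transcript exon chain index shared by projection and counting
.txIndex <- function(sim) {
  ex <- sim$iso_exons[order(match(sim$iso_exons$transcript_id,
                                  sim$transcripts$transcript_id),
                            sim$iso_exons$start), , drop = FALSE]
  runs <- rle(ex$transcript_id)
  stopifnot(identical(runs$values, sim$transcripts$transcript_id))
  offsets <- c(0L, cumsum(runs$lengths))
  list(estart = ex$start, eend = ex$end,
       offset = offsets,                      # 0-based, length nT+1
       n_exons = runs$lengths,
       tx_gene = match(sim$transcripts$gene_id, sim$annotation$genes$gene_id))
}

## project a transcript interval [a, b] (1-based transcript coords) through
## the exon chain; returns genomic blocks and bridged introns
.projectInterval <- function(estart, eend, a, b) {
  elen <- eend - estart + 1L
  cum <- cumsum(elen)
  if (a < 1L || b > cum[length(cum)] || a > b)
    stop("interval [", a, ", ", b, "] outside transcript of length ",
         cum[length(cum)])
  first <- findInterval(a - 1L, cum) + 1L
  last <- findInterval(b - 1L, cum) + 1L
  prev <- c(0L, cum)
  bs <- integer(0); be <- integer(0)
  for (k in first:last) {
    lo <- max(a, prev[k] + 1L); hi <- min(b, cum[k])
    bs <- c(bs, estart[k] + (lo - prev[k] - 1L))
    be <- c(be, estart[k] + (hi - prev[k] - 1L))
  }
  jx <- if (last > first)
    cbind(intron_start = eend[first:(last - 1L)] + 1L,
          intron_end = estart[(first + 1L):last] - 1L)
  else matrix(integer(0), 0L, 2L,
              dimnames = list(NULL, c("intron_start", "intron_end")))
  list(blocks = cbind(start = bs, end = be), junctions = jx)
}

#' Expand compact fragments to genomic records
#'
#' Projects each mate of each fragment through its transcript's exon chain,
#' producing the genomic block structure and the set of introns the mates
#' bridge (with at least 1 bp on each side). Intended for desk-scale
#' inspection, export and tests rather than full-depth simulations.
#'
#' @param frags compact fragment table from \code{\link{simulateFragments}}.
#' @param sim the \code{deju_sim} the fragments were simulated from.
#' @return data.frame with one row per fragment: \code{sample_id},
#'   \code{transcript_id}, \code{gene_id}, \code{mate1_blocks},
#'   \code{mate2_blocks} (comma-separated \code{start-end}) and
#'   \code{junctions} (comma-separated \code{start-end} of bridged introns,
#'   union over both mates).
#' @export
fragmentRecords <- function(frags, sim) {
  R <- attr(frags, "readLength")
  if (is.null(R)) stop("fragment table lacks the readLength attribute")
  idx <- .txIndex(sim)
  fmt <- function(m) if (nrow(m)) paste(m[, 1], m[, 2], sep = "-", collapse = ",") else ""
  n <- nrow(frags)
  m1b <- m2b <- jx <- character(n)
  for (i in seq_len(n)) {
    t <- frags$tx[i]
    lo <- idx$offset[t] + 1L; hi <- idx$offset[t + 1L]
    es <- idx$estart[lo:hi]; ee <- idx$eend[lo:hi]
    s <- frags$tstart[i]; L <- frags$flen[i]
    a1 <- s; b1 <- min(s + R - 1L, s + L - 1L)
    a2 <- max(s, s + L - R); b2 <- s + L - 1L
    p1 <- .projectInterval(es, ee, a1, b1)
    p2 <- .projectInterval(es, ee, a2, b2)
    m1b[i] <- fmt(p1$blocks); m2b[i] <- fmt(p2$blocks)
    ju <- unique(rbind(p1$junctions, p2$junctions))
    jx[i] <- fmt(ju)
  }
  data.frame(sample_id = frags$sample_id,
             transcript_id = sim$transcripts$transcript_id[frags$tx],
             gene_id = sim$transcripts$gene_id[frags$tx],
             mate1_blocks = m1b, mate2_blocks = m2b, junctions = jx,
             stringsAsFactors = FALSE)
}

#' Write fragment records as TSV
#'
#' @param records data.frame from \code{\link{fragmentRecords}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFragments <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
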