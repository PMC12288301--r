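test_that("Zipf baseline weights follow k^-s / H", {
  ## 2 genes x 2 isoforms = 4 transcripts
  sim <- simTranscriptome(nGenes = 2, nTrueDEU = 0, seed = 1)
  w <- baselineExpression(sim, zipf = 1, seed = 4)
  expect_equal(sum(w), 1)
  w4 <- sort(w, decreasing = TRUE)
  H4 <- sum(1 / (1:4))
  expect_equal(as.numeric(w4), (1 / (1:4)) / H4, tolerance = 1e-12)

  ## three ranks at s = 1: 1/H3 * (1, 1/2, 1/3)
  sim3 <- manual_sim(list(A = cbind(c(100, 300), c(200, 400)),
                          B = cbind(100, 200),
                          C = cbind(300, 400)))
  w3 <- sort(baselineExpression(sim3, zipf = 1, seed = 4), decreasing = TRUE)
  expect_equal(as.numeric(w3), c(0.54545455, 0.27272727, 0.18181818),
               tolerance = 1e-7)

  ## s = 0 gives uniform weights
  w0 <- baselineExpression(sim, zipf = 0, seed = 4)
  expect_true(all(abs(w0 - 0.25) < 1e-12))

  ## same seed, same ranking
  expect_identical(baselineExpression(sim, seed = 9),
                   baselineExpression(sim, seed = 9))
})

test_that("fold-change 3 yields 75/25 isoform usage without noise", {
  sim <- simTranscriptome(nGenes = 4, nTrueDEU = 1, patterns = "ES",
                          seed = 10)
  des <- sampleDesign(3)
  baseline <- rep(1 / 8, 8)
  names(baseline) <- sim$transcripts$transcript_id
  ab <- sampleAbundances(sim, baseline, des, foldChange = 3, bcv = 0)
  g <- sim$labels$gene_id[sim$labels$is_true_deu]
  iA <- which(sim$transcripts$gene_id == g & sim$transcripts$isoform == "A")
  iB <- which(sim$transcripts$gene_id == g & sim$transcripts$isoform == "B")
  usageA <- ab[iA, ] / (ab[iA, ] + ab[iB, ])
  expect_equal(unname(usageA[des$group == "1"]), rep(0.75, 3))
  expect_equal(unname(usageA[des$group == "2"]), rep(0.25, 3))
  ## columns sum to one
  expect_true(all(abs(colSums(ab) - 1) < 1e-12))
})

test_that("null mode without noise gives identical columns", {
  sim <- simTranscriptome(nGenes = 4, nTrueDEU = 4, seed = 10)
  des <- sampleDesign(2)
  ab <- sampleAbundances(sim, baselineExpression(sim, seed = 1), des,
                         bcv = 0, nullMode = TRUE)
  expect_true(all(ab == ab[, 1]))
})

test_that("gamma noise has the declared coefficient of variation", {
  sim <- simTranscriptome(nGenes = 50, nTrueDEU = 0, seed = 12)
  des <- sampleDesign(nPerGroup = 5000, depth = 1)  # many replicates
  ab <- sampleAbundances(sim, baselineExpression(sim, seed = 2), des,
                         bcv = 0.2, nullMode = TRUE, seed = 3)
  ## CV across replicates of a well-expressed transcript ~ bcv (the column
  ## renormalisation adds a small common factor)
  cv <- apply(ab[1:20, ], 1, function(x) sd(x) / mean(x))
  expect_true(all(abs(cv - 0.2) < 0.03))
})

test_that("per-sample fragment counts equal the declared library sizes", {
  sim <- simTranscriptome(nGenes = 6, nTrueDEU = 0, seed = 13)
  des <- sampleDesign(2, depth = 1000)
  ab <- sampleAbundances(sim, baselineExpression(sim, seed = 1), des,
                         seed = 2)
  fr <- simulateFragments(sim, ab, des, seed = 3)
  expect_equal(unname(table(fr$sample_id)[des$sample_id]),
               rep(1000L, 4), ignore_attr = TRUE)
  ## fragments lie within their transcripts
  tlen <- sim$transcripts$length[fr$tx]
  expect_true(all(fr$tstart >= 1))
  expect_true(all(fr$tstart + fr$flen - 1L <= tlen))
  expect_true(all(fr$flen >= pmin(150L, tlen)))
})

test_that("transcript intervals project to the documented genomic blocks", {
  ## isoform skipping a middle exon: transcript = (100,200) + (500,600)
  p <- deju:::.projectInterval(c(100L, 500L), c(200L, 600L), 95L, 135L)
  expect_equal(unname(p$blocks), cbind(c(194L, 500L), c(200L, 533L)),
               ignore_attr = TRUE)
  expect_equal(unname(p$junctions), cbind(201L, 499L), ignore_attr = TRUE)
  ## fully inside one exon: a single block, no junction
  p2 <- deju:::.projectInterval(c(100L, 500L), c(200L, 600L), 10L, 60L)
  expect_equal(nrow(p2$blocks), 1L)
  expect_equal(nrow(p2$junctions), 0L)
})

test_that("projection round-trips through the exon chain", {
  ## mapping genomic blocks back to transcript coordinates recovers the
  ## original interval (independent inverse implemented here)
  set.seed(31)
  sim <- simTranscriptome(nGenes = 10, nTrueDEU = 0, seed = 31)
  idx <- deju:::.txIndex(sim)
  for (rep in 1:50) {
    t <- sample(nrow(sim$transcripts), 1)
    lo <- idx$offset[t] + 1L; hi <- idx$offset[t + 1L]
    es <- idx$estart[lo:hi]; ee <- idx$eend[lo:hi]
    tlen <- sum(ee - es + 1L)
    a <- sample(tlen - 1L, 1); b <- sample(a:tlen, 1)
    p <- deju:::.projectInterval(es, ee, a, b)
    ## inverse: genomic position -> transcript coordinate
    cum <- c(0L, cumsum(ee - es + 1L))
    g2t <- function(pos) {
      k <- which(pos >= es & pos <= ee)
      cum[k] + (pos - es[k] + 1L)
    }
    expect_equal(unname(g2t(p$blocks[1, 1])), a)
    expect_equal(unname(g2t(p$blocks[nrow(p$blocks), 2])), b)
    expect_equal(sum(p$blocks[, 2] - p$blocks[, 1] + 1), b - a + 1L)
  }
})

test_that("fragment records report blocks and spanned junctions", {
  sim <- manual_sim(list(A = cbind(c(100, 300, 500), c(200, 400, 600)),
                         B = cbind(c(100, 500), c(200, 600))))
  ## isoform B (transcript length 202): fragment [40, 189]; mate1 covers
  ## transcript 40-114 and bridges the skip junction (201,499), mate2
  ## covers 115-189 inside the second exon
  fr <- manual_frags("S1", tx = 2L, tstart = 40L, flen = 150L)
  rec <- fragmentRecords(fr, sim)
  expect_equal(rec$transcript_id, "G1.B")
  expect_equal(rec$mate1_blocks, "139-200,500-512")
  expect_equal(rec$mate2_blocks, "513-587")
  expect_equal(rec$junctions, "201-499")
  ## non-split fragment inside exon 1 of isoform A
  fr2 <- manual_frags("S1", tx = 1L, tstart = 1L, flen = 90L)
  rec2 <- fragmentRecords(fr2, sim)
  expect_equal(rec2$junctions, "")
  expect_equal(rec2$mate1_blocks, "100-174")
})

test_that("null simulations have balanced junction usage across groups", {
  ## with bcv = 0 and null mode, empirical junction frequencies agree
  ## between groups within 3 standard errors
  sim <- simTranscriptome(nGenes = 20, nTrueDEU = 4, seed = 77)
  des <- sampleDesign(2, depth = 5e4)
  ab <- sampleAbundances(sim, baselineExpression(sim, seed = 1), des,
                         bcv = 0, nullMode = TRUE)
  cm <- simulateCounts(sim, ab, des, modes = "DEJU", seed = 5)$DEJU
  jx <- cm$features$feature_type == "JUNCTION"
  g1 <- cm$samples$group == "1"
  n1 <- rowSums(cm$counts[jx, g1, drop = FALSE])
  n2 <- rowSums(cm$counts[jx, !g1, drop = FALSE])
  t1 <- sum(cm$samples$lib_size[g1]); t2 <- sum(cm$samples$lib_size[!g1])
  p1 <- n1 / t1; p2 <- n2 / t2
  se <- sqrt(p1 * (1 - p1) / t1 + p2 * (1 - p2) / t2)
  ok <- abs(p1 - p2) <= 3 * se + 1e-12
  expect_gt(mean(ok), 0.99)
})
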