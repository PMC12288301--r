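# Counting fixture: gene G1 with parent chain (100,200),(300,400),(500,600),
# isoform A = parent, isoform B skips the middle exon. Reference flattened
# exons are the three parent exons; the skip junction (201,499) is novel.
es_sim <- function() {
  manual_sim(list(A = cbind(c(100, 300, 500), c(200, 400, 600)),
                  B = cbind(c(100, 500), c(200, 600))))
}

test_that("junction-spanning fragments count once, to the junction only", {
  sim <- es_sim()
  ## isoform B fragment bridging the skip junction with mate1
  fr <- manual_frags("S1", tx = 2, tstart = 40, flen = 150)
  cm <- countFeatures(fr, sim, minJunctionReads = 0L)
  expect_equal(sum(cm$counts), 1L)
  jrow <- cm$features$feature_type == "JUNCTION"
  expect_equal(cm$features$start[jrow], 201L)
  expect_equal(cm$features$end[jrow], 499L)
  expect_equal(unname(cm$counts[jrow, 1]), 1L)
  ## exon rows all zero
  expect_true(all(cm$counts[!jrow, ] == 0L))

  ## the same fragment in DEU mode double-counts both flanking exons
  cmd <- countFeatures(fr, sim, mode = "DEU")
  expect_equal(unname(cmd$counts[, 1]), c(1L, 0L, 1L))
  expect_equal(cmd$samples$lib_size, 2L)  # inflated library size
})

test_that("non-split fragments go to the largest-overlap flattened exon", {
  sim <- es_sim()
  ## isoform A fragment fully inside exon 2 (transcript coords 102-202)
  fr <- manual_frags("S1", tx = 1, tstart = 110, flen = 80, readLength = 40)
  cm <- countFeatures(fr, sim, minJunctionReads = 0L)
  hit <- which(cm$counts[, 1] > 0)
  expect_equal(length(hit), 1L)
  expect_equal(cm$features$start[hit], 300L)
  expect_equal(cm$features$feature_type[hit], "EXON")
})

test_that("intron-retention reads in the retained intron are unassigned", {
  sim <- manual_sim(list(A = cbind(c(100, 500), c(200, 600)),
                         B = cbind(100, 600)), pattern = "IR",
                    parent = cbind(c(100, 500), c(200, 600)))
  ## isoform B fragment fully inside the retained intron
  ## (genomic 201-499 = transcript coords 102-400 of B)
  fr <- manual_frags("S1", tx = 2, tstart = 150, flen = 160, readLength = 75)
  cm <- countFeatures(fr, sim, minJunctionReads = 0L)
  expect_equal(sum(cm$counts), 0L)
  expect_equal(cm$samples$unassigned, 1L)
  ## and in DEU mode it hits nothing either
  cmd <- countFeatures(fr, sim, mode = "DEU")
  expect_equal(sum(cmd$counts), 0L)
})

test_that("pooled junction support filter is strictly greater-than", {
  sim <- es_sim()
  ## three junction-bridging fragments spread over samples: support 3 -> drop
  fr3 <- manual_frags(c("S1", "S1", "S2"), tx = c(2, 2, 2),
                      tstart = c(40, 50, 60), flen = c(150, 150, 150))
  cm3 <- countFeatures(fr3, sim, minJunctionReads = 3L)
  expect_false(any(cm3$features$feature_type == "JUNCTION"))
  expect_equal(cm3$samples$unassigned, c(2L, 1L))  # dropped, not re-assigned
  ## support 4 -> kept with its counts
  fr4 <- manual_frags(c("S1", "S1", "S2", "S2"), tx = 2,
                      tstart = c(40, 50, 60, 70), flen = 150)
  cm4 <- countFeatures(fr4, sim, minJunctionReads = 3L)
  jrow <- cm4$features$feature_type == "JUNCTION"
  expect_equal(sum(jrow), 1L)
  expect_equal(unname(rowSums(cm4$counts)[jrow]), 4L)
})

test_that("every fragment contributes at most one DEJU count (100-fragment fixture)", {
  set.seed(101)
  sim <- simTranscriptome(nGenes = 10, nTrueDEU = 4, seed = 101)
  des <- sampleDesign(1, depth = 50)
  ab <- sampleAbundances(sim, baselineExpression(sim), des)
  fr <- simulateFragments(sim, ab, des)
  expect_equal(nrow(fr), 100L)
  cm <- countFeatures(fr, sim, design = des)
  expect_equal(colSums(cm$counts) + cm$samples$unassigned,
               c(50, 50), ignore_attr = TRUE)
  ## legacy mode double-counts junction fragments
  cmd <- countFeatures(fr, sim, design = des, mode = "DEU")
  recs <- fragmentRecords(fr, sim)
  expect_gt(sum(nzchar(recs$junctions)), 0)   # fixture has split fragments
  expect_gt(sum(cmd$counts), sum(cm$counts))
})

test_that("compiled counting matches the pure-R reference classifier", {
  sim <- simTranscriptome(nGenes = 25, nTrueDEU = 4, seed = 202)
  des <- sampleDesign(2, depth = 4000)
  ab <- sampleAbundances(sim, baselineExpression(sim, seed = 1), des,
                         seed = 2)
  fr <- simulateFragments(sim, ab, des, seed = 3)
  cm <- countFeatures(fr, sim, design = des, minJunctionReads = 0L)

  cl <- classifyFragments(fr, sim, mode = "DEJU")
  ## aggregate the per-fragment reference assignments into a matrix
  ref_key <- ifelse(cl$type == "junction",
                    sprintf("%s:J:%d-%d", cl$gene_id, cl$start, cl$end),
                    sprintf("%s:E:%d-%d", cl$gene_id, cl$start, cl$end))
  keep <- cl$type != "unassigned"
  tab <- table(ref_key[keep], cl$sample_id[keep])
  expect_equal(sum(!keep), sum(cm$samples$unassigned))
  common <- rownames(cm$counts)[rowSums(cm$counts) > 0]
  expect_setequal(common, rownames(tab))
  for (s in des$sample_id)
    expect_equal(unname(cm$counts[rownames(tab), s]),
                 as.vector(tab[, s]))

  ## DEU mode: reference per-fragment exon sets reproduce the matrix totals
  cmd <- countFeatures(fr, sim, design = des, mode = "DEU")
  cld <- classifyFragments(fr, sim, mode = "DEU")
  nhits <- vapply(strsplit(cld$features, ";"),
                  function(x) sum(nzchar(x)), 0L)
  expect_equal(unname(colSums(cmd$counts)),
               unname(tapply(nhits, factor(cld$sample_id, des$sample_id),
                             sum)),
               ignore_attr = TRUE)
})

test_that("streamed simulateCounts reproduces countFeatures exactly", {
  sim <- simTranscriptome(nGenes = 15, nTrueDEU = 4, seed = 303)
  des <- sampleDesign(2, depth = 3000)
  ab <- sampleAbundances(sim, baselineExpression(sim, seed = 1), des,
                         seed = 2)
  set.seed(99)
  fr <- simulateFragments(sim, ab, des)
  cm1 <- countFeatures(fr, sim, design = des)
  cm2 <- simulateCounts(sim, ab, des, modes = "DEJU", seed = 99)$DEJU
  expect_identical(cm1$counts, cm2$counts)
  expect_identical(cm1$features, cm2$features)
})

test_that("junctions are assigned to genes by match or unique containment", {
  ann <- toy_annotation()
  ## exact match against the junction database
  obs <- data.frame(chrom = "chr1", intron_start = 201L, intron_end = 299L,
                    strand = "+")
  res <- assignJunctionsToGenes(obs, ann)
  expect_equal(res$gene_id, "G1")
  expect_true(res$annotated)
  ## novel junction inside the gene span only
  obs2 <- data.frame(chrom = "chr1", intron_start = 201L, intron_end = 329L,
                     strand = "+")
  res2 <- assignJunctionsToGenes(obs2, ann)
  expect_equal(res2$gene_id, "G1")
  expect_false(res2$annotated)
  ## junction straddling two overlapping genes is unknown
  ex2 <- rbind(exon_table(T1 = cbind(c(100, 500), c(200, 600))),
               exon_table(T2 = cbind(c(150, 550), c(250, 650)),
                          gene_id = "G2"))
  ann2 <- buildJunctionDatabase(flattenExons(newAnnotation(ex2)))
  obs3 <- data.frame(chrom = "chr1", intron_start = 260L, intron_end = 490L,
                     strand = "+")
  expect_true(is.na(assignJunctionsToGenes(obs3, ann2)$gene_id))
})

test_that("count matrices round-trip as TSV", {
  sim <- simTranscriptome(nGenes = 8, nTrueDEU = 4, seed = 12)
  des <- sampleDesign(2, depth = 2000)
  ab <- sampleAbundances(sim, baselineExpression(sim, seed = 1), des, seed = 2)
  cm <- simulateCounts(sim, ab, des, modes = "DEJU", seed = 3)$DEJU
  path <- tempfile()
  writeCountMatrix(cm, path)
  back <- readCountMatrix(path)
  expect_equal(back$counts, cm$counts, ignore_attr = TRUE)
  expect_equal(back$features$feature_id, cm$features$feature_id)
})

test_that("unknown sample ids are rejected", {
  sim <- es_sim()
  fr <- manual_frags("S9", tx = 1, tstart = 1, flen = 150)
  des <- sampleDesign(1, depth = 10)
  expect_error(countFeatures(fr, sim, design = des), "S9")
})
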