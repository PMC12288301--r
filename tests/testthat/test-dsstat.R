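test_that("per-feature OLS recovers group mean differences", {
  y <- rbind(c(5, 5, 5, 6, 6, 6),
             c(1, 2, 3, 4, 5, 6))
  grp <- factor(rep(c("1", "2"), each = 3))
  fit <- fitFeatureModels(y, grp, ebayes = FALSE)
  expect_equal(fit$beta[1], 1)
  expect_equal(fit$beta[2], 3)
  expect_equal(fit$df, 4L)
  expect_equal(fit$v, 1/3 + 1/3)
  expect_error(fitFeatureModels(y, factor(c(1, 1, 1, 1, 1, 2))),
               "at least 2")
})

test_that("equal residual variances are a shrinkage fixed point", {
  set.seed(81)
  y <- matrix(rnorm(60), 10)
  y <- y - rowMeans(y[, 1:3]) %o% c(1, 1, 1, 0, 0, 0) -
       rowMeans(y[, 4:6]) %o% c(0, 0, 0, 1, 1, 1)
  ## force identical s2 by scaling every feature's residuals
  grp <- factor(rep(c("1", "2"), each = 3))
  f0 <- fitFeatureModels(y, grp, ebayes = FALSE)
  y2 <- y / sqrt(f0$s2)
  fit <- fitFeatureModels(y2, grp, ebayes = TRUE)
  expect_equal(fit$s2post, fit$s2, tolerance = 1e-10)
})

test_that("moment matching recovers the variance prior", {
  set.seed(71)
  d <- 4; d0 <- 10; s02 <- 1; n <- 5000
  sigma2 <- d0 * s02 / rchisq(n, d0)
  s2 <- sigma2 * rchisq(n, d) / d
  pr <- deju:::.estimatePrior(s2, d)
  expect_gt(pr$d0, 6); expect_lt(pr$d0, 16)
  expect_gt(pr$s02, 0.9); expect_lt(pr$s02, 1.1)
})

test_that("variance moderation agrees with the independent implementation", {
  set.seed(82)
  s2 <- rchisq(2000, 5) / 5 * (10 / rchisq(2000, 10))
  d <- 4
  pr <- deju:::.estimatePrior(s2, d)
  sq <- limma::squeezeVar(s2, d)
  expect_equal(pr$d0, sq$df.prior, tolerance = 1e-8)
  expect_equal(pr$s02, sq$var.prior, tolerance = 1e-8)
  expect_equal((pr$d0 * pr$s02 + d * s2) / (pr$d0 + d), sq$var.post,
               tolerance = 1e-10)
})

test_that("usage deltas contrast features against the gene average", {
  ## two features with identical logFC show no usage change
  y <- rbind(c(0, 0, 0, 1, 1, 1),
             c(5, 5, 5, 6, 6, 6)) + 0
  set.seed(83)
  y <- y + matrix(rnorm(12, sd = 0.1), 2)
  grp <- factor(rep(c("1", "2"), each = 3))
  fit <- fitFeatureModels(y, grp, ebayes = FALSE)
  fs <- diffSpliceTest(fit, c("g1", "g1"))
  expect_equal(fs$delta[1], -fs$delta[2])  # exact zero-sum for 2 features
  expect_equal(sum(1 / fit$v * fs$delta), 0, tolerance = 1e-9)

  ## identical betas -> delta 0, p 1
  yy <- rbind(c(0, 0.2, -0.2, 1, 1.2, 0.8),
              c(4, 4.2, 3.8, 5, 5.2, 4.8))
  fit2 <- fitFeatureModels(yy, grp, ebayes = FALSE)
  fs2 <- diffSpliceTest(fit2, c("g1", "g1"))
  expect_equal(fs2$delta, c(0, 0), tolerance = 1e-12)
  expect_equal(fs2$p, c(1, 1))

  ## single-feature genes are excluded and reported untested
  fs3 <- diffSpliceTest(fit2, c("g1", "g2"))
  expect_equal(nrow(fs3), 0L)
  expect_setequal(attr(fs3, "untested"), c("g1", "g2"))
})

test_that("moderated t matches a brute-force OLS oracle", {
  ## 5 genes x 4 features, eBayes off: per-feature lm() plus explicit
  ## weighted-average contrast reproduces t to 1e-10
  set.seed(84)
  nfeat <- 20
  y <- matrix(rnorm(nfeat * 6, sd = 0.5), nfeat) +
    rep(rnorm(5), each = 4)
  gid <- rep(paste0("g", 1:5), each = 4)
  grp <- factor(rep(c("1", "2"), each = 3))
  fit <- fitFeatureModels(y, grp, ebayes = FALSE)
  fs <- diffSpliceTest(fit, gid)

  xdes <- model.matrix(~grp)
  beta <- s2 <- numeric(nfeat)
  for (i in seq_len(nfeat)) {
    lmfit <- lm(y[i, ] ~ grp)
    beta[i] <- coef(lmfit)[2]
    s2[i] <- summary(lmfit)$sigma^2
  }
  v <- 2 / 3
  for (g in unique(gid)) {
    j <- gid == g
    w <- rep(1 / v, sum(j))
    bbar <- sum(w * beta[j]) / sum(w)
    delta <- beta[j] - bbar
    tt <- delta / sqrt(s2[j] * (v - 1 / sum(w)))
    expect_equal(fs$t[fs$gene_id == g], tt, tolerance = 1e-10)
  }
})

test_that("Simes, F and BH follow their closed forms", {
  expect_equal(simesP(c(0.01, 0.04, 0.5)), 0.03)
  expect_equal(simesP(c(1, 1, 1)), 1)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.2), 0.2)
  p <- sort(bhAdjust(runif(50)))
  expect_true(all(diff(p) >= 0))

  ## two-feature gene with t = (2, -2): F = 8 on (1, dfTotal)
  fs <- data.frame(gene_id = c("g1", "g1"), logFC = 0, delta = 0, se = 1,
                   t = c(2, -2), p = c(0.1, 0.1))
  gs <- aggregateGenes(fs, untested = character(0), dfTotal = 10)
  expect_equal(gs$p_F, pf(8, 1, 10, lower.tail = FALSE))
  expect_equal(gs$p_simes, 0.1)
})

test_that("null feature p-values are uniform in the calibrated regime", {
  ## genes share one true variance drawn from the fitted prior; moderated
  ## t is then exactly t-distributed and p-values exactly uniform
  set.seed(72)
  nG <- 2500; J <- 4
  d0 <- 10; s02 <- 1
  sig <- rep(sqrt(d0 * s02 / rchisq(nG, d0)), each = J)
  y <- matrix(rnorm(nG * J * 6), nG * J) * sig
  grp <- factor(rep(c("1", "2"), each = 3))
  fit <- fitFeatureModels(y, grp)
  fs <- diffSpliceTest(fit, rep(sprintf("g%04d", 1:nG), each = J))
  ks <- suppressWarnings(ks.test(fs$p, "punif")$statistic)
  expect_lt(ks, 0.02)
  ## gene-level Simes p-values are valid but conservative under the
  ## negative within-gene dependence of the deltas
  gs <- aggregateGenes(fs)
  expect_lte(mean(gs$fdr_simes <= 0.05), 0.07)
  expect_gte(min(gs$p_simes), 0)
  ## sub-uniformity: the detected fraction at any alpha stays below alpha
  for (a in c(0.01, 0.05, 0.1))
    expect_lte(mean(gs$p_simes <= a), a + 3 * sqrt(a * (1 - a) / nG))
})

test_that("gene aggregation reports untested genes as NA", {
  fs <- data.frame(gene_id = c("g1", "g1"), logFC = 0, delta = 0, se = 1,
                   t = c(1, -1), p = c(0.3, 0.3))
  gs <- aggregateGenes(fs, untested = "g9", dfTotal = 8)
  expect_true(is.na(gs$p_simes[gs$gene_id == "g9"]))
  expect_false(anyNA(gs$p_simes[gs$gene_id == "g1"]))
})

test_that("dejuFit runs end-to-end and its methods are consistent", {
  sim <- simTranscriptome(nGenes = 40, nTrueDEU = 8, seed = 7)
  des <- sampleDesign(3, depth = 4e4)
  ab <- sampleAbundances(sim, baselineExpression(sim), des, seed = 8)
  cm <- simulateCounts(sim, ab, des, modes = "DEJU", seed = 9)$DEJU
  fit <- dejuFit(cm)
  expect_s3_class(fit, "deju_fit")
  expect_true(all(fit$genes$p_simes >= 0 & fit$genes$p_simes <= 1,
                  na.rm = TRUE))
  ## weighted deltas sum to zero within every gene
  zs <- tapply(fit$features$delta / fit$features$se^2 * 0 +
               fit$features$delta, fit$features$gene_id, sum)
  ## weights are equal across features here (same design), so plain sums
  expect_true(all(abs(zs) < 1e-8))
  ## topGenes ranks by ascending p
  tg <- topGenes(fit, 5)
  expect_equal(tg$p_simes, sort(tg$p_simes))
  ## print/summary/coef do not error
  expect_output(print(fit), "deju_fit")
  expect_output(print(summary(fit)), "genes tested")
  expect_equal(nrow(coef(fit)), nrow(fit$features))
})

test_that("opposite deltas flag the isoform switch of an ES gene", {
  ## the skip junction and the skipped exon inclusion junctions must move
  ## in opposite directions for a genuine exon-skipping switch
  sim <- simTranscriptome(nGenes = 30, nTrueDEU = 8, seed = 15)
  des <- sampleDesign(3, depth = 2e5)
  ab <- sampleAbundances(sim, baselineExpression(sim, seed = 1), des,
                         seed = 2)
  cm <- simulateCounts(sim, ab, des, modes = "DEJU", seed = 3)$DEJU
  fit <- dejuFit(cm)
  esg <- sim$labels$gene_id[sim$labels$is_true_deu &
                            sim$labels$pattern == "ES"]
  found <- 0
  for (g in esg) {
    A <- sim$iso_exons[sim$iso_exons$gene_id == g &
                       sim$iso_exons$isoform == "A", ]
    B <- sim$iso_exons[sim$iso_exons$gene_id == g &
                       sim$iso_exons$isoform == "B", ]
    skipj <- setdiff(chain_junctions(as.matrix(B[, c("start", "end")])),
                     chain_junctions(as.matrix(A[, c("start", "end")])))
    incj <- setdiff(chain_junctions(as.matrix(A[, c("start", "end")])),
                    chain_junctions(as.matrix(B[, c("start", "end")])))
    ff <- fit$features
    fid_skip <- sprintf("%s:J:%s", g, skipj)
    fid_inc <- sprintf("%s:J:%s", g, incj)
    if (!fid_skip %in% ff$feature_id || !any(fid_inc %in% ff$feature_id))
      next
    found <- found + 1
    d_skip <- ff$delta[ff$feature_id == fid_skip]
    d_inc <- ff$delta[ff$feature_id %in% fid_inc]
    expect_true(all(sign(d_inc) == -sign(d_skip)))
  }
  expect_gt(found, 0)
})
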