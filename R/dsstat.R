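## Moderated linear-model test of differential exon-junction usage.
##
## Per feature, log-CPM values are regressed on the two-group design by
## ordinary least squares; residual variances are shrunk towards a common
## prior by empirical Bayes (log-variance moment matching on the
## digamma/trigamma scale). The usage statistic contrasts each feature's
## group log-fold-change against the precision-weighted gene average, and
## feature p-values are combined per gene by the Simes rule or an F
## statistic, with Benjamini-Hochberg control across genes.

#' Inverse trigamma function
#'
#' Newton iteration solving \code{trigamma(x) = y} for x > 0.
#'
#' @param y positive numeric vector.
#' @return numeric vector x with \code{trigamma(x) = y}.
#' @keywords internal
trigammaInverse <- function(y) {
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (max(abs(dif) / x) < 1e-10) break
  }
  x
}

## moment-matching estimate of the variance prior (d0, s02) from observed
## residual variances s2 on d degrees of freedom
.estimatePrior <- function(s2, d) {
  z <- log(s2)
  ok <- is.finite(z)
  if (sum(ok) < 2L) return(list(d0 = Inf, s02 = mean(s2)))
  e <- z[ok] - digamma(d / 2) + log(d / 2)
  evar <- stats::var(e) - trigamma(d / 2)
  if (is.na(evar) || evar <= 0)
    return(list(d0 = Inf, s02 = mean(s2)))
  d0 <- 2 * trigammaInverse(evar)
  s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

#' Fit per-feature two-group linear models
#'
#' Ordinary least squares of each feature's log-CPM on the group indicator:
#' the coefficient is the group-2 minus group-1 mean, the residual variance
#' has n - 2 degrees of freedom, and the unscaled coefficient variance is
#' 1/n1 + 1/n2. With \code{ebayes}, residual variances are moderated
#' towards the moment-matched prior, giving posterior variances on
#' d + d0 total degrees of freedom; when the trigamma moment equation has
#' no positive solution the prior is degenerate (d0 infinite) and the
#' common value \code{mean(s2)} is used.
#'
#' @param y numeric matrix of log-CPM values (features x samples).
#' @param group two-level factor, each level with at least 2 samples.
#' @param ebayes moderate variances (default \code{TRUE}).
#' @return list with \code{beta}, \code{s2}, \code{df}, \code{v},
#'   \code{s2post}, \code{dfTotal}, \code{d0}, \code{s02}.
#' @export
fitFeatureModels <- function(y, group, ebayes = TRUE) {
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("group must have exactly two levels")
  i1 <- group == levels(group)[1]
  i2 <- group == levels(group)[2]
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples")
  m1 <- rowMeans(y[, i1, drop = FALSE])
  m2 <- rowMeans(y[, i2, drop = FALSE])
  beta <- m2 - m1
  rss <- rowSums((y[, i1, drop = FALSE] - m1)^2) +
         rowSums((y[, i2, drop = FALSE] - m2)^2)
  d <- n1 + n2 - 2L
  s2 <- rss / d
  v <- 1 / n1 + 1 / n2
  if (ebayes) {
    prior <- .estimatePrior(s2, d)
    if (is.finite(prior$d0)) {
      s2post <- (prior$d0 * prior$s02 + d * s2) / (prior$d0 + d)
      dfTotal <- d + prior$d0
    } else {
      s2post <- rep(prior$s02, length(s2))
      dfTotal <- Inf
    }
  } else {
    prior <- list(d0 = 0, s02 = NA_real_)
    s2post <- s2
    dfTotal <- d
  }
  list(beta = beta, s2 = s2, df = d, v = v, s2post = s2post,
       dfTotal = dfTotal, d0 = prior$d0, s02 = prior$s02)
}

#' Feature-level differential-usage test
#'
#' Within each gene, feature log-fold-changes are contrasted against the
#' precision-weighted gene average (weights 1/v): \code{delta = beta -
#' betabar}, with standard error \code{sqrt(s2post * (v - 1/sum(w)))} and a
#' moderated t-statistic on \code{dfTotal} degrees of freedom. The weighted
#' deltas of a gene sum to zero by construction. Genes with fewer than
#' \code{geneMinFeatures} features are excluded and reported untested.
#'
#' @param fit result of \code{\link{fitFeatureModels}}.
#' @param geneid character vector of gene ids, one per feature.
#' @param geneMinFeatures minimum features per testable gene (default 2).
#' @return data.frame of feature statistics (\code{gene_id}, \code{logFC},
#'   \code{delta}, \code{se}, \code{t}, \code{p}), with untested gene ids
#'   in attribute \code{"untested"} and \code{dfTotal} in attribute
#'   \code{"dfTotal"}.
#' @export
diffSpliceTest <- function(fit, geneid, geneMinFeatures = 2L) {
  geneid <- as.character(geneid)
  J <- table(geneid)[geneid]
  testable <- J >= geneMinFeatures
  untested <- unique(geneid[!testable])
  beta <- fit$beta[testable]
  v <- rep_len(fit$v, length(fit$beta))[testable]
  s2post <- fit$s2post[testable]
  g <- geneid[testable]
  w <- 1 / v
  sw <- rowsum(w, g)[g, 1]
  betabar <- rowsum(w * beta, g)[g, 1] / sw
  delta <- beta - betabar
  se <- sqrt(s2post * (v - 1 / sw))
  t <- delta / se
  p <- 2 * stats::pt(-abs(t), df = fit$dfTotal)
  out <- data.frame(gene_id = g, logFC = beta, delta = delta, se = se,
                    t = t, p = p, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "untested") <- untested
  attr(out, "dfTotal") <- fit$dfTotal
  out
}

#' Simes combination of p-values
#'
#' \code{min_k (J * p_(k) / k)} over the sorted p-values of one gene.
#'
#' @param p numeric vector of p-values.
#' @return the Simes combined p-value.
#' @export
simesP <- function(p) {
  p <- sort(p)
  min(length(p) * p / seq_along(p))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment
#' (\code{stats::p.adjust(method = "BH")} behind a stable name).
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values in input order.
#' @export
bhAdjust <- function(p) stats::p.adjust(p, method = "BH")

#' Gene-level aggregation of feature statistics
#'
#' Combines the feature-level p-values of each gene by the Simes rule and
#' the feature t-statistics by \code{F = sum(t^2) / (J - 1)} referred to an
#' F distribution on (J - 1, dfTotal) degrees of freedom, then adjusts each
#' gene-level p-value column by Benjamini-Hochberg separately. Untested
#' genes are reported with \code{NA}.
#'
#' @param features data.frame from \code{\link{diffSpliceTest}}.
#' @param untested character vector of untested gene ids (default from the
#'   attribute on \code{features}).
#' @param dfTotal denominator degrees of freedom (default from attribute).
#' @return data.frame with \code{gene_id}, \code{n_features},
#'   \code{p_simes}, \code{fdr_simes}, \code{p_F}, \code{fdr_F}.
#' @export
aggregateGenes <- function(features,
                           untested = attr(features, "untested"),
                           dfTotal = attr(features, "dfTotal")) {
  bygene <- split(seq_len(nrow(features)), features$gene_id)
  gene_id <- names(bygene)
  J <- lengths(bygene)
  p_simes <- vapply(bygene, function(i) simesP(features$p[i]), 0)
  p_F <- vapply(bygene, function(i) {
    Fg <- sum(features$t[i]^2) / (length(i) - 1L)
    stats::pf(Fg, length(i) - 1L, dfTotal, lower.tail = FALSE)
  }, 0)
  out <- data.frame(gene_id = gene_id, n_features = as.integer(J),
                    p_simes = p_simes, fdr_simes = bhAdjust(p_simes),
                    p_F = p_F, fdr_F = bhAdjust(p_F),
                    stringsAsFactors = FALSE)
  if (length(untested)) {
    na <- data.frame(gene_id = untested, n_features = NA_integer_,
                     p_simes = NA_real_, fdr_simes = NA_real_,
                     p_F = NA_real_, fdr_F = NA_real_,
                     stringsAsFactors = FALSE)
    out <- rbind(out, na)
  }
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit the differential exon-junction usage model
#'
#' The one-stop fitting function: filters low-expression features, computes
#' TMM normalization factors and log-CPM values, fits the moderated
#' per-feature linear models, tests each feature's usage against its gene
#' average, and aggregates to gene-level Simes and F p-values with BH FDR
#' control.
#'
#' @param x a \code{deju_counts}.
#' @param group two-level factor of sample groups (defaults to the design
#'   stored in \code{x}).
#' @param filter apply \code{\link{filterCounts}} first (default TRUE).
#' @param normalize apply TMM normalization (default TRUE).
#' @param ebayes empirical-Bayes variance moderation (default TRUE).
#' @param geneMinFeatures minimum surviving features for a gene to be
#'   tested (default 2).
#' @param minCount,minTotal,minProp filtering thresholds, see
#'   \code{\link{filterCounts}}.
#' @return An object of class \code{deju_fit}: list with \code{features}
#'   (per-feature statistics), \code{genes} (gene-level results),
#'   \code{prior} (d0, s02), \code{dfTotal}, \code{normFactors},
#'   \code{samples} and \code{mode}.
#' @examples
#' sim <- simTranscriptome(nGenes = 40, nTrueDEU = 8, seed = 7)
#' des <- sampleDesign(3, depth = 4e4)
#' ab <- sampleAbundances(sim, baselineExpression(sim), des, seed = 8)
#' fr <- simulateFragments(sim, ab, des, seed = 9)
#' cm <- countFeatures(fr, sim, design = des)
#' fit <- dejuFit(cm)
#' topGenes(fit, 5)
#' @export
dejuFit <- function(x, group = x$samples$group, filter = TRUE,
                    normalize = TRUE, ebayes = TRUE, geneMinFeatures = 2L,
                    minCount = 10, minTotal = 15, minProp = 0.7) {
  if (!inherits(x, "deju_counts")) stop("x must be a deju_counts object")
  if (is.null(group)) stop("no group factor available")
  group <- as.factor(group)
  if (filter)
    x <- filterCounts(x, group, minCount = minCount, minTotal = minTotal,
                      minProp = minProp)
  nf <- if (normalize) tmmNormFactors(x) else rep(1, ncol(x$counts))
  y <- logCPM(x, nf)
  fit <- fitFeatureModels(y, group, ebayes = ebayes)
  feats <- diffSpliceTest(fit, x$features$gene_id, geneMinFeatures)
  tested <- x$features$gene_id %in% feats$gene_id
  features <- cbind(x$features[tested, c("feature_id", "feature_type"),
                               drop = FALSE], feats)
  rownames(features) <- NULL
  genes <- aggregateGenes(feats)
  structure(list(features = features, genes = genes,
                 untested = attr(feats, "untested"),
                 prior = list(d0 = fit$d0, s02 = fit$s02),
                 dfTotal = fit$dfTotal, normFactors = nf,
                 samples = x$samples, mode = x$mode,
                 group = group),
            class = "deju_fit")
}

#' @export
print.deju_fit <- function(x, ...) {
  tested <- sum(!is.na(x$genes$p_simes))
  cat("deju_fit (", x$mode, " counting): ", nrow(x$features),
      " features in ", tested, " tested genes (",
      length(x$untested), " untested)\n", sep = "")
  cat(sprintf("  variance prior: d0 = %.2f, s0^2 = %.4f; df total = %.2f\n",
              x$prior$d0, x$prior$s02, x$dfTotal))
  cat("  genes at FDR 0.05: Simes ",
      sum(x$genes$fdr_simes <= 0.05, na.rm = TRUE), ", F ",
      sum(x$genes$fdr_F <= 0.05, na.rm = TRUE), "\n", sep = "")
  invisible(x)
}

#' @export
summary.deju_fit <- function(object, alpha = 0.05, ...) {
  g <- object$genes
  out <- list(
    n_features = nrow(object$features),
    n_genes_tested = sum(!is.na(g$p_simes)),
    n_genes_untested = length(object$untested),
    detected_simes = sum(g$fdr_simes <= alpha, na.rm = TRUE),
    detected_F = sum(g$fdr_F <= alpha, na.rm = TRUE),
    prior = object$prior, dfTotal = object$dfTotal, alpha = alpha)
  class(out) <- "summary.deju_fit"
  out
}

#' @export
print.summary.deju_fit <- function(x, ...) {
  cat("Differential exon-junction usage fit\n")
  cat("  features tested:   ", x$n_features, "\n")
  cat("  genes tested:      ", x$n_genes_tested,
      " (untested: ", x$n_genes_untested, ")\n", sep = "")
  cat(sprintf("  variance prior:     d0 = %.2f, s0^2 = %.4f\n",
              x$prior$d0, x$prior$s02))
  cat("  detected at FDR ", x$alpha, ": Simes ", x$detected_simes,
      ", F ", x$detected_F, "\n", sep = "")
  invisible(x)
}

#' @export
coef.deju_fit <- function(object, ...) {
  out <- as.matrix(object$features[, c("logFC", "delta")])
  rownames(out) <- object$features$feature_id
  out
}

#' @export
plot.deju_fit <- function(x, test = c("simes", "F"), ...) {
  test <- match.arg(test)
  p <- if (test == "simes") x$genes$p_simes else x$genes$p_F
  graphics::hist(p[!is.na(p)], breaks = 40, col = "grey80",
                 main = paste("Gene-level", test, "p-values"),
                 xlab = "p-value", ...)
  invisible(x)
}

#' Top-ranked differential-usage genes
#'
#' @param fit a \code{deju_fit}.
#' @param n number of genes to report (default 10).
#' @param test rank by \code{"simes"} (default) or \code{"F"} gene
#'   p-values; ties break by gene id.
#' @return the top rows of the gene-level results table.
#' @export
topGenes <- function(fit, n = 10L, test = c("simes", "F")) {
  test <- match.arg(test)
  g <- fit$genes[!is.na(fit$genes$p_simes), , drop = FALSE]
  p <- if (test == "simes") g$p_simes else g$p_F
  o <- order(p, g$gene_id)
  head(g[o, , drop = FALSE], n)
}

#' Write feature- and gene-level result tables
#'
#' @param fit a \code{deju_fit}.
#' @param featurePath,genePath TSV output paths (either may be NULL).
#' @return invisibly, a list of the written paths.
#' @export
writeResults <- function(fit, featurePath = NULL, genePath = NULL) {
  if (!is.null(featurePath))
    utils::write.table(fit$features, featurePath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(genePath))
    utils::write.table(fit$genes, genePath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(list(features = featurePath, genes = genePath))
}
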