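---
title: "Differential exon-junction usage: models and design"
author: "deju package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential exon-junction usage: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deju)
```

## The problem

Differential exon usage (DEU) analysis asks whether the *relative* usage of
an exon within its gene changes between conditions — a count-level proxy for
differential splicing. The standard approach counts reads on flattened
(merged, disjoint) exon bins and tests each bin against the gene average.
Two well-known weaknesses motivate this package:

* **Double counting.** A read whose alignment is split across an intron
  overlaps both flanking exon bins and, under default exon-level counting,
  increments both. Junction-spanning reads are therefore counted twice,
  library sizes are inflated, and the extra shared counts distort
  dispersion estimation.
* **Blind spots.** Intron retention leaves no trace in exon bins (the
  retained intron is not exonic in the annotation), and an alternative
  splice site that truncates an exon by a few tens of bases barely moves
  the bin count even when isoform usage switches completely.

Differential exon-*junction* usage (DEJU) addresses both by treating
exon–exon junctions as first-class features alongside internal exons, with
the counting rule that **each fragment is assigned to exactly one
feature**:

1. if either mate of a paired-end fragment bridges a junction (at least
   1 bp on each side), the fragment counts toward one junction feature —
   the bridged junction with the longest minimum overhang (ties broken by
   the leftmost intron start);
2. otherwise the fragment counts toward the single flattened exon with the
   largest total overlap across both mates (ties leftmost);
3. fragments overlapping no exon (e.g. reads inside a retained intron that
   is not exonic in the reference) stay unassigned.

Column sums of the resulting matrix equal the number of assigned
fragments, so library sizes track true sequencing depth. The legacy
exon-only counting mode (`mode = "DEU"`), in which a fragment increments
*every* flattened exon either mate overlaps, is retained for contrast; the
package's benchmark quantifies what the unique-assignment rule buys.

Junctions observed in the reads are assigned to genes through a junction
database derived from transcript exon chains (exact intron match), or, for
novel junctions, by requiring both flanking exonic bases to fall inside the
span of exactly one gene — the analogue of novel-junction discovery in
two-pass spliced alignment. Junctions whose support summed over all samples
does not exceed `minJunctionReads` (default 3, strictly-greater rule) are
dropped, and their fragments remain unassigned.

## The statistical model

Let $y_{js}$ be the log2-CPM of feature $j$ in sample $s$,
$y = \log_2\!\big((\text{count} + 0.5) / (\text{lib} \cdot f + 1) \times
10^6\big)$, where $f$ is the TMM normalization factor. For a two-group
design, ordinary least squares per feature gives the group log-fold-change
$\beta_j$, residual variance $s_j^2$ on $d = n_1 + n_2 - 2$ degrees of
freedom, and unscaled coefficient variance $v = 1/n_1 + 1/n_2$.

Residual variances are moderated by empirical Bayes: the prior
$(d_0, s_0^2)$ is estimated by moment matching on the log-variance scale
(digamma/trigamma equations), and the posterior variance is
$\tilde s_j^2 = (d_0 s_0^2 + d s_j^2)/(d_0 + d)$ with total degrees of
freedom $d + d_0$. When the trigamma equation has no positive solution the
prior is degenerate and the common value $\overline{s^2}$ is used.

Usage, rather than expression, is tested by contrasting each feature
against its gene: with weights $w_j = 1/v_j$,

$$\delta_j = \beta_j - \frac{\sum_k w_k \beta_k}{\sum_k w_k}, \qquad
t_j = \frac{\delta_j}{\sqrt{\tilde s_j^2\,(v_j - 1/\textstyle\sum_k w_k)}},$$

referred to a t-distribution on $d + d_0$ degrees of freedom. The weighted
deltas of a gene sum to zero by construction. Gene-level significance
combines features by the Simes rule
$p_{\text{gene}} = \min_k \{J\,p_{(k)}/k\}$ or by
$F = \sum_j t_j^2/(J-1)$ on $(J-1,\ d+d_0)$ degrees of freedom, each
followed by Benjamini–Hochberg adjustment across genes (separately per
test). Genes with fewer than two surviving features cannot have "relative"
usage and are reported untested (`NA`), not as $p = 1$.

### Calibration properties and honest caveats

The standard error of $\delta_j$ treats features within a gene as
independent with a shared variance. Two consequences are deliberate and
documented rather than hidden:

* In the exactly-matching regime (features of a gene sharing one true
  variance drawn from the fitted prior), the feature-level moderated t is
  exactly t-distributed; the test suite verifies near-perfect uniformity of
  null feature p-values (Kolmogorov–Smirnov distance below 0.02 at $10^4$
  features).
* The deltas of a gene are negatively correlated by construction (they sum
  to zero), and in simulated counts features of the same isoform share
  biological noise. Gene-level Simes p-values are therefore *valid but
  conservative* under the null: their distribution is stochastically larger
  than uniform, so the realized false discovery rate sits below the nominal
  level. The test suite asserts sub-uniformity and FDR control rather than
  exact uniformity, which the Simes construction does not promise under
  dependence.
* The $F$ statistic $\sum_j t_j^2/(J-1)$ inherits a scale inflation of
  roughly $J/(J-1)$ from the zero-sum constraint, making the F-based gene
  p-values mildly anti-conservative for small $J$; the Simes column is the
  primary, calibrated summary and is what the benchmark reports.

## The simulator

The synthetic study is generated, not loaded. Defaults are the scaled study
conditions; every one is a function argument.

**Transcriptome** (`simTranscriptome`): genes are laid out without overlap
on synthetic chromosomes; each gene's parent chain draws 4–12 exons of
80–300 bp separated by introns of 200–2000 bp (uniform draws — the
published study derives structures from a real annotation, whose exact
size distributions are not reproducible from the text; uniform ranges are
declared, configurable stand-ins). Each gene carries two isoforms derived
from the parent by one of four patterns: exon skipping (ES), mutually
exclusive exons (MXE), alternative splice site (ASS, inward shift of one
internal boundary by 30–100 bp so that flattened exons are unchanged), and
intron retention (IR). Genuine DEU genes — 124 of 500 at the scaled
default, split equally over the four patterns — are chosen uniformly at
random; the remaining genes keep two structurally distinct isoforms with
stable usage, so the null set is not artificially easy.

The counting reference is the parent chain: flattened exons and the
junction database come from it, while fragments are simulated from the
isoforms. Event-specific junctions are consequently *novel* with respect to
the reference and exercise the containment-based gene assignment, exactly
as novel splice variants do in practice. The retained intron of an IR gene
is not exonic in the reference, which is what makes IR invisible to
exon-only counting.

**Abundances** (`sampleAbundances`): baseline transcript weights follow
Zipf's law (rank $k$ weight $\propto k^{-s}$, $s = 1$) over a random
ranking of all isoforms. In genuine DEU genes, isoform A is multiplied by
the fold-change (3) in group 1 and isoform B in group 2 — a usage switch
from 75/25 to 25/75 at equal baselines. Biological variation multiplies
every transcript-by-sample cell by an independent mean-1 gamma variable
with coefficient of variation `bcv` (0.2), after which columns are
renormalized; noise is per transcript, so isoform usage itself varies
between replicates. Null simulations skip the fold-change step.

**Fragments** (`simulateFragments` / `simulateCounts`): per sample,
fragment counts per transcript are multinomial with the declared library
size (5 million at scale, i.e. one tenth of the 50-million study
condition, preserving per-gene coverage since the gene count is scaled by
the same factor). Fragment length is Normal(250, 40) truncated to
[2 × 75, transcript length]; the start is uniform; mates are the first and
last 75 bases. Fragments carry their exact origin and are projected through
the exon chain to genomic blocks — there is no sequence, no sequencing
error and no alignment step. Consequences worth stating plainly: junction
detection is perfect down to 1 bp overhang, and operating characteristics
for patterns whose real-data difficulty lies in alignment (short-overhang
novel junctions for ASS, intron reads for IR) will be at least as good
as in an alignment-based study. Passing simulation benchmarks here
demonstrates the counting and testing machinery, not robustness to
mapping error, GC bias, or positional effects, none of which are
emulated.

## Numerical and design choices

* Coordinates are 1-based inclusive; junctions are stored as the first and
  last intron base (the splice-junction table dialect of common aligners).
* Book-ended exons merge during flattening (configurable off).
* Expression filtering keeps a feature when its CPM reaches the
  median-library CPM equivalent of `minCount = 10` in at least
  `ceiling(0.7 × smallest group)` samples and its total count is at least
  15. The rule is fixed in-package because the corresponding helper in
  widely used count packages has changed its cutoff formula between
  versions; a fixed rule keeps results reproducible.
* TMM normalization is delegated to `edgeR::calcNormFactors` (trim 30% on
  M, 5% on A, inverse-asymptotic-variance weights, factors scaled to unit
  product); with fewer than 10 features the factors fall back to 1 with a
  warning.
* A fragment whose two mates bridge different junctions is assigned to the
  junction with the longest minimum overhang, ties to the leftmost intron
  start — any deterministic rule preserves the one-count invariant; this
  one favours the best-supported junction.
* Fragments of filtered-out junctions stay unassigned rather than falling
  back to exon bins: re-assignment would silently convert junction evidence
  into exon counts.
* Per-run benchmark seeds derive from the master seed as
  `seed * 1000 + run`, so cells of the design grid share transcriptomes
  and paired comparisons across sample sizes are meaningful.
* Gene ranking ties (identical p-values) break by gene id for
  reproducibility.
* The statistical engine is the linear-model path only; a quasi-likelihood
  negative-binomial engine is out of scope. No precision weights are
  applied to the log-CPM values; moderation of the residual variances
  carries the mean–variance burden at the simulated depths.

## Problem sizes

The package's own benchmarks and tests run at a 1/10 linear scaling of the
full study (500 genes / 124 true DEU genes / 5 million fragments per
sample instead of 5000 / 1000 / 50 million), which preserves reads per
gene. A single scaled run (simulation, both counting modes, fit) takes on
the order of 15 seconds; the acceptance script averages five runs. The
null-calibration check pools twenty scaled null runs for $10^4$ gene-level
p-values.

## Limitations

* Two-group designs only; no covariates or multi-factor contrasts.
* No BAM/SAM ingestion: the quantifier consumes the simulator's fragment
  records (externally produced count tables can enter through
  `newCounts`).
* Strand-specific protocols, multi-mapping reads and overlapping genes are
  not modelled; fragments overlapping multiple genes would be unassigned.
* The five-transcript-per-gene mode adds baseline-only isoforms that spare
  the labelled event; it broadens structural complexity but does not add
  new event types.
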