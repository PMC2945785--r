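---
title: "Methods: gene models, anchored counting and differential-expression testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene models, anchored counting and differential-expression testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`anchorde` computes gene-level differential expression for bulk RNA-seq
from uniquely aligned reads. This vignette documents the statistical
model, the interval and counting conventions, the tunable parameters and
their defaults, what the synthetic-data generator does and does not
emulate, and the numerical and design choices a maintainer should know
about.

## Gene interval models

Spliced transcription makes "the counts for a gene" ambiguous: different
transcripts of one gene cover different exonic bases, and neighbouring
genes can share sequence. `anchorde` resolves this with per-gene interval
sets built from exon annotation (GTF or GFF3):

* **union-intersection** (default): the minimal interval set whose bases
  are covered by *every* annotated transcript of the gene — its
  constitutive bases. Evidence falling here is attributable to the gene
  as a whole rather than to one isoform.
* **union**: every base included in any exon annotation of the gene.

After per-gene construction, any base covered by two or more genes' sets
is removed from *all* of them, so the final sets are pairwise disjoint
and a read can support at most one gene. Genes reduced to zero length are
kept in the gene table (they produce zero counts and fall to the
expression filter downstream), which keeps the gene universe traceable.

A single-transcript gene is treated uniformly: the intersection over one
transcript is the transcript itself, so both models coincide there.
Adjacent intervals are merged, giving each set a canonical sorted
disjoint form that can be compared for equality. Genes whose transcripts
span several chromosomes or strands — which real annotations do contain —
are skipped with a warning rather than aborting the run.

Internally, intervals live in `GenomicRanges` objects and therefore use
the 1-based closed convention native to the Bioconductor stack; BED
output (0-based half-open) is converted at the boundary by
`export_bed()`. We chose this over carrying a 0-based representation
through the package because every neighbouring tool in an R analysis
(rtracklayer, Rsamtools, IRanges set algebra) speaks 1-based closed
coordinates, and a single well-tested conversion at the BED boundary is
easier to keep correct than conversions at every internal interface. The
test suite pins the observable contracts — BED lines, anchor arithmetic,
oracle equality — so the internal convention is not observable.

## Anchored counting

Each alignment is reduced to an anchor before overlap testing. The
default anchor is the **3'-most aligned base**: the highest reference
coordinate of the aligned span for a plus-strand read, the lowest for a
minus-strand read (the biological 3' end of a minus-strand read sits at
the lower coordinate). An alignment is counted for gene *i* exactly when
its anchor base lies inside gene *i*'s interval set; membership is
strand-blind. Because the sets are disjoint this yields at most one
overlap record per alignment, and gene totals are conserved: a planted
read either contributes one count to its gene or, if its anchor fell in
a removed region, none.

The alternative `five_prime_k` policy anchors on the 5'-most *k* aligned
bases (truncated to the span) and counts any-base overlap. A *k*-base
window can in principle straddle two genes' sets; we then assign the gene
containing the most-5' anchored base, a deterministic rule. The stricter
all-bases-overlap variant is not implemented.

Spans are computed from the alignment position plus the
reference-consuming CIGAR operations (M/D/N/=/X), so soft-clipped bases
never shift an anchor. Reads flagged multi-mapped (`NH > 1`) are
dropped; in the absence of such metadata the input is trusted to be
pre-filtered to unique alignments, which is the aligner's knowledge, not
ours.

## Normalization

Sequencing depth differs between samples, so raw counts are not
comparable. The default per-sample factor is the **75th percentile of the
non-zero gene counts** (upper-quartile normalization), which is robust to
the handful of extremely highly expressed genes that dominate total
counts. Alternatives: another quantile, the median of non-zero counts,
or the total count (zeros included). Zeros are excluded before
quantile/median computation but included in totals.

The quantile estimator interpolates linearly between order statistics
(`stats::quantile` type 7, the common convention in statistical
software); a nearest-rank variant is available behind `type = "nearest"`.
Factors are computed on the post-filter (expressed-gene) matrix; computing
them before filtering would change nothing for the default method, since
only non-zero counts enter, but would lower "total" factors.

Genes with no counts in any sample are removed before normalization and
testing; a gene with a single count anywhere is retained.

## The differential-expression model

For gene *i* with counts \(c_{ij}\), outcome \(y_j\) and factors
\(q_j\):

\[
g\!\left(E[f(c_{ij}) \mid y_j]\right)
  = b_{i0} + \eta_i \log(q_j) + \sum_{k=1}^{K} b_{ik}\, s_k(y_j)
\]

with \(g = \log\), \(f = \mathrm{id}\) for the Poisson family and
\(g = \mathrm{id}\), \(f(c) = \log(c + 0.5)\) for the Gaussian family.
A factor outcome with \(K\) groups uses indicator functions
\(s_k\); a continuous outcome uses \(K = 1\) with the identity. The
normalization term enters either as an **offset** (\(\eta_i = 1\) for all
genes) or as an estimated **term** (a per-gene nuisance coefficient,
present under both null and full models).

The gene-level null hypothesis is "no outcome effect". Written with an
intercept, a dummy for every one of the \(K\) groups is not identifiable,
so the package encodes the identifiable contrast: reference-level
dummies, \(K - 1\) test columns, and an asymptotic likelihood-ratio test
on \(\chi^2_{K-1}\). The statistic is
\(D_i = 2(\ell_{\text{full}} - \ell_{\text{null}})\), clamped at zero
against fit tolerance.

Numerical choices:

* Poisson fits use iteratively reweighted least squares
  (`stats::glm.fit`), convergence tolerance `1e-8`, at most 50
  iterations; non-convergence is flagged but the statistic from the best
  iterate is still reported. Likelihood evaluation uses the
  \(0 \log 0 := 0\) convention.
* Gaussian fits are exact least squares via a QR projection, with the
  profile log-likelihood, so \(D_i = n \log(RSS_0 / RSS_1)\). On a
  two-group factor this is a monotone function of the squared pooled
  t statistic, i.e. the familiar t-test in likelihood-ratio clothing.
* The pseudocount in \(f(c) = \log(c + 0.5)\) is configurable; 0.5 keeps
  per-sample zeros finite, which occur even after gene filtering.
* When all \(q_j\) are equal, the offset is absorbed by the intercept and
  results equal an unnormalized fit to within `1e-8`; in term mode a
  constant \(\log q\) column would be collinear with the intercept and is
  dropped with a warning.

## Permutation inference

Asymptotic \(\chi^2\) p-values lean on distributional assumptions. The
permutation route randomly permutes the outcome vector \(B\) times —
factors stay attached to their samples — and recomputes all statistics
for each permutation, one shared permutation per replicate so cross-gene
structure is preserved. P-values pool the null statistics over all genes
and permutations:

\[
p_i = \frac{\#\{D^{0b}_j > D_i\} + 1}{mB + 1}
\]

The inequality is strict (ties do not count as exceeding), the smallest
attainable value is \(1/(mB+1)\), and the computation is a single linear
scan of the merged sorted statistics. Pooling borrows nulls across genes,
which buys resolution at small \(B\) at the price of assuming
exchangeable null statistics across genes; the permutation draws flow
from a recorded seed, so results are reproducible.

## Summaries

Q-values are Benjamini-Hochberg step-up values (an FDR analog of the
p-value) with an optional \(\pi_0\) multiplier; the default \(\pi_0 = 1\)
is the conservative classical adjustment, and no claim is made that the
option reproduces any particular \(\pi_0\) estimator. RPKM is
\(c_{ij} / ((L_i/10^3)(N_j/10^6))\) with \(L_i\) the interval-set length;
the default depth \(N_j\) is the total of reads assigned to any gene for
that sample, which is computable self-contained, with externally supplied
totals (e.g. all uniquely aligned reads) available through
`depth_totals`. Zero-length genes get `NA`. Top-N ranking sorts by
p-value with gene-id tie-breaks and includes every gene tied at the Nth
p-value, so output is deterministic without arbitrary truncation.

## The synthetic-data generator

`simulate_counts()` draws \(c_{ij}\) with mean
\(\mu_{ij} = d_j \lambda_i\) (times a fold change for planted DE genes in
the last group): Poisson when `phi = 0`, Gamma-Poisson with
\(\mathrm{Var} = \mu + \phi\mu^2\) when `phi > 0`. This is the standard
contrast between technical replication (Poisson, lane-to-lane) and
biological replication (overdispersed, individual-to-individual).
Defaults, chosen once as a realistic desk-scale design:

* `m = 2000` genes, `n = 20` samples in two groups of 10 — large enough
  for stable rejection fractions, small enough that the full calibration
  panel runs in seconds;
* depth multipliers \(d_j\) log-uniform on `[0.5, 2]` — a 4-fold spread
  that exercises normalization without dominating it;
* \(\lambda_i\) log-normal, `meanlog = log(100)`, `sdlog = 1.5` — median
  100 counts with a long right tail, echoing the several-orders-of-
  magnitude spread of real gene counts;
* `phi = 0.5` for the overdispersed scenarios, a dispersion at which
  biological variation clearly dominates shot noise at typical depths.

`simulate_alignments()` goes one level deeper and emits SAM: per
gene/sample it draws (or accepts) a read count and places each read so
its 3'-anchor base is uniform over the gene's interval set, with random
strand and per-sample read groups. Round-tripping these reads through
the counter recovers the planted counts exactly, which is the basis of
the conservation tests.

The generator emulates count structure, not sequencing physics: no
sequencing errors or quality strings, no junction reads, no GC or
transcript-length bias, uniform rather than biased coverage within the
interval set. Passing tests therefore demonstrate the correctness of the
interval algebra, counting, normalization and inference machinery, and
the *direction* of calibration effects — not that the pipeline is robust
to every artefact of real libraries.

## The calibration experiment

`null_calibration_experiment()` simulates a global-null matrix (no fold
change), assigns samples to two groups, runs a panel of six strategies —
Poisson LRT, Gaussian LRT and Gaussian-statistic permutation inference,
each with normalization as offset and as term — and reports the fraction
of genes with \(p < \alpha\) next to the expected count
\(\mathrm{round}(\alpha m)\). Under a well-calibrated test the p-values
are uniform. With matched Poisson data the Poisson LRT sits inside the
99% binomial band around \(\alpha\); with Gamma-Poisson data
(`phi = 0.5`) it rejects an order of magnitude too often, because the
Poisson family ties the variance to the mean and interprets biological
variability as signal. The Gaussian and permutation strategies, which
estimate a variance, stay near nominal. The acceptance checks assert the
band membership and this ordering at `m = 2000`, `n = 20`, the vignette's
default design.

## Pipeline and determinism

`run_pipeline()` chains overlap → normalize → statistics → summarize,
writing TSV/BED outputs and a flat key-value manifest that fully
determines the run; `run_stage()` re-runs any stage from the manifest
(e.g. statistics with a different family on cached counts). Per-gene
computations are independent: permutations are drawn up-front from the
seed and gene chunks are distributed to workers, so outputs are
byte-identical for any `threads` value. A thin command-line wrapper with
the same options ships in `inst/scripts/anchorde` (exit codes 0/2/3 for
success, configuration error, stage failure).

## Known limitations

* Junction-spanning reads are not modelled; constitutive-interval
  counting deliberately trades signal for comparability, and reads whose
  anchors fall outside any set are discarded.
* Unpaired reads only; no fragment-level logic for paired ends.
* No transcript-length bias correction and no moderated/empirical-Bayes
  variance sharing; at small sample sizes the per-gene Gaussian variance
  estimate is noisy and the permutation route is preferable.
* The trimmed-mean alternative test statistic is not implemented.
* The quantile of the normalization factor is computed per sample
  independently; full between-sample quantile normalization is out of
  scope.
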