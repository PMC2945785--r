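# anchorde

Gene-level differential expression for bulk RNA-seq from uniquely aligned
reads, built around three ideas:

1. **Constitutive gene models.** For each gene, the minimal interval set
   whose bases are covered by *all* annotated transcripts
   (union-intersection model; a plain union model is also available),
   with bases shared between genes removed from every set. The final
   sets are pairwise disjoint, so a read can support at most one gene.
2. **Anchored counting.** Each alignment is reduced to its 3'-most
   aligned base (or optionally its 5'-most *k* bases); the alignment
   counts for gene *i* exactly when the anchor falls in gene *i*'s
   interval set, producing a gene × sample count matrix
   *c<sub>ij</sub>*.
3. **GLM testing with honest calibration.** After upper-quartile
   normalization (the 75th percentile *q<sub>j</sub>* of each sample's
   non-zero gene counts), each gene is tested with the generalized
   linear model

   *g*(E[*f*(c<sub>ij</sub>) | y<sub>j</sub>]) = b<sub>i0</sub> +
   η<sub>i</sub> log(q<sub>j</sub>) + Σ<sub>k</sub> b<sub>ik</sub>
   s<sub>k</sub>(y<sub>j</sub>)

   with a Poisson (log link) or Gaussian (identity link, log counts)
   family, normalization entering as an offset (η<sub>i</sub> = 1) or as
   an estimated term, and inference by the asymptotic likelihood-ratio
   test D<sub>i</sub> = 2(ℓ<sub>full</sub> − ℓ<sub>null</sub>) on
   χ²<sub>K−1</sub> or by pooled permutation p-values
   p<sub>i</sub> = (#{D⁰<sup>b</sup><sub>j</sub> > D<sub>i</sub>} + 1)/(mB + 1).

The package also ships a synthetic-data generator (Poisson or
Gamma-Poisson replicate variation, planted fold changes, SAM output) and
a **null-calibration experiment**: simulate a global-null matrix, assign
samples to two arbitrary groups, and measure each strategy's type-I
error. Under biological (overdispersed) replication the Poisson model is
badly anti-conservative — it reads biological variability as
differential expression — while variance-estimating strategies
(Gaussian, permutation) stay near nominal. Quantifying that contrast is
the package's central purpose; the defaults reproduce it in seconds.

Intended users: analysts testing group differences in gene-level RNA-seq
counts, and methodologists who want a compact, fully testable
implementation of interval-model counting and calibration experiments.

## Worked example

Simulate a 2,000-gene, 20-sample null experiment with biological
(Gamma-Poisson, φ = 0.5) replicate variation and run the six-strategy
significance panel:

```r
library(anchorde)

cfg <- simulation_config(m = 2000, n = 20, K = 2, phi = 0.5, seed = 20)
report <- null_calibration_experiment(cfg, B = 50)
report
```

```
Null-calibration experiment: 2000 genes
                    strategy   family norm_mode   inference alpha    m observed fraction expected
          poisson_offset_lrt  poisson    offset         lrt  0.01 2000     1367   0.6835       20
          poisson_offset_lrt  poisson    offset         lrt  0.05 2000     1529   0.7645      100
            poisson_term_lrt  poisson      term         lrt  0.01 2000     1366   0.6830       20
            poisson_term_lrt  poisson      term         lrt  0.05 2000     1480   0.7400      100
         gaussian_offset_lrt gaussian    offset         lrt  0.01 2000       31   0.0155       20
         gaussian_offset_lrt gaussian    offset         lrt  0.05 2000      138   0.0690      100
           gaussian_term_lrt gaussian      term         lrt  0.01 2000       45   0.0225       20
           gaussian_term_lrt gaussian      term         lrt  0.05 2000      156   0.0780      100
 gaussian_offset_permutation gaussian    offset permutation  0.01 2000       17   0.0085       20
 gaussian_offset_permutation gaussian    offset permutation  0.05 2000      101   0.0505      100
   gaussian_term_permutation gaussian      term permutation  0.01 2000       19   0.0095       20
   gaussian_term_permutation gaussian      term permutation  0.05 2000      113   0.0565      100
```

Reading the 5% rows: under a true null we expect 100 significant genes
by chance. The Poisson tests call ~1,500 of 2,000 genes "significant" —
the variance-equals-mean assumption is a poor fit to overdispersed
counts — while the Gaussian tests land near 140–160 and the permutation
strategies essentially on the nominal 100. With `phi = 0` (technical,
Poisson replication) the Poisson test is well calibrated; see the
acceptance checks.

The same machinery runs from files end to end:

```r
run_pipeline("genes.gtf", "samples.tsv", "out/",
             gene_model = "union_intersection", family = "gaussian",
             norm_mode = "term", inference = "permutation", B = 100,
             seed = 1)
```

`samples.tsv` has columns `file` (SAM/BAM per sample), `sample`,
`label`. Outputs in `out/`: `intervals.bed`, `gene_table.tsv`,
`counts.tsv`, `overlaps.tsv`, `factors.tsv`, `stats.tsv`,
`pvalues.tsv`, `qvalues.tsv`, `pvalue_histogram.tsv`, `rpkm.tsv`,
`top_genes.tsv`, `top_overlaps.tsv` and a `manifest.txt` that fully
determines the run; `run_stage("statistics", "out/")` re-runs a single
stage from cached inputs. A command-line wrapper with the same options
is installed at `inst/scripts/anchorde`.

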