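# svhotspots

Somatic structural variants (SVs) in cancer whole genomes are not spread
evenly: local rates depend on replication timing, GC content, chromatin and
repeat context, and on top of that background sit genuine recurrently
rearranged loci — candidate drivers — and mechanistically fragile sites.
`svhotspots` is an R package for cohort-scale SV analysis that separates
these layers:

* **SV catalogue** — consensus merging of per-caller BEDPE callsets
  (two-caller rule with a 3 kb copy-number-boundary rescue), footprint/cluster
  grouping, orientation-based classification of simple events (deletion,
  tandem duplication, balanced inversion, balanced/unbalanced translocation)
  and kinase-domain fusion detection.
* **Complex events** — chromothripsis calls (oscillating copy-number runs,
  interleaved rearrangements, multinomial orientation test) and chromoplexy
  calls (breakpoint-graph chains across ≥3 chromosomes of balanced
  translocations), plus permutation-based complex-SV enrichment per 1 Mb bin.
* **Hotspot detection** — negative binomial regression of per-bin breakend
  counts on genome covariates; count- and length-preserving permutation of
  the observed catalogue under the fitted rates; exact piecewise constant
  fitting (PCF) of log10 inter-mutational distances; empirical FDR; fragile
  site triage and candidate-gene annotation.
* **Copy-number states** — whole-genome duplication calls, the six-category
  CNA classification (HD/LOH/OLOSS/NOC/Gain/AMP), normalized SegCN tables for
  GISTIC-style input, purity/ploidy re-estimation and arm-level events.
* **Synthetic cohorts** — a generator producing genomes, covariates,
  NB-driven SV catalogues with injected hotspots, complex-event templates and
  allele-specific copy-number profiles, so the whole pipeline is testable
  without access-controlled patient data.

## The statistics in brief

Per-bin expected breakend counts come from an NB2 regression with log link,
`E[y_j] = exp(x_j' beta)`, fitted over callable 1 Mb bins with z-scored
covariates. Each observed SV is re-placed by sampling a bin with probability
proportional to the fitted expectation `b_j`, preserving its intrachromosomal
length exactly (partner upstream/downstream with equal probability) and
redrawing junctions that land in uncallable regions. PCF segments the log10
inter-mutational distances of sorted breakends; for segment *i* with *a_i*
breakends spanning *s_i* bp,

```
d_obs_i = a_i / s_i
d_exp_i = (sum_j b_j) / (n * s_bin)        over the n overlapping bins
beta_i  = d_obs_i / d_exp_i
```

and the empirical FDR at level `v` is the mean number of permuted-catalogue
segments with `beta >= v` divided by the number of observed segments with
`beta >= v`, capped at 1, with zeros replaced by the smallest non-zero value.
A tumour is WGD when `2.9 - 2H < psi_ave`, where `psi_ave` is the
length-weighted mean total copy number and `H` the genome fraction with minor
allele copy number 0.

## Worked example

The shipped demo config generates a synthetic cohort (6 chromosomes x 50 Mb,
60 tumours, ~2,300 SVs) with two 1 Mb bins injected at 15x the background
rate, then runs the full hotspot pipeline with gamma = 10, kmin = 10 and 50
permutation replicates:

```r
library(svhotspots)
cfg <- run_config(system.file("extdata", "demo_config.json",
                              package = "svhotspots"))
cfg$out_dir <- tempfile()
res <- run_pipeline(cfg)
res$hotspots[, c("chrom", "start", "end", "beta", "fdr", "n_samples")]
#>   chrom    start      end      beta         fdr n_samples
#> 1  chr2 49069580 50000000  9.996112 0.006666667        33
#> 2  chr4  9015824  9991138 11.074578 0.006666667        40
```

The two injected bins (chr2 49-50 Mb and chr4 9-10 Mb, written to
`truth_hotspots.tsv` in the output directory) are both recovered at
FDR ≈ 0.007 with no false positives: `beta` is the observed/expected breakend
density ratio of the merged PCF segment and `n_samples` the number of tumours
contributing breakends. Full-scale FDR calibration and recovery behaviour is
exercised by `tests/testthat/test-acceptance.R` (criteria 9 and 10).

The same run from the command line:

```sh
Rscript inst/exec/svhotspots run --config inst/extdata/demo_config.json \
    --out demo_out --seed 1
```

## Orientation convention

BEDPE strands are interpreted with breakends ordered (bnd1 <= bnd2): `+`
means the retained fragment extends toward lower coordinates. Hence (+,-) is
deletion-like, (-,+) duplication-like, (+,+) head-to-head inversion and
(-,-) tail-to-tail inversion. Callers differ in strand semantics; convert on
import if yours differs.
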