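---
title: "Models and methods in svhotspots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in svhotspots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it implements:
the models and their assumptions, the tunable parameters and their defaults,
what the synthetic-data generator does and does not emulate, and the design
choices made where the methodology left room. It states no empirical result
that the test suite does not itself compute.

## 1. Background model for structural variant occurrence

Somatic SV breakend counts per non-overlapping genome bin (default
`s_bin = 1e6` bp; `build_bins()`) are modelled by negative binomial (NB2)
regression with log link:

$$ y_j \sim \mathrm{NB}(\mu_j, \alpha), \qquad
   \log \mu_j = \beta_0 + x_j^\top \beta, \qquad
   \mathrm{Var}(y_j) = \mu_j + \alpha \mu_j^2 . $$

Covariates (replication timing, GC, repeat/segdup/fragile-site coverage,
chromatin marks, expression class, mean total copy number — any set the user
supplies via `bin_covariates()`) are z-scored over callable bins with the
$n-1$ denominator (`normalize_covariates()`); zero-variance columns are
dropped with a warning, and rank-deficient designs lose aliased columns
with a warning. Fitting is by maximum likelihood (`MASS::glm.nb`); when the
size estimate diverges (no overdispersion) the model falls back to the
Poisson limit and reports `dispersion = 0`. Counts are *breakends* (each
junction contributes two); whether the original analysis counted breakends or
events per bin is not derivable from its description, and the choice only
rescales the intercept.

**Assumptions.** Bin counts are conditionally independent given covariates
(no spatial autocorrelation term), cohort-pooled (no per-sample random
effects), and the covariate effects are log-linear. Per simple-SV class
(deletions, tandem duplications, inversions, translocations, unclassified),
models are fitted independently.

## 2. Null catalogues by length-preserving permutation

`simulate_catalog()` re-places each observed SV: the first breakend samples a
bin with probability proportional to the fitted expectation $b_j$ and a
uniform position within the bin (the bin draw is specified by the method; the
within-bin law is not, and uniform is the natural non-informative choice).
Intrachromosomal partners sit at exactly the observed distance, upstream or
downstream by a fair coin; interchromosomal partners redraw a bin
proportional to $b_j$ excluding the first chromosome. Junctions with a
breakend off-chromosome, in the mask or in an uncallable bin are redrawn
*whole* (bin draw included) to avoid edge bias. Replicate $r$ of
`run_replicates()` derives its seed deterministically from `(seed, r)`, so
replicates are reproducible and order-independent. Counts per class and the
intrachromosomal length multiset are conserved exactly, by construction.

## 3. Hotspots: PCF on inter-mutational distances and empirical FDR

Breakends are sorted per chromosome; the series
$y_i = \log_{10}\max(\mathrm{gap}_i, 1)$ (1 bp floor for coincident
breakends) is segmented by **exact** piecewise constant fitting: minimize
within-segment sum of squares plus $\gamma$ per segment, each segment holding
at least $k_{\min}$ points, via an $O(n^2)$ dynamic program in C++. Ties are
broken toward fewer segments, then lexicographically earliest boundaries, so
results are platform-stable and an exhaustive-enumeration oracle can verify
both cost and boundaries (acceptance criterion 1).

For a segment with $a_i$ breakends spanning $s_i$ bp overlapping $n$ bins:
$d^{obs}_i = a_i/s_i$, $d^{exp}_i = \sum_j b_j / (n\, s_{bin})$,
$\beta_i = d^{obs}_i / d^{exp}_i$. The segment span is first-to-last breakend
($s_i$ is otherwise undefined by the method description); partial terminal
bins keep their true width in the overlap count while $s_{bin}$ stays
nominal. The empirical FDR at level $v$ is the mean number of
permuted-catalogue segments with $\beta \ge v$ divided by the observed count
with $\beta \ge v$, capped at 1; zero FDRs become the lowest non-zero FDR
value observed. The FDR is a curve over $\beta$ values, and we evaluate that
minimum over the pooled candidate values (observed and simulated): restricted
to observed-segment values only, the replacement collapses to a coarse
mid-range FDR whenever the observed $\beta$ distribution has a gap between
true hotspots and the null bulk — exactly the situation hotspot detection
hopes for — whereas on the pooled grid it scales as roughly
$1/(R \cdot \#\{\mathrm{obs} \ge \max \beta^{null}\})$ with the replicate
count $R$. With few segments or few replicates the floor is still coarse,
which is why the demo configuration uses 6×50 Mb chromosomes and 50
replicates rather than a toy genome.

Parameter search (`select_parameters()`) scans $\gamma \in [1,20]$,
$k_{\min} \in [2,20]$ and keeps the pair maximizing the number of FDR <
threshold segments; the original "maximize hotspots while minimizing FDR"
trade-off is not a well-defined objective, so we use the lexicographic rule
(count, then median FDR, then smaller $\gamma$, then smaller $k_{\min}$) and
default to $\gamma = 10$, $k_{\min} = 10$, with the documented per-context
overrides ($k_{\min} = 2$ translocations, $k_{\min} = 4$ MSI unclassified).

Filtering (`filter_and_collapse()`): hotspots whose contributing SVs never
have a breakend within 3 kb of a copy-number segment boundary in their own
sample are treated as potential artefacts and dropped (the 3 kb distance
reuses the consensus-merge rescue radius; "supported by CNAs" is not further
specified); overlapping survivors merge (union span, min FDR, max $\beta$).
Candidate genes are supplied drivers or the sole expressed gene in the
region, with focal counts restricted to SVs < 3 Mb. Fragile-site triage
(`classify_fragile()`) needs at least three of six criteria — late
replication (mean timing ≤ 0), < 5 genes/Mb, an overlapping gene > 300 kb, a
> 5-fold in-gene vs 1 Mb-flank breakpoint density ratio, and two known-site
lists — and is vetoed by any contained driver gene. Missing annotations
count criteria as unmet (conservative).

## 4. Complex events

Clusters are connected components of rearrangements whose breakends co-locate
within `d_cl = 1 Mb`; footprints are breakend runs with gaps ≤ `d_fp = 10 kb`.
The likelihood-based grouping of the original tooling is not reproducible
from its description; these distance thresholds are a documented
approximation (1 Mb matches the chromoplexy chain-edge rule), and exact
cluster membership may differ from the original.

**Chromothripsis** (all three required): a contiguous run of ≥ 4 copy-number
segments oscillating between ≤ 2 states, or ≥ 5 between ≤ 3 (adjacent values
must differ; segments considered are those between the cluster's outermost
breakends per chromosome — footprint-bounded, configurable); ≥ 6 interleaved
(crossing, not nested) intrachromosomal rearrangements; and no evidence
(BH FDR > 0.2 across candidate clusters) that junction orientations deviate
from the equal-probability multinomial. The multinomial test is exact
(enumeration, outcomes no more probable than observed) for totals ≤ 60,
chi-square above; the BH step implements the unspecified "FDR".

**Chromoplexy** (all three): a breakpoint-graph chain (junction edges plus
≤ 1 Mb proximity edges between different rearrangements) touching ≥ 3
chromosomes; ≥ 50% of footprints balanced-translocation-like (≥ 2 breakends,
all from interchromosomal junctions, both orientations present within the
10 kb deletion-bridge tolerance); and 3–30 rearrangements.

**Complex enrichment**: per bin, the count of tumours with overlapping
complex footprints versus its mean over permutations that re-place each
footprint uniformly on the genome (equal length, redrawn when crossing a
chromosome end), with the same empirical FDR machinery. The default
permutation count for real analyses is large (the method used 100,000); tests
use hundreds to thousands, which is sufficient for the calibration checks
performed.

## 5. Copy-number layer

WGD: $\psi_{ave} = \sum L_i (C_{Maj}+C_{Min}) / \sum L_i$ over the
largest-cell-fraction states; WGD iff $2.9 - 2H < \psi_{ave}$ strictly, $H$
the fraction with minor allele 0 (the boundary case is non-WGD). The
six-category classification uses WGD-dependent thresholds with precedence
HD > LOH > NOC > Gain > AMP > OLOSS; HD is defined as total copy 0 and OLOSS
(WGD-only) as minor ≥ 1, total ≤ 4, not 2+2 — the source gives these
categories without numeric rules in its text, so both are documented
assumptions, flagged here. Arm-level events sum per-category segment lengths
against 50% of the arm (whether a single spanning segment was required is
ambiguous; summation is our reading). SegCN is total copy recentred on
assumed ploidy (2 or 4) and clipped to $[-2, 2]$, male X handled separately.
The pass/fail QC logic and the $\rho_{new} = \rho\,\mathrm{CCF}_{top}$,
$\psi_{new} = (\rho\psi + 2(\rho_{new}-\rho))/\rho_{new}$ update operate on
externally supplied cluster/purity summaries; re-running the upstream callers
is out of scope. Note $\psi = 2$ is a fixed point of the update for any
$\rho$, CCF — a useful invariant test.

## 6. Synthetic cohorts: the stated world

`synth_config()` defaults describe the world the tests assume: a 3,000-Mb
genome (10 × 300 Mb; 3,000 one-Mb bins), four covariates (two Gaussian, two
Bernoulli) with true effects in $[-0.5, 0.8]$, NB dispersion 1.0, hotspot
injections at 15×, log-normal SV lengths (median 60 kb, sdlog 1.2), a 40/30/
20/10 deletion/duplication/inversion/translocation mix, WGD fraction 0.45 and
purity uniform on (0.3, 0.9). Each chromosome's first megabase is masked as a
telomere stand-in and the centromere sits at the midpoint. Hotspot bins are
injected into bins whose covariate-driven rate lies in the middle 50% of
callable bins: the multiplier then measures the designed 15× excess at a
typical background rate. Injecting uniformly would compound the effect size
with the background-rate lottery — 15× a bin in the low tail of the
covariate lift yields a handful of breakends that no segmentation method can
distinguish from noise at desk scale, which would contradict the generator's
stated purpose of making recovery challenging but feasible. Per-tumour per-bin
counts are NB with the configured dispersion, so cohort totals over $T$
tumours have dispersion $\approx \alpha/T$ — nearly Poisson, matching the
permutation null; this is why FDR calibration (acceptance criterion 9) is a
fair test. What the generator does **not** emulate: microhomology or
breakpoint-sequence realism, per-sample correlation between SV burden and
copy-number state, driver selection, signature structure, or subclonal CNA
mixtures beyond a two-state model. A green test therefore establishes the
statistical machinery, not biological realism.

## 7. Numerical and degenerate-input choices

* Coordinates: 0-based half-open internally; 1-based inclusive segment TSVs
  converted on read/write.
* PCF tie-breaks as above; cost comparisons use a relative 1e-9 tolerance.
* IMD pseudocount: 1 bp for coincident breakends.
* Series shorter than $k_{\min}$: single segment with a warning.
* Multinomial test outcome comparison uses a 1e-9 relative log-probability
  tolerance; all-zero counts give p = 1.
* `dnbinom` at size ≥ 1e9 carries ~1e-7 float noise; the Poisson limit is
  therefore implemented as an exact branch at dispersion 0.
* Bin callability: > 50% mask overlap (configurable); simulated breakends are
  additionally rejected against the interval mask itself.
* Consensus merge representative coordinates are per-component medians;
  output order is sorted, making the merge independent of callset order.
* CLI exit codes: 0 ok, 1 validation, 2 runtime. Subcommands `run`, `synth`,
  `bins`, `cna`, `classify`; the remaining pipeline stages are reachable via
  `run` and the R API rather than as stand-alone wrappers.

## 8. Known limitations

* Cluster membership approximates the original likelihood-based grouping.
* The balanced-translocation footprint rule is geometric (orientation pairing
  within tolerance) and does not inspect copy-number steps at the footprint.
* The orientation multinomial's chi-square fallback (totals > 60) is
  asymptotic.
* `run` logs carry timestamps; determinism is asserted on the TSV/model
  outputs, not the log.
* No liftover, no reference-sequence handling, no read-level evidence.
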