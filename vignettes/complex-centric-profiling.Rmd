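---
title: "Complex-centric co-elution analysis: models and methods"
author: "coelute package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complex-centric co-elution analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coelute)
```

## The problem

Co-fractionation mass spectrometry separates a native proteome extract by
size-exclusion chromatography (SEC) and quantifies the proteins of each
fraction by DIA/SWATH mass spectrometry. Proteins that are part of the
same physical assembly co-elute: their quantitative profiles across the
fraction axis peak together. `coelute` implements the *complex-centric*
analysis of such data: rather than clustering all profiles de novo, it
*queries* the data with complex hypotheses derived from prior interaction
knowledge (curated complex databases, AP-MS or functional-association
networks), detects co-elution features for each query, and controls the
error of the reported set with a target-decoy model.

The package covers the full path from the long-format peptide table
produced by peptide-centric DIA analysis to collapsed, FDR-controlled
complex signals, protein-centric elution features, and assembled-state
mass accounting.

## Data model

Elution profiles live in a dense `sec_traces` matrix (analytes × ordered
fractions, missing observations as explicit zeros). SEC axes are short
(81 fractions in the datasets this design targets), so dense storage is
the right trade-off. Peptide-level traces carry their parent protein id
and the upstream search's decoy flag; protein-level traces are derived
from them. Import sums precursor rows to peptide level, removes
non-proteotypic rows (a protein id containing `;` or `/` names a peptide
shared between proteins), and is order-independent.

## SEC-informed filtering and protein-level FDR

Two filters exploit the fractionation structure before any protein is
quantified:

* **Consecutive-stretch filter** (`filter_consecutive_stretches`,
  default `min_len = 3`): elution peaks span several fractions; runs of
  non-zero signal shorter than 3 consecutive fractions are almost always
  false transfers and are zeroed. The operation is idempotent.
* **Sibling peptide correlation** (`filter_by_sibling_correlation`):
  each peptide's trace is correlated with its sibling peptides of the
  same protein; the average (spc) scores quantification coherence.
  Thresholds are scanned over the observed spc values and the
  protein-level FDR at each threshold is estimated by decoy counting,
  `FDR(t) = FFT × D(t)/T(t)`, where D and T count decoy and target
  proteins retaining at least one peptide at or above t. The smallest
  threshold achieving the target FDR (default 1%) is chosen.

The **FFT** (fraction of false targets) rescales the decoy count for
target proteins that are genuinely absent from the sample. It is an
upstream, experiment-specific estimate and therefore a plain parameter
here (default 1, the conservative choice). Raw D/T ratios are made
monotone by a cumulative minimum from high to low threshold so that "the
smallest passing threshold" is well defined. Zero-variance traces
contribute correlation 0 rather than NaN; single-peptide proteins pass
through this filter unscored but cannot rescue a protein's FDR count.

Protein traces are then inferred by **top-N summation** (default top 2
peptides by total intensity, ties broken by peptide id so the result is
independent of input order). The peptide selection is recorded so a
replicate can be quantified from the same peptides. Proteins with fewer
than `top_n` peptides are dropped unless `keep_less = TRUE`.

## Molecular-weight calibration

SEC columns separate log-linearly over their working range:
`ln(MW) = intercept + slope × fraction` with `slope < 0` (larger
assemblies elute earlier). `fit_calibration` is an OLS fit of ln(kDa) on
the apex fractions of reference standards; a non-negative slope is
rejected as non-physical. Natural logs are used internally; all reported
masses are kDa. Apparent MW per fraction is evaluated at integer
fraction centers; fractions outside the standards' span extrapolate on
the same line (apexes of very large assemblies routinely do). The
expected apex of a complex under 1:1 stoichiometry is the calibrated
fraction of its summed subunit mass (`expected_complex_fraction`).

## Queries and decoys

Complex hypotheses come from two sources. A **complex table** is
expanded into variants (alternative-subunit cells by Cartesian product),
homo-oligomers are removed, and duplicate subunit sets are merged. A
**network** yields one candidate per node — the node plus all neighbors
within `max_distance` hops (default 1) — after which candidates fully
contained in another candidate are removed (`redundancy_cutoff = 0`,
the strictest containment reading; other values are not implemented).

**Decoy queries** are size-matched 1:1 to targets, drawn uniformly from
the network's nodes under the constraint that all pairwise path lengths
exceed `min_distance` (2 for curated complex/AP-MS networks, 1 for dense
functional-association networks whose distance-2 neighborhoods are
already exhausted). Each member is redrawn up to `n_tries = 3` times,
then the whole decoy restarts; after bounded restarts the constraint is
relaxed with a warning and a `relaxed` flag so the 1:1 pairing is never
silently broken. Queries are intersected with the observed proteins
identically for targets and decoys, preserving the null.

## Co-elution feature detection

`find_features` implements the sliding-window detector:

1. **Zero perturbation**: zeros are replaced by uniform draws on
   `[0, q]`, q the 5% quantile of non-zero intensities. Identical zero
   stretches would otherwise correlate perfectly. Perturbation precedes
   correlation; correlations are computed on perturbed *raw* traces,
   while apexes and boundaries use the smoothed traces — smoothing
   inflates correlation, so the two concerns are kept separate.
2. **Smoothing**: centered moving average (default length 9), shrinking
   symmetrically at the edges.
3. **Window scan**: within each window of `window_size` fractions
   (default 8), analytes with any pre-perturbation signal in the window
   are pairwise Pearson-correlated; pairs at `corr ≥ corr_cutoff`
   (default 0.95) are linked and connected components of size ≥ 2 are
   window-local groups. Components (not cliques) are used: transitive
   chaining is exactly what downstream apex-network merging expresses,
   and components are deterministic and cheap. Analytes that are
   all-zero in a window before perturbation can never be "detected"
   through perturbation noise.
4. **Group apex**: the argmax of the group's summed smoothed trace
   within the window, then hill-climbed to the nearest local maximum of
   the full-axis group sum. The hill-climb matters: a window that covers
   only a peak's flank has its within-window argmax at the window edge,
   which would displace apexes by several fractions; climbing to the
   local maximum makes the apex a property of the peak rather than of
   the window grid. Ties break toward the lower fraction.
5. **Apex clustering**: groups are clustered on apex (complete linkage,
   cut at `rt_height = 3` fractions). Within a cluster, `apex_network`
   merges all groups connected in the union correlation graph (shared
   member or cross-window edge); `apex_only` merges only groups with the
   identical apex.
6. **Boundaries**: nearest local minima of the merged group's summed
   smoothed trace around the consensus apex, with a floor at 5% of apex
   height to stop runaway plateaus and a minimum width of 2 fractions.
7. **Reporting**: mean within-boundary pairwise correlation
   (`peak_corr`), per-subunit raw areas inside the boundaries, apparent
   MW at the apex when a calibration is given.

**Completeness** is reported as detected subunits over the query
subunits *observed in the matrix* (the full query size travels as
`n_query`). This keeps detection invariant to padding a query with
unobservable proteins and treats targets and decoys identically; the
trade-off is that a query observed only partially can reach completeness
1 from a partial signal.

Features eluting below `min_monomer_distance_factor` (default 2) times
the largest detected monomer mass are removed (`filter_features`) — the
two-fold rule that separates assembled signals from monomer elution.

## Target-decoy statistics

The best (most complete) feature per query is scored by
`score = max(0, peak_corr) × completeness`. The statistic competition is
score-agnostic, so the calibration of the error estimate, not the score
formula, is the contract. Queries with no detected feature enter the
competition with score 0: every decoy query is a null trial, and
dropping featureless decoys would shrink the p-value denominator.

P-values use the empirical decoy distribution with add-one smoothing,
`p(s) = (1 + #{decoy ≥ s}) / (1 + D)`, so p is never 0. The fraction of
true nulls is the Storey estimate at a fixed `lambda = 0.5`,
`pi0 = min(1, #{p > λ} / (m(1 − λ)))`, and q-values follow the Storey
step-up. `decoy_fdr` gives the FFT-scaled decoy-counting FDR at any
score threshold. `grid_search` scans correlation cutoffs, window sizes,
smoothing lengths, and rt heights, and selects the combination with the
most detections among those whose decoy-estimated FDR stays at or below
the cutoff (ties: fewer decoys, then grid order).

## Postprocessing

* **Variants** (`secondary_variant_features`): for queries whose best
  feature is confident (q ≤ 0.05), additional features with peak
  correlation ≥ 0.5 are reported as candidate complex variants; they
  carry no FDR of their own — the decoy model is defined per query, not
  per secondary signal.
* **Collapsing** (`collapse_features`): features from overlapping
  queries describing one physical signal are merged with the distance
  `(1 − Jaccard) + |Δapex|/rt_height`, gated to infinity when apexes are
  more than `rt_height` apart or compositions are disjoint
  (fully disjoint sets never merge, whatever their apexes); single
  linkage cut at 1.25. Under this metric identical compositions merge
  anywhere within the apex gate while distinct compositions need
  substantial overlap. The collapsed signal takes the subunit union and
  the area-weighted mean apex.
* **Stoichiometry** (`estimate_stoichiometry`): within-boundary subunit
  areas normalized by the smallest, integer scalings k = 1..10 scanned
  for minimal rounding error; larger complexes fall back to raw ratios.
* **Assembly state** (`assembly_state_report`): a protein peak is
  assembled when its apparent/monomer MW ratio is ≥ 2. Peak areas pool
  into assembled vs monomeric mass; intensity outside any detected peak
  is reported as *unassigned* rather than silently folded into the
  monomer pool, and both denominators (with and without peak-less
  proteins) are accessible.
* **Deconvolution** (`gaussian_deconvolve`): a sum of Gaussians is
  least-squares fitted (Levenberg–Marquardt) to a trace segment;
  initialization from the global apex and the largest residual; the
  mixing fraction of component i is its integrated-area share
  `A_i σ_i / Σ A_j σ_j`.

## The synthetic-data generator

`simulate_dataset` emulates the *structure* of filtered peptide traces
from an SEC-SWATH experiment: 81 fractions; complexes (default 50, sizes
2–8) eluting as Gaussian peaks (sd 1.5 fractions) at the fraction given
by their summed subunit mass under a log-linear calibration spanning
roughly 5 MDa to 10 kDa; log-normal monomer masses (median 60 kDa);
Poisson(6) peptides per protein scaled by log-normal flyability;
multiplicative log-normal noise (cv 0.15); threshold dropout (1000
intensity units, cutting peak tails about three peak-sds out); half the
complex subunits with an extra monomer peak; 30% monomer-only null
proteins; moonlighting (10%) and sub-complex (10%) rates; decoy proteins
(20%) whose peptides are mutually uncorrelated noise peaks, standing in
for the upstream search's decoys. The network contains all true
co-complex edges plus 20% random extras; calibration standards are
noiseless. These values were fixed once as a realistic desk-scale
emulation; they are surfaced in `simulation_params` but are not tuning
knobs for the tests.

What the generator does *not* emulate: fragment-level interference,
retention-time drift, batch effects between fractions, heavy-tailed
contaminant intensities, or shared (non-proteotypic) peptides. Passing
tests on this generator therefore demonstrate the correctness and
calibration of the algorithms under idealized DIA-like noise, not
end-to-end performance on real instrument data.

`simulate_null_queries` draws protein sets with no shared complex
membership — false by construction — which makes the empirical false
discovery proportion measurable.

## Problem sizes and runtime choices

The test-suite and acceptance computations use the generator defaults
(50 complexes, ≈350 proteins, ≈2,600 peptides, 81 fractions) with 10
seeds for the error-control and sensitivity checks, 100 randomized
instances for the window-group oracle equivalence, and 20 seeds for the
deconvolution recovery; these sizes give stable estimates while keeping
a full run in tens of seconds on one CPU.

## Known limitations

* The FDR model applies to the *query* level; collapsed signals and
  secondary variant features inherit no error estimate.
* The monomer-distance filter uses the largest *detected* monomer; when
  a large subunit is entirely undetected a low-MW feature can survive.
* Completeness relative to observed subunits can overstate coverage of
  sparsely observed queries (the `n_query` column exposes the full
  size).
* The collapsing metric is a declared design choice; compositions
  sharing less than ~75% of subunits at one apex stay separate, which
  may over-split families of closely related complexes.
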