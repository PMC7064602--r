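---
title: "Group-specific local FDR for proteogenomic immunopeptidomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-specific local FDR for proteogenomic immunopeptidomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peplfdr)
```

## The problem

HLA class I immunopeptidomics searches tandem-MS spectra against a
canonical proteome. When the search space is extended with putative
non-canonical sequences — three-frame translations of expressed
non-coding transcripts (lncRNAs, pseudogenes, transposable elements) —
two things happen at once: the database grows enormously, and almost all
of the added sequence has no chance of generating a true match. A single
false-discovery-rate threshold applied to the pooled result list then
floods the small, interesting non-canonical fraction with false
positives, because the prior odds of a non-canonical peptide-spectrum
match (PSM) being correct are far lower than those of a
proteome-derived PSM.

`peplfdr` addresses this with three composable ideas:

1. a **charge-stratified 3D histogram** local-FDR estimator over the
   Comet scores (XCorr, deltaCn, spScore), which uses the full
   three-dimensional structure of the score space instead of a single
   projection;
2. **group-specific prior odds**: the score densities are shared across
   groups, but the ratio of true to wrong PSMs is estimated separately
   for proteome-derived and non-canonical PSMs and plugged into the
   local FDR of each PSM;
3. **two-engine intersection**: only PSMs for which a second engine
   reports the identical match (same spectrum, same modified peptide,
   same charge) are retained.

## The model

PSMs are split into charge strata (Z = 1, which occurs for HLA class I
peptides; Z = 2; Z ≥ 3). Within a stratum the score space
$x = (XCorr,\ deltaCn,\ spScore)$ is partitioned into 40 equal-width
intervals per dimension between the observed minimum and maximum. For
each cell the number of wrong hits $n_0$ is set to the decoy PSM count,
and the number of true hits to $n_1 = \max(n_\text{target} - n_0, 0)$;
both arrays are smoothed by a border-clipped box mean over the
$3^3$-cell neighborhood and normalized to the conditional densities
$p(x \mid Z, H=0)$ and $p(x \mid Z, H=1)$. With
$\gamma(x, Z) = p(x \mid Z, H=1) / p(x \mid Z, H=0)$ and the prior odds
$\pi_1/\pi_0$ of true to wrong PSMs, the local FDR of a PSM is

$$ lFDR(x, Z) = \left(1 + \frac{\pi_1}{\pi_0}\, \gamma(x, Z)\right)^{-1}. $$

In two-group mode, $\gamma$ is estimated **from all PSMs** (the
non-canonical group alone is far too small for a 3D histogram), while
$\pi_1/\pi_0 = \max(T_g - D_g, 0) / \max(D_g, 1)$ is estimated per
group from its target count $T_g$ and decoy count $D_g$. Decoy PSMs
carry the group of the database section their accession derives from,
which is what makes $D_g$ meaningful. The low non-canonical odds raise
every non-canonical PSM's lFDR, so fewer but cleaner non-canonical PSMs
pass any given threshold — the group is protected from the canonical
group's favourable priors.

### Threshold selection

The lFDR threshold is adjusted to achieve a requested global FDR
$\alpha$ (default 0.03, applied per group in two-group mode). The
default adjustment counts decoys: target and decoy PSMs are ordered by
lFDR and the threshold is the largest value at which
$\#\text{decoys} / \#\text{targets}$ at or below it stays
$\le \alpha$. This is the field-standard target-decoy estimate of the
global FDR and is insensitive to bias in the lFDR values themselves.
The alternative rule (`threshold_rule = "mean_lfdr"`) thresholds on the
running mean of the sorted lFDR values; it relies on the lFDR estimates
being well calibrated pointwise. In our synthetic studies the histogram
estimator is systematically conservative in its small-lFDR range
(smoothing flattens the density ratio through the steep flank between
the true and false score bulks, roughly halving the odds there), so the
mean-lFDR rule under-accepts the minority group by a factor of two to
three in realized error, while the decoy-counting rule achieves the
nominal level in both groups. Both rules are exposed; the decoy-based
estimate of the achieved FDR is always reported as a diagnostic.

### Numerical choices

* **Binning.** Equal-width bins between the per-stratum min and max of
  each score; values exactly at the global maximum fall into the last
  bin (left-closed, right-open bins, last bin closed). A dimension with
  zero range raises an error suggesting the 1D mode.
* **Smoothing.** The "nearest neighborhood" box is $(2w+1)^d$ cells
  with $w = 1$ by default, clipped at the grid borders (so a corner
  cell averages over its existing 8 neighbors in 3D). The window is a
  parameter.
* **Pseudocounts.** Decoy-free cells would give an infinite density
  ratio, so $\varepsilon_0 = \varepsilon_1 = 0.5$ counts *per smoothing
  neighborhood* (i.e. $\varepsilon / 27$ per smoothed cell) are added
  to both arrays before normalization. Scaling by the neighborhood
  volume matters: adding 0.5 to each of the $40^3$ cells outright would
  inject more pseudo-mass than there are decoys in a realistic stratum
  and flatten $\gamma$ toward 1, destroying the estimator's dynamic
  range. With the neighborhood scaling, an isolated false hit in a
  decoy-free region still receives $\gamma \approx N_0/N_1 < 1$
  (because $\varepsilon_1$ floors the numerator at the same scale),
  while dense true-score cells remain unsaturated.
* **Prior odds guards.** The denominator of $\pi_1/\pi_0$ is floored at
  one decoy and the ratio capped at $10^6$; a group with zero target
  PSMs is an error that recommends one-group mode.
* **1D comparison mode.** `mode = "1g1d"` / `"2g1d"` bins XCorr alone
  into 40 intervals and runs the identical downstream machinery; this
  reproduces the simpler single-score baseline the 3D method is
  compared against.

## The non-canonical search space

`build_noncanonical_db()` translates every transcript with expression
strictly above a cutoff (FPKM/TPM; default 0) in all three forward
frames and keeps stop-to-stop segments of at least 8 amino acids.
Segments bounded by the transcript ends are kept: requiring a flanking
stop on both sides would discard the long open segments that dominate
real non-coding ORF databases. Codons containing an ambiguous base (N)
translate to X and segments are split there, so no fabricated residue
enters the search space. Reverse-strand frames are out of scope —
expressed transcripts have a known orientation.

Identified peptides are classified by exact substring matching against
the canonical proteome with isoleucine and leucine collapsed (they are
isobaric and indistinguishable by MS). A peptide matching only
accessions on a transposable-element whitelist is retained as
non-canonical with `te_exception = TRUE`, since TEs integrated into the
canonical database would otherwise silently absorb genuine TE-derived
peptides. The relative position of a peptide in its source protein is
reported by its C-terminal residue (an N-terminal convention is a
flag), which is the natural coordinate when looking for C-terminal
enrichment of HLA ligands.

## What the simulator emulates — and what it does not

`simulate_psms()` generates the target/decoy structure the estimator
assumes, with known true/false labels:

* target PSMs are a mixture of true and false matches, with true
  fractions 0.9 (proteome) and 0.3 (non-canonical) by default and a
  10% non-canonical share;
* scores are drawn from three-variate location-scale models with a
  positive XCorr-deltaCn correlation for true PSMs and near
  independence for false ones, so the 3D histogram genuinely separates
  better than any 1D projection;
* XCorr and spScore carry a rare exponential tail (probability 0.004)
  in both classes. Real search-score distributions are strongly
  right-tailed: the observed range spans many bulk standard deviations,
  so the equal-width min/max grid is densely populated in the bulk.
  This is the regime a 40-bin histogram over >100,000 PSMs presumes;
  without the tails the bulk spreads over too many cells for the
  density ratio to be resolved;
* decoys are drawn from the false-score distribution (target-decoy
  symmetry), one decoy per *false target* on average. This mirrors a
  search against an equal-size decoy database, where a decoy wins a
  spectrum at roughly the rate at which wrong target matches do; it is
  what makes $(T-D)/D$ a consistent estimate of the group odds;
* engine B reproduces a true engine A match with probability 0.9; for
  a false engine A match it reports the same wrong peptide with
  probability 0.1 (engines pick the same wrong candidate from the same
  database occasionally) and an unrelated wrong peptide with
  probability 0.5.

The simulator does **not** model spectra, retention-time structure,
peptide-length effects, shared peptides between the canonical and
non-canonical sections, or inter-spectrum dependence. Passing the
calibration study therefore shows that the estimator is correct *under
its own assumptions* (decoy symmetry, group-shared score densities); it
does not certify performance on real data where those assumptions hold
only approximately.

Study sizes: the packaged validation uses 20 replicate datasets of
200,000 target PSMs (strata 20k/120k/60k for Z = 1/2/≥3) for the
calibration, group-protection and intersection studies; 1,000 random
transcripts for the translation oracle; and 500 random sharing plans
for protein grouping.

## Protein grouping and sampling

`group_proteins()` performs a greedy set cover on the peptide-protein
bipartite graph: the protein explaining the most unexplained peptides
becomes a group lead (ties to the lexicographically smallest accession,
for byte-reproducible output), and proteins sharing a peptide with a
lead join its group. Members are ranked by decreasing total peptide
count and each member's *adjusted* count excludes peptides already
credited to higher-ranked members; a peptide reachable from several
groups is credited to the first group in lead order, so adjusted counts
sum exactly to the number of distinct peptides. HLA sampling is the
adjusted count divided by protein length, and
`expression_sampling_correlation()` relates it to expression through a
degree-3 polynomial fit on $\log_{10}(\text{FPKM} + 1)$ (the offset of
1 keeps unexpressed genes finite) with the Pearson correlation between
the fitted curve and the data.

Plain cardinality-greedy covering is used; on small random instances it
coincides with the exhaustive minimum cover, but greedy set cover is
not guaranteed minimal in general.

## QC statistics

Three external-evidence checks are wrapped: the fraction of predicted
HLA binders (predictor p-value ≤ 0.05, inclusive), the regression of
observed retention times on sequence-specific hydrophobicity indices
(slope, intercept, residual standard error and absolute residuals), and
a one-sided F-test comparing residual variances between a putatively
noisier identification set and a reference set ($F = s_A^2/s_B^2$,
upper-tail p-value on $(n_A-1, n_B-1)$ degrees of freedom; the caller
declares the direction). The binding predictor and the hydrophobicity
calculator themselves are consumed as annotation columns, never
reimplemented. Residuals are compared after per-set regression fits by
default; a shared fit can be requested by regressing the pooled data
upstream.

## Known limitations

* The histogram estimator needs large strata; below roughly $10^5$
  PSMs per stratum the 40³ grid is sparse and a warning is emitted.
  The 1D mode or fewer bins are the fallback.
* lFDR values in the densest true-score cells are floored by the
  pseudocount and should be read as "small", not as precise
  probabilities; group-level error control comes from the
  decoy-counting threshold, not from the pointwise values.
* Classification treats the proteome as a flat set of sequences;
  isoform-junction-spanning matches and variant peptides are out of
  scope.
* The engine intersection assumes both engines searched the same
  database; peptide strings are compared exactly (after modification
  normalization), with I/L kept distinct.
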