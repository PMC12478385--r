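---
title: "Models and methods behind katcomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind katcomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(katcomp)
```

`katcomp` implements the computational pipeline of a competitive
chemoproteomic study of MYST-family lysine acetyltransferase (KAT)
inhibitors. This vignette describes the models each stage assumes, the
parameters that matter and their defaults, what the synthetic-data
generator does and does not emulate, and the numerical choices made where
the design was genuinely open.

## Competition model and occupancy

A resin-immobilized bisubstrate CoA analogue captures CoA-binding proteins
through their active sites. Pre-incubating the extract with a competitor at
dose $d$ reduces capture of a protein whose site is engaged; for a single
site with half-competition concentration $K$ and Hill slope $h$, the
captured fraction is

$$ f(d) = 1 - m\,\frac{d^h}{d^h + K^h}, $$

where $m \le 1$ is the maximal competable fraction ($m < 1$ models proteins
with a pool residing in a complex the competitor does not engage, e.g. a
TRRAP-like subunit shared with a non-target complex). Profiles are
summarized per dose as the mean difference of log2 abundances versus
vehicle, and *occupancy* is defined as
$\mathrm{occ} = \mathrm{clamp}(1 - 2^{\mathrm{log2FC}},\,0,\,1)$ — capture
loss read as fractional engagement of the site, clamped because increased
capture carries no occupancy information.

Two statistical choices were open and are config-exposed rather than
asserted as the original analysts' choices:

* **Test**: Welch two-sample t-test on log2 intensities (volcano-style
  p-values; a moderated test could be substituted). Raw p-values are
  thresholded by default (log2FC > 0.6, p < 0.05 against the capped-bead
  control); Benjamini–Hochberg is available via `p_adjust`.
* **Normalization**: per-sample median (or total) equalization, or none.

Missing values in a treated condition are imputed at a floor (default half
the global minimum observed abundance): absence after competition is
evidence of complete competition, not missingness at random. Proteins
absent from all vehicle captures are excluded with a warning.

## Co-competition clustering and candidate discovery

Proteins in one complex co-deplete, so their dose-profiles are parallel.
The discovery stage embeds per-protein log2FC vectors (optionally
per-protein min-max scaled, to emphasize shape over magnitude) in two
dimensions with exact t-SNE, then k-means clusters the embedding.

* **Perplexity** defaults to 30, reduced to $n/4$ for small cohorts;
  t-SNE requires $3\,\mathrm{perplexity} < n - 1$.
* **k = 5** by default, matching the five-group structure of the original
  analysis; both the embedding seed and the k-means seed (10 restarts) are
  fixed for reproducibility. Whether to cluster embedding coordinates or
  the feature matrix directly was left open in the source analysis;
  `cluster_kmeans()` accepts either (pass `features$features` as the
  coordinates for the latter).
* A cluster is **dose-responsive** when its mean signature is monotone
  non-increasing (tolerance 0.1 log2 units, absorbing replicate noise) and
  drops at least `min_drop = 1` log2 unit in total — an operationalization
  of the qualitative "antagonized in a dose-dependent fashion" cluster
  description.

Candidates are proteins in dose-responsive clusters with no complex
annotation. With the default synthetic conditions the two planted
unannotated proteins (a forkhead transcription factor profile and a
variant-histone profile) are the only candidates, so candidate precision
is 1 by construction; on real data precision depends on the annotation's
completeness.

## Interface metrics for predicted structures

For a bait–candidate structure prediction the package computes, from the
PAE matrix, per-residue pLDDT and representative-atom coordinates
(C$\beta$; C$\alpha$ for glycine):

* **Contacts**: inter-chain representative-atom pairs within 8 Å.
* **pDockQ / mpDockQ**: $L/(1+e^{-k(x-x_0)})+b$ with
  $x = \langle \mathrm{pLDDT}_{\mathrm{interface}} \rangle \cdot
  \ln(\mathrm{contacts})$; dimer constants
  $(L,k,x_0,b) = (0.724, 0.052, 152.611, 0.018)$, multimer constants
  $(0.728, 0.098, 309.375, 0.262)$, from the metrics' defining literature
  and stored in `dockq_constants()` rather than hard-coded. Zero contacts
  returns the baseline $b$ exactly ($\ln 0$ is undefined; no interface
  means no support).
* **LIS/LIA**: over inter-chain residue pairs whose symmetrized PAE (mean
  of the two directions; `min` is the obvious alternative and the choice
  is recorded in the function's documentation) falls below 12 Å, the
  per-pair score is $(12 - \mathrm{PAE})/12$; LIS is the mean per-pair
  score, LIA the count of qualifying unordered pairs.
* **Composite**: min-max normalize LIA, LIS and the dockq proxy across the
  screen (constant columns map to 0), sum, and weight by the confidence
  coefficient — the fraction of metric cutoffs passed (defaults ipTM 0.5,
  dockq 0.23, LIS 0.073, LIA 1610, the metrics' published working
  cutoffs). The composite therefore lies in $[0, 3]$ and is 0 whenever
  every filter fails. The exact filter set used in the source analysis's
  supplement is not restated here; the threshold map is an argument.

## Histone biomarker stoichiometry and IC50s

Stoichiometry of a peptidoform is its share of the summed intensity of all
forms of the same backbone peptide in the same (dose, replicate); forms of
one peptide therefore sum to 100% by construction. Filtering follows the
counting unit of the source analysis — the *peptidoform*: a form is
reproducible when its vehicle mean exceeds 1% with SD ≤ mean, and
responsive when its mean changes ≥ 2-fold (boundary inclusive) between 0.1
and 30 µM. Marks measured on several forms (co-modified peptides) are
aggregated by summing stoichiometries *after* filtering, for IC50 fits and
the per-KAT panel; aggregating before filtering would change the counted
units from peptides to marks.

Dose–response fits use a constrained 4PL in log10 dose:
$y = \mathrm{bottom} + (\mathrm{top}-\mathrm{bottom})/(1 +
10^{h(\log_{10} d - \log_{10}\mathrm{IC50})})$, with top constrained to
±20% of the vehicle mean, bottom ≥ 0, and $h \in [0.2, 5]$. The vehicle
point enters at the exact zero-dose limit (the logistic term vanishes at
$\log_{10} d = -\infty$), which pins the top plateau without biasing the
midpoint — a finite pseudo-dose two decades below the lowest tested dose
biases the fitted IC50 by ~0.2%, which matters only because the test suite
demands exact noiseless recovery; the two treatments are otherwise
interchangeable. Optimization is bounded Levenberg–Marquardt
(`minpack.lm::nlsLM`) behind a short cascade of perturbed starts, because
single fixed starts occasionally trigger a spurious singular-gradient stop.
A fit is flagged `insensitive` when the midpoint lies above the tested
range or the fitted span is under 5% of the top plateau; flat data
therefore never yield a quotable IC50.

## Percent growth and GI50

Percent growth follows the NCI-60 developmental-therapeutics convention
with time-zero correction:
$PG = 100\,(T_i - T_z)/(C - T_z)$ when $T_i \ge T_z$ and
$100\,(T_i - T_z)/T_z$ otherwise; both branches vanish at $T_i = T_z$, so
PG is continuous there and bounded below by −100. The formula itself is
not configurable — only the crossing level (default 50) is. GI50 is
computed two ways: linear interpolation in log10 dose between the
bracketing pair (doses are log-spaced, so interpolating in linear dose
would be systematically biased) and a 4PL fit. On a decade-spaced ladder
the interpolation carries up to ~10–15% systematic error depending on the
slope; the fit does not, which is why both are reported.

## What the synthetic generator emulates — and what it does not

The generator's defaults are the study conditions: capture doses
{0, 0.1, 1, 10} µM, cellular doses {0, 0.1, 1, 10, 30} µM, growth doses
{0.01, 0.1, 1, 10, 100} µM, triplicate capture/histone and quadruplicate
viability measurements, multiplicative log-normal noise with CV 10%
(capture, histone) and 5–15% (viability), chosen as typical label-free
quantification and plate-assay precision. The planted truth encodes the
study's findings as conditions: a six-member KAT7/JADE complex
half-competed at 0.05 µM, a BRPF arm at 5 µM, KAT8 MSL/NSL complexes near
1 µM, a 13-member NuA4 complex at 2.5 µM (33 annotated members in all),
four partially competable NuA4-associated proteins, 65 specific but
dose-invariant CoA binders, 100 non-specific background proteins, and two
unannotated proteins with complex-like profiles. The histone roster plants
38 reproducible peptidoforms of which 8 (all acetyl) respond ≥ 2-fold,
with mark IC50s 0.025 µM (H3K23ac), 1 µM (H3K14ac), 10 µM (H4K16ac) and
18 µM (H2A.Z acetylation); the viability truth plants GI50 = 7 µM with
Hill slope 1.3.

The generator does **not** emulate: spectrum-level variation or
peptide-to-protein rollup (inputs start at quant tables), retention-time
or charge effects, batch structure, realistic structure geometry beyond
chain-labelled representative atoms with controllable contacts, or
correlated noise between complex members. Passing tests therefore
demonstrate that the analysis recovers planted truth under realistic
marginal noise — not that it is robust to every pathology of real
LC-MS/MS data.

Missing values are generated by a detection floor (`detection_floor`,
disabled by default and exercised explicitly in tests), below which
abundances are reported missing — the mechanism the imputation floor in
the competition stage is designed for.

## Problem sizes and determinism

All simulations are sized for interactive use: the default capture matrix
is 204 proteins × 15 samples, the histone table 50 peptidoforms × 5 doses
× 3 replicates, the in-silico screen 38 candidate pairs of 110 residues,
and recovery simulations use 100 seeded replicates; the full test suite
runs in well under a minute. Every generator and every stochastic analysis
step (t-SNE, k-means) is seed-deterministic; `run_pipeline()` reruns with
the same config and seed produce byte-identical outputs, verified by MD5
in the manifest.

## Known limitations

* Sensitive-cluster structure depends on the t-SNE layout: across seeds
  the default conditions nearly always yield two dose-responsive clusters
  (the two planted sensitivity tiers), but an occasional layout merges
  them into one; cluster *membership* (which proteins are dose-responsive)
  is stable throughout.
* The enrichment stage tests each protein independently; no shrinkage
  across proteins is attempted, so very small replicate numbers give
  noisy p-values.
* mpDockQ pools all inter-chain interfaces into a single contact count and
  interface-pLDDT mean; per-chain-pair aggregation variants exist and
  would need a different aggregation rule.
* The 4PL top-plateau window (±20% of vehicle) assumes the vehicle
  condition measures the uninhibited plateau; designs without a vehicle
  fall back to the maximum response, which underestimates the plateau when
  the lowest dose already inhibits.
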