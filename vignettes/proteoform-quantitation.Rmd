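---
title: "Methods: integrating top-down identifications with intact-mass features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating top-down identifications with intact-mass features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdpquant)
```

# The problem

Quantitative top-down proteomics of micro-dissected tissue pairs three
result streams that were never designed to agree: PrSM tables from an
open-modification search engine, proteoform tables from a
database-driven engine, and deconvoluted MS1 features that carry the
abundances. Between runs, chromatography drifts smoothly in retention
time and the mass axis carries a small per-run calibration error; within
runs, deconvolution occasionally reports a monoisotopic mass off by one
or two isotope spacings, so one proteoform's abundance is split across
"isotopologue ghosts" about 1.00235 Da apart. FAIMS acquisition
additionally splits each sample into one file per compensation voltage.
`tdpquant` resolves all of this with explicit, configurable tolerance
rules and produces a proteoform × sample matrix suitable for
differential analysis between two tissue regions (the default design:
five cortex vs four hypothalamus replicates).

This vignette records the model, the parameters that matter, the design
decisions made where the design was genuinely open, and what the
synthetic-data tests do and do not demonstrate.

# Alignment and recalibration

Anchors are proteoforms identified in both the reference run (most
PrSMs; ties break lexicographically so the choice is deterministic) and
the run being aligned, each located at its apex PrSM — the most intense
one, falling back to the best E-value when intensities are absent. The
warp is a LOESS regression of reference RT on target RT: span 0.5,
locally linear, two robustness iterations. These values are defaults,
not doctrine: with a few hundred anchors and the occasional mis-assigned
open-modification PrSM, a generous span plus robust reweighting is the
standard recipe, and all three are exposed as arguments. The span is
floored so each local window holds about a dozen anchors; outside the
anchor range the warp continues linearly with the boundary slope
(extrapolating a LOESS curve itself is not meaningful). Perfectly
collinear anchors make the robust variant degenerate (all residuals
zero), in which case the fit silently falls back to least squares;
fewer than five usable anchors or anchors without RT spread yield the
identity warp with a warning, so a thin run never gets a wild warp.

Two deliberate choices deserve a note:

* **Anchor identity.** Anchors are keyed by (accession, proteoform
  string), not by a rounded observed mass. At intact-protein masses a
  realistic per-run offset of a few ppm moves the observed mass by more
  than any fixed rounding granularity (3 ppm at 20 kDa is 0.06 Da), so a
  mass-rounded key silently empties the anchor set exactly when
  recalibration is most needed. The proteoform string is run-invariant;
  a rounded mass is kept only as a fallback for tables without strings.
* **Recalibration model.** A single per-run constant ppm offset, the
  median over anchors. A constant is the minimal model consistent with
  "recalibrate per run"; the median resists the rare wildly wrong
  anchor. Only engines reporting *experimental* masses are recalibrated
  (and contribute mass anchors): a database-driven engine reports
  theoretical proteoform masses that carry no instrument error, and
  recalibrating them would *introduce* run dependence where none exists.

Simulation recovery (tested): an affine drift (slope 1.05, intercept
2 min, anchor noise 0.05 min, 100 anchors) is recovered to a median
residual below 0.1 min; a sinusoidal drift of 1 min amplitude over
120 min to below 0.2 min; an injected +8 ppm offset to within 0.5 ppm.

# Proteoform clusters

PrSMs are partitioned by accession and single-linkage clustered, linking
two PrSMs when their masses agree within 15 ppm — evaluated against the
smaller mass, which is symmetric and conservative — and their RTs within
4 min. The engine's own merging step uses a proteoform-level mass
tolerance, but no clustering thresholds are published for this
post-hoc step, so the defaults intentionally equal the downstream
matching tolerances (15 ppm / 4 min); both are configurable. Clustering
runs on the recalibrated experimental precursor mass by default; an
option switches to the engine's adjusted mass, which trades
deisotoping-error redundancy for extra reported-mass variance.

Clusters with fewer than three PrSMs are pooled into a noise cluster
whose id ends in `_0`; noise is kept (it may still annotate a feature
group) but always loses conflicts to non-noise identifications. The
cluster representative is the proteoform string backed by the most
PrSMs, ties to the lowest E-value.

Ambiguity is graded on four attributes — PTM localization (A), PTM
identity (B), amino-acid sequence (C), gene (D) — with level "1" for
none flagged, "2A"–"2D" for exactly one, and level `1 + k` for `k ≥ 2`.
An unknown (bare) mass shift flags A and B together, since neither the
modification nor its site is determined; a named PTM whose scope spans
more than one residue flags A alone. Sequence ambiguity is always false
here: both engines report a definite backbone. Gene ambiguity requires
an accession-to-gene map; without one the flag stays false and a caveat
is logged.

# Feature alignment and grouping

The cross-run aligner is intentionally minimal (a match-between-runs
scheme standing in for a dedicated external alignment tool): per CV, the
run with the most features seeds a master list; every other run's
features match greedily by smallest ppm error within 15 ppm / 4 min,
each feature used at most once; unmatched features append new rows, and
a sample that lacks a feature keeps a true missing value, never zero.
On simulated three-run data with 10% dropout it reconstructs ≥ 98% of
known correspondences, which is sufficient for its role; it does not
attempt chromatogram-level warping.

Grouping then chains the concatenated, mass-sorted features: a feature
joins the current mass group iff its gap *to the immediately preceding
feature* is ≤ 1 Da and ≤ 15 ppm; within a mass group, RT-sorted features
chain with gaps ≤ 4 min. Chaining against the predecessor (rather than
any member) is one of two defensible readings of "within … of a previous
mass"; it is equivalent to single-linkage on a line, matches the
sort-then-scan procedure described, and is what the brute-force oracle
in the test suite implements independently. All comparisons are
inclusive (`≤`), pinned by a boundary test (RT gaps of exactly 4 min
chain into one group).

Each feature group is summarized by member count, its **maximum**
member mass (the consensus mass — deisotoping errors only subtract
isotopes in the common case, and the summary mirrors the max-mass
convention of the final table), mean RT, and per-sample **median**
intensity over member features (across CVs and split features).

# Identification attachment

Engine results are collapsed before matching: one candidate per PfC
(noise included) and one per (accession, monoisotopic mass rounded to
0.01 Da) for the second engine, each represented by its lowest-E-value
record. A candidate matches a feature group when, for some shift
`k ∈ {0, ±1, ±2}`, the shifted ID mass `m + k · 1.00235` agrees with the
group consensus within 15 ppm and the RTs within 4 min. The shift grid
uses isotope spacing rather than exactly 1 Da because deconvolution
off-by-one errors are isotopologue errors; at protein masses the
difference from 1.0 Da is far inside the 15 ppm gate either way. Shift 0
is preferred, then increasing `|k|`; the shift is applied to the ID mass
(the window is symmetric, so the direction is a bookkeeping choice).

When several candidates hit one group, the winner is chosen
lexicographically: no unknown modification first, then non-noise PfC,
then smaller E-value, then smaller `|k|`, then engine order, then stable
input order. The complete priority table is verified exhaustively over
all eight flag combinations in the tests. One candidate may annotate
several groups in distinct RT windows (the same proteoform eluting
twice is two quantifiable rows).

# Quantitation

The stage order is fixed and one-way — filter → normalize → log2 →
impute → test — and the matrix object refuses out-of-order transitions.

* **Min-samples filter:** a proteoform must be observed (pre-imputation)
  in ≥ 2 samples.
* **Normalization:** each sample's abundances are divided by the
  sample median, then rescaled by the grand median of sample medians so
  the global intensity scale is preserved; afterwards all sample medians
  are equal. Normalizing raw intensities (a ratio) rather than centering
  log intensities is the more literal reading of "normalized to the
  median of each sample"; a log-scale centering variant can be obtained
  by normalizing after `log2_transform()` is deliberately *not* offered
  as a hidden default.
* **Imputation:** missing log2 cells draw from
  `Normal(μ_s − 1.8 σ_s, (0.3 σ_s)²)` per sample, deterministic under a
  seed. The tests pin the distribution (10⁴ draws for a sample with
  μ = 20, σ = 2 give mean 16.4 and sd 0.6 within ±0.02) and the
  determinism. At the default downshift the imputed values sit below the
  sample's observed median with probability ≈ 1; the 99th percentile of
  a large draw is asserted.
* **Testing:** per-row unpaired two-sided t-tests; the equal-variance
  (Student) form is the default since the variant is not specified, with
  Welch one argument away. Rows that are exactly constant within both
  groups (possible on noise-free synthetic data) are handled explicitly:
  t = 0 / p = 1 when the groups agree, ±∞ / p = 0 when they differ. Raw
  p-values are the primary output; Benjamini–Hochberg q-values ride
  along as an extra column.
* **PCA:** standard PCA of samples with proteoforms centered; for
  non-imputed data the sample covariance is assembled from
  pairwise-complete observations and eigen-decomposed, so missingness
  needs no imputation to visualize.

# The synthetic-data generator

`generate_truth()` fixes the study conditions: proteoform masses
log-uniform in 3.5–30 kDa, elution 10–120 min, log-normal base
abundances (meanlog `log(1e7)`, sdlog 1), 25% of proteoforms with a
two-fold region effect of random sign, Dirichlet-like CV usage profiles
over −30/−40/−50 V, ~30% of identifications carrying an unknown mass
shift (matching the ~70% unmodified share typical of such studies), and
each engine independently observing ~70% of proteoforms so the engine
Venn has all three cells. Per run: affine RT drift (slope sd 0.02,
intercept sd 1 min), ppm offset sd 3, 10% dropout, 5% deisotoping
errors, 20% multiplicative abundance noise. Values without a stated
counterpart in the study design (dropout, deisotoping and noise rates,
drift magnitudes) were chosen once as field-realistic and are not tuned.
One non-physical constraint is imposed: true masses are at least 3 Da
apart, so that "distinct proteoform" is well defined under the 1 Da
chaining rule and recovery can be scored exactly.

All randomness flows from one seed; substreams (tables, MALDI) derive
deterministically from it, so regeneration is byte-stable. What passing
tests show — and what they do not: the generator emulates the
*statistical* structure (drift, offsets, splits, dropout, overlap), not
chromatographic peak shapes, charge-state envelopes, co-elution, or
engine-specific scoring quirks; real data will stress the aligner and
the conflict rules harder than the simulation does. The zero-noise
configuration (all rates and sds zero, both engines complete) is the
end-to-end identity check: the pipeline must return exactly the true
proteoform count with every effect sign correct, and does. At the
default (noisy) settings the pipeline quantifies slightly *more* rows
than true proteoforms — deisotoping splits that survive as separate
groups — and fold-change sign accuracy drops to roughly 3 in 4, driven
almost entirely by downshifted imputation of randomly missing cells;
that bias is a documented property of this imputation family, visible
here because the simulator's missingness is random rather than
abundance-dependent.

# MALDI annotation

Intact-protein MALDI peaks carry low charge (≤ 3) and rarely fragment,
so annotation is by accurate mass against the LC-MS/MS proteoform
library. Monoisotopic mode (15 ppm default) compares against the
monoisotopic m/z and is the right choice for resolved, deisotoped peak
lists. Apex mode (50 ppm default) adds `round(5.5e−4 · M)` isotope
spacings to approximate the envelope apex of an unresolved protein
envelope — a linear averagine-like heuristic, not an isotope-pattern
simulation, which is the honest level of modelling for peak-list-only
input; its residual error of tens of ppm is why the apex tolerance is
looser. Each peak takes the library entry minimizing |ppm| across
charges 1..z_max; annotation is deterministic and order-independent.

# Problem sizes and numerical choices

The shipped tests and the acceptance script run synthetic studies of
40–150 proteoforms × 9 samples × 3 CVs and 200-instance oracle sweeps;
these sizes exercise every code path (multi-CV alignment, noise
clusters, conflicting IDs, splits) while keeping the whole suite in the
low minutes on one core. Tolerance comparisons are inclusive throughout;
ppm is always evaluated against a stated denominator (the smaller mass
for PrSM linkage, the predecessor for chaining, the group consensus for
matching); ties break deterministically everywhere (lexicographic run
ids, stable input order in conflicts), which is what makes byte-identical
reruns possible.

# Known limitations

* The cross-run feature aligner is greedy and per-CV; it does not model
  systematic intensity differences between runs or split/merged feature
  boundaries.
* Protein-level FDR is approximated by the best record q-value per
  protein when only record-level q-values are present; engines' own
  protein-level statistics are preferred when available.
* Gene-level ambiguity depends entirely on the supplied accession→gene
  map.
* The MALDI apex model ignores resolution and adducts; it annotates, it
  does not identify.
* TDViewer/TDPortal export schemas vary by version; the shipped dialect
  is best-effort and fully overridable via the dialect objects.
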