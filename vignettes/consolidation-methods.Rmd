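---
title: "Methods: consolidating tentative GC-MS identifications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consolidating tentative GC-MS identifications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mzexacto)
```

## What the package models

After deconvolution and library search, a GC-MS experiment is a flat table
of tentative identifications: per sample, per deconvoluted component, a
library-hit name, a match factor in [0, 100], a retention time (RT) in
minutes, the base-peak *m/z* and an integrated area. The quantity of
scientific interest is the compounds × samples area matrix. The gap
between the two is an assignment problem: the same chemical elutes at
slightly different RTs across runs, and the library search sometimes
reports a near-isomer instead of the true compound, because distinct
chemicals can share fragmentation behavior. `mzexacto` closes that gap
deterministically, using a local store of published compound knowledge
(exact monoisotopic mass, fragment spectrum, synonyms, structure).

## The matching model and its assumptions

The consolidation in `mz_exacto()` assumes:

* a chemical's correct identifications agree on the name (up to synonyms
  and case) and carry high match factors;
* its RT is reproducible across samples within a narrow window;
* a misassigned component still shares the true compound's two most
  intense published fragment *m/z* values with the query, because the top
  of the fragment spectrum is what drove the (wrong) library hit.

**Windows.** Each query's window is `median(anchor RTs) ± rt_halfwidth`,
where anchors are its name matches above the match-factor floor. The
median is used rather than the mean because a single misintegrated
component should not shift the window. The default half-width of 0.35 min
was chosen to comfortably admit the RT discrepancies that practitioners
accept when reconciling automated against manual annotation of the same
runs — up to roughly 0.3 min for early-eluting aromatics — while staying
well below typical peak-to-peak spacing.

**Unanchored queries.** A query that never occurs by name gets, in order
of preference: a window centered on the median RT of records whose
tentative identity shares its unit-rounded top-2 *m/z* (the same evidence
class the rescue uses — this is what separates equal-mass isomers); else a
window interpolated from the exact-mass → median-RT trend of the data
(linear between the two nearest masses, extrapolation clamped to the
observed RT range); else no window, in which case only name matches could
have applied.

**Strictness and exclusivity.** All match-factor comparisons are strict
(`> 75` by default, matching the convention of reporting compound sets
"above 75%"). Every input record is claimable by at most one query; when
two queries could claim one record (shared synonyms), the lower exact mass
wins, purely so the outcome is deterministic, and the conflict is logged.
The rescue pass deliberately has no match-factor floor: the whole point of
rescue is that the match factor belongs to the *wrong* identity; evidence
comes from fragment agreement and the RT window instead.

**m/z equality** is set equality after round-half-up to unit mass, the
single-quadrupole convention (`round()`'s half-even rule would misplace
x.5 values); a Dalton tolerance is exposed for high-resolution data.

**Aggregation.** Within a (chemical, sample), claimed areas are summed,
because deconvolution can split one elution into adjacent components; a
`max` alternative is exposed for users who prefer the dominant component
only. The reported `optimal_rt` is the area-weighted mean of claimed RTs
— the best single-number summary of where the compound's signal mass sat
— and is always inside the span of the matched records.

**Decontamination** quantifies "no strong match across samples" as: best
match factor not strictly above `strong_mf` (default 75) or matched in
fewer than `min_samples` samples (default 1), plus the two identity
criteria (resolvable in the store; has an identifier or structure). Both
numeric knobs are exposed because reasonable studies differ; the defaults
are the permissive end.

## Structure comparison

Tanimoto similarity is computed over the **maximum common connected
substructure** (MCS): `T = n / (n_a + n_b − n)` with `n` the MCS atom
count and `n_a`, `n_b` the heavy-atom counts. The tier thresholds (strong
`> 0.95`, moderate `> 0.85`, both strict) are calibrated for MCS-style
scores and would not transfer to hashed-fingerprint Tanimoto, so the MCS
definition is normative here.

Matching rules: atoms must agree on element *and* aromaticity, bonds on
order with aromatic a distinct order, and zero mismatches are allowed —
so methane shares nothing with benzene, and cyclohexane shares nothing
with benzene either. The common subgraph must be connected; bonds that
disagree between the molecules are simply not part of it. The search is an
exact McGregor-style branch-and-bound with partial-mapping deduplication,
exhaustive up to a 40-heavy-atom budget (GC-MS volatiles sit far below
this); larger inputs fall back to a greedy seeded extension whose result
is flagged approximate. Exactness is verified in the test suite against an
independent brute-force enumeration of connected common subgraphs on a
fixture set of ≤ 8-atom molecules.

Ring counts are the cyclomatic number (bonds − atoms + components), not
SSSR; for fused bicyclics the two conventions agree on the count of
independent cycles, and the cyclomatic number is well-defined on every
graph the SMILES subset can produce.

The SMILES subset covers organic-subset atoms, aromatic lowercase
notation, brackets with explicit H counts and charges, branches, ring
closures up to %99, and bond symbols `- = # :`. Stereo bonds are read as
single bonds and chirality/isotope marks are ignored, each with a warning:
the MCS matcher is deliberately stereo-blind, so retaining the marks would
only suggest a precision the comparisons do not have. Implicit hydrogens
follow the Daylight valence rules with aromatic bonds counting 1.5;
masses are monoisotopic (most abundant isotope per element), the
mass-spectrometric meaning of "exact mass".

## Quantification

External calibration regresses detector response on amount (`linear`) or
on ln(amount) (`log`) by ordinary least squares and inverse-predicts
analyte amounts. Response-on-amount is the univariate calibration
convention; the log variant models the saturating response some esters
show over wide dilution ranges. Predictions from responses outside the
fitted response range are flagged extrapolated, and negative linear
inversions are reported as-is with the flag rather than clamped — silently
zeroing them would bias low-end statistics. Internal standardization
divides by the standard's area in the same sample, which makes the result
invariant to any per-sample multiplicative effect (injection volume,
detector drift), and multiplies by the spiked amount when one is given.

## The synthetic-experiment generator

`experiment_config()` + `generate_feature_table()` emulate the
post-deconvolution stage directly: per planted compound and sample, one
record with Gaussian RT jitter around a fixed elution center,
multiplicative Gaussian area noise truncated at zero, a match factor
uniform in a configurable range, and — with the configured probability — a
name corrupted to a "rescue partner": a wrong name whose store spectrum
shares the planted compound's top-2 *m/z*, exactly the failure mode the
rescue pass exists for. Decoys never share a top-2 pair with any planted
compound, so a single decoy claim is a hard failure, and a siloxane
contaminant with no store entry is injected into every sample to exercise
decontamination. All outputs are pure functions of (configuration, seed).

The baseline conditions used throughout the tests are 25 compounds × 12
samples (clean), and the same size with 0.05 min RT jitter, 20% corrupted
names and 5 decoys over 20 seeds (stressed); the standards design is the
published four-compound serial dilution (ethyl hexanoate, methyl
salicylate, octanal, undecane at low/medium/high amounts) with responses
proportional to amount. Noise draws are scaled by the noise parameter
rather than redrawn per level, so fit quality degrades monotonically in
the noise scale for a fixed seed — the property the tests assert.

What the generator does *not* emulate — and therefore what passing tests
cannot show about real data: co-elution and deconvolution failure, real
fragment spectra (the bundled panel's spectra are synthetic ladders with
unique top-2 pairs), retention drift that accumulates across a sequence,
match factors correlated with spectral similarity, and missing areas from
integration failures. Results on real exports depend on the quality of the
user's reference store in ways the synthetic world cannot probe.

## Numerical and degenerate-input choices

* Round-half-up for unit mass; ≥ 12-significant-digit isotope masses.
* Rescue tie-break order: match factor, then |RT − window center|, then
  area — the same order a manual analyst applies.
* Empty chemical lists, empty libraries, all-structureless query sets and
  zero-area internal standards are errors naming the offender; a single
  unresolvable name is never an error, only a logged `unresolved` record.
* Match factors supplied on the 0–1 scale (detected when *all* values
  ≤ 1) are rescaled ×100 with a warning.
* CSV output writes numerics at 15 significant digits so write → read
  round-trips are exact to representation.

## Known limitations

Retention-index (alkane-ladder) calibration is out of scope, as are raw
signal integration, spectral deconvolution and MS2. The mass → RT
interpolation is a stand-in for a boiling-point model and can mislocate
unanchored queries in chemically heterogeneous runs; spectral anchoring
usually catches these first. Exact MCS is exponential in the worst case;
the atom budget and the approximate fallback bound the cost but large
natural products lose the exactness guarantee.
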