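---
title: "Models and methods behind pinflex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pinflex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pinflex)
```

`pinflex` packages the quantitative machinery used to study how a
protein–protein interaction network (PIN) of MADS-domain transcription
factors rewires across whole-genome duplications, and how the
conformational flexibility of its hub proteins changes alongside. This
vignette explains each model, the tunable parameters and their defaults,
the numerical choices, and what the synthetic-data generator does and does
not emulate.

## 1. Quantitative interaction calling

The observable is β-galactosidase reporter activity in Miller units per
bait–prey (Y2H) or bait–prey–mediator (Y3H) combination, with replicates,
empty-vector controls (reporter leakiness) and per-bait auto-activation
controls (bait + empty AD vector).

A **dimeric call** is positive when (i) a one-sided Welch *t*-test of the
pair's replicates against the pooled empty-vector background rejects at
`alpha` and (ii) the pair mean exceeds `min_fold` times the background
mean. Both knobs are exposed (`alpha = 0.05`, `min_fold = 2` by default);
"significantly enhanced" is not operationalized in the original assay
description, so the Welch test is this package's choice and the defaults
are labelled as such. Auto-activating baits — whose bait + empty-AD control
is significantly above background *and* reaches the same fold threshold —
have all their pairs excluded rather than called; requiring the fold gate
here keeps one-in-twenty test flukes from discarding entire baits. Ties
and exact equality of means are conservative (negative). Calls are
symmetrized over bait/prey orientation: a pair is positive if either
orientation is.

A **mediated call** implements the subtraction definition of a positive
ternary interaction: `delta = mean(Y3H) − baseline`, where the baseline is
the pair's dimeric mean when the pair is dimerically positive and the
pooled empty-vector background mean otherwise (subtraction needs a finite
baseline; the source protocol does not state one, so the pooled background
is this package's choice). A pair is positive when it is Y2H-negative but
clearly Y3H-active (background test + fold gate), or when `delta >
min_delta` (default 0) with a one-sided test at `alpha`. Negative deltas
are negative calls — a lost or false-positive ternary signal. Missing
mediator auto-activation controls are a hard error.

Because the Welch statistic and the fold ratio are both scale-free, calls
are invariant under a common rescaling of all Miller values — assay-wide
calibration constants cancel.

## 2. Network evolution statistics

Networks are undirected with homodimer self-pairs as genuine loop edges,
so the potential-interaction count is `n(n+1)/2` and density is observed
over potential interactions. An alternative convention is provided because
of a subtlety worth stating plainly: under all-versus-all polyploid edge
inheritance, a non-loop edge expands into `m²` copy-pair edges while a
loop expands into `m(m+1)/2`, and the unordered-pair potential grows by
yet another factor — so pairwise density is only preserved up to `O(1/n)`
by triplication. Counting occupied adjacency-matrix entries (diagonal
included) over `n²` — `network_density(, convention = "matrix")` — *is*
exactly invariant, and the package uses that convention where exact
conservation is asserted; the two agree as networks grow.

`rescale_by_polyploidy()` copies every node `m` times, inherits edges
all-versus-all (an ancestral loop yields all pairs among the copies), and
removes redundant copies down to an explicit keep-list or a target size.
Which copies to drop is not determined by the original construction, so
removal is deterministic: lowest copy index first, ancestors in sorted
order.

`compare_networks()` classifies descendant edges as conserved (some
ancestral edge maps onto the pair through the ortholog map) or gained, and
ancestral edges as lost when no descendant-pair image survives. Edges with
unmapped endpoints count as gained; ancestral edges with no descendants
count as lost (the treatment of unmapped nodes is a package decision).
Rates divide gained/lost counts by potential edges times divergence time,
i.e. per *potential* edge per million years — "per edge per mya" alone is
ambiguous, and the normalization follows the defining formula of the rate
(counts over potential interactions times divergence time). The epoch
anchors 180/120/109 mya are configuration defaults, never constants.

Hub metrics: degree counts each distinct partner once (a loop adds one —
the protein is its own partner), promiscuity is degree over `n` (possible
partners including self), and nodes are classed hub / intermediate /
island by configurable degree thresholds. `swap_protein()` evaluates a
foreign protein's calls against a host network of a different age and
reports its degree and promiscuity in the host frame.
`subfunctionalization_check()` is the additivity test: descendants'
combined degree versus the ancestor's, with the deficit as the net loss
relative to perfectly additive partitioning.

## 3. The synthetic network history generator

`simulate_pin_evolution()` is a forward simulator defining the study
conditions for every downstream test: an Erdős–Rényi start (`n0` nodes,
edge probability `p0` over all pairs including self-pairs), per-mya
Bernoulli edge dynamics (each absent pair gained with probability
`gain_rate` per mya; each present edge lost with probability `loss_rate`
per mya — note the different exposure bases), and polyploidy events that
copy every node with all-versus-all inheritance. With probability
`subfunc_prob` a parent's edge set is partitioned among its copies: each
ancestral edge is assigned to exactly one copy per subfunctionalizing
endpoint, so the union of the copies' mapped edge sets equals the parent's
and pairwise intersections are empty. Time is discretized in 1-mya steps;
epoch and event times are treated as integers on that grid.

The attached ground-truth rates are *realized* rates — gain/loss event
counts divided by potential-edge exposure in mya — which puts truth and
the comparison-based estimator on the same scale (per potential edge per
mya). The configured `gain_rate` shares that scale; the configured
`loss_rate` does not (it is per existing edge), which is why recovery is
checked against the realized truth. Estimator and truth differ only
through within-interval churn (edges gained then lost, or lost then
regained), which is quadratic in the rates.

The recovery study runs 20 replicate histories with `n0 = 30`, `p0 = 0.2`,
`gain_rate = 0.002`, `loss_rate = 0.01` over the 120 → 109 mya interval:
roughly 8 gain and 10 loss events per replicate, enough events for the
estimate to be informative while keeping churn near 1–2 events in total.
The estimator's mean across replicates is required to fall within two
standard errors of the realized truth.

The assay generator emulates background leakiness, auto-activation,
true-interaction signal and replicate noise. Replicate noise is log-normal
with a coefficient-of-variation parameter (`noise_cv = 0.15` by default)
because Miller units are positive and errors multiplicative; no
distributional form is asserted by the source data, so this is a
parameterized stand-in. Defaults place the background at 5 and true
signal at 40 Miller units (8× background) with 3 replicates — a clearly
separated regime; the calibration tests (false-positive rate at most α on
pure background, recall ≥ 95 % on planted signal) are statements about the
caller under *these* conditions, not about any real screen. What the
generator does not emulate: plate effects, bait-specific expression
differences, growth-based selection, or correlated replicate errors.

## 4. Conformational flexibility

Conformer probabilities follow the Boltzmann distribution
`P_i ∝ exp(−(E_i − E_min)/RT)` (the minimum-energy shift is exact
mathematics, not an approximation, and makes the exponentials stable), and
the conformational entropy is `S = −R Σ P_i ln P_i` with
`R = 1.98720 cal mol⁻¹ K⁻¹`. Entropies are reported as molar quantities
(cal K⁻¹ mol⁻¹): per-molecule values with Boltzmann's constant would be
~10²³-fold smaller than the few-cal/K magnitudes these analyses work with.
The default temperature is 298.15 K; the weighting temperature is
otherwise unspecified upstream. The "conformational space" descriptor is
the number of conformers within `window` kcal/mol of the global minimum
(default 5, configurable — low-energy minima are defined upstream by a
search protocol rather than an explicit window, so the window is a package
parameter). `compare_flexibility()` refuses ensembles at different
temperatures rather than silently reweighting.

Published minima counts and entropies for specific peptides depend on a
proprietary conformational-search protocol and force field and are not
reproducible from energies this package can generate; synthetic ensembles
sized like those results (269 vs 645 conformers) are used to exercise the
comparison machinery, not to reproduce the printed values.

## 5. Structural geometry

**Superposition and RMSD.** `kabsch_superpose()` computes the closed-form
least-squares rigid alignment via SVD with the determinant correction that
guarantees a proper rotation (no reflections). Collinear or undersized
selections are rejected. `trajectory_rmsd()` reports per-frame RMSD over a
selection (chain / residue range / atom names, e.g. Cα of residues
98–111), with optional per-frame superposition; residue ranges are closed
intervals in author numbering.

**SASA.** Shrake–Rupley quadrature with a deterministic golden-spiral
point lattice (no RNG), probe radius 1.4 Å and 960 points per atom by
default; atomic radii C 1.7, N 1.55, O 1.52, S 1.8, H 1.2, P 1.8 Å,
overridable per element. A point is accessible when outside every
neighbour's probe-expanded sphere; boundary points count as accessible,
and exactly coincident equal spheres are resolved by letting the
lower-index atom own the surface, so duplicated atoms do not double the
area. Only atoms present in the structure occlude — chain-alone SASA is
computed on the subsetted structure.

**Dihedrals and the fixture builder.** φ/ψ/ω follow the IUPAC sign
convention (validated against an independent torsion implementation);
termini and chain gaps (peptide C–N distance > 1.8 Å) yield absent values,
never interpolation. `build_backbone_from_dihedrals()` extends a chain
with ideal bond lengths/angles via natural-extension (NeRF) placement;
the L-configuration is selected by the +122.6° N–C–Cα–Cβ improper. Because
each torsion is placed directly, rebuilding and remeasuring reproduces the
inputs to well under 1°, which is what makes the builder a trustworthy
oracle for the turn and RMSD tests.

**Turn classification.** A four-residue window is a β-turn when
Cα(i)–Cα(i+3) < 7 Å and its two inner residues are not both helical
(φ ∈ (−100, −30), ψ ∈ (−70, −25)) — the helix exclusion applied to the
inner residues keeps helix termini, whose flanking residues have undefined
angles, from being read as turns. Inner (φ, ψ) pairs are matched against
the canonical table (types I, I′, II, II′ and the cis-proline types VIa1,
VIa2, VIb) within ±30°, one angle allowed up to 45°. A cis peptide bond at
i+2 (|ω| < 30°) restricts candidates to the type VI classes; this gate is
load-bearing: inner dihedrals near (−50, −51, −62, −20) lie within
tolerance of type I for a trans bond, and it is the cis-proline that
forces the no-canonical-match type IV outcome. γ-turns use a 3-residue
window (Cα span < 6 Å — the classic γ geometry spans ~5.5 Å — plus the
stabilizing i→i+2 N–O hydrogen bond < 3.5 Å), α-turns a 5-residue window
(Cα span < 6.5 Å, neither flank continuing a helix). Windows matching the
canonical γ (75, −64) / inverse-γ (−79, 69) or α (−60, −30)³ angles are
labelled γ/α; windows passing the gates without a canonical match are
pseudo-γ / pseudo-α. The pseudo gates are implementation definitions — the
source analyses name such turns without defining criteria — and γ windows
nested inside reported β-turns are suppressed. Overlapping windows of
different lengths may all be reported.

**Polar contacts.** A salt bridge is the minimal
Asp/Glu-carboxylate-O-to-Arg/Lys/His-side-chain-N distance under 4.0 Å per
residue pair; hydrogen bonds are heavy-atom N/O–N/O distances under 3.5 Å
(no angle term, because the distances being compared are reported bare;
an angle filter would be an opt-in refinement). Intra-residue and
sequence-adjacent backbone pairs are excluded as covalent context, and
records are canonically ordered so the output is invariant under chain
relabeling.

## 6. Trajectory fixtures

`perturb_structure()` builds multi-frame test trajectories as a fixed
rigid transform of a structure plus isotropic Gaussian coordinate noise;
frame 1 is noise-free, so rigid-motion invariance of superposed RMSD can
be asserted exactly, and the mean superposed RMSD of noisy frames is
checked against a Monte-Carlo reference computed independently in the
tests. These fixtures probe the metrics, not molecular dynamics: there is
no force field, integrator, or solvent anywhere in the package —
trajectory *analysis* consumes coordinates from wherever they came.

## 7. Problem sizes and determinism

The test-suite and acceptance problem sizes — 20 replicate histories of 30
nodes, ~1000-pair calibration tables, 100 Kabsch instances against 10,000
random rotations, 960-point SASA quadrature — were chosen so each
statistical check has real resolving power while the whole suite stays
interactive (tens of seconds). Every stochastic step takes an explicit
seed; identical configuration and seed give byte-identical JSON/TSV
outputs, and every written artifact embeds the package version and a
configuration fingerprint.

## 8. Known limitations

* The caller assumes approximately log-normal, independent replicates;
  heavy-tailed or correlated assay noise will inflate the effective
  false-positive rate beyond the nominal α.
* Rate estimates are net counts over an interval: gained-then-lost edges
  are invisible, so rates are mildly underestimated when `rate × Δt` is
  not small.
* Ortholog maps are inputs; the package never infers orthology from
  sequence.
* Turn "pseudo" classes and the γ/α gates are package definitions and
  should not be compared directly against other software's turn
  inventories.
* SASA treats all atoms as present-and-rigid; missing side chains simply
  do not occlude.
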