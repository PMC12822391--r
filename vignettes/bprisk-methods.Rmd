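---
title: "Models and methods behind bprisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bprisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bprisk)
```

`bprisk` analyses the interaction of bisphenol analogs with the
progesterone-receptor ligand-binding domain (PR-LBD) through a chain of
small, well-defined models, and integrates the results into a single risk
ranking. This vignette explains each model, its assumptions, the tunable
parameters, and the design decisions taken where more than one reasonable
convention exists.

## Fluorescence quenching and binding

A titration series is a set of emission spectra (300–400 nm) of one
protein–ligand pair at increasing ligand concentration, sharing one
temperature; exactly one spectrum is the zero-ligand (F₀) scan. Intrinsic
tryptophan fluorescence of the untreated receptor peaks near 335 nm.

**Observation wavelength.** Downstream fits read intensities at the
*control* spectrum's emission maximum (fixed wavelength), because the
Stern–Volmer model assumes a fixed observation channel. A
`"per-spectrum-max"` mode is retained for dose–response style plots; for
unshifted spectra the two coincide. Spectral shifts are classified against
a 2 nm threshold — small enough to flag a genuine 9 nm displacement,
large enough to ignore grid-resolution jitter; any threshold strictly
between 0 and 9 nm gives the same labels on the bundled systems.

**Stern–Volmer.** F₀/F = 1 + K_sv[Q] has no free intercept, so K_sv is the
through-origin least-squares slope of (F₀/F − 1) on [Q]; a free-intercept
fit is attached as a diagnostic only. The bimolecular quenching rate
constant is k_q = K_sv/τ₀ with τ₀ = 10⁻⁸ s, the canonical unquenched
biopolymer fluorescence lifetime (configurable). Quenching is called
*static* when k_q exceeds the diffusion-controlled ceiling
2×10¹⁰ L mol⁻¹ s⁻¹ at both temperatures *and* K_sv falls as temperature
rises (complexes destabilize on heating); *dynamic* on the mirrored
pattern; *indeterminate* otherwise, with both criteria reported so the
caller can see which one failed.

**Binding constants.** For quenching-type series the double-log fit
log₁₀((F₀−F)/F) = log₁₀K_a + n·log₁₀[Q] gives K_a (base-invariant) and the
apparent site count n (base-dependent; base 10 is recorded in the output).
For enhancement-type series the saturation relation
(F∞−F₀)/(Fx−F₀) = 1 + 1/(K_a[Q]) is linearized as
1/(Fx−F₀) = a + b/[Q], whence K_a = a/b and F∞ = F₀ + 1/a. Model selection
is by the strict monotone trend of the series; mixed series are rejected
rather than silently fitted. Association constants between 10⁴ and
10⁶ L mol⁻¹ (inclusive) are flagged as the biologically relevant window
for competing with endogenous ligand; the check is strict, so
0.98×10⁴ falls outside — callers studying borderline systems can lower
the bound.

**Noise sensitivity (a known limitation).** Both binding-constant
estimators work in transformed coordinates and amplify intensity noise
substantially. In the double-reciprocal fit, the smallest increment
Fx − F₀ carries the largest 1/[Q] lever arm, so 2 % multiplicative
intensity noise becomes tens of percent of error in K_a (the test suite
quantifies this; recovery is within 5 % at 0.1 % noise). The double-log
K_a = 10^intercept extrapolates several decades below the measured
concentration range and is even more sensitive. K_sv, by contrast, is
robust (median error a few percent at 2 % noise). The estimators are kept
in their conventional linearized forms — they are the field's standard
and are exactly reproducible from published constants — rather than
replaced by weighted or nonlinear variants, which our simulations showed
do not rescue the enhancement fit at realistic noise anyway.

## Binding thermodynamics

With constants at two temperatures (298 and 310 K in the bundled data),
the enthalpy is the exact two-point van't Hoff solution
ΔH = R·ln(k₂/k₁)/(1/T₁ − 1/T₂) — with only two temperatures a regression
would be overparameterized. ΔG = −RT·ln K_a at each temperature and
ΔS = (ΔH − ΔG)/T, the Gibbs–Helmholtz rearrangement, reported at the lower
temperature (both temperatures agree to the third decimal for the bundled
systems). R = 8.314 J mol⁻¹ K⁻¹, configurable. Systems with a constant at
only one temperature get ΔG only; ΔH/ΔS stay `NA` rather than being
imputed.

Force classes follow the Ross–Subramanian sign rules: ΔH > 0, ΔS > 0 →
hydrophobic; ΔH < 0, ΔS < 0 → van der Waals + hydrogen bonding;
ΔH < 0, ΔS > 0 → electrostatic. Components within 10⁻⁶ of zero — and the
thermodynamically unfavourable ΔH > 0, ΔS < 0 pattern — map to `mixed`.
Note the electrostatic label for systems like BPAF is rule-derived; the
underlying study only discusses the two patterns it observed.

Units: this module works in kJ/mol throughout; the docking/MM/GBSA module
keeps kcal/mol (its field's convention) and the two are never mixed.

## CETSA melt curves

Soluble-band intensities are normalized to the lowest-temperature band
(first point = 1) — the usual densitometry convention, and idempotent.
The descending sigmoid

f(T) = bottom + (top − bottom) / (1 + exp((T − Tm50)/slope))

is fitted by bounded Levenberg–Marquardt (`minpack.lm::nls.lm`), with
top/bottom free in [−0.2, 1.5] because densitometry rarely reaches exactly
0 or 1, slope in [0.01, 20] °C, and Tm50 constrained to the measured
range. Initialization: top = max, bottom = min, Tm50 = the temperature
nearest the half-range, slope = 1 °C. Tm50 is the sigmoid midpoint — the
temperature at which half of the initially soluble protein has
precipitated; the linearly interpolated 50 %-of-range crossing is reported
alongside for comparison, and agrees on clean curves. Curves that do not
decline from first to last point are rejected ("no melt transition")
rather than fitted. ΔTm50 = treated − control, positive meaning
ligand-induced stabilization; it is antisymmetric by construction. The
standard seven-point gradient 43.5–54.0 °C is the default simulation and
test grid.

The single-temperature (46 °C) comparison used for tissue samples is a
plain treated/control band ratio.

## Table validation and the biomarker screen

MM/GBSA rows must satisfy component additivity within 0.01 kcal/mol (with
a 10⁻⁹ slack so values printed exactly at tolerance are not rejected by
floating-point representation); CD secondary-structure rows must sum to
100 % within 0.5 (0.1 for the bundled table, which meets it). Rankings
place the most negative energy first, with deterministic lexicographic
tie-breaks, so repeated runs and permuted inputs agree.

The DEG screen applies |log2FC| > 1 and p < 0.05, both strictly — a gene
at exactly log2FC = 1 is excluded. Malformed p-values (≤ 0 or > 1) are
dropped with a warning count instead of poisoning the set. Gene symbols
are matched case-sensitively with no alias resolution: the screen operates
on symbol lists as given, and alias handling would silently change set
intersections. The screen is the intersection of every per-condition pass
set with the disease list.

## ToxPi integration

Each metric is first *oriented* so larger = higher concern: docking scores
and binding free energies are negated (more negative binding = stronger =
more concerning), structural fractions are replaced by |value − control|
(perturbation in either direction is the signal), and assay fold-changes
pass through unchanged. Orientation is declared per metric in the config,
never inferred from the data. Metrics are then min–max scaled to [0,1]
across chemicals (the ToxPi convention for "making data uniform"; an
x/max alternative sits behind a flag), slice scores are the arithmetic
mean of each class's scaled metrics, and the overall score is the
weighted sum of slices — 20 % per class for the packaged five-class
layout. Two degenerate cases are defined rather than fatal: a constant
metric scales to 0 for every chemical (it shows no variation, so it
contributes nothing while keeping the 13-metric layout intact), and a
missing value scales to 0 (the ToxPi missing-data convention; this is how
the one system lacking a 298 K ΔG enters the chemical-analysis slice).

Scores are invariant to positive affine transforms of any raw metric, lie
in [0,1], and improving a chemical on any metric never lowers its overall
score; the test suite checks all three properties. Ties in the final
ranking break lexicographically.

**Provenance of the packaged table.** Of the 13 × 6 cells, the docking,
MM/GBSA, ΔG(298 K) and CD-fraction columns and a minority of the assay
cells come from printed values; the remaining assay and ΔTm50 cells are
figure-read estimates, flagged `figure_estimate_synthetic` in the
companion provenance table. Consequently only "BPAF ranks first" is
asserted as a hard outcome in the tests; the full six-way order is
computed and reported but treated as soft.

## The synthetic-data generators

Generators exist so that every estimator can be validated by round-trip
against known truth. They emulate:

- single-Gaussian emission bands (25 nm width) whose peak follows the
  static-quenching law F₀/(1 + K_sv[Q]) or the enhancement saturation law,
  over the 0, 1, 5, 10, 15, 20 µM titration ladder;
- multiplicative Gaussian intensity noise truncated at zero, because
  fluorescence shot/instrument noise scales with signal;
- descending sigmoidal melt curves with planted midpoints on the
  seven-point CETSA gradient;
- DEG tables in which planted genes pass both strict criteria in every
  condition and appear in the disease list, while every background gene is
  forced to fail at least one criterion in at least one condition — so the
  screen provably returns exactly the planted set;
- metric tables with an optional strictly dominant chemical.

They do *not* emulate spectral asymmetry, baseline drift, inner-filter
effects, correlated replicate structure (titrations default to a single
scan), blot saturation, or probe-to-gene mapping ambiguity. Passing
round-trip tests therefore demonstrates estimator correctness, not
robustness to those real-data artifacts.

All generators scope their RNG with `withr::with_seed`, so a fixed seed
gives byte-identical output without disturbing the caller's RNG state.

## Problem sizes and numerical choices

Recovery studies use 200 seeds (enough for a stable median at the noise
levels studied) with 6-point titrations at 2 % noise and 7-point melt
curves at 3 % noise; DEG fixtures use a 400-gene universe over five
conditions. Noiseless round-trips are asserted to 10⁻⁶ relative for
K_sv and K_a and for planted melt midpoints. Monotonicity tie detection
uses a 10⁻⁶ relative tolerance; force-class zero detection likewise.
Melt fits failing to converge, non-declining melt curves, mixed titration
trends, enhancement fits with non-positive double-reciprocal coefficients,
and series violating F < F₀ (or Fx > F₀) preconditions all raise errors
with messages naming the violated assumption — noisy data can legitimately
trigger them, and callers (and the recovery studies) treat such series as
invalid rather than forcing a fit.

## Known limitations

- Published ΔTm50 values for the bisphenol series derive from unpublished
  densitometry, so they are simulation targets (planted and recovered)
  rather than recomputation targets.
- The enhancement and double-log K_a estimators are noise-amplifying, as
  quantified above; confidence intervals are not provided and would be
  wide at realistic noise.
- The ToxPi fixture's figure-read cells bound what its full ranking can
  claim (see provenance discussion).
- Multi-temperature (> 2) van't Hoff regression and heat-capacity terms
  are out of scope; with data at exactly two temperatures the two-point
  solution is the complete answer.
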