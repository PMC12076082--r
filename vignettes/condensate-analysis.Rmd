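---
title: "Methods: condensate phase-behaviour analysis in condensatr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: condensate phase-behaviour analysis in condensatr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`condensatr` implements the computational side of characterising
liquid-liquid phase separation (LLPS) in engineered LCD2-CTPR proteins:
intrinsically disordered low-complexity domains (LCD2) fused to the N- and
C-termini of a folded consensus tetratricopeptide repeat (CTPR) scaffold,
optionally carrying LC3-interacting (LIR) loops between repeats. This
vignette records the models, the assumptions behind them, the synthetic
data used to validate them, and the numerical decisions a maintainer
should know about.

```{r setup}
library(condensatr)
```

## Construct representation

A construct is an ordered list of segments (`LCD2_N`, `REPEAT`,
`SOLVATING_HELIX`, `LIR_LINKER`, `TC_LOOP`, `OTHER_LOOP`, `LCD2_C`), each
a contiguous amino-acid stretch. Residue indexing is 1-based inclusive
everywhere; any half-open conversion is internal. Only `REPEAT` and
`SOLVATING_HELIX` are flagged rigid — these are the folded helical
elements held rigid in coarse-grained simulation, while LCDs and loops
are flexible.

`lcd2_ctpr_spec()` ships the six named variants. Their segment
architectures reproduce the published domain boundaries exactly (LCD2
termini at 1–173 and 267–334 / 301–369 / 320–388 / 337–409 / 339–411 for
CTPR2 / CTPR3 and R-CTPR3 / CTPR4 / CTPR4-FUNDC1 / CTPR4-ATG13; LIR
linkers at 282–306 and 282–308), but the sequences are synthetic
placeholders of the correct lengths, built from the TPR consensus repeat
and LCD-like filler. The full published sequences were not available to
this package; nothing downstream depends on sequence identity beyond
residue masses and domain labels, and the placeholder masses are within a
few percent of any realistic sequence. Repeat boundaries within the CTPR
block follow the 34-residue helix-turn-helix register declared in the
construct definition; the lysine-to-arginine surface variant
(`LCD2-R-CTPR3`) is an ordinary sequence difference, not a special type,
because no analysis step branches on it.

`coarse_grain()` maps an atomistic structure to one bead per residue at
the alpha-carbon position and carries the rigidity flags. It refuses
structures with missing alpha carbons (naming the residue) or mismatched
sequences.

## Synthetic slab configurations

`gen_slab_trajectory()` emulates the *geometry* of an equilibrated
direct-coexistence simulation: a dense slab centred in an elongated
periodic box, dilute surroundings, and frames that are independent
configurations. Molecules are rendered as compact bead clouds — flexible
segments as isotropic Gaussians (default spread 8 Å) around the molecule
centre, rigid repeat blocks as straight rods with the 3.8 Å
alpha-carbon spacing in random orientations. The default system size is
140 molecules, matching the direct-coexistence system size this
generator stands in for.

What it does **not** emulate: force fields, dynamics, conformational
statistics, interfacial fluctuations, or finite-size capillary waves.
Passing tests therefore demonstrate that the *analysis* stages recover
densities and critical parameters from configurations with known density
structure; they say nothing about the physical accuracy of any
simulation model.

The slab half-width is not a free choice: given the box, molecule count
and the two target densities, mass balance fixes
`V_slab = (M_total − rho_l V) / (rho_h − rho_l)`. The generator derives
the half-width from this relation (an explicitly supplied half-width is
validated against it within 5%) and errors with the maximum achievable
density when the requested pair is infeasible — the box-average density
must lie strictly between `rho_l` and `rho_h`.

Densities are mass densities in mg/mL throughout, converted from
Da/Å³ by the factor 1660.54; per-residue masses are the standard average
residue masses summed over the sequence. Density-profile plateaus of
generated slabs match the requested values within the molecule-counting
noise of the configuration (a few percent at 140 molecules and ~10
retained frames).

## Density profiles and coexisting densities

`density_profile()` discards a configurable initial fraction of frames
(default 0.5, mirroring the usual discard of the equilibration period),
recentres each remaining frame so the mass-weighted circular mean of z
sits at the box centre, bins bead masses (default bin width 10 Å,
capped at box-z/10), and averages. Binning conserves total mass exactly
per frame; this is asserted in the tests at 1e-9 relative.

`coexisting_densities()` fits the symmetric tanh interface profile and
returns the two plateau densities. Initial values come from the top and
bottom deciles of the profile and the half-maximum crossing; the
Levenberg–Marquardt fit (`minpack.lm`) is bounded below at zero density.
If the fit fails, a plateau-average fallback is used (bins above 75% /
below 25% of the contrast band). A *one-phase verdict* is returned when
the relative contrast `(rho_h − rho_l)/rho_h` falls below a configurable
threshold, default 0.1 — the threshold is a package choice; no universal
criterion exists for "two phases detected".

## Critical-point fitting

Two coexistence laws link the phase densities to the critical point: the
law of coexisting densities
`(rho_h − rho_l)^3.06 = d (1 − T/T_c)` with the 3D-Ising exponent 3.06
(overridable), and the law of rectilinear diameters
`rho_h + rho_l = 2 rho_c + 2 A (T − T_c)`.

`fit_binodal()` fits them sequentially: the first law is *linear* in
`(d, d/T_c)` once written as `(rho_h − rho_l)^3.06` versus `T`, so stage
1 is an exact ordinary-least-squares solve — deterministic, no starting
values, and exact on noiseless input; stage 2 fits `(rho_c, A)` by OLS
with `T_c` fixed. Whether the two laws should be fitted jointly is
genuinely open; sequential was chosen as the default because it is
deterministic and exactly invertible against the generator, and a joint
Nelder–Mead refinement (initialised from the sequential solution) is
available via `method = "joint"`. Standard errors come from the linear
covariances (delta method for `T_c = −a/b`); the fit refuses fewer than
3 distinct temperatures, non-decreasing density gaps, or a fitted `T_c`
not exceeding the largest fitted temperature.

`normalised_binodal()` rescales temperature by a reference critical
temperature (e.g. a reference variant's `T_c`) for cross-variant
comparison; being a positive linear map it preserves the ordering of
critical temperatures.

The end-to-end check generates slabs at six temperatures from a planted
binodal (`T_c` = 357 K, `rho_c` = 170 mg/mL, `d` = 3e8, `A` = −0.3 —
chosen once as a physically sensible condensate binodal whose dilute
branch stays feasible in a 150 × 150 × 4000 Å box at 140 molecules) and
requires the pipeline to return `T_c` within 3%. Eight frames per
temperature keep the test inside a half-minute budget.

## Contacts and molecular valency

A contact is an **unordered** pair of beads on **different** molecules at
minimum-image distance **strictly below** the cutoff (default 7 Å, per
the "smaller than 7 Å" convention; whether the original analysis used
strict or non-strict comparison is unknowable from the text, so the
quoted wording is implemented). Unordered counting keeps the
domain-pair percentage table symmetric; an ordered mode (each contact
counted from both domains' perspectives) is available for comparison.

The cell-list search is exact — property tests assert identity with an
all-pairs brute-force oracle on random periodic frames up to 500 beads —
and errors when the cutoff reaches half the smallest box length, where
the minimum-image convention breaks.

`domain_contact_fractions()` averages raw per-frame counts first and
normalises once (not per-frame percentages averaged), reporting the
standard error of per-frame percentages across frames. Repeats are
pooled into one `REPEAT` category in the summary.

`molecular_valency()` scores, per frame, each molecule whose centre of
mass (circular mean along z, so boundary-straddling molecules are
handled) lies in a caller-supplied bulk z-interval, counting distinct
contact partners anywhere in the box. The dense-phase interval is the
caller's choice — the tanh-fitted slab half-width around the slab centre
is the natural input — because "protein bulk" has no unique definition.
Valency is monotone non-decreasing in the cutoff (property-tested).

## C_sat fitting

The sedimentation assay yields dilute-phase concentration `y` versus
total concentration `x`; below saturation `y` tracks `m x` (the slope
`m` is left free — it is an arbitrary gradient absorbing assay scaling),
above it `y` plateaus at the saturation concentration `c`. The model
`y = if (m x < c, m x, c)` is continuous at the breakpoint `x* = c/m` by
construction. For fixed `x*` the least-squares slope has a closed form,
so `fit_csat()` profiles the breakpoint over the observed x-values and
refines between the bracketing candidates with `optimize()` at ~1e-10 of
the data range — deterministic, no random starts, exact on noiseless
series (verified to 1e-6 relative over a grid of `(m, c)`), and
scale-equivariant. Degenerate series — no points above the fitted
breakpoint (no plateau) or none below (no linear regime) — are refused
rather than extrapolated. The uncertainty on `c` comes from the
piecewise-linear Jacobian; because published ± values are replicate
spreads, `csat_replicates()` additionally reports mean ± sd across
series.

Gel calibrations (`fit_calibration()`) use a free intercept by default —
the intercept absorbs background band signal — with a through-origin
option.

The dye equations are evaluated literally with their published constants
as defaults: FlAsH correction factor 0.27, ROX correction factor 0.49,
ROX extinction 93 000 M⁻¹cm⁻¹. Negative concentrations
(over-subtraction) and efficiencies above 100% are flagged with
warnings, not errors, since both occur in practice with mis-estimated
extinction coefficients.

## PhaseScan probability maps and boundaries

Droplet barcodes map to compositions through the fixed stock ratio:
`[urea] = 3 M × signal`, `[NaCl] = 1 M × signal`. Because the two
solutes co-vary by construction, the analysis collapses them onto one
dilution coordinate; plots may label either unit.

`probability_map()` min-max normalises the protein and dilution axes to
[0, 1] (which makes the map invariant under affine rescaling of either
axis), then assigns each droplet and each node of a 60 × 60 grid the mean
phase class over droplets within a Euclidean radius — default 5% of the
normalised data range, exposed in configuration since the neighbourhood
percentage is a free parameter of the method. The protein axis is
normalised linearly by default; the scale of the protein axis is not
prescribed by the method, and a log option can be applied upstream. In
the large-radius limit every probability collapses to the global class
mean (tested).

`fit_boundary()` selects grid nodes with `|p − 0.5| ≤ 0.05` (the band
half-width is configurable) and fits a total-least-squares line (first
principal component) through them, reporting normalised and
physical-unit parameters; near-vertical level sets are reported as a
constant protein concentration. Nodes within one neighbourhood radius of
the window edge are excluded when enough interior nodes exist: truncated
neighbourhoods bias the estimated probability and visibly bend the level
set near the border. A straight-line boundary is the default model; the
synthetic recovery tests use a 5000-droplet logistic scan (decision
width 0.02) and recover the planted line to within 2% at the canonical
seed. The band-selection estimator's sampling error is of the same order
as that tolerance — the probability field's droplet-sampling noise is
spatially correlated over the neighbourhood radius, which limits how
much averaging the level-set extraction can do — so recovery at the 2%
level should be read as typical rather than guaranteed for arbitrary
seeds; larger radii do not help (the level-set gradient flattens
proportionally).

## Imaging

`triangle_threshold()` implements the Triangle method on a 256-bin
equal-width histogram over the observed intensity range (the binning is a
package choice; the method itself only prescribes the peak-to-tail
geometric construction). The line runs from the histogram peak to the
farthest non-empty tail bin; the threshold is the bin centre maximising
perpendicular distance. Constant images are refused. The implementation
is property-tested against an independently written exhaustive per-bin
distance search and mirrors correctly under intensity inversion.

`segment_condensates()` thresholds, labels 8-connected components
(8-connectivity matches the defaults of the standard particle-analysis
workflow), and removes components below 0.5 μm²; no circularity
criterion is applied, preserving irregular condensates.
`partition_coefficient()` divides the mean intensity inside the mask by
the mean over *all* non-mask pixels — the full-image complement, not an
annulus — matching the "surrounding dilute phase" convention; an annulus
can be emulated by masking upstream. No background subtraction is
applied by default since none is part of the described workflow. Empty
or full masks give a flagged undefined result which
`partition_summary()` excludes from the replicate mean ± sd.
`colocalisation()` applies the green-derived (scaffold) mask to the red
(client) channel, so an unrecruited client reads ~1 by construction.
`compare_partition()` wraps a one-way ANOVA over replicate tables for
cross-variant comparison — reporting convenience, not a
condensate-specific algorithm.

The image generator plants ideal disks with additive Gaussian noise; it
does not emulate point-spread blur, shot noise, uneven illumination or
out-of-focus condensates, so imaging tests validate the mask/ratio
arithmetic, not robustness to real microscopy artefacts.

## Problem sizes and determinism

All generators are pure functions of their parameter records (including
the seed): reruns are bit-identical and the caller's RNG stream is left
untouched. The test suite uses desk-scale problems chosen to exercise
each stage meaningfully: 140-molecule slabs (~54 000 beads per frame for
the four-repeat construct) at 6 temperatures for the end-to-end critical
temperature recovery; ≤500-bead frames for the brute-force contact
equivalence; 5000-droplet scans for boundary recovery; 12-point dilution
series; 128×128–200×200 px images. The full suite runs in well under a
minute.

## Known limitations

- Placeholder sequences: domain boundaries and lengths are exact, but
  sequence-dependent quantities (exact molecular masses) differ slightly
  from the real constructs.
- The slab generator produces independent frames; autocorrelation-aware
  error estimation cannot be exercised against it.
- Boundary extraction assumes a boundary crossing the scanned window and
  a monotone probability field near it; closed or re-entrant phase
  boundaries need the (non-default) spline option or manual windowing.
- `fit_binodal()` trusts the 3.06 exponent; fitting the exponent itself
  is deliberately unsupported (it is not identifiable from a handful of
  temperatures).
- No free-energy, surface-tension, viscosity, or finite-size
  extrapolation; no droplet detection from raw microfluidic video; no
  gel densitometry (band densities are inputs).
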