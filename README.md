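# condensatr

Analysis toolkit for engineered protein condensates — an R package for the
computational characterisation of liquid-liquid phase separation (LLPS) in
proteins built from low-complexity domains (LCDs) fused to consensus
tetratricopeptide repeat (CTPR) scaffolds, and for the assays used to map
their phase behaviour.

It is aimed at groups who run coarse-grained direct-coexistence ("slab")
simulations and wet-lab condensate assays and want one tested pipeline for
the downstream numbers: critical temperatures from binodals, contact and
valency statistics from trajectories, saturation concentrations from
sedimentation gels, phase boundaries from droplet microfluidics, and
partition coefficients from fluorescence images. Every stage ships with a
synthetic-data generator with known ground truth, so the whole pipeline is
testable end to end without cluster-scale simulations or wet-lab data.

## What it computes

**Slab analysis.** From a trajectory of bead coordinates in an elongated
periodic box, `density_profile()` bins mass along z (recentring the slab
via a periodic centre of mass), `coexisting_densities()` extracts the
dilute- and dense-phase densities with a symmetric interface fit

    rho(z) = (rho_h + rho_l)/2 - (rho_h - rho_l)/2 * tanh((|z - z0| - w)/delta)

and `fit_binodal()` estimates the critical point from the law of
coexisting densities and the law of rectilinear diameters,

    (rho_h(T) - rho_l(T))^3.06 = d (1 - T/T_c)
    rho_h(T) + rho_l(T)        = 2 rho_c + 2 A (T - T_c)

with 3.06 the Ising critical exponent. Stage 1 is an exact linear
least-squares fit of the first law (linear in `d` and `d/T_c`); stage 2
fits `rho_c` and `A` with `T_c` fixed; a joint nonlinear refinement is
optional.

**Contacts and valency.** `contact_pairs()` finds intermolecular bead
pairs at minimum-image distance strictly below 7 Å (cell-list search,
verified against brute force), `domain_contact_fractions()` turns them
into the percentage of contacts between domain classes (LCD2 N/C termini,
repeats, LIR linkers), and `molecular_valency()` counts how many distinct
molecules each molecule in the protein bulk touches.

**C_sat assay.** `fit_calibration()` converts gel-band densities to
concentrations; `fit_csat()` fits the piecewise saturation model
`y = if (m x < c, m x, c)` by profiled breakpoint search, recovering the
saturation concentration `c` exactly on noiseless data.
`protein_conc_flash()`, `protein_conc_rox()` and `labelling_efficiency()`
implement the dye-corrected absorbance equations (correction factors 0.27
for FlAsH, 0.49 for ROX, dye extinction 93 000 M⁻¹cm⁻¹).

**PhaseScan.** `barcode_to_composition()` maps the normalised droplet
barcode to co-varied urea/NaCl (3 M : 1 M stocks),
`probability_map()` averages droplet phase classes over a configurable
neighbourhood in normalised composition space, and `fit_boundary()`
extracts the 0.5-probability phase boundary by total least squares.

**Imaging.** `triangle_threshold()` (Triangle method over a 256-bin
histogram), `segment_condensates()` (8-connected components, minimum area
0.5 μm², no circularity filter), `partition_coefficient()` (mean in-mask /
mean out-of-mask intensity) and `colocalisation()` (green-derived mask
applied to the red client channel).

**Constructs.** `assemble_construct()`, `annotate_regions()` and
`coarse_grain()` represent LCD2-CTPR variants as ordered segments with
per-residue domain labels and map atomistic structures onto
one-bead-per-residue chains (alpha-carbon positions, rigid repeats).
`lcd2_ctpr_spec()` provides the six named variants with published domain
boundaries and synthetic placeholder sequences of the published lengths.

## Worked example

Fit a binodal from six coexistence points and recover the critical point:

```r
library(condensatr)
pts <- gen_binodal_points(346, 300, 1e7, -0.5, seq(295, 342, length.out = 6))
fit_binodal(pts)
#> binodal_fit (sequential): T_c = 346 +/- 4.18e-14 K, rho_c = 300 +/- 5.07e-14 mg/mL
#>   d = 1e+07, A = -0.5, exponent = 3.06
```

The generator plants a binodal with critical temperature 346 K and
critical density 300 mg/mL; the two-stage fit returns both exactly
(noiseless input, hence the vanishing standard errors).

Fit a saturation concentration from a noisy synthetic dilution series:

```r
x <- seq(0.05, 5, length.out = 12)
g <- gen_csat_series(csat_gen_params(m = 1, c = 0.48, x_grid = x,
                                     noise_sd = 0.05, seed = 7))
fit_csat(g$series$x, g$series$y)
#> csat_fit: C_sat = 0.484 +/- 0.0093 uM (slope m = 1.114, breakpoint 0.4343 uM)
```

With 5% multiplicative noise on a 12-point series the planted plateau of
0.48 μM comes back as 0.484 ± 0.009 μM.

Measure scaffold and client partitioning in a synthetic two-channel image:

```r
img <- gen_condensate_image(image_gen_params(
  centres = rbind(c(4, 4), c(9, 9)), radii = c(2, 1),
  intensity_in = 500, intensity_bg = 100, red_in = 300, red_bg = 100,
  noise_sd = 10, seed = 3))
cl <- colocalisation(img)
cl$green
#> partition coefficient: 4.996 (in 499.4 / out 99.95)
cl$red
#> partition coefficient: 3.003 (in 300.1 / out 99.96)
```

The planted 5x scaffold and 3x client enrichment are recovered from the
Triangle-threshold mask.

## Documentation

The methods vignette (`vignettes/condensate-analysis.Rmd`) describes the
models, the synthetic-data generators and what they do and do not emulate,
the numerical choices, and known limitations. Every exported function has
roxygen documentation with examples.
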