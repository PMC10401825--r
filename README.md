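# lungstrain

Quantitative analysis of dynamic (respiratory-gated) lung CT for studies of
mechanical ventilation: whole-lung and regional aeration, voxel-level tidal
volumetric strain from deformable registration, tidal recruitment, vertical
(gravitational) distributions, and maximal-compliance PEEP selection from
decremental-trial respiratory mechanics. It is aimed at researchers in
ventilator-induced lung injury and PEEP individualization who work with
paired end-expiratory (EE) / end-inspiratory (EI) CT volumes of injured
(e.g. surfactant-depleted, partly atelectatic) lungs.

## What it computes

- **Aeration**: voxel gas fraction `F_gas = HU / -1000`; aeration
  categories (non `< 0.1`, poor `0.1-0.5`, normal `0.5-0.9`, hyper
  `>= 0.9`) as fractions of lung mass; end-expiratory lung volume;
  spatial heterogeneity as the coefficient of variation on an image
  filtered to 2.5 mm effective in-plane resolution.
- **Strain**: a multistage diffeomorphic B-spline-regularized registration
  (windowed local cross-correlation via local intensity standardization,
  knot schedule 26/13/6.5/3.25 mm) estimates the EE-to-EI displacement
  field; the Jacobian determinant `J = det(I + grad u)` is the local EI/EE
  volume ratio and volumetric strain is `s = J - 1`. Texture-free regions
  (atelectasis at soft-tissue density) are handled by harmonic infill, a
  mass-conservation (density-ratio) divergence correction, and global
  volume calibration against the EI segmentation.
- **Tidal recruitment**: `(M_non^EE - M_non^EI) / M^EE`, the fraction of
  lung mass leaving the non-aerated compartment over a breath; regional
  profiles over 10 iso-gravitational ROIs (ROI 1 most dorsal).
- **Joint structure**: strain medians/IQRs by EI-aeration interval and
  strain-colored parametric response maps (100 x 100 EE-vs-EI gas-fraction
  bins, 0.05% volume occupancy threshold).
- **Mechanics**: per-breath single-compartment equation-of-motion fits
  `P = V/C + R V' + P0` and maximal-compliance PEEP selection.
- **Statistics**: paired t-tests, Pearson/Spearman correlations, two-way
  (region x strategy) repeated-measures ANOVA.
- **Synthetic phantom**: a deformable lung phantom (ventral-dorsal
  aeration gradient, dorsal atelectasis, parenchymal texture, closed-form
  diffeomorphic warp with analytic Jacobian, mass-consistent density
  transport, optional tidal recruitment, HU noise) provides exact ground
  truth for every stage.

## Worked example

```r
library(lungstrain)

ph <- generate_phantom(phantom_spec())          # EE/EI pair + ground truth
fgas_ee <- hu_to_fgas(ph$ee$ct, ph$ee$mask)
fgas_ei <- hu_to_fgas(ph$ei$ct, ph$ei$mask)
ms_ee <- mass_summary(fgas_ee)
ms_ei <- mass_summary(fgas_ei)

reg <- register_pair(ph$ee$ct, ph$ei$ct, ph$ei$mask,
                     registration_config(), mask_ee = ph$ee$mask)
jm <- jacobian_map(reg$field, ph$ee$mask)
strain_summary(jm$strain)
```

Output of the full example script (about two minutes, single core):

```
EE mean aeration  0.420   (95th pct 0.680, CoV 0.454)
EELV              117 ml
mass percent      non 23.1 | poor 50.5 | normal 26.4 | hyper 0.00
tidal recruitment 0.0007 of lung mass
mean strain       0.130   (95th pct 0.308)
median |strain error| vs ground truth: 0.037
```

Reading: the phantom's end-expiratory lung is 42% gas on average with about
a quarter of its mass non-aerated (the dorsal atelectatic slab) and no
hyperinflation; its 117 ml of end-expiratory gas expand over the breath
with a mean voxel-level volumetric strain of 0.13 (95th percentile 0.31),
and essentially no tidal recruitment, as specified. The registration-based
strain field agrees with the phantom's closed-form truth to a median
absolute error of 0.037 strain units.

The same functions run on real data read from NIfTI files
(`read_volume()`), or end-to-end via `run_case()` /
`compare_strategies()`, or from a shell through
`inst/cli/lungstrain.R` (subcommands `phantom`, `register`, `aeration`,
`recruitment`, `peeptrial`, `run`).

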