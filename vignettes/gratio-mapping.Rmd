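---
title: "Myelin-sensitive measures and aggregate g-ratio mapping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Myelin-sensitive measures and aggregate g-ratio mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gratiomap)
```

# The scientific problem

The aggregate g-ratio — the ratio of inner axonal radius to outer
myelinated-fiber radius, estimated per voxel as

$$ g = \sqrt{\frac{\mathrm{AVF}}{\mathrm{AVF} + \mathrm{MVF}}} $$

— combines a myelin volume fraction (MVF) with an axonal volume fraction
(AVF). Different MRI contrasts measure "myelin" through very different
physics, and the resulting g-ratio maps can disagree, most strongly in
pathological tissue such as multiple sclerosis lesions. This package
implements five MVF channels and the machinery to compare them:

1. **MWF by regularized NNLS** — voxelwise multi-exponential T2 spectrum
   fitting of multi-echo spin-echo data with extended-phase-graph (EPG)
   stimulated-echo correction, summarized by the short-T2 window.
2. **MWF by SPIJN** — the same data fit jointly across all voxels under a
   row-sparsity constraint that restricts the T2 distribution to a small
   set of relaxation times shared by all voxels.
3. **ihMTR** — the inhomogeneous magnetization transfer ratio,
   `(S+ + S- - S_dualA - S_dualB) / (2 M0)`, sensitive to the dipolar
   order of myelin lipids.
4. **MTsat** — per-excitation MT saturation from a T1-/PD-/MT-weighted
   spoiled-gradient-echo triple via the rational small-angle estimators.
5. **MTV** — macromolecular tissue volume `1 - PD/100` from
   reference-region-calibrated proton density.

The MWF channels are converted to MVF through the four-compartment
hydration model

$$ \mathrm{MVF} = \frac{\mathrm{MWF}\,\kappa_{nm}}
   {\mathrm{MWF}\,(\kappa_{nm}-\kappa_{my}) + \kappa_{my}},
   \qquad \kappa_{my} = 0.36,\; \kappa_{nm} = 0.86, $$

the MT channels through calibrated linear scalings
$\mathrm{MVF} = \alpha x$, and MTV is used directly. AVF comes from NODDI
signal fractions, $\mathrm{AVF} = (1-\mathrm{MVF}-\mathrm{NMVF})
(1-\nu_{iso})\,\nu_{ic}$, where the non-myelin macromolecular volume
fraction NMVF is zero in the primary model and nonzero in the extended
one.

Because the study data behind this design are not publicly available, the
package ships a synthetic brain-phantom cohort generator that emulates
every acquired contrast with known ground truth; the full pipeline is
exercised and graded on that cohort.

# Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| T2 grid | 40 log points, 10–2000 | ms | community standard for 3 T multi-echo spin-echo myelin water imaging |
| myelin window | T2 ≤ 40 | ms | places the 20 ms myelin water pool inside and the 80 ms intra/extracellular pool outside |
| `reg_factor` | 1.02 | – | chi-squared inflation of the regularized NNLS misfit; the standard smoothing criterion of the cited NNLS lineage |
| flip-angle grid | 90–180 in 5° steps | degrees | stimulated-echo correction; parabolic refinement between grid points |
| `t1_assumed` | 1000 | ms | damps stored longitudinal EPG states; MWF is insensitive to it at 8 ms echo spacing |
| `sparsity_weight` | 0.02 | – | SPIJN: maximal relative joint-misfit increase allowed when eliminating a global T2 component |
| `max_components` | 6 | – | SPIJN global support budget |
| `kappa_my`, `kappa_nm` | 0.36, 0.86 | – | MR-visible water ratios of the myelin and non-myelin compartments |
| `g_target` | 0.7 | – | healthy-cohort splenium g-ratio used to calibrate the linear MT scalings |
| PD reference | CSF = 100 % (or WM = 69 %) | % | reference-region proton-density calibration |
| `noise_sigma` | 0.005 | – | relative noise SD (first-echo SNR 200), chosen so recovery tests are meaningful; no SNR is stated for the source protocol |

# The synthetic cohort

`cohort_spec()` + `build_phantom()` generate an ellipsoidal brain with CSF
ventricles, a cortical gray-matter shell, white matter with a smooth
myelin heterogeneity field (`wm_mvf_mean` 0.30 ± per-subject jitter), a
midline corpus-callosum slab whose posterior third serves as the splenium
calibration region, corona-radiata and internal-capsule style WM
sub-regions, and — for patients — spherical lesions with one-voxel
sigmoid edges, each demyelinated by its own factor drawn from
[0.2, 0.9]. Forward simulators produce:

* a 48-echo spin-echo series at 8 ms spacing via the EPG model with three
  water pools (myelin 20 ms, intra/extracellular 80 ms, free water
  2000 ms) and Rician noise (complex Gaussian, magnitude taken);
* the four MT-weighted volumes plus reference, constructed so the
  noiseless ihMTR equals `forward_slope * mvf_true` exactly;
* the gradient-echo triple following the small-angle rational signal
  model, with `delta_true = mtsat_slope * (mvf_true + nmvf_true)`;
* NODDI fractions as truth plus clipped Gaussian noise.

With the default `nmvf_lesion = 0` every channel encodes `mvf_true`
exactly, which is what makes the five-method identity test possible: all
five g maps agree to 1e-6 on the noiseless phantom. With
`nmvf_lesion > 0` the MT-saturation and MTV channels see the elevated
non-myelin macromolecular pool in lesions while the MWF channels and
ihMTR do not — the directional mechanism the extended axonal model
describes — and the between-method dispersion of lesion g-ratios grows
accordingly. What a green test establishes is therefore internal
consistency of the models and estimators under stated noise, **not**
fidelity to any real scanner: there is no B0/B1 field, no k-space, no
motion, no registration error, and all maps share one grid.

Two generator switches exist purely so that null hypotheses can be made
true: `regional_contrast = 0` removes the splenium/internal-capsule
myelin offsets and `wm_heterogeneity = 0` / `subject_sd = 0` remove
spatial and between-subject variation. The null-calibration experiment
uses them because lesions are placed uniformly in eroded WM: with
regional offsets present, lesion and non-lesion WM means would differ by
construction and the "no-effect" rejection rate would not be a size
measurement but a power measurement against a real confound.

# Numerical choices

**EPG.** The recursion tracks F+/F−/Z states to the echo-train order and
returns the magnitude of the k = 0 transverse state (deep stimulated-echo
pathways can invert the echo sign; magnitude acquisition sees its
modulus). It is validated against an independent isochromat-summation
oracle (Bloch rotations with ideal crushers realized as evenly spaced
dephasing phases) to 1e-6, and reduces to `exp(-TE/T2)` at 180° to
machine precision.

**Regularized NNLS.** Lawson–Hanson active sets; the Tikhonov weight is
found by bisection so the regularized squared misfit equals
`reg_factor` times the unregularized minimum, within 0.1%. A noiseless
voxel (minimum misfit numerically zero) is left unregularized.

**SPIJN.** The joint row-sparsity penalty is applied in its greedy
hard-threshold limit: the multiple-measurement-vector NNLS is re-solved
on the active dictionary (Gram-based solves, one shared dictionary for
all voxels), candidates are ranked by inverse row norms, and a component
is eliminated only when re-solving without it raises the joint misfit by
at most `sparsity_weight` (relative); eliminations are forced — cheapest
first — while the support exceeds `max_components`. A reweighted ridge
surrogate was implemented first and rejected: on two-pool mixtures the
per-voxel quadratic penalty prefers intermediate single-T2 atoms and
either destroys the myelin peak or never sparsifies. The elimination
form preserves the iteratively re-solved joint NNLS with
inverse-row-norm weights and converges in at most `n_t2` passes;
`sparsity_weight = 0` returns the unregularized voxelwise solutions
unchanged. Because the support is global, small tissue classes can be
overruled by the majority — the same mechanism that makes joint-sparsity
MWF estimates diverge from voxelwise ones inside lesions.

**Calibration.** `calibrate_alpha()` averages voxelwise g over splenium
voxels per subject, then over subjects (matching "average g-ratio in the
splenium across the cohort"), and bisects on the scaling factor, which is
well-posed because g is strictly decreasing in MVF. Subject-mean rather
than voxel-pooled averaging was chosen; the alternative is a one-line
change and was not observed to matter at the phantom's homogeneity.

**Invalid voxels** are NaN everywhere (zero signal, zero reference,
MVF + NMVF > 1, MVF = AVF = 0) and are excluded from VOI means and
calibrations; clip and invalid counts are logged in `qc` attributes.

**Morphology and statistics.** 6-connectivity (face neighbors) for
erosion, dilation, shells, and lesion labeling, with volume boundaries
treated as outside; pooled-variance two-sample t-tests (the cited
`ttest2` default) and Pearson correlations with t-transform p values; no
multiple-testing correction (none is stated in the source design), the
number of tests is reported instead.

# Known limitations

* The generator's MT forward models are linear proxies by construction —
  they state the assumed linear ihMTR/MTsat–myelin relations rather than
  spin physics; dipolar-order dynamics, B1 effects and orientation
  dependence are out of scope.
* Lesion MWF divergence between the two fitting algorithms reproduces the
  *mechanism* (different regularization under noise) but no attempt is
  made to match the magnitudes reported for the clinical cohort, whose
  data are unavailable.
* All synthetic maps share one grid; registration, resampling and
  differential partial-volume effects between acquisitions are not
  emulated.
* The t-test size experiment compares VOI means with very different voxel
  counts; with equal group sizes the pooled statistic equals the Welch
  statistic and only the degrees of freedom differ, which keeps the
  empirical size near nominal (measured 5.5% over 200 replicates).
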