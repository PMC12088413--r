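---
title: "Quantifying synapsis dynamics on the HEI10 accumulation clock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying synapsis dynamics on the HEI10 accumulation clock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Fixed-cell microscopy gives snapshots of meiotic prophase I, not movies. To
study how fast synapsis (the zipping of homologous chromosomes by the
synaptonemal complex) progresses in different genotypes, meioclock uses the
redistribution of the pro-crossover protein HEI10 as a within-cell
pseudo-time axis: early pachytene nuclei show many dim HEI10 foci; as
meiosis proceeds, signal concentrates into a few bright foci at prospective
crossover sites ("coarsening"). The **HEI10 accumulation level** of a cell
is the percentage of total HEI10 signal intensity residing in its prominent
foci; plotting any other per-cell quantity against it orders cells along
developmental progression without live imaging.

The second axis is **asynapsis**, proxied by the 3D length of the remaining
ASY1 signal (an axis protein largely removed upon synapsis); ZYP1 (the
transverse filament of the synaptonemal complex) marks synapsed regions.
The package implements the full chain from three-channel 3D stacks to
genotype comparisons, and a synthetic-data layer that generates both image
stacks and tabular populations with known ground truth, so every stage is
testable end to end.

## The synthetic generator

`simulate_cell_table()` draws per-cell ground truth with exactly the
structure the inference layer assumes:

* `H_true ~ Uniform(h_range)`;
* `asynapsis_true ~ Gamma(shape, mean = exp(beta0_g + beta1_g * H + u_plant))`
  with `u_plant ~ N(0, plant_sd^2)` — the exponential-decay mixed model;
* counts (crossover foci, coalignment structures, ZYP1 segment classes,
  quadrivalents, univalents) from Poisson / negative-binomial models with
  the links documented in `?genotype_params`.

The default genotype parameters emulate the four-cytotype study system: a
diploid with ~50 µm of asynapsis (on the ploidy-doubled scale) at the onset
of accumulation decaying at −0.030 per accumulation point, a stalled
neo-tetraploid pinned near 200 µm with a zero decay exponent, an
established tetraploid starting below 10 µm with the steepest decay
(−0.035), and an intermediate hybrid (−0.020). The plant random-intercept
SD defaults to 0.15 on the log scale. Where the emulated system reports no
value we fixed biologically plausible ones once: Gamma shape 3 (log-scale
residual SD ≈ 0.64, matching a conditional R² near 0.85 at these signal
sizes), negative-binomial dispersion θ = 5, total axis content 160 µm
(diploid) / 320 µm (tetraploid) per nucleus. Draws exceeding the axis
budget are resampled (rare except for the stalled genotype, where the cap
acts as a physical ceiling). One master seed splits into per-plant and
per-cell substreams, so any cell is reproducible in isolation.

`render_cell()` turns a truth row into a three-channel stack. Axis
structures are cubic splines through bounded random walks, arc-length
resampled and cut so painted track lengths match the truth within 2%;
coaligned pairs are drawn by offsetting a curve 0.3 µm along a propagated
normal. The default volume is 64×256×256 voxels at (0.125, 0.04, 0.04) µm
(z, y, x): 0.125 µm optical sections with typical structured-illumination
lateral sampling. HEI10 is painted as `n_prominent_true` bright compact
foci (truncated Gaussians; an untruncated profile would hide several
percent of focus mass under any permissive threshold, making the stated
pre-blur share unrecoverable by any thresholding measurement), plus a
dispersed component realised as a faint coating along the axes and
discrete dim foci at a nominal 10:1 amplitude ratio. The dispersed field is
scaled so the bright-focus share of pre-blur intensity equals `H_true`
exactly; its split between coating and dim foci follows the remaining
budget, mimicking coarsening kinetics (early: mostly coating; late: a few
dim foci). The scene is blurred with an anisotropic Gaussian PSF (default
σ = 0.15/0.06/0.06 µm), offset by a flat background, optionally
Poisson/Gaussian-noised, and digitised to 16-bit counts, which makes
TIFF round trips exact.

What the generator does **not** emulate: structured-illumination
reconstruction artefacts, chromatin texture, antibody background beyond a
flat offset, interlocks, or spatial correlation between noise and signal.
Tests passing on these renders therefore validate the measurement chain's
geometry and intensity logic, not its robustness to every real-data
pathology.

## The quantification layer

`quantify_cell()` composes the measurement operators:

* **Normalization** (`normalize_channel`): min → 0 and the 0.9999 quantile
  → 1 (clipped above). The high quantile tolerates hundreds of hot voxels
  yet stays above the bright-focus cores, which occupy well under 0.01% of
  a stack; a looser quantile (e.g. 0.999) clips both focus classes to 1.0
  and destroys their separability.
* **Dual HEI10 thresholds** (`dual_threshold_hei10`): Triangle (permissive)
  for total signal; a two-stage Otsu within the total mask for prominent
  foci. A single Otsu restricted to a permissive mask separates background
  shoulders from signal rather than dim from bright foci, because the
  shoulder voxels dominate the histogram; the second stage splits the
  upper class. Both methods are classical histogram thresholds and both
  are configurable.
* **Prominent-focus photometry** (`prominent_components`): foci are cores
  of the stringent mask (26-connected, ≥ 4 voxels, with a relative-size
  filter at 40% of the median core — dispersed-signal shoulders poking
  over the threshold are a fraction of a real core). Each focus is
  integrated over its core dilated by an anisotropic margin (0.40 µm
  axially, 0.22 µm laterally — the axial PSF spreads tails about twice as
  far) minus a local background read from a thin annulus. Because the
  annulus lies inside the permissive mask its values are floored at that
  threshold, so the background estimate is
  `camera_baseline + max(annulus_quantile − mask_floor, 0)`; the floor
  correction recovers the true baseline when no dispersed coating
  surrounds the focus. Margin and annulus quantile were calibrated on
  training renders and validated on held-out seeds; on noiseless renders
  the measured accumulation tracks the imposed share within ~1 point
  across the 10–90% range.
* **Accumulation level** (`hei10_accumulation`): background-corrected
  prominent mass over baseline-corrected total-mask intensity, in percent.
  With a fixed background estimate this is non-increasing in the stringent
  threshold; the estimate itself is re-derived per threshold, so exact
  monotonicity holds whenever the background is stable (as in the tests).
* **Skeleton lengths** (`skeleton_paths`, `skeleton_length`): per
  26-connected component, the geodesic diameter path (double-sweep
  Dijkstra with physical-unit edge weights, honoring z-anisotropy without
  resampling), then residual branch paths until nothing ≥ 0.5 µm remains.
  Raw voxel paths are resampled, smoothed (removing the lattice zigzag
  that inflates 26-connected path lengths by up to ~15%) and end-trimmed
  by 0.12 µm (compensating the cap the blur adds beyond a structure's
  true end). This geodesic centerline is a robust medial-curve surrogate
  for thinning-based skeletonization on tube-like signals; its known
  biases are small cap effects on short structures and slight
  inner-corner cutting on tightly curved ones (the helix phantom reads
  ~6% short, within its 10% band). Axis-channel masks default to Otsu:
  these channels have a strong foreground mode, and the permissive
  Triangle would keep a wide blur halo that corrupts skeletons.
* **ZYP1 classes** (`classify_zyp1`): components shorter than 0.4 µm are
  punctate (initiation sites), the rest elongated; the total length uses
  the full skeleton so crossing stretches are not undercounted.
* **Coalignment geometry** (`detect_parallel_axes`): an automated
  surrogate for by-eye scoring — a parallel structure is a pair of
  centerline paths ≥ 0.5 µm whose nearest-point separation stays within
  0.1–0.8 µm over ≥ 0.5 µm of arc with SD < 0.15 µm; overlapping pairs
  merge; leftover qualifying paths count as irregular. Parameters were
  calibrated on parallel-pair phantoms, and the operator is bypassable
  (geometry counts may come in the input table).
* **Linear-HEI10 flag** (`flag_linear_hei10`): a prominent component with
  a centerline over 1.5 µm and at least half its voxels within 0.2 µm of
  the ASY1 mask marks the rare cells where HEI10 coats unsynapsed axes;
  such cells are excluded from accumulation analyses.
* **QC**: a cell fails when its HEI10 total mask is empty or both axis
  channels are empty.

## Staging cutoffs

Three calibrations convert raw accumulation into analyzable windows
(`background_cutoff`, `plateau_cutoff`, `late_pachytene_cutoffs`):

1. **Background**: cells with no true HEI10 signal still register a
   nonzero level (the measurement is relative); the cutoff is the maximum
   level among somatic/leptotene controls, and cells below it are
   excluded (along with QC failures and linear-HEI10 cells; retained and
   excluded sets partition the input exactly).
2. **Plateau**: the smallest integer cutoff (grid 13–90) above which every
   genotype's decay exponent is statistically flat (Wald p ≥ 0.05 on the
   refit model). The search refits on strict subsets and warm-starts each
   candidate from the previous fit.
3. **Late pachytene**: per genotype, the cutoff whose mean prominent-focus
   count above it is closest (absolute distance on means) to the
   genotype's diakinesis crossover mean; at least 5 cells must remain.
   Exact ties resolve to the *smallest* candidate: a constructed
   population whose focus mean equals the diakinesis mean everywhere above
   a crossing point must be cut at the crossing, not at the top of the
   grid, and the degenerate everywhere-equal population must return the
   first candidate.

`normalize_diploid()` doubles diploid ASY1 lengths onto the tetraploid
scale, guarded by a provenance flag so it cannot be applied twice.

## The inference layer

`fit_gamma_decay()` maximizes the marginal likelihood of the Gamma GLMM
(log link, per-genotype intercept and decay exponent, shared plant
random-intercept SD and shape) with a Laplace approximation. With a single
scalar intercept per plant the inner mode solves by a per-plant Newton
iteration on sufficient statistics, so one likelihood evaluation is a few
vector operations regardless of cell count; the outer optimizer is
L-BFGS-B over (fixed effects, log σ\_u, log shape), started from a plain
Gamma GLM. At σ\_u → 0 the Laplace objective equals the GLM likelihood
identically, which the tests verify to 10⁻⁴ relative; an independent
mixed-model fitter (glmmTMB) reproduces the coefficients on simulated
data to within 2%. Numerical choices: linear predictors are clamped to
±30 during optimizer excursions; exact zeros in the response (fully
synapsed cells) are incompatible with the Gamma density and are replaced
by half the smallest positive measured length, recorded in the fit; with
a single plant per genotype the random intercept is unidentifiable and
the fit falls back to the GLM limit, flagged. Fixed-effect covariance is
the observed information at the optimum conditional on the variance
parameters (as mixed-model software conventionally reports); the test
suite checks empirically that nominal 95% intervals for the decay
exponents cover within [88%, 99%] over 200 replicates of the study design
size.

`predict_asynapsis()` gives population-level means `exp(beta0 + beta1*H)`
with delta-method intervals; `wald_contrasts()` evaluates linear
combinations of coefficients with two-sided normal p-values and Holm
adjustment within the requested family (onset comparisons, decay-exponent
comparisons, final-asynapsis comparisons are separate families).
`pseudo_r2()` is the Nakagawa variance partition on the latent scale,
with distribution-specific residual variance `trigamma(shape)` for the
log-link Gamma, `log(1 + 1/mean)` (+ `1/theta` for negative binomial) for
log-link counts, and the mean response-scale variance for identity-link
counts.

Count models (`fit_count_model`) — quadrivalents and univalents (with an
optional scorability-class covariate), coaligned parallels against ASY1
length (slope per 100 µm), elongated ZYP1 segments against total ZYP1
length — are ordinary Poisson / negative-binomial regressions and are
fitted with glmmTMB behind the package's interface. The elongation model
uses the identity link by default so its intercept reads as the initial
number of elongated stretches at zero ZYP1 and its slope as the gain per
micrometre of synaptonemal complex (the generator draws that variable
with the same identity-link mean, so the fitted model is correctly
specified against it; the log link remains available). `fit_co_asynapsis`
is the late-pachytene Poisson GLM of crossover count on asynapsis, with a
`log1p` covariate variant. `select_family()` ranks candidate
specifications by AIC with a Pearson χ²/df overdispersion flag (> 1.5); a
within-2-AIC tie goes to the simpler family, logged.

## Simulation-based validation

The test suite validates the chain against its own generators at fixed
seeds: 95% CI coverage of every decay exponent within [88%, 99%] over 200
replicates of the study design (4 plants × 40 cells per genotype; the
stalled genotype reads as flat in ≥ 90% of replicates); recovery of a
known synapsis plateau at 50% accumulation within ±5 points in ≥ 90% of
100 replicates. The change-point populations for the plateau check use
2 genotypes × 3 plants × 100 cells with a pre-plateau decay exponent of
−0.15 and Gamma shape 6 — set by a power calculation so that pre-plateau
candidates are reliably rejected at α = 0.05 and the first passing
candidate concentrates at the true change point; with weaker decay the
rule (by construction) fires at the earliest cutoff where the residual
decay is no longer *detectable*, which sits below the true change point.
Image-layer checks run on noiseless renders (oracle equivalence of the
accumulation level to the imposed pre-blur share; phantom arc lengths);
problem sizes (50 oracle cells; the replicate counts above) were chosen to
keep the default suite comfortably reproducible on a single CPU.

## Known limitations

* The geodesic centerline undercuts tightly curved thick tubes by up to
  ~6–8% and trims structure ends by a fixed 0.12 µm; on real SIM data
  with inhomogeneous staining, thinning-based skeletons may behave
  differently.
* The accumulation photometry assumes foci sit on a locally flat
  dispersed background; strongly textured coating would bias the annulus
  estimate.
* Coalignment detection was calibrated on rendered pairs at 0.3 µm
  separation; real pairing geometry is more varied, and expert
  by-eye scoring remains the reference for real data (the operator is
  bypassable).
* The Gamma-GLMM uses a single shared shape and random-intercept SD
  across genotypes, as in the emulated analysis; genotype-specific
  dispersion would need a different parameterization.
* Wald/normal inference throughout; no small-sample degrees-of-freedom
  correction.
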