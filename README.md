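# meioclock

Synapsis dynamics in meiotic prophase I, quantified against the HEI10
accumulation clock.

## The problem

During meiotic prophase I, homologous chromosomes pair and are zipped
together by the synaptonemal complex (synapsis) while crossovers are
designated. Fixed-cell immunofluorescence gives only snapshots, so the
*pace* of synapsis cannot be read from any single image. The pro-crossover
protein HEI10 provides an internal clock: its signal coarsens from many dim
foci into a few bright crossover-site foci as pachytene progresses. The
**HEI10 accumulation level** of a cell —

```
accumulation = 100 × (HEI10 intensity in prominent foci) / (total HEI10 intensity)
```

— orders cells along developmental time. Plotting the remaining
**asynapsis** (3D length of ASY1-marked unsynapsed axis, in µm) against it
and fitting an exponential-decay Gamma GLMM with per-plant random
intercepts,

```
asy1_length ~ Gamma(shape),   log E[asy1_length] = β0_g + β1_g · H + u_plant,
u_plant ~ N(0, σ_u²)
```

turns snapshots into genotype-resolved synapsis kinetics: the intercepts
give the predicted asynapsis at the onset of accumulation, the decay
exponents β1 give the pace (a β1 indistinguishable from 0 means synapsis
has stalled), and cutoff calibrations define the analyzable windows
(background ≤ max control level; synapsis plateau; late pachytene, where
prominent foci count crossovers). The motivating application is comparing
diploid, neo-tetraploid, established-tetraploid and hybrid cytotypes of a
plant whose genome duplication perturbs synapsis.

This package implements the complete framework — a synthetic microscopy
and population generator with known ground truth, the image-quantification
operators (dual-threshold HEI10 photometry, 3D skeleton lengths on
anisotropic voxel grids, ZYP1 segment classes, coalignment geometry), the
staging-cutoff calibrations, and the statistical layer (Gamma GLMM via
Laplace-approximated marginal likelihood, count regressions, Wald
contrasts with Holm correction, Nakagawa pseudo-R²) — exercised entirely
on synthetic data.

## Worked example

```r
library(meioclock)

# a four-cytotype study population with known ground truth
tab   <- simulate_cell_table(default_genotype_params(),
                             plants_per_genotype = 4, cells_per_plant = 40,
                             h_range = c(12, 100), seed = 11)
cells <- truth_to_measurements(tab)

fit <- fit_gamma_decay(cells)
fit
#> <decay_fit> Gamma-GLMM, log link, 640 cells / 16 plants
#>         beta0   beta1
#> DIP-2X 3.5426 -0.0298
#> EST-4X 2.1977 -0.0316
#> HYB-4X 3.7227 -0.0207
#> NEO-4X 5.0659  0.0004
#> sigma_u = 0.119, shape = 3.28, logLik = -2055.2, R2m = 0.896, R2c = 0.900

round(decay_p_values(fit), 3)
#> DIP-2X EST-4X HYB-4X NEO-4X
#>  0.000  0.000  0.000  0.807

predict_asynapsis(fit, H = 12)   # asynapsis at the onset of accumulation
#>   genotype   mean_um     lo_um     hi_um
#> 1   DIP-2X  24.15716  19.55041  29.84943
#> 2   EST-4X   6.16508   5.03074   7.55521
#> 3   HYB-4X  32.29049  26.32547  39.60710
#> 4   NEO-4X 159.30610 130.46354 194.52510
```

The generator planted decay exponents (−0.030, −0.035, −0.020, 0) and the
fit recovers them; the stalled genotype (true β1 = 0) is correctly read as
flat (p = 0.81) while every other genotype's decay is highly significant.
Its predicted onset asynapsis (~160 µm raw; the diploid's ~24 µm doubles
to ~48 µm on the tetraploid-comparable scale) shows the stalled cytotype
entering pachytene with an order of magnitude more unsynapsed axis.

The imaging layer works the same way from rendered stacks:

```r
spec <- render_spec(shot_noise = FALSE, read_noise_sd = 0, seed = 3)
st   <- render_cell(tab[5, ], spec)     # 3-channel 3D stack + ground truth
quantify_cell(st)                       # accumulation %, foci, lengths, QC
```

`run_pipeline(pipeline_config(...))` chains quantification, cutoff
calibration, filtering, diploid doubling and all models into one report;
the numbered scripts under `analysis/` run the whole study
(`01_simulate.R` … `05_report.R`) and write tables under `results/`.

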