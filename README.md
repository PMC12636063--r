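# adipocomp

Adipose fatty-acid composition mapping from chemical-shift-encoded
multi-echo MRI, with the depot-specific genetic statistics built on top
of it — all over synthetic data with planted ground truth.

## Who this is for and what problem it solves

Body-composition imaging studies estimate the *chemical* make-up of
subcutaneous (SAT) and visceral (VAT) adipose tissue — the fractions of
saturated (fSFA), monounsaturated (fMUFA) and polyunsaturated (fPUFA)
fatty acids — from multi-echo gradient-echo MRI, then treat those
fractions as quantitative traits in genetic association analyses. The
cohorts involved are access-restricted, so methods work on this chain is
hard to test openly. `adipocomp` provides the full chain as tested,
seedable R code: a triglyceride spectral signal model and phantom
generator, a constrained voxel-wise fitter, depot mask hygiene, a cohort
simulator with planted genetic effects, and the statistics layer (GWAS
scan, depot heterogeneity, meta-analysis, colocalization, gene–diet
interaction). Every stage can be checked against the generator's truth.

## The model in brief

A voxel's magnitude signal at echo time $t$ is

$$ s(t) = \left| W + F\,c(t) \right| e^{-R_2^* t}, \qquad
   c(t) = \frac{\sum_p a_p e^{2\pi i \Delta f_p t}}{\sum_p a_p}, $$

with water/fat amplitudes $W, F$, shared relaxation rate $R_2^*$, and a
nine-peak fat spectrum whose proton counts $a_p$ are linear in the
triglyceride number of double bonds (NDB), methylene-interrupted double
bonds (NMIDB) and chain length (CL). Two reductions make the fit
identifiable from ten echoes: $\mathrm{NMIDB} = 0.093\,\mathrm{NDB}^2$
and CL fixed at 17.4. NDB is estimated per voxel by bounded nonlinear
least squares with $1 \le \mathrm{NDB} \le 6$, and mapped to fractions
via

$$ \mathrm{fUFA} = \tfrac{\mathrm{NDB}-\mathrm{NMIDB}}{3},\quad
   \mathrm{fSFA} = 1-\mathrm{fUFA},\quad
   \mathrm{fPUFA} = \tfrac{\mathrm{NMIDB}}{3},\quad
   \mathrm{fMUFA} = \mathrm{fUFA}-\mathrm{fPUFA}. $$

Downstream, depot traits are inverse-normal transformed, associated
per-variant by OLS, compared across depots with Cochran's Q and $I^2$
(depot-specific: HetPval < 0.05 and $I^2$ > 75%), meta-analysed by
inverse variance, colocalized by Wakefield approximate Bayes factors
with the standard five-hypothesis enumeration, and probed for
genotype × diet interactions with an in-package IRLS logistic model.
See the methods vignette (`vignettes/adipose-fatty-acid-pipeline.Rmd`)
for assumptions, parameter defaults and design rationale.

## Worked example

Simulate one adipose voxel on the default 1.5 T ten-echo protocol and
fit it back:

```r
library(adipocomp)
p <- acq_protocol()
series <- simulate_signal(
  voxel_signal_params(water = 10, fat = 90, r2star = 40,
                      tg_composition(ndb = 2.5)), p)
round(series$values, 2)
#>  [1] 53.57 65.90 33.52 35.15 26.80 27.99 23.49 26.94 18.55 22.72
fit <- fit_voxel(series)
sprintf("ndb = %.3f, fat fraction = %.3f, R2* = %.1f /s",
        fit$ndb, fit$fat_fraction, fit$r2star)
#> "ndb = 2.500, fat fraction = 0.900, R2* = 40.0 /s"
```

The ten values are the echo magnitudes: the low/high alternation of the
early echoes is water–fat phase interference (out-of-phase vs in-phase
echoes), and the overall decay is $R_2^*$. The noiseless fit recovers
the generating parameters exactly.

A small phantom, end to end — render, fit every depot voxel, erode the
partial-volume rim, filter fat fraction below 20%, summarise:

```r
spec <- phantom_spec(grid = c(64L, 64L, 2L), seed = 1)
truth <- make_phantom(spec)
echoes <- render_multiecho(truth)
maps <- fit_volume(echoes, list(truth$sat_mask, truth$vat_mask))
rbind(summarize_depot(maps, truth$sat_mask, "SAT"),
      summarize_depot(maps, truth$vat_mask, "VAT"))
#>   depot n_voxels_initial n_voxels_after_erosion n_voxels_after_ff_filter
#> 1   SAT             1960                   1208                     1208
#> 2   VAT              568                    336                      336
#>   mean_f_sfa mean_f_mufa mean_f_pufa ...
#> 1      0.444       0.420       0.135
#> 2      0.475       0.407       0.118
```

The recovered depot means (SAT fSFA 0.444, VAT fSFA 0.475) sit within
sampling error of the phantom's planted truth (0.442 and 0.472) and in
the range typical of human adipose tissue. `run_pipeline()` chains
these stages with the cohort simulation, GWAS, heterogeneity,
meta-analysis, interaction and colocalization stages, writing NIfTI
maps, summary-statistics TSVs and an MD5 manifest for exact re-runs.

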