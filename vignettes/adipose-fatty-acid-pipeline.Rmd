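---
title: "From multi-echo MRI signals to depot-specific fatty-acid genetics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From multi-echo MRI signals to depot-specific fatty-acid genetics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adipocomp)
```

## What the package computes

`adipocomp` implements, over fully synthetic data with planted ground
truth, the computational chain that turns chemical-shift-encoded
multi-echo abdominal MRI into depot-specific adipose fatty-acid
composition traits, and those traits into GWAS-style genetic statistics:
per-variant association, depot heterogeneity, inverse-variance
meta-analysis, approximate-Bayes-factor colocalization, and gene-diet
interaction models. Every stage is testable against the generator's
truth, which is the point: the real cohorts this kind of analysis runs on
are access-restricted, so the package's claims are about the correctness
and calibration of the machinery, not about any particular cohort.

## The signal model

A voxel containing water and triglyceride protons, imaged with a
multi-echo gradient-echo sequence, produces the magnitude signal

$$ s(t) \;=\; \bigl|\,W + F\,c(t)\,\bigr| \; e^{-R_2^{*} t}, $$

where $W, F \ge 0$ are water and fat proton amplitudes, $R_2^*$ (1/s) is
a single effective transverse relaxation rate shared by both pools, and
$c(t)$ is the complex chemical-shift modulation of the fat spectrum:

$$ c(t) = \frac{\sum_p a_p\, e\,^{2\pi i \Delta f_p t}}{\sum_p a_p},
   \qquad \Delta f_p = (\delta_p - \delta_w)\cdot 42.577\ \mathrm{MHz/T}
   \cdot B_0 . $$

The nine fat peaks sit at 5.3, 5.2, 4.2, 2.75, 2.2, 2.0, 1.6, 1.3 and
0.9 ppm (water at 4.7 ppm), with proton counts linear in the
triglyceride composition parameters: number of double bonds (NDB),
methylene-interrupted double bonds (NMIDB) and chain length (CL):

| peak | ppm | protons |
|---|---|---|
| olefinic | 5.3 | 2·NDB |
| glycerol CH | 5.2 | 1 |
| glycerol CH₂ | 4.2 | 4 |
| diallylic | 2.75 | 2·NMIDB |
| α-carboxyl | 2.2 | 6 |
| allylic | 2.0 | 4·(NDB − NMIDB) |
| β-carboxyl | 1.6 | 6 |
| bulk methylene | 1.3 | 6·(CL − 4) − 8·NDB + 2·NMIDB |
| terminal methyl | 0.9 | 9 |

Total protons are $6\,\mathrm{CL} - 2\,\mathrm{NDB} + 2$, an identity the
test suite checks symbolically against the summed table. Two empirical
reductions make the model identifiable from ten echoes: NMIDB is tied to
NDB by the constraint $\mathrm{NMIDB} = 0.093\,\mathrm{NDB}^2$, and CL is
fixed at 17.4 carbons (configurable, not estimated). Estimating CL as a
free parameter is not supportable with ten magnitude echoes; 17.4 is the
conventional human-adipose value for this family of models.

The default acquisition is the 1.5 T abdominal protocol the package
targets: TEs 2.38, 4.76, 7.15, 9.53, 11.91, 14.29, 16.67, 19.06, 21.44,
23.82 ms; TR 27 ms; flip angle 20°. Noise is applied per complex channel
before the magnitude is taken, so magnitude noise is Rician; at the
SNR ≈ 100 regime of the default phantom the Gaussian approximation is
excellent, and the 10⁴-replicate noise-scale test works at high SNR for
that reason.

### Fractions from NDB

With $\mathrm{fUFA} = (\mathrm{NDB} - \mathrm{NMIDB})/3$ and
$\mathrm{fSFA} = 1 - \mathrm{fUFA}$, the package splits the unsaturated
share as $\mathrm{fPUFA} = \mathrm{NMIDB}/3$ and
$\mathrm{fMUFA} = \mathrm{fUFA} - \mathrm{fPUFA}$ — one
methylene-interrupted pattern per (predominantly di-unsaturated) PUFA
chain, three chains per triglyceride. This split is a convention: the
fraction formulas pin down only fSFA and the MUFA+PUFA total, and the
exact decomposition used upstream of published depot tables is not
printed anywhere we could verify. The chosen convention reproduces the
qualitative ordering of human adipose tables (fSFA ≈ 0.44-0.47,
fMUFA ≈ 0.36-0.40, fPUFA ≈ 0.15-0.18) at NDB ≈ 1.9-2.1. Above
NDB ≈ 5.38 the quadratic NMIDB constraint would push fPUFA past fUFA;
the PUFA share is capped there so the triplet stays in $[0,1]$ and sums
to 1 exactly. Adipose tissue never approaches that regime.

## The voxel fitter

`fit_voxel()`/`fit_volume()` minimise the sum of squared magnitude
residuals over $(W, F, \mathrm{NDB}, R_2^*)$ with NDB box-constrained to
$[1, 6]$ (bounded optimisation, not post-hoc clipping — a truth of
NDB = 8 is returned as exactly 6). The objective is multi-modal in NDB
and has the classic water-fat amplitude ambiguity, so the solver — a
compiled projected Levenberg-Marquardt with forward-difference
Jacobians, relative tolerance 1e-10, at most 500 model evaluations per
start — is run from a small multi-start set: NDB ∈ {1.5, 3, 5}, $R_2^*$
= 30 1/s, and amplitudes from a two-point Dixon-style split of the first
two echoes (near out-of-phase / in-phase at 1.5 T) *in both
assignments*. The both-assignments detail matters: the magnitude of two
echoes cannot tell a 90% fat voxel from a 90% water voxel, and with a
single assignment the solver reliably lands in swap minima. The
lowest-residual solution wins; ties break toward lower NDB. Voxels whose
solve fails carry NA everywhere and are excluded from summaries; the
convergence rate is recorded on the returned maps.

Correctness anchors in the tests: noiseless recovery to machine
precision across an NDB × fat-fraction × $R_2^*$ truth grid; agreement
with a 1e-4-step brute-force NDB scan; and, under noise, attainment of
the residual floor of an independent bounded least-squares solver
(`minpack.lm`) started at the truth. The last check is the honest
version of "accuracy at SNR 50": at a fat fraction of 0.5 the first
(out-of-phase) echo nearly cancels, and no estimator does better than
the ≈0.3 median NDB error the noise floor dictates there.

Fat fraction is defined as $F/(W+F)$ from the fitted amplitudes — a
signal-weighted fraction with no T1 or noise-bias correction, applied
uniformly to truth and estimate so comparisons are internally
consistent.

## Phantom and post-processing

The phantom emulates a single-station abdominal slab: a subcutaneous-like
outer ring and visceral-like interior blobs on each slice (96 × 96 × 6
voxels of 2.5 × 2.5 × 6 mm by default), with per-depot Gaussian truth
fields for NDB (SAT 2.08 ± 0.15, VAT 1.94 ± 0.15 — the values whose fSFA
is ≈0.44 and ≈0.47), fat fraction (0.90/0.88 ± 0.04), and $R_2^*$
(40/45 ± 8 1/s), smoothed in-slice for spatial coherence. A one-voxel
rim of each depot is rendered as a 50/50 mixture of the tissue signal
and the background water signal (its own relaxation), deliberately
violating the single-compartment model the way real partial-volume edges
do — this gives mask erosion something real to remove. Background voxels
carry water-only signal at 40% amplitude.

Post-processing follows the mask-hygiene chain: in-slice binary erosion
(3 × 3 square element, one pass, no through-slice erosion — the
acquisition is effectively single-slice and thin depots would empty
along z) followed by exclusion of voxels with fitted fat fraction below
20% (inclusive retention at exactly 0.20). The participant-level trait
is the arithmetic mean over retained voxels; median aggregation is a
one-line change but the mean is the default. The end-to-end test checks
that the eroded, filtered depot mean lands within sampling error of the
truth mean while counts decrease monotonically through the chain.

## The synthetic cohort

The cohort generator plants a known causal chain: genotype → latent
depot NDB → fraction triplets → (separately) dietary intake → disease.

* **Genotypes.** Hard calls Binomial(2, MAF) under Hardy-Weinberg;
  imputation-style dosages add truncated Gaussian noise (SD 0.05 by
  default), clipped to [0, 2]; INFO = var(dosage)/(2p(1−p)). Allele
  pairs are drawn so A/T and C/G strand-ambiguous variants never occur.
* **Traits.** Latent NDB per depot = baseline (SAT 2.08, VAT 1.94) +
  per-allele effects in latent-SD units (SD 0.15) + small age and sex
  effects + Gaussian noise, mapped through `fractions_from_ndb()`.
  Planting on latent NDB rather than on the fractions means downstream
  tests exercise the full nonlinearity of the fraction map.
  Depot-specific genetics is just `beta_sat != beta_vat`.
* **Covariates.** Age (64.5 ± 7.7 y), sex, age², 10 standard-normal
  PC-like columns, 2-level array and 3-level centre factors —
  structurally the standard imaging-GWAS covariate set.
* **Diet and disease.** Intakes are truncated Gaussians with UK-cohort
  descriptive means (SFA 27.54 ± 11.78 g, MUFA 26.96 ± 10.73 g, PUFA
  19.90 ± 7.51 g), z-standardised before entering the logistic disease
  model: prevalence-anchored intercept, genotype and diet main effects,
  a planted genotype × diet interaction γ (default 0.15 on
  cardiovascular disease × SFA), plus age and sex. A 50,000-participant
  test checks simulated prevalence against the semi-analytic
  HWE-by-quadrature expectation within 2%.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: linkage disequilibrium outside the
dedicated colocalization locus, relatedness and population structure,
genotype-covariate correlation, measurement error in diet recall,
case-control ascertainment, and any real segmentation error beyond the
synthetic rim. Conclusions from this package are about algorithmic
correctness and statistical calibration under its stated model.

## The statistics layer

* **Inverse normal transform**: Blom offsets, $(r - 3/8)/(n + 1/4)$,
  through $\Phi^{-1}$; ties get average ranks. The n = 3 fixture value
  is $\Phi^{-1}(2.625/3.25) = 0.8694$.
* **Variant QC**: strict inequalities, MAF > 0.01 and INFO > 0.9; a
  variant at exactly the cutoff is excluded.
* **Association**: per-variant OLS of the transformed trait on dosage
  plus covariates, p-values from the normal approximation (the GWAS
  convention; at n ≥ 5000 the difference from t is negligible). The
  whole-genome mixed-model machinery real pipelines use for relatedness
  is deliberately absent — the generator makes unrelated individuals, so
  OLS is the correct reduction. The vectorised scan residualises trait
  and dosages against covariates once (Frisch-Waugh-Lovell) and is
  tested to agree with `stats::lm` at 1e-10.
* **Depot heterogeneity**: Cochran's Q on the two depot estimates
  (df = 1), $I^2 = \max(0, (Q-1)/Q) \cdot 100$; depot-specific means
  HetPval < 0.05 *and* $I^2$ > 75%. Worked oracle: β = ±0.1,
  SE = 0.05 gives Q = 8, p = 0.00468, $I^2$ = 87.5%.
* **Meta-analysis**: fixed-effect inverse-variance; the pipeline stage
  realises the two-study setting with two disjoint cohort halves.
* **Gene-diet interaction**: logistic regression by IRLS implemented in
  the package (the model is the contribution here, so it is not
  delegated), Wald inference, genotype-stratified diet effects with 95%
  CIs, separation and non-convergence raised as errors. Cross-checked
  against `stats::glm` and a direct BFGS maximisation of the
  log-likelihood at 1e-6.
* **Thresholds**: α/m with its 1-significant-figure rounding (17 tests
  → 0.00294 → 0.003) as the division-based default, plus
  Benjamini-Hochberg adjustment for vectors. The 17-test threshold is
  labelled FDR in some published methods text though numerically it is
  a Bonferroni-type bound; both routes are exposed.

## Colocalization

Per-variant Wakefield log-ABFs, $\tfrac12[\log(1-r) + r z^2]$ with
$r = w^2/(w^2 + \mathrm{se}^2)$ (prior SD $w$ = 0.15 for quantitative
traits, 0.2 for binary), feed the standard five-hypothesis enumeration
with priors $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$ — the cited
tool's defaults. All mass arithmetic is log-sum-exp; the suite checks no
underflow at z = 40. The locus workflow selects a 200-kb window around
the lead variant (lowest p, ties by |β| then position), harmonises
alleles (flipping β and EAF for swapped EA/OA), greedily prunes r² > 0.5
by ascending p, and runs the enumeration on the pruned set. Fine
mapping is a single-causal-variant softmax PIP, explicitly labelled a
simplification in its output attribute — multi-signal methods are out of
scope. Decision rules: PP.H4 ≥ 0.95 for shared signal, with a 0.70
sensitivity threshold that by construction can only flag more loci.

The colocalization test locus uses a thresholded Gaussian-copula LD
block (latent AR(1) ρ = 0.9; dichotomisation attenuates adjacent dosage
r² to ≈0.45) with a causal effect of 0.25-0.3 trait-SD at n = 2000,
i.e. causal z ≈ 8-9; distinct-causal scenarios place the two causal
variants at opposite ends of the block (r² < 0.1).

## Determinism and problem sizes

Every stochastic function takes a seed; a single master seed derives
independent per-stage streams, so regenerating any stage in isolation
reproduces it exactly. The pipeline writes uncompressed `.nii` volumes
and TSV tables and records an MD5 manifest; two runs with the same seed
produce byte-identical manifests, which is tested.

Simulation sizes were chosen to give each check real statistical teeth
on a single CPU: the full-phantom fraction-identity check fits ~16,500
voxels; type-I calibration uses 500 null variants at n = 5000 and 1000
interaction replicates at n = 5000; colocalization behaviour uses 100
replicates per scenario; prevalence calibration uses n = 50,000 against
quadrature. The complete suite runs in about a minute.

## Known limitations

Magnitude-only fitting (no B0 field map, no complex-domain separation),
a single shared $R_2^*$, no T1 bias correction at flip angle 20°, fixed
chain length, signal-weighted (not proton-density) fat fraction, no
multi-compartment relaxation. On the genetics side: no LD reference
panels, no mixed models or kinship, no X-chromosome model, no
multi-signal fine mapping. These mirror the stated scope; each would be
a model extension, not a bug fix.
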