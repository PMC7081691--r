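---
title: "Quantifying choriocapillaris flow deficits and modelling their topography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying choriocapillaris flow deficits and modelling their topography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccfd)
```

## The problem

The choriocapillaris (CC) is the capillary monolayer that supplies the
retinal pigment epithelium and photoreceptors. On en face swept-source OCT
angiography, regions of absent or subthreshold flow signal — *flow
deficits* — mark impaired CC perfusion. Both normal ageing and diabetic
retinopathy (DR) reduce CC perfusion, and both effects are strongest near
the fovea, so a topographic analysis needs three ingredients: a
reproducible per-image deficit quantification, a regional (ring-wise)
summary, and a regression model that respects the fact that two eyes from
one patient are not independent observations.

`ccfd` implements that full chain: image binarisation and noise filtering,
ETDRS-ring flow-deficit percentages, and a generalized estimating
equations (GEE) analysis of regional FD % against age and DR severity with
patients as clusters. Because clinical OCTA exports cannot be
redistributed, the package also ships synthetic generators — angiograms
with exactly known deficit maps and cohorts with known generating
coefficients — so every stage is testable end to end.

## Imaging pipeline

An en face angiogram is a square matrix of flow values on [0, 1] covering
a `field_width` (default 6 mm) square centred on the fovea, typically
sampled 500 × 500, i.e. a 12 µm pixel pitch and 144 µm² pixel area.

1. **Binarisation.** A pixel is a deficit iff its value is *strictly
   below* the fixed global threshold (default 0.2). The strict rule is a
   declared convention: an image uniformly at the threshold contains no
   deficits.
2. **Component labeling.** Deficits are grouped into connected components,
   8-connectivity by default (diagonal neighbours touch), 4-connectivity
   available. Component area is exactly `pixel_count * pixel_area`.
3. **Noise filter.** Components with area < 500 µm² are removed, once,
   globally, before any regional statistic; a component exactly at
   500 µm² is retained. At 12 µm pitch this removes components of 1–3
   pixels (144–432 µm²) and keeps 4-pixel components (576 µm²). A
   component straddling a ring boundary contributes its pixels to every
   ring it overlaps.

## Regions and FD %

Four regions derive from the ETDRS grid rings centred on the fovea: Inner
(r < 0.5 mm), Middle (0.5–1.5 mm), Outer (1.5–3 mm) and Full-Field.
Membership uses the pixel-centre distance with half-open bins, so the
rings exactly partition the 3 mm disc. Full-Field is defined as the whole
6 mm × 6 mm frame, corners included; the alternative 3 mm-disc definition
is available (`full_field = "circle"`). The whole-frame choice also
reproduces the empirical ordering in which full-field effect sizes sit
between the outer- and middle-ring effects.

Per region, FD % = 100 · (deficit pixels in region) / (region pixels) —
pure integer counting, so the computation is exact. On the 500-pixel grid
the pixelised ring areas are within 1 % of the analytic circle/annulus
areas; the inner-disc pixel count (5452) differs from the analytic value
(π · 0.25 mm² / 144 µm² ≈ 5454.2) only by pixelisation.

The fovea centre defaults to the frame centre and can be overridden per
eye (in mm); a 3 mm circle that would leave the frame is an error rather
than a silently clipped region.

## Paired-eye GEE

Regional FD % is modelled marginally as

$$\mathrm{FD}\%_{ij} = \beta_0 + \beta_{\mathrm{age}}\,\mathrm{age}_i +
\beta_{\mathrm{sev}}\,\mathrm{stage}_i + \epsilon_{ij}$$

for eye *j* of patient *i*, with Gaussian working variance and identity
link, so each coefficient is the average FD % change per unit covariate.
DR severity enters as a continuous 0–4 score (no DR, mild, moderate,
severe NPDR, PDR). Patients are clusters; the working correlation is
exchangeable, i.e. the two eyes of a patient share a single correlation
α. Estimation iterates:

1. solve the estimating equations
   $\sum_i X_i' V_i^{-1}(y_i - X_i\beta) = 0$ with
   $V_i = \phi R_i(\alpha)$, starting at the OLS solution (the
   exchangeable $V_i^{-1}$ is analytic, so each update is a single set of
   grouped matrix products);
2. update the dispersion $\hat\phi = \sum r^2/(N-p)$;
3. update $\hat\alpha = \left[\sum_{i}\sum_{j<k} r_{ij} r_{ik} /
   (N^\ast - p)\right]/\hat\phi$ over within-cluster pairs
   ($N^\ast$ = number of pairs) — the classic moment estimators with
   degrees-of-freedom corrections.

Convergence is `max |Δβ| < 1e-8` (at most 100 iterations; typically
< 10). Estimates of α outside the valid range are clipped just inside it
with a warning; with no paired cluster, α is undefined and the fit
reduces exactly to OLS, flagged `no_pairs`. Inference uses the robust
sandwich covariance (bread–meat–bread over cluster contributions) and
two-sided Wald normal p-values; model-based SEs are also reported. Model
confirmation uses the quasi-likelihood-under-independence criterion

$$\mathrm{QIC} = -2\,QL(\hat\beta) + 2\,\mathrm{tr}(\hat\Omega_I \hat V_R),
\qquad QL = -\tfrac{1}{2\hat\phi}\sum (y-\hat y)^2,$$

with $\hat\Omega_I = X'X/\hat\phi$ the independence-model information and
$\hat V_R$ the robust covariance. For independent data under an
independence working model the trace term approaches the coefficient
count, recovering the quasi-AIC penalty. The whole engine is written in
the package and verified, on fixed fixtures, against an independent GEE
implementation to 1e-6 relative agreement.

## Synthetic data: what it emulates and what it does not

**Angiograms.** `generate_angiogram()` places a requested number of
connected deficit blobs, grown by randomised accretion under the same
connectivity the labeler uses, positioned so no two blobs touch even
diagonally. Deficit pixels take values in [0, 0.15] and background in
[0.3, 1], leaving a guard gap around the 0.2 threshold so binarisation
recovers the ground truth pixel-exactly even after 8-bit PNG
quantisation, and detected components correspond one-to-one with placed
ones. Component sizes can be an explicit list or drawn from Poisson,
geometric or uniform families — the defaults straddle the 500 µm² filter
so the area rule is exercised on both sides. These images are
*statistically*, not photometrically, realistic: no speckle texture,
projection artifacts or signal-strength gradients are simulated, so
passing pipeline tests demonstrates correctness of the computation, not
robustness to device noise.

**Cohorts.** `generate_cohort()` draws a study-sized population: 90
patients with severity-stage counts (33, 17, 8, 10, 22), a second eye
with probability 7/9 (≈160 eyes in expectation), ages from a normal with
mean 58.14 years truncated to [18, 100], and regional FD % from the
linear model plus a shared patient effect and an eye-level residual.
The default age SD (12 years) is an assumption chosen to span roughly
20–90 years; the study population's spread was not reported. The default
slopes and inter-eye correlations per region follow published effect
sizes for CC flow deficits in diabetic cohorts (age 0.12/0.09/0.05/0.06
FD %/year and severity 0.65/0.56/0.33/0.36 FD %/stage for
inner/middle/outer/full, α 0.29–0.35). The marginal SDs
(`sigma_total` = 4.7/3.2/2.1/2.3 FD %) were chosen once so that the
robust SEs implied at study size match the magnitudes such studies
report, and the intercepts keep marginal FD % in a realistic 8–20 %
range, which makes clamping to [0, 100] essentially impossible (clamping
events are nevertheless counted and reported). Severity is assigned per
patient, both eyes sharing a stage, mirroring per-patient clinical
grading.

```{r}
cfg <- cohort_config(seed = 1)
dat <- generate_cohort(cfg)
fit_gee(dat, "fd_inner")
```

## Numerical and design choices

- **Threshold rule** strict below; **area rule** strict below 500 µm²;
  both declared conventions where wording alone would be ambiguous at
  the boundary.
- **Connectivity** defaults to 8, the common choice for blob-like
  structures; the generator and labeler always share it.
- **Exact rational FD.** FD % is a ratio of integer counts; the
  weighted-sum identity (full-field FD × frame pixels = Σ ring FD × ring
  pixels + deficits outside 3 mm) holds exactly and is tested exactly.
- **α/φ estimators** use the N − p and N* − p denominator corrections;
  α is clipped to the open validity interval when tiny samples push the
  moment estimate outside it.
- **QIC convention.** The penalty is tr(information × robust
  covariance), the standard form of the criterion; note some texts write
  the same quantity with the inverse on the other factor.
- **Degenerate inputs.** Singular designs, fewer than p + 2 clusters, an
  all-singleton cohort (α undefined), over-dense angiogram specs and
  invalid metadata rows (stage outside 0–4, duplicate patient/eye,
  unreadable files) all fail with typed conditions; the study pipeline
  logs per-row rejections with machine-readable reasons and continues.
- **Problem sizes.** The package's recovery experiment defaults to 500
  simulated cohorts at study size (a few seconds per hundred cohorts);
  variance-component checks use 5000–10000 patients; the QIC
  working-correlation comparison is run at 1000 patients because with
  cluster-constant covariates QIC separates correlation structures only
  slowly — at 90 patients its preference for the correct structure is
  weak (about 2 in 3 simulations), which is a property of the criterion,
  not a defect of the implementation.

## Known limitations

- The robust sandwich variance is mildly anti-conservative at ~90
  clusters (its small-sample downward bias is well documented), so the
  nominal 5 % Wald test rejects slightly more than 5 % of null
  simulations at study size; no small-sample SE correction is applied,
  matching standard practice in the source analyses.
- Only exchangeable and independence working correlations are
  implemented; cluster sizes other than 1–2 are accepted but the
  exchangeable structure is most meaningful for paired organs.
- FD % is modelled as Gaussian despite being a bounded percentage; with
  FD % far from 0 and 100 this is the interpretation the field uses
  (coefficients as absolute FD % change), but it would be inappropriate
  near the bounds.
- The pipeline consumes already-exported en face CC slabs; device-side
  slab segmentation, image-quality grading and clinical severity grading
  are out of scope.
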