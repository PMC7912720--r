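---
title: "Models and methods behind vertebrotwin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vertebrotwin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vertebrotwin)
```

vertebrotwin asks a quantitative-genetics question about vascular anatomy:
how much of the person-to-person variation in the geometry of the
vertebrobasilar system — the two vertebral arteries (VA) merging into the
basilar artery (BA) — is attributable to genes, to environment shared within
a family, and to environment unique to the individual? The package contains
three layers: a morphometry engine that turns labeled 3D centerlines into
geometric indices, a classical-twin variance-component engine that
decomposes the covariance of those indices across monozygotic (MZ) and
dizygotic (DZ) twin pairs, and a synthetic cohort generator that makes the
whole chain testable without access to any imaging data.

## The twin variance-component model

For a phenotype measured on both members of a twin pair, write the pair
vector as bivariate normal with a common mean model
$\mu_{ij} = x_{ij}^\top\beta$ and covariance

$$
\Sigma_z \;=\;
\begin{pmatrix} \sigma^2 & c_z \\ c_z & \sigma^2 \end{pmatrix},
\qquad
\sigma^2 = a^2 + c^2 + e^2,
\qquad
c_{MZ} = a^2 + c^2,\quad c_{DZ} = \tfrac12 a^2 + c^2 .
$$

The decomposition rests on the classical-twin assumptions: MZ pairs share
all their segregating genes and DZ pairs on average half (the DZ genetic
correlation of 0.5 assumes random mating and purely additive gene action —
no dominance, hence no ADE variant here); both kinds of pairs share their
common environment to the same degree (the equal-environments assumption);
and unique environment $e^2$, which includes measurement error, is
independent between members. Heritability is the standardized share
$A = a^2/\sigma^2$, and the model-implied intrapair correlations are
$r_{MZ} = (a^2+c^2)/\sigma^2$ and $r_{DZ} = (a^2/2+c^2)/\sigma^2$, so
$r_{MZ} \ge r_{DZ}$ with equality exactly when $a^2 = 0$.

`twin_ace()` maximises the sum of pair log-densities by full-information
maximum likelihood. Implementation choices that matter:

* **Non-negativity** is enforced by optimising path coefficients
  $(a, c, e)$ whose squares are the variance components, rather than by
  constrained optimisation; $e^2$ additionally carries a floor of $10^{-8}$
  times the phenotypic variance so $\Sigma_z$ stays positive definite at
  the $E \to 0$ boundary.
* **Mean profiling.** Given the covariance parameters, the mean
  coefficients have a closed-form generalised-least-squares solution, so
  the numeric optimisation runs over at most three parameters. Because the
  pair likelihood depends on the data only through per-zygosity sufficient
  statistics (cross-products of responses and design columns), one
  likelihood evaluation costs the same at 30 pairs as at 30,000.
* **Multi-start.** The default is five quasi-Newton starts: one at the
  Falconer method-of-moments point ($A = 2(r_{MZ}-r_{DZ})$,
  $C = 2r_{DZ}-r_{MZ}$, clipped to the simplex) and four jittered
  variants. The deterministic jitter stream is derived from a fixed label,
  so fits are reproducible.
* **The saturated reference** frees both within-order variances and the
  covariance per zygosity group (six covariance parameters) while keeping
  the means order-symmetric. Twin order is arbitrary, so this reference
  also exercises variance homogeneity across order; the likelihood-ratio
  test of any structured model against it has df equal to the parameter
  difference (3 for ACE).
* **Model selection** is by minimal AIC ($-2\ell + 2k$), with BIC
  ($-2\ell + k\ln N$) and then parameter count as tie-breakers. $N$ in the
  BIC is the number of *subjects* (twice the pair count); conventions
  differ across software and published tables cannot always be inverted to
  reveal one, so the package fixes and documents this choice.
* **Confidence intervals** for the standardized shares are
  profile-likelihood intervals: the share $t$ is fixed, the total variance
  and the split of the complement are re-maximised, and the bound solves
  $2\{\ell_{\max}-\ell_p(t)\} = \chi^2_{1,0.95} = 3.841$, truncated to
  $[0,1]$. This reproduces the boundary-touching intervals
  (e.g. lower bounds of exactly 0) that Wald intervals cannot produce. A
  parametric bootstrap is used in the test suite as an independent check,
  not as the default method.
* **Intrapair correlations** are one-way ANOVA intraclass correlations on
  residuals after an ordinary least-squares age/sex adjustment,
  $(MSB - MSW)/(MSB + MSW)$ with pairs as groups, and Fisher-z intervals
  with effective $n$ equal to the pair count. Pearson on arbitrarily
  ordered pairs depends on the ordering and double-entry inflates the
  effective sample size, so the ANOVA form was chosen.
* **Covariate adjustment** follows the two-model idiom: "Model 1" adjusts
  means for age and sex only; "Model 2" additionally includes the recorded
  risk factors (exercise, alcohol, smoking, diabetes, hypertension,
  dyslipidemia, height, weight, BMI — nine extra terms). Their joint
  contribution is tested by the deviance difference on 9 df
  (`deviance_lrt()`); per-covariate effects carry Wald intervals from the
  GLS information. No multiple-testing correction is applied across
  phenotypes; this mirrors the analysis convention of the field and is
  flagged here rather than silently changed.
* Incomplete pairs are dropped and counted (`n_dropped`), matching a
  complete-pair design; collinear covariates raise an error instead of
  being silently absorbed.

## Morphometry of vessel centerlines

All measurements operate on ordered 3D polylines with a per-point
maximum-inscribed-sphere radius, in millimetres, in a patient-LPS-like frame
(+X patient-left, +Z superior). The measurement pipeline per vessel is:
resample to uniform arc length (default 0.5 mm), Taubin-smooth
(default $\lambda = 0.5$, $\mu = -0.53$, 20 double passes), then estimate.

* **Curvature** at each interior point is the inverse circumradius of the
  circle through the point and its neighbours — the discrete osculating
  circle. **Torsion** is the signed dihedral angle between consecutive
  osculating planes divided by the arc step; it is the noisiest discrete
  quantity, which is why smoothing and uniform resampling precede it, and
  why the per-vessel summary uses the mean *absolute* torsion.
* The tabulated "curvature (%)" and "torsion (%)" indices are the mean
  pointwise values in mm⁻¹ multiplied by 100; this normalisation
  reproduces the magnitude of published population values (≈0.08 mm⁻¹ →
  8%). The exact normalisation behind published percent units is not
  stated anywhere authoritative; this reading is fixed and documented.
* **Tortuosity** is $(1 - \text{chord}/\text{arc}) \times 100$. Verbal
  definitions in the literature sometimes state the inverted ratio, which
  conflicts with the small percentages those same papers tabulate; both
  the percentage and the raw chord/arc ratio are therefore returned.
* **Basilar bend** follows a two-step construction: join the
  vertebrobasilar confluence and the basilar tip with a straight line;
  project every centerline point perpendicularly onto that chord and take
  the *median absolute* X offset as the bend magnitude, and the sign of
  the *median signed* offset as the lean (+X = leaning patient-left).
  Median-of-absolute gives a magnitude robust to single kinks; the signed
  median carries the direction.
* **Diameter** is the equivalent diameter $2\sqrt{\bar A/\pi}$ of the
  arc-length-weighted mean cross-sectional area over the full V4 segment
  (published tables do not state where along V4 a single diameter is
  read, so an integral summary is used). **Volume** is the trapezoidal
  integral of area along arc length; a watertight swept tube mesh with a
  divergence-theorem volume serves as an independent oracle, agreeing
  within 1% at 64 circumferential segments and 0.1 mm spacing.
* **Dominance**: a side is dominant when its diameter exceeds the other
  side's by strictly more than 0.3 mm; a boundary-exact difference is
  "equal".
* **Branch identification** prunes spur branches shorter than 3 mm
  (reconstruction artifacts; no published threshold exists, so 3 mm — an
  order of magnitude below a V4 length — is the default), requires exactly
  one three-way junction, labels the most superior free endpoint as the
  basilar artery, and splits the vertebral arteries by the X coordinate of
  their free endpoints. Labels are invariant to input order and polyline
  direction; an exact X tie is an error rather than an arbitrary choice.
* The Taubin passes use an umbrella Laplacian projected onto the local
  normal plane, so points do not slide tangentially and a straight
  polyline is an exact fixed point; the negative $\mu$ pass keeps circle
  shrinkage two orders of magnitude below plain Laplacian smoothing at the
  default settings.

## The synthetic cohort

The generator exists so that every downstream stage has a ground truth. It
emulates the study conditions of a mid-sized adult twin registry sample —
67 MZ and 33 DZ same-sex pairs, MZ ages 49.57 (SD 14.42) and DZ ages 56.0
(SD 15.23) years, about two-thirds female, adult risk-factor prevalences —
and, per subject, a Y-shaped vessel network.

Phenotypes are Gaussian with the exact ACE covariance structure:
shared-environment deviates are drawn once per pair, unique deviates per
subject, and the additive-genetic deviate is pair-identical for MZ and
built as $\sqrt{0.5}\,(\text{shared}) + \sqrt{0.5}\,(\text{unique})$ for
DZ. Default means, dispersions and A/C/E shares per index are set to the
published population values where those exist; dispersions of the percent
indices, which are published without SDs, use coefficients of variation
comparable to the indices that do have them (about 30%). Covariate effects
default to the two consistently reported ones — smoking on the basilar and
left vertebral diameters (≈0.21–0.22 mm) and height on the basilar diameter
(0.025 mm/cm) — with all other slopes zero. Gaussianity itself is an
assumption of the ACE likelihood, not an established property of these
indices; the generator states it rather than asserts it.

Vessel networks are built from twelve per-subject geometric targets. The
basilar artery is a parametric space curve along the confluence–tip chord:
an X-direction half-sine bump whose amplitude is solved (by nested
root-finding against the *measurement pipeline itself*) to hit the bend
target, plus a Y-direction full-sine wiggle solved to hit the arc length,
hence the tortuosity. The vertebral arteries are circular-helix arcs: for
target curvature $\kappa$ and torsion $\tau$ the helix parameters are the
closed forms $a = \kappa/(\kappa^2+\tau^2)$, $b = \tau/(\kappa^2+\tau^2)$,
swept until the chord/arc ratio meets the tortuosity target, then placed
rigidly so the arc terminates at the confluence from below and from the
correct side. Rigid placement — rather than blending into the confluence
with an easing segment — was chosen deliberately: a blend region perturbs
the mean curvature and torsion and would break the closed-form round-trip
guarantee, while the network contract only requires endpoint coincidence
at the confluence. A small fixed-point calibration inflates the effective
helix parameters so that the *measured* (smoothed) indices, not the ideal
ones, land on the targets; smoothing otherwise attenuates discrete torsion
by a few percent.

Not every target combination is geometrically realisable: a given bend
forces a minimum arc-length excess (minimum tortuosity), and a helix cannot
exceed the tortuosity of one full turn. `clamp_geometry_targets()`
projects simulated target vectors into the feasible region (and, for bends
too deep for any tortuosity, shrinks the bend); the round-trip property —
build, then measure, recover every index within 2% relative and the bend
within 0.05 mm — is tested over 100 random draws in the physiological
range. Perturbation adds Gaussian jitter to points and radii and, with a
configurable probability, one sub-threshold spur branch, emulating
segmentation artifacts; landmarks are never jittered.

What passing tests on this generator do **not** show: real TOF-MRA
reconstructions have spatially correlated segmentation noise, flow-related
signal dropout, true anatomical variants (fenestrations, hypoplastic
V4 segments ending in PICA), and non-Gaussian index distributions. The
generator makes no attempt at voxel-level realism; it validates the
measurement and inference machinery, not the imaging chain.

## The pipeline and its numbers

`run_pipeline()` chains simulate → build/perturb/measure → model. Each
stage writes plain CSV and can be re-run standalone; every number in the
report bundle is a deterministic function of (configuration, master seed),
with per-stage streams derived from the master seed by a labelled
counter-based split. The heritability table carries one row per measured
index (16 by default: the 12 generated targets plus the derived area,
volume, VA difference and BA diameter), with the AIC-selected model's
standardized components, profile intervals, intrapair correlations and the
saturated-model p-value; the covariate tables mirror the two-model
adjustment logic described above.

Problem sizes used in the shipped test-suite and acceptance script were
chosen to bound Monte-Carlo error at the tolerance being asserted: e.g.
parameter recovery uses 2000 MZ + 1000 DZ pairs and 200 replicates per
corner of the (A, C, E) grid, where the standard error of the mean absolute
error is well below the 0.05 criterion; the profile-interval coverage check
uses an interior simplex point (0.3, 0.3, 0.4), since at boundary truths
the 95% two-sided coverage statement itself does not apply. The power check
for the MZ/DZ age contrast asserts the pilot-computed ~51% detection rate
band rather than a "significant in most runs" claim that the design cannot
support.

## Known limitations

* No dominance (ADE), sex-limitation, or bivariate/Cholesky models; no
  opposite-sex DZ pairs. These are out of scope of the univariate same-sex
  design implemented here.
* Mean-model inference conditions on the fitted variance parameters (the
  usual GLS practice); coverage of covariate Wald intervals is verified by
  simulation but will degrade at very small pair counts.
* The saturated model uses order-symmetric means; designs with meaningful
  twin order (e.g. birth order effects on the mean) would need an extended
  reference.
* Geometric feasibility clamping slightly distorts the tails of the
  simulated index distributions (deep bends get extra tortuosity), so the
  ACE structure of *measured* indices is approximate in those tails at the
  defaults.
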