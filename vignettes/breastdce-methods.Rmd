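---
title: "Models and methods behind breastdce"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind breastdce}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breastdce)
```

`breastdce` reimplements, as a reusable and fully tested pipeline, a
volumetric DCE-MRI radiomics analysis for discriminating benign from
malignant enhancing breast lesions and for quantifying avoidable benign
biopsies at high-sensitivity operating points. This vignette explains
the underlying models, the parameters that matter, the numerical
choices, and what the synthetic experiments do and do not demonstrate.

## Signal and pharmacokinetic model

Each voxel carries a signal-intensity time curve sampled by the
acquisition protocol: one precontrast frame (P⁰, t = 0) and seven
postcontrast frames at 60 s spacing, with the early readout P¹ at 1 min
and the delayed readout P² at 7 min (`dce_protocol()`). Tissue contrast
concentration follows the two-compartment Tofts model,

$$C_t(t) = k^{trans} \int_0^t C_p(\tau)\, e^{-k_{ep}(t-\tau)} d\tau,
\qquad k_{ep} = k^{trans}/v_e,$$

with a bi-exponential population AIF
$C_p(t) = D\,(a_1 e^{-m_1 t} + a_2 e^{-m_2 t})$. For this AIF the
convolution has a closed form (implemented in `tofts_concentration()`,
verified in the test suite against trapezoid numerical convolution to
1e-4 relative across a 20×20 parameter grid, including the removable
singularity $k_{ep} = m_i$).

The signal model is linear in concentration:
$SI(t) = S_0\,(1 + \alpha\, C_t(t)) + \varepsilon$, with
$\varepsilon \sim N(0, \sigma^2)$. Working in relative-enhancement units
through the single gain $\alpha$ avoids committing to a T1/relaxivity
calibration that clinical software resolves with population T1 values;
the consequence, discussed under *Limitations*, is that absolute
$k^{trans}$/$v_e$ scales are internally consistent but not comparable
across software.

Key parameters, defaults and rationale:

| parameter | default | unit | why |
|---|---|---|---|
| dose $D$ | 0.1 | mmol/kg | standard Gd-DTPA bolus |
| $a_1, a_2$ | 3.99, 4.78 | kg/L | Weinmann-type population constants |
| $m_1, m_2$ | 0.144, 0.0111 | 1/min | fast/slow plasma clearance |
| $\alpha$ | 8 | 1/(mM-equiv.) | puts benign mean wash-in near 50% and malignant near 115%, the clinically typical range |
| $S_0$ | 100 | a.u. | arbitrary baseline |
| noise SD | 3 | a.u. | ≈3% of baseline, a high-SNR breast protocol |
| iAUC window | 90 | s | common convention for "initial" enhancement area |

## Synthetic cohort generator

The generator exists so the whole analysis is exercisable end to end
with known ground truth. Defaults mirror the population structure of a
consecutive clinical series of biopsied enhancing lesions: 470 lesions,
62.8% malignant, largest diameters between 5 and 91 mm with median
16 mm. The size distribution itself is unreported in that series; we
default to a log-normal (median 16 mm, log-SD 0.55, truncated to
5–91 mm) and flag this as a modeling assumption, not a reproduced fact.

Lesions are ellipsoids whose voxelwise kinetics are class means
modulated by a smooth multiplicative log-normal random field (Gaussian
white noise, separably smoothed at a 3 mm correlation length,
exponentiated to unit mean and configured CV). Class defaults — malignant
$k^{trans}$ 0.25/min vs benign 0.08/min; malignant $v_e$ 0.30 vs benign
0.55; all CVs 0.3 — follow the qualitative direction established for
breast lesions (malignancy: higher transfer constant, smaller EES
fraction) at magnitudes typical of the quantitative-DCE literature.
Between-lesion variability uses the same CV on the class means. An
optional `parenchyma_fraction` gives background voxels slow persistent
enhancement below the segmentation threshold, to exercise edge cases.

What the generator deliberately does **not** emulate: patient motion
(the clinical pipeline's elastic registration is out of scope and the
synthetic scenes are motion-free), coil bias fields, Rician noise floors
at low SNR (noise is Gaussian; a Rician flag would be a small extension),
irregular/spiculated lesion shapes, and background parenchymal
enhancement overlapping the lesion threshold. Passing tests therefore
show the *pipeline machinery* is correct under the stated statistical
structure; they do not certify classifier performance on clinical data.

## Segmentation and curve typing

Segmentation reproduces supervised threshold-driven volumetric region
growing: from a seed voxel, the 26-connected component of voxels whose
wash-in $(SI(P^1) - SI(P^0))/SI(P^0)$ is at least 33%. Inclusivity of
the threshold follows from the first curve category being "33–50%
(slow)". A sub-threshold seed raises a "non-enhancing seed" error; no
morphological cleanup is applied. Externally supplied masks are accepted
through `as_lesion_mask()` in place of the clinical manual-segmentation
fallback. In-memory voxel indices are 1-based (the R convention); all
files written by the I/O layer use 0-based indices.

Curve types combine the initial band — slow (33–50%], medium (50–100%],
fast (>100%) — with the delayed change relative to P¹: persistent
(>+10%), plateau (±10%, inclusive), washout (<−10%). Boundary ties are
resolved downward for the initial band (exactly 0.50 → slow, exactly
1.00 → medium) and into plateau for the delayed band, reading "stable
signal ± 10%" as inclusive.

## The 86-feature vector

Seven groups, concatenated in a fixed documented order
(8+8+7+7+9+33+8+3+3 = 86): mean curve SIs; the three most-suspicious
3×3 voxel-cluster curves (maximum wash-in, absolute 8 points; maximum
wash-out and maximum wash-in/wash-out, relative 7 points); curve-type
subvolume percentages (the 9 cells sum to 100); percentiles
{10,20,25,30,40,50,60,70,75,80,90} of iAUC, $k^{trans}$ and $v_e$ over
successfully fitted voxels; two wash-out rates per representative curve
(relative SI at the first/second postcontrast frame minus the final
value); the three overall delayed-phase percentages (marginals of the
9 cells); and the three pharmacokinetic IQRs.

Open design points we had to pin down:

- **Cluster scoring.** Clusters are in-plane (axial) 3×3 neighborhoods
  fully inside the mask, matching a multislice axial acquisition. The
  combined wash-in/wash-out score is the unweighted sum of the wash-in
  score (mean P⁰→P¹ relative enhancement) and wash-out score (mean
  P¹→P² relative decrease) — the simplest choice monotone in both.
  Masks admitting no complete neighborhood fall back to the single most
  extreme voxel, with a flag counted in the run summary.
- **Percentile method.** Linear interpolation between closest ranks
  (R's type 7), pinned so that the values are exactly reproducible and
  testable against a sort-and-interpolate oracle.
- **Wash-out rate references.** "Two values per curve" is implemented
  literally: the first and the second postcontrast frames each serve as
  the initial reference against the final frame, for each of the four
  curves.
- **Voxel universe.** All curve-derived features are computed over
  threshold-passing voxels only; sub-threshold voxels are excluded from
  analysis. Histogram features use only voxels whose Tofts fit
  converged.

## Voxelwise fitting

`fit_tofts_map()` solves bounded nonlinear least squares
($k^{trans} \in [0, 5]$/min, $v_e \in (0.01, 1]$) for every voxel
simultaneously: a damped Gauss–Newton (Levenberg–Marquardt) iteration in
matrix form, started from a 3×3 coarse parameter grid with the best of
the nine local solutions kept per voxel. On noise-free model data the
fitter recovers parameters to better than 1e-3 and residual RMS below
1e-8; with 5% Gaussian noise on 8-point curves the median relative
$k^{trans}$ error stays under 15% (both are test assertions). All-zero
or non-finite curves are flagged `fit_ok = FALSE` and excluded from
histogram features rather than raising.

## Dimension reduction and classifier

PCA operates on the training-set correlation matrix: the features mix
signal intensities, percentages and fractions, so an eigenvalue cutoff
is only meaningful after standardization. Components with eigenvalue
strictly greater than 3 are retained ("higher than" the cutoff);
zero-variance features are dropped with a warning and recorded in the
model; eigenvector signs are fixed by making the largest-magnitude
loading positive. Held-out lesions are standardized with training means
and SDs only — no leakage, verified by test.

The classifier is a one-hidden-layer MLP with softmax output (the
malignant-class output is the *pseudo-probability* used as decision
score), trained in batch mode by Møller's scaled conjugate gradient with
$\lambda_1 = 5\times10^{-7}$ and $\sigma = 5\times10^{-5}$.
Cross-entropy is the loss — the canonical pairing with a softmax output
layer. Training stops when the relative change in training error falls
below 1e-4 or the relative change in the error ratio (error scaled by
its initial value) falls below 1e-3; because single SCG steps can be
transiently tiny on plateaus, the rule requires three consecutive
sub-tolerance steps, with a hard ceiling of 1000 epochs guaranteeing
termination. Weights initialize uniformly in [−0.5, 0.5] under the
configured seed.

The architecture — hidden-unit count within 1–50 and tanh vs logistic
activation — is chosen automatically on an internal 80/20 validation
split of the training data by validation cross-entropy, ties going to
the smaller network. The default search ladder spans
{1,…,6, 8, 10, 12, 16, 20, 25, 30, 40, 50}; `study_config()` uses a
10-point ladder. Searching every integer would add cost without
changing the selected region of model capacity.

## Cutoffs, intervals and avoidable biopsies

Cutoffs are identified on the training set only: among all observed
scores (plus −∞), the threshold maximizing specificity subject to
training sensitivity ≥ 100% (C₁) or ≥ 95% (C₂), under the operating
rule *positive ⇔ score > threshold*, ties resolved toward the larger
threshold. They are then applied unchanged to the untouched test set,
where specificity equals the fraction of avoidable benign biopsies,
since the modeled population consists exclusively of biopsied
suspicious findings. False-negative lesions are listed for audit.

Proportion CIs default to the exact Clopper–Pearson interval; the
Wilson score interval is available as an option. The published
benchmark that `reproduce_reference_metrics()` recomputes is internally
mixed on this point — its test-set and training-sensitivity intervals
match Clopper–Pearson exactly, while its training-specificity intervals
match Wilson — so both are reported for those rows and no intent is
guessed. One display value in that benchmark (PPV at C₁) prints as
60.0% where the raw counts give 88/147 = 59.9%; the package reports the
arithmetic value. ROC AUC uses the trapezoid (equivalently the
tie-corrected Mann–Whitney statistic, asserted against exhaustive pair
counting), with DeLong variance for the CI and the test against
AUC = 0.5.

## Reference synthetic study and problem sizes

`study_config()` defines the package's canonical experiment: 470
lesions at 62.8% prevalence with the default class kinetics, rendered
on compact grids — log-normal largest diameters with median 8 mm,
truncated to 5–25 mm — so that the complete study (≈10⁵ voxelwise Tofts
fits plus training) finishes in about two minutes on one CPU. The
compact grids are the package's chosen problem size for routine runs
and testing; the generator's own defaults retain the full clinical size
range (5–91 mm, median 16 mm). Under the reference study the test-set
AUC is far above the 0.75 floor asserted in the acceptance suite; the
default synthetic effect sizes separate the classes more cleanly than
clinical feature distributions do, which is exactly why the synthetic
AUC must not be read as a clinical performance estimate.

## Known limitations

- Absolute $k^{trans}$/$v_e$ values depend on the chosen AIF constants
  and the linear signal gain; only their statistical behavior — class
  separation, heterogeneity, percentile ordering — is meaningful.
- The extended Tofts model (plasma-volume term), measured per-patient
  AIFs, T1/B1 mapping and motion correction are out of scope.
- With the default kinetics and the slow terminal decay of the
  bi-exponential AIF, pronounced delayed-phase washout occurs only at
  high $k_{ep}$; malignant lesions separate mainly through wash-in
  magnitude and the pharmacokinetic histograms, slightly muting the
  curve-type features relative to clinical data.
- Morphological, textural and T2-based features are not implemented.
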