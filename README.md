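# breastdce

Volumetric (4D) DCE-MRI radiomics for classifying enhancing breast
lesions as benign or malignant, and for quantifying how many benign
biopsies a high-sensitivity classifier could avoid.

## The problem

In dynamic contrast-enhanced breast MRI (DCE-MRI), a T1-weighted volume
is acquired once before and repeatedly after contrast injection
(here: 8 frames at 60 s temporal resolution). Malignant lesions tend to
enhance faster (higher transfer constant k<sup>trans</sup>) and wash out
earlier (lower extravascular extracellular fraction v<sub>e</sub>) than
benign ones. Because suspicious lesions are referred to biopsy and most
biopsied lesions in screening populations are nevertheless benign, a
classifier operating at (near-)perfect sensitivity can only help by
raising specificity — every correctly identified benign lesion is an
avoidable biopsy.

`breastdce` implements the complete analysis chain as a tested R
package:

1. **Synthetic cohort generator** — seeded 4D signal-intensity series
   from the Tofts pharmacokinetic model with a population arterial input
   function (AIF), class-conditional kinetics, smooth intra-lesion
   heterogeneity fields and Gaussian noise. Every downstream stage is
   testable without any image download.
2. **Pharmacokinetics** — closed-form Tofts tissue concentration
   C<sub>t</sub>(t) = k<sup>trans</sup> ∫ C<sub>p</sub>(τ)
   e<sup>−k<sub>ep</sub>(t−τ)</sup> dτ for a bi-exponential
   C<sub>p</sub>, bounded voxelwise least-squares mapping of
   (k<sup>trans</sup>, v<sub>e</sub>), and the initial area under the
   enhancement curve (iAUC, 90 s window).
3. **Segmentation** — seed-grown 26-connected region of voxels whose
   wash-in (P⁰→P¹ relative enhancement) is at least 33%.
4. **Feature extraction** — the 86-parameter lesion vector: mean and
   representative 3×3-cluster curves, the 9 enhancement-curve-type
   subvolume percentages (initial slow/medium/fast × delayed
   persistent/plateau/washout), wash-out rates, and histogram summaries
   (11 percentiles + IQR) of iAUC, k<sup>trans</sup> and v<sub>e</sub>.
5. **Dimension reduction** — PCA on the training correlation matrix,
   retaining components with eigenvalue > 3.
6. **Classifier** — one-hidden-layer MLP (softmax output = the
   pseudo-probability of malignancy) trained with Møller's scaled
   conjugate gradient in batch mode (λ₀ = 5×10⁻⁷, σ = 5×10⁻⁵),
   architecture selected automatically over 1–50 hidden units and
   tanh/sigmoid activations.
7. **Diagnostic evaluation** — ROC with DeLong inference, the
   high-sensitivity training cutoffs C₁ (sensitivity 100%) and C₂
   (≥ 95%) transferred unchanged to the test set, Clopper–Pearson exact
   (or Wilson) confidence intervals, likelihood ratios and the
   avoidable-biopsy fraction (= specificity in an all-biopsied
   population).

## Worked example

```r
library(breastdce)
set.seed(1)

# one synthetic malignant lesion (12 x 10 x 8 mm ellipsoid)
les  <- generate_lesion_volume(lesion_spec(label = "malignant",
                                           semi_axes = c(6, 5, 4)))
mask <- segment_lesion(les, les$seed_voxel)
mask
#> lesion mask: 164 voxels, seed (12, 13, 6), wash-in >= 0.33

fx <- extract_lesion_features(les, mask)
round(fx$features[c("mean_si_t0", "mean_si_t1", "ktrans_p50", "ve_p50",
                    "iauc_p50", "overall_pct_persistent")], 3)
#>             mean_si_t0             mean_si_t1             ktrans_p50
#>                 99.687                207.773                  0.243
#>                 ve_p50               iauc_p50 overall_pct_persistent
#>                  0.278                 67.185                 68.902
```

The lesion enhances from a baseline of ~100 to ~208 at 1 min (wash-in
above 100%), the median fitted k<sup>trans</sup> (0.243/min) recovers the
simulated class mean (0.25/min), and v<sub>e</sub> sits in the malignant
range.

Diagnostic arithmetic from a 2×2 table (88 cancers, 69 benign lesions;
the published benchmark's test-set counts at its 100%-sensitivity
cutoff):

```r
contingency_metrics(tp = 88, fp = 59, tn = 10, fn = 0)
#> counts TP=88 FP=59 TN=10 FN=0
#>  sensitivity 100.0% (95% CI 95.9-100.0%)
#>  specificity 14.5% (95% CI 7.2-25.0%) (avoidable biopsies)
#>  PPV 59.9% (95% CI 51.5-67.9%)  NPV 100.0% (95% CI 69.2-100.0%)
#>  accuracy 62.4% (95% CI 54.3-70.0%)
#>   +LR 1.2  -LR 0.0
```

At 100% sensitivity, 14.5% of the benign biopsies would have been
avoided.

## The analysis workflow

The `analysis/` directory holds the numbered drivers of the full
synthetic study (470 lesions, 62.8% malignant), each writing its tables
under `results/`:

| script | what it does |
|---|---|
| `01_simulate_cohort.R` | draw the seeded cohort; truth table + NIfTI samples |
| `02_segment_extract.R` | segment every lesion and extract the 86 features |
| `03_reduce_train.R` | 70/30 split, PCA (eigenvalue > 3), SCG-trained MLP |
| `04_evaluate_cutoffs.R` | ROC, C₁/C₂ cutoffs, avoidable-biopsy report |
| `05_benchmark_table.R` | recompute the published benchmark table from counts |

Run them in order from the repository root:
`for s in analysis/0*.R; do Rscript $s; done`

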