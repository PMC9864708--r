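# capmech

Coronary plaque cap mechanics and vulnerability-index prediction in R.

Fibrous-cap rupture drives most acute coronary events, and the classic
marker of a vulnerable plaque is a thin fibrous cap over a lipid core.
`capmech` implements an analysis pipeline for studying how plaque
vulnerability evolves between a baseline and a follow-up imaging study,
working from segmented IVUS+OCT cross-section contours:

1. **Morphology** — lumen area (LA), plaque area (PA), plaque burden
   PB = PA/(PA+LA), and minimum/mean fibrous-cap thickness
   (MinCapT/MeanCapT) sampled at 100 evenly spaced lumen points grouped in
   four quarters (Four-Quarter Even-Spacing).
2. **Zero-load recovery** — in-vivo contours are pre-shrunk (5% axial,
   per-slice circumferential shrink found by bisection/regula falsi) so
   that re-pressurising the zero-load geometry reproduces the in-vivo
   lumen area.
3. **Thin-slice biomechanics** — a generalized-plane-strain finite-element
   model with modified Mooney–Rivlin materials

   W_iso = c1(I1̄−3) + c2(I2̄−3) + D1[exp(D2(I1̄−3))−1],
   W_aniso = W_iso + (K1/K2){exp[K2(I4̄−1)²]−1},

   with literature constants per tissue (vessel c1 = −262.6 kPa,
   c2 = 22.9 kPa, D1 = 125.9 kPa, D2 = 2.0, K1 = 7.19 kPa, K2 = 23.5;
   lipid c1 = 0.5, D1 = 0.5, D2 = 1.5; calcification c1 = 92, D1 = 36,
   D2 = 2.0), solved under lumen pressure (follower load) and prescribed
   axial stretch 1/0.95. Cap predictors: maximum/mean principal Cauchy
   stress (MaxCapS/MeanCapS, kPa) and Green–Lagrange strain
   (MaxCapSn/MeanCapSn) at the lumen wall over the cap.
4. **PVI scoring** — five ordinal plaque-vulnerability indices (1 = least,
   4 = most vulnerable): cap-thickness C-PVI with cuts (0.20, 0.26,
   0.36] mm and stress/strain indices whose cuts are either the published
   ones or calibrated to best match C-PVI.
5. **Prediction** — a 50-tree random forest under five-fold
   cross-validation repeated 100 times predicts the binary change
   (ΔPVI > 0) of each index from the nine baseline risk factors, sweeping
   all 2⁹−1 = 511 predictor combinations and reporting Acc/Sen/Spe/AUC at
   the Youden-optimal cutoff.

Patient data of this kind are not publicly available, so the package
ships a seeded synthetic cohort generator (`generate_cohort()`) that
reproduces the study conditions: 114 matched baseline/follow-up slice
pairs from 10 patients, a right-skewed cap-thickness distribution
(≈ 79/21/7/7 across the four C-PVI categories), and minority-class
progression outcomes linked to baseline morphology.

## Worked example

```r
library(capmech)

# one synthetic slice pair
pairs <- generate_cohort(cohort_spec(n_patients = 1, slices_per_patient = 1,
                                     seed = 3))
sl <- pairs[[1]]$baseline
morphology(sl)[, c("LA", "PA", "PB", "MinCapT", "MeanCapT")]
#>         LA       PA        PB   MinCapT  MeanCapT
#> 1 8.636407 17.60181 0.6708463 0.5322692 0.6158724

# zero-load recovery + FE solve + cap mechanics
f <- slice_features(sl)
f[, c("MaxCapS", "MeanCapS", "MaxCapSn", "MeanCapSn", "circ_shrink")]
#>    MaxCapS MeanCapS MaxCapSn MeanCapSn circ_shrink
#> 1 135.8635 120.7467 0.151743 0.1449054   0.1205848
```

LA/PA are in mm², cap thicknesses in mm, stresses in kPa, strains
dimensionless. A MinCapT of 0.53 mm scores C-PVI 1 (thick, stable cap);
a maximum cap stress of 136 kPa falls in the most vulnerable published
MaxS-PVI category (> 110 kPa), and a 12% circumferential shrink was
needed to recover the zero-load geometry. The numbers above are what the
code prints for this seed; run the snippet to reproduce them.

The numbered scripts under `analysis/` chain the full study on the
synthetic cohort (simulate → morphology → mechanics → PVI scoring →
prediction sweep), writing tables under `results/`.

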