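# hiplife

Fatigue-life prediction for the femoral component of a hip prosthesis.

`hiplife` is for orthopedic-biomechanics researchers and implant
engineers who want a patient-level estimate of how long a femoral stem
will last before **aseptic loosening** — the non-infectious failure of
the bone–stem interface — and for biostatisticians evaluating such
models.  Instead of a regression fitted to a large registry, it
implements a mechanistic three-parameter model that is fully identified
from the data of just **three** patients.

## The model

The implant–femur system is treated as a heterogeneous structure under
cyclic load obeying Basquin's stress-life law, S_amp = σ′_f·N^c.  The
cyclic contact stress at the hip–femur junction is eccentric
compression plus bending (torsion optional), driven by body mass *Q*
(kg), femoral offset *h* (mm), daily activity *T* (h/day) and a
lifestyle load coefficient *K* (multiples of body weight, 2.2 = normal
walking … 7.2 = stumbling).  Everything implant-specific collapses into
three constants (c₁, c̄₂, c):

```
Q·K·(1 + c₁h) = c̄₂·(T·N_M)^c      ⇒      N_M = (1/T)·( c̄₂ / (K·Q·(1 + c₁h)) )^(−1/c)
```

where N_M is durability in months (30-day months, one step per 1.11 s).
Three patients with known (Q, K, h, T) and observed months determine
(c₁, c̄₂, c) exactly; `hiplife` solves that system by a transparent
one-dimensional log-collinearity root-find.

The package also provides the activity-score→K mappings, a full
validation suite (error metrics, exact Mann–Whitney U, Pearson
correlations, an OLS regression baseline), triplet cross-validation
with t-based parameter confidence intervals, a synthetic-cohort
generator, the bundled 18-patient reference cohort for the non-cemented
HA-coated RCM stem, and a `hiplife` command-line interface
(`exec/hiplife`).

## Worked example

```r
library(hiplife)

cohort <- reference_cohort("all")            # bundled 18-patient cohort
coeffs <- calibrate_triplet(cohort, ids = c(16, 17, 18))
coeffs
#> <model_coefficients>
#>   c1     = 0.05588659251  (per mm)
#>   c2_bar = 2616074054
#>   c      = -2.187400665  (fatigue exponent)
#>   provenance: triplet: 16, 17, 18
```

The calibrated exponent c ≈ −2.19 means stress roughly halves the
cycle count when it grows by 2^(1/2.19); c₁ ≈ 0.056/mm says each extra
millimeter of femoral offset adds ~5.6 % to the effective load.
Predicting for a heavy, very active patient (Q = 100 kg, T = 6 h/day,
h = 35.4 mm, K = 5.06):

```r
predict_months(Q = 100, K = 5.06, h = 35.4, T = 6, coeffs = coeffs)
#> [1] 118.6669       # months; this patient's implant was revised at 125
```

Validation on the 15 held-out assessment patients:

```r
validation_report(reference_cohort("assessment15"))
#> <validation_report>
#>   predicted months: min=118.86 max=297.65 mean=219.89 sd=48.84
#>   recorded months:  min=125.00 max=302.00 mean=224.33 sd=50.08
#>   Mann-Whitney U = 105.0, two-sided p = 0.767 (exact)
#>   r(recorded months vs): Q=-0.54 T=-0.84 h=-0.42
#>   model RMSE = 10.24 months; OLS baseline RMSE = 14.66 months
```

The predicted and recorded distributions are statistically
indistinguishable (high Mann–Whitney p), daily activity is the dominant
correlate of durability (r = −0.84), and the mechanistic model beats
the linear regression baseline by ~4.4 months of RMSE.  Triplet
cross-validation (calibrate on 3, test on 15, ten runs):

```r
summarize_cv(run_cv(cohort, triplets = published_cv_triplets()))
#> <cv_summary> 10 runs (0 failed)
#>   metrics (mean / sd):   rmse 13.49266 3.4664347   mape 5.02387 1.1206188  ...
#>   parameters (mean / sd / 95% CI):
#>  parameter        mean         sd    ci_lower    ci_upper
#>         c1  5.8378e-02 5.6207e-02  1.8170e-02  9.8586e-02
#>     c2_bar  8.7281e+09 1.0810e+10  9.9543e+08  1.6461e+10
#>          c -2.1425e+00 3.0887e-01 -2.3634e+00 -1.9215e+00
```

Out-of-sample error averages ~13.5 months; the wide parameter intervals
are the price of exact three-point identification.  Actionable
sensitivities come straight from the power law, e.g.
`sensitivity_table_mass()`: a 60 kg patient gains 8.7 % of implant life
by losing 10 kg, and one hour less daily exercise at T = 4 h/day buys
33.3 % (`sensitivity_activity(4, -1)`).

The same workflow runs from the shell:

```sh
hiplife calibrate --cohort cohort.csv --ids 16,17,18 --out coeffs.json
hiplife predict   --cohort cohort.csv --coefficients coeffs.json --out predicted.csv
hiplife crossval  --cohort cohort.csv --runs 10 --seed 1
```

## Scope notes

The coefficients are implant specific: the bundled triple applies to
the RCM stem the reference cohort received, and new implants need their
own three-patient calibration.  The model covers the fatigue-driven
aseptic-loosening pathway only — it does not predict infection, wear
debris, or patients whose implant never fails — and is meaningful for
roughly 2–7 h/day of activity and K within the interpolated 2.2–7.2
range.  See the methods vignette (`vignettes/fatigue-life-model.Rmd`)
for the model's assumptions, numerical choices, and known limitations.
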