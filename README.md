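# beadpk

Non-compartmental pharmacokinetics of dual-route hepatic irinotecan
delivery: transarterial chemoembolization with irinotecan-eluting beads
(DEBIRI) paired with intravenous infusion of the same drug.

## Who this is for

Pharmacokineticists and preclinical scientists analysing crossover designs
in which each subject receives, in every cycle, a hepatic bead embolization
(sampled over 20 h) followed 24 h later by an IV infusion (sampled over
48 h post-infusion), with plasma measured for the parent drug and its
~1000-fold-lower metabolite and censored at the assay's lower limit of
quantification (LLOQ).

## What it computes

**Dosing.** IV doses from body weight through the porcine allometric
surface-area relation, dose (mg) = 0.0734 · W^0.656 · dose-per-m².

**Per-profile NCA.** Linear-trapezoid AUC(0–t); terminal rate constant
k = β from least squares of log₁₀ concentration vs time with
β = slope × (−2.303); T½ = 0.693/β; observed Cmax/Tmax;
AUC(0–∞) = AUC(0–t) + C_last/k; nAUC(0–∞) rescaled to a 174 mg reference
dose; clearance CL = dose/AUC(0–∞) (apparent CL/F for the bead route).
Parameters whose preconditions fail are flagged, never fatal.

**Cross-route bioavailability.** F = 100 · nAUC(0–∞, bead)/nAUC(0–∞, IV)
per subject and cycle, summarized both as the mean of per-subject ratios
(the convention of the source report) and as the ratio of group means.

**Forward models.** Exact two-compartment closed forms for constant-rate
infusion and for bead delivery as an immediate bolus fraction (5–15 % of
the loaded dose) plus slow first-order release — including the flip-flop
regime in which the terminal slope is the release rate, not elimination —
plus multi-start nonlinear least-squares fitting of either model.

**Synthetic studies.** A seeded generator reproducing the 7-subject,
two-cycle design with between-subject variability, residual noise, LLOQ
censoring and a route-specific clearance multiplier (default 0.5) for the
bead phase, so the whole pipeline is testable with no external data.

## Worked example

```r
library(beadpk)

compute_dose(31.0, 250)          # 174.5699 mg; reported as 174.6
half_life(0.219)                 # 3.164 h;    reported as 3.2

study  <- generate_study(study_design_config(seed = 1))
report <- analyze_study(study$profiles)
report
#> <study_report>
#>   56 profiles analysed, 35 exclusions
#>   F (mean of ratios): 248.9 % (n=13); ratio of means: 232.7 %
subset(report$parameter_summary, phase == "primary_iv")
#>         phase  parameter       mean        sd cv_percent n   units
#>    primary_iv       Dose   185.3471   24.1837      13.05 7      mg
#>    primary_iv          k     0.1254    0.0401      31.97 7      /h
#>    primary_iv    AUC_0-t  6379.3768 2205.3465      34.57 7 ng h/ml
#>    primary_iv nAUC_0-inf  6392.4886 2297.8054      35.95 7 ng h/ml
#>    primary_iv         CL   504.8519  170.8551      33.85 7  ml/min
```

Reading this: seven subjects received a mean primary-cycle IV dose of
185 mg; their dose-normalized total exposure averaged ~6400 ng·h/ml,
giving a mean systemic clearance of ~505 ml/min. The pooled
bioavailability of the bead route, 248.9 % by the mean-of-ratios
convention, reflects the halved bead-phase clearance built into the
generator (which alone predicts 200 %) inflated by two observation
effects the methods vignette quantifies: IV exposure during the infusion
falls before the post-infusion sampling clock starts, and the slow bead
tail is extrapolated beyond the 20 h sampling window. The per-profile
table carries quality flags (`high_extrapolation`, rejected terminal
fits) and the report lists excluded profile/parameter combinations with
reasons.

A thin command-line wrapper covers the same pipeline:

```sh
Rscript inst/cli/beadpk.R dose --weight-kg 31 --dose-per-m2 250   # 174.6
Rscript inst/cli/beadpk.R simulate --seed 7 --out study/
Rscript inst/cli/beadpk.R analyze --input study/profiles.csv --out report/
```

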