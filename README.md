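# fafpipe

Analysis pipeline for **frequency-altered feedback (FAF)** experiments on
vocal pitch control — the paradigm in which a speaker sustains a vowel while
their voice feedback is briefly pitch-shifted (here −50 or −200 cents for
200 ms), eliciting a compensatory rise in voice F0 and an N1–P2 cortical
response. The package is aimed at speech-motor-control and auditory-ERP
researchers who need the full measurement chain — voice F0, ERP QC, and the
genotype-association statistics — as tested, scriptable R functions, plus a
synthetic-cohort generator so every stage can be validated against known
ground truth.

## What it computes

**Vocal.** F0 contours are converted to cents,
`cents = 1200 · log₂(F0 / 195.997)` (G3 reference), epoched over
[−200, 700) ms around each perturbation, baseline-normalized, classified as
compensatory / following / bad, and averaged; the response magnitude is the
maximum of the averaged contour, the latency its time, and the across-trial
SD of baseline F0 indexes the natural variability of the voice.

**ERP.** 1–20 Hz zero-phase band-pass; [−200, 500) ms epochs; the
±55 µV / 80-ms moving-average artifact rule (catching both fast muscle
artifacts and slow blinks); channels bad when flagged in >20 % of epochs;
subjects excluded at >10 bad channels; mastoid re-referencing; N1 = minimum
in 80–160 ms and P2 = maximum in 180–280 ms at FC1–4, FCz, C1–4, Cz.

**Statistics.** Split-plot repeated-measures ANOVA (within: stimulus
magnitude, electrode; between: genotype) with Type III hypotheses,
Greenhouse–Geisser–corrected p-values and partial η²; Bonferroni post hocs;
per-genotype Pearson correlations between compensation magnitude and
baseline variability; Hardy–Weinberg equilibrium χ² (1 df) on genotype
counts.

**Simulation.** `cohort_spec()` / `run_faf_study()` emulate a 133-subject
cohort (49 AA / 63 AG / 21 GG), 100 trials per magnitude, with configurable
genotype effects (GG compensation deficit, GG P2 boost, genotype-graded
variability–gain correlations) and blink-like EEG artifacts.

## Worked example

Simulate a small cohort, run both measurement pipelines subject by subject,
and fit the statistical battery:

```r
library(fafpipe)

spec <- cohort_spec(n_per_genotype = c(AA = 8, AG = 8, GG = 6),
                    trials_per_condition = 30)
study <- run_faf_study(spec, seed = 42)

head(study$vocal[, c(1, 2, 4, 6, 7, 8)], 4)
#>   subject_id condition_cents n_compensatory peak_magnitude_cents
#> 1       S001             -50             28             27.38786
#> 2       S001            -200             25             35.56780
#> 3       S002             -50             25             30.79932
#> 4       S002            -200             19             28.47097
#>   peak_latency_ms baseline_sd_cents
#> 1             400          2.496374
#> 2             400          2.618666
#> 3             290          2.197371
#> 4             300          2.204417

report <- replicate_paper_analyses(study$vocal, study$erp, study$genotypes,
                                   genotype_counts = c(55, 71, 24))
print(report)
#> FAF study statistical report
#>   HWE: chi2 = 0.018, df = 1, p = 0.892
#>
#> Vocal compensation magnitude (condition x genotype):
#>              effect df1 df2        ss ss_error         f        p gg_epsilon
#>            genotype   2  19 1.953e+02   2832.0 0.6551000 0.530700          1
#>           condition   1  19 6.603e-03    262.1 0.0004786 0.982800          1
#>  condition:genotype   2  19 2.521e+02    262.1 9.1360000 0.001659          1
#>  ...
```

Reading the output: each subject contributes one row per perturbation
magnitude; `peak_magnitude_cents` is the compensatory response size (upward,
opposing the downward shift), `baseline_sd_cents` the voice-variability
index. In the ANOVA table, the `condition:genotype` row is the key test that
the genotype groups differ in how compensation scales with perturbation
size (here F(2,19) = 9.14, p = 0.0017, η²ₚ = 0.49 — the simulated GG deficit
at −200 cents, detected even in this 22-subject toy cohort). The HWE line
checks the genotype counts against Hardy–Weinberg proportions
(χ² = 0.018, p = 0.892 for counts 55/71/24). For multi-level within factors
(electrode), the table also reports the Greenhouse–Geisser ε and the
sphericity-corrected p (`p_gg`).

`run_all(run_config(seed = 1), "out/")` runs the same chain and writes all
summary tables, ANOVA tables, correlations, and a JSON manifest whose stage
counts reconcile.

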