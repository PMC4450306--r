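# afmp — matching-pursuit analysis of atrial activity

`afmp` predicts whether a patient with persistent atrial fibrillation (AF)
will stay in sinus rhythm after direct-current electric cardioversion,
using only a single-lead surface ECG. The working hypothesis is
electrophysiological: the more disorganized the atrial fibrillatory
(f-) waves, the more remodelled the atrial substrate and the likelier the
relapse. The package quantifies that organization with a multiresolution
sparse decomposition and turns it into a classifier — and, because clinical
cardioversion datasets are private, it ships a seeded synthetic AF-ECG
generator with known ground truth so the whole pipeline is reproducible
end to end.

## The method

For each record, the atrial activity (AA) `x(t)` is extracted from the ECG
(band-pass 0.01–50 Hz, R-wave fiducials at maximum absolute derivative,
average beat subtraction with a per-beat scale/offset fit, segments gated
at 90% QRST-template correlation, and the 10-second excerpt with minimal
excess kurtosis). The excerpt is then expanded by greedy matching pursuit
over an overcomplete dictionary of Coiflet-1 and Symlet-2 wavelet atoms at
six dyadic scales and every temporal shift:

    x(t) = Σ_{m=1..M} b_m · A_(W_m, S_m, T_m)(t) + R_x^M(t),   M = 1000

where each iteration selects the atom `A` maximizing `|⟨R, A⟩|`. Thirteen
features summarize the expansion: twelve occupancy counts
`MPF_{W,Si} = Σ_j O_W(i, j)` (how many temporal locations of wavelet type
`W` and scale `Si` were occupied) and the decay rate
`MPF_residue = ln(|b_M| / |b_1|)`. Features are screened by two-sided
Mann-Whitney U tests and fed to quadratic discriminant analysis under
leave-one-out cross-validation; performance is reported as a ROC curve,
its AUC, and the Youden-optimal sensitivity/specificity. The dominant
atrial fibrillatory rate (AFR, Welch spectrum peak in 3–12 Hz) provides
the classical single-number comparator.

## Worked example

Simulate one disorganized (AF-Relapse-like) record, extract its atrial
activity, and decompose it:

```r
library(afmp)

rec <- synthesize_record(synth_config(duration = 60), label = 1, seed = 8,
                         record_id = "demo-01")
seg <- extract_aa(rec)
seg
#> <aa_segment demo-01>  10 s @ 250 Hz, start 9672, excess kurtosis -0.155
aa_truth_correlation(rec, seg)
#> [1] 0.95

dict <- build_dictionary(length(seg$samples), fs = seg$fs)
mp <- mp_decompose(seg$samples, dict)
mp
#> <mp_result>  1000 iterations, |b1| = 0.4078, residual energy = 0.1247
glance(mp)
#> # A tibble: 1 × 5
#>   M_done    b1 final_energy energy_fraction mpf_residue
#> 1   1000 0.408        0.125          0.0326       -3.98
afr(seg)
#> [1] 7
```

The excerpt's excess kurtosis is negative (sub-Gaussian, f-wave-like), the
extracted activity correlates 0.95 with the generator's ground-truth
f-wave, 1000 pursuit iterations capture ~97% of the excerpt energy, and
the dominant fibrillatory rate lands at 7 Hz for this disorganized record.

Running the full study pipeline — simulate a balanced 40-record cohort,
preprocess, decompose, extract and screen features, cross-validate — is one
call:

```r
run <- run_all(pipeline_config())
report(run)
#> Cohort: 40 records (20 AF-Free, 20 AF-Relapse)
#> Segments per record: 2.0 +/- 0.7; excerpt excess kurtosis: -0.00 +/- 0.23
#> Beats below the correlation gate: 6.9% +/- 2.7%
#> Selected MP features (8):
#>   mpf_coif1_s0     U = 295.5  P = 0.009885
#>   mpf_coif1_s1     U = 300.5  P = 0.006682
#>   mpf_coif1_s3     U =  25.0  P = 2.305e-06
#>   mpf_coif1_s4     U = 346.0  P = 8.185e-05
#>   mpf_coif1_s5     U =  93.0  P = 0.003915
#>   mpf_sym2_s2      U = 329.5  P = 0.0004731
#>   mpf_sym2_s3      U =  79.5  P = 0.001151
#>   mpf_sym2_s4      U = 319.0  P = 0.001312
#> LOOCV QDA (inside selection): AUC = 0.955; best sens = 95%, spec = 90%
#> AFR-only comparator: AUC = 0.670 (mean AFR 6.22 Hz free, 6.53 Hz relapse)
```

Eight of the thirteen MP features separate the classes; the
cross-validated MP pipeline (AUC 0.955, sensitivity 95%, specificity 90%)
clearly outperforms the fibrillatory rate alone (AUC 0.670). `autoplot()`
methods draw records, coefficient decay curves, occupancy matrices and ROC
curves; `tidy()`/`glance()` return every result as a tibble.

A thin command-line interface wraps the same functions
(`inst/cli/afmp.R` with subcommands `simulate`, `preprocess`, `decompose`,
`features`, `classify`, `run-all`, `report`).

## Package layout

- `R/synth.R` — seeded AF-ECG generator (`synth_config()`,
  `synthesize_cohort()`, …)
- `R/preprocess.R` — AA extraction chain (`bandpass_filter()`,
  `detect_fiducials()`, `cancel_qrst()`, `pick_excerpt()`, `extract_aa()`)
- `R/dictionary.R`, `R/mp.R` — wavelet dictionary and matching pursuit
- `R/features.R` — occupancy/decay features, Mann-Whitney screening
- `R/classify.R` — QDA/LDA, LOOCV, ROC/AUC, AFR
- `R/pipeline.R` — `run_all()`, `report()`, artifact I/O
- `vignettes/af-mp-methods.Rmd` — models, parameter choices, limitations
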