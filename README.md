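# aptascreen

Signal analysis for electrochemical aptasensor diagnostics: feature
extraction from paired before/after-plasma cyclic voltammetry (CV) and
electrochemical impedance spectroscopy (EIS), equivalent-circuit fitting, and
exhaustive leave-one-out-cross-validated screening of feature combinations
that separate lung-cancer (LC) from healthy (H) plasma samples.

## Who this is for

Electrochemists and biosensor developers who record a redox-probe CV and an
impedance spectrum before and after incubating a sensor with a clinical
sample, and who want a reproducible, tested route from raw sweeps to a ranked
list of discriminating feature combinations — plus a synthetic cohort
generator so the whole pipeline can be exercised and validated without
clinical data.

## What it computes

**CV features.** Per branch (anodic/cathodic): peak potential and
baseline-corrected height (`Ea`, `Ia`, …), onset potential and current
(`Einit`, `Iinit`), full width at half maximum (`Ew`), a shape ratio of the
half-widths (`Esh`), and the peak area (`S`); plus the derived scalars
`ΔE = |Ea − Ec|`, `R(I) = Ia/Ic`, `R(S) = Sa/Sc`, `E½ = (Ea + Ec)/2`.
Surface coverage of a blocking layer is `(1 − S_after/S_before) × 100 %` on
the oxidation peak.

**EIS features.** The spectrum is transformed to complex capacitance
`C*(ω) = 1/(jωZ)` (Cole–Cole representation) and summarised by the
double-layer plateau `C_dl`, the interior extrema locations `ω_min`/`ω_max`
of `C′` vs `log ω` and the capacitance `C_min` at the minimum.

**Circuit fits.** `fit_circuit()` solves the complex nonlinear least-squares
problem `min Σ wᵢ |Z_model(ωᵢ) − Zᵢ|²` (modulus weighting `wᵢ = 1/|Zᵢ|²`)
over Randles and two-interface non-Faradaic topologies built from resistors,
constant phase elements `Z = 1/(T(jω)^α)` and generalized Warburg diffusion
elements, with multi-start Levenberg–Marquardt in log/logit space.  A
before/after decision rule calls a sample LC-positive when the fitted
electrode-interface `CPE₁-T` drops by ≥ 1 order of magnitude while the
biolayer `CPE₂-T` rises.

**Change-features and screening.** For every base feature `P`:
`Dlt[P] = P₀ − P_pl` and `Incr[P] = Dlt[P]/P₀ × 100 %`.  All feature
singles/pairs/triples are scored by LOOCV mean accuracy over a nine-member
bank (k-NN with k = 1, 3, 5; linear SVMs and L2 logistic regressions with
C = 0.1, 1, 10), with fold-internal standardization and imputation, in
compiled code.

## Worked example

```r
library(aptascreen)

# a synthetic 10 LC + 10 H cohort with paired before/after CV + EIS
cohort <- simulate_cohort(cohort_config(n_lc = 10, n_h = 10, seed = 1))
tab <- build_feature_table(cohort, base_set = "full")
pairs <- screen_combinations(tab, subset_size = 2)
summarize_screen(pairs, top_n = 3)
```

```
Best LOOCV mean accuracy: 1.000
Top combinations (best classifier each):
   rank      features family param accuracy
1     1 C_dl,Dlt_C_dl    knn     1        1
9     2   C_dl,Dlt_Ic    knn     1        1
17    3  C_dl,Dlt_R_I    knn     1        1
```

The top pairs combine the double-layer capacitance with its own
change-feature or with the cathodic-current change — exactly the channels
through which the generator injects the LC effect (a 30-fold
`CPE₁-T` drop and a 15 % cathodic current attenuation), so on this synthetic
cohort they separate the classes perfectly (accuracy 1.0 over the 20 LOOCV
folds).

Circuit fitting recovers generating parameters from a noiseless spectrum to
machine precision:

```r
truth <- circuit_spec("M0_randles_w",
                      c(Rs = 100, CPE_T = 4.2e-5, CPE_P = 0.72, Rct = 2e3,
                        W_R = 3e3, W_T = 0.05, W_P = 0.45))
fit <- fit_circuit(simulate_eis(truth, default_eis_frequencies(40)),
                   "M0_randles_w")
fit
```

```
Equivalent-circuit fit: M0_randles_w 
  40 frequencies, modulus weighting, chi^2 = 1.354e-29, AIC = -5654.32, converged
     Rs   CPE_T   CPE_P     Rct     W_R     W_T     W_P 
1.0e+02 4.2e-05 7.2e-01 2.0e+03 3.0e+03 5.0e-02 4.5e-01 
```

and the surface-coverage extractor round-trips the generator:

```r
pair <- simulate_coverage_pair(68, cv_shape(noise_sd = 0))
surface_coverage(pair$before, pair$after)
#> [1] 68
```

`run_pipeline(config, out_dir)` chains simulate → extract → fit/decide →
build-table → screen into a run directory with plain-text artifacts, a
resolved YAML config and a checksummed manifest; a thin command-line wrapper
lives at `inst/cli/aptascreen.R`.

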