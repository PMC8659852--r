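---
title: "Methods: simulating and screening aptasensor electrochemistry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and screening aptasensor electrochemistry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis problem

An electrochemical aptasensor is read out twice: once before and once after
the sensing layer has been incubated with a patient's blood plasma.  Each
readout consists of a cyclic voltammogram (CV) of a reversible redox probe and
an electrochemical impedance spectrum (EIS).  The diagnostic question is
whether the *change* between the two readouts carries a signature of the
target analyte (here: lung-cancer-associated plasma proteins bound by the
immobilized aptamer).  Because no single scalar feature separates diseased
from healthy plasma reliably, the pipeline extracts a large set of candidate
features from both measurement types, forms before/after change-features, and
screens all small feature combinations with a bank of simple classifiers under
leave-one-out cross-validation (LOOCV).

`aptascreen` implements that pipeline end to end, together with a synthetic
cohort generator so that every stage is testable without clinical data.

## The synthetic data generator

The generator is a first-class module: its defaults define the study
conditions under which the package's end-to-end claims are evaluated.

### Voltammograms

A one-cycle CV is modelled per sweep branch as a linear capacitive baseline
plus one peak, with the anodic peak on the forward sweep and a negative
cathodic peak on the reverse sweep.  The peak is an exponentially modified
Gaussian (EMG) whose exponential tail points in the sweep direction,
reproducing the asymmetric diffusional decay of a real voltammetric wave with
only two shape parameters (Gaussian width $\sigma$ and tail ratio
$\tau/\sigma$).  The EMG is used in density form, so its analytic integral is
available in closed form (`emg_peak_area()`) and serves as the oracle for the
trapezoidal area extractor.  The amplitude is rescaled so the configured peak
height appears exactly at the configured peak potential.

Measurement geometry defaults follow the sensor protocol: a $-0.5$ to $0.8$ V
window at $0.03$ V/s, 260 points per sweep segment (a 5 mV grid).  Default
peak placement (anodic 0.30 V, cathodic 0.20 V, heights $10\ \mu$A, width
0.05 V) is a calibration choice of the simulator, not a measured constant:
no probe peak values are available to anchor it, and every extractor claim is
relative to the generator's own truth.

Noise is additive Gaussian on the current; sensor-to-sensor variability is
log-normal on peak currents and circuit magnitudes with small Gaussian jitter
on peak potentials.

### Impedance spectra

Spectra are generated by exact forward evaluation of an equivalent circuit on
the 1 Hz--1 kHz grid of the measurement protocol (40 log-spaced points by
default), with multiplicative Gaussian noise applied independently to the
real and imaginary parts.  Implemented elements: resistors, constant phase
elements $Z = 1/(T(j\omega)^\alpha)$, and a Warburg diffusion element in
semi-infinite or generalized (free-exponent, `tanh`/`coth`) form.  Implemented
topologies:

* `M0_randles_w` --- $R_s + [\mathrm{CPE} \parallel (R_{ct} + W)]$, the
  Randles circuit used in redox-probe solution;
* `M1_randles_w_extra` --- M0 plus an extra parallel $[\mathrm{CPE}_2
  \parallel R_2]$ relaxation, the circuit of a partially decomposed layer;
* `M2_nonfaradaic` --- $R_s + [\mathrm{CPE}_1 \parallel R_{p1}] +
  [\mathrm{CPE}_2 \parallel (R_{p2} + W)]$, the two-interface non-Faradaic
  circuit (electrode surface, then biolayer) used for plasma measurements in
  background electrolyte.

The circuit topologies are reconstructed from their textual descriptions
(series/parallel composition of the named elements); the registry is
extensible if other compositions are needed.

The default non-Faradaic population circuit (`default_cohort_circuit()`)
places the electrode-surface relaxation near 10 Hz and the biolayer
relaxation near 1 Hz so that both are identifiable from a single 3-decade
sweep; after a factor-30 drop of $CPE_1\!-\!T$, the first relaxation moves to
roughly 500 Hz and remains inside the window.

### Cohorts

`simulate_cohort()` draws `n_lc + n_h` sensors around the population
baselines (log-normal inter-sensor scatter, default 5%), then applies
class-dependent effects to the "after" state:

* lung-cancer (LC) samples: $CPE_1\!-\!T$ divided by 30 (the centre of a
  one-to-two-orders-of-magnitude drop on a log scale), $CPE_2\!-\!T$
  multiplied by 3, the cathodic peak shifted by $+0.02$ V, its current
  attenuated by 15% and its tail asymmetry increased by a factor 1.2;
* healthy (H) samples: only a small symmetric drift (default 2% log-normal).

The LC effect sizes were chosen once so that the screening stage operates in
the reported separability regime of the clinical study; they are exposed in
`cohort_config()` and are not adjusted anywhere else in the package.  The
class effects are applied deterministically (no per-sample jitter on the
effect itself), so zero-noise cohorts have exactly reproducible generating
ratios --- which is what the fit-recovery claims are checked against.

What the generator deliberately does *not* emulate: electrode aging and
drift within a measurement, non-Gaussian instrument noise, Faradaic
nonlinearities, overlapping impurity peaks, or any relationship between the
CV and EIS responses of one sensor beyond sharing a seed.  Tests passing on
this generator therefore demonstrate the correctness and sensitivity of the
*analysis*, not clinical performance.

## Feature extraction

### Voltammetry

Each branch is processed independently: a linear baseline is fitted to the
leading 20% of the segment (the approach side, the conventional tangent
method); the peak is the interior extremum of the baseline-corrected current,
required to exceed a floor of five baseline residual standard deviations; the
onset is the first potential from which the corrected current stays above 5%
of the peak height through to the peak (a sustained-crossing rule, robust to
noise); the width is the interpolated full width at half maximum; the shape
parameter is the ratio of approach-side to departure-side half-widths
(dimensionless, scale-invariant, $<1$ for a diffusional tail); the area is
the trapezoidal integral between the threshold crossings.  Width and shape
are not standardized quantities in voltammetry; FWHM and the half-width ratio
were chosen as the most conventional scale-invariant definitions.

Surface coverage of a blocking layer is quantified from the attenuation of
the anodic (oxidation) peak area,
$\theta = (1 - S_{after}/S_{before}) \times 100\%$.  Area is preferred over
height (a height option exists) because the area statement is the sharper of
the two descriptions of the protocol; all proportionality constants cancel in
the ratio.  A negative coverage is reported with a warning flag instead of an
error, since it is representable (a grown peak) even if physically odd.

### Impedance

Spectra are transformed to complex capacitance,
$C^*(\omega) = 1/(j\omega Z(\omega))$ (the Cole--Cole representation), and
four features are taken from the real part $C'$ against $\log\omega$: the
high-frequency plateau median (`C_dl`, the double-layer capacitance), the
interior local minimum and maximum locations (`omega_min`, `omega_max`) and
the capacitance at the minimum (`C_min`).  $C'$ is used because the "active
capacitance" conventionally denotes the real part; extrema are detected with
a $10^{-9}$ relative prominence floor so that an ideal capacitor (flat curve)
reports no extrema.  Absent extrema are missing values, not errors --- they
are imputed inside the screening folds.

## Circuit fitting

`fit_circuit()` minimises the weighted complex residual
$\sum_i w_i |Z_{model}(\omega_i) - Z_i|^2$ by Levenberg--Marquardt
(`minpack.lm`), with modulus weighting $w_i = 1/|Z_i|^2$ by default so that
decades of impedance magnitude contribute comparably.  Magnitudes are
optimized in log space and the $(0,1)$-bounded exponents through a logit
transform, enforcing positivity and bounds without constraints.  Standard
errors come from the local curvature (finite-difference Jacobian at the
optimum, delta method back to natural scale); the reported AIC is
$2n\log(\chi^2/2n) + 2k$.

Multi-block circuits over a 3-decade window are practically degenerate:
many parameter sets fit to a fraction of a percent.  The optimizer therefore
starts from a *grid* of structured, data-driven initial guesses (series
resistance from the high-frequency real part, total polarization from the
low-frequency span, CPE scale from the top-of-window reactance, with the CPE
magnitudes and the resistance split spread over the degeneracy directions ---
12 starts for the two-interface topology), plus deterministic log-space
perturbations, and the best solution is re-polished with a fresh
trust-region.  On noiseless self-generated spectra this recovers all
parameters of all three topologies to optimizer precision; under 1% noise the
median parameter error on a fully resolved spectrum is a few percent.  Fits
never throw on non-convergence; `converged` is part of the result, and the
decision rule refuses to classify from non-converged fits.

Model choice among candidate topologies is by minimum AIC over converged
fits, ties (within $10^{-9}$) going to the smaller circuit.  Note a structural
caveat: a generalized Warburg with a free exponent can imitate an additional
parallel relaxation, so at noise levels above a few tenths of a percent the
simpler circuit may legitimately win even when the data were generated with
the extra block.

The CPE-to-capacitance conversion is not uniquely defined; both the
Hsu--Mansfeld relation ($C = T\omega_{peak}^{\alpha-1}$) and the Brug
relation ($C = T^{1/\alpha}(1/R_s + 1/R_{ct})^{(\alpha-1)/\alpha}$) are
provided as options, and neither is asserted against any external value.

### The before/after decision rule

For a before/after pair of two-interface fits, the sample is called
LC-positive when $\log_{10}(CPE_1\!-\!T_{before}/CPE_1\!-\!T_{after}) \ge 1$
(at least one order of magnitude, configurable) *and*
$CPE_2\!-\!T_{after} > CPE_2\!-\!T_{before}$ --- capacitance falling at the
electrode interface while rising at the biolayer interface.  Non-converged
fits yield an indeterminate call.

## Change-features and the feature table

For every base feature $P$ measured before ($P_0$) and after ($P_{pl}$)
incubation, two change-features are formed:
$\mathrm{Dlt}[P] = P_0 - P_{pl}$ and
$\mathrm{Incr}[P] = \mathrm{Dlt}[P]/P_0 \times 100\%$ (undefined at
$P_0 = 0$, reported missing with a warning).  The table carries the
before-state value as the base column (the sensor's reference condition)
plus both change columns, so change columns always number exactly twice the
base columns.

Two registries exist: `full` (18 CV + 4 EIS = 22 base, 66 columns) and
`paper12`, a reduced 12-feature set (8 CV + 4 EIS, 36 columns) matching the
historically reported dataset dimensions.  The stated count of eight CV
features is not accompanied by their identity, so `paper12` uses the most
conventional eight (peak potentials, separation, peak currents, areas, area
ratio); since several features appearing in reported winning combinations
(e.g. cathodic onset, width, shape) fall outside any such eight, the `full`
registry is the default for screening and `paper12` serves the structural
column-count contract.

Missing values propagate into the table and are mean-imputed *within
training folds* during screening, never globally --- global imputation would
leak the held-out sample into training.

## The combination screen

The classifier bank is fixed at nine members: $k$-NN with $k \in \{1,3,5\}$,
linear soft-margin SVMs with $C \in \{0.1,1,10\}$ and L2-penalised logistic
regressions with inverse regularization $C \in \{0.1,1,10\}$.  Every feature
subset of size 1, 2 or 3 is evaluated against every member by LOOCV; within
each fold, features are z-scored and imputed with training-fold statistics
only, and a fold whose training set degenerates to one class predicts the
majority class.  Results are ranked by accuracy with fully deterministic
tie-breaks (lexicographic feature names, then family, then hyperparameter).

The solvers are implemented in compiled code because exhaustive enumeration
($\binom{66}{3} = 45{,}760$ triples $\times$ 9 members $\times$ 20 folds)
is the hot loop: $k$-NN with smallest-index distance tie-breaks, the C-SVM
dual solved by sequential minimal optimization with maximal-violating-pair
selection and a libsvm-compatible intercept, and logistic regression by
damped Newton on the sklearn-style objective
$\tfrac12\|w\|^2 + C\sum_i \log(1+e^{-y_i f_i})$ with an unpenalised
intercept.  All three are deterministic.  The test suite checks the whole
LOOCV machinery, prediction by prediction, against independent
implementations (`e1071::svm`, ridge-logistic `glmnet`, and a hand-rolled
$k$-NN loop) on exhaustive small tables, and checks the SVM dual objective
directly against `e1071`.

### What "chance level" means under LOOCV

For a balanced cohort of $n$ samples, leave-one-out training folds
under-represent the held-out class ($n/2 - 1$ of $n-1$), so the exact
exchangeable-null accuracy of 1-NN is $(n/2-1)/(n-1)$ --- $9/19 \approx
0.474$ at $n = 20$, slightly below $1/2$.  The permutation-null test in the
suite is therefore calibrated against this exact value (and additionally
checks that the mean sits within 0.05 of 0.5) rather than against 0.5 with a
standard error that the known LOOCV pessimism would violate by construction.

Because tens of thousands of combinations are screened, the *maximum*
accuracy over combinations is strongly optimistic on null data; the screen is
a hypothesis generator, not a validated classifier.  No multiple-testing
correction is applied, deliberately matching the screening protocol it
reproduces; the permutation machinery is available to calibrate expectations.

## Pipeline and reproducibility

`run_pipeline()` chains simulate, extract, (optionally) fit/decide,
build-table and screen, writing every artifact in plain-text dialects
(voltammogram CSV, spectrum CSV, manifest JSON, feature-table CSV,
screen/decisions JSON) plus the fully resolved YAML configuration and a
checksummed run manifest.  Identical configurations give byte-identical
tables and rankings; `resume = TRUE` regenerates only stages whose outputs
are missing.  Every generator accepts a seed and is bit-for-bit reproducible;
fitting and screening are deterministic given their inputs.

## Problem sizes used in the checks

The shipped test-suite and acceptance runs use: 20-sample cohorts at the
default 260-point CVs and 40-point spectra for the screening claims; a
40-point noiseless spectrum for the printed-parameter recovery claim; a
zero-noise 6--10-sample cohort for the decision-rule claim; 30--40 replicates
for the Monte-Carlo noise and recovery studies; 200 label permutations for
the null calibration; and 400 replicate spectra for the noise-contract check.
These sizes were chosen as the smallest that make the corresponding
statistical statements sharp.

## Known limitations

* The CV peak model is phenomenological (EMG on a linear baseline), not a
  Butler--Volmer/Nicholson digital simulation; electrode geometry and
  diffusion-layer physics are out of scope.
* Equivalent-circuit fits over three decades are weakly identified for the
  diffusion-side parameters; interpret $R_{ct}$/Warburg values from narrow
  windows with care (the CPE parameters driving the decision rule are the
  well-identified ones under the default conditions).
* EIS extrema features (`omega_min`, `omega_max`) are frequently missing on
  smooth spectra and enter the screen only through fold-internal imputation.
* LOOCV maxima over exhaustive combination screens are optimistically biased;
  external validation is required before any diagnostic claim.
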