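---
title: "Methods: continuous diaphragm monitoring during weaning trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: continuous diaphragm monitoring during weaning trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diaphmon)
```

# The problem

When a mechanically ventilated patient is ready to breathe alone, a
spontaneous breathing trial (SBT) tests that readiness; failing the trial,
or passing it but needing reintubation within 48 h, defines weaning
failure. The diaphragm drives most of quiet inspiration, so indices of its
motion — excursion per breath (EXdi, cm) and peak contraction velocity
(PCVdi, cm/s) — carry prognostic information, and a continuous,
operator-independent ultrasound monitor can track them breath by breath
where a handheld exam yields only snapshots. Against this, the reference
physiology is the transdiaphragmatic pressure `Pdi = Pga − Pes` from a
double-balloon catheter, with per-breath peak rise (Pdi,peak, cmH2O) and
the pressure–time product (PTPdi, cmH2O·s) as effort indices.

`diaphmon` implements the complete analysis of such a study —
per-breath signal metrics, device agreement, weaning-failure prediction,
and within-patient pressure–excursion coupling — and, because no
patient-level data are publicly deposited for this kind of study, ships a
first-class synthetic-data module that generates the signals and cohort
with known ground truth. Everything the statistical layers consume can
therefore be validated against what the generator actually put in.

# The synthetic signal model

`simulate_breath_train()` concatenates breaths. With breath duration `d`
(lognormal around `60/mean_rr` with CV `rr_cv`) and inspiratory time
`Ti = insp_fraction · d`:

* **Displacement** rises as a raised cosine from 0 to the breath's
  excursion `E` over `Ti`, then relaxes exponentially with time constant
  `0.4 (d − Ti)`. The exponential is shifted and rescaled to reach zero
  exactly at the breath end: a raw exponential would leave an
  `exp(−1/0.4) ≈ 8%` residual, creating an artificial jump between
  breaths and biasing onset-referenced excursion by the same amount.
  `E` itself is lognormal with mean `mean_exdi` and CV `exdi_cv`
  (lognormal because excursion is positive and cohort summaries of it are
  right-skewed; this is an assumption, not an observation).
* **Pdi** is a half-sine of amplitude `pdi_gain · E + ε`,
  `ε ~ N(0, pdi_noise_sd)`, over `Ti`, zero in expiration. The esophageal
  and gastric channels are constructed as `Pes = 5 − 0.4·Pdi` and
  `Pga = Pes + Pdi`, so the defining identity `Pga − Pes = Pdi` holds to
  machine precision at every sample. The per-breath amplitude noise is
  the single knob controlling within-subject pressure–excursion
  correlation: the realized Spearman correlation of (Pdi,peak, EXdi) is
  monotone decreasing in `pdi_noise_sd` and equals 1 exactly at 0.
* **Flow** is the analytic derivative of a volume trace that rises to
  `VT = vt_per_exdi · E` over inspiration and returns to zero by the
  breath end (cosine descent), so `∫|flow| dt = 2·VT` exactly over each
  breath.
* **Artifacts** (cough/swallow/motion) arrive at Poisson rate
  `artifact_rate`/min as half-sine transients of 0.3–0.8 s and 5× the
  typical displacement and Pdi amplitude, added to both channels and
  logged in the ground truth. Real artifacts are messier; these are the
  minimal shape that the amplitude-outlier rejection rule must catch.

`simulate_patient()` assembles baseline (15 min), SBT (30 min) and
recovery (15 min) phases at 200 Hz by default — the full monitored
session — and draws a patient-level median excursion
`m_s = mean_exdi · exp(σ_b Z)` with `σ_b² = log(1 + between_cv²)`.
This between-patient spread is essential: cohort tables in this field
show interquartile ranges like 0.9–2.2 cm (success) against 0.6–1.0 cm
(failure), and without it every simulated patient of a group would be a
clone and any predictive analysis would degenerate to AUC 1. The group
presets (`phenotype_weaning_success()`: median EXdi 1.4 cm, RR 26/min,
`between_cv` 0.7; `phenotype_weaning_failure()`: 0.8 cm, 27/min,
`between_cv` 0.4; `pdi_gain` and `vt_per_exdi` the ratios implied by the
group medians of Pdi,peak and tidal volume) encode the minute-2 group
contrasts the prediction stage is supposed to detect.

Failure patients truncate the SBT with probability
`sbt_failure_fraction` (default 12/25, the intra-trial share of failures)
at a uniform time between minute 3 and the scheduled end — uniform being
the least-informative choice when only the count of early terminations is
known; the remaining failures complete the trial and count as
post-extubation reintubations, which is what `weaning_outcome()`
classifies.

**Snapshot model.** The paired handheld-ultrasound exams are emulated as
the 5% trimmed mean of 10 consecutive true breath values (last 10
baseline breaths pre-SBT, first 10 recovery breaths post-SBT) plus
`N(snapshot_bias, snapshot_noise_sd)` error, plus a fixed patient-level
offset of `±3·snapshot_noise_sd` for a designated `poor_agreement_fraction`
of patients. Defaults (`bias` 0.1 cm, `noise` 0.35 cm, fraction 0.15)
were chosen once so the pooled difference SD lands near 0.4 cm — the
scale of published excursion-agreement limits — with the poor-agreement
subgroup included; PCVdi snapshot error is scaled 2.5× (velocity
agreement is looser than excursion agreement). Note an asymmetry this
model creates deliberately: all snapshot error sits in the snapshot arm,
while the continuous value is the truth-derived trimmed mean. Real
method-comparison data have error in both arms; Passing–Bablok assumes
comparable error in both, so on these synthetic pairs its slope runs
above 1 even though the Bland–Altman bias is centred on `snapshot_bias`.
That is a property of the error budget, not of the estimator (under an
equal-error model the implementation's slope is centred on 1).

**Determinism.** Every generator is a pure function of its seed; cohort
labels are assigned by exact count (stratified), not Bernoulli draws;
per-patient and per-phase seeds derive from the master seed. Two runs of
`run_study()` with the same configuration are bit-identical.

# Breath analysis

`detect_breaths()` implements zero-crossing segmentation on a
baseline-corrected signal. The baseline is a centered rolling median over
10 s — much longer than a breath (1.5–7.5 s for RR 8–40), much shorter
than a session phase — subtracted before finding positive-going zero
crossings; `endrule = "constant"` extends the first full-window median
outward, because shrinking end-windows bend the baseline toward the
signal itself and misplace the first breath. On Pdi the expiratory
baseline is exactly zero, so crossings sit on the true onsets (the
segmentation oracle in the tests demands agreement within 2 samples on
noise-free trains, for every RR from 8 to 40). On displacement-only
records the crossings sit mid-inspiration: counts and per-breath windows
survive, onset-referenced metrics shift, which is why Pdi is the
preferred detection channel whenever present. Candidates shorter than
0.5 s or smaller than the amplitude threshold (10% of the record's median
breath amplitude, floored at 0.5 cmH2O for Pdi / 0.05 cm for
displacement) are merged into neighbors.

`reject_artifacts()` automates what is done visually at the bench: a
breath is flagged (never deleted) when its amplitude exceeds `k_mad = 5`
median absolute deviations above the rolling median amplitude of its
3-minute neighborhood, or when it is shorter than 0.5 s. A small absolute
tolerance (`1e-6·max(1, median)`) keeps floating-point jitter on
perfectly uniform trains from producing spurious flags; `k_mad = Inf`
disables amplitude flagging.

Per-breath metrics (`compute_breath_metrics()`):

* `exdi = max(disp) − disp(onset)` within the breath;
* `pcvdi` = maximum central-difference derivative of the displacement
  smoothed by a 50 ms moving average, over onset→displacement-peak. The
  window is forced to an odd sample count so the average is symmetric —
  an even window in `stats::filter()` is shifted half a sample and
  inflates the peak derivative; 50 ms suppresses sample noise at 200 Hz
  without biasing peak velocity (a linear ramp's derivative is recovered
  exactly);
* `pdi_peak = max(pdi) − pdi(onset)`;
* `ptpdi` = trapezoidal integral of `max(pdi − pdi(onset), 0)` over the
  breath. Referencing to the onset value and clipping negatives is the
  conventional reading of "area under the curve during inspiration"; on a
  half-sine of amplitude `A` and duration `T` it equals `2AT/π` (the
  tests demand 0.1% agreement at 200 Hz; observed error is ~1e-5);
* `vt` = half the trapezoidal integral of `|flow|` over the breath
  (inspired + expired volume, halved; exact under flow balance), with an
  inspiration-only mode as an option.

`minute_summary()` aggregates valid breaths whose onsets fall in
leading-edge windows `[(m−1)·60, m·60)` after SBT onset (the protocol
timepoints default to 1–5, 10, 20, 30 min): respiratory rate is the
contributing-breath count, metric means are 5%/5% trimmed with the
floor rule `k = ⌊fraction·n⌋` per tail (so at n = 10 the trim drops
nothing — deliberately matching how a 10-breath snapshot mean behaves),
PTPdi is summed per minute, and the derived indices are
`rsbi = rr / VT[L]`, `dia_rsbi = rr / EXdi[mm]` (the excursion is carried
in cm everywhere else; the mm conversion is explicit here) and
`vt_over_exdi` (mL/cm). Windows extending past the record end — a
truncated SBT — yield no row rather than a partial one.

# Agreement statistics

`bland_altman()` reports bias, the ±2 SD limits of agreement (the
convention in this field's figures; 1.96 is available via
`loa_multiplier`) and the t-based CI of the bias, declaring bias
significant when 0 falls outside. Both intervals are always reported
because published summaries sometimes print one with the width of the
other. `classify_agreement()` marks a patient poor when any single
difference falls strictly outside the pooled limits.

`passing_bablok()` follows the original 1983 procedure: all pairwise
slopes with `S = −1` omitted and fully tied pairs dropped, vertical pairs
scored `±Inf`, the slope the `K`-shifted median (`K` = slopes below −1),
rank-offset confidence bounds with
`w = z_{1−α/2}·√(n(n−1)(2n+5)/18)`, intercept `median(y − b·x)` with its
CI from the slope bounds. Shifted ranks are clamped to the slope list —
relevant only for degenerate draws far from the estimator's
positive-association domain. The CUSUM linearity statistic accumulates
residual signs (±`√(M/L)` / `√(L/M)`) in order of the score
`D = y + x/b` and compares `max|cusum|/√(L+M)` with 1.36, the 5%
Kolmogorov–Smirnov value; a Monte-Carlo sign-permutation p-value is
optional. Two calibration facts worth knowing, both verified in the test
suite: a pure quadratic cannot exceed 1.36 below n = 30 (its sign pattern
caps the statistic at `√n/4`), and because the fitted slope and median
intercept force the residual-sign path toward balance, the realized size
of the 1.36 rule on linear Gaussian data is far below 5% — the rule is
the field's standard, but it is conservative.

# Prediction

`roc_curve()` places thresholds at midpoints between distinct scores plus
`±Inf` sentinels and never infers direction from the data: published
reports can print contradictory inequality directions for the same
cutoff, so direction is an explicit argument (`"lower"` = low excursion
predicts failure, the default orientation consistent with the group
medians), and a mismatched direction shows up honestly as AUC < 0.5.
The trapezoidal AUC coincides with the tie-corrected Mann–Whitney
probability (an identity the tests check on random tied instances).
`youden_cutoff()` maximizes `J = sens + spec − 1`, breaking ties first
toward sensitivity (a missed weaning failure is the costlier error) and
then toward more positive calls, making the cutoff deterministic.
`diagnostic_metrics()` attaches exact Clopper–Pearson intervals to each
proportion — exact rather than Wald because the cohort scale (tens of
patients) makes normal approximations visibly wrong, and exhaustive
enumeration for n ≤ 20 confirms ≥95% coverage. `bootstrap_roc()`
resamples patients with replacement stratified by outcome class (at
n ≈ 46 an unstratified bootstrap produces single-class replicates), and
`delong_test()` compares paired AUCs via placement values, returning
`z = 0, p = 1` on the degenerate all-placements-equal case (identical or
monotone-transformed markers).

# Repeated-measures correlation

`rmcorr()` fits the shared-slope ANCOVA `y = subject intercepts + b·x`
by within-subject centering (algebraically identical to the sequential
least-squares fit with subject entered first — the unit tests verify the
equality against `lm()`/`anova()` on unbalanced data) and reports
`r_rm = sign(b)·√(SSx/(SSx + SSerr))` on `df = n_obs − n_subjects − 1`,
the F-based p, and a Fisher-z CI with standard error `1/√(df − 1)`.
Subjects contribute whatever complete pairs they have (data with 3 to 60
pairs per patient are first-class); subjects with fewer than two pairs
are excluded and listed. Between-subject level shifts are absorbed by
the intercepts — adding a distinct constant per subject to both
variables leaves `r_rm` unchanged.

`simulate_effort_pairs()` generates minute-level pairs for studying this
estimator at a chosen coupling: within subject,
`y = α_s + gain·x + ε` with a *single* noise SD calibrated so the pooled
within-subject correlation equals the target
(`σ = gain·√(E[var_s])·√(1/r² − 1)`). The noise is homoscedastic across
subjects, mirroring the phenotype model's constant `pdi_noise_sd`; a
subject-scaled alternative was rejected because it breaks the equal-
variance assumption under which the analytic CI is calibrated. At the
weak-coupling operating point (30 subjects × 25 pairs, r = 0.22) the
estimator's mean absolute error is ~0.03 and the analytic CI covers the
generating value slightly above 90% — below its nominal 95% because the
realized pooled correlation of a finite cohort varies around the
parameter; the bootstrap CI option in the literature addresses exactly
this, and the analytic interval should be read accordingly.

# Pipeline and reproducibility

`run_study()` chains the stages — simulate per patient, analyze, discard
waveforms (memory stays flat at any cohort size), pool snapshots into the
agreement analyses per metric, run the prediction stage at the configured
minute, and feed the SBT minute series into `rmcorr()` — and attaches a
manifest (package version, master seed, config hash). All randomness
descends from the single master seed through derived per-patient and
per-stage seeds; there is no wall-clock seeding and no global RNG
leakage (`cohort_plan()` restores the caller's RNG state).

The two-proportion sample-size utility implements the standard
normal-approximation formula
`n = ⌈(z_α√(2p̄q̄) + z_β√(p₁q₁ + p₂q₂))² / (p₁ − p₂)²⌉ `per group. At
rates 40% vs 10%, α = 0.05 two-sided, power 0.8 it returns 32 per group
(≈64 total; ~50 one-sided): planning statements of "40 patients" at
these rates are not recoverable from this standard formula, and the
package documents rather than reverse-engineers that gap.

**Problem sizes.** The defaults are the study conditions (200 Hz,
15/30/15-minute phases, 46 patients, 1000 bootstrap replicates). The
test suite and the acceptance script run reduced instances chosen as
adequate for what each check measures: 50–100 Hz sampling (detection at
50 Hz still resolves 0.5 s breaths with 25 samples), 1–3 min baselines,
3–12 min SBTs, and 100-seed sweeps for the cohort-ordering property.
Sampling-rate and duration scaling never touch the phenotype parameters.

# What passing tests do and do not show

The generator reproduces the *statistical structure* the analysis relies
on — outcome-dependent excursion distributions with realistic between-
and within-patient spread, exact pressure-channel identities, calibrated
within-subject coupling, artifact transients, truncated trials, paired
snapshot error with a poor-agreement subgroup. It does not model probe
physics, liver echogenicity, abdominal-motion compensation, sensor
drift, non-stationary breathing patterns (ramps, sighs, ineffective
efforts under assist), or correlated multi-breath artifacts. Green tests
therefore certify the estimators and the pipeline plumbing, not the
clinical performance of any device; numbers such as an AUC of ~0.75 at
minute 2 are properties of the synthetic cohort's effect sizes, and
real-data values will differ.

Known limitations: breath onsets within half a baseline window of a
record edge can shift when the signal lacks a stable zero baseline
(displacement-channel detection); the CUSUM 1.36 rule is conservative
(see above); Deming regression and ordinary least squares are
deliberately out of scope as comparison modes; and the rmcorr model is
fixed-slope by construction — random-slope extensions are a different
estimator.
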