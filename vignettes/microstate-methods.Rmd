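---
title: "Microstate analysis of longitudinal EEG cohorts: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate analysis of longitudinal EEG cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

EEG microstate analysis treats the multichannel scalp potential as a
sequence of brief (tens of milliseconds) quasi-stable topographies: at any
time `t` the average-referenced scalp map `v_t` (a vector over the C
channels) is modelled as one of K unit-norm template maps `a_k`, scaled by
an arbitrary amplitude and an arbitrary *polarity*,

    v_t ≈ s_t * g_t * a_{L_t},   s_t ∈ {−1, +1},  g_t > 0,

plus residual activity. Polarity invariance is fundamental: an oscillating
source flips the sign of the whole map twice per cycle without changing
the underlying generator configuration, so every quantity in this package
(assignment, clustering cost, explained variance) depends on maps only
through squared or absolute spatial correlations.

`microflight` implements the complete chain for longitudinal cohorts —
many subjects, many sessions, several curriculum stages — together with a
synthetic generator that plants known ground truth, so that every stage of
the chain can be validated end to end on data whose answer is known.

### Global field power and peak maps

GFP is the spatial standard deviation across channels at one sample
(population divisor C; for average-referenced data this is the column norm
over sqrt(C)). Moments of high GFP have the best topographic
signal-to-noise, so clustering uses only maps at local GFP maxima, thinned
so that retained peaks are at least `min_distance = 10` samples apart;
when two candidate maxima are closer, the higher one is kept (greedy by
height, ties to the earlier sample).

### Modified k-means and the CV criterion

`modified_kmeans()` alternates (a) assignment of each peak map to the
template with maximal squared spatial correlation and (b) template update
as the dominant eigenvector of the assigned maps' outer-product sum — the
polarity-free analogue of the k-means centroid. Convergence is declared
when the relative change of the mean orthogonal residual variance σ² falls
below `tol = 1e-6`. Because the alternation only finds local optima, the
procedure is restarted `n_init = 100` times from random subsets of the
data and the restart minimizing the cross-validation criterion

    CV = σ² * ((C − 1) / (C − 1 − K))²

is kept. CV penalizes K relative to the channel count; it is undefined for
K ≥ C − 1, which the code refuses. An empty cluster is re-seeded from the
currently worst-fit map. Tie-breaks everywhere go to the lowest class
index, and template signs are canonicalized (largest-magnitude entry
positive), so results are bit-reproducible given the seed.

On small instances (≤ 8 maps, K ≤ 3) the restarted search is verified in
the test suite against exhaustive enumeration of every surjective
assignment, each scored with its per-cluster optimal template.

### Group-level aggregation

Group templates are obtained hierarchically: session fits are pooled and
re-clustered to a subject-stage set, subject-stage sets to a stage
(condition) set, and stage sets to the global set. Each aggregation level
draws K of the pooled lower-level templates as initial templates `n_iter =
100` times, refines them with the same modified k-means update on the
pooled maps, and keeps the best CV. The literal alternative — score the
drawn candidate sets without refinement — is available via
`refine = FALSE`; refinement is the default because scoring unrefined
subsets converges to the same fixed points only when the pooled sets
already agree.

### Backfitting, letters, parameters

`backfit()` labels every sample of a recording with the template of
maximal absolute Pearson spatial correlation. Deliberately, **no temporal
smoothing and no minimum-duration post-processing** are applied, so the
label dynamics reflect the raw topographic time course. A flat sample
(zero variance) takes class 1 with correlation recorded as 0.

Conventional letters A–G are attached by solving the assignment problem
(maximal total |correlation|) against a packaged library of *synthetic*
canonical-like templates built from fixed low-degree harmonic patterns on
the montage. The letters are cosmetic metadata for plots and tables; no
numeric result depends on them.

Three temporal parameters summarize a label sequence per class: coverage
(fraction of samples), mean duration (mean run length, ms) and occurrence
(runs per second). Truncated boundary runs are counted in full, which
makes

    coverage_k = occurrence_k × duration_k / 1000

an exact identity (asserted to 1e−12 in the tests); the common alternative
of dropping boundary runs is available (`count_truncated = FALSE`) but
breaks the identity and is off by default. A class absent from a sequence
has coverage and occurrence 0 and duration `NA` — never 0, which would
bias stage means downward.

The global explained variance of a labeled recording is

    GEV = Σ_t (GFP_t · corr_t)² / Σ_t GFP_t²,

with `corr_t` the correlation between sample `t` and its assigned
template.

## The statistics layer

`rm_anova_2way()` implements the fully within-subject two-factor ANOVA
from first principles: sums of squares partitioned with subject as a
random blocking factor, each effect tested against its own
factor-by-subject interaction. Greenhouse–Geisser epsilon is computed per
effect from the covariance of the subject-level cell scores projected onto
the effect's orthonormal contrasts, and the corrected p-value uses
epsilon-scaled degrees of freedom. Because the labelling of effect sizes
in published tables is often ambiguous, both partial and generalized eta
squared are reported. Missing cells are an error — no imputation,
anywhere.

Post-hoc machinery is classical: paired t-tests with Bonferroni adjustment
over an explicitly declared family (`p_adj = min(1, p × family)`), with
the zero-variance edge case handled as t = 0, p = 1.

`spearman_matrix()` correlates each class's parameter values with each
evaluation dimension's scores, pairing observations by (subject, stage) —
n = subjects × stages — with parameters averaged over sessions within a
stage. A subject-level mode (`unit = "subject"`, n = subjects) is
available. P-values use the t approximation; the Bonferroni family is all
class × dimension cells within one parameter type (35 cells for K = 7 and
5 dimensions). Spearman's rank basis makes every result invariant under
strictly monotone transforms of either variable, which is also why the
generator can plant target rank-correlations exactly (below).

## The synthetic cohort generator

The generator emulates a pilot-training-style study: 24 subjects, a
64-channel cap at 250 Hz, 7 microstate classes, and 22 task sessions split
7/8/7 across three curriculum stages (Training, PracticeA, PracticeB).
Session durations default to 30 s so that desk-scale experiments stay
cheap; the demonstration configuration reduces subjects, channels and
sessions further (stated in `inst/extdata/demo_config.yaml`).

* **Topographies** are random mixtures of degree-1 and degree-2 real
  spherical harmonics on the montage plus a small rough component,
  average-referenced, unit-norm, and mutually decorrelated to
  |corr| ≤ 0.5 by rejection sampling (exact orthogonalization when the
  bound is 0).
* **Dynamics** are semi-Markov: gamma dwell times (shape 2 — peaked, not
  geometric, matching the non-exponential dwell histograms of real
  microstates) with an 80 ms mean, uniform transitions that never repeat
  the current class. Each *subject × class* dwell mean is multiplied by a
  log-normal factor (σ = 0.15, i.e. ~15 % between-subject coefficient of
  variation, in the range reported for temporal microstate parameters).
  This between-subject structure is essential: without it every subject
  shares one generative parameter set, subject-level parameters are pure
  Monte-Carlo noise, and a planted brain–behavior association would be a
  statement about sampling error rather than about dynamics.
* **EEG rendering** multiplies the active template by a rectified 10 Hz
  sinusoid envelope with an additive floor, a random sign per run (forcing
  polarity invariance downstream), plus spatially white Gaussian sensor
  noise projected onto the average-reference subspace. The envelope is
  scaled so the clean signal's time-mean GFP is `gfp_mean = 10` µV — a
  typical band-limited scalp EEG value — which keeps per-channel
  amplitudes channel-count-invariant and well under the ±100 µV artifact
  threshold for clean data. The floor is 0.5 (GFP troughs about a third of
  peaks): real broadband GFP does not collapse to zero between alpha
  peaks, and an envelope that nearly vanishes would make unsmoothed
  backfitting flicker freely at troughs, destroying the occurrence and
  duration parameters' rank structure for reasons unrelated to the method
  under test. SNR is parametrized as mean signal power per channel entry
  over noise variance; the default is 4.
* **Evaluation scores** (five dimensions, 1–5 scale, continuous) are
  planted per dimension as a strictly monotone transform of the chosen
  subject × stage parameter plus calibrated noise. Calibration uses the
  Gaussian-copula relation r = 2·sin(π·ρ/6) on normal scores of the
  parameter, so the population Spearman correlation approximates the
  target ρ; a target of ±1 with no extra noise yields a sample Spearman of
  exactly ±1. At most one effect is planted per dimension (a dimension's
  score can be a monotone transform of only one parameter); dimensions
  without an effect are pure noise. The default plants positive effects
  for two late classes' coverage and one class's duration and a negative
  one for another class's occurrence, with one dimension left null.

Ground-truth parameters in a simulated cohort are always computed from the
realized label sequences by the same `parameters` module the analysis
uses, never copied from the configuration targets, so generator and
estimator are exactly closed over noiseless data.

What the generator does **not** emulate: volume-conducted spatially
correlated background activity, artifacts (blinks, muscle, line noise),
biophysical head geometry, non-stationary dwell statistics, or any
systematic stage effect on the dynamics. Passing tests therefore
demonstrate correctness of the algorithms under the stated state model,
not robustness to every property of real recordings.

## Preprocessing: rules and their interaction with synthetic data

The cleaning chain mirrors standard practice for microstate studies:
zero-phase Hamming windowed-sinc FIR band-pass (1–40 Hz; kernel length set
by the transition bandwidth, single centered application so the phase is
exactly zero and the magnitude response is not squared), bad-channel
detection, a pluggable artifact-removal hook (identity by default; the
place where an ICA-based classifier would sit), 2-s epoching, FASTER-style
per-epoch channel statistics (variance, median gradient, amplitude range,
deviation from mean amplitude; any |z| > 3 across channels repairs the
channel by spherical-spline interpolation, more than 25 % implicated flags
the epoch), segment rejection (±100 µV amplitude rule plus kernel-density
negative-log-likelihood probability statistics at 3 SD per electrode and
per epoch), spherical-spline repair of global bad channels, average
referencing and anti-aliased downsampling to 250 Hz. Channel count is
preserved end to end; bad channels are interpolated, never dropped.

Three deliberate choices deserve notice:

* **Neighbor-correlation rule vs. white noise.** The bad-channel rule
  "mean absolute correlation with the 4 nearest neighbours < 0.8"
  presumes the spatial smoothness of volume-conducted EEG. The generator's
  sensor noise is spatially *white*, and even its noiseless signal
  decorrelates neighbours whose template loadings differ, so on synthetic
  cohorts this rule flags healthy channels wholesale. It is therefore
  exercised on constructed data in the unit tests, and the pipeline's
  simulate path disables it (`use_neighbors: false`). On real recordings
  it should be on.
* **Band-pass vs. the rectified envelope.** The generator's clean signal
  is already band-limited and drift-free, and its rectified-sinusoid
  envelope carries its run-level polarity in a DC pedestal. A 1 Hz
  high-pass removes that pedestal, making the within-run amplitude
  oscillate through zero ~20 times per second — i.e. the filter distorts
  the generative model itself rather than removing any planted noise, and
  unsmoothed backfitting then flickers at the zero crossings. The
  demonstration configuration consequently runs with `bandpass: false`;
  the filter itself is validated in unit tests on signals with out-of-band
  content (DC, drift, 60 Hz).
* **Amplitude statistic.** The whole-recording amplitude rule z-scores
  log-RMS across channels (log for symmetry of the across-channel
  distribution); the flatness floor is an absolute first difference below
  1e−8 µV/sample for more than 5 s.

Spherical-spline interpolation uses the standard Legendre-series g
function (order 4, 50 terms, Tikhonov regularization 1e−5), solved once
per bad-channel set and applied as a linear operator to all samples.
Resampling applies a windowed-sinc anti-alias low-pass at 0.45× the target
rate and evaluates the band-limited signal on the new grid by cubic
splines — after anti-aliasing the signal is oversampled manyfold, so the
interpolation error is far below the 2 % amplitude contract (measured
< 0.5 % on a 10 Hz tone for 2048 → 250 Hz).

## Pipeline, reproducibility, problem sizes

`run_pipeline()` chains simulate → preprocess → session fits → hierarchical
aggregation → letters → backfit → parameters → statistics, writing CSV/JSON
artifacts plus a manifest (package and R versions, seed, per-stage
timings, output checksums). One global seed fans out to per-stage,
per-session sub-streams through a documented derivation, so any single
session can be re-rendered bit-identically in isolation and a rerun with
the same configuration reproduces identical outputs (asserted by checksum
in the tests). EEG is rendered lazily one session at a time: memory stays
flat regardless of cohort size.

Validation problem sizes were chosen to keep the full suite comfortably
desk-scale while leaving no estimator starved: clustering-oracle instances
of ≤ 8 maps (where exhaustive search over all assignments is exact),
recovery runs with 2 000 GFP-peak maps at SNR 4 on 64 channels, an
8-subject hierarchical cohort, 20 replicates of 120 s for the dwell-time
law, and 500/100 replicates for the null error rate and power of the
35-cell Bonferroni family. The bundled demonstration uses 16 subjects ×
6 sessions × 20 s on 32 channels with 20 restarts — enough for every
planted correlation to clear Bonferroni-corrected significance — and runs
in a few minutes on one CPU.

## Known limitations

* The statistics layer requires complete designs; unbalanced or missing
  cells fail loudly rather than being imputed.
* GG epsilon estimation is biased low for small n (a property of the
  estimator, visible if compound-symmetric data are simulated with few
  subjects).
* The canonical A–G library is a synthetic approximation; letter
  assignments on real data should be reviewed against published
  topographies.
* The assignment solver for letters is exhaustive and limited to template
  libraries of ≤ 9 maps.
* Recordings are read and written in a package-specific plain-text layout
  (JSON header + full-precision matrix); standard binary biosignal
  containers are not parsed.
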