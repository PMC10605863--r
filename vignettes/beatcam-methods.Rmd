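---
title: "Detecting BMI-associated beat morphology changes in paediatric ECGs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting BMI-associated beat morphology changes in paediatric ECGs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Obesity is associated with electrocardiographic changes in adults (axis
shifts, ventricular hypertrophy patterns, T-wave flattening), but evidence
in children is thin. `beatcam` implements a beat-level analysis pipeline
for asking that question of single-lead (lead I) paediatric ECGs: segment
each 10-s, 500 Hz recording into complete PQRST beats, label each beat
with the child's BMI category, train a 1D convolutional network to
classify beats as coming from normal-weight or obese children, and then
use Grad-CAM++ to localise *which part of the beat* the classifier relies
on. If the classifier beats chance, the beat waveform carries
BMI-associated information; the relevance profile says where.

Because the motivating cohort data are not publicly available, the
package ships a first-class synthetic cohort generator that emulates the
statistical structure the analysis assumes. Every stage of the pipeline
is exercised and tested offline against that generator's ground truth.

## Synthetic cohort generator

`build_template()` models a beat as a sum of five Gaussians, one per
PQRST deflection (centres −140, −22, 0, +25, +250 ms relative to the R
peak; widths 22, 9, 11, 9, 35 ms; amplitudes +0.15, −0.10, +1.10, −0.25,
+0.35 mV). These values are ordinary lead-I morphology at paediatric
heart rates; they are a modelling convenience, not a physiological claim.
The two classes differ only inside a configurable *difference window*,
by default the T-wave region +150 to +350 ms after the R peak: at effect
size $e$ the obese template's T amplitude is scaled by $\max(0, 1-0.5e)$
and its centre shifted $+8e$ ms. At $e=0$ the classes are identical
(the null used for calibration tests). The window placement follows the
adult literature's T-wave flattening; where real differences lie in
children is exactly what the real analysis would estimate, so the window
is a simulation parameter, not a claim about biology — it is what lets
the test suite check *parameter recovery*: inject a difference at a known
place, then verify the explanation stage finds it.

Gaussian components have infinite support, so "identical outside the
window" holds only up to tail leakage; with the 35 ms T width the largest
outside-window difference is ~2.5% of the in-window peak difference, and
tests assert < 3%.

`synth_record()` draws R-to-R intervals uniformly from the configured
heart-rate range (default 70–110 bpm, ordinary for 9–11-year-olds;
a degenerate range gives perfectly regular beats), snaps R times to the
2 ms sample grid so the retained ground-truth indices are exact,
superimposes the class template at each R position, and adds noise per
`noise_spec()`: white Gaussian noise (default SD 0.03 mV), sinusoidal
baseline wander (0.10 mV at 0.25 Hz, the respiration band), powerline
interference (0.02 mV at 50 Hz) and Poisson-count transient bumps
(rate 0.5/record) standing in for motion artefacts. Defaults are set so
records look noisy to the eye but remain detectable — the study the
pipeline emulates used clinical resting ECGs, not ambulatory recordings.
The noise-free waveform and true R indices ride along as attributes
(`clean_mV`, `r_truth`) purely as test oracles.

Anthropometry is sampled to *guarantee* label consistency: height from a
sex-specific normal (1.40/1.39 m ± 0.065 m), a BMI uniform inside the
target category's interval with a 0.25 kg/m² guard margin against the
category boundaries (so that rounding weight to 0.1 kg and height to
0.1 cm for storage can never flip the recomputed category), then weight
solved from BMI and height. Ages are uniform over 9–11 completed years at
the collection date. One root seed drives everything; each record derives
a substream via a fixed Lehmer-style rule (`derive_seed()`), so cohorts
are byte-reproducible and individual records are independently
reproducible.

`write_cohort()` serialises records into a small XML dialect (subject id,
ISO dates, sex, weight in kg, height in cm, free-text report, and the
waveform as whitespace-separated integer microvolts with a declared
scale) plus a manifest CSV. Deliberately invalid records (empty waveform,
999 cm height) and abnormal-report records are allocated
deterministically to the first records of each class, so exclusion
counts in tests are exact rather than probabilistic.

## Ingest and validation

`parse_record()` reads the dialect back; an empty waveform parses
successfully (classification happens later), a missing element is a
schema error naming the element. `validate_record()` classifies rather
than raises, with a documented first-failure order: duplicate (key:
subject id + collection date) → missing signal → abnormal signal →
invalid dates → invalid anthropometry. The abnormal-signal heuristics
are explicit guesses, configurable in `signal_sanity_limits()`: wrong
length (≠ 5000 samples), a constant run longer than 1 s, more than 5% of
samples pinned at the record maximum (clipping), or any amplitude above
10 mV. Anthropometry plausibility defaults to 100–200 cm and 10–120 kg.
Age is completed years at collection (the age increments on the birthday)
and the cohort filter keeps the inclusive 9–11 band.

## BMI categories

BMI is weight/height². The operational category cutoffs are the
sex-specific values used in the motivating analysis: girls — normal
< 19, obese > 22.6; boys — normal < 18.5, obese > 21.4; overweight in
between. The printed intervals leave the exact boundary values (19, 22.6,
18.5, 21.4) unassigned; `classify_bmi()` assigns boundaries to
overweight, the middle class, since both neighbouring intervals exclude
them — a conservative choice because overweight children are excluded
from the analysis anyway. WHO z-score classification is out of scope;
the numeric cutoffs are the operational contract.

## Filtering and beat segmentation

The band-pass is a linear-phase windowed-sinc FIR (Hamming), applied by
forward convolution followed by an explicit group-delay shift of
(taps−1)/2 samples, so filtered sample *t* is aligned with raw sample
*t* and R indices share one time base. Band edges and length are
implementation choices: 0.5–40 Hz (the conventional diagnostic-ECG band:
0.5 Hz removes baseline wander, 40 Hz suppresses mains/EMG) with 2001
taps. The length matters: at 500 Hz a Hamming design needs a transition
band of roughly 3.3·fs/N, so a 501-tap filter with a 0.5 Hz corner still
passes 73% of DC — it does not actually remove baseline wander. 2001
taps give a ~0.8 Hz transition, DC gain 0.0013 and mid-band gain 1.000.
Both are verified numerically in the tests by evaluating the transfer
function.

R peaks are found with a classical adaptive-threshold detector in the
Hamilton style: an 8–16 Hz detection band emphasises QRS energy, a
zero-phase central-difference derivative and 80 ms moving-average
integration build the detection function, and candidate peaks are
accepted against an adaptive threshold noise + 0.3125·(signal − noise)
maintained from running means of the last eight signal and noise peaks,
with a 200 ms refractory period. Two implementation details matter in
practice and are covered by tests: candidates are first thinned by
non-maximum suppression over the refractory neighbourhood (otherwise a
P wave can fire just before the QRS and push the true R peak into the
refractory window), and each accepted detection is refined to the local
signal maximum by hill-climbing in ±10-sample steps (a single fixed
window can stop at the window edge one sample short of the peak). On
noise-free synthetic records the detector recovers every hidden R
position exactly; at the default noise profile sensitivity and positive
predictive value are 1.0 over 50 records (asserted ≥ 0.99).

A *complete beat* is the half-open window [r−100, r+200) of the filtered
signal: 300 samples (600 ms) with the R peak at offset 100 (1-based
position 101). The verbal rule "100 samples before, 200 after, plus the
peak" would give 301 samples; the half-open convention reconciles it
with the stated 300 and is asserted prominently in tests. R peaks closer
than 100 samples to the start or 200 to the end are discarded and logged,
so every detection is accounted for (kept + discarded = detected).

## Dataset assembly

`apply_exclusions()` drops overweight children (sharpening the contrast
between groups) and any record whose free-text cardiologist report
contains an abnormality keyword (case-insensitive match against a
configurable lexicon: arrhythmia, early repolarisation, bradycardia,
atrioventricular block, ventricular hypertrophy, axis deviation) — so
that diagnosed cardiac conditions cannot masquerade as BMI effects.
Remaining beats inherit their subject's class.

`split_dataset()` is stratified by class and defaults to *subject-level*
splitting at 70/20/10: all beats of one child land in one split. The
alternative `level = "beat"` assigns beats independently; it is provided
for protocol compatibility but inflates apparent accuracy, because
near-identical beats from the same child then appear in both training
and evaluation. Counts use largest-remainder allocation, so 1000 beats at
70/20/10 give exactly 700/200/100. No class rebalancing is applied.

## The classifier

`canonical_spec()` is the fixed reference architecture: input 300;
four convolutional blocks, each kernel 3 / stride 1 / length-preserving
padding, with 128 (ReLU, dropout 0.45), 16 (sigmoid, 0.10), 8 (batch
norm + ReLU, 0.05) and 128 (sigmoid, 0.40) filters; flatten (38,400
units — which is only consistent with length-preserving padding, the
reason that padding is forced); a 32-unit dense block; softmax over two
classes. Block-internal order is conv → batch norm (where present) →
activation → dropout. Training: Adam at 10⁻³, batch size 200,
categorical cross-entropy on one-hot labels, Xavier weight
initialisation, zero biases, early stopping with patience 30 monitored
on validation accuracy, best-validation weights restored. "Patience"
counts epochs by default; a `patience_unit = "batches"` reading is
available since "optimisation steps" is ambiguous.

Two choices deserve emphasis:

* **Dense-block activation.** The architecture description names an
  activation for every convolutional block and for the output, but none
  for the dense block. We take that literally: the dense block is linear
  by default (`dense_activation = "linear"`), with ReLU and sigmoid
  available. This is not merely textual: the dense block's inputs are
  outputs of a sigmoid layer and hence all-positive, and in that regime
  a ReLU dense layer can die wholesale early in training (every unit
  negative for every input), after which gradients upstream are exactly
  zero and the network is permanently stuck at chance. We observed
  precisely this failure before adopting the linear reading.
* **Input standardisation.** Beats are standardised with a single global
  mean and SD estimated from the training split, stored on the model and
  re-applied at prediction and explanation time. A scalar scale
  preserves relative morphology. Without it convergence is erratic.

The engine itself (forward/backward passes, Adam, batch norm, dropout,
early stopping) is part of the package: activations live in
(n·300) × channels matrices, and the kernel-3 convolution is one wide
matrix product per layer with compiled shift/sum plumbing
(`src/conv1d.cpp`). Backpropagation is verified against central finite
differences to ~10⁻⁹ relative error in the test suite, on a small model
that includes every layer type; this is the anti-bug oracle for both
training and the explanation stage.

## Explanation: Grad-CAM++ in 1D

For a class score $S_c$ (pre-softmax logit) and last-block feature maps
$A^k(t)$, per-location weights are

$$\alpha_k(t) = \frac{g_k(t)^2}{2 g_k(t)^2 + \sum_{t'} A^k(t')\, g_k(t')^3}\,, \qquad
g_k(t) = \frac{\partial S_c}{\partial A^k(t)}\,,$$

with $\alpha$ set to 0 where the denominator vanishes; channel weights
$w_k = \sum_t \alpha_k(t)\,\mathrm{relu}(g_k(t))$; and the map is
$\mathrm{CAM}(t) = \mathrm{relu}\big(\sum_k w_k A^k(t)\big)$, rescaled to
maximum 1 per beat. The $\alpha$ closed form uses the standard
powers-of-gradient substitution for the higher derivatives, which is
exact when the score is (an exponential of) a linear function of the
feature maps — true here with the linear dense block. Because all blocks
preserve length, the map already lives on the 300-sample beat axis; no
upsampling is involved.

Class profiles average per-beat maps over *correctly classified* beats
of one class only (default split: validation), and the overlap profile
is the pointwise mean of the two class profiles. Per-beat normalisation
before averaging prevents high-amplitude beats from dominating;
`normalize = FALSE` gives raw maps. `localization_score()` measures the
fraction of profile mass inside a half-open sample window — the
instrument used by the parameter-recovery tests: when the generator
injects differences only in the T window, an informative explanation
should concentrate mass there beyond the window's length share (1/3).

One honest limitation, documented rather than hidden: with a sigmoid
final block, feature maps carry a positive pedestal (values near 0.5
everywhere), and the rectified weighted sum inherits it. Localisation
mass ratios are therefore conservative — structure rides on a baseline.
The parameter-recovery experiments in `tests/testthat/test-acceptance.R`
quantify exactly how much enrichment the full pipeline achieves under
the study conditions, and the permutation-null check verifies that the
enrichment disappears when labels are shuffled before training.

## Architecture search

`random_search()` and `genetic_search()` cover the two strategies whose
budgets the reference settings parameterise (max trials 400; 20
generations of 20 — available as `budget_preset("full")`). The desk
preset (10 trials × 10 epochs; 3 generations of 4) keeps a search run in
the minutes range on one CPU. The genetic operators are this package's
choices: tournament selection of size 2, blockwise crossover
(position-wise block inheritance from either parent, coin-flip scalars),
per-field mutation at a configurable rate, single-individual elitism
(making the best fitness non-decreasing across generations — a tested
invariant), and fitness memoisation keyed on the genome so unchanged
individuals are not retrained. Fitness is early-stopped validation
accuracy. Both searches accept an injectable fitness function, which the
mechanics tests use to stay fast and deterministic.

## Reporting

`mean_beat_profile()` gives pointwise class means with SD bands;
`render_report()` writes deterministic CSV/JSON tables (accuracy per
split formatted as integer percentages, confusion matrix with rows =
true class) and figures (class-mean beats with SD ribbons, binned CAM
histograms — binning is display-only, statistics always use unbinned
vectors — the overlap profile, and a composite overlaying mean beats on
the overlap histogram). Figures regenerate from the persisted CSVs, so
tests compare numbers, never pixels.

## Problem sizes and numerical choices

The test suite trains reduced models (2 blocks, 8/4 filters) on cohorts
of ~30 subjects for mechanics, and the full canonical network on a
200-subject, ~2700-beat cohort for the end-to-end recovery experiments
(≈ 25 s/epoch on one CPU; the recovery run uses 12 epochs, the null and
permutation runs 6). The full-scale reference protocol (200 epochs,
patience 30) is available through the same interfaces. Other fixed
choices: batch-norm ε = 10⁻⁵ with running-statistic momentum 0.9;
Adam β = (0.9, 0.999), ε = 10⁻⁸; cross-entropy clamps probabilities at
10⁻¹²; softmax subtracts the row maximum; ties in `max.col` resolve to
the first class deterministically. Degenerate inputs are defined
behaviour: an all-zero signal yields no R peaks; an all-zero CAM has an
undefined localisation score (error, not NaN); a single-class dataset
warns at labelling time and errors at training time.

## What passing tests do and do not show

The synthetic generator produces stylised beats: Gaussian deflections,
stationary noise, a single injected class difference at a known
location, no arrhythmias, no electrode artefact structure, no
inter-subject morphology families beyond the two class templates.
Passing recovery tests therefore demonstrates that the *pipeline* —
segmentation, labelling, training, explanation — can detect and localise
a class difference of plausible magnitude under controlled conditions.
It does not validate any clinical claim about real paediatric ECGs, nor
that real BMI-associated differences live in the T wave.
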