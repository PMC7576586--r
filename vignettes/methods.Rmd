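---
title: "Methods: synthetic gait generation, stride variables, and classification"
author: "equigait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic gait generation, stride variables, and classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equigait)
```

## The problem

Horses perform a wide repertoire of gaits: the universal walk, trot and
canter, plus breed-specific gaits such as the Icelandic toelt and pace and
the Colombian paso fino and trocha.  Classifying the gait of a moving
horse from body-mounted inertial sensors (IMUs) is a standard task in
equine biomechanics, veterinary gait analysis and phenotyping for
breeding.  The classical description of symmetrical gaits is Hildebrand's
two-dimensional diagram: duty factor (stance duration as a percentage of
stride) against limb phase / advanced placement.  Modern work shows the
gaits separate better in a higher-dimensional space of stride-timing and
interlimb-coordination variables, or directly from windowed raw signals
with a recurrent network.

`equigait` implements that full analysis as a reusable, tested pipeline:

1. a **synthetic cohort generator** (footfall timelines and IMU-like
   multichannel signals) with realistic per-gait parameters,
2. **stride segmentation and feature extraction** (the complete
   stride-timing / interlimb variable set plus the Hildebrand
   projection),
3. a **classifier suite** (LDA, QDA, decision tree, random forest, SVM,
   a one-hidden-layer network, and an LSTM sequence model), and
4. **horse-disjoint 5-fold cross-validation** with confusion-matrix
   reporting and experiment grids.

Because no public IMU recordings accompany the reference cohort, the
generator is a first-class, tested component: it defines the study
conditions under which every downstream claim is evaluated.

## The synthetic generator

### Footfall timelines

A gait preset (`gaitPresets()`) holds, per gait: the hoof-on phase of
each limb within the stride (fraction in $[0,1)$), the stride-duration
distribution (s), the duty-factor distribution (% of stride) and the
per-limb hoof-on jitter (fraction of stride).  Stride-duration and
duty-factor means and SDs are the descriptive statistics of a large
multi-breed reference cohort (7576 strides); for example trot strides
last $0.63 \pm 0.12$ s at duty factor $44.2 \pm 4.8$ %.

Per stride $k$ the generator draws

$$T_k \sim \mathcal N(\mu_T \cdot m_h,\ \sigma_T)\ \text{truncated at}\ 0.2\,\mathrm{s},
\qquad d_k \sim \mathcal N(\mu_d, \sigma_d),$$

where $m_h$ is a per-horse multiplier.  Each limb's hoof-on lands at its
phase offset plus $\mathcal N(0, \sigma_\phi)$ jitter, and its hoof-off
at hoof-on $+ (d_k + \epsilon_l)/100 \cdot T_k$ with a small per-limb
perturbation $\epsilon_l \sim \mathcal N(0, 0.5\,\%)$.  Drawing one
stride-level duty factor shared by all limbs keeps stance and stride
durations correlated across limbs, as in real locomotion.

Choices worth noting:

* **Walk stride duration.**  The reference table's walk row is internally
  inconsistent: the printed stride duration (1.80 s) disagrees with the
  printed stance duration (0.65 s), duty factor (60.6 %) and stride
  frequency (0.95 Hz), which jointly imply $\approx$ 1.07 s.  All other
  rows satisfy both identities ($\text{stance} = \text{duty} \times
  \text{stride}$, $f = 1/T$).  The default preset uses the internally
  consistent 1.07 s; `gaitPresets(walkPrinted = TRUE)` selects the
  printed value.  The Jensen check below supports the choice: simulated
  mean stride frequency under the 1.07 s preset is $\approx 0.96$ Hz,
  matching the printed 0.95 Hz, while 1.80 s would give 0.56 Hz.
* **Canter presets.**  Canter footfall times are not tabulated; the
  presets encode the standard transverse three-beat order (right lead:
  LH at 0, the synchronous diagonal RH+LF at 0.30, RF at 0.45; left lead
  mirrored).  These offsets are configurable.
* **Trocha.**  The trocha is modelled as a trot whose diagonal fore
  contact is dissociated by $\delta = 0.08$ stride, with the fore landing
  *before* its diagonal hind partner (offsets LH 0, RF 0.92, RH 0.5,
  LF 0.42).  That places synthetic trocha at (dap $-8$, lap $+42$),
  adjacent to trot's (0, 50) in Hildebrand space — reflecting the
  well-documented closeness of the two gaits.  Trocha also carries a
  larger phase jitter (0.03 stride vs 0.015 elsewhere) because its
  footfall timing is characteristically less regular.
* **Horse profiles.**  Each horse gets a stride-duration multiplier
  $\sim \mathcal N(1, 0.12)$ truncated to $[0.6, 1.4]$ (drawn once and
  reused across its trials) and a sensor noise SD (default 0.3 signal
  units).  The multiplier spread reproduces the strong per-horse/breed
  clustering of stride durations seen in real cohorts.
* **Seeding.**  One root seed; per-horse and per-trial child streams are
  derived by stable string hashing (`childSeed`), so enlarging a cohort
  never reshuffles existing horses' data.

### Signal blocks

`simulateSignals()` renders 42 channels (7 sites $\times$ 3 accelerometer
+ 3 gyroscope axes) at 200 Hz.  Limb channels receive an exponentially
decaying transient (decay 30 ms) at each hoof-on, with amplitude
inversely proportional to that stance's duration — so faster gaits peak
higher — plus a swing-phase sinusoid.  Upper-body channels receive
attenuated sums of the limb transients plus a vertical harmonic locked to
stride phase (two cycles per stride for gaits with a synchronous limb
pair, one otherwise) plus Gaussian noise.  Lateral axes carry the limb
side as a sign, so midline sensors retain left/right-lead information, as
real roll/sway channels do.

This signal model is deliberately simple plumbing for the raw-signal
classification path: it carries gait-dependent periodic structure,
amplitude ordering and limb attribution, but it is **not** a
biomechanical simulation.  Passing tests on it demonstrate that the
pipeline's machinery is correct, not that the models would reach the same
accuracy on real recordings.

## Stride variables

Strides are segmented between consecutive hoof-on events of a reference
limb (left hind by default, matching the hind-centric convention of the
classical diagram; configurable).  Each limb's hoof-on events are paired
with strides by *index* (the k-th onset belongs to the k-th stride),
anchored at the first onset within half a stride of the first window and
re-locked locally if external data are irregular.  Pairing by index
rather than by window containment matters for limbs whose phase sits
near the stride boundary (the trot's diagonal partner of the reference
limb, or the trocha's dissociated fore): with containment, a marginally
jittered onset either drops the stride (a selection correlated with
window length) or shifts all later pairings by one, and both distort
duty-factor recovery.  Windows in which some limb has no pairable event
are flagged incomplete and dropped from feature tables — mirroring
expert segment selection rather than imputing.

Stance duration is an *event-level* variable: the full duration of the
stance each limb initiates in its stride, not the sum of window-clipped
stance time.  Summing clipped pieces would mix the neighbouring strides'
durations into the duty-factor ratio and bias it upward (by
$\approx$ duty $\times \sigma_T^2/\mu_T^2$ for limbs whose stance
crosses the stride boundary — about $+0.3$ percentage points for the
walk).  The support-phase and overlap variables, by contrast, describe
the distribution of time *within* the window and correctly use the
clipped intervals.  A small $O(\sigma_\phi^2)$ ratio term from jitter in
the window denominator remains: the expectation of measured duty is
$\mu_d\,(1 + \sigma_\phi^2(2 + 4\sigma_T^2/\mu_T^2))$ — about $+0.02$
percentage points at the default jitter and $+0.09$ for the trocha's
doubled jitter, and the recovery tests verify the mean against this
second-order expectation, exactly as the stride-frequency check verifies
$E[1/T]$ against $(1/\mu)(1+\sigma^2/\mu^2)$.

Per complete stride the package computes: stride duration and frequency;
per-limb and mean stance duration and duty factor; diagonal and lateral
advanced placement; minimum, maximum and time-weighted median number of
supporting limbs; the stride percentages in quadrupedal, tripedal,
bipedal, single-limb support and suspension; and the six limb-pair
overlap percentages.

Numerical conventions:

* **Support profile.**  An event sweep over the sorted on/off boundaries
  yields the piecewise-constant limbs-in-stance count; segment lengths
  sum to the stride duration exactly, so the five support percentages sum
  to 100 at machine precision.  The sweep is verified against a
  dense-grid brute-force oracle in the tests.
* **Advanced placements.**  For each hind limb, the signed circular
  difference (fore hoof-on $-$ hind hoof-on) as a percentage of stride,
  mapped to $(-50, 50]$; fore = ipsilateral for LAP, diagonal for DAP;
  positive = fore follows hind.  The two pairs are averaged
  *circularly*: a trot stride can jitter to $+49.6$ on one pair and
  $-49.8$ on the other, and an arithmetic mean would collapse that to
  $\approx 0$; the circular mean correctly returns $\approx \pm 50$.
  Away from the wrap the circular mean equals the arithmetic mean.
  Canonical corners: trot (0, 50), pace (50, 0), walk ($-25$, 25).
  Because trot sits exactly on the $\pm 50$ discontinuity, analyses of
  lateral dissociation magnitude should use $|$lap$|$.
* **Median limbs.**  The time-weighted median of the support profile
  (smallest count whose cumulative support time reaches half the
  stride).
* **Overlaps.**  Pairwise stance intersection measured on the
  window-clipped stance sets; a stance phase split by the window edge
  contributes both fragments, which is equivalent to measuring on the
  stride circle, so nothing is undercounted.
* **Simultaneity.**  Onsets within 1 ms are displayed as simultaneous
  but never merged in arithmetic.

The Hildebrand projection (`hildebrandCoordinates`, `hildebrandTable`) is
a pure accessor: $x =$ dap, $y =$ lap.  Where the classical diagram's
duty-factor axis is wanted, both the hind-limb and the four-limb mean
duty factors are available as columns; the package defaults to the
four-limb mean, which is how the reference cohort tabulates duty factor.

## Classifier suite

Feature models (`trainFeatureModel`) operate on three column subsets:
`all` (the 20 scalar stride variables, using four-limb means),
`stride_only` (stride duration, mean stance duration, stride frequency,
mean duty factor) and `hildebrand2` (duty factor + lateral advanced
placement).  LDA/QDA/SVM/FC see per-column z-scored features with exactly
collinear columns removed by rank-revealing QR (the five support
percentages sum to 100 by construction); QDA additionally drops columns
that make any within-class covariance rank-deficient at QDA's own
tolerance.  Trees and forests consume raw features.  Defaults: forest
100 trees; SVM radial kernel, one-vs-one.

The FC network is one hidden layer (40 tanh units by default) with a
softmax output, trained by full-batch Adam with early stopping on a 10 %
held-out slice of the training fold (patience 20, at most 200 epochs) —
the optimizer, epoch budget and regularization were open choices and are
fixed here as package defaults.  Gradients are verified against numerical
differentiation in the tests.

The sequence model (`trainSequenceModel`) is a stack of LSTM layers
(two by default) whose final hidden state feeds a softmax classification
layer, with an optional bidirectional variant that reads each window in
both directions and concatenates the final states (roughly doubling the
recurrent parameter count).  The reference architecture used width 500 on
GPU; the package default is width 64, and the desk-scale configuration
used in tests and in the acceptance script is width 32 with `timeStride
= 8`.  Two model-side preprocessing choices matter at desk scale:

* inputs (in $[0,1]$ after min-max normalization) are centered around
  zero inside the model — with all-positive inputs, sigmoid/tanh units
  receive strongly correlated gradients and training plateaus at the
  class prior for hundreds of updates;
* `timeStride` keeps every $k$-th sample, shortening the recurrence;
  at stride 8 the effective rate is 25 Hz, still far above the $\le$
  10 Hz band where gait fundamentals and impact envelopes live.

Training is minibatch Adam (default lr 0.01, batch 16) for a fixed epoch
budget, bit-reproducible given the seed.

Signal normalization (`normalizeSignals`) is per-channel min-max to
$[0,1]$.  The normalization scope (per recording vs per training set) was
an open choice; the default is per recording, and frozen training
statistics can be supplied and are then applied with clipping.  Windowing
(`windowSignals`) crops non-overlapping 1/2/3 s subsections, dropping the
trailing remainder; synthetic blocks are single-gait by construction, so
windows never span gait transitions.

Class imbalance is handled by duplication (`balanceByDuplication`):
training-fold strides of minority classes are upsampled with replacement
to the majority count.  This is applied to training folds only.

## Evaluation protocol

`groupedKFold` partitions *horses* (never strides) into k validation
folds, balancing fold stride counts by greedy longest-processing-time
assignment — fold balancing targets stride counts rather than horse
counts because breeds contribute very different stride totals.  An
optional held-out test fraction (20 % of strides by default in the
full protocol) is carved off before folding; the experiment grids in this
package run plain 5-fold CV over all horses unless a test set is
requested.  Every fold asserts at run time that no horse appears on both
sides of the train/validation boundary.  "Mean accuracy of five runs" is
read as the five CV folds; accuracy is micro-averaged (trace over total),
and the pooled confusion matrix therefore reproduces the stride-weighted
mean of fold accuracies exactly.

## What the tests establish — and what they cannot

The package's quantitative claims are property-based, computed fresh on
synthetic cohorts at documented desk scales:

* event-sweep support statistics match a $10^4$-point dense-grid oracle
  on 1000 randomized timelines;
* ideal-gait closed forms hold exactly (trot: suspension $= 100 - 2d$,
  bipedal $= 2d$; walk at duty 60 %/spacing 25 %: tripedal 40 %, bipedal
  60 %; canonical Hildebrand corners);
* per-gait feature means over $\ge 10^4$ synthetic strides recover the
  generating parameters within 3 standard errors, and mean per-stride
  frequency matches the second-order expansion
  $\frac{1}{\mu}\left(1 + \sigma^2/\mu^2\right)$ within 1 % for every
  gait row;
* on the default 16-horse cohort (25 strides per trial), the accuracy
  ordering all $>$ hildebrand2 $>$ stride-only holds; trocha's largest
  confusion is with trot; excluding trocha raises the best model's
  accuracy; and the sequence model's sensor ordering is all $\ge$
  upper-body $\ge$ single (16-horse signal cohort, 6 strides per trial,
  1 s windows; many short trials rather than few long ones, because
  horse-disjoint folds over few subjects carry more variance than the
  ordering effect being tested).

Because the synthetic generator — not real locomotion — defines these
conditions, the published absolute accuracies obtained on 120 real horses
are *not* reproduction targets: real IMU data have sensor artefacts,
speed and rider effects, transitions and label noise that the generator
deliberately omits (no rigid-body physics, no speed model, no lameness or
asymmetry, no dual-range accelerometer saturation).  What the passing
suite shows is that the statistical machinery — features, projections,
balancing, grouped CV, model training — is correct and that the
qualitative structure of the published findings (which feature sets and
sensor sets carry gait information, and where the confusions lie) emerges
from first-principles gait geometry alone.

## Known limitations

* The stride-detection step of real pipelines (hoof events from raw limb
  accelerometry) is out of scope; the generator emits ground-truth
  events directly.
* QDA may silently drop features on small training folds where a class
  covariance is rank-deficient; the dropped set is recorded in the
  fitted model's scaling slot.
* The LSTM at desk scale (width 32, stride 8, 60 epochs) is tuned for
  CPU minutes, not accuracy ceilings; the full-scale width-500
  architecture is supported but untested here.
* Advanced placements of gaits sitting at the $\pm 50$ wrap (trot) are
  bimodal across strides by construction; linear models see two clusters.
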