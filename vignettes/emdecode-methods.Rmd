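---
title: "Masking EMD decoding of epoched MEG: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Masking EMD decoding of epoched MEG: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`emdecode` analyses epoched multichannel electrophysiology — typically MEG —
with a nonstationary decomposition front end instead of fixed band-pass
filters. The chain is: masking empirical mode decomposition (EMD) of every
trial-and-channel series into intrinsic mode functions (IMFs); Hilbert
spectral characterisation of each IMF; time-resolved two-condition decoding
with cross-validated ROC AUC; group-level cluster-based sign-flip permutation
inference; and, for spatial questions, a simplified L2 minimum-norm inverse
with dSPM noise normalisation. A bundled simulator generates cohorts with the
statistical structure the analysis assumes, so every stage is testable
without access to real recordings.

## Why EMD for brain rhythms

Band-pass filters impose fixed frequency boundaries and ring on transients;
brain signals are nonstationary and their rhythms drift. EMD instead extracts
oscillatory modes adaptively: the *sifting* loop connects local maxima and
minima with natural cubic splines and repeatedly subtracts the envelope mean
until the remainder has (i) nearly equal numbers of extrema and zero
crossings (within one) and (ii) a locally zero-mean envelope. Each such
remainder is one IMF; subtracting it and repeating yields a bank of modes
ordered from fast to slow, plus a monotone-trend residual. On white noise the
bank is approximately dyadic: each successive IMF's dominant frequency is
about half the previous one's. At a 200 Hz sampling rate this places IMF4 in
the theta range, IMF5 in upper delta and IMF6 in lower delta, which is the
band layout the decoding stage exploits.

Plain EMD suffers from *mode mixing*: an intermittent fast oscillation (a
burst) and a continuous slow one can end up sharing an IMF, with the mode
switching scale mid-epoch. Masking EMD mitigates this by adding a known mask
sinusoid before sifting, which keeps the sifting anchored at the mask's time
scale, and cancelling the mask afterwards.

## The masking EMD implementation

For mode `k` (signal at working stage `r`):

1. Mask frequency: dyadic schedule `f_mask(k) = fs / 2^(k+1)` (50, 25, 12.5,
   6.25, 3.125, ... Hz at `fs = 200`). An adaptive schedule (half the
   amplitude-weighted mean instantaneous frequency of the previous mode) is
   selectable; the dyadic default keeps mode numbering comparable across
   signals and participants.
2. Mask amplitude: `2 * SD(r)` — large enough to dominate the extrema
   structure at the mask scale, small enough not to swamp the data.
3. The mask is added at 4 phases (0, pi/2, pi, 3pi/2); each masked signal is
   sifted once (S-number stop, `S = 4`, at most 100 sifting iterations) and
   the four first-IMFs are averaged. The four mask sinusoids sum to zero, so
   the mask cancels in the average.
4. The averaged candidate is passed through one final plain sift. Averaging
   leaves micro-ripples — a handful of tiny extrema without zero crossings —
   that violate the IMF count property; the polishing sift removes them
   exactly. Without it roughly a quarter of masked modes fail the property.
5. The mode is subtracted and the procedure recurses; after 7 oscillatory
   modes (default `n_imfs = 8`) the remainder is stored as the residual
   trend, the conventional "IMF 8", which is dropped before analysis.

Completeness — input equals the sum of IMFs plus residual — holds to machine
precision by construction, because every extracted mode is subtracted from
the working signal.

Numerical details worth knowing:

* Envelope splines are natural cubic splines through the extrema, extended
  beyond each epoch edge by mirroring the two outermost extrema across the
  boundary. Epoch edges are still the least trustworthy part of any EMD
  output; the Hilbert stage therefore trims 5% of samples at each end.
* The S-number stopping rule can cycle (extrema/zero-crossing counts
  oscillating between two states). When the iteration budget is exhausted
  the sift returns the most recent iterate that satisfied the count
  property rather than the last iterate.
* Signals with fewer than two maxima or two minima are flagged monotone and
  become (part of) the residual.

## Hilbert spectra

The analytic signal is built in the frequency domain (negative frequencies
zeroed, positive doubled); the real part is the input restored exactly.
Instantaneous amplitude is the modulus; instantaneous frequency is the
central difference of the unwrapped phase. Negative instantaneous
frequencies — spline-overshoot artifacts — are excluded and counted. The
*marginal spectrum* accumulates amplitude-squared into 0.25 Hz frequency
bins over all trials and channels of one IMF; bin centres sit on integer
multiples of the bin width so canonical rhythm frequencies (1, 3, 7 Hz) fall
at a centre rather than on an edge. The *dominant frequency* of an IMF is
the centre of its maximum-energy bin, ties broken toward the lower
frequency. Energy is conserved within the retained samples: bin totals sum
to the accumulated amplitude-squared.

When spectra are pooled across participants the package computes the peak of
the pooled (mean) spectrum rather than the mean of per-participant peaks;
the pooled spectrum is less sensitive to individually noisy peak picks.

## Decoding

For each timepoint the feature vector is every channel's value at that
timepoint (a single time frame, no temporal window). Trials are shuffled
once into 30 stratified subsets (seeded); each subset serves once as test
set for an L2-regularised logistic regression trained on the other 29, with
feature standardisation fitted on the training folds only. The penalty is
fixed (inverse regularisation strength 1, i.e. ridge `lambda = 1/n_train`);
no tuning is performed, since per-timepoint model selection would leak
information across folds and timepoints. The reported score is the mean over
folds of the held-out ROC AUC (probability that a random trial of one
condition outranks a random trial of the other; 0.5 is chance). Pooling
held-out scores into a single AUC is available as an option; fold-averaging
is the default because per-fold test sets are small and a single score per
timepoint is wanted.

## Group inference

Per participant and timepoint the effect is AUC minus 0.5. The group t
series (one-sample t against zero) is thresholded at `t = 2`; maximal
contiguous supra-threshold runs form clusters scored by their summed t
(cluster mass). The null distribution of the maximal mass is built by
flipping the sign of each participant's entire series independently — the
exchangeability that a one-sample design affords — 1000 times, and each
cluster's p-value is `(1 + #(null >= mass)) / (n_perm + 1)`, so the smallest
attainable p is 1/1001, and no cluster ever gets p = 0. The test is
one-tailed by default (above-chance decoding); the two-tailed variant forms
negative clusters symmetrically and compares absolute masses. Temporal
adjacency only: clusters are runs along the decoding time axis, not across
sensors. Bonferroni correction over timepoints is provided for the
parametric companion analysis.

Calibration is checked empirically: over 200 null cohorts of 16 simulated
chance-level AUC series, the fraction with any significant cluster must stay
within the binomial band around the nominal 0.05 (between 0.02 and 0.09 at
n = 200).

## Source estimation

The inverse stage implements the textbook L2 minimum norm with identity
source covariance: `M = G'(G G' + lambda2 C)^-1`, fixed orientation, no
depth weighting, `lambda2 = 1/9` (the SNR = 3 convention). `C` is a
shrinkage-regularised empirical noise covariance from noise segments
(empty-room style recordings; the simulator provides source-free trials for
this purpose). dSPM divides each source estimate by its noise sensitivity
`sqrt(diag(M C M'))`, so pure covariance-matched noise maps to unit-variance
source traces — a property the test suite verifies directly. Single-trial
dSPM time courses, reduced over regions of interest (mean or
absolute-value mean), feed back into the decoder unchanged.

Real anatomical modelling — cortical surfaces, boundary-element forward
models, subject-to-template morphing — is out of scope; the module accepts
an externally computed gain matrix and channel list for real-data use, and
otherwise uses the package's toy lead field: sensors on a quasi-uniform
upper-hemisphere helmet, each cortical patch projecting a smooth
distance-decaying gain pattern.

## The simulator and the benchmark replica

The simulator's defaults are the package's study conditions, fixed once:

* 200 Hz sampling, epochs from -100 to 1000 ms (221 samples), 16
  participants, 60 trials per condition.
* Three evoked sources: 3 Hz at the left and right supramarginal patches and
  7 Hz at the right inferior frontal patch. All patch positions are
  normalised to a common depth, matching the no-depth-weighting inverse.
* Envelope: raised-cosine burst, onset 80 ms, 50 ms rise and fall, ending at
  500 ms, so the evoked peak lands near 100-140 ms. The evoked component is
  phase-locked at envelope onset (per-trial random phase is available for
  induced-activity simulations).
* Noise: 1/f background generated at 20 random nuisance patches and
  projected through the lead field — so the noise covariance is spatially
  structured, as dSPM assumes — plus white sensor noise. Source amplitudes
  are calibrated to a single-trial evoked-to-noise RMS ratio of 0.5 at the
  most strongly driven sensor.
* Inter-participant variability: lognormal amplitude multipliers (log-SD
  0.2). All randomness flows from explicit seeds; identical spec and seed
  give identical data.
* The replica driver decomposes each participant's trial-averaged evoked
  signals (30 sensors by default). Averaging first is what an evoked
  analysis warrants and keeps the benchmark inside a desk-scale compute
  budget; per-trial decomposition is used by the decoding path, where the
  single-trial structure is the point.

The replica (`run_simulation_replica()`) verifies three things: the IMF
with maximal energy at the sensors dominated by each source group recovers
the generating frequency (3 and 7 Hz within half a hertz) as its dominant
Hilbert frequency; the theta source's energy sits in a lower-index IMF than
the delta sources'; and dSPM localises each source to its patch among 23
candidate patches that include the nuisance background generators.

One localisation subtlety is worth recording. The 3 Hz burst lasts about 1.3
cycles, so it is spectrally broad; its upper sidebands leak into the
theta-carrying IMF with sensor amplitudes comparable to the theta source
itself. A plain spatial maximum on that IMF therefore reflects the
(stronger) supramarginal pair, not a failure of the inverse. The replica
instead scores each candidate patch by its narrowband dSPM power at the
dominant frequencies the Hilbert stage itself measured — a
frequency-indexed localisation that uses no ground-truth values and is
stable across seeds with a several-fold margin.

What the simulator does *not* emulate: realistic head geometry and field
physics, artifacts (blinks, cardiac, movement), non-stationary background
rhythms (alpha bursts), or inter-participant latency variability. Passing
tests therefore demonstrate that the algorithms do what they claim under the
assumed signal model, not that any particular real dataset will yield the
same IMF partition; on real recordings the mask schedule and rejection
thresholds deserve inspection before trusting mode numbering.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `n_imfs` | 8 | modes | 7 oscillatory modes + residual trend covers 0.8-50 Hz at `fs = 200` |
| mask schedule | dyadic | Hz | reproducible mode numbering; adaptive variant available |
| mask amplitude | 2 x SD | a.u. | anchors sifting without swamping data |
| mask phases | 4 | — | exact mask cancellation; diminishing returns beyond |
| sift stop | S = 4, max 100 | iterations | standard S-number rule |
| spectrum bins | 0.25 | Hz | finer than any band boundary used |
| edge trim | 5% | of samples | EMD epoch-edge distortion |
| `n_folds` | 30 | subsets | small held-out sets, averaged fold AUCs |
| ridge penalty | 1/n | — | fixed inverse-strength-1 convention, no tuning |
| `t_thresh` | 2 | t units | cluster-forming threshold |
| `n_perm` | 1000 | permutations | p floor 1/1001 |
| `alpha` | 0.05 | — | one-tailed |
| `lambda2` | 1/9 | — | SNR = 3 minimum-norm convention |

## Interfaces and formats

Epochs travel as a documented on-disk layout written by `write_epochs()`:
an RDS payload with a JSON metadata sidecar (sampling rate, epoch origin,
labels, channels). Spectra and cluster tables export as TSV with JSON
parameter sidecars. Real recordings in vendor formats should be epoched and
exported with the user's acquisition toolchain, then ingested through this
layout; the pipeline itself is format-agnostic from that point on. All
result objects are tibble-backed with `tidy()`, `glance()` and `autoplot()`
methods, and `run_decoding_study()` stamps every output with the
configuration hash and stage seeds for provenance.

## Known limitations

* EMD mode numbering is sampling-rate dependent; comparing IMF indices
  across datasets requires a common `fs` (hence the resampling stage).
* Epoch edges remain distorted after decomposition; all spectral statistics
  trim them, but time-domain cluster boundaries within ~25 ms of an epoch
  edge should be read with caution.
* The toy lead field supports algorithm validation, not anatomical claims.
* The decoder is binary; three-condition designs are handled as the three
  pairwise problems.
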