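---
title: "From raw sEMG to gesture labels: the models and choices behind emgsign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw sEMG to gesture labels: the models and choices behind emgsign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgsign)
```

## The problem

Sign-language gestures produce coordinated bursts of muscle activity that a
ring of surface-EMG electrodes on the forearm picks up as a multichannel,
non-stationary, noise-like signal. Turning a continuous multichannel
recording into a gesture label requires four stages, each of which this
package implements and tests separately:

1. **Denoising** — bandpass to the 20–450 Hz band where surface-EMG power
   lives, notch at the 50 Hz mains frequency.
2. **Active-segment detection** — find when a gesture is actually being
   performed by thresholding short-term energy and variance of the
   channel-mean signal, then cut the multichannel slices and
   length-normalize them.
3. **Time–frequency transformation** — sliding-window DFT per channel,
   turning each segment into a channels × frames × bins tensor.
4. **Classification** — a parallel 1-D convolutional network whose
   Inception-style branches, residual shortcuts, and dilated convolutions
   are designed to enlarge the receptive field without adding parameters.

## Signal model and preprocessing

The bandpass is a Butterworth design (order 4 per edge, applied
forward–backward through `signal::filtfilt`, hence zero phase and order 8
in effect). Zero phase matters because segment boundaries feed the
classifier: a causal filter would delay onsets by a frequency-dependent
lag. Channels are demeaned before filtering; the DC response of the
designed filter is essentially zero anyway, and demeaning keeps a large
baseline offset from leaking a start-up transient into the first samples.
The notch is a constrained second-order IIR biquad (zeros on the unit
circle at ±50 Hz, poles pulled in to give a 2 Hz 3-dB bandwidth, i.e.
Q = 25). No installed package provides a notch designer, so the package
computes those five coefficients itself and applies them through the same
zero-phase machinery. `filter_response()` exposes the analytic magnitude
response of both designs, and the test-suite compares measured sinusoid
gains against it.

## Active-segment detection

Detection operates on the channel-mean signal only (the average of all
channels), framed into windows of 100 ms. Each frame is summarized by its
short-term energy `E = mean(x^2)` and population variance
`Var = mean((x - mean(x))^2)` — the divide-by-length convention, so both
statistics are exact means and a constant frame has variance zero. A frame
is *active* when both statistics exceed their thresholds (the conjunction
is configurable to a disjunction); a maximal run of active frames becomes
one segment, runs shorter than two frames are discarded as blips, and when
the expected number of repetitions is known, surplus runs are dropped
lowest-total-energy-first.

Two defaults deserve justification:

* **Non-overlapping detection frames** (`hop = frame_len`). Segment
  boundaries are defined as the first/last sample of the first/last active
  frame. With overlapping frames, the first frame to overlap an onset by
  even one sample can trip the threshold, so the reported start can precede
  the true onset by almost a full frame — about two hops at 50% overlap.
  With non-overlapping frames that slack is exactly one hop, making the
  "boundary error of at most one hop" recovery property structural rather
  than statistical.
* **Threshold calibration on 40 rest frames.** Thresholds default to
  `mean + 3·sd` of each statistic over the leading rest frames. A 3-sigma
  rule is only as good as its sd estimate: with 10 calibration frames the
  estimate's own standard error (~24%) produces roughly a 1% per-frame
  false-positive rate, and a false positive adjacent to a genuine run
  extends its boundary past one hop. The recording protocol guarantees 4 s
  of lead-in rest — 40 frames — and calibrating on all of it stabilizes the
  rule; `generate_dataset()` derives the calibration window from the
  protocol's rest duration automatically.

Detected segments are mapped back to all channels verbatim and
length-normalized by per-channel piecewise-linear interpolation onto the
maximal detected segment length (a fixed target length can be supplied
instead, e.g. 2664 samples to mirror a 1000 Hz protocol whose longest
repetition lasts 2.664 s).

## Time–frequency features

Each channel of a segment is framed (default 50 ms frames, 40% overlap, so
the hop is 60% of the frame), each frame is transformed by the DFT
(`stats::fft`; the test-suite verifies it against a direct cosine/sine
summation on all lengths up to 64, plus Hermitian symmetry and Parseval's
identity), and the one-sided bins 0..⌊N/2⌋ are kept — for real signals the
other half is redundant. Four components are available — real, imaginary,
magnitude, and phase (two-argument arctangent, with the phase of an exactly
zero bin defined as 0) — of which **magnitude** is the default classifier
input; `stacked` concatenates all four as extra channel groups. Frames are
rectangular by default (plain framing, no taper), with a Hann option. The
flattening into the channels × (frames·bins) network input keeps frames in
temporal order and bins in ascending frequency, and is exactly invertible
(`unflatten_model_input()`).

The frame length is a genuine trade-off — shorter frames give finer
temporal resolution but coarser frequency bins — which is why the
experiment harness sweeps 20/50/100 ms rather than fixing one.

## The classifier

The network is built from a configuration object and instantiated in
compiled code (RcppArmadillo; forward pass, backpropagation, and Adam are
implemented in `src/nn.cpp`, with convolutions evaluated as im2col + BLAS
matrix products):

* **STEM**: conv(32 filters, kernel 7, stride 2) → Leaky ReLU →
  max-pool(2,2) → conv(32, kernel 3) → Leaky ReLU → max-pool(2,2). An
  eight-fold dimensionality reduction that extracts low-level features
  before the expensive parallel blocks.
* **Inception-ResNet A** (×2 by default): three parallel dilated
  convolutions with kernels 8, 12, and 24 (dilation 5), 16 filters each,
  Leaky ReLU, merged by **element-wise summation**; Branch 4 is the
  residual shortcut (identity when the channel counts match, otherwise a
  1×1 projection) added onto the merge, followed by a final activation.
* **Inception-ResNet B** (×1 by default): the same three-branch pattern
  with 64 filters and dilation 3, each branch followed by a kernel-3
  convolution with 16 filters that reduces dimensionality before the merge.
* **Head**: dropout (rate 0.8, interpreted literally as the probability of
  dropping a unit; a flag flips it to keep-probability), flatten, dense to
  the class count, softmax.

All activations are Leaky ReLU with negative slope 0.3 (a common framework
default; the slope is configurable). Branch summation rather than
concatenation is the deliberate merge choice, which requires equal filter
counts across branches and makes the A-block width 16 so residual sums
type-check; concatenation remains available as a configuration option.
Weights are initialized from a seeded uniform fan-in scheme
(`U(±sqrt(1/fan_in))`), biases at zero.

The four **ablation variants** differ only in two switches: `baseline`
(no shortcuts, all dilations forced to 1), `residual_only`, `dilation_only`,
and `full`. Because dilation spaces kernel taps without adding any,
`residual_only` and `full` have identical parameter counts — a property the
test-suite checks by comparing the closed-form count
`filters·(kernel·in_channels + 1)` per convolution against the
instantiated models' parameter vectors.

**Receptive fields** are computed geometrically: a kernel `k` with dilation
`d` spans `k + (k−1)(d−1)` inputs, and stacking composes through
`RF ← RF + (k_eff − 1)·jump`, `jump ← jump·stride`. An independent oracle
traces the exact index-dependency set of a central output element through
the stack and must agree on randomized stacks; `rf_table()` reports both
the nominal kernel and the dilated effective kernel per layer, because the
two diverge exactly where dilation is active.

### Training

Adam (learning rate 1e-3), batch size 32, categorical cross-entropy,
30 epochs by default — deliberately modest settings chosen once as
conventional defaults. Inputs are standardized by a single mean and
standard deviation computed on the training split only; a single global
pair (rather than per-feature scaling) preserves the relative
channel-activation pattern, which is the main class-discriminative signal.
Every random element — weight draws, shuffling, dropout masks — flows from
explicit integer seeds, and the C++ engine is single-threaded and
deterministic, so a configuration replays bit-identically. The gradient
implementation is verified against central finite differences at a
configuration where every kernel fits inside its feature map (at zero bias
with fully-padded positions, the Leaky ReLU sits exactly at its kink, where
a subgradient and a finite difference legitimately disagree).

## What the synthetic generator emulates — and what it does not

The generator reproduces the *protocol structure* of a 10-subject,
10-gesture, 5-repetition, 7-channel, 1000 Hz acquisition: repetitions of
2–2.664 s separated by 4 s of rest, assembled into 10×10 = 100 basic
structures and 100·5·7 = 3500 per-channel samples. Each gesture class is a
template of relative channel gains — emulating which muscles a hand shape
recruits — with either a single plateau envelope ("static" gestures) or
two-to-three phases with phase-specific gains ("dynamic" gestures composed
of sub-movements, the way a compound sign strings together simpler ones).
Subjects share templates up to multiplicative lognormal gain jitter
(σ = 0.1), emulating inter-subject variation in muscle activation.

The signal model is amplitude-modulated band-limited Gaussian noise:
unit-variance white baseline noise everywhere, plus a 20–450 Hz filtered
Gaussian carrier scaled by `10^(snr_db/20)` (default 20 dB) times the
envelope during active windows. Envelopes rise and fall with raised-cosine
ramps of 100 ms — within physiological force-onset times, and deliberately
no longer than one detection frame so that the sub-threshold tail of a
ramp cannot push a detected boundary more than one hop from the annotated
edge. `spectral_validity_check()` confirms that at least 90% of
active-window power lies in the EMG band while rest windows sit near the
flat-spectrum reference (430/500 of Nyquist at 1000 Hz).

This surrogate captures exactly the statistics the pipeline relies on —
band-limited power bursts with class-specific channel patterns and
envelope shapes — and nothing more. It does **not** model motor-unit
action potentials, electrode geometry, signal propagation, fatigue,
electrode shift, or realistic inter-class confusability (real gestures
overlap in channel space far more than independent random gain vectors
do). Passing tests therefore certify that the pipeline's machinery is
correct and that the network can learn a separable multichannel pattern;
they say nothing about accuracy on real recordings, and the headline
accuracies of real-data studies are out of scope here.

## Problem sizes and numerical choices

The test-suite and the acceptance script run everything at the scale the
defaults describe: the full 100-recording default dataset (500 classifier
instances) for the dataset-arithmetic and learnability checks, 100 seeded
single-gesture recordings at 15 dB SNR for segment recovery, and a reduced
3-subject protocol with 2-epoch trainings for the ablation/frame-sweep
determinism checks — sizes chosen so each property is exercised end-to-end
by an ordinary desktop R session. Numerical tie-breaks worth recording:
max-pooling keeps the first maximum; the one-sided spectrum keeps bin 0 and
the Nyquist bin; stratified splits use largest-remainder rounding (ties
broken by class order) so per-class counts always sum to the global
fraction; undefined precision/recall (empty predicted or true class) is
reported as 0 and the class flagged.

## Known limitations

* The network trains on CPU via BLAS-backed convolutions; it is sized for
  hundreds of instances, not for large real corpora.
* Detection assumes the recording begins at rest (threshold calibration)
  and that rests are long relative to the detection frame.
* The generator's class structure is optimistic about separability, as
  discussed above.
* Recordings are processed whole in memory; no streaming.
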