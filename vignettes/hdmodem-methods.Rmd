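---
title: "Integer hyperdimensional modulation and near-channel classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integer hyperdimensional modulation and near-channel classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdmodem)
```

## The representation

Everything in this package is built from very long random vectors
(dimension $D$ in the hundreds to tens of thousands) manipulated with the
multiply--add--permute algebra: element-wise multiplication (*binding*),
element-wise addition (*bundling* / superposition), and random reordering of
coordinates (*permutation*, realized where possible as hardware-friendly
cyclic shifts $\rho$). Atomic vectors are bipolar, $e_i \in \{-1,+1\}^D$,
drawn once per seed into a fixed dictionary (*item memory*, IM). At large
$D$ any two dictionary entries are quasi-orthogonal: their cosine similarity

$$c = \frac{\langle x, y\rangle}{\lVert x\rVert_2\,\lVert y\rVert_2}$$

concentrates around zero with standard deviation $1/\sqrt{D}$. Superposing
$V$ bipolar vectors gives an integer vector whose elements lie on the grid
$\{-V, -V+2, \dots, V\}$; each addend remains individually retrievable by an
associative-memory (AM) search as long as $V$ is small relative to the
available quasi-orthogonal "room" in $D$ dimensions.

Two dictionary flavors are provided:

* `item_memory()` — independent quasi-orthogonal entries. By default each
  entry is *exactly* balanced (a shuffled half-and-half template of signs),
  which pins every column sum to zero; `balanced = FALSE` gives plain
  i.i.d. Rademacher draws. Exact balance is the default because the encoder
  literature describes equal counts of each sign; the two options are
  statistically indistinguishable for every experiment in this package.
* `continuous_item_memory()` — a *level* dictionary for scalar values:
  level 1 is a random bipolar seed vector, and each successive level flips a
  growing, nested set of randomly chosen positions until exactly $D/2$
  positions are flipped at the top level. Nesting the flip sets makes
  $\cos(\text{level }1, \text{level }l)$ decrease *exactly* linearly from 1
  to 0, so the dictionary preserves scalar distance and the extreme levels
  are orthogonal. We fix the cumulative flip count at level $l$ to
  $\mathrm{round}\!\big((l-1)/(L-1)\cdot D/2\big)$: incrementing by the
  naive $D/(2L)$ per level would only reach $(L-1)D/(2L) \ne D/2$ flips, so
  the endpoint condition (orthogonal extremes) is taken as the defining
  constraint. $D$ must be even for the top level to be exactly orthogonal.

All random components (dictionaries, permutation sets, tie-breakers, channel
noise, synthetic data) draw from independent streams derived from one master
seed (`derive_seed()`), so any single component can be regenerated without
perturbing the others.

### Numerical conventions

* **Rotation**: `hv_rotate(x, r)[i] = x[(i - r) mod D]` (a right cyclic
  shift); `hv_rotate(x, -r)` is its exact inverse. Any consistent convention
  works; this one is fixed for reproducibility.
* **Bipolarization**: `hv_bipolarize()` maps signs element-wise; exact zeros
  (possible only for even superpositions) take the sign of a deterministic
  tie-breaker vector generated once per configuration, so repeated runs are
  bit-identical.
* **Argmax ties**: every search (codec AM search, symbol retrieval, level
  retrieval, classification) breaks ties toward the lexicographically
  smallest index, making all decoders deterministic functions of their
  inputs.

## The integer-HDM channel code

A binary string of length $k = V(\log_2 N + \log_2 D + 1)$ is split into $V$
blocks. Each block maps to three indexes — dictionary index
$q \in [0, N-1]$, rotation $r \in [0, D-1]$, sign $s \in \{-1,+1\}$ — read
MSB-first from the slices (q | r | s). The block is materialized as
$s\cdot\rho^{r}(e_q)$, permuted with a block-specific random permutation
$\Pi_v$, and all blocks are superposed:

$$x = \sum_{v=1}^{V} \Pi_v\!\big(s_v\,\rho^{r_v}(e_{q_v})\big), \qquad
  r = \frac{k}{D} = \frac{V(\log_2 N + \log_2 D + 1)}{D}.$$

The rotation stage is what makes the code memory-efficient: it virtually
inflates the dictionary by a factor $D$ without storing anything, so small
devices can reach useful throughputs ($r \approx 0.26$ at
$V{=}7, N{=}D{=}512$) with a 512-entry table.

### Decoding

The decoder estimates all $V$ blocks per iteration. Block $v$ is estimated
from the cleaned query $y - \sum_{j\ne v}\tilde x_j$, where $\tilde x_j$ is
block $j$'s re-encoded estimate from the *previous* iteration (all zero at
the start). The estimation computes
$\hat c_v[q,r] = \tfrac1D\langle\rho^{-r}(\Pi_v^{-1}(\hat y_v)), e_q\rangle$
over all $N \cdot D$ pairs, and picks the pair maximizing $|\hat c_v|$; the
sign estimate is the sign of the winning inner product, and $|\hat c_v|$ at
the winner is the block's *confidence*. Decoding stops when no index changed
between consecutive iterations or at `max_iterations` (default 10 — the
decoder converges in 2–3 iterations in its operating regime, and a single
block needs exactly one pass).

Feedback comes in three strengths:

* `none` — one estimation pass, no interference cancellation;
* `unit` — estimates subtracted at full scale;
* `soft` — each estimate scaled by $\min(|\hat c_v|, 1)$, which damps the
  oscillations unit feedback can show when early estimates are wrong. The
  clip at 1 matters: confidences can exceed one in noise, and amplifying
  feedback would destabilize the loop rather than damp it.

Two quantized decoder variants are provided: `quantize_readout()` maps query
elements to the nearest noise-free superposition value in
$\{-V', \dots, V'\}$ (at $V'=1$ the AM search degenerates to a Hamming
comparison), and `decoder_config(fixed_point = c(m, q))` runs the whole
decoder on a fixed-point grid with $m$ integer and $q$ fractional bits.
At $q = 1$ the soft-feedback scale collapses to $\{0, 0.5, 1\}$ — ignore,
halve, or trust each estimate — which is empirically sufficient.

The AM search is implemented as circular cross-correlation in the frequency
domain (a compiled kernel; two real queries share one complex transform),
which is algebraically identical to the literal $N \times D$ scan; the test
suite asserts index-level equivalence against an independent brute-force
double loop, and `am_search(method = "direct")` keeps the literal scan
available.

### Channel model

`awgn()` adds i.i.d. Gaussian noise with per-dimension variance
$P/\mathrm{SNR}$, where the signal power $P$ is $V$ for an integer
superposition of $V$ bipolar vectors and 1 for a bipolar vector;
$E_b/N_0 = \mathrm{SNR}/(2r)$. `add_interference()` superposes $J$
equal-power, symbol-synchronous bipolar vectors from independent nodes —
worst-case alignment, no fading, since relative powers and timing are not
otherwise constrained. Interferers default to fresh Rademacher vectors,
which are statistically indistinguishable from an unrelated node's encoded
bipolar output; an `encoder` hook lets an experiment produce them through a
full encoding pipeline instead.

## Learned MMSE readout and operational capacity

For plain symbol superpositions (no sign/rotation encoding),
$x = \sum_v \Pi_v(e_{q_v})$, a learned alternative to the AM readout fits
one matrix $F_v$ per position by minimizing the squared error between the
one-hot symbol vector and $F_v^\top x$ over training pairs. Training sees
only $(x, c_v)$ pairs — neither the dictionary nor the permutations — so the
readout can be learned purely from examples. The objective is convex; the
default solver is ridge-stabilized normal equations (the ridge,
$10^{-8}\times$ the mean Gram diagonal, only handles the rank-deficient case
$NV < D$), with full-batch gradient descent available and verified to give
the same accuracy. The default training-set size is $R = 20 D$ samples.

Feedback decoding with either readout re-encodes the current estimates
through the true dictionary and permutations and subtracts them — this
*does* require the dictionary, a documented departure from the
dictionary-free readout-only mode, because interference cancellation has to
reconstruct what to subtract.

Retrieval quality converts to an **operational capacity** in bits/dimension:

$$\mathrm{Capacity}(p_c) = \frac{V}{D}\Big\{p_c\log_2(p_c N) +
  (1-p_c)\log_2\big(\tfrac{N}{N-1}(1-p_c)\big)\Big\},$$

which vanishes algebraically at chance level $p_c = 1/N$ and equals
$(V/D)\log_2 N$ at $p_c = 1$. `p_c` is estimated as the fraction of
correctly retrieved positions pooled over trials.

A note on the measured corner points at $D=500$, $N=5$: the trained MMSE
readout holds 100% retrieval to $V \approx 140$, and with unit feedback its
peak capacity reaches $\approx 1.2$ bits/dimension near $V \approx 258$. The
plain AM readout on integer superpositions holds 100% retrieval to
$V \approx 15$–17 under these exact equations; bipolarizing the
superposition before readout (a common practice this package also supports
via `hv_bipolarize()`) lowers that corner to $\approx 12$. Both variants are
measurable with the exported functions; the shipped experiments use the
integer superpositions that the retrieval equations define.

## The EMG near-channel pipeline

The case study couples the codec machinery to 64-channel surface-EMG gesture
recognition. One **spatial encoder** serves two modes:

1. raw EMG at 1 kS/s passes a 60 Hz notch (biquad, $Q=50$), an 8th-order
   Butterworth band-pass (1–200 Hz), rectification, a 100-tap moving
   average, and 100× decimation to 10 frames/s; frames are normalized by
   per-channel 95% training-set quantiles so features lie in $[0,1]$ with
   high probability (the ~5% overshoot is clamped at quantization);
2. features are quantized to $L = 128$ uniform levels
   ($\mathrm{level} = \mathrm{clamp}(\lfloor f L\rfloor + 1, 1, L)$),
   embedded through the continuous item memory, rotated cyclically by the
   0-based channel index, and superposed:
   $x^t = \sum_{\mathrm{ch}} \rho^{\mathrm{ch}}(\mathrm{cim}[l_{\mathrm{ch}}])$.

In **classification mode**, five consecutive bipolarized spatial vectors are
bound into a 5-gram (newest frame unpermuted, older frames under distinct
fixed random permutations — only "random permutations and binding" is
prescribed for the n-gram, so the minimal assignment is used), transmitted
as a bipolar vector, and classified at the receiver against per-class
prototypes (sum then bipolarize). One decision is emitted per frame (every
100 ms); n-grams never span trial boundaries, so the first $n-1$ frames of
each trial produce no decision. The encoding throughput is
$r = 64\cdot7\cdot5/D$ — e.g. 4.375 at $D=512$ (compression) and 1.094 at
$D=2048$ (no redundancy).

In **transmission mode**, the integer spatial vector $x^t$ itself is sent
and the receiver reconstructs the quantized features with the same iterative
feedback decoder, using the CiM as dictionary and channel rotations in place
of block permutations; there is no rotation or sign search. Estimated levels
map back to bin centers $(\hat l - 0.5)/L$, so a noise-free reconstruction
is exact to quantizer resolution ($\le 1/L$ per channel), and a
nearest-neighbor level error costs only $1/L$ — the distance-preserving CiM
makes decoding errors graceful rather than catastrophic. Because adjacent
levels are nearly collinear, the feedback iterations (not dimensionality
alone) are what make exact recovery possible: with 64 channels superposed,
cross-channel interference exceeds the cosine gap between neighboring
levels until it is cancelled.

## The synthetic data generator

The generator stands in for real recordings so every pipeline stage is
testable offline. It emulates: 5 classes (4 gestures + rest), 64 channels on
a 16×4 grid, 3 s trials at 10 frames/s, 10 trials/class, interleaved. Each
active class has a smooth random spatial template (a Gaussian random field
smoothed over grid distance, so neighboring electrodes co-activate as they
do for surface EMG), modulated per trial by an onset–hold–offset envelope
with 0.5 s ramps; rest sits at a 0.02 baseline. Additive Gaussian noise is
clipped to $[0,1]$. `generate_raw()` additionally synthesizes 1 kS/s raw
signals (band-limited 20–150 Hz carriers amplitude-modulated by the feature
envelope, plus a 60 Hz mains line) for exercising the preprocessing chain.

Two knobs matter. `noise_sd` (default 0.05) adds frame-level noise, but the
encoder averages such noise out almost completely, so it barely moves
accuracy. `separability` (default 0.2) blends class templates with a shared
background pattern and is the effective difficulty control: at the default,
noise-free accuracy at $D = 10{,}000$ sits in the mid-90s (%), comparable to
real forearm recordings, so robustness trends (SNR, interference,
dimensionality) are visible rather than saturated. Both defaults were fixed
once, against the pipeline, and are not tuned per experiment.

What the generator does *not* emulate: subject and session variability,
electrode shift, correlated physiological artifacts, or realistic motor-unit
statistics. Passing tests on synthetic data therefore demonstrate the
*representational* claims (noise and interference robustness, reconstruction
quality, mode equivalence) — not subject-level accuracy on real recordings,
which requires the public dataset the case study used.

## Experiment harnesses and problem sizes

`run_ber_sweep()`, `run_retrieval_sweep()`, `run_ncc_grid()` and
`run_reconstruction_grid()` return one self-describing record per grid cell
(full parameter set + seed), so any row can be re-run bit-identically.
Proportions carry 95% Wilson half-widths.

Default problem sizes are desk-scale by design: BER points default to
$10^3$–$10^4$ blocks, retrieval points to 200 trials, capacity scans to
~100 trials/point, and the shipped analyses use 2000 codewords for the
iteration-count statistic. Publication-grade waterfall curves (e.g.
resolving a 0.2 dB gap at BER $10^{-4}$ on a 0.1 dB grid) need $10^6$+
information bits per SNR point and are left to overnight runs with larger
`n_blocks`; the suite instead checks the desk-scale surrogate (soft-feedback
block accuracy $\ge$ unit-feedback at 0 dB). Retrieval corners are located
by bisection over $V$ (valid because accuracy is monotone in $V$ up to
Monte-Carlo jitter), which keeps the corner search at unit resolution
without sweeping all 300 values.

## Known limitations

* The corner-point discrepancy discussed above: the plain-integer AM corner
  (~15–17) differs from bipolarized readout (~12); both are supported, the
  integer protocol is shipped as the default experiment.
* Reconstruction at heavy compression ($r \gg 1$, e.g. $D = 512$ for 64
  channels) cannot recover exact levels even noise-free; the decoder
  degrades gracefully but the quantizer-resolution bound only applies when
  $D$ gives the 64 superposed levels enough quasi-orthogonal room
  ($D \gtrsim 2048$ in practice).
* The MMSE readout stores $V$ dense $D \times N$ matrices; memory grows
  linearly in $V$, which is the price of the dictionary-free readout.
* Complex-valued encodings, CRC-aided list decoding, fading channels, and
  online prototype updates are out of scope.
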