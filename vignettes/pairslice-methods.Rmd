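---
title: "Neuron-pair structural learning and time-sliced decoding: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neuron-pair structural learning and time-sliced decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pairslice)
```

This vignette documents the science inside `pairslice`: the neuron and
plasticity models, the structural-learning algorithm, the time-sliced
decoder, every tunable that matters, and the choices we made where the
design space was genuinely open. Nothing here asserts an empirical result
that the package's tests and `scripts/acceptance.R` do not themselves
compute.

## The problem

A shallow spiking network observes 28×28 grayscale images encoded as
single-spike latencies and has to (a) grow class-specific structure from
co-firing statistics alone — unsupervised except for grouping presentations
by class — and (b) expose what it has learned in an interpretable,
set-valued form ("expressions") that a simple set distance can classify.
Both halves exploit spike *timing*: the encoder writes stimulus intensity
into time, the structural learner reads temporal order, and the decoder
reads time-resolved population membership.

## Encoding: from pixels to first spikes

Images are filtered with four fixed 5×5 zero-DC kernels (horizontal, 45°,
vertical, 135°), rectified, 2×2 max-pooled (28 → 24 by valid convolution,
then 24 → 12), and each 12×12 block is rescaled by its own maximum into
[0, 1]. Design notes:

* **Kernels are fixed, not learned**, for reproducibility. They are
  integer-valued ridge detectors — weight +4 on the ridge, +2 one pixel
  off, negative surround — sized for the 2–3 px strokes of handwritten
  digits and of the built-in glyph generator. Integer weights make the
  zero-DC property exact in floating point: a constant image produces
  exactly zero response, and a 1-px line at the orthogonal orientation is
  cancelled exactly.
* **Per-block normalization** (not global) lets each orientation channel
  use the full latency range; an all-zero block stays zero rather than
  dividing 0/0.
* The latency map is `T(v) = T_start + (2·0.5^v − 1)(T_stop − T_start)` for
  `v ≥ v_min`, silent otherwise. The exponential-of-value form keeps the
  rank-order-coding property (strictly earlier spikes for stronger
  features) while mapping `v ∈ [0, 1]` exactly onto
  `[T_start, T_stop]`; the un-rescaled variant `(0.5^v − 1)(T_stop −
  T_start) + T_start`, which places all spikes at or before `T_start`, is
  available behind `compat_raw = TRUE` for inspection only.
* `v_min = 0.05` (sub-threshold features emit no spike) keeps silent
  background pixels silent; encoding window 0–100 ms; neuron ids are
  block-major, `id = block·144 + row·12 + col`.

## Neuron and synapse model

Neurons are leaky integrate-and-fire with alpha-shaped post-synaptic
currents:

* membrane: `dV/dt = −(V − E_L)/τ_m + (I_syn + I_DC)/C_m`, threshold
  `V_th`, reset `V_reset`, absolute refractory clamp `t_ref`;
* synapse: each arriving spike of weight `w` (pA) injects an alpha current
  peaking at `w` after `τ_syn`.

Defaults: `C_m = 250 pF`, `τ_m = 10 ms`, `E_L = V_reset = −70 mV`,
`V_th = −55 mV`, `τ_syn = 2 ms`, `t_ref = 1 ms`, synaptic delay 1 ms,
`dt = 0.1 ms`. These are the de-facto standard alpha-current LIF defaults;
they fix the rheobase at `C_m(V_th − E_L)/τ_m = 375 pA`, so the smallest
spiking current on a 1 pA grid is **376 pA** (`rheobase()` recomputes this
by simulation, and the acceptance script reports it).

The simulator is clock-driven with the *exact* exponential propagator of
the linear subsystem per step, so integration error comes only from
threshold detection on the grid: halving `dt` moves spike times by at most
one coarse step, and a 3-neuron microcircuit agrees with an independent
fine-step Euler integrator to within 0.1 ms per spike (both are tests).
Within a step, all threshold crossings are processed before any plasticity
update, using the pre-step spike history, so results do not depend on
neuron ordering.

A single spike through a synapse at the default parameters needs a PSC peak
of ≈1154 pA to reach threshold from rest. The one-to-one input→M1 synapses
use `w = 1800 pA` (comfortably suprathreshold), so the first memory layer
mirrors the encoded spike timing plus the delay — the premise the pair
former relies on.

## STDP

Plastic synapses follow a nearest-neighbour pair rule with soft bounds:
potentiation `A₊·exp(−Δt/τ₊)(w_max − w)` for `Δt = t_post − t_pre > 0`,
depression `−A₋·exp(Δt/τ₋)(w − w_min)` for `Δt < 0`, zero at `Δt = 0`;
somatic spike times are used. Weights therefore never leave
`[w_min, w_max] = [0, 1800]`. Defaults `τ₊ = τ₋ = 20 ms`, `A₊ = 0.05`,
`A₋ = 0.0525` (a 5% depression bias), initial weight `w_max/4`: the
amplitudes are sized for training rounds of tens of presentations per
class, so that a pair co-firing in most presentations of one class ends the
round clearly separated (beyond the dominance ratio below) from its weight
under other classes, while idle pairs stay at the initial value.

## Structural learning

**Pair formation.** For each class, each ordered pair of same-block grid
neighbours (Chebyshev radius `S_thre = 1` on the 12×12 grid; orientation
blocks are parallel channels, so cross-block adjacency is undefined and
cross-block pairs are not formed) counts the presentations with
`0 < T(post) − T(pre) ≤ T_thre` on first spikes; pairs with at least
`C_thre` co-firings become candidates. `T_thre = 10 ms` is half the STDP
potentiation time constant — the lags that would drive substantial
potentiation. `C_thre` defaults to `ceiling(0.4 × presentations)`; with the
default study conditions this lands the candidate count in the
50–130-pair operating range the downstream experiments are designed
around. Latency codes emit essentially one spike per neuron, so each
presentation contributes at most one count.

**Pair training and refinement.** All candidate pairs (union across
classes) get plastic synapses in one network; each class's samples are
presented in turn, final weights recorded, and weights reset between
rounds. (Training each class's candidates in isolation is the natural
alternative reading; the union network is the default because the weight
reset between rounds only makes sense if candidates persist across rounds.)
A pair is then assigned to its argmax class only if that weight is
positive and at least `dominance_ratio = 1.2` times the second best;
among survivors sharing a post neuron only the largest weight (tie: lowest
pre id) is kept, making builds deterministic.

**Topology.** 2-layer: one static intra-M1 synapse per refined pair.
3-layer: one dedicated M2 neuron per refined pair, receiving from both the
pair's pre and post neurons; M1 and M2 are both monitored. Learned weights
transfer to the static testing synapses by linear rescaling into
`[0, 0.6·w_max] = [0, 1080 pA]` — *below* the ≈1154 pA single-spike
threshold. This makes an M2 neuron a coincidence detector: either member
alone sub-excites it; the pair arriving within a few milliseconds fires
it. A suprathreshold transfer would make M2 mirror M1 and carry no pair
information, and would leave sub-threshold preset currents (below) nothing
to improve.

## Time-sliced decoding

The simulation window `[0, T_sim)` (default 120 ms = encoding window +
20 ms of delay headroom) is split into `n` equal half-open slices (the last
slice also includes the endpoint). A record's slice maps are the sets of
neurons spiking at least once in each slice; multiple spikes collapse to
one membership. Per class, a neuron joins expression map `i` when its
per-sample activation frequency in slice `i` is at least the threshold θ
(inclusive — with sweep values like 0.2/0.4/0.5 the boundary convention
must be fixed to reproduce results). Classification minimizes the summed
per-slice Jaccard distance; ties break to the lowest class id.

Two conventions matter:

* **Empty slices.** The Jaccard term is 0/0 when both sets are empty; we
  define identical silence as perfect agreement (term 0). If exactly one
  side is empty the term is 1. With this convention the per-slice term is a
  genuine metric, the total is symmetric, bounded by `n`, additive over
  concatenated schemes, and zero exactly on slice-wise equality — all
  property-tested.
* **Namespace.** With a 3-layer network, expressions and samples are built
  over the union of M1 and M2 ids (`gid = 1000·layer_index + id`); an
  M1-only or M2-only view is available through the `layers` argument.

Per-sample activation *frequency* (fraction of samples active) is used for
the aggregation; normalizing by total spike count instead would conflate a
neuron's reliability with overall activity, and membership is already
binary per sample.

## Synthetic data: what it emulates and what it does not

`generate_glyphs()` rasterizes ten fixed stroke templates (ring, vertical
bar, cross, diagonal, L, T, S-curve, dot grid, chevron, H), jitters each
instance by up to ±2 px per axis, and adds Gaussian intensity noise
(sd 8, rounded, clipped to [0, 255]) to the *stroke* pixels. Noise is
confined to strokes deliberately: handwritten-digit rasters have an exactly
zero background, the nonzero-pixel fraction stays in a realistic 5–40%
band, and "delete a fraction of the nonzero pixels" remains a well-defined
corruption. What the generator does **not** emulate: stroke-width and
shape deformation, rotation, and the within-class style diversity of real
handwriting. Consequently the full-window (1-slice) code is often already
sufficient to separate four well-separated glyph classes, and the
advantage of finer slicing — which on rich data appears when single-map
sets saturate — shows up here mainly in the decision margin and at higher
slice counts, not necessarily as a strict accuracy ordering at every slice
count. Passing tests on glyphs demonstrate mechanical correctness and the
direction of effects, not digit-level accuracy.

## Preset currents

`attach_preset_current()` injects a constant DC into every neuron of a
layer. Sub-rheobase amplitudes (the experiments use 100 and 300 pA against
the 376 pA threshold) depolarize neurons by `I·τ_m/C_m` (4 mV and 12 mV)
without firing a silent network — simulated, not assumed, in the tests.
Whether the original procedure applied them during training, testing or
both is unspecified; here they act during the static-synapse phases
(expression building and classification), because pre-activating neurons
is a read-out aid and letting DC drive STDP would distort the learned
weights. `run_preset_current_experiment()` reports accuracy, M2 spike
counts, and both absolute and relative accuracy deltas against the (0,0)
baseline, since "improvement" is ambiguous between the two.

## Numerical and degenerate-input conventions

* Deletion noise removes exactly `round(ratio · n_nonzero)` pixels
  (base-R `round`, ties to even), never touches zero pixels, and preserves
  surviving values — tested exactly.
* `dt` must divide the duration and not exceed the smallest synaptic
  delay; arrivals act on the step beginning at their arrival time.
* A spike exactly on an internal slice boundary belongs to the later slice
  (half-open convention); the duration endpoint belongs to the last slice.
* All-empty slice maps classify to the class whose expression has the most
  empty slices (each non-empty expression slice contributes 1), with the
  lowest-id tie break — chance-level behavior by construction.
* Every stage is a deterministic function of its config and seed; the only
  randomness sources are the glyph generator and deletion noise.

## Problem sizes

The reference study conditions used by the end-to-end tests are 4 glyph
classes with 50 training and 20 test images per class, slice counts 1 and
4, θ = 0.2, seed 1; pair formation, STDP training, expression building and
testing then take a few hundred 120 ms simulations in total. The
acceptance script's rheobase search simulates ~400 candidate amplitudes
for 1000 ms each in one vectorized pass. These sizes were chosen so the
full pipeline runs comfortably on a laptop-class single core while keeping
the candidate-pair count in the 50–130 operating range.

## Known limitations

* The glyph generator's limited within-class variability caps how much
  finer slicing can improve on the full-window code (see above).
* The simulator is clock-driven; exact event-driven simulation,
  conductance-based synapses and richer neuron models are out of scope.
* Deeper networks (chains/bypasses beyond one pair layer), supervised
  variants, and learned convolutional front ends are out of scope.
* Slice boundaries are even; entropy-optimized slicing points are not
  implemented.
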