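---
title: "Directed information flow with mimenet: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed information flow with mimenet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

`mimenet` infers *directed* statistical influence between channels of
synchronized multichannel recordings — the motivating application is EEG
"hyperscanning", where several people (e.g. an ensemble of musicians and a
listener) are recorded simultaneously and one wants to know which brain
regions, within and across subjects, drive which others.  Symmetric
correlation measures cannot answer this; the package implements a
conditional-mutual-information causality index built on a non-uniform mixed
state-space embedding (the MIME family of measures), plus the network layer
that turns moving-window causality matrices into intra-subject networks,
between-condition contrast networks, degree-centrality contrasts, and
subject-level cross-brain links.

## The causality index

For a driver series $X$ and a driven series $Y$ (both z-scored), define the
future vector $w_t = (y_{t+1},\dots,y_{t+T})$ and a candidate set of lagged
values $\{x_{t-j}\}_{j=0}^{L_x-1} \cup \{y_{t-j}\}_{j=0}^{L_y-1}$.  An
embedding $B$ is grown greedily: at each cycle the candidate $c$ maximizing
the estimated conditional mutual information $I(w; c \mid B)$ is appended
(plain mutual information on the first cycle).  Growth stops when

$$\frac{I(w;B_{j-1})}{I(w;B_j)} \ge A,$$

i.e. when the new component added almost nothing ($A = 0.95$ by default, the
published default of the measure's reference software), when the best
criterion value is non-positive, or at `max_cycles`.  The index is

$$R(X \to Y) \;=\; \frac{I\!\left(w;\,B^X \mid B^Y\right)}{I\!\left(w;\,B\right)} \in [0,1],$$

the share of the information about $Y$'s future carried by the driver's
selected lags, given the target's own selected lags.  If no driver lag is
selected, $R = 0$ exactly; a non-positive denominator also yields 0.  $R$ is
directed but *bivariate*: it cannot distinguish direct from indirect
influence (a chain $X \to Z \to Y$ will show $X \to Y$ flow), which is a
known, accepted limitation of the bivariate form.

### Estimation

Mutual information is estimated with the Kraskov–Stögbauer–Grassberger
k-nearest-neighbour estimator (algorithm 1) and its Frenzel–Pompe
conditional extension, under the Chebyshev norm — the counting identities of
the estimator require the max-norm.  Defaults: $k = 4$ neighbours, a floor of
50 points per estimate, and $k < n/10$.  Neighbour searches scan points in
the order of one projected coordinate and abandon early, which keeps each
estimate near-linear in practice without tree structures; estimates are
deterministic given their inputs.  Ties from quantized signals are broken by
a seeded uniform jitter of amplitude $10^{-10}$ applied **once** when the
lag clouds are built, so the selection loop, any re-evaluation of the
criterion, and the final ratio all see identical coordinates (this is what
makes the brute-force oracle test exact).  Small negative raw estimates are
ordinary estimator noise; they are clamped to zero wherever ratios are
formed.

### Parameters that matter

| parameter | default | meaning / rationale |
|---|---|---|
| `T` | 1 | future horizon in samples; must not exceed `min(Lx, Ly)` (adopted as a guard; the original restriction is not fully legible in the source material) |
| `Lx`, `Ly` | 5 | maximum lags searched per series; 10 candidates resolve lag-1..3 couplings at 100 Hz |
| `A` | 0.95 | stopping threshold close to 1; smaller values admit more spurious components |
| `k` | 4 | neighbour count; variance grows as k shrinks, bias as k grows |
| `window_s` | 10 s | moving-window length; at 100 Hz this is 1000 samples, enough for stable estimates (estimator floor: 100 samples/window) |
| `frac_intra` | 0.2 | intra-network threshold as a fraction of the max averaged causality (0.2 performer / 0.1 listener in the motivating study) |
| `delta` | 0.10 | cross-brain dominance margin above the per-window mean of the two directions |
| `noise_floor` | 0.1 | causality entries below this are residual estimator flow and are zeroed before cross-brain electrode averaging |

## The network layer

* **Intra networks** — causality matrices are averaged over windows; an edge
  $i \to j$ is drawn when the entry is positive and at least
  `frac` × (max off-diagonal entry).  The comparison is *inclusive* so that
  a uniform matrix yields the complete directed graph rather than an empty
  one (the source material does not specify the boundary case).
* **Contrast networks** — for two condition-averaged matrices the contrast
  is the entrywise difference; with $R = (\max - \min)/2$ over off-diagonal
  contrast entries, entries outside $[-R/2, +R/2]$ are significant; positive
  ones are "condition-A-stronger" (red), negative "B-stronger" (green).
  Averaging order: matrices are averaged over windows within a condition
  first, then differenced.
* **Degree centrality** — the averaged intra matrix is binarized by the
  intra rule and transposed to the adjacency convention; in/out degrees are
  counted per node and averaged over windows as real numbers, with the mean
  over nodes appended as a pseudo-node; condition contrasts subtract the
  averaged profiles.
* **Cross-brain links** — for augmented (channel-stacked) recordings the
  off-diagonal block of each window's matrix is averaged over electrodes to
  one weight per direction, after the noise-floor filter.  A direction
  dominates a window when its weight exceeds $(1+\delta)$ times the mean of
  the two directional weights; a link is drawn when one direction dominates
  a majority of windows *and* has the larger time-averaged weight, otherwise
  the flows cancel and no link is drawn.
* **Threshold sweeps** — every thresholded extraction can be repeated at
  perturbed thresholds (±10% by default); edges surviving all perturbations
  are reported as dominant links.

### Why the cross-brain noise floor exists

The dominance rule is scale-free: with two truly uncoupled subjects both
directional weights are near zero, and their *relative* asymmetry is random,
so the rule alone draws a spurious link in roughly 40% of pilot replicates.
The measure itself supplies the fix: on independent channels the index
exceeds 0.1 in well under 5% of runs, so entries below 0.1 are residual flow
and are zeroed before electrode averaging.  This reproduces the qualitative
behaviour that genuine links have "significantly positive" weights in one
direction and "almost vanished" weights in the other, without adding any
permutation testing.

## The synthetic world

No recordings of the motivating study are deposited, so correctness is
established on seeded generators with known ground truth:

* **Linear base** — each channel is AR(1) with coefficient 0.9 by default.
  This is deliberate: EEG sampled near 100 Hz has lag-1 autocorrelation
  around 0.9, and the target's self-information sets the absolute scale of
  the stopping bar $A$.  With an unrealistically weak base (coefficient 0.5)
  the 5% relative-information bar is only ~0.007 nats and estimator noise
  clears it, producing spurious driver components; with the EEG-realistic
  base the no-false-positive property holds.  A green false-positive test
  therefore certifies the measure *in the realistic autocorrelation regime*,
  not for arbitrarily weakly self-correlated signals.
* **Band-limited base** — a resonant AR(2) (pole radius 0.9, centre 10 Hz)
  emulating alpha-band EEG; its autocorrelation decays within 0.5 s.
* **Nonlinear base** — unidirectionally coupled Hénon maps
  ($x_{t+1} = 1.4 - u\,x_t + 0.3\,x_{t-1}$ with the driven map's $u$ a
  $c$-mixture of driver and self), the standard nonlinear causality
  benchmark; diverging orbits are rejected and re-seeded.
* **Two-brain scenario** — a reader/listener pair where reader channels
  drive listener channels one-way (strength 0.8, lag 1 after pilot
  calibration); the ground-truth link is reader → listener.
* **Ensemble scenario** — four subjects with a planted star (one leader
  driving the two other musicians and the listener, all musicians driving
  the listener) plus a "ping-pong" pair whose active direction alternates
  between window blocks.  Each subject-level edge is routed onto a dedicated
  target channel: piloting showed that stacking several drivers on one
  channel destroys bivariate detectability entirely (an honest exhibition of
  the measure's bivariate limitation, not an estimator bug).
* **Two-condition scenario** — condition B reuses condition A's seed and
  innovations with coupling strengths added on chosen edges, so contrasts
  isolate the planted difference exactly.

What the generators do *not* emulate: volume conduction and shared
references (which induce zero-lag mixing), nonstationary artifacts, and
oscillatory phase coupling.  Green tests certify the estimator, the
selection scheme and the network rules on well-posed ground truth — not that
real EEG satisfies the model.

## Numerical and degenerate-input conventions

* Windows are consecutive and non-overlapping by default, indexed from 1; a
  trailing partial window is dropped.  Standardization is per-window by
  default (windows are analyzed independently; the source material does not
  state the scope), with a global option.
* A zero causality matrix yields an empty network, not an error; a
  zero-range contrast matrix likewise.
* All randomness (generators, jitter) flows from explicit seeds; identical
  inputs and seeds give bit-identical matrices.  Generators save and restore
  the caller's RNG state.
* Simulation sizes in the acceptance suite are scaled down relative to the
  study (3-channel "brains" instead of 10, six windows instead of ~20) to
  fit the test-time budget; coupling strengths were calibrated once in a
  pilot run and then frozen.

## Known limitations

* Bivariate only: indirect and direct influence are not distinguished (the
  partial/multivariate extension is out of scope).
* The index's absolute scale depends on the target's self-information;
  thresholds (0.1 noise floor, intra fractions) are calibrated for
  standardized, strongly autocorrelated signals.
* The EDF reader covers the common single-rate, int16 layout only.
* No statistical testing beyond the thresholding rules described above — by
  design, mirroring the analysis this package operationalizes.
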