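---
title: "Wake and N3 staging from a single EEG channel: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wake and N3 staging from a single EEG channel: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepwvd)
```

## The problem

Sleep technicians score polysomnography in 30-second epochs against the
AASM manual: an epoch is *wake* when alpha rhythm (8–13 Hz) is present for
more than 15 s, and *N3* (slow-wave sleep) when at least 20% of the epoch
consists of slow waves (0.5–2 Hz, > 75 µV peak-to-peak). Epochs obscured by
major body movement are staged indirectly, from alpha presence or from
neighboring epochs. `sleepwvd` automates exactly this reasoning for the two
stages a technician can call from a single referenced EEG derivation
(typically C3−M2), leaving N1/N2/REM pooled as `OTHER`.

The pipeline is: per-second band energies from the Wigner–Ville marginal
spectrum → three normalized features → a rule engine with three thresholds
→ particle-swarm optimization of the two trainable thresholds against
technician hypnograms → epoch-level agreement metrics.

## Time–frequency analysis

The Wigner–Ville distribution (WVD) of a signal $x(t)$,

$$W_x(t,f) = \int x\left(t+\tfrac{\tau}{2}\right)
  x^*\left(t-\tfrac{\tau}{2}\right) e^{-i2\pi f\tau}\, d\tau,$$

is a real-valued quadratic energy density with ideal time–frequency
concentration and the *marginal property*: integrating it over time gives
the signal's power spectrum. Its notorious drawback — oscillatory
cross-terms between signal components — vanishes in that time integral, so
band energies read off the *marginal spectrum* are cross-term-free without
any smoothing kernel (smoothing would trade away exactly the resolution the
method wants).

### Discretization choices

The continuous definition leaves several things open; the package fixes
them as follows.

* **Per-second blocks.** Energy is needed *per second*, so each second of
  `N = fs` samples is transformed independently with the instantaneous
  autocorrelation kernel $K[n,m] = z[n+m]\,\bar z[n-m]$, $z$ zero-extended
  outside the block, and an $N$-point DFT over the lag $m$. Because the
  kernel advances two signal samples per unit lag, bin $k$ sits at
  $k\,f_s/2N$ Hz: 0.5 Hz spacing at every hospital rate (200/256/512 Hz),
  which places the band edges 0.5, 4, 8, 13 Hz exactly on bin centers.
  Cost is $O(N^2)$ per second rather than an infeasible whole-night
  $N^2$.
* **Analytic signal first.** The discrete WVD of a real signal aliases
  above $f_s/4$ and mixes positive and negative frequencies. Each second
  is therefore extended to its analytic signal (Hilbert transform via the
  FFT; real part equals the input, negative-frequency bins zero) and the
  factor-of-two energy inflation at positive frequencies is divided back
  out, so band energies refer to the real µV trace: one second of an
  $A$-µV sinusoid carries $A^2/2$ µV²·s.
* **The marginal is computed as the time-integral of the kernel**, not as
  a periodogram: summing $K[n,m]$ over $n$ before the single DFT is
  algebraically identical to `colSums(wvd_matrix(z))`. That this equals
  the (folded) squared DFT magnitude of the zero-padded block to $10^{-8}$
  relative — the discrete marginal identity — is *checked*, on a thousand
  random segments, against an independent FFT oracle; it is not assumed.
* **Half-open bands** `[f_lo, f_hi)` prevent double counting at shared
  edges: 4 Hz belongs to theta, 8 Hz to alpha, 13 Hz to neither.
* **No taper.** The per-second block is rectangular. Consequently a pure
  tone keeps about 96–98% of its energy inside its band; the remainder is
  ordinary finite-window leakage, identical along the WVD route and the
  FFT-oracle route. Tests assert these measured concentrations rather
  than an idealized 100%. For the same reason the marginal is *not*
  invariant under circular shifts of arbitrary content (the zero-extended
  kernel implements a linear, not circular, autocorrelation); invariance
  holds exactly for bin-centered tones, which is what the test asserts.
* Negative matrix values are inherent to the WVD and permitted; the
  marginal is clipped at zero only after the identity check, at rounding
  level.

## Features and rules

With per-second band energies $E_{\delta s}, E_{\theta s}, E_{\alpha s},
E_{Ts}$ (T = 0.3–35 Hz, the AASM amplifier passband) and their all-night
totals:

* $P_M = E_{Ts}/E_{T\,\mathrm{all}}$ — movement feature. A second is
  flagged when $P_M > T_M$ (default $5\times10^{-4}$) or $P_M \le
  10^{-12}$ (electrode loss; exact zeros occur only in ideal signals, so a
  small tolerance stands in for "$P_M = 0$"). An epoch with strictly more
  than 15 flagged seconds is a movement epoch.
* $P_W = (E_{\alpha s} - E_{\theta s})/E_{\theta\,\mathrm{all}}$ — wake
  feature, negative values retained. An epoch with strictly more than 15
  seconds above $T_1$ is wake.
* $P_{N3} = E_{\delta s}/E_{\delta\,\mathrm{all}}$ — deep-sleep feature.
  An epoch whose *80th percentile* of the 30 per-second values (the
  rank-$\lceil 0.8\cdot30\rceil = 24$ order statistic) exceeds $T_2$ is
  N3. The rank mirrors the "≥ 20% slow-wave" criterion: six slow-wave
  seconds leave the rank-24 value in the background, seven lift it to the
  slow-wave level.

All-night normalization makes every feature invariant to overall recording
amplitude — the point being that absolute EEG amplitude varies strongly
between subjects and hospitals. The totals deliberately include movement
and wake seconds (no exclusions), and $P_W$ is computed for every second,
including seconds inside movement epochs, because the movement-resolution
branch needs it.

Staging precedence: wake first (a wake-positive epoch is not examined
further), then N3, else OTHER. All "more than 15 s" rules and all
threshold comparisons are strict; boundary cases are pinned in tests.

**Movement resolution.** A movement epoch is staged, in order: (a) wake if
any second has $P_W > T_1$ — alpha presence reuses the wake feature and
threshold so the system has exactly one alpha definition; (b) wake if an
adjacent epoch is staged wake (an alpha-resolved movement neighbor
counts); (c) otherwise the stage of the following epoch, resolved right to
left so a run of movement epochs inherits the first non-movement stage
after it. A run at the very end of the night has no following epoch and
inherits the preceding stage — the rule is silent there and this is the
conservative completion.

Note that $T_M$ is a *fraction of the night's total energy*: on a full
(~8 h) clinical night $5\times10^{-4}$ corresponds to roughly 15× the mean
per-second energy, on a 100-epoch synthetic night to 1.5×. Nights much
shorter than that over-flag movement by construction; short fixtures in
the tests therefore pass `tm` explicitly.

## Threshold training

$T_1$ and $T_2$ are trained jointly by global-best PSO maximizing pooled
3-class epoch accuracy over the labelled training nights (per-class or
multi-objective fitness alternatives are not implemented). Swarm settings:
200 particles, 40 iterations, $c_1=c_2=1$, inertia redrawn from
$U(0,1)$ each iteration — "a random inertia weight" interpreted as a fresh
uniform draw shared across the swarm; a fixed numeric inertia can be set
for diagnostics. The defaults the search box adds (the published method
states none): $T_1 \in [0, 10^{-4}]$, $T_2 \in [0, 10^{-3}]$, spanning
plausible optima by one to two orders of magnitude; velocities are clamped
at 20% of each range to prevent divergence; personal/global bests update
only on strict improvement, so ties keep the first-found position and runs
are exactly reproducible under a seed. Band-energy features are extracted
once per night and cached so each of the 8,000 fitness evaluations is a
vector comparison, not a re-extraction; the cached fitness is tested equal
to the reference implementation.

## Agreement metrics

Binary (one-vs-rest) confusion matrices give sensitivity
$A/(A+C)$, accuracy $(A+D)/N$ and Cohen's kappa
$\kappa = (p_o - p_c)/(1 - p_c)$ with $p_o = (A+D)/N$ and
$p_c = [(N_1 N_3/N) + (N_2 N_4/N)]/N$; the 3-class matrix gives global
accuracy and per-class TP rates. Technician labels collapse to the three
classifier classes (W→WAKE, N3→N3, N1/N2/REM→OTHER) exactly once, at
evaluation time. Display rounds percentages and kappa to two decimals;
all computation and testing is at full precision. Kappa is cross-checked
against an independent implementation (`e1071::classAgreement`) in the
tests, never computed by it.

## The synthetic generator

Real training data for this kind of method are restricted clinical
recordings, so the package ships a seeded generator with exactly the
statistical structure the classifier senses — and deliberately nothing
more (no spindles, K-complexes or sawtooth waves; background is Gaussian
band-limited 0.3–35 Hz noise at 10 µV RMS rather than 1/f):

* **WAKE** — 10 Hz, 30 µV alpha sinusoid in 22 randomly placed seconds
  (comfortably past the >15 s rule);
* **N3** — 1 Hz slow wave, 150 µV peak-to-peak (twice the 75 µV floor),
  covering 80% of the epoch;
* **LIGHT / REM** — 5 Hz, 20 µV mixed-frequency rhythm;
* **MOVEMENT** — 500 µV broadband burst over 20 contiguous seconds,
  band-limited to the same 0.3–35 Hz passband (everything a real channel
  records has passed the amplifier filter; this also makes burst in-band
  energy identical across the 200/256/512 Hz hospital profiles), or —
  with probability 0.3 — a flat, exactly-zero electrode-loss segment.

The default stage sequence is a deterministic 20-epoch cycle (4 wake, a
light-sleep descent, a 6-epoch slow-wave block, brief REM, two isolated
movement epochs → 20% W / 30% N3 / 40% light-REM / 10% movement). A
deterministic mix was chosen over a Markov draw so that the night-level
energy composition — which the fixed $T_M$ divides by — is stable across
seeds; users can pass an explicit script or a Markov specification
instead. Truth labels for movement epochs follow the technician rule:
burst epochs (which genuinely contain alpha-band energy) are scored W,
flat epochs take a wake neighbor's stage or the following epoch's,
through the same resolution routine the classifier uses.

What passing the end-to-end test shows — and what it does not: with
well-separated synthetic morphologies, PSO-trained thresholds recover the
generated stages essentially perfectly (≥95% training, ≥90% held-out
accuracy at 100 epochs per night, 4+4 nights). That validates the
machinery — features, rules, optimization, metrics — under the stated
separability, not clinical performance: real EEG has drifting amplitudes,
alpha riding on delta, sub-criterion slow waves and scorer disagreement,
none of which the generator emulates.

## Problem sizes and numerical notes

Test and acceptance runs use 100-epoch nights (50 min of signal; a real
night is ~900 epochs) and the default 200×40 PSO budget; extraction costs
a few seconds per night at 256 Hz in pure R. EDF output quantizes to 16
bits over each channel's own symmetric range (round-trip error below one
quantization step, ~0.015% of full scale). Degenerate inputs fail loudly:
all-zero nights (undefined normalizations), nights where every epoch is
movement ("unresolvable"), empty training sets, non-finite fitness values.
Hypnogram files are plain `epoch,stage` CSV with 0-based contiguous
indices; technician and predicted label sets are kept distinct and
validated on read.

## Worked example

```{r example, eval = FALSE}
library(sleepwvd)

## four labelled training nights and one held-out night
cfg <- function(s) synthetic_night_config(seed = s)
train <- lapply(1:4, function(s) generate_night(cfg(s), 100))
held <- generate_night(cfg(9), 100)

th <- train_thresholds(train, pso = pso_config(seed = 42))
th

pred <- score_night(held$recording, th)
evaluate_nights(list(list(pred = pred, truth = held$truth)))
```

## Limitations

* Only wake and N3 are staged; N1/N2/REM discrimination is out of scope.
* No smoothing or transition model post-processes the stage sequence.
* The fixed movement threshold presumes realistic night lengths (see
  above).
* Band-energy leakage of a few percent across band edges is accepted by
  design (no taper).
* EDF support covers continuous 16-bit recordings with one-second records;
  EDF+ annotation channels are not parsed.
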