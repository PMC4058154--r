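---
title: "Methods: synergy-driven stimulation simulation in synstim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synergy-driven stimulation simulation in synstim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synstim)
```

# The model

`synstim` simulates a balance-training platform in which transcutaneous
electrical stimulation is modulated by *muscle synergies*. The synergy model
writes the activation of muscle $i$ as a weighted sum of a few time-varying
neural commands:

$$ m_i(t) = \sum_{j=1}^{K} h_j(t)\, w_{ji}, \qquad \mathbf{M} = \mathbf{H}\mathbf{W}, $$

with $\mathbf{M}$ ($T \times N$) the EMG-envelope matrix of $N$ muscles,
$\mathbf{H}$ ($T \times K$) the commands of $K$ synergy modules and
$\mathbf{W}$ ($K \times N$) nonnegative synergy weights. During a training
session the subject follows a sinusoidal center-of-pressure (CoP) target
(rhythmic weight shift); the controller converts the instantaneous phase of
that target into a neural command, then into per-channel stimulation currents
$\mathbf{M} = \mathbf{H}\mathbf{W}\,I_{\max}$.

The package covers the full chain: synergy extraction from EMG envelopes,
the phase-locked command table, an open-loop controller, a simulated
32-channel stimulator, a four-sensor force-plate model, a timing-tolerance
analysis of the update periods, and envelope reconstruction from the
simulated pulse train.

# Synergy extraction

`extract_synergies()` factorizes a nonnegative envelope matrix by
nonnegative matrix factorization with multiplicative updates (Lee–Seung,
Frobenius objective). Numerical choices:

* convergence when the relative objective change over ten iterations falls
  below `tol = 1e-6`, with a cap of 2000 iterations;
* `restarts = 20` uniform-random initializations; the best objective is
  kept. NMF objectives are non-convex and restarts are the standard remedy;
* the scale indeterminacy of $\mathbf{HW}$ is resolved by normalizing each
  row of $\mathbf{W}$ to unit maximum and rescaling the paired column of
  $\mathbf{H}$; all-zero rows are left untouched;
* reconstruction quality is the global variance accounted for,
  $\mathrm{VAF} = 1 - \lVert \mathbf{M}-\mathbf{HW} \rVert_F^2 /
  \lVert\mathbf{M}\rVert_F^2$. Conventions differ in the synergy literature
  (global vs. averaged per muscle); the global Frobenius form is used for
  decisions and the per-muscle analogue is reported alongside
  (`per_muscle_vaf`). The raw value is retained unclipped in `vaf_raw`,
  while `vaf` is clipped to $[0,1]$ for reporting.

`select_module_count()` returns the smallest $K$ whose best-of-restarts VAF
reaches the threshold (ties in VAF resolve to the smaller $K$ because the
scan is ascending). For rhythmic sway, two modules typically exceed 90%
VAF, which the synthetic recovery experiment reproduces.

Inputs are assumed to be nonnegative envelope matrices; rectification and
smoothing of raw EMG are out of scope, as no raw recordings exist in a
simulation-first toolkit. Normalization of envelopes before factorization
(per-muscle maximum, unit variance, none) is left to the caller; the
synthetic generator produces envelopes already in $[0,1]$, so none is
applied by default.

# Sway reference and command table

The reference is $r(t) = A\cos(2\pi p(t)/100)$ with
$p(t) = (p_0 + 100 f t) \bmod 100$ the cycle percentage. The cycle origin
($p = 0$) is the positive extreme; the *ascending zero crossing then falls
at exactly 75%* of the cycle, which is the canonical start posture
($p_0 = 75$): the subject stands at zero CoP about to sway toward the
positive extreme. The underlying convention is only anchored by "zero CoP ≈
75%"; the cosine parameterization is the unique smooth choice that makes
that anchor exact, and it is adopted as the module's convention.

Inverting an amplitude to a phase is two-valued; a movement-direction flag
(the sign of the reference slope, known from the previous sample) selects
the branch. Out-of-range CoP values (measurement overshoot) are clamped to
$\pm A$ with a warning.

Commands are tabulated at 1% cycle resolution — exactly 100 entries per
cycle — by linear resampling with periodic wrap. Lookup uses the
*nearest entry* (no interpolation): the table is defined as 100 discrete
samples, and nearest-entry keeps stored grid values bit-identical.

Metronome beats are placed at the direction reversals (the extremes of the
reference), one per half period — the natural cueing points of rhythmic
sway; if the session starts exactly on an extreme the beat at $t = 0$ is
included.

# Stimulator model

The simulated device has 32 current-controlled channels in two independent
groups of 16; groups fire concurrently and the 16 slots of a group fire
sequentially in channel-id order, spread uniformly over one stimulation
period $T_t = 1/F_t$ (the hardware schedule is not public; a fixed uniform
schedule is the simplest one that makes the mid-period update rule
well-defined and testable). Constraints enforced: currents in
$(0, 150]$ mA, pulse widths in $(0, 5]$ ms, $F_t \le 100$ Hz.

Currents are quantized to the DAC lattice of 0.7827 mA: round to the
nearest multiple, and if that multiple exceeds the channel's $I_{\max}$,
take the largest multiple below it. Quantization is idempotent and never
exceeds $I_{\max}$.

Parameter frames arriving mid-period follow the hardware rule: channels
that already fired in the ongoing period keep their old parameters until
the next period; channels not yet fired adopt the new values immediately.
Internally each pulse simply takes the latest frame at or before its onset,
which is equivalent under the deterministic firing schedule. Amplitude and
pulse width follow the same rule. The controller drives amplitude only;
width stays at each channel's configured value.

# Controller

`run_session()` ticks at nominal period $1/F_s$ with additive jitter from
the session's jitter model (default: truncated normal, $\sigma = 8$ ms,
$\pm 3\sigma$ — a stand-in for a non-real-time scheduler). The phase is
computed from *elapsed simulated time*, not tick count, so jitter does not
accumulate phase error. The loop is open: measured CoP is logged for
feedback display but never alters stimulation, so replacing the measured
stream leaves the dispatched frames bit-identical under the same seed.

Activations $h^\top \mathbf{W}$ are clipped to $[0,1]$ before scaling by
$I_{\max}$ — unnormalized inputs must never push a channel past its limit.
The timing monitor checks each inter-tick period against a tolerance of one
stimulation period ($T_t$) and stops stimulation at the first violation,
marking the log. `single_burst` mode runs one sway cycle; `continuous` runs
for the configured duration. $F_s$ must be below $F_t$ and within the
supported 1–20 Hz range.

# Force plate

CoP follows from the four vertical corner forces by moment balance; the
inverse (needed to synthesize sensor streams) distributes the load
bilinearly across the corners, which round-trips the CoP to $10^{-9}$ cm
and conserves total weight. Shear forces are neglected, as on the real
board. Default stream settings: 100 Hz nominal rate with Gamma-distributed
inter-sample intervals (mean 10 ms, shape 25 — occasional slow samples, a
realistic spread for a consumer wireless board whose true interval
distribution is nonparametric and unpublished), 700 N load, and Gaussian
CoP sensor noise with $\sigma = 0.5$ mm (the board's approximate CoP
resolution).

# Timing analysis

Update periods are simulated as $T_{sE}$ plus truncated-normal jitter
($\sigma = 8$ ms, $\pm 3\sigma$). Summaries are nonparametric: a
right-continuous ECDF (the $P(T_s \le x)$ convention) and the
tolerance-window probabilities $P(T_s \le T_{sE} + T_t)$,
$P(T_s \le T_{sE} - T_t)$ and their difference. With the default model the
truncation bound ($24$ ms) sits just inside the $T_t = 25$ ms tolerance, so
the in-window mass is exactly 1 and the early mass exactly 0 — comfortably
inside the > 95% / < 3% performance bounds expected of the platform. Real
hardware logs (which produced percentages like 98–99% in window) can be
imported through `read_timing_csv()` and summarized with the same report;
the simulator's parametric jitter is a stand-in, not a model of any
particular host. Default sample size is 2000 periods per condition, the
scale of events in a 50 s session.

# Envelope reconstruction

`render_waveform()` samples the pulse train as rectangular pulses at 1 kHz
(resolving 1 ms widths); biphasic pulses are rendered by absolute amplitude
since only the envelope matters. `lowpass_envelope()` applies a zero-phase
(forward–backward) Butterworth low-pass, default order 4 and cutoff 2 Hz:
the sway band (≤ 0.5 Hz) passes with < 0.1% attenuation while a 40 Hz
carrier is rejected by more than four orders of magnitude per pass. The
filter roughly models the low-pass behavior of the skin–muscle system; both
parameters are configurable. Two numerical details: the numerator is
rescaled so the DC gain is exactly 1 (designed coefficients carry ~1e-9
rounding), and the input is padded by odd reflection (10/cutoff seconds per
side, capped at the series length) because a plain zero-padded
forward–backward pass leaves large edge transients.

`compare_envelopes()` min–max normalizes both series and reports Pearson
correlation and normalized RMSE over the grid minus a settling window
(default 1 s per end). A constant series makes the correlation undefined
and is flagged rather than silently scored. Under the default session
(3 modules, 8 muscles, 10 cm / 0.1 Hz sway, $F_t = 40$ Hz, $F_s = 20$ Hz,
50 s) every channel's filtered envelope correlates above 0.95 with the
theoretical $\mathbf{HW} I_{\max}$ envelope, and quantization at 782.7 µA
moves the correlation by less than 0.01.

# Synthetic data

The generators define the study conditions:

* **Commands**: raised-cosine bumps locked to the sway cycle, peak 1,
  sampled at 400 points per period. Defaults place $K$ bumps evenly with
  disjoint supports (width $100/K$ percent). Real neural commands are
  smooth, unimodal and sway-locked in this task; the raised cosine is the
  minimal shape family with those properties.
* **Synergy matrices**: muscles split into $K$ contiguous blocks; dominant
  weights in $[0.7, 1]$ within the owning block, cross-talk in
  $[0, 0.15]$, rows normalized to unit maximum. The disjoint dominant
  blocks make the factorization identifiable, so recovery tests have a
  well-defined ground truth.
* **EMG**: $\mathbf{M} = \mathbf{HW}$ plus additive Gaussian noise with
  $\sigma$ = 5% of the signal maximum, clipped at zero (the simplest noise
  preserving nonnegativity).
* **Default session**: 3 modules, 8 muscles, 10 cm / 0.1 Hz ML sway
  starting at 75%, $F_t = 40$ Hz, $F_s = 20$ Hz, 50 s, identity channel
  map, $I_{\max} = 50$ mA (a mid-range value; the device range is
  0–150 mA).

What the generators do *not* emulate: real EMG spectral content and
amplitude distributions, inter-subject variability of synergy composition,
overlapping or multimodal commands, multiplicative noise, and electrode or
skin dynamics. Passing tests demonstrate that the *pipeline* is correct
under its stated model, not that the factorization or the envelope claim
holds on arbitrary clinical recordings.

# Problem sizes and determinism

Unit tests run recovery problems of 200–400 samples × 6–8 muscles with 5–20
restarts, and sessions of 6–50 s; the full suite completes in well under a
minute, and the heaviest single check (the 50 s envelope reconstruction at
1 kHz across 8 channels) in a few seconds. Every stochastic operation takes
an explicit integer seed and restores the caller's RNG state; identical
configuration plus seed reproduces sessions, streams and factorizations
bit-identically.

# Known limitations

* The NNMF is plain multiplicative-update; for much larger matrices an
  alternating-least-squares or coordinate-descent solver would converge
  faster.
* The stimulator's intra-period firing schedule is an assumption (uniform
  slots); other schedules would shift which mid-period updates land in the
  same period, though never by more than one period per channel.
* Session persistence is CSV/YAML/JSON only; all numeric arrays round-trip
  losslessly via 17-significant-digit text.
* Closed-loop stimulation driven by measured CoP is intentionally absent;
  the controller is open-loop by design.
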