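---
title: "Methods: dual-brain EEG synchronization and hyperbrain networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-brain EEG synchronization and hyperbrain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, estimators, parameter choices and
known limitations of `hyperbrain`. The package analyzes two-person
("hyperscanning") EEG: both participants' channels form a single
*hyperbrain* graph whose edges are either *intra-brain* (within one
participant) or *inter-brain* (between participants).

## The analysis chain

The pipeline follows a two-step design that avoids circularity. Step 1
is a data-driven band search: for each frequency band — theta (4–8 Hz),
alpha (8–12 Hz), lower beta (13–20 Hz), upper beta (21–30 Hz), gamma
(30–45 Hz) — a nonparametric cluster permutation test compares
edge-wise synchronization between the eye-contact and control
conditions. Step 2 computes z-scored, thresholded hyperbrain graphs and
their graph-theoretical summaries only on the band(s) selected in step
1, and relates them to variables (friendship, leadership) that step 1
never saw.

## Preprocessing

* **Re-referencing.** Channels are re-referenced to the algebraic mean
  of the two earlobe electrodes (A1/A2), which are then dropped. If a
  recording carries no reference channels the operation can be
  configured as a no-op.
* **Filtering.** All band-pass filtering uses the squared magnitude
  response of a 4th-order digital Butterworth filter — the transfer
  function realized by forward–backward (zero-phase) filtering — applied
  in the frequency domain, with records zero-padded to a 2-3-5-smooth
  FFT length. Zero-phase filtering matters because phase is the measured
  quantity; the frequency-domain implementation differs from a
  time-domain forward–backward pass only in its boundary handling
  (circular rather than reflected), which is negligible for the
  interior analysis windows used here. The band-pass and the Hilbert
  one-sided spectrum doubling share a single inverse FFT per channel.
* **Blink masking.** Samples where |Fp1| or |Fp2| of either participant
  exceeds ±70 µV are masked, dilated by ±0.040 s, and the mask applies
  to every channel of both participants. Masked samples are excluded
  from phase-difference averages (sample-wise exclusion, not trial
  rejection). Masking is applied after the Hilbert transform; the
  alternative (masking before) would distort the analytic signal at the
  mask edges.
* **Epoching.** The epoch onset is the start of the common
  tone-reproduction period; the analysis window is 0.5–2.0 s after
  onset (avoiding eye-movement contamination at the transition). Trials
  whose common reproduction period is shorter than 2 s are excluded;
  conditions retaining fewer than 5 valid trials flag the dyad invalid.

## Synchronization estimators

**ciPLV.** With `z` the mean of `exp(i(φᵢ − φⱼ))` pooled over unmasked
samples of all valid trials, `ciPLV = |Im z| / sqrt(1 − Re z²)`. Because
only the imaginary part enters the numerator, strictly zero-lag
coupling — the signature of a single source volume-conducted into both
channels — contributes nothing. Pooling samples across trials (rather
than averaging trial-wise estimates) maximizes the effective sample
count in the short 1.5 s windows. When the phase difference is exactly
constant at zero lag the expression is 0/0 and is defined as 0. Edges
with fewer than a configurable minimum of unmasked samples (default
100) are reported missing (`NA`), never as zero.

**PSI.** Cross-spectra are estimated from Hanning-windowed segments of
1 s with 50 % overlap cut from the trial windows (frequency resolution
δf = 1 Hz); segments touching masked samples are dropped. The complex
coherency `C(f)` gives the raw slope `Ψ̃ = Im Σ_f C*(f) C(f+δf)` over the
band's discrete frequencies, normalized by its leave-one-segment-out
jackknife standard deviation. At least 8 clean segments are required
(the jackknife is unstable below that); at least 3 discrete frequencies
must fall in the band. Trials are pooled as segments rather than
estimating PSI per trial; a per-trial variant would discard most of the
already-short windows. The output is enforced to be exactly
antisymmetric (`Ψᵢⱼ = −Ψⱼᵢ`) by antisymmetrization, which removes
summation-order rounding from the BLAS.

**Band power** (control analysis): absolute power is the mean squared
analytic amplitude in the band; relative power divides by the total
0.5–45 Hz power computed by Parseval's theorem from the raw spectrum
(a second Butterworth pass would attenuate components near the broadband
edges and bias the ratio).

## Cluster permutation inference

Edge-wise paired t values (eye-contact minus control; pairing unit =
dyad for inter-brain edges, participant for intra-brain edges) are
thresholded at |t| > 2. Surviving edges of the same sign are grouped
into connected components of the graph they induce; for directed
(antisymmetric) matrices each matrix cell is an ordered edge, so the
sign separation doubles as a direction separation. The cluster score is
the summed t of its member edges. The null distribution records, for
each of `n_perm` random sign flips of the per-unit condition labels, the
maximum absolute cluster score; the critical value corresponds to a
two-tailed test at α = 0.05 and cluster p-values use the add-one
permutation convention `p = (1 + #{null ≥ |score|}) / (n_perm + 1)`.

Design notes: on a directed acyclic suprathreshold edge set, *strongly*
connected components would be all singletons, so components are formed
under weak connectivity ("at least one path between all pairs of
nodes"). Single-edge components are admitted as clusters (the
max-statistic null still controls family-wise error) and flagged;
a switch excludes them.

The **shuffled-pairs control** re-pairs participant 1 of each dyad with
participant 2 of another dyad (uniform random derangement per shuffle,
1000 shuffles by default) and recomputes the full inter-brain cluster
statistic per shuffled dataset. Pair-specific coupling vanishes under
the shuffle while coupling driven by a stimulus common to all dyads
survives, so an observed statistic that is extreme against this null
cannot be explained by shared input.

## Hyperbrain networks

For each dyad, eye-contact edges are z-scored against the mean and SD
of the control condition computed across all edges of the same block —
the inter-brain block at pair level, each intra-brain block at
single-subject level (intra-brain synchronization runs higher in
absolute terms, so a common normalization would swamp the inter-brain
edges). Graphs retain edges with Z > 1 (one SD of the control), in a
binary view (used for shortest-path measures) and a weighted view
holding the retained z (used for strength and modularity). For PSI the
z-scores are computed on magnitudes and the sign/direction of the
eye-contact value is kept on retained edges, giving a signed
(0, −1, +1) directed graph; signed values and magnitudes are both
defensible inputs to the z-scoring, and magnitude scoring is the
default because it keeps the inter- and intra-brain blocks on the same
scale (signed intra-brain blocks are antisymmetric, forcing their mean
to zero).

Measures (all authored in the package; `igraph` is used only for
GraphML export and as an independent oracle in the tests):

* Global efficiency `E = ⟨1/dᵢⱼ⟩` over all pairs (0 for disconnected
  pairs), with the per-node version (harmonic closeness) measuring how
  much access a node has to the entire network.
* Local efficiency: mean over nodes of the global efficiency of the
  subgraph induced by the node's neighbors after removing the node;
  subgraphs with fewer than two nodes contribute 0.
* Modularity of the fixed two-community partition (P1 nodes vs. P2
  nodes), weighted and directed:
  `Q = W⁻¹ Σᵢⱼ (wᵢⱼ − sᵢᵒᵘᵗ sⱼⁱⁿ / W) δ(Cᵢ, Cⱼ)`; undirected graphs count
  each edge in both directions.
* Degree assortativity in the discrete-type form
  `r = (Σ eᵢᵢ − Σ aᵢbᵢ)/(1 − Σ aᵢbᵢ)` with node degree as the type. Note
  this differs from the "remaining degree" Pearson form used by some
  libraries; the tests compare against a brute-force evaluation of the
  same sums.
* Rich club: `φ(k) = 2E_{>k} / (N_{>k}(N_{>k}−1))`, normalized by the
  mean `φ_ran(k)` over 100 degree-preserving randomizations (double-edge
  swaps, 10·|E| attempted swaps each — standard convergence for 36-node
  graphs). A rich club is declared when `ρ(k) = φ/φ_ran > 1` holds for a
  contiguous run covering the top tertile of evaluable degrees; this
  operationalizes "ρ > 1 for large k", which has no canonical cutoff,
  and is configuration-exposed. The club onset is the smallest `k` from
  which `ρ > 1` holds through the largest evaluable `k`; membership
  frequency counts, across club-positive dyads, how often a channel's
  degree exceeds the onset.
* Directed flow: per participant, the count and mean |z| strength of
  outgoing vs. incoming inter-brain edges; a zero incoming count is
  reported missing with counts preserved, and dyads without any
  inter-brain edge are flagged rather than dropped.

Shortest-path measures run on the binary undirected skeleton, including
for PSI graphs (no directed-distance variant is defined for them); the
weighted view feeds strength and modularity only.

## The synthetic dyad generator

Each channel of each brain is a sum of band-limited oscillations — one
phase process per band at the band's center frequency — plus a zero-lag
shared source, white sensor noise, and blink artifacts:

* **Phase model.** Phases evolve as constant-frequency random walks
  (diffusion `phase_noise` = 3 rad/√s; per-channel center-frequency
  jitter SD 0.2 Hz) with Kuramoto-style sine pull terms
  (rate `pull_rate` = 40 s⁻¹). This is the simplest model with tunable
  phase locking with or without a time lag.
* **Within-brain coupling** pulls every channel toward its brain's
  rhythm with a fixed per-channel phase offset (default coupling 0.45 in
  both conditions and all bands).
* **Inter-brain coupling** acts on a configurable channel set (default:
  right hemisphere + midline, 10 channels). Coupled channels lock with
  unit strength onto the weighted circular mean of their brain's rhythm
  and that brain's *received copy* of a dyad-level rhythm; the mixing
  weight (`mix_weight` = 0.75) is fixed whenever inter-brain coupling is
  scheduled, and the coupling strength κ controls the *fidelity* of the
  received copy — a slow Ornstein–Uhlenbeck phase error with stationary
  SD `fidelity_sd · (1 − κ)` (defaults 1.8 rad — calibrated once so that κ = 0.4 is distinguishable from κ = 0 at desk-scale cohorts — mean reversion
  `fidelity_rate` = 2 s⁻¹, slow relative to the 40 s⁻¹ tracking
  bandwidth so channels track it without slipping). Because the copy
  error is common to all channels of a brain, every within-brain phase
  relation — locking tightness, slip rate, pairwise lags — is invariant
  in κ by construction; only the between-brain alignment improves as κ
  grows. This is what lets a friends-vs-strangers coupling increment
  move inter-brain z-scores while leaving intra-brain z-scores
  unchanged, without tuning. Earlier designs that scaled the pull
  strength with κ leaked κ into within-brain synchrony (locking
  tightness and attractor-conflict slip rates both depend on pull
  weights) and were discarded. Per-channel phase offsets are applied
  after mixing, giving locked pairs non-zero phase lags — without which
  the lag-discarding ciPLV would see nothing — while keeping same-brain
  target differences constant.
* **Directed coupling** delivers the follower's rhythm copy delayed by
  `directed_delay_s` (default 20 ms), so the leader's phases
  consistently precede the follower's and PSI recovers the direction.
* **Shared source.** A gain `g` mixes a common zero-lag source into
  every channel of both brains convexly
  (`(1−g)·private + g·shared`), emulating volume conduction; at
  `g = 0.5` this inflates the uncorrected PLV strongly while leaving
  ciPLV near its baseline. The default gain is 0.3.
* **Amplitudes and artifacts.** Band amplitudes (theta 8, alpha 10,
  lower beta 6, upper beta 5, gamma 4 µV) and noise (2 µV) keep the
  background below the ±70 µV blink threshold; blinks are +100 µV,
  60 ms raised-cosine pulses on Fp1/Fp2 at 0.1 Hz.
* **Trials and behavior.** Each task (eye-contact, control) has
  `n_trials` trials (default 40); tone durations are 1.5 s or 2.5 s per
  participant, all four combinations equally likely, as in a
  time-reproduction paradigm. Reproduced durations are the tone duration
  times log-normal noise whose log is correlated between partners
  (default 0.4); the common reproduction window — the epoch — ends when
  the first partner finishes, so roughly the both-long quarter of trials
  survives the 2 s window requirement. Gaze-break order is Bernoulli
  with `leadership_bias` (default 0.75). Friend dyads receive
  `friend_effect` (default 0.2) added to their inter-brain coupling.
  Coupling strengths are free parameters of the generator, chosen once
  so that recovery is comfortably detectable at cohort sizes of 8–20
  dyads (κ = 0.6 default, κ = 0.8 in the recovery studies).

What the generator does **not** emulate: forward-modeled scalp
topographies (channels are statistically exchangeable up to the coupled
set), 1/f background spectra, line noise, muscle or movement artifacts,
eye-tracking traces, and non-stationary coupling within a trial.
Passing recovery tests on this generator therefore shows that the
estimators and inference recover the modeled coupling structure — not
that they would behave identically on real scalp EEG.

## Behavioral pipeline

Reproduced durations outside 0.5–4 s are excluded; summaries are per
participant × task × tone duration × pair-duration (same/different)
cell. The partner correlation uses Spearman correlation on
same-duration trials only (different tone durations would inflate it),
requires ≥ 5 usable trials, and is compared against a null built by
shuffling each participant's trial order independently (5000
iterations) — never across participants. Leadership: the fraction of
same-duration eye-contact trials on which P1 broke gaze first, reflected
to [0.5, 1]; exactly 0.5 means no leadership and excludes the dyad from
leadership analyses; the cohort splits at its median strength (ties to
"strong", configurable). Gaze-break ties carry no direction and are
skipped.

## Numerical choices and degenerate inputs

* Permutation p-values use the add-one convention; with `n` pairing
  units only `2ⁿ` sign patterns exist, so cohorts below 7 units cannot
  reach p ≤ 0.05 — the pipeline does not warn about this, but the
  problem sizes below respect it.
* Zero control-condition SD in a z-scoring block, missing reference or
  frontal channels, < 8 clean PSI segments, < 3 pairing units, and
  empty leadership tables are errors naming the offending block/channel;
  zero-power channels, empty cells and zero-denominator ratios
  propagate as `NA` with counts preserved.
* Edge "missing" (`NA`) propagates as an absent edge, never as zero.
* Degree-preserving randomization asserts unchanged degrees per batch
  (tested); swaps rejecting self-loops and multi-edges keep the graph
  simple.

## Problem sizes used in the tests

The package's own validation runs at desk scale, chosen to keep the
statistical contracts testable: graph-measure equivalence on 100 random
graphs of ≤ 12 nodes; volume-conduction robustness over 20 simulated
dyads (> 100 pooled epochs); PSI direction recovery over 100 delayed-copy
simulations; family-wise error over 200 null cohorts of 20 dyads at 500
permutations; band-and-edge recovery over 50 cohorts of 10 dyads (24
trials per condition, 128 Hz, 200 permutations); directed recovery on
10 strong- and 10 weak-leadership dyads (40 trials, 250 Hz);
friend-effect recovery pooled over three 16-dyad cohorts (~45 dyads,
the scale between-dyad friendship contrasts need);
rich-club consistency on 50 Erdős–Rényi graphs (N = 36,
p = 0.2); and the full default pipeline (20 dyads, 40 trials/condition,
500 Hz, 500 permutations) run twice for bit-identical manifests.
Simulation sampling rates below the 500 Hz default (128–250 Hz, always
well above twice the highest band edge) are used where they do not
change what a test demonstrates.

## Known limitations

* The frequency-domain zero-phase filter assumes circular boundaries;
  recordings begin and end in inter-trial silence, but streaming or
  heavily truncated data would see edge artifacts.
* PSI pooled over trials assumes stationary coupling across the session
  within a condition.
* The rich-club "presence" rule (top-tertile contiguous run) is one
  codification of an informal criterion; conclusions about marginal
  clubs depend on it.
* EDF output quantizes to 16 bits over each channel's observed range;
  round trips are exact only to that resolution.
* The two-community modularity uses the fixed P1/P2 partition; no
  community detection is performed.
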