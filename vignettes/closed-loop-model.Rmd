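---
title: "Modelling closed-loop dynamics between cortical neurons and artificial integrate-and-fire units"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling closed-loop dynamics between cortical neurons and artificial integrate-and-fire units}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridloop)
```

## The system being modelled

A bidirectional closed-loop brain-computer interface (clBCI) couples a small
set of cortical single neurons (SNs), recorded extracellularly, to a small
artificial network of integrate-and-fire units (IFUs). Each SN spike evokes
an excitatory or inhibitory postsynaptic potential (EPSP/IPSP) in connected
IFUs; when an IFU's membrane potential reaches its threshold it spikes,
resets, and — if it is an *output* IFU — triggers a single pulse of
intracortical microstimulation (ICMS) on its target SN after a per-IFU delay
$t_{\mathrm{stim}}$. The stimulus can evoke a short-latency spike in the
target, transiently inhibits it, and produces a ~1 ms electrical artifact
during which no spike on any channel can be detected.

This package simulates that loop end to end and provides the analysis layer
used to characterise it: feedback-loop detection from elementary spike
patterns, spike-train correlograms, and parameter sweeps over inhibition
strength, stimulation delay, and network size.

## The IFU network

PSPs are current-based and modelled as the difference of two exponential
traces updated at 10 kHz (0.1 ms ticks):

$$S_{t+1} = C_{\text{slow}}\,S_t,\qquad F_{t+1} = C_{\text{fast}}\,F_t,
\qquad \mathrm{PSP}_{t+1} = S_{t+1} - F_{t+1},$$

with $C = e^{-\Delta t/\tau}$ calibrated so the kernel has a 1.5 ms rise and
4 ms decay time constant (`calibrate_kernel()`). When a spike from SN $i$
arrives at IFU $j$ (after a one-tick, 0.1 ms conduction delay) both traces
are incremented. The membrane potential is $v_j = \sum_i (S_{ij} - F_{ij})$,
and the IFU fires when $v_j \ge T_j$, with a 0 ms refractory period.

Three semantics required decisions the recursion itself does not fix:

* **Weight normalization.** Connection weights are specified as the fraction
  of the *realized PSP peak* to the activation threshold, because that is
  how calibrated networks are naturally described (an "EPSP of 75% of
  threshold"). The unit-increment kernel $c_{\text{slow}}^n -
  c_{\text{fast}}^n$ peaks at about 0.347, so traces are incremented by
  $w\,T_j/\text{peak gain}$; a lone arrival with $w = 0.75$ then drives
  $v$ to exactly $0.75\,T_j$ at the kernel peak (2.35 ms after arrival).
* **Reset.** "Reset to 0" is implemented by zeroing all of the spiking
  IFU's input traces: with an exponential-trace state this is the only
  reset under which $v$ is exactly 0 on the same tick and stays there
  absent input. Subtracting $T_j$ would leave a decaying remainder.
* **No lower clamp.** IPSPs may drive $v$ arbitrarily negative; recovery is
  then governed by the IPSP decay constant. This matters for the
  inhibition sweep, where long IPSP decays suppress later coincidences.

Within a tick the order is: decay, then arrivals, then the threshold test;
all IFUs are evaluated independently, so several may fire on the same tick.

### Coincidence windows and the calibration envelope

Excitatory weights are meant to be calibrated so that *two* EPSPs arriving
within a narrow window are necessary and sufficient to fire an IFU.
`coincidence_window(w)` computes, by brute-force tick scan, the largest
offset at which two EPSPs of amplitude $wT$ still reach threshold. For the
stated kernel the envelope of amplitudes 52.5%–97.5% maps to windows of
about 1.5–16.5 ms. The experimental calibration for the same envelope is
reported as 1.1–12.6 ms; the upper ends disagree (16.5 vs 12.6 ms). The
scan is elementary, so the package reports its own value rather than
hard-coding the narrower figure; plausible sources of the difference are
details of the hardware's fixed-point kernel or of the manual calibration
procedure. Nothing downstream depends on the exact window width.

## The spontaneous-activity model

Each SN's baseline activity is modelled by a first-order Markov chain on
interspike intervals. From a baseline recording, ISIs are rounded to the
nearest millisecond (sub-millisecond intervals are clamped to 1 ms — two
events in the same millisecond bin are indistinguishable downstream), and
every consecutive pair $(\mathrm{ISI}_1, \mathrm{ISI}_2)$ is stored.
Generation seeds the chain with an $\mathrm{ISI}_1$ drawn uniformly from all
stored observations (so the seed is weighted by multiplicity) and then
repeatedly draws a successor uniformly from the multiset stored under the
current interval — which reproduces the empirical conditional distribution
$P(\mathrm{ISI}_2 \mid \mathrm{ISI}_1)$ exactly in expectation.

A drawn interval that was never observed as a predecessor (a dead end) falls
back to the nearest stored key in absolute distance, ties toward the smaller
key; this keeps the local ISI statistics intact while guaranteeing the chain
never stalls.

## The stimulation-response model

Built per SN from an open-loop (OL) epoch of Poisson ICMS
(`build_response_library()`):

* **Evoked window.** From a 0.5 ms-binned PSTH, the earliest post-stimulus
  peak exceeding *baseline mean + 3 SD* (baseline = the −20..0 ms
  pre-stimulus bins) defines the evoked window as the maximal contiguous
  super-threshold run. No published criterion exists for this step; the
  excess-over-baseline rule is the standard PSTH convention and the
  multiplier is exposed as a parameter. A second spike within 3 ms of the
  first evoked spike counts as part of the evoked response (doublet).
* **Evoked probability.** The probability of evoking a spike depends on
  $\Delta t_{\text{prev}}$, the interval between the SN's previous spike
  and stimulation onset (rounded to 1 ms). The raw per-ms curve over
  1–100 ms is smoothed with a 10 ms boxcar whose window shrinks
  symmetrically at the domain edges (so no mass is imported from outside
  1–100 ms); empty bins are imputed by the same pass. Beyond 100 ms the
  curve plateaus at the SN's average evoked probability, computed over
  *all* stimuli — the natural reading of "average probability for that
  SN"; stimuli with no recorded prior spike are treated as plateau
  observations.
* **Rebound spikes.** Stimulation transiently inhibits the SN; the first
  non-evoked post-stimulus spike (the "rebound spike") captures this, and
  its latency distribution is used directly. Because OL epochs are short,
  the raw multiset is oversampled: 10 000 draws with replacement, each
  jittered by uniform noise on (−10, 10) ms, are merged with the originals;
  anything landing inside the evoked window or at non-positive latency is
  discarded. For SNs whose next stimulus routinely precedes the rebound, a
  Gaussian supplement (defaults: raw mean and SD) extends the support.

The rebound draw is made on every stimulus, independently of whether a
spike was evoked.

## The closed-loop engine

`run_closed_loop()` advances integer ticks at 10 kHz. Per tick:

1. **Stimulus delivery.** A stimulus due within 1 ms of a previously
   delivered one is postponed to the end of that artifact (postponements
   cascade). On delivery to SN $k$: an evoked spike is scheduled with
   probability $p_{\text{evoke}}(\Delta t_{\text{prev}})$ at a latency
   drawn from the library; SN $k$'s pending spontaneous spike is cancelled
   and a rebound spike is scheduled at a drawn latency. A newer stimulus
   cancels and redraws a still-pending rebound — stimuli arriving before
   the rebound are common for strongly driven SNs, and the most recent
   stimulus is the one whose inhibition is current.
2. **Spike emission.** Due spontaneous, evoked, and rebound spikes are
   emitted. After a rebound spike the Markov chain resumes with the
   *realized* post-stimulus interval (rebound time minus previous spike,
   rounded to ms) as its context, via the dead-end fallback if unseen:
   this anchors post-stimulus statistics to the empirical table instead of
   inventing a new state.
3. **Obstruction.** A spike within 1 ms after any delivered stimulus is
   flagged obstructed: it exists biologically — by default it still resets
   $\Delta t_{\text{prev}}$ (switchable) — but it is invisible to the IFUs.
   The target SN's own evoked spike is exempt from its causal stimulus's
   artifact (also switchable): evoked latencies of a few ms put it past
   the artifact in practice, and the OL library could not have been built
   if the evoked spike were systematically hidden.
4. **IFU update.** Visible spikes from the previous tick (0.1 ms
   conduction) drive the trace updates; threshold crossings emit IFU
   spikes, reset traces, and schedule stimuli at $t + t_{\mathrm{stim}}$.

Response libraries are indexed by stimulation target: stimulating channel
$k$ affects SN $k$ only. Cross-channel activation (one stimulus evoking
spikes in two SNs) is observed in real arrays and the data model could hold
a library per directed pair, but the packaged engine does not simulate it.

All randomness flows through R's RNG, so `set.seed()` makes entire
simulations, including every library draw inside the engine, byte-for-byte
reproducible.

## Feedback loops

Each evoked spike, the IFU spike that triggered its stimulus, and the two
most recent excitatory arrivals that drove that IFU over threshold define an
*elementary pattern* of exactly three SN spikes (two triggers + one evoked).
The engine records trigger provenance exactly, so patterns are read off the
event log rather than re-inferred from spike times. Patterns sharing at
least one spike are merged into *feedback loops* (union-find over connected
components); a loop's size is its number of distinct spikes, so the minimal
loop — two triggers and one evoked spike — has size 3, and two patterns
sharing one spike merge to size 5.

Two provenance corner cases: an evoked spike whose IFU was fired by a single
suprathreshold EPSP has no second trigger and is counted separately rather
than forced into a degenerate pattern; and in hidden-layer networks the
output IFU's triggers are hidden-IFU spikes, which are resolved recursively
to those units' own SN triggers and flagged `indirect` (such patterns may
contain more than three spikes).

## Correlograms

Spike times are rounded to 1 ms and binarized; the correlogram value at lag
$\ell$ is the probability of a spike of train B at offset $\ell$ from a
reference spike of train A, over $\pm 50$ ms, with the central bin zeroed
for autocorrelograms. Similarity between correlograms is plain Pearson
correlation over paired bins, excluding the zeroed central bin when either
input is an autocorrelogram. A 3 ms moving-average smoother is provided for
display only.

## The synthetic-data layer

Tests and the acceptance analyses run without any recordings, on synthetic
ground truth chosen to emulate the recorded cohort:

* **Spontaneous trains** are gamma-renewal processes with an absolute
  refractory period (`make_synthetic_sn()`), with rates defaulting to the
  13 recorded baseline rates (1.4–51.4 Hz, `reference_sn_rates()`) and a
  shape parameter of 2 (moderately regular cortical firing at rest).
  A gamma-renewal process was chosen deliberately so that the Markov
  generator is validated against an *independent* process rather than
  against itself.
* **Response libraries** (`make_synthetic_library()`) use a saturating
  recovery curve $p(\Delta t) = p_{\max}(1 - e^{-\Delta t/\tau_r})$
  (default $p_{\max} = 0.8$ inside the observed 25%–95% envelope,
  $\tau_r = 30$ ms), Gaussian evoked latencies (2.5 ± 0.4 ms) truncated to
  the evoked window, and Gaussian rebound latencies (40 ± 12 ms) truncated
  positive and outside the window.
* **Fixture networks** (`make_fixture_network()`) reproduce the four
  studied architectures' published structure: 3 SN / 3 IFU recurrent;
  4 SN / 4 IFU with three excitatory + one inhibitory connection per SN;
  4 SN / 4 IFU with two + two; and 3 SN / 3 hidden / 2 output, purely
  excitatory. Per-connection weights were published only as figure panels,
  so fixtures default to the midpoint of the calibrated envelope (75% of
  threshold) with inhibitory magnitudes at half that.

What the synthetic layer does *not* emulate — and hence what passing tests
do not establish about real recordings: firing-rate non-stationarity,
cross-channel evoked responses, evoked-latency variability beyond a
truncated Gaussian, electrode geometry, and any waveform-level effects
(the artifact is a pure 1 ms blanking abstraction; amplifier fast-settle
recovery is not modelled below that).

## Sweeps and their statistics

* **Inhibition sweep** (`inhibition_sweep()`): a 9 × 9 grid (81 conditions)
  over IPSP magnitude 0–200% of threshold and IPSP decay 4–20 ms — the only
  uniform square grid consistent with "81 unique combinations" over those
  ranges. All inhibitory magnitudes are set jointly (per-connection
  rescaling is not distinguishable from the published description);
  excitatory weights stay at their base values; inhibitory synapses get
  their own kernel so the decay constant can vary. Average loop size is
  regressed on magnitude (%) and decay (ms).
* **Delay sweep** (`delay_sweep()`): loop-size distributions across delay
  assignments, Kruskal–Wallis plus pairwise Wilcoxon post-hocs. Replicates
  share seeds across conditions (common random numbers), so identical
  delay sets produce identical distributions and condition contrasts are
  not diluted by generator noise.
* **Artifact sweep** (`artifact_sweep()`): random purely excitatory
  networks of 4–10 SNs/IFUs (step 2), EPSP weights 50–87.5% of threshold
  (step 12.5%), exactly 4 presynaptic connections per IFU (to separate
  network size from synapse count), delays $4n$ ms with $n$ drawn without
  replacement from 1..10, 10 replicates with fresh connectivity, SN
  draws, and delays. The evoked/inhibited condition and the
  obstruction-only baseline use the same machinery with the response
  model switched off. Missed-spike fraction is regressed on weight and
  size; per-SN missed percentages feed an ANCOVA-style model
  (`artifact_ancova()`) with a rate × condition interaction.

### Problem sizes used by the packaged analyses

The published simulations ran 5 simulated minutes per condition. The
packaged test-suite and acceptance analyses use the same grids but shorter
runs — 30–120 s per simulation, 5-minute baseline epochs for transition
tables, and a 13-SN pool at the recorded rates — sizes at which every
qualitative result (sign, ordering, significance structure) is stable under
seed changes while the whole suite stays comfortably re-runnable on a
laptop. The full-length settings remain the documented defaults of the
sweep functions themselves.

## Numerical choices and degenerate inputs

* Time is integer ticks at 0.1 ms; all millisecond quantities must sit on
  the tick grid (validated). ISIs and $\Delta t_{\text{prev}}$ round to
  1 ms; a rebound latency rounds to at least one tick.
* Ties within a tick: stimuli are delivered before spikes are emitted, so
  a spike coincident with a stimulus is obstructed; IFU arrivals are
  consumed one tick after emission (conduction delay).
* Two stimuli scheduled for the same tick: the first (in scheduling order)
  is delivered, the second staggers to the artifact's end.
* Empty successor pools cannot occur (every stored predecessor has at
  least one successor by construction); empty rebound multisets are a
  configuration error caught before simulation.
* The engine skips trace updates on ticks where total trace magnitude is
  below 1e-14 and nothing arrives; sub-1e-14 stale traces are the only
  deviation from exact recursion and are far below any threshold scale.
* Union-find membership is order-invariant; loop ids are assigned in
  first-appearance order.

## Known limitations

* One response library per stimulated SN: no cross-channel activation.
* Evoked doublets are not simulated (they were rare in the source data);
  the analysis side still labels them correctly when present in logs.
* The Markov model is first-order and stationary by construction; slow
  drifts in excitability are outside its scope.
* Hidden-layer trigger attribution is a convention (two most recent hidden
  inputs, resolved to their SN triggers); other attributions are defensible
  and would change indirect-pattern sizes.
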