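---
title: "Methods: event detection and statistics for the GnRH pulse generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event detection and statistics for the GnRH pulse generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kisssync)
```

# Scope

The arcuate kisspeptin (ARN^KISS) neuron population discharges in episodic,
near-simultaneous activations — synchronization events (SEs) — each of which
drives one LH pulse. kisssync implements the detection and quantification
procedures used to study this system at three scales (in vivo photometry,
brain-slice network imaging, patch-clamp electrophysiology), the exact
nonparametric statistics used for cohort inference, and seeded simulators
that generate each recording type with known ground truth. This vignette
documents the models, the tunable parameters, and the choices made where
the procedures required concrete numerical decisions.

# Photometry pipeline

## Signal model

A dual-channel trace consists of timestamps (seconds, with off-duty gaps),
a calcium-dependent channel f465 and an isosbestic reference f405. The
working model is

f465(t) = b465(t) + A·k(t) ∗ SE train + g·m(t) + ε465(t),
f405(t) = b405(t) + g·m(t) + ε405(t),

where b(·) are slow baselines (bleaching plus drift), m(t) is a shared
motion/artifact component coupled with gain g into both channels, k is the
GCaMP6s impulse response and ε white measurement noise. Subtracting f405
removes m exactly when the channel gains are matched; `subtract_background`
therefore subtracts the reference as-is by default and offers a
least-squares affine fit (`fit_isosbestic = TRUE`) for unmatched gains.

## Baseline adjustment

`correct_baseline` estimates the slow baseline as the 10th percentile of
the signal in sliding 900-s windows at 450-s stride, interpolates between
window centers with a natural cubic spline, and subtracts. The 900-s window
is the one fixed, published choice; the within-window statistic, the stride
and the interpolant are not published anywhere we know of, so they are this
package's own: a low quantile tracks the inter-event baseline because SE
transients (tens of seconds) occupy a small fraction of any window, and the
half-window stride with spline interpolation keeps the estimate smooth at
the window scale. Correctness is therefore asserted behaviorally in the
test suite — a pure linear drift is removed to within 5 % of its range and
planted transient amplitudes survive within 10 % — rather than by
bit-parity with any particular legacy implementation. Recordings shorter
than two windows fall back to subtracting the global 10th percentile, with
a warning.

## Peak detection and SE classification

After z-scoring over the full recording (`zscore`; degenerate zero-variance
input is an error), `detect_peaks` returns every strict local maximum with
topographic prominence ≥ `min_prominence` (default 1 z; no published value
exists, and 1 z simply suppresses sub-noise ripples). Plateau maxima
resolve to the plateau midpoint. Prominence is computed in C++ by walking
from each peak to the nearest higher sample on either side and taking the
height above the higher of the two intervening minima; the test suite
checks it sample-for-sample against a naive exhaustive scan.

`classify_ses` applies the two SE rules: a peak qualifies only if it
exceeds one third of the recording's highest peak, and accepted SEs must be
more than 160 s apart peak-to-peak. The published rules do not say how to
resolve a spacing conflict among qualifying peaks, so conflicts are
resolved greedily highest-amplitude-first (ties to the earlier peak). The
greedy order guarantees that the accepted set satisfies both rules
regardless of input order, and a property-based test shows it equals the
exhaustive maximum-amplitude-first search on every random instance of up to
10 peaks. For recordings shorter or longer than 24 h the one-third rule
uses the maximum over the available recording.

## SE shape and timing

Per SE, `se_shape` measures: amplitude, the z value at the peak minus the
median of the preceding 300 s (the median is an unbiased local level
estimate when transients are sparse); width at half maximum, the time
between the half-amplitude crossings bracketing the peak with linear
interpolation between samples; and onset, the last upward crossing of 20 %
of the SE amplitude before the peak (the published onset figures are
schematic and define no formula; 20 % of amplitude is this package's
convention). Crossings are interpolated only within nominally contiguous
acquisition — a crossing that falls in an off-duty gap is attributed to the
adjacent sample time, and all temporal rules (160-s spacing, widths,
latencies) operate in wall-clock time on the gapped grid. A half-crossing
not found within 300 s of the peak leaves the width flagged undefined.

`se_timeline` counts SEs (by peak time) in 4-h bins after an injection and
one 4-h bin before it, and measures the latency from injection to the
*onset* of the next SE plus subsequent inter-onset intervals; latencies use
onsets rather than peaks because the question the latency answers is when
the pulse generator resumed, not when it peaked. With no SE after the
injection the latency is flagged undefined rather than silently dropped.

# Slice pipeline

`compute_dff` subtracts the background ROI and normalizes to F0, the 20th
percentile of the background-subtracted trace (F0 is not published; a low
quantile is robust to sparse transients, and F0 ≤ 0 is raised as a named
degenerate-cell error). `detect_events` thresholds at mean + 2 SD computed
over the **full** trace, events included — the literal reading of the
published rule — and emits one event per maximal supra-threshold run; an
alternative baseline-only reading would shift thresholds but is not the
stated rule. `detect_mses` chains the time-sorted peaks of all cells
greedily from the earliest unconsumed event while consecutive gaps are
< 10 s (strict), and emits chains spanning ≥ 2 distinct neurons; with
sorted input the chain partition is unique (chains break exactly at gaps
≥ 10 s), every event belongs to at most one mSE, and same-cell repeats may
ride along in a chain without counting toward the two-neuron requirement.
Per-cell mSE participation counts the mSEs containing that cell (not its
member events). `epoch_rates` normalizes counts as total / n_cells /
hours over 12-min measurement windows separated by 2-min wash-in/out gaps
(`epoch_plan`).

# Patch pipeline

`quantify_vmem_response` smooths the voltage with a 1-s running median
(resistant to brief electrical artifacts; how the drug extremum was read
out is unpublished), takes the pre-drug level as the mean over the 60 s
before application ("immediately before" is unpublished; 60 s is this
package's choice), and the drug level as the minimum from application start
to 120 s past its end, because responses outlast a 1-min application while
washout takes minutes. A neuron is a responder iff ΔV_mem ≤ −5 mV — the
threshold separating the two clusters of the bimodal response distribution
— with the boundary inclusive ("−5 mV as a minimum for a response").
Washout recovery requires the smoothed trace to return within 2 mV of the
pre-drug level at some point 7–17 min after application end.
`paired_application_summary` compares each antagonist group's mean NA2
amplitude against the pooled NA1 mean as
100·(|mean NA1| − |mean NA2|)/|mean NA1|. `firing_rate_change` counts
spikes in the 60 s before application and in the 0.5–1.5-min window after
application start; a silent baseline flags the percent reduction undefined.

# Statistics

The statistic conventions mirror how this literature prints results:
Wilcoxon W is the absolute sum of signed ranks (six uniformly decreasing
pairs give W = 21), Mann–Whitney U is min(U1, U2), and the mean rank Δ is
the difference of group mean ranks on the pooled ranking (complete
separation of n1 and n2 observations gives U = 0 and |Δ| = (n1 + n2)/2 —
a proved identity, also property-tested). Exact two-sided p-values are
computed by full enumeration of the permutation distribution — a
dynamic-programming convolution over doubled midranks, so ties are handled
exactly — for n ≤ 25 (signed-rank) and n1 + n2 ≤ 20 (rank-sum); these
cutoffs keep enumeration instant at desk scale and are configurable. Above
the cutoffs a normal approximation with midrank tie correction and
continuity correction is used, and the result records which path ran. The
test suite checks the enumeration against literal 2^n sign assignments and
choose(N, n2) subset scans.

Holm–Šidák adjustment is the step-down closed form
adj p(i) = 1 − (1 − p(i))^(k − i + 1) with monotonicity enforcement; the
comparison family size k is always supplied by the caller, because
published families are implicit in the analysis design (e.g. k = 4 for the
antagonist comparisons). t-tests wrap the standard implementations, with
the unpaired variant gated by an F-test for variance homogeneity at 0.05
(pooled variance when not rejected, Welch otherwise, outcome logged in the
method string). The repeated-measures ANOVA uses the standard
within-subject F on (k−1, (k−1)(n−1)) degrees of freedom with no
sphericity correction (none is used in the source analyses), and follows
with all pairwise paired-t contrasts under Holm–Šidák.
`leave_one_animal_out` re-runs any such test with each animal's complete
observation set removed, flagging (not hiding) exclusions that leave too
little data.

# Synthetic data: what it emulates, and what it does not

The simulators generate the statistical structure the analyses assume, with
every random draw taken from a per-component seeded sub-stream so that
identical configuration and seed give bit-identical output and adding one
component does not reshuffle the others.

**Photometry** (`simulate_photometry`): scheduled acquisition at 10 Hz in a
5 s on / 10 s off duty cycle (only on-duty samples are emitted); SE times
from a gamma renewal process (default mean interval 4320 s, shape 4 —
about 20 SEs per 24 h, a convention for the diestrous low-frequency regime,
since no quantitative per-state SE frequency is published); transients from
a difference-of-exponentials kernel (rise 1.5 s, decay 25 s — conventional
GCaMP6s kinetics, unpublished for this preparation and configurable);
amplitudes Normal(25, 3) truncated at 15 in units of the channel noise SD,
reflecting that SE transients in this preparation tower over the baseline
(z ≈ 20–40) and that the one-third-of-max rule presupposes a narrow
amplitude range — at much lower SNR the extreme-value tail of white noise
over a 24-h, ~290k-sample recording enters the one-third threshold and the
published rule itself stops being usable; bleaching exponential plus slow
sinusoidal wander; a smoothed shared artifact coupled into both channels;
post-injection suppression as multiplicative hazard scaling implemented by
operational-time warping of the renewal process (a hazard scale factor is
exactly a time change), with no rebound modeled; an ovariectomized mode as
a two-state (cluster/quiescent) modulated renewal with higher amplitudes in
clusters.

**Slice** (`simulate_slice_network`): per-cell independent Poisson events
plus a latent network process (default 6 events/h) recruiting each cell
with probability 0.5, jittered within the 10-s window; the independent rate
is set so the total per-cell rate equals `cell_event_rate` (default 22.9
events/cell/h). Amplitudes default to Normal(0.20, 0.02) ΔF/F; noise is
0.003 ΔF/F, the ROI-mean shot-noise scale for a bright several-hundred-
pixel soma at 2 Hz — and, as with photometry, the regime in which a literal
mean + 2 SD run rule does not fragment each transient at its slow
threshold re-crossing. Event kinetics default to rise 0.5 s / decay 4 s
(brief burst transients). A drug epoch multiplies all rates; recruited-
event jitter never crosses an epoch boundary, so epoch rate factors apply
exactly to planted times.

**Patch** (`simulate_patch`): responders drawn Bernoulli(0.40); amplitudes
Normal(−9.9, 2.5) truncated beyond the −5 mV threshold by a 1-mV margin
(so planted responders are classifiable by construction; constant
amplitudes are taken literally to allow sub-threshold planting); a
smoothstep envelope that is exactly zero before application and exactly one
on the plateau; antagonist scales {none 1, α 0.38, β 0.33, both 0.02}
matching the relative NA2 reductions; washout lag uniform 7–17 min.
**Spikes** (`simulate_spiketrain`): piecewise-homogeneous Poisson at
1.48 Hz scaled by 0.142 inside non-overlapping application windows
(1.48 → 0.21 Hz).

None of the simulators model the biology below the event level: no
biophysics of synchronization, no hormone output, no estrous-cycle
dynamics, no motion artifacts beyond a linear shared component, no
photobleaching nonstationarity in noise, and no correlated (pink) noise.
Passing recovery tests therefore demonstrates that the pipeline implements
its stated rules correctly at realistic SNR — not that it is robust to
every pathology of real recordings.

# Problem sizes and estimators used in the checks

The recovery checks run 20 seeds of a full 24-h photometry simulation
(~290k samples each) for SE detection F1 at ±20 s matching tolerance, and
20 seeds of the 3-h hazard-silencing protocol for the latency; slice
recovery uses 10 cells × 40 min with the drug epoch at rate factor 0.23,
with the percent reduction estimated from rates pooled across seeds
(pooling avoids the Jensen bias of averaging per-seed ratios); the patch
cohort is 50 neurons at 1 mV membrane noise. These sizes put Monte-Carlo
error comfortably inside the asserted tolerances while keeping the whole
suite at about two minutes.

# Known limitations

* The baseline estimator is behaviorally, not bitwise, equivalent to the
  legacy routine it stands in for; recordings dominated by transients
  (transient duty cycle approaching the window) would bias the quantile
  baseline upward.
* Whether the original analyses applied the one-third rule to z-scored or
  raw-amplitude peaks is unknowable from the published description; this
  package applies it to z (the scale on which peaks are detected), and both
  scales agree up to the affine z map within a recording.
* The mean + 2 SD slice rule degrades gracefully but inevitably at high
  noise: threshold re-crossings fragment events. The simulator documents
  the SNR regime in which the rule is reliable.
* Exact p-values condition on the observed midrank pattern (the standard
  exact treatment of ties); no continuity correction is applied in exact
  mode.
* Repeated-measures ANOVA offers no Greenhouse–Geisser correction yet; the
  F test assumes sphericity, as in the source analyses.
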