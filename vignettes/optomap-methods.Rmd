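---
title: "Mapping and quantal analysis of optogenetically evoked synaptic inputs"
author: "optomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping and quantal analysis of optogenetically evoked synaptic inputs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optomap)
```

## The analysis problem

Paired (double-patch) voltage-clamp experiments compare synaptic input
strength onto two neighboring layer-2/3 pyramidal neurons — one wild-type
and one knockout — that receive the same presynaptic axons and the same
photostimulus. Four experiment classes share one analysis skeleton:

* **LED bulk stimulation**: one wide-field flash over channelrhodopsin-
  expressing callosal axons; the measure is the peak amplitude of the
  averaged EPSC (3–10 sweeps per cell), read 5–80 ms after the flash and
  optionally normalized to LED power.
* **sCRACM**: a blue laser steps over a 12 × 12 grid (50 µm spacing) in
  TTX/4-AP, so only monosynaptic terminal release survives; each spot's
  input strength is the peak of the averaged EPSC 5–80 ms after laser onset.
* **AP-dependent maps**: an 8 × 8 grid (75 × 100 µm) without TTX; EPSC
  amplitudes are averaged 2–30 ms after onset to exclude polysynaptic
  contamination.
* **LSPS glutamate uncaging**: a 16 × 16 grid (50 × 60 µm) of focal
  photolysis fires presynaptic neurons. Responses beginning within 5 ms of
  the flash with fast kinetics are non-synaptic "direct" responses of the
  recorded cell and must be excluded or, when mixed with a synaptic
  component, subtracted.
* **Sr²⁺ quantal analysis**: with strontium substituted for calcium, evoked
  release desynchronizes into resolvable quantal events. Events in the
  second before the flash are spontaneous; events 50–350 ms after it are
  evoked. Frequency reflects release-site number and release probability,
  amplitude reflects unitary synaptic strength.

Per-cell maps are aligned (to the soma, or to the home barrel for LSPS),
interpolated to half pixel size for display, averaged by genotype with a
minimum-sampling mask (pixels sampled by fewer than eight cells are
blacked out), and summarized as vertical profiles and region means. Paired
statistics are *normality-gated*: the D'Agostino–Pearson and
Anderson–Darling tests both must pass at α = 0.05 before a paired *t* test
is used; otherwise the Wilcoxon matched-pairs test. Two-way interaction
ANOVA (genotype × age, genotype × deprivation) handles crossed designs,
with Sidák-corrected pairwise comparisons.

## The synthetic-experiment generator

No raw recordings are distributed with the studies this pipeline targets,
so `synthConfig()` + `simulateGridExperiment()` / `simulateLedExperiment()`
/ `simulateSrExperiment()` generate complete experiments with known ground
truth. The generator emulates:

* **EPSC waveforms** as peak-normalized differences of exponentials
  (`makeEpscKernel()`); compound evoked EPSCs use τ_rise = 2 ms,
  τ_decay = 15 ms; single quantal events are faster (τ 0.8/6 ms), as for
  miniature AMPAR EPSCs.
* **Binomial quantal release**: each stimulus releases
  Binomial(`n_sites` = 20, `p_release` = 0.5) quanta with lognormal sizes
  (mean 12 pA, CV 0.3). The closed-form CV of binomial release,
  √((1−p)/(Np)), anchors the coefficient-of-variation analysis.
* **A shared innervation field**: both cells of a pair draw their per-spot
  true amplitudes from one isotropic 2-D Gaussian (σ = 100 µm) peaked
  100 µm pia-ward of the soma — over the proximal apical dendrites — and
  the KO cell's synaptic amplitudes are multiplied by `ko_scale`
  (default 0.6, i.e. a 40 % reduction).
* **Shared presynaptic release**: within a pair, the per-sweep binomial
  release realization (counts and quantal sizes) is shared between the two
  cells, because neighbors receive the same axons and the same flash. A
  consequence used heavily in testing: with recording noise off, every
  downstream KO/WT ratio equals `ko_scale` *exactly*.
* **Synaptic latency**: synaptic responses begin `syn_latency` = 7 ms after
  the stimulus (presynaptic spike initiation plus conduction), while direct
  responses begin at 2 ms with a 20–80 % rise time well under 1 ms, so the
  "< 5 ms and fast kinetics" classification rule is discriminative by
  construction. Direct responses occur only within 50 µm of the soma, only
  in LSPS and AP-map modes (sCRACM in TTX/4-AP has none), with probability
  `direct_frac` per spot.
* **Asynchronous release** in Sr²⁺: spontaneous events are a homogeneous
  Poisson process (1.3 Hz); evoked events follow an exponentially decaying
  intensity r₀·exp(−t/τ), τ = 100 ms, with r₀ calibrated by
  `evokedRateForWindow()` so the mean rate over the 50–350 ms window is
  8.3 Hz. The knockout effect in this mode is a reduction of evoked
  *frequency* (scaled so the KO window rate is 6.7 Hz) with unchanged
  quantal amplitude; spontaneous quanta average 12 pA and evoked quanta
  15 pA.
* **Recording noise**: Gaussian, 3 pA SD for mapping sweeps and 2 pA for
  Sr²⁺ sweeps (quantal-event recordings require lower noise). LED bulk
  amplitudes are scaled (`bulk_scale` = 3.5) so wild-type means sit near
  420 pA, the few-hundred-pA range of power-adjusted bulk recordings.

Everything is sampled at 10 kHz (`dt` = 0.1 ms), which resolves
sub-millisecond direct-response rise times without large traces. The same
seed and configuration always produce a bit-identical dataset, and the
generator returns the per-sweep ground truth (true synaptic and direct
amplitudes; true event times and sizes) alongside the recordings.

**What the generator does not emulate.** Opsin kinetics and desensitization,
dendritic cable filtering (beyond the fixed kernel), series-resistance
artifacts, polysynaptic network activity, barrel-map anatomy, and any
correlation structure of biological noise. Tests passing on this generator
therefore validate the *analysis* — measurement, classification,
subtraction, alignment, masking, statistics — not the biology of real
recordings.

## Numerical and algorithmic choices

* **Windows are half-open** `[start, end)` in ms, times relative to the
  flash, so no sample or event is double-counted at a boundary. An event at
  +49.9 ms is neither spontaneous nor evoked.
* **Amplitude measurement.** Peaks of averaged EPSCs are read after a short
  boxcar low-pass (1 ms for bulk recordings, 0.5 ms for grid spots). The
  raw maximum of a noisy average is biased upward by noise maxima; in the
  paired design this bias inflates weak (KO) amplitudes relative to strong
  ones and shifts recovered ratios. The filter widths attenuate the
  compound-EPSC peak by well under 1 %.
* **Onset latency** is the first time the inward deflection stays beyond
  3 × the baseline noise SD for at least 0.5 ms — robust to single-sample
  noise. The 20–80 % rise time of the first component operationalizes
  "visibly faster" kinetics; responses with onset < 5 ms and rise < 1 ms
  (configurable `directRiseMax`) are direct.
* **Direct-response subtraction** fits A₁e^(−t/τ₁) + A₂e^(−t/τ₂) to the
  decay of the direct component by Levenberg–Marquardt (`minpack.lm`),
  initialized by a log-linear peel, with τ ∈ [0.05, 100] ms and free
  amplitudes (the post-peak rise term of a difference of exponentials is
  negative). The fit region stops where the smoothed decay reaches the
  noise floor, and for mixed responses 1 ms short of the trough before the
  synaptic component. A candidate fit whose *slower* component has negative
  amplitude is rejected as a cancellation artifact, because its
  extrapolated tail is meaningless. The fitted decay is subtracted over the
  analysis window (clamped to a decaying, non-negative course); the stretch
  from direct onset to the end of the fitted region — direct-only by
  construction — is zeroed. Pure direct responses are additionally flagged
  and excluded from maps, mirroring deleted pixels; a fit whose residual
  RMS exceeds the noise floor flags the response unusable instead.
* **Event detection** re-implements standard threshold-crossing mEPSC
  detection (the original analyses used closed-source MiniAnalysis): local
  minima of a lightly smoothed trace whose amplitude relative to a local
  pre-event baseline exceeds `kSigma` = 3 × the noise SD, sustained beyond
  threshold ≥ 0.5 ms, separated by ≥ `minIei` = 2 ms (closer troughs merge
  into the larger event; rising-phase noise blips deduplicate by onset).
  The noise SD comes from the median absolute successive difference, which
  ignores the slow event waveforms riding on the noise. Event time is the
  20 % rising-phase crossing (an onset estimate), so window boundaries are
  not shifted by the kernel's time to peak; amplitude is read from a local
  quadratic fit (±1 ms) around the trough rather than the raw minimum.
* **Alignment and interpolation** share one bilinear resampling primitive.
  Mask propagation is conservative: an output pixel touching any masked
  contributor is masked, so interpolation never fabricates values where
  direct responses were deleted. Group averaging runs on interpolated,
  aligned maps (matching the halved display pixels, 25 × 25 µm for sCRACM
  and 25 × 30 µm for LSPS); per-cell statistics (region means, vertical
  profiles) use un-interpolated maps. Per-cell maps are power-normalized
  before genotype averaging by default.
* **Normality gate**: α = 0.05 per test (the gating rule itself specifies
  no level; 0.05 is the conventional default, configurable). Below n = 8
  pairs, omnibus normality tests are uninformative, so the gate skips to
  Wilcoxon with a warning. The D'Agostino–Pearson omnibus statistic is
  implemented from the standard Z(√b₁)/Z(b₂) transformations and checked
  against an independent reference implementation; Anderson–Darling comes
  from `nortest`.
* **Vertical profiles** are compared per row and with the two-way
  interaction ANOVA; a random-effects profile model is out of scope since
  its structure is not specified by the protocols this package follows.

## Validation sizes and what they show

The acceptance-level checks (also in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`) use: 20 replicate 15-pair experiments for ratio
recovery; 1,000 replicate null experiments for the gated test's type-I
error; 100 seeded traces for direct-subtraction accuracy (4-sweep averages,
the upper repeat count of the grid protocols); 1,000 sweeps per rate at
0.5–15 Hz with fixed 15 pA quanta (≥ 4 × noise SD) for detector bias,
compared against the generator's realized ground-truth event lists so
Poisson sampling noise cancels; 10,000 trials for the binomial CV; and 200
datasets × 10,000 sign-flip permutations for the gated-vs-permutation
agreement. On one CPU the whole suite runs in a few minutes.

## Known limitations

* Trace-minima event detection cannot resolve events closer than the
  quantal kernel's time to peak (~2 ms); at instantaneous rates above
  ~20 Hz — e.g. at the very start of a strongly peaked evoked window —
  a few percent of events merge. Recovered evoked rates under the default
  Sr²⁺ conditions run ~3–6 % low for this reason.
* The windowed peak of a noisy average retains a small positive bias on
  weak grid pixels even after smoothing; single-spot KO/WT ratios are
  therefore slightly compressed toward 1 at low SNR. Paired comparisons of
  region means and bulk amplitudes, where signals are far above noise, are
  unaffected in practice.
* Barrel rectangles for LSPS alignment are user-supplied metadata, as in
  DIC-based annotation; there is no automatic barrel segmentation.
* The statistics module controls error rates per comparison; it does not
  correct across the many metrics a study reports.

## A worked example

```{r example, eval = FALSE}
cfg <- pipelineConfig("sCRACM",
                      synth = synthConfig(n_pairs = 15, ko_scale = 0.6),
                      seed = 1)
res <- runPipeline(cfg)
res@tests          # gated paired comparison of proximal region means
res@groupMaps$WT   # genotype-average map, 25 x 25 um pixels, min n = 8
verticalProfile(res@cellMaps[[1]])
```
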