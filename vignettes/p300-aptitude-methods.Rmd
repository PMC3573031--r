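---
title: "Simulating and predicting P300 speller aptitude: models and methods"
author: "p300aptitude"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and predicting P300 speller aptitude: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p300aptitude)
```

## The scientific question

P300 spellers let a user select letters from a 5x5 matrix by attending
to row and column stimuli: the attended (rare, task-relevant) stimulus
elicits an event-related potential (ERP) complex, and a classifier sums
evidence over stimulus repetitions until the attended row and column —
and hence the letter — can be identified. Users differ widely in how
well this works for them. The question this package operationalises is
whether that *aptitude* can be predicted from a five-minute passive
auditory oddball recording made before any speller use: do features of
the oddball ERP (the fronto-central N200, the P300, a late
anterior-negative/posterior-positive slow wave) rank-correlate with the
number of stimulus repetitions a user later needs to reach 70% letter
accuracy?

Because no public recordings of such a protocol exist, the package is
built around a synthetic-data generator that plants exactly this
correlation structure, plus the full analysis chain: preprocessing,
stepwise linear discriminant analysis (SWLDA) classification, offline
performance evaluation, ERP component detection and rank-correlation
analysis. Everything the analysis claims about recovery of planted
effects is demonstrated by the test suite and the acceptance script on
simulated cohorts — never asserted.

## The synthetic participant model

A participant is a latent aptitude $a \sim U(0,1)$ plus per-component
ERP parameters. Each component is a Gaussian bump
$A\,\exp(-(t-\ell)^2/2w^2)$ in time, scaled by a smooth spatial map over
the electrode montage (unit maximum absolute weight). Components:

| component | amplitude (uV) | latency (ms) | width (ms) | role |
|---|---|---|---|---|
| N1 | $-1.2 \pm 0.25$ | $105 \pm 8$ | 20 | exogenous, all stimuli |
| P2 | $+2.2 \pm 0.4$ | $180 \pm 10$ | 30 | exogenous, all stimuli |
| N2 | $-(1.42 + 3.66a) \pm 1.98$ | $229 \pm 43$ | 32 | target only, aptitude-linked |
| P3 | $+4.99 \pm 2.66$ | $378 \pm 89$ | 50 | target only, independent of aptitude |
| late slow wave | $+(1.94 + 3.35a) \pm 1.86$ | $549 \pm 80$ | 80 | target only, aptitude-linked |

The N2/late link coefficients were chosen so that the population mean
and SD of |N2| are about 3.25 and 2.25 uV (and 3.61/2.10 uV for the
late component) while the implied Spearman correlation with aptitude is
0.47 (N2) and 0.46 (late) — the reported effect sizes this design is
meant to make recoverable. `planted_link_rho()` returns the implied
rank correlations, evaluated once by Monte Carlo with $10^6$ draws.
P3 amplitude is deliberately drawn independently of aptitude: the
planted null.

Latencies are drawn around the reported group means but with the
component order enforced (N2 at least 110 ms before P3, the late wave
at least 90 ms after it). Without this separation an early-latency P3
bump overlaps and cancels the N2 at Cz, and the specified sequential
peak detection (below) cannot recover the planted link even from
noiseless data — a genuine identifiability constraint of the detection
procedure, not a convenience.

The late slow wave is anterior-negative and posterior-positive
(posterior lobe centred near POz minus a weaker frontal lobe); N1/N2
are fronto-central, P3 centro-parietal, matching the usual topography
of these components.

### Speller sessions

The oddball session uses the planted components as drawn. Speller
sessions scale them per modality: visual targets keep the N2 and late
wave at full size with the P3 and exogenous complex attenuated
(latencies scaled by 309/378); auditory targets are attenuated further
and delayed (latency scale 508/378), with the N1–P2 complex almost
absent — the auditory speller's spoken-number stimuli do not elicit the
sharp onset response of tones. Two deliberate choices:

* **Speller P3 amplitude is fixed at the population mean (4.99 uV) for
  everyone.** Individual speller performance then derives from the
  attention-linked N2 and late components, so the oddball P3 — which
  *is* individual — stays uncorrelated with performance. This is the
  generative mechanism behind the reported dissociation (performance
  predicted by N2/late but not by P3); a generator in which the
  speller response simply reused the individual P3 would contradict it.
* **Speller latencies shrink individual deviations toward the modality
  mean (factor 0.35).** The reported between-group latency differences
  in the spellers are an order of magnitude smaller than the oddball
  latency SDs; full latency variance would also inject
  performance variance unrelated to the planted amplitudes.

### Background activity

Noise has four parts, all seeded and reproducible:

* **Spatially correlated 1/f sources** — six sources with random smooth
  scalp topographies, per-channel RMS `2 * noise_sigma`. These model
  the common-mode background a spatial classifier cannot average away;
  with only independent per-channel noise, SWLDA over many channels
  becomes unrealistically good and every simulated user saturates.
* **Independent per-channel 1/f noise** at `0.6 * noise_sigma` RMS.
* **Posterior alpha**: an amplitude-modulated 10 Hz sinusoid
  (`alpha_power`, default 2 uV).
* **Blinks**: Poisson (default 4/min) raised-cosine transients of
  200–400 ms, about 120 uV at the forehead, mirrored with opposite
  polarity into the vertical EOG pair.

`noise_sigma` defaults to 5 uV. The calibration constraint is the
measured scale: with 60 deviant trials averaged, the nose-referenced
Cz average carries little enough residual noise that the *measured*
N2 SD across a cohort (about 1.8–2 uV) approaches the planted 2.1 uV
and the reported 2.25 uV; substantially larger noise compresses the
measured between-subject spread below what the study tabulates. At the
same time the correlated-noise level puts full-length speller sessions
in the reported operating regime (visual accuracy near ceiling with
repetitions-to-criterion of a few; auditory around 60% at 15
repetitions). These values were fixed once, during generator
calibration, before the acceptance checks were frozen.

Trial-to-trial variability multiplies each planted response by a
Gaussian factor (SD `amp_jitter = 0.12`). Setting `noise_sigma`,
`alpha_power`, `ocular_rate` and `amp_jitter` to zero yields exactly
the planted template — the basis of the noiseless-recovery tests.

## Preprocessing

The offline chain is fixed: zero-phase FIR band-pass, AMUSE-based
ocular artifact removal, common average reference, epoching (0–800 ms)
with baseline correction (−100–0 ms). `preprocess_session()` runs it
and records the stage order.

* **Filtering.** High-pass at 0.5 Hz then low-pass at 20 Hz, each a
  linear-phase least-squares FIR applied forward and backward (zero
  phase; the effective response is the squared magnitude). Orders
  follow the classic heuristic of 3 x rate/cutoff taps. The low-pass is
  designed by solving the band-restricted least-squares normal
  equations in closed form, with a transition band of 15% of the cutoff
  but never narrower than the kernel's frequency resolution; the
  high-pass is its spectral inversion with the DC gain normalised to
  exactly one, so constant offsets are removed exactly. Edges are
  handled by odd reflection padding of one total kernel length, and the
  whole cascade is evaluated in a single FFT round per channel.
* **AMUSE.** Whiten via the eigendecomposition of the zero-lag
  covariance, then eigendecompose the symmetrised lag-1 covariance of
  the whitened data; components are ordered by decreasing lagged
  eigenvalue. Rank-deficient covariances are ridge-regularised with a
  warning. Components whose absolute correlation with either bipolar
  EOG derivation (above-minus-below eye; left-minus-right canthus)
  exceeds 0.7 are zeroed; the EEG is reconstructed from the rest and
  EOG channels pass through. The decomposition runs once per session
  (configurable), on the EEG channels only.
* **Reference.** The classifier pipeline re-references to the common
  average. For ERP *peak measurement* the package defaults to the
  recording (nose) reference: whether the tabulated peaks were measured
  before or after re-referencing is not documented, peak norms are
  conventionally nose-referenced, and on reduced montages the common
  average subtracts a large fraction of the broad central components —
  halving the measured between-subject N2 spread relative to the
  tabulated SD. `preprocess_session(reference = "nose")` selects this.
* **Epochs** are half-open sample windows `[onset, onset + 400)` at
  500 Hz with 0-based sample indices; events too close to a recording
  edge are dropped with a message.

## Classification and evaluation

Features are per-channel trailing moving averages (width 25 samples)
decimated by 25 — 16 bins per channel, 1008 features over 63 EEG
channels at 500 Hz; EOG channels never enter the feature space. SWLDA
regresses the ±1 class label on the features: each iteration adds the
excluded feature with the smallest partial-F p-value if below
`p_enter = 0.10`, then repeatedly removes included features whose
p-value exceeds `p_remove = 0.15`, stopping after at most 60 additions
or when nothing qualifies; if nothing enters on the first step, model
generation fails (a typed error). The published thresholds for this
paradigm are unrecoverable from the source text, so the conventional
P300-speller values are the defaults, configurable. An intercept is
used during fitting but not stored: scoring is a pure weighted sum, and
row/column argmax selection is invariant to per-trial constants, so no
bias term is needed. Ties in the argmax go to the lower index.

Offline evaluation reclassifies each six-run session in a
leave-one-run-out loop (every letter scored exactly once by a model
that never saw its run), computes accuracy as a function of the number
of repetitions k (selection from the first k sequences only), and
linearly interpolates the repetitions needed for 70% accuracy,
anchoring at (0, 0) when accuracy is already at criterion after one
repetition. Participants who never reach criterion get `NA`;
`reps_for_ranking()` maps this to the sentinel `max_reps + 1` (16 at
the defaults) so rank statistics keep them ordered worst without
discarding them. Selection time is
`reps x 10 x SOA + 2.4 s` with SOA 240 ms (visual) or 1000 ms
(auditory).

Two transfer rates are implemented: Pierce's symmetric-channel formula,
and the mutual information between a uniform target and the selection
under the empirical selection-offset distribution (the 9x9 histogram of
row/column offsets), with offsets clipped and renormalised to the cells
reachable from each target. The mutual-information rate is bounded by
log2(25) bits/selection and equals Pierce's only when errors are
uniform over the non-target symbols; row/column spellers concentrate
errors on the target's row and column, which is the reason both are
provided.

## ERP features and aptitude prediction

Component detection is strictly sequential on the target-average
waveform: P300 = maximum at Cz in 250–700 ms; N200 = minimum at Cz
before the P300 latency (search floor 0 ms, configurable); late
component = maximum at POz after the P300 latency up to the end of the
epoch. Latencies are reported on the sample grid with no sub-sample
fitting. Degenerate windows (flat input, P300 on a window edge) are
flagged rather than silently reported.

`spearman_map()` computes, per channel and time bin, the mid-rank
Spearman correlation between oddball target amplitudes and the
performance metric, with signed $r^2 = \mathrm{sign}(\rho)\rho^2$ and
two-sided p from the t approximation. Because the metric counts
repetitions, *positive* correlations mean higher amplitude goes with
worse performance. `median_split()` assigns participants at or below
the median (fewer repetitions = better) to the high-aptitude group.
Raw p-values are reported, as in the original analysis; an optional
Benjamini–Hochberg layer (`spearman_map(..., p_adjust = "BH")`) is
available as a clearly-labelled extension and is deliberately off by
default.

## Problem sizes used by the tests and the acceptance script

The full protocol (63 + 4 channels at 500 Hz, three oddball runs, six
speller runs of five letters and fifteen sequences each, both
modalities) is what the defaults generate, and single full-schedule
sessions are exercised in the tests. The repeated end-to-end studies
use scaled-down conditions chosen as the package's own compromise
between statistical meaning and runtime: a 12-channel spread montage
(frontal through occipital midline/paramedian sites, so the common
average retains component contrast), 80 Hz sampling (50 ms feature bins
stay exact at 4 samples), two oddball runs, and a visual session of two
runs x three letters x eight sequences. One hundred such 40-participant
replicates verify that (i) the planted |N2|–aptitude rank correlation
lies inside the 95% sampling interval of its estimates, both from the
drawn profiles and as measured through the entire
simulate–preprocess–detect pipeline; (ii) the planted P3 null is
retained at the 5% level in at least 90% of replicates; and (iii)
larger measured |N2| predicts fewer repetitions-to-criterion in the
clear majority of replicates. The pipeline-measured link is attenuated
relative to the planted value (peak-picking on noisy 40-trial averages
adds measurement noise), which is why the sampling-interval check —
not a point comparison — is the right acceptance form. The acceptance
script's demonstration cohort uses ten participants at 100 Hz with the
full session schedule in both modalities.

## Numerical and interface choices

* 0-based sample indices in event tables; half-open `[start, end)`
  time windows in ms throughout.
* The letter matrix is the latin alphabet without Z, filled row-major
  (A–Y); the original layout beyond "5x5 without Z" is not documented,
  so this assumption is stated rather than asserted.
* Oddball deviants occupy a uniformly random position within each
  five-tone sequence; visual speller sequences are random permutations
  of the ten row/column stimuli, auditory sequences present rows 1–5
  then columns 1–5 in fixed order.
* The auditory speller SOA is exactly 450 + 550 ms = 1 s; the 2.4 s
  pause sits between letter selections only.
* Event onsets are rounded from cumulative real time, so schedules
  do not drift at sampling rates where the SOA is a fractional number
  of samples.
* EDF export uses 16-bit samples with per-channel symmetric physical
  ranges (round-trip error at most half a quantisation step); the
  event table, channel roles/positions, reference state and exact
  sample count travel in a JSON sidecar and round-trip exactly.
* `run_study()` output tables carry an MD5 hash of the configuration;
  `write_study()` refuses to overwrite a directory written under a
  different hash.

## Limitations

The generator plants Gaussian bumps with fixed widths and stationary
noise; real EEG has non-stationary rhythms, session effects,
habituation and learning, none of which are modelled (deliberately —
the study design holds sequence counts fixed partly to avoid them).
Passing recovery tests therefore demonstrates that the analysis chain
is correct and well-calibrated under the stated generative assumptions,
not that the predictor works on real recordings. The simulated
selection-error structure reproduces the row/column concentration of
errors qualitatively, but its exact spatial profile depends on the
noise model. Correlation values printed by the acceptance script for
the ten-participant demonstration cohort are illustrative summaries at
small n, not estimates of the large-cohort effect sizes.
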