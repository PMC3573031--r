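# p300aptitude

Simulation and analysis tools for predicting P300 brain–computer
interface (BCI) aptitude from a passive auditory oddball recording.

P300 spellers select letters from a 5×5 matrix by flashing (visual) or
speaking (auditory) row and column cues; the attended cue elicits an
event-related potential (ERP) complex and a linear classifier sums
evidence over stimulus repetitions. Users differ strongly in attainable
performance, and screening candidates with a five-minute passive
oddball — instead of full speller sessions — would let clinicians pick
a suitable paradigm quickly. This package implements that analysis as a
fully tested, simulation-backed pipeline for methods researchers:

* a **seeded synthetic-EEG generator** that plants N1/P2/N2/P3/late
  slow-wave components whose amplitudes covary with a latent aptitude
  (|N2| and the late wave linked with Spearman ρ ≈ 0.47/0.46, P3
  independent — the planted null), on top of spatially correlated 1/f
  noise, posterior alpha and blinks mirrored into EOG channels;
* **preprocessing**: zero-phase least-squares FIR band-pass
  (0.5–20 Hz), AMUSE blind source separation with bipolar-EOG
  correlation gating for ocular artifact removal, common average
  reference, 0–800 ms epochs with −100–0 ms baseline correction;
* **SWLDA classification**: trailing moving-average features (width 25,
  decimation 25; 63 × 16 = 1008 features at 500 Hz), forward/backward
  partial-F stepwise regression (p_enter 0.10, p_remove 0.15, ≤ 60
  steps), bias-free row/column argmax letter selection;
* **performance evaluation**: leave-one-run-out cross validation,
  accuracy versus repetitions, linearly interpolated
  repetitions-to-70%-criterion, selection timing, and both transfer
  rates — Pierce’s formula and mutual information over the empirical
  5×5 selection-offset distribution;
* **ERP feature extraction**: sequential peak detection (P300 = max at
  Cz in 250–700 ms, N200 = min before it at Cz, late = max after it at
  POz) and group statistics;
* **aptitude prediction**: median splits, channel × time Spearman
  correlation maps with signed r², and component-level correlation
  tables, with an end-to-end `run_study()` orchestrator.

The core statistic is the mid-rank Spearman correlation between
oddball component amplitudes and the per-participant
repetitions-to-criterion metric (lower = better), reported per
channel/time cell as signed r² = sign(ρ)·ρ², and the
mutual-information transfer rate
I(target; selection) · selections/min with targets uniform over the
matrix and the selection distribution induced by the offset histogram.

## Worked example

```r
library(p300aptitude)

profile <- make_participant(seed = 42, aptitude = 0.8)
profile
#> Participant P042  (aptitude 0.800, seed 42)
#>   N1     -0.82 uV @ 104.2 ms (width 20 ms)
#>   P2      3.01 uV @ 179.4 ms (width 30 ms)
#>   N2     -7.06 uV @ 256.0 ms (width 32 ms)
#>   P3      3.49 uV @ 414.0 ms (width 50 ms)
#>   late    5.30 uV @ 540.2 ms (width 80 ms)
#>   noise 5 uV, alpha 2 uV, 4 blinks/min, jitter 0.12

tc <- timing_config(sampling_rate_hz = 100)   # scaled-down rate
mont <- montage("reduced")                    # 16 EEG + 4 EOG channels

oddball <- simulate_oddball_session(profile, tc, seed = 1, montage = mont)
epochs  <- preprocess_session(oddball, reference = "nose")
detect_components(average_erp(epochs, "target"))
#>   n200_amp_uV n200_lat_ms p300_amp_uV p300_lat_ms late_amp_uV late_lat_ms degenerate
#> 1   -7.505533         250    2.747897         440     5.78043         510      FALSE

speller <- simulate_bci_session(profile, "visual", tc, seed = 2, montage = mont)
scores  <- cross_validate(preprocess_session(speller), ma_width = 5, decim = 5)
curve   <- accuracy_vs_repetitions(scores)
curve
#> Accuracy over 30 letters:
#>     1     2     3     4     5     6     7     8     9    10    11    12    13    14    15
#>  46.7  70.0  80.0  86.7  93.3  96.7  96.7  96.7 100.0 100.0 100.0 100.0 100.0 100.0 100.0

reps_to_criterion(curve)
#> [1] 2
selection_time(2, "visual")
#> $seconds
#> [1] 7.2
#> $selections_per_min
#> [1] 8.333333
```

The high-aptitude participant’s planted N2 (−7.06 uV at 256 ms) is
recovered by the sequential detector from the noisy deviant average
(−7.51 uV at 250 ms on the 10 ms sample grid), reaches 70% letter
accuracy after 2 interpolated repetitions (7.2 s per letter, 8.3
selections/min), and is at ceiling from nine repetitions on. A full
cohort with both speller modalities, correlation maps and
component–performance tables is one call:

```r
study <- run_study(study_config(n_participants = 10, montage = "reduced",
                                timing = list(sampling_rate_hz = 100),
                                ma_width = 5, decim = 5))
study          # per-modality accuracy, repetitions-to-criterion, ITR, rho table
write_study(study, "study-out/")
```

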