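# Shared fixtures: everything is generated in code at test time.

# profile with every stochastic ingredient switched off: sessions then
# contain exactly the planted templates
quiet_profile <- function(seed = 1, aptitude = 0.7) {
  make_participant(seed, aptitude = aptitude, noise_sigma = 0,
                   alpha_power = 0, ocular_rate = 0, amp_jitter = 0)
}

# 12-channel spread montage used for scaled-down simulation studies
test_montage <- function() {
  montage(c("F3", "Fz", "F4", "FC5", "FC1", "Cz", "C2", "Pz",
            "PO7", "POz", "PO2", "Oz"))
}

# scaled-down timing: 80 Hz keeps 50 ms feature bins (4 samples) exact
rep_timing_oddball <- function() {
  timing_config(sampling_rate_hz = 80, oddball_runs = 2)
}
rep_timing_speller <- function() {
  timing_config(sampling_rate_hz = 80, runs_per_session = 2,
                letters_per_run = 3, sequences_per_letter = 8)
}

# a synthetic epoch_set built directly from an array (no simulation)
make_epochs <- function(data, events = NULL, montage = NULL, srate = 500,
                        window_ms = c(0, 800)) {
  n_samp <- dim(data)[3]
  if (is.null(montage)) {
    labs <- paste0("ch", seq_len(dim(data)[2]))
    montage <- data.frame(label = labs, role = "eeg", x = 0, y = 0)
  }
  if (is.null(events))
    events <- data.frame(is_target = rep(TRUE, dim(data)[1]))
  structure(list(data = data, events = events, montage = montage,
                 srate = srate,
                 times_ms = window_ms[1] + (seq_len(n_samp) - 1L) * 1000 / srate,
                 window_ms = window_ms, baseline_ms = c(-100, 0),
                 n_dropped = 0L),
            class = "epoch_set")
}

# One scaled-down end-to-end study replicate: simulate a cohort, run the
# full pipeline (oddball -> preprocess -> component extraction; speller
# -> preprocess -> SWLDA cross-validation -> repetitions-to-criterion)
# and return per-participant truth and measured quantities.
run_replicate <- function(rep_seed, n = 40) {
  mont <- test_montage()
  tco <- rep_timing_oddball()
  tcs <- rep_timing_speller()
  out <- vector("list", n)
  for (i in seq_len(n)) {
    p <- make_participant((rep_seed * 1009 + i * 7) %% 2147483647)
    odd <- simulate_oddball_session(p, tco, seed = p$seed + 11, montage = mont)
    comp <- extract_oddball_amplitudes(
      preprocess_session(odd, reference = "nose"), "component_peaks")
    rec <- simulate_bci_session(p, "visual", tcs, seed = p$seed + 101,
                                montage = mont)
    sc <- cross_validate(preprocess_session(rec), ma_width = 4L, decim = 4L,
                         max_iter = 12L, require_runs = 2L)
    curve <- accuracy_vs_repetitions(sc)
    out[[i]] <- data.frame(
      aptitude = p$aptitude,
      n2_true = abs(p$components$N2$amp_uV),
      n2_meas = abs(comp$n200_amp_uV),
      p3_meas = comp$p300_amp_uV,
      late_meas = comp$late_amp_uV,
      reps70 = reps_for_ranking(reps_to_criterion(curve),
                                tcs$sequences_per_letter))
  }
  do.call(rbind, out)
}

spearman <- function(x, y) suppressWarnings(cor(x, y, method = "spearman"))
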