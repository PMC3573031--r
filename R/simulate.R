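# Add every planted stimulus response into the data matrix by direct
# block addition (in-place on the run matrix).
plant_events <- function(data, tmpl_t, tmpl_n, onsets0, is_tgt, scales) {
  n_t <- ncol(tmpl_t)
  for (k in seq_along(onsets0)) {
    cols <- (onsets0[k] + 1L):(onsets0[k] + n_t)
    data[, cols] <- data[, cols] +
      scales[k] * (if (is_tgt[k]) tmpl_t else tmpl_n)
  }
  data
}

empty_events <- function() {
  data.frame(sample_index = integer(), kind = character(),
             stimulus_index = integer(), is_target = logical(),
             sequence_index = integer(), letter_index = integer(),
             run_index = integer(), letter = character(),
             target_row = integer(), target_col = integer(),
             stringsAsFactors = FALSE)
}

#' Simulate an auditory oddball session
#'
#' Three runs (default) of 20 sequences of five tones each — four
#' standards and one deviant in a uniformly random position per sequence
#' — at a 960 ms onset-to-onset interval (160 ms tone + 800 ms ISI), so
#' one run carries 100 tone events over 96 s of stimulation and the
#' session 60 deviants + 240 standards. Deviants carry the participant's
#' full planted target response (N1, P2, N2, P3, late slow wave);
#' standards carry only the exogenous N1-P2 complex. Structured
#' background noise (1/f spectrum, posterior alpha, frontal blinks
#' mirrored into the EOG channels) is added per the profile.
#'
#' @param profile a [make_participant()] profile.
#' @param timing a [timing_config()].
#' @param seed RNG seed; identical inputs give a bit-identical recording.
#' @param montage montage data frame.
#' @return an [new_recording()] object (nose-referenced) whose event
#'   table has `kind` in `standard`/`deviant`, `is_target` true for
#'   deviants, 1-based `sequence_index` within run and `run_index`.
#' @export
simulate_oddball_session <- function(profile, timing = timing_config(),
                                     seed = profile$seed,
                                     montage = p300aptitude::montage("full")) {
  validate_timing(timing)
  srate <- timing$sampling_rate_hz
  soa <- (timing$oddball_tone_ms + timing$oddball_isi_ms) / 1000
  lead_n <- round(1.0 * srate)
  tail_n <- round(1.2 * srate)
  n_seq <- timing$oddball_sequences_per_run
  # onsets rounded from cumulative real time, so the schedule stays
  # aligned at sampling rates where the SOA is not a whole sample count
  rel_onsets <- as.integer(round((seq_len(5 * n_seq) - 1L) * soa * srate))
  run_len <- lead_n + as.integer(round(5 * n_seq * soa * srate)) + tail_n

  tmpl_t <- erp_template(profile, "target", "oddball", montage, srate)
  tmpl_n <- erp_template(profile, "nontarget", "oddball", montage, srate)

  with_seed(seed, {
    runs <- vector("list", timing$oddball_runs)
    ev_all <- vector("list", timing$oddball_runs)
    for (r in seq_len(timing$oddball_runs)) {
      data <- synth_background(profile, montage, run_len, srate)
      dev_pos <- sample.int(5, n_seq, replace = TRUE)
      n_ev <- 5L * n_seq
      scales <- if (profile$amp_jitter > 0)
        pmax(0, 1 + profile$amp_jitter * stats::rnorm(n_ev)) else rep(1, n_ev)
      onsets <- lead_n + rel_onsets
      seqs <- rep(seq_len(n_seq), each = 5L)
      is_dev <- rep(dev_pos, each = 5L) == rep(1:5, n_seq)
      kinds <- ifelse(is_dev, "deviant", "standard")
      data <- plant_events(data, tmpl_t, tmpl_n, onsets, is_dev, scales)
      runs[[r]] <- data
      ev_all[[r]] <- data.frame(
        sample_index = onsets, kind = kinds, stimulus_index = NA_integer_,
        is_target = kinds == "deviant", sequence_index = seqs,
        letter_index = NA_integer_, run_index = r, letter = NA_character_,
        target_row = NA_integer_, target_col = NA_integer_,
        stringsAsFactors = FALSE)
    }
    offsets <- cumsum(c(0L, vapply(runs, ncol, integer(1))))
    events <- do.call(rbind, lapply(seq_along(ev_all), function(r) {
      e <- ev_all[[r]]; e$sample_index <- e$sample_index + offsets[r]; e
    }))
    new_recording(do.call(cbind, runs), srate, montage, events, "nose")
  })
}

# Stimulus order of one speller sequence: visual flashes are a random
# permutation of the 10 row/column stimuli; the auditory speller presents
# first the five rows, then the five columns, in fixed order.
sequence_order <- function(modality, timing) {
  nr <- timing$matrix_rows; nc <- timing$matrix_cols
  stim <- rbind(data.frame(what = "row", index = seq_len(nr)),
                data.frame(what = "col", index = seq_len(nc)))
  if (modality == "visual") stim[sample.int(nrow(stim)), ] else stim
}

#' Simulate a P300 speller session
#'
#' Simulates the full copy-spelling session of one participant in one
#' modality: `runs_per_session` runs of `letters_per_run` letters, the
#' words BRAIN and POWER alternating across runs, with
#' `sequences_per_letter` sequences of 10 row/column stimuli per letter
#' selection and a 2.4 s pause between selections. Stimuli whose row or
#' column matches the current letter are targets and carry the
#' endogenous components; the auditory speller's components are
#' attenuated and delayed relative to the visual one, and rows are
#' presented before columns within each sequence.
#'
#' @inheritParams simulate_oddball_session
#' @param modality `"visual"` or `"auditory"`.
#' @param words words alternated across runs (their first
#'   `letters_per_run` letters are spelled).
#' @return an [new_recording()] object. Event `kind` is
#'   `row_flash`/`col_flash` (visual) or `row_spoken`/`col_spoken`
#'   (auditory); `stimulus_index` is the 1-based row or column index;
#'   `letter_index` counts letters across the session.
#' @export
simulate_bci_session <- function(profile, modality = c("visual", "auditory"),
                                 timing = timing_config(),
                                 seed = profile$seed + 1L,
                                 montage = p300aptitude::montage("full"),
                                 words = c("BRAIN", "POWER")) {
  modality <- match.arg(modality)
  validate_timing(timing)
  srate <- timing$sampling_rate_hz
  soa_s <- speller_soa_s(timing, modality)
  pause_n <- round(timing$inter_selection_pause_s * srate)
  lead_n <- round(1.0 * srate)
  n_seq <- timing$sequences_per_letter
  n_stim <- timing$stimuli_per_sequence
  # per-event onsets rounded from cumulative real time (no drift at
  # rates where the SOA is a fractional sample count)
  rel_onsets <- as.integer(round((seq_len(n_seq * n_stim) - 1L) *
                                   soa_s * srate))
  letter_n <- as.integer(round(n_seq * n_stim * soa_s * srate)) + pause_n
  kinds <- if (modality == "visual") c("row_flash", "col_flash")
           else c("row_spoken", "col_spoken")

  tmpl_t <- erp_template(profile, "target", modality, montage, srate)
  tmpl_n <- erp_template(profile, "nontarget", modality, montage, srate)

  with_seed(seed, {
    runs <- vector("list", timing$runs_per_session)
    ev_all <- vector("list", timing$runs_per_session)
    letter_counter <- 0L
    for (r in seq_len(timing$runs_per_session)) {
      word <- words[(r - 1L) %% length(words) + 1L]
      pos <- word_positions(word)[seq_len(timing$letters_per_run), ]
      run_len <- lead_n + nrow(pos) * letter_n + round(1.2 * srate)
      data <- synth_background(profile, montage, run_len, srate)
      ev <- vector("list", nrow(pos))
      run_onsets <- integer(0); run_tgt <- logical(0); run_scales <- numeric(0)
      for (li in seq_len(nrow(pos))) {
        letter_counter <- letter_counter + 1L
        t_row <- pos$row[li]; t_col <- pos$col[li]
        base <- lead_n + (li - 1L) * letter_n
        ord <- do.call(rbind, lapply(seq_len(n_seq), function(s)
          cbind(sequence_order(modality, timing), s = s)))
        onsets <- base + rel_onsets
        is_row <- ord$what == "row"
        is_tgt <- (is_row & ord$index == t_row) |
                  (!is_row & ord$index == t_col)
        scales <- if (profile$amp_jitter > 0)
          pmax(0, 1 + profile$amp_jitter * stats::rnorm(length(onsets)))
          else rep(1, length(onsets))
        run_onsets <- c(run_onsets, onsets)
        run_tgt <- c(run_tgt, is_tgt)
        run_scales <- c(run_scales, scales)
        ev[[li]] <- data.frame(
          sample_index = onsets,
          kind = ifelse(is_row, kinds[1], kinds[2]),
          stimulus_index = ord$index, is_target = is_tgt,
          sequence_index = ord$s, letter_index = letter_counter,
          run_index = r, letter = pos$letter[li],
          target_row = t_row, target_col = t_col,
          stringsAsFactors = FALSE)
      }
      runs[[r]] <- plant_events(data, tmpl_t, tmpl_n, run_onsets,
                                run_tgt, run_scales)
      ev_all[[r]] <- do.call(rbind, ev)
    }
    offsets <- cumsum(c(0L, vapply(runs, ncol, integer(1))))
    events <- do.call(rbind, lapply(seq_along(ev_all), function(r) {
      e <- ev_all[[r]]; e$sample_index <- e$sample_index + offsets[r]; e
    }))
    row.names(events) <- NULL
    new_recording(do.call(cbind, runs), srate, montage, events, "nose")
  })
}
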