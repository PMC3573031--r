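#' Session timing and layout parameters
#'
#' All stimulus-schedule constants of the study design in one validated
#' object. Defaults reproduce the published protocol: an auditory oddball
#' of 3 runs x 20 sequences x (4 standards + 1 deviant), 160 ms tones with
#' an 800 ms inter-stimulus interval (960 ms onset-to-onset, 96 s of
#' stimulation per run), and 5x5-matrix spellers with 15 sequences of 10
#' stimuli per letter selection: visual flashes of 80 ms + 160 ms
#' inter-flash interval (240 ms SOA, 38.4 s per letter including the
#' 2.4 s classification pause), auditory spoken numbers of 450 ms + 550 ms
#' ISI (1 s SOA, 150 s of stimulation per letter).
#'
#' @param ... named overrides of any default field.
#' @return An object of class `timing_config` (a validated named list).
#' @examples
#' tc <- timing_config()
#' oddball_run_duration_s(tc)        # 96
#' letter_selection_time_s(tc, "visual")  # 38.4
#' @export
timing_config <- function(...) {
  tc <- list(
    oddball_tone_ms = 160,
    oddball_isi_ms = 800,
    oddball_sequences_per_run = 20,
    oddball_runs = 3,
    vis_flash_ms = 80,
    vis_interflash_ms = 160,
    aud_stim_ms = 450,
    aud_isi_ms = 550,
    sequences_per_letter = 15,
    stimuli_per_sequence = 10,
    inter_selection_pause_s = 2.4,
    letters_per_run = 5,
    runs_per_session = 6,
    matrix_rows = 5,
    matrix_cols = 5,
    sampling_rate_hz = 500)
  dots <- list(...)
  bad <- setdiff(names(dots), names(tc))
  if (length(bad) > 0L)
    stop("unknown timing fields: ", paste(bad, collapse = ", "))
  tc[names(dots)] <- dots
  validate_timing(tc)
  structure(tc, class = "timing_config")
}

validate_timing <- function(tc) {
  dur <- c("oddball_tone_ms", "oddball_isi_ms", "vis_flash_ms",
           "vis_interflash_ms", "aud_stim_ms", "aud_isi_ms",
           "inter_selection_pause_s", "sampling_rate_hz")
  for (f in dur)
    if (!is.numeric(tc[[f]]) || tc[[f]] <= 0)
      stop("timing field ", f, " must be a positive number")
  if (tc$stimuli_per_sequence != tc$matrix_rows + tc$matrix_cols)
    stop("stimuli_per_sequence must equal matrix_rows + matrix_cols")
  invisible(tc)
}

#' @export
print.timing_config <- function(x, ...) {
  cat("Timing configuration:\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# stimulus-onset asynchrony (s) of one speller stimulus
speller_soa_s <- function(timing, modality) {
  switch(modality,
    visual = (timing$vis_flash_ms + timing$vis_interflash_ms) / 1000,
    auditory = (timing$aud_stim_ms + timing$aud_isi_ms) / 1000,
    stop("unknown modality: ", modality))
}

#' Derived schedule durations
#'
#' `oddball_run_duration_s` is the stimulation time of one oddball run
#' (sequences x 5 tones x onset-to-onset interval).
#' `letter_selection_time_s` is the span of one letter selection: for the
#' visual speller the full selection including the inter-selection pause
#' (15 x 10 x 0.24 s + 2.4 s = 38.4 s), for the auditory speller the
#' stimulation time excluding the pause (15 x 10 x 1 s = 150 s), matching
#' how each is conventionally quoted.
#'
#' @param timing a [timing_config()].
#' @param modality `"visual"` or `"auditory"`.
#' @return duration in seconds.
#' @export
oddball_run_duration_s <- function(timing) {
  soa <- (timing$oddball_tone_ms + timing$oddball_isi_ms) / 1000
  timing$oddball_sequences_per_run * 5 * soa
}

#' @rdname oddball_run_duration_s
#' @export
letter_selection_time_s <- function(timing, modality) {
  stim <- timing$sequences_per_letter * timing$stimuli_per_sequence *
    speller_soa_s(timing, modality)
  if (modality == "visual") stim + timing$inter_selection_pause_s else stim
}

#' The 5x5 speller letter matrix
#'
#' The latin alphabet without Z, filled row-major: rows and columns are
#' indexed 1..5 and letter (r, c) sits at position (r - 1) * 5 + c.
#'
#' @return a 5x5 character matrix.
#' @examples
#' matrix_letters()[2, 4]  # "I"
#' @export
matrix_letters <- function() {
  matrix(LETTERS[1:25], nrow = 5, ncol = 5, byrow = TRUE)
}

# (row, col) of each letter of a word in the 5x5 matrix
word_positions <- function(word) {
  letters_mat <- matrix_letters()
  chars <- strsplit(word, "")[[1]]
  idx <- match(chars, t(letters_mat))  # row-major linear index
  if (anyNA(idx)) stop("letters not in matrix: ", word)
  data.frame(letter = chars,
             row = (idx - 1L) %/% 5L + 1L,
             col = (idx - 1L) %% 5L + 1L)
}
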