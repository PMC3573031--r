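# subset the trials of a feature matrix
fm_subset <- function(fm, idx) {
  fm$values <- fm$values[idx, , drop = FALSE]
  fm$labels <- fm$labels[idx]
  fm$events <- fm$events[idx, , drop = FALSE]
  fm
}

#' Leave-one-run-out cross-validated stimulus scores
#'
#' Trains an SWLDA model on all runs but one and scores the held-out
#' run's stimulus epochs, rotating over runs so every letter selection
#' is scored exactly once by a model that never saw it.
#'
#' @param epochs an [epoch_and_baseline()] epoch set of a full speller
#'   session (events carry `run_index`).
#' @param p_enter,p_remove,max_iter SWLDA parameters.
#' @param ma_width,decim featurization parameters.
#' @param require_runs expected run count (default 6, the study's
#'   session layout); sessions with a different number of runs are
#'   rejected unless `require_runs` is set accordingly or `NULL`.
#' @param on_failure what to do when model generation fails in a fold
#'   (no feature reaches `p_enter`): `"error"` propagates the failure,
#'   `"zero_scores"` scores the held-out run as all zeros (chance-level
#'   selection), which is the useful behaviour for per-time-bin
#'   classification of uninformative windows.
#' @return a data frame of class `letter_scores`: the event rows plus a
#'   `score` column.
#' @export
cross_validate <- function(epochs, p_enter = 0.10, p_remove = 0.15,
                           max_iter = 60L, ma_width = 25L, decim = 25L,
                           require_runs = 6L,
                           on_failure = c("error", "zero_scores")) {
  on_failure <- match.arg(on_failure)
  runs <- sort(unique(epochs$events$run_index))
  if (!is.null(require_runs) && length(runs) != require_runs)
    stop("expected ", require_runs, " runs, got ", length(runs))
  if (length(runs) < 2L) stop("need at least two runs")
  fm <- featurize(epochs, ma_width, decim)
  out <- fm$events
  out$score <- NA_real_
  for (r in runs) {
    test <- which(fm$events$run_index == r)
    train <- which(fm$events$run_index != r)
    model <- tryCatch(
      swlda(fm_subset(fm, train), p_enter = p_enter,
            p_remove = p_remove, max_iter = max_iter),
      swlda_no_features = function(e) {
        if (on_failure == "error") stop(e)
        NULL
      })
    out$score[test] <- if (is.null(model)) 0
      else predict(model, fm_subset(fm, test))
  }
  class(out) <- c("letter_scores", "data.frame")
  out
}

#' Letter accuracy as a function of stimulus repetitions
#'
#' For k = 1..`max_reps`, selects every letter using only its first k
#' sequences of scores and reports the percentage of correct selections.
#'
#' @param scores a [cross_validate()] result (or any data frame with
#'   `score` plus the event columns).
#' @param max_reps number of repetitions to evaluate (defaults to the
#'   largest sequence index present).
#' @return object of class `accuracy_curve`: `accuracy_percent`
#'   (length `max_reps`), `n_letters`.
#' @export
accuracy_vs_repetitions <- function(scores, max_reps = NULL) {
  if (is.null(max_reps)) max_reps <- max(scores$sequence_index)
  letters <- unique(scores$letter_index)
  # per letter: accumulate row/column score sums over sequences once,
  # then take the argmax prefix-wise for every repetition count
  # (identical to calling select_letter() for each k; ties go to the
  # lower index because max.col/which.max return the first maximum)
  correct <- matrix(FALSE, length(letters), max_reps)
  for (li in seq_along(letters)) {
    rows <- scores$letter_index == letters[li]
    ev <- scores[rows, , drop = FALSE]
    use <- ev$sequence_index <= max_reps
    ev <- ev[use, , drop = FALSE]
    if (max(ev$sequence_index) < max_reps)
      stop("scores cover fewer sequences than max_reps")
    is_row <- grepl("^row", ev$kind)
    grp <- (!is_row) * 5L + ev$stimulus_index          # rows 1-5, cols 6-10
    sums <- rowsum(ev$score, grp + 10L * (ev$sequence_index - 1L))
    tab <- matrix(sums, nrow = 10)                     # grp x sequence
    cum <- if (ncol(tab) == 1L) tab else t(apply(tab, 1, cumsum))
    sel_row <- apply(cum[1:5, , drop = FALSE], 2, which.max)
    sel_col <- apply(cum[6:10, , drop = FALSE], 2, which.max)
    correct[li, ] <- sel_row == ev$target_row[1] & sel_col == ev$target_col[1]
  }
  structure(list(accuracy_percent = 100 * colMeans(correct),
                 n_letters = length(letters)),
            class = "accuracy_curve")
}

#' @export
print.accuracy_curve <- function(x, ...) {
  cat(sprintf("Accuracy over %d letters:\n", x$n_letters))
  print(round(stats::setNames(x$accuracy_percent,
                              seq_along(x$accuracy_percent)), 1))
  invisible(x)
}

#' @export
plot.accuracy_curve <- function(x, ...) {
  graphics::plot(seq_along(x$accuracy_percent), x$accuracy_percent,
                 type = "b", xlab = "stimulus repetitions",
                 ylab = "letter accuracy (%)", ylim = c(0, 100), ...)
  graphics::abline(h = 70, lty = 2)
  invisible(x)
}

#' Interpolated repetitions to reach the accuracy criterion
#'
#' The smallest number of stimulus repetitions at which letter accuracy
#' reaches the criterion (default 70%), linearly interpolated between
#' the bracketing integer repetition counts. If accuracy is already at
#' criterion after one repetition, interpolation anchors at (0, 0). If
#' the criterion is never reached, `NA` is returned;
#' [reps_for_ranking()] maps `NA` to the sentinel `max_reps + 1`
#' (16 at the defaults) for rank statistics.
#'
#' @param curve an [accuracy_vs_repetitions()] curve or a numeric vector
#'   of accuracies (percent) for repetitions 1, 2, ...
#' @param criterion criterion accuracy in percent.
#' @return repetitions as a (possibly non-integer) number, or `NA`.
#' @export
reps_to_criterion <- function(curve, criterion = 70) {
  acc <- if (inherits(curve, "accuracy_curve")) curve$accuracy_percent
         else as.numeric(curve)
  aug <- c(0, acc)                        # anchor at (0 repetitions, 0%)
  k <- which(aug >= criterion)[1]
  if (is.na(k)) return(NA_real_)
  if (k == 1L) return(0)                  # criterion 0 or negative
  x0 <- k - 2L; y0 <- aug[k - 1L]; y1 <- aug[k]
  x0 + (criterion - y0) / (y1 - y0)
}

#' @rdname reps_to_criterion
#' @param reps vector of [reps_to_criterion()] results.
#' @param max_reps repetitions available; the not-reached sentinel is
#'   `max_reps + 1`.
#' @export
reps_for_ranking <- function(reps, max_reps = 15) {
  ifelse(is.na(reps), max_reps + 1, reps)
}

#' Letter selection time and speed
#'
#' Selection time is `reps x stimuli_per_sequence x SOA +
#' inter-selection pause` (SOA 240 ms visual, 1000 ms auditory at the
#' default timing), and speed its reciprocal in selections per minute.
#'
#' @param reps (possibly fractional) stimulus repetitions per selection.
#' @param modality `"visual"` or `"auditory"`.
#' @param timing a [timing_config()].
#' @return list with `seconds` and `selections_per_min`.
#' @export
selection_time <- function(reps, modality, timing = timing_config()) {
  if (any(reps <= 0, na.rm = TRUE)) stop("reps must be positive")
  secs <- reps * timing$stimuli_per_sequence *
    speller_soa_s(timing, modality) + timing$inter_selection_pause_s
  list(seconds = secs, selections_per_min = 60 / secs)
}

#' Classification accuracy per post-stimulus time bin
#'
#' Splits the epoch window into non-overlapping bins of `bin_ms` and
#' trains/tests the classifier on each bin alone (one feature per
#' channel per bin), using the same leave-one-run-out cross validation.
#' Localises which latencies carry discriminative information.
#'
#' @param epochs a speller-session epoch set.
#' @param bin_ms bin width in ms; must divide the epoch window.
#' @param range_ms sub-window to analyse (defaults to the epoch window).
#' @param n_reps repetitions used for letter selection (default: all).
#' @param ... passed to [cross_validate()].
#' @return data frame with `bin_start_ms`, `bin_center_ms`,
#'   `accuracy_percent`.
#' @export
timewindow_accuracy <- function(epochs, bin_ms = 50, range_ms = NULL,
                                n_reps = NULL, ...) {
  if (is.null(range_ms)) range_ms <- epochs$window_ms
  span <- diff(range_ms)
  if (span <= 0 || span %% bin_ms != 0)
    stop("bin_ms must divide the analysis range")
  n_bins <- span %/% bin_ms
  bin_n <- round(bin_ms / 1000 * epochs$srate)
  if (bin_n < 1) stop("empty bin")
  acc <- numeric(n_bins)
  starts <- range_ms[1] + (seq_len(n_bins) - 1L) * bin_ms
  for (b in seq_len(n_bins)) {
    idx <- which(epochs$times_ms >= starts[b] &
                   epochs$times_ms < starts[b] + bin_ms)
    sub <- epochs
    sub$data <- epochs$data[, , idx, drop = FALSE]
    sub$times_ms <- epochs$times_ms[idx]
    sub$window_ms <- c(starts[b], starts[b] + bin_ms)
    sc <- cross_validate(sub, ma_width = length(idx), decim = length(idx),
                         on_failure = "zero_scores", ...)
    curve <- accuracy_vs_repetitions(sc, max_reps = n_reps)
    acc[b] <- utils::tail(curve$accuracy_percent, 1)
  }
  data.frame(bin_start_ms = starts, bin_center_ms = starts + bin_ms / 2,
             accuracy_percent = acc)
}

#' Pierce information transfer rate
#'
#' Bits per selection of the symmetric N-ary channel,
#' `log2 N + P log2 P + (1 - P) log2((1 - P) / (N - 1))`, times the
#' selection rate. `P = 1` is handled as the limit `log2 N`; accuracy
#' below chance returns 0 bits with a warning.
#'
#' @param accuracy selection accuracy as a fraction in \[0, 1\].
#' @param n_classes number of selectable symbols (25 for the 5x5 matrix).
#' @param selections_per_min selection rate; 1 gives bits per selection
#'   scaled to the minute trivially.
#' @return list with `bits_per_selection` and `bits_per_min`.
#' @export
pierce_itr <- function(accuracy, n_classes = 25, selections_per_min = 1) {
  if (accuracy < 0 || accuracy > 1) stop("accuracy must be in [0, 1]")
  if (accuracy < 1 / n_classes) {
    warning("accuracy below chance; reporting 0 bits")
    bits <- 0
  } else if (accuracy == 1) {
    bits <- log2(n_classes)
  } else {
    P <- accuracy
    bits <- log2(n_classes) + P * log2(P) +
      (1 - P) * log2((1 - P) / (n_classes - 1))
    bits <- max(bits, 0)
  }
  list(bits_per_selection = bits,
       bits_per_min = bits * selections_per_min)
}

#' Selection-offset error distribution
#'
#' Histogram of (selected - target) row/column offsets over all letter
#' selections, normalised to a probability distribution on the 9x9
#' offset grid (-4..+4 in each direction). Entry (0, 0) is the
#' correct-selection probability; row/column spellers concentrate error
#' mass on the zero-offset row and column.
#'
#' @param selections,targets data frames (or matrices) of `row`, `col`
#'   pairs, aligned by selection.
#' @return 9x9 matrix of class `error_offset_matrix` with dimnames
#'   giving the offsets.
#' @export
error_offset_matrix <- function(selections, targets) {
  selections <- as.data.frame(selections)
  targets <- as.data.frame(targets)
  if (nrow(selections) == 0L) stop("no selections")
  if (nrow(selections) != nrow(targets))
    stop("selections and targets must align")
  dr <- selections$row - targets$row
  dc <- selections$col - targets$col
  m <- matrix(0, 9, 9, dimnames = list(-4:4, -4:4))
  for (i in seq_along(dr))
    m[dr[i] + 5L, dc[i] + 5L] <- m[dr[i] + 5L, dc[i] + 5L] + 1
  structure(m / sum(m), class = c("error_offset_matrix", "matrix"))
}

#' Joint target/selection distribution implied by an offset matrix
#'
#' Treats the offset distribution as the channel's conditional error
#' structure: targets are uniform over the `n_rows x n_cols` matrix and,
#' given a target, selection probabilities follow the offset matrix
#' restricted (and renormalised) to the cells reachable from that
#' target position.
#'
#' @param offsets an [error_offset_matrix()] (9x9, offsets -4..4).
#' @param n_rows,n_cols matrix dimensions.
#' @return a `(n_rows * n_cols) x (n_rows * n_cols)` joint probability
#'   matrix (targets in rows, selections in columns).
#' @export
offset_joint_distribution <- function(offsets, n_rows = 5, n_cols = 5) {
  n_sym <- n_rows * n_cols
  joint <- matrix(0, n_sym, n_sym)
  p_t <- 1 / n_sym
  for (tr in seq_len(n_rows)) for (tc in seq_len(n_cols)) {
    ti <- (tr - 1L) * n_cols + tc
    cond <- matrix(0, n_rows, n_cols)
    for (sr in seq_len(n_rows)) for (sc in seq_len(n_cols))
      cond[sr, sc] <- offsets[sr - tr + 5L, sc - tc + 5L]
    s <- sum(cond)
    if (s == 0) stop("offset matrix unreachable from target ", ti)
    cond <- cond / s
    joint[ti, ] <- p_t * as.numeric(t(cond))
  }
  joint
}

#' Mutual information of a joint distribution, in bits
#'
#' @param joint matrix of joint probabilities (rows: targets, columns:
#'   selections), summing to 1.
#' @return mutual information I(target; selection) in bits.
#' @export
mutual_information_bits <- function(joint) {
  if (abs(sum(joint) - 1) > 1e-9) stop("joint must sum to 1")
  px <- rowSums(joint); py <- colSums(joint)
  terms <- joint * log2(joint / outer(px, py))
  sum(terms[joint > 0])
}

#' Mutual-information transfer rate
#'
#' The information transfer rate computed from the empirical
#' selection-offset distribution rather than the symmetric-channel
#' assumption: mutual information between a uniform target and the
#' selection under the offset-matrix channel, times the selection rate.
#' Upper-bounded by `log2(25)` bits/selection; equals the Pierce formula
#' only when errors are uniform over the non-target symbols.
#'
#' @param offsets an [error_offset_matrix()]; must be non-negative and
#'   sum to 1 within 1e-9.
#' @param selections_per_min selection rate.
#' @inheritParams offset_joint_distribution
#' @return list with `bits_per_selection` and `bits_per_min`.
#' @export
mutual_information_itr <- function(offsets, selections_per_min = 1,
                                   n_rows = 5, n_cols = 5) {
  if (any(offsets < 0)) stop("offset probabilities must be non-negative")
  if (abs(sum(offsets) - 1) > 1e-9)
    stop("offset probabilities must sum to 1")
  bits <- mutual_information_bits(
    offset_joint_distribution(offsets, n_rows, n_cols))
  list(bits_per_selection = bits,
       bits_per_min = bits * selections_per_min)
}
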