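# synthetic letter-score table: one row per stimulus event
synth_scores <- function(n_letters, n_seq, margin = 1, noise = 0,
                         seed = 1) {
  set.seed(seed)
  out <- NULL
  for (li in seq_len(n_letters)) {
    t_r <- sample(5, 1); t_c <- sample(5, 1)
    ev <- do.call(rbind, lapply(seq_len(n_seq), function(s)
      data.frame(kind = rep(c("row_flash", "col_flash"), each = 5),
                 stimulus_index = rep(1:5, 2), sequence_index = s)))
    ev$letter_index <- li
    ev$target_row <- t_r; ev$target_col <- t_c
    hit <- (grepl("row", ev$kind) & ev$stimulus_index == t_r) |
      (grepl("col", ev$kind) & ev$stimulus_index == t_c)
    ev$score <- margin * hit + rnorm(nrow(ev), sd = noise)
    out <- rbind(out, ev)
  }
  out
}

test_that("leave-one-run-out cross-validation scores every letter once", {
  tc <- timing_config(sampling_rate_hz = 80, runs_per_session = 6,
                      letters_per_run = 5, sequences_per_letter = 3)
  p <- make_participant(31, noise_sigma = 3)
  rec <- simulate_bci_session(p, "visual", tc, seed = 8,
                              montage = test_montage())
  ep <- preprocess_session(rec)
  sc <- cross_validate(ep, ma_width = 4, decim = 4, max_iter = 8)
  expect_equal(length(unique(sc$letter_index)), 30)   # 6 runs x 5 letters
  expect_false(anyNA(sc$score))
  expect_equal(nrow(sc), nrow(ep$events))
  # deterministic given fixed epochs and parameters
  sc2 <- cross_validate(ep, ma_width = 4, decim = 4, max_iter = 8)
  expect_identical(sc$score, sc2$score)
  # a session with a different run count is rejected at the default
  ep5 <- ep
  keep <- ep5$events$run_index <= 5
  ep5$data <- ep5$data[keep, , , drop = FALSE]
  ep5$events <- ep5$events[keep, , drop = FALSE]
  expect_error(cross_validate(ep5, ma_width = 4, decim = 4), "expected 6 runs")
})

test_that("accuracy curves behave at the separable and chance extremes", {
  sep <- synth_scores(10, 5, margin = 2, noise = 0.01)
  cv <- accuracy_vs_repetitions(sep)
  expect_equal(length(cv$accuracy_percent), 5)
  expect_true(all(cv$accuracy_percent == 100))
  # pure-noise scores select at the 1/25 chance level
  rnd <- synth_scores(400, 2, margin = 0, noise = 1, seed = 3)
  cvr <- accuracy_vs_repetitions(rnd)
  expect_gt(cvr$accuracy_percent[1], 0.5)
  expect_lt(cvr$accuracy_percent[1], 9)
  # full-data accuracy is invariant to sequence relabelling
  sh <- synth_scores(8, 6, margin = 0.3, noise = 0.6, seed = 4)
  cv1 <- accuracy_vs_repetitions(sh)
  sh2 <- sh
  for (li in unique(sh2$letter_index)) {
    rows <- sh2$letter_index == li
    perm <- sample(6)
    sh2$sequence_index[rows] <- perm[sh2$sequence_index[rows]]
  }
  cv2 <- accuracy_vs_repetitions(sh2)
  expect_equal(cv1$accuracy_percent[6], cv2$accuracy_percent[6])
})

test_that("repetitions-to-criterion interpolates as specified", {
  expect_equal(reps_to_criterion(c(20, 40, 65, 75, 80, rep(90, 10))), 3.5)
  expect_equal(reps_to_criterion(rep(100, 15)), 0.7)
  expect_true(is.na(reps_to_criterion(rep(60, 15))))
  expect_equal(reps_for_ranking(NA_real_), 16)
  expect_equal(reps_for_ranking(c(3.5, NA), max_reps = 8), c(3.5, 9))
  # exact on random piecewise-linear curves: invert the interpolation
  set.seed(5)
  for (i in 1:25) {
    acc <- sort(runif(15, 0, 100))
    r <- reps_to_criterion(acc, criterion = 70)
    if (is.na(r)) {
      expect_lt(max(acc), 70)
    } else {
      # the interpolated curve value at r equals the criterion
      aug <- c(0, acc)
      k <- floor(r)
      y <- aug[k + 1] + (r - k) * (aug[k + 2] - aug[k + 1])
      expect_equal(y, 70, tolerance = 1e-10)
      if (k >= 1) expect_lt(aug[k + 1], 70)
    }
  }
})

test_that("selection times reproduce the published conversions", {
  expect_equal(selection_time(15, "visual")$seconds, 38.4)
  expect_equal(round(selection_time(9.01, "auditory")$seconds, 1), 92.5)
  expect_equal(round(selection_time(12.80, "auditory")$seconds, 1), 130.4)
  expect_equal(round(selection_time(12.80, "auditory")$selections_per_min, 2),
               0.46)
  expect_equal(round(selection_time(1.73, "visual")$seconds, 1), 6.6)
  expect_equal(round(selection_time(5.10, "visual")$seconds, 1), 14.6)
  expect_error(selection_time(0, "visual"), "positive")
})

test_that("time-binned classification localises the planted components", {
  tc <- timing_config(sampling_rate_hz = 80, runs_per_session = 2,
                      letters_per_run = 3, sequences_per_letter = 5)
  p <- make_participant(33, noise_sigma = 2, alpha_power = 1,
                        ocular_rate = 2)
  rec <- simulate_bci_session(p, "visual", tc, seed = 12,
                              montage = test_montage())
  ep <- preprocess_session(rec)
  tw <- timewindow_accuracy(ep, bin_ms = 50, max_iter = 4, require_runs = 2)
  expect_equal(nrow(tw), 16)                     # 800 / 50
  expect_equal(tw$bin_center_ms[1], 25)
  # the best bin sits where the planted components live, not at epoch start
  tmpl <- erp_template(p, "target", "visual", test_montage(), 80)
  diff_cz <- tmpl["Cz", ] - erp_template(p, "nontarget", "visual",
                                         test_montage(), 80)["Cz", ]
  best <- tw$bin_center_ms[which.max(tw$accuracy_percent)]
  expect_gt(best, 100)
  expect_lt(best, 700)
  expect_gt(max(tw$accuracy_percent), tw$accuracy_percent[1])
  expect_error(timewindow_accuracy(ep, bin_ms = 70), "divide")
})

test_that("Pierce transfer rate matches its closed form", {
  expect_equal(pierce_itr(1, 25)$bits_per_selection, log2(25))
  expect_equal(pierce_itr(0.5, 2)$bits_per_selection, 0)
  P <- 0.945; N <- 25
  ref <- log2(N) + P * log2(P) + (1 - P) * log2((1 - P) / (N - 1))
  expect_equal(pierce_itr(P, N, 6)$bits_per_selection, ref)
  expect_equal(pierce_itr(P, N, 6)$bits_per_min, 6 * ref)
  expect_warning(out <- pierce_itr(0.01, 25), "chance")
  expect_equal(out$bits_per_selection, 0)
})

test_that("mutual-information transfer rate equals brute-force enumeration", {
  identity <- matrix(0, 9, 9); identity[5, 5] <- 1
  expect_equal(mutual_information_itr(identity)$bits_per_selection, log2(25))
  unif <- matrix(1 / 81, 9, 9)
  expect_equal(mutual_information_itr(unif)$bits_per_selection, 0,
               tolerance = 1e-12)
  three <- matrix(0, 9, 9)
  three[5, 5] <- 0.8; three[5, 6] <- 0.1; three[4, 5] <- 0.1
  expect_equal(mutual_information_itr(three, 2)$bits_per_selection,
               mi_bruteforce(three))
  expect_equal(mutual_information_itr(three, 2)$bits_per_min,
               2 * mi_bruteforce(three))
  set.seed(6)
  for (i in 1:5) {
    off <- matrix(rexp(81), 9); off <- off / sum(off)
    mi <- mutual_information_itr(off, 3)
    expect_equal(mi$bits_per_selection, mi_bruteforce(off))
    expect_lt(mi$bits_per_min, log2(25) * 3 + 1e-9)
  }
  bad <- matrix(1 / 81, 9, 9); bad[1, 1] <- 0.5
  expect_error(mutual_information_itr(bad), "sum to 1")
})

test_that("Pierce and mutual information agree on the symmetric channel", {
  P <- 0.85; N <- 25
  joint <- matrix((1 - P) / (N - 1) / N, N, N)
  diag(joint) <- P / N
  expect_equal(mutual_information_bits(joint),
               pierce_itr(P, N)$bits_per_selection)
})

test_that("error-offset matrices histogram selection errors", {
  sel <- data.frame(row = c(2, 2), col = c(3, 3))
  tgt <- data.frame(row = c(2, 2), col = c(3, 3))
  m <- error_offset_matrix(sel, tgt)
  expect_equal(sum(m), 1)
  expect_equal(m[5, 5], 1)
  sel10 <- data.frame(row = rep(3, 10), col = c(rep(3, 9), 4))
  tgt10 <- data.frame(row = rep(3, 10), col = rep(3, 10))
  m10 <- error_offset_matrix(sel10, tgt10)
  expect_equal(m10[5, 5], 0.9)
  expect_equal(m10["0", "1"], 0.1)
  expect_error(error_offset_matrix(sel[0, ], tgt[0, ]), "no selections")
})

test_that("row/column selection errors concentrate on the target's row and column", {
  set.seed(7)
  sel <- tgt <- NULL
  for (i in 1:600) {
    t_r <- sample(5, 1); t_c <- sample(5, 1)
    row_sc <- rnorm(5); row_sc[t_r] <- row_sc[t_r] + 1.2
    col_sc <- rnorm(5); col_sc[t_c] <- col_sc[t_c] + 1.2
    sel <- rbind(sel, data.frame(row = which.max(row_sc),
                                 col = which.max(col_sc)))
    tgt <- rbind(tgt, data.frame(row = t_r, col = t_c))
  }
  m <- error_offset_matrix(sel, tgt)
  same_axis <- sum(m[5, ]) + sum(m[, 5]) - m[5, 5]
  off_axis <- sum(m) - same_axis - m[5, 5]
  expect_gt(same_axis, off_axis)
})
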