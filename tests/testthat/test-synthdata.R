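test_that("participant profiles are deterministic and respect the aptitude link", {
  p_hi <- make_participant(1, aptitude = 0.9)
  p_lo <- make_participant(1, aptitude = 0.1)
  expect_gt(abs(p_hi$components$N2$amp_uV), abs(p_lo$components$N2$amp_uV))
  expect_gt(p_hi$components$late$amp_uV, p_lo$components$late$amp_uV)
  expect_identical(make_participant(7), make_participant(7))
  expect_error(make_participant(1, aptitude = 1.4), "aptitude")
  # component-sign and ordering invariants
  for (s in 1:20) {
    p <- make_participant(s)
    expect_lt(p$components$N2$amp_uV, 0)
    expect_gt(p$components$P3$amp_uV, 0)
    expect_gt(p$components$late$amp_uV, 0)
    expect_lt(p$components$N2$lat_ms, p$components$P3$lat_ms)
    expect_gt(p$components$late$lat_ms, p$components$P3$lat_ms)
  }
})

test_that("drawn population reproduces the reported N2 amplitude distribution", {
  prof <- draw_cohort(40, seed = 11)
  n2 <- vapply(prof, function(p) p$components$N2$amp_uV, numeric(1))
  expect_lt(abs(mean(n2) - (-3.25)), 3 * 2.25 / sqrt(40))
  expect_gt(sd(n2), 1.4)
  expect_lt(sd(n2), 3.0)
})

test_that("aptitude link calibration matches the configured rank correlation", {
  prof <- draw_cohort(250, seed = 21)
  apt <- vapply(prof, function(p) p$aptitude, numeric(1))
  n2 <- vapply(prof, function(p) abs(p$components$N2$amp_uV), numeric(1))
  late <- vapply(prof, function(p) p$components$late$amp_uV, numeric(1))
  expect_lt(abs(spearman(n2, apt) - planted_link_rho()[["n2"]]), 0.12)
  expect_lt(abs(spearman(late, apt) - planted_link_rho()[["late"]]), 0.12)
})

test_that("component topographies have unit maximum and zero EOG weight", {
  m <- montage()
  for (cmp in c("N1", "P2", "N2", "P3", "late")) {
    w <- component_topography(cmp, m)
    expect_equal(max(abs(w)), 1)
    expect_true(all(w[m$role == "eog"] == 0))
  }
})

test_that("oddball sessions follow the 3 x 20 x (4+1) schedule", {
  tc <- timing_config()
  expect_equal(oddball_run_duration_s(tc), 96)
  p <- make_participant(3)
  rec <- simulate_oddball_session(p, rep_timing_oddball(), seed = 5,
                                  montage = test_montage())
  ev <- rec$events
  expect_equal(nrow(ev), 200)            # 2 runs x 100 tones here
  for (r in unique(ev$run_index)) {
    run <- ev[ev$run_index == r, ]
    expect_equal(nrow(run), 100)
    expect_equal(sum(run$kind == "deviant"), 20)
    expect_equal(sum(run$kind == "standard"), 80)
    expect_true(all(diff(run$sample_index) > 0))
    # exactly one deviant per 5-tone sequence
    expect_true(all(tapply(run$kind == "deviant", run$sequence_index, sum) == 1))
  }
  # determinism: identical profile/timing/seed give identical recordings
  rec2 <- simulate_oddball_session(p, rep_timing_oddball(), seed = 5,
                                   montage = test_montage())
  expect_identical(rec$data, rec2$data)
  expect_identical(rec$events, rec2$events)
})

test_that("full-schedule sessions conserve the published event counts and spans", {
  tc <- timing_config()
  expect_equal(letter_selection_time_s(tc, "visual"), 38.4)
  expect_equal(letter_selection_time_s(tc, "auditory"), 150)
  tc80 <- timing_config(sampling_rate_hz = 80)
  p <- quiet_profile(4)
  rec <- simulate_bci_session(p, "visual", tc80, seed = 9,
                              montage = test_montage())
  ev <- rec$events
  expect_equal(nrow(ev), 6 * 5 * 15 * 10)      # 4500 stimulus events
  expect_equal(length(unique(ev$letter_index)), 30)
  # 2 targets per sequence (one row, one column), 30 per letter
  expect_true(all(tapply(ev$is_target, ev$letter_index, sum) == 30))
  one_seq <- ev[ev$letter_index == 1 & ev$sequence_index == 1, ]
  expect_equal(sum(one_seq$is_target), 2)
  # successive letter onsets are 38.4 s apart
  starts <- tapply(ev$sample_index, ev$letter_index, min)
  expect_equal(unname(diff(starts[1:2])), 38.4 * 80)
  # spelled words alternate BRAIN and POWER
  expect_equal(unname(unique(ev$letter[ev$run_index == 1])),
               c("B", "R", "A", "I", "N"))
  expect_equal(unname(unique(ev$letter[ev$run_index == 2])),
               c("P", "O", "W", "E", "R"))
})

test_that("auditory speller presents rows before columns in fixed order", {
  tc <- timing_config(sampling_rate_hz = 80, runs_per_session = 1,
                      letters_per_run = 1, sequences_per_letter = 2)
  rec <- simulate_bci_session(quiet_profile(5), "auditory", tc, seed = 3,
                              montage = test_montage())
  s1 <- rec$events[rec$events$sequence_index == 1, ]
  expect_equal(s1$kind, rep(c("row_spoken", "col_spoken"), each = 5))
  expect_equal(s1$stimulus_index, rep(1:5, 2))
})

test_that("noiseless deviant average recovers the planted template exactly", {
  p <- quiet_profile(6)
  tc <- rep_timing_oddball()
  mont <- test_montage()
  rec <- simulate_oddball_session(p, tc, seed = 2, montage = mont)
  ep <- epoch_and_baseline(rec)
  avg <- average_erp(ep, "target")
  tmpl <- erp_template(p, "target", "oddball", mont, tc$sampling_rate_hz)
  expect_lt(max(abs(avg - tmpl)), 1e-9)
  # standards carry only the exogenous components
  avg_std <- average_erp(ep, "nontarget")
  tmpl_n <- erp_template(p, "nontarget", "oddball", mont, tc$sampling_rate_hz)
  expect_lt(max(abs(avg_std - tmpl_n)), 1e-9)
})

test_that("erp_template separates target and non-target responses", {
  p <- quiet_profile(8)
  mont <- test_montage()
  tt <- erp_template(p, "target", "oddball", mont)
  tn <- erp_template(p, "nontarget", "oddball", mont)
  t_ms <- attr(tt, "times_ms")
  # non-target trace at Cz is purely exogenous at the P3 latency
  i_p3 <- which.min(abs(t_ms - p$components$P3$lat_ms))
  expect_lt(abs(tn["Cz", i_p3]), 1e-6)
  # target minus non-target peaks at the P3 latency at Cz
  diff_cz <- tt["Cz", ] - tn["Cz", ]
  expect_lt(abs(t_ms[which.max(diff_cz)] - p$components$P3$lat_ms), 4)
})

test_that("Gaussian component integral matches the closed form", {
  t_ms <- seq(-600, 1200, by = 0.01)
  for (par in list(c(3, 300, 40), c(-3.25, 229, 32), c(4.99, 378, 50))) {
    num <- sum(gaussian_bump(t_ms, par[1], par[2], par[3])) * 0.01
    expect_lt(abs(num / (par[1] * par[3] * sqrt(2 * pi)) - 1), 1e-6)
  }
})
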