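freq_gain <- function(h, f_hz, srate) {
  w <- 2 * pi * f_hz / srate
  abs(sum(h * exp(-1i * w * (seq_along(h) - 1))))
}

test_that("band-pass removes DC and meets the stated gain targets", {
  # forward-backward application of each filter squares its response
  hp <- p300aptitude:::cached_filter("high", 0.5, 500, 3L * 1000L)
  lp <- p300aptitude:::cached_filter("low", 20, 500, 3L * 25L)
  gain <- function(f) freq_gain(hp, f, 500)^2 * freq_gain(lp, f, 500)^2
  expect_equal(sum(hp), 0)                       # exact DC null
  expect_gt(gain(10), 0.95)
  expect_lt(gain(10), 1.05)
  expect_lt(gain(40), 0.1)
  # constant-offset signal comes out with near-zero mean
  x <- matrix(5, 2, 4000)
  y <- fir_bandpass(x, srate = 500)
  expect_lt(max(abs(rowMeans(y))), 1e-6)
})

test_that("band-pass is zero-phase and linear", {
  srate <- 250
  t <- seq_len(3000)
  pulse <- exp(-((t - 1500) / 40)^2)             # symmetric pulse
  y <- fir_bandpass(matrix(pulse, 1), low_hz = 0.5, high_hz = 20,
                    srate = srate)
  expect_equal(which.max(y[1, ]), which.max(pulse))
  set.seed(42)
  a <- matrix(rnorm(3000), 1); b <- matrix(rnorm(3000), 1)
  lhs <- fir_bandpass(2 * a - 3 * b, srate = srate)
  rhs <- 2 * fir_bandpass(a, srate = srate) - 3 * fir_bandpass(b, srate = srate)
  expect_lt(max(abs(lhs - rhs)), 1e-8)
  expect_error(fir_bandpass(a, low_hz = 0.5, high_hz = 130, srate = 250),
               "Nyquist")
})

test_that("AMUSE recovers independent AR(1) sources from mixtures", {
  set.seed(7)
  n <- 4000
  s1 <- as.numeric(arima.sim(list(ar = 0.9), n))
  s2 <- as.numeric(arima.sim(list(ar = 0.2), n))
  S <- rbind(s1, s2)
  A <- matrix(rnorm(8), 4, 2)
  dec <- suppressWarnings(amuse(A %*% S))  # 2 sources in 4 channels
  # each true source matched by some component with |r| > 0.95
  r <- abs(cor(t(dec$sources), t(S)))
  expect_gt(max(r[, 1]), 0.95)
  expect_gt(max(r[, 2]), 0.95)
  expect_false(is.unsorted(rev(dec$eigenvalues)))  # sorted decreasing
  # mixing inverts unmixing on the retained subspace
  expect_lt(max(abs(dec$mixing %*% dec$unmixing - diag(4))), 1e-6)
})

test_that("AMUSE on pre-whitened sources is a signed permutation", {
  set.seed(8)
  n <- 20000
  s1 <- as.numeric(arima.sim(list(ar = 0.8), n))
  s2 <- as.numeric(arima.sim(list(ar = -0.5), n))
  S <- rbind(s1 / sd(s1), s2 / sd(s2))
  dec <- amuse(S)
  U <- abs(dec$unmixing)
  perm <- apply(U, 1, which.max)
  expect_equal(sort(perm), 1:2)
  expect_true(all(apply(U, 1, max) > 0.95))
  expect_true(all(apply(U, 1, min) < 0.2))
})

test_that("AMUSE matches the generalized-eigenvalue oracle", {
  set.seed(9)
  x <- matrix(rnorm(3 * 3000), 3)
  x[2, ] <- x[2, ] + 0.5 * c(0, x[2, -3000])     # give it temporal structure
  dec <- amuse(x, lag = 1)
  xc <- x - rowMeans(x)
  n <- ncol(x)
  C0 <- tcrossprod(xc) / n
  C1 <- xc[, 2:n] %*% t(xc[, 1:(n - 1)]) / (n - 1)
  Asym <- (C1 + t(C1)) / 2
  lam <- sort(Re(eigen(solve(C0) %*% Asym)$values), decreasing = TRUE)
  expect_equal(dec$eigenvalues, lam, tolerance = 1e-8)
  # unmixing jointly diagonalises both covariances
  D0 <- dec$unmixing %*% C0 %*% t(dec$unmixing)
  D1 <- dec$unmixing %*% Asym %*% t(dec$unmixing)
  expect_lt(max(abs(D0 - diag(3))), 1e-8)
  expect_lt(max(abs(D1 - diag(dec$eigenvalues))), 1e-8)
})

test_that("ocular components are identified and removed", {
  mont <- test_montage()
  set.seed(10)
  n <- 8000
  blink <- numeric(n)
  for (b in seq(500, n - 200, by = 900))
    blink[b:(b + 79)] <- blink[b:(b + 79)] + 80 * sin(pi * (1:80) / 80)^2
  topo <- component_topography("blink", mont)
  data <- topo %o% blink + matrix(rnorm(nrow(mont) * n, sd = 2), nrow(mont))
  iu <- which(mont$label == "VEOGU"); il <- which(mont$label == "VEOGL")
  data[iu, ] <- data[iu, ] + 1.6 * blink
  data[il, ] <- data[il, ] - 1.0 * blink
  rec <- new_recording(data, 250, mont, data.frame(sample_index = integer(),
    kind = character(), is_target = logical()))
  dec <- amuse(rec)
  veog <- data[iu, ] - data[il, ]
  frontal <- which(mont$label == "Fz")
  expect_gt(abs(cor(rec$data[frontal, ], veog)), 0.5)
  clean <- remove_ocular(rec, dec, 0.7)
  expect_gt(length(attr(clean, "removed_components")), 0)
  expect_lt(abs(cor(clean$data[frontal, ], veog)), 0.2)
  # EOG channels pass through untouched
  expect_identical(clean$data[iu, ], rec$data[iu, ])
  # threshold 1.0 removes nothing: reconstruction is the identity
  same <- remove_ocular(rec, dec, 1.0)
  expect_equal(length(attr(same, "removed_components")), 0)
  expect_lt(max(abs(same$data - rec$data)), 1e-8)
})

test_that("common average reference has the defining properties", {
  mont <- montage()                               # full 63 + 4
  set.seed(11)
  data <- matrix(rnorm(67 * 500), 67)
  rec <- new_recording(data, 500, mont,
                       data.frame(sample_index = integer(),
                                  kind = character(), is_target = logical()))
  car <- common_average_reference(rec)
  eeg <- which(mont$role == "eeg")
  expect_lt(max(abs(colSums(car$data[eeg, ]))), 1e-9)
  expect_equal(car$reference, "car")
  expect_identical(car$data[-eeg, ], rec$data[-eeg, ])
  twice <- common_average_reference(car)
  expect_lt(max(abs(twice$data - car$data)), 1e-12)
  # single nonzero channel retains 62/63 of its value
  one <- rec; one$data[] <- 0; one$data[eeg[5], ] <- 1
  car1 <- common_average_reference(one)
  expect_equal(car1$data[eeg[5], 1], 62 / 63)
})

test_that("epoching yields half-open 400-sample windows with zeroed baseline", {
  mont <- montage(c("Cz", "Pz"))
  n <- 6000
  data <- matrix(rnorm(nrow(mont) * n), nrow(mont))
  ev <- data.frame(sample_index = c(200L, 1000L, 2000L, n - 100L),
                   kind = "deviant", stimulus_index = NA,
                   is_target = TRUE, sequence_index = 1:4,
                   letter_index = NA, run_index = 1L)
  rec <- new_recording(data, 500, mont, ev)
  expect_message(ep <- epoch_and_baseline(rec), "dropped")
  expect_equal(dim(ep$data), c(3, nrow(mont), 400))   # edge event dropped
  expect_equal(ep$n_dropped, 1L)
  # per-epoch baseline mean is zero after correction
  for (e in 1:3) {
    on <- ep$events$sample_index[e]
    base <- rowMeans(data[, (on - 49):on])
    expect_equal(ep$data[e, , 1], data[, on + 1] - base)
  }
  # constant signal epochs to all-zero
  rec2 <- rec; rec2$data[] <- 7.5
  ep2 <- epoch_and_baseline(rec2)
  expect_lt(max(abs(ep2$data)), 1e-12)
})

test_that("a full oddball session epochs into 60 deviants and 240 standards", {
  p <- make_participant(12, noise_sigma = 1)
  rec <- simulate_oddball_session(p, timing_config(sampling_rate_hz = 80),
                                  seed = 4, montage = test_montage())
  ep <- epoch_and_baseline(rec)
  expect_equal(sum(ep$events$is_target), 60)
  expect_equal(sum(!ep$events$is_target), 240)
})

test_that("the preprocessing pipeline runs its stages in the fixed order", {
  p <- make_participant(13)
  rec <- simulate_oddball_session(p, rep_timing_oddball(), seed = 6,
                                  montage = test_montage())
  ep <- preprocess_session(rec)
  expect_equal(attr(ep, "stages"),
               c("fir_bandpass", "remove_ocular",
                 "common_average_reference", "epoch_and_baseline"))
  ep_nose <- preprocess_session(rec, reference = "nose")
  expect_false("common_average_reference" %in% attr(ep_nose, "stages"))
})
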