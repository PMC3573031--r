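#' Continuous multichannel EEG recording
#'
#' Container for a simulated or loaded recording: a channels x samples
#' matrix in uV, the sampling rate, the montage (labels, roles,
#' positions), the stimulus event table and the reference state.
#' Sample indices in the event table are 0-based (sample 0 is the first
#' stored sample); time windows elsewhere in the package are half-open
#' `[start, end)` in ms.
#'
#' @param data channels x samples numeric matrix (uV).
#' @param srate sampling rate in Hz.
#' @param montage montage data frame ([montage()]).
#' @param events data frame of stimulus events (see
#'   [simulate_oddball_session()]).
#' @param reference `"nose"` or `"car"`.
#' @return object of class `eeg_recording`.
#' @export
new_recording <- function(data, srate, montage, events,
                          reference = c("nose", "car")) {
  reference <- match.arg(reference)
  stopifnot(is.matrix(data), nrow(data) == nrow(montage))
  if (nrow(events) > 0 && max(events$sample_index) >= ncol(data))
    stop("event sample_index beyond end of recording")
  structure(list(data = data, srate = srate, montage = montage,
                 events = events, reference = reference),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "EEG recording: %d channels (%d EEG, %d EOG) x %d samples @ %g Hz (%.1f s)\n",
    nrow(x$data), sum(x$montage$role == "eeg"), sum(x$montage$role == "eog"),
    ncol(x$data), x$srate, ncol(x$data) / x$srate))
  cat(sprintf("  reference: %s; %d stimulus events\n",
              x$reference, nrow(x$events)))
  if (nrow(x$events) > 0)
    print(utils::head(x$events, 3))
  invisible(x)
}

eeg_rows <- function(recording) which(recording$montage$role == "eeg")
eog_rows <- function(recording) which(recording$montage$role == "eog")

channel_index <- function(recording, label) {
  i <- match(label, recording$montage$label)
  if (is.na(i)) stop("channel not in montage: ", label)
  i
}

# --- background noise synthesis -------------------------------------------

# Spectrally shaped (1/f amplitude) Gaussian noise, RMS-normalised.
one_over_f_noise <- function(n, srate, rms) {
  m <- one_over_f_noise_pair(n, srate, rms)
  m[1, ]
}

# Two independent 1/f channels from one complex FFT: a complex white
# spectrum times the amplitude shape gives, after the inverse transform,
# independent real and imaginary parts with the same power spectrum.
one_over_f_noise_pair <- function(n, srate, rms) {
  if (rms <= 0) return(matrix(0, 2, n))
  nfft <- stats::nextn(n, 2)                    # keep FFT lengths fast
  f <- seq(0, srate, length.out = nfft + 1)[1:nfft]
  f[f > srate / 2] <- srate - f[f > srate / 2]  # fold to physical frequency
  shape <- 1 / sqrt(pmax(f, 0.5))               # flatten below 0.5 Hz
  shape[1] <- 0                                 # no DC
  z <- complex(real = stats::rnorm(nfft), imaginary = stats::rnorm(nfft))
  y <- stats::fft(z * shape, inverse = TRUE)[seq_len(n)]
  out <- rbind(Re(y), Im(y))
  out * (rms / sqrt(rowMeans(out^2) - rowMeans(out)^2))
}

# Raised-cosine blink transient of given length.
blink_waveform <- function(n) sin(pi * seq_len(n) / (n + 1))^2

# Full structured background: spatially correlated 1/f sources plus
# per-channel independent 1/f noise, amplitude-modulated posterior 10 Hz
# alpha, and frontal blink transients mirrored (with opposite polarity
# below the eye) into the EOG channels. The shared sources have random
# smooth scalp topographies; they model the common-mode background that
# a spatial filter cannot simply average away.
synth_background <- function(profile, montage, n_samples, srate,
                             n_shared = 6L, shared_frac = 2,
                             indep_frac = 0.6) {
  nch <- nrow(montage)
  out <- matrix(0, nch, n_samples)
  is_eog <- montage$role == "eog"
  if (profile$noise_sigma > 0) {
    for (i in seq_len(ceiling(nch / 2))) {
      rows <- unique(c(2 * i - 1, min(2 * i, nch)))
      pair <- one_over_f_noise_pair(n_samples, srate, 1)
      out[rows, ] <- pair[seq_along(rows), , drop = FALSE]
    }
    rms <- profile$noise_sigma * indep_frac * ifelse(is_eog, 0.8, 1)
    out <- out * rms
    k <- 0L
    while (k < n_shared) {
      pair <- one_over_f_noise_pair(n_samples, srate, 1)
      for (j in 1:2) {
        k <- k + 1L
        if (k > n_shared) break
        ctr <- stats::runif(2, -1, 1)
        rad <- stats::runif(1, 0.3, 0.8)
        w <- exp(-((montage$x - ctr[1])^2 + (montage$y - ctr[2])^2) /
                   (2 * rad^2)) * sample(c(-1, 1), 1)
        w[is_eog] <- 0
        amp <- profile$noise_sigma * shared_frac /
          sqrt(n_shared * max(mean(w[!is_eog]^2), 1e-3))
        out <- out + outer(amp * w, pair[j, ])
      }
    }
  }
  tt <- seq_len(n_samples) / srate
  if (profile$alpha_power > 0) {
    env <- 1 + 0.6 * sin(2 * pi * 0.15 * tt + stats::runif(1, 0, 2 * pi))
    alpha <- profile$alpha_power * env *
      sin(2 * pi * 10 * tt + stats::runif(1, 0, 2 * pi))
    out <- out + outer(component_topography("alpha", montage), alpha)
  }
  if (profile$ocular_rate > 0) {
    dur_min <- n_samples / srate / 60
    n_blinks <- stats::rpois(1, profile$ocular_rate * dur_min)
    topo <- component_topography("blink", montage)
    iu <- which(montage$label == "VEOGU")
    il <- which(montage$label == "VEOGL")
    for (b in seq_len(n_blinks)) {
      len <- round(stats::runif(1, 0.2, 0.4) * srate)
      start <- sample.int(max(1L, n_samples - len), 1)
      amp <- stats::rnorm(1, 120, 25)
      wave <- amp * blink_waveform(len)
      idx <- start:(start + len - 1L)
      out[, idx] <- out[, idx] + outer(topo, wave)
      if (length(iu) == 1L) out[iu, idx] <- out[iu, idx] + 1.6 * wave
      if (length(il) == 1L) out[il, idx] <- out[il, idx] - 1.0 * wave
    }
  }
  out
}
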