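# --- least-squares linear-phase FIR design --------------------------------

# Closed-form least-squares type-I FIR over a union of constant-desired
# bands (normalised rad/sample, transition regions are don't-care). The
# band-restricted normal equations have analytic entries:
#   G[k,l] = 0.5 * (I(k - l) + I(k + l)),  b[k] = sum_bands d * I_band(k)
# with I(m) = sum_bands (sin(m w2) - sin(m w1)) / m and I(0) the total
# band width. Solving G a = b gives the cosine-series coefficients.
firls_bands <- function(n_taps, bands, desired) {
  if (n_taps %% 2L == 0L) n_taps <- n_taps + 1L
  M <- (n_taps - 1L) %/% 2L
  Iband <- function(m, w1, w2) {
    ifelse(m == 0, w2 - w1, (sin(m * w2) - sin(m * w1)) / ifelse(m == 0, 1, m))
  }
  Ifun <- function(m) {
    out <- numeric(length(m))
    for (b in seq_along(bands))
      out <- out + Iband(m, bands[[b]][1], bands[[b]][2])
    out
  }
  k <- 0:M
  # G via Toeplitz + Hankel structure
  Idiff <- Ifun(outer(k, k, "-"))
  Isum <- Ifun(outer(k, k, "+"))
  G <- 0.5 * (Idiff + Isum)
  bv <- numeric(M + 1)
  for (b in seq_along(bands))
    bv <- bv + desired[b] * Iband(k, bands[[b]][1], bands[[b]][2])
  a <- solve(G, bv)
  h <- c(rev(a[-1] / 2), a[1], a[-1] / 2)
  h
}

# Least-squares low-pass, DC gain normalised to exactly 1 so the
# spectral-inversion high-pass nulls DC. The transition band is 15% of
# the cutoff but never narrower than the filter's frequency resolution
# (about two DFT bins of the kernel length), which keeps the passband
# flat at moderate orders.
design_lowpass <- function(cutoff_hz, srate, n_taps) {
  nyq <- srate / 2
  trans <- max(0.15 * cutoff_hz, 2 * srate / n_taps)
  wpass <- cutoff_hz / nyq * pi
  wstop <- min((cutoff_hz + trans) / nyq, 1) * pi
  h <- firls_bands(n_taps, list(c(0, wpass), c(wstop, pi)), c(1, 0))
  h / sum(h)
}

design_highpass <- function(cutoff_hz, srate, n_taps) {
  h <- -design_lowpass(cutoff_hz, srate, n_taps)
  mid <- (length(h) + 1L) %/% 2L
  h[mid] <- h[mid] + 1
  h
}

# cache of designed filters (keyed by kind/cutoff/rate/taps)
.filter_cache <- new.env(parent = emptyenv())

cached_filter <- function(kind, cutoff_hz, srate, n_taps) {
  key <- paste(kind, cutoff_hz, srate, n_taps, sep = "_")
  if (is.null(.filter_cache[[key]])) {
    .filter_cache[[key]] <- switch(kind,
      low = design_lowpass(cutoff_hz, srate, n_taps),
      high = design_highpass(cutoff_hz, srate, n_taps))
  }
  .filter_cache[[key]]
}

# Zero-phase (forward-backward) filtering of the rows of a matrix with a
# cascade of symmetric FIR kernels, each applied forward and backward.
# A symmetric kernel makes the backward pass equal the forward pass, so
# the cascade is one linear convolution with the composite kernel
# hp * hp * lp * lp (frequency response = product of squared responses),
# evaluated in a single FFT round per channel. Edges are handled by odd
# reflection padding of the total kernel length.
filtfilt_cascade <- function(x, kernels) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  lens <- vapply(kernels, length, integer(1))
  Lpad <- sum(lens)
  if (n <= Lpad + 1L) stop("signal shorter than filter length")
  delay <- sum(lens - 1L)            # each kernel applied twice: 2M = L - 1
  npad <- n + 2L * Lpad
  nfft <- stats::nextn(npad + 2L * delay + 1L, 2)
  Gf <- rep(1 + 0i, nfft)
  for (h in kernels)
    Gf <- Gf * stats::fft(c(h, numeric(nfft - length(h))))^2
  pad <- function(i) {
    v <- x[i, ]
    c(2 * v[1] - v[(Lpad + 1):2], v, 2 * v[n] - v[(n - 1):(n - Lpad)],
      numeric(nfft - npad))
  }
  keep <- (delay + Lpad + 1L):(delay + Lpad + n)
  out <- x
  # real kernels let two channels share one FFT (one in the real, one in
  # the imaginary part)
  for (i in seq_len(ceiling(nrow(x) / 2))) {
    r1 <- 2L * i - 1L
    r2 <- min(2L * i, nrow(x))
    zp <- if (r2 > r1) complex(real = pad(r1), imaginary = pad(r2))
          else pad(r1)
    y <- stats::fft(stats::fft(zp) * Gf, inverse = TRUE)[keep] / nfft
    out[r1, ] <- Re(y)
    if (r2 > r1) out[r2, ] <- Im(y)
  }
  out
}

#' Zero-phase FIR band-pass filter
#'
#' Two-pass least-squares FIR filtering as used for ERP preprocessing:
#' the recording is first high-pass filtered, then low-pass filtered,
#' each filter applied forward and backward (zero phase, no latency
#' distortion). Filter orders follow the classic heuristic of 3 times
#' the sampling rate over the cutoff; the high-pass is the spectral
#' inversion of a DC-normalised least-squares low-pass, so constant
#' offsets are removed exactly.
#'
#' @param recording an [new_recording()] object (all channels filtered),
#'   or a plain channels x samples matrix.
#' @param low_hz high-pass cutoff (Hz).
#' @param high_hz low-pass cutoff (Hz); must be below Nyquist.
#' @param srate sampling rate, taken from the recording if omitted.
#' @return the filtered recording (same class as the input).
#' @export
fir_bandpass <- function(recording, low_hz = 0.5, high_hz = 20,
                         srate = NULL) {
  is_rec <- inherits(recording, "eeg_recording")
  x <- if (is_rec) recording$data else recording
  if (is_rec) srate <- recording$srate
  if (is.null(srate)) stop("srate required for matrix input")
  if (high_hz >= srate / 2) stop("low-pass cutoff must be below Nyquist")
  if (low_hz <= 0 || high_hz <= low_hz) stop("need 0 < low_hz < high_hz")
  hp <- cached_filter("high", low_hz, srate, 3L * floor(srate / low_hz))
  lp <- cached_filter("low", high_hz, srate, 3L * floor(srate / high_hz))
  y <- filtfilt_cascade(x, list(hp, lp))
  if (is_rec) { recording$data <- y; recording } else y
}

# --- AMUSE blind source separation ----------------------------------------

#' AMUSE second-order blind source separation
#'
#' The two-step AMUSE algorithm: whiten the (internally centred) data via
#' the eigendecomposition of the zero-lag covariance, then eigendecompose
#' the symmetrised lag-`lag` covariance of the whitened data. Sources are
#' uncorrelated at lag zero and (by the second step) have extremal lagged
#' autocovariances, which separates sources with distinct temporal
#' spectra — ocular artifacts being a prime example. Components are
#' ordered by decreasing lagged-covariance eigenvalue. Near-singular
#' covariances are regularised (ridge on the eigenvalues) with a warning.
#'
#' @param recording an [new_recording()] (EEG channels only are
#'   decomposed) or a channels x samples matrix.
#' @param lag lag in samples for the second covariance (default 1,
#'   the original algorithm).
#' @return object of class `bss_decomposition`: `unmixing`
#'   (components x channels), `mixing` (channels x components), `sources`
#'   (components x samples), `lag`, `eigenvalues` (sorted decreasing),
#'   `center`, and `channel_labels`.
#' @export
amuse <- function(recording, lag = 1L) {
  is_rec <- inherits(recording, "eeg_recording")
  x <- if (is_rec) recording$data[eeg_rows(recording), , drop = FALSE]
       else recording
  labels <- if (is_rec) recording$montage$label[eeg_rows(recording)]
            else rownames(x)
  nch <- nrow(x); n <- ncol(x)
  if (n <= nch) stop("need more samples than channels")
  ctr <- rowMeans(x)
  xc <- x - ctr
  C0 <- tcrossprod(xc) / n
  e0 <- eigen(C0, symmetric = TRUE)
  tol <- max(e0$values) * 1e-10
  if (any(e0$values < tol)) {
    warning("rank-deficient covariance; regularising whitening")
    e0$values <- e0$values + max(e0$values) * 1e-8
  }
  W <- diag(1 / sqrt(e0$values), nch) %*% t(e0$vectors)   # whitener
  y <- W %*% xc
  C1 <- y[, (lag + 1):n, drop = FALSE] %*%
    t(y[, 1:(n - lag), drop = FALSE]) / (n - lag)
  Cs <- (C1 + t(C1)) / 2
  es <- eigen(Cs, symmetric = TRUE)
  ord <- order(es$values, decreasing = TRUE)
  V <- es$vectors[, ord, drop = FALSE]
  unmixing <- t(V) %*% W
  mixing <- e0$vectors %*% diag(sqrt(e0$values), nch) %*% V
  structure(list(unmixing = unmixing, mixing = mixing,
                 sources = unmixing %*% xc, lag = as.integer(lag),
                 eigenvalues = es$values[ord], center = ctr,
                 channel_labels = labels),
            class = "bss_decomposition")
}

#' @export
print.bss_decomposition <- function(x, ...) {
  cat(sprintf("AMUSE decomposition: %d components, lag %d\n",
              nrow(x$unmixing), x$lag))
  cat("  lagged-covariance eigenvalues:",
      paste(sprintf("%.3f", utils::head(x$eigenvalues, 6)), collapse = ", "),
      if (length(x$eigenvalues) > 6) "..." else "", "\n")
  invisible(x)
}

#' Remove ocular artifact components from a recording
#'
#' Components of a [amuse()] decomposition whose absolute correlation
#' with either bipolar EOG derivation (vertical: above minus below the
#' eye; horizontal: left minus right canthus) exceeds the threshold are
#' zeroed and the EEG is reconstructed from the remaining components.
#' EOG channels pass through unchanged.
#'
#' @param recording the recording the decomposition was computed from.
#' @param decomposition a `bss_decomposition` of its EEG channels.
#' @param eog_corr_threshold absolute-correlation threshold (default 0.7).
#' @return the cleaned recording; attribute `removed_components` lists
#'   the zeroed component indices.
#' @export
remove_ocular <- function(recording, decomposition,
                          eog_corr_threshold = 0.7) {
  iog <- eog_rows(recording)
  if (length(iog) == 0L) stop("recording has no EOG channels")
  lab <- recording$montage$label
  pick <- function(a, b) {
    ia <- match(a, lab); ib <- match(b, lab)
    if (is.na(ia) || is.na(ib)) return(NULL)
    recording$data[ia, ] - recording$data[ib, ]
  }
  derivs <- Filter(Negate(is.null),
                   list(veog = pick("VEOGU", "VEOGL"),
                        heog = pick("HEOGL", "HEOGR")))
  if (length(derivs) == 0L) stop("montage lacks bipolar EOG pairs")
  src <- decomposition$sources
  rmax <- apply(abs(vapply(derivs, function(d)
    as.numeric(stats::cor(t(src), d)), numeric(nrow(src)))), 1, max)
  remove <- which(rmax > eog_corr_threshold)
  keep <- setdiff(seq_len(nrow(src)), remove)
  clean <- decomposition$mixing[, keep, drop = FALSE] %*%
    src[keep, , drop = FALSE] + decomposition$center
  out <- recording
  out$data[eeg_rows(recording), ] <- clean
  attr(out, "removed_components") <- remove
  out
}

#' Common average reference
#'
#' Subtracts the instantaneous mean over EEG channels from every EEG
#' channel; EOG channels are untouched. Idempotent.
#'
#' @param recording an [new_recording()] object.
#' @return re-referenced recording with `reference = "car"`.
#' @export
common_average_reference <- function(recording) {
  ie <- eeg_rows(recording)
  if (length(ie) < 2L) stop("need at least two EEG channels")
  eeg <- recording$data[ie, , drop = FALSE]
  recording$data[ie, ] <- sweep(eeg, 2, colMeans(eeg))
  recording$reference <- "car"
  recording
}

# --- epoching -------------------------------------------------------------

#' Epoch a recording and baseline-correct
#'
#' Cuts one stimulus-locked epoch per event over the half-open window
#' `[window_ms[1], window_ms[2])` (400 samples for 0-800 ms at 500 Hz)
#' and subtracts per channel the mean of the `[-100, 0)` ms pre-stimulus
#' baseline. Events too close to a recording edge are dropped with a
#' message.
#'
#' @param recording an [new_recording()] object.
#' @param window_ms epoch window in ms relative to stimulus onset.
#' @param baseline_ms baseline window in ms (half-open, before onset).
#' @return object of class `epoch_set`: `data` (epochs x channels x
#'   samples), `events` (rows for kept epochs), `montage`, `srate`,
#'   `times_ms`, `window_ms`, `baseline_ms`, `n_dropped`.
#' @export
epoch_and_baseline <- function(recording, window_ms = c(0, 800),
                               baseline_ms = c(-100, 0)) {
  srate <- recording$srate
  w0 <- round(window_ms[1] / 1000 * srate)
  n_samp <- round(diff(window_ms) / 1000 * srate)
  b0 <- round(baseline_ms[1] / 1000 * srate)
  b1 <- round(baseline_ms[2] / 1000 * srate)
  N <- ncol(recording$data)
  ev <- recording$events
  first <- pmin(ev$sample_index + w0, ev$sample_index + b0)
  last <- pmax(ev$sample_index + w0 + n_samp - 1L, ev$sample_index + b1 - 1L)
  ok <- first >= 0L & last < N
  if (any(!ok))
    message(sum(!ok), " epoch(s) dropped at recording edges")
  ev <- ev[ok, , drop = FALSE]
  nch <- nrow(recording$data)
  n_ep <- nrow(ev)
  # gather all epochs in one indexing pass: columns picked per epoch
  cols <- outer(ev$sample_index + w0, seq_len(n_samp), "+")      # ep x samp
  seg <- recording$data[, as.vector(cols), drop = FALSE]         # ch x (ep*samp)
  out <- aperm(array(seg, dim = c(nch, n_ep, n_samp)), c(2, 1, 3))
  if (b1 > b0) {
    bcols <- outer(ev$sample_index + b0, seq_len(b1 - b0), "+")
    bseg <- recording$data[, as.vector(bcols), drop = FALSE]
    base <- t(matrix(rowMeans(matrix(bseg, nch * n_ep, b1 - b0)),
                     nch, n_ep))                                 # ep x ch
    out <- out - as.vector(base)                                 # recycles over samples
  }
  row.names(ev) <- NULL
  structure(list(data = out, events = ev, montage = recording$montage,
                 srate = srate,
                 times_ms = window_ms[1] + (seq_len(n_samp) - 1L) * 1000 / srate,
                 window_ms = window_ms, baseline_ms = baseline_ms,
                 n_dropped = sum(!ok)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Epoch set: %d epochs x %d channels x %d samples (%g-%g ms, %g Hz)\n",
              d[1], d[2], d[3], x$window_ms[1], x$window_ms[2], x$srate))
  if ("is_target" %in% names(x$events))
    cat(sprintf("  %d target / %d non-target epochs\n",
                sum(x$events$is_target), sum(!x$events$is_target)))
  invisible(x)
}

#' Standard preprocessing pipeline
#'
#' Runs the offline processing chain in its fixed order: band-pass
#' filter, AMUSE ocular artifact removal, common average reference,
#' epoching with baseline correction. The stage order is recorded in the
#' result's `stages` attribute.
#'
#' @param recording an [new_recording()] object.
#' @param low_hz,high_hz band-pass cutoffs.
#' @param eog_corr_threshold ocular component threshold; `NULL` skips
#'   the BSS stage (useful for tiny montages in simulation studies).
#' @param reference `"car"` re-references to the common average (the
#'   classifier pipeline); `"nose"` keeps the recording reference, the
#'   conventional choice for ERP peak measurement.
#' @param window_ms,baseline_ms epoch windows.
#' @return an [epoch_and_baseline()] epoch set.
#' @export
preprocess_session <- function(recording, low_hz = 0.5, high_hz = 20,
                               eog_corr_threshold = 0.7,
                               reference = c("car", "nose"),
                               window_ms = c(0, 800),
                               baseline_ms = c(-100, 0)) {
  reference <- match.arg(reference)
  stages <- "fir_bandpass"
  rec <- fir_bandpass(recording, low_hz, high_hz)
  if (!is.null(eog_corr_threshold)) {
    dec <- amuse(rec)
    rec <- remove_ocular(rec, dec, eog_corr_threshold)
    stages <- c(stages, "remove_ocular")
  }
  if (reference == "car") {
    rec <- common_average_reference(rec)
    stages <- c(stages, "common_average_reference")
  }
  ep <- epoch_and_baseline(rec, window_ms, baseline_ms)
  stages <- c(stages, "epoch_and_baseline")
  attr(ep, "stages") <- stages
  ep
}
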