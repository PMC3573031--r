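# Evaluate code under a temporary RNG state so simulators are
# deterministic in their seed argument without disturbing the caller's
# random stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed < 0)
    stop("seed must be a single non-negative integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, lower), upper)
}

# Population link between latent aptitude and component amplitudes.
# |N2| = n2_base + n2_gain * aptitude + N(0, n2_sd) reproduces the
# reported group mean/SD (|N2| ~ 3.25, SD 2.25) while the gain fixes the
# planted rank correlation near the reported effect size; the late
# component is parameterised the same way (mean 3.61, SD 2.10, rho ~ 0.46).
# P3 amplitude is drawn independently of aptitude (the reported null).
aptitude_link <- function() {
  list(n2_base = 1.42, n2_gain = 3.66, n2_sd = 1.98,
       late_base = 1.94, late_gain = 3.35, late_sd = 1.86,
       p3_mean = 4.99, p3_sd = 2.66)
}

#' Rank correlation implied by the planted aptitude link
#'
#' The simulator links |N2| and late-component amplitudes linearly to the
#' latent aptitude with Gaussian scatter. This returns the population
#' Spearman correlation between amplitude and aptitude implied by those
#' link parameters (evaluated once by large-sample Monte Carlo, 1e6
#' draws; see the methods vignette).
#'
#' @return named numeric vector with elements `n2` and `late`.
#' @export
planted_link_rho <- function() {
  c(n2 = 0.468, late = 0.459)
}

#' Draw a synthetic participant profile
#'
#' A participant is a latent BCI aptitude in \[0, 1\] plus per-component
#' ERP parameters (amplitude in uV, peak latency in ms, temporal width in
#' ms) for N1, P2, N2, P3 and the late slow wave, together with noise
#' parameters. |N2| and late amplitudes increase with aptitude through
#' the documented linear link; P3 amplitude is independent of aptitude.
#' Identical seed and arguments give an identical profile.
#'
#' @param seed non-negative integer RNG seed.
#' @param aptitude latent aptitude in \[0, 1\]; drawn uniformly if `NULL`.
#' @param noise_sigma broadband (1/f) noise RMS in uV.
#' @param alpha_power posterior alpha oscillation amplitude in uV.
#' @param ocular_rate blink rate per minute.
#' @param amp_jitter trial-to-trial multiplicative amplitude scatter
#'   (SD of a unit-mean Gaussian factor); 0 makes every trial identical.
#' @param participant_id optional id string.
#' @return object of class `participant_profile`.
#' @examples
#' p <- make_participant(seed = 1, aptitude = 0.8)
#' p$components$N2$amp_uV   # negative, larger in magnitude for high aptitude
#' @export
make_participant <- function(seed, aptitude = NULL, noise_sigma = 5,
                             alpha_power = 2, ocular_rate = 4,
                             amp_jitter = 0.12,
                             participant_id = sprintf("P%03d", seed %% 1000L)) {
  if (!is.null(aptitude)) {
    if (!is.numeric(aptitude) || length(aptitude) != 1L ||
        is.na(aptitude) || aptitude < 0 || aptitude > 1)
      stop("aptitude must be a single value in [0, 1]")
  }
  lk <- aptitude_link()
  with_seed(seed, {
    a <- if (is.null(aptitude)) stats::runif(1) else aptitude
    n2_abs <- max(0.3, lk$n2_base + lk$n2_gain * a +
                    stats::rnorm(1, 0, lk$n2_sd))
    p3_amp <- max(0.5, stats::rnorm(1, lk$p3_mean, lk$p3_sd))
    late_amp <- max(0.3, lk$late_base + lk$late_gain * a +
                      stats::rnorm(1, 0, lk$late_sd))
    # latencies drawn around the reported group means with the component
    # order (and enough separation that the bumps stay resolvable)
    # enforced: N2 < P3 < late
    n2_lat <- rnorm_trunc(1, 229.05, 42.57, 150, 300)
    p3_lat <- rnorm_trunc(1, 378, 89, max(310, n2_lat + 110), 560)
    late_lat <- rnorm_trunc(1, 548.65, 80, max(440, p3_lat + 90), 720)
    comp <- list(
      N1 = list(amp_uV = rnorm_trunc(1, -1.2, 0.25, upper = -0.5),
                lat_ms = rnorm_trunc(1, 105, 8, 85, 130),
                width_ms = 20),
      P2 = list(amp_uV = rnorm_trunc(1, 2.2, 0.4, lower = 0.8),
                lat_ms = rnorm_trunc(1, 180, 10, 150, 215),
                width_ms = 30),
      N2 = list(amp_uV = -n2_abs, lat_ms = n2_lat, width_ms = 32),
      P3 = list(amp_uV = p3_amp, lat_ms = p3_lat, width_ms = 50),
      late = list(amp_uV = late_amp, lat_ms = late_lat, width_ms = 80))
    structure(list(
      participant_id = participant_id,
      aptitude = a,
      components = comp,
      noise_sigma = noise_sigma,
      alpha_power = alpha_power,
      ocular_rate = ocular_rate,
      amp_jitter = amp_jitter,
      seed = as.integer(seed)), class = "participant_profile")
  })
}

#' @export
print.participant_profile <- function(x, ...) {
  cat(sprintf("Participant %s  (aptitude %.3f, seed %d)\n",
              x$participant_id, x$aptitude, x$seed))
  for (nm in names(x$components)) {
    cp <- x$components[[nm]]
    cat(sprintf("  %-5s %6.2f uV @ %5.1f ms (width %g ms)\n",
                nm, cp$amp_uV, cp$lat_ms, cp$width_ms))
  }
  cat(sprintf("  noise %g uV, alpha %g uV, %g blinks/min, jitter %g\n",
              x$noise_sigma, x$alpha_power, x$ocular_rate, x$amp_jitter))
  invisible(x)
}

#' Draw a cohort of participant profiles
#'
#' @param n number of participants.
#' @param seed base seed; participant i uses `seed * 1000 + i`.
#' @param ... passed to [make_participant()].
#' @return list of `participant_profile` objects.
#' @export
draw_cohort <- function(n, seed, ...) {
  lapply(seq_len(n), function(i)
    make_participant(seed = (seed * 1000 + i) %% .Machine$integer.max,
                     participant_id = sprintf("P%03d", i), ...))
}

# Per-modality scaling of planted components. The speller tasks elicit
# smaller and (for the auditory speller) later endogenous components than
# the oddball; the auditory speller additionally lacks the sharp N1-P2
# complex of the tone oddball.
modality_scaling <- function(modality) {
  switch(modality,
    oddball = list(endo_amp = 1, n2_amp = 1, late_amp = 1, exo_amp = 1,
                   lat_scale = 1, lat_shrink = 1),
    visual = list(endo_amp = 0.85, n2_amp = 1, late_amp = 1, exo_amp = 0.7,
                  lat_scale = 309 / 378, lat_shrink = 0.35),
    auditory = list(endo_amp = 0.5, n2_amp = 0.6, late_amp = 0.6,
                    exo_amp = 0.25, lat_scale = 508 / 378, lat_shrink = 0.35),
    stop("unknown modality: ", modality))
}

# oddball population-mean latencies of the endogenous components (ms)
component_mean_lat <- c(N2 = 229.05, P3 = 378, late = 548.65)

#' Gaussian ERP component waveform
#'
#' `amp * exp(-(t - lat)^2 / (2 width^2))`; its exact time integral is
#' `amp * width * sqrt(2 * pi)`.
#'
#' @param t_ms time points in ms.
#' @param amp_uV,lat_ms,width_ms amplitude, peak latency and temporal SD.
#' @export
gaussian_bump <- function(t_ms, amp_uV, lat_ms, width_ms) {
  amp_uV * exp(-(t_ms - lat_ms)^2 / (2 * width_ms^2))
}

#' Planted ERP template of a stimulus class
#'
#' The noiseless channels x time waveform planted for a stimulus of the
#' given class, over the 0-800 ms epoch window: the sum of
#' Gaussian-windowed components scaled by their spatial maps. Non-target
#' stimuli carry only the exogenous N1-P2 complex; targets/deviants add
#' N2, P3 and the late slow wave. Speller modalities attenuate and (for
#' auditory) delay the endogenous components relative to the oddball.
#'
#' @param profile a [make_participant()] profile.
#' @param stimulus_class `"target"` or `"nontarget"`.
#' @param modality `"oddball"`, `"visual"` or `"auditory"`.
#' @param montage montage data frame; defaults to the full montage.
#' @param srate_hz sampling rate; template covers samples at
#'   `0, 1/srate, ...` up to (excluding) 800 ms.
#' @return channels x samples matrix (uV) with dimnames from the montage
#'   and attribute `times_ms`.
#' @export
erp_template <- function(profile, stimulus_class = c("target", "nontarget"),
                         modality = c("oddball", "visual", "auditory"),
                         montage = p300aptitude::montage("full"),
                         srate_hz = 500) {
  stimulus_class <- match.arg(stimulus_class)
  modality <- match.arg(modality)
  sc <- modality_scaling(modality)
  t_ms <- seq(0, 800 - 1000 / srate_hz, by = 1000 / srate_hz)
  comps <- c("N1", "P2")
  if (stimulus_class == "target") comps <- c(comps, "N2", "P3", "late")
  out <- matrix(0, nrow(montage), length(t_ms),
                dimnames = list(montage$label, NULL))
  for (nm in comps) {
    cp <- profile$components[[nm]]
    exo <- nm %in% c("N1", "P2")
    # Speller sessions use the population-mean P3 amplitude: individual
    # speller performance is driven by the attention-linked N2 and late
    # components, while the oddball P3 stays an individual draw that is
    # independent of performance (the study's null finding).
    amp <- if (nm == "P3" && modality != "oddball") aptitude_link()$p3_mean
           else cp$amp_uV
    amp <- amp * (if (exo) sc$exo_amp
                  else switch(nm, N2 = sc$n2_amp, late = sc$late_amp,
                              sc$endo_amp))
    # speller latencies: scaled modality mean plus a shrunken individual
    # deviation (between-subject latency spread in the speller tasks is
    # much narrower than in the oddball)
    lat <- if (exo) cp$lat_ms
           else sc$lat_scale * (component_mean_lat[[nm]] +
             sc$lat_shrink * (cp$lat_ms - component_mean_lat[[nm]]))
    w <- component_topography(nm, montage)
    out <- out + outer(w, gaussian_bump(t_ms, amp, lat, cp$width_ms))
  }
  attr(out, "times_ms") <- t_ms
  out
}
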