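#' Class-average ERP waveform
#'
#' Arithmetic mean over all epochs of one stimulus class.
#'
#' @param epochs an [epoch_and_baseline()] epoch set.
#' @param class `"target"` or `"nontarget"`.
#' @return channels x time matrix (uV) with channel labels as rownames
#'   and attribute `times_ms`.
#' @export
average_erp <- function(epochs, class = c("target", "nontarget")) {
  class <- match.arg(class)
  idx <- if (class == "target") which(epochs$events$is_target)
         else which(!epochs$events$is_target)
  if (length(idx) == 0L) stop("no epochs of class ", class)
  avg <- colMeans(epochs$data[idx, , , drop = FALSE], dims = 1)
  rownames(avg) <- epochs$montage$label
  attr(avg, "times_ms") <- epochs$times_ms
  avg
}

#' Target minus non-target difference map
#'
#' @param target_avg,nontarget_avg matched channels x time matrices.
#' @return elementwise difference with the inputs' time attribute.
#' @export
difference_map <- function(target_avg, nontarget_avg) {
  if (!all(dim(target_avg) == dim(nontarget_avg)))
    stop("shape mismatch between target and non-target averages")
  out <- target_avg - nontarget_avg
  attr(out, "times_ms") <- attr(target_avg, "times_ms")
  out
}

#' Sequential N200 / P300 / late component detection
#'
#' The study's fixed detection order on the target-average waveform:
#' the P300 is located first as the maximum at Cz between 250 and
#' 700 ms; the N200 is then the minimum at Cz before the P300 latency;
#' finally the late component is the maximum at POz after the P300
#' latency, up to the end of the epoch. Amplitudes are in uV, latencies
#' in ms on the sample grid (2 ms at 500 Hz, no sub-sample fitting).
#' Degenerate windows (e.g. a P300 on the first sample of its window,
#' leaving no N200 search range, or an all-flat waveform) are flagged.
#'
#' @param target_avg channels x time matrix with `times_ms` attribute
#'   (from [average_erp()]), rownames holding channel labels.
#' @param p300_channel,late_channel channel labels to search.
#' @param p300_window_ms P300 search window.
#' @param n200_floor_ms lower bound of the N200 search (default 0 ms).
#' @return one-row data frame: `n200_amp_uV`, `n200_lat_ms`,
#'   `p300_amp_uV`, `p300_lat_ms`, `late_amp_uV`, `late_lat_ms`,
#'   `degenerate`.
#' @export
detect_components <- function(target_avg, p300_channel = "Cz",
                              late_channel = "POz",
                              p300_window_ms = c(250, 700),
                              n200_floor_ms = 0) {
  t_ms <- attr(target_avg, "times_ms")
  if (is.null(t_ms)) stop("target_avg lacks a times_ms attribute")
  cz <- target_avg[p300_channel, ]
  poz <- target_avg[late_channel, ]
  degenerate <- FALSE

  w <- which(t_ms >= p300_window_ms[1] & t_ms <= p300_window_ms[2])
  if (length(w) == 0L) stop("P300 window outside the epoch")
  ip3 <- w[which.max(cz[w])]
  p3_amp <- cz[ip3]; p3_lat <- t_ms[ip3]

  wn <- which(t_ms >= n200_floor_ms & t_ms < p3_lat)
  if (length(wn) == 0L) {
    degenerate <- TRUE
    n2_amp <- NA_real_; n2_lat <- NA_real_
  } else {
    in2 <- wn[which.min(cz[wn])]
    n2_amp <- cz[in2]; n2_lat <- t_ms[in2]
  }

  wl <- which(t_ms > p3_lat)
  if (length(wl) == 0L) {
    degenerate <- TRUE
    late_amp <- NA_real_; late_lat <- NA_real_
  } else {
    il <- wl[which.max(poz[wl])]
    late_amp <- poz[il]; late_lat <- t_ms[il]
  }
  if (all(abs(target_avg) < .Machine$double.eps^0.5)) degenerate <- TRUE

  data.frame(n200_amp_uV = n2_amp, n200_lat_ms = n2_lat,
             p300_amp_uV = p3_amp, p300_lat_ms = p3_lat,
             late_amp_uV = late_amp, late_lat_ms = late_lat,
             degenerate = degenerate)
}

#' Group comparison statistics
#'
#' Standard t-tests used for the group analyses: a paired t-test between
#' two within-participant conditions (e.g. visual vs auditory accuracy)
#' or a pooled-variance two-sample t-test between independent groups
#' (e.g. high vs low aptitude component amplitudes).
#'
#' @param x,y numeric vectors; for `paired = TRUE` aligned by
#'   participant.
#' @param paired whether the samples are dependent.
#' @return data frame with `t`, `df`, `p`, `mean_x`, `mean_y`.
#' @export
erp_group_stats <- function(x, y, paired = FALSE) {
  if (length(x) < 2L || length(y) < 2L) stop("need at least two per group")
  if (paired && stats::sd(x - y) == 0) {
    # zero-variance differences: t = 0 when means agree
    d <- mean(x - y)
    return(data.frame(t = if (d == 0) 0 else sign(d) * Inf,
                      df = length(x) - 1L, p = if (d == 0) 1 else 0,
                      mean_x = mean(x), mean_y = mean(y)))
  }
  ht <- stats::t.test(x, y, paired = paired, var.equal = !paired)
  data.frame(t = unname(ht$statistic), df = unname(ht$parameter),
             p = ht$p.value, mean_x = mean(x), mean_y = mean(y))
}
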