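#' Spatiotemporal feature extraction for SWLDA
#'
#' Per channel, each epoch is smoothed with a trailing moving average of
#' `ma_width` samples and then decimated by `decim`: feature bin `b`
#' covers samples `[(b-1) * decim + 1, b * decim]` and its value is the
#' smoothed amplitude at the bin's last sample (for `ma_width == decim`
#' this is exactly the block mean). A 400-sample epoch at the defaults
#' yields 16 bins per channel — 1008 features over 63 channels.
#'
#' @param epochs an [epoch_and_baseline()] epoch set.
#' @param ma_width moving-average width in samples.
#' @param decim decimation factor.
#' @return object of class `feature_matrix`: `values` (trials x
#'   features), `feature_index` (data frame: `channel`, `bin`,
#'   `bin_center_ms`), `labels` (+1 target / -1 non-target), `events`.
#' @export
featurize <- function(epochs, ma_width = 25L, decim = 25L) {
  eeg <- which(epochs$montage$role == "eeg")
  d <- dim(epochs$data)
  n_ep <- d[1]; n_samp <- d[3]
  nch <- length(eeg)
  if (ma_width > n_samp) stop("ma_width exceeds epoch length")
  n_bins <- n_samp %/% decim
  take <- seq_len(n_bins) * decim             # last sample of each bin
  lo <- pmax(take - ma_width, 0L)
  # trailing moving average sampled at bin ends, as one linear map
  W <- matrix(0, n_samp, n_bins)
  for (b in seq_len(n_bins))
    W[(lo[b] + 1L):take[b], b] <- 1 / (take[b] - lo[b])
  vals <- matrix(0, n_ep, nch * n_bins)
  for (ch in seq_len(nch)) {
    x <- epochs$data[, eeg[ch], , drop = TRUE]
    if (n_ep == 1L) x <- matrix(x, nrow = 1)
    vals[, (ch - 1L) * n_bins + seq_len(n_bins)] <- x %*% W
  }
  fi <- data.frame(
    channel = rep(epochs$montage$label[eeg], each = n_bins),
    bin = rep(seq_len(n_bins), nch),
    bin_center_ms = epochs$window_ms[1] +
      (rep(seq_len(n_bins), nch) - 0.5) * decim * 1000 / epochs$srate,
    stringsAsFactors = FALSE)
  labels <- if ("is_target" %in% names(epochs$events))
    ifelse(epochs$events$is_target, 1, -1) else rep(NA_real_, n_ep)
  structure(list(values = vals, feature_index = fi, labels = labels,
                 events = epochs$events,
                 ma_width = ma_width, decim = decim),
            class = "feature_matrix")
}

# partial-F p-values for adding each column of `cand` to the model whose
# orthonormal column basis (including intercept) is Q, with current
# residual r and residual sum of squares rss on n observations and p
# current coefficients (including intercept).
forward_p_values <- function(cand, Q, r, rss, n, p) {
  proj <- crossprod(Q, cand)                 # basis coords of candidates
  res <- cand - Q %*% proj                   # candidate residuals
  s2 <- colSums(res^2)
  num <- as.numeric(crossprod(res, r))
  drop_rss <- ifelse(s2 > 1e-12 * colSums(cand^2) & s2 > 0,
                     num^2 / s2, 0)
  rss1 <- pmax(rss - drop_rss, 0)
  df2 <- n - p - 1L
  Fv <- ifelse(rss1 <= 1e-12 * rss, Inf, drop_rss / (rss1 / df2))
  p_val <- stats::pf(Fv, 1, df2, lower.tail = FALSE)
  p_val[s2 <= 1e-12 * colSums(cand^2)] <- 1   # collinear with model
  p_val
}

#' Stepwise linear discriminant analysis (SWLDA)
#'
#' Forward/backward stepwise regression of the class label (+1 target,
#' -1 non-target) on the spatiotemporal features, the classic sparse
#' linear scorer of P300 spellers. Each iteration adds the excluded
#' feature with the smallest partial-F p-value if it is below `p_enter`,
#' then repeatedly removes included features whose p-value exceeds
#' `p_remove`; fitting stops after `max_iter` additions or when no
#' feature qualifies. Weights are the ordinary least-squares
#' coefficients of the label on the selected features (an intercept is
#' used during fitting but not stored: scoring is a pure weighted sum,
#' and the row/column argmax is invariant to a per-trial constant, so no
#' bias term is needed).
#'
#' If no feature reaches `p_enter` on the first step, model generation
#' fails with an error of class `swlda_no_features`.
#'
#' @param features a [featurize()] feature matrix, or a plain trials x
#'   features matrix (then `labels` must be given).
#' @param labels +1/-1 class labels (taken from `features` if omitted).
#' @param p_enter,p_remove inclusion/removal p-value thresholds.
#' @param max_iter maximum number of forward inclusions.
#' @return object of class `swlda`: `selected` (feature column indices
#'   in inclusion order), `weights`, `feature_index` rows of the
#'   selected features, thresholds, `n_iterations`.
#' @export
swlda <- function(features, labels = NULL, p_enter = 0.10,
                  p_remove = 0.15, max_iter = 60L) {
  fi <- NULL
  if (inherits(features, "feature_matrix")) {
    x <- features$values
    if (is.null(labels)) labels <- features$labels
    fi <- features$feature_index
  } else x <- as.matrix(features)
  y <- as.numeric(labels)
  n <- nrow(x)
  if (length(y) != n) stop("labels length must match trial count")
  if (min(table(y)) < 2L) stop("need at least two trials per class")
  p_total <- ncol(x)

  selected <- integer(0)
  Q <- matrix(1 / sqrt(n), n, 1)              # orthonormal intercept
  r <- y - mean(y)
  rss <- sum(r^2)
  iter <- 0L
  repeat {
    if (iter >= max_iter) break
    excl <- setdiff(seq_len(p_total), selected)
    if (length(excl) == 0L) break
    pv <- forward_p_values(x[, excl, drop = FALSE], Q, r, rss, n,
                           length(selected) + 1L)
    j <- which.min(pv)
    if (pv[j] >= p_enter) {
      if (length(selected) == 0L)
        stop(structure(class = c("swlda_no_features", "error", "condition"),
                       list(message = paste0(
                         "model generation failed: no feature reaches p_enter = ",
                         p_enter), call = sys.call(-1))))
      break
    }
    selected <- c(selected, excl[j])
    iter <- iter + 1L
    # backward elimination
    repeat {
      fit <- stats::lm.fit(cbind(1, x[, selected, drop = FALSE]), y)
      qr_R <- qr.R(fit$qr)
      rss_cur <- sum(fit$residuals^2)
      df2 <- n - length(selected) - 1L
      xtxi_diag <- diag(chol2inv(qr_R))[-1]
      se <- sqrt(pmax(xtxi_diag, 0) * rss_cur / df2)
      tstat <- fit$coefficients[-1] / se
      p_drop <- 2 * stats::pt(abs(tstat), df2, lower.tail = FALSE)
      worst <- which.max(p_drop)
      if (length(selected) > 1L && p_drop[worst] > p_remove) {
        selected <- selected[-worst]
      } else break
    }
    dec <- qr(cbind(1, x[, selected, drop = FALSE]))
    Q <- qr.Q(dec)
    r <- y - Q %*% crossprod(Q, y)
    rss <- sum(r^2)
  }
  fit <- stats::lm.fit(cbind(1, x[, selected, drop = FALSE]), y)
  structure(list(selected = selected,
                 weights = unname(fit$coefficients[-1]),
                 intercept = unname(fit$coefficients[1]),
                 feature_index = if (!is.null(fi)) fi[selected, ] else NULL,
                 p_enter = p_enter, p_remove = p_remove,
                 n_iterations = iter, n_features = p_total),
            class = "swlda")
}

#' @export
print.swlda <- function(x, ...) {
  cat(sprintf("SWLDA model: %d of %d features selected (%d iterations)\n",
              length(x$selected), x$n_features, x$n_iterations))
  cat(sprintf("  p_enter %.3g / p_remove %.3g\n", x$p_enter, x$p_remove))
  if (!is.null(x$feature_index)) {
    fi <- x$feature_index
    fi$weight <- x$weights
    print(utils::head(fi, 8), row.names = FALSE)
    if (nrow(fi) > 8) cat("  ...\n")
  }
  invisible(x)
}

#' @export
coef.swlda <- function(object, ...) {
  stats::setNames(object$weights,
                  if (!is.null(object$feature_index))
                    paste0(object$feature_index$channel, "@",
                           object$feature_index$bin_center_ms, "ms")
                  else paste0("f", object$selected))
}

#' Score trials with a fitted SWLDA model
#'
#' The score of a trial is the weighted sum over the selected features;
#' no bias is applied and no threshold is taken (downstream selection is
#' an argmax over summed scores).
#'
#' @param object a fitted [swlda()] model.
#' @param newdata a [featurize()] feature matrix or plain matrix with
#'   the same feature space as at training.
#' @param ... unused.
#' @return numeric vector of per-trial scores.
#' @export
predict.swlda <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "feature_matrix")) newdata$values
       else as.matrix(newdata)
  if (ncol(x) != object$n_features)
    stop("feature space mismatch: model has ", object$n_features,
         " features, data has ", ncol(x))
  as.numeric(x[, object$selected, drop = FALSE] %*% object$weights)
}

#' Row/column letter selection from stimulus scores
#'
#' Sums classifier scores over the first `n_reps` sequences separately
#' per row and per column; the argmax row and argmax column (ties broken
#' toward the lower index) select the letter in the 5x5 matrix.
#'
#' @param scores numeric score per stimulus event.
#' @param events matching event rows (needs `kind` containing
#'   `row`/`col`, `stimulus_index`, `sequence_index`).
#' @param n_reps number of sequences to use.
#' @param n_rows,n_cols matrix dimensions.
#' @return list with `row`, `col`, `letter`.
#' @export
select_letter <- function(scores, events, n_reps = 15L,
                          n_rows = 5L, n_cols = 5L) {
  use <- events$sequence_index <= n_reps
  ev <- events[use, , drop = FALSE]
  sc <- scores[use]
  is_row <- grepl("^row", ev$kind)
  rows_seen <- sort(unique(as.integer(ev$stimulus_index[is_row])))
  cols_seen <- sort(unique(as.integer(ev$stimulus_index[!is_row])))
  if (!identical(rows_seen, seq_len(n_rows)) ||
      !identical(cols_seen, seq_len(n_cols)))
    stop("events do not cover all rows and columns")
  row_sum <- vapply(seq_len(n_rows), function(i)
    sum(sc[is_row & ev$stimulus_index == i]), numeric(1))
  col_sum <- vapply(seq_len(n_cols), function(i)
    sum(sc[!is_row & ev$stimulus_index == i]), numeric(1))
  r <- which.max(row_sum)      # which.max takes the first (lowest) index
  cl <- which.max(col_sum)
  list(row = r, col = cl, letter = matrix_letters()[r, cl])
}
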