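#' Electrode montages with approximate 2-D scalp positions
#'
#' Returns the channel montage used by the simulator and the analysis:
#' 63 EEG electrodes of the modified 10-20 system plus 4 EOG channels
#' (above/below the right eye, and at the outer canthi). Positions are
#' approximate 2-D projections (x: left negative to right positive,
#' y: posterior negative to anterior positive, both roughly in [-1, 1]);
#' they are used for component topographies and spatial plots only, not
#' for source analysis.
#'
#' @param channels `"full"` (63 EEG + 4 EOG), `"reduced"` (a 16-channel
#'   fronto-central/parietal subset plus EOG, convenient for small
#'   simulation studies), or a character vector of EEG labels to keep
#'   (EOG channels are always appended).
#' @return A data frame with columns `label`, `role` (`"eeg"`/`"eog"`),
#'   `x`, `y`.
#' @examples
#' m <- montage()
#' nrow(m)            # 67
#' sum(m$role == "eeg")  # 63
#' @export
montage <- function(channels = "full") {
  full <- eeg_labels_full()
  pos <- t(vapply(full, electrode_position, numeric(2)))
  eeg <- data.frame(label = full, role = "eeg",
                    x = pos[, 1], y = pos[, 2],
                    stringsAsFactors = FALSE, row.names = NULL)
  if (identical(channels, "reduced")) {
    keep <- c("F3", "Fz", "F4", "FC5", "FC1", "FCz", "FC2", "Cz", "C2",
              "CP1", "CP2", "Pz", "PO7", "POz", "PO2", "Oz")
    eeg <- eeg[match(keep, eeg$label), ]
  } else if (!identical(channels, "full")) {
    miss <- setdiff(channels, eeg$label)
    if (length(miss) > 0L)
      stop("unknown EEG labels: ", paste(miss, collapse = ", "))
    eeg <- eeg[match(channels, eeg$label), ]
  }
  eog <- data.frame(
    label = c("VEOGU", "VEOGL", "HEOGL", "HEOGR"),
    role = "eog",
    x = c(0.35, 0.35, -1.05, 1.05),
    y = c(1.15, 1.3, 1.0, 1.0),
    stringsAsFactors = FALSE)
  out <- rbind(eeg, eog)
  row.names(out) <- NULL
  out
}

# 63 EEG labels in recording order.
eeg_labels_full <- function() {
  c("Fp1", "Fpz", "Fp2",
    "F7", "F3", "Fz", "F4", "F8",
    "FT9", "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8", "FT10",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP9", "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8", "TP10",
    "P9", "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8", "P10",
    "PO7", "PO5", "PO1", "POz", "PO2", "PO6", "PO8",
    "O1", "Oz", "O2", "O9", "Iz", "O10")
}

# Approximate (x, y) scalp projection from a 10-20 style label.
electrode_position <- function(label) {
  rows <- c(FP = 0.95, AF = 0.8, F = 0.65, FT = 0.45, FC = 0.35,
            T = 0.1, C = 0.05, TP = -0.25, CP = -0.3, P = -0.55,
            PO = -0.75, O = -0.95, I = -1.05)
  m <- regmatches(label, regexec("^([A-Za-z]+)(z|[0-9]+)$", label))[[1]]
  if (length(m) == 0L) stop("cannot place electrode ", label)
  prefix <- toupper(m[2])
  digit <- m[3]
  y <- unname(rows[prefix])
  if (is.na(y)) stop("cannot place electrode ", label)
  if (digit == "z") {
    x <- 0
  } else {
    d <- as.integer(digit)
    side <- if (d %% 2L == 1L) -1 else 1
    x <- side * 0.21 * ceiling(d / 2)
  }
  c(x = x, y = y)
}

#' Spatial weight map of a planted ERP component
#'
#' Topographies are smooth Gaussian profiles over the 2-D electrode
#' positions, normalised to unit maximum absolute weight. The late slow
#' wave is modelled as an anterior-negative, posterior-positive
#' distribution (posterior lobe centred near POz minus a weaker frontal
#' lobe); all other components are single central/fronto-central or
#' centro-parietal lobes. EOG channels get zero weight.
#'
#' @param component one of `"N1"`, `"P2"`, `"N2"`, `"P3"`, `"late"`,
#'   `"alpha"`, `"blink"`.
#' @param montage montage data frame from [montage()].
#' @return numeric vector of weights, one per montage row, max |w| = 1.
#' @export
component_topography <- function(component, montage) {
  lobes <- switch(component,
    N1    = list(c(0,  0.45, 0.50,  1)),
    P2    = list(c(0,  0.15, 0.55,  1)),
    N2    = list(c(0,  0.20, 0.50,  1)),
    P3    = list(c(0, -0.10, 0.65,  1)),
    late  = list(c(0, -0.75, 0.50,  1), c(0, 0.70, 0.60, -0.6)),
    alpha = list(c(0, -0.80, 0.55,  1)),
    blink = list(c(0,  1.00, 0.45,  1)),
    stop("unknown component: ", component))
  w <- numeric(nrow(montage))
  is_eeg <- montage$role == "eeg"
  for (lb in lobes) {
    d2 <- (montage$x - lb[1])^2 + (montage$y - lb[2])^2
    w <- w + lb[4] * exp(-d2 / (2 * lb[3]^2))
  }
  w[!is_eeg] <- 0
  w / max(abs(w))
}
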