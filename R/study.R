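#' Configuration of a full simulation study
#'
#' Bundles every knob of the study replica — cohort size, seeds, timing,
#' montage, preprocessing, classifier and criterion settings — in one
#' serialisable object. [write_study_config()] / [read_study_config()]
#' round-trip it through a human-readable YAML file.
#'
#' @param n_participants cohort size.
#' @param seed base seed; all per-participant and per-session seeds
#'   derive from it.
#' @param modalities speller modalities to simulate.
#' @param montage `"full"` (63 EEG + 4 EOG) or `"reduced"` (16 + 4).
#' @param timing named list of [timing_config()] overrides.
#' @param noise_sigma,alpha_power,ocular_rate,amp_jitter profile
#'   parameters passed to [make_participant()].
#' @param eog_corr_threshold ocular-removal threshold; `NULL` disables
#'   the BSS stage.
#' @param p_enter,p_remove,max_iter SWLDA parameters.
#' @param ma_width,decim featurization parameters in samples (25/25 at
#'   500 Hz = 50 ms bins; scale with the sampling rate).
#' @param criterion accuracy criterion in percent.
#' @param words words alternated across speller runs.
#' @return object of class `study_config`.
#' @export
study_config <- function(n_participants = 40, seed = 1,
                         modalities = c("visual", "auditory"),
                         montage = "full", timing = list(),
                         noise_sigma = 5, alpha_power = 2,
                         ocular_rate = 4, amp_jitter = 0.12,
                         eog_corr_threshold = 0.7,
                         p_enter = 0.10, p_remove = 0.15, max_iter = 60,
                         ma_width = 25, decim = 25,
                         criterion = 70, words = c("BRAIN", "POWER")) {
  cfg <- list(n_participants = n_participants, seed = seed,
              modalities = modalities, montage = montage, timing = timing,
              noise_sigma = noise_sigma, alpha_power = alpha_power,
              ocular_rate = ocular_rate, amp_jitter = amp_jitter,
              eog_corr_threshold = eog_corr_threshold,
              p_enter = p_enter, p_remove = p_remove,
              max_iter = max_iter, ma_width = ma_width, decim = decim,
              criterion = criterion, words = words)
  structure(cfg, class = "study_config")
}

#' @rdname study_config
#' @param config a `study_config`.
#' @param path file path.
#' @export
write_study_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname study_config
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(study_config, raw)
}

#' @export
print.study_config <- function(x, ...) {
  cat("Study configuration:\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

# short deterministic hash of a config (for output manifests)
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(unclass(config)), f)
  unname(tools::md5sum(f))
}

#' Run the full simulation study
#'
#' Executes the complete replica for every participant: simulate the
#' oddball and speller sessions, preprocess (band-pass, optional AMUSE
#' ocular removal, common average reference, epoching), classify with
#' leave-one-run-out SWLDA cross validation, compute the
#' accuracy-vs-repetitions curve and interpolated
#' repetitions-to-criterion, selection timing and transfer rates,
#' extract oddball ERP components and amplitude grids, and correlate
#' them with performance.
#'
#' @param config a [study_config()].
#' @param progress print per-participant progress lines.
#' @return object of class `bci_study` with elements `performance`
#'   (wide per-participant data frame), `components`,
#'   `component_correlations`, `maps` (per modality
#'   [spearman_map()] objects), `offset_matrices`, `itr` (per-modality
#'   cohort transfer rates), `aptitude` (latent truth), `config`,
#'   `config_hash`.
#' @export
run_study <- function(config = study_config(), progress = FALSE) {
  timing <- do.call(timing_config, config$timing)
  mont <- montage(config$montage)
  profiles <- draw_cohort(config$n_participants, config$seed,
                          noise_sigma = config$noise_sigma,
                          alpha_power = config$alpha_power,
                          ocular_rate = config$ocular_rate,
                          amp_jitter = config$amp_jitter)
  max_reps <- timing$sequences_per_letter

  comp_rows <- list(); perf_rows <- list(); grids <- list()
  sel_tgt <- stats::setNames(
    vector("list", length(config$modalities)), config$modalities)
  for (i in seq_along(profiles)) {
    pr <- profiles[[i]]
    stage <- "oddball"
    res <- tryCatch({
      odd <- simulate_oddball_session(pr, timing, seed = pr$seed + 11L,
                                      montage = mont)
      ep_odd <- preprocess_session(
        odd, eog_corr_threshold = config$eog_corr_threshold)
      comp <- extract_oddball_amplitudes(ep_odd, "component_peaks")
      grid <- extract_oddball_amplitudes(ep_odd, "raw_grid",
                                         decim = config$decim)
      row <- data.frame(participant = pr$participant_id,
                        aptitude = pr$aptitude, comp)
      perf <- list(participant = pr$participant_id)
      for (mod in config$modalities) {
        stage <- mod
        rec <- simulate_bci_session(
          pr, mod, timing,
          seed = pr$seed + if (mod == "visual") 101L else 202L,
          montage = mont, words = config$words)
        ep <- preprocess_session(
          rec, eog_corr_threshold = config$eog_corr_threshold)
        sc <- cross_validate(ep, p_enter = config$p_enter,
                             p_remove = config$p_remove,
                             max_iter = config$max_iter,
                             ma_width = config$ma_width,
                             decim = config$decim,
                             require_runs = timing$runs_per_session)
        curve <- accuracy_vs_repetitions(sc, max_reps = max_reps)
        reps <- reps_to_criterion(curve, config$criterion)
        tm <- selection_time(reps_for_ranking(reps, max_reps), mod, timing)
        # letter selections at full repetitions, for the error-offset map
        sels <- do.call(rbind, lapply(unique(sc$letter_index), function(li) {
          rows <- sc$letter_index == li
          s <- select_letter(sc$score[rows], sc[rows, ], n_reps = max_reps)
          data.frame(row = s$row, col = s$col,
                     target_row = sc$target_row[rows][1],
                     target_col = sc$target_col[rows][1])
        }))
        perf[[paste0("acc_", mod)]] <-
          utils::tail(curve$accuracy_percent, 1)
        perf[[paste0("reps70_", mod)]] <- reps
        perf[[paste0("time_s_", mod)]] <- tm$seconds
        perf[[paste0("sel_per_min_", mod)]] <- tm$selections_per_min
        sel_tgt[[mod]] <- rbind(sel_tgt[[mod]], sels)
      }
      list(row = row, perf = as.data.frame(perf), grid = grid)
    }, error = function(e) {
      stop("study failed for participant ", pr$participant_id,
           " at stage '", stage, "': ", conditionMessage(e), call. = FALSE)
    })
    comp_rows[[i]] <- res$row
    perf_rows[[i]] <- res$perf
    grids[[i]] <- res$grid
    if (progress)
      message(sprintf("participant %s done (aptitude %.2f)",
                      pr$participant_id, pr$aptitude))
  }
  components <- do.call(rbind, comp_rows)
  performance <- do.call(rbind, perf_rows)

  # rank-ready performance (not-reached -> sentinel max_reps + 1)
  for (mod in config$modalities)
    performance[[paste0("reps70_rank_", mod)]] <-
      reps_for_ranking(performance[[paste0("reps70_", mod)]], max_reps)

  amp_grid <- array(
    unlist(grids), dim = c(dim(grids[[1]])[1], dim(grids[[1]])[2],
                           length(grids)))
  amp_grid <- aperm(amp_grid, c(3, 1, 2))
  dimnames(amp_grid) <- list(performance$participant,
                             rownames(grids[[1]]), NULL)
  attr(amp_grid, "bin_center_ms") <- attr(grids[[1]], "bin_center_ms")

  maps <- list(); itr <- list(); offmats <- list()
  for (mod in config$modalities) {
    perf_rank <- performance[[paste0("reps70_rank_", mod)]]
    maps[[mod]] <- if (length(perf_rank) >= 4 &&
                         length(unique(perf_rank)) > 1) {
      spearman_map(amp_grid, perf_rank)
    } else {
      message("correlation map skipped for ", mod,
              ": too few participants or constant performance")
      NULL
    }
    sels <- sel_tgt[[mod]]
    offmats[[mod]] <- error_offset_matrix(
      sels[, c("row", "col")],
      data.frame(row = sels$target_row, col = sels$target_col))
    acc_full <- mean(performance[[paste0("acc_", mod)]]) / 100
    spm <- selection_time(max_reps, mod, timing)$selections_per_min
    itr[[mod]] <- list(
      mean_accuracy_percent = 100 * acc_full,
      selections_per_min = spm,
      pierce_bits_per_min = pierce_itr(
        max(acc_full, 1 / 25), 25, spm)$bits_per_min,
      mi_bits_per_min = mutual_information_itr(
        offmats[[mod]], spm)$bits_per_min)
  }

  perf_cols <- intersect(c("participant", "reps70_visual",
                           "reps70_rank_visual", "reps70_auditory",
                           "reps70_rank_auditory"), names(performance))
  cc_perf <- performance[perf_cols]
  names(cc_perf) <- sub("^reps70_rank_", "reps70_", names(cc_perf))
  cc_perf <- cc_perf[!duplicated(names(cc_perf))]
  # rank-sentinel columns take precedence for the correlations
  rank_first <- performance["participant"]
  for (mod in config$modalities)
    rank_first[[paste0("reps70_", mod)]] <-
      performance[[paste0("reps70_rank_", mod)]]
  corr <- component_correlations(components, rank_first,
                                 modalities = config$modalities)

  structure(list(performance = performance, components = components,
                 component_correlations = corr, maps = maps,
                 offset_matrices = offmats, itr = itr,
                 amplitude_grid = amp_grid,
                 aptitude = stats::setNames(components$aptitude,
                                            components$participant),
                 config = config, config_hash = config_hash(config),
                 timing = timing),
            class = "bci_study")
}

#' @export
print.bci_study <- function(x, ...) {
  cat(sprintf("Simulated P300-BCI study: %d participants (config %s)\n",
              nrow(x$performance), substr(x$config_hash, 1, 8)))
  for (mod in x$config$modalities) {
    reps <- x$performance[[paste0("reps70_", mod)]]
    cat(sprintf(
      "  %-8s mean accuracy %.1f%%, median reps-to-70%% %.2f (%d/%d reached), ITR %.2f bits/min\n",
      mod, x$itr[[mod]]$mean_accuracy_percent,
      stats::median(reps, na.rm = TRUE), sum(!is.na(reps)), length(reps),
      x$itr[[mod]]$pierce_bits_per_min))
  }
  cat("Component correlations with performance (rho):\n")
  cc <- x$component_correlations
  amp <- cc[cc$measure == "amplitude", ]
  for (i in seq_len(nrow(amp)))
    cat(sprintf("  %-5s %-8s rho = %+.2f (p = %.3g)\n", amp$component[i],
                amp$modality[i], amp$rho[i], amp$p[i]))
  invisible(x)
}

#' @export
summary.bci_study <- function(object, ...) {
  list(n = nrow(object$performance),
       itr = object$itr,
       component_correlations = object$component_correlations,
       map_extrema = lapply(object$maps, function(m)
         if (is.null(m)) NULL else map_extrema(m)))
}

#' Write study outputs as CSV/JSON
#'
#' Writes the per-participant performance table, the component table,
#' the component-correlation table, per-modality correlation maps
#' (long CSV: channel, bin_center_ms, rho, signed_r2, p) and a JSON
#' manifest carrying the config, its hash and the map extrema. Refuses
#' to overwrite a directory written under a *different* config hash.
#'
#' @param study a [run_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (file.exists(manifest_path)) {
    old <- jsonlite::read_json(manifest_path)
    if (!identical(old$config_hash, study$config_hash))
      stop("output dir holds results for a different config (",
           old$config_hash, "); refusing to overwrite")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(d, name)
    utils::write.csv(d, file.path(dir, name), row.names = FALSE)
  wcsv(study$performance, "performance.csv")
  wcsv(study$components, "components.csv")
  wcsv(study$component_correlations, "component_correlations.csv")
  for (mod in names(study$maps)) {
    m <- study$maps[[mod]]
    if (is.null(m)) next
    long <- data.frame(
      channel = rep(m$channel_labels, ncol(m$rho)),
      bin_center_ms = rep(m$bin_center_ms, each = nrow(m$rho)),
      rho = as.numeric(m$rho), signed_r2 = as.numeric(m$signed_r2),
      p = as.numeric(m$p))
    wcsv(long, paste0("correlation_map_", mod, ".csv"))
  }
  manifest <- list(package = "p300aptitude",
                   version = as.character(utils::packageVersion("p300aptitude")),
                   config = unclass(study$config),
                   config_hash = study$config_hash,
                   itr = study$itr,
                   map_extrema = lapply(study$maps, function(m)
                     if (is.null(m)) NULL else map_extrema(m)))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
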