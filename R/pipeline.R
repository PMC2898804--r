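# Experiment orchestration: simulate -> forward -> inverse per modality ->
# synchrony statistics -> two-level aggregation (spindles within subject,
# then across subjects).

#' Experiment configuration
#'
#' Defaults mirror the emulated study design: 7 subjects x ~12 spindles (~85 events),
#' 100 quiet 600-ms epochs per subject, EEG/MEG/combined dSPM solutions.
#' The source space defaults to 642 dipoles per hemisphere, a desk-scale
#' stand-in for the ~3200/hemisphere of a decimated cortical reconstruction.
#'
#' @param generator A [generator_config()].
#' @param head A [spherical_head_model()].
#' @param n_per_hemisphere Sources per hemisphere.
#' @param fold_amplitude,fold_wavenumber Folding of the cortical surrogate.
#' @param source_radius Mean source-shell radius (m).
#' @param snr Assumed SNR for inverse regularization.
#' @param covariance_mode `"baseline_epochs"` (quiet sleep epochs; both
#'   modalities) or `"empty_room"` (MEG noise covariance from an empty-room
#'   recording; EEG still uses baseline epochs).
#' @param coherence_max_sources Sources used for the per-source
#'   between-modality coherences (a fixed-seed subsample keeps the runtime
#'   linear; correlations always use all sources).
#' @param meg_inverse_kinds MEG channel kinds entering the MEG-only and
#'   combined inverse solutions; defaults to the planar gradiometers, whose
#'   focal sensitivity profiles match the gradiometer-based source analysis
#'   (magnetometers are still simulated and recorded).
#' @param stat_component Source time courses entering the correlation and
#'   coherence statistics: `"magnitude"` (nonnegative sqrt-F, the quantity
#'   the stacked activity plots show; default) or `"signed"` (the
#'   noise-normalized surface-normal component, which carries oscillatory
#'   phase but whose sign flips between opposing fold banks, washing out
#'   within-modality synchrony on a folded surface). Activation maps always
#'   use the magnitude.
#' @param seed Master seed.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(generator = generator_config(),
                              head = spherical_head_model(),
                              n_per_hemisphere = 642L,
                              fold_amplitude = 0.2,
                              fold_wavenumber = 12L,
                              source_radius = 0.06,
                              snr = 4,
                              covariance_mode = c("baseline_epochs", "empty_room"),
                              coherence_max_sources = 128L,
                              meg_inverse_kinds = c("GRAD1", "GRAD2"),
                              stat_component = c("magnitude", "signed"),
                              seed = 1L) {
  covariance_mode <- match.arg(covariance_mode)
  stat_component <- match.arg(stat_component)
  structure(list(generator = generator, head = head,
                 n_per_hemisphere = as.integer(n_per_hemisphere),
                 fold_amplitude = fold_amplitude,
                 fold_wavenumber = as.integer(fold_wavenumber),
                 source_radius = source_radius, snr = snr,
                 covariance_mode = covariance_mode,
                 coherence_max_sources = as.integer(coherence_max_sources),
                 meg_inverse_kinds = meg_inverse_kinds,
                 stat_component = stat_component,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

# Ground-truth source activities of one subject's record.
subject_activities <- function(events, source_space, gen) {
  acts <- list()
  for (ev in events) {
    if (gen$matrix_amplitude > 0)
      acts[[length(acts) + 1L]] <- synthesize_matrix_activity(ev, source_space, gen)
    if (gen$core_amplitude > 0 && length(ev$core_patches) > 0)
      acts[[length(acts) + 1L]] <- synthesize_core_activity(ev, source_space, gen)
  }
  acts
}

# Per-spindle Welch/MVDR parameters adapted to the interval length.
spindle_welch_segment <- function(T) max(32L, 2^floor(log2(T / 2)))
spindle_mvdr_length <- function(T) max(8L, min(64L, floor(T / 20)))

#' Run the full simulated experiment
#'
#' For each subject: lay out spindle events, synthesize matrix/core/background
#' source activity, render EEG and MEG recordings plus quiet epochs (and an
#' empty-room recording when requested), low-pass at 40 Hz, band-pass
#' 10–15 Hz for the covariance epochs, compute EEG-only, MEG-only and
#' combined dSPM operators, apply them to every annotated spindle and
#' compute the synchrony statistics and maximum maps. Statistics are
#' averaged over spindles within subject, then across subjects (grand mean
#' and SD over subject means).
#'
#' @param config An [experiment_config()].
#' @param verbose Print stage progress.
#' @return An `experiment_report`; see `print()` for the headline numbers.
#' @export
run_experiment <- function(config = experiment_config(), verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  head <- config$head
  ss <- build_source_space(config$n_per_hemisphere, config$fold_amplitude,
                           config$fold_wavenumber, seed = config$seed,
                           radius = config$source_radius, center = head$center)
  arr_eeg <- build_sensor_array("EEG", head, seed = config$seed)
  arr_meg <- build_sensor_array("MEG", head, seed = config$seed)
  say("assembling gain matrices (%d sources)", nrow(ss$positions))
  gain_eeg <- assemble_gain(ss, arr_eeg, head)
  gain_meg <- assemble_gain(ss, arr_meg, head)
  gain_meg_inv <- subset_gain(gain_meg, config$meg_inverse_kinds)
  meg_rows <- which(gain_meg$channels$kind %in% config$meg_inverse_kinds)
  gen0 <- config$generator
  n_src <- nrow(ss$positions)
  coh_idx <- with_seed(config$seed + 77L,
                       sort(sample.int(n_src, min(config$coherence_max_sources, n_src))))
  per_spindle <- list()
  subj_maps <- list()
  for (s in seq_len(gen0$n_subjects)) {
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e)
        stop(sprintf("stage '%s' failed for subject %d: %s", what, s,
                     conditionMessage(e)), call. = FALSE))
    }
    sub_seed <- config$seed * 1000L + s
    gen <- gen0
    gen$seed <- sub_seed
    say("subject %d: simulating", s)
    events <- stage("simulate", sample_spindle_events(gen, ss, seed = sub_seed))
    n_samples <- round(attr(events, "record_duration") * gen$sampling_rate)
    acts <- stage("simulate", subject_activities(events, ss, gen))
    if (gen$background_amplitude > 0)
      acts[[length(acts) + 1L]] <- stage("simulate",
        synthesize_background(n_samples, ss, gen, seed = sub_seed))
    rec_eeg <- stage("render", render_recording(acts, gain_eeg, gen,
                                                seed = sub_seed + 1L, n_samples = n_samples))
    rec_meg <- stage("render", render_recording(acts, gain_meg, gen,
                                                seed = sub_seed + 2L, n_samples = n_samples))
    rm(acts)
    say("subject %d: filtering", s)
    rec_eeg <- stage("filter", filter_recording(rec_eeg, "lowpass40"))
    rec_meg <- stage("filter", filter_recording(rec_meg, "lowpass40"))
    ep_eeg <- stage("covariance",
                    annotated_segments(filter_recording(rec_eeg, "band10_15"), "quiet_epoch"))
    ep_meg <- stage("covariance",
                    annotated_segments(filter_recording(rec_meg, "band10_15"), "quiet_epoch"))
    ep_meg <- lapply(ep_meg, function(m) m[meg_rows, , drop = FALSE])
    ncov_eeg <- stage("covariance",
                      estimate_noise_covariance(ep_eeg, "baseline_epochs",
                                                channel_names = rec_eeg$channels$name))
    ncov_meg <- if (config$covariance_mode == "empty_room") {
      er <- stage("covariance",
                  empty_room_recording(arr_meg, gen, n_samples = 10000L, seed = sub_seed + 3L))
      stage("covariance",
            estimate_noise_covariance(er$values[meg_rows, , drop = FALSE], "empty_room",
                                      channel_names = er$channels$name[meg_rows]))
    } else {
      stage("covariance",
            estimate_noise_covariance(ep_meg, "baseline_epochs",
                                      channel_names = gain_meg_inv$channels$name))
    }
    say("subject %d: inverse operators", s)
    op_eeg <- stage("inverse", compute_inverse_operator(gain_eeg, ncov_eeg, config$snr))
    op_meg <- stage("inverse", compute_inverse_operator(gain_meg_inv, ncov_meg, config$snr))
    op_comb <- stage("inverse", combined_inverse(gain_eeg, gain_meg_inv,
                                                 ncov_eeg, ncov_meg, config$snr))
    comb_values <- rbind(rec_eeg$values, rec_meg$values[meg_rows, , drop = FALSE])
    sp <- rec_eeg$annotations[rec_eeg$annotations$label == "spindle", , drop = FALSE]
    maps <- list(EEG = list(), MEG = list(), combined = list())
    for (i in seq_len(nrow(sp))) {
      interval <- c(sp$onset[i], sp$duration[i])
      cmp <- config$stat_component
      xm <- recording_segment(rec_meg, interval[1], interval[2])[meg_rows, , drop = FALSE]
      est_e <- stage("dSPM", apply_dspm(op_eeg, rec_eeg, interval, component = cmp))
      est_m <- stage("dSPM", apply_dspm(op_meg, xm, component = cmp))
      est_m$modality <- "MEG"
      i0 <- round(interval[1] * gen$sampling_rate) + 1L
      xcomb <- comb_values[, i0:(i0 + ncol(est_e$values) - 1L), drop = FALSE]
      est_c <- stage("dSPM", apply_dspm(op_comb, xcomb, component = cmp))
      map_e <- stage("dSPM", apply_dspm(op_eeg, rec_eeg, interval))
      map_m <- stage("dSPM", apply_dspm(op_meg, xm))
      map_m$modality <- "MEG"
      map_c <- stage("dSPM", apply_dspm(op_comb, xcomb))
      T <- ncol(est_e$values)
      seg <- spindle_welch_segment(T)
      Lm <- spindle_mvdr_length(T)
      cw <- cm <- numeric(length(coh_idx))
      for (k in seq_along(coh_idx)) {
        a <- est_e$values[coh_idx[k], ]
        b <- est_m$values[coh_idx[k], ]
        cw[k] <- welch_coherence(a, b, gen$sampling_rate, segment_length = seg)
        cm[k] <- mvdr_coherence(a, b, gen$sampling_rate, filter_length = Lm)
      }
      per_spindle[[length(per_spindle) + 1L]] <- data.frame(
        subject = s, spindle = i,
        within_eeg = as.numeric(mean_pairwise_correlation(est_e)),
        within_meg = as.numeric(mean_pairwise_correlation(est_m)),
        within_combined = as.numeric(mean_pairwise_correlation(est_c)),
        between_r = as.numeric(between_modality_correlation(est_e, est_m)),
        coherence_welch = mean(cw),
        coherence_mvdr = mean(cm))
      maps$EEG[[i]] <- spindle_max_map(map_e)
      maps$MEG[[i]] <- spindle_max_map(map_m)
      maps$combined[[i]] <- spindle_max_map(map_c)
    }
    subj_maps[[s]] <- lapply(maps, average_max_maps)
    say("subject %d: done (%d spindles)", s, nrow(sp))
  }
  per_spindle <- do.call(rbind, per_spindle)
  stats_cols <- setdiff(names(per_spindle), c("subject", "spindle"))
  per_subject <- stats::aggregate(per_spindle[stats_cols],
                                  by = list(subject = per_spindle$subject), mean)
  summary <- lapply(stats_cols, function(cn)
    c(mean = mean(per_subject[[cn]]), sd = stats::sd(per_subject[[cn]])))
  names(summary) <- stats_cols
  map_r <- vapply(subj_maps, function(m) map_correlation(m$EEG, m$MEG), 0)
  grand_maps <- lapply(c(EEG = "EEG", MEG = "MEG", combined = "combined"), function(mod) {
    subj <- lapply(subj_maps, `[[`, mod)
    list(max1 = average_max_maps(subj),
         raw = Reduce(`+`, lapply(subj, `[[`, "values")) / length(subj))
  })
  structure(list(per_spindle = per_spindle, per_subject = per_subject,
                 summary = summary,
                 map_correlation = c(mean = mean(map_r), sd = stats::sd(map_r)),
                 map_correlation_per_subject = map_r,
                 maps = grand_maps, subject_maps = subj_maps,
                 n_pairs = n_source_pairs(nrow(ss$positions)),
                 n_sources = nrow(ss$positions),
                 nominal_spacing = ss$nominal_spacing,
                 coherence_sources = coh_idx,
                 config = config),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Source-space spindle synchrony report\n")
  cat(sprintf("  %d subjects, %d spindles, %d sources (%.0f pairs per spindle)\n",
              nrow(x$per_subject), nrow(x$per_spindle), x$n_sources, x$n_pairs))
  fmt <- function(v) sprintf("%.3f +/- %.3f", v["mean"], v["sd"])
  cat("  within-modality mean pairwise r:\n")
  cat(sprintf("    EEG-dSPM:      %s\n", fmt(x$summary$within_eeg)))
  cat(sprintf("    MEG-dSPM:      %s\n", fmt(x$summary$within_meg)))
  cat(sprintf("    MEG+EEG-dSPM:  %s\n", fmt(x$summary$within_combined)))
  cat(sprintf("  between-modality r:        %s\n", fmt(x$summary$between_r)))
  cat(sprintf("  between-modality coherence (Welch): %s\n",
              fmt(x$summary$coherence_welch)))
  cat(sprintf("  between-modality coherence (MVDR):  %s\n",
              fmt(x$summary$coherence_mvdr)))
  cat(sprintf("  EEG-vs-MEG map correlation: %.3f +/- %.3f\n",
              x$map_correlation["mean"], x$map_correlation["sd"]))
  invisible(x)
}
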