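# Synthetic spindle generator: ground-truth source activity for the diffuse
# synchronous ("matrix") and focal asynchronous ("core") systems, background
# noise dipoles, sensor rendering, quiet epochs and empty-room recordings.

# Evaluate code under a local RNG state without disturbing the global stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generator configuration
#'
#' Defaults encode the emulated recording conditions: 7 subjects with ~12 spindles each
#' (~85 events), 100 quiet 600-ms epochs per subject, 500 Hz sampling,
#' spindle durations from a Beta(0.273, 0.460) distribution rescaled to
#' 483–1123 ms (matching mean 721 ms and SD 235 ms within that range), and
#' spindle frequencies uniform in 10–15 Hz.
#'
#' Amplitudes are desk-scale physiological choices (see the methods
#' vignette): per-source matrix moments and per-patch core moments sized so
#' simulated sensor amplitudes fall in the range of real sleep-spindle EEG
#' (tens of microvolts) and MEG (hundreds of fT/cm on planar gradiometers),
#' with sensor noise at typical instrument levels.
#'
#' @param n_subjects Number of simulated subjects.
#' @param spindles_per_subject Spindle events per subject.
#' @param sampling_rate Hz; 500 or 600.
#' @param matrix_amplitude Per-source dipole moment of the matrix system (A·m).
#' @param matrix_gain_map_smoothness Standard deviation of the log spatial
#'   gain field of the matrix system (a low-order harmonic field; 0 gives a
#'   spatially flat map).
#' @param n_core_patches_range Integer range (min, max) of core patches per
#'   spindle.
#' @param core_burst_fraction Range of the fraction of the spindle duration
#'   each core patch is active for; burst windows are placed uniformly at
#'   random within the spindle, so the focal generators tile the event in
#'   time.
#' @param core_patch_radius Geodesic radius of a core patch (m); the default
#'   8 mm keeps a patch on a single fold bank (below half the default fold
#'   wavelength), so its member dipoles share orientation.
#' @param core_amplitude Per-source dipole moment within a core patch (A·m).
#' @param core_tangential_quantile Core patch centers are drawn uniformly
#'   among the sources whose normals are most tangential to the skull (the
#'   lowest quantile of |normal . radial|): core generators live on sulcal
#'   walls, which is what makes them MEG-visible but EEG-quiet. Set to 1 for
#'   unrestricted uniform placement.
#' @param background_amplitude RMS moment of each background noise dipole (A·m).
#' @param n_background_dipoles Number of randomly placed background dipoles.
#' @param sensor_noise_sd Named vector of white sensor-noise SDs for kinds
#'   EEG (V), MAG (T) and GRAD (T/m).
#' @param quiet_epochs_per_subject,quiet_epoch_duration Quiet-epoch layout.
#' @param inter_spindle_gap Range (s) of gaps between consecutive spindles.
#' @param seed Master seed of the generator.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_subjects = 7L,
                             spindles_per_subject = 12L,
                             sampling_rate = 500,
                             matrix_amplitude = 20e-9,
                             matrix_gain_map_smoothness = 0.5,
                             n_core_patches_range = c(8L, 14L),
                             core_patch_radius = 0.008,
                             core_amplitude = 50e-9,
                             core_tangential_quantile = 0.25,
                             core_burst_fraction = c(0.15, 0.35),
                             background_amplitude = 0.9e-9,
                             n_background_dipoles = 250L,
                             sensor_noise_sd = c(EEG = 9e-6, MAG = 4e-14, GRAD = 1.6e-12),
                             quiet_epochs_per_subject = 100L,
                             quiet_epoch_duration = 0.6,
                             inter_spindle_gap = c(5.5, 6.5),
                             seed = 1L) {
  if (!sampling_rate %in% c(500, 600))
    stop("sampling_rate must be 500 or 600 Hz")
  amps <- c(matrix_amplitude, core_amplitude, background_amplitude)
  if (any(amps < 0)) stop("amplitudes must be nonnegative")
  stopifnot(all(c("EEG", "MAG", "GRAD") %in% names(sensor_noise_sd)))
  structure(list(n_subjects = as.integer(n_subjects),
                 spindles_per_subject = as.integer(spindles_per_subject),
                 sampling_rate = sampling_rate,
                 matrix_amplitude = matrix_amplitude,
                 matrix_gain_map_smoothness = matrix_gain_map_smoothness,
                 n_core_patches_range = as.integer(n_core_patches_range),
                 core_patch_radius = core_patch_radius,
                 core_amplitude = core_amplitude,
                 core_tangential_quantile = core_tangential_quantile,
                 core_burst_fraction = core_burst_fraction,
                 background_amplitude = background_amplitude,
                 n_background_dipoles = as.integer(n_background_dipoles),
                 sensor_noise_sd = sensor_noise_sd,
                 quiet_epochs_per_subject = as.integer(quiet_epochs_per_subject),
                 quiet_epoch_duration = quiet_epoch_duration,
                 inter_spindle_gap = inter_spindle_gap,
                 duration_beta = c(alpha = 0.273, beta = 0.460),
                 duration_range = c(0.483, 1.123),
                 frequency_range = c(10, 15),
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Draw spindle durations (seconds)
#'
#' Beta(0.273, 0.460) rescaled to 483–1123 ms; the parameters reproduce the
#' duration mean of 721 ms and SD of 235 ms within that range.
#'
#' @param n Number of draws.
#' @param config A [generator_config()].
#' @return Durations in seconds.
#' @export
sample_spindle_durations <- function(n, config = generator_config()) {
  rng <- config$duration_range
  rng[1] + diff(rng) * stats::rbeta(n, config$duration_beta["alpha"],
                                    config$duration_beta["beta"])
}

#' Sample ground-truth spindle events
#'
#' Events are laid out sequentially with random inter-spindle gaps so they
#' never overlap. Each event has a single matrix frequency/phase and 3–6
#' core patches with independent centers, frequencies, phases and active
#' subintervals (onset lag / offset lead), emulating focal generators that
#' shift in location and time within the same spindle.
#'
#' @param config A [generator_config()].
#' @param source_space A [build_source_space()].
#' @param seed Integer seed.
#' @param record_duration Optional fixed record length (s); error if the
#'   requested spindle count does not fit.
#' @return List of `spindle_event`s; attribute `record_duration` gives the
#'   total record length implied by the layout.
#' @export
sample_spindle_events <- function(config, source_space, seed = config$seed,
                                  record_duration = NULL) {
  stopifnot(inherits(config, "generator_config"), inherits(source_space, "source_space"))
  n <- config$spindles_per_subject
  n_src <- nrow(source_space$positions)
  with_seed(seed, {
    durations <- sample_spindle_durations(n, config)
    gaps <- stats::runif(n + 1, config$inter_spindle_gap[1], config$inter_spindle_gap[2])
    onsets <- gaps[1] + cumsum(c(0, durations[-n] + gaps[2:n]))
    total <- onsets[n] + durations[n] + gaps[n + 1]
    if (!is.null(record_duration)) {
      if (total > record_duration)
        stop(sprintf("%d spindles (%.1f s layout) do not fit in %.1f s record",
                     n, total, record_duration))
      total <- record_duration
    }
    rhat <- sweep(source_space$positions, 2, source_space$center, `-`)
    rhat <- rhat / sqrt(rowSums(rhat^2))
    tangentiality <- abs(rowSums(source_space$orientations * rhat))
    centers <- which(tangentiality <= stats::quantile(tangentiality,
                                                      config$core_tangential_quantile))
    events <- lapply(seq_len(n), function(i) {
      np <- sample(seq(config$n_core_patches_range[1], config$n_core_patches_range[2]), 1)
      patches <- lapply(seq_len(np), function(p) {
        # each patch is active over a short burst placed anywhere in the
        # spindle: focal generators shift in location and time
        bf <- stats::runif(1, config$core_burst_fraction[1], config$core_burst_fraction[2])
        start <- stats::runif(1, 0, 1 - bf)
        lag <- start * durations[i]
        lead <- (1 - start - bf) * durations[i]
        list(center_source_index = centers[sample.int(length(centers), 1)],
             radius = config$core_patch_radius,
             frequency = stats::runif(1, config$frequency_range[1], config$frequency_range[2]),
             phase = stats::runif(1, 0, 2 * pi),
             onset_lag = lag, offset_lead = lead,
             amplitude = config$core_amplitude)
      })
      structure(list(onset = onsets[i], duration = durations[i],
                     matrix_frequency = stats::runif(1, config$frequency_range[1],
                                                     config$frequency_range[2]),
                     matrix_phase = stats::runif(1, 0, 2 * pi),
                     core_patches = patches),
                class = "spindle_event")
    })
    attr(events, "record_duration") <- total
    events
  })
}

# Internal container for source-level activity. values is k x T for the k
# active sources in source_index; inactive sources are implicitly zero.
source_activity <- function(values, source_index, n_sources, onset,
                            sampling_rate, ground_truth = NULL, kind = "activity") {
  stopifnot(nrow(values) == length(source_index), all(is.finite(values)))
  structure(list(values = values, source_index = as.integer(source_index),
                 n_sources = as.integer(n_sources), onset = onset,
                 sampling_rate = sampling_rate, ground_truth = ground_truth,
                 kind = kind),
            class = "source_activity")
}

#' @export
print.source_activity <- function(x, ...) {
  cat(sprintf("source activity (%s): %d active of %d sources, %d samples at %g Hz, onset %.2f s\n",
              x$kind, nrow(x$values), x$n_sources, ncol(x$values), x$sampling_rate, x$onset))
  invisible(x)
}

# Smooth strictly positive spatial gain map: exponential of a low-order
# harmonic field (linear + quadratic in the unit position), unit-SD scaled to
# `smoothness`, so the map has one sign everywhere.
matrix_gain_map <- function(source_space, seed, smoothness) {
  if (smoothness <= 0) return(rep(1, nrow(source_space$positions)))
  u <- sweep(source_space$positions, 2, source_space$center, `-`)
  u <- u / sqrt(rowSums(u^2))
  with_seed(seed + 101L, {
    a <- stats::rnorm(3)
    A <- matrix(stats::rnorm(9), 3, 3); A <- (A + t(A)) / 2
    h <- as.vector(u %*% a) + rowSums((u %*% A) * u)
    h <- (h - mean(h)) / stats::sd(h)
    g <- exp(smoothness * h)
    g / mean(g)
  })
}

hann_window <- function(n) {
  if (n == 1) return(0)
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
}

#' Synthesize matrix-system activity for one spindle
#'
#' Every source oscillates with the same frequency and phase under a Hann
#' envelope spanning the event, scaled by a smooth strictly positive spatial
#' gain map: a diffuse, cortex-wide synchronous generator.
#'
#' @param event A `spindle_event`.
#' @param source_space A [build_source_space()].
#' @param config A [generator_config()].
#' @return A `source_activity` (moments along local surface normals, A·m).
#' @export
synthesize_matrix_activity <- function(event, source_space, config) {
  stopifnot(inherits(event, "spindle_event"))
  fs <- config$sampling_rate
  nt <- max(2L, round(event$duration * fs))
  t <- (seq_len(nt) - 1) / fs
  wave <- hann_window(nt) * sin(2 * pi * event$matrix_frequency * t + event$matrix_phase)
  g <- matrix_gain_map(source_space, config$seed, config$matrix_gain_map_smoothness)
  vals <- (config$matrix_amplitude * g) %o% wave
  source_activity(vals, seq_len(nrow(source_space$positions)),
                  nrow(source_space$positions), event$onset, fs,
                  ground_truth = event, kind = "matrix")
}

# Sources within a geodesic disc (same hemisphere, chord distance below the
# chord equivalent of the geodesic radius).
patch_members <- function(source_space, center_index, radius) {
  r0 <- source_space$radius
  if (radius >= pi * r0 / 2)
    stop("core patch radius exceeds the hemisphere extent")
  chord <- 2 * r0 * sin(min(radius / r0, pi) / 2)
  d <- sqrt(rowSums(sweep(source_space$positions, 2,
                          source_space$positions[center_index, ], `-`)^2))
  which(d <= chord & source_space$hemisphere == source_space$hemisphere[center_index])
}

#' Synthesize core-system activity for one spindle
#'
#' Each core patch is a geodesic disc of sources sharing one waveform (own
#' frequency, phase and Hann-enveloped active subinterval); different patches
#' are mutually independent and may be disjoint in time, emulating focal
#' generators that shift location within a spindle.
#'
#' @inheritParams synthesize_matrix_activity
#' @return A `source_activity` covering the union of patch sources.
#' @export
synthesize_core_activity <- function(event, source_space, config) {
  stopifnot(inherits(event, "spindle_event"))
  if (length(event$core_patches) < 1) stop("event has no core patches")
  fs <- config$sampling_rate
  nt <- max(2L, round(event$duration * fs))
  t <- (seq_len(nt) - 1) / fs
  members <- lapply(event$core_patches, function(p)
    patch_members(source_space, p$center_source_index, p$radius))
  idx <- sort(unique(unlist(members)))
  vals <- matrix(0, length(idx), nt)
  for (k in seq_along(event$core_patches)) {
    p <- event$core_patches[[k]]
    i0 <- round(p$onset_lag * fs) + 1L
    i1 <- nt - round(p$offset_lead * fs)
    if (i1 - i0 + 1L < 2L) next
    seg <- i0:i1
    wave <- numeric(nt)
    wave[seg] <- hann_window(length(seg)) *
      sin(2 * pi * p$frequency * t[seg] + p$phase)
    rows <- match(members[[k]], idx)
    vals[rows, ] <- vals[rows, ] + rep(p$amplitude, length(rows)) %o% wave
  }
  source_activity(vals, idx, nrow(source_space$positions), event$onset, fs,
                  ground_truth = event, kind = "core")
}

#' Synthesize background source noise
#'
#' Spatially random, temporally 1/f-shaped (power slope about -1 over
#' 1–40 Hz) stationary noise dipoles, placed uniformly over the source space.
#'
#' @param n_samples Number of samples.
#' @param source_space A [build_source_space()].
#' @param config A [generator_config()]; `n_background_dipoles` and
#'   `background_amplitude` control density and RMS amplitude.
#' @param seed Integer seed.
#' @return A `source_activity` with onset 0 spanning the record.
#' @export
synthesize_background <- function(n_samples, source_space, config, seed = config$seed) {
  n_src <- nrow(source_space$positions)
  k <- min(config$n_background_dipoles, n_src)
  fs <- config$sampling_rate
  with_seed(seed + 202L, {
    idx <- sort(sample.int(n_src, k))
    if (config$background_amplitude == 0) {
      vals <- matrix(0, k, n_samples)
    } else {
      X <- matrix(stats::rnorm(n_samples * k), n_samples, k)
      f <- seq(0, fs, length.out = n_samples + 1)[seq_len(n_samples)]
      f <- pmin(f, fs - f)             # two-sided frequency axis
      shape <- 1 / sqrt(pmax(f, 1))    # amplitude ~ f^(-1/2): power slope -1
      shape[1] <- 0                    # no DC
      Xf <- stats::mvfft(X) * shape
      vals <- t(Re(stats::mvfft(Xf, inverse = TRUE)) / n_samples)
      vals <- vals * (config$background_amplitude /
                        sqrt(rowMeans(vals^2)))
    }
    source_activity(vals, idx, n_src, 0, fs, kind = "background")
  })
}

#' Render sensor recordings from source activities
#'
#' Projects source activities (moments along the local surface normals)
#' through the gain matrix and adds white sensor noise per channel kind.
#' Spindle annotations are carried from the activities' ground-truth events;
#' quiet epochs are tiled into the spindle-free gaps (0.3 s guard around
#' each spindle).
#'
#' @param activities List of `source_activity` objects (may be empty).
#' @param gain A [assemble_gain()] gain matrix.
#' @param config A [generator_config()].
#' @param seed Integer seed for the sensor noise.
#' @param n_samples Record length; defaults to the span of the activities.
#' @return A `recording`: `values` (n_channels x n_samples in channel units),
#'   `sampling_rate`, `channels`, `annotations` (label/onset/duration) and
#'   `provenance`.
#' @export
render_recording <- function(activities, gain, config, seed = config$seed,
                             n_samples = NULL) {
  stopifnot(inherits(gain, "gain_matrix"))
  fs <- config$sampling_rate
  if (is.null(n_samples)) {
    if (length(activities) == 0) stop("n_samples required when no activities given")
    n_samples <- max(vapply(activities, function(a)
      round(a$onset * fs) + ncol(a$values), 0))
  }
  n_ch <- nrow(gain$values)
  Gn <- gain_along_normals(gain)
  X <- matrix(0, n_ch, n_samples)
  events <- list()
  for (a in activities) {
    stopifnot(inherits(a, "source_activity"), a$n_sources == ncol(Gn))
    i0 <- round(a$onset * fs)
    cols <- i0 + seq_len(ncol(a$values))
    if (max(cols) > n_samples) stop("activity extends past the record end")
    X[, cols] <- X[, cols] + Gn[, a$source_index, drop = FALSE] %*% a$values
    if (!is.null(a$ground_truth))
      events[[length(events) + 1L]] <- a$ground_truth
  }
  kindmap <- c(EEG = "EEG", MAG = "MAG", GRAD1 = "GRAD", GRAD2 = "GRAD")
  sds <- config$sensor_noise_sd[kindmap[gain$channels$kind]]
  with_seed(seed + 303L, {
    X <- X + matrix(stats::rnorm(n_ch * n_samples), n_ch, n_samples) * sds
  })
  ann <- spindle_annotations(events)
  ann <- rbind(ann, quiet_epoch_annotations(ann, n_samples / fs, config))
  recording(X, fs, gain$channels, ann, "simulated", events)
}

spindle_annotations <- function(events) {
  if (length(events) == 0)
    return(data.frame(label = character(), onset = numeric(), duration = numeric()))
  on <- vapply(events, `[[`, 0, "onset")
  du <- vapply(events, `[[`, 0, "duration")
  keep <- !duplicated(round(on * 1e6))
  data.frame(label = "spindle", onset = on[keep], duration = du[keep])[order(on[keep]), ]
}

# Tile quiet epochs into spindle-free gaps, 0.3 s guard around spindles.
quiet_epoch_annotations <- function(spindles, record_duration, config) {
  guard <- 0.3
  dur <- config$quiet_epoch_duration
  want <- config$quiet_epochs_per_subject
  sp <- spindles[spindles$label == "spindle", , drop = FALSE]
  edges <- rbind(data.frame(s = -Inf, e = 0.5),
                 data.frame(s = sp$onset - guard, e = sp$onset + sp$duration + guard),
                 data.frame(s = record_duration - 0.2, e = Inf))
  edges <- edges[order(edges$s), ]
  onsets <- numeric(0)
  for (i in seq_len(nrow(edges) - 1)) {
    lo <- edges$e[i]; hi <- edges$s[i + 1]
    k <- floor((hi - lo) / dur)
    if (k > 0) onsets <- c(onsets, lo + dur * (seq_len(k) - 1))
    if (length(onsets) >= want) break
  }
  if (length(onsets) < want)
    warning(sprintf("only %d of %d quiet epochs fit the record", length(onsets), want))
  onsets <- onsets[seq_len(min(want, length(onsets)))]
  data.frame(label = rep("quiet_epoch", length(onsets)),
             onset = onsets, duration = rep(dur, length(onsets)))
}

recording <- function(values, sampling_rate, channels, annotations,
                      provenance, events = NULL) {
  if (nrow(annotations) > 0) {
    ends <- annotations$onset + annotations$duration
    stopifnot(all(annotations$onset >= 0),
              all(ends <= ncol(values) / sampling_rate + 1e-9))
  }
  structure(list(values = values, sampling_rate = sampling_rate,
                 channels = channels, annotations = annotations,
                 provenance = provenance, events = events),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("recording (%s): %d channels x %d samples at %g Hz; %d spindles, %d quiet epochs\n",
              x$provenance, nrow(x$values), ncol(x$values), x$sampling_rate,
              sum(x$annotations$label == "spindle"),
              sum(x$annotations$label == "quiet_epoch")))
  invisible(x)
}

#' Simulated empty-room recording
#'
#' Sensor noise only, no brain sources: the MEG instrumentation/environment
#' noise reference. EEG has no empty-room analog (electrodes must contact a
#' scalp), so EEG arrays are refused.
#'
#' @param array An MEG [build_sensor_array()].
#' @param config A [generator_config()].
#' @param n_samples Number of samples.
#' @param seed Integer seed.
#' @return A `recording` with provenance `"empty_room"`.
#' @export
empty_room_recording <- function(array, config, n_samples, seed = config$seed) {
  stopifnot(inherits(array, "sensor_array"))
  if (array$modality == "EEG")
    stop("EEG has no empty-room analog; empty-room recordings are MEG-only")
  kindmap <- c(MAG = "MAG", GRAD1 = "GRAD", GRAD2 = "GRAD")
  sds <- config$sensor_noise_sd[kindmap[array$channels$kind]]
  X <- with_seed(seed + 404L, {
    matrix(stats::rnorm(nrow(array$channels) * n_samples),
           nrow(array$channels), n_samples) * sds
  })
  recording(X, config$sampling_rate, array$channels,
            data.frame(label = character(), onset = numeric(), duration = numeric()),
            "empty_room")
}

#' Zero-phase filtering of a recording
#'
#' 4th-order Butterworth applied forward-backward (`signal::filtfilt`), so
#' the passband is phase-neutral. `lowpass40` is the anti-alias/cleanup
#' filter; `band10_15` isolates the spindle band.
#'
#' @param rec A `recording`.
#' @param kind `"lowpass40"` or `"band10_15"`.
#' @return The filtered `recording` (annotations preserved).
#' @export
filter_recording <- function(rec, kind = c("lowpass40", "band10_15")) {
  kind <- match.arg(kind)
  stopifnot(inherits(rec, "recording"))
  fs <- rec$sampling_rate
  upper <- if (kind == "lowpass40") 40 else 15
  if (fs <= 2 * upper) stop("sampling rate must exceed twice the upper band edge")
  bw <- if (kind == "lowpass40") 40 else 5
  min_len <- ceiling(3 * fs / bw)
  if (ncol(rec$values) < min_len)
    stop(sprintf("record too short for %s filter edge effects (need >= %d samples)",
                 kind, min_len))
  flt <- if (kind == "lowpass40")
    signal::butter(4, 40 / (fs / 2), type = "low")
  else
    signal::butter(4, c(10, 15) / (fs / 2), type = "pass")
  out <- rec$values
  for (i in seq_len(nrow(out)))
    out[i, ] <- signal::filtfilt(flt, rec$values[i, ])
  rec$values <- out
  rec
}

#' Extract a time segment of a recording
#'
#' @param rec A `recording`.
#' @param onset Segment onset (s).
#' @param duration Segment duration (s).
#' @return Channels x samples matrix.
#' @export
recording_segment <- function(rec, onset, duration) {
  fs <- rec$sampling_rate
  i0 <- round(onset * fs) + 1L
  i1 <- i0 + max(1L, round(duration * fs)) - 1L
  if (i0 < 1 || i1 > ncol(rec$values)) stop("segment outside record bounds")
  rec$values[, i0:i1, drop = FALSE]
}

#' Extract all annotated segments with a given label
#'
#' @param rec A `recording`.
#' @param label Annotation label (e.g. `"quiet_epoch"`, `"spindle"`).
#' @return List of channels x samples matrices.
#' @export
annotated_segments <- function(rec, label) {
  ann <- rec$annotations[rec$annotations$label == label, , drop = FALSE]
  lapply(seq_len(nrow(ann)), function(i)
    recording_segment(rec, ann$onset[i], ann$duration[i]))
}
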