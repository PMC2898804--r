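gen_small <- function(...) {
  generator_config(n_subjects = 1L, spindles_per_subject = 3L,
                   quiet_epochs_per_subject = 20L, ...)
}

test_that("spindle durations match the target moments and range", {
  cfg <- generator_config()
  set.seed(42)
  d <- sample_spindle_durations(10000, cfg)
  expect_true(all(d >= 0.483 & d <= 1.123))
  expect_equal(mean(d) * 1000, 721, tolerance = 5 / 721)
  expect_equal(sd(d) * 1000, 235, tolerance = 5 / 235)
})

test_that("sampled events never overlap and stay in band", {
  ss <- fix_ss()
  cfg <- generator_config(spindles_per_subject = 12L)
  ev <- sample_spindle_events(cfg, ss, seed = 9)
  on <- sapply(ev, `[[`, "onset")
  off <- on + sapply(ev, `[[`, "duration")
  expect_true(all(on[-1] > off[-length(off)]))
  freqs <- c(sapply(ev, `[[`, "matrix_frequency"),
             unlist(lapply(ev, function(e) sapply(e$core_patches, `[[`, "frequency"))))
  expect_true(all(freqs >= 10 & freqs <= 15))
  np <- sapply(ev, function(e) length(e$core_patches))
  expect_true(all(np >= cfg$n_core_patches_range[1] & np <= cfg$n_core_patches_range[2]))
  expect_error(sample_spindle_events(cfg, ss, seed = 9, record_duration = 10),
               "do not fit")
})

test_that("matrix activity is perfectly synchronous with a Hann envelope", {
  ss <- fix_ss()
  cfg <- gen_small()
  ev <- sample_spindle_events(cfg, ss, seed = 2)[[1]]
  act <- synthesize_matrix_activity(ev, ss, cfg)
  expect_equal(nrow(act$values), nrow(ss$positions))
  expect_equal(act$values[, 1], rep(0, nrow(act$values)))
  expect_equal(act$values[, ncol(act$values)], rep(0, nrow(act$values)))
  r <- cor(act$values[5, ], act$values[250, ])
  expect_equal(r, 1, tolerance = 1e-12)
  # spectral peak at the matrix frequency (zero-padded periodogram)
  x <- act$values[5, ]
  pad <- c(x, rep(0, 8192 - length(x)))
  P <- Mod(fft(pad))^2
  freqs <- (seq_along(pad) - 1) * cfg$sampling_rate / length(pad)
  half <- freqs < cfg$sampling_rate / 2
  expect_lt(abs(freqs[half][which.max(P[half])] - ev$matrix_frequency), 0.5)
})

test_that("core patches share waveforms within and differ across patches", {
  ss <- fix_ss()
  cfg <- gen_small()
  # hand-built event: two full-duration patches at distinct frequencies,
  # centered well inside each hemisphere
  centers <- c(which.max(ss$positions[, 1]), which.min(ss$positions[, 1]))
  # 2 cm patches: the coarse test fixture has ~12 mm dipole spacing
  ev <- structure(list(onset = 1, duration = 0.8, matrix_frequency = 12,
                       matrix_phase = 0, core_patches = lapply(1:2, function(k)
                         list(center_source_index = centers[k], radius = 0.02,
                              frequency = c(10.5, 14.5)[k], phase = 0,
                              onset_lag = 0, offset_lead = 0, amplitude = 5e-8))),
                  class = "spindle_event")
  act <- synthesize_core_activity(ev, ss, cfg)
  m1 <- spindlesync:::patch_members(ss, centers[1], 0.02)
  m2 <- spindlesync:::patch_members(ss, centers[2], 0.02)
  expect_true(all(m1 %in% act$source_index))
  i1 <- match(m1, act$source_index)
  i2 <- match(m2, act$source_index)
  expect_equal(cor(act$values[i1[1], ], act$values[i1[2], ]), 1, tolerance = 1e-12)
  expect_lt(abs(cor(act$values[i1[1], ], act$values[i2[1], ])), 0.2)
  # sources outside every patch carry nothing
  expect_true(all(act$source_index %in% c(m1, m2)))
  expect_error(spindlesync:::patch_members(ss, 1, radius = 0.2), "hemisphere extent")
})

test_that("background is 1/f-shaped, stationary and independent across sources", {
  ss <- fix_ss()
  cfg <- gen_small()
  act <- synthesize_background(8192, ss, cfg, seed = 3)
  expect_equal(nrow(act$values), cfg$n_background_dipoles)
  # log-log slope of the periodogram between 1 and 40 Hz is about -1
  sp <- spec.pgram(ts(act$values[1, ], frequency = 500), plot = FALSE,
                   spans = 15, taper = 0)
  sel <- sp$freq >= 1 & sp$freq <= 40
  slope <- coef(lm(log(sp$spec[sel]) ~ log(sp$freq[sel])))[2]
  expect_equal(unname(slope), -1, tolerance = 0.3)
  # independence across sources: correlate the differenced series (the 1/f
  # autocorrelation inflates the raw sample correlation far beyond 1/sqrt(T))
  r12 <- cor(diff(act$values[1, ]), diff(act$values[2, ]))
  expect_lt(abs(r12), 3 / sqrt(8191))
  z <- synthesize_background(512, ss, gen_small(background_amplitude = 0), seed = 3)
  expect_true(all(z$values == 0))
})

test_that("rendering is linear, reproducible and annotates quiet epochs", {
  ss <- fix_ss()
  gain <- fix_gain("EEG")
  cfg <- gen_small(sensor_noise_sd = c(EEG = 0, MAG = 0, GRAD = 0))
  ev <- sample_spindle_events(cfg, ss, seed = 5)
  acts <- lapply(ev, synthesize_matrix_activity, source_space = ss, config = cfg)
  ns <- round(attr(ev, "record_duration") * cfg$sampling_rate)
  rec <- render_recording(acts, gain, cfg, seed = 6, n_samples = ns)
  cfg2 <- gen_small(sensor_noise_sd = c(EEG = 0, MAG = 0, GRAD = 0),
                    matrix_amplitude = 2 * cfg$matrix_amplitude)
  acts2 <- lapply(ev, synthesize_matrix_activity, source_space = ss, config = cfg2)
  rec2 <- render_recording(acts2, gain, cfg2, seed = 6, n_samples = ns)
  expect_equal(rec2$values, 2 * rec$values, tolerance = 1e-12)
  # zero activity and zero noise -> all-zero recording (too short for quiet
  # epochs, which render warns about)
  rec0 <- suppressWarnings(render_recording(list(), gain, cfg, seed = 6,
                                            n_samples = 500))
  expect_true(all(rec0$values == 0))
  # reproducibility with sensor noise
  cfgn <- gen_small()
  reca <- render_recording(acts, gain, cfgn, seed = 7, n_samples = ns)
  recb <- render_recording(acts, gain, cfgn, seed = 7, n_samples = ns)
  expect_identical(reca$values, recb$values)
  # quiet epochs never overlap spindles
  sp <- rec$annotations[rec$annotations$label == "spindle", ]
  qe <- rec$annotations[rec$annotations$label == "quiet_epoch", ]
  expect_equal(nrow(qe), cfg$quiet_epochs_per_subject)
  for (i in seq_len(nrow(qe)))
    expect_true(all(qe$onset[i] + qe$duration[i] <= sp$onset |
                      qe$onset[i] >= sp$onset + sp$duration))
  # first principal sensor pattern is stable across matrix spindles
  seg1 <- recording_segment(rec, sp$onset[1], sp$duration[1])
  seg2 <- recording_segment(rec, sp$onset[2], sp$duration[2])
  p1 <- svd(seg1, nu = 1, nv = 0)$u[, 1]
  p2 <- svd(seg2, nu = 1, nv = 0)$u[, 1]
  expect_gt(abs(cor(p1, p2)), 0.9)
})

test_that("empty-room recordings carry pure sensor noise and refuse EEG", {
  cfg <- gen_small()
  arr <- fix_array("MEG")
  er <- empty_room_recording(arr, cfg, n_samples = 10000, seed = 8)
  expect_identical(er$provenance, "empty_room")
  v <- apply(er$values, 1, var)
  kindmap <- c(MAG = "MAG", GRAD1 = "GRAD", GRAD2 = "GRAD")
  want <- cfg$sensor_noise_sd[kindmap[arr$channels$kind]]^2
  expect_true(all(abs(v / want - 1) < 0.1))
  r <- cor(er$values[1, ], er$values[2, ])
  expect_lt(abs(r), 3 / sqrt(10000))
  expect_error(empty_room_recording(fix_array("EEG"), cfg, 100), "MEG-only")
})

test_that("zero-phase filters pass, stop and de-mean as designed", {
  cfg <- gen_small()
  fs <- 500
  t <- (0:4999) / fs
  mk <- function(x) recording(matrix(x, 1), fs, data.frame(name = "a", kind = "EEG",
                                                           unit = "V", baseline = NA),
                              data.frame(label = character(), onset = numeric(),
                                         duration = numeric()), "simulated")
  x12 <- sin(2 * pi * 12 * t)
  y12 <- filter_recording(mk(x12), "band10_15")$values[1, ]
  core <- 1000:4000
  expect_gt(sqrt(mean(y12[core]^2)) / sqrt(0.5), 0.95)
  # zero phase: peak cross-correlation at zero lag
  cc <- ccf(y12[core], x12[core], lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  x25 <- sin(2 * pi * 25 * t)
  y25 <- filter_recording(mk(x25), "band10_15")$values[1, ]
  expect_lt(sqrt(mean(y25[core]^2)) / sqrt(0.5), 0.05)
  ydc <- filter_recording(mk(rep(1, 5000)), "band10_15")$values[1, ]
  expect_lt(abs(mean(ydc[core])), 1e-6)
  expect_error(filter_recording(mk(rnorm(100)), "band10_15"), "too short")
  slow <- recording(matrix(rnorm(500), 1), 60,
                    data.frame(name = "a", kind = "EEG", unit = "V", baseline = NA),
                    data.frame(label = character(), onset = numeric(),
                               duration = numeric()), "simulated")
  expect_error(filter_recording(slow, "lowpass40"), "sampling rate")
})

test_that("default design yields the intended event and epoch counts", {
  cfg <- generator_config()
  expect_equal(cfg$n_subjects * cfg$spindles_per_subject, 84)  # ~85 events
  expect_equal(cfg$quiet_epochs_per_subject, 100L)
  expect_equal(cfg$quiet_epoch_duration, 0.6)
  expect_error(generator_config(sampling_rate = 250), "500 or 600")
  expect_error(generator_config(matrix_amplitude = -1), "nonnegative")
})

test_that("EEG prefers the matrix system and MEG the core system", {
  ss <- fix_ss()
  cfg <- generator_config()
  ev <- sample_spindle_events(cfg, ss, seed = 11)[[1]]
  am <- synthesize_matrix_activity(ev, ss, cfg)
  ac <- synthesize_core_activity(ev, ss, cfg)
  pw <- function(gain, act) {
    Gn <- spindlesync:::gain_along_normals(gain)
    kindmap <- c(EEG = "EEG", MAG = "MAG", GRAD1 = "GRAD", GRAD2 = "GRAD")
    sds <- cfg$sensor_noise_sd[kindmap[gain$channels$kind]]
    mean(((Gn[, act$source_index, drop = FALSE] %*% act$values) / sds)^2)
  }
  ratio_eeg <- pw(fix_gain("EEG"), am) / pw(fix_gain("EEG"), ac)
  ratio_meg <- pw(fix_gain("MEG"), am) / pw(fix_gain("MEG"), ac)
  expect_gt(ratio_eeg, ratio_meg)
})
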