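test_that("baseline covariance follows the averaged-epoch convention", {
  set.seed(20)
  K <- 100
  epochs <- lapply(seq_len(K), function(i) matrix(rnorm(5 * 300, sd = 2), 5, 300))
  nc <- estimate_noise_covariance(epochs, "baseline_epochs",
                                  channel_names = letters[1:5])
  # averaging K iid epochs scales the variance by 1/K
  expect_true(all(abs(nc$diagonal / (4 / K) - 1) < 0.25))
  expect_identical(nc$n_epochs_used, 100L)
  # identical epochs: diagonal equals the per-epoch variance exactly
  one <- matrix(rnorm(5 * 300), 5, 300)
  nc2 <- estimate_noise_covariance(rep(list(one), 12), "baseline_epochs",
                                   channel_names = letters[1:5])
  expect_equal(nc2$diagonal, unname(apply(one, 1, var)), tolerance = 1e-12)
  expect_error(estimate_noise_covariance(epochs[1:5], "baseline_epochs"),
               "fewer than 10")
  expect_error(estimate_noise_covariance(rep(list(one, one[1:3, ]), 6),
                                         "baseline_epochs"),
               "share one channel")
})

test_that("empty-room covariance is the raw per-channel variance", {
  set.seed(21)
  x <- matrix(rnorm(4 * 5000, sd = 3), 4, 5000)
  rownames(x) <- paste0("m", 1:4)
  nc <- estimate_noise_covariance(x, "empty_room")
  expect_equal(nc$diagonal, unname(apply(x, 1, var)))
  expect_identical(nc$provenance, "empty_room")
})

test_that("with identity covariance and no regularization W is the pseudoinverse", {
  set.seed(22)
  G <- qr.Q(qr(matrix(rnorm(30 * 12), 30, 12)))  # orthonormal columns
  G <- t(G)                                      # 12 channels, orthonormal rows
  gain <- structure(list(values = G,
                         channels = data.frame(name = paste0("c", 1:12),
                                               kind = "EEG", unit = "V",
                                               baseline = NA),
                         modality = "EEG", source_order = 1:10,
                         source_orientations = matrix(rnorm(30), 10, 3),
                         nominal_spacing = 0.01),
                    class = "gain_matrix")
  nc <- structure(list(diagonal = rep(1, 12), channel_order = paste0("c", 1:12),
                       provenance = "baseline_epochs", n_epochs_used = 100L),
                  class = "noise_covariance")
  op <- compute_inverse_operator(gain, nc, snr = 1e6)
  expect_equal(op$weights, MASS::ginv(G), tolerance = 1e-6)
  expect_true(all(op$dspm_norm > 0))
  bad <- gain
  bad$values[, 4:6] <- 0
  expect_error(compute_inverse_operator(bad, nc), "all-zero gain column triplet")
  expect_error(compute_inverse_operator(gain, nc, snr = -1), "positive")
})

test_that("dSPM F is quadratic in the data and zero for zero input", {
  gain <- fix_gain("MEG")
  op <- compute_inverse_operator(gain, fix_noise_cov(gain), snr = 2)
  set.seed(23)
  x <- matrix(rnorm(306 * 50), 306, 50) * 1e-13
  est <- apply_dspm(op, x)
  est3 <- apply_dspm(op, 3 * x)
  expect_equal(est3$values^2, 9 * est$values^2, tolerance = 1e-12)
  z <- apply_dspm(op, matrix(0, 306, 4))
  expect_true(all(z$values == 0))
})

test_that("F is invariant to rotating the global dipole axes", {
  gain <- fix_gain("MEG")
  nc <- fix_noise_cov(gain)
  theta <- 0.7
  R <- matrix(c(cos(theta), -sin(theta), 0, sin(theta), cos(theta), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  rot <- gain
  n_src <- ncol(gain$values) / 3
  for (j in seq_len(n_src))
    rot$values[, 3 * (j - 1) + 1:3] <- gain$values[, 3 * (j - 1) + 1:3] %*% t(R)
  op1 <- compute_inverse_operator(gain, nc, snr = 2)
  op2 <- compute_inverse_operator(rot, nc, snr = 2)
  set.seed(24)
  x <- matrix(rnorm(306 * 20), 306, 20) * 1e-13
  F1 <- apply_dspm(op1, x)$values^2
  F2 <- apply_dspm(op2, x)$values^2
  expect_lt(max(abs(F1 - F2)) / max(F1), 1e-10)
  expect_equal(op1$dof, op2$dof, tolerance = 1e-9)
})

test_that("changing a channel's units leaves the estimate unchanged", {
  gain <- fix_gain("EEG")
  nc <- fix_noise_cov(gain)
  set.seed(25)
  x <- matrix(rnorm(60 * 30), 60, 30) * 1e-6
  est <- apply_dspm(compute_inverse_operator(gain, nc, snr = 2), x)
  a <- 1e3   # express channel 7 in different units
  gain2 <- gain
  gain2$values[7, ] <- a * gain2$values[7, ]
  nc2 <- nc
  nc2$diagonal[7] <- a^2 * nc2$diagonal[7]
  x2 <- x
  x2[7, ] <- a * x2[7, ]
  est2 <- apply_dspm(compute_inverse_operator(gain2, nc2, snr = 2), x2)
  expect_equal(est2$values, est$values, tolerance = 1e-9)
})

test_that("pure noise from C gives E[F] = 1 and uniform p-values", {
  gain <- fix_gain("MEG")
  nc <- fix_noise_cov(gain)
  op <- compute_inverse_operator(gain, nc, snr = 1)
  set.seed(26)
  X <- matrix(rnorm(306 * 2000), 306, 2000) * sqrt(nc$diagonal)
  est <- apply_dspm(op, X)
  expect_equal(mean(est$values^2), 1, tolerance = 0.05)
  # per-sample p-values for a spread of sources, Satterthwaite numerator dof
  src <- seq(1, 300, by = 6)
  p <- as.vector(pf(est$values[src, ]^2, op$dof[src], 1e9, lower.tail = FALSE))
  expect_lt(suppressWarnings(ks.test(p, "punif")$statistic), 0.02)
})

test_that("f_significance reproduces the chi-square tail and monotonicity", {
  est <- structure(list(values = matrix(1, 3, 1), sampling_rate = 500,
                        modality = "MEG", dof = rep(3, 3), interval = NULL,
                        component = "magnitude"),
                   class = "source_estimate")
  p <- f_significance(est, n_noise_dof = 1e9)
  expect_equal(unname(p[1]), pchisq(3, df = 3, lower.tail = FALSE), tolerance = 1e-4)
  expect_equal(unname(p[1]), 0.3916, tolerance = 1e-3)
  big <- est
  big$values[] <- 5
  expect_true(all(f_significance(big, 1e9) < p))
  expect_error(f_significance(est, 2), "at least 3")
})

test_that("localization of isolated superficial tangential dipoles is tight", {
  ss <- fix_ss()
  gain <- fix_gain("MEG")
  op <- compute_inverse_operator(gain, fix_noise_cov(gain), snr = 4)
  Gn <- spindlesync:::gain_along_normals(gain)
  rhat <- ss$positions / sqrt(rowSums(ss$positions^2))
  tangential <- which(abs(rowSums(ss$orientations * rhat)) < 0.7)
  set.seed(27)
  err <- sapply(sample(tangential, 50), function(j) {
    est <- apply_dspm(op, Gn[, j, drop = FALSE] * 2e-8)
    jh <- which.max(est$values[, 1])
    sqrt(sum((ss$positions[jh, ] - ss$positions[j, ])^2))
  })
  expect_lte(median(err), 2 * ss$nominal_spacing)
})

test_that("combined operator degenerates to the single-modality solution", {
  ge <- fix_gain("EEG")
  gm <- fix_gain("MEG")
  nce <- fix_noise_cov(ge)
  ncm <- fix_noise_cov(gm, seed = 12)
  gm0 <- gm
  gm0$values[] <- 0
  # MEG block zeroed: combined estimate equals the EEG-only estimate
  expect_error(compute_inverse_operator(gm0, ncm), "all-zero")
  op_c <- combined_inverse(ge, gm0, nce, ncm, snr = 2)
  # same weights family: match the regularization, which is normalized by the
  # stacked channel count (366 vs 60)
  op_e <- compute_inverse_operator(ge, nce, snr = 2 * sqrt(366 / 60))
  set.seed(28)
  xe <- matrix(rnorm(60 * 25), 60, 25) * 1e-6
  x <- rbind(xe, matrix(0, 306, 25))
  expect_equal(apply_dspm(op_c, x)$values, apply_dspm(op_e, xe)$values,
               tolerance = 1e-8)
})

test_that("combined operator stays noise-calibrated under modality weighting", {
  ge <- fix_gain("EEG")
  gm <- fix_gain("MEG")
  nce <- fix_noise_cov(ge)
  ncm <- fix_noise_cov(gm, seed = 12)
  op <- combined_inverse(ge, gm, nce, ncm, snr = 1)
  set.seed(29)
  X <- rbind(matrix(rnorm(60 * 1500), 60, 1500) * sqrt(nce$diagonal),
             matrix(rnorm(306 * 1500), 306, 1500) * sqrt(ncm$diagonal))
  est <- apply_dspm(op, X)
  expect_equal(mean(est$values^2), 1, tolerance = 0.05)
})

test_that("baseline-epoch and empty-room normalizations agree spatially", {
  ss <- fix_ss()
  gain <- subset_gain(fix_gain("MEG"), c("GRAD1", "GRAD2"))
  gr <- grepl("GRAD", fix_gain("MEG")$channels$kind)
  cfg <- generator_config(n_subjects = 1L, spindles_per_subject = 3L,
                          quiet_epochs_per_subject = 30L, seed = 31)
  ev <- sample_spindle_events(cfg, ss, seed = 31)
  acts <- list()
  for (e in ev) {
    acts[[length(acts) + 1]] <- synthesize_matrix_activity(e, ss, cfg)
    acts[[length(acts) + 1]] <- synthesize_core_activity(e, ss, cfg)
  }
  ns <- round(attr(ev, "record_duration") * cfg$sampling_rate)
  acts[[length(acts) + 1]] <- synthesize_background(ns, ss, cfg, seed = 31)
  rec <- render_recording(acts, fix_gain("MEG"), cfg, seed = 32, n_samples = ns)
  rec <- filter_recording(rec, "lowpass40")
  ep <- annotated_segments(filter_recording(rec, "band10_15"), "quiet_epoch")
  ep <- lapply(ep, function(m) m[gr, , drop = FALSE])
  nc_base <- estimate_noise_covariance(ep, "baseline_epochs",
                                       channel_names = gain$channels$name)
  er <- empty_room_recording(fix_array("MEG"), cfg, n_samples = 8000, seed = 33)
  nc_er <- estimate_noise_covariance(er$values[gr, ], "empty_room",
                                     channel_names = gain$channels$name)
  sp <- rec$annotations[rec$annotations$label == "spindle", ][1, ]
  seg <- recording_segment(rec, sp$onset, sp$duration)[gr, ]
  m_base <- rowMeans(apply_dspm(compute_inverse_operator(gain, nc_base, 4), seg)$values^2)
  m_er <- rowMeans(apply_dspm(compute_inverse_operator(gain, nc_er, 4), seg)$values^2)
  expect_gt(cor(m_base, m_er), 0.9)
})
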