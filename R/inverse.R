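# Noise covariance estimation and noise-normalized minimum-norm (dSPM)
# source estimation for EEG-only, MEG-only and combined data.

#' Estimate a diagonal noise covariance
#'
#' Baseline mode reproduces the evoked-response convention: the K quiet
#' epochs are averaged sample-wise and the diagonal is the per-channel
#' variance of the averaged trace (so the variance scales ~1/K; the same
#' covariance is used for data whitening and noise normalization, keeping
#' the F statistic internally calibrated). Empty-room mode takes the
#' per-channel variance of one long raw recording.
#'
#' @param epochs List of channels x samples matrices (baseline mode, all the
#'   same shape, at least 10), or a single matrix / `recording`
#'   (empty-room mode).
#' @param mode `"baseline_epochs"` or `"empty_room"`.
#' @param channel_names Optional channel names (taken from matrix rownames
#'   otherwise).
#' @return A `noise_covariance`: `diagonal` (channel units squared),
#'   `channel_order`, `provenance`, `n_epochs_used`.
#' @export
estimate_noise_covariance <- function(epochs,
                                      mode = c("baseline_epochs", "empty_room"),
                                      channel_names = NULL) {
  mode <- match.arg(mode)
  if (inherits(epochs, "recording")) {
    channel_names <- channel_names %||% epochs$channels$name
    epochs <- epochs$values
  }
  if (mode == "baseline_epochs") {
    if (!is.list(epochs)) stop("baseline mode expects a list of epoch matrices")
    if (length(epochs) < 10) stop("fewer than 10 epochs: covariance unstable")
    dims <- vapply(epochs, dim, c(0L, 0L))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("epochs must share one channel set and length")
    avg <- Reduce(`+`, epochs) / length(epochs)
    d <- apply(avg, 1, stats::var)
    n_used <- length(epochs)
    channel_names <- channel_names %||% rownames(avg)
  } else {
    if (is.list(epochs)) stop("empty-room mode expects one long recording")
    d <- apply(epochs, 1, stats::var)
    n_used <- 1L
    channel_names <- channel_names %||% rownames(epochs)
  }
  if (any(d <= 0)) stop("non-positive channel variance at index ",
                        paste(which(d <= 0), collapse = ", "))
  structure(list(diagonal = as.numeric(d),
                 channel_order = channel_names,
                 provenance = mode, n_epochs_used = n_used),
            class = "noise_covariance")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.noise_covariance <- function(x, ...) {
  cat(sprintf("diagonal noise covariance (%s): %d channels, %d epoch(s)\n",
              x$provenance, length(x$diagonal), x$n_epochs_used))
  invisible(x)
}

# Core operator computation in whitened coordinates (C = I).
# Gw: whitened gain; white: per-channel 1/sd applied to raw data.
inverse_operator_core <- function(Gw, white, snr, modality, channels,
                                  source_orientations = NULL, noise_var_w = 1) {
  n_src <- ncol(Gw) / 3L
  colnorm <- sqrt(colSums(Gw^2))
  dead <- which(vapply(seq_len(n_src), function(j)
    all(colnorm[3 * (j - 1) + 1:3] == 0), TRUE))
  if (length(dead) > 0)
    stop("all-zero gain column triplet(s) at source index ",
         paste(utils::head(dead, 10), collapse = ", "))
  if (!is.numeric(snr) || snr <= 0) stop("snr must be a positive scalar")
  lambda2 <- sum(Gw^2) / (nrow(Gw) * snr^2)
  M <- tcrossprod(Gw)
  diag(M) <- diag(M) + lambda2
  Ww <- t(solve(M, Gw))          # (3 n_src) x n_channels, whitened coords
  # per-channel noise variance in the (possibly block-rescaled) whitened
  # coordinates; 1 for plain whitening
  nv <- rep_len(noise_var_w, ncol(Ww))
  dspm_norm <- numeric(n_src)
  dof <- numeric(n_src)
  Wn <- Ww * rep(sqrt(nv), each = nrow(Ww))
  for (j in seq_len(n_src)) {
    rows <- 3L * (j - 1L) + 1:3
    blk <- tcrossprod(Wn[rows, , drop = FALSE])
    ev <- pmax(0, eigen(blk, symmetric = TRUE, only.values = TRUE)$values)
    dspm_norm[j] <- sum(ev) / 3
    dof[j] <- if (sum(ev) > 0) sum(ev)^2 / sum(ev^2) else 3
  }
  if (any(dspm_norm <= 0)) stop("non-positive dSPM noise sensitivity")
  W <- Ww * rep(white, each = nrow(Ww))
  structure(list(weights = W, regularization = lambda2,
                 source_covariance_scale = 1,
                 dspm_norm = dspm_norm, dof = dof,
                 whitener = white, modality = modality, channels = channels,
                 source_orientations = source_orientations),
            class = "inverse_operator")
}

#' Compute a dSPM inverse operator
#'
#' Minimum-norm weights `W = R G' (G R G' + lambda^2 C)^{-1}` with identity
#' source covariance, computed in whitened coordinates (channels divided by
#' their noise SD, so C becomes the identity). The regularization is
#' `lambda^2 = trace(G~ R G~') / (n_channels * snr^2)` on the whitened gain
#' `G~`. `dspm_norm[i]` is the mean noise variance of source i's three
#' components (diagonal of `W C W'`), the denominator of the dSPM F
#' statistic; `dof[i]` is the Satterthwaite effective dof of the component
#' noise mixture (3 when the three component variances are equal).
#'
#' @param gain A [assemble_gain()] gain matrix.
#' @param noise A [estimate_noise_covariance()] with matching channel order.
#' @param snr Assumed amplitude SNR; default 1 for unaveraged single-trial
#'   data.
#' @return An `inverse_operator`.
#' @export
compute_inverse_operator <- function(gain, noise, snr = 1) {
  stopifnot(inherits(gain, "gain_matrix"), inherits(noise, "noise_covariance"))
  if (!identical(as.character(noise$channel_order), as.character(gain$channels$name)))
    stop("channel order of gain and noise covariance differ")
  white <- 1 / sqrt(noise$diagonal)
  Gw <- gain$values * white
  inverse_operator_core(Gw, white, snr, gain$modality, gain$channels,
                        gain$source_orientations)
}

#' Combined EEG+MEG inverse operator
#'
#' Each modality's gain and data are whitened by its own diagonal noise
#' covariance, stacked into one system (EEG rows first), and solved with
#' identity noise covariance in the whitened coordinates. The combined
#' solution fits the spatial patterns of both modalities; the relative
#' scaling between modalities that a joint fit should assume is not
#' identifiable from the data themselves, so by default each whitened block
#' is additionally rescaled to equal total gain power
#' (`modality_weighting = "equal_power"`), giving both spatial patterns
#' equal a priori weight; `"none"` keeps plain per-channel whitening. The
#' noise normalization accounts for the rescaling, so the F statistic stays
#' calibrated either way.
#'
#' @param gain_eeg,gain_meg Per-modality gain matrices on the same source
#'   space.
#' @param noise_eeg,noise_meg Matching noise covariances.
#' @param snr Assumed amplitude SNR.
#' @param modality_weighting `"equal_power"` or `"none"`.
#' @return An `inverse_operator` with modality `"combined"`.
#' @export
combined_inverse <- function(gain_eeg, gain_meg, noise_eeg, noise_meg, snr = 1,
                             modality_weighting = c("equal_power", "none")) {
  modality_weighting <- match.arg(modality_weighting)
  stopifnot(inherits(gain_eeg, "gain_matrix"), inherits(gain_meg, "gain_matrix"))
  if (ncol(gain_eeg$values) != ncol(gain_meg$values))
    stop("EEG and MEG gains must share one source space")
  if (!identical(as.character(noise_eeg$channel_order), as.character(gain_eeg$channels$name)) ||
      !identical(as.character(noise_meg$channel_order), as.character(gain_meg$channels$name)))
    stop("channel order of gain and noise covariance differ")
  we <- 1 / sqrt(noise_eeg$diagonal)
  wm <- 1 / sqrt(noise_meg$diagonal)
  Ge <- gain_eeg$values * we
  Gm <- gain_meg$values * wm
  se <- sm <- 1
  if (modality_weighting == "equal_power") {
    pe <- sum(Ge^2)
    pm <- sum(Gm^2)
    if (pe > 0 && pm > 0) {
      # scale each block to the geometric-mean power
      se <- (pm / pe)^0.25
      sm <- (pe / pm)^0.25
    }
  }
  Gw <- rbind(Ge * se, Gm * sm)
  channels <- rbind(gain_eeg$channels, gain_meg$channels)
  inverse_operator_core(Gw, c(we * se, wm * sm), snr, "combined", channels,
                        gain_eeg$source_orientations,
                        noise_var_w = c(rep(se^2, nrow(Ge)), rep(sm^2, nrow(Gm))))
}

#' @export
print.inverse_operator <- function(x, ...) {
  cat(sprintf("dSPM inverse operator (%s): %d sources, %d channels, lambda^2 = %.3g\n",
              x$modality, length(x$dspm_norm), ncol(x$weights), x$regularization))
  invisible(x)
}

#' Apply a dSPM operator to a recording interval
#'
#' For source i and sample t, the noise-normalized local power is
#' `F(i,t) = ||(W x(t))_i||^2 / (3 * dspm_norm[i])` (sum of squared dipole
#' component strengths over the summed component noise variances); the
#' stored value is `sqrt(F)`, so `E[F] = 1` under pure noise drawn from the
#' operator's covariance.
#'
#' @param op An `inverse_operator`.
#' @param rec A `recording` (or channels x samples matrix) whose channels
#'   match the operator.
#' @param interval Optional `c(onset, duration)` in seconds restricting the
#'   estimate to an annotated interval.
#' @param component `"magnitude"` returns the nonnegative `sqrt(F)` (the
#'   quantity mapped on the cortex); `"signed"` returns the noise-normalized
#'   signed amplitude of the component along the source's surface normal,
#'   which carries oscillatory phase and is the appropriate input for
#'   phase-sensitive correlation statistics.
#' @return A `source_estimate`: `values` (n_sources x n_samples),
#'   `sampling_rate`, `modality`, per-source `dof`, `component`.
#' @export
apply_dspm <- function(op, rec, interval = NULL,
                       component = c("magnitude", "signed")) {
  component <- match.arg(component)
  stopifnot(inherits(op, "inverse_operator"))
  if (inherits(rec, "recording")) {
    if (!identical(as.character(rec$channels$name), as.character(op$channels$name)))
      stop("recording channels do not match the operator")
    x <- if (is.null(interval)) rec$values
    else recording_segment(rec, interval[1], interval[2])
    fs <- rec$sampling_rate
  } else {
    x <- rec
    if (nrow(x) != ncol(op$weights)) stop("channel count mismatch")
    fs <- NA_real_
  }
  WX <- op$weights %*% x
  n_src <- length(op$dspm_norm)
  if (component == "magnitude") {
    p <- WX[seq(1, 3 * n_src, 3), , drop = FALSE]^2 +
      WX[seq(2, 3 * n_src, 3), , drop = FALSE]^2 +
      WX[seq(3, 3 * n_src, 3), , drop = FALSE]^2
    vals <- sqrt(p / (3 * op$dspm_norm))
  } else {
    ori <- op$source_orientations
    if (is.null(ori)) stop("operator carries no source orientations")
    vals <- (ori[, 1] * WX[seq(1, 3 * n_src, 3), , drop = FALSE] +
               ori[, 2] * WX[seq(2, 3 * n_src, 3), , drop = FALSE] +
               ori[, 3] * WX[seq(3, 3 * n_src, 3), , drop = FALSE]) /
      sqrt(3 * op$dspm_norm)
  }
  structure(list(values = vals, sampling_rate = fs, modality = op$modality,
                 dof = op$dof, interval = interval, component = component),
            class = "source_estimate")
}

#' @export
print.source_estimate <- function(x, ...) {
  cat(sprintf("source estimate (%s): %d sources x %d samples (sqrt dSPM F)\n",
              x$modality, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' F-test significance of source activity
#'
#' The time-averaged F statistic per source is referred to an F reference
#' distribution. The numerator dof is the per-source effective dof of the
#' three-component noise mixture (3 for equal component variances, as in the
#' classical three-component F-test) times the number of samples averaged;
#' the denominator dof reflects the noise samples behind the covariance.
#'
#' @param est A `source_estimate`.
#' @param n_noise_dof Denominator degrees of freedom (>= 3); use a large
#'   value (e.g. `1e9`) for an effectively known noise covariance.
#' @return Upper-tail p-value per source.
#' @export
f_significance <- function(est, n_noise_dof) {
  stopifnot(inherits(est, "source_estimate"))
  if (n_noise_dof < 3) stop("n_noise_dof must be at least 3")
  Fbar <- rowMeans(est$values^2)
  df1 <- (est$dof %||% 3) * ncol(est$values)
  stats::pf(Fbar, df1, n_noise_dof, lower.tail = FALSE)
}
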