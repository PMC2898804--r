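# Source-space synchrony and topography statistics: mean pairwise
# correlation, between-modality correlation, Welch and MVDR band coherence,
# per-spindle maximum activation maps and map correlation.

est_values <- function(est) {
  if (inherits(est, "source_estimate")) est$values else as.matrix(est)
}

#' Mean pairwise correlation across sources
#'
#' Mean over all unordered distinct source pairs (self-pairs excluded) of
#' the zero-lag Pearson correlation of the two sources' time courses. The
#' default path uses the identity
#' `mean_r = (||sum_j z_j||^2 / T - n) / (n (n - 1))` on rows standardized
#' to zero mean and unit (population) variance, which is O(n T); the
#' brute-force double loop is retained for verification.
#'
#' @param est A `source_estimate` or numeric matrix (sources x samples).
#' @param method `"identity"` (fast) or `"brute"` (reference double loop).
#' @return Scalar mean pairwise correlation. Zero-variance rows are dropped
#'   with a message; fewer than 2 variable rows is an error. The number of
#'   pairs used is attached as attribute `n_pairs`.
#' @export
mean_pairwise_correlation <- function(est, method = c("identity", "brute")) {
  method <- match.arg(method)
  x <- est_values(est)
  if (nrow(x) < 2 || ncol(x) < 8)
    stop("need at least 2 sources and 8 samples")
  T <- ncol(x)
  mu <- rowMeans(x)
  sd_pop <- sqrt(rowMeans(x^2) - mu^2)
  keep <- sd_pop > 0
  if (sum(!keep) > 0)
    message(sum(!keep), " constant row(s) excluded from pairwise correlation")
  if (sum(keep) < 2) stop("fewer than 2 non-constant rows")
  z <- (x[keep, , drop = FALSE] - mu[keep]) / sd_pop[keep]
  n <- nrow(z)
  r <- if (method == "identity") {
    (sum(colSums(z)^2) / T - n) / (n * (n - 1))
  } else {
    acc <- 0
    for (j in seq_len(n - 1))
      acc <- acc + sum((z[(j + 1):n, , drop = FALSE] %*% z[j, ]) / T)
    acc / n_source_pairs(n)
  }
  structure(r, n_pairs = n_source_pairs(n))
}

#' Between-modality correlation of source estimates
#'
#' Zero-lag Pearson correlation, per source, of the same dipole's activity
#' as estimated from the two modalities, averaged over sources.
#'
#' @param est_eeg,est_meg Source estimates on the same source space and
#'   interval.
#' @return Mean per-source correlation (attribute `per_source` holds the
#'   vector).
#' @export
between_modality_correlation <- function(est_eeg, est_meg) {
  a <- est_values(est_eeg)
  b <- est_values(est_meg)
  if (!all(dim(a) == dim(b)))
    stop("estimates differ in source count or interval length")
  sda <- apply(a, 1, stats::sd)
  sdb <- apply(b, 1, stats::sd)
  keep <- sda > 0 & sdb > 0
  if (!any(keep)) stop("no source with variance in both estimates")
  r <- vapply(which(keep), function(i) stats::cor(a[i, ], b[i, ]), 0)
  structure(mean(r), per_source = r)
}

#' Welch magnitude-squared band coherence
#'
#' Magnitude-squared coherence `|S_xy|^2 / (S_x S_y)` from Hann-windowed,
#' overlapping segment-averaged periodograms, averaged over the frequency
#' bins inside the band.
#'
#' @param x,y Equal-length numeric time series.
#' @param sampling_rate Hz.
#' @param segment_length Samples per segment (default 256).
#' @param overlap Fractional segment overlap (default 0.5).
#' @param band Frequency band in Hz (default 10–15, the spindle band).
#' @return Band-averaged magnitude-squared coherence in [0, 1].
#' @export
welch_coherence <- function(x, y, sampling_rate, segment_length = 256,
                            overlap = 0.5, band = c(10, 15)) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2 * segment_length)
    stop("series must be at least twice the segment length")
  L <- as.integer(segment_length)
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq(1L, length(x) - L + 1L, by = step)
  if (length(starts) < 2)
    stop("a single segment makes coherence identically 1; use shorter segments")
  w <- hann_window(L)
  Sxx <- Syy <- numeric(L)
  Sxy <- complex(L)
  for (s in starts) {
    seg <- s:(s + L - 1L)
    fx <- stats::fft((x[seg] - mean(x[seg])) * w)
    fy <- stats::fft((y[seg] - mean(y[seg])) * w)
    Sxx <- Sxx + Mod(fx)^2
    Syy <- Syy + Mod(fy)^2
    Sxy <- Sxy + fx * Conj(fy)
  }
  freqs <- (seq_len(L) - 1) * sampling_rate / L
  sel <- which(freqs >= band[1] & freqs <= band[2])
  if (length(sel) == 0)
    sel <- which.min(abs(freqs[seq_len(floor(L / 2))] - mean(band)))
  msc <- Mod(Sxy[sel])^2 / (Sxx[sel] * Syy[sel])
  mean(pmin(1, msc))
}

# MVDR (Capon) spectrum of one series on a frequency grid: the output power
# of the data-adaptive distortionless filter bank, S(f) = L / (e^H R^-1 e).
mvdr_spectrum <- function(x, sampling_rate, filter_length = 64, freqs,
                          loading = 1e-6) {
  L <- as.integer(filter_length)
  E <- steering_matrix(freqs, L, sampling_rate)
  R <- lag_covariance(x, L, loading)
  Ri <- chol2inv(chol(R))
  vapply(seq_along(freqs), function(k) {
    e <- E[, k]
    L / Re(Conj(e) %*% Ri %*% e)[1]
  }, 0)
}

steering_matrix <- function(freqs, L, fs) {
  outer(0:(L - 1), freqs, function(l, f) exp(-2i * pi * f * l / fs))
}

lag_covariance <- function(x, L, loading, y = NULL) {
  T <- length(x)
  n <- T - L + 1L
  X <- sapply(seq_len(L), function(l) x[(L - l + 1):(T - l + 1)])
  if (is.null(y)) {
    R <- crossprod(X) / n
    R + loading * mean(diag(R)) * diag(L)
  } else {
    Y <- sapply(seq_len(L), function(l) y[(L - l + 1):(T - l + 1)])
    crossprod(X, Y) / n
  }
}

#' MVDR (Capon) band coherence
#'
#' Coherence from data- and frequency-dependent minimum variance
#' distortionless response filter banks: with `h_x = R_x^-1 e / (e^H R_x^-1
#' e)` the distortionless filter for series x at frequency f (and likewise
#' h_y), the cross-spectrum is the covariance of the two filter outputs,
#' `S_xy = h_x^H R_xy h_y`, and the magnitude-squared coherence
#' `|S_xy|^2 / (S_x S_y)` is bounded by 1 by Cauchy–Schwarz. Values are
#' averaged over a grid of frequencies spanning the band. MVDR's
#' data-adaptive filters discriminate nearby frequencies better than
#' fixed-window (Welch) estimates at equal data length.
#'
#' @param x,y Equal-length series, length at least `20 * filter_length`.
#' @param sampling_rate Hz.
#' @param filter_length MVDR filter length L (at least 8).
#' @param band Frequency band (Hz).
#' @param loading Diagonal loading factor (fraction of the mean tap
#'   variance) stabilizing the covariance inverses.
#' @param n_freqs Number of band frequencies averaged.
#' @return Band-averaged magnitude-squared MVDR coherence in [0, 1].
#' @export
mvdr_coherence <- function(x, y, sampling_rate, filter_length = 64,
                           band = c(10, 15), loading = 1e-6, n_freqs = 6) {
  stopifnot(length(x) == length(y))
  L <- as.integer(filter_length)
  if (L < 8) stop("filter_length must be at least 8")
  if (length(x) < 20 * L)
    stop("series length must be at least 20 * filter_length")
  freqs <- seq(band[1], band[2], length.out = n_freqs)
  E <- steering_matrix(freqs, L, sampling_rate)
  Rx <- lag_covariance(x, L, loading)
  Ry <- lag_covariance(y, L, loading)
  Rxy <- lag_covariance(x, L, loading, y = y)
  Rxi <- chol2inv(chol(Rx))
  Ryi <- chol2inv(chol(Ry))
  msc <- vapply(seq_along(freqs), function(k) {
    e <- E[, k]
    ax <- Rxi %*% e
    ay <- Ryi %*% e
    qx <- Re(Conj(e) %*% ax)[1]   # e^H Rx^-1 e
    qy <- Re(Conj(e) %*% ay)[1]
    hx <- ax / qx
    hy <- ay / qy
    Sxy <- (t(Conj(hx)) %*% Rxy %*% hy)[1]
    Sx <- 1 / qx
    Sy <- 1 / qy
    min(1, Mod(Sxy)^2 / (Sx * Sy))
  }, 0)
  mean(msc)
}

#' Per-spindle maximum activation map
#'
#' Per-source maximum of the dSPM value over the spindle interval.
#'
#' @param est A `source_estimate`.
#' @return An `activation_map` with raw normalization.
#' @export
spindle_max_map <- function(est) {
  x <- est_values(est)
  if (ncol(x) < 1) stop("empty interval")
  structure(list(values = apply(x, 1, max), normalization = "raw",
                 modality = if (inherits(est, "source_estimate")) est$modality else NA,
                 n_spindles = 1L),
            class = "activation_map")
}

#' Average maximum maps and normalize to the maximum
#'
#' Element-wise mean of per-spindle maximum maps, divided by the global
#' maximum (so the output maximum is exactly 1).
#'
#' @param maps Nonempty list of `activation_map`s on one source space.
#' @return An `activation_map` with normalization `"max1"`.
#' @export
average_max_maps <- function(maps) {
  if (length(maps) == 0) stop("empty map list")
  n <- vapply(maps, function(m) length(m$values), 0L)
  if (any(n != n[1])) stop("maps differ in source count")
  avg <- Reduce(`+`, lapply(maps, `[[`, "values")) / length(maps)
  structure(list(values = avg / max(avg), normalization = "max1",
                 modality = maps[[1]]$modality,
                 n_spindles = sum(vapply(maps, `[[`, 0L, "n_spindles"))),
            class = "activation_map")
}

#' Correlation of two activation maps
#'
#' Pearson correlation over sources of the two maps' values.
#'
#' @param a,b `activation_map`s on one source space.
#' @return Scalar correlation.
#' @export
map_correlation <- function(a, b) {
  stopifnot(inherits(a, "activation_map"), inherits(b, "activation_map"))
  if (length(a$values) != length(b$values)) stop("maps differ in source count")
  if (stats::sd(a$values) == 0 || stats::sd(b$values) == 0)
    stop("zero-variance map")
  stats::cor(a$values, b$values)
}

#' Mean power time course
#'
#' Per-sample mean over sources of the squared dSPM value (the F statistic).
#' For a pure sinusoidal source the power is modulated at twice the source
#' frequency.
#'
#' @param est A `source_estimate`.
#' @return Numeric vector, one value per sample.
#' @export
mean_power_timecourse <- function(est) {
  x <- est_values(est)
  colMeans(x^2)
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf("activation map (%s, %s): %d sources, %d spindle(s), max %.3g\n",
              x$modality, x$normalization, length(x$values), x$n_spindles,
              max(x$values)))
  invisible(x)
}
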