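# Independent oracles used by the forward-model tests.

# Closed-form surface potential of a dipole inside a homogeneous conducting
# sphere with insulating exterior, derived by summing the Legendre series in
# closed form with generating functions (checked against the classical
# dipole-at-center result V = 3 q.r / (4 pi sigma R^3)). Independent of the
# package's truncated-series implementation.
oracle_homog_sphere_potential <- function(dipole_pos, moment, electrodes, R, sigma) {
  b <- sqrt(sum(dipole_pos^2))
  zhat <- if (b < 1e-12) c(0, 0, 1) else dipole_pos / b
  rhat <- electrodes / sqrt(rowSums(electrodes^2))
  u <- as.vector(pmin(1, pmax(-1, rhat %*% zhat)))
  mr <- sum(moment * zhat)
  qt <- moment - mr * zhat
  that <- rhat - u %*% t(zhat)
  nr <- sqrt(rowSums(that^2))
  ok <- nr > 1e-14
  that[ok, ] <- that[ok, ] / nr[ok]
  that[!ok, ] <- 0
  mt <- as.vector(that %*% qt)
  x <- b / R
  s <- sqrt(1 - 2 * x * u + x^2)
  radial <- if (x > 0) 2 * (u - x) / s^3 + (1 / s - 1) / x else 3 * u
  tangential <- sqrt(pmax(0, 1 - u^2)) * (2 / s^3 + (s + 1) / (s * (1 - x * u + s)))
  (mr * radial + mt * tangential) / (4 * pi * sigma * R^2)
}

# Hand evaluation of the spherical-conductor magnetic field for the textbook
# configuration: tangential y-dipole on the z-axis, sensors on the z-axis.
# Everything reduces to scalars; no vector code shared with the package.
oracle_sarvas_axis_bx <- function(dipole_z, sensor_z, moment_y) {
  a <- sensor_z - dipole_z
  f <- a * (sensor_z * a + sensor_z^2 - dipole_z * sensor_z)
  1e-7 * moment_y * dipole_z / f
}

# Fixture geometry shared by the forward tests (built once per test run).
fixture_env <- new.env()

fix_head <- function() {
  if (is.null(fixture_env$head)) fixture_env$head <- spherical_head_model()
  fixture_env$head
}
fix_array <- function(modality) {
  key <- paste0("arr_", modality)
  if (is.null(fixture_env[[key]]))
    fixture_env[[key]] <- build_sensor_array(modality, fix_head(), seed = 1)
  fixture_env[[key]]
}
# small folded and unfolded source spaces plus their gains
fix_gain <- function(modality, folded = TRUE) {
  key <- paste0("gain_", modality, "_", folded)
  if (is.null(fixture_env[[key]])) {
    sskey <- paste0("ss_", folded)
    if (is.null(fixture_env[[sskey]]))
      fixture_env[[sskey]] <- if (folded)
        build_source_space(150, 0.2, 12, seed = 1)
      else
        build_source_space(150, 0, 0, seed = 1)
    fixture_env[[key]] <- assemble_gain(fixture_env[[sskey]], fix_array(modality), fix_head())
  }
  fixture_env[[key]]
}
fix_ss <- function(folded = TRUE) {
  invisible(fix_gain("EEG", folded))
  fixture_env[[paste0("ss_", folded)]]
}

# random diagonal covariance for operator tests
fix_noise_cov <- function(gain, seed = 11, scale = NULL) {
  set.seed(seed)
  kinds <- gain$channels$kind
  base <- c(EEG = 1e-12, MAG = 1e-27, GRAD1 = 1e-24, GRAD2 = 1e-24)[kinds]
  if (!is.null(scale)) base <- rep(scale, length(kinds))
  structure(list(diagonal = base * stats::runif(length(kinds), 0.5, 2),
                 channel_order = gain$channels$name,
                 provenance = "baseline_epochs", n_epochs_used = 100L),
            class = "noise_covariance")
}
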