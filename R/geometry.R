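# Head geometry, sensor arrays and the cortical source-space surrogate.

#' Three-shell spherical head model
#'
#' Concentric-sphere stand-in for a realistic three-compartment head:
#' brain (inner shell), skull, scalp. EEG potentials are computed by a
#' truncated Legendre series over this geometry; MEG fields use the Sarvas
#' closed form, which depends only on the sphere center.
#'
#' @param center Sphere center in meters (length-3).
#' @param shell_radii Radii of the brain/skull/scalp boundaries in meters,
#'   strictly increasing. Defaults 0.08/0.085/0.092 m.
#' @param conductivities Compartment conductivities in S/m
#'   (brain, skull, scalp). Defaults 0.33/0.0042/0.33 S/m.
#' @param legendre_order Truncation order of the EEG Legendre series
#'   (at least 20).
#' @return An object of class `spherical_head_model`.
#' @examples
#' head <- spherical_head_model()
#' head$shell_radii
#' @export
spherical_head_model <- function(center = c(0, 0, 0),
                                 shell_radii = c(0.08, 0.085, 0.092),
                                 conductivities = c(0.33, 0.0042, 0.33),
                                 legendre_order = 60L) {
  stopifnot(length(center) == 3, is.numeric(center),
            length(shell_radii) == 3, length(conductivities) == 3)
  if (any(diff(shell_radii) <= 0))
    stop("shell_radii must be strictly increasing (inner to outer)")
  if (any(conductivities <= 0)) stop("conductivities must be positive")
  legendre_order <- as.integer(legendre_order)
  if (legendre_order < 20L) stop("legendre_order must be at least 20")
  structure(list(center = as.numeric(center),
                 shell_radii = as.numeric(shell_radii),
                 conductivities = as.numeric(conductivities),
                 legendre_order = legendre_order),
            class = "spherical_head_model")
}

#' @export
print.spherical_head_model <- function(x, ...) {
  cat("Three-shell spherical head model\n")
  cat(sprintf("  shell radii (m): %s\n", paste(x$shell_radii, collapse = " / ")))
  cat(sprintf("  conductivities (S/m): %s\n", paste(x$conductivities, collapse = " / ")))
  cat(sprintf("  Legendre order: %d\n", x$legendre_order))
  invisible(x)
}

# Fibonacci lattice on the unit sphere; frac < 1 restricts to the upper cap
# (z in (1-2*frac, 1]), giving quasi-uniform coverage of that cap.
fibonacci_points <- function(n, frac = 1) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * frac * i / n
  phi <- 2 * pi * i * (1 + sqrt(5)) / 2
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(x = rho * cos(phi), y = rho * sin(phi), z = z)
}

# Deterministic rotation matrix from a seed: azimuthal (about z) for arrays,
# full 3-D for source spaces.
seed_rotation <- function(seed, full = FALSE) {
  r <- withr_seed_runif(seed, if (full) 3 else 1)
  a <- 2 * pi * r[1]
  Rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  if (!full) return(Rz)
  b <- acos(2 * r[2] - 1)
  c <- 2 * pi * r[3]
  Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3, byrow = TRUE)
  Rz2 <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rz2
}

# Draw uniforms under a local RNG state without touching the global stream.
withr_seed_runif <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  stats::runif(n)
}

#' Build an EEG or MEG sensor array
#'
#' EEG: 60 electrodes quasi-uniform over the upper half of the scalp sphere
#' (Fibonacci lattice, seed-rotated about the vertical axis), oriented along
#' the outward radial direction. MEG: 102 sites on a sphere 2.5 cm outside
#' the scalp; each site carries one radial magnetometer and two planar
#' gradiometers whose derivative directions are the two orthogonal local
#' tangent directions. Gradiometers are modeled as two-point finite
#' differences over a 16.8 mm baseline.
#'
#' @param modality `"EEG"` or `"MEG"`.
#' @param head A [spherical_head_model()].
#' @param seed Integer; rotates the lattice so arrays differ reproducibly.
#' @return A `sensor_array`: list with `channels` (data frame of name, kind,
#'   unit, baseline), `position` and `orientation` matrices (rows follow
#'   `channels`), and `modality`. For gradiometers `orientation` is the
#'   derivative direction; the coil normal is the site radial direction.
#' @examples
#' arr <- build_sensor_array("MEG", spherical_head_model(), seed = 1)
#' table(arr$channels$kind)
#' @export
build_sensor_array <- function(modality = c("EEG", "MEG"), head, seed = 1L) {
  modality <- match.arg(modality)
  stopifnot(inherits(head, "spherical_head_model"))
  rot <- seed_rotation(seed)
  if (modality == "EEG") {
    pts <- fibonacci_points(60, frac = 0.5) %*% t(rot)
    pos <- sweep(pts * head$shell_radii[3], 2, head$center, `+`)
    channels <- data.frame(name = sprintf("EEG%03d", 1:60),
                           kind = "EEG", unit = "V", baseline = NA_real_,
                           stringsAsFactors = FALSE)
    orient <- pts
  } else {
    sites <- fibonacci_points(102, frac = 0.55) %*% t(rot)
    rad <- head$shell_radii[3] + 0.025
    spos <- sweep(sites * rad, 2, head$center, `+`)
    # local tangent frame at each site
    up <- matrix(rep(c(0, 0, 1), each = 102), 102, 3)
    flip <- abs(sites[, 3]) > 0.95
    up[flip, ] <- matrix(rep(c(1, 0, 0), each = sum(flip)), ncol = 3)
    t1 <- pracma_cross(up, sites)
    t1 <- t1 / sqrt(rowSums(t1^2))
    t2 <- pracma_cross(sites, t1)
    t2 <- t2 / sqrt(rowSums(t2^2))
    idx <- rep(1:102, each = 3)
    pos <- spos[idx, ]
    orient <- matrix(0, 306, 3)
    orient[seq(1, 306, 3), ] <- sites      # MAG: radial coil normal
    orient[seq(2, 306, 3), ] <- t1         # GRAD1: derivative direction
    orient[seq(3, 306, 3), ] <- t2         # GRAD2: orthogonal derivative direction
    channels <- data.frame(
      name = sprintf("MEG%03d_%s", idx, rep(c("MAG", "GRAD1", "GRAD2"), 102)),
      kind = rep(c("MAG", "GRAD1", "GRAD2"), 102),
      unit = rep(c("T", "T/m", "T/m"), 102),
      baseline = rep(c(NA_real_, 0.0168, 0.0168), 102),
      stringsAsFactors = FALSE)
  }
  rownames(pos) <- channels$name
  structure(list(channels = channels, position = pos, orientation = orient,
                 modality = modality, center = head$center),
            class = "sensor_array")
}

pracma_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("%s sensor array: %d channels\n", x$modality, nrow(x$channels)))
  print(table(x$channels$kind))
  invisible(x)
}

#' Build a folded-sphere cortical source space
#'
#' Dipole seeding points quasi-uniform on a radially perturbed sphere
#' `r(theta, phi) = radius * (1 + a * sin(w*theta) * cos(w*phi))`, a surrogate
#' for the folded cortical sheet: with nonzero fold amplitude, nearby surface
#' normals can point in opposing directions (as on the two banks of a
#' sulcus), which is what drives signal cancellation for distributed
#' synchronous sources. Orientations are the analytic outward normals of the
#' perturbed surface; the hemisphere label is the sign of the x coordinate.
#'
#' @param n_per_hemisphere Number of dipoles per hemisphere (>= 40).
#' @param fold_amplitude Relative amplitude `a` of the radial perturbation
#'   (must be < 0.5; 0 gives a perfect sphere with radial normals).
#' @param fold_wavenumber Angular wavenumber `w` of the perturbation.
#' @param seed Integer; applies a random 3-D rotation to the lattice.
#' @param radius Mean radius `radius` in meters (default 0.06 m, which keeps
#'   the folded surface inside the default inner shell with room for the EEG
#'   series to converge).
#' @param center Center in meters.
#' @return A `source_space`: `positions` (n x 3, m), `orientations`
#'   (n x 3 unit normals), `hemisphere` ("L"/"R"), `nominal_spacing`
#'   (median nearest-neighbour distance, m).
#' @examples
#' ss <- build_source_space(100, fold_amplitude = 0, fold_wavenumber = 0, seed = 1)
#' ss$nominal_spacing
#' @export
build_source_space <- function(n_per_hemisphere, fold_amplitude = 0.2,
                               fold_wavenumber = 12L, seed = 1L,
                               radius = 0.06, center = c(0, 0, 0)) {
  n_per_hemisphere <- as.integer(n_per_hemisphere)
  if (n_per_hemisphere < 40L) stop("n_per_hemisphere must be at least 40")
  if (fold_amplitude < 0) stop("fold_amplitude must be nonnegative")
  if (fold_amplitude >= 0.5)
    stop("fold_amplitude >= 0.5 risks surface self-intersection")
  n <- 2L * n_per_hemisphere
  u <- fibonacci_points(n) %*% t(seed_rotation(seed, full = TRUE))
  theta <- acos(pmin(1, pmax(-1, u[, 3])))
  phi <- atan2(u[, 2], u[, 1])
  a <- fold_amplitude; w <- fold_wavenumber
  f <- sin(w * theta) * cos(w * phi)
  r <- radius * (1 + a * f)
  pos <- u * r
  # analytic normal of r(theta,phi)*rhat:
  #   N = rhat - (1/r) dr/dtheta * that - (1/(r sin theta)) dr/dphi * phat
  drdth <- radius * a * w * cos(w * theta) * cos(w * phi)
  drdph <- -radius * a * w * sin(w * theta) * sin(w * phi)
  st <- sin(theta)
  that <- cbind(cos(theta) * cos(phi), cos(theta) * sin(phi), -st)
  phat <- cbind(-sin(phi), cos(phi), 0)
  inv_sin <- ifelse(st > 1e-9, 1 / st, 0)
  nrm <- u - (drdth / r) * that - (drdph * inv_sin / r) * phat
  nrm <- nrm / sqrt(rowSums(nrm^2))
  pos <- sweep(pos, 2, center, `+`)
  hemi <- ifelse(pos[, 1] - center[1] >= 0, "R", "L")
  structure(list(positions = pos, orientations = nrm, hemisphere = hemi,
                 nominal_spacing = median_nn_distance(pos),
                 radius = radius, fold_amplitude = fold_amplitude,
                 fold_wavenumber = fold_wavenumber, center = center),
            class = "source_space")
}

# Median nearest-neighbour distance, chunked to bound memory.
median_nn_distance <- function(pos, chunk = 512L) {
  n <- nrow(pos)
  nn <- numeric(n)
  sq <- rowSums(pos^2)
  for (i0 in seq(1, n, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, n)
    d2 <- outer(sq[i0:i1], sq, `+`) - 2 * pos[i0:i1, , drop = FALSE] %*% t(pos)
    d2[cbind(seq_len(i1 - i0 + 1L), i0:i1)] <- Inf
    nn[i0:i1] <- sqrt(pmax(0, apply(d2, 1, min)))
  }
  stats::median(nn)
}

#' @export
print.source_space <- function(x, ...) {
  cat(sprintf("Source space: %d dipoles (%d L / %d R), nominal spacing %.1f mm\n",
              nrow(x$positions), sum(x$hemisphere == "L"), sum(x$hemisphere == "R"),
              1000 * x$nominal_spacing))
  invisible(x)
}

#' Number of unordered distinct source pairs
#'
#' `n * (n - 1) / 2`, the pair count entering mean pairwise correlation
#' (self-pairs excluded).
#'
#' @param n Number of sources.
#' @return Pair count (double, to stay exact beyond integer range).
#' @examples
#' n_source_pairs(6500)
#' @export
n_source_pairs <- function(n) {
  n <- as.numeric(n)
  stopifnot(n >= 0)
  n * (n - 1) / 2
}
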