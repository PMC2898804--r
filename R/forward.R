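# Analytic forward solutions: three-shell sphere EEG (Legendre series) and
# Sarvas-formula MEG, plus gain-matrix assembly.

# Legendre polynomials P_n(u), rows n = 0..nmax.
legendre_pn <- function(nmax, u) {
  P <- matrix(0, nmax + 1, length(u))
  P[1, ] <- 1
  if (nmax >= 1) P[2, ] <- u
  if (nmax >= 2) for (n in 2:nmax)
    P[n + 1, ] <- ((2 * n - 1) * u * P[n, ] - (n - 1) * P[n - 1, ]) / n
  P
}

# Associated Legendre P_n^1(u) = sqrt(1-u^2) dP_n/du (no Condon-Shortley phase).
legendre_pn1 <- function(nmax, u) {
  s <- sqrt(pmax(0, 1 - u^2))
  P1 <- matrix(0, nmax + 1, length(u))
  if (nmax >= 1) P1[2, ] <- s
  if (nmax >= 2) for (n in 2:nmax)
    P1[n + 1, ] <- ((2 * n - 1) * u * P1[n, ] - n * P1[n - 1, ]) / (n - 1)
  P1
}

# Per-harmonic surface-potential coefficient for the three-shell sphere.
# In region 1 (brain) the primary potential contributes K / r^(n+1) per
# harmonic; this returns V(scalp surface) per unit K, obtained by solving the
# 5x5 boundary-condition system (continuity of V and sigma*dV/dr at the two
# internal boundaries, zero normal current at the scalp). Radii are
# normalized to the scalp radius and columns equilibrated for conditioning.
shell_surface_coefs <- function(head, nmax) {
  sc <- head$shell_radii[3]
  r1 <- head$shell_radii[1] / sc
  r2 <- head$shell_radii[2] / sc
  s1 <- head$conductivities[1]
  s2 <- head$conductivities[2]
  s3 <- head$conductivities[3]
  out <- numeric(nmax)
  for (n in seq_len(nmax)) {
    M <- matrix(0, 5, 5)
    b <- numeric(5)
    M[1, ] <- c(r1^n, -r1^n, -r1^(-(n + 1)), 0, 0)
    b[1] <- -r1^(-(n + 1))
    M[2, ] <- c(s1 * n * r1^(n - 1), -s2 * n * r1^(n - 1),
                s2 * (n + 1) * r1^(-(n + 2)), 0, 0)
    b[2] <- s1 * (n + 1) * r1^(-(n + 2))
    M[3, ] <- c(0, r2^n, r2^(-(n + 1)), -r2^n, -r2^(-(n + 1)))
    M[4, ] <- c(0, s2 * n * r2^(n - 1), -s2 * (n + 1) * r2^(-(n + 2)),
                -s3 * n * r2^(n - 1), s3 * (n + 1) * r2^(-(n + 2)))
    M[5, ] <- c(0, 0, 0, n, -(n + 1))
    cs <- apply(abs(M), 2, max)
    x <- solve(M %*% diag(1 / cs), b) / cs
    out[n] <- (x[4] + x[5]) / sc^(n + 1)
  }
  out
}

# Shared angular decomposition for the EEG series: radial/tangential moment
# components and electrode angular factors relative to the dipole axis.
eeg_angular <- function(rq, elec_rel) {
  b <- sqrt(sum(rq^2))
  zhat <- if (b < 1e-12) c(0, 0, 1) else rq / b
  rhat <- elec_rel / sqrt(rowSums(elec_rel^2))
  u <- as.vector(pmin(1, pmax(-1, rhat %*% zhat)))
  that <- rhat - u %*% t(zhat)
  nrm <- sqrt(rowSums(that^2))
  nz <- nrm > 1e-14
  that[nz, ] <- that[nz, ] / nrm[nz]
  that[!nz, ] <- 0
  list(b = b, zhat = zhat, u = u, that = that)
}

# Core of the EEG forward: potentials at electrodes for one dipole, given
# precomputed shell coefficients. Returns average-referenced potentials.
eeg_forward_core <- function(rq, q, head, elec_rel, coefs, check_convergence = TRUE) {
  nmax <- length(coefs)
  ang <- eeg_angular(rq, elec_rel)
  mr <- sum(q * ang$zhat)
  mt_cosb <- as.vector(ang$that %*% (q - mr * ang$zhat))
  P <- legendre_pn(nmax, ang$u)
  P1 <- legendre_pn1(nmax, ang$u)
  bpow <- if (ang$b < 1e-12) c(1, numeric(nmax - 1)) else ang$b^(0:(nmax - 1))
  V <- numeric(nrow(elec_rel))
  last <- NULL
  for (n in seq_len(nmax)) {
    term <- bpow[n] * coefs[n] * (n * mr * P[n + 1, ] + mt_cosb * P1[n + 1, ])
    V <- V + term
    if (n == nmax) last <- term
  }
  V <- V / (4 * pi * head$conductivities[1])
  if (check_convergence) {
    scale <- max(abs(V))
    if (scale > 0 && max(abs(last)) / (4 * pi * head$conductivities[1]) > 1e-6 * scale)
      stop("EEG Legendre series not converged at order ", nmax,
           "; increase legendre_order or move the dipole inward")
  }
  V - mean(V)
}

#' EEG forward solution for one dipole
#'
#' Scalp potentials of a current dipole inside the three-shell spherical head,
#' computed by a truncated Legendre series (per-harmonic boundary-condition
#' solves give the shell coefficients) and returned average-referenced.
#'
#' @param dipole_position Dipole location (m, length-3), strictly inside the
#'   inner shell.
#' @param dipole_moment Dipole moment (A·m, length-3).
#' @param head A [spherical_head_model()].
#' @param array An EEG [build_sensor_array()].
#' @return Named numeric vector of average-referenced potentials (V), one per
#'   electrode.
#' @examples
#' head <- spherical_head_model()
#' arr <- build_sensor_array("EEG", head, seed = 1)
#' v <- eeg_forward(c(0, 0.02, 0.05), c(1e-9, 0, 0), head, arr)
#' sum(v)  # average reference: ~0
#' @export
eeg_forward <- function(dipole_position, dipole_moment, head, array) {
  stopifnot(inherits(head, "spherical_head_model"), inherits(array, "sensor_array"))
  if (array$modality != "EEG") stop("array must be an EEG array")
  rq <- as.numeric(dipole_position) - head$center
  if (sqrt(sum(rq^2)) >= head$shell_radii[1])
    stop("dipole must lie strictly inside the inner shell")
  elec_rel <- sweep(array$position, 2, head$center, `-`)
  coefs <- shell_surface_coefs(head, head$legendre_order)
  v <- eeg_forward_core(rq, as.numeric(dipole_moment), head, elec_rel, coefs)
  names(v) <- array$channels$name
  v
}

# Vectorized Sarvas field: magnetic field (rows) at sensor points rs (m x 3,
# relative to sphere center) of dipole q at rq (relative to center).
sarvas_field <- function(rq, q, rs) {
  a <- rs - matrix(rq, nrow(rs), 3, byrow = TRUE)
  an <- sqrt(rowSums(a^2))
  rn <- sqrt(rowSums(rs^2))
  ar <- rowSums(a * rs)
  r0r <- as.vector(rs %*% rq)
  FF <- an * (rn * an + rn^2 - r0r)
  qxr0 <- c(q[2] * rq[3] - q[3] * rq[2],
            q[3] * rq[1] - q[1] * rq[3],
            q[1] * rq[2] - q[2] * rq[1])
  if (all(qxr0 == 0)) return(matrix(0, nrow(rs), 3))
  gF_r <- an^2 / rn + ar / an + 2 * an + 2 * rn
  gF_r0 <- an + 2 * rn + ar / an
  gradF <- sweep(rs, 1, gF_r, `*`) - outer(gF_r0, rq)
  num <- sweep(matrix(qxr0, nrow(rs), 3, byrow = TRUE), 1, FF, `*`) -
    sweep(gradF, 1, as.vector(rs %*% qxr0), `*`)
  1e-7 * num / FF^2
}

#' Extract one channel from a sensor array
#'
#' @param array A [build_sensor_array()].
#' @param i Channel index or name.
#' @return A `sensor_channel` (name, kind, position, orientation, baseline,
#'   unit, and the array center).
#' @export
array_channel <- function(array, i) {
  stopifnot(inherits(array, "sensor_array"))
  if (is.character(i)) i <- match(i, array$channels$name)
  structure(list(name = array$channels$name[i], kind = array$channels$kind[i],
                 position = array$position[i, ], orientation = array$orientation[i, ],
                 baseline = array$channels$baseline[i], unit = array$channels$unit[i],
                 center = array$center),
            class = "sensor_channel")
}

#' MEG forward solution for one dipole and one channel
#'
#' Magnetic field outside a spherically symmetric conductor by the Sarvas
#' closed form. Magnetometers read the field component along the coil normal
#' (the site radial direction); planar gradiometers read the two-point finite
#' difference of that component along the channel's derivative direction over
#' its baseline.
#'
#' @param dipole_position Dipole location (m), strictly inside the inner shell.
#' @param dipole_moment Dipole moment (A·m).
#' @param head A [spherical_head_model()].
#' @param channel A `sensor_channel` from [array_channel()] with kind MAG,
#'   GRAD1 or GRAD2.
#' @return Scalar reading in T (magnetometer) or T/m (gradiometer).
#' @examples
#' head <- spherical_head_model()
#' arr <- build_sensor_array("MEG", head, seed = 1)
#' meg_forward(c(0, 0, 0.05), c(0, 1e-8, 0), head, array_channel(arr, 1))
#' @export
meg_forward <- function(dipole_position, dipole_moment, head, channel) {
  stopifnot(inherits(head, "spherical_head_model"), inherits(channel, "sensor_channel"))
  if (!channel$kind %in% c("MAG", "GRAD1", "GRAD2"))
    stop("channel must be a MEG channel (MAG, GRAD1 or GRAD2)")
  rq <- as.numeric(dipole_position) - head$center
  if (sqrt(sum(rq^2)) >= head$shell_radii[1])
    stop("dipole must lie strictly inside the inner shell")
  p <- channel$position - head$center
  if (sqrt(sum(p^2)) <= head$shell_radii[3])
    stop("MEG sensor lies inside the scalp shell")
  q <- as.numeric(dipole_moment)
  if (channel$kind == "MAG") {
    # coil normal is the channel orientation (radial in built arrays)
    B <- sarvas_field(rq, q, matrix(p, 1))
    return(sum(B * channel$orientation))
  }
  normal <- p / sqrt(sum(p^2))
  d <- channel$orientation
  L <- channel$baseline
  if (!is.finite(L) || L <= 0) stop("gradiometer baseline must be positive")
  pts <- rbind(p + (L / 2) * d, p - (L / 2) * d)
  B <- sarvas_field(rq, q, pts)
  (sum(B[1, ] * normal) - sum(B[2, ] * normal)) / L
}

#' Assemble the forward gain matrix
#'
#' Columns `3j-2 .. 3j` hold the sensor readings of unit dipoles along the
#' three global axes at source `j`. EEG gains are average-referenced (each
#' column sums to zero over channels).
#'
#' @param source_space A [build_source_space()].
#' @param array A [build_sensor_array()].
#' @param head A [spherical_head_model()].
#' @return A `gain_matrix`: `values` (n_channels x 3*n_sources), `channels`
#'   data frame, `modality`, `source_orientations` and `nominal_spacing`
#'   carried from the source space.
#' @examples
#' head <- spherical_head_model()
#' ss <- build_source_space(50, 0, 0, seed = 1, radius = 0.05)
#' g <- assemble_gain(ss, build_sensor_array("EEG", head, seed = 1), head)
#' dim(g$values)
#' @export
assemble_gain <- function(source_space, array, head) {
  stopifnot(inherits(source_space, "source_space"), inherits(array, "sensor_array"),
            inherits(head, "spherical_head_model"))
  pos <- sweep(source_space$positions, 2, head$center, `-`)
  rad <- sqrt(rowSums(pos^2))
  if (any(rad >= head$shell_radii[1]))
    stop("source positions must lie strictly inside the inner shell (",
         sum(rad >= head$shell_radii[1]), " outside)")
  n_src <- nrow(pos)
  axes <- diag(3)
  if (array$modality == "EEG") {
    elec_rel <- sweep(array$position, 2, head$center, `-`)
    coefs <- shell_surface_coefs(head, head$legendre_order)
    G <- matrix(0, nrow(array$channels), 3L * n_src)
    for (j in seq_len(n_src)) {
      for (k in 1:3) {
        G[, 3L * (j - 1L) + k] <- tryCatch(
          eeg_forward_core(pos[j, ], axes[k, ], head, elec_rel, coefs),
          error = function(e) stop("EEG forward failed at source ", j,
                                   ", component ", k, ": ", conditionMessage(e)))
      }
    }
  } else {
    p <- sweep(array$position, 2, head$center, `-`)
    if (any(sqrt(rowSums(p^2)) <= head$shell_radii[3]))
      stop("MEG sensors must lie outside the scalp shell")
    kinds <- array$channels$kind
    is_mag <- kinds == "MAG"
    normals <- p / sqrt(rowSums(p^2))  # gradiometer coil normal = site radial
    normals[is_mag, ] <- array$orientation[is_mag, ]
    L <- array$channels$baseline
    # evaluation points: magnetometer sites, then +/- offsets for gradiometers
    gi <- which(!is_mag)
    pts <- rbind(p[is_mag, , drop = FALSE],
                 p[gi, , drop = FALSE] + (L[gi] / 2) * array$orientation[gi, , drop = FALSE],
                 p[gi, , drop = FALSE] - (L[gi] / 2) * array$orientation[gi, , drop = FALSE])
    nmag <- sum(is_mag); ngrad <- length(gi)
    G <- matrix(0, nrow(array$channels), 3L * n_src)
    for (j in seq_len(n_src)) {
      for (k in 1:3) {
        B <- sarvas_field(pos[j, ], axes[k, ], pts)
        col <- numeric(nrow(array$channels))
        col[is_mag] <- rowSums(B[seq_len(nmag), , drop = FALSE] *
                                 normals[is_mag, , drop = FALSE])
        bp <- rowSums(B[nmag + seq_len(ngrad), , drop = FALSE] *
                        normals[gi, , drop = FALSE])
        bm <- rowSums(B[nmag + ngrad + seq_len(ngrad), , drop = FALSE] *
                        normals[gi, , drop = FALSE])
        col[gi] <- (bp - bm) / L[gi]
        G[, 3L * (j - 1L) + k] <- col
      }
    }
  }
  if (array$modality == "EEG") G <- sweep(G, 2, colMeans(G))
  rownames(G) <- array$channels$name
  structure(list(values = G, channels = array$channels, modality = array$modality,
                 source_order = seq_len(n_src),
                 source_orientations = source_space$orientations,
                 nominal_spacing = source_space$nominal_spacing),
            class = "gain_matrix")
}

#' @export
print.gain_matrix <- function(x, ...) {
  cat(sprintf("%s gain matrix: %d channels x %d sources x 3 components\n",
              x$modality, nrow(x$values), ncol(x$values) / 3))
  invisible(x)
}

#' Restrict a gain matrix to a subset of channel kinds
#'
#' Used e.g. to invert MEG from the planar gradiometers alone, whose tighter
#' spatial sensitivity profiles give a more focal inverse solution.
#'
#' @param gain A `gain_matrix`.
#' @param kinds Character vector of channel kinds to keep (e.g.
#'   `c("GRAD1", "GRAD2")`).
#' @return A `gain_matrix` with the selected rows. EEG subsets are
#'   re-referenced to the average of the remaining electrodes.
#' @export
subset_gain <- function(gain, kinds) {
  stopifnot(inherits(gain, "gain_matrix"))
  keep <- gain$channels$kind %in% kinds
  if (!any(keep)) stop("no channels of the requested kind(s)")
  gain$values <- gain$values[keep, , drop = FALSE]
  gain$channels <- gain$channels[keep, , drop = FALSE]
  if (gain$modality == "EEG")
    gain$values <- sweep(gain$values, 2, colMeans(gain$values))
  gain
}

# Gain collapsed onto the source normals: n_channels x n_sources.
gain_along_normals <- function(gain) {
  n_src <- ncol(gain$values) / 3L
  ori <- gain$source_orientations
  G <- gain$values
  G[, seq(1, 3 * n_src, 3)] * rep(ori[, 1], each = nrow(G)) +
    G[, seq(2, 3 * n_src, 3)] * rep(ori[, 2], each = nrow(G)) +
    G[, seq(3, 3 * n_src, 3)] * rep(ori[, 3], each = nrow(G))
}
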