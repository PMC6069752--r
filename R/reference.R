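#' Analytic free energy of the ideal Einstein molecule (point particles)
#'
#' For a crystal of N point particles tethered by isotropic harmonic
#' restraints of constant k (one particle fixed, carrying no restraint), the
#' absolute reduced free energy of the ideal Einstein molecule is
#' \deqn{A^{EM} = \frac{1}{\beta}\ln\frac{N\Lambda^3}{V} +
#'   (N-1)\,\frac{3}{2\beta}\,\ln\frac{\beta k \Lambda^2}{2\pi},}
#' the first term from the fixed particle's lost translational freedom and
#' the second from the Gaussian restraint integral of each mobile particle.
#' The restraint integrals are taken over all space rather than the finite
#' box: at the default k = 4000 k_B T / A^2 the Gaussian tails truncate with
#' error far below machine precision.
#'
#' @param N number of particles (>= 1).
#' @param k restraint constant (k_B T / A^2, > 0).
#' @param lambda_db thermal de Broglie wavelength (Angstrom), see
#'   [de_broglie_wavelength].
#' @param V box volume (Angstrom^3).
#' @param beta inverse temperature in reduced units (default 1).
#' @return an object of class `einstein_reference` with `A` (k_B T), the
#'   per-term `decomposition`, `se = 0` and `method = "analytic"`.
#' @export
em_free_energy_analytic <- function(N, k, lambda_db, V, beta = 1) {
  if (N < 1) stop("N must be >= 1")
  if (k <= 0) stop("restraint constant must be positive")
  fixed_term <- log(N * lambda_db^3 / V) / beta
  trans_term <- if (N > 1) (N - 1) * (3 / (2 * beta)) * log(beta * k * lambda_db^2 / (2 * pi)) else 0
  structure(list(
    A = fixed_term + trans_term,
    decomposition = c(fixed_particle = fixed_term, orientational = 0,
                      translational_orientational = trans_term),
    se = 0, n_samples = NA_integer_, method = "analytic"
  ), class = "einstein_reference")
}

#' @export
print.einstein_reference <- function(x, ...) {
  cat(sprintf("A_EM = %.6g +/- %.2g k_BT (%s)\n", x$A, x$se, x$method))
  invisible(x)
}

random_quaternion <- function(n) {
  q <- matrix(rnorm(4 * n), n, 4)
  q / sqrt(rowSums(q^2))
}

quat_to_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# rotation taking unit vector a to unit vector b (for linear molecules)
rotation_a_to_b <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (cth < -1 + 1e-12) return(diag(c(-1, -1, 1))) # antipodal: any 180-degree rotation
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + cth)
}

orientational_measure <- function(topology) {
  n_sites <- nrow(topology$coords)
  if (n_sites == 1) 1 else if (topology$linear) 4 * pi else 8 * pi^2
}

#' Monte Carlo estimate of the ideal Einstein molecule free energy
#'
#' Estimates the two configurational integrals of the Einstein molecule
#' reference for rigid-reference molecules: the orientational integral of the
#' molecule holding the fixed atom (rotations about the fixed site) and the
#' joint positional-orientational integral of a mobile molecule. Orientations
#' are sampled uniformly over SO(3) via random unit quaternions (measure
#' 8*pi^2; 4*pi for linear molecules via uniform axis directions; 1 for
#' atoms), and positions by Gaussian importance sampling matched to the
#' isotropic site-restraint energy, which is quadratic in the molecular
#' displacement at fixed orientation. For atomic systems the importance
#' weight is constant and the estimate coincides with
#' [em_free_energy_analytic] up to roundoff.
#'
#' @param topology a [molecule_topology] (rigid reference geometry).
#' @param crystal the [crystal_spec] providing lattice reference coordinates,
#'   box volume and the fixed atom.
#' @param k restraint constant (k_B T / A^2).
#' @param lambda_db molecular thermal de Broglie wavelength (Angstrom).
#' @param n_samples Monte Carlo samples per integral (>= 1000).
#' @param seed RNG seed.
#' @param beta inverse temperature (default 1).
#' @return an `einstein_reference` with MC standard error; flagged
#'   `converged = FALSE` when the relative error of either integral exceeds
#'   10 %.
#' @export
em_free_energy_mc <- function(topology, crystal, k, lambda_db, n_samples,
                              seed = 1L, beta = 1) {
  stopifnot(inherits(topology, "molecule_topology"),
            inherits(crystal, "crystal_spec"))
  if (n_samples < 1000) stop("n_samples must be >= 1000")
  if (k <= 0) stop("restraint constant must be positive")
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  N <- crystal$n_molecules
  V <- prod(crystal$box)
  n_sites <- crystal$n_sites
  measure <- orientational_measure(topology)
  fixed_mol <- ceiling(crystal$fixed_atom / n_sites)
  fixed_site <- crystal$fixed_atom - (fixed_mol - 1L) * n_sites

  draw_rotations <- function(n) {
    if (n_sites == 1) {
      replicate(n, diag(3), simplify = FALSE)
    } else if (topology$linear) {
      axis0 <- topology$coords[n_sites, ] - topology$coords[1, ]
      axis0 <- axis0 / sqrt(sum(axis0^2))
      z <- rnorm(3 * n)
      dirs <- matrix(z, n, 3) / sqrt(rowSums(matrix(z, n, 3)^2))
      lapply(seq_len(n), function(i) rotation_a_to_b(axis0, dirs[i, ]))
    } else {
      q <- random_quaternion(n)
      lapply(seq_len(n), function(i) quat_to_rot(q[i, ]))
    }
  }

  # --- integral 1: orientations of the molecule holding the fixed atom ---
  # rotate the molecule rigidly about the fixed site; restraint energy of the
  # remaining sites
  ref1 <- crystal$coords[molecule_atoms(crystal, fixed_mol), , drop = FALSE]
  pivot <- ref1[fixed_site, ]
  rel1 <- sweep(ref1, 2, pivot)
  se_log_I1 <- 0
  if (n_sites == 1) {
    log_I1 <- 0
  } else {
    rots <- draw_rotations(n_samples)
    w <- vapply(rots, function(R) {
      d <- rel1 %*% t(R) - rel1
      exp(-beta * k / 2 * sum(d[-fixed_site, ]^2))
    }, 0)
    log_I1 <- log(measure) + log(mean(w))
    se_log_I1 <- sd(w) / (mean(w) * sqrt(n_samples))
  }

  # --- integral 2: position + orientation of one mobile molecule ---
  # at fixed orientation the site-restraint energy is quadratic in the rigid
  # displacement r: U = (n_s k / 2) |r - mu(R)|^2 + E_min(R); importance
  # sample r from the matched Gaussian
  mob <- if (fixed_mol == 1L && N > 1) 2L else 1L
  ref2 <- crystal$coords[molecule_atoms(crystal, mob), , drop = FALSE]
  cen2 <- colMeans(ref2)
  a2 <- sweep(ref2, 2, cen2) # body-frame site offsets
  sd_pos <- 1 / sqrt(beta * k * n_sites)
  if (n_sites == 1) {
    # atoms: no orientations; fully vectorized importance sampling
    r <- matrix(rnorm(3 * n_samples, 0, sd_pos), n_samples, 3)
    U <- beta * k / 2 * rowSums(r^2)
    lq <- rowSums(matrix(dnorm(as.vector(r), 0, sd_pos, log = TRUE), n_samples, 3))
    w2 <- exp(-U - lq)
  } else {
    rots <- draw_rotations(n_samples)
    w2 <- vapply(seq_len(n_samples), function(i) {
      Rm <- rots[[i]]
      sites0 <- a2 %*% t(Rm) # rotated offsets about the molecular center
      mu <- colMeans(ref2 - sites0) # optimal center position
      r <- mu + rnorm(3, 0, sd_pos)
      d <- sweep(sites0, 2, r, "+") - ref2
      U <- beta * k / 2 * sum(d^2)
      lq <- sum(dnorm(r, mu, sd_pos, log = TRUE))
      exp(-U - lq)
    }, 0)
  }
  log_I2 <- log(measure) + log(mean(w2)) - 3 * log(lambda_db)
  se_log_I2 <- sd(w2) / (mean(w2) * sqrt(n_samples))

  fixed_term <- log(N * lambda_db^3 / V) / beta
  orient_term <- -log_I1 / beta
  trans_term <- -(N - 1) * log_I2 / beta
  se <- sqrt((se_log_I1 / beta)^2 + ((N - 1) * se_log_I2 / beta)^2)
  rel_err <- max(se_log_I1, se_log_I2)
  structure(list(
    A = fixed_term + orient_term + trans_term,
    decomposition = c(fixed_particle = fixed_term, orientational = orient_term,
                      translational_orientational = trans_term),
    se = se, n_samples = as.integer(n_samples), method = "monte-carlo",
    converged = rel_err <= 0.1
  ), class = "einstein_reference")
}

#' Molecular symmetry correction to the solid free energy
#'
#' Isotropic site restraints have no angular field, so configurations that
#' differ by a proper rotation of a molecule onto itself are counted as
#' distinct; the analytic correction \eqn{-N \ln(\Sigma_{rot}) / \beta}
#' removes the overcounting. Additive in N, zero for asymmetric molecules.
#'
#' @param N number of molecules.
#' @param sigma_rot proper-rotation symmetry number (integer >= 1).
#' @param beta inverse temperature (default 1).
#' @return correction in k_B T (to be added to the solid free energy).
#' @examples
#' symmetry_correction(64, 2)  # -64 log(2) ~ -44.36 k_BT
#' @export
symmetry_correction <- function(N, sigma_rot, beta = 1) {
  if (sigma_rot < 1 || sigma_rot != round(sigma_rot))
    stop("sigma_rot must be an integer >= 1")
  -N * log(sigma_rot) / beta
}
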