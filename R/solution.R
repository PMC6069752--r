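#' Ideal (translational) term of the solution chemical potential
#'
#' \eqn{(1/\beta) \ln(\Lambda^3 N_i / V)}: the concentration-dependent ideal
#' contribution of \eqn{N_i} solute molecules in volume V.
#'
#' @param N_i number of solute molecules (>= 1).
#' @param V system volume.
#' @param lambda_db thermal de Broglie wavelength (Angstrom).
#' @param volume_unit `"A3"` (default) or `"nm3"`.
#' @param beta inverse temperature (default 1).
#' @return energy in k_B T.
#' @export
ideal_term <- function(N_i, V, lambda_db, volume_unit = c("A3", "nm3"), beta = 1) {
  volume_unit <- match.arg(volume_unit)
  if (any(N_i < 1)) stop("N_i must be >= 1")
  if (any(V <= 0)) stop("V must be positive")
  if (volume_unit == "nm3") V <- V * 1e3
  log(lambda_db^3 * N_i / V) / beta
}

#' Standard chemical potential from the single-Einstein-molecule cycle
#'
#' The configuration-independent single-molecule part of the solution
#' chemical potential, obtained without knowing the internal partition
#' function by transforming one solute molecule into a single Einstein
#' molecule:
#' \deqn{\mu^0 = \mu^{ideal} - (\mu^{FF off} + \mu^{restraining}),}
#' where the two subtracted legs are the free energies of turning off the
#' molecule's force field and of restraining its atoms to reference
#' positions, and \eqn{\mu^{ideal}} is the analytically/numerically known
#' free energy of the single Einstein molecule.
#'
#' @param mu_ideal single-Einstein-molecule free energy (k_B T).
#' @param mu_ffoff force-field-off leg (k_B T).
#' @param mu_restraining restraining leg (k_B T).
#' @param se_ideal,se_ffoff,se_restraining standard errors of the legs.
#' @return list with `value` and `se` (k_B T, quadrature-combined).
#' @examples
#' mu_standard(9.3, 65.7409, 94.3)$value  # -150.7409 k_BT
#' @export
mu_standard <- function(mu_ideal, mu_ffoff, mu_restraining,
                        se_ideal = 0, se_ffoff = 0, se_restraining = 0) {
  list(value = mu_ideal - (mu_ffoff + mu_restraining),
       se = sqrt(se_ideal^2 + se_ffoff^2 + se_restraining^2))
}

#' Assemble the chemical potential of a solute in solution
#'
#' \eqn{\mu_i = \mu^0 + (1/\beta)\ln(\Lambda^3 N_i / V) + \mu^{ex}}, with
#' uncertainties combined in quadrature under the documented assumption of
#' independent legs.
#'
#' @param x solute mole fraction (bookkeeping only).
#' @param N_i solute molecule count.
#' @param V volume.
#' @param lambda_db thermal de Broglie wavelength (Angstrom).
#' @param mu0,se0 standard chemical potential and its error (k_B T).
#' @param mu_ex,se_ex excess chemical potential and its error (k_B T).
#' @param volume_unit `"A3"` or `"nm3"`.
#' @return an object of class `mu_components` with the three components, the
#'   `total`, and `se`.
#' @export
chemical_potential_components <- function(x, N_i, V, lambda_db, mu0, mu_ex,
                                          se0 = 0, se_ex = 0,
                                          volume_unit = c("A3", "nm3")) {
  ideal <- ideal_term(N_i, V, lambda_db, volume_unit)
  structure(list(x = x, N_i = N_i, V = V, mu0 = mu0, ideal = ideal,
                 mu_ex = mu_ex, total = mu0 + ideal + mu_ex,
                 se = sqrt(se0^2 + se_ex^2)),
            class = "mu_components")
}

#' @export
print.mu_components <- function(x, ...) {
  cat(sprintf("mu(x = %.4g) = %.4f k_BT  [mu0 %.4f + ideal %.4f + mu_ex %.4f] +/- %.3g\n",
              x$x, x$total, x$mu0, x$ideal, x$mu_ex, x$se))
  invisible(x)
}

#' Total solution chemical potential
#'
#' @param components a `mu_components` object (all three components present).
#' @return list with `value` and `se`.
#' @export
mu_solution <- function(components) {
  stopifnot(inherits(components, "mu_components"))
  if (anyNA(c(components$mu0, components$ideal, components$mu_ex)))
    stop("missing chemical potential component")
  list(value = components$total, se = components$se)
}

#' Excess chemical potential by alchemical decoupling
#'
#' Builds a toy solution — one Lennard-Jones solute in a periodic LJ solvent
#' box at fixed V and T — and computes the excess chemical potential as the
#' free energy of coupling the solute, estimated by MBAR over a soft-core
#' decoupling path (`lambda = 0` ideal / decoupled, `lambda = 1` fully
#' coupled). The solute's internal Hamiltonian is never scaled; only
#' solute-solvent interactions pass through the soft core. The solvent box
#' volume is recorded from the fully coupled state.
#'
#' @param n_solvent number of solvent particles (<= 256).
#' @param rho_sigma3 reduced solvent density \eqn{\rho \sigma^3}.
#' @param eps,sigma solvent-solvent (and solute-solvent) LJ parameters
#'   (k_B T, Angstrom). `eps = 1/T*` links to the conventional reduced
#'   temperature.
#' @param solute_eps,solute_sigma solute-solvent parameters (default: same).
#' @param cutoff pair cutoff (Angstrom; at most half the box edge).
#' @param n_lambda number of decoupling states (default 12).
#' @param n_steps MC sweeps per state.
#' @param seed master seed.
#' @param save_every keep every nth sweep before decorrelation subsampling.
#' @return list with `mu_ex` (a [free_energy_estimate]), `mbar`, `rpm`,
#'   `diagnostics`, `volume` (Angstrom^3), `box`, `solvent_frames` (frames of
#'   the decoupled end state, for Widom cross-checks), `solute_index`.
#' @export
mu_excess_decoupling <- function(n_solvent = 100, rho_sigma3 = 0.05, eps = 0.5,
                                 sigma = 3.4, solute_eps = eps,
                                 solute_sigma = sigma, cutoff = NULL,
                                 n_lambda = 12, n_steps = 2000, seed = 1L,
                                 save_every = 1L) {
  if (n_solvent > 256) stop("toy solvent boxes are limited to 256 particles")
  L <- sigma * (n_solvent / rho_sigma3)^(1 / 3)
  if (is.null(cutoff)) cutoff <- min(4 * sigma, 0.49 * L)
  n <- n_solvent + 1L
  # start from a cubic lattice: solvent + one solute (last index)
  m <- ceiling(n^(1 / 3))
  g <- as.matrix(expand.grid(seq_len(m), seq_len(m), seq_len(m)))[seq_len(n), ] - 0.5
  coords0 <- g * (L / m)
  solute <- n
  solvent <- seq_len(n_solvent)

  states <- lapply(make_schedule("linear", n_lambda), function(l) {
    energy_model(
      lj_pair(eps, sigma, cutoff, atoms = solvent, name = "solvent"),
      softcore_pair(solute_eps, solute_sigma, cutoff, lambda = l,
                    atoms = solute, between = solvent, name = "solute"),
      box = rep(L, 3)
    )
  })
  samples <- sample_path(states, coords0, n_steps, seed, fixed_atom = 0L,
                         step = 0.3 * sigma, save_every = save_every)
  rpm <- cross_evaluate(samples, states)
  mb <- mbar_solve(rpm)
  est <- mbar_difference(mb, 1L, n_lambda) # coupling free energy = mu_ex
  est$estimator <- "MBAR-decoupling"
  diag <- diagnose_path(overlap_matrix(mb))
  list(mu_ex = est, mbar = mb, rpm = rpm, diagnostics = diag,
       volume = L^3, box = rep(L, 3),
       solvent_frames = samples$samples[[1]]$frames,
       solute_index = solute, params = list(eps = eps, sigma = sigma,
                                            cutoff = cutoff, L = L))
}

#' Widom test-particle insertion
#'
#' Independent oracle for the excess chemical potential:
#' \eqn{\mu^{ex} = -(1/\beta) \ln \langle e^{-\beta \Delta U} \rangle} over
#' uniform random insertions of a ghost solute into equilibrated pure-solvent
#' configurations.
#'
#' @param frames n_atoms x 3 x n_frames array of solvent configurations.
#' @param box length-3 box edges.
#' @param solvent indices of solvent atoms within the frames.
#' @param eps,sigma,cutoff LJ parameters of the inserted solute.
#' @param n_insertions number of trial insertions.
#' @param seed RNG seed.
#' @return a [free_energy_estimate] (`value` = mu_ex); errors if every
#'   insertion is rejected at machine precision.
#' @export
widom_oracle <- function(frames, box, solvent, eps, sigma, cutoff,
                         n_insertions = 1e5, seed = 1L) {
  dU <- cpp_widom(frames, box, as.integer(solvent), eps, sigma, cutoff,
                  as.integer(n_insertions), as.numeric(seed))
  w <- exp(-dU)
  mw <- mean(w)
  if (!is.finite(mw) || mw <= 0)
    stop("Widom insertion non-converged: all insertions rejected")
  se <- sd(w) / (mw * sqrt(length(w)))
  free_energy_estimate(-log(mw), se, "Widom", 1L,
                       diagnostics = list(n_insertions = n_insertions,
                                          accept_fraction = mean(dU < 30)))
}

#' Second virial coefficient of a truncated LJ fluid
#'
#' \eqn{B_2 = -2\pi \int_0^{r_c} (e^{-\beta u(r)} - 1) r^2 dr} by adaptive
#' quadrature of the same truncated, unshifted potential the simulations
#' use. At low density the excess chemical potential approaches
#' \eqn{2 B_2 \rho / \beta}.
#'
#' @param eps,sigma,cutoff LJ parameters (k_B T, Angstrom).
#' @param beta inverse temperature (default 1).
#' @return B2 in Angstrom^3.
#' @export
lj_b2 <- function(eps, sigma, cutoff, beta = 1) {
  f <- function(r) {
    u <- 4 * eps * ((sigma / r)^12 - (sigma / r)^6)
    (exp(-beta * u) - 1) * r^2
  }
  -2 * pi * integrate(f, 0, cutoff, rel.tol = 1e-10,
                      subdivisions = 500L)$value
}

#' Read a concentration-series table
#'
#' CSV columns: `mole_fraction` (as a fraction, or percent when
#' `percent = TRUE`), `volume` (nm^3), `n_solute`, `n_solvent`, `mu_ex`,
#' `sigma` (k_B T).
#'
#' @param file CSV path.
#' @param percent interpret `mole_fraction` as percent.
#' @return data.frame with a `mole_fraction` column as a plain fraction.
#' @export
read_concentration_series <- function(file, percent = FALSE) {
  df <- read.csv(file)
  need <- c("mole_fraction", "volume", "n_solute", "n_solvent", "mu_ex", "sigma")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  if (percent) df$mole_fraction <- df$mole_fraction / 100
  df
}
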