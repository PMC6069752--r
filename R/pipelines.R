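#' Build restraint-coupling states over a solid Hamiltonian
#'
#' State l has Hamiltonian \eqn{H_{solid} + \lambda_l (k/2) \sum |r - r_0|^2}
#' (fixed atom excluded): \eqn{\lambda = 0} is the bare solid and
#' \eqn{\lambda = 1} the interacting Einstein molecule. With a power-law
#' schedule the states concentrate at the weak-restraint end, where atoms
#' decorrelate from the lattice and overlap degrades fastest. The
#' restraint-removal leg of the cycle is this path traversed from 1 to 0.
#'
#' @param solid_terms list of `energy_term`s of the bare solid Hamiltonian
#'   (may be empty for a reference-only crystal).
#' @param crystal the [crystal_spec] (reference coordinates, box, fixed
#'   atom).
#' @param k full restraint constant (k_B T / A^2).
#' @param lambdas restraint coupling coefficients, one per state.
#' @return list of [energy_model]s.
#' @export
restraint_states <- function(solid_terms, crystal, k, lambdas) {
  lapply(lambdas, function(l) {
    energy_model(c(solid_terms, list(
      site_restraint(k, crystal$coords, exclude = crystal$fixed_atom,
                     coeff = l, name = "restraint"))),
      box = crystal$box)
  })
}

#' Build harmonic-switch states between two restraint constants
#'
#' State l restrains every mobile atom with constant
#' \eqn{k_1 + (k_0 - k_1) \lambda_l} (implemented as a coefficient on the
#' \eqn{k_0} restraint so all states share one term). Used for
#' restraint-strength switching legs, where the free energy has the Gaussian
#' closed form \eqn{(3(N-1)/2\beta) \ln(k_{end}/k_{start})}.
#'
#' @param crystal a [crystal_spec].
#' @param k0 reference (full) restraint constant.
#' @param k_values restraint constants of the states, in path order.
#' @return list of [energy_model]s.
#' @export
restraint_switch_states <- function(crystal, k0, k_values) {
  lapply(k_values, function(kv) {
    energy_model(site_restraint(k0, crystal$coords,
                                exclude = crystal$fixed_atom,
                                coeff = kv / k0, name = "restraint"),
                 box = crystal$box)
  })
}

#' Thermodynamic integration over a sampled path
#'
#' Evaluates the analytic \eqn{\partial H / \partial \lambda} on every
#' state's own samples using per-state derivative models (models whose term
#' coefficients are the lambda derivatives of the state Hamiltonian's), then
#' integrates by [ti_estimate].
#'
#' @param samples a [sample_set].
#' @param dstates list of [energy_model]s evaluating dH/dlambda, one per
#'   state.
#' @param lambdas the lambda value of each state.
#' @return a [free_energy_estimate].
#' @export
ti_from_path <- function(samples, dstates, lambdas) {
  K <- length(dstates)
  stopifnot(length(samples$samples) == K, length(lambdas) == K)
  means <- numeric(K)
  ses <- numeric(K)
  for (l in seq_len(K)) {
    raw <- cpp_term_energies_frames(samples$samples[[l]]$frames,
                                    term_list(dstates[[l]]),
                                    dstates[[l]]$box)
    co <- vapply(dstates[[l]]$terms, `[[`, 1.0, "coeff")
    dhdl <- as.vector(raw %*% co)
    means[l] <- mean(dhdl)
    ses[l] <- if (length(dhdl) > 1) sd(dhdl) / sqrt(length(dhdl)) else 0
  }
  ti_estimate(lambdas, means, ses)
}

#' Absolute solid free energy by the Einstein molecule cycle
#'
#' Runs the full cycle on a toy crystal: (a) the ideal Einstein molecule
#' reference free energy (analytic for atomic crystals, Monte Carlo
#' integration otherwise); (b) the force-field-on leg, sampling
#' \eqn{H = H_{EM} + \lambda H_{solid}} over a linear schedule; (c) the
#' restraint-removal leg, sampling \eqn{H = H_{solid} + \lambda H_{EM}} over
#' a power-law schedule dense at the weak-restraint end; both legs estimated
#' with MBAR. Assembles \eqn{A_{solid} = A^{EM} + \Delta A_{EM \to IEM} +
#' \Delta A_{IEM \to solid}} plus the symmetry correction, and
#' \eqn{\mu = A/N}.
#'
#' @param crystal a [crystal_spec].
#' @param solid_terms list of `energy_term`s of the bare solid Hamiltonian.
#' @param k_ref Einstein molecule restraint constant (default 4000
#'   k_B T / A^2).
#' @param lambda_db thermal de Broglie wavelength of one molecule (Angstrom).
#' @param n_ff,n_rest numbers of states of the two legs.
#' @param rest_exponent power-law exponent of the restraint-removal schedule
#'   (default 4).
#' @param n_steps MC sweeps per state.
#' @param seed master seed.
#' @param n_mc_reference MC samples for the reference integral (molecular
#'   crystals only).
#' @param ... passed to [sample_path].
#' @return list with `solid` (a [solid_free_energy]), the per-leg MBAR
#'   results, overlap diagnostics, and the reference decomposition.
#' @export
emm_solid_mu <- function(crystal, solid_terms, k_ref = 4000, lambda_db,
                         n_ff = 12, n_rest = 24, rest_exponent = 4,
                         n_steps = 1500, seed = 1L, n_mc_reference = 2e4, ...) {
  top <- crystal$topology
  atomic <- crystal$n_sites == 1
  ref <- if (atomic) {
    em_free_energy_analytic(crystal$n_molecules, k_ref, lambda_db,
                            prod(crystal$box))
  } else {
    em_free_energy_mc(top, crystal, k_ref, lambda_db, n_mc_reference,
                      seed = seed + 1)
  }

  # leg 1 (ff_on): H = H_EM + lambda * H_solid
  ff_states <- lapply(make_schedule("linear", n_ff), function(l) {
    energy_model(c(
      list(site_restraint(k_ref, crystal$coords, exclude = crystal$fixed_atom,
                          name = "restraint")),
      lapply(solid_terms, function(t) { t$coeff <- t$coeff * l; t })
    ), box = crystal$box)
  })
  s_ff <- sample_path(ff_states, crystal$coords, n_steps, seed + 100,
                      fixed_atom = crystal$fixed_atom, ...)
  mb_ff <- mbar_solve(cross_evaluate(s_ff, ff_states))
  dA_ff <- mbar_difference(mb_ff, 1L, n_ff)

  # leg 2 (restraints_off): H = H_solid + lambda * H_EM, traversed 1 -> 0
  rest_states <- restraint_states(solid_terms, crystal, k_ref,
                                  make_schedule("power", n_rest, rest_exponent))
  s_rest <- sample_path(rest_states, crystal$coords, n_steps, seed + 200,
                        fixed_atom = crystal$fixed_atom, ...)
  mb_rest <- mbar_solve(cross_evaluate(s_rest, rest_states))
  dA_rest <- mbar_difference(mb_rest, n_rest, 1L) # IEM -> solid

  solid <- assemble_solid_mu(ref$A, dA_ff$value, dA_rest$value,
                             N = crystal$n_molecules,
                             sigma_rot = top$sigma_rot,
                             se_A_EM = ref$se, se_em_iem = dA_ff$se,
                             se_iem_solid = dA_rest$se)
  list(solid = solid, reference = ref, ff_on = mb_ff, restraints_off = mb_rest,
       diagnostics = list(ff_on = diagnose_path(overlap_matrix(mb_ff)),
                          restraints_off = diagnose_path(overlap_matrix(mb_rest))))
}

#' Bundled reference dataset: acetylsalicylic acid (GAFF/TIP3P, 298.15 K)
#'
#' Published free-energy components for the polymorph-I acetylsalicylic acid
#' solid (Einstein molecule cycle, per-molecule, k_B T), the single-molecule
#' standard-chemical-potential cycle legs, and the aqueous concentration
#' series (mole fraction in percent, NPT volumes in nm^3, excess chemical
#' potentials in k_B T). These are the worked-example inputs for assembling
#' chemical potentials and the solubility verdict without re-running the
#' underlying molecular dynamics.
#'
#' @param which one of `"solid_components"`, `"standard_mu"`,
#'   `"solution_series"`.
#' @return a data.frame.
#' @export
asa_reference_data <- function(which = c("solid_components", "standard_mu",
                                         "solution_series")) {
  which <- match.arg(which)
  f <- system.file("extdata", paste0("asa_", which, ".csv"),
                   package = "emmsol", mustWork = TRUE)
  if (which == "solution_series") read_concentration_series(f, percent = TRUE)
  else read.csv(f)
}

#' Reconstruct a solution chemical-potential series
#'
#' Combines a standard chemical potential with the per-concentration ideal
#' and excess terms of a concentration table (as from
#' [read_concentration_series]) into the \eqn{(x, \mu, \sigma)} series
#' consumed by [find_solubility].
#'
#' @param df concentration table with `mole_fraction`, `volume` (nm^3),
#'   `n_solute`, `mu_ex`, `sigma`.
#' @param mu0,se0 standard chemical potential and error (k_B T).
#' @param mass molecular mass (u) for the de Broglie wavelength.
#' @param temperature temperature (K).
#' @return data.frame with `x`, `mu`, `sigma`.
#' @export
reconstruct_solution_series <- function(df, mu0, se0 = 0, mass,
                                        temperature = 298.15) {
  lam <- de_broglie_wavelength(mass, temperature)
  mu <- vapply(seq_len(nrow(df)), function(i) {
    mu0 + ideal_term(df$n_solute[i], df$volume[i], lam, "nm3") + df$mu_ex[i]
  }, 0)
  data.frame(x = df$mole_fraction, mu = mu,
             sigma = sqrt(se0^2 + df$sigma^2))
}
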