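---
title: "Absolute chemical potentials and solubility with the Einstein molecule method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Absolute chemical potentials and solubility with the Einstein molecule method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emmsol)
```

## The problem

The solubility of a crystalline compound is the concentration at which the
chemical potential of the dissolved molecule equals the chemical potential of
the same molecule in its solid,

$$\mu^{solid} = \mu^{solution}(x^\ast).$$

Both sides are *absolute* free energies per molecule, which molecular
simulation cannot produce directly: a sampled trajectory only yields free
energy *differences*. The route implemented here closes that gap with two
thermodynamic cycles built on a reference system whose absolute free energy
is known in closed form — the **Einstein molecule**: every atom tethered to
its lattice position by an isotropic harmonic restraint of constant $k$, no
other interactions, and *one atom fixed in space*. Fixing one atom (rather
than the center of mass, as the older Einstein-crystal construction does)
removes lattice drift without requiring a separate release term, at the cost
of one fixed-particle factor $\ln(N\Lambda^3/V)/\beta$ in the reference free
energy.

All internal computation uses reduced units: energies in $k_BT$
($\beta \equiv 1$), lengths in Å. Temperature and molecular mass enter only
through the thermal de Broglie wavelength
$\Lambda = h/\sqrt{2\pi m k_B T}$ and through pressure-volume conversions.

## The solid side

The absolute free energy of the solid is assembled as

$$A^{solid} = A^{EM} + \Delta A_{EM \to IEM} + \Delta A_{IEM \to solid}
  - N\ln(\Sigma_{rot})/\beta, \qquad \mu^{solid} = A^{solid}/N .$$

* $A^{EM}$ — the ideal Einstein molecule. For point particles
  `em_free_energy_analytic()` evaluates the Gaussian integrals exactly,
  $$A^{EM} = \tfrac{1}{\beta}\ln\tfrac{N\Lambda^3}{V}
    + (N-1)\tfrac{3}{2\beta}\ln\tfrac{\beta k \Lambda^2}{2\pi}.$$
  For rigid molecules `em_free_energy_mc()` estimates the orientational
  integral of the anchored molecule and the joint positional–orientational
  integral of a mobile molecule by Monte Carlo: orientations uniform over
  SO(3) (measure $8\pi^2$; $4\pi$ for linear molecules; 1 for atoms),
  positions by Gaussian importance sampling matched to the restraint, which
  is exact in the positional coordinates because the site-restraint energy is
  quadratic in the rigid-body displacement at fixed orientation. The
  restraint integrals are taken over all space rather than the finite box; at
  the default $k = 4000\,k_BT/\text{Å}^2$ the truncated Gaussian tail is far
  below machine precision.
* $\Delta A_{EM \to IEM}$ — switching on the solid's interaction Hamiltonian
  in the presence of full restraints, sampled over a linear schedule of
  mixing states $H_{EM} + \lambda H_{solid}$.
* $\Delta A_{IEM \to solid}$ — removing the restraints. This is the fragile
  leg: as $k\lambda \to 0$ the atoms decorrelate from their lattice sites and
  configurations sampled at weak restraint look impossible to the strongly
  restrained states. States are therefore placed on a power-law schedule
  $\lambda_i = (i/(K-1))^p$ (default $p = 4$) that packs them into the
  weak-restraint end.
* the symmetry term $-N\ln(\Sigma_{rot})/\beta$ corrects for the proper
  rotations that map a molecule onto itself: isotropic site restraints carry
  no angular field, so those orientations are otherwise counted as distinct.

Restraints are isotropic and harmonic in $x,y,z$ about the lattice
coordinates; there is no angular restraint term, which is exactly why the
symmetry correction is needed. The fixed atom defaults to atom 1 of
molecule 1 — the choice is arbitrary in principle and enters no formula.

## Estimators and the overlap diagnostic

`mbar_solve()` implements the multistate acceptance-ratio estimator on the
cross-evaluated reduced-potential matrix (every retained sample re-evaluated
in every state's Hamiltonian), solved by self-consistent iteration with
adaptive Newton polishing to a residual of $10^{-10}\,k_BT$; the tight
tolerance is what makes the overlap diagnostics reproducible run to run. The
two-state special case `bar_estimate()` solves the same stationarity
condition by bracketed root finding — an independent code path, which the
test suite exploits as a cross-check ($|{\rm MBAR}(K{=}2) - {\rm BAR}| <
10^{-8}$). One-sided exponential averaging (`exp_estimate()`) and
trapezoidal thermodynamic integration (`ti_estimate()`) are provided for
comparison; TI's reported uncertainty propagates only the per-state
integrand errors and is documented as blind to overlap failure and to
curvature between the sampled $\lambda$ values.

The phase-space overlap matrix $O_{ij} = \sum_n W_{ni}W_{nj}N_j$ is
row-stochastic; its near-zero entries between neighboring states flag path
segments whose free energy rests on extrapolation. Two numerical choices
deserve explanation:

* **Pair-normalized neighbor overlap.** Raw entries dilute as $1/K$ when
  many states crowd the same region — a dense, perfectly healthy schedule
  spreads each row's unit mass over dozens of near-identical neighbors, and
  even *identical* states give $O_{ij} = N_j/\sum N \approx 1/K$.
  `diagnose_path()` therefore thresholds
  $O_{i,i+1}/(O_{i,i} + O_{i,i+1})$, which is $\approx 1/2$ for
  indistinguishable neighbors and $\to 0$ for disconnected ones regardless
  of discretization. The warn threshold is 0.03.
* **Divergent variance on broken paths.** The MBAR asymptotic covariance is
  computed through an eigendecomposition pseudo-inverse. Exactly one null
  direction is structural (the common-shift gauge of the $f_k$) and is
  projected out; any *additional* near-null directions mean the path has
  disconnected into blocks, and they are inverted rather than truncated, so
  the reported uncertainty diverges instead of quietly looking small. A
  sparse restraint-removal path on a Lennard-Jones toy crystal reproduces
  this failure mode — broken first link, uncertainty many orders of
  magnitude above the dense-path value — and a 150-state power-4 schedule
  repairs it; that experiment is part of the test suite.

## Sampling

The default engine is single-particle-move Metropolis with the displacement
auto-tuned to 30–50 % acceptance *during the equilibration window only*
(the first 10 % of sweeps, discarded); tuning during production would break
detailed balance. BAOAB-discretized Langevin dynamics is available as an
alternative. One master seed drives per-state RNG streams through fixed
offsets, so every run is reproducible and states are independent. Before
estimation, each state's configurations are subsampled at the statistical
inefficiency $g = 1 + 2\sum_t (1 - t/n)\rho_t$ of its energy series
(autocorrelation truncated at the first non-positive value), so estimator
inputs are approximately independent samples; $N_k$ in all formulas counts
these retained samples. Tuned Metropolis on these toys has $g \approx$ 5–15
in sweep units, which the defaults in the tests and acceptance script are
sized for.

## The solution side

The chemical potential of a solute at mole fraction $x$ decomposes as

$$\mu(x) = \mu^0 + \tfrac{1}{\beta}\ln\!\big(\Lambda^3 N_i / V\big)
  + \mu^{ex}(x).$$

$\mu^{ex}$ is the solvation (coupling) free energy of one solute molecule,
computed by `mu_excess_decoupling()`: soft-core Lennard-Jones decoupling of
the solute–solvent interaction over 12 states by default, estimated with
MBAR; the solute's internal Hamiltonian is never scaled. The Beutler-form
soft core ($\alpha = 0.5$) is finite at $r \to 0$ for $\lambda < 1$, which
is what makes the $\lambda \to 0$ end integrable. Two independent oracles
check the decoupling route: Widom test-particle insertion into the
decoupled-state configurations, and the low-density virial limit
$2B_2\rho/\beta$ with $B_2$ from quadrature of the same truncated, unshifted
potential to the same cutoff.

$\mu^0$, the configuration-independent single-molecule term, bypasses the
unknown internal partition function through a single-molecule Einstein
cycle: $\mu^0 = \mu^{ideal} - (\mu^{FF\,off} + \mu^{restraining})$. The
package assembles this from its three legs (`mu_standard()`); the bundled
acetylsalicylic-acid dataset carries published GAFF/TIP3P values for all
legs so the full assembly can be exercised without force-field simulations.

## Solubility

`find_solubility()` interpolates $\mu(x)$ piecewise-linearly in $\ln x$
(the ideal term is logarithmic in composition) and returns the smallest
crossing with $\mu^{solid}$, or a *range-relative* verdict —
`insoluble-in-range` / `supersaturated-in-range` — when no crossing exists
among the sampled concentrations; extrapolation beyond them is never
attempted. The verdict carries a `confident` flag when the gap exceeds the
joint $3\sigma$ band everywhere. Exact ties resolve to the smaller
concentration. $P\Delta V$ corrections are reported by `pdv_correction()`
but never silently added: at crystal-relaxation scales
(${\sim}0.1\,\text{nm}^3$ at ambient pressure) they are
${\sim}3\times10^{-3}\,k_BT$, far below the statistical error of any
sampled leg, so $\Delta G \approx \Delta A$ for the solid.

```{r toy, eval = FALSE}
cr <- build_fcc_crystal(2, 5.26) # 32 atoms
lam <- de_broglie_wavelength(39.948, 298.15)
solid_terms <- list(site_restraint(25, cr$coords, exclude = cr$fixed_atom,
                                   name = "springs"))
res <- emm_solid_mu(cr, solid_terms, k_ref = 4000, lambda_db = lam,
                    n_ff = 8, n_rest = 20, n_steps = 3000, seed = 77,
                    step = 0.016)
res$solid
```

## What the toy systems do and do not show

The synthetic crystals and solutions exercised by the tests are chosen so
that every pipeline stage has an independent oracle: pure-restraint solids
are themselves Einstein molecules (closed-form $A$), restraint switches have
Gaussian free energies $(3(N-1)/2\beta)\ln(k_0/k_1)$, dilute Lennard-Jones
solutions have Widom and virial limits. Passing these tests demonstrates
that the estimators, the cycle bookkeeping, the overlap diagnostics and the
crossing logic are correct — it does *not* demonstrate that any particular
force field yields accurate solubilities for real molecular crystals, nor
that the sampling lengths adequate for harmonic toys transfer to systems
with slow internal degrees of freedom, hydrogen-bond networks or polymorph
competition. The bundled acetylsalicylic-acid tables illustrate exactly this
gap: the assembled model chemical potentials place the solution tens of
$k_BT$ above the solid at every sampled concentration (an insoluble-in-range
verdict), while the real compound is modestly soluble.

## Numerical choices and problem sizes

* MBAR: anchor $f_1 = 0$, tolerance $10^{-10}$, SCF + adaptive Newton,
  maximum 2000 iterations; non-convergence is reported with the residual.
* BAR: root bracketed and expanded geometrically, solved to $10^{-10}$;
  variance from the logistic-information expression.
* TI: trapezoid; for restraint switches the integration variable is chosen
  so the restraint constant varies as $k \propto t^4$ on a linear $t$ grid
  (states packed at the weak end), where the integrand is mild — integrating
  the same states directly in the power-spaced variable has a quadrature
  bias an order of magnitude above the statistical error.
* Uncertainties: MBAR asymptotic covariance by default; seeded bootstrap
  (200 resamples) for EXP; leg errors combine in quadrature under the
  documented independent-leg assumption.
* Degenerate inputs: constant time series report one effective sample;
  zero-acceptance states raise a warning naming the state pathological;
  exact chemical-potential ties resolve to the smaller mole fraction.
* Test and acceptance problem sizes — 32-atom crystals, 100-particle
  solvent boxes, $10^4$ retained samples per state for the switch oracle,
  $10^6$ reference-integral samples — are the package's chosen study
  conditions for desk-scale verification: large enough that every
  statistical check has power, small enough to run in minutes.

## Known limitations

Orthorhombic boxes and minimum-image truncated (unshifted) Lennard-Jones
only; no electrostatics, no NPT sampling (NPT volumes enter as inputs when
reconstructing solution series); molecules are rigid references for the
reference integral (internal flexibility is handled by the sampled legs, not
by $A^{EM}$); uncertainties assume independent legs and decorrelated
samples. The `estimate` and `solubility` command-line wrappers under
`inst/cli/` are thin covers over the functions documented here.
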