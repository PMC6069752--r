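#' Energy model terms
#'
#' An energy model is an ordered set of named terms, each carrying a scaling
#' coefficient so Hamiltonians can be mixed along alchemical paths. Three term
#' families are provided:
#'
#' * `site_restraint(k, ref, exclude)` — isotropic harmonic tethers
#'   \eqn{(k/2) \sum_i |r_i - r_{0,i}|^2} over all atoms except the excluded
#'   (fixed) one, which carries no restraint;
#' * `lj_pair(eps, sigma, cutoff, atoms, between)` — truncated (unshifted)
#'   Lennard-Jones pairs under the minimum-image convention, either all pairs
#'   within `atoms` or cross pairs `atoms` x `between`;
#' * `harmonic_bond(bonds, kb, r0)` — intramolecular harmonic bonds;
#' * `softcore_pair(...)` — Beutler-style soft-core Lennard-Jones used to
#'   decouple a solute (finite at r = 0 for lambda < 1), see
#'   [softcore_pair_energy].
#'
#' @param k restraint constant in k_B T / A^2.
#' @param ref n x 3 reference coordinate matrix.
#' @param exclude index of the fixed atom (its restraint energy is
#'   identically zero), or NULL.
#' @param eps,sigma,cutoff Lennard-Jones well depth (k_B T), diameter and
#'   cutoff (Angstrom).
#' @param atoms indices the term acts on (all pairs within, when `between` is
#'   NULL).
#' @param between optional second index set for cross interactions.
#' @param lambda soft-core coupling parameter in `[0, 1]` (1 = plain LJ).
#' @param alpha soft-core parameter (default 0.5).
#' @param bonds m x 2 integer matrix of bonded pairs.
#' @param kb,r0 bond constants (k_B T / A^2) and rest lengths (Angstrom).
#' @param coeff initial scaling coefficient of the term.
#' @param name optional term name.
#' @return a term object (a list with class `energy_term`).
#' @name energy_terms
NULL

new_term <- function(type, name, coeff, ...) {
  structure(c(list(type = type, name = name, coeff = coeff), list(...)),
            class = "energy_term")
}

#' @rdname energy_terms
#' @export
site_restraint <- function(k, ref, exclude = NULL, coeff = 1, name = "restraint") {
  if (k <= 0) stop("restraint constant must be positive")
  new_term("site_restraint", name, coeff, k = k, ref = as.matrix(ref),
           exclude = if (is.null(exclude)) 0L else as.integer(exclude))
}

#' @rdname energy_terms
#' @export
lj_pair <- function(eps, sigma, cutoff, atoms, between = NULL, coeff = 1,
                    name = "lj") {
  if (sigma <= 0 || cutoff <= 0) stop("sigma and cutoff must be positive")
  new_term("lj_pair", name, coeff, eps = eps, sigma = sigma, cutoff = cutoff,
           A = as.integer(atoms), B = as.integer(if (is.null(between)) integer(0) else between))
}

#' @rdname energy_terms
#' @export
softcore_pair <- function(eps, sigma, cutoff, lambda = 1, alpha = 0.5,
                          atoms, between, coeff = 1, name = "softcore") {
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  new_term("softcore_pair", name, coeff, eps = eps, sigma = sigma,
           cutoff = cutoff, lambda = lambda, alpha = alpha,
           A = as.integer(atoms), B = as.integer(between))
}

#' @rdname energy_terms
#' @export
harmonic_bond <- function(bonds, kb, r0, coeff = 1, name = "bonds") {
  bonds <- matrix(as.integer(bonds), ncol = 2)
  new_term("harmonic_bond", name, coeff, bonds = bonds,
           kb = rep_len(as.numeric(kb), nrow(bonds)),
           r0 = rep_len(as.numeric(r0), nrow(bonds)))
}

#' Assemble an energy model
#'
#' @param ... `energy_term` objects (or a single list of them).
#' @param box length-3 orthorhombic box edges (Angstrom). Pair cutoffs must
#'   not exceed half the smallest box edge (minimum-image validity).
#' @return an object of class `energy_model`.
#' @export
energy_model <- function(..., box) {
  terms <- list(...)
  if (length(terms) == 1 && !inherits(terms[[1]], "energy_term")) terms <- terms[[1]]
  stopifnot(all(vapply(terms, inherits, TRUE, "energy_term")))
  box <- as.numeric(box)
  stopifnot(length(box) == 3, all(box > 0))
  for (tm in terms) {
    if (!is.null(tm$cutoff) && tm$cutoff > min(box) / 2 + 1e-9)
      stop("pair cutoff exceeds half the smallest box edge")
  }
  nm <- vapply(terms, `[[`, "", "name")
  if (anyDuplicated(nm)) nm <- make.unique(nm)
  for (i in seq_along(terms)) terms[[i]]$name <- nm[i]
  structure(list(terms = terms, box = box), class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf("Energy model: %d terms [%s]; box %.2f x %.2f x %.2f A\n",
              length(x$terms),
              paste(vapply(x$terms, function(t)
                sprintf("%s (x%.3g)", t$name, t$coeff), ""), collapse = ", "),
              x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' Rescale term coefficients of a model
#'
#' @param model an [energy_model].
#' @param coeffs named (by term name) or positional numeric coefficients;
#'   existing coefficients are multiplied by these factors when
#'   `multiply = TRUE` (default: replaced).
#' @param multiply multiply instead of replace.
#' @return the modified model.
#' @export
set_coeffs <- function(model, coeffs, multiply = FALSE) {
  nm <- vapply(model$terms, `[[`, "", "name")
  if (!is.null(names(coeffs))) {
    idx <- match(names(coeffs), nm)
    if (anyNA(idx)) stop("unknown term name in coeffs")
  } else {
    idx <- seq_along(coeffs)
  }
  for (j in seq_along(idx)) {
    i <- idx[j]
    model$terms[[i]]$coeff <- if (multiply) model$terms[[i]]$coeff * coeffs[[j]] else coeffs[[j]]
  }
  model
}

term_list <- function(model) lapply(model$terms, unclass)

#' Evaluate an energy model
#'
#' Returns the total reduced energy \eqn{\sum_t c_t E_t} together with the
#' per-term breakdown (after scaling) needed for thermodynamic-integration
#' derivatives. Deterministic for a given configuration.
#'
#' @param model an [energy_model].
#' @param coords n x 3 configuration (Angstrom).
#' @param scalings optional per-term coefficients overriding the model's; must
#'   lie in `[0, 1]` for all terms except soft-core (whose coupling lives in
#'   its `lambda` parameter).
#' @return list with `total` (k_B T), `terms` (named, scaled) and `raw`
#'   (unscaled term energies).
#' @export
evaluate_energy <- function(model, coords, scalings = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must be an n x 3 matrix")
  if (anyNA(coords) || any(!is.finite(coords))) stop("non-finite coordinates")
  types <- vapply(model$terms, `[[`, "", "type")
  if (!is.null(scalings)) {
    bad <- types != "softcore_pair" & (unlist(scalings) < 0 | unlist(scalings) > 1)
    if (any(bad, na.rm = TRUE)) stop("scalings must lie in [0, 1]")
    model <- set_coeffs(model, scalings)
  }
  raw <- cpp_term_energies(coords, term_list(model), model$box)
  names(raw) <- vapply(model$terms, `[[`, "", "name")
  co <- vapply(model$terms, `[[`, 1.0, "coeff")
  scaled <- raw * co
  list(total = sum(scaled), terms = scaled, raw = raw)
}

#' Soft-core pair potential
#'
#' Beutler-form soft-core Lennard-Jones,
#' \deqn{U(r; \lambda) = 4 \epsilon \lambda \left[ (\alpha (1-\lambda)^2 +
#'   (r/\sigma)^6)^{-2} - (\alpha (1-\lambda)^2 + (r/\sigma)^6)^{-1} \right],}
#' which reduces to the plain LJ potential at \eqn{\lambda = 1}, vanishes at
#' \eqn{\lambda = 0}, and stays finite as \eqn{r \to 0} for
#' \eqn{\lambda < 1} — the property that makes solute decoupling paths
#' integrable.
#'
#' @param eps well depth (k_B T).
#' @param sigma LJ diameter (Angstrom).
#' @param r distance(s) (Angstrom), > 0 allowed down to 0 for lambda < 1.
#' @param lambda coupling parameter in `[0, 1]`.
#' @param alpha soft-core parameter (default 0.5).
#' @return energy in k_B T (vectorized over `r`).
#' @export
softcore_pair_energy <- function(eps, sigma, r, lambda, alpha = 0.5) {
  if (any(lambda < 0 | lambda > 1)) stop("lambda must lie in [0, 1]")
  s6 <- (r / sigma)^6
  D <- alpha * (1 - lambda)^2 + s6
  4 * eps * lambda * (1 / D^2 - 1 / D)
}
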