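#' Define a molecule topology
#'
#' A molecule is described by its atom labels, masses, a rigid reference
#' geometry, an optional harmonic bond list, and its proper-rotation symmetry
#' number. The symmetry number enters the solid free energy as
#' \eqn{-N \ln(\Sigma_{rot}) / \beta} because isotropic site restraints
#' distinguish orientations that are physically equivalent.
#'
#' @param labels character vector of atom labels (element symbols).
#' @param masses atomic masses in u, one per atom, all positive.
#' @param coords reference geometry, an n x 3 matrix in Angstrom.
#' @param bonds optional m x 2 integer matrix of bonded atom index pairs.
#' @param bond_k harmonic bond constants (k_B T / A^2), length m.
#' @param bond_r0 bond rest lengths (Angstrom), length m.
#' @param sigma_rot integer proper-rotation symmetry number, >= 1.
#' @param linear logical; TRUE for linear molecules (orientational measure
#'   4*pi instead of 8*pi^2).
#' @return an object of class `molecule_topology`.
#' @examples
#' dumbbell <- molecule_topology(
#'   labels = c("A", "A"), masses = c(10, 10),
#'   coords = rbind(c(0, 0, 0), c(1.2, 0, 0)),
#'   bonds = rbind(c(1L, 2L)), bond_k = 100, bond_r0 = 1.2,
#'   sigma_rot = 2, linear = TRUE
#' )
#' @export
molecule_topology <- function(labels, masses, coords, bonds = NULL,
                              bond_k = numeric(0), bond_r0 = numeric(0),
                              sigma_rot = 1L, linear = FALSE) {
  coords <- as.matrix(coords)
  n <- length(labels)
  stopifnot(length(masses) == n, nrow(coords) == n, ncol(coords) == 3)
  if (any(masses <= 0)) stop("masses must be positive")
  if (sigma_rot < 1 || sigma_rot != round(sigma_rot))
    stop("sigma_rot must be an integer >= 1")
  if (!is.null(bonds)) {
    bonds <- matrix(as.integer(bonds), ncol = 2)
    if (any(bonds < 1L) || any(bonds > n)) stop("bond indices out of range")
    stopifnot(length(bond_k) == nrow(bonds), length(bond_r0) == nrow(bonds))
  } else {
    bonds <- matrix(integer(0), ncol = 2)
  }
  structure(list(
    labels = as.character(labels), masses = as.numeric(masses),
    coords = unname(coords), bonds = bonds,
    bond_k = as.numeric(bond_k), bond_r0 = as.numeric(bond_r0),
    sigma_rot = as.integer(sigma_rot), linear = isTRUE(linear)
  ), class = "molecule_topology")
}

#' @export
print.molecule_topology <- function(x, ...) {
  cat(sprintf("Molecule topology: %d atoms, mass %.3f u, %d bonds, sigma_rot = %d%s\n",
              length(x$labels), sum(x$masses), nrow(x$bonds), x$sigma_rot,
              if (x$linear) " (linear)" else ""))
  invisible(x)
}

#' Atomic (single-site) topology helper
#'
#' @param label element symbol.
#' @param mass atomic mass in u.
#' @return a `molecule_topology` with a single site and symmetry number 1.
#' @export
atomic_topology <- function(label = "Ar", mass = 39.948) {
  molecule_topology(label, mass, matrix(0, 1, 3))
}

#' Serialize / restore a molecule topology as JSON
#'
#' Round-trips all fields, including the symmetry number, so topologies can be
#' carried in structured run configuration documents.
#'
#' @param topology a `molecule_topology`.
#' @param file path to write to / read from.
#' @return `read_topology_json` returns a `molecule_topology`.
#' @export
write_topology_json <- function(topology, file) {
  stopifnot(inherits(topology, "molecule_topology"))
  obj <- topology
  class(obj) <- NULL
  jsonlite::write_json(obj, file, digits = NA, auto_unbox = FALSE)
  invisible(file)
}

#' @rdname write_topology_json
#' @export
read_topology_json <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  molecule_topology(
    labels = obj$labels, masses = obj$masses,
    coords = matrix(unlist(obj$coords), ncol = 3,
                    byrow = !is.matrix(obj$coords)),
    bonds = if (length(obj$bonds) > 0)
      matrix(unlist(obj$bonds), ncol = 2, byrow = !is.matrix(obj$bonds))
    else NULL,
    bond_k = obj$bond_k, bond_r0 = obj$bond_r0,
    sigma_rot = obj$sigma_rot, linear = obj$linear
  )
}
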