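#' Crystal specification
#'
#' Bundles an orthorhombic periodic box, per-atom lattice reference
#' coordinates, the molecule topology, and the index of the single fixed atom
#' that anchors the Einstein molecule reference state (fixing one atom, rather
#' than the center of mass, removes lattice-drift complications and the need
#' for a release-free-energy term).
#'
#' @param coords n_atoms x 3 matrix of lattice reference coordinates (Angstrom).
#' @param box length-3 numeric, orthorhombic box edges (Angstrom).
#' @param topology a [molecule_topology] describing one molecule.
#' @param n_molecules number of molecules; `nrow(coords)` must equal
#'   `n_molecules * n_sites`.
#' @param fixed_atom index (1-based, over all atoms) of the fixed atom.
#' @return an object of class `crystal_spec`.
#' @export
crystal_spec <- function(coords, box, topology, n_molecules, fixed_atom = 1L) {
  coords <- as.matrix(coords)
  box <- as.numeric(box)
  stopifnot(length(box) == 3, all(box > 0), ncol(coords) == 3)
  n_sites <- nrow(topology$coords)
  if (nrow(coords) != n_molecules * n_sites)
    stop("coords rows must equal n_molecules * sites per molecule")
  if (n_molecules < 1) stop("need at least one molecule")
  if (length(fixed_atom) != 1 || fixed_atom < 1 || fixed_atom > nrow(coords))
    stop("exactly one fixed atom, with a valid index, is required")
  if (any(coords < -1e-9) || any(sweep(coords, 2, box) > 1e-9))
    stop("reference coordinates must lie inside the box")
  structure(list(
    coords = unname(coords), box = box, topology = topology,
    n_molecules = as.integer(n_molecules), n_sites = n_sites,
    fixed_atom = as.integer(fixed_atom)
  ), class = "crystal_spec")
}

#' @export
print.crystal_spec <- function(x, ...) {
  cat(sprintf(
    "Crystal: %d molecules x %d sites = %d atoms; box %.3f x %.3f x %.3f A; fixed atom %d\n",
    x$n_molecules, x$n_sites, nrow(x$coords), x$box[1], x$box[2], x$box[3],
    x$fixed_atom))
  invisible(x)
}

#' Build a face-centered cubic atomic crystal
#'
#' Generates `4 * n^3` lattice sites in a cubic box of edge
#' `n_cells * lattice_constant` (the conventional fcc cell has four sites).
#' A six-cell edge gives the 864-atom argon crystal used as a small test
#' system for restraint-removal free energies.
#'
#' @param n_cells conventional cells per box edge (>= 1).
#' @param lattice_constant fcc lattice constant a in Angstrom (> 0).
#' @param fixed_atom index of the fixed reference atom (default 1; the choice
#'   is in principle arbitrary).
#' @param element,mass element label and atomic mass (u) for the topology.
#' @return a [crystal_spec].
#' @examples
#' ar <- build_fcc_crystal(2, 5.26)  # 32 atoms
#' @export
build_fcc_crystal <- function(n_cells, lattice_constant, fixed_atom = 1L,
                              element = "Ar", mass = 39.948) {
  if (n_cells < 1 || n_cells != round(n_cells)) stop("n_cells must be a positive integer")
  if (lattice_constant <= 0) stop("lattice_constant must be positive")
  a <- lattice_constant
  basis <- rbind(c(0, 0, 0), c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0)) * a
  cells <- as.matrix(expand.grid(x = 0:(n_cells - 1), y = 0:(n_cells - 1),
                                 z = 0:(n_cells - 1))) * a
  coords <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sweep(basis, 2, cells[i, ], "+")
  }))
  crystal_spec(coords, rep(n_cells * a, 3), atomic_topology(element, mass),
               n_molecules = nrow(coords), fixed_atom = fixed_atom)
}

#' Build a toy molecular crystal
#'
#' Places rigid copies of the topology's reference geometry on a simple cubic
#' lattice (one molecule per cell, centered), giving per-atom lattice
#' reference positions for a periodic molecular crystal. A stand-in for
#' force-field molecular crystals at the scale where the Einstein molecule
#' cycle can be exercised end to end.
#'
#' @param topology a [molecule_topology].
#' @param n_cells cells per edge (scalar or length 3).
#' @param lattice_constant cell edge in Angstrom; must exceed the molecular
#'   extent so neighboring copies do not overlap.
#' @param fixed_atom fixed atom index (default: first atom of first molecule).
#' @return a [crystal_spec].
#' @examples
#' top <- molecule_topology(c("A", "B"), c(12, 16),
#'                          rbind(c(-0.6, 0, 0), c(0.6, 0, 0)),
#'                          bonds = rbind(c(1L, 2L)), bond_k = 500, bond_r0 = 1.2)
#' cr <- build_toy_molecular_crystal(top, 2, 6)  # 8 molecules, 16 atoms
#' @export
build_toy_molecular_crystal <- function(topology, n_cells, lattice_constant,
                                        fixed_atom = 1L) {
  stopifnot(inherits(topology, "molecule_topology"))
  if (length(n_cells) == 1) n_cells <- rep(n_cells, 3)
  if (any(n_cells < 1) || lattice_constant <= 0) stop("invalid lattice parameters")
  a <- lattice_constant
  geom <- sweep(topology$coords, 2, colMeans(topology$coords)) # center molecule
  cells <- as.matrix(expand.grid(x = seq_len(n_cells[1]) - 0.5,
                                 y = seq_len(n_cells[2]) - 0.5,
                                 z = seq_len(n_cells[3]) - 0.5)) * a
  coords <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sweep(geom, 2, cells[i, ], "+")
  }))
  box <- n_cells * a
  d <- min_pair_distance(coords, box)
  if (d < 0.5)
    stop(sprintf("overlapping sites: minimum pair distance %.3f A < 0.5 A", d))
  crystal_spec(coords, box, topology, n_molecules = nrow(cells),
               fixed_atom = fixed_atom)
}

#' Minimum-image pair distance
#'
#' Smallest distance between any two atoms under the minimum-image convention
#' in an orthorhombic box.
#'
#' @param coords n x 3 coordinate matrix.
#' @param box length-3 box edges.
#' @return smallest pair distance (Angstrom).
#' @export
min_pair_distance <- function(coords, box) {
  n <- nrow(coords)
  if (n < 2) return(Inf)
  dmin <- Inf
  for (i in seq_len(n - 1)) {
    d <- sweep(coords[(i + 1):n, , drop = FALSE], 2, coords[i, ])
    d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
    dmin <- min(dmin, sqrt(min(rowSums(d^2))))
  }
  dmin
}

#' Atom indices of one molecule
#'
#' @param crystal a [crystal_spec].
#' @param i molecule index.
#' @return integer vector of atom indices (1-based).
#' @export
molecule_atoms <- function(crystal, i) {
  (i - 1L) * crystal$n_sites + seq_len(crystal$n_sites)
}

#' Write / read configurations as XYZ
#'
#' Standard XYZ layout: atom count, a comment line carrying the box vectors
#' (`box: Lx Ly Lz`), then `element x y z` records. `read_xyz` returns a list
#' with `coords`, `box` and `labels`.
#'
#' @param coords n x 3 coordinate matrix, or a [crystal_spec].
#' @param file output path.
#' @param labels element labels (recycled); taken from the crystal if given.
#' @param box box edges; taken from the crystal if given.
#' @export
write_xyz <- function(coords, file, labels = "X", box = NULL) {
  if (inherits(coords, "crystal_spec")) {
    box <- coords$box
    labels <- rep(coords$topology$labels, coords$n_molecules)
    coords <- coords$coords
  }
  n <- nrow(coords)
  labels <- rep_len(labels, n)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(as.character(n), con)
  writeLines(if (is.null(box)) "" else paste("box:", paste(format(box, digits = 12), collapse = " ")), con)
  writeLines(sprintf("%s %.8f %.8f %.8f", labels, coords[, 1], coords[, 2], coords[, 3]), con)
  invisible(file)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(file) {
  lines <- readLines(file)
  n <- as.integer(lines[1])
  box <- NULL
  if (grepl("^box:", lines[2])) {
    box <- as.numeric(strsplit(trimws(sub("^box:", "", lines[2])), "\\s+")[[1]])
  }
  rec <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  labels <- vapply(rec, `[`, "", 1)
  coords <- t(vapply(rec, function(r) as.numeric(r[2:4]), numeric(3)))
  list(coords = coords, box = box, labels = labels)
}

#' Write / read minimal PDB files
#'
#' Emits a CRYST1 record with the orthorhombic box and one ATOM record per
#' site; `read_pdb` parses only those records. Intended for interchange with
#' molecular viewers, not as a full PDB implementation.
#'
#' @inheritParams write_xyz
#' @export
write_pdb <- function(coords, file, labels = "X", box = NULL) {
  if (inherits(coords, "crystal_spec")) {
    box <- coords$box
    labels <- rep(coords$topology$labels, coords$n_molecules)
    coords <- coords$coords
  }
  if (is.null(box)) stop("a box is required for the CRYST1 record")
  n <- nrow(coords)
  labels <- rep_len(labels, n)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     box[1], box[2], box[3], 90, 90, 90), con)
  writeLines(sprintf("ATOM  %5d %-4s MOL A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                     seq_len(n), substr(labels, 1, 4), 1L,
                     coords[, 1], coords[, 2], coords[, 3],
                     substr(labels, 1, 2)), con)
  writeLines("END", con)
  invisible(file)
}

#' @rdname write_pdb
#' @export
read_pdb <- function(file) {
  lines <- readLines(file)
  cryst <- lines[startsWith(lines, "CRYST1")]
  box <- NULL
  if (length(cryst) > 0) {
    box <- as.numeric(c(substr(cryst[1], 7, 15), substr(cryst[1], 16, 24),
                        substr(cryst[1], 25, 33)))
  }
  at <- lines[startsWith(lines, "ATOM")]
  coords <- cbind(as.numeric(substr(at, 31, 38)), as.numeric(substr(at, 39, 46)),
                  as.numeric(substr(at, 47, 54)))
  labels <- trimws(substr(at, 13, 16))
  list(coords = coords, box = box, labels = labels)
}
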