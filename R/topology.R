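#' Molecular topology
#'
#' A `molecule_topology` collects the atoms, connectivity and derived term
#' lists of one molecule: bonds, angles, proper dihedrals, the 1-2/1-3
#' exclusion set and the scaled 1-4 pair set, symmetry-equivalent atom
#' groups (used by RESP stage 2), and named dihedral roles. The roles follow
#' the convention used for side-chain rotamers: `chi`, `phi` (or `phi1`,
#' `phi2` for difluoro species) and `psi` identify the threefold backbone
#' torsions whose g+/t/g- labels build a conformer key.
#'
#' Angles, dihedrals, exclusions and 1-4 pairs are derived from the bond
#' list alone: atoms separated by one or two bonds are excluded from
#' nonbonded interactions, atoms separated by exactly three bonds interact
#' with scaled 1-4 nonbonded terms.
#'
#' @param elements character vector of element symbols, one per atom.
#' @param bonds two-column integer matrix of bonded atom pairs (1-based).
#' @param symmetry_groups list of integer vectors of atoms declared
#'   chemically equivalent (e.g. the hydrogens of a methyl group).
#' @param dihedral_roles named list mapping role names (`chi`, `phi`,
#'   `phi1`, `phi2`, `psi`) to length-4 integer atom quadruples. Every role
#'   quadruple must be a proper dihedral of the bond graph.
#' @param net_charge integer total molecular charge in e.
#'
#' @return An object of class `molecule_topology` with fields `elements`,
#'   `n_atoms`, `bonds`, `angles`, `dihedrals`, `excl_12_13` (two-column
#'   matrix), `pairs_14` (two-column matrix), `nb_pairs` (all non-excluded
#'   pairs with a logical `is14` attribute), `symmetry_groups`,
#'   `dihedral_roles`, `net_charge`.
#' @export
molecule_topology <- function(elements, bonds, symmetry_groups = list(),
                              dihedral_roles = list(), net_charge = 0L) {
  n <- length(elements)
  if (n < 2) stop("a topology needs at least two atoms")
  bonds <- as.matrix(bonds)
  if (ncol(bonds) != 2) stop("bonds must be a two-column matrix")
  storage.mode(bonds) <- "integer"
  if (any(bonds < 1L) || any(bonds > n)) stop("bond index out of range")
  if (any(bonds[, 1] == bonds[, 2])) stop("self-bond not allowed")
  # canonical order, drop duplicates
  bonds <- t(apply(bonds, 1, sort))
  bonds <- unique(bonds)
  bonds <- bonds[order(bonds[, 1], bonds[, 2]), , drop = FALSE]

  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }

  # angles: i-j-k with i < k, j the apex
  angles <- matrix(integer(0), 0, 3)
  for (j in seq_len(n)) {
    nb <- sort(adj[[j]])
    if (length(nb) >= 2) {
      cmb <- utils::combn(nb, 2)
      angles <- rbind(angles, t(rbind(cmb[1, ], rep(j, ncol(cmb)), cmb[2, ])))
    }
  }

  # proper dihedrals: i-j-k-l over every central bond j-k
  dihedrals <- matrix(integer(0), 0, 4)
  for (k in seq_len(nrow(bonds))) {
    j <- bonds[k, 1]; kk <- bonds[k, 2]
    for (i in setdiff(adj[[j]], kk)) {
      for (l in setdiff(adj[[kk]], j)) {
        if (i != l) dihedrals <- rbind(dihedrals, c(i, j, kk, l))
      }
    }
  }
  # canonicalize i-j-k-l vs l-k-j-i and deduplicate
  if (nrow(dihedrals) > 0) {
    flip <- dihedrals[, 2] > dihedrals[, 3] |
      (dihedrals[, 2] == dihedrals[, 3] & dihedrals[, 1] > dihedrals[, 4])
    dihedrals[flip, ] <- dihedrals[flip, 4:1]
    dihedrals <- unique(dihedrals)
  }

  excl <- rbind(bonds, angles[, c(1, 3), drop = FALSE])
  excl <- unique(t(apply(excl, 1, sort)))

  p14 <- dihedrals[, c(1, 4), drop = FALSE]
  if (nrow(p14) > 0) {
    p14 <- unique(t(apply(p14, 1, sort)))
    # a 1-4 pair that is also 1-2/1-3 through a ring path stays excluded
    keyE <- paste(excl[, 1], excl[, 2])
    p14 <- p14[!(paste(p14[, 1], p14[, 2]) %in% keyE), , drop = FALSE]
  }

  # all nonbonded pairs: every i<j not excluded; 1-4 pairs flagged
  all_pairs <- t(utils::combn(n, 2))
  keyE <- paste(excl[, 1], excl[, 2])
  key14 <- paste(p14[, 1], p14[, 2])
  keyA <- paste(all_pairs[, 1], all_pairs[, 2])
  nb_pairs <- all_pairs[!(keyA %in% keyE), , drop = FALSE]
  is14 <- paste(nb_pairs[, 1], nb_pairs[, 2]) %in% key14

  roles_ok <- c("chi", "phi", "phi1", "phi2", "psi")
  if (length(dihedral_roles)) {
    if (is.null(names(dihedral_roles)) ||
        !all(names(dihedral_roles) %in% roles_ok)) {
      stop("dihedral role names must be among: ",
           paste(roles_ok, collapse = ", "))
    }
    dkey <- paste(dihedrals[, 1], dihedrals[, 2], dihedrals[, 3], dihedrals[, 4])
    for (nm in names(dihedral_roles)) {
      q <- as.integer(dihedral_roles[[nm]])
      if (length(q) != 4) stop("role '", nm, "' must be an atom quadruple")
      k1 <- paste(q[1], q[2], q[3], q[4])
      k2 <- paste(q[4], q[3], q[2], q[1])
      if (!(k1 %in% dkey || k2 %in% dkey)) {
        stop("role '", nm, "' quadruple is not a dihedral of the bond graph")
      }
      dihedral_roles[[nm]] <- q
    }
  }

  sg <- lapply(symmetry_groups, as.integer)
  if (length(sg) > 1 && anyDuplicated(unlist(sg))) {
    stop("symmetry groups must be disjoint")
  }

  structure(
    list(
      elements = as.character(elements),
      n_atoms = n,
      bonds = bonds,
      angles = angles,
      dihedrals = dihedrals,
      excl_12_13 = excl,
      pairs_14 = p14,
      nb_pairs = structure(nb_pairs, is14 = is14),
      symmetry_groups = sg,
      dihedral_roles = dihedral_roles,
      net_charge = as.integer(net_charge)
    ),
    class = "molecule_topology"
  )
}

#' @export
print.molecule_topology <- function(x, ...) {
  cat("molecule_topology:", x$n_atoms, "atoms (",
      paste(x$elements, collapse = " "), ")\n")
  cat("  bonds:", nrow(x$bonds), " angles:", nrow(x$angles),
      " dihedrals:", nrow(x$dihedrals), "\n")
  cat("  exclusions (1-2/1-3):", nrow(x$excl_12_13),
      " 1-4 pairs:", nrow(x$pairs_14), "\n")
  if (length(x$dihedral_roles)) {
    cat("  roles:", paste(names(x$dihedral_roles), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Conformation container
#'
#' @param coords N x 3 numeric matrix of Cartesian coordinates in Angstrom.
#' @param energy optional potential energy in kJ/mol.
#' @param tag optional provenance string.
#' @return An object of class `conformation`.
#' @export
conformation <- function(coords, energy = NA_real_, tag = "") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must be an N x 3 matrix")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  structure(list(coords = coords, energy = as.numeric(energy), tag = tag),
            class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat("conformation:", nrow(x$coords), "atoms")
  if (is.finite(x$energy)) cat(", energy", format(x$energy), "kJ/mol")
  if (nzchar(x$tag)) cat(", tag '", x$tag, "'", sep = "")
  cat("\n")
  invisible(x)
}
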