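#' Force-field parameter set
#'
#' Holds every symbol of the class-I potential
#' \deqn{U = \sum K_b (r - r_{eq})^2 + \sum K_\theta (\theta - \theta_{eq})^2
#'   + \sum \frac{V_n}{2}\left[1 + \cos(n\phi - \gamma_n)\right]
#'   + \sum 4\epsilon_{ij}\left[(\sigma_{ij}/r)^{12} - (\sigma_{ij}/r)^6\right]
#'   + \sum k_e q_i q_j / r_{ij}}
#' with one record per topological term. Nonbonded pairs use
#' Lorentz-Berthelot combination (arithmetic-mean sigma, geometric-mean
#' epsilon); 1-4 pairs are scaled by `scale_14_lj` and `scale_14_coul`
#' (AMBER defaults 0.5 and 1/1.2).
#'
#' @param bond_terms data.frame with columns `i`, `j` (atom indices),
#'   `K` (kJ/mol/A^2, >= 0), `r_eq` (A).
#' @param angle_terms data.frame with columns `i`, `j`, `k`,
#'   `K` (kJ/mol/rad^2, >= 0), `theta_eq` (rad).
#' @param dihedral_terms data.frame with columns `i`, `j`, `k`, `l`,
#'   `V` (kJ/mol), `n` (positive integer multiplicity), `gamma` (rad,
#'   normally 0 or pi). Several rows may share one quadruple (a cosine
#'   series).
#' @param lj data.frame with per-atom `sigma` (A, > 0) and `epsilon`
#'   (kJ/mol, >= 0).
#' @param charges numeric vector of per-atom partial charges in e.
#' @param coulomb_constant Coulomb prefactor, kJ mol^-1 A e^-2.
#' @param scale_14_lj,scale_14_coul dimensionless 1-4 scale factors.
#'
#' @return An object of class `ff_parameters`.
#' @export
ff_parameters <- function(bond_terms, angle_terms, dihedral_terms, lj, charges,
                          coulomb_constant = ff_constants$coulomb,
                          scale_14_lj = 0.5, scale_14_coul = 1 / 1.2) {
  stopifnot(all(c("i", "j", "K", "r_eq") %in% names(bond_terms)),
            all(c("i", "j", "k", "K", "theta_eq") %in% names(angle_terms)),
            all(c("i", "j", "k", "l", "V", "n", "gamma") %in%
                  names(dihedral_terms)),
            all(c("sigma", "epsilon") %in% names(lj)))
  if (any(bond_terms$K < 0) || any(angle_terms$K < 0)) {
    stop("force constants must be non-negative")
  }
  if (any(lj$sigma <= 0) || any(lj$epsilon < 0)) {
    stop("LJ sigma must be positive and epsilon non-negative")
  }
  if (any(dihedral_terms$n < 1)) stop("dihedral multiplicity must be >= 1")
  if (nrow(lj) != length(charges)) {
    stop("lj table and charges must cover the same atoms")
  }
  structure(
    list(
      bond_terms = as.data.frame(bond_terms),
      angle_terms = as.data.frame(angle_terms),
      dihedral_terms = as.data.frame(dihedral_terms),
      lj = as.data.frame(lj),
      charges = as.numeric(charges),
      coulomb_constant = coulomb_constant,
      scale_14_lj = scale_14_lj,
      scale_14_coul = scale_14_coul
    ),
    class = "ff_parameters"
  )
}

#' @export
print.ff_parameters <- function(x, ...) {
  cat("ff_parameters:", nrow(x$bond_terms), "bond,",
      nrow(x$angle_terms), "angle,",
      nrow(x$dihedral_terms), "dihedral terms;",
      length(x$charges), "atoms\n")
  invisible(x)
}

.term_key <- function(m) apply(m, 1, paste, collapse = "-")

# Order parameter tables to match a topology's term lists; errors name the
# first missing term. Bond/angle/dihedral rows may be given in either atom
# order.
match_parameters <- function(params, topo) {
  bt <- params$bond_terms
  bk <- paste(pmin(bt$i, bt$j), pmax(bt$i, bt$j))
  want <- paste(topo$bonds[, 1], topo$bonds[, 2])
  ib <- match(want, bk)
  if (anyNA(ib)) {
    stop("missing bond parameter for atoms ",
         want[which(is.na(ib))[1]])
  }
  at <- params$angle_terms
  ak <- paste(pmin(at$i, at$k), at$j, pmax(at$i, at$k))
  want <- paste(pmin(topo$angles[, 1], topo$angles[, 3]), topo$angles[, 2],
                pmax(topo$angles[, 1], topo$angles[, 3]))
  ia <- match(want, ak)
  if (anyNA(ia)) {
    stop("missing angle parameter for atoms ",
         want[which(is.na(ia))[1]])
  }
  dt <- params$dihedral_terms
  dk1 <- paste(dt$i, dt$j, dt$k, dt$l)
  dk2 <- paste(dt$l, dt$k, dt$j, dt$i)
  want <- paste(topo$dihedrals[, 1], topo$dihedrals[, 2],
                topo$dihedrals[, 3], topo$dihedrals[, 4])
  # dihedrals may carry several series terms: map each param row to a quad
  row_quad <- match(dk1, want)
  row_quad[is.na(row_quad)] <- match(dk2, want)[is.na(row_quad)]
  if (anyNA(row_quad)) {
    stop("dihedral parameter row ", which(is.na(row_quad))[1],
         " matches no topology dihedral")
  }
  if (!all(seq_along(want) %in% row_quad)) {
    miss <- setdiff(seq_along(want), row_quad)[1]
    stop("missing dihedral parameter for atoms ", want[miss])
  }
  if (nrow(params$lj) != topo$n_atoms) {
    stop("LJ table covers ", nrow(params$lj), " atoms but topology has ",
         topo$n_atoms)
  }
  list(bond_rows = ib, angle_rows = ia, dihedral_quad = row_quad)
}
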