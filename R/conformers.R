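#' Label a torsion angle with its rotamer well
#'
#' Threefold rotamer assignment by half-open intervals:
#' `0 <= angle < 120` degrees is `g+`, `120 <= angle < 240` is `t`, and
#' `-120 <= angle < 0` is `g-`. Any finite input angle is first wrapped
#' into `[-120, 240)`, so e.g. 300 degrees labels as `g-`. The three
#' preimages partition the circle.
#'
#' @param angle numeric vector of torsions in degrees.
#' @return character vector of labels among `"g+"`, `"t"`, `"g-"`.
#' @export
label_rotamer <- function(angle) {
  if (any(!is.finite(angle))) stop("angles must be finite")
  a <- ((angle + 120) %% 360) - 120
  out <- character(length(a))
  out[a >= 0 & a < 120] <- "g+"
  out[a >= 120 & a < 240] <- "t"
  out[a >= -120 & a < 0] <- "g-"
  out
}

#' Conformer key of a conformation
#'
#' Measures the role torsions of the molecule and assembles the class
#' string: monofluoro species use `chi phi (psi)`, difluoro species
#' `chi phi1 phi2 (psi)` canonicalized by taking the lexicographically
#' smaller of the two printed orderings (`chi phi1 phi2 (psi)` vs
#' `chi phi2 phi1 (psi)`) so symmetric assignments merge, and trifluoro
#' species `chi (psi)`.
#'
#' @inheritParams compute_energy
#' @param molecule_class one of `"mono"`, `"di"`, `"tri"`.
#' @return single conformer key string, e.g. `"g+t(g-)"`.
#' @export
conformer_key <- function(conf, topo, molecule_class = c("mono", "di", "tri")) {
  molecule_class <- match.arg(molecule_class)
  roles <- topo$dihedral_roles
  need <- switch(molecule_class,
                 mono = c("chi", "phi", "psi"),
                 di = c("chi", "phi1", "phi2", "psi"),
                 tri = c("chi", "psi"))
  for (nm in need) {
    if (is.null(roles[[nm]])) {
      stop("missing dihedral role '", nm, "' for class ", molecule_class)
    }
  }
  lab <- vapply(need, function(nm) {
    label_rotamer(measure_dihedral(conf, roles[[nm]]))
  }, "")
  key_from_labels(lab, molecule_class)
}

# assemble a key from named rotamer labels; used by conformer_key and the
# synthetic trajectory generator
key_from_labels <- function(lab, molecule_class) {
  switch(molecule_class,
         mono = paste0(lab[["chi"]], lab[["phi"]], "(", lab[["psi"]], ")"),
         di = {
           a <- paste0(lab[["chi"]], lab[["phi1"]], lab[["phi2"]],
                       "(", lab[["psi"]], ")")
           b <- paste0(lab[["chi"]], lab[["phi2"]], lab[["phi1"]],
                       "(", lab[["psi"]], ")")
           min(a, b)
         },
         tri = paste0(lab[["chi"]], "(", lab[["psi"]], ")"),
         stop("unknown molecule class"))
}

#' Conformer populations of a trajectory
#'
#' Clusters every frame into its conformer key and returns the relative
#' frequencies.
#'
#' @param traj list of [conformation()]s.
#' @param topo a [molecule_topology()] with the role torsions declared.
#' @param molecule_class one of `"mono"`, `"di"`, `"tri"`.
#' @return named numeric vector (class `population_table`): conformer key
#'   -> probability, summing to 1.
#' @export
trajectory_populations <- function(traj, topo, molecule_class = "mono") {
  if (length(traj) == 0) stop("empty trajectory")
  roles <- topo$dihedral_roles
  need <- switch(molecule_class,
                 mono = c("chi", "phi", "psi"),
                 di = c("chi", "phi1", "phi2", "psi"),
                 tri = c("chi", "psi"),
                 stop("unknown molecule class"))
  for (nm in need) {
    if (is.null(roles[[nm]])) {
      stop("missing dihedral role '", nm, "' for class ", molecule_class)
    }
  }
  # measure every role over all frames in one vectorized torsion call
  n <- topo$n_atoms
  coords_all <- do.call(rbind, lapply(traj, function(cf) {
    if (inherits(cf, "conformation")) cf$coords else as.matrix(cf)
  }))
  offsets <- (seq_along(traj) - 1L) * n
  labs <- sapply(need, function(nm) {
    quads <- matrix(rep(roles[[nm]], each = length(traj)), ncol = 4) + offsets
    deg <- rad2deg(.dihedral_rad(coords_all, quads))
    label_rotamer(((deg + 180) %% 360) - 180)
  })
  labs <- matrix(labs, ncol = length(need),
                 dimnames = list(NULL, need))
  keys <- switch(molecule_class,
    mono = paste0(labs[, "chi"], labs[, "phi"], "(", labs[, "psi"], ")"),
    di = pmin(paste0(labs[, "chi"], labs[, "phi1"], labs[, "phi2"],
                     "(", labs[, "psi"], ")"),
              paste0(labs[, "chi"], labs[, "phi2"], labs[, "phi1"],
                     "(", labs[, "psi"], ")")),
    tri = paste0(labs[, "chi"], "(", labs[, "psi"], ")"))
  tab <- table(keys)
  structure(as.numeric(tab) / length(keys), names = names(tab),
            class = "population_table")
}

#' Boltzmann populations from relative free energies
#'
#' `p_i = exp(-dG_i / RT) / sum_j exp(-dG_j / RT)` with
#' `R = 8.3144621e-3` kJ/mol/K. Invariant to adding a constant to all
#' free energies.
#'
#' @param dG named numeric vector of relative Gibbs free energies, kJ/mol
#'   (names are conformer keys).
#' @param T temperature, K.
#' @return named numeric vector (class `population_table`) summing to 1.
#' @export
boltzmann_populations <- function(dG, T = 298.15) {
  if (length(dG) == 0) stop("empty free-energy table")
  if (any(!is.finite(dG))) stop("free energies must be finite")
  w <- exp(-(dG - min(dG)) / (ff_constants$kB * T))
  structure(as.numeric(w / sum(w)), names = names(dG),
            class = "population_table")
}

#' @export
print.population_table <- function(x, ...) {
  df <- data.frame(conformer = names(x), probability = as.numeric(x))
  print(df[order(-df$probability), ], row.names = FALSE)
  invisible(x)
}

#' Flag conformers with an intramolecular hydrogen bond
#'
#' A representative (minimized) geometry is flagged when the declared donor
#' hydrogen to acceptor distance falls below a threshold.
#'
#' @inheritParams compute_energy
#' @param donor_h index of the donor hydrogen (e.g. the hydroxyl proton).
#' @param acceptor index of the acceptor atom (e.g. fluorine).
#' @param threshold distance threshold in A (default 2.5).
#' @return logical flag with attribute `distance` (A).
#' @export
has_imhb <- function(conf, donor_h, acceptor, threshold = 2.5) {
  coords <- if (inherits(conf, "conformation")) conf$coords else as.matrix(conf)
  d <- sqrt(sum((coords[donor_h, ] - coords[acceptor, ])^2))
  structure(d < threshold, distance = d)
}
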