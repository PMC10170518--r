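#' @importFrom stats optim rnorm runif setNames sd var
NULL

# row-wise cross product of two N x 3 matrices
.cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

.rownorm <- function(a) sqrt(rowSums(a * a))

# signed torsions for an M x 4 index matrix, radians in (-pi, pi]
.dihedral_rad <- function(coords, quads) {
  quads <- matrix(as.integer(quads), ncol = 4)
  x1 <- coords[quads[, 1], , drop = FALSE]
  x2 <- coords[quads[, 2], , drop = FALSE]
  x3 <- coords[quads[, 3], , drop = FALSE]
  x4 <- coords[quads[, 4], , drop = FALSE]
  b1 <- x2 - x1; b2 <- x3 - x2; b3 <- x4 - x3
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  nb2 <- .rownorm(b2)
  if (any(.rownorm(n1) < 1e-10 * nb2) || any(.rownorm(n2) < 1e-10 * nb2)) {
    stop("degenerate geometry: three consecutive collinear atoms in a dihedral")
  }
  atan2(rowSums(.cross(n1, n2) * b2) / nb2, rowSums(n1 * n2))
}

#' Measure a signed torsion angle
#'
#' Returns the IUPAC right-hand signed torsion about the 2-3 axis of an atom
#' quadruple, in degrees in `[-180, 180)`; the anti (trans) boundary is
#' reported as -180.
#'
#' @param conf a [conformation()] (or a bare N x 3 coordinate matrix).
#' @param quad length-4 integer vector of distinct atom indices.
#' @return angle in degrees in `[-180, 180)`.
#' @export
measure_dihedral <- function(conf, quad) {
  coords <- if (inherits(conf, "conformation")) conf$coords else as.matrix(conf)
  quad <- as.integer(quad)
  if (length(quad) != 4 || anyDuplicated(quad) ||
      any(quad < 1) || any(quad > nrow(coords))) {
    stop("quad must be four distinct in-range atom indices")
  }
  deg <- rad2deg(.dihedral_rad(coords, matrix(quad, 1)))
  ((deg + 180) %% 360) - 180
}

# bond lengths, angle values (rad) and dihedral values (rad) for all
# topology terms of one conformation
internal_coordinates <- function(coords, topo) {
  b <- topo$bonds
  d <- coords[b[, 2], , drop = FALSE] - coords[b[, 1], , drop = FALSE]
  r <- .rownorm(d)
  a <- topo$angles
  theta <- numeric(0)
  if (nrow(a) > 0) {
    u <- coords[a[, 1], , drop = FALSE] - coords[a[, 2], , drop = FALSE]
    v <- coords[a[, 3], , drop = FALSE] - coords[a[, 2], , drop = FALSE]
    cs <- rowSums(u * v) / (.rownorm(u) * .rownorm(v))
    theta <- acos(pmin(1, pmax(-1, cs)))
  }
  phi <- if (nrow(topo$dihedrals) > 0) {
    .dihedral_rad(coords, topo$dihedrals)
  } else numeric(0)
  list(r = r, theta = theta, phi = phi)
}

# nonbonded pair distances and the per-pair LJ/Coulomb prefactors
.nb_tables <- function(topo, params) {
  np <- topo$nb_pairs
  is14 <- attr(np, "is14")
  i <- np[, 1]; j <- np[, 2]
  sig <- (params$lj$sigma[i] + params$lj$sigma[j]) / 2
  eps <- sqrt(params$lj$epsilon[i] * params$lj$epsilon[j])
  qq <- params$coulomb_constant * params$charges[i] * params$charges[j]
  slj <- ifelse(is14, params$scale_14_lj, 1)
  scl <- ifelse(is14, params$scale_14_coul, 1)
  list(i = i, j = j, sigma = sig, eps = eps * slj, qq = qq * scl)
}

#' Evaluate the force-field energy of a conformation
#'
#' Computes each term of the class-I potential (see [ff_parameters()]):
#' harmonic bonds and angles, a cosine dihedral series
#' `(V_n/2)(1 + cos(n phi - gamma_n))`, and Lennard-Jones plus Coulomb
#' interactions over all non-excluded pairs with scaled 1-4 terms. No
#' distance cutoffs are applied: the target systems are small gas-phase
#' molecules.
#'
#' @inheritParams measure_dihedral
#' @param topo a [molecule_topology()].
#' @param params an [ff_parameters()] covering every term of `topo`.
#' @return A list of class `energy_breakdown` with components `bond`,
#'   `angle`, `dihedral`, `lj`, `coulomb` and `total` (kJ/mol).
#' @export
compute_energy <- function(conf, topo, params) {
  coords <- if (inherits(conf, "conformation")) conf$coords else as.matrix(conf)
  if (nrow(coords) != topo$n_atoms) stop("atom count mismatch")
  rows <- match_parameters(params, topo)
  ic <- internal_coordinates(coords, topo)

  bt <- params$bond_terms[rows$bond_rows, ]
  e_bond <- sum(bt$K * (ic$r - bt$r_eq)^2)

  at <- params$angle_terms[rows$angle_rows, ]
  e_angle <- sum(at$K * (ic$theta - at$theta_eq)^2)

  dt <- params$dihedral_terms
  phi_per_row <- ic$phi[rows$dihedral_quad]
  e_dih <- sum(dt$V / 2 * (1 + cos(dt$n * phi_per_row - dt$gamma)))

  nb <- .nb_tables(topo, params)
  e_lj <- 0; e_coul <- 0
  if (length(nb$i) > 0) {
    d <- coords[nb$j, , drop = FALSE] - coords[nb$i, , drop = FALSE]
    r <- .rownorm(d)
    if (any(r < 1e-6)) stop("overlapping atoms: nonbonded distance < 1e-6 A")
    sr6 <- (nb$sigma / r)^6
    e_lj <- sum(4 * nb$eps * (sr6^2 - sr6))
    e_coul <- sum(nb$qq / r)
  }

  total <- e_bond + e_angle + e_dih + e_lj + e_coul
  structure(list(bond = e_bond, angle = e_angle, dihedral = e_dih,
                 lj = e_lj, coulomb = e_coul, total = total),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  v <- unlist(x)
  cat(sprintf("%-9s %12.4f kJ/mol\n", names(v), v), sep = "")
  invisible(x)
}

# scatter-add `add` (M x 3) into F (N x 3) at row indices idx (may repeat)
.acc <- function(F, idx, add) {
  s <- rowsum(add, group = idx)
  at <- as.integer(rownames(s))
  F[at, ] <- F[at, , drop = FALSE] + s
  F
}

#' Analytic forces of the force field
#'
#' Returns the negative gradient `-dU/dx` of every term evaluated by
#' [compute_energy()], as an N x 3 matrix in kJ/mol/A. Agreement with central
#' finite differences is part of the test suite.
#'
#' @inheritParams compute_energy
#' @return N x 3 numeric matrix of forces.
#' @export
compute_forces <- function(conf, topo, params) {
  coords <- if (inherits(conf, "conformation")) conf$coords else as.matrix(conf)
  if (nrow(coords) != topo$n_atoms) stop("atom count mismatch")
  rows <- match_parameters(params, topo)
  F <- matrix(0, nrow(coords), 3)

  # bonds
  b <- topo$bonds
  bt <- params$bond_terms[rows$bond_rows, ]
  d <- coords[b[, 2], , drop = FALSE] - coords[b[, 1], , drop = FALSE]
  r <- .rownorm(d)
  coef <- 2 * bt$K * (r - bt$r_eq) / r          # dU/dr / r
  g2 <- d * coef                                 # dU/dx on atom j
  F <- .acc(F, b[, 2], -g2)
  F <- .acc(F, b[, 1], g2)

  # angles
  a <- topo$angles
  if (nrow(a) > 0) {
    at <- params$angle_terms[rows$angle_rows, ]
    u <- coords[a[, 1], , drop = FALSE] - coords[a[, 2], , drop = FALSE]
    v <- coords[a[, 3], , drop = FALSE] - coords[a[, 2], , drop = FALSE]
    nu <- .rownorm(u); nv <- .rownorm(v)
    uh <- u / nu; vh <- v / nv
    cs <- pmin(1, pmax(-1, rowSums(uh * vh)))
    sn <- sqrt(pmax(1e-12, 1 - cs^2))
    theta <- acos(cs)
    dU <- 2 * at$K * (theta - at$theta_eq)
    gi <- (uh * cs - vh) / (nu * sn) * dU        # dU/dx_i
    gk <- (vh * cs - uh) / (nv * sn) * dU
    F <- .acc(F, a[, 1], -gi)
    F <- .acc(F, a[, 3], -gk)
    F <- .acc(F, a[, 2], gi + gk)
  }

  # dihedrals (cosine series; several parameter rows may share a quad)
  dtab <- params$dihedral_terms
  if (nrow(dtab) > 0) {
    q <- topo$dihedrals[rows$dihedral_quad, , drop = FALSE]
    x1 <- coords[q[, 1], , drop = FALSE]; x2 <- coords[q[, 2], , drop = FALSE]
    x3 <- coords[q[, 3], , drop = FALSE]; x4 <- coords[q[, 4], , drop = FALSE]
    b1 <- x2 - x1; b2 <- x3 - x2; b3 <- x4 - x3
    n1 <- .cross(b1, b2); n2 <- .cross(b2, b3)
    nb2 <- .rownorm(b2)
    phi <- atan2(rowSums(.cross(n1, n2) * b2) / nb2, rowSums(n1 * n2))
    dU <- -dtab$V / 2 * dtab$n * sin(dtab$n * phi - dtab$gamma)
    g1 <- -n1 * (nb2 / rowSums(n1 * n1))         # dphi/dx1
    g4 <- n2 * (nb2 / rowSums(n2 * n2))          # dphi/dx4
    tt <- rowSums(b1 * b2) / nb2^2
    ss <- rowSums(b3 * b2) / nb2^2
    g2m <- -g1 * (1 + tt) + g4 * ss              # dphi/dx2
    g3m <- g1 * tt - g4 * (1 + ss)               # dphi/dx3
    F <- .acc(F, q[, 1], -g1 * dU)
    F <- .acc(F, q[, 2], -g2m * dU)
    F <- .acc(F, q[, 3], -g3m * dU)
    F <- .acc(F, q[, 4], -g4 * dU)
  }

  # nonbonded
  nb <- .nb_tables(topo, params)
  if (length(nb$i) > 0) {
    d <- coords[nb$j, , drop = FALSE] - coords[nb$i, , drop = FALSE]
    r <- .rownorm(d)
    if (any(r < 1e-6)) stop("overlapping atoms: nonbonded distance < 1e-6 A")
    sr6 <- (nb$sigma / r)^6
    # dU/dr for LJ + Coulomb
    dU <- 4 * nb$eps * (-12 * sr6^2 + 6 * sr6) / r - nb$qq / r^2
    g <- d * (dU / r)                            # dU/dx on atom j
    F <- .acc(F, nb$j, -g)
    F <- .acc(F, nb$i, g)
  }
  F
}

#' Locally minimize a conformation
#'
#' L-BFGS minimization of the force-field energy using the analytic forces,
#' run until the force max-norm falls below `tol`.
#'
#' @inheritParams compute_energy
#' @param tol convergence tolerance on the gradient max-norm, kJ/mol/A.
#' @param max_rounds number of L-BFGS restarts before giving up.
#' @return The minimized [conformation()] with its energy set. If the force
#'   tolerance was not reached a warning is raised and the attribute
#'   `converged` is `FALSE`.
#' @export
minimize_conformation <- function(conf, topo, params, tol = 1e-4,
                                  max_rounds = 5) {
  coords <- if (inherits(conf, "conformation")) conf$coords else as.matrix(conf)
  n <- nrow(coords)
  fn <- function(x) compute_energy(matrix(x, n, 3), topo, params)$total
  gr <- function(x) -as.vector(compute_forces(matrix(x, n, 3), topo, params))
  if (!is.finite(fn(as.vector(coords)))) stop("non-finite starting energy")
  x <- as.vector(coords)
  converged <- FALSE
  for (round in seq_len(max_rounds)) {
    opt <- stats::optim(x, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = 2000, factr = 10,
                                       pgtol = tol / 10))
    x <- opt$par
    if (max(abs(gr(x))) <= tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("minimization did not reach force tolerance ", tol,
            " kJ/mol/A; returning best iterate")
  }
  out <- conformation(matrix(x, n, 3), energy = fn(x),
                      tag = if (inherits(conf, "conformation")) conf$tag else "")
  attr(out, "converged") <- converged
  out
}

# atoms on the l-side of bond j-k (excluding j), by BFS on the bond graph
# with the j-k edge removed
downstream_atoms <- function(topo, j, k) {
  adj <- vector("list", topo$n_atoms)
  for (e in seq_len(nrow(topo$bonds))) {
    a <- topo$bonds[e, 1]; b <- topo$bonds[e, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- rep(FALSE, topo$n_atoms)
  seen[j] <- TRUE; seen[k] <- TRUE
  queue <- k
  out <- integer(0)
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    for (nb in adj[[cur]]) {
      if (!seen[nb]) {
        seen[nb] <- TRUE
        out <- c(out, nb)
        queue <- c(queue, nb)
      }
    }
  }
  c(k, out)
}

#' Set a torsion to a target value
#'
#' Rotates every atom on the far side of the central bond of `quad` about
#' that bond so that the measured torsion equals `angle_deg`. The bond graph
#' must be acyclic across the central bond.
#'
#' @inheritParams compute_energy
#' @param quad atom quadruple defining the torsion.
#' @param angle_deg target torsion in degrees.
#' @return The modified [conformation()].
#' @export
set_dihedral <- function(conf, topo, quad, angle_deg) {
  coords <- if (inherits(conf, "conformation")) conf$coords else as.matrix(conf)
  quad <- as.integer(quad)
  current <- measure_dihedral(coords, quad)
  delta <- deg2rad(angle_deg - current)
  j <- quad[2]; k <- quad[3]
  axis <- coords[k, ] - coords[j, ]
  axis <- axis / sqrt(sum(axis^2))
  movers <- setdiff(downstream_atoms(topo, j, k), k)
  if (length(movers)) {
    # Rodrigues rotation about the j->k axis through atom k
    p <- sweep(coords[movers, , drop = FALSE], 2, coords[k, ])
    cs <- cos(delta); sn <- sin(delta)
    K <- matrix(c(0, axis[3], -axis[2],
                  -axis[3], 0, axis[1],
                  axis[2], -axis[1], 0), 3, 3)
    Rm <- diag(3) * cs + sn * K + (1 - cs) * outer(axis, axis)
    coords[movers, ] <- sweep(p %*% t(Rm), 2, coords[k, ], "+")
  }
  if (inherits(conf, "conformation")) {
    conf$coords <- coords
    conf
  } else {
    conformation(coords)
  }
}
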