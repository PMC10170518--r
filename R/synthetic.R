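#' Build a toy fluorinated molecule with full parameter coverage
#'
#' Constructs a small acyclic molecule that mimics, at toy scale, the
#' connectivity of a gamma-fluorohydrin: a hydroxyl oxygen followed by a
#' carbon backbone, hydrogens filling every valence, and fluorine
#' substituents placed by pattern. The starting geometry is tetrahedral-ish
#' (ideal bond lengths, tetrahedral angles, staggered substituents) with a
#' small deterministic jitter. A generic parameter set covers every bond,
#' angle and dihedral term, with per-element Lennard-Jones values and small
#' partial charges summing exactly to the net charge.
#'
#' Substituent patterns and their dihedral roles:
#' \describe{
#'   \item{mono}{one F on the terminal carbon; roles `chi` (C-C-C-F),
#'     `phi` (O-C-C-C), `psi` (H-O-C-C). Needs `n_heavy >= 4`.}
#'   \item{di}{one F on each of the last two carbons; roles `chi`
#'     (O-C1-C2-C3), `phi1`, `phi2` (the two C-C-C-F torsions), `psi`.
#'     Needs `n_heavy >= 5`.}
#'   \item{tri}{a terminal CF3 group; roles `chi` (O-C1-C2-C3), `psi`.
#'     Needs `n_heavy >= 4`.}
#' }
#'
#' @param n_heavy number of heavy atoms (the oxygen plus `n_heavy - 1`
#'   carbons), 4 to 8.
#' @param pattern substituent pattern, one of `"mono"`, `"di"`, `"tri"`.
#' @param seed seed for the small coordinate jitter (pure function of it).
#' @return list with `topo` ([molecule_topology()]), `params`
#'   ([ff_parameters()]), `conf` (starting [conformation()]) and
#'   `molecule_class` (equal to `pattern`).
#' @export
make_toy_molecule <- function(n_heavy = 4, pattern = c("mono", "di", "tri"),
                              seed = 1L) {
  pattern <- match.arg(pattern)
  if (n_heavy < 4 || n_heavy > 8) stop("n_heavy must be in 4..8")
  if (pattern == "di" && n_heavy < 5) stop("pattern 'di' needs n_heavy >= 5")
  n_c <- n_heavy - 1

  elements <- c("O", rep("C", n_c))
  bonds <- cbind(seq_len(n_heavy - 1), 2:n_heavy)
  # substituents: fluorines by pattern, then hydrogens filling valence
  # (O gets one H; each C is filled to 4 bonds)
  sub_of <- vector("list", n_heavy)
  last <- n_heavy
  if (pattern == "mono") sub_of[[last]] <- "F"
  if (pattern == "di") {
    sub_of[[last]] <- "F"
    sub_of[[last - 1]] <- "F"
  }
  if (pattern == "tri") sub_of[[last]] <- c("F", "F", "F")

  heavy_deg <- tabulate(c(bonds), n_heavy)
  for (i in seq_len(n_heavy)) {
    cap <- if (elements[i] == "O") 2L else 4L
    n_h <- cap - heavy_deg[i] - length(sub_of[[i]])
    if (n_h < 0) stop("unsupported pattern: valence exceeded at atom ", i)
    sub_of[[i]] <- c(sub_of[[i]], rep("H", n_h))
  }

  # append substituent atoms, remembering indices
  sub_idx <- vector("list", n_heavy)
  for (i in seq_len(n_heavy)) {
    for (el in sub_of[[i]]) {
      elements <- c(elements, el)
      bonds <- rbind(bonds, c(i, length(elements)))
      sub_idx[[i]] <- c(sub_idx[[i]], length(elements))
    }
  }
  n_atoms <- length(elements)

  # --- geometry: zigzag backbone + tetrahedral substituents -------------
  blen <- function(a, b) {
    key <- paste(sort(c(a, b)), collapse = "-")
    switch(key, "C-C" = 1.526, "C-O" = 1.410, "H-O" = 0.960,
           "C-H" = 1.090, "C-F" = 1.350, stop("no bond length for ", key))
  }
  tet <- acos(-1 / 3)                      # 109.47 deg
  alpha <- (pi - tet) / 2
  coords <- matrix(0, n_atoms, 3)
  dirs <- rbind(c(cos(alpha), 0, sin(alpha)), c(cos(alpha), 0, -sin(alpha)))
  for (i in 2:n_heavy) {
    d <- dirs[1 + (i %% 2), ]
    coords[i, ] <- coords[i - 1, ] + d * blen(elements[i - 1], elements[i])
  }
  unit <- function(v) v / sqrt(sum(v * v))
  for (i in seq_len(n_heavy)) {
    subs <- sub_idx[[i]]
    if (length(subs) == 0) next
    heavy_nb <- setdiff(c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1]),
                        subs)
    if (length(heavy_nb) >= 2) {
      # two in-chain neighbors: fill the two remaining tetrahedral sites
      na_ <- unit(coords[heavy_nb[1], ] - coords[i, ])
      nb_ <- unit(coords[heavy_nb[2], ] - coords[i, ])
      u <- unit(-(na_ + nb_))
      v <- unit(.cross(matrix(na_, 1), matrix(nb_, 1))[1, ])
      hh <- tet / 2
      dlist <- list(u * cos(hh) + v * sin(hh), u * cos(hh) - v * sin(hh))
      for (s in seq_along(subs)) {
        coords[subs[s], ] <- coords[i, ] +
          dlist[[s]] * blen(elements[i], elements[subs[s]])
      }
    } else {
      # chain end: stagger substituents about the single backbone bond
      na_ <- unit(coords[heavy_nb[1], ] - coords[i, ])
      p <- unit(.cross(matrix(na_, 1), matrix(c(0, 1, 0), 1))[1, ])
      if (!all(is.finite(p))) {
        p <- unit(.cross(matrix(na_, 1), matrix(c(0, 0, 1), 1))[1, ])
      }
      q <- .cross(matrix(na_, 1), matrix(p, 1))[1, ]
      phis <- pi / 3 + (seq_along(subs) - 1) * 2 * pi / 3
      for (s in seq_along(subs)) {
        d <- na_ * (-1 / 3) +
          sqrt(8) / 3 * (p * cos(phis[s]) + q * sin(phis[s]))
        coords[subs[s], ] <- coords[i, ] +
          unit(d) * blen(elements[i], elements[subs[s]])
      }
    }
  }
  set.seed(seed)
  coords <- coords + matrix(stats::rnorm(3 * n_atoms, sd = 0.01), n_atoms, 3)

  # --- roles and symmetry groups ----------------------------------------
  hydroxyl_h <- sub_idx[[1]][1]
  roles <- switch(pattern,
    mono = list(chi = c(n_heavy - 2, n_heavy - 1, n_heavy,
                        sub_idx[[n_heavy]][1]),
                phi = c(1, 2, 3, 4),
                psi = c(hydroxyl_h, 1, 2, 3)),
    di = list(chi = c(1, 2, 3, 4),
              phi1 = c(n_heavy - 3, n_heavy - 2, n_heavy - 1,
                       sub_idx[[n_heavy - 1]][1]),
              phi2 = c(n_heavy - 2, n_heavy - 1, n_heavy,
                       sub_idx[[n_heavy]][1]),
              psi = c(hydroxyl_h, 1, 2, 3)),
    tri = list(chi = c(1, 2, 3, 4),
               psi = c(hydroxyl_h, 1, 2, 3)))

  sym <- list()
  for (i in seq_len(n_heavy)) {
    h_here <- sub_idx[[i]][sub_of[[i]] == "H"]
    if (i == 1) h_here <- setdiff(h_here, hydroxyl_h)
    if (length(h_here) >= 2) sym[[length(sym) + 1]] <- h_here
    f_here <- sub_idx[[i]][sub_of[[i]] == "F"]
    if (length(f_here) >= 2) sym[[length(sym) + 1]] <- f_here
  }

  topo <- molecule_topology(elements, bonds, symmetry_groups = sym,
                            dihedral_roles = roles, net_charge = 0L)

  # --- generic parameters ----------------------------------------------
  bK <- function(a, b) {
    key <- paste(sort(c(a, b)), collapse = "-")
    switch(key, "C-C" = 1300, "C-O" = 1340, "H-O" = 2300,
           "C-H" = 1420, "C-F" = 1500)
  }
  bt <- data.frame(i = topo$bonds[, 1], j = topo$bonds[, 2])
  bt$K <- mapply(bK, elements[bt$i], elements[bt$j])
  bt$r_eq <- mapply(blen, elements[bt$i], elements[bt$j])

  at <- data.frame(i = topo$angles[, 1], j = topo$angles[, 2],
                   k = topo$angles[, 3])
  at$K <- 260
  at$theta_eq <- tet

  dt <- data.frame(i = topo$dihedrals[, 1], j = topo$dihedrals[, 2],
                   k = topo$dihedrals[, 3], l = topo$dihedrals[, 4],
                   V = 0.65, n = 3L, gamma = 0)

  lj_sigma <- c(H = 2.60, C = 3.40, O = 3.00, F = 3.10)
  lj_eps <- c(H = 0.065, C = 0.36, O = 0.88, F = 0.255)
  lj <- data.frame(sigma = unname(lj_sigma[elements]),
                   epsilon = unname(lj_eps[elements]))

  q <- numeric(n_atoms)
  q[1] <- -0.55
  q[hydroxyl_h] <- 0.40
  q[elements == "F"] <- -0.22
  q[2] <- 0.15                              # carbon bonded to O
  for (i in seq_len(n_heavy)) {
    nf <- sum(sub_of[[i]] == "F")
    if (nf > 0) q[i] <- q[i] + 0.11 * nf
  }
  q[elements == "H"] <- q[elements == "H"] + 0.03
  q[hydroxyl_h] <- 0.40                     # restore after the H bump
  # absorb the remainder on the backbone carbons so the sum is exactly 0
  carbons <- which(elements == "C")
  q[carbons] <- q[carbons] - sum(q) / length(carbons)

  params <- ff_parameters(bt, at, dt, lj, q)
  conf <- conformation(coords, tag = "start")
  e <- compute_energy(conf, topo, params)
  conf$energy <- e$total
  list(topo = topo, params = params, conf = conf, molecule_class = pattern)
}

#' Surrogate reference potential
#'
#' Builds a "reference" potential that differs from a base force field by
#' smooth perturbations: force constants and amplitudes multiplied by
#' `1 + perturb_scale * u` with fixed `u ~ U(-1, 1)` per term, equilibrium
#' values jittered proportionally, plus an additive cubic bond-stretch
#' correction `cubic_coeff * sum_b (r_b - r_eq,b)^3` that the class-I
#' functional form cannot represent. Everything is a pure function of
#' `seed`; with zero perturbation and zero cubic coefficient the surrogate
#' equals the base force field.
#'
#' @param base_params an [ff_parameters()].
#' @param topo the matching [molecule_topology()].
#' @param perturb_scale multiplicative perturbation scale on force
#'   constants (dimensionless).
#' @param cubic_coeff coefficient of the cubic bond correction, kJ/mol/A^3.
#' @param seed RNG seed for the fixed perturbation draws.
#' @return a [potential_handle()] with attributes `params` (the perturbed
#'   [ff_parameters()]) and `cubic_coeff`.
#' @export
make_surrogate_reference <- function(base_params, topo, perturb_scale = 0.15,
                                     cubic_coeff = 0, seed = 1L) {
  set.seed(seed)
  p <- base_params
  u <- function(n) stats::runif(n, -1, 1)
  p$bond_terms$K <- p$bond_terms$K * (1 + perturb_scale * u(nrow(p$bond_terms)))
  p$bond_terms$r_eq <- p$bond_terms$r_eq *
    (1 + 0.05 * perturb_scale * u(nrow(p$bond_terms)))
  p$angle_terms$K <- p$angle_terms$K *
    (1 + perturb_scale * u(nrow(p$angle_terms)))
  p$angle_terms$theta_eq <- p$angle_terms$theta_eq *
    (1 + 0.05 * perturb_scale * u(nrow(p$angle_terms)))
  p$dihedral_terms$V <- p$dihedral_terms$V *
    (1 + perturb_scale * u(nrow(p$dihedral_terms)))

  n <- topo$n_atoms
  req <- p$bond_terms$r_eq[match_parameters(p, topo)$bond_rows]
  b <- topo$bonds
  cubic_energy <- function(coords) {
    d <- coords[b[, 2], , drop = FALSE] - coords[b[, 1], , drop = FALSE]
    r <- .rownorm(d)
    cubic_coeff * sum((r - req)^3)
  }
  cubic_forces <- function(coords) {
    d <- coords[b[, 2], , drop = FALSE] - coords[b[, 1], , drop = FALSE]
    r <- .rownorm(d)
    g2 <- d * (3 * cubic_coeff * (r - req)^2 / r)
    F <- matrix(0, n, 3)
    F <- .acc(F, b[, 2], -g2)
    .acc(F, b[, 1], g2)
  }
  m3 <- rep(element_masses(topo$elements), each = 3)
  h <- potential_handle(
    energy = function(x) {
      coords <- matrix(x, n, 3)
      compute_energy(coords, topo, p)$total + cubic_energy(coords)
    },
    forces = function(x) {
      coords <- matrix(x, n, 3)
      as.vector(compute_forces(coords, topo, p) + cubic_forces(coords))
    },
    masses = m3, label = "surrogate-reference"
  )
  attr(h, "params") <- p
  attr(h, "cubic_coeff") <- cubic_coeff
  h
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler for the von Mises circular distribution;
#' used by the trajectory generator for the peaked torsion wells.
#'
#' @param n number of draws.
#' @param mu center, radians.
#' @param kappa concentration (>= 0; 0 gives the uniform circle).
#' @return numeric vector of angles in `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0
  while (got < n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      got <- got + 1
      out[got] <- sign(u3 - 0.5) * acos(f) + mu
    }
  }
  ((out + pi) %% (2 * pi)) - pi
}

# parse a conformer key back into per-role rotamer labels
parse_conformer_key <- function(key, molecule_class) {
  inner <- sub("\\((.*)\\)$", "", key)
  psi <- sub(".*\\((.*)\\)$", "\\1", key)
  toks <- regmatches(inner, gregexpr("g\\+|g-|t", inner))[[1]]
  lab <- switch(molecule_class,
    mono = {
      if (length(toks) != 2) stop("bad mono key: ", key)
      c(chi = toks[1], phi = toks[2])
    },
    di = {
      if (length(toks) != 3) stop("bad di key: ", key)
      c(chi = toks[1], phi1 = toks[2], phi2 = toks[3])
    },
    tri = {
      if (length(toks) != 1) stop("bad tri key: ", key)
      c(chi = toks[1])
    },
    stop("unknown molecule class"))
  c(lab, psi = psi)
}

.rotamer_centers <- c("g+" = 60, "t" = 180, "g-" = -60)

#' Generate a dihedral trajectory with known rotamer weights
#'
#' Draws, for each frame, a conformer key from `weights` and then each role
#' torsion from a von Mises distribution centered at the rotamer well
#' (g+ = 60, t = 180, g- = -60 degrees) with concentration `kappa`; the
#' frame is built by rigid rotations about the role bonds starting from
#' `conf`. Realized key frequencies converge to `weights` by the law of
#' large numbers. The default `kappa = 16` keeps the wells essentially
#' non-overlapping: the mass a torsion places outside its 120-degree
#' assignment interval is about 3e-5, negligible against binomial
#' counting error even for very long trajectories.
#'
#' @param topo a [molecule_topology()] with role torsions declared.
#' @param conf base [conformation()] supplying everything the role
#'   torsions do not change.
#' @param weights named numeric vector: conformer key -> mixture weight
#'   (normalized internally).
#' @param molecule_class one of `"mono"`, `"di"`, `"tri"`.
#' @param kappa von Mises concentration (dimensionless).
#' @param n_frames number of frames.
#' @param seed RNG seed; the trajectory is a pure function of it.
#' @return list of [conformation()]s with attribute `keys` (the generating
#'   key of each frame).
#' @export
generate_dihedral_trajectory <- function(topo, conf, weights,
                                         molecule_class = "mono",
                                         kappa = 16, n_frames = 1000,
                                         seed = 1L) {
  if (is.null(names(weights)) || any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be a named non-negative vector")
  }
  weights <- weights / sum(weights)
  roles <- topo$dihedral_roles
  labels_per_key <- lapply(names(weights), parse_conformer_key,
                           molecule_class = molecule_class)
  names(labels_per_key) <- names(weights)
  role_names <- names(labels_per_key[[1]])
  for (nm in role_names) {
    if (is.null(roles[[nm]])) stop("topology lacks role '", nm, "'")
  }

  base <- if (inherits(conf, "conformation")) conf$coords else as.matrix(conf)
  # per-role rotation machinery, ordered so that no earlier rotation moves
  # a later axis (outermost fragment first)
  mach <- lapply(role_names, function(nm) {
    q <- roles[[nm]]
    movers <- setdiff(downstream_atoms(topo, q[2], q[3]), q[3])
    list(name = nm, quad = q, j = q[2], k = q[3], movers = movers,
         base_angle = measure_dihedral(base, q))
  })
  mach <- mach[order(vapply(mach, function(m) length(m$movers), 0L))]
  touched <- integer(0)
  for (m in mach) {
    if (any(c(m$j, m$k) %in% touched)) {
      stop("role torsions are not nested: cannot precompute rotations")
    }
    touched <- union(touched, m$movers)
  }

  set.seed(seed)
  key_draw <- sample(names(weights), n_frames, replace = TRUE,
                     prob = weights)
  # sample all torsion targets up front (radians)
  targets <- matrix(0, n_frames, length(mach))
  for (mi in seq_along(mach)) {
    nm <- mach[[mi]]$name
    labs <- vapply(labels_per_key[key_draw], `[[`, "", nm)
    for (lab in unique(labs)) {
      sel <- labs == lab
      targets[sel, mi] <- rvonmises(sum(sel),
                                    deg2rad(.rotamer_centers[[lab]]), kappa)
    }
  }

  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    coords <- base
    for (mi in seq_along(mach)) {
      m <- mach[[mi]]
      delta <- targets[f, mi] - deg2rad(m$base_angle)
      axis <- coords[m$k, ] - coords[m$j, ]
      axis <- axis / sqrt(sum(axis^2))
      K <- matrix(c(0, axis[3], -axis[2],
                    -axis[3], 0, axis[1],
                    axis[2], -axis[1], 0), 3, 3)
      cs <- cos(delta); sn <- sin(delta)
      Rm <- diag(3) * cs + sn * K + (1 - cs) * outer(axis, axis)
      pm <- sweep(coords[m$movers, , drop = FALSE], 2, coords[m$k, ])
      coords[m$movers, ] <- sweep(pm %*% t(Rm), 2, coords[m$k, ], "+")
    }
    frames[[f]] <- conformation(coords, tag = "synthetic-traj")
  }
  attr(frames, "keys") <- key_draw
  frames
}

#' Generate exact point-charge ESP grids
#'
#' Samples grid points on shells at 1.4-2.0 times the element van der
#' Waals radii (rejecting points closer than `min_dist` to any atom or
#' inside 1.4 vdW of any atom) and evaluates the exact point-charge
#' electrostatic potential of the given charges there.
#'
#' @param topo a [molecule_topology()].
#' @param charges per-atom charges in e.
#' @param confs list of [conformation()]s (one grid per conformation).
#' @param n_points grid points per conformation.
#' @param seed RNG seed.
#' @param shell numeric length-2: shell range as multiples of vdW radii.
#' @param min_dist hard minimum distance to any atom, A.
#' @return list of ESP grids (fields `points`, `values`,
#'   `conformation_ref`).
#' @export
generate_esp_fixture <- function(topo, charges, confs, n_points = 400,
                                 seed = 1L, shell = c(1.4, 2.0),
                                 min_dist = 1.0) {
  if (inherits(confs, "conformation")) confs <- list(confs)
  if (length(charges) != topo$n_atoms) stop("one charge per atom required")
  vdw <- element_vdw_radii(topo$elements)
  set.seed(seed)
  kc <- ff_constants$coulomb
  lapply(seq_along(confs), function(ci) {
    X <- confs[[ci]]$coords
    pts <- matrix(0, n_points, 3)
    got <- 0
    while (got < n_points) {
      i <- sample.int(topo$n_atoms, 1)
      v <- stats::rnorm(3)
      v <- v / sqrt(sum(v^2))
      rad <- vdw[i] * stats::runif(1, shell[1], shell[2])
      p <- X[i, ] + v * rad
      d <- sqrt(colSums((t(X) - p)^2))
      if (all(d >= min_dist) && all(d >= shell[1] * vdw)) {
        got <- got + 1
        pts[got, ] <- p
      }
    }
    vals <- as.vector((kc / sqrt(outer(rowSums(pts^2), rowSums(X^2), "+") -
                                   2 * pts %*% t(X))) %*% charges)
    list(points = pts, values = vals,
         conformation_ref = if (nzchar(confs[[ci]]$tag)) confs[[ci]]$tag
                            else paste0("conf", ci))
  })
}
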