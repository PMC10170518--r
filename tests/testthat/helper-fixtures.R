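# shared fixtures, built in code

# cached toy molecule (12 atoms, mono pattern)
toy_mol <- make_toy_molecule(4, "mono", seed = 2)
toy_min <- minimize_conformation(toy_mol$conf, toy_mol$topo, toy_mol$params,
                                 tol = 1e-4)

# bare 5-atom carbon chain: every dihedral has a unique central bond, so
# all bonded force constants are identifiable from energies
chain5_system <- function() {
  n <- 5
  topo <- molecule_topology(rep("C", n), cbind(1:(n - 1), 2:n))
  tet <- acos(-1 / 3)
  bt <- data.frame(i = topo$bonds[, 1], j = topo$bonds[, 2],
                   K = 1300, r_eq = 1.526)
  at <- data.frame(i = topo$angles[, 1], j = topo$angles[, 2],
                   k = topo$angles[, 3], K = 260, theta_eq = tet)
  dt <- data.frame(i = topo$dihedrals[, 1], j = topo$dihedrals[, 2],
                   k = topo$dihedrals[, 3], l = topo$dihedrals[, 4],
                   V = 4, n = 3L, gamma = 0)
  lj <- data.frame(sigma = rep(3.4, n), epsilon = rep(0.36, n))
  q <- rep(c(0.05, -0.05), length.out = n)
  q <- q - mean(q)
  params <- ff_parameters(bt, at, dt, lj, q)
  # zigzag start
  alpha <- (pi - tet) / 2
  dirs <- rbind(c(cos(alpha), 0, sin(alpha)), c(cos(alpha), 0, -sin(alpha)))
  coords <- matrix(0, n, 3)
  for (i in 2:n) coords[i, ] <- coords[i - 1, ] + dirs[1 + (i %% 2), ] * 1.526
  list(topo = topo, params = params, conf = conformation(coords))
}

# central finite-difference gradient of the total energy
fd_gradient <- function(coords, topo, params, h = 1e-5) {
  g <- matrix(0, nrow(coords), 3)
  for (i in seq_len(nrow(coords))) {
    for (d in 1:3) {
      xp <- coords; xp[i, d] <- xp[i, d] + h
      xm <- coords; xm[i, d] <- xm[i, d] - h
      g[i, d] <- (compute_energy(xp, topo, params)$total -
                    compute_energy(xm, topo, params)$total) / (2 * h)
    }
  }
  g
}

# two-atom system with forward-generated ESP for charge-recovery tests
esp_two_atom <- function(n_points = 600, seed = 4, q = c(0.4, -0.4)) {
  topo <- molecule_topology(c("C", "O"), rbind(c(1, 2)))
  confA <- conformation(rbind(c(0, 0, 0), c(1.4, 0, 0)))
  confB <- conformation(rbind(c(0, 0, 0), c(0, 1.4, 0)))
  grids <- generate_esp_fixture(topo, q, list(confA, confB),
                                n_points = n_points, seed = seed)
  list(topo = topo, confs = list(confA, confB), grids = grids, q = q)
}

# methane-like 4-atom system with one symmetric H pair
esp_four_atom <- function(n_points = 1200, seed = 5) {
  topo <- molecule_topology(c("C", "H", "H", "F"),
                            rbind(c(1, 2), c(1, 3), c(1, 4)),
                            symmetry_groups = list(c(2, 3)))
  conf <- conformation(rbind(c(0, 0, 0), c(1.09, 0, 0),
                             c(-0.36, 1.03, 0), c(-0.45, -0.6, 1.1)))
  q <- c(0.25, 0.05, 0.05, -0.35)
  grids <- generate_esp_fixture(topo, q, list(conf), n_points = n_points,
                                seed = seed)
  list(topo = topo, confs = list(conf), grids = grids, q = q)
}

# 1-D analytic potentials for sampler tests (unit mass)
harmonic_pot <- function(k) {
  potential_handle(function(x) 0.5 * k * sum(x * x), function(x) -k * x,
                   masses = 1, label = paste0("harmonic-k", k))
}

double_well_pot <- function(h = 4) {
  potential_handle(function(x) h * sum((x^2 - 1)^2),
                   function(x) -4 * h * x * (x^2 - 1),
                   masses = 1, label = "double-well")
}
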