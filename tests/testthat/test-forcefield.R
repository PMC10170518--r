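test_that("torsion measurement follows the signed IUPAC convention", {
  # planar anti chain reports the boundary as -180
  anti <- rbind(c(0, 0, 0), c(1, 0, 0), c(1.5, 1, 0), c(2.5, 1, 0))
  expect_equal(measure_dihedral(anti, 1:4), -180)
  # planar syn chain
  syn <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(measure_dihedral(syn, 1:4), 0)
  # distal atom rotated +60 about the 2->3 axis by an explicit rotation
  th <- pi / 3
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  rot <- syn
  rot[4, ] <- rot[3, ] + as.vector(R %*% (syn[4, ] - syn[3, ]))
  expect_equal(measure_dihedral(rot, 1:4), 60)

  # range is [-180, 180)
  for (target in c(-180, -90, 0, 90, 179)) {
    conf <- set_dihedral(toy_min, toy_mol$topo, toy_mol$topo$dihedral_roles$chi,
                         target)
    expect_equal(measure_dihedral(conf, toy_mol$topo$dihedral_roles$chi),
                 target, tolerance = 1e-8)
  }

  collinear <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0))
  expect_error(measure_dihedral(collinear, 1:4), "collinear")
  expect_error(measure_dihedral(anti, c(1, 1, 2, 3)), "distinct")
})

test_that("energy terms reproduce closed forms", {
  # single harmonic bond, K = 1000, displaced 0.1 A from r_eq
  topo <- molecule_topology(c("C", "C"), rbind(c(1, 2)))
  params <- ff_parameters(
    data.frame(i = 1, j = 2, K = 1000, r_eq = 1.5),
    data.frame(i = integer(0), j = integer(0), k = integer(0),
               K = numeric(0), theta_eq = numeric(0)),
    data.frame(i = integer(0), j = integer(0), k = integer(0),
               l = integer(0), V = numeric(0), n = integer(0),
               gamma = numeric(0)),
    lj = data.frame(sigma = c(3, 3), epsilon = c(0, 0)),
    charges = c(0, 0))
  conf <- conformation(rbind(c(0, 0, 0), c(1.6, 0, 0)))
  e <- compute_energy(conf, topo, params)
  expect_equal(e$bond, 10.0, tolerance = 1e-12)
  expect_equal(e$total, e$bond + e$angle + e$dihedral + e$lj + e$coulomb)

  # +1/-1 e pair at 3 A with no exclusion, via a 5-atom chain whose only
  # charged atoms are the unexcluded ends
  sys <- chain5_system()
  p <- sys$params
  p$bond_terms$K[] <- 0
  p$angle_terms$K[] <- 0
  p$dihedral_terms$V[] <- 0
  p$lj$epsilon[] <- 0
  p$charges <- c(1, 0, 0, 0, -1)
  # ends 3 A apart (their pair is neither excluded nor 1-4); uncharged
  # middle atoms parked far away and off-axis
  coords <- rbind(c(0, 0, 0), c(0, 50, 0), c(40, 100, 0), c(0, 150, 30),
                  c(3, 0, 0))
  e <- compute_energy(coords, sys$topo, p)
  expect_equal(e$coulomb, -ff_constants$coulomb / 3, tolerance = 1e-6)
  expect_equal(e$coulomb, -463.1182, tolerance = 1e-4)

  # LJ pair at its minimum distance contributes exactly -epsilon
  p2 <- sys$params
  p2$bond_terms$K[] <- 0; p2$angle_terms$K[] <- 0
  p2$dihedral_terms$V[] <- 0; p2$charges[] <- 0
  p2$lj$epsilon <- c(0.5, 0, 0, 0, 0.5)
  p2$lj$sigma[] <- 3.2
  coords[5, ] <- c(2^(1 / 6) * 3.2, 0, 0)   # LJ-minimum separation from atom 1
  e2 <- compute_energy(coords, sys$topo, p2)
  expect_equal(e2$lj, -0.5, tolerance = 1e-10)

  # overlapping atoms raise a singularity error
  bad <- coords; bad[5, ] <- bad[1, ] + 1e-9
  expect_error(compute_energy(bad, sys$topo, p2), "overlapping")
})

test_that("missing parameters are reported by term", {
  sys <- chain5_system()
  p <- sys$params
  p$bond_terms <- p$bond_terms[-2, ]
  expect_error(compute_energy(sys$conf, sys$topo, p), "missing bond")
  p <- sys$params
  p$angle_terms <- p$angle_terms[-1, ]
  expect_error(compute_energy(sys$conf, sys$topo, p), "missing angle")
  p <- sys$params
  p$dihedral_terms <- p$dihedral_terms[-1, ]
  expect_error(compute_energy(sys$conf, sys$topo, p), "missing dihedral")
})

test_that("exclusion bookkeeping matches the chain formulas", {
  for (n in 4:8) {
    topo <- molecule_topology(rep("C", n), cbind(1:(n - 1), 2:n))
    expect_equal(nrow(topo$pairs_14), n - 3)
    expect_equal(nrow(topo$excl_12_13), (n - 1) + (n - 2))
  }
})

test_that("analytic forces agree with finite differences", {
  sys <- chain5_system()
  set.seed(101)
  for (rep in 1:100) {
    coords <- sys$conf$coords + matrix(rnorm(15, sd = 0.08), 5, 3)
    F <- compute_forces(coords, sys$topo, sys$params)
    G <- fd_gradient(coords, sys$topo, sys$params)
    expect_lt(max(abs(F + G)), 1e-4 * max(1, max(abs(F))))
  }
  # and on the full toy molecule with all term types active
  set.seed(102)
  for (rep in 1:5) {
    coords <- toy_min$coords +
      matrix(rnorm(3 * nrow(toy_min$coords), sd = 0.05),
             nrow(toy_min$coords), 3)
    F <- compute_forces(coords, toy_mol$topo, toy_mol$params)
    G <- fd_gradient(coords, toy_mol$topo, toy_mol$params)
    expect_lt(max(abs(F + G)) / max(abs(F)), 1e-4)
  }
})

test_that("stretched bond forces follow the harmonic closed form", {
  topo <- molecule_topology(c("C", "C"), rbind(c(1, 2)))
  params <- ff_parameters(
    data.frame(i = 1, j = 2, K = 1000, r_eq = 1.5),
    data.frame(i = integer(0), j = integer(0), k = integer(0),
               K = numeric(0), theta_eq = numeric(0)),
    data.frame(i = integer(0), j = integer(0), k = integer(0),
               l = integer(0), V = numeric(0), n = integer(0),
               gamma = numeric(0)),
    lj = data.frame(sigma = c(3, 3), epsilon = c(0, 0)),
    charges = c(0, 0))
  conf <- rbind(c(0, 0, 0), c(1.7, 0, 0))
  F <- compute_forces(conf, topo, params)
  # stretched bond pulls the atoms toward each other, magnitude 2K(r-r_eq)
  expect_equal(F[1, 1], 2 * 1000 * 0.2, tolerance = 1e-10)
  expect_equal(F[2, 1], -2 * 1000 * 0.2, tolerance = 1e-10)
  expect_equal(F[1, ], -F[2, ])
  # at the exact minimum the force vanishes
  F0 <- compute_forces(rbind(c(0, 0, 0), c(1.5, 0, 0)), topo, params)
  expect_lt(max(abs(F0)), 1e-8)
})

test_that("energy is invariant under rigid transforms", {
  e0 <- compute_energy(toy_min, toy_mol$topo, toy_mol$params)
  set.seed(7)
  for (rep in 1:5) {
    # random rotation via QR with positive determinant
    Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    shift <- rnorm(3, sd = 10)
    moved <- sweep(toy_min$coords %*% Q, 2, shift, "+")
    e1 <- compute_energy(moved, toy_mol$topo, toy_mol$params)
    for (comp in c("bond", "angle", "dihedral", "lj", "coulomb", "total")) {
      expect_lt(abs(e1[[comp]] - e0[[comp]]), 1e-8)
    }
  }
})

test_that("minimization reaches a stationary point and lowers energy", {
  sys <- chain5_system()
  # stretched single bond relaxes to r_eq
  topo <- molecule_topology(c("C", "C"), rbind(c(1, 2)))
  params <- ff_parameters(
    data.frame(i = 1, j = 2, K = 1000, r_eq = 1.5),
    data.frame(i = integer(0), j = integer(0), k = integer(0),
               K = numeric(0), theta_eq = numeric(0)),
    data.frame(i = integer(0), j = integer(0), k = integer(0),
               l = integer(0), V = numeric(0), n = integer(0),
               gamma = numeric(0)),
    lj = data.frame(sigma = c(3, 3), epsilon = c(0, 0)),
    charges = c(0, 0))
  m <- minimize_conformation(rbind(c(0, 0, 0), c(1.9, 0, 0)), topo, params,
                             tol = 1e-8)
  expect_equal(sqrt(sum((m$coords[2, ] - m$coords[1, ])^2)), 1.5,
               tolerance = 1e-6)

  # perturbed rotamers of the toy chain relax with energy never above start
  set.seed(11)
  for (rep in 1:3) {
    start <- sys$conf$coords + matrix(rnorm(15, sd = 0.15), 5, 3)
    e_start <- compute_energy(start, sys$topo, sys$params)$total
    m <- minimize_conformation(start, sys$topo, sys$params, tol = 1e-5)
    expect_lte(m$energy, e_start)
    expect_lt(max(abs(compute_forces(m, sys$topo, sys$params))), 1e-5)
  }

  # starting at a minimum returns it essentially unchanged
  m2 <- minimize_conformation(toy_min, toy_mol$topo, toy_mol$params,
                              tol = 1e-4)
  expect_lt(abs(m2$energy - toy_min$energy), 1e-6)
})
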