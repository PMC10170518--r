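test_that("toy molecules are valid, parameterized and deterministic", {
  for (spec in list(list(4, "mono"), list(5, "di"), list(4, "tri"))) {
    mol <- make_toy_molecule(spec[[1]], spec[[2]], seed = 3)
    need <- switch(spec[[2]], mono = c("chi", "phi", "psi"),
                   di = c("chi", "phi1", "phi2", "psi"),
                   tri = c("chi", "psi"))
    expect_setequal(names(mol$topo$dihedral_roles), need)
    # full parameter coverage: energy evaluates finitely
    e <- compute_energy(mol$conf, mol$topo, mol$params)
    expect_true(is.finite(e$total))
    # charges sum exactly to the declared net charge
    expect_equal(sum(mol$params$charges), mol$topo$net_charge,
                 tolerance = 1e-12)
    # symmetry groups exist and index atoms of one element
    expect_gt(length(mol$topo$symmetry_groups), 0)
    for (g in mol$topo$symmetry_groups) {
      expect_length(unique(mol$topo$elements[g]), 1)
    }
  }
  m1 <- make_toy_molecule(4, "mono", seed = 9)
  m2 <- make_toy_molecule(4, "mono", seed = 9)
  expect_identical(m1$conf$coords, m2$conf$coords)
  expect_error(make_toy_molecule(4, "di"), "n_heavy >= 5")
  expect_error(make_toy_molecule(3, "mono"), "4..8")
})

test_that("toy molecules round-trip through the file formats", {
  mol <- make_toy_molecule(5, "mono", seed = 3)
  xyz <- withr::local_tempfile(fileext = ".xyz")
  prm <- withr::local_tempfile(fileext = ".txt")
  write_xyz(mol$conf, mol$topo$elements, xyz)
  write_ff_parameters(mol$params, prm)
  back_c <- read_xyz(xyz)
  back_p <- read_ff_parameters(prm)
  e1 <- compute_energy(mol$conf, mol$topo, mol$params)$total
  e2 <- compute_energy(back_c$conformations[[1]], mol$topo, back_p)$total
  expect_equal(e1, e2, tolerance = 1e-8)
})

test_that("surrogate reference reduces to the base FF at zero perturbation", {
  mol <- toy_mol
  h0 <- make_surrogate_reference(mol$params, mol$topo, perturb_scale = 0,
                                 cubic_coeff = 0, seed = 5)
  x <- as.vector(toy_min$coords)
  expect_equal(h0$energy(x),
               compute_energy(toy_min, mol$topo, mol$params)$total,
               tolerance = 1e-12)
  expect_equal(h0$forces(x),
               as.vector(compute_forces(toy_min, mol$topo, mol$params)),
               tolerance = 1e-12)
})

test_that("surrogate perturbation grows monotonically with its scale", {
  mol <- toy_mol
  x <- as.vector(toy_min$coords)
  e0 <- compute_energy(toy_min, mol$topo, mol$params)$total
  gaps <- vapply(c(0.05, 0.1, 0.2, 0.4), function(s) {
    h <- make_surrogate_reference(mol$params, mol$topo, perturb_scale = s,
                                  cubic_coeff = 0, seed = 5)
    abs(h$energy(x) - e0)
  }, 0)
  expect_true(all(diff(gaps) > 0))
})

test_that("surrogate forces agree with finite differences of its energy", {
  mol <- toy_mol
  h <- make_surrogate_reference(mol$params, mol$topo, perturb_scale = 0.15,
                                cubic_coeff = 30, seed = 6)
  set.seed(61)
  x <- as.vector(toy_min$coords) + rnorm(3 * mol$topo$n_atoms, sd = 0.03)
  F <- h$forces(x)
  num <- vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + 1e-5
    xm <- x; xm[i] <- xm[i] - 1e-5
    -(h$energy(xp) - h$energy(xm)) / 2e-5
  }, 0)
  expect_lt(max(abs(F - num)) / max(abs(F)), 1e-4)
})

test_that("von Mises sampler concentrates around its center", {
  set.seed(71)
  x <- rvonmises(20000, pi / 3, 16)
  # circular mean near the center, dispersion near 1/sqrt(kappa)
  expect_lt(abs(atan2(mean(sin(x)), mean(cos(x))) - pi / 3), 0.01)
  expect_equal(sd(x - pi / 3), 1 / sqrt(16), tolerance = 0.05)
  # mass outside the 120-degree assignment window (+-60 degrees) is
  # negligible
  expect_lt(mean(abs(x - pi / 3) > pi / 3), 1e-3)
})

test_that("dihedral trajectories honor their mixture weights", {
  w1 <- c("g+g+(g+)" = 1)
  tr <- generate_dihedral_trajectory(toy_mol$topo, toy_min, w1, "mono",
                                     n_frames = 200, seed = 3)
  pops <- trajectory_populations(tr, toy_mol$topo, "mono")
  expect_equal(as.numeric(pops["g+g+(g+)"]), 1.0)

  # deterministic per seed
  t1 <- generate_dihedral_trajectory(toy_mol$topo, toy_min,
                                     c("g+t(g-)" = 0.5, "tt(t)" = 0.5),
                                     "mono", n_frames = 50, seed = 4)
  t2 <- generate_dihedral_trajectory(toy_mol$topo, toy_min,
                                     c("g+t(g-)" = 0.5, "tt(t)" = 0.5),
                                     "mono", n_frames = 50, seed = 4)
  expect_identical(t1[[30]]$coords, t2[[30]]$coords)
  # generating keys recorded per frame
  expect_length(attr(t1, "keys"), 50)
})

test_that("ESP fixtures carry the exact point-charge potential", {
  # a single +1 charge: potential at 2 A is k/2
  topo <- molecule_topology(c("C", "O"), rbind(c(1, 2)))
  conf <- conformation(rbind(c(0, 0, 0), c(50, 0, 0)))
  grids <- generate_esp_fixture(topo, c(1, 0), list(conf), n_points = 50,
                                seed = 5)
  g <- grids[[1]]
  d1 <- sqrt(rowSums(sweep(g$points, 2, conf$coords[1, ])^2))
  d2 <- sqrt(rowSums(sweep(g$points, 2, conf$coords[2, ])^2))
  expect_equal(g$values, ff_constants$coulomb / d1, tolerance = 1e-10)
  # no grid point closer than 1 A to any atom
  expect_true(all(pmin(d1, d2) >= 1.0))

  # superposition: values are additive in the charges
  gA <- generate_esp_fixture(topo, c(0.3, -0.1), list(conf), n_points = 40,
                             seed = 6)[[1]]
  gB <- generate_esp_fixture(topo, c(0.2, 0.4), list(conf), n_points = 40,
                             seed = 6)[[1]]
  gAB <- generate_esp_fixture(topo, c(0.5, 0.3), list(conf), n_points = 40,
                              seed = 6)[[1]]
  expect_equal(gA$values + gB$values, gAB$values, tolerance = 1e-9)
})
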