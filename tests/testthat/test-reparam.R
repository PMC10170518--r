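test_that("X_U matches hand-computed values and shift invariance", {
  u_qm <- c(0, 10, 20)
  u_mm <- c(0, 10, 30)
  # population variance of (0,10,20) is 66.667; weighted residual term 200/9
  expect_equal(xu_from_energies(u_qm, u_mm), 1 / 3, tolerance = 1e-9)
  expect_equal(xu_from_energies(u_qm, u_qm), 0)
  # mean-offset term removes any constant shift of either column
  expect_equal(xu_from_energies(u_qm, u_mm + 57.3),
               xu_from_energies(u_qm, u_mm), tolerance = 1e-12)
  expect_equal(xu_from_energies(u_qm + 19, u_mm + 19),
               xu_from_energies(u_qm, u_mm), tolerance = 1e-12)
  expect_equal(xu_from_energies(u_qm, u_qm + 3.14), 0, tolerance = 1e-12)
  expect_error(xu_from_energies(c(5, 5, 5), c(1, 2, 3)), "zero variance")
})

test_that("energy_term_XU agrees with a direct per-conformation oracle", {
  sys <- chain5_system()
  set.seed(31)
  confs <- lapply(1:20, function(i) {
    conformation(sys$conf$coords + matrix(rnorm(15, sd = 0.05), 5, 3))
  })
  u_mm <- vapply(confs, function(cf) compute_energy(cf, sys$topo,
                                                    sys$params)$total, 0)
  u_qm <- u_mm + rnorm(20, sd = 2)
  tr <- training_set(confs, u_qm)
  # independent recomputation from the definition
  d <- u_qm - u_mm
  expected <- mean((d - mean(d))^2) / mean((u_qm - mean(u_qm))^2)
  expect_equal(energy_term_XU(sys$params, sys$topo, tr), expected,
               tolerance = 1e-10)
})

test_that("harmonic regularization follows its closed form", {
  sys <- chain5_system()
  pv <- param_vector(sys$params)
  expect_equal(regularization_theta(pv), 0)

  # one entry deviated by its width, alpha = 1/N_p with 4 optimizable
  # entries -> 0.25
  pv4 <- pv
  pv4$mask[] <- FALSE
  pv4$mask[1:4] <- TRUE
  pv4$N_p <- 4
  pv4$alpha <- 1 / 4
  v <- pv4$values
  v[2] <- v[2] + pv4$gamma[2]
  expect_equal(regularization_theta(pv4, v), 0.25)
  # doubling a deviation quadruples its contribution
  v2 <- pv4$values
  v2[2] <- v2[2] + 2 * pv4$gamma[2]
  expect_equal(regularization_theta(pv4, v2), 1.0)
})

test_that("total objective is the sum of its two terms", {
  sys <- chain5_system()
  set.seed(33)
  confs <- lapply(1:15, function(i) {
    conformation(sys$conf$coords + matrix(rnorm(15, sd = 0.05), 5, 3))
  })
  u_qm <- vapply(confs, function(cf) compute_energy(cf, sys$topo,
                                                    sys$params)$total, 0) +
    rnorm(15)
  tr <- training_set(confs, u_qm)
  pv <- param_vector(sys$params)
  pv$values <- pv$values * (1 + runif(length(pv$values), -0.05, 0.05))
  perturbed <- apply_param_vector(sys$params, pv)
  expect_equal(total_objective(sys$params, sys$topo, tr, pv),
               energy_term_XU(perturbed, sys$topo, tr) +
                 regularization_theta(pv),
               tolerance = 1e-12)
})

test_that("param_vector masks phases unless requested and round-trips", {
  sys <- chain5_system()
  pv <- param_vector(sys$params)
  expect_false(any(pv$mask[pv$type == "dih_gamma"]))
  pv2 <- param_vector(sys$params, optimize_phases = TRUE)
  expect_true(all(pv2$mask))
  expect_equal(pv2$alpha, 1 / pv2$N_p)
  # writing the values back reproduces the original tables
  back <- apply_param_vector(sys$params, pv)
  expect_equal(back$bond_terms, sys$params$bond_terms)
  expect_equal(back$dihedral_terms, sys$params$dihedral_terms)
})

test_that("train/test split is disjoint, sized and deterministic", {
  sys <- chain5_system()
  confs <- lapply(1:50, function(i) sys$conf)
  u <- rnorm(50)
  s1 <- split_train_test(confs, u, 20, 25, seed = 5)
  expect_length(s1$train$conformations, 20)
  expect_length(s1$test$conformations, 25)
  expect_length(intersect(s1$train$u_ref, s1$test$u_ref), 0)
  s2 <- split_train_test(confs, u, 20, 25, seed = 5)
  expect_identical(s1$train$u_ref, s2$train$u_ref)
  expect_error(split_train_test(confs, u, 30, 30, seed = 1), "not enough")
})

test_that("self-generated energies leave parameters essentially unchanged", {
  sys <- chain5_system()
  set.seed(41)
  confs <- lapply(1:60, function(i) {
    conformation(sys$conf$coords + matrix(rnorm(15, sd = 0.06), 5, 3))
  })
  u <- vapply(confs, function(cf) compute_energy(cf, sys$topo,
                                                 sys$params)$total, 0)
  tr <- training_set(confs, u)
  fit <- optimize_parameters(sys$params, sys$topo, tr)
  expect_lt(fit$objective_final, 1e-8)
  expect_equal(fit$params$bond_terms$K, sys$params$bond_terms$K,
               tolerance = 0.01)
  # phases untouched and in {0, pi}
  expect_true(all(fit$params$dihedral_terms$gamma %in% c(0, pi)))
})

test_that("tight priors pin the optimized parameters to the prior", {
  sys <- chain5_system()
  set.seed(43)
  confs <- lapply(1:40, function(i) {
    conformation(sys$conf$coords + matrix(rnorm(15, sd = 0.06), 5, 3))
  })
  # energies from a *different* FF so the fit would like to move
  other <- sys$params
  other$bond_terms$K <- other$bond_terms$K * 1.3
  u <- vapply(confs, function(cf) compute_energy(cf, sys$topo, other)$total, 0)
  tr <- training_set(confs, u)
  tight <- list(bond_K = 1e-4, bond_req = 1e-8, angle_K = 1e-4,
                angle_theta = 1e-8, dih_V = 1e-6)
  fit <- optimize_parameters(sys$params, sys$topo, tr, prior_widths = tight)
  expect_equal(fit$params$bond_terms$K, sys$params$bond_terms$K,
               tolerance = 1e-4)
})

test_that("objective trace is non-increasing over accepted iterates", {
  sys <- chain5_system()
  set.seed(47)
  confs <- lapply(1:40, function(i) {
    conformation(sys$conf$coords + matrix(rnorm(15, sd = 0.06), 5, 3))
  })
  other <- sys$params
  other$bond_terms$K <- other$bond_terms$K * 1.15
  u <- vapply(confs, function(cf) compute_energy(cf, sys$topo, other)$total, 0)
  fit <- optimize_parameters(sys$params, sys$topo, training_set(confs, u))
  expect_true(all(diff(fit$trace) <= 0))
  expect_lte(fit$objective_final, fit$objective_initial)
})
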