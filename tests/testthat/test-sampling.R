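kT300 <- ff_constants$kB * 300

test_that("leapfrog is a drift under zero force and is time-reversible", {
  free <- potential_handle(function(x) 0, function(x) numeric(length(x)),
                           masses = 2)
  out <- leapfrog(c(1, -1), c(0.4, 0.2), free, dt = 0.05, n = 20)
  expect_equal(out$x, c(1, -1) + c(0.4, 0.2) / 2 * 0.05 * 20,
               tolerance = 1e-12)

  # negating momenta and integrating again returns to the start
  pot <- harmonic_pot(30)
  set.seed(3)
  x0 <- rnorm(3); p0 <- rnorm(3)
  fwd <- leapfrog(x0, p0, pot, dt = 0.02, n = 50)
  back <- leapfrog(fwd$x, -fwd$p, pot, dt = 0.02, n = 50)
  expect_lt(max(abs(back$x - x0)), 1e-8)
  expect_lt(max(abs(back$p + p0)), 1e-8)
})

test_that("leapfrog closes a harmonic orbit to O(dt^2)", {
  k <- 25; m <- 1
  period <- 2 * pi / sqrt(k / m)
  for (dt in c(0.02, 0.01)) {
    n <- round(period / dt)
    out <- leapfrog(0.7, 0, harmonic_pot(k), dt = dt, n = n)
    # error after one period shrinks roughly like dt^2
    expect_lt(abs(out$x - 0.7), 5 * dt^2 * sqrt(k))
  }
})

test_that("hybrid MC accepts everything in the small-step limit", {
  ch <- hmc_chain(harmonic_pot(50), T = 300,
                  mc_settings(dt = 0.05, n_leapfrog = 3, sweeps = 300,
                              seed = 5),
                  start = 0.2)
  expect_equal(ch$acceptance, 1)
})

test_that("hybrid MC samples the canonical harmonic distribution", {
  k <- 50
  ch <- hmc_chain(harmonic_pot(k), T = 300,
                  mc_settings(dt = 3, n_leapfrog = 10, sweeps = 20000,
                              seed = 7),
                  start = 0.3)
  v <- var(ch$samples[, 1])
  target <- kT300 / k
  # conservative 3-SE band for the sample variance with correlated draws
  se <- target * sqrt(2 / (20000 / 20))
  expect_lt(abs(v - target), 3 * se)
  expect_lt(abs(mean(ch$samples[, 1])), 3 * sqrt(target / (20000 / 20)))
})

test_that("samplers are gauge-invariant and deterministic per seed", {
  pot <- harmonic_pot(40)
  shifted <- potential_handle(function(x) pot$energy(x) + 123.4,
                              pot$forces, masses = 1)
  st <- mc_settings(dt = 3, n_leapfrog = 8, sweeps = 500, seed = 9)
  a <- hmc_chain(pot, 300, st, 0.1)
  b <- hmc_chain(shifted, 300, st, 0.1)
  expect_identical(a$samples, b$samples)
  expect_identical(a$acceptance, b$acceptance)

  r1 <- nmcmc_run(pot, double_well_pot(3), st, 0.5)
  r2 <- nmcmc_run(pot, double_well_pot(3), st, 0.5)
  expect_identical(r1$states, r2$states)
  expect_identical(r1$switch_acceptance, r2$switch_acceptance)
})

test_that("random-walk Metropolis has sane acceptance and moments", {
  ch <- metropolis_chain(harmonic_pot(50), 300, step_size = 0.3, n = 30000,
                         seed = 11, start = 0)
  expect_gt(ch$acceptance, 0)
  expect_lt(ch$acceptance, 1)
  expect_lt(abs(var(ch$samples[, 1]) - kT300 / 50), 0.15 * kT300 / 50)
  # constant shift leaves the trajectory unchanged
  sh <- potential_handle(function(x) 0.5 * 50 * x^2 - 7, masses = 1)
  ch2 <- metropolis_chain(sh, 300, 0.3, 1000, seed = 11, start = 0)
  expect_identical(ch$samples[1:1000, ], ch2$samples[1:1000, ])
})

test_that("nested sampler accepts every switch when levels coincide", {
  pot <- harmonic_pot(50)
  rep <- nmcmc_run(pot, pot,
                   mc_settings(T_low = 300, T_target = 300, dt = 3,
                               n_leapfrog = 10, sweeps = 2000,
                               switch_period = 2, seed = 8),
                   0.3)
  expect_identical(rep$switch_acceptance, 1)
})

test_that("nested sampler recovers the high-level harmonic ensemble", {
  rep <- nmcmc_run(harmonic_pot(50), harmonic_pot(80),
                   mc_settings(T_low = 300, T_target = 300, dt = 3,
                               n_leapfrog = 10, sweeps = 40000,
                               switch_period = 2, seed = 9),
                   0.3)
  target <- kT300 / 80
  n_eff <- nrow(rep$states) / 10
  expect_lt(abs(var(rep$states[, 1]) - target), 3 * target * sqrt(2 / n_eff))
  expect_lt(abs(mean(rep$states[, 1])), 3 * sqrt(target / n_eff))
  expect_gt(rep$switch_acceptance, 0)
  expect_lt(rep$switch_acceptance, 1)
})

test_that("nested sampler matches direct Metropolis on a double well", {
  high <- double_well_pot(4)
  low <- harmonic_pot(5)
  rep <- nmcmc_run(low, high,
                   mc_settings(T_low = 300, T_target = 300, dt = 3,
                               n_leapfrog = 10, sweeps = 40000,
                               switch_period = 2, seed = 3),
                   0.9)
  met <- metropolis_chain(high, 300, step_size = 0.6, n = 200000, seed = 4,
                          start = 0.9)
  br <- seq(-3, 3, by = 0.2)
  clip <- function(x) pmax(pmin(x, 2.99), -2.99)
  h1 <- hist(clip(rep$states[, 1]), breaks = br, plot = FALSE)$counts
  h2 <- hist(clip(met$samples[, 1]), breaks = br, plot = FALSE)$counts
  tv <- 0.5 * sum(abs(h1 / sum(h1) - h2 / sum(h2)))
  expect_lt(tv, 0.05)
})

test_that("switch acceptance decays as the levels are pulled apart", {
  st <- mc_settings(T_low = 300, T_target = 300, dt = 3, n_leapfrog = 8,
                    sweeps = 6000, switch_period = 2, seed = 21)
  acc <- vapply(c(50, 70, 110, 200), function(k_high) {
    nmcmc_run(harmonic_pot(50), harmonic_pot(k_high), st,
              0.3)$switch_acceptance
  }, 0)
  expect_identical(acc[1], 1)
  expect_true(all(diff(acc) < 0))
})

test_that("report_to_ensemble carries states and high-level energies", {
  pot <- harmonic_pot(50)
  rep <- nmcmc_run(pot, pot,
                   mc_settings(dt = 3, n_leapfrog = 5, sweeps = 60,
                               switch_period = 3, seed = 2), c(0.1, 0.2, 0.3))
  ens <- report_to_ensemble(rep, n_atoms = 1)
  expect_length(ens, nrow(rep$states))
  expect_equal(ens[[5]]$coords, matrix(rep$states[5, ], 1, 3))
  expect_equal(ens[[5]]$energy, rep$energies_high[5])
})
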