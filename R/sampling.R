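#' Potential handle
#'
#' Wraps an energy function (and optionally its forces) over a flat
#' coordinate vector, together with per-coordinate masses, for use by the
#' samplers. Masses are in amu, energies in kJ/mol, coordinates in A.
#'
#' @param energy function(x) -> kJ/mol for a numeric state vector `x`.
#' @param forces function(x) -> -dU/dx, same shape as `x`; required for
#'   hybrid Monte Carlo.
#' @param masses numeric vector of per-coordinate masses (recycled to the
#'   state length).
#' @param label identifying string.
#' @return list of class `potential_handle`.
#' @export
potential_handle <- function(energy, forces = NULL, masses = 1,
                             label = "potential") {
  stopifnot(is.function(energy), is.null(forces) || is.function(forces))
  structure(list(energy = energy, forces = forces, masses = masses,
                 label = label),
            class = "potential_handle")
}

#' Force-field potential handle
#'
#' Binds a topology and parameter set into a [potential_handle()] over the
#' flattened N x 3 coordinate vector, with per-atom masses from the element
#' table.
#'
#' @inheritParams compute_energy
#' @param label identifying string.
#' @return a [potential_handle()].
#' @export
ff_potential <- function(topo, params, label = "ff") {
  n <- topo$n_atoms
  m3 <- rep(element_masses(topo$elements), each = 3)
  potential_handle(
    energy = function(x) compute_energy(matrix(x, n, 3), topo, params)$total,
    forces = function(x) as.vector(compute_forces(matrix(x, n, 3), topo,
                                                  params)),
    masses = m3, label = label
  )
}

#' Monte Carlo sampler settings
#'
#' Defaults mirror a typical nested-sampling setup for small molecules:
#' hybrid-MC runs of 100 leapfrog steps with a 1 fs time step, a 350 K
#' low-level chain targeting a 300 K ensemble, 2.5e4 sweeps.
#'
#' @param T_low low-level (propagating) chain temperature, K.
#' @param T_target target ensemble temperature, K.
#' @param dt leapfrog time step in fs.
#' @param n_leapfrog leapfrog steps per hybrid-MC move.
#' @param sweeps number of hybrid-MC moves.
#' @param switch_period low-level moves between switch attempts.
#' @param seed RNG seed.
#' @return list of class `mc_settings`.
#' @export
mc_settings <- function(T_low = 350, T_target = 300, dt = 1,
                        n_leapfrog = 100, sweeps = 25000,
                        switch_period = 10, seed = 1L) {
  stopifnot(T_low > 0, T_target > 0, dt > 0, n_leapfrog >= 1,
            sweeps >= 1, switch_period >= 1)
  structure(list(T_low = T_low, T_target = T_target, dt = dt,
                 n_leapfrog = n_leapfrog, sweeps = sweeps,
                 switch_period = switch_period, seed = as.integer(seed)),
            class = "mc_settings")
}

.dt_internal <- function(dt_fs) dt_fs / ff_constants$fs_per_time_unit

#' Leapfrog (velocity Verlet) integration
#'
#' Symplectic, time-reversible propagation of `(x, p)` under a potential
#' handle for `n` steps of size `dt` (internal time units,
#' 1 unit = `ff_constants$fs_per_time_unit` fs).
#'
#' @param x numeric state vector (A).
#' @param p numeric momentum vector (amu A / time unit).
#' @param potential a [potential_handle()] with forces.
#' @param dt time step in internal units.
#' @param n number of steps.
#' @return list with `x`, `p` and the force at the final state.
#' @export
leapfrog <- function(x, p, potential, dt, n) {
  if (is.null(potential$forces)) stop("potential handle has no forces")
  m <- rep_len(potential$masses, length(x))
  f <- potential$forces(x)
  for (step in seq_len(n)) {
    p <- p + 0.5 * dt * f
    x <- x + dt * p / m
    f <- potential$forces(x)
    if (!all(is.finite(f)) || !all(is.finite(x))) {
      stop("leapfrog divergence: non-finite state (energy blow-up)")
    }
    p <- p + 0.5 * dt * f
  }
  list(x = x, p = p, force = f)
}

# one hybrid-MC move; returns new state, its energy and acceptance flag
.hmc_move <- function(x, U_x, potential, kT, dt, n_leapfrog) {
  m <- rep_len(potential$masses, length(x))
  p <- stats::rnorm(length(x), sd = sqrt(m * kT))
  H0 <- U_x + sum(p^2 / (2 * m))
  prop <- tryCatch(leapfrog(x, p, potential, dt, n_leapfrog),
                   error = function(e) NULL)
  if (is.null(prop)) return(list(x = x, U = U_x, accepted = FALSE))
  U1 <- potential$energy(prop$x)
  H1 <- U1 + sum(prop$p^2 / (2 * m))
  if (is.finite(H1) && stats::runif(1) < exp(-(H1 - H0) / kT)) {
    list(x = prop$x, U = U1, accepted = TRUE)
  } else {
    list(x = x, U = U_x, accepted = FALSE)
  }
}

#' Hybrid Monte Carlo chain
#'
#' Each move resamples momenta from the Maxwell distribution at `T`, runs
#' `n_leapfrog` leapfrog steps of `dt` fs, and accepts with the Metropolis
#' probability `min(1, exp(-dH / kB T))`, so the chain's invariant
#' distribution is proportional to `exp(-U / kB T)`.
#'
#' @param potential a [potential_handle()] with forces.
#' @param T temperature, K.
#' @param settings an [mc_settings()] (uses `dt`, `n_leapfrog`, `sweeps`,
#'   `seed`).
#' @param start numeric state vector.
#' @return list with `samples` (moves x dim matrix of post-move states),
#'   `energies`, and `acceptance` fraction.
#' @export
hmc_chain <- function(potential, T, settings, start) {
  set.seed(settings$seed)
  kT <- ff_constants$kB * T
  dt <- .dt_internal(settings$dt)
  x <- as.numeric(start)
  U <- potential$energy(x)
  n <- settings$sweeps
  samples <- matrix(NA_real_, n, length(x))
  energies <- numeric(n)
  acc <- 0
  for (s in seq_len(n)) {
    mv <- .hmc_move(x, U, potential, kT, dt, settings$n_leapfrog)
    x <- mv$x; U <- mv$U
    acc <- acc + mv$accepted
    samples[s, ] <- x
    energies[s] <- U
    if (s == 1000 && acc == 0) {
      stop("hybrid MC diagnostics: zero acceptance over 1000 moves")
    }
  }
  list(samples = samples, energies = energies, acceptance = acc / n)
}

#' Random-walk Metropolis chain
#'
#' Plain Gaussian random-walk Metropolis; in this package it serves as the
#' independent equivalence oracle for the nested sampler.
#'
#' @param potential a [potential_handle()] (energy only).
#' @param T temperature, K.
#' @param step_size Gaussian proposal standard deviation.
#' @param n number of moves.
#' @param seed RNG seed.
#' @param start numeric state vector.
#' @return list with `samples`, `energies`, `acceptance`.
#' @export
metropolis_chain <- function(potential, T, step_size, n, seed, start) {
  set.seed(seed)
  kT <- ff_constants$kB * T
  x <- as.numeric(start)
  U <- potential$energy(x)
  samples <- matrix(NA_real_, n, length(x))
  energies <- numeric(n)
  acc <- 0
  for (s in seq_len(n)) {
    xp <- x + stats::rnorm(length(x), sd = step_size)
    Up <- potential$energy(xp)
    if (is.finite(Up) && stats::runif(1) < exp(-(Up - U) / kT)) {
      x <- xp; U <- Up; acc <- acc + 1
    }
    samples[s, ] <- x
    energies[s] <- U
  }
  list(samples = samples, energies = energies, acceptance = acc / n)
}

#' Nested Markov chain Monte Carlo
#'
#' Advances a cheap ("low-level") potential by hybrid MC at `T_low` and,
#' every `switch_period` moves, proposes the current low-level state `x'`
#' against the last accepted high-level state `x` with acceptance
#' probability
#' `min(1, exp(-[U_high(x') - U_high(x)] / kB T_target
#'             + [U_low(x') - U_low(x)] / kB T_low))`.
#' On rejection the low-level chain is reset to `x`, which preserves the
#' target distribution `exp(-U_high / kB T_target)` for the promoted
#' ensemble. With identical potentials and equal temperatures the criterion
#' cancels and every switch is accepted.
#'
#' @param low,high [potential_handle()]s on the same configuration space
#'   (`low` must provide forces).
#' @param settings an [mc_settings()].
#' @param start numeric state vector.
#' @return list of class `sampler_report` with `states` (one row per switch
#'   attempt: the current high-level ensemble member), `energies_high`,
#'   `hmc_acceptance`, `switch_acceptance`, and `settings`.
#' @export
nmcmc_run <- function(low, high, settings, start) {
  x_len <- length(as.numeric(start))
  set.seed(settings$seed)
  kT_low <- ff_constants$kB * settings$T_low
  kT_tgt <- ff_constants$kB * settings$T_target
  dt <- .dt_internal(settings$dt)

  x_hi <- as.numeric(start)
  U_hi_high <- high$energy(x_hi)
  U_hi_low <- low$energy(x_hi)
  if (!is.finite(U_hi_high) || !is.finite(U_hi_low)) {
    stop("non-finite energy at the starting state")
  }

  y <- x_hi
  U_y <- U_hi_low
  n_switch <- floor(settings$sweeps / settings$switch_period)
  states <- matrix(NA_real_, n_switch, x_len)
  energies_high <- numeric(n_switch)
  hmc_acc <- 0; sw_acc <- 0; sw_done <- 0

  for (s in seq_len(settings$sweeps)) {
    mv <- .hmc_move(y, U_y, low, kT_low, dt, settings$n_leapfrog)
    y <- mv$x; U_y <- mv$U
    hmc_acc <- hmc_acc + mv$accepted
    if (s %% settings$switch_period == 0) {
      sw_done <- sw_done + 1
      U_p_high <- high$energy(y)
      log_acc <- -(U_p_high - U_hi_high) / kT_tgt + (U_y - U_hi_low) / kT_low
      if (is.finite(log_acc) && stats::runif(1) < exp(log_acc)) {
        sw_acc <- sw_acc + 1
        x_hi <- y
        U_hi_high <- U_p_high
        U_hi_low <- U_y
      } else {
        y <- x_hi
        U_y <- U_hi_low
      }
      states[sw_done, ] <- x_hi
      energies_high[sw_done] <- U_hi_high
    }
  }
  structure(list(states = states, energies_high = energies_high,
                 hmc_acceptance = hmc_acc / settings$sweeps,
                 switch_acceptance = if (sw_done > 0) sw_acc / sw_done else NA,
                 settings = settings),
            class = "sampler_report")
}

#' @export
print.sampler_report <- function(x, ...) {
  cat("sampler_report:", nrow(x$states), "promoted states\n")
  cat(sprintf("  hMC acceptance:    %.3f\n", x$hmc_acceptance))
  cat(sprintf("  switch acceptance: %.3f\n", x$switch_acceptance))
  invisible(x)
}

#' Convert sampler states to conformations
#'
#' @param report a `sampler_report` from [nmcmc_run()].
#' @param n_atoms number of atoms (states are flattened N x 3 matrices).
#' @param tag provenance tag for the frames.
#' @return list of [conformation()]s carrying the high-level energies.
#' @export
report_to_ensemble <- function(report, n_atoms, tag = "nmcmc") {
  lapply(seq_len(nrow(report$states)), function(i) {
    conformation(matrix(report$states[i, ], n_atoms, 3),
                 energy = report$energies_high[i], tag = tag)
  })
}
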