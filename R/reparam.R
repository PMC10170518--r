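#' Training set of conformations with reference energies
#'
#' @param confs list of [conformation()]s.
#' @param u_ref reference potential energies (kJ/mol), parallel to `confs`.
#' @param weights per-conformation weights, normalized to sum to 1
#'   (default uniform). The weighting interface is pluggable so that
#'   non-Boltzmann schemes can be supplied.
#' @return list of class `training_set`.
#' @export
training_set <- function(confs, u_ref, weights = NULL) {
  if (inherits(confs, "conformation")) confs <- list(confs)
  n <- length(confs)
  if (n == 0) stop("training set is empty")
  if (length(u_ref) != n) stop("one reference energy per conformation needed")
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(weights) != n || any(weights < 0)) {
    stop("weights must be non-negative and parallel to conformations")
  }
  weights <- weights / sum(weights)
  structure(list(conformations = confs, u_ref = as.numeric(u_ref),
                 weights = weights),
            class = "training_set")
}

# default prior widths gamma_m by entry type (kJ/mol/A^2, A, kJ/mol/rad^2,
# rad, kJ/mol, rad)
.default_prior_widths <- list(
  bond_K = 400, bond_req = 0.05,
  angle_K = 100, angle_theta = 0.1,
  dih_V = 8, dih_gamma = pi / 2
)

#' Flatten bonded force-field parameters into an optimizable vector
#'
#' Builds the flat parameter vector used by the regularized objective:
#' bond `K` and `r_eq`, angle `K` and `theta_eq`, dihedral `V` per series
#' row, and the dihedral phases `gamma_n` when `optimize_phases` is TRUE.
#' Each entry carries its prior (the initial value) and a Gaussian prior
#' width by entry type. Nonbonded parameters (LJ, charges) are not part of
#' the vector: only the bonded terms are retuned.
#'
#' @param params an [ff_parameters()].
#' @param optimize_phases include dihedral phases among the optimizable
#'   entries.
#' @param alpha regularization scale; default `1 / N_p` where `N_p` is the
#'   number of optimizable entries.
#' @param prior_widths named list overriding the default widths per entry
#'   type (`bond_K`, `bond_req`, `angle_K`, `angle_theta`, `dih_V`,
#'   `dih_gamma`).
#' @return list of class `param_vector` with `values`, `p0`, `gamma`,
#'   `mask`, `type`, `row`, `alpha`, `N_p`.
#' @export
param_vector <- function(params, optimize_phases = FALSE, alpha = NULL,
                         prior_widths = list()) {
  w <- utils::modifyList(.default_prior_widths, prior_widths)
  nb <- nrow(params$bond_terms)
  na <- nrow(params$angle_terms)
  nd <- nrow(params$dihedral_terms)
  type <- c(rep("bond_K", nb), rep("bond_req", nb),
            rep("angle_K", na), rep("angle_theta", na),
            rep("dih_V", nd), rep("dih_gamma", nd))
  row <- c(seq_len(nb), seq_len(nb), seq_len(na), seq_len(na),
           seq_len(nd), seq_len(nd))
  values <- c(params$bond_terms$K, params$bond_terms$r_eq,
              params$angle_terms$K, params$angle_terms$theta_eq,
              params$dihedral_terms$V, params$dihedral_terms$gamma)
  mask <- type != "dih_gamma" | optimize_phases
  gam <- unlist(w[type], use.names = FALSE)
  if (any(gam <= 0)) stop("prior widths must be positive")
  N_p <- sum(mask)
  if (is.null(alpha)) alpha <- 1 / N_p
  structure(list(values = values, p0 = values, gamma = gam, mask = mask,
                 type = type, row = row, alpha = alpha, N_p = N_p),
            class = "param_vector")
}

#' Write a flat parameter vector back into a parameter set
#'
#' @param params an [ff_parameters()] matching the one the vector was built
#'   from.
#' @param pv a [param_vector()].
#' @param values replacement flat values (default `pv$values`).
#' @return the updated [ff_parameters()].
#' @export
apply_param_vector <- function(params, pv, values = pv$values) {
  stopifnot(length(values) == length(pv$values))
  put <- function(tab, col, type) {
    sel <- pv$type == type
    tab[[col]][pv$row[sel]] <- values[sel]
    tab
  }
  params$bond_terms <- put(params$bond_terms, "K", "bond_K")
  params$bond_terms <- put(params$bond_terms, "r_eq", "bond_req")
  params$angle_terms <- put(params$angle_terms, "K", "angle_K")
  params$angle_terms <- put(params$angle_terms, "theta_eq", "angle_theta")
  params$dihedral_terms <- put(params$dihedral_terms, "V", "dih_V")
  params$dihedral_terms <- put(params$dihedral_terms, "gamma", "dih_gamma")
  params
}

#' Energy-fitting term of the objective
#'
#' Dimensionless weighted mean-square residual between model and reference
#' energies after removing the (weighted) mean energy offset, normalized by
#' the unweighted population variance of the reference energies:
#' \deqn{X_U = \sum_i \omega_i (U_i^{ref} - U_i^{MM} - \bar\Delta)^2 /
#'   \mathrm{Var}(U^{ref})}
#' The offset term makes the statistic invariant to any constant shift of
#' either energy column.
#'
#' @param params an [ff_parameters()].
#' @param topo a [molecule_topology()].
#' @param training a [training_set()].
#' @return dimensionless X_U.
#' @export
energy_term_XU <- function(params, topo, training) {
  u_mm <- vapply(training$conformations,
                 function(cf) compute_energy(cf, topo, params)$total, 0)
  xu_from_energies(training$u_ref, u_mm, training$weights)
}

#' X_U from precomputed energy columns
#'
#' @param u_ref,u_mm reference and model energies, kJ/mol.
#' @param weights normalized weights (default uniform).
#' @return dimensionless X_U.
#' @export
xu_from_energies <- function(u_ref, u_mm, weights = NULL) {
  n <- length(u_ref)
  if (is.null(weights)) weights <- rep(1 / n, n)
  v <- mean((u_ref - mean(u_ref))^2)
  if (v <= 0) stop("reference energies have zero variance: X_U undefined")
  d <- u_ref - u_mm
  dbar <- sum(weights * d)
  sum(weights * (d - dbar)^2) / v
}

#' Harmonic regularization term
#'
#' \deqn{\Theta = \alpha \sum_m (p_m - p_m^0)^2 / \gamma_m^2} over the
#' optimizable entries: a Gaussian prior centered at the initial guess with
#' per-entry width.
#'
#' @param pv a [param_vector()].
#' @param values current flat values (default `pv$values`).
#' @return dimensionless Theta.
#' @export
regularization_theta <- function(pv, values = pv$values) {
  sel <- pv$mask
  pv$alpha * sum(((values[sel] - pv$p0[sel]) / pv$gamma[sel])^2)
}

#' Total reparametrization objective
#'
#' `X_U + Theta`: the energy-fitting term plus the harmonic prior penalty.
#'
#' @inheritParams energy_term_XU
#' @param pv a [param_vector()] whose `values` are applied to `params`
#'   before evaluation.
#' @return dimensionless objective value.
#' @export
total_objective <- function(params, topo, training, pv) {
  p <- apply_param_vector(params, pv)
  energy_term_XU(p, topo, training) + regularization_theta(pv)
}

# Precompute, over the training conformations, every internal coordinate
# and the fixed nonbonded energy, so the objective is a closed form in the
# bonded parameters (LJ and charges do not change during tuning).
.precompute_training <- function(params, topo, training) {
  rows <- match_parameters(params, topo)
  confs <- training$conformations
  ns <- length(confs)
  Rb <- matrix(0, ns, nrow(topo$bonds))
  Th <- matrix(0, ns, nrow(topo$angles))
  Ph <- matrix(0, ns, nrow(params$dihedral_terms))
  nb_fixed <- numeric(ns)
  nb <- .nb_tables(topo, params)
  for (i in seq_len(ns)) {
    coords <- confs[[i]]$coords
    ic <- internal_coordinates(coords, topo)
    Rb[i, ] <- ic$r
    if (length(ic$theta)) Th[i, ] <- ic$theta
    if (nrow(params$dihedral_terms)) Ph[i, ] <- ic$phi[rows$dihedral_quad]
    if (length(nb$i) > 0) {
      d <- coords[nb$j, , drop = FALSE] - coords[nb$i, , drop = FALSE]
      r <- .rownorm(d)
      sr6 <- (nb$sigma / r)^6
      nb_fixed[i] <- sum(4 * nb$eps * (sr6^2 - sr6)) + sum(nb$qq / r)
    }
  }
  # columns of Rb/Th follow topology term order; bond_rows/angle_rows map
  # them to parameter-table rows
  list(bond_rows = rows$bond_rows, angle_rows = rows$angle_rows,
       Rb = Rb, Th = Th, Ph = Ph, nb_fixed = nb_fixed)
}

# model energies for flat bonded values, using precomputed internals
.energies_from_values <- function(pre, pv, values, n_dihedral_terms) {
  sel <- function(type) values[pv$type == type]
  Kb <- sel("bond_K"); req <- sel("bond_req")
  Ka <- sel("angle_K"); teq <- sel("angle_theta")
  V <- sel("dih_V"); gam <- sel("dih_gamma")
  # pre$Rb columns follow topology bond order; parameters follow table rows
  Rb <- pre$Rb[, , drop = FALSE]
  e_bond <- (sweep(Rb, 2, req[pre$bond_rows])^2) %*% Kb[pre$bond_rows]
  e_ang <- 0
  if (ncol(pre$Th)) {
    e_ang <- (sweep(pre$Th, 2, teq[pre$angle_rows])^2) %*% Ka[pre$angle_rows]
  }
  e_dih <- 0
  if (n_dihedral_terms) {
    arg <- sweep(sweep(pre$Ph, 2, attr(pre, "mult"), "*"), 2, gam)
    e_dih <- (1 + cos(arg)) %*% (V / 2)
  }
  as.vector(e_bond) + as.vector(e_ang) + as.vector(e_dih) + pre$nb_fixed
}

#' Optimize bonded parameters against reference energies
#'
#' Gradient-based local minimization of [total_objective()] over the bonded
#' parameters (bond force constants and equilibrium lengths, angle force
#' constants and equilibrium angles, dihedral amplitudes, and optionally
#' the dihedral phases). Internal coordinates of the training conformations
#' and the fixed nonbonded energies are precomputed once, making each
#' objective evaluation a closed form in the parameters. Optimization is
#' performed in prior-scaled units `(p - p0) / gamma_m` for conditioning,
#' with force constants bounded below at zero.
#'
#' @inheritParams energy_term_XU
#' @param optimize_phases also optimize dihedral phases `gamma_n`; when
#'   FALSE every phase stays at its initial value (0 or pi). When TRUE,
#'   phases are wrapped into `[0, 2pi)` and a warning is raised if a final
#'   phase leaves {0, pi} (it breaks the energetic equivalence of mirror
#'   conformers).
#' @param alpha regularization scale (default `1 / N_p`).
#' @param prior_widths see [param_vector()].
#' @param reltol relative objective-change tolerance.
#' @return list with `params` (tuned [ff_parameters()]), `pv` (final
#'   [param_vector()]), `objective_initial`, `objective_final`, `trace`
#'   (best objective after each evaluation, non-increasing), `converged`.
#' @export
optimize_parameters <- function(initial, topo, training,
                                optimize_phases = FALSE, alpha = NULL,
                                prior_widths = list(), reltol = 1e-8) {
  pv <- param_vector(initial, optimize_phases = optimize_phases,
                     alpha = alpha, prior_widths = prior_widths)
  pre <- .precompute_training(initial, topo, training)
  attr(pre, "mult") <- initial$dihedral_terms$n
  ndt <- nrow(initial$dihedral_terms)
  u_ref <- training$u_ref
  wts <- training$weights
  v <- mean((u_ref - mean(u_ref))^2)
  if (v <= 0) stop("reference energies have zero variance")

  sel <- which(pv$mask)
  z0 <- numeric(length(sel))
  trace <- numeric(0)
  best <- Inf
  obj_z <- function(z) {
    vals <- pv$values
    vals[sel] <- pv$p0[sel] + z * pv$gamma[sel]
    u_mm <- .energies_from_values(pre, pv, vals, ndt)
    d <- u_ref - u_mm
    dbar <- sum(wts * d)
    xu <- sum(wts * (d - dbar)^2) / v
    val <- xu + pv$alpha * sum(z^2)
    if (!is.finite(val)) stop("non-finite objective during optimization")
    best <<- min(best, val)
    trace <<- c(trace, best)
    val
  }
  # lower bounds keep force constants non-negative
  lower <- rep(-Inf, length(sel))
  kcon <- pv$type[sel] %in% c("bond_K", "angle_K")
  lower[kcon] <- -pv$p0[sel][kcon] / pv$gamma[sel][kcon]

  obj0 <- obj_z(z0)
  opt <- stats::optim(z0, obj_z, method = "L-BFGS-B", lower = lower,
                      control = list(maxit = 1000,
                                     factr = reltol / .Machine$double.eps))
  # L-BFGS-B reports an abnormal line search when no further descent is
  # possible (e.g. starting at the optimum); with a non-increased objective
  # that is convergence for our purposes
  converged <- opt$convergence == 0 ||
    (grepl("ABNORMAL_TERMINATION_IN_LNSRCH",
           if (is.null(opt$message)) "" else opt$message) &&
       opt$value <= obj0 + 1e-12)
  if (!converged) {
    warning("parameter optimization did not converge: ", opt$message)
  }
  z <- if (opt$value <= obj0) opt$par else z0
  vals <- pv$values
  vals[sel] <- pv$p0[sel] + z * pv$gamma[sel]
  if (optimize_phases) {
    gsel <- pv$type == "dih_gamma"
    vals[gsel] <- vals[gsel] %% (2 * pi)
    off <- abs(vals[gsel]) > 1e-6 & abs(vals[gsel] - pi) > 1e-6
    if (any(off)) {
      warning(sum(off), " dihedral phase(s) left {0, pi}: mirror-conformer ",
              "energies may no longer be symmetric")
    }
  }
  pv$values <- vals
  list(params = apply_param_vector(initial, pv), pv = pv,
       objective_initial = obj0, objective_final = min(obj0, opt$value),
       trace = trace, converged = converged)
}

#' Split an ensemble into disjoint train and test sets
#'
#' @param confs list of [conformation()]s.
#' @param u_ref reference energies parallel to `confs`.
#' @param n_train,n_test subset sizes (must satisfy
#'   `n_train + n_test <= length(confs)`).
#' @param seed RNG seed; the split is deterministic per seed.
#' @return list with `train` and `test` [training_set()]s.
#' @export
split_train_test <- function(confs, u_ref, n_train, n_test, seed = 1L) {
  n <- length(confs)
  if (n_train + n_test > n) stop("not enough conformations to split")
  set.seed(seed)
  idx <- sample.int(n, n_train + n_test)
  tr <- idx[seq_len(n_train)]
  te <- idx[n_train + seq_len(n_test)]
  list(train = training_set(confs[tr], u_ref[tr]),
       test = training_set(confs[te], u_ref[te]))
}
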