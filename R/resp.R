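#' Build the stacked ESP least-squares system
#'
#' For a multiconformational restrained electrostatic-potential fit, each
#' grid point of each conformation contributes one row
#' `A[m, i] = k_e / |r_m - x_i|` so that `A q` is the point-charge potential
#' at the grid points. Conformations are stacked into a single
#' least-squares system, which is equivalent to fitting all conformations
#' simultaneously.
#'
#' @param grids list of ESP grids (each with `points` M x 3 in A and
#'   `values` in kJ/mol/e), one per conformation.
#' @param confs list of [conformation()]s, parallel to `grids`.
#' @param coulomb_constant Coulomb prefactor, kJ mol^-1 A e^-2.
#' @return list with design matrix `A` (M_total x N_atoms) and target
#'   vector `b` (M_total).
#' @export
build_esp_system <- function(grids, confs,
                             coulomb_constant = ff_constants$coulomb) {
  if (inherits(confs, "conformation")) confs <- list(confs)
  if (!is.null(grids$points)) grids <- list(grids)
  if (length(grids) != length(confs)) {
    stop("need exactly one ESP grid per conformation")
  }
  blocks <- vector("list", length(grids))
  for (g in seq_along(grids)) {
    pts <- grids[[g]]$points
    X <- if (inherits(confs[[g]], "conformation")) confs[[g]]$coords
         else as.matrix(confs[[g]])
    d2 <- outer(rowSums(pts^2), rowSums(X^2), "+") - 2 * pts %*% t(X)
    r <- sqrt(pmax(d2, 0))
    if (any(r < 1e-6)) {
      stop("ESP grid point coincident with an atom position")
    }
    blocks[[g]] <- coulomb_constant / r
  }
  list(A = do.call(rbind, blocks),
       b = unlist(lapply(grids, `[[`, "values"), use.names = FALSE))
}

#' Specification of one RESP stage
#'
#' @param a hyperbolic restraint strength (dimensionless scale multiplying
#'   the penalty, in the units of the stacked design system).
#' @param b_width hyperbolic restraint width in e (standard RESP, 0.1 e).
#' @param frozen integer vector of atom indices whose charges are fixed.
#' @param frozen_values charges of the frozen atoms, parallel to `frozen`.
#' @param equivalence_groups list of integer vectors of atoms constrained to
#'   carry the same charge.
#' @param total_charge total molecular charge in e (enforced exactly).
#' @return list of class `resp_stage_spec`.
#' @export
resp_stage_spec <- function(a, b_width = 0.1, frozen = integer(0),
                            frozen_values = numeric(0),
                            equivalence_groups = list(), total_charge = 0) {
  if (a < 0) stop("restraint scale a must be >= 0")
  if (length(frozen) != length(frozen_values)) {
    stop("frozen and frozen_values must be parallel")
  }
  if (length(equivalence_groups) > 1 &&
      anyDuplicated(unlist(equivalence_groups))) {
    stop("equivalence groups must be disjoint")
  }
  if (any(unlist(equivalence_groups) %in% frozen)) {
    stop("frozen and varying (equivalenced) sets must be disjoint")
  }
  structure(list(a = a, b_width = b_width, frozen = as.integer(frozen),
                 frozen_values = as.numeric(frozen_values),
                 equivalence_groups = lapply(equivalence_groups, as.integer),
                 total_charge = total_charge),
            class = "resp_stage_spec")
}

#' One restrained ESP fitting stage
#'
#' Minimizes
#' `||A q - b||^2 + a * sum_varying( sqrt(q_j^2 + b_width^2) - b_width )`
#' subject to an exact total-charge constraint and equality within each
#' equivalence group, with frozen atoms held fixed. The hyperbolic penalty
#' is handled by iteratively reweighted least squares: at each iterate the
#' penalty is replaced by its tangent quadratic `w_j q_j^2` with
#' `w_j = a / (2 sqrt(q_j^2 + b_width^2))`, and the resulting
#' equality-constrained linear system is solved via its KKT form. The fit
#' is performed in the Coulomb-normalized system (`A` and `b` divided by
#' the Coulomb constant), so `a` is dimensionally consistent with charges
#' in e and comparable to conventional RESP restraint scales.
#'
#' @param A design matrix from [build_esp_system()].
#' @param b target potentials.
#' @param spec a [resp_stage_spec()].
#' @param q0 initial charges (defaults to zeros).
#' @param tol convergence threshold on max |delta q| in e.
#' @param max_iter iteration cap.
#' @return numeric vector of charges with attributes `iterations` and
#'   `objective`.
#' @export
resp_stage <- function(A, b, spec, q0 = NULL, tol = 1e-6, max_iter = 200) {
  # fit in the dimensionless coulomb-normalized system so the restraint
  # scale a is in units consistent with charges in e (as in standard RESP,
  # where the design matrix is O(1))
  A <- A / ff_constants$coulomb
  b <- b / ff_constants$coulomb
  n <- ncol(A)
  if (is.null(q0)) q0 <- numeric(n)
  varying <- setdiff(seq_len(n), spec$frozen)
  if (length(varying) < 1) stop("no varying charges: system is fully frozen")

  # reduced parametrization: one variable per equivalence group, one per
  # independent varying atom
  group_of <- integer(n)
  next_var <- 0
  for (g in spec$equivalence_groups) {
    next_var <- next_var + 1
    group_of[g] <- next_var
  }
  for (i in varying) {
    if (group_of[i] == 0) {
      next_var <- next_var + 1
      group_of[i] <- next_var
    }
  }
  T_ <- matrix(0, n, next_var)
  for (i in varying) T_[i, group_of[i]] <- 1
  f <- numeric(n)
  f[spec$frozen] <- spec$frozen_values

  AT <- A %*% T_
  H0 <- crossprod(AT)
  g0 <- crossprod(AT, b - A %*% f)
  cvec <- colSums(T_)
  rhs_q <- spec$total_charge - sum(f)

  penalty <- function(q) {
    sum(sqrt(q[varying]^2 + spec$b_width^2) - spec$b_width)
  }
  objective <- function(q) sum((A %*% q - b)^2) + spec$a * penalty(q)

  q <- q0
  for (iter in seq_len(max_iter)) {
    w <- spec$a / (2 * sqrt(q[varying]^2 + spec$b_width^2))
    W <- numeric(n)
    W[varying] <- w
    H <- H0 + crossprod(T_, T_ * W)
    KKT <- rbind(cbind(H, cvec), c(cvec, 0))
    sol <- solve(KKT, c(g0, rhs_q))
    u <- sol[seq_len(next_var)]
    q_new <- as.vector(T_ %*% u + f)
    if (max(abs(q_new - q)) < tol) {
      q <- q_new
      attr(q, "iterations") <- iter
      attr(q, "objective") <- objective(q)
      return(q)
    }
    q <- q_new
  }
  stop("RESP stage did not converge in ", max_iter,
       " iterations; last max charge ", format(max(abs(q))))
}

#' Two-stage RESP charge derivation
#'
#' Stage 1 fits all atoms with a weak hyperbolic restraint (scale
#' `stage1_a`) and no equivalence constraints. Stage 2 refits only the
#' atoms in the topology's declared symmetry groups, constrained equal
#' within each group, with a tighter restraint (scale `stage2_a`), while
#' all other atoms are frozen at their stage-1 charges. The total charge is
#' preserved exactly in both stages.
#'
#' @inheritParams build_esp_system
#' @param topo a [molecule_topology()] declaring `symmetry_groups` and
#'   `net_charge`.
#' @param stage1_a,stage2_a restraint scales for the two stages.
#' @param b_width hyperbolic restraint width, e.
#' @return charges (e) with attribute `stage1` holding the stage-1 fit.
#' @export
two_stage_resp <- function(grids, confs, topo, stage1_a = 0.01,
                           stage2_a = 0.001, b_width = 0.1,
                           coulomb_constant = ff_constants$coulomb) {
  sys <- build_esp_system(grids, confs, coulomb_constant)
  s1 <- resp_stage_spec(a = stage1_a, b_width = b_width,
                        total_charge = topo$net_charge)
  q1 <- resp_stage(sys$A, sys$b, s1)
  if (length(topo$symmetry_groups) == 0) {
    message("no symmetry groups declared: stage 2 skipped")
    return(structure(as.vector(q1), stage1 = as.vector(q1)))
  }
  sym_atoms <- unlist(topo$symmetry_groups)
  frozen <- setdiff(seq_len(topo$n_atoms), sym_atoms)
  s2 <- resp_stage_spec(a = stage2_a, b_width = b_width, frozen = frozen,
                        frozen_values = q1[frozen],
                        equivalence_groups = topo$symmetry_groups,
                        total_charge = topo$net_charge)
  q2 <- resp_stage(sys$A, sys$b, s2, q0 = as.vector(q1))
  structure(as.vector(q2), stage1 = as.vector(q1))
}
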