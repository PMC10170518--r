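#' Relative energy differences against a reference minimum
#'
#' For paired model/reference energy columns over the same structures,
#' \deqn{\Delta\Delta E_i = (E_i^X - E_0^X) - (E_i^{ref} - E_0^{ref})}
#' where index 0 is the structure with the lowest reference energy. The
#' reference structure itself (identically zero) is excluded from the
#' returned vector, and the statistic is invariant to global offsets in
#' either column.
#'
#' @param e_model,e_ref energies in kJ/mol over the same structures.
#' @param ref_index index of the reference structure; defaults to the
#'   reference-column minimum. A warning is raised if it is not the
#'   reference minimum.
#' @return numeric vector of per-structure differences (reference item
#'   dropped), kJ/mol.
#' @export
delta_delta_E <- function(e_model, e_ref, ref_index = which.min(e_ref)) {
  if (length(e_model) != length(e_ref)) stop("energy columns differ in length")
  if (ref_index < 1 || ref_index > length(e_ref)) stop("reference id missing")
  if (ref_index != which.min(e_ref)) {
    warning("reference structure is not the reference-energy minimum")
  }
  dde <- (e_model - e_model[ref_index]) - (e_ref - e_ref[ref_index])
  dde[-ref_index]
}

#' RMSE-about-zero and mean of an error distribution
#'
#' @param values numeric vector (e.g. relative energy differences).
#' @return named vector with `rmse` (root mean square about zero) and
#'   `mean`.
#' @export
distribution_summary <- function(values) {
  c(rmse = sqrt(mean(values^2)), mean = mean(values))
}

#' Sum of absolute errors of populations (SAEP)
#'
#' `sum_i |p_i^model - p_i^ref|` over the union of conformer keys, missing
#' keys reading as zero. Symmetric, zero iff the tables agree, and bounded
#' by 2 (attained on disjoint support).
#'
#' @param p_model,p_ref named probability vectors (conformer key ->
#'   probability).
#' @return dimensionless value in `[0, 2]`.
#' @export
saep <- function(p_model, p_ref) {
  keys <- union(names(p_model), names(p_ref))
  if (is.null(keys)) {
    if (length(p_model) != length(p_ref)) {
      stop("unnamed population tables must have equal length")
    }
    return(sum(abs(p_model - p_ref)))
  }
  a <- ifelse(keys %in% names(p_model), p_model[keys], 0)
  b <- ifelse(keys %in% names(p_ref), p_ref[keys], 0)
  sum(abs(a - b))
}

#' Minimum RMSD under rigid superposition
#'
#' Removes the centroids and solves the optimal proper rotation by singular
#' value decomposition of the covariance matrix, with the determinant sign
#' corrected so reflections are excluded (chirality is preserved).
#'
#' @param A,B N x 3 coordinate matrices (or [conformation()]s) with equal
#'   atom counts, N >= 3 non-collinear atoms.
#' @return RMSD in A.
#' @export
superposition_rmsd <- function(A, B) {
  A <- if (inherits(A, "conformation")) A$coords else as.matrix(A)
  B <- if (inherits(B, "conformation")) B$coords else as.matrix(B)
  if (!all(dim(A) == dim(B))) stop("atom-count mismatch")
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  H <- crossprod(Ac, Bc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  Rm <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sqrt(mean(rowSums((Ac %*% t(Rm) - Bc)^2)))
}

#' Drop structure pairs above an RMSD threshold
#'
#' @param rmsd numeric vector of superposition RMSDs, A.
#' @param threshold cut in A (default 0.3).
#' @return logical keep-mask with attribute `n_removed`; warns when nothing
#'   survives.
#' @export
outlier_filter <- function(rmsd, threshold = 0.3) {
  keep <- rmsd <= threshold
  if (!any(keep)) warning("all structures exceed the RMSD threshold")
  structure(keep, n_removed = sum(!keep))
}
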