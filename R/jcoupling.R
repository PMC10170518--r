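#' Packaged through-hydrogen-bond J-coupling table
#'
#' Experimental and computed hydroxyl-proton-to-fluorine spin-spin coupling
#' constants (h1J(OH...F), Hz, in chloroform) for a set of nine
#' gamma-fluorohydrins (13 couplings: three molecules contribute two
#' couplings each, treated as independent records). Experimental signs are
#' not determined and the values are stored as magnitudes with
#' `sign_known = FALSE`; computed columns are signed. Columns: `mp2`
#' (MP2/6-311++G(2d,p)/PCM populations), `wb97x` (omega-B97X/6-31G*/PCM),
#' `gaff`, `gaff_mod` (base and retuned force field in chloroform), `ani2x`
#' (neural-network potential in chloroform). Reported MD uncertainties are
#' dropped.
#'
#' @return data.frame with columns `molecule`, `coupling`, `exptl`,
#'   `sign_known`, `mp2`, `wb97x`, `gaff`, `gaff_mod`, `ani2x`.
#' @export
jcoupling_fixture <- function() {
  path <- system.file("extdata", "jcouplings_fluorohydrins.csv",
                      package = "fluorff", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Population-weighted ensemble average of a J-coupling
#'
#' `sum_i p_i J_i` over conformers: the per-conformer coupling values are
#' averaged according to the conformer populations of a given model. Every
#' populated conformer must have a coupling value.
#'
#' @param js named numeric vector of per-conformer coupling values, Hz.
#' @param pops named probability vector (conformer key -> probability).
#' @return ensemble-averaged coupling, Hz.
#' @export
ensemble_average_j <- function(js, pops) {
  missing <- setdiff(names(pops)[pops > 0], names(js))
  if (length(missing)) {
    stop("no J value for populated conformer(s): ",
         paste(missing, collapse = ", "))
  }
  keys <- names(pops)
  sum(as.numeric(pops) * as.numeric(js[keys]))
}

.jc_stats <- function(x, y) {
  if (length(x) < 3) stop("need at least 3 records")
  rmse <- sqrt(mean((x - y)^2))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: R^2 undefined (RMSE = ", format(rmse), " Hz)")
  }
  c(rmse = rmse, r2 = stats::cor(x, y)^2)
}

#' Agreement of a computed J-coupling column with experiment
#'
#' When any experimental sign is undetermined (`sign_known = FALSE`), the
#' comparison is magnitude against magnitude: `|computed|` vs the stored
#' experimental magnitude. Returns the root-mean-square error and the
#' squared Pearson correlation.
#'
#' @param records data.frame in the layout of [jcoupling_fixture()].
#' @param source name of the computed column to compare.
#' @return named vector with `rmse` (Hz) and `r2`.
#' @export
compare_to_experiment <- function(records, source) {
  if (!source %in% names(records)) stop("unknown source column: ", source)
  comp <- records[[source]]
  expt <- records$exptl
  if (any(!records$sign_known)) {
    comp <- abs(comp)
    expt <- abs(expt)
  }
  .jc_stats(comp, expt)
}

#' Agreement between two computed J-coupling columns
#'
#' Signed comparison (both columns have known signs): RMSE and squared
#' Pearson correlation of column `source_a` against `source_b`.
#'
#' @inheritParams compare_to_experiment
#' @param source_a,source_b computed column names.
#' @return named vector with `rmse` (Hz) and `r2`.
#' @export
compare_model_to_reference <- function(records, source_a, source_b) {
  for (s in c(source_a, source_b)) {
    if (!s %in% names(records)) stop("unknown source column: ", s)
  }
  .jc_stats(records[[source_a]], records[[source_b]])
}

#' All summary statistics of the packaged J-coupling table
#'
#' Convenience wrapper computing, for each computed column, its RMSE and
#' R^2 against experiment, plus the signed RMSE/R^2 of the retuned force
#' field and the neural potential against the reference DFT column.
#'
#' @param records data.frame (default the packaged fixture).
#' @return data.frame with `comparison`, `rmse`, `r2`.
#' @export
jcoupling_statistics <- function(records = jcoupling_fixture()) {
  sources <- c("mp2", "wb97x", "gaff", "gaff_mod", "ani2x")
  rows <- lapply(sources, function(s) {
    st <- compare_to_experiment(records, s)
    data.frame(comparison = paste0(s, "_vs_exptl"),
               rmse = unname(st["rmse"]), r2 = unname(st["r2"]))
  })
  for (s in c("gaff_mod", "ani2x")) {
    st <- compare_model_to_reference(records, s, "wb97x")
    rows[[length(rows) + 1]] <- data.frame(
      comparison = paste0(s, "_vs_wb97x"),
      rmse = unname(st["rmse"]), r2 = unname(st["r2"]))
  }
  do.call(rbind, rows)
}
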