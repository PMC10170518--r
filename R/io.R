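#' Write conformations to a multi-frame XYZ file
#'
#' Standard XYZ: atom count line, comment line, then `element x y z` rows in
#' Angstrom. The comment line carries `energy=<kJ/mol> tag=<tag>` so
#' ensembles round-trip with their provenance.
#'
#' @param confs a [conformation()] or list of them.
#' @param elements character vector of element symbols.
#' @param path output file path.
#' @export
write_xyz <- function(confs, elements, path) {
  if (inherits(confs, "conformation")) confs <- list(confs)
  con <- file(path, "w")
  on.exit(close(con))
  for (cf in confs) {
    n <- nrow(cf$coords)
    if (n != length(elements)) stop("element count does not match coordinates")
    comment <- sprintf("energy=%.10g tag=%s",
                       if (is.finite(cf$energy)) cf$energy else NA, cf$tag)
    writeLines(c(as.character(n), comment), con)
    writeLines(sprintf("%-2s %18.10f %18.10f %18.10f",
                       elements, cf$coords[, 1], cf$coords[, 2],
                       cf$coords[, 3]), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ file
#'
#' @param path file path.
#' @return list with `elements` (from the first frame) and `conformations`
#'   (list of [conformation()]; energies/tags recovered from comment lines
#'   when present).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  confs <- list()
  elements <- NULL
  pos <- 1
  frame_line <- 1
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n) || n < 1) {
      stop("XYZ parse error at line ", pos, ": expected an atom count")
    }
    if (pos + 1 + n > length(lines)) {
      stop("XYZ parse error at line ", pos, ": truncated frame")
    }
    comment <- lines[pos + 1]
    rows <- lines[(pos + 2):(pos + 1 + n)]
    tok <- strsplit(trimws(rows), "[[:space:]]+")
    bad <- which(vapply(tok, length, 1L) < 4)
    if (length(bad)) {
      stop("XYZ parse error at line ", pos + 1 + bad[1],
           ": expected 'element x y z'")
    }
    el <- vapply(tok, `[[`, "", 1)
    xyz <- t(vapply(tok,
                    function(t) suppressWarnings(as.numeric(t[2:4])),
                    numeric(3)))
    if (anyNA(xyz)) stop("XYZ parse error near line ", pos + 2,
                         ": non-numeric coordinate")
    if (is.null(elements)) elements <- el
    else if (length(el) != length(elements)) {
      stop("XYZ frame starting at line ", pos,
           " has a different atom count than the first frame")
    }
    energy <- NA_real_
    tag <- ""
    me <- regmatches(comment, regexec("energy=([^ ]+)", comment))[[1]]
    if (length(me) == 2) energy <- suppressWarnings(as.numeric(me[2]))
    mt <- regmatches(comment, regexec("tag=(.*)$", comment))[[1]]
    if (length(mt) == 2) tag <- mt[2]
    confs[[frame_line]] <- conformation(xyz, energy = energy, tag = tag)
    frame_line <- frame_line + 1
    pos <- pos + 2 + n
  }
  list(elements = elements, conformations = confs)
}

#' Write a force-field parameter file
#'
#' Structured text with one block per term class and an explicit units
#' header; round-trips losslessly through [read_ff_parameters()].
#'
#' @param params an [ff_parameters()].
#' @param path output file path.
#' @export
write_ff_parameters <- function(params, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("# fluorff parameters v1")
  wl("# units: energy kJ/mol, distance A, angle rad, charge e")
  wl("[meta]")
  wl("coulomb_constant %.17g", params$coulomb_constant)
  wl("scale_14_lj %.17g", params$scale_14_lj)
  wl("scale_14_coul %.17g", params$scale_14_coul)
  wl("[bonds]  # i j K r_eq")
  with(params$bond_terms,
       for (r in seq_along(i)) wl("%d %d %.17g %.17g", i[r], j[r], K[r], r_eq[r]))
  wl("[angles]  # i j k K theta_eq")
  with(params$angle_terms,
       for (r in seq_along(i)) wl("%d %d %d %.17g %.17g",
                                  i[r], j[r], k[r], K[r], theta_eq[r]))
  wl("[dihedrals]  # i j k l V n gamma")
  with(params$dihedral_terms,
       for (r in seq_along(i)) wl("%d %d %d %d %.17g %d %.17g",
                                  i[r], j[r], k[r], l[r], V[r], n[r], gamma[r]))
  wl("[lj]  # atom sigma epsilon")
  for (r in seq_len(nrow(params$lj))) {
    wl("%d %.17g %.17g", r, params$lj$sigma[r], params$lj$epsilon[r])
  }
  wl("[charges]  # atom q")
  for (r in seq_along(params$charges)) wl("%d %.17g", r, params$charges[r])
  invisible(path)
}

#' Read a force-field parameter file
#'
#' @param path file written by [write_ff_parameters()].
#' @return An [ff_parameters()].
#' @export
read_ff_parameters <- function(path) {
  lines <- sub("\r$", "", readLines(path))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  section <- ""
  meta <- list()
  rows <- list(bonds = list(), angles = list(), dihedrals = list(),
               lj = list(), charges = list())
  for (ln in seq_along(lines)) {
    l <- lines[ln]
    if (!nzchar(l)) next
    if (grepl("^\\[", l)) {
      section <- sub("^\\[(.*)\\]$", "\\1", l)
      next
    }
    tok <- strsplit(l, "[[:space:]]+")[[1]]
    if (section == "meta") {
      meta[[tok[1]]] <- as.numeric(tok[2])
    } else if (section %in% names(rows)) {
      v <- suppressWarnings(as.numeric(tok))
      if (anyNA(v)) stop("parameter parse error at line ", ln)
      rows[[section]][[length(rows[[section]]) + 1]] <- v
    } else {
      stop("parameter parse error at line ", ln, ": unknown section")
    }
  }
  mk <- function(name, cols) {
    m <- do.call(rbind, rows[[name]])
    if (is.null(m)) m <- matrix(numeric(0), 0, length(cols))
    if (ncol(m) != length(cols)) stop("bad column count in [", name, "]")
    stats::setNames(as.data.frame(m), cols)
  }
  bt <- mk("bonds", c("i", "j", "K", "r_eq"))
  at <- mk("angles", c("i", "j", "k", "K", "theta_eq"))
  dt <- mk("dihedrals", c("i", "j", "k", "l", "V", "n", "gamma"))
  ljm <- mk("lj", c("atom", "sigma", "epsilon"))
  qm <- mk("charges", c("atom", "q"))
  ff_parameters(bt, at, dt,
                lj = ljm[order(ljm$atom), c("sigma", "epsilon")],
                charges = qm$q[order(qm$atom)],
                coulomb_constant = meta$coulomb_constant,
                scale_14_lj = meta$scale_14_lj,
                scale_14_coul = meta$scale_14_coul)
}

#' Write an ESP grid file
#'
#' Whitespace-separated `x y z value` rows with a one-line header stating
#' the units and the conformation tag.
#'
#' @param grid list with `points` (M x 3, A), `values` (kJ/mol/e) and
#'   `conformation_ref` tag.
#' @param path output path.
#' @export
write_esp_grid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# esp-grid units=A,kJ/mol/e conformation=%s",
                     grid$conformation_ref), con)
  writeLines(sprintf("%18.10f %18.10f %18.10f %18.10f",
                     grid$points[, 1], grid$points[, 2], grid$points[, 3],
                     grid$values), con)
  invisible(path)
}

#' Read an ESP grid file
#'
#' @param path file written by [write_esp_grid()].
#' @return list with `points`, `values`, `conformation_ref`.
#' @export
read_esp_grid <- function(path) {
  lines <- sub("\r$", "", readLines(path))
  hdr <- lines[1]
  tag <- sub(".*conformation=", "", hdr)
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  m <- do.call(rbind, lapply(strsplit(trimws(body), "[[:space:]]+"),
                             as.numeric))
  if (is.null(m) || ncol(m) != 4 || anyNA(m)) {
    stop("ESP grid parse error in ", path)
  }
  list(points = m[, 1:3, drop = FALSE], values = m[, 4],
       conformation_ref = tag)
}

#' Write a population table as CSV
#'
#' @param pops named numeric vector (conformer key -> probability).
#' @param path output path.
#' @export
write_population_csv <- function(pops, path) {
  utils::write.csv(data.frame(conformer = names(pops),
                              probability = as.numeric(pops)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a population table from CSV
#'
#' @param path CSV with `conformer` and `probability` columns.
#' @return named numeric vector.
#' @export
read_population_csv <- function(path) {
  df <- utils::read.csv(path)
  stats::setNames(df$probability, df$conformer)
}
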