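#' Read a nonbonded parameter table
#'
#' Whitespace-delimited text with the header line
#' `# residue atom charge epsilon rmin_half` followed by one row per atom
#' type: 3-letter residue name, atom name, partial charge (e), LJ well
#' depth (kcal/mol, >= 0) and LJ Rmin/2 (Angstrom, > 0). Lookups against
#' the table are total: a missing (residue, atom) entry is an error, never
#' a silent zero.
#'
#' @param path Path to the parameter file.
#' @return Tibble with columns `residue`, `atom`, `charge`, `epsilon`,
#'   `rmin_half`.
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) abort("parameter file contains no rows")
  fields <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(fields) != 5)
  if (length(bad)) abort(sprintf("malformed parameter row %d", bad[1]))
  out <- tibble(
    residue = vapply(fields, `[`, "", 1),
    atom = vapply(fields, `[`, "", 2),
    charge = as.numeric(vapply(fields, `[`, "", 3)),
    epsilon = as.numeric(vapply(fields, `[`, "", 4)),
    rmin_half = as.numeric(vapply(fields, `[`, "", 5))
  )
  if (anyNA(out$charge) || anyNA(out$epsilon) || anyNA(out$rmin_half)) {
    abort("non-numeric value in parameter file")
  }
  validate_params(out)
}

validate_params <- function(out) {
  key <- paste(out$residue, out$atom)
  if (anyDuplicated(key)) {
    abort(paste0("duplicate parameter entry: ", key[duplicated(key)][1]))
  }
  if (any(out$epsilon < 0)) abort("negative LJ epsilon in parameter table")
  if (any(out$rmin_half <= 0)) abort("non-positive LJ rmin_half in parameter table")
  out
}

#' Write a nonbonded parameter table
#' @param params Parameter tibble (see [read_params()]).
#' @param path Output path.
#' @export
write_params <- function(params, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# residue atom charge epsilon rmin_half", con)
  writeLines(sprintf(
    "%s %s %.6f %.6f %.6f",
    params$residue, params$atom, params$charge, params$epsilon,
    params$rmin_half
  ), con)
  invisible(path)
}

params_row <- function(params, residue, atom) {
  hit <- params$residue == residue & params$atom == atom
  if (!any(hit)) {
    abort(sprintf("no nonbonded parameters for %s %s", residue, atom))
  }
  params[which(hit)[1], ]
}

#' Read an NOE restraint list
#'
#' Whitespace-delimited rows `res_i atoms_i res_j atoms_j upper`, where
#' each atom field may list comma-separated equivalent protons (e.g.
#' `HD1,HD2,HD3` for a methyl group) and `upper` is the upper distance
#' bound in Angstrom. A restraint between two methyl groups thus carries
#' the full 3 x 3 cross-product of proton pairs.
#'
#' @param path Path to the restraint file.
#' @return A restraint tibble with columns `id`, `res_i`, `atoms_i`
#'   (list of character vectors), `res_j`, `atoms_j`, `upper`.
#' @export
read_restraints <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) abort("restraint file contains no rows")
  fields <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(fields) != 5)
  if (length(bad)) abort(sprintf("malformed restraint row %d", bad[1]))
  upper <- as.numeric(vapply(fields, `[`, "", 5))
  if (anyNA(upper) || any(upper <= 0)) {
    abort("malformed upper bound in restraint file (must be a positive length)")
  }
  new_restraints(
    res_i = as.integer(vapply(fields, `[`, "", 1)),
    atoms_i = lapply(fields, function(f) strsplit(f[2], ",")[[1]]),
    res_j = as.integer(vapply(fields, `[`, "", 3)),
    atoms_j = lapply(fields, function(f) strsplit(f[4], ",")[[1]]),
    upper = upper
  )
}

new_restraints <- function(res_i, atoms_i, res_j, atoms_j, upper,
                           id = NULL) {
  if (is.null(id)) id <- sprintf("noe_%03d", seq_along(upper))
  out <- tibble(
    id = id, res_i = res_i, atoms_i = atoms_i,
    res_j = res_j, atoms_j = atoms_j, upper = upper
  )
  same <- out$res_i == out$res_j &
    mapply(function(a, b) length(intersect(a, b)) > 0, atoms_i, atoms_j)
  if (any(same)) abort("restraint proton groups must be disjoint")
  out
}

#' Write an NOE restraint list
#' @param restraints Restraint tibble (see [read_restraints()]).
#' @param path Output path.
#' @export
write_restraints <- function(restraints, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# res_i atoms_i res_j atoms_j upper_A", con)
  writeLines(sprintf(
    "%d %s %d %s %.3f",
    restraints$res_i,
    vapply(restraints$atoms_i, paste, "", collapse = ","),
    restraints$res_j,
    vapply(restraints$atoms_j, paste, "", collapse = ","),
    restraints$upper
  ), con)
  invisible(path)
}
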