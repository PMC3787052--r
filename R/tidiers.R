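#' Tidy an energy map into a long pair table
#'
#' @param x An `energy_map`.
#' @param ... Unused.
#' @return Tibble with one row per unordered residue pair: `res_i`,
#'   `res_j`, `name_i`, `name_j`, `energy` (kcal/mol) and `class` (the
#'   interaction class of [classify_energy()]).
#' @export
tidy.energy_map <- function(x, ...) {
  ut <- which(upper.tri(x$values), arr.ind = TRUE)
  out <- tibble(
    res_i = x$residue_ids[ut[, 1]],
    res_j = x$residue_ids[ut[, 2]],
    name_i = x$residue_names[ut[, 1]],
    name_j = x$residue_names[ut[, 2]],
    energy = x$values[ut],
    class = classify_energy(x$values[ut])
  )
  arrange(out, .data$res_i, .data$res_j)
}

#' Summarise an energy map
#'
#' @param x An `energy_map`.
#' @param ... Unused.
#' @return One-row tibble: residue and frame counts, the sampling
#'   metadata, the energy range and the number of salt-bridge entries
#'   (< -30 kcal/mol).
#' @export
glance.energy_map <- function(x, ...) {
  e <- x$values[upper.tri(x$values)]
  tibble(
    n_residues = length(x$residue_ids),
    n_frames = x$n_frames,
    stride = x$stride,
    window = x$window,
    min_energy = min(e),
    max_energy = max(e),
    n_salt_bridges = sum(e < -30)
  )
}

#' Tidy a NOE report into its per-restraint table
#'
#' @param x A `noe_report`.
#' @param ... Unused.
#' @return The per-restraint tibble (`id`, residues, `upper`, `r_eff`,
#'   `violated`, `violation`).
#' @export
tidy.noe_report <- function(x, ...) x$details

#' Summarise a NOE report
#'
#' @param x A `noe_report`.
#' @param ... Unused.
#' @return One-row tibble with `n_restraints`, `n_violated`,
#'   `fraction_satisfied` and `mean_violation` (the average over violated
#'   restraints only; `NA` when nothing is violated).
#' @export
glance.noe_report <- function(x, ...) {
  tibble(
    n_restraints = x$n_restraints,
    n_violated = x$n_violated,
    fraction_satisfied = x$fraction_satisfied,
    mean_violation = x$mean_violation
  )
}

#' Tidy a cluster assignment into a per-frame table
#'
#' @param x A `cluster_assignment`.
#' @param ... Unused.
#' @return Tibble with `frame` (original frame index when known), `time`
#'   (ps, when known), `cluster` and `is_representative`.
#' @export
tidy.cluster_assignment <- function(x, ...) {
  n <- length(x$labels)
  tibble(
    frame = if (!is.null(x$frames)) x$frames else seq_len(n),
    time = if (!is.null(x$times)) x$times else NA_real_,
    cluster = x$labels,
    is_representative = seq_len(n) %in% x$representatives
  )
}

#' Summarise a cluster assignment
#'
#' @param x A `cluster_assignment`.
#' @param ... Unused.
#' @return One-row tibble with `n_frames`, `n_clusters`, the population of
#'   the largest cluster and the cutoff used.
#' @export
glance.cluster_assignment <- function(x, ...) {
  tibble(
    n_frames = length(x$labels),
    n_clusters = length(x$populations),
    top_population = x$populations[1],
    cutoff = x$cutoff,
    linkage = x$linkage
  )
}
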