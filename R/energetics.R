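COULOMB_CONST <- 332.0636 # kcal A / (mol e^2)

#' CHARMM-style switching function
#'
#' Smoothly tapers nonbonded energies between an inner and an outer cutoff
#' so that interactions vanish continuously: `S = 1` for `r <= r_on`, 0 for
#' `r >= r_off`, and the standard cubic switch in between.
#'
#' @param r Distance(s), Angstrom.
#' @param r_on,r_off Inner and outer switching radii (default 10 and 12 A).
#' @return Switching factor(s) in `[0, 1]`.
#' @export
switching_function <- function(r, r_on = 10, r_off = 12) {
  stopifnot(r_off > r_on)
  s <- rep(1, length(r))
  mid <- r > r_on & r < r_off
  s[r >= r_off] <- 0
  rm2 <- r[mid]^2
  s[mid] <- (r_off^2 - rm2)^2 * (r_off^2 + 2 * rm2 - 3 * r_on^2) /
    (r_off^2 - r_on^2)^3
  s
}

# vectorised switched Coulomb + Lennard-Jones energy for parameter vectors
pair_energy_num <- function(q1, q2, eps1, eps2, rmin1, rmin2, r,
                            r_on = 10, r_off = 12) {
  if (any(r <= 0)) abort("interatomic distance must be positive")
  eij <- sqrt(eps1 * eps2)
  rmin <- rmin1 + rmin2
  x6 <- (rmin / r)^6
  e <- COULOMB_CONST * q1 * q2 / r + eij * (x6^2 - 2 * x6)
  e * switching_function(r, r_on, r_off)
}

#' Nonbonded energy of one atom pair
#'
#' Switched Coulomb plus Lennard-Jones energy between two parameterised
#' atoms: `E = S(r) * (C q_i q_j / r + eps_ij ((Rmin/r)^12 - 2 (Rmin/r)^6))`
#' with `C = 332.0636` kcal A/(mol e^2), geometric-mean `eps_ij` and
#' `Rmin = rmin_half_i + rmin_half_j` (CHARMM Lorentz-Berthelot
#' convention). The switching function tapers the energy between 10 and
#' 12 A and zeroes it beyond 12 A.
#'
#' @param params Nonbonded parameter table (see [read_params()]).
#' @param atom_i,atom_j Length-2 character vectors
#'   `c(residue_name, atom_name)` identifying the atom types.
#' @param r Distance(s), Angstrom (> 0).
#' @param r_on,r_off Switching radii, Angstrom.
#' @return Energy (kcal/mol), vectorised over `r`.
#' @export
atom_pair_energy <- function(params, atom_i, atom_j, r,
                             r_on = 10, r_off = 12) {
  pi_ <- params_row(params, atom_i[1], atom_i[2])
  pj <- params_row(params, atom_j[1], atom_j[2])
  pair_energy_num(
    pi_$charge, pj$charge, pi_$epsilon, pj$epsilon,
    pi_$rmin_half, pj$rmin_half, r, r_on, r_off
  )
}

# map every atom of a structure to its nonbonded parameters (total lookup)
lookup_params <- function(structure, params) {
  key_s <- paste(structure$resname, structure$name)
  key_p <- paste(params$residue, params$atom)
  m <- match(key_s, key_p)
  if (anyNA(m)) {
    miss <- unique(key_s[is.na(m)])
    abort(paste0(
      "unparameterized atom type(s): ",
      paste(head(miss, 5), collapse = ", "),
      if (length(miss) > 5) sprintf(" (and %d more)", length(miss) - 5) else ""
    ))
  }
  params[m, c("charge", "epsilon", "rmin_half")]
}

#' Detect covalent bonds by interatomic distance
#'
#' Simple geometric bond perception on one conformation: two heavy atoms
#' closer than 1.9 A, or a hydrogen and any atom closer than 1.3 A, are
#' considered bonded. Used to derive the bonded-neighbour exclusions of
#' [residue_pair_energy()].
#'
#' @param structure A structure tibble.
#' @return A two-column integer matrix of bonded atom index pairs.
#' @export
detect_bonds <- function(structure) {
  xyz <- coords(structure)
  d <- as.matrix(stats::dist(xyz))
  is_h <- structure$element == "H"
  lim <- matrix(1.9, nrow(xyz), nrow(xyz))
  lim[is_h, ] <- 1.3
  lim[, is_h] <- 1.3
  hit <- which(d > 0 & d < lim, arr.ind = TRUE)
  hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  colnames(hit) <- c("i", "j")
  hit
}

# atoms within `depth` bonds of each atom, as an adjacency-list BFS
bonded_within <- function(bonds, n_atoms, from, to, depth = 3) {
  adj <- vector("list", n_atoms)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  out <- matrix(FALSE, length(from), length(to))
  to_pos <- setNames(seq_along(to), to)
  for (a in seq_along(from)) {
    frontier <- from[a]
    seen <- from[a]
    for (step in seq_len(depth)) {
      frontier <- unique(unlist(adj[frontier]))
      frontier <- setdiff(frontier, seen)
      if (length(frontier) == 0) break
      seen <- c(seen, frontier)
      hits <- frontier[as.character(frontier) %in% names(to_pos)]
      if (length(hits)) out[a, to_pos[as.character(hits)]] <- TRUE
    }
  }
  out
}

#' Nonbonded interaction energy between two residues in one conformation
#'
#' Sums [atom_pair_energy()] over every atom pair with one atom in each
#' residue, excluding pairs separated by at most `exclude_bonded` covalent
#' bonds (1-2, 1-3 and 1-4 neighbours across the peptide bond). The pair is
#' evaluated only when the minimum heavy-atom distance between the residues
#' is within the outer cutoff; beyond it the energy is 0, consistent with
#' neglecting the long-range part of the electrostatics.
#'
#' @param structure A structure tibble (one conformation).
#' @param params Nonbonded parameter table.
#' @param res_i,res_j Distinct residue ids.
#' @param exclude_bonded Bond-separation threshold for exclusions
#'   (default 3; set 0 to disable).
#' @param bonds Optional precomputed bond matrix from [detect_bonds()].
#' @param r_on,r_off Switching radii, Angstrom.
#' @param atom_params Optional precomputed [lookup_params()] result.
#' @return Energy, kcal/mol.
#' @export
residue_pair_energy <- function(structure, params, res_i, res_j,
                                exclude_bonded = 3, bonds = NULL,
                                r_on = 10, r_off = 12, atom_params = NULL) {
  if (res_i == res_j) abort("residue pair energy needs two distinct residues")
  ia <- which(structure$resid == res_i)
  ib <- which(structure$resid == res_j)
  if (length(ia) == 0 || length(ib) == 0) abort("residue not found in structure")
  xa <- coords(structure, ia)
  xb <- coords(structure, ib)
  # cutoff gate on the minimum heavy-atom distance
  ha <- structure$element[ia] != "H"
  hb <- structure$element[ib] != "H"
  d2h <- outer(rowSums(xa[ha, , drop = FALSE]^2),
    rowSums(xb[hb, , drop = FALSE]^2), `+`
  ) - 2 * xa[ha, , drop = FALSE] %*% t(xb[hb, , drop = FALSE])
  if (min(d2h) > r_off^2) return(0)
  if (is.null(atom_params)) atom_params <- lookup_params(structure, params)
  pa <- atom_params[ia, ]
  pb <- atom_params[ib, ]
  d <- sqrt(pmax(outer(rowSums(xa^2), rowSums(xb^2), `+`) -
    2 * xa %*% t(xb), 0))
  E <- pair_energy_num(
    rep(pa$charge, times = length(ib)),
    rep(pb$charge, each = length(ia)),
    rep(pa$epsilon, times = length(ib)),
    rep(pb$epsilon, each = length(ia)),
    rep(pa$rmin_half, times = length(ib)),
    rep(pb$rmin_half, each = length(ia)),
    as.vector(d), r_on, r_off
  )
  E <- matrix(E, length(ia), length(ib))
  if (exclude_bonded > 0) {
    if (is.null(bonds)) bonds <- detect_bonds(structure)
    excl <- bonded_within(bonds, nrow(structure), ia, ib, exclude_bonded)
    E[excl] <- 0
  }
  sum(E)
}

#' Time-averaged inter-residue energy map (IEM)
#'
#' Computes [residue_pair_energy()] for every residue pair on frames
#' sampled every `stride` ps over the final `window` ns of the trajectory,
#' and averages arithmetically over time. With the defaults (50 ps stride,
#' 100 ns window) a 2000-frame trajectory at dt = 50 ps is used in full.
#' Excluded residue ids (e.g. calcium ions kept as residues) are absent
#' from the matrix entirely.
#'
#' @param traj An `md_trajectory`.
#' @param params Nonbonded parameter table.
#' @param stride Sampling interval, ps (multiple of the frame step).
#' @param window Averaging window counted from the trajectory end, ns.
#' @param exclude_ids Residue ids to drop (e.g. ions).
#' @inheritParams residue_pair_energy
#' @return An `energy_map`: list with `residue_ids`, `residue_names`,
#'   symmetric `values` matrix (kcal/mol, zero diagonal) and the sampling
#'   metadata.
#' @export
compute_iem <- function(traj, params, stride = 50, window = 100,
                        exclude_ids = NULL, exclude_bonded = 3,
                        r_on = 10, r_off = 12) {
  idx <- sample_frames(traj, stride = stride, window = window)
  top <- traj$topology
  res_tbl <- distinct(tibble(resid = top$resid, resname = top$resname))
  if (!is.null(exclude_ids)) {
    res_tbl <- res_tbl[!res_tbl$resid %in% exclude_ids, ]
  }
  ids <- res_tbl$resid
  n <- length(ids)
  if (n < 2) abort("need at least two residues for an energy map")
  atom_params <- lookup_params(top, params)
  bonds <- detect_bonds(top) # fixed bond topology, perceived once
  acc <- matrix(0, n, n)
  for (f in idx) {
    s <- set_coords(top, traj$frames[[f]])
    for (a in seq_len(n - 1)) {
      for (b in seq((a + 1), n)) {
        e <- residue_pair_energy(
          s, params, ids[a], ids[b],
          exclude_bonded = exclude_bonded, bonds = bonds,
          r_on = r_on, r_off = r_off, atom_params = atom_params
        )
        acc[a, b] <- acc[a, b] + e
      }
    }
  }
  vals <- acc / length(idx)
  vals <- vals + t(vals)
  diag(vals) <- 0
  dimnames(vals) <- list(ids, ids)
  structure(
    list(
      residue_ids = ids, residue_names = res_tbl$resname, values = vals,
      stride = stride, window = window, cutoff = r_off,
      n_frames = length(idx)
    ),
    class = "energy_map"
  )
}

#' @export
print.energy_map <- function(x, ...) {
  cat(sprintf(
    "<energy_map> %d residues, %d frames averaged (stride %g ps, window %g ns)\n",
    length(x$residue_ids), x$n_frames, x$stride, x$window
  ))
  rng <- range(x$values[upper.tri(x$values)])
  cat(sprintf("  energies: %.2f .. %.2f kcal/mol\n", rng[1], rng[2]))
  invisible(x)
}

.interaction_levels <- c(
  "ionic", "strong_polar", "hbond_like", "weak", "repulsive"
)

#' Classify interaction energies into physical classes
#'
#' Bins energies (kcal/mol) into the interaction classes used to read an
#' inter-residue energy map: `ionic` (<= -30), `strong_polar` (-30, -15],
#' `hbond_like` (-15, -2] — the range typical of hydrogen bonds — `weak`
#' (-2, 0] for dispersion/hydrophobic contacts, and `repulsive` (> 0).
#' Each bin edge belongs to the more-negative class.
#'
#' @param energy Numeric energies, kcal/mol.
#' @return Factor with levels
#'   `ionic, strong_polar, hbond_like, weak, repulsive`.
#' @export
classify_energy <- function(energy) {
  cut(energy,
    breaks = c(-Inf, -30, -15, -2, 0, Inf),
    labels = .interaction_levels, right = TRUE
  )
}

#' Classify every entry of an energy map
#'
#' @param map An `energy_map`.
#' @return A character matrix of interaction classes with the map's
#'   dimensions; diagonal entries are `NA` (self-interaction undefined).
#' @export
classify_map <- function(map) {
  cls <- matrix(as.character(classify_energy(map$values)),
    nrow = nrow(map$values), dimnames = dimnames(map$values)
  )
  diag(cls) <- NA_character_
  cls
}

#' Extract salt bridges from an energy map
#'
#' Returns the residue pairs whose time-averaged interaction energy falls
#' strictly below a threshold; at the conventional -30 kcal/mol this
#' isolates the salt bridges of the map. Each pair is reported once
#' (`res_i < res_j`).
#'
#' @param map An `energy_map`.
#' @param threshold Energy threshold, kcal/mol (must be negative).
#' @return Tibble with `res_i`, `res_j`, `name_i`, `name_j`, `energy`,
#'   sorted by increasing energy.
#' @export
filter_map <- function(map, threshold = -30) {
  if (threshold >= 0) abort("salt-bridge threshold must be negative")
  v <- map$values
  hit <- which(upper.tri(v) & v < threshold, arr.ind = TRUE)
  out <- tibble(
    res_i = map$residue_ids[hit[, 1]],
    res_j = map$residue_ids[hit[, 2]],
    name_i = map$residue_names[hit[, 1]],
    name_j = map$residue_names[hit[, 2]],
    energy = v[hit]
  )
  arrange(out, .data$energy)
}

#' Salt bridges conserved between two energy maps
#'
#' A pair is conserved when its energy is strictly below the threshold in
#' both maps — the criterion used to mark the bridges shared by two
#' independent trajectories of the same protein.
#'
#' @param map_a,map_b `energy_map` objects.
#' @param threshold Energy threshold, kcal/mol (negative).
#' @return Tibble with `res_i`, `res_j`, `energy_a`, `energy_b`.
#' @export
conserved_bridges <- function(map_a, map_b, threshold = -30) {
  ba <- filter_map(map_a, threshold)
  bb <- filter_map(map_b, threshold)
  out <- dplyr::inner_join(
    ba, bb,
    by = c("res_i", "res_j", "name_i", "name_j"),
    suffix = c("_a", "_b")
  )
  arrange(out, .data$energy_a)
}
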