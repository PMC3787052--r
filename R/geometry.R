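#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' corresponding atoms of two coordinate sets. Reflections are rejected by
#' determinant correction, so the returned rotation always has
#' `det(R) = +1`.
#'
#' @param mobile,reference Structure tibbles.
#' @param fit_mobile,fit_reference Equal-length integer atom index vectors
#'   defining the fitted correspondence (pairing by position in the two
#'   vectors). Defaults to all atoms of each structure.
#' @return An object of class `superposition`: list with `rotation` (3x3,
#'   det +1), `translation` (length-3, Angstrom; the transform is
#'   `x' = R x + t` for column vectors) and `rmsd` (Angstrom, over the fit
#'   set after transformation).
#' @export
superpose <- function(mobile, reference,
                      fit_mobile = seq_len(nrow(mobile)),
                      fit_reference = seq_len(nrow(reference))) {
  P <- coords(mobile, fit_mobile)
  Q <- coords(reference, fit_reference)
  if (nrow(P) != nrow(Q)) {
    abort(sprintf(
      "fit sets must be equal length (%d vs %d)", nrow(P), nrow(Q)
    ))
  }
  res <- kabsch(P, Q)
  structure(res, class = "superposition")
}

kabsch <- function(P, Q) {
  n <- nrow(P)
  if (n < 3) abort("superposition needs at least 3 atoms")
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp)
  Qc <- sweep(Q, 2, cq)
  if (qr(Pc)$rank < 2) abort("fit atoms are collinear; superposition is degenerate")
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  moved <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Qc)^2)))
  list(
    rotation = R,
    translation = as.numeric(cq - R %*% cp),
    rmsd = rmsd
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

apply_transform <- function(xyz, sp) {
  sweep(xyz %*% t(sp$rotation), 2, sp$translation, `+`)
}

#' Match atoms of two structures by identity
#'
#' Pairs atoms by the `(chain, resid, name)` key, in the order of the first
#' structure. Atoms present in only one structure are dropped, which makes
#' comparison between e.g. a crystal structure and an NMR model robust to
#' differing hydrogen content.
#'
#' @param a,b Structure tibbles.
#' @param idx_a,idx_b Optional index vectors restricting each side before
#'   matching.
#' @return A list with integer vectors `a` and `b` of equal length.
#' @export
atom_correspondence <- function(a, b, idx_a = seq_len(nrow(a)),
                                idx_b = seq_len(nrow(b))) {
  key_a <- paste(a$chain, a$resid, a$name)[idx_a]
  key_b <- paste(b$chain, b$resid, b$name)[idx_b]
  common <- intersect(key_a, key_b)
  if (length(common) == 0) abort("no common atoms between the two structures")
  list(
    a = idx_a[match(common, key_a)],
    b = idx_b[match(common, key_b)]
  )
}

#' Partial RMSD after a core fit
#'
#' Superposes `mobile` on `reference` over the `fit` selection only, then
#' measures the RMSD over the `measure` selection without refitting. This
#' is the standard way to quantify how much a segment has moved relative to
#' a rigidly aligned core: with `fit = "PC"` and `measure = "H1"` it gives
#' the displacement of helix H1 after a protein-core alignment.
#'
#' @param mobile,reference Structure tibbles. When the two structures have
#'   different atom content, atoms are paired by `(chain, resid, name)`.
#' @param fit,measure Segment name vectors (see [select_atoms()]);
#'   `measure` defaults to `fit`.
#' @param atom_class,table,backbone Passed to [select_atoms()].
#' @return RMSD in Angstrom (a single number).
#' @export
rmsd_partial <- function(mobile, reference, fit = "PC", measure = fit,
                         atom_class = "backbone", table = ncs1_segments(),
                         backbone = .backbone_names) {
  sel <- function(s, segs) {
    select_atoms(s, segs,
      atom_class = atom_class, table = table,
      backbone = backbone
    )
  }
  fit_pair <- atom_correspondence(
    mobile, reference, sel(mobile, fit), sel(reference, fit)
  )
  sp <- superpose(mobile, reference, fit_pair$a, fit_pair$b)
  meas <- atom_correspondence(
    mobile, reference, sel(mobile, measure), sel(reference, measure)
  )
  if (length(meas$a) == 0) abort("empty measure selection")
  moved <- apply_transform(coords(mobile, meas$a), sp)
  sqrt(mean(rowSums((moved - coords(reference, meas$b))^2)))
}

new_series <- function(times, values, label = "", unit = "A") {
  stopifnot(length(times) == length(values))
  if (any(diff(times) <= 0)) abort("series times must be strictly increasing")
  out <- tibble(time = times, value = values)
  class(out) <- c("md_series", class(out))
  attr(out, "label") <- label
  attr(out, "unit") <- unit
  out
}

#' RMSD time series of a trajectory against a reference
#'
#' Each frame is independently superposed on the reference over the fit
#' selection (Kabsch) and the post-fit RMSD recorded, reproducing the
#' familiar RMSD-vs-time trace used to monitor structural drift.
#'
#' @param traj An `md_trajectory`.
#' @param reference Structure tibble (defaults to the trajectory topology,
#'   i.e. the first frame's atom table with its coordinates).
#' @param fit Segment names for the fitted selection.
#' @inheritParams rmsd_partial
#' @return An `md_series` tibble with columns `time` (ps) and `value` (A).
#' @export
rmsd_series <- function(traj, reference = traj$topology, fit = "PC",
                        atom_class = "backbone", table = ncs1_segments(),
                        backbone = .backbone_names) {
  pair <- atom_correspondence(
    traj$topology, reference,
    select_atoms(traj$topology, fit,
      atom_class = atom_class, table = table, backbone = backbone
    ),
    select_atoms(reference, fit,
      atom_class = atom_class, table = table, backbone = backbone
    )
  )
  Q <- coords(reference, pair$b)
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    P <- traj$frames[[i]][pair$a, , drop = FALSE]
    tryCatch(kabsch(P, Q)$rmsd, error = function(e) {
      abort(sprintf("frame %d: %s", i, conditionMessage(e)))
    })
  }, numeric(1))
  new_series(frame_times(traj), vals,
    label = sprintf("RMSD(%s)", paste(fit, collapse = ",")), unit = "A"
  )
}

#' Centered moving-average smoothing of a time series
#'
#' Cosmetic smoothing for plotting RMSD or distance traces; edge values use
#' truncated windows so the series keeps its length. Never used in any
#' statistic computed by this package.
#'
#' @param series An `md_series` (or any tibble with `time` and `value`).
#' @param window Odd window width in frames (default 51).
#' @return A smoothed series of the same length.
#' @export
smooth_series <- function(series, window = 51) {
  if (window < 1 || window %% 2 == 0) abort("window must be a positive odd integer")
  v <- series$value
  n <- length(v)
  h <- (window - 1) / 2
  sm <- vapply(seq_len(n), function(i) {
    mean(v[max(1, i - h):min(n, i + h)])
  }, numeric(1))
  out <- series
  out$value <- sm
  attr(out, "label") <- paste0(attr(series, "label"), " (smoothed)")
  out
}

#' Centre of mass of an atom selection
#'
#' @param structure A structure tibble.
#' @param idx Integer atom indices (default: all atoms).
#' @param mass_weighted Use atomic masses (default); `FALSE` gives the
#'   geometric centroid.
#' @return Length-3 numeric vector, Angstrom.
#' @export
com <- function(structure, idx = seq_len(nrow(structure)),
                mass_weighted = TRUE) {
  if (length(idx) == 0) abort("empty selection for centre of mass")
  xyz <- coords(structure, idx)
  w <- if (mass_weighted) structure$mass[idx] else rep(1, length(idx))
  if (sum(w) <= 0) abort("zero total mass in centre-of-mass selection")
  colSums(xyz * w) / sum(w)
}

#' Distance between the centres of mass of two selections, per frame
#'
#' The classic order parameter for a domain or tail docking process: e.g.
#' the distance between the centre of mass of the C-terminal tail and the
#' centre of mass of the whole protein, followed along a trajectory.
#'
#' @param traj An `md_trajectory`.
#' @param set_a,set_b Segment name vectors (atom class `"all"` within the
#'   segments) or integer index vectors.
#' @inheritParams com
#' @param table Segment table for name resolution.
#' @return An `md_series` with `time` (ps) and `value` (A).
#' @export
com_distance_series <- function(traj, set_a, set_b, mass_weighted = TRUE,
                                table = ncs1_segments()) {
  resolve <- function(s) {
    if (is.numeric(s)) {
      as.integer(s)
    } else {
      select_atoms(traj$topology, s, atom_class = "all", table = table)
    }
  }
  ia <- resolve(set_a)
  ib <- resolve(set_b)
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    s <- set_coords(traj$topology, traj$frames[[i]])
    sqrt(sum((com(s, ia, mass_weighted) - com(s, ib, mass_weighted))^2))
  }, numeric(1))
  new_series(frame_times(traj), vals, label = "COM distance", unit = "A")
}
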