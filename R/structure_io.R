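#' Read one model of a PDB file into a tidy atom table
#'
#' Parses a (possibly multi-model) PDB file and returns a single
#' conformation as a tibble with one row per atom. Heteroatoms (waters,
#' ions, glycols and other `HETATM` records) are excluded by default, so a
#' crystal entry with bound calcium yields the polypeptide only. Hydrogens
#' are retained when present. Alternate locations are resolved by keeping
#' the highest-occupancy record (ties go to altLoc `"A"`). Insertion codes
#' are not supported and raise an error.
#'
#' @param path Path to a PDB file.
#' @param model_index 1-based model number (`MODEL` records); files without
#'   `MODEL` records count as a single model.
#' @param chain Optional chain identifier; when given, only that chain is
#'   returned.
#' @param keep_hetatm Keep `HETATM` records (default `FALSE`).
#' @param label Label stored on the returned structure; defaults to the
#'   file name plus model number.
#'
#' @return A structure: a tibble with columns `serial`, `name`, `resname`,
#'   `resid`, `chain`, `element`, `mass`, `x`, `y`, `z` (coordinates in
#'   Angstrom) and attribute `label`.
#' @export
read_structure <- function(path, model_index = 1, chain = NULL,
                           keep_hetatm = FALSE, label = NULL) {
  if (!file.exists(path)) abort(paste0("PDB file not found: ", path))
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  n_models <- nrow(pdb$xyz)
  if (model_index < 1 || model_index > n_models) {
    abort(sprintf(
      "model %d requested but '%s' contains %d model(s)",
      model_index, basename(path), n_models
    ))
  }
  at <- pdb$atom
  if (any(!is.na(at$insert) & at$insert != "")) {
    abort("insertion codes are not supported")
  }
  xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  if (!keep_hetatm) at <- at[at$type == "ATOM", , drop = FALSE]
  if (!is.null(chain)) {
    if (!chain %in% at$chain) {
      abort(sprintf(
        "chain '%s' not found in '%s' (chains present: %s)",
        chain, basename(path), paste(unique(at$chain), collapse = ", ")
      ))
    }
    at <- at[at$chain == chain, , drop = FALSE]
  }
  if (nrow(at) == 0) abort(paste0("no atoms selected from ", path))
  at <- resolve_altloc(at)
  el <- at$elesy
  if (is.null(el) || all(is.na(el) | el == "")) el <- guess_element(at$elety)
  el[is.na(el) | el == ""] <- guess_element(at$elety[is.na(el) | el == ""])
  out <- tibble(
    serial = as.integer(at$eleno),
    name = at$elety,
    resname = at$resid,
    resid = as.integer(at$resno),
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    element = toupper(el),
    mass = element_mass(el),
    x = at$x, y = at$y, z = at$z
  )
  if (is.null(label)) label <- sprintf("%s#%d", basename(path), model_index)
  new_structure(out, label = label)
}

resolve_altloc <- function(at) {
  alt <- at$alt
  if (is.null(alt)) return(at)
  alt[is.na(alt)] <- ""
  if (all(alt == "")) return(at)
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$elety, sep = "\r")
  # keep highest occupancy per (chain, resid, name); tie broken toward 'A'
  ord <- order(key, -occ, alt != "A", alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$elety, sep = "\r")), ,
    drop = FALSE
  ]
  at[order(at$eleno), , drop = FALSE]
}

#' Validate a tidy atom table as a structure
#'
#' Checks the column contract (serial, name, resname, resid, chain,
#' element, mass, x, y, z), coordinate finiteness and the uniqueness of
#' the `(chain, resid, name)` atom key, and attaches a label.
#'
#' @param df Data frame of atoms.
#' @param label Structure label.
#' @return A structure tibble.
#' @export
as_structure <- function(df, label = "structure") new_structure(df, label)

new_structure <- function(df, label = "structure") {
  df <- as_tibble(df)
  stopifnot(all(c(
    "serial", "name", "resname", "resid", "chain", "element",
    "mass", "x", "y", "z"
  ) %in% names(df)))
  if (nrow(df) == 0) abort("a structure must contain at least one atom")
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z))) {
    abort("non-finite coordinates in structure")
  }
  key <- paste(df$chain, df$resid, df$name)
  if (anyDuplicated(key)) {
    abort(paste0(
      "duplicate (chain, resid, name) atom key: ",
      key[duplicated(key)][1]
    ))
  }
  attr(df, "label") <- label
  df
}

#' Extract the coordinate matrix of a structure
#'
#' @param structure A structure tibble.
#' @param idx Optional integer atom indices.
#' @return An `n x 3` numeric matrix (Angstrom).
#' @export
coords <- function(structure, idx = NULL) {
  m <- cbind(structure$x, structure$y, structure$z)
  if (!is.null(idx)) m <- m[idx, , drop = FALSE]
  m
}

set_coords <- function(structure, xyz) {
  stopifnot(nrow(xyz) == nrow(structure))
  structure$x <- xyz[, 1]; structure$y <- xyz[, 2]; structure$z <- xyz[, 3]
  structure
}

#' Write a structure (or trajectory) to a PDB file
#'
#' Coordinates are written in the fixed-format PDB convention (1e-3 A
#' precision). A trajectory is written as consecutive `MODEL` blocks.
#'
#' @param x A structure tibble or an `md_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  if (inherits(x, "md_trajectory")) {
    top <- x$topology
    xyz <- do.call(rbind, lapply(x$frames, function(f) as.vector(t(f))))
    bio3d::write.pdb(
      file = path, xyz = xyz, resno = top$resid, resid = top$resname,
      chain = top$chain, elety = top$name, eleno = top$serial
    )
  } else {
    bio3d::write.pdb(
      file = path, xyz = as.vector(t(coords(x))), resno = x$resid,
      resid = x$resname, chain = x$chain, elety = x$name, eleno = x$serial
    )
  }
  invisible(path)
}

#' Read an ordered set of PDB models as a trajectory
#'
#' Concatenates all models of one or more PDB files, in file order, into a
#' trajectory sharing a single atom topology (taken from the first model).
#' Every model must list the same atoms in the same order; the first
#' mismatching atom is reported otherwise.
#'
#' @param paths Character vector of PDB file paths.
#' @param dt Time between consecutive frames, ps (> 0).
#' @inheritParams read_structure
#' @return An `md_trajectory`: list with `topology` (structure tibble),
#'   `frames` (list of `n_atoms x 3` matrices) and `dt`.
#' @export
read_trajectory <- function(paths, dt, keep_hetatm = FALSE, chain = NULL) {
  stopifnot(length(paths) >= 1)
  if (!is.numeric(dt) || dt <= 0) abort("dt must be a positive time step, ps")
  topology <- NULL
  frames <- list()
  for (p in paths) {
    pdb <- bio3d::read.pdb(p, multi = TRUE, verbose = FALSE)
    n_models <- nrow(pdb$xyz)
    for (m in seq_len(n_models)) {
      s <- read_structure(p,
        model_index = m, chain = chain,
        keep_hetatm = keep_hetatm
      )
      if (is.null(topology)) {
        topology <- s
      } else {
        check_same_topology(topology, s, where = sprintf("%s model %d", p, m))
      }
      frames[[length(frames) + 1]] <- coords(s)
    }
  }
  new_trajectory(topology, frames, dt)
}

check_same_topology <- function(a, b, where = "frame") {
  if (nrow(a) != nrow(b)) {
    abort(sprintf(
      "topology mismatch at %s: %d atoms vs %d in topology",
      where, nrow(b), nrow(a)
    ))
  }
  same <- a$name == b$name & a$resid == b$resid & a$chain == b$chain
  if (!all(same)) {
    i <- which(!same)[1]
    abort(sprintf(
      "topology mismatch at %s, atom %d: %s %s/%d vs %s %s/%d",
      where, i, a$name[i], a$chain[i], a$resid[i],
      b$name[i], b$chain[i], b$resid[i]
    ))
  }
  invisible(TRUE)
}

#' Assemble a trajectory from a topology and frame coordinates
#'
#' @param topology A structure tibble giving the shared atom topology.
#' @param frames List of `n_atoms x 3` coordinate matrices (Angstrom).
#' @param dt Time between frames, ps (> 0).
#' @return An `md_trajectory`.
#' @export
as_trajectory <- function(topology, frames, dt) {
  if (dt <= 0) abort("dt must be positive")
  new_trajectory(topology, frames, dt)
}

new_trajectory <- function(topology, frames, dt) {
  n <- nrow(topology)
  ok <- vapply(frames, function(f) is.matrix(f) && nrow(f) == n &&
    ncol(f) == 3, logical(1))
  if (!all(ok)) abort("every frame must be an n_atoms x 3 coordinate matrix")
  structure(
    list(topology = topology, frames = frames, dt = dt),
    class = "md_trajectory"
  )
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf(
    "<md_trajectory> %d frames x %d atoms, dt = %g ps (span %g ps)\n",
    n_frames(x), nrow(x$topology), x$dt, (n_frames(x) - 1) * x$dt
  ))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj An `md_trajectory`.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Frame times of a trajectory
#' @param traj An `md_trajectory`.
#' @return Numeric vector of times in ps, starting at 0.
#' @export
frame_times <- function(traj) (seq_len(n_frames(traj)) - 1) * traj$dt

#' Materialise one frame of a trajectory as a structure
#' @param traj An `md_trajectory`.
#' @param i Frame index (1-based).
#' @export
frame_structure <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  s <- set_coords(traj$topology, traj$frames[[i]])
  attr(s, "label") <- sprintf("%s frame %d", attr(traj$topology, "label"), i)
  s
}

# resolve the frame indices selected by a sampling stride (ps) and window
# (ns, counted back from the end of the trajectory)
sample_frames <- function(traj, stride = NULL, window = NULL) {
  n <- n_frames(traj)
  dt <- traj$dt
  if (is.null(stride)) stride <- dt
  if (stride <= 0 || abs(stride / dt - round(stride / dt)) > 1e-9) {
    abort(sprintf("stride (%g ps) must be a positive multiple of dt (%g ps)",
      stride, dt))
  }
  step <- as.integer(round(stride / dt))
  idx <- rev(seq(n, 1, by = -step))
  if (!is.null(window)) {
    span_ns <- n * dt / 1000 # each frame stands for dt of sampling
    if (window > span_ns + 1e-9) {
      abort(sprintf(
        "window (%g ns) exceeds the trajectory span (%g ns)",
        window, span_ns
      ))
    }
    n_keep <- as.integer(floor(window * 1000 / stride))
    if (n_keep < 1) abort("sampling window selects no frames")
    idx <- tail(idx, n_keep)
  }
  if (length(idx) == 0) abort("empty frame sample")
  idx
}
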