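# run code with a private, restored RNG state so generators are seeded
# without disturbing the caller's random stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.aa3 <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

unit3 <- function(v) v / sqrt(sum(v^2))

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

# natural-extension placement: position D given A-B-C, the C-D bond length,
# the B-C-D angle and the A-B-C-D dihedral (degrees)
place_atom <- function(A, B, C, length, angle, dihedral) {
  th <- angle * pi / 180
  chi <- dihedral * pi / 180
  bc <- unit3(C - B)
  n <- unit3(cross3(B - A, bc))
  m <- cbind(bc, cross3(n, bc), n)
  d_local <- length * c(-cos(th), sin(th) * cos(chi), sin(th) * sin(chi))
  C + as.vector(m %*% d_local)
}

#' Measure a dihedral angle
#'
#' @param a,b,c,d Length-3 coordinate vectors.
#' @return Signed dihedral in degrees, in (-180, 180].
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * unit3(b2))
  atan2(y, x) * 180 / pi
}

# canonical backbone geometry (lengths A, angles deg)
.helix_geom <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8
)

#' Build an ideal alpha-helical backbone
#'
#' Constructs N/CA/C/O backbone coordinates for a polypeptide in the ideal
#' alpha-helix conformation (phi = -57, psi = -47, omega = 180 degrees,
#' canonical bond lengths and angles), mimicking the helical segments of an
#' EF-hand protein. The geometry places the i -> i+4 carbonyl O to amide N
#' pairs at hydrogen-bonding distance.
#'
#' @param sequence Character vector of 3-letter residue names (length >= 4),
#'   or a single integer n for a poly-alanine of n residues.
#' @param phi,psi Backbone dihedrals, degrees.
#' @param chain Chain identifier.
#' @return A structure tibble with 4 atoms (N, CA, C, O) per residue.
#' @export
build_helix <- function(sequence, phi = -57, psi = -47, chain = "A") {
  if (is.numeric(sequence) && length(sequence) == 1) {
    sequence <- rep("ALA", sequence)
  }
  sequence <- toupper(sequence)
  if (length(sequence) < 4) abort("a helix needs at least 4 residues")
  unknown <- setdiff(sequence, .aa3)
  if (length(unknown)) {
    abort(paste0("unknown residue name(s): ", paste(unknown, collapse = ", ")))
  }
  g <- .helix_geom
  n_res <- length(sequence)
  N <- CA <- C <- O <- matrix(NA_real_, n_res, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  th <- g$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(th), sin(th), 0)
  for (i in seq(2, n_res)) {
    N[i, ] <- place_atom(
      N[i - 1, ], CA[i - 1, ], C[i - 1, ],
      g$b_c_n, g$a_ca_c_n, psi
    )
    CA[i, ] <- place_atom(
      CA[i - 1, ], C[i - 1, ], N[i, ],
      g$b_n_ca, g$a_c_n_ca, 180 # trans peptide bond
    )
    C[i, ] <- place_atom(
      C[i - 1, ], N[i, ], CA[i, ],
      g$b_ca_c, g$a_n_ca_c, phi
    )
  }
  for (i in seq_len(n_res)) {
    # carbonyl O anti to the next amide N (dihedral psi + 180)
    O[i, ] <- place_atom(
      N[i, ], CA[i, ], C[i, ],
      g$b_c_o, g$a_ca_c_o, psi + 180
    )
  }
  atoms <- lapply(seq_len(n_res), function(i) {
    tibble(
      name = c("N", "CA", "C", "O"),
      resname = sequence[i],
      resid = i,
      x = c(N[i, 1], CA[i, 1], C[i, 1], O[i, 1]),
      y = c(N[i, 2], CA[i, 2], C[i, 2], O[i, 2]),
      z = c(N[i, 3], CA[i, 3], C[i, 3], O[i, 3])
    )
  })
  df <- bind_rows(atoms)
  df$serial <- seq_len(nrow(df))
  df$chain <- chain
  df$element <- c("N", "C", "C", "O")[match(df$name, c("N", "CA", "C", "O"))]
  df$mass <- element_mass(df$element)
  new_structure(
    df[, c(
      "serial", "name", "resname", "resid", "chain", "element",
      "mass", "x", "y", "z"
    )],
    label = sprintf("ideal helix (%d residues)", n_res)
  )
}

#' Plant a charged pseudo-atom pair (synthetic salt bridge)
#'
#' Adds one charged pseudo-atom to each of two residues, placed on an
#' outward ray clear of the backbone and separated by exactly the requested
#' distance, and emits a matching nonbonded parameter table in which every
#' backbone atom is neutral with a small dispersion well. At contact
#' separation (~3 A) and unit charges the pair energy is dominated by the
#' Coulomb term and falls deep below the -30 kcal/mol salt-bridge
#' threshold, giving the energy pipeline a known ground truth.
#'
#' @param structure A structure tibble (e.g. from [build_helix()]).
#' @param res_i,res_j Distinct residue ids receiving the pseudo-atoms
#'   (atom names `QP` on `res_i`, `QN` on `res_j`).
#' @param distance Pseudo-atom separation, Angstrom.
#' @param charges Length-2 charges (e) for the two pseudo-atoms.
#' @param epsilon,rmin_half LJ parameters applied to every atom.
#' @return List with `structure` (augmented) and `params` (tibble ready
#'   for [residue_pair_energy()] / round-trippable via [write_params()]).
#' @export
plant_salt_bridge <- function(structure, res_i, res_j, distance = 3.0,
                              charges = c(1, -1), epsilon = 0.05,
                              rmin_half = 2.0) {
  if (res_i == res_j) abort("salt-bridge residues must be distinct")
  for (r in c(res_i, res_j)) {
    if (!r %in% structure$resid) abort(sprintf("residue %d not in structure", r))
  }
  ca_all <- coords(structure)[structure$name == "CA", , drop = FALSE]
  centroid <- colMeans(ca_all)
  ca_i <- as.numeric(coords(structure)[
    which(structure$resid == res_i & structure$name == "CA")[1],
  ])
  # outward direction perpendicular to the molecule's principal axis, so
  # the pseudo-atoms sit clear of the backbone even for terminal residues
  axis <- svd(sweep(ca_all, 2, centroid))$v[, 1]
  v_raw <- (ca_i - centroid) - sum((ca_i - centroid) * axis) * axis
  if (sqrt(sum(v_raw^2)) < 1e-6) v_raw <- cross3(axis, c(1, 0, 0))
  v <- unit3(v_raw)
  qp <- ca_i + 5.0 * v
  qn <- qp + distance * v
  add <- tibble(
    serial = max(structure$serial) + 1:2,
    name = c("QP", "QN"),
    resname = structure$resname[match(c(res_i, res_j), structure$resid)],
    resid = c(res_i, res_j),
    chain = structure$chain[1],
    element = "X",
    mass = element_mass("X"),
    x = c(qp[1], qn[1]), y = c(qp[2], qn[2]), z = c(qp[3], qn[3])
  )
  aug <- bind_rows(structure, add)
  aug <- arrange(aug, .data$resid, .data$serial)
  aug$serial <- seq_len(nrow(aug))
  aug <- new_structure(aug, label = paste0(
    attr(structure, "label"), " + planted bridge"
  ))
  base_types <- distinct(tibble(
    residue = structure$resname, atom = structure$name
  ))
  params <- bind_rows(
    mutate(base_types, charge = 0, epsilon = epsilon, rmin_half = rmin_half),
    tibble(
      residue = add$resname, atom = add$name, charge = charges,
      epsilon = epsilon, rmin_half = rmin_half
    )
  )
  params <- distinct(validate_params(params))
  list(structure = aug, params = params, planted = c(res_i, res_j))
}

#' Generate a seeded fluctuation trajectory around a base structure
#'
#' Frames are the base coordinates plus independent isotropic Gaussian
#' displacements of the stated per-axis amplitude, reproducible bitwise for
#' a fixed seed (Mersenne-Twister). Optionally a named segment is rigidly
#' drifted by a linear ramp over the frames, emulating the docking-style
#' centre-of-mass motion of a mobile terminal tail against a rigid core.
#'
#' @param base A structure tibble.
#' @param n_frames Number of frames.
#' @param dt Frame interval, ps.
#' @param amplitude Per-axis Gaussian displacement amplitude, Angstrom.
#' @param seed Integer RNG seed.
#' @param drift_resids Residue ids to drift rigidly (optional).
#' @param drift_vector Length-3 total displacement (A) reached at the last
#'   frame by the drifting residues.
#' @return An `md_trajectory`.
#' @export
make_trajectory <- function(base, n_frames = 20, dt = 50, amplitude = 0.15,
                            seed = 1, drift_resids = NULL,
                            drift_vector = c(0, 0, 5)) {
  stopifnot(n_frames >= 1, amplitude >= 0)
  x0 <- coords(base)
  n_atoms <- nrow(x0)
  drift_idx <- if (!is.null(drift_resids)) {
    which(base$resid %in% drift_resids)
  } else {
    integer(0)
  }
  frames <- with_seed(seed, {
    lapply(seq_len(n_frames), function(f) {
      xf <- x0 + matrix(rnorm(n_atoms * 3, sd = amplitude), n_atoms, 3)
      if (length(drift_idx) && n_frames > 1) {
        frac <- (f - 1) / (n_frames - 1)
        xf[drift_idx, ] <- xf[drift_idx, ] +
          matrix(frac * drift_vector, length(drift_idx), 3, byrow = TRUE)
      }
      xf
    })
  })
  new_trajectory(base, frames, dt)
}

#' Generate a restraint set with a planted violation fraction
#'
#' Samples `n` residue pairs of the structure (single-atom proton-selector
#' groups on the chosen atom name) and assigns upper bounds from the actual
#' effective distances so that the violation status of every restraint is
#' known by construction: satisfied restraints get `upper = r + 1.0` A of
#' slack, violated ones get `upper = r - depth - 0.6` A, so on the static
#' structure each planted violation has `V = depth + 0.6` exactly and the
#' violated count is `round(n * violated_fraction)` deterministically.
#'
#' @param structure A structure tibble.
#' @param n Number of restraints.
#' @param violated_fraction Fraction in `[0, 1]` planted as violated.
#' @param depth Violation depth parameter, Angstrom.
#' @param seed Integer RNG seed.
#' @param atom Atom name used for the selector groups (default `"CA"`).
#' @param max_distance Largest pair distance eligible, Angstrom.
#' @return Restraint tibble with attribute `planted_violated` (logical).
#' @export
make_restraints <- function(structure, n, violated_fraction = 0,
                            depth = 0.3, seed = 1, atom = "CA",
                            max_distance = 15) {
  stopifnot(violated_fraction >= 0, violated_fraction <= 1, depth >= 0)
  sel <- structure[structure$name == atom, ]
  if (nrow(sel) < 2) abort("structure needs at least two residues")
  xyz <- cbind(sel$x, sel$y, sel$z)
  d <- as.matrix(stats::dist(xyz))
  cand <- which(upper.tri(d) & d > depth + 0.7 & d <= max_distance,
    arr.ind = TRUE
  )
  if (nrow(cand) < n) {
    abort(sprintf(
      "only %d eligible residue pairs for %d restraints", nrow(cand), n
    ))
  }
  n_viol <- round(n * violated_fraction)
  pick <- with_seed(seed, {
    rows <- sample(nrow(cand), n)
    list(rows = rows, viol = sample(n, n_viol))
  })
  ci <- cand[pick$rows, 1]
  cj <- cand[pick$rows, 2]
  r <- d[cbind(ci, cj)]
  violated <- seq_len(n) %in% pick$viol
  upper <- ifelse(violated, r - depth - 0.6, r + 1.0)
  out <- new_restraints(
    res_i = sel$resid[ci],
    atoms_i = as.list(rep(atom, n)),
    res_j = sel$resid[cj],
    atoms_j = as.list(rep(atom, n)),
    upper = upper
  )
  attr(out, "planted_violated") <- violated
  out
}

#' Ready-made synthetic study presets
#'
#' Bundles the generator calls into the three fixtures used throughout the
#' package's own validation: `"bridge"` (an ideal helix with one planted
#' charged pair at contact distance, plus a fluctuating trajectory and
#' parameter table), `"noe"` (a helix with a 200-restraint list carrying
#' 20% planted violations of depth 0.3 A, static and fluctuating), and
#' `"twostate"` (a trajectory split between two conformers ~5 A apart with
#' ~0.4 A within-state spread, for clustering).
#'
#' @param preset One of `"bridge"`, `"noe"`, `"twostate"`.
#' @param seed Integer RNG seed driving all randomness in the preset.
#' @return A list of fixture objects with a `truth` element describing the
#'   planted ground truth.
#' @export
synth_preset <- function(preset = c("bridge", "noe", "twostate"), seed = 1) {
  preset <- match.arg(preset)
  if (preset == "bridge") {
    helix <- build_helix(24)
    planted <- plant_salt_bridge(helix, res_i = 4, res_j = 20, distance = 3.0)
    traj <- make_trajectory(planted$structure,
      n_frames = 10, dt = 50,
      amplitude = 0.15, seed = seed
    )
    list(
      structure = planted$structure, params = planted$params, traj = traj,
      truth = list(bridge = c(4L, 20L))
    )
  } else if (preset == "noe") {
    helix <- build_helix(60)
    restraints <- make_restraints(helix,
      n = 200, violated_fraction = 0.2,
      depth = 0.3, seed = seed
    )
    traj <- make_trajectory(helix,
      n_frames = 20, dt = 50, amplitude = 0.15,
      seed = seed + 1
    )
    list(
      structure = helix, restraints = restraints, traj = traj,
      truth = list(
        violated = attr(restraints, "planted_violated"),
        fraction_satisfied = 1 - mean(attr(restraints, "planted_violated")),
        violation_depth = 0.3 + 0.6
      )
    )
  } else {
    helix <- build_helix(30)
    tail_res <- 21:30
    conf_b <- helix
    idx <- which(conf_b$resid %in% tail_res)
    shifted <- coords(conf_b)
    shifted[idx, ] <- sweep(shifted[idx, , drop = FALSE], 2, c(9, 0, 0), `+`)
    conf_b <- set_coords(conf_b, shifted)
    traj_a <- make_trajectory(helix,
      n_frames = 15, dt = 50, amplitude = 0.15,
      seed = seed
    )
    traj_b <- make_trajectory(conf_b,
      n_frames = 15, dt = 50,
      amplitude = 0.15, seed = seed + 1
    )
    traj <- new_trajectory(helix, c(traj_a$frames, traj_b$frames), 50)
    list(
      traj = traj,
      truth = list(blocks = rep(1:2, each = 15))
    )
  }
}
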