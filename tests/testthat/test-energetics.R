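two_atom_params <- function(q1, q2, eps = 0, rmin = 2) {
  tibble::tibble(
    residue = c("AAA", "BBB"), atom = c("X1", "X2"),
    charge = c(q1, q2), epsilon = eps, rmin_half = rmin
  )
}

test_that("atom pair energies match the closed forms", {
  p <- two_atom_params(1, -1, eps = 0)
  # pure Coulomb at 5 A inside the switching region
  expect_equal(
    atom_pair_energy(p, c("AAA", "X1"), c("BBB", "X2"), 5),
    -332.0636 / 5,
    tolerance = 1e-9
  )
  # beyond the outer cutoff everything vanishes
  expect_equal(atom_pair_energy(p, c("AAA", "X1"), c("BBB", "X2"), 12.5), 0)
  # neutral LJ pair at its minimum distance gives -eps
  plj <- two_atom_params(0, 0, eps = 0.1, rmin = 2)
  expect_equal(
    atom_pair_energy(plj, c("AAA", "X1"), c("BBB", "X2"), 4),
    -0.1,
    tolerance = 1e-12
  )
  expect_error(
    atom_pair_energy(p, c("AAA", "X9"), c("BBB", "X2"), 5),
    "no nonbonded parameters"
  )
  expect_error(atom_pair_energy(p, c("AAA", "X1"), c("BBB", "X2"), 0), "positive")
})

test_that("the switching function is continuous at both switching radii", {
  eps <- 1e-7
  expect_equal(switching_function(10 - eps), switching_function(10 + eps),
    tolerance = 1e-9
  )
  expect_equal(switching_function(12 - eps), switching_function(12 + eps),
    tolerance = 1e-9
  )
  set.seed(8)
  for (k in 1:20) {
    p <- two_atom_params(runif(1, -1, 1), runif(1, -1, 1),
      eps = runif(1, 0, 0.2), rmin = runif(1, 1.5, 2.5)
    )
    e <- function(r) atom_pair_energy(p, c("AAA", "X1"), c("BBB", "X2"), r)
    expect_lt(abs(e(10 - 1e-7) - e(10 + 1e-7)), 1e-6)
    expect_lt(abs(e(12 - 1e-7) - e(12 + 1e-7)), 1e-6)
  }
  # monotone taper inside the switching region
  s <- switching_function(seq(10, 12, by = 0.05))
  expect_true(all(diff(s) <= 0))
})

test_that("residue pair energies are symmetric and vanish beyond the cutoff", {
  b <- synth_preset("bridge", seed = 2)
  s <- b$structure
  e_ij <- residue_pair_energy(s, b$params, 4, 20)
  e_ji <- residue_pair_energy(s, b$params, 20, 4)
  expect_equal(e_ij, e_ji, tolerance = 1e-12)
  expect_lt(e_ij, -30) # the planted contact pair is ionic-class
  # distant residue pair: every atom beyond 12 A -> exactly zero
  h <- build_helix(30)
  prm <- uniform_params(h)
  expect_equal(residue_pair_energy(h, prm, 1, 30), 0)
  expect_error(residue_pair_energy(s, b$params, 4, 4), "distinct")
})

test_that("a 13 A pseudo-atom pair on distant residues has zero energy", {
  h <- build_helix(30)
  pb <- plant_salt_bridge(h, res_i = 4, res_j = 26, distance = 13)
  expect_equal(residue_pair_energy(pb$structure, pb$params, 4, 26), 0)
})

test_that("residue pair energy equals an independent naive double loop", {
  b <- synth_preset("bridge", seed = 13)
  traj <- make_trajectory(b$structure,
    n_frames = 50, dt = 50,
    amplitude = 0.15, seed = 99
  )
  set.seed(21)
  res_ids <- unique(b$structure$resid)
  max_diff <- 0
  for (f in seq_len(n_frames(traj))) {
    s <- frame_structure(traj, f)
    pair <- sample(res_ids, 2)
    got <- residue_pair_energy(s, b$params, pair[1], pair[2])
    want <- naive_pair_energy(s, b$params, pair[1], pair[2])
    max_diff <- max(max_diff, abs(got - want))
  }
  # and the planted pair explicitly, where the energy is large
  s1 <- frame_structure(traj, 1)
  max_diff <- max(max_diff, abs(
    residue_pair_energy(s1, b$params, 4, 20) -
      naive_pair_energy(s1, b$params, 4, 20)
  ))
  expect_lt(max_diff, 1e-9)
})

test_that("bonded-neighbour exclusions remove 1-2/1-3/1-4 pairs across the peptide bond", {
  h <- build_helix(6)
  prm <- uniform_params(h, charge = 0.3) # charged so exclusions matter
  with_excl <- residue_pair_energy(h, prm, 3, 4)
  without <- residue_pair_energy(h, prm, 3, 4, exclude_bonded = 0)
  # the C(i)-N(i+1) bonded pair alone carries a huge Coulomb term
  expect_gt(abs(without - with_excl), 10)
  expect_equal(without, naive_pair_energy(h, prm, 3, 4, exclude_bonded = 0),
    tolerance = 1e-9
  )
})

test_that("the time-averaged map equals the mean of single-frame maps", {
  b <- synth_preset("bridge", seed = 4)
  traj <- make_trajectory(b$structure,
    n_frames = 10, dt = 50,
    amplitude = 0.2, seed = 17
  )
  iem <- compute_iem(traj, b$params, stride = 50, window = 0.5)
  ids <- iem$residue_ids
  bonds <- detect_bonds(traj$topology) # shared fixed bond topology
  oracle <- matrix(0, length(ids), length(ids))
  for (f in 1:10) {
    s <- frame_structure(traj, f)
    for (a in seq_along(ids)) {
      for (bb in seq_along(ids)) {
        if (a < bb) {
          oracle[a, bb] <- oracle[a, bb] +
            residue_pair_energy(s, b$params, ids[a], ids[bb], bonds = bonds)
        }
      }
    }
  }
  oracle <- (oracle + t(oracle)) / 10
  expect_lt(max(abs(iem$values - oracle)), 1e-9)
  expect_equal(iem$values, t(iem$values))
  expect_equal(diag(iem$values), setNames(rep(0, length(ids)), ids))
})

test_that("a trajectory of identical frames gives the single-frame map", {
  b <- synth_preset("bridge", seed = 5)
  traj <- make_trajectory(b$structure,
    n_frames = 6, dt = 50, amplitude = 0,
    seed = 1
  )
  iem <- compute_iem(traj, b$params, stride = 50, window = 0.3)
  e <- residue_pair_energy(b$structure, b$params, 4, 20)
  expect_equal(iem$values["4", "20"], e, tolerance = 1e-9)
})

test_that("default sampling uses all frames of a 50 ps / 100 ns trajectory", {
  h <- build_helix(4)
  traj <- make_trajectory(h, n_frames = 2000, dt = 50, amplitude = 0, seed = 1)
  idx <- ncstraj:::sample_frames(traj, stride = 50, window = 100)
  expect_equal(length(idx), 2000)
  expect_equal(idx, 1:2000)
  # a 50 ns window takes the last 1000 frames
  idx2 <- ncstraj:::sample_frames(traj, stride = 50, window = 50)
  expect_equal(idx2, 1001:2000)
  # stride 100 ps halves the sample, keeping the final frame
  idx3 <- ncstraj:::sample_frames(traj, stride = 100, window = 100)
  expect_equal(length(idx3), 1000)
  expect_equal(max(idx3), 2000)
  expect_error(ncstraj:::sample_frames(traj, stride = 30), "multiple")
  expect_error(ncstraj:::sample_frames(traj, stride = 50, window = 150), "span")
})

test_that("excluded residues (ions) are absent from the map", {
  b <- synth_preset("bridge", seed = 6)
  traj <- make_trajectory(b$structure,
    n_frames = 3, dt = 50, amplitude = 0,
    seed = 1
  )
  iem <- compute_iem(traj, b$params,
    stride = 50, window = 0.15,
    exclude_ids = c(4, 20)
  )
  expect_false(any(c(4, 20) %in% iem$residue_ids))
  expect_equal(nrow(iem$values), 22)
})

test_that("energy classification bins follow the published boundaries", {
  e <- c(-120, -35, -30, -20, -15, -10, -2, -1, 0, 5)
  got <- as.character(classify_energy(e))
  expect_equal(got, c(
    "ionic", "ionic", "ionic", "strong_polar", "strong_polar",
    "hbond_like", "hbond_like", "weak", "weak", "repulsive"
  ))
})

test_that("salt-bridge filtering is strict and conservation requires both maps", {
  mk_map <- function(entries) {
    ids <- sort(unique(c(entries$i, entries$j)))
    v <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    for (k in seq_len(nrow(entries))) {
      a <- match(entries$i[k], ids)
      b <- match(entries$j[k], ids)
      v[a, b] <- v[b, a] <- entries$e[k]
    }
    structure(
      list(
        residue_ids = ids, residue_names = rep("ALA", length(ids)),
        values = v, stride = 50, window = 100, cutoff = 12, n_frames = 1
      ),
      class = "energy_map"
    )
  }
  map_a <- mk_map(data.frame(i = c(1, 3, 5), j = c(2, 4, 6), e = c(-35, -20, 5)))
  br <- filter_map(map_a, -30)
  expect_equal(nrow(br), 1)
  expect_equal(c(br$res_i, br$res_j), c(1, 2))
  # boundary: -30 exactly does not pass a strict -30 threshold
  map_b <- mk_map(data.frame(i = c(1, 3), j = c(2, 4), e = c(-31, -30)))
  expect_equal(nrow(filter_map(map_b, -30)), 1)
  cons <- conserved_bridges(map_a, map_b, -30)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$energy_a, -35)
  expect_equal(cons$energy_b, -31)
  map_c <- mk_map(data.frame(i = 1, j = 2, e = -29))
  expect_equal(nrow(conserved_bridges(map_a, map_c, -30)), 0)
  expect_error(filter_map(map_a, 5), "negative")
})

test_that("planted-bridge recovery: the filtered map contains exactly the planted pair", {
  b <- synth_preset("bridge", seed = 31)
  iem <- compute_iem(b$traj, b$params, stride = 50, window = 0.5)
  br <- filter_map(iem, -30)
  expect_equal(nrow(br), 1)
  expect_equal(c(br$res_i, br$res_j), c(4, 20))
})

test_that("uniform dilution beyond the cutoff drives every entry to zero", {
  b <- synth_preset("bridge", seed = 12)
  s <- b$structure
  # scale all coordinates outward about each residue centroid's global frame
  big <- ncstraj:::set_coords(s, coords(s) * 10)
  ids <- unique(s$resid)
  pairs <- utils::combn(ids, 2)
  e <- vapply(seq_len(ncol(pairs)), function(k) {
    residue_pair_energy(big, b$params, pairs[1, k], pairs[2, k])
  }, numeric(1))
  expect_true(all(e == 0))
})
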