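rigid_move <- function(s, angle = pi / 3, axis = c(0, 0, 1), shift = c(5, -2, 1)) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  ncstraj:::set_coords(s, coords(s) %*% t(R) +
    matrix(shift, nrow(s), 3, byrow = TRUE))
}

test_that("superposition recovers rigid transforms exactly", {
  h <- build_helix(10)
  expect_equal(superpose(h, h)$rmsd, 0, tolerance = 1e-12)
  moved <- rigid_move(h, angle = pi / 2, shift = c(5, 0, 0))
  sp <- superpose(moved, h)
  expect_lt(sp$rmsd, 1e-9)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  # the recovered transform maps the moved coordinates back onto the original
  back <- ncstraj:::apply_transform(coords(moved), sp)
  expect_lt(max(abs(back - coords(h))), 1e-9)
})

test_that("superposition rejects degenerate fits", {
  line <- as_structure(tibble::tibble(
    serial = 1:3, name = c("N", "CA", "C"), resname = "ALA", resid = 1L,
    chain = "A", element = c("N", "C", "C"), mass = 12,
    x = c(0, 1, 2), y = 0, z = 0
  ), "line")
  expect_error(superpose(line, line), "collinear")
  h <- build_helix(5)
  expect_error(superpose(h, h, 1:2, 1:2), "at least 3")
})

test_that("noisy-cloud superposition matches an independent rotation-search oracle", {
  set.seed(11)
  for (rep in 1:5) {
    P <- matrix(rnorm(15, sd = 3), 5, 3)
    Q <- P + matrix(rnorm(15, sd = 0.3), 5, 3)
    a <- as_structure(tibble::tibble(
      serial = 1:5, name = paste0("C", 1:5), resname = "ALA", resid = 1L,
      chain = "A", element = "C", mass = 12,
      x = P[, 1], y = P[, 2], z = P[, 3]
    ), "a")
    b <- ncstraj:::set_coords(a, Q)
    got <- superpose(a, b)$rmsd
    # oracle: numeric minimisation over Euler angles of centred clouds,
    # multi-start so it cannot ride the same algebra as Kabsch
    Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
    obj <- function(ang) {
      cz <- cos(ang[1]); sz <- sin(ang[1])
      cy <- cos(ang[2]); sy <- sin(ang[2])
      cx <- cos(ang[3]); sx <- sin(ang[3])
      Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
      Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
      Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
      sqrt(mean(rowSums((Pc %*% t(Rz %*% Ry %*% Rx) - Qc)^2)))
    }
    best <- min(vapply(1:20, function(k) {
      stats::optim(runif(3, -pi, pi), obj,
        control = list(maxit = 2000, reltol = 1e-12)
      )$value
    }, numeric(1)))
    expect_equal(got, best, tolerance = 0.01)
  }
})

test_that("Kabsch agrees with the quaternion oracle on random instances", {
  set.seed(42)
  for (k in 1:100) {
    P <- matrix(rnorm(30, sd = 4), 10, 3)
    Q <- matrix(rnorm(30, sd = 4), 10, 3)
    expect_lt(abs(ncstraj:::kabsch(P, Q)$rmsd - horn_rmsd(P, Q)), 1e-6)
  }
})

test_that("RMSD is symmetric and invariant to rigid motions of either input", {
  h <- build_helix(12)
  set.seed(3)
  g <- ncstraj:::set_coords(h, coords(h) + matrix(rnorm(nrow(h) * 3, sd = 0.8),
    nrow(h), 3
  ))
  ab <- superpose(h, g)$rmsd
  ba <- superpose(g, h)$rmsd
  expect_equal(ab, ba, tolerance = 1e-9)
  gm <- rigid_move(g, angle = 1.1, axis = c(1, 2, 0.5), shift = c(-3, 7, 2))
  expect_equal(superpose(h, gm)$rmsd, ab, tolerance = 1e-6)
  expect_equal(rmsd_partial(h, gm, fit = "ALL", atom_class = "all"),
    rmsd_partial(h, g, fit = "ALL", atom_class = "all"),
    tolerance = 1e-6
  )
})

test_that("partial RMSD measures without refitting and reduces to superpose when fit == measure", {
  h <- build_helix(20)
  set.seed(7)
  # perturb the tail much more than the core
  xyz <- coords(h)
  tail_idx <- which(h$resid >= 15)
  xyz[tail_idx, ] <- xyz[tail_idx, ] + matrix(rnorm(length(tail_idx) * 3, sd = 2),
    length(tail_idx), 3
  )
  g <- ncstraj:::set_coords(h, xyz)
  tab <- segment_table(core = c(1, 14), tail = c(15, 20), all = c(1, 20))
  r_core <- rmsd_partial(g, h, fit = "core", table = tab)
  r_tail <- rmsd_partial(g, h, fit = "core", measure = "tail", table = tab)
  expect_gt(r_tail, r_core) # the mobile tail stands out after a core fit
  # fit == measure consistency with plain superposition
  sel <- select_atoms(g, "core", table = tab)
  expect_equal(
    rmsd_partial(g, h, fit = "core", measure = "core", table = tab),
    superpose(g, h, sel, sel)$rmsd,
    tolerance = 1e-12
  )
})

test_that("partial RMSD pairs atoms by identity, tolerating different atom content", {
  h <- build_helix(10)
  g <- h[h$name != "O", ] # reference lacking carbonyl oxygens
  g <- as_structure(g, "no-O")
  tab <- segment_table(all = c(1, 10))
  r <- rmsd_partial(h, g, fit = "all", table = tab)
  expect_equal(r, 0, tolerance = 1e-12) # common N,CA,C atoms align exactly
})

test_that("rmsd_series is per-frame independent and tracks fluctuation amplitude", {
  h <- build_helix(10)
  tab <- segment_table(all = c(1, 10))
  const <- make_trajectory(h, n_frames = 5, dt = 50, amplitude = 0, seed = 1)
  s0 <- rmsd_series(const, fit = "all", table = tab)
  expect_equal(s0$value, rep(0, 5), tolerance = 1e-9)
  means <- vapply(c(0.1, 0.5, 1.0), function(a) {
    tr <- make_trajectory(h, n_frames = 12, dt = 50, amplitude = a, seed = 9)
    mean(rmsd_series(tr, fit = "all", table = tab)$value)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  # frame order reversal reverses the series values
  tr <- make_trajectory(h, n_frames = 8, dt = 50, amplitude = 0.4, seed = 5)
  rev_tr <- as_trajectory(tr$topology, rev(tr$frames), tr$dt)
  expect_equal(
    rmsd_series(rev_tr, fit = "all", table = tab)$value,
    rev(rmsd_series(tr, fit = "all", table = tab)$value),
    tolerance = 1e-12
  )
})

test_that("smoothing is a truncated-window moving average", {
  h <- build_helix(5)
  tr <- make_trajectory(h, n_frames = 9, dt = 1, amplitude = 0, seed = 1)
  s <- rmsd_series(tr, fit = "ALL")
  s$value <- rep(2.5, 9)
  expect_equal(smooth_series(s, 5)$value, rep(2.5, 9))
  s$value <- c(0, 0, 0, 0, 1, 1, 1, 1, 1) # unit step
  expect_equal(smooth_series(s, 1)$value, s$value)
  # direct convolution oracle with truncated edges
  oracle <- vapply(1:9, function(i) {
    mean(s$value[max(1, i - 1):min(9, i + 1)])
  }, numeric(1))
  expect_equal(smooth_series(s, 3)$value, oracle)
  expect_error(smooth_series(s, 4), "odd")
})

test_that("centres of mass follow masses and COM distances follow construction", {
  two <- as_structure(tibble::tibble(
    serial = 1:2, name = c("A1", "A2"), resname = "ALA", resid = 1:2,
    chain = "A", element = "C", mass = c(12, 12),
    x = c(0, 2), y = 0, z = 0
  ), "two")
  expect_equal(com(two), c(1, 0, 0))
  heavy <- two
  heavy$mass <- c(36, 12)
  expect_equal(com(heavy)[1], 0.5)
  expect_equal(com(heavy, mass_weighted = FALSE)[1], 1)
  expect_error(com(two, integer(0)), "empty")
})

test_that("a drifting terminal segment shifts the COM distance by the planted amount", {
  h <- build_helix(20)
  tab <- segment_table(core = c(1, 14), tail = c(15, 20))
  core_idx <- select_atoms(h, "core", atom_class = "all", table = tab)
  tail_idx <- select_atoms(h, "tail", atom_class = "all", table = tab)
  u <- com(h, tail_idx) - com(h, core_idx)
  u <- u / sqrt(sum(u^2))
  tr <- make_trajectory(h,
    n_frames = 10, dt = 50, amplitude = 0, seed = 1,
    drift_resids = 15:20, drift_vector = 5 * u
  )
  s <- com_distance_series(tr, "tail", "core", table = tab)
  expect_equal(s$value[10] - s$value[1], 5.0, tolerance = 0.1)
  # identical selections give a zero series
  z <- com_distance_series(tr, "tail", "tail", table = tab)
  expect_equal(z$value, rep(0, 10), tolerance = 1e-12)
})
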