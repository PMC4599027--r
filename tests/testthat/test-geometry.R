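# Superposition, RMSD/RMSF, hydrogen bonds, rings, distances

random_coords <- function(n, spread = 10) matrix(rnorm(n * 3, sd = spread), n, 3)

test_that("Kabsch superposition recovers rigid transforms exactly", {
  set.seed(1)
  x <- random_coords(6)
  expect_equal(kabsch_superpose(x, x)$rmsd, 0, tolerance = 1e-12)

  shifted <- sweep(x, 2, c(5, 0, 0), `+`)
  expect_equal(kabsch_superpose(x, shifted)$rmsd, 0, tolerance = 1e-12)

  for (i in 1:10) {
    tf <- random_rigid()
    moved <- apply_rigid(x, tf)
    fit <- kabsch_superpose(moved, x)
    expect_lt(fit$rmsd, 1e-9)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
    expect_equal(apply_transform(moved, fit), x, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("Kabsch RMSD is symmetric and refuses degenerate input", {
  set.seed(2)
  x <- random_coords(5); y <- x + matrix(rnorm(15, sd = 0.3), 5, 3)
  expect_equal(kabsch_superpose(x, y)$rmsd, kabsch_superpose(y, x)$rmsd,
               tolerance = 1e-12)
  expect_error(kabsch_superpose(x[1:2, ], y[1:2, ]), "at least 3")
  line <- cbind(1:4, 0, 0)
  expect_error(kabsch_superpose(line, line + 1), "collinear|degenerate")
})

test_that("Kabsch RMSD matches the exhaustive rotation-grid oracle", {
  # 4-point set with one point displaced 1 Angstrom along a known axis
  ref <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(0, 0, 3))
  mob <- ref; mob[4, ] <- mob[4, ] + c(1, 0, 0)
  got <- kabsch_superpose(mob, ref)$rmsd
  expect_equal(got, oracle_grid_rmsd(mob, ref), tolerance = 1e-3)

  set.seed(3)
  for (i in 1:3) {
    a <- random_coords(5, spread = 3)
    b <- a + matrix(rnorm(15, sd = 0.5), 5, 3)
    expect_equal(kabsch_superpose(a, b)$rmsd, oracle_grid_rmsd(a, b),
                 tolerance = 1e-3)
  }
})

test_that("superposition RMSD agrees with the bio3d reference fit", {
  set.seed(12)
  for (i in 1:5) {
    a <- random_coords(7, spread = 5)
    b <- a + matrix(rnorm(21, sd = 0.4), 7, 3)
    ours <- kabsch_superpose(a, b)$rmsd
    fitted <- bio3d::fit.xyz(fixed = as.vector(t(b)),
                             mobile = matrix(as.vector(t(a)), nrow = 1),
                             fixed.inds = 1:21, mobile.inds = 1:21)
    theirs <- bio3d::rmsd(as.vector(t(b)), fitted)
    expect_equal(ours, theirs, tolerance = 1e-3)
  }
})

# small helper: trajectory object straight from a topology + frame list
toy_traj <- function(atoms, frames) {
  topo <- structure(list(atoms = atoms, coords = frames[[1]]),
                    class = "structure")
  structure(list(topology = topo, frames = frames,
                 n_frames = length(frames)), class = "trajectory")
}

ca_atoms <- function(n) data.frame(
  serial = seq_len(n), atom = "CA", resname = "ALA", resno = seq_len(n),
  chain = "A", element = "C", stringsAsFactors = FALSE)

test_that("static trajectories give identically zero RMSD and RMSF", {
  set.seed(4)
  base <- random_coords(8)
  traj <- toy_traj(ca_atoms(8), replicate(5, base, simplify = FALSE))
  expect_equal(rmsd_series(traj), rep(0, 5), tolerance = 1e-12)
  expect_equal(rmsf(traj)$rmsf, rep(0, 8), tolerance = 1e-12)

  # rigid-body motion of every frame is invisible after superposition
  frames <- lapply(1:6, function(k) apply_rigid(base, random_rigid()))
  traj2 <- toy_traj(ca_atoms(8), frames)
  expect_lt(max(rmsd_series(traj2)), 1e-9)
  expect_lt(max(rmsf(traj2)$rmsf), 1e-9)
})

test_that("per-frame RMSD of a displaced atom matches the grid oracle", {
  set.seed(5)
  base <- random_coords(6, spread = 5)
  amp <- sin(seq(0, pi, length.out = 6))
  frames <- lapply(seq_along(amp), function(k) {
    fr <- base; fr[2, ] <- fr[2, ] + c(0, 0, amp[k]); fr
  })
  traj <- toy_traj(ca_atoms(6), frames)
  got <- rmsd_series(traj, reference = 1L, selection = 1:6)
  want <- vapply(frames, function(fr) oracle_grid_rmsd(fr, base), numeric(1))
  expect_equal(got, want, tolerance = 1e-3)
  expect_equal(got[1], 0, tolerance = 1e-12)
})

test_that("RMSF of an isotropically jittered atom approaches sigma*sqrt(3)", {
  set.seed(6)
  n_atoms <- 12; n_frames <- 600; sigma <- 0.05
  base <- random_coords(n_atoms, spread = 8)
  frames <- lapply(seq_len(n_frames), function(k) {
    fr <- base
    fr[1, ] <- fr[1, ] + rnorm(3, sd = sigma)
    fr
  })
  res <- rmsf(toy_traj(ca_atoms(n_atoms), frames), selection = 1:n_atoms)
  expect_equal(res$rmsf[1], sigma * sqrt(3), tolerance = 0.1)
  expect_lt(max(res$rmsf[-1]), 0.02)
  expect_error(rmsf(toy_traj(ca_atoms(3), list(base[1:3, ]))), "2 frames")
})

hb_structure <- function(elements, xyz) {
  n <- length(elements)
  atoms <- data.frame(serial = seq_len(n),
                      atom = paste0(elements, seq_len(n)),
                      resname = "UNK", resno = seq_len(n), chain = "A",
                      element = elements, stringsAsFactors = FALSE)
  structure(list(atoms = atoms, coords = xyz), class = "structure")
}

test_that("hydrogen-bond detection applies both cutoffs", {
  # collinear N-H...O at 2.9 Angstrom: inside both cutoffs
  s <- hb_structure(c("N", "H", "O"),
                    rbind(c(0, 0, 0), c(1, 0, 0), c(2.9, 0, 0)))
  hb <- detect_hbonds(s)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$donor, 1); expect_equal(hb$acceptor, 3)

  # distance 3.2 Angstrom fails
  far <- hb_structure(c("N", "H", "O"),
                      rbind(c(0, 0, 0), c(1, 0, 0), c(3.2, 0, 0)))
  expect_equal(nrow(detect_hbonds(far)), 0)

  # deviation 35 deg at 2.8 Angstrom fails
  u <- c(cos(35 * pi / 180), sin(35 * pi / 180), 0)
  tt <- -u[1] + sqrt(u[1]^2 - 1 + 2.8^2)
  bent <- hb_structure(c("N", "H", "O"),
                       rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0) + tt * u))
  expect_equal(nrow(detect_hbonds(bent)), 0)

  # no hydrogens: empty result with warning
  expect_warning(res <- detect_hbonds(hb_structure(c("N", "O"),
                                                   rbind(c(0, 0, 0),
                                                         c(2.9, 0, 0)))),
                 "no hydrogens")
  expect_equal(nrow(res), 0)
})

test_that("detection equals the all-pairs brute-force oracle", {
  set.seed(7)
  for (i in 1:15) {
    n <- sample(10:30, 1)
    elements <- sample(c("N", "O", "C", "H"), n, replace = TRUE,
                       prob = c(0.25, 0.25, 0.2, 0.3))
    xyz <- random_coords(n, spread = 3)
    s <- hb_structure(elements, xyz)
    got <- suppressWarnings(detect_hbonds(s))
    want <- oracle_hbonds(elements, xyz)
    got_keys <- sort(paste(got$donor, got$hydrogen, got$acceptor))
    want_keys <- sort(paste(want[, 1], want[, 2], want[, 3]))
    expect_identical(got_keys, want_keys)
  }
})

test_that("occupancy tightens monotonically as cutoffs tighten", {
  rec <- trajectory_recipe(n_frames = 20,
                           hbond_schedule = rep(c(TRUE, FALSE), 10))
  traj <- gen_trajectory(rec)$trajectory
  don <- list(resno = 1, atom = "N"); acc <- list(resno = 2, atom = "O")
  loose <- as.numeric(hbond_occupancy(traj, don, acc,
                                      hbond_criteria(3.6, 50)))
  std <- as.numeric(hbond_occupancy(traj, don, acc))
  tight <- as.numeric(hbond_occupancy(traj, don, acc,
                                      hbond_criteria(2.0, 10)))
  expect_true(loose >= std && std >= tight)
  expect_equal(std, 50)
  expect_error(hbond_occupancy(traj, list(resno = 99), acc), "no atoms")
})

hexagon_xy <- function() {
  th <- (0:5) * pi / 3
  cbind(1.4 * cos(th), 1.4 * sin(th), 0)
}

test_that("ring geometry gives centroid and canonicalised normal", {
  hex <- sweep(hexagon_xy(), 2, c(2, -1, 3), `+`)
  g <- ring_geometry(hex)
  expect_equal(g$centroid, c(2, -1, 3))
  expect_equal(g$normal, c(0, 0, 1))

  # rotate 90 deg about x: normal in the y-axis, canonicalised to +y
  rot <- hexagon_xy() %*% t(matrix(c(1, 0, 0, 0, 0, 1, 0, -1, 0), 3, 3))
  g2 <- ring_geometry(rot)
  expect_equal(abs(g2$normal), c(0, 1, 0), tolerance = 1e-12)
  expect_gte(g2$normal[2], 0)

  # noisy planar ring recovers its normal within 1 degree
  set.seed(8)
  noisy <- hexagon_xy() + matrix(rnorm(18, sd = 0.01), 6, 3)
  g3 <- ring_geometry(noisy)
  ang <- acos(abs(sum(g3$normal * c(0, 0, 1)))) * 180 / pi
  expect_lt(ang, 1)

  expect_error(ring_geometry(cbind(1:4, 0, 0)), "collinear")
})

test_that("stacking metrics classify parallel and tilted ring pairs", {
  rec <- trajectory_recipe(n_frames = 10, ring_distance = rep(3.5, 10),
                           ring_angle = rep(0, 10))
  traj <- gen_trajectory(rec)$trajectory
  rep1 <- stacking_metrics(traj, list(resno = 101), list(resno = 901))
  expect_equal(rep1$verdict, "stacked")
  expect_equal(rep1$stacked_fraction, 1)
  expect_equal(rep1$mean_angle, 0, tolerance = 1e-6)
  expect_equal(rep1$mean_distance, 3.5, tolerance = 1e-9)

  # distant, strongly tilted rings: geometry incompatible with pi-stacking
  rec2 <- trajectory_recipe(n_frames = 10, ring_distance = rep(5.79, 10),
                            ring_angle = rep(52, 10))
  traj2 <- gen_trajectory(rec2)$trajectory
  rep2 <- stacking_metrics(traj2, list(resno = 101), list(resno = 901))
  expect_equal(rep2$verdict, "not_stacked")
  expect_equal(rep2$stacked_fraction, 0)
  expect_equal(rep2$mean_angle, 52, tolerance = 1e-6)
})

test_that("stacking angle is symmetric and rotation-invariant", {
  rec <- trajectory_recipe(n_frames = 4, ring_distance = rep(4, 4),
                           ring_angle = c(10, 20, 40, 70))
  traj <- gen_trajectory(rec)$trajectory
  a <- stacking_metrics(traj, list(resno = 101), list(resno = 901))
  b <- stacking_metrics(traj, list(resno = 901), list(resno = 101))
  expect_equal(a$angle, b$angle, tolerance = 1e-9)
  expect_equal(a$distance, b$distance, tolerance = 1e-9)

  set.seed(9)
  tf <- random_rigid()
  traj2 <- traj
  traj2$frames <- lapply(traj$frames, apply_rigid, tf = tf)
  c2 <- stacking_metrics(traj2, list(resno = 101), list(resno = 901))
  expect_equal(c2$angle, a$angle, tolerance = 1e-9)
  expect_equal(c2$distance, a$distance, tolerance = 1e-9)
})

test_that("distance statistics use plain Euclidean distances and population SD", {
  atoms <- ca_atoms(2)
  static <- toy_traj(atoms, replicate(5, rbind(c(0, 0, 0), c(4.3, 0, 0)),
                                      simplify = FALSE))
  ds <- distance_stats(static, 1, 2)
  expect_equal(ds$mean, 4.3); expect_equal(ds$sd, 0)

  two <- toy_traj(atoms, list(rbind(c(0, 0, 0), c(3, 0, 0)),
                              rbind(c(0, 0, 0), c(5, 0, 0))))
  ds2 <- distance_stats(two, 1, 2)
  expect_equal(ds2$mean, 4); expect_equal(ds2$sd, 1)

  set.seed(10)
  rec <- trajectory_recipe(n_frames = 2000,
                           pair_distance = list(mean = 7.7, sd = 0.4))
  g <- gen_trajectory(rec)
  ds3 <- distance_stats(g$trajectory, list(resno = 401), list(resno = 402))
  expect_equal(ds3$mean, g$truth$pair_mean_distance, tolerance = 1e-9)
  expect_equal(ds3$sd, g$truth$pair_sd_distance, tolerance = 1e-9)
  expect_equal(ds3$mean, 7.7, tolerance = 0.05)
  expect_equal(ds3$sd, 0.4, tolerance = 0.05)
})
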