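test_that("Kabsch superposition recovers exact rigid transforms", {
  set.seed(1)
  x <- matrix(rnorm(30), ncol = 3)
  sp <- kabsch_superpose(x, x)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-8)

  rot90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE)
  y <- x %*% t(rot90)
  sp2 <- kabsch_superpose(x, y)
  expect_lt(sp2$rmsd, 1e-8)
  expect_equal(det(sp2$rotation), 1, tolerance = 1e-8)
  expect_lt(max(abs(x %*% sp2$rotation +
                      matrix(sp2$translation, 10, 3, byrow = TRUE) - y)), 1e-8)
})

test_that("Kabsch RMSD matches an independent fit and a rotation search", {
  set.seed(2)
  x <- matrix(rnorm(30), ncol = 3)
  y <- x %*% t(random_rotation()) + matrix(rnorm(30, sd = 0.1), ncol = 3)
  ours <- kabsch_superpose(x, y)$rmsd
  # independent implementation oracle (bio3d reports 3 decimals)
  ref <- bio3d::rmsd(as.vector(t(y)), as.vector(t(x)), fit = TRUE)
  expect_lt(abs(ours - ref), 1e-3)
  # no sampled rotation does better (centered point sets)
  xc <- sweep(x, 2, colMeans(x)); yc <- sweep(y, 2, colMeans(y))
  set.seed(3)
  best <- min(vapply(1:20000, function(i) {
    sqrt(mean(rowSums((xc %*% random_rotation() - yc)^2)))
  }, 0))
  expect_lte(ours, best + 1e-9)
})

test_that("degenerate point sets are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "degenerate")
})

test_that("alignment collapses rigidly moved copies of one structure", {
  sys <- toy_system(n_res = 5, n_frames = 1, noise = 0)
  ref <- sys$model$xyz
  frames <- t(vapply(1:6, function(i) {
    set.seed(i)
    moved <- ref %*% random_rotation() +
      matrix(rnorm(3, sd = 5), nrow(ref), 3, byrow = TRUE)
    dimerdyn:::flatten_coords(moved)
  }, numeric(3 * nrow(ref))))
  traj <- trajectory_ensemble(sys$model, frames)
  al <- align_ensemble(traj, reference = "first_frame")
  expect_true(al$aligned)
  for (f in 2:6) expect_lt(max(abs(al$xyz[f, ] - al$xyz[1, ])), 1e-6)
  expect_error(align_ensemble(al), "already aligned")
})

test_that("iterative-mean alignment of two frames converges to the midpoint", {
  sys <- toy_system(n_res = 5, n_frames = 2, noise = 0.3, seed = 4)
  al <- align_ensemble(sys$traj, reference = "mean_iterative")
  idx <- select_atoms(sys$model, "calpha")
  f1 <- matrix(al$xyz[1, ], ncol = 3, byrow = TRUE)[idx, ]
  f2 <- matrix(al$xyz[2, ], ncol = 3, byrow = TRUE)[idx, ]
  mid <- (f1 + f2) / 2
  # the mean structure is the midpoint of the two aligned frames, and both
  # frames are optimally superposed on it (symmetric residual)
  r1 <- kabsch_superpose(f1, mid)$rmsd
  expect_equal(r1, kabsch_superpose(f2, mid)$rmsd, tolerance = 1e-6)
  expect_equal(sqrt(mean(rowSums((f1 - mid)^2))), r1, tolerance = 1e-4)
})

test_that("RMSD and RMSF vanish on a constant ensemble", {
  sys <- toy_system(n_res = 4, n_frames = 4, noise = 0, diss_sd = 0)
  al <- align_ensemble(sys$traj)
  expect_equal(rmsd_series(al)$rmsd, rep(0, 4), tolerance = 1e-10)
  expect_warning(
    one <- rmsf_profile(align_ensemble(
      trajectory_ensemble(sys$model, sys$traj$xyz[1, , drop = FALSE]))),
    "single-frame"
  )
  expect_equal(one$rmsf, rep(0, 8), tolerance = 1e-10)
})

test_that("RMSF matches the analytic two-point fluctuation", {
  # one CA oscillating +/-1 A along x, all else fixed
  sys <- toy_system(n_res = 4, n_frames = 2, noise = 0, diss_sd = 0,
                    atoms_per_residue = 1)
  xyz <- sys$traj$xyz
  target_col <- 3 * 2 - 2  # x of CA of residue A:2
  xyz[1, target_col] <- xyz[1, target_col] + 1
  xyz[2, target_col] <- xyz[2, target_col] - 1
  traj <- trajectory_ensemble(sys$model, xyz, aligned = TRUE)
  prof <- rmsf_profile(traj)
  expect_equal(prof$rmsf[prof$chain_id == "A" & prof$residue_index == 2], 1.0,
               tolerance = 1e-9)
  expect_equal(sum(prof$rmsf > 1e-9), 1)
})

test_that("RMSD is symmetric under frame exchange", {
  sys <- toy_system(n_res = 5, n_frames = 2, noise = 0.4, seed = 8)
  a <- frame_coords <- matrix(sys$traj$xyz[1, ], ncol = 3, byrow = TRUE)
  b <- matrix(sys$traj$xyz[2, ], ncol = 3, byrow = TRUE)
  expect_equal(kabsch_superpose(a, b)$rmsd, kabsch_superpose(b, a)$rmsd,
               tolerance = 1e-10)
})

test_that("chain-center distance sees a planted rigid separation and is
           invariant under global rigid motion", {
  sys <- toy_system(n_res = 6, n_frames = 10, noise = 0, diss_sd = 0)
  xyz <- sys$traj$xyz
  bidx <- which(sys$model$atoms$chain_id == "B")
  ycols <- 3 * bidx - 1
  xyz[6:10, ycols] <- xyz[6:10, ycols] + 3  # +3 A along the interface normal
  traj <- trajectory_ensemble(sys$model, xyz)
  d <- chain_center_distance(traj)$distance
  expect_equal(d[6:10] - d[1:5], rep(3, 5), tolerance = 1e-9)

  moved <- t(vapply(1:10, function(f) {
    set.seed(f)
    fr <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    dimerdyn:::flatten_coords(fr %*% random_rotation() +
                                matrix(rnorm(3, sd = 10), nrow(fr), 3,
                                       byrow = TRUE))
  }, numeric(ncol(xyz))))
  d2 <- chain_center_distance(trajectory_ensemble(sys$model, moved))$distance
  expect_equal(d, d2, tolerance = 1e-8)
})
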