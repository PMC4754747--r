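# build a mode_set directly from given unit mode vectors over n residues
fake_mode_set <- function(modes, n_res, chain = rep("A", n_res)) {
  structure(
    list(atom_indices = seq_len(n_res),
         residues = tibble::tibble(chain_id = chain,
                                   residue_index = seq_len(n_res)),
         mean_structure = matrix(0, n_res, 3),
         modes = modes,
         variances = rev(seq_len(ncol(modes)))),
    class = "mode_set"
  )
}

aligned_toy <- function(...) {
  sys <- toy_system(...)
  sys$aligned <- align_ensemble(sys$traj)
  sys
}

test_that("PCA recovers a single planted field and its variance", {
  spec0 <- synthetic_spec(n_residues_per_chain = 8, atoms_per_residue = 1,
                          n_frames = 1)
  model <- build_toy_dimer(spec0)
  field <- planted_wave_mode(model, wavelength = 6)
  sys <- aligned_toy(n_res = 8, n_frames = 1500, noise = 0, diss_sd = 0,
                     atoms_per_residue = 1,
                     modes = list(list(field = field, stddev = 2)))
  m <- pca_modes(sys$aligned)
  truth <- internal_component(
    field_on_atoms(model, sys$gen$fields[[2]], m$atom_indices),
    m$mean_structure
  )
  expect_gt(abs(sum(m$modes[, 1] * truth)), 0.999)
  expect_equal(m$variances[1], 4, tolerance = 0.4)
})

test_that("PCA rejects unaligned and degenerate input", {
  sys <- toy_system(n_res = 4, n_frames = 5, noise = 0.1)
  expect_error(pca_modes(sys$traj), "aligned")
  frozen <- toy_system(n_res = 4, n_frames = 5, noise = 0, diss_sd = 0)
  al <- trajectory_ensemble(frozen$model, frozen$traj$xyz, aligned = TRUE)
  expect_error(pca_modes(al), "degenerate")
})

test_that("two planted fields give variances in the planted 4:1 ratio", {
  spec0 <- synthetic_spec(n_residues_per_chain = 8, atoms_per_residue = 1,
                          n_frames = 1)
  model <- build_toy_dimer(spec0)
  f1 <- planted_wave_mode(model, wavelength = 6)
  f2 <- planted_wave_mode(model, wavelength = 3, axis = "x")
  sys <- aligned_toy(n_res = 8, n_frames = 5000, noise = 0, diss_sd = 0,
                     atoms_per_residue = 1,
                     modes = list(list(field = f1, stddev = 2),
                                  list(field = f2, stddev = 1)))
  m <- pca_modes(sys$aligned)
  expect_equal(m$variances[1] / m$variances[2], 4, tolerance = 0.4)
})

test_that("mode vectors are unit, orthogonal and sign-fixed", {
  sys <- aligned_toy(n_res = 6, n_frames = 100, noise = 0.1, seed = 13)
  m <- pca_modes(sys$aligned, k = 5)
  g <- crossprod(m$modes)
  expect_equal(g, diag(5), tolerance = 1e-8)
  for (j in 1:5) {
    v <- m$modes[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
  expect_true(all(diff(m$variances) <= 1e-12))
})

test_that("residue amplitudes are block norms with dimer-wide unit norm", {
  # localized mode: all weight on residue 2
  v <- rep(0, 12); v[4] <- 1
  ms <- fake_mode_set(matrix(v, ncol = 1), 4)
  amp <- residue_amplitudes(ms, 1)
  expect_equal(amp$amplitude, c(0, 1, 0, 0))
  expect_false(amp$defined[1])

  # random unit mode: amplitudes equal the direct 3-block norms
  set.seed(7)
  w <- dimerdyn:::unit(rnorm(15))
  ms2 <- fake_mode_set(matrix(w, ncol = 1), 5)
  amp2 <- residue_amplitudes(ms2, 1)
  oracle <- vapply(1:5, function(r) sqrt(sum(w[(3 * r - 2):(3 * r)]^2)), 0)
  expect_equal(amp2$amplitude, oracle, tolerance = 1e-12)
  expect_equal(sum(amp2$amplitude^2), 1, tolerance = 1e-9)
})

test_that("direction cosines match the dot-product oracle and flag
           undefined blocks", {
  set.seed(8)
  a <- dimerdyn:::unit(rnorm(9))
  b <- dimerdyn:::unit(rnorm(9))
  ms <- fake_mode_set(cbind(a, b), 3)
  cs <- direction_cosines(ms, 1, mode_b = 2)
  oracle <- vapply(1:3, function(r) {
    i <- (3 * r - 2):(3 * r)
    sum(a[i] * b[i]) / sqrt(sum(a[i]^2) * sum(b[i]^2))
  }, 0)
  expect_equal(cs$cosine, oracle, tolerance = 1e-12)

  same <- direction_cosines(ms, 1, mode_b = 1)
  expect_equal(same$cosine, rep(1, 3), tolerance = 1e-12)
  neg <- fake_mode_set(cbind(a, -a), 3)
  expect_equal(direction_cosines(neg, 1, mode_b = 2)$cosine, rep(-1, 3),
               tolerance = 1e-12)

  # zero block -> undefined
  z <- c(1, 0, 0, rep(0, 6)) / 1
  msz <- fake_mode_set(cbind(dimerdyn:::unit(z), b), 3)
  expect_true(is.na(direction_cosines(msz, 1, mode_b = 2)$cosine[2]))
})

test_that("mode similarity and projection behave as Pearson correlations", {
  set.seed(9)
  v <- dimerdyn:::unit(rnorm(12))
  expect_equal(mode_similarity(v, v), 1, tolerance = 1e-12)
  expect_equal(mode_similarity(v, -v), -1, tolerance = 1e-12)
  expect_error(mode_similarity(v, rnorm(9)), "dimension")

  # orthogonal zero-mean vectors have ~0 PCC
  a <- rep(c(1, -1), 6) / sqrt(12)
  b <- rep(c(1, 1, -1, -1), 3); b <- b - mean(b); b <- dimerdyn:::unit(b)
  expect_lt(abs(mode_similarity(a, b)), 1e-6)

  ms <- fake_mode_set(cbind(a, b), 4)
  pr <- project_mode(a, ms, top_k = 2)
  expect_equal(attr(pr, "best_pc"), 1)
  expect_equal(pr$pcc[1], 1, tolerance = 1e-12)
  # exact tie breaks toward the lower PC index
  tie <- project_mode(dimerdyn:::unit(a + b), ms, top_k = 2)
  expect_equal(attr(tie, "best_pc"), 1)
})

test_that("projection onto all modes reconstructs centered coordinates", {
  sys <- aligned_toy(n_res = 5, n_frames = 80, noise = 0.2, seed = 14)
  m <- pca_modes(sys$aligned)
  proj <- dimerdyn:::mode_projections(sys$aligned, m)
  idx <- m$atom_indices
  cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  xc <- sweep(sys$aligned$xyz[, cols], 2,
              dimerdyn:::flatten_coords(m$mean_structure))
  back <- proj %*% t(m$modes)
  expect_lt(max(abs(back - xc)), 1e-6)
})

test_that("FMA is exact in the noiseless linear case", {
  sys <- aligned_toy(n_res = 8, n_frames = 300, noise = 0.05, seed = 15)
  m <- pca_modes(sys$aligned)
  y <- dimerdyn:::mode_projections(sys$aligned, m)[, 1]
  f <- fma(sys$aligned, m, y)
  expect_equal(f$train_pcc, 1, tolerance = 1e-6)
  expect_equal(f$validation_pcc, 1, tolerance = 1e-6)
  expect_gt(abs(sum(f$mode * m$modes[, 1])), 0.999)
})

test_that("FMA finds no spurious mode for a coordinate-independent function", {
  sys <- aligned_toy(n_res = 8, n_frames = 2000, noise = 0.05, seed = 16)
  m <- pca_modes(sys$aligned)
  pccs <- vapply(1:20, function(s) {
    set.seed(100 + s)
    fma(sys$aligned, m, rnorm(2000))$validation_pcc
  }, 0)
  expect_lt(max(abs(pccs)), 0.2)
})

test_that("FMA recovers the planted dissociation mode from a noisy function", {
  sys <- aligned_toy(n_res = 8, n_frames = 2000, noise = 0.05, seed = 17)
  m <- pca_modes(sys$aligned)
  truth <- internal_component(
    field_on_atoms(sys$model, sys$gen$fields[[1]], m$atom_indices),
    m$mean_structure
  )
  d <- sys$gen$coefficients$dissociation
  stats <- vapply(1:10, function(s) {
    set.seed(200 + s)
    f <- fma(sys$aligned, m, d + rnorm(length(d), 0, sd(d) / 5))
    c(f$validation_pcc, abs(sum(f$mode * truth)))
  }, numeric(2))
  expect_true(all(stats[1, ] > 0.8))
  expect_true(all(stats[2, ] > 0.95))
})

test_that("FMA statistics are invariant to affine rescaling of the function", {
  sys <- aligned_toy(n_res = 6, n_frames = 400, noise = 0.05, seed = 18)
  m <- pca_modes(sys$aligned)
  y <- sys$gen$coefficients$dissociation
  f1 <- fma(sys$aligned, m, y)
  f2 <- fma(sys$aligned, m, 3.7 * y + 42)
  expect_equal(f1$train_pcc, f2$train_pcc, tolerance = 1e-9)
  expect_equal(f1$validation_pcc, f2$validation_pcc, tolerance = 1e-9)
  expect_equal(f1$mode, f2$mode, tolerance = 1e-9)
  expect_error(fma(sys$aligned, m, rep(1, 400)), "zero-variance")
})

test_that("the PLS core agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(19)
  X <- matrix(rnorm(200 * 6), 200); colnames(X) <- paste0("x", 1:6)
  y <- as.vector(X %*% c(1, -0.5, 0, 0, 0.2, 0) + rnorm(200, 0, 0.3))
  fit <- dimerdyn:::pls1_fit(X, y, 3)
  ours <- dimerdyn:::pls1_predict(fit, X)
  mf <- mixOmics::pls(X, y, ncomp = 3, mode = "regression", scale = FALSE)
  theirs <- predict(mf, X)$predict[, 1, 3]
  expect_equal(ours, unname(theirs), tolerance = 1e-10)
})
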