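# Principal component analysis of CA motions and partial-least-squares
# functional mode analysis (FMA) against a scalar per-frame functional
# quantity (here: total interface SASA).

#' Principal component analysis of CA coordinates
#'
#' Eigendecomposition of the 3N x 3N sample covariance of the flattened,
#' aligned CA coordinates. Modes are unit 3N vectors; the sign convention
#' (the largest-magnitude component of each mode is positive) makes outputs
#' deterministic across runs and linear-algebra backends.
#'
#' @param traj An aligned [trajectory_ensemble()].
#' @param k Number of modes to keep (default all with positive variance,
#'   capped at F - 1).
#' @param selection Selection expression for the analysed atoms (default CA).
#' @return Object of class `mode_set`: `atom_indices`, `residues` (tibble),
#'   `mean_structure` (N x 3), `modes` (3N x K, unit columns), `variances`
#'   (descending, Angstrom^2).
#' @export
pca_modes <- function(traj, k = NULL, selection = "calpha") {
  if (!traj$aligned) abort("pca_modes needs an aligned ensemble")
  idx <- select_atoms(traj$model, selection)
  cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  x <- traj$xyz[, cols, drop = FALSE]
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  cv <- crossprod(xc) / (nrow(x) - 1)
  eig <- eigen(cv, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  if (max(vals) < 1e-12) abort("degenerate covariance: ensemble has no motion")
  k <- min(k %||% sum(vals > 1e-12), ncol(cv), nrow(x) - 1)
  modes <- eig$vectors[, seq_len(k), drop = FALSE]
  modes <- apply(modes, 2, fix_mode_sign)
  structure(
    list(
      atom_indices = idx,
      residues = tibble(chain_id = traj$model$atoms$chain_id[idx],
                        residue_index = traj$model$atoms$residue_index[idx]),
      mean_structure = matrix(mu, ncol = 3, byrow = TRUE),
      modes = modes,
      variances = vals[seq_len(k)]
    ),
    class = "mode_set"
  )
}

fix_mode_sign <- function(v) if (v[which.max(abs(v))] < 0) -v else v

#' Internal (non-rigid) component of a displacement field
#'
#' Superposing every frame on a common reference removes global translation
#' and rotation, so a planted collective mode appears in a PCA of the aligned
#' ensemble only through its internal component: the projection of the field
#' onto the orthogonal complement of the six rigid-body motions (three
#' translations, three infinitesimal rotations about the centroid) of the
#' reference structure. Use this to compare planted fields with recovered
#' modes.
#'
#' @param field 3N displacement vector (or N x 3 matrix).
#' @param coords N x 3 reference coordinates the rigid motions refer to.
#' @return Unit 3N vector with the rigid-body components removed.
#' @export
internal_component <- function(field, coords) {
  v <- as.vector(if (is.matrix(field)) t(field) else field)
  n <- nrow(coords)
  stopifnot(length(v) == 3 * n)
  xc <- sweep(coords, 2, colMeans(coords))
  basis <- matrix(0, 3 * n, 6)
  for (k in 1:3) basis[seq(k, 3 * n, by = 3), k] <- 1    # translations
  basis[, 4] <- as.vector(t(cbind(0, -xc[, 3], xc[, 2])))  # rot about x
  basis[, 5] <- as.vector(t(cbind(xc[, 3], 0, -xc[, 1])))  # rot about y
  basis[, 6] <- as.vector(t(cbind(-xc[, 2], xc[, 1], 0)))  # rot about z
  q <- qr.Q(qr(basis))
  unit(v - q %*% crossprod(q, v))
}

#' Restrict a full-atom displacement field to a subset of atoms
#'
#' Extracts the (x, y, z) blocks of the given atoms from a 3A field over the
#' whole model and renormalizes, e.g. to map a planted full-atom field onto
#' the CA atoms of a [pca_modes()] mode set.
#'
#' @param model The [structure_model()] the field is dimensioned to.
#' @param field 3A numeric vector.
#' @param atom_indices Atom indices (model order) to keep.
#' @return Unit vector of length `3 * length(atom_indices)`.
#' @export
field_on_atoms <- function(model, field, atom_indices) {
  stopifnot(length(field) == 3 * n_atoms(model))
  cols <- as.vector(rbind(3 * atom_indices - 2, 3 * atom_indices - 1,
                          3 * atom_indices))
  unit(field[cols])
}

#' @export
print.mode_set <- function(x, ...) {
  cat("<mode_set> ", ncol(x$modes), " modes over ", length(x$atom_indices),
      " CA atoms; top variances: ",
      paste(signif(head(x$variances, 3), 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# per-frame projections of centered CA coordinates onto the mode columns
mode_projections <- function(traj, modes) {
  idx <- modes$atom_indices
  cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  xc <- sweep(traj$xyz[, cols, drop = FALSE], 2,
              flatten_coords(modes$mean_structure))
  xc %*% modes$modes
}

# rows of the residue block (x,y,z) of residue r inside a 3N mode vector
residue_block <- function(modes, chain_id, residue_index) {
  pos <- which(modes$residues$chain_id == chain_id &
                 modes$residues$residue_index == residue_index)
  if (length(pos) != 1) {
    abort(paste0("residue not in mode set: ", chain_id, ":", residue_index))
  }
  (3 * pos - 2):(3 * pos)
}

#' Per-residue amplitudes and directions within one mode
#'
#' The amplitude of a residue is the Euclidean norm of its 3-component block
#' of the (unit) mode vector, so amplitudes over the whole dimer satisfy
#' `sum(amplitude^2) = 1`. The direction is the residue's unit 3-vector;
#' it is flagged undefined when the amplitude falls below `1e-6`.
#'
#' @param modes A [pca_modes()] result (or compatible `mode_set`).
#' @param mode_index Which mode (1-based).
#' @return Tibble: `chain_id`, `residue_index`, `amplitude`, `dx`, `dy`,
#'   `dz` (unit direction; `NA` when undefined), `defined`.
#' @export
residue_amplitudes <- function(modes, mode_index = 1L) {
  v <- modes$modes[, mode_index]
  m <- matrix(v, ncol = 3, byrow = TRUE)
  amp <- sqrt(rowSums(m^2))
  defined <- amp >= 1e-6
  dir <- m / ifelse(amp > 0, amp, 1)
  dir[!defined, ] <- NA_real_
  tibble(
    chain_id = modes$residues$chain_id,
    residue_index = modes$residues$residue_index,
    amplitude = amp,
    dx = dir[, 1], dy = dir[, 2], dz = dir[, 3],
    defined = defined
  )
}

#' Cosine between one residue's motion directions in two modes
#'
#' @param modes_a,modes_b Mode sets over the same residues (or the same set
#'   twice to compare two of its modes).
#' @param mode_a,mode_b Mode indices.
#' @return Tibble `chain_id`, `residue_index`, `cosine` (`NA` where either
#'   block has amplitude < 1e-6 and the direction is undefined).
#' @export
direction_cosines <- function(modes_a, mode_a, modes_b = modes_a, mode_b) {
  if (!identical(modes_a$residues, modes_b$residues)) {
    abort("mode sets cover different residues")
  }
  va <- matrix(modes_a$modes[, mode_a], ncol = 3, byrow = TRUE)
  vb <- matrix(modes_b$modes[, mode_b], ncol = 3, byrow = TRUE)
  na <- sqrt(rowSums(va^2)); nb <- sqrt(rowSums(vb^2))
  cosv <- rowSums(va * vb) / (na * nb)
  cosv[na < 1e-6 | nb < 1e-6] <- NA_real_
  tibble(chain_id = modes_a$residues$chain_id,
         residue_index = modes_a$residues$residue_index,
         cosine = cosv)
}

#' Pearson similarity between two 3N mode vectors
#'
#' @param mode_a,mode_b Numeric vectors of equal length.
#' @return Pearson correlation of the component vectors.
#' @export
mode_similarity <- function(mode_a, mode_b) {
  if (length(mode_a) != length(mode_b)) abort("mode dimension mismatch")
  cor(as.vector(mode_a), as.vector(mode_b))
}

#' Project a mode onto the leading PCs of a mode set
#'
#' Reports the Pearson similarity of `mode` with each of the top `top_k`
#' PC modes and the best-matching PC (argmax of |PCC|, ties broken toward
#' the lower PC index).
#'
#' @param mode A 3N vector (e.g. a functional mode from another system,
#'   mapped onto the same CA atoms).
#' @param modes A `mode_set`.
#' @param top_k How many leading PCs to project on (default 20).
#' @return Tibble `pc`, `pcc` with attribute `best_pc`.
#' @export
project_mode <- function(mode, modes, top_k = 20L) {
  k <- min(top_k, ncol(modes$modes))
  pcc <- vapply(seq_len(k), function(j) {
    mode_similarity(mode, modes$modes[, j])
  }, 0)
  out <- tibble(pc = seq_len(k), pcc = pcc)
  attr(out, "best_pc") <- which.max(abs(pcc))  # which.max takes first tie
  out
}

# PLS1 (NIPALS): univariate response; returns the regression vector in
# predictor space plus the training means needed for prediction
pls1_fit <- function(X, y, ncomp) {
  mx <- colMeans(X); my <- mean(y)
  Xc <- sweep(X, 2, mx); yc <- y - my
  p <- ncol(X)
  W <- P <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- a - 1L; break }
    w <- w / nw
    t <- Xc %*% w
    tt <- sum(t^2)
    pvec <- crossprod(Xc, t) / tt
    qa <- sum(yc * t) / tt
    Xc <- Xc - t %*% t(pvec)
    yc <- yc - qa * t
    W[, a] <- w; P[, a] <- pvec; q[a] <- qa
  }
  if (ncomp == 0) abort("response has no covariance with the predictors")
  W <- W[, seq_len(ncomp), drop = FALSE]
  P <- P[, seq_len(ncomp), drop = FALSE]
  q <- q[seq_len(ncomp)]
  beta <- W %*% solve(crossprod(P, W), q)
  list(beta = as.vector(beta), x_mean = mx, y_mean = my, ncomp = ncomp)
}

pls1_predict <- function(fit, X) {
  as.vector(sweep(X, 2, fit$x_mean) %*% fit$beta) + fit$y_mean
}

#' Functional mode analysis by partial least squares
#'
#' Finds the linear combination of PC modes maximally correlated with a
#' scalar per-frame functional quantity (PLS1 regression of the centered
#' function on the frame projections onto the top `n_components`-constrained
#' pool of PC modes). The functional mode is the normalized back-projection
#' of the PLS regression vector into coordinate space. The model is fitted
#' on the first half of the frames and evaluated on the held-out second
#' half (a contiguous split, respecting temporal autocorrelation); both
#' Pearson correlations are reported.
#'
#' @param traj The aligned [trajectory_ensemble()] the modes came from.
#' @param modes A [pca_modes()] result.
#' @param function_series Numeric per-frame functional values (length F), or
#'   a tibble with a `sasa` (or second) column as returned by
#'   [interface_sasa_series()].
#' @param n_components Number of PLS latent components (default 10).
#' @param top_k Size of the PC-mode pool to regress on (default 20).
#' @return Object of class `functional_mode`: `mode` (unit 3N vector),
#'   `pc_coefficients`, `train_pcc`, `validation_pcc`, `n_components`,
#'   `projection` (per-frame tibble: frame_label, half, functional value,
#'   fitted value).
#' @export
fma <- function(traj, modes, function_series, n_components = 10L,
                top_k = 20L) {
  y <- if (is.data.frame(function_series)) {
    function_series[[if ("sasa" %in% names(function_series)) "sasa" else 2L]]
  } else as.numeric(function_series)
  if (length(y) != n_frames(traj)) {
    abort("function_series length must equal the number of frames")
  }
  if (sd(y) == 0) abort("zero-variance function series")
  K <- min(top_k, ncol(modes$modes))
  X <- mode_projections(traj, modes)[, seq_len(K), drop = FALSE]
  f_count <- nrow(X)
  train <- seq_len(floor(f_count / 2))
  valid <- setdiff(seq_len(f_count), train)
  ncomp <- min(n_components, K, length(train) - 1)
  fit <- pls1_fit(X[train, , drop = FALSE], y[train], ncomp)
  yhat <- pls1_predict(fit, X)
  train_pcc <- safe_cor(yhat[train], y[train])
  validation_pcc <- safe_cor(yhat[valid], y[valid])
  # ensemble-weighted mode: weight the regression vector by the per-PC
  # variances before back-projection. This is the motion that actually moves
  # the functional quantity; the raw regression direction divides by small
  # variances and is dominated by noise PCs.
  wts <- apply(X[train, , drop = FALSE], 2, stats::var) * fit$beta
  mode_vec <- fix_mode_sign(unit(as.vector(
    modes$modes[, seq_len(K), drop = FALSE] %*% wts
  )))
  structure(
    list(
      mode = mode_vec,
      pc_coefficients = setNames(fit$beta, paste0("PC", seq_len(K))),
      train_pcc = train_pcc,
      validation_pcc = validation_pcc,
      n_components = fit$ncomp,
      residues = modes$residues,
      projection = tibble(
        frame_label = traj$frame_labels,
        half = ifelse(seq_len(f_count) %in% train, "train", "validation"),
        functional = y,
        fitted = yhat
      )
    ),
    class = "functional_mode"
  )
}

#' @export
print.functional_mode <- function(x, ...) {
  cat("<functional_mode> ", x$n_components, " PLS components; train PCC ",
      round(x$train_pcc, 3), ", validation PCC ",
      round(x$validation_pcc, 3), "\n", sep = "")
  invisible(x)
}
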