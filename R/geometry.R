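# Rigid-body superposition and basic structural descriptors.

#' Kabsch superposition of two point sets
#'
#' Finds the proper rotation and translation minimizing the RMSD of `mobile`
#' onto `target` (unweighted). A reflection in the SVD solution is corrected
#' by flipping the sign of the smallest singular vector, so the returned
#' rotation always has determinant +1.
#'
#' @param mobile,target N x 3 matrices (N >= 3, not all collinear).
#' @return List of class `superposition` with `rotation` (3 x 3),
#'   `translation` (length 3) and `rmsd` (Angstrom). The transform maps
#'   `mobile %*% rotation + translation` onto `target`.
#' @export
kabsch_superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (nrow(mobile) < 3 || !identical(dim(mobile), dim(target))) {
    abort("need two equally sized N x 3 point sets with N >= 3")
  }
  cm <- colMeans(mobile); ct <- colMeans(target)
  P <- sweep(mobile, 2, cm); Q <- sweep(target, 2, ct)
  if (all(svd(P)$d[2:3] < 1e-10)) abort("degenerate (collinear) point set")
  H <- crossprod(P, Q)
  s <- svd(H)
  sign_fix <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, sign_fix))
  R <- s$v %*% D %*% t(s$u)        # column-vector convention: y = R x
  rot <- t(R)                      # row-vector convention: Y = X %*% rot
  moved <- P %*% rot
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  structure(
    list(rotation = rot, translation = ct - as.vector(cm %*% rot), rmsd = rmsd),
    class = "superposition"
  )
}

# RMSD of two coordinate sets after optimal superposition on `fit_idx`
fitted_rmsd <- function(a, b, fit_idx = NULL) {
  fit_idx <- fit_idx %||% seq_len(nrow(a))
  sp <- kabsch_superpose(a[fit_idx, , drop = FALSE], b[fit_idx, , drop = FALSE])
  moved <- a %*% sp$rotation + matrix(sp$translation, nrow(a), 3, byrow = TRUE)
  sqrt(mean(rowSums((moved[fit_idx, , drop = FALSE] -
                       b[fit_idx, , drop = FALSE])^2)))
}

#' Align every frame of an ensemble onto a common reference
#'
#' Superposes each frame via its CA atoms (unweighted Kabsch) onto either the
#' first frame or the iterative mean structure (align, recompute the mean,
#' repeat until the mean moves by less than `tol` or 100 iterations).
#'
#' @param traj An unaligned [trajectory_ensemble()].
#' @param reference `"first_frame"` or `"mean_iterative"`.
#' @param selection Selection expression for the fit atoms (default CA).
#' @param tol Convergence threshold on mean-structure movement (Angstrom).
#' @return The ensemble with all atoms transformed and `aligned = TRUE`.
#' @export
align_ensemble <- function(traj, reference = c("mean_iterative", "first_frame"),
                           selection = "calpha", tol = 1e-6) {
  reference <- match.arg(reference)
  if (traj$aligned) abort("ensemble is already aligned")
  idx <- select_atoms(traj$model, selection)
  xyz <- traj$xyz
  align_to <- function(xyz, ref_sel) {
    for (f in seq_len(nrow(xyz))) {
      fr <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
      sp <- kabsch_superpose(fr[idx, , drop = FALSE], ref_sel)
      moved <- fr %*% sp$rotation + matrix(sp$translation, nrow(fr), 3, byrow = TRUE)
      xyz[f, ] <- flatten_coords(moved)
    }
    xyz
  }
  sel_coords <- function(xyz, f) matrix(xyz[f, ], ncol = 3, byrow = TRUE)[idx, , drop = FALSE]
  mean_sel <- function(xyz) {
    m <- colMeans(xyz)
    matrix(m, ncol = 3, byrow = TRUE)[idx, , drop = FALSE]
  }
  if (reference == "first_frame") {
    xyz <- align_to(xyz, sel_coords(xyz, 1))
  } else {
    xyz <- align_to(xyz, sel_coords(xyz, 1))
    ref <- mean_sel(xyz)
    for (it in seq_len(100)) {
      xyz <- align_to(xyz, ref)
      new_ref <- mean_sel(xyz)
      shift <- sqrt(mean(rowSums((new_ref - ref)^2)))
      ref <- new_ref
      if (shift < tol) break
    }
  }
  trajectory_ensemble(traj$model, xyz, traj$frame_labels, aligned = TRUE)
}

#' Per-frame RMSD series against a reference frame
#'
#' Each frame is optimally superposed on the reference over `selection`
#' before the deviation is measured, so the series does not depend on any
#' prior alignment of the ensemble.
#'
#' @param traj A [trajectory_ensemble()].
#' @param reference_frame Frame index (1-based) of the reference; default 1.
#' @param selection Selection expression (default CA).
#' @return Tibble with `frame_label` and `rmsd` (Angstrom).
#' @export
rmsd_series <- function(traj, reference_frame = 1L, selection = "calpha") {
  idx <- select_atoms(traj$model, selection)
  ref <- frame_coords(traj, reference_frame)[idx, , drop = FALSE]
  r <- vapply(seq_len(n_frames(traj)), function(f) {
    fr <- frame_coords(traj, f)[idx, , drop = FALSE]
    kabsch_superpose(fr, ref)$rmsd
  }, 0)
  tibble(frame_label = traj$frame_labels, rmsd = r)
}

#' Per-residue RMSF profile about the ensemble mean
#'
#' `RMSF_i = sqrt(mean_t ||x_i(t) - <x_i>||^2)` over CA atoms of an aligned
#' ensemble; the reference is the ensemble mean structure.
#'
#' @param traj An aligned [trajectory_ensemble()].
#' @return Tibble with `chain_id`, `residue_index`, `rmsf` (Angstrom).
#' @export
rmsf_profile <- function(traj) {
  if (!traj$aligned) abort("rmsf_profile needs an aligned ensemble")
  if (n_frames(traj) == 1) {
    warn("single-frame ensemble: RMSF is identically zero")
  }
  idx <- select_atoms(traj$model, "calpha")
  cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  x <- traj$xyz[, cols, drop = FALSE]
  xc <- sweep(x, 2, colMeans(x))
  msf_per_coord <- colMeans(xc^2)
  msf <- colSums(matrix(msf_per_coord, nrow = 3))  # x+y+z per atom
  tibble(
    chain_id = traj$model$atoms$chain_id[idx],
    residue_index = traj$model$atoms$residue_index[idx],
    rmsf = sqrt(msf)
  )
}

#' Distance between subunit centers along a trajectory
#'
#' Unweighted CA centroid of each chain, per frame; the pairwise distance is
#' invariant under any rigid motion of a frame, so aligned and unaligned
#' ensembles give identical series.
#'
#' @param traj A [trajectory_ensemble()].
#' @param chains Length-2 character vector of chain ids.
#' @return Tibble with `frame_label` and `distance` (Angstrom).
#' @export
chain_center_distance <- function(traj, chains = c("A", "B")) {
  idx_ca <- select_atoms(traj$model, "calpha")
  idx1 <- intersect(idx_ca, which(traj$model$atoms$chain_id == chains[1]))
  idx2 <- intersect(idx_ca, which(traj$model$atoms$chain_id == chains[2]))
  if (length(idx1) == 0 || length(idx2) == 0) abort("chain without CA atoms")
  d <- vapply(seq_len(n_frames(traj)), function(f) {
    fr <- frame_coords(traj, f)
    sqrt(sum((colMeans(fr[idx1, , drop = FALSE]) -
                colMeans(fr[idx2, , drop = FALSE]))^2))
  }, 0)
  tibble(frame_label = traj$frame_labels, distance = d)
}
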