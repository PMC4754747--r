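# Shrake-Rupley solvent-accessible surface area with a deterministic
# golden-spiral point set, interface detection by SASA loss on the static
# structure, and the per-frame interface-SASA series used as the functional
# quantity for functional mode analysis.

# n approximately evenly distributed unit-sphere points (golden spiral);
# deterministic, so SASA values are exactly reproducible for fixed n
sphere_points <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - 2 * (i + 0.5) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

# per-atom SASA for atoms `compute_idx`, occluded by all atoms in `coords`
sasa_atoms <- function(coords, radii, compute_idx, probe = 1.4, n_points = 960,
                       pts = NULL) {
  if (n_points < 32) abort("n_points must be at least 32")
  pts <- pts %||% sphere_points(n_points)
  ext <- radii + probe
  out <- numeric(length(compute_idx))
  for (k in seq_along(compute_idx)) {
    i <- compute_idx[k]
    ri <- ext[i]
    d2 <- rowSums(sweep(coords, 2, coords[i, ])^2)
    nb <- which(d2 < (ri + ext)^2 & seq_along(d2) != i)
    if (length(nb) == 0) {
      out[k] <- 4 * pi * ri^2
      next
    }
    p <- pts * ri
    p <- sweep(p, 2, coords[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (p[, 1] - coords[j, 1])^2 + (p[, 2] - coords[j, 2])^2 +
        (p[, 3] - coords[j, 3])^2
      exposed <- exposed & (dj2 >= ext[j]^2)
      if (!any(exposed)) break
    }
    out[k] <- sum(exposed) / n_points * 4 * pi * ri^2
  }
  out
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere over the van der Waals spheres of the selected atoms
#' using a fixed golden-spiral point set, so results are deterministic for a
#' given `n_points`. The SASA of atom i is
#' `(exposed points / n_points) * 4 * pi * (r_i + probe)^2`. Hydrogens are
#' excluded by the default selection; selected atoms are also the only
#' occluders considered.
#'
#' @param model A [structure_model()].
#' @param coords Optional A x 3 coordinates to use instead of the model's
#'   reference coordinates (same atom order).
#' @param selection Selection expression or integer atom indices
#'   (default `"heavy"`).
#' @param probe Probe radius in Angstrom (water: 1.4).
#' @param n_points Sphere points per atom (>= 32; default 960).
#' @return Object of class `sasa_result`: `per_atom` tibble (`atom_id`,
#'   `area`), `per_residue` tibble (`chain_id`, `residue_index`, `area`),
#'   and `total` (Angstrom^2).
#' @export
sasa <- function(model, coords = NULL, selection = "heavy", probe = 1.4,
                 n_points = 960) {
  coords <- coords %||% model$xyz
  idx <- if (is.numeric(selection)) as.integer(selection) else {
    select_atoms(model, selection)
  }
  sub <- coords[idx, , drop = FALSE]
  areas <- sasa_atoms(sub, model$atoms$vdw_radius[idx],
                      seq_along(idx), probe, n_points)
  per_atom <- tibble(atom_id = model$atoms$atom_id[idx], area = areas)
  per_residue <- tibble(
    chain_id = model$atoms$chain_id[idx],
    residue_index = model$atoms$residue_index[idx],
    area = areas
  )
  per_residue <- dplyr::summarise(
    dplyr::group_by(per_residue, .data$chain_id, .data$residue_index),
    area = sum(.data$area), .groups = "drop"
  )
  structure(
    list(per_atom = per_atom, per_residue = per_residue, total = sum(areas)),
    class = "sasa_result"
  )
}

#' @export
print.sasa_result <- function(x, ...) {
  cat("<sasa_result> total ", round(x$total, 2), " A^2 over ",
      nrow(x$per_atom), " atoms\n", sep = "")
  invisible(x)
}

#' Detect the dimer interface by SASA loss on the static structure
#'
#' Interface residues are those whose SASA decreases when the two rigid
#' subunits are associated versus isolated: per-residue SASA is computed once
#' per isolated chain and once in the complex (reference coordinates), and
#' residues with `delta_sasa > tolerance` are returned for both chains.
#'
#' @param model A [structure_model()] with both chains.
#' @param chains Length-2 character vector of chain ids.
#' @param tolerance Minimum SASA loss (Angstrom^2) to count as interface.
#' @inheritParams sasa
#' @return Tibble (`chain_id`, `residue_index`, `delta_sasa`) of class
#'   `interface_set`; empty (with a warning) when no residue is buried.
#' @export
detect_interface <- function(model, chains = c("A", "B"), tolerance = 0.1,
                             probe = 1.4, n_points = 960) {
  if (!all(chains %in% model$atoms$chain_id)) {
    abort(paste0("chain not present: ",
                 paste(setdiff(chains, model$atoms$chain_id), collapse = ", ")))
  }
  heavy <- select_atoms(model, "heavy")
  complex_sasa <- sasa(model, selection = heavy, probe = probe,
                       n_points = n_points)$per_residue
  iso <- lapply(chains, function(ch) {
    idx <- intersect(heavy, which(model$atoms$chain_id == ch))
    sasa(model, selection = idx, probe = probe, n_points = n_points)$per_residue
  })
  iso <- dplyr::bind_rows(iso)
  merged <- dplyr::inner_join(iso, complex_sasa,
                              by = c("chain_id", "residue_index"),
                              suffix = c("_iso", "_cpx"))
  out <- dplyr::transmute(merged, chain_id = .data$chain_id,
                          residue_index = .data$residue_index,
                          delta_sasa = .data$area_iso - .data$area_cpx)
  out <- dplyr::filter(out, .data$delta_sasa > tolerance)
  out <- dplyr::arrange(out, .data$chain_id, .data$residue_index)
  if (nrow(out) == 0) warn("no interface residues found")
  class(out) <- c("interface_set", class(out))
  out
}

#' Total interface SASA per frame
#'
#' For each frame, sums the in-complex per-residue SASA over the (fixed)
#' interface residues. This series quantifies the degree of dimer
#' dissociation and is the functional quantity handed to [fma()].
#'
#' @param traj A [trajectory_ensemble()].
#' @param interface Interface set from [detect_interface()] (or any residue
#'   selection tibble).
#' @inheritParams sasa
#' @return Tibble with `frame_label` and `sasa` (Angstrom^2).
#' @export
interface_sasa_series <- function(traj, interface, probe = 1.4,
                                  n_points = 960) {
  if (nrow(interface) == 0) abort("interface is empty")
  model <- traj$model
  heavy <- select_atoms(model, "heavy")
  iface_atoms <- intersect(heavy, atom_indices(model, interface))
  compute_idx <- match(iface_atoms, heavy)
  radii <- model$atoms$vdw_radius[heavy]
  cols <- as.vector(rbind(3 * heavy - 2, 3 * heavy - 1, 3 * heavy))
  pts <- sphere_points(n_points)
  s <- vapply(seq_len(n_frames(traj)), function(f) {
    coords <- matrix(traj$xyz[f, cols], ncol = 3, byrow = TRUE)
    sum(sasa_atoms(coords, radii, compute_idx, probe, n_points, pts = pts))
  }, 0)
  tibble(frame_label = traj$frame_labels, sasa = s)
}
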