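# Synthetic dimer ensembles with planted collective modes.
#
# The generator emulates what downstream stages need from an MD ensemble of a
# two-chain protein: Gaussian-weighted orthonormal collective modes, one
# "dissociation" mode that rigidly translates chain B along the interface
# normal (so interface SASA responds to it), isotropic thermal noise, and
# residue-pair contact schedules with controllable occupancy. Everything is
# seeded and reproducible.

#' Specification for a synthetic dimer ensemble
#'
#' @param n_residues_per_chain Residues per chain (>= 4).
#' @param atoms_per_residue Atoms per residue (>= 1); atom 1 is the CA, the
#'   rest are pseudo side-chain atoms at fixed offsets.
#' @param n_frames Number of frames to generate.
#' @param planted_modes List of planted collective modes, each a
#'   `list(field = <A x 3 matrix or 3A vector>, stddev = <Angstrom>)`. Fields
#'   are re-orthonormalized (Gram-Schmidt) against the dissociation field and
#'   each other; near-degenerate inputs (pairwise |cos| > 0.99) are rejected.
#' @param dissociation_stddev Std. dev. (Angstrom, along the unit field) of
#'   the planted dissociation-mode coefficient.
#' @param noise_stddev Std. dev. of i.i.d. Gaussian noise per coordinate.
#' @param contact_targets Data frame with columns `chain_i`, `res_i`,
#'   `chain_j`, `res_j`, `occupancy` ([0,1]): residue pairs whose minimal
#'   atom distance is jittered across the 4.5 Angstrom contact threshold on a
#'   seeded Bernoulli schedule with the given hit rate. The second residue of
#'   each pair is displaced; pairs should not share residues.
#' @param seed Integer RNG seed; one stream per generator call.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_residues_per_chain = 12,
                           atoms_per_residue = 2,
                           n_frames = 2000,
                           planted_modes = list(),
                           dissociation_stddev = 2.0,
                           noise_stddev = 0.05,
                           contact_targets = NULL,
                           seed = 1L) {
  if (n_residues_per_chain < 4) abort("need at least 4 residues per chain")
  if (atoms_per_residue < 1) abort("need at least 1 atom per residue")
  if (n_frames < 1) abort("need at least one frame")
  if (dissociation_stddev < 0 || noise_stddev < 0) abort("stddevs must be >= 0")
  for (m in planted_modes) {
    if (is.null(m$field) || is.null(m$stddev) || m$stddev < 0) {
      abort("each planted mode needs a field and a non-negative stddev")
    }
  }
  if (!is.null(contact_targets)) {
    contact_targets <- as_tibble(contact_targets)
    stopifnot(all(c("chain_i", "res_i", "chain_j", "res_j", "occupancy") %in%
                    names(contact_targets)))
    if (any(contact_targets$occupancy < 0 | contact_targets$occupancy > 1)) {
      abort("contact occupancies must lie in [0, 1]")
    }
  }
  structure(
    list(n_residues_per_chain = as.integer(n_residues_per_chain),
         atoms_per_residue = as.integer(atoms_per_residue),
         n_frames = as.integer(n_frames),
         planted_modes = planted_modes,
         dissociation_stddev = dissociation_stddev,
         noise_stddev = noise_stddev,
         contact_targets = contact_targets,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# geometry constants of the toy dimer
TOY_CA_SPACING <- 3.8      # Angstrom between consecutive CA along the strand
TOY_INTERFACE_GAP <- 4.0   # Angstrom between facing CA of chains A and B
TOY_SIDE_OFFSET <- 1.5     # Angstrom between stacked pseudo side-chain atoms
CONTACT_DIST_IN <- 3.5     # planted min distance when a contact is "on"
CONTACT_DIST_OUT <- 6.5    # and when it is "off" (threshold is 4.5)

#' Build the toy dimer structure
#'
#' Two chains (A, B) laid out as facing extended strands: CA atoms 3.8
#' Angstrom apart along x within a chain, facing CA pairs exactly 4.0
#' Angstrom apart across the interface (the y axis is the interface normal).
#' Pseudo side-chain atoms stack away from the interface at 1.5 Angstrom
#' spacing. Deterministic for a fixed spec.
#'
#' @param spec A [synthetic_spec()].
#' @return A [structure_model()].
#' @export
build_toy_dimer <- function(spec) {
  n <- spec$n_residues_per_chain
  m <- spec$atoms_per_residue
  atom_names <- c("CA", paste0("S", seq_len(max(m - 1, 0))))[seq_len(m)]
  one_chain <- function(chain, y0, side_sign) {
    res <- rep(seq_len(n), each = m)
    k <- rep(seq_len(m) - 1L, times = n)
    x <- (res - 1) * TOY_CA_SPACING
    y <- y0 + side_sign * TOY_SIDE_OFFSET * k
    z <- rep(0, n * m)
    list(
      atoms = tibble(
        name = rep(atom_names, times = n),
        element = "C",
        residue_index = as.integer(res),
        residue_name = "ALA",
        chain_id = chain
      ),
      xyz = cbind(x, y, z)
    )
  }
  a <- one_chain("A", 0, -1)
  b <- one_chain("B", TOY_INTERFACE_GAP, +1)
  atoms <- dplyr::bind_rows(a$atoms, b$atoms)
  atoms$atom_id <- seq_len(nrow(atoms))
  structure_model(atoms, rbind(a$xyz, b$xyz))
}

# unit 3A field translating chain B rigidly along +y (the interface normal)
dissociation_field <- function(model) {
  field <- matrix(0, n_atoms(model), 3)
  field[model$atoms$chain_id == "B", 2] <- 1
  unit(as.vector(t(field)))
}

#' A smooth planted wave mode for the toy dimer
#'
#' Sinusoidal displacement along `axis` with period `wavelength` residues,
#' identical for all atoms of a residue — a simple stand-in for a low-frequency
#' internal collective motion, orthogonal to the dissociation field when the
#' axis is not y.
#'
#' @param model Toy dimer [structure_model()].
#' @param wavelength Period in residues.
#' @param axis One of "x", "z" (y is the interface normal).
#' @param phase Phase offset in radians.
#' @return Unit 3A numeric vector.
#' @export
planted_wave_mode <- function(model, wavelength = 8, axis = "z", phase = 0) {
  ax <- match(axis, c("x", "y", "z"))
  field <- matrix(0, n_atoms(model), 3)
  field[, ax] <- sin(2 * pi * model$atoms$residue_index / wavelength + phase)
  unit(as.vector(t(field)))
}

# Gram-Schmidt the user modes against the dissociation field and each other
orthonormalize_modes <- function(fields, diss) {
  basis <- list(diss)
  out <- list()
  for (f in fields) {
    v <- unit(as.vector(if (is.matrix(f)) t(f) else f))
    for (b in basis) {
      if (abs(sum(v * b)) > 0.99) {
        abort("planted mode fields are near-degenerate (|cos| > 0.99)")
      }
    }
    for (b in basis) v <- v - sum(v * b) * b
    v <- unit(v)
    basis <- c(basis, list(v))
    out <- c(out, list(v))
  }
  out
}

#' Generate a synthetic trajectory ensemble with planted modes
#'
#' Each frame is `reference + sum_k a_k(t) m_k + d(t) m_diss + noise`, with
#' mode coefficients `a_k ~ N(0, stddev_k)`, dissociation coefficient
#' `d ~ N(0, dissociation_stddev)` along the rigid chain-B translation field,
#' and i.i.d. Gaussian coordinate noise. Contact targets are then imposed by
#' displacing the second residue of each pair so that its minimal atom
#' distance to the first sits below (3.5 A) or above (6.5 A) the 4.5 A
#' contact threshold following a Bernoulli(occupancy) schedule.
#'
#' The single RNG stream is seeded from `spec$seed` and consumed in a fixed
#' documented order: planted-mode coefficients (mode by mode), dissociation
#' coefficients, coordinate noise, then one Bernoulli schedule per contact
#' target in listed order.
#'
#' @param model Structure from [build_toy_dimer()] (or any two-chain model
#'   whose interface normal is y).
#' @param spec The [synthetic_spec()].
#' @return List with `traj` (a [trajectory_ensemble()]), `coefficients`
#'   (tibble: frame_label, dissociation, mode_1, ...), and `fields` (the
#'   orthonormalized planted fields, dissociation first).
#' @export
generate_ensemble <- function(model, spec) {
  A3 <- 3L * n_atoms(model)
  f_count <- spec$n_frames
  diss <- dissociation_field(model)
  fields <- orthonormalize_modes(lapply(spec$planted_modes, `[[`, "field"), diss)
  sds <- vapply(spec$planted_modes, `[[`, 0, "stddev")

  with_local_seed(spec$seed, {
    a <- matrix(0, f_count, length(fields))
    for (k in seq_along(fields)) a[, k] <- rnorm(f_count, 0, sds[k])
    d <- rnorm(f_count, 0, spec$dissociation_stddev)
    noise <- if (spec$noise_stddev > 0) {
      matrix(rnorm(f_count * A3, 0, spec$noise_stddev), f_count, A3)
    } else {
      matrix(0, f_count, A3)
    }
    ref <- flatten_coords(model$xyz)
    xyz <- matrix(rep(ref, each = f_count), f_count, A3)
    for (k in seq_along(fields)) xyz <- xyz + outer(a[, k], fields[[k]])
    xyz <- xyz + outer(d, diss) + noise

    if (!is.null(spec$contact_targets) && nrow(spec$contact_targets) > 0) {
      for (ti in seq_len(nrow(spec$contact_targets))) {
        tg <- spec$contact_targets[ti, ]
        on <- runif(f_count) < tg$occupancy
        idx_i <- atom_indices(model, tibble(chain_id = tg$chain_i,
                                            residue_index = tg$res_i))
        idx_j <- atom_indices(model, tibble(chain_id = tg$chain_j,
                                            residue_index = tg$res_j))
        xyz <- impose_contact_schedule(xyz, idx_i, idx_j, on)
      }
    }

    coeff <- tibble(frame_label = seq_len(f_count) - 1L, dissociation = d)
    for (k in seq_along(fields)) coeff[[paste0("mode_", k)]] <- a[, k]
    list(
      traj = trajectory_ensemble(model, xyz, aligned = FALSE),
      coefficients = coeff,
      fields = c(list(diss), fields)
    )
  })
}

# shift residue-j atoms along the current closest-approach direction so the
# pair's minimal distance lands at CONTACT_DIST_IN or CONTACT_DIST_OUT
impose_contact_schedule <- function(xyz, idx_i, idx_j, on) {
  cols_x <- function(idx) c(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  ci <- cols_x(idx_i); cj <- cols_x(idx_j)
  ni <- length(idx_i); nj <- length(idx_j)
  for (f in seq_len(nrow(xyz))) {
    xi <- matrix(xyz[f, ci], ncol = 3, byrow = TRUE)
    xj <- matrix(xyz[f, cj], ncol = 3, byrow = TRUE)
    d2 <- outer(rowSums(xi^2), rowSums(xj^2), "+") - 2 * xi %*% t(xj)
    amin <- arrayInd(which.min(d2), dim(d2))
    dmin <- sqrt(max(d2[amin], 0))
    u <- unit(xj[amin[2], ] - xi[amin[1], ])
    target <- if (on[f]) CONTACT_DIST_IN else CONTACT_DIST_OUT
    shift <- (target - dmin) * u
    xyz[f, cj] <- xyz[f, cj] + as.vector(t(matrix(shift, nj, 3, byrow = TRUE)))
  }
  xyz
}

#' Generate paired per-residue binding-energy tables with planted effects
#'
#' Emulates per-residue binding-free-energy decompositions for a wild-type /
#' mutant pair: the mutant-minus-wildtype difference is centered at
#' `-effect_size` for planted stabilized residues, `+effect_size` for planted
#' destabilized ones and 0 elsewhere, with Gaussian noise on top.
#'
#' @param residues Residue selection tibble (`chain_id`, `residue_index`).
#' @param stabilized,destabilized Disjoint subsets of `residues` (same
#'   format) planted as stabilized / destabilized in the mutant.
#' @param effect_size Planted |mutant - wildtype| shift, kcal/mol.
#' @param noise Gaussian noise std. dev. on the difference, kcal/mol.
#' @param seed Integer RNG seed.
#' @param systems Character vector of length 2: wild-type and mutant ids.
#' @return List of two energy-table tibbles (`wt`, `mut`) with columns
#'   `system`, `chain_id`, `residue_index`, `dG`.
#' @export
generate_energy_tables <- function(residues, stabilized = NULL,
                                   destabilized = NULL, effect_size = 2.0,
                                   noise = 0.2, seed = 1L,
                                   systems = c("wt", "mut")) {
  residues <- as_tibble(residues)
  key <- function(x) paste(x$chain_id, x$residue_index)
  k_all <- key(residues)
  k_st <- if (is.null(stabilized)) character() else key(as_tibble(stabilized))
  k_de <- if (is.null(destabilized)) character() else key(as_tibble(destabilized))
  if (length(intersect(k_st, k_de)) > 0) {
    abort("stabilized and destabilized sets must be disjoint")
  }
  if (!all(c(k_st, k_de) %in% k_all)) {
    abort("planted residues must be a subset of the residue universe")
  }
  center <- numeric(length(k_all))
  center[k_all %in% k_st] <- -effect_size
  center[k_all %in% k_de] <- +effect_size
  with_local_seed(seed, {
    wt_dg <- rnorm(length(k_all), mean = -0.5, sd = noise)
    delta <- center + rnorm(length(k_all), 0, noise)
    list(
      wt = tibble(system = systems[1], chain_id = residues$chain_id,
                  residue_index = residues$residue_index, dG = wt_dg),
      mut = tibble(system = systems[2], chain_id = residues$chain_id,
                   residue_index = residues$residue_index, dG = wt_dg + delta)
    )
  })
}
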