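# Domain containers: structure_model (topology + reference coordinates) and
# trajectory_ensemble (F frames over the same atoms). Coordinates are always
# in Angstrom; residue identity is (chain_id, author residue number).

# van der Waals radii (Angstrom) used for SASA; unknown elements fall back to C.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
VDW_DEFAULT <- 1.70

vdw_radius_of <- function(element) {
  r <- unname(VDW_RADII[element])
  r[is.na(r)] <- VDW_DEFAULT
  r
}

#' Build a structure model
#'
#' A `structure_model` holds the atom table of a (typically dimeric) protein
#' together with one set of reference coordinates. It is the topology shared
#' by every frame of a [trajectory_ensemble()].
#'
#' @param atoms Data frame with columns `atom_id`, `name`, `element`,
#'   `residue_index`, `residue_name`, `chain_id` and optionally `vdw_radius`
#'   (filled from a built-in element table when absent).
#' @param xyz Numeric A x 3 matrix of reference coordinates in Angstrom.
#' @return An object of class `structure_model` with fields `atoms` (tibble)
#'   and `xyz` (A x 3 matrix).
#' @export
structure_model <- function(atoms, xyz) {
  atoms <- as_tibble(atoms)
  needed <- c("atom_id", "name", "element", "residue_index", "residue_name", "chain_id")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("atoms is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!("vdw_radius" %in% names(atoms))) {
    atoms$vdw_radius <- vdw_radius_of(atoms$element)
  }
  xyz <- as.matrix(xyz)
  if (!is.numeric(xyz) || ncol(xyz) != 3 || nrow(xyz) != nrow(atoms)) {
    abort("xyz must be a numeric matrix with one row per atom and 3 columns")
  }
  if (any(!is.finite(xyz))) abort("xyz contains non-finite coordinates")
  if (any(atoms$vdw_radius <= 0)) abort("all van der Waals radii must be positive")
  key <- paste(atoms$chain_id, atoms$residue_index, atoms$name)
  if (anyDuplicated(key)) {
    abort(paste0("duplicate (chain, residue, atom name): ", key[duplicated(key)][1]))
  }
  # residue numbering must be strictly increasing within each chain (file order)
  for (ch in unique(atoms$chain_id)) {
    res <- atoms$residue_index[atoms$chain_id == ch]
    if (is.unsorted(res)) {
      abort(paste0("residue_index not non-decreasing within chain ", ch))
    }
  }
  structure(
    list(atoms = atoms, xyz = unname(xyz)),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  cat("<structure_model> ", nrow(x$atoms), " atoms, ",
      nrow(residue_table(x)), " residues, chains: ",
      paste(unique(x$atoms$chain_id), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# one row per residue, in model order
residue_table <- function(model) {
  dplyr::distinct(model$atoms, .data$chain_id, .data$residue_index, .data$residue_name)
}

n_atoms <- function(model) nrow(model$atoms)

#' Read a structure from a PDB file
#'
#' Parses coordinate records through [bio3d::read.pdb()] and validates them
#' into a [structure_model()]. The element is taken from the element column
#' when present and inferred from the atom name otherwise; van der Waals radii
#' come from a fixed element table (C 1.70, N 1.55, O 1.52, S 1.80, H 1.20,
#' P 1.80 Angstrom; 1.70 for anything else).
#'
#' Insertion codes are rejected: residue identity here is strictly
#' (chain, author residue number).
#'
#' @param path Path to a PDB file.
#' @return A [structure_model()].
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  check_pdb_records(path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  atoms_from_bio3d(pdb$atom, matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE))
}

# light structural validation with line numbers, ahead of the bio3d parse
check_pdb_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      abort(paste0("malformed ATOM record at line ", i, ": too short"))
    }
    coords <- suppressWarnings(as.numeric(c(
      substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54)
    )))
    if (any(is.na(coords))) {
      abort(paste0("malformed ATOM record at line ", i, ": non-numeric coordinates"))
    }
    if (substr(ln, 27, 27) != " ") {
      abort(paste0("insertion code at line ", i,
                   " is not supported; renumber residues first"))
    }
  }
  invisible(TRUE)
}

atoms_from_bio3d <- function(atom_df, xyz) {
  element <- atom_df$elesy
  blank <- is.na(element) | element == ""
  element[blank] <- infer_element(atom_df$elety[blank])
  chain <- atom_df$chain
  chain[is.na(chain) | chain == ""] <- " "
  atoms <- tibble(
    atom_id = seq_len(nrow(atom_df)),
    name = atom_df$elety,
    element = toupper(element),
    residue_index = as.integer(atom_df$resno),
    residue_name = atom_df$resid,
    chain_id = chain
  )
  structure_model(atoms, xyz)
}

# strip leading digits, first letter is the element (adequate for C/N/O/S/P/H)
infer_element <- function(name) {
  stripped <- sub("^[0-9]*", "", name)
  toupper(substr(stripped, 1, 1))
}

#' Build a trajectory ensemble
#'
#' Bundles F coordinate frames with the [structure_model()] they share.
#' Frames are stored as an F x 3A matrix in (x1, y1, z1, x2, ...) layout.
#'
#' @param model A [structure_model()].
#' @param xyz F x 3A numeric matrix of frame coordinates (Angstrom).
#' @param frame_labels Integer frame labels, unique; defaults to `0:(F-1)`.
#' @param aligned Logical flag recording whether superposition was applied.
#' @return An object of class `trajectory_ensemble`.
#' @export
trajectory_ensemble <- function(model, xyz, frame_labels = NULL, aligned = FALSE) {
  stopifnot(inherits(model, "structure_model"))
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * n_atoms(model)) {
    abort("xyz must have 3 columns per atom of the model")
  }
  if (nrow(xyz) < 1) abort("an ensemble needs at least one frame")
  frame_labels <- frame_labels %||% (seq_len(nrow(xyz)) - 1L)
  if (length(frame_labels) != nrow(xyz) || anyDuplicated(frame_labels)) {
    abort("frame_labels must be unique and match the number of frames")
  }
  structure(
    list(model = model, xyz = unname(xyz),
         frame_labels = as.integer(frame_labels), aligned = isTRUE(aligned)),
    class = "trajectory_ensemble"
  )
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat("<trajectory_ensemble> ", n_frames(x), " frames x ", n_atoms(x$model),
      " atoms (aligned: ", x$aligned, ")\n", sep = "")
  invisible(x)
}

n_frames <- function(traj) nrow(traj$xyz)

# A x 3 coordinates of one frame
frame_coords <- function(traj, i) {
  matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE)
}

flatten_coords <- function(mat) as.vector(t(mat))

#' Read a coordinate ensemble over a known topology
#'
#' Reads a multi-model PDB whose every MODEL block contains the same atoms,
#' in the same order, as `model`. A custom reader can be supplied for other
#' trajectory formats via `reader`; it must return an F x 3A matrix.
#'
#' @param model The [structure_model()] topology.
#' @param path Path to a multi-model PDB file.
#' @param reader Optional function `(path) -> F x 3A matrix` adapter for
#'   other on-disk formats; when given, `path` is passed straight to it.
#' @return A [trajectory_ensemble()] with `aligned = FALSE`.
#' @export
read_ensemble <- function(model, path, reader = NULL) {
  if (!is.null(reader)) {
    return(trajectory_ensemble(model, reader(path), aligned = FALSE))
  }
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  counts <- model_atom_counts(path)
  bad <- which(counts != n_atoms(model))
  if (length(bad) > 0) {
    abort(paste0("frame ", bad[1] - 1L, " has ", counts[bad[1]],
                 " atoms; topology has ", n_atoms(model)))
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  trajectory_ensemble(model, pdb$xyz, aligned = FALSE)
}

# ATOM/HETATM record count per MODEL block (whole file = one block if no MODEL)
model_atom_counts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) == 0) return(sum(is_atom))
  block <- findInterval(which(is_atom), model_starts)
  as.vector(table(factor(block, levels = seq_along(model_starts))))
}

#' Write a structure or ensemble as (multi-model) PDB
#'
#' Writes fixed-width v3 coordinate records; ensembles become one MODEL block
#' per frame. Coordinates round-trip through [read_structure()] /
#' [read_ensemble()] to within the 1e-3 Angstrom precision of the format.
#'
#' @param x A [structure_model()] or [trajectory_ensemble()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "structure_model")) {
    writeLines(c(pdb_block(x$atoms, x$xyz), "END"), path)
  } else if (inherits(x, "trajectory_ensemble")) {
    out <- vector("list", n_frames(x))
    for (i in seq_len(n_frames(x))) {
      out[[i]] <- c(sprintf("MODEL     %4d", i),
                    pdb_block(x$model$atoms, frame_coords(x, i)),
                    "ENDMDL")
    }
    writeLines(c(unlist(out), "END"), path)
  } else {
    abort("write_pdb expects a structure_model or trajectory_ensemble")
  }
  invisible(path)
}

pdb_block <- function(atoms, xyz) {
  name <- ifelse(nchar(atoms$name) >= 4, atoms$name, sprintf(" %-3s", atoms$name))
  sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          atoms$atom_id %% 100000L, name, atoms$residue_name, atoms$chain_id,
          atoms$residue_index, xyz[, 1], xyz[, 2], xyz[, 3], atoms$element)
}

#' Select atoms by a simple expression
#'
#' @param model A [structure_model()].
#' @param expression One of `"calpha"` (CA atoms), `"heavy"` (element != H),
#'   `"chain:<id>"`, or `"residues:<chain>:<i>,<chain>:<j>,..."`.
#' @return Integer atom indices in model (file) order.
#' @export
select_atoms <- function(model, expression) {
  atoms <- model$atoms
  if (expression == "calpha") {
    idx <- which(atoms$name == "CA")
  } else if (expression == "heavy") {
    idx <- which(atoms$element != "H")
  } else if (startsWith(expression, "chain:")) {
    ch <- sub("^chain:", "", expression)
    if (!(ch %in% atoms$chain_id)) abort(paste0("unknown chain: ", ch))
    idx <- which(atoms$chain_id == ch)
  } else if (startsWith(expression, "residues:")) {
    spec <- strsplit(sub("^residues:", "", expression), ",", fixed = TRUE)[[1]]
    parts <- strsplit(spec, ":", fixed = TRUE)
    sel <- tibble(
      chain_id = vapply(parts, `[`, "", 1),
      residue_index = as.integer(vapply(parts, `[`, "", 2))
    )
    idx <- atom_indices(model, sel)
  } else {
    abort(paste0("unknown selection expression: ", expression))
  }
  idx
}

#' Construct a residue selection
#'
#' @param chain_id Character vector of chain identifiers.
#' @param residue_index Integer vector of residue numbers, same length.
#' @param model Optional [structure_model()] to validate against.
#' @return A tibble with columns `chain_id`, `residue_index`, unique rows.
#' @export
residue_selection <- function(chain_id, residue_index, model = NULL) {
  sel <- tibble(chain_id = as.character(chain_id),
                residue_index = as.integer(residue_index))
  if (anyDuplicated(sel)) abort("residue selection contains duplicates")
  if (!is.null(model)) {
    known <- residue_table(model)
    miss <- dplyr::anti_join(sel, known, by = c("chain_id", "residue_index"))
    if (nrow(miss) > 0) {
      abort(paste0("residue not in model: ", miss$chain_id[1], ":",
                   miss$residue_index[1]))
    }
  }
  sel
}

# atom indices (model order) of all atoms belonging to the selected residues
atom_indices <- function(model, selection) {
  key <- paste(model$atoms$chain_id, model$atoms$residue_index)
  want <- paste(selection$chain_id, selection$residue_index)
  if (!all(want %in% key)) {
    abort(paste0("residue not in model: ", want[!(want %in% key)][1]))
  }
  which(key %in% want)
}
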