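# Binding-free-energy tables: windowed statistics of per-frame binding
# energies, two-system comparison, and key-residue selection from
# per-residue decompositions. The energies themselves (e.g. MM/PBSA output)
# are consumed as delimited text; this module never computes them.

#' Read a per-frame binding-energy series
#'
#' Expects a delimited file with header columns `system`, `time_ns`,
#' `dG_kcal_mol`.
#'
#' @param path CSV/TSV path.
#' @return Tibble `system`, `time_ns`, `dG` with strictly increasing times.
#' @export
read_energy_series <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("system", "time_ns", "dG_kcal_mol") %in% names(df)))
  out <- tibble(system = df$system, time_ns = df$time_ns, dG = df$dG_kcal_mol)
  validate_energy_series(out)
}

validate_energy_series <- function(series) {
  if (any(!is.finite(series$dG))) abort("non-finite energy values")
  if (is.unsorted(series$time_ns, strictly = TRUE)) {
    abort("frame times must be strictly increasing")
  }
  series
}

#' Read a per-residue binding-energy decomposition table
#'
#' Expects header columns `system`, `chain`, `residue`, `dG_kcal_mol`.
#'
#' @param path CSV/TSV path.
#' @return Tibble `system`, `chain_id`, `residue_index`, `dG`.
#' @export
read_energy_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("system", "chain", "residue", "dG_kcal_mol") %in% names(df)))
  out <- tibble(system = df$system, chain_id = as.character(df$chain),
                residue_index = as.integer(df$residue), dG = df$dG_kcal_mol)
  if (anyDuplicated(out[, c("chain_id", "residue_index")])) {
    abort("duplicate residues in energy table")
  }
  out
}

#' Windowed mean and SD of a binding-energy series
#'
#' For each window end time, reports the mean and standard deviation over all
#' frames with `time_ns <= window`. `digits = 0` reproduces the integer
#' kcal/mol reporting convention of simulation binding-energy tables.
#'
#' @param series Energy-series tibble (`system`, `time_ns`, `dG`).
#' @param windows Numeric vector of window end times (ns).
#' @param digits Rounding for the reported columns (default 0; use `NA` to
#'   disable).
#' @return Tibble `system`, `window_ns`, `n_frames`, `mean_dG`, `sd_dG`.
#' @export
windowed_stats <- function(series, windows, digits = 0) {
  validate_energy_series(series)
  purrr::map_dfr(windows, function(w) {
    sel <- series$dG[series$time_ns <= w]
    if (length(sel) == 0) abort(paste0("empty window at ", w, " ns"))
    m <- mean(sel); s <- if (length(sel) > 1) sd(sel) else 0
    if (!is.na(digits)) { m <- round(m, digits); s <- round(s, digits) }
    tibble(system = series$system[1], window_ns = w,
           n_frames = length(sel), mean_dG = m, sd_dG = s)
  })
}

#' Compare the binding energies of two systems
#'
#' Welch two-sample t-test on the per-frame values (optionally after block
#' averaging to tame autocorrelation). P-values below the double-precision
#' floor are labelled `"< 2.2e-16"`.
#'
#' @param a,b Energy-series tibbles.
#' @param block Block size (frames) for optional block averaging (default 1:
#'   raw per-frame values).
#' @return One-row tibble: `system_a`, `system_b`, `mean_a`, `mean_b`,
#'   `difference` (a - b), `statistic`, `p_value`, `p_label`.
#' @export
compare_systems <- function(a, b, block = 1L) {
  avg_blocks <- function(x, k) {
    if (k <= 1) return(x)
    grp <- (seq_along(x) - 1) %/% k
    as.vector(tapply(x, grp, mean))
  }
  xa <- avg_blocks(a$dG, block); xb <- avg_blocks(b$dG, block)
  tt <- t.test(xa, xb)
  p <- tt$p.value
  tibble(
    system_a = a$system[1], system_b = b$system[1],
    mean_a = mean(xa), mean_b = mean(xb),
    difference = mean(xa) - mean(xb),
    statistic = unname(tt$statistic),
    p_value = p,
    p_label = if (p < 2.2e-16) "< 2.2e-16" else format(p, digits = 3)
  )
}

#' Select key residues by binding-energy difference
#'
#' Computes the per-residue difference `ddG = mutant - wildtype` and selects
#' residues past a threshold: stabilizing residues have `ddG < -threshold`
#' (sorted ascending, most stabilizing first), destabilizing residues have
#' `ddG > threshold` (sorted descending). Both inequalities are strict. Ties
#' preserve residue order.
#'
#' @param wt,mut Energy-table tibbles over the same residue universe.
#' @param threshold kcal/mol (default 1.0).
#' @param direction `"stabilizing"` or `"destabilizing"`.
#' @return Tibble `chain_id`, `residue_index`, `ddG`, ordered by effect.
#' @export
select_key_residues <- function(wt, mut, threshold = 1.0,
                                direction = c("stabilizing", "destabilizing")) {
  direction <- match.arg(direction)
  key <- function(x) paste(x$chain_id, x$residue_index)
  if (!setequal(key(wt), key(mut)) || nrow(wt) != nrow(mut)) {
    off <- c(setdiff(key(wt), key(mut)), setdiff(key(mut), key(wt)))
    abort(paste0("residue universes differ: ",
                 paste(head(off, 5), collapse = ", ")))
  }
  mut_ord <- mut[match(key(wt), key(mut)), ]
  dd <- tibble(chain_id = wt$chain_id, residue_index = wt$residue_index,
               ddG = mut_ord$dG - wt$dG)
  if (direction == "stabilizing") {
    sel <- dd[dd$ddG < -threshold, ]
    sel[order(sel$ddG), ]
  } else {
    sel <- dd[dd$ddG > threshold, ]
    sel[order(-sel$ddG), ]
  }
}

#' Residues common to two key-residue selections
#'
#' @param set_a,set_b Tibbles with `chain_id`, `residue_index` (extra columns
#'   from `set_a` are kept).
#' @return The intersection, ordered as in `set_a`.
#' @export
common_key_residues <- function(set_a, set_b) {
  dplyr::semi_join(as_tibble(set_a), as_tibble(set_b),
                   by = c("chain_id", "residue_index"))
}
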