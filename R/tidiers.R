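# broom-style tidiers for the fitted/derived objects.

#' Tidy a mode set into a long per-residue table
#'
#' One row per residue and mode: amplitude and unit direction components.
#'
#' @param x A `mode_set` from [pca_modes()].
#' @param modes Which mode indices to include (default all).
#' @param ... Unused.
#' @return Tibble: `mode`, `chain_id`, `residue_index`, `amplitude`,
#'   `dx`, `dy`, `dz`, `defined`.
#' @export
tidy.mode_set <- function(x, modes = seq_along(x$variances), ...) {
  purrr::map_dfr(modes, function(k) {
    dplyr::mutate(residue_amplitudes(x, k), mode = k, .before = 1)
  })
}

#' One-row summary of a mode set
#'
#' @param x A `mode_set`.
#' @param ... Unused.
#' @return Tibble: `n_modes`, `n_atoms`, `total_variance`,
#'   `top_variance_fraction`.
#' @export
glance.mode_set <- function(x, ...) {
  tibble(
    n_modes = ncol(x$modes),
    n_atoms = length(x$atom_indices),
    total_variance = sum(x$variances),
    top_variance_fraction = x$variances[1] / sum(x$variances)
  )
}

#' Tidy a functional mode into per-frame projections
#'
#' @param x A `functional_mode` from [fma()].
#' @param ... Unused.
#' @return Tibble: `frame_label`, `half`, `functional`, `fitted`.
#' @export
tidy.functional_mode <- function(x, ...) x$projection

#' One-row summary of a functional-mode fit
#'
#' @param x A `functional_mode`.
#' @param ... Unused.
#' @return Tibble: `n_components`, `train_pcc`, `validation_pcc`.
#' @export
glance.functional_mode <- function(x, ...) {
  tibble(n_components = x$n_components, train_pcc = x$train_pcc,
         validation_pcc = x$validation_pcc)
}

#' Tidy a network summary into one row per node
#'
#' @param x A `network_summary` from [summarize_network()].
#' @param ... Unused.
#' @return Tibble: `node`, `degree`.
#' @export
tidy.network_summary <- function(x, ...) {
  tibble(node = names(x$degree), degree = unname(x$degree))
}

#' One-row summary of a residue network
#'
#' @param x A `network_summary`.
#' @param ... Unused.
#' @return Tibble: `chain_id`, `n_nodes`, `n_edges`, `average_degree`,
#'   `average_clustering`.
#' @export
glance.network_summary <- function(x, ...) {
  tibble(chain_id = x$chain_id, n_nodes = x$n_nodes, n_edges = x$n_edges,
         average_degree = x$average_degree,
         average_clustering = x$average_clustering)
}

#' Tidy a clustering result into one row per cluster
#'
#' @param x A `cluster_result` from [gromos_cluster()] or [select_cutoff()].
#' @param ... Unused.
#' @return Tibble: `cluster`, `size`, `fraction`, `representative`.
#' @export
tidy.cluster_result <- function(x, ...) {
  total <- sum(x$sizes)
  tibble(cluster = seq_along(x$sizes), size = x$sizes,
         fraction = x$sizes / total, representative = x$representatives)
}

#' One-row summary of a clustering result
#'
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @return Tibble: `cutoff`, `n_clusters`, `coverage_top8`.
#' @export
glance.cluster_result <- function(x, ...) {
  tibble(cutoff = x$cutoff, n_clusters = length(x$sizes),
         coverage_top8 = x$coverage_top8)
}
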