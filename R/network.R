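# Dynamic residue-interaction networks: an edge requires BOTH correlated
# motion direction in a chosen PC mode (angle < 45 degrees by default) AND
# persistent physical contact (min heavy-atom distance < 4.5 Angstrom in at
# least 75% of frames).

#' Residue-pair contact occupancy along a trajectory
#'
#' A residue pair counts as in contact in a frame iff the minimum distance
#' over its heavy-atom pairs is strictly below `distance`; occupancy is the
#' fraction of frames in contact.
#'
#' @param traj A [trajectory_ensemble()].
#' @param distance Contact threshold in Angstrom (default 4.5, strict `<`).
#' @param selection Atom selection used for the distances (default heavy).
#' @param keep_frames Keep the per-frame hit matrix (needed by
#'   [bootstrap_networks()] to resample frames without recomputing).
#' @return Object of class `contact_occupancy`: `pairs` tibble (`chain_i`,
#'   `res_i`, `chain_j`, `res_j`, `occupancy`), `threshold_distance`,
#'   `frame_count`, and optionally `frame_hits` (pairs x F logical matrix).
#' @export
contact_occupancy <- function(traj, distance = 4.5, selection = "heavy",
                              keep_frames = FALSE) {
  model <- traj$model
  idx <- select_atoms(model, selection)
  res_key <- paste(model$atoms$chain_id[idx], model$atoms$residue_index[idx])
  res_levels <- unique(res_key)
  res_of_atom <- match(res_key, res_levels)
  n_at <- length(idx)
  # all atom pairs belonging to different residues
  pair_i <- rep(seq_len(n_at), times = n_at)
  pair_j <- rep(seq_len(n_at), each = n_at)
  keep <- pair_i < pair_j & res_of_atom[pair_i] != res_of_atom[pair_j]
  pair_i <- pair_i[keep]; pair_j <- pair_j[keep]
  rp <- paste(pmin(res_of_atom[pair_i], res_of_atom[pair_j]),
              pmax(res_of_atom[pair_i], res_of_atom[pair_j]))
  rp_f <- factor(rp, levels = unique(rp))
  group <- as.integer(rp_f)
  n_pairs <- nlevels(rp_f)

  cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  th2 <- distance^2
  f_count <- n_frames(traj)
  hits <- matrix(FALSE, n_pairs, f_count)
  for (f in seq_len(f_count)) {
    co <- matrix(traj$xyz[f, cols], ncol = 3, byrow = TRUE)
    d2 <- (co[pair_i, 1] - co[pair_j, 1])^2 +
      (co[pair_i, 2] - co[pair_j, 2])^2 +
      (co[pair_i, 3] - co[pair_j, 3])^2
    hit <- d2 < th2
    hits[, f] <- rowsum(as.integer(hit), group, reorder = FALSE)[, 1] > 0
  }
  first_of_pair <- match(levels(rp_f), rp)
  ri <- res_of_atom[pair_i[first_of_pair]]
  rj <- res_of_atom[pair_j[first_of_pair]]
  lev <- strsplit(res_levels, " ", fixed = TRUE)
  lev_chain <- vapply(lev, `[`, "", 1)
  lev_res <- as.integer(vapply(lev, `[`, "", 2))
  pairs <- tibble(
    chain_i = lev_chain[pmin(ri, rj)], res_i = lev_res[pmin(ri, rj)],
    chain_j = lev_chain[pmax(ri, rj)], res_j = lev_res[pmax(ri, rj)],
    occupancy = rowMeans(hits)
  )
  structure(
    list(pairs = pairs, threshold_distance = distance,
         frame_count = f_count,
         frame_hits = if (keep_frames) hits else NULL),
    class = "contact_occupancy"
  )
}

#' @export
print.contact_occupancy <- function(x, ...) {
  cat("<contact_occupancy> ", nrow(x$pairs), " residue pairs over ",
      x$frame_count, " frames (< ", x$threshold_distance, " A)\n", sep = "")
  invisible(x)
}

#' Build per-chain residue-interaction networks
#'
#' Two residues are connected iff (i) both have a defined motion direction in
#' the chosen mode and the angle between their directions is below
#' `angle_threshold`, and (ii) their contact occupancy is at least
#' `occupancy_threshold`. Only residues with at least one incident edge
#' become nodes. By default edges are intra-chain and one network is returned
#' per chain; `scope = "all"` keeps inter-chain edges in a single network.
#'
#' @param modes A [pca_modes()] `mode_set`.
#' @param mode_index Mode whose per-residue directions define criterion (i).
#' @param occupancy A [contact_occupancy()] result over the same residues.
#' @param angle_threshold Degrees; edge requires direction cosine
#'   `> cos(angle_threshold)` (default 45).
#' @param occupancy_threshold Minimum contact occupancy, inclusive
#'   (default 0.75).
#' @param min_sequence_separation Exclude pairs with |res_i - res_j| below
#'   this within a chain (default 0: sequential neighbours are kept).
#' @param scope `"intra"` (per-chain networks) or `"all"`.
#' @return List of `residue_network` objects (one per chain for `"intra"`),
#'   each with `chain_id`, `nodes`, `edges` (tibble with `occupancy` and
#'   `direction_cosine`), `parameters`.
#' @export
build_network <- function(modes, mode_index, occupancy,
                          angle_threshold = 45, occupancy_threshold = 0.75,
                          min_sequence_separation = 0L,
                          scope = c("intra", "all")) {
  scope <- match.arg(scope)
  amp <- residue_amplitudes(modes, mode_index)
  key <- paste(amp$chain_id, amp$residue_index)
  dirs <- as.matrix(amp[, c("dx", "dy", "dz")])
  pairs <- occupancy$pairs
  ki <- match(paste(pairs$chain_i, pairs$res_i), key)
  kj <- match(paste(pairs$chain_j, pairs$res_j), key)
  ok <- !is.na(ki) & !is.na(kj) & pairs$occupancy >= occupancy_threshold
  ok <- ok & amp$defined[ki] & amp$defined[kj]
  cosine <- rowSums(dirs[ki, , drop = FALSE] * dirs[kj, , drop = FALSE])
  ok <- ok & !is.na(cosine) & cosine > cos(angle_threshold * pi / 180)
  if (scope == "intra") {
    ok <- ok & pairs$chain_i == pairs$chain_j
  }
  if (min_sequence_separation > 0) {
    same <- pairs$chain_i == pairs$chain_j
    ok <- ok & !(same & abs(pairs$res_i - pairs$res_j) < min_sequence_separation)
  }
  edges <- dplyr::mutate(pairs[ok, ], direction_cosine = cosine[ok])
  params <- list(angle_threshold = angle_threshold,
                 occupancy_threshold = occupancy_threshold,
                 distance = occupancy$threshold_distance,
                 mode_index = mode_index, scope = scope)
  if (scope == "all") {
    return(list(new_residue_network("all", edges, params)))
  }
  chains <- sort(unique(modes$residues$chain_id))
  lapply(chains, function(ch) {
    new_residue_network(ch, dplyr::filter(edges, .data$chain_i == ch), params)
  })
}

new_residue_network <- function(chain_id, edges, parameters) {
  nodes <- unique(rbind(
    data.frame(chain_id = edges$chain_i, residue_index = edges$res_i),
    data.frame(chain_id = edges$chain_j, residue_index = edges$res_j)
  ))
  nodes <- dplyr::arrange(as_tibble(nodes), .data$chain_id, .data$residue_index)
  structure(
    list(chain_id = chain_id, nodes = nodes, edges = as_tibble(edges),
         parameters = parameters),
    class = "residue_network"
  )
}

#' @export
print.residue_network <- function(x, ...) {
  cat("<residue_network> chain ", x$chain_id, ": ", nrow(x$nodes),
      " nodes, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

node_name <- function(chain, res) paste0(chain, ":", res)

# igraph view of a residue_network
network_graph <- function(network) {
  if (nrow(network$edges) == 0) abort("network has no edges")
  igraph::graph_from_data_frame(
    data.frame(from = node_name(network$edges$chain_i, network$edges$res_i),
               to = node_name(network$edges$chain_j, network$edges$res_j)),
    directed = FALSE,
    vertices = node_name(network$nodes$chain_id, network$nodes$residue_index)
  )
}

#' Topological summary of a residue network
#'
#' Node and edge counts, per-node degree, average degree (`2E/N`) and the
#' average local clustering coefficient
#' (`2 * triangles(v) / (deg(v) * (deg(v) - 1))`, defined as 0 for
#' degree < 2, averaged over nodes).
#'
#' @param network A `residue_network` from [build_network()].
#' @return Object of class `network_summary` with fields `chain_id`,
#'   `n_nodes`, `n_edges`, `degree` (named vector), `average_degree`,
#'   `average_clustering`.
#' @export
summarize_network <- function(network) {
  g <- network_graph(network)
  deg <- igraph::degree(g)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  structure(
    list(chain_id = network$chain_id,
         n_nodes = igraph::vcount(g),
         n_edges = igraph::ecount(g),
         degree = deg,
         average_degree = 2 * igraph::ecount(g) / igraph::vcount(g),
         average_clustering = mean(cc)),
    class = "network_summary"
  )
}

#' @export
print.network_summary <- function(x, ...) {
  cat("<network_summary> chain ", x$chain_id, ": N=", x$n_nodes,
      " E=", x$n_edges, " <k>=", round(x$average_degree, 3),
      " <C>=", round(x$average_clustering, 3), "\n", sep = "")
  invisible(x)
}

#' Shortest paths from a perturbation residue to target residues
#'
#' Breadth-first shortest-path lengths (in edges) plus the number of distinct
#' geodesics and one example path per target. Targets missing from the
#' network, or disconnected from the source, are flagged unreachable.
#'
#' @param network A `residue_network`.
#' @param source Length-2 list/vector-like (`chain_id`, `residue_index`) or
#'   one-row tibble identifying the source residue.
#' @param targets Residue selection tibble (`chain_id`, `residue_index`).
#' @return Tibble: `chain_id`, `residue_index`, `reachable`, `path_length`,
#'   `n_shortest_paths`, `example_path` (list of node-name vectors).
#' @export
network_paths <- function(network, source, targets) {
  if (is.data.frame(source)) {
    src <- node_name(source$chain_id[1], source$residue_index[1])
  } else {
    src <- node_name(as.character(source[[1]]), as.integer(source[[2]]))
  }
  g <- network_graph(network)
  if (!(src %in% igraph::V(g)$name)) {
    abort(paste0("source residue ", src, " is not a network node"))
  }
  targets <- as_tibble(targets)
  tnames <- node_name(targets$chain_id, targets$residue_index)
  res <- purrr::map(tnames, function(tn) {
    if (!(tn %in% igraph::V(g)$name) ||
        is.infinite(igraph::distances(g, v = src, to = tn)[1, 1])) {
      return(list(reachable = FALSE, len = NA_integer_, n = 0L,
                  path = list(character())))
    }
    asp <- igraph::all_shortest_paths(g, from = src, to = tn)
    list(reachable = TRUE,
         len = length(asp$vpaths[[1]]) - 1L,
         n = length(asp$vpaths),
         path = list(igraph::V(g)$name[asp$vpaths[[1]]]))
  })
  tibble(
    chain_id = targets$chain_id,
    residue_index = targets$residue_index,
    reachable = purrr::map_lgl(res, "reachable"),
    path_length = purrr::map_int(res, "len"),
    n_shortest_paths = purrr::map_int(res, "n"),
    example_path = purrr::map(res, ~ .x$path[[1]])
  )
}

#' Bootstrap robustness of network properties
#'
#' Repeatedly resamples a fraction of the frames without replacement
#' (seeded), recomputes contact occupancies on the subsample, rebuilds the
#' networks with the same mode (the mode itself is not recomputed), and
#' summarizes each replicate.
#'
#' @inheritParams build_network
#' @param traj The [trajectory_ensemble()] the occupancies come from.
#' @param fraction Fraction of frames per replicate, in (0, 1] (default 0.8).
#' @param repeats Number of replicates (default 10).
#' @param seed RNG seed for the frame resampling.
#' @param distance Contact distance threshold (Angstrom).
#' @param selection Atom selection for contacts.
#' @return List with `replicates` (tibble: repeat, chain_id, n_nodes,
#'   n_edges, average_degree, average_clustering) and `dispersion` (tibble of
#'   per-chain mean and sd for each property).
#' @export
bootstrap_networks <- function(traj, modes, mode_index,
                               angle_threshold = 45,
                               occupancy_threshold = 0.75,
                               distance = 4.5, selection = "heavy",
                               min_sequence_separation = 0L,
                               fraction = 0.8, repeats = 10L, seed = 1L) {
  if (fraction <= 0 || fraction > 1) abort("fraction must be in (0, 1]")
  if (repeats < 1) abort("repeats must be >= 1")
  occ <- contact_occupancy(traj, distance = distance, selection = selection,
                           keep_frames = TRUE)
  f_count <- occ$frame_count
  n_take <- max(1L, floor(fraction * f_count))
  reps <- with_local_seed(seed, {
    purrr::map(seq_len(repeats), function(r) {
      take <- if (n_take == f_count) seq_len(f_count) else {
        sort(sample.int(f_count, n_take))
      }
      sub <- occ
      sub$pairs$occupancy <- rowMeans(occ$frame_hits[, take, drop = FALSE])
      sub$frame_count <- n_take
      nets <- build_network(modes, mode_index, sub,
                            angle_threshold = angle_threshold,
                            occupancy_threshold = occupancy_threshold,
                            min_sequence_separation = min_sequence_separation)
      purrr::map_dfr(nets, function(nw) {
        if (nrow(nw$edges) == 0) {
          return(tibble(chain_id = nw$chain_id, n_nodes = 0L, n_edges = 0L,
                        average_degree = NA_real_,
                        average_clustering = NA_real_))
        }
        s <- summarize_network(nw)
        tibble(chain_id = s$chain_id, n_nodes = s$n_nodes,
               n_edges = s$n_edges, average_degree = s$average_degree,
               average_clustering = s$average_clustering)
      })
    })
  })
  replicates <- dplyr::bind_rows(reps, .id = "replicate")
  replicates$replicate <- as.integer(replicates$replicate)
  dispersion <- dplyr::summarise(
    dplyr::group_by(
      tidyr::pivot_longer(replicates, -c("replicate", "chain_id"),
                          names_to = "property"),
      .data$chain_id, .data$property
    ),
    mean = mean(.data$value), sd = sd(.data$value), .groups = "drop"
  )
  list(replicates = replicates, dispersion = dispersion)
}
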