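# Independent oracles and small fixture builders used across the suite.

# Monte-Carlo SASA oracle: per-atom accessible area estimated by sampling
# `n` random points on each extended sphere and rejecting those inside any
# other extended sphere. Independent of the golden-spiral implementation.
mc_sasa_oracle <- function(coords, radii, probe = 1.4, n = 1e6, seed = 42) {
  set.seed(seed)
  ext <- radii + probe
  vapply(seq_len(nrow(coords)), function(i) {
    u <- matrix(rnorm(3 * n), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    p <- sweep(u * ext[i], 2, coords[i, ], "+")
    ok <- rep(TRUE, n)
    for (j in seq_len(nrow(coords))[-i]) {
      d2 <- (p[, 1] - coords[j, 1])^2 + (p[, 2] - coords[j, 2])^2 +
        (p[, 3] - coords[j, 3])^2
      ok <- ok & (d2 >= ext[j]^2)
    }
    mean(ok) * 4 * pi * ext[i]^2
  }, 0)
}

# exhaustive shortest-path count oracle: enumerate all simple paths up to
# the BFS distance by depth-first search
brute_force_geodesics <- function(adj, from, to) {
  n <- nrow(adj)
  # BFS distance
  dist <- rep(Inf, n); dist[from] <- 0
  queue <- from
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (w in which(adj[v, ] > 0)) {
      if (is.infinite(dist[w])) { dist[w] <- dist[v] + 1; queue <- c(queue, w) }
    }
  }
  if (is.infinite(dist[to])) return(list(length = NA_integer_, count = 0L))
  target_len <- dist[to]
  count <- 0L
  recurse <- function(v, depth) {
    if (v == to) {
      if (depth == target_len) count <<- count + 1L
      return()
    }
    if (depth >= target_len) return()
    for (w in which(adj[v, ] > 0)) recurse(w, depth + 1)
  }
  recurse(from, 0)
  list(length = as.integer(target_len), count = count)
}

# Erdos-Renyi-style random graph as a symmetric adjacency matrix
random_graph_adj <- function(n_nodes, p_edge, seed) {
  set.seed(seed)
  adj <- matrix(0L, n_nodes, n_nodes)
  for (i in seq_len(n_nodes - 1)) {
    for (j in (i + 1):n_nodes) {
      if (runif(1) < p_edge) adj[i, j] <- adj[j, i] <- 1L
    }
  }
  adj
}

# wrap an adjacency matrix (nodes on chain A) as a residue_network
network_from_adj <- function(adj) {
  idx <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  edges <- tibble::tibble(
    chain_i = "A", res_i = as.integer(idx[, 1]),
    chain_j = "A", res_j = as.integer(idx[, 2]),
    occupancy = 1, direction_cosine = 1
  )
  dimerdyn:::new_residue_network("A", edges, list())
}

# random proper rotation matrix
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# tiny two-chain PDB text (3 residues per chain, CA + CB)
write_tiny_dimer_pdb <- function(path) {
  model <- build_toy_dimer(synthetic_spec(n_residues_per_chain = 4,
                                          atoms_per_residue = 2,
                                          n_frames = 1))
  write_pdb(model, path)
  model
}

# quick default: small toy system + generated ensemble
toy_system <- function(n_res = 8, n_frames = 200, noise = 0.05, seed = 7,
                       diss_sd = 2, modes = list(), contacts = NULL,
                       atoms_per_residue = 2) {
  spec <- synthetic_spec(
    n_residues_per_chain = n_res, atoms_per_residue = atoms_per_residue,
    n_frames = n_frames, planted_modes = modes,
    dissociation_stddev = diss_sd, noise_stddev = noise,
    contact_targets = contacts, seed = seed
  )
  model <- build_toy_dimer(spec)
  gen <- generate_ensemble(model, spec)
  list(spec = spec, model = model, gen = gen, traj = gen$traj)
}
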