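# fixed-geometry ensembles for contact tests
static_traj <- function(model, n_frames = 4) {
  ref <- dimerdyn:::flatten_coords(model$xyz)
  trajectory_ensemble(model, matrix(rep(ref, each = n_frames), n_frames))
}

test_that("contact occupancy is 1 for permanent contacts and 0 beyond the
           cutoff", {
  sys <- toy_system(n_res = 6, n_frames = 1)
  traj <- static_traj(sys$model)
  occ <- contact_occupancy(traj)$pairs
  # sequential CA neighbours sit at 3.8 A < 4.5 A in every frame
  seq_pairs <- occ[occ$chain_i == "A" & occ$chain_j == "A" &
                     occ$res_j == occ$res_i + 1, ]
  expect_true(all(seq_pairs$occupancy == 1))
  # residues three apart (11.4 A) never touch
  far <- occ[occ$chain_i == "A" & occ$chain_j == "A" &
               occ$res_j == occ$res_i + 3, ]
  expect_true(all(far$occupancy == 0))
})

test_that("a planted Bernoulli(0.75) schedule lands within the binomial CI", {
  ct <- tibble::tibble(chain_i = "A", res_i = 2, chain_j = "B", res_j = 9,
                       occupancy = 0.75)
  sys <- toy_system(n_res = 10, n_frames = 4000, noise = 0.02, diss_sd = 0,
                    contacts = ct, seed = 23)
  occ <- contact_occupancy(sys$traj)$pairs
  got <- occ$occupancy[occ$chain_i == "A" & occ$res_i == 2 &
                         occ$chain_j == "B" & occ$res_j == 9]
  expect_equal(got, 0.75, tolerance = 0.02 / 0.75)
})

test_that("network edges require both motion and contact criteria", {
  sys <- toy_system(n_res = 4, n_frames = 1)
  traj <- static_traj(sys$model)
  occ <- contact_occupancy(traj)
  n_ca <- 8
  # all residues moving identically: complete graph over contacting pairs
  same <- dimerdyn:::unit(rep(c(1, 0, 0), n_ca))
  ms_same <- structure(
    list(atom_indices = select_atoms(sys$model, "calpha"),
         residues = dimerdyn:::residue_table(sys$model)[, 1:2],
         mean_structure = sys$model$xyz[select_atoms(sys$model, "calpha"), ],
         modes = matrix(same, ncol = 1), variances = 1),
    class = "mode_set"
  )
  nets <- build_network(ms_same, 1, occ)
  got_a <- nets[[1]]$edges
  want_a <- occ$pairs[occ$pairs$chain_i == "A" & occ$pairs$chain_j == "A" &
                        occ$pairs$occupancy >= 0.75, ]
  expect_equal(nrow(got_a), nrow(want_a))

  # orthogonal motions (90 degrees) kill every edge
  alt <- dimerdyn:::unit(as.vector(t(cbind(rep(c(1, 0), 4), rep(c(0, 1), 4), 0))))
  ms_alt <- ms_same; ms_alt$modes <- matrix(alt, ncol = 1)
  nets_alt <- build_network(ms_alt, 1, occ)
  expect_true(all(vapply(nets_alt, function(n) nrow(n$edges), 0L) == 0))
})

test_that("a planted edge set is recovered exactly under the default
           thresholds", {
  # contacts at occupancy {0.6, 0.8, 1.0} crossed with angles {20, 70} deg,
  # on residue pairs well separated along chain A
  ct <- tibble::tibble(
    chain_i = "A", res_i = c(1, 5, 9, 13, 17, 21),
    chain_j = "A", res_j = c(3, 7, 11, 15, 19, 23),
    occupancy = rep(c(0.6, 0.8, 1.0), 2)
  )
  angle <- rep(c(20, 70), each = 3) * pi / 180
  sys <- toy_system(n_res = 24, n_frames = 1500, noise = 0.02, diss_sd = 0,
                    contacts = ct, seed = 25)
  occ <- contact_occupancy(sys$traj)
  # handcrafted mode: direction x for res_i, rotated by the planted angle for
  # res_j, zero (undefined) for every other residue
  ca <- select_atoms(sys$model, "calpha")
  res <- dimerdyn:::residue_table(sys$model)[, 1:2]
  v <- matrix(0, length(ca), 3)
  for (k in seq_len(nrow(ct))) {
    i <- which(res$chain_id == "A" & res$residue_index == ct$res_i[k])
    j <- which(res$chain_id == "A" & res$residue_index == ct$res_j[k])
    v[i, ] <- c(1, 0, 0)
    v[j, ] <- c(cos(angle[k]), sin(angle[k]), 0)
  }
  ms <- structure(
    list(atom_indices = ca, residues = res,
         mean_structure = sys$model$xyz[ca, ],
         modes = matrix(dimerdyn:::unit(as.vector(t(v))), ncol = 1),
         variances = 1),
    class = "mode_set"
  )
  nets <- build_network(ms, 1, occ)
  edges <- nets[[1]]$edges
  # expected: angle < 45 AND occupancy >= 0.75 -> pairs (5,7) and (9,11)
  expect_equal(nrow(edges), 2)
  expect_equal(sort(edges$res_i), c(5, 9))
  expect_equal(sort(edges$res_j), c(7, 11))

  # edge monotonicity: stricter thresholds never add edges
  for (ang in c(30, 15)) {
    for (occ_th in c(0.85, 0.95)) {
      fewer <- build_network(ms, 1, occ, angle_threshold = ang,
                             occupancy_threshold = occ_th)[[1]]$edges
      expect_lte(nrow(fewer), nrow(edges))
    }
  }
})

test_that("network summaries match hand-enumerated graphs and 2E/N", {
  # triangle: clustering 1
  tri <- matrix(0L, 3, 3); tri[cbind(c(1, 1, 2), c(2, 3, 3))] <- 1L
  tri <- tri + t(tri)
  s_tri <- summarize_network(network_from_adj(tri))
  expect_equal(s_tri$average_clustering, 1)
  expect_equal(s_tri$average_degree, 2)

  # path of 4 nodes: no triangles, degrees 1,2,2,1
  p4 <- matrix(0L, 4, 4); p4[cbind(1:3, 2:4)] <- 1L; p4 <- p4 + t(p4)
  s_p4 <- summarize_network(network_from_adj(p4))
  expect_equal(s_p4$average_clustering, 0)
  expect_equal(s_p4$average_degree, 1.5)
  expect_equal(s_p4$average_degree, 2 * s_p4$n_edges / s_p4$n_nodes,
               tolerance = 1e-9)
})

test_that("shortest-path lengths and geodesic counts match brute force", {
  # adjacent pair
  adj2 <- matrix(0L, 2, 2); adj2[1, 2] <- adj2[2, 1] <- 1L
  p <- network_paths(network_from_adj(adj2), list("A", 1),
                     tibble::tibble(chain_id = "A", residue_index = 2L))
  expect_equal(p$path_length, 1L)
  expect_equal(p$n_shortest_paths, 1L)

  # 4-cycle, opposite corners: two geodesics of length 2
  c4 <- matrix(0L, 4, 4); c4[cbind(c(1, 2, 3, 4), c(2, 3, 4, 1))] <- 1L
  c4 <- c4 + t(c4)
  p2 <- network_paths(network_from_adj(c4), list("A", 1),
                      tibble::tibble(chain_id = "A", residue_index = 3L))
  expect_equal(p2$path_length, 2L)
  expect_equal(p2$n_shortest_paths, 2L)

  # random graphs against exhaustive enumeration
  for (s in 1:5) {
    adj <- random_graph_adj(12, 0.25, seed = 300 + s)
    nw <- network_from_adj(adj)
    nodes <- sort(unique(c(nw$edges$res_i, nw$edges$res_j)))
    src <- nodes[1]
    tg <- tibble::tibble(chain_id = "A", residue_index = setdiff(nodes, src))
    got <- network_paths(nw, list("A", src), tg)
    for (r in seq_len(nrow(got))) {
      oracle <- brute_force_geodesics(adj, src, got$residue_index[r])
      if (got$reachable[r]) {
        expect_equal(got$path_length[r], oracle$length)
        expect_equal(got$n_shortest_paths[r], oracle$count)
      } else {
        expect_equal(oracle$count, 0L)
      }
    }
  }

  # unreachable targets are flagged, not zero-length
  disc <- matrix(0L, 4, 4); disc[1, 2] <- disc[2, 1] <- 1L
  disc[3, 4] <- disc[4, 3] <- 1L
  p3 <- network_paths(network_from_adj(disc), list("A", 1),
                      tibble::tibble(chain_id = "A", residue_index = 3L))
  expect_false(p3$reachable)
  expect_true(is.na(p3$path_length))
})

test_that("bootstrap at fraction 1.0 reproduces the full network and
           degenerate occupancies have zero dispersion", {
  sys <- toy_system(n_res = 6, n_frames = 60, noise = 0.02, diss_sd = 0,
                    seed = 27)
  al <- align_ensemble(sys$traj)
  m <- pca_modes(al)
  occ <- contact_occupancy(sys$traj)
  full <- build_network(m, 1, occ)
  full_edges <- vapply(full, function(nw) nrow(nw$edges), 0L)
  names(full_edges) <- vapply(full, `[[`, "", "chain_id")
  boot <- bootstrap_networks(sys$traj, m, 1, fraction = 1.0, repeats = 3,
                             seed = 5)
  for (r in 1:3) {
    rep_rows <- boot$replicates[boot$replicates$replicate == r, ]
    for (ch in rep_rows$chain_id) {
      got <- rep_rows[rep_rows$chain_id == ch, ]
      expect_equal(got$n_edges, unname(full_edges[ch]))
      if (full_edges[ch] > 0) {
        fs <- glance(summarize_network(full[[match(ch, names(full_edges))]]))
        expect_equal(got$average_degree, fs$average_degree)
      }
    }
  }
  expect_true(all(boot$dispersion$sd == 0, na.rm = TRUE))

  # noise-free geometry: occupancies are all 0/1, dispersion 0 at fraction 0.8
  frozen <- toy_system(n_res = 6, n_frames = 40, noise = 0, diss_sd = 0)
  al2 <- align_ensemble(trajectory_ensemble(
    frozen$model,
    frozen$traj$xyz + matrix(rnorm(length(frozen$traj$xyz), 0, 1e-4),
                             nrow = 40)
  ))
  m2 <- pca_modes(al2)
  boot2 <- bootstrap_networks(frozen$traj, m2, 1, fraction = 0.8,
                              repeats = 5, seed = 6)
  expect_true(all(boot2$dispersion$sd == 0, na.rm = TRUE))
})

test_that("high-occupancy planted edges survive every bootstrap replicate", {
  ct <- tibble::tibble(chain_i = "A", res_i = c(1, 5),
                       chain_j = "A", res_j = c(3, 8),
                       occupancy = c(0.95, 1.0))
  sys <- toy_system(n_res = 10, n_frames = 500, noise = 0.02, diss_sd = 2,
                    contacts = ct, seed = 29)
  al <- align_ensemble(sys$traj)
  m <- pca_modes(al)
  occ <- contact_occupancy(sys$traj, keep_frames = TRUE)
  boot <- bootstrap_networks(sys$traj, m, 1, fraction = 0.8, repeats = 10,
                             seed = 8)
  # dissociation mode moves all chain-A residues coherently, so criterion (i)
  # holds; the planted high-occupancy contacts must appear in all replicates
  full <- build_network(m, 1, occ)[[1]]$edges
  has_planted <- function(edges) {
    all(c(any(edges$res_i == 1 & edges$res_j == 3),
          any(edges$res_i == 5 & edges$res_j == 8)))
  }
  expect_true(has_planted(full))
  expect_true(all(boot$replicates$n_edges[boot$replicates$chain_id == "A"] >=
                    2))
})
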