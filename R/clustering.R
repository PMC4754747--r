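# Conformational clustering by pairwise CA RMSD: greedy neighbour-count
# (GROMOS-style) clustering plus the cutoff-selection rule requiring the top
# 8 clusters to cover > 90% of the snapshots.

#' Pairwise RMSD matrix of an ensemble
#'
#' Entry (i, j) is the Kabsch-optimal RMSD between frames i and j over the
#' selection; the matrix is symmetric with a zero diagonal.
#'
#' @param traj A [trajectory_ensemble()].
#' @param selection Selection expression (default CA).
#' @return F x F numeric matrix (Angstrom) with frame labels as dimnames.
#' @export
pairwise_rmsd_matrix <- function(traj, selection = "calpha") {
  f_count <- n_frames(traj)
  if (f_count < 2) abort("need at least two frames")
  idx <- select_atoms(traj$model, selection)
  frames <- lapply(seq_len(f_count), function(f) {
    x <- frame_coords(traj, f)[idx, , drop = FALSE]
    sweep(x, 2, colMeans(x))
  })
  m <- matrix(0, f_count, f_count)
  for (i in seq_len(f_count - 1)) {
    for (j in (i + 1):f_count) {
      m[i, j] <- m[j, i] <- kabsch_superpose(frames[[i]], frames[[j]])$rmsd
    }
  }
  dimnames(m) <- list(traj$frame_labels, traj$frame_labels)
  m
}

#' Greedy neighbour-count (GROMOS-style) clustering
#'
#' Iteratively seeds a cluster at the unassigned frame with the most
#' unassigned neighbours within `cutoff` (ties broken toward the lowest frame
#' label), assigns it and those neighbours, removes them, and repeats. The
#' representative of a cluster is the member minimizing the mean RMSD to the
#' other members. Clusters are ordered largest first (size ties by seed
#' order).
#'
#' @param rmsd_matrix Symmetric pairwise RMSD matrix (from
#'   [pairwise_rmsd_matrix()]).
#' @param cutoff Neighbour cutoff in Angstrom.
#' @return Object of class `cluster_result`: `cutoff`, `clusters` (list of
#'   frame-label vectors, sizes non-increasing), `representatives`,
#'   `sizes`, `coverage_top8`.
#' @export
gromos_cluster <- function(rmsd_matrix, cutoff) {
  if (cutoff <= 0) abort("cutoff must be positive")
  f_count <- nrow(rmsd_matrix)
  labels <- as.integer(rownames(rmsd_matrix) %||% seq_len(f_count))
  nb <- rmsd_matrix < cutoff
  diag(nb) <- TRUE
  left <- rep(TRUE, f_count)
  clusters <- list()
  while (any(left)) {
    counts <- colSums(nb[left, left, drop = FALSE])
    cand <- which(left)
    seed <- cand[which.max(counts)]  # which.max: first max = lowest label
    members <- cand[nb[seed, left]]
    clusters <- c(clusters, list(members))
    left[members] <- FALSE
  }
  ord <- order(-vapply(clusters, length, 0L))
  clusters <- clusters[ord]
  reps <- vapply(clusters, function(mem) {
    if (length(mem) == 1) return(mem)
    mean_r <- rowMeans(rmsd_matrix[mem, mem, drop = FALSE])
    mem[which.min(mean_r)]
  }, 0L)
  sizes <- vapply(clusters, length, 0L)
  structure(
    list(cutoff = cutoff,
         clusters = lapply(clusters, function(i) labels[i]),
         representatives = labels[reps],
         sizes = sizes,
         coverage_top8 = sum(head(sizes, 8)) / f_count),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> cutoff ", x$cutoff, " A: ", length(x$clusters),
      " clusters, top-8 coverage ", round(x$coverage_top8, 3), "\n", sep = "")
  invisible(x)
}

#' Choose the clustering cutoff by top-cluster coverage
#'
#' Scans cutoffs upward on a grid and returns the clustering at the smallest
#' cutoff whose largest `top_n` clusters together contain more than
#' `coverage` of the snapshots.
#'
#' @inheritParams gromos_cluster
#' @param top_n Number of leading clusters that must reach the coverage
#'   (default 8).
#' @param coverage Required fraction, exclusive (default 0.90).
#' @param step Grid step in Angstrom (default 0.1).
#' @return A `cluster_result` (see [gromos_cluster()]); errors if no grid
#'   cutoff up to the matrix maximum plus one step achieves the coverage.
#' @export
select_cutoff <- function(rmsd_matrix, top_n = 8L, coverage = 0.90,
                          step = 0.1) {
  if (step <= 0) abort("grid step must be positive")
  for (cutoff in seq(step, max(rmsd_matrix) + step, by = step)) {
    res <- gromos_cluster(rmsd_matrix, cutoff)
    cov <- sum(head(res$sizes, top_n)) / nrow(rmsd_matrix)
    if (cov > coverage) {
      res$coverage_top8 <- sum(head(res$sizes, 8)) / nrow(rmsd_matrix)
      return(res)
    }
  }
  abort("no cutoff on the grid achieves the required coverage")
}
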