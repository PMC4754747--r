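# End-to-end orchestration on the bundled synthetic system: simulate ->
# align -> interface -> PCA -> FMA -> amplitudes -> networks (+bootstrap,
# paths) -> energetics -> clustering, with one manifest per stage. All
# randomness funnels through config$seed; outputs carry no timestamps, so a
# rerun with the same config is byte-identical.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    out_dir = "dimerdyn_run",
    n_residues_per_chain = 12L,
    atoms_per_residue = 2L,
    n_frames = 300L,
    planted_mode_stddev = 1.0,
    planted_mode_wavelength = 8,
    dissociation_stddev = 2.0,
    noise_stddev = 0.05,
    probe_radius = 1.4,
    sasa_n_points = 240L,
    interface_tolerance = 0.1,
    fma_components = 10L,
    fma_top_k = 20L,
    contact_distance = 4.5,
    occupancy_threshold = 0.75,
    angle_threshold = 45,
    bootstrap_fraction = 0.8,
    bootstrap_repeats = 10L,
    energy_effect_size = 2.0,
    energy_noise = 0.2,
    energy_threshold = 1.0,
    cluster_top_n = 8L,
    cluster_coverage = 0.90,
    cluster_grid_step = 0.1,
    cluster_max_frames = 100L
  )
}

#' Build and validate a pipeline configuration
#'
#' Starts from the bundled defaults (a small synthetic dimer: 12 residues
#' per chain, 2 atoms per residue, 300 frames) and applies overrides.
#' Unknown keys and out-of-range thresholds are rejected before any compute.
#'
#' @param ... Named overrides of the default keys (see
#'   `dimerdyn:::pipeline_defaults()`), or a single named list.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]])) {
    over <- over[[1]]
  }
  cfg <- pipeline_defaults()
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg[names(over)] <- over
  check <- function(ok, msg) if (!ok) abort(paste0("invalid config: ", msg))
  check(cfg$occupancy_threshold >= 0 && cfg$occupancy_threshold <= 1,
        "occupancy_threshold must be in [0, 1]")
  check(cfg$angle_threshold > 0 && cfg$angle_threshold <= 180,
        "angle_threshold must be in (0, 180] degrees")
  check(cfg$contact_distance > 0, "contact_distance must be positive")
  check(cfg$bootstrap_fraction > 0 && cfg$bootstrap_fraction <= 1,
        "bootstrap_fraction must be in (0, 1]")
  check(cfg$cluster_coverage > 0 && cfg$cluster_coverage < 1,
        "cluster_coverage must be in (0, 1)")
  check(cfg$probe_radius > 0, "probe_radius must be positive")
  check(cfg$sasa_n_points >= 32, "sasa_n_points must be >= 32")
  check(cfg$n_frames >= 10, "n_frames must be >= 10")
  structure(cfg, class = "pipeline_config")
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

stage_manifest <- function(dir, stage, params, files) {
  files <- files[file.exists(files)]
  write_json_file(
    list(stage = stage, parameters = params,
         outputs = lapply(files, function(f) {
           list(file = basename(f), md5 = unname(tools::md5sum(f)))
         })),
    file.path(dir, paste0("manifest_", stage, ".json"))
  )
}

#' Write a synthetic dataset to disk
#'
#' Emits the toy-dimer topology (PDB), the generated ensemble (multi-model
#' PDB), the ground-truth planted-mode coefficients (CSV), a wild-type /
#' mutant pair of per-residue energy tables (CSV) and a JSON echo of the
#' spec.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the generated objects and file paths.
#' @export
simulate_dataset <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  model <- build_toy_dimer(spec)
  gen <- generate_ensemble(model, spec)
  res <- residue_table(model)[, c("chain_id", "residue_index")]
  n <- spec$n_residues_per_chain
  stab <- res[res$chain_id == "A" & res$residue_index <= 3, ]
  destab <- res[res$chain_id == "B" & res$residue_index > n - 3, ]
  tables <- generate_energy_tables(res, stab, destab, seed = spec$seed)
  paths <- list(
    topology = file.path(dir, "topology.pdb"),
    ensemble = file.path(dir, "ensemble.pdb"),
    coefficients = file.path(dir, "coefficients.csv"),
    energy_wt = file.path(dir, "energy_wt.csv"),
    energy_mut = file.path(dir, "energy_mut.csv"),
    spec = file.path(dir, "spec.json")
  )
  write_pdb(model, paths$topology)
  write_pdb(gen$traj, paths$ensemble)
  readr::write_csv(gen$coefficients, paths$coefficients)
  energy_csv <- function(tb) {
    tibble(system = tb$system, chain = tb$chain_id,
           residue = tb$residue_index, dG_kcal_mol = tb$dG)
  }
  readr::write_csv(energy_csv(tables$wt), paths$energy_wt)
  readr::write_csv(energy_csv(tables$mut), paths$energy_mut)
  echo <- unclass(spec)
  echo$planted_modes <- length(spec$planted_modes)
  write_json_file(echo, paths$spec)
  invisible(list(model = model, generated = gen, energy = tables,
                 paths = paths))
}

#' Run the full analysis pipeline on the bundled synthetic system
#'
#' Chains every stage on a generated dimer ensemble and writes one artifact
#' plus a manifest (parameters and md5 checksums) per stage into
#' `config$out_dir`. Deterministic for a fixed config: rerunning yields
#' byte-identical numeric outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of per-stage results.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir <- config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", stage, "' failed: ",
                   conditionMessage(e)))
    })
  }

  # -- simulate ------------------------------------------------------------
  sim <- run_stage("simulate", {
    spec0 <- synthetic_spec(
      n_residues_per_chain = config$n_residues_per_chain,
      atoms_per_residue = config$atoms_per_residue,
      n_frames = config$n_frames,
      dissociation_stddev = config$dissociation_stddev,
      noise_stddev = config$noise_stddev,
      seed = config$seed
    )
    model0 <- build_toy_dimer(spec0)
    spec <- synthetic_spec(
      n_residues_per_chain = config$n_residues_per_chain,
      atoms_per_residue = config$atoms_per_residue,
      n_frames = config$n_frames,
      planted_modes = list(list(
        field = planted_wave_mode(model0, config$planted_mode_wavelength),
        stddev = config$planted_mode_stddev
      )),
      dissociation_stddev = config$dissociation_stddev,
      noise_stddev = config$noise_stddev,
      seed = config$seed
    )
    out <- simulate_dataset(spec, dir)
    stage_manifest(dir, "simulate", list(seed = config$seed,
                                         n_frames = config$n_frames),
                   unlist(out$paths))
    out
  })
  model <- sim$model
  traj <- sim$generated$traj

  # -- geometry ------------------------------------------------------------
  geo <- run_stage("geometry", {
    aligned <- align_ensemble(traj)
    rmsd <- rmsd_series(aligned)
    rmsf <- rmsf_profile(aligned)
    cdist <- chain_center_distance(traj)
    readr::write_csv(rmsd, file.path(dir, "rmsd.csv"))
    readr::write_csv(rmsf, file.path(dir, "rmsf.csv"))
    readr::write_csv(cdist, file.path(dir, "center_distance.csv"))
    stage_manifest(dir, "geometry", list(reference = "mean_iterative"),
                   file.path(dir, c("rmsd.csv", "rmsf.csv",
                                    "center_distance.csv")))
    list(aligned = aligned, rmsd = rmsd, rmsf = rmsf, center = cdist)
  })

  # -- interface -----------------------------------------------------------
  iface <- run_stage("interface", {
    iset <- detect_interface(model, tolerance = config$interface_tolerance,
                             probe = config$probe_radius,
                             n_points = config$sasa_n_points)
    series <- interface_sasa_series(traj, iset, probe = config$probe_radius,
                                    n_points = config$sasa_n_points)
    readr::write_csv(as_tibble(iset), file.path(dir, "interface_residues.csv"))
    readr::write_csv(series, file.path(dir, "sasa_series.csv"))
    stage_manifest(dir, "interface",
                   list(probe = config$probe_radius,
                        n_points = config$sasa_n_points,
                        tolerance = config$interface_tolerance),
                   file.path(dir, c("interface_residues.csv",
                                    "sasa_series.csv")))
    list(interface = iset, series = series)
  })

  # -- pca + fma -----------------------------------------------------------
  fm <- run_stage("fma", {
    modes <- pca_modes(geo$aligned)
    diss <- dissociation_field(model)
    diss_ca <- internal_component(
      field_on_atoms(model, diss, modes$atom_indices),
      modes$mean_structure
    )
    proj <- project_mode(diss_ca, modes, top_k = config$fma_top_k)
    best_pc <- attr(proj, "best_pc")
    fmode <- fma(geo$aligned, modes, iface$series,
                 n_components = config$fma_components,
                 top_k = config$fma_top_k)
    amps <- residue_amplitudes(modes, best_pc)
    readr::write_csv(amps, file.path(dir, "mode_amplitudes.csv"))
    readr::write_csv(proj, file.path(dir, "mode_projection.csv"))
    write_json_file(
      list(best_pc = best_pc,
           best_pc_abs_pcc = abs(proj$pcc[best_pc]),
           train_pcc = fmode$train_pcc,
           validation_pcc = fmode$validation_pcc,
           n_components = fmode$n_components,
           mode_recovery_cos = abs(sum(fmode$mode * diss_ca)),
           pc_coefficients = as.list(fmode$pc_coefficients)),
      file.path(dir, "fma_report.json")
    )
    stage_manifest(dir, "fma",
                   list(n_components = config$fma_components,
                        top_k = config$fma_top_k),
                   file.path(dir, c("mode_amplitudes.csv",
                                    "mode_projection.csv",
                                    "fma_report.json")))
    list(modes = modes, best_pc = best_pc, fmode = fmode,
         diss_ca = diss_ca)
  })

  # -- network -------------------------------------------------------------
  net <- run_stage("network", {
    occ <- contact_occupancy(traj, distance = config$contact_distance)
    nets <- build_network(fm$modes, fm$best_pc, occ,
                          angle_threshold = config$angle_threshold,
                          occupancy_threshold = config$occupancy_threshold)
    edges <- dplyr::bind_rows(lapply(nets, `[[`, "edges"))
    readr::write_csv(edges, file.path(dir, "network_edges.csv"))
    sums <- lapply(nets, function(nw) {
      if (nrow(nw$edges) == 0) {
        return(list(chain = nw$chain_id, n_nodes = 0, n_edges = 0))
      }
      s <- summarize_network(nw)
      list(chain = s$chain_id, n_nodes = s$n_nodes, n_edges = s$n_edges,
           average_degree = s$average_degree,
           average_clustering = s$average_clustering)
    })
    write_json_file(sums, file.path(dir, "network_summary.json"))
    boot <- bootstrap_networks(
      traj, fm$modes, fm$best_pc,
      angle_threshold = config$angle_threshold,
      occupancy_threshold = config$occupancy_threshold,
      distance = config$contact_distance,
      fraction = config$bootstrap_fraction,
      repeats = config$bootstrap_repeats,
      seed = config$seed + 101L
    )
    readr::write_csv(boot$replicates, file.path(dir, "bootstrap_replicates.csv"))
    readr::write_csv(boot$dispersion, file.path(dir, "bootstrap_dispersion.csv"))
    src <- list("A", ceiling(config$n_residues_per_chain / 2))
    targets <- dplyr::filter(as_tibble(iface$interface), .data$chain_id == "A")
    paths <- tryCatch(
      network_paths(nets[[1]], src, targets[, c("chain_id", "residue_index")]),
      error = function(e) tibble()
    )
    if (nrow(paths) > 0) {
      readr::write_csv(dplyr::select(paths, -"example_path"),
                       file.path(dir, "network_paths.csv"))
    }
    stage_manifest(dir, "network",
                   list(distance = config$contact_distance,
                        occupancy_threshold = config$occupancy_threshold,
                        angle_threshold = config$angle_threshold,
                        bootstrap_fraction = config$bootstrap_fraction,
                        bootstrap_repeats = config$bootstrap_repeats),
                   file.path(dir, c("network_edges.csv",
                                    "network_summary.json",
                                    "bootstrap_replicates.csv",
                                    "bootstrap_dispersion.csv",
                                    "network_paths.csv")))
    list(occupancy = occ, networks = nets, bootstrap = boot, paths = paths)
  })

  # -- energetics ----------------------------------------------------------
  en <- run_stage("energetics", {
    wt <- sim$energy$wt
    mut <- sim$energy$mut
    stab <- select_key_residues(wt, mut, threshold = config$energy_threshold,
                                direction = "stabilizing")
    destab <- select_key_residues(wt, mut, threshold = config$energy_threshold,
                                  direction = "destabilizing")
    readr::write_csv(stab, file.path(dir, "key_residues_stabilizing.csv"))
    readr::write_csv(destab, file.path(dir, "key_residues_destabilizing.csv"))
    series <- synthetic_energy_series(config$seed + 202L)
    ws <- dplyr::bind_rows(
      windowed_stats(series$a, c(80, 90, 100)),
      windowed_stats(series$b, c(80, 90, 100))
    )
    cmp <- compare_systems(series$a, series$b)
    readr::write_csv(ws, file.path(dir, "energy_windows.csv"))
    readr::write_csv(dplyr::select(cmp, -"p_label"),
                     file.path(dir, "energy_comparison.csv"))
    stage_manifest(dir, "energetics",
                   list(threshold = config$energy_threshold),
                   file.path(dir, c("key_residues_stabilizing.csv",
                                    "key_residues_destabilizing.csv",
                                    "energy_windows.csv",
                                    "energy_comparison.csv")))
    list(stabilizing = stab, destabilizing = destab, windows = ws,
         comparison = cmp)
  })

  # -- clustering ----------------------------------------------------------
  cl <- run_stage("clustering", {
    take <- unique(round(seq(1, n_frames(traj),
                             length.out = min(config$cluster_max_frames,
                                              n_frames(traj)))))
    sub <- trajectory_ensemble(model, traj$xyz[take, , drop = FALSE],
                               traj$frame_labels[take])
    m <- pairwise_rmsd_matrix(sub)
    res <- select_cutoff(m, top_n = config$cluster_top_n,
                         coverage = config$cluster_coverage,
                         step = config$cluster_grid_step)
    write_json_file(
      list(cutoff = res$cutoff, sizes = res$sizes,
           representatives = res$representatives,
           coverage_top8 = res$coverage_top8),
      file.path(dir, "clusters.json")
    )
    stage_manifest(dir, "clustering",
                   list(top_n = config$cluster_top_n,
                        coverage = config$cluster_coverage,
                        step = config$cluster_grid_step),
                   file.path(dir, "clusters.json"))
    res
  })

  echo <- unclass(config)
  echo$out_dir <- NULL  # keep the echo path-independent so reruns are byte-identical
  write_json_file(echo, file.path(dir, "config_echo.json"))
  invisible(list(simulate = sim, geometry = geo, interface = iface,
                 fma = fm, network = net, energetics = en, clustering = cl,
                 out_dir = dir))
}

# two seeded per-frame binding-energy series with the magnitudes typical of
# a stable vs. a stabilized dimer (kcal/mol), 0.1 ns sampling over 100 ns
synthetic_energy_series <- function(seed, n = 1000,
                                    mean_a = -181, sd_a = 31,
                                    mean_b = -202, sd_b = 24) {
  with_local_seed(seed, {
    t_ns <- seq_len(n) * 100 / n
    list(
      a = tibble(system = "wt", time_ns = t_ns,
                 dG = rnorm(n, mean_a, sd_a)),
      b = tibble(system = "mut", time_ns = t_ns,
                 dG = rnorm(n, mean_b, sd_b))
    )
  })
}
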