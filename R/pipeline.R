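#' Default end-to-end pipeline configuration
#'
#' Problem sizes are chosen small enough for an interactive smoke run while
#' still exercising every stage: a dimpled bilayer for the maps, two-state
#' tilt dynamics for the orientation statistic, an enriched lipid shell for
#' the D-E index and a harmonic potential for the umbrella/WHAM stage.
#'
#' @return nested configuration list (the YAML schema of [mt_run()]).
#' @export
default_config <- function() {
  list(
    synth = list(
      bilayer = list(n_lipids_per_leaflet = 400, n_frames = 5,
                     dimple_depth = 0.4, dimple_sigma = 2,
                     thickness = 4, noise_sd = 0.1),
      tilt = list(n_replicas = 8, n_frames = 500, dt = 100,
                  model = "two_state_markov",
                  topple_rate = 2e-3, untopple_rate = 2e-4,
                  mean_toppled = 90, mean_canonical = 30, noise_sd = 5),
      shell = list(n_shell = 25, n_bulk = 400, n_frames = 50,
                   bulk = c(POPE = 0.70, POPG = 0.25, CL = 0.05),
                   shell = c(POPE = 0.60, POPG = 0.30, CL = 0.10)),
      umbrella = list(k_harm = 100, centers_from = -1.2, centers_to = 1.2,
                      spacing = 0.1, force_constant = 2500,
                      n_per_window = 500, temperature = 303)),
    orient = list(band = c(75, 125), threshold = 0.5),
    maps = list(half_width = 4, spacing = 0.2, what = "both"),
    fingerprint = list(cutoff = 0.7),
    pmf = list(bin_width = 0.02, tol = 1e-7, n_boot = 50))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

write_tsv_commented <- function(df, path, header_lines) {
  con <- file(path, "w")
  writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Run the full synthetic-data pipeline
#'
#' Generates synthetic inputs and runs all four analysis stages
#' (orientation, membrane maps, lipid fingerprint, PMF), writing every
#' result as TSV with commented headers naming units. One seed drives all
#' generators (sub-seeds are derived deterministically).
#'
#' @param config configuration list, a YAML file path, or NULL for
#'   [default_config()]; partial configs are merged over the defaults.
#' @param seed integer seed for all randomness.
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with the in-memory results of each stage.
#' @export
mt_run <- function(config = NULL, seed = 1, out_dir = "memtraj_out") {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- default_config()
  if (!is.null(config)) cfg <- merge_config(cfg, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  results <- list()

  # --- orientation ------------------------------------------------------
  tc <- cfg$synth$tilt
  replicas <- lapply(seq_len(tc$n_replicas), function(r)
    make_tilt_trajectory(tilt_spec(
      model = tc$model,
      mean_angles = c(toppled = tc$mean_toppled, canonical = tc$mean_canonical),
      angle_noise_sd = tc$noise_sd,
      transition_rates = c(topple = tc$topple_rate, untopple = tc$untopple_rate),
      n_frames = tc$n_frames, dt = tc$dt, seed = seed + 101 * r),
      replica_id = sprintf("rep%02d", r)))
  summ <- stability_summary(replicas, label = "synthetic",
                            band = cfg$orient$band,
                            threshold = cfg$orient$threshold)
  per <- do.call(rbind, lapply(replicas, function(s) {
    top <- classify_toppled(s$angles, cfg$orient$band)
    data.frame(replica = s$replica_id, time_ps = s$times,
               angle_deg = s$angles, toppled = as.integer(top))
  }))
  write_tsv_commented(per, file.path(out_dir, "orient_replicas.tsv"),
                      "per-frame helix tilt: replica, time (ps), angle (degrees), toppled (0/1)")
  write_tsv_commented(
    data.frame(condition = summ$condition_label, n_replicas = summ$n_replicas,
               n_stable = summ$n_stable, stable_fraction = summ$stable_fraction,
               binomial_sd = summ$sd),
    file.path(out_dir, "orient_summary.tsv"),
    "replica-stability summary: stable fraction of toppled starts, binomial SD (fraction scale)")
  results$orientation <- summ

  # --- membrane maps ----------------------------------------------------
  bc <- cfg$synth$bilayer
  bs <- bilayer_spec(
    n_lipids_per_leaflet = bc$n_lipids_per_leaflet,
    thickness_field = function(x, y)
      bc$thickness - bc$dimple_depth * exp(-(x^2 + y^2) / (2 * bc$dimple_sigma^2)),
    phosphate_noise_sd = bc$noise_sd, seed = seed + 17)
  bl <- make_bilayer_trajectory(bs, n_frames = bc$n_frames)
  grid <- mt_grid(cfg$maps$half_width, cfg$maps$spacing)
  maps <- membrane_maps(bl$frames, bl$topology, grid = grid,
                        what = cfg$maps$what)
  for (nm in names(maps))
    write_grid_map(maps[[nm]], file.path(out_dir, paste0(nm, "_map.tsv")))
  results$maps <- maps

  # --- lipid fingerprint ------------------------------------------------
  sc <- cfg$synth$shell
  sh <- make_enriched_shell_frames(unlist(sc$bulk), unlist(sc$shell),
                                   n_shell = sc$n_shell, n_bulk = sc$n_bulk,
                                   n_frames = sc$n_frames, seed = seed + 29,
                                   cutoff = cfg$fingerprint$cutoff)
  census <- shell_census(sh$frames, sh$protein_sel, sh$topology,
                         cutoff = cfg$fingerprint$cutoff)
  de <- de_index(census)
  write_tsv_commented(as.data.frame(de),
                      file.path(out_dir, "de_index.tsv"),
                      sprintf("depletion-enrichment index per lipid type (dimensionless), %.2f nm cutoff; se = standard error over frames",
                              cfg$fingerprint$cutoff))
  prof <- residue_contact_profile(sh$frames, sh$protein_sel, sh$topology,
                                  cutoff = cfg$fingerprint$cutoff)
  occ <- data.frame(residue_id = prof$residues, prof$occupancy,
                    check.names = FALSE)
  write_tsv_commented(occ, file.path(out_dir, "residue_occupancy.tsv"),
                      "per-residue lipid contact occupancy (fraction of frames) per lipid type")
  dens <- headgroup_density_map(sh$frames, sh$topology,
                                lipid_type = names(sc$bulk)[1],
                                grid = mt_grid(4, 0.5),
                                protein_sel = sh$protein_sel)
  write_grid_map(dens, file.path(out_dir, "headgroup_density_map.tsv"))
  results$fingerprint <- list(census = census, de = de, profile = prof)

  # --- free energy ------------------------------------------------------
  uc <- cfg$synth$umbrella
  ps <- potential_spec(
    U = function(x) 0.5 * uc$k_harm * x^2,
    domain = c(uc$centers_from - 0.4, uc$centers_to + 0.4),
    centers = seq(uc$centers_from, uc$centers_to, by = uc$spacing),
    force_constant = uc$force_constant, n_per_window = uc$n_per_window,
    temperature = uc$temperature, seed = seed + 43)
  ws <- make_umbrella_samples(ps)
  prof_pmf <- wham(ws, bin_width = cfg$pmf$bin_width, tol = cfg$pmf$tol)
  prof_pmf <- bootstrap_pmf(ws, prof_pmf, n_boot = cfg$pmf$n_boot,
                            seed = seed + 57,
                            bin_width = cfg$pmf$bin_width, tol = cfg$pmf$tol)
  write_pmf(prof_pmf, file.path(out_dir, "pmf.tsv"))
  results$pmf <- prof_pmf

  invisible(results)
}
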