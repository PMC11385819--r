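#' Experiment configuration
#'
#' Defines the full factorial simulation study. The defaults reproduce the
#' study grid: 100 landscapes per fragmentation level, three levels, four
#' movement processes (1,200 simulation runs), 10,000 recorded steps
#' (20,000 with a 10,000-step burn-in for the territorial process),
#' resampling factors 2..50, and 100-graph null ensembles.
#'
#' @param n_landscapes Landscapes per fragmentation level.
#' @param levels Fragmentation levels to simulate.
#' @param processes Movement processes to run.
#' @param n_steps Recorded relocations per run.
#' @param burn_in_ft Burn-in for the territorial process.
#' @param ks Resampling factors.
#' @param ensemble_size Random graphs per small-world test.
#' @param params A [movement_params()] set.
#' @param seed Master seed; all landscape/movement/ensemble seeds derive
#'   from it and are recorded in the manifest.
#' @param out_dir Optional output directory for CSV tables.
#' @param store_trajectories Write relocation CSVs (large; default FALSE).
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n_landscapes = 100L,
                              levels = c("low", "medium", "high"),
                              processes = c("F", "F+Pe", "F+Ps", "F+T"),
                              n_steps = 10000L, burn_in_ft = 10000L,
                              ks = 2:50, ensemble_size = 100L,
                              params = movement_params(), seed = 1L,
                              out_dir = NULL, store_trajectories = FALSE) {
  stopifnot(n_landscapes >= 1, length(levels) >= 1, length(processes) >= 1,
            all(levels %in% c("low", "medium", "high")),
            all(processes %in% c("F", "F+Pe", "F+Ps", "F+T")))
  structure(list(n_landscapes = as.integer(n_landscapes), levels = levels,
                 processes = processes, n_steps = as.integer(n_steps),
                 burn_in_ft = as.integer(burn_in_ft), ks = as.integer(ks),
                 ensemble_size = as.integer(ensemble_size), params = params,
                 seed = as.integer(seed), out_dir = out_dir,
                 store_trajectories = store_trajectories),
            class = "experiment_config")
}

#' Enumerate the simulation runs of a configuration
#'
#' One row per (fragmentation level, landscape replicate, movement process),
#' with the derived landscape, movement and ensemble seeds. Enumeration is
#' cheap and deterministic under the master seed; [run_experiment()] executes
#' exactly these rows.
#'
#' @param config An [experiment_config()].
#' @return Data frame manifest (`run_id`, `frag_level`, `landscape_rep`,
#'   `process`, `landscape_seed`, `movement_seed`, `ensemble_seed`).
#' @export
experiment_manifest <- function(config) {
  grid <- expand.grid(process = config$processes,
                      landscape_rep = seq_len(config$n_landscapes),
                      frag_level = config$levels,
                      stringsAsFactors = FALSE)
  set.seed(config$seed)
  n <- nrow(grid)
  # landscape seed shared by the runs on the same landscape
  land <- unique(grid[c("frag_level", "landscape_rep")])
  land$landscape_seed <- sample.int(2^30, nrow(land))
  m <- merge(grid, land, by = c("frag_level", "landscape_rep"), sort = FALSE)
  m$movement_seed <- sample.int(2^30, n)
  m$ensemble_seed <- sample.int(2^30, n)
  m <- m[order(match(m$frag_level, config$levels), m$landscape_rep,
               match(m$process, config$processes)), ]
  m$run_id <- seq_len(n)
  rownames(m) <- NULL
  m[c("run_id", "frag_level", "landscape_rep", "process",
      "landscape_seed", "movement_seed", "ensemble_seed")]
}

# simulate one run and return its trajectories (territorial runs yield one
# per forager, pooled downstream like multi-individual empirical data) plus
# the landscape objects, caching landscapes by seed
.run_one <- function(row, config, cache) {
  key <- as.character(row$landscape_seed)
  lp <- cache[[key]]
  if (is.null(lp)) {
    grid <- generate_landscape_nonempty(frag_level_spec(row$frag_level),
                                        seed = row$landscape_seed)
    pm <- delineate_patches(grid)
    lp <- list(grid = grid, pm = pm, dist = NULL)
    cache[[key]] <- lp
  }
  burn <- if (row$process == "F+T") config$burn_in_ft else 0L
  tr <- simulate_movement(lp$grid, row$process, config$params,
                          n_steps = config$n_steps, burn_in = burn,
                          seed = row$movement_seed)
  if (inherits(tr, "trajectory")) tr <- list(tr)
  list(grid = lp$grid, pm = lp$pm, traj = tr)
}

#' Run the full simulation experiment
#'
#' Executes every run of the manifest: generates landscapes (redrawing empty
#' ones), simulates trajectories, builds the full-trajectory network and the
#' resampled networks, computes topology metrics, scores the four theoretical
#' networks (MPG, DIST50, DIST95, random) with Cohen's kappa, and measures
#' information loss per resampling factor. Identical config and seed give
#' identical tables.
#'
#' @param config An [experiment_config()].
#' @param progress Print one line per run (default FALSE).
#' @return List with `manifest`, `metrics` (one row per network), `kappa`
#'   (one row per theoretical model per run), `loss` (one row per resampling
#'   factor per run), `landscape_indices` (fragmentation indices per
#'   landscape). Tables are also written as CSV when `config$out_dir` is set.
#' @export
run_experiment <- function(config, progress = FALSE) {
  manifest <- experiment_manifest(config)
  cache <- new.env(parent = emptyenv())
  metrics <- list(); kappa <- list(); loss <- list(); frag <- list()
  mpg_cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    one <- .run_one(row, config, cache)
    pm <- one$pm
    key <- as.character(row$landscape_seed)
    if (is.null(frag[[key]])) {
      fi <- fragmentation_indices(pm)
      frag[[key]] <- data.frame(frag_level = row$frag_level,
                                landscape_seed = row$landscape_seed,
                                n_patches = pm$n_patches,
                                ai = fi$ai, cohesion = fi$cohesion,
                                division = fi$division,
                                proportion = fi$proportion)
    }
    meta0 <- list(frag_level = row$frag_level, process = row$process,
                  landscape_id = row$landscape_seed, run_id = row$run_id)
    n_reloc_full <- sum(vapply(one$traj, length, numeric(1)))
    full <- trajectory_network(one$traj, pm, k = 1L)
    metrics[[length(metrics) + 1L]] <-
      network_metrics(full, config$ensemble_size, seed = row$ensemble_seed,
                      meta = c(meta0, list(k = 1L,
                                           n_relocations = n_reloc_full)))
    for (k in config$ks) {
      rs <- lapply(one$traj, resample_trajectory, k = k, start = 0L)
      net <- trajectory_network(rs, pm, k = k)
      metrics[[length(metrics) + 1L]] <-
        network_metrics(net, config$ensemble_size,
                        seed = row$ensemble_seed + k,
                        meta = c(meta0,
                                 list(k = k,
                                      n_relocations = sum(vapply(rs, length,
                                                                 numeric(1))))))
      il <- information_loss(full, net, k = k)
      loss[[length(loss) + 1L]] <-
        data.frame(meta0, k = k,
                   prop_patches_detected = il$prop_patches_detected,
                   prop_links_detected = il$prop_links_detected,
                   prop_spurious = il$prop_spurious)
    }
    # theoretical networks scored against the full-trajectory network
    if (pm$n_patches >= 2 && nrow(full$links) >= 1) {
      mpg <- mpg_cache[[key]]
      if (is.null(mpg)) {
        mpg <- build_mpg(pm)
        mpg_cache[[key]] <- mpg
      }
      dmat <- mpg_cache[[paste0(key, ".d")]]
      if (is.null(dmat)) {
        dmat <- patch_distances(pm)
        mpg_cache[[paste0(key, ".d")]] <- dmat
      }
      th <- realized_link_lengths(full, pm, dist = dmat)
      nets <- list(DIST50 = build_distance_network(pm, th$L_med, dist = dmat),
                   DIST95 = build_distance_network(pm, th$L_95, dist = dmat),
                   MPG = mpg,
                   Rand = build_random_network(pm, nrow(full$links),
                                               seed = row$ensemble_seed))
      for (mdl in names(nets)) {
        kr <- cohens_kappa(nets[[mdl]], full)
        kappa[[length(kappa) + 1L]] <-
          data.frame(meta0, model = mdl, kappa = kr$kappa,
                     n_links_pred = nrow(nets[[mdl]]$links),
                     n_links_real = nrow(full$links))
      }
    }
    if (progress)
      message(sprintf("run %d/%d: %s %s (%d patches, %d nodes)",
                      i, nrow(manifest), row$frag_level, row$process,
                      pm$n_patches, length(full$nodes)))
  }
  res <- list(manifest = manifest,
              metrics = do.call(rbind, metrics),
              kappa = do.call(rbind, kappa),
              loss = do.call(rbind, loss),
              landscape_indices = do.call(rbind, frag))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(res))
      utils::write.csv(res[[nm]], file.path(config$out_dir,
                                            paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  res
}
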