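#' Default analysis configuration (motor-domain recipe)
#'
#' Parameters of the two end-to-end recipes, with the motor-domain defaults:
#' network contacts at 4.5 Angstrom / 75% occupancy, contact events with
#' 6.5/7.5 Angstrom hysteresis and a 14 ns median-filter half-width, K = 3
#' conformer clusters on the first five PCs, an 8 Angstrom docking cutoff,
#' and a 0.5 Angstrom^3 invariant-core stop volume. The half-width in frames
#' is derived from `time_step_ns` (14 ns at 20 ps sampling = 700 frames).
#'
#' @return named list of parameters.
#' @export
default_config <- function() {
  list(
    core_stop_volume = 0.5,        # A^3, invariant-core stop criterion
    network_cutoff = 4.5,          # A, heavy-atom contact cutoff
    network_occupancy = 0.75,      # fraction of frames
    exclude_neighbors = 1L,        # sequence-neighbor exclusion
    event_on = 6.5,                # A, contact-on cutoff
    event_off = 7.5,               # A, contact-off cutoff
    half_width_ns = 14,            # median-filter half-width
    time_step_ns = 0.02,           # trajectory frame spacing
    k_clusters = 3L,
    n_pcs = 5L,
    docking_cutoff = 8,            # A, Cbeta-Cbeta
    segment_prominence = NULL,     # default: half the peak activity
    cap_floor = 1e-6,
    seed = 1L
  )
}

#' Read an analysis configuration from YAML
#'
#' Supports a single-level `include:` mechanism (a path, resolved relative
#' to the config file, whose keys are loaded first and overridden by the
#' including file). All parameters are validated against their documented
#' ranges before any computation.
#'
#' @param path YAML file.
#' @return validated configuration list (defaults filled in).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$include)) {
    inc <- yaml::read_yaml(file.path(dirname(path), cfg$include))
    cfg$include <- NULL
    cfg <- utils::modifyList(inc, cfg)
  }
  validate_config(utils::modifyList(default_config(), cfg))
}

#' Validate a configuration list
#' @param cfg configuration list (missing entries filled from
#'   [default_config()]).
#' @return the validated list.
#' @export
validate_config <- function(cfg) {
  cfg <- utils::modifyList(default_config(), cfg)
  chk <- function(ok, msg) if (!ok) stop("config: ", msg, call. = FALSE)
  chk(cfg$network_cutoff > 0, "network_cutoff must be positive")
  chk(cfg$network_occupancy > 0 && cfg$network_occupancy <= 1,
      "network_occupancy must be in (0, 1]")
  chk(cfg$event_on < cfg$event_off,
      "event_on cutoff must be below event_off")
  chk(cfg$half_width_ns > 0, "half_width_ns must be positive")
  chk(cfg$time_step_ns > 0, "time_step_ns must be positive")
  chk(cfg$k_clusters >= 1, "k_clusters must be >= 1")
  chk(cfg$n_pcs >= 1, "n_pcs must be >= 1")
  chk(cfg$core_stop_volume > 0, "core_stop_volume must be positive")
  chk(cfg$docking_cutoff > 0, "docking_cutoff must be positive")
  cfg
}

half_width_frames <- function(cfg, time_step = NULL) {
  ts <- if (!is.null(time_step)) time_step else cfg$time_step_ns
  max(1L, as.integer(round(cfg$half_width_ns / ts)))
}

write_tsv_artifact <- function(x, dir, name) {
  write.table(x, file.path(dir, name), sep = "\t", quote = FALSE,
              row.names = FALSE)
}

write_summary_json <- function(summary, dir) {
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the conformer-ensemble analysis recipe
#'
#' End-to-end interconformer analysis: (optionally) assemble an ensemble
#' from equivalenced and completeness-filtered chains, find the invariant
#' core, superpose on it, run covariance PCA, project, compute per-residue
#' contributions, cluster conformers in PC space, and compute the RMSF
#' profile (with B-factor agreement when B-factors are present). All
#' artifacts are written under `out_dir` with fixed names, plus a
#' machine-readable `summary.json`.
#'
#' @param x a [coord_ensemble()] of conformers, or a list of
#'   `chain_record`s (then equivalences are built and
#'   `required_regions`/`cfg` drive the completeness filter).
#' @param out_dir output directory (created if needed).
#' @param cfg configuration list (see [default_config()]).
#' @param required_regions named list of alignment-column vectors for the
#'   completeness filter (chain input only).
#' @return list with every intermediate object and `summary`.
#' @export
run_conformer_analysis <- function(x, out_dir, cfg = default_config(),
                                   required_regions = NULL) {
  cfg <- validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  exclusions <- NULL
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (!inherits(x, "coord_ensemble")) {
    chains <- x
    map <- stage("equivalences", build_equivalences(chains))
    if (!is.null(required_regions)) {
      flt <- stage("filter", filter_structures(chains, map, required_regions))
      chains <- flt$retained; map <- flt$map
      exclusions <- flt$exclusions
      write_tsv_artifact(exclusions, out_dir, "exclusions.tsv")
    }
    x <- stage("ensemble", ensemble_from_chains(chains, map))
  }
  if (n_frames(x) < 2L) stop("conformer analysis needs at least 2 structures")
  core <- if (n_frames(x) >= 3L) {
    stage("core", find_invariant_core(x, stop_volume = cfg$core_stop_volume))
  } else {
    # two conformers cannot constrain an invariant core; use all positions
    structure(list(core = seq_len(n_positions(x)),
                   history = tibble(iteration = 1L,
                                    n_candidates = n_positions(x),
                                    max_volume = NA_real_, n_dropped = 0L),
                   volumes = rep(NA_real_, n_positions(x))),
              class = "core_selection")
  }
  fitted <- stage("fit", fit_ensemble(x, selection = core$core))
  model <- stage("pca", ens_pca(fitted))
  proj <- stage("project", project_frames(fitted, model, k = cfg$n_pcs))
  contrib <- stage("contributions", dplyr::bind_rows(
    dplyr::mutate(residue_contributions(model, 1L), pc = 1L),
    if (length(model$values) >= 2L)
      dplyr::mutate(residue_contributions(model, 2L), pc = 2L)))
  clusters <- stage("cluster", cluster_conformers(
    proj, k = min(cfg$k_clusters, n_frames(x)), n_pcs = cfg$n_pcs))
  fluct <- stage("rmsf", rmsf_profile(fitted))
  bfit <- if (!is.null(x$bfactors))
    bfactor_correlation(fluct, x$bfactors) else NULL
  write_tsv_artifact(proj, out_dir, "projections.tsv")
  write_tsv_artifact(contrib, out_dir, "contributions.tsv")
  write_tsv_artifact(clusters$labels, out_dir, "clusters.tsv")
  write_tsv_artifact(fluct, out_dir, "rmsf.tsv")
  write_core_selection(core, x, file.path(out_dir, "core.tsv"))
  cum <- function(k) if (length(model$cum_frac) >= k)
    100 * model$cum_frac[k] else 100
  summary <- list(
    n_structures = n_frames(x), n_positions = n_positions(x),
    core_size = length(core$core),
    cum_variance_pc2 = cum(2L), cum_variance_pc3 = cum(3L),
    cum_variance_pc5 = cum(5L),
    cluster_sizes = as.integer(table(clusters$labels$cluster)),
    n_excluded = if (is.null(exclusions)) 0L else
      length(unique(exclusions$source_id)),
    bfactor_r_squared = if (is.null(bfit)) NULL else bfit$r_squared)
  write_summary_json(summary, out_dir)
  list(ensemble = fitted, core = core, model = model, projections = proj,
       contributions = contrib, clusters = clusters, rmsf = fluct,
       bfactor_fit = bfit, exclusions = exclusions, summary = summary)
}

#' Run the trajectory analysis recipe
#'
#' End-to-end trajectory analysis against a crystallographic reference:
#' superpose snapshots on the invariant core, project onto the crystal PCs,
#' compute RMSD/RMSF traces, the cross-correlation matrix, the contact-
#' filtered network with communities and betweenness, contact-event
#' activity and segmentation (with per-segment DCCM + community analysis),
#' and geometric order-parameter traces when the trajectory carries labeled
#' regions. Artifacts are written under `out_dir`; `summary.json` is
#' byte-reproducible for a fixed config and seed.
#'
#' @param traj a [coord_ensemble()] trajectory (e.g. from
#'   [read_trajectory()] or a generator).
#' @param reference a `run_conformer_analysis` result, an `ens_pca` model
#'   plus core (list with `model`, `core`), or `NULL` to derive core and
#'   PCs from the trajectory itself.
#' @param out_dir output directory.
#' @param cfg configuration list.
#' @return list of stage results and `summary`.
#' @export
run_trajectory_analysis <- function(traj, out_dir, reference = NULL,
                                    cfg = default_config()) {
  cfg <- validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(reference)) {
    core <- find_invariant_core(traj, stop_volume = cfg$core_stop_volume)
    fitted <- fit_ensemble(traj, selection = core$core)
    model <- ens_pca(fitted)
  } else {
    core <- reference$core
    fitted <- fit_ensemble(traj, selection = core$core)
    model <- reference$model
  }
  proj <- project_frames(fitted, model, k = cfg$n_pcs)
  ref_frame <- frame_coords(fitted, 1L)
  rmsd_trace <- tibble(
    frame = seq_len(n_frames(fitted)), label = fitted$labels,
    rmsd = vapply(seq_len(n_frames(fitted)), function(f)
      rmsd_frames(frame_coords(fitted, f), ref_frame, fit = FALSE),
      numeric(1)))
  fluct <- rmsf_profile(fitted)
  cc <- dccm(fitted)
  adj <- contact_adjacency(fitted, cutoff = cfg$network_cutoff,
                           occupancy = cfg$network_occupancy,
                           exclude_neighbors = cfg$exclude_neighbors)
  net <- build_network(cc, adj, cap_floor = cfg$cap_floor)
  comm <- detect_communities(net)
  btw <- betweenness_and_critical_nodes(net, comm)
  dists <- sidechain_distance_series(
    fitted, exclude_neighbors = cfg$exclude_neighbors)
  states <- hysteretic_contacts(dists$dist, on = cfg$event_on,
                                off = cfg$event_off)
  hw <- half_width_frames(cfg, fitted$time_step)
  ev <- event_activity(states, half_width = hw)
  prom <- if (is.null(cfg$segment_prominence))
    max(ev$events$activity) / 2 else cfg$segment_prominence
  segs <- segment_by_activity(ev, prominence = prom)
  seg_analyses <- lapply(seq_len(nrow(segs)), function(s) {
    fr <- segs$start[s]:segs$end[s]
    if (length(fr) < 2L) return(NULL)
    sub <- subset_ensemble(fitted, frames = fr)
    scc <- dccm(sub)
    snet <- build_network(scc, adj, cap_floor = cfg$cap_floor)
    list(dccm = scc, network = snet,
         communities = detect_communities(snet))
  })
  geom <- NULL
  if (!is.null(fitted$regions) && all(c("a4", "b3") %in%
                                      names(fitted$regions))) {
    geom <- protrusion(fitted, "a4", "b3")
    write_tsv_artifact(geom, out_dir, "protrusion.tsv")
  }
  write_tsv_artifact(proj, out_dir, "projections.tsv")
  write_tsv_artifact(rmsd_trace, out_dir, "rmsd.tsv")
  write_tsv_artifact(fluct, out_dir, "rmsf.tsv")
  write_tsv_artifact(ev$events, out_dir, "activity.tsv")
  write_tsv_artifact(segs, out_dir, "segments.tsv")
  write_tsv_artifact(tibble(node = seq_len(net$n_nodes),
                            community = comm$membership),
                     out_dir, "communities.tsv")
  write_network_tsv(net, file.path(out_dir, "network.tsv"), comm, btw)
  summary <- list(
    n_frames = n_frames(traj), n_positions = n_positions(traj),
    core_size = length(core$core),
    mean_rmsd = mean(rmsd_trace$rmsd),
    n_contact_edges = nrow(net$edges),
    n_communities = comm$n_communities,
    modularity = comm$modularity,
    n_critical_nodes = sum(btw$nodes$critical),
    total_events = sum(ev$events$total),
    n_segments = nrow(segs),
    segment_boundaries = segs$boundary[-1L],
    mean_protrusion_distance = if (is.null(geom)) NULL else
      mean(geom$distance),
    mean_protrusion_angle = if (is.null(geom)) NULL else mean(geom$angle))
  write_summary_json(summary, out_dir)
  list(ensemble = fitted, core = core, model = model, projections = proj,
       rmsd = rmsd_trace, rmsf = fluct, dccm = cc, adjacency = adj,
       network = net, communities = comm, betweenness = btw,
       events = ev, segments = segs, segment_analyses = seg_analyses,
       protrusion = geom, summary = summary)
}
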