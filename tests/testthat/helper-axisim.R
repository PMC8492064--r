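# Shared fixtures: all inputs are generated in code.

FATES_levels <- function() c("progenitor", "NT", "PSM")

# small, fast simulation config for structural tests
quick_config <- function(...) {
  sim_config(population_scale = 0.1, total_time = 1, snapshot_interval = 0.5,
             ...)
}

# hand-built track table: one row per frame per track
make_tracks <- function(pos_list, frame_interval = 0.1, tissue = "PZ") {
  out <- lapply(names(pos_list), function(id) {
    p <- pos_list[[id]]
    tibble::tibble(track_id = id, frame = seq_len(nrow(p)),
                   t_hours = (seq_len(nrow(p)) - 1) * frame_interval,
                   x_um = p[, 1], y_um = p[, 2], tissue = tissue)
  })
  tr <- dplyr::bind_rows(out)
  attr(tr, "frame_interval") <- frame_interval
  tr
}

# minimal sim_result wrapper for metric unit tests
fake_result <- function(snapshots, config = sim_config()) {
  structure(list(snapshots = snapshots,
                 counts = dplyr::count(snapshots, time_h, state, name = "n"),
                 switches = tibble::tibble(),
                 config = config,
                 layout = build_default_layout(config),
                 seed = 0L),
            class = "sim_result")
}

# default 10-h full-scale run, computed once and shared by the acceptance
# blocks that probe the same study conditions
default_run_cache <- new.env(parent = emptyenv())
get_default_run <- function(seed = 1) {
  key <- paste0("s", seed)
  if (is.null(default_run_cache[[key]])) {
    default_run_cache[[key]] <- run_simulation(sim_config(), seed = seed)
  }
  default_run_cache[[key]]
}

# posterior-region tissue integrity: the progenitor zone and its immediate
# surroundings, where fate sorting actually happens
pz_region_integrity <- function(result, time_h = 10, radius_um = 20) {
  fin <- dplyr::filter(result$snapshots, time_h == !!time_h)
  y5 <- quantile(fin$y_unit[fin$state == "progenitor"], 0.05, names = FALSE)
  tissue_integrity(dplyr::filter(fin, y_unit >= y5), radius_um,
                   result$layout)
}

# per-step displacements of a track table (internal helper re-exported for
# test assertions)
track_steps_for_test <- function(tracks) axisim:::track_steps(tracks)
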