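#' Default fate-pair adhesion matrix
#'
#' Attraction strengths between fate pairs, in the order progenitor, NT, PSM.
#' Neural cells adhere to each other more strongly than PSM cells
#' (a(NT,NT) > a(PSM,PSM)); cross-fate attraction is zero by default, the
#' non-mixing boundary being carried by a separate cross-fate repulsion.
#'
#' @return A symmetric 3x3 numeric matrix with fate dimnames.
#' @export
default_adhesion_matrix <- function() {
  m <- diag(c(0.5, 1.0, 0.4))
  dimnames(m) <- list(FATES, FATES)
  m
}

#' Simulation configuration
#'
#' Builds the full parameter set of the agent-based elongation model. Defaults
#' encode the published model conditions: 1100 progenitor, 1200 neural and
#' 3200 PSM cells at t = 0; doubling times 11.49 / 10.83 / 8.75 h; fate
#' thresholds 0.4 and 1.6 on the 0-2 Sox2/Bra ratio scale; 1 model unit =
#' 150 micrometres; a 10 h run at dt = 0.1 h.
#'
#' @param dt Timestep in hours.
#' @param total_time Simulated duration in hours.
#' @param snapshot_interval Hours between recorded snapshots.
#' @param theta_low,theta_high Fate thresholds on the ratio scale: a
#'   progenitor whose ratio falls below `theta_low` is specified as PSM, one
#'   rising above `theta_high` as NT.
#' @param ratio_noise_sigma Noise amplitude of the ratio SDE, per sqrt(hour).
#' @param ratio_relaxation_kappa Drift (mean-reversion) rate of the ratio SDE,
#'   per hour.
#' @param v_high,v_mid,v_low Motility speeds (micron/h) conferred by low,
#'   intermediate and high ratios respectively.
#' @param motility_profile `"linear"` (default) interpolates speed from
#'   `v_high` to `v_low` across the undetermined band; `"step"` assigns the
#'   single plateau `v_mid` to the whole band. See [motility_of()].
#' @param adhesion_matrix Symmetric 3x3 attraction strengths by fate pair
#'   (progenitor, NT, PSM order).
#' @param cross_repulsion Strength of the cross-fate repulsion implementing
#'   the non-mixing boundary (same units as adhesion entries).
#' @param adhesion_ratio_coupling Per-cell adhesion coupling to the Sox2/Bra
#'   ratio for progenitor pairs: a cell's adhesion scale is
#'   `1 + coupling * (ratio - 1)`, so Sox2-high progenitors adhere more and
#'   Bra-high ones less; 0 disables.
#' @param f_core,f_adh Force scales (micron/h) of the hard-core repulsion and
#'   of the adhesion/non-mixing terms.
#' @param r_core,r_adh,r_pack Interaction radii in micrometres: hard-core
#'   exclusion, adhesion range, and the packing (density-cap) radius.
#' @param n_max Maximum number of neighbors allowed within `r_pack`; moves
#'   that would exceed it are rejected.
#' @param packing_sweeps Iterations of the hard-core packing projection per
#'   step (pairwise separation to at least `r_core`).
#' @param doubling_times Named vector of per-fate population doubling times
#'   in hours.
#' @param initial_counts Named vector of per-fate cell counts at t = 0.
#' @param population_scale Scale factor applied to `initial_counts` (and to
#'   nothing else) for reduced-size runs.
#' @param initial_ratio_range Interval from which progenitor ratios are drawn
#'   in the random regime. The published 0.15-0.85 interval, read on an
#'   internal 0-1 scale, maps to 0.3-1.7 on the depicted 0-2 scale; the raw
#'   interval remains selectable here.
#' @param regime Spatial organisation of progenitor ratios and SDE anchors:
#'   `"random"` (anchor 1 everywhere), `"gradient"` (anchor graded from
#'   anterior-high to posterior-low across the PZ) or `"mixed"` (gradient
#'   plus a per-cell random offset fixed at birth).
#' @param deregulation Forced-ratio experiment: `"bra_high"` anchors a
#'   fraction of progenitors below `theta_low`, `"sox2_high"` above
#'   `theta_high`, `"none"` leaves dynamics intact.
#' @param deregulated_fraction Fraction of progenitors subject to
#'   deregulation.
#' @param deregulation_anchor_low,deregulation_anchor_high Anchor values used
#'   by the `bra_high` and `sox2_high` deregulations.
#' @param mixed_offset Half-width of the per-cell anchor offset in the mixed
#'   regime (ratio units).
#' @param gradient_anchor_range Anchor values at the anterior and posterior
#'   PZ edges in the gradient/mixed regimes.
#' @param motility_enabled,interactions_enabled Ablation switches for the
#'   random-motility term and for the adhesion/non-mixing/packing bias.
#' @param ratio_dynamics_enabled When `FALSE`, ratios are frozen and no fate
#'   switching occurs (used for pure-proliferation calibration runs).
#' @param unit_scale_um Physical length of one model unit in micrometres.
#' @param nt_width,nt_length,psm_width,psm_length,pz_width,pz_length Region
#'   extents at t = 0, in model units.
#' @param seed Default RNG seed used by [run_simulation()] when none is given.
#'
#' @return An object of class `sim_config` (a named list).
#' @seealso [run_simulation()], [build_default_layout()]
#' @export
sim_config <- function(dt = 0.1,
                       total_time = 10,
                       snapshot_interval = dt,
                       theta_low = 0.4,
                       theta_high = 1.6,
                       ratio_noise_sigma = 0.09,
                       ratio_relaxation_kappa = 0.10,
                       v_high = 60,
                       v_mid = 36,
                       v_low = 12,
                       motility_profile = c("linear", "step"),
                       adhesion_matrix = default_adhesion_matrix(),
                       cross_repulsion = 0.5,
                       adhesion_ratio_coupling = 0.5,
                       f_core = 60,
                       f_adh = 10,
                       r_core = 7.5,
                       r_adh = 15,
                       r_pack = 15,
                       n_max = 16,
                       packing_sweeps = 20,
                       doubling_times = c(progenitor = 11.49, NT = 10.83,
                                          PSM = 8.75),
                       initial_counts = c(progenitor = 1100, NT = 1200,
                                          PSM = 3200),
                       population_scale = 1,
                       initial_ratio_range = c(0.3, 1.7),
                       regime = c("mixed", "random", "gradient"),
                       deregulation = c("none", "bra_high", "sox2_high"),
                       deregulated_fraction = 1,
                       deregulation_anchor_low = 0.2,
                       deregulation_anchor_high = 1.8,
                       mixed_offset = 0.35,
                       gradient_anchor_range = c(anterior = 1.7,
                                                 posterior = 0.3),
                       motility_enabled = TRUE,
                       interactions_enabled = TRUE,
                       ratio_dynamics_enabled = TRUE,
                       unit_scale_um = 150,
                       nt_width = 1.0,
                       nt_length = 4.0,
                       psm_width = 1.3,
                       psm_length = 4.0,
                       pz_width = 3.6,
                       pz_length = 1.5,
                       seed = 1L) {
  regime <- match.arg(regime)
  deregulation <- match.arg(deregulation)
  motility_profile <- match.arg(motility_profile)
  cfg <- list(
    dt = dt, total_time = total_time, snapshot_interval = snapshot_interval,
    theta_low = theta_low, theta_high = theta_high,
    ratio_noise_sigma = ratio_noise_sigma,
    ratio_relaxation_kappa = ratio_relaxation_kappa,
    v_high = v_high, v_mid = v_mid, v_low = v_low,
    motility_profile = motility_profile,
    adhesion_matrix = adhesion_matrix,
    cross_repulsion = cross_repulsion,
    adhesion_ratio_coupling = adhesion_ratio_coupling,
    f_core = f_core, f_adh = f_adh,
    r_core = r_core, r_adh = r_adh, r_pack = r_pack, n_max = n_max,
    packing_sweeps = packing_sweeps,
    doubling_times = doubling_times,
    initial_counts = initial_counts,
    population_scale = population_scale,
    initial_ratio_range = initial_ratio_range,
    regime = regime,
    deregulation = deregulation,
    deregulated_fraction = deregulated_fraction,
    deregulation_anchor_low = deregulation_anchor_low,
    deregulation_anchor_high = deregulation_anchor_high,
    mixed_offset = mixed_offset,
    gradient_anchor_range = gradient_anchor_range,
    motility_enabled = motility_enabled,
    interactions_enabled = interactions_enabled,
    ratio_dynamics_enabled = ratio_dynamics_enabled,
    unit_scale_um = unit_scale_um,
    nt_width = nt_width, nt_length = nt_length,
    psm_width = psm_width, psm_length = psm_length,
    pz_width = pz_width, pz_length = pz_length,
    seed = seed
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  pos <- c("dt", "snapshot_interval", "ratio_noise_sigma",
           "ratio_relaxation_kappa", "r_core", "r_adh", "r_pack",
           "unit_scale_um", "nt_width", "nt_length", "psm_width",
           "psm_length", "pz_width", "pz_length", "population_scale")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0) {
      stop("`", f, "` must be a single positive number", call. = FALSE)
    }
  }
  if (cfg$total_time < 0) stop("`total_time` must be >= 0", call. = FALSE)
  if (cfg$theta_low >= cfg$theta_high) {
    stop("`theta_low` must be strictly below `theta_high`", call. = FALSE)
  }
  if (!(cfg$v_low <= cfg$v_mid && cfg$v_mid <= cfg$v_high)) {
    stop("motility speeds must satisfy v_low <= v_mid <= v_high",
         call. = FALSE)
  }
  if (any(cfg$v_low < 0)) stop("speeds must be non-negative", call. = FALSE)
  a <- cfg$adhesion_matrix
  if (!is.matrix(a) || !identical(dim(a), c(3L, 3L)) || !isTRUE(all.equal(a, t(a)))) {
    stop("`adhesion_matrix` must be a symmetric 3x3 matrix", call. = FALSE)
  }
  if (!(a["NT", "NT"] > a["PSM", "PSM"])) {
    stop("adhesion(NT,NT) must exceed adhesion(PSM,PSM)", call. = FALSE)
  }
  if (any(cfg$doubling_times <= 0)) {
    stop("doubling times must be positive", call. = FALSE)
  }
  if (any(cfg$initial_counts < 0) ||
      !all(FATES %in% names(cfg$initial_counts))) {
    stop("`initial_counts` must name non-negative counts for ",
         paste(FATES, collapse = ", "), call. = FALSE)
  }
  if (cfg$r_adh < cfg$r_core) {
    stop("`r_adh` must be >= `r_core`", call. = FALSE)
  }
  if (cfg$deregulated_fraction < 0 || cfg$deregulated_fraction > 1) {
    stop("`deregulated_fraction` must lie in [0, 1]", call. = FALSE)
  }
  rr <- cfg$initial_ratio_range
  if (length(rr) != 2L || rr[1] > rr[2] || rr[1] < 0 || rr[2] > 2) {
    stop("`initial_ratio_range` must be an increasing interval within [0, 2]",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Apply a Sox2/Bra deregulation to a configuration
#'
#' Validates and normalises the forced-ratio experiment encoded in a config:
#' `bra_high` drives the SDE anchor of the deregulated progenitor fraction
#' below the PSM threshold, `sox2_high` above the NT threshold. With
#' `deregulation = "none"` the configuration is returned unchanged.
#'
#' @param config A [sim_config()].
#' @return The configuration, with deregulation anchors checked against the
#'   fate thresholds.
#' @export
apply_deregulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  mode <- config$deregulation
  if (!mode %in% c("none", "bra_high", "sox2_high")) {
    stop("unknown deregulation mode: ", mode, call. = FALSE)
  }
  if (mode == "bra_high" && config$deregulation_anchor_low >= config$theta_low) {
    stop("`deregulation_anchor_low` must lie below `theta_low`",
         call. = FALSE)
  }
  if (mode == "sox2_high" &&
      config$deregulation_anchor_high <= config$theta_high) {
    stop("`deregulation_anchor_high` must lie above `theta_high`",
         call. = FALSE)
  }
  config
}

#' Read and write simulation configurations as YAML
#'
#' The on-disk representation uses the `sim_config` field names verbatim; the
#' adhesion matrix is stored row-wise.
#'
#' @param config A [sim_config()].
#' @param path File path.
#' @return `write_sim_config()` returns `path` invisibly; `read_sim_config()`
#'   returns a validated [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  x$adhesion_matrix <- apply(config$adhesion_matrix, 1, as.list,
                             simplify = FALSE)
  # named vectors as mappings (YAML sequences drop names)
  for (f in c("doubling_times", "initial_counts", "gradient_anchor_range")) {
    x[[f]] <- as.list(x[[f]])
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$adhesion_matrix)) {
    m <- matrix(unlist(x$adhesion_matrix), 3, 3, byrow = TRUE)
    dimnames(m) <- list(FATES, FATES)
    x$adhesion_matrix <- m
  }
  for (f in c("doubling_times", "initial_counts")) {
    if (!is.null(x[[f]])) x[[f]] <- unlist(x[[f]])
  }
  for (f in c("initial_ratio_range", "gradient_anchor_range")) {
    if (!is.null(x[[f]])) x[[f]] <- unlist(x[[f]])
  }
  do.call(sim_config, x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  regime:", x$regime, "  deregulation:", x$deregulation, "\n")
  cat("  duration:", x$total_time, "h at dt =", x$dt, "h\n")
  cat("  thresholds: [", x$theta_low, ",", x$theta_high, "] on the 0-2 ratio scale\n")
  cat("  initial counts:",
      paste(names(x$initial_counts), x$initial_counts, sep = "=",
            collapse = ", "),
      if (x$population_scale != 1) paste0("(x", x$population_scale, ")"),
      "\n")
  cat("  motility (um/h): high", x$v_high, "mid", x$v_mid, "low", x$v_low, "\n")
  invisible(x)
}
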