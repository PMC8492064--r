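#' Initialize the cell population
#'
#' Places exactly the configured number of progenitor, NT and PSM cells
#' uniformly at random inside their t = 0 regions. NT cells start with a
#' fixed high ratio (above `theta_high`), PSM cells with a fixed low ratio
#' (below `theta_low`). Progenitor ratios are drawn according to the regime:
#' uniform over `initial_ratio_range` (random), equal to the anterior-to-
#' posterior anchor gradient (gradient), or gradient plus a per-cell offset
#' fixed at birth (mixed).
#'
#' @param config A [sim_config()].
#' @param layout A `domain_layout`; defaults to [build_default_layout()].
#' @return A tibble of cells: `cell_id`, `parent_id`, `state`, `ratio`,
#'   `x_um`, `y_um`, `birth_time`, `anchor_offset`, `deregulated`.
#' @export
initialize_population <- function(config, layout = build_default_layout(config)) {
  stopifnot(inherits(config, "sim_config"))
  config <- apply_deregulation(config)
  counts <- setNames(pmax(0L, as.integer(round(config$initial_counts[FATES] *
                                                 config$population_scale))),
                     FATES)
  scale <- layout$unit_scale_um
  r <- layout$regions

  rect_um <- function(region) {
    k <- r[r$region == region, ]
    c(x_min = k$x_min * scale, x_max = k$x_max * scale,
      y_min = k$y_min * scale, y_max = k$y_max * scale)
  }
  check_density <- function(n, rects) {
    area <- sum(vapply(rects, function(b) {
      (b["x_max"] - b["x_min"]) * (b["y_max"] - b["y_min"])
    }, numeric(1)))
    if (n > 0 && n / area * pi * config$r_pack^2 > config$n_max) {
      stop("initial region too small for the density cap (n_max = ",
           config$n_max, " within r_pack = ", config$r_pack, " um)",
           call. = FALSE)
    }
  }
  sample_rect <- function(n, b) {
    list(x = runif(n, b["x_min"], b["x_max"]),
         y = runif(n, b["y_min"], b["y_max"]))
  }

  pz <- rect_um("PZ"); nt <- rect_um("NT")
  pl <- rect_um("PSM_left"); pr <- rect_um("PSM_right")
  check_density(counts["progenitor"], list(pz))
  check_density(counts["NT"], list(nt))
  check_density(counts["PSM"], list(pl, pr))

  n_p <- counts[["progenitor"]]; n_n <- counts[["NT"]]; n_m <- counts[["PSM"]]
  p_pos <- sample_rect(n_p, pz)
  n_pos <- sample_rect(n_n, nt)
  side <- runif(n_m) < 0.5
  m_left <- sample_rect(sum(side), pl)
  m_right <- sample_rect(sum(!side), pr)

  # progenitor ratios per regime; gradient runs anterior-high to posterior-low
  g <- config$gradient_anchor_range
  grad_at <- function(y) {
    t <- (y - pz["y_min"]) / (pz["y_max"] - pz["y_min"])
    g[["anterior"]] + (g[["posterior"]] - g[["anterior"]]) * pmin(pmax(t, 0), 1)
  }
  # initial progenitors are undetermined by definition: graded draws are
  # clamped just inside the fate thresholds (the SDE anchors, not the t = 0
  # values, carry cells across them)
  band <- c(config$theta_low + 0.1, config$theta_high - 0.1)
  offset <- rep(0, n_p)
  ratio_p <- switch(config$regime,
    random = runif(n_p, config$initial_ratio_range[1],
                   config$initial_ratio_range[2]),
    gradient = pmin(pmax(grad_at(p_pos$y), band[1]), band[2]),
    mixed = {
      offset <- runif(n_p, -config$mixed_offset, config$mixed_offset)
      pmin(pmax(grad_at(p_pos$y) + offset, band[1]), band[2])
    })

  dereg <- rep(FALSE, n_p)
  if (config$deregulation != "none" && n_p > 0) {
    k <- round(config$deregulated_fraction * n_p)
    dereg[sample.int(n_p, k)] <- TRUE
  }

  n_tot <- n_p + n_n + n_m
  tibble::tibble(
    cell_id = seq_len(n_tot),
    parent_id = NA_integer_,
    state = rep(FATES, times = c(n_p, n_n, n_m)),
    ratio = c(ratio_p, rep(1.9, n_n), rep(0.1, n_m)),
    x_um = c(p_pos$x, n_pos$x, m_left$x, m_right$x),
    y_um = c(p_pos$y, n_pos$y, m_left$y, m_right$y),
    birth_time = 0,
    anchor_offset = c(offset, rep(0, n_n + n_m)),
    deregulated = c(dereg, rep(FALSE, n_n + n_m))
  )
}

# SDE anchor per progenitor: 1 in the random regime; graded across the
# current progenitor AP span (robust 5th-95th percentile) in the gradient
# regime; gradient plus the cell's birth offset in the mixed regime.
# Deregulated cells are anchored beyond the relevant threshold regardless.
progenitor_anchor <- function(cells, config) {
  idx <- cells$state == "progenitor"
  y <- cells$y_um[idx]
  mu <- switch(config$regime,
    random = rep(1, sum(idx)),
    gradient = ,
    mixed = {
      span <- quantile(y, c(0.05, 0.95), names = FALSE)
      t <- if (diff(span) > 0) (y - span[1]) / diff(span) else rep(0.5, length(y))
      g <- config$gradient_anchor_range
      m <- g[["anterior"]] + (g[["posterior"]] - g[["anterior"]]) *
        pmin(pmax(t, 0), 1)
      if (config$regime == "mixed") m <- m + cells$anchor_offset[idx]
      pmin(pmax(m, 0.05), 1.95)
    })
  if (config$deregulation == "bra_high") {
    mu[cells$deregulated[idx]] <- config$deregulation_anchor_low
  } else if (config$deregulation == "sox2_high") {
    mu[cells$deregulated[idx]] <- config$deregulation_anchor_high
  }
  mu
}

#' One Euler-Maruyama step of the Sox2/Bra ratio SDE
#'
#' Progenitor ratios follow an Ornstein-Uhlenbeck process,
#' dR = -kappa (R - mu) dt + sigma dW, clipped to the depicted 0-2 scale.
#' Noise-driven excursions below `theta_low` or above `theta_high` are what
#' specify fates. Vectorised over cells; uses the current R RNG stream.
#'
#' @param ratio Numeric vector of progenitor ratios.
#' @param mu Anchor value(s) of the drift.
#' @param config A [sim_config()] (supplies kappa and sigma).
#' @param dt Timestep in hours.
#' @param noise If `FALSE`, take the deterministic drift step only.
#' @return Updated ratios, clipped to `[0, 2]`.
#' @export
update_ratio <- function(ratio, mu, config, dt = config$dt, noise = TRUE) {
  k <- config$ratio_relaxation_kappa
  s <- if (noise) config$ratio_noise_sigma else 0
  r <- ratio - k * (ratio - mu) * dt +
    if (s > 0) s * sqrt(dt) * rnorm(length(ratio)) else 0
  pmin(pmax(r, 0), 2)
}

#' Threshold fate specification
#'
#' A progenitor whose ratio has fallen below `theta_low` is specified as PSM
#' (Bra-high); one whose ratio has risen above `theta_high` becomes NT
#' (Sox2-high). Specification is irreversible: NT and PSM states are
#' returned unchanged whatever their ratio.
#'
#' @param state Character vector of fates.
#' @param ratio Numeric vector of ratios.
#' @param config A [sim_config()].
#' @return Updated character vector of fates.
#' @export
specify_state <- function(state, ratio, config) {
  prog <- state == "progenitor"
  state[prog & ratio < config$theta_low] <- "PSM"
  state[prog & ratio > config$theta_high] <- "NT"
  state
}

#' Ratio-dependent motility
#'
#' Low ratios (below `theta_low`) or PSM fate confer high motility; high
#' ratios (above `theta_high`) or NT fate inhibit motility; intermediate
#' ratios confer intermediate levels of motility. With the default
#' `"linear"` profile, speed interpolates from `v_high` at `theta_low` down
#' to `v_low` at `theta_high` (so a ratio of 1 gives `(v_high + v_low) / 2`,
#' the default `v_mid`); cell-to-cell ratio heterogeneity then translates
#' into motility heterogeneity inside the undetermined band, which is what
#' distinguishes the spatially random ratio organisation from the graded
#' one. The `"step"` profile assigns the single plateau `v_mid` to the whole
#' band. Both are non-increasing in the ratio.
#'
#' @param ratio Numeric vector of ratios.
#' @param state Character vector of fates.
#' @param config A [sim_config()].
#' @return Speeds in micrometres per hour.
#' @export
motility_of <- function(ratio, state, config) {
  prof <- config$motility_profile %||% "linear"
  if (prof == "step") {
    v <- rep(config$v_mid, length(ratio))
  } else {
    t <- (ratio - config$theta_low) / (config$theta_high - config$theta_low)
    v <- config$v_high + (config$v_low - config$v_high) * pmin(pmax(t, 0), 1)
  }
  v[state == "PSM" | ratio < config$theta_low] <- config$v_high
  v[state == "NT" | ratio > config$theta_high] <- config$v_low
  v
}

#' One position update of the biased random walk
#'
#' Each cell proposes a displacement composed of an isotropic random step of
#' length `motility * dt` plus an interaction bias (fate-pair adhesion,
#' hard-core repulsion, cross-fate non-mixing repulsion). Candidates that
#' cross the anterior or lateral walls, or that would push the local density
#' above `n_max` neighbors within `r_pack`, are rejected and the cell stays
#' put for the step. When interactions are enabled, a hard-core packing pass
#' (`packing_sweeps` Gauss-Seidel projections to pairwise distance >=
#' `r_core`) then resolves residual overlaps; the resulting contact-chain
#' pressure is what pushes the proliferating tissue into the open posterior
#' space.
#'
#' @param cells Cell tibble (see [initialize_population()]).
#' @param layout A `domain_layout`.
#' @param config A [sim_config()]; honours `motility_enabled` and
#'   `interactions_enabled`.
#' @param dt Timestep in hours.
#' @return The cell tibble with updated `x_um`, `y_um`.
#' @export
step_positions <- function(cells, layout, config, dt = config$dt) {
  n <- nrow(cells)
  if (n == 0) return(cells)
  if (!config$motility_enabled && !config$interactions_enabled) return(cells)
  scale <- layout$unit_scale_um
  if (!config$motility_enabled) {
    # interactions only bias the random motion: with motility ablated the
    # cells make no moves, and only the hard-core packing still acts
    pos <- resolve_overlaps_cpp(
      cells$x_um, cells$y_um, config$r_core,
      as.integer(config$packing_sweeps),
      layout$anterior_wall_y * scale,
      layout$lateral_wall_x_left * scale,
      layout$lateral_wall_x_right * scale, 1.0)
    cells$x_um <- pos[, 1]
    cells$y_um <- pos[, 2]
    return(cells)
  }
  speed <- motility_of(cells$ratio, cells$state, config)
  angle <- runif(n, 0, 2 * pi)
  # Sox2-high progenitors adhere more: per-cell adhesion scale rises with
  # the ratio (coupling 0 switches this off); specified fates use their
  # fate-pair adhesion unchanged
  cpl <- config$adhesion_ratio_coupling %||% 0
  adh_scale <- ifelse(cells$state == "progenitor",
                      pmax(1 + cpl * (cells$ratio - 1), 0), 1)
  repel <- matrix(config$cross_repulsion, 3, 3)
  diag(repel) <- 0
  pos <- step_positions_cpp(
    cells$x_um, cells$y_um, fate_int(cells$state), speed, angle, adh_scale, dt,
    config$r_core, config$r_adh, config$r_pack, as.integer(config$n_max),
    config$f_core, config$f_adh,
    config$adhesion_matrix, repel,
    layout$anterior_wall_y * scale,
    layout$lateral_wall_x_left * scale,
    layout$lateral_wall_x_right * scale,
    config$motility_enabled, config$interactions_enabled)
  if (config$interactions_enabled) {
    pos <- resolve_overlaps_cpp(
      pos[, 1], pos[, 2], config$r_core, as.integer(config$packing_sweeps),
      layout$anterior_wall_y * scale,
      layout$lateral_wall_x_left * scale,
      layout$lateral_wall_x_right * scale, 1.0)
  }
  cells$x_um <- pos[, 1]
  cells$y_um <- pos[, 2]
  cells
}

#' Cell division
#'
#' Each cell divides with probability `dt * ln(2) / T` per step, `T` being
#' its fate's doubling time. Daughters inherit state and ratio and are
#' placed at distance `r_core / 2` from the mother at a uniform random
#' angle (the density cap is not applied to the birth placement itself).
#' There is no cell death.
#'
#' @param cells Cell tibble.
#' @param config A [sim_config()].
#' @param dt Timestep in hours.
#' @param time Current simulation time, stamped as the daughters'
#'   `birth_time`.
#' @return The cell tibble with daughters appended.
#' @export
proliferate <- function(cells, config, dt = config$dt, time = NA_real_) {
  n <- nrow(cells)
  if (n == 0) return(cells)
  p <- dt * log(2) / config$doubling_times[cells$state]
  divides <- runif(n) < p
  nd <- sum(divides)
  if (nd == 0) return(cells)
  ang <- runif(nd, 0, 2 * pi)
  d <- config$r_core / 2
  off <- if (config$regime == "mixed") {
    runif(nd, -config$mixed_offset, config$mixed_offset)
  } else rep(0, nd)
  half_um <- (config$nt_width / 2 + config$psm_width) * config$unit_scale_um
  dx_um <- pmin(pmax(cells$x_um[divides] + d * cos(ang), -half_um), half_um)
  dy_um <- pmax(cells$y_um[divides] + d * sin(ang), 0)
  daughters <- tibble::tibble(
    cell_id = max(cells$cell_id) + seq_len(nd),
    parent_id = cells$cell_id[divides],
    state = cells$state[divides],
    ratio = cells$ratio[divides],
    x_um = dx_um,
    y_um = dy_um,
    birth_time = time,
    anchor_offset = off,
    deregulated = cells$deregulated[divides]
  )
  dplyr::bind_rows(cells, daughters)
}

#' Run the agent-based elongation model
#'
#' Iterates ratio update, fate specification, position update and
#' proliferation for `total_time` hours at timestep `dt`, recording
#' snapshots every `snapshot_interval`. The run is fully reproducible:
#' identical config and seed give identical results.
#'
#' Specified (NT/PSM) cells stop taking SDE noise; their ratios relax
#' deterministically toward 2 and 0 respectively at rate kappa, and they
#' keep moving with their new fate's motility immediately.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return A `sim_result`: list with `snapshots` (tibble: `time_h`,
#'   `cell_id`, `parent_id`, `state`, `ratio`, `x_unit`, `y_unit`),
#'   `counts` (tibble: `time_h`, `state`, `n`), `switches` (tibble of fate
#'   switch events with the ratio at switching), `config`, `layout`,
#'   `seed`.
#' @examples
#' cfg <- sim_config(total_time = 0.5, population_scale = 0.1)
#' res <- run_simulation(cfg, seed = 1)
#' dplyr::count(res$snapshots, time_h)
#' @export
run_simulation <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  config <- apply_deregulation(config)
  set.seed(seed)
  layout <- build_default_layout(config)
  cells <- initialize_population(config, layout)
  scale <- layout$unit_scale_um

  n_steps <- round(config$total_time / config$dt)
  every <- max(1L, round(config$snapshot_interval / config$dt))
  snaps <- vector("list", n_steps + 1L)
  take <- function(cells, t) {
    tibble::tibble(time_h = t, cell_id = cells$cell_id,
                   parent_id = cells$parent_id, state = cells$state,
                   ratio = cells$ratio, x_unit = cells$x_um / scale,
                   y_unit = cells$y_um / scale)
  }
  snaps[[1L]] <- take(cells, 0)
  sw <- list()

  for (step in seq_len(n_steps)) {
    t_now <- step * config$dt
    if (config$ratio_dynamics_enabled) {
      prog <- cells$state == "progenitor"
      if (any(prog)) {
        mu <- progenitor_anchor(cells, config)
        cells$ratio[prog] <- update_ratio(cells$ratio[prog], mu, config,
                                          config$dt)
      }
      nt <- cells$state == "NT"; psm <- cells$state == "PSM"
      k <- config$ratio_relaxation_kappa
      cells$ratio[nt] <- pmin(cells$ratio[nt] +
                                k * (2 - cells$ratio[nt]) * config$dt, 2)
      cells$ratio[psm] <- pmax(cells$ratio[psm] -
                                 k * cells$ratio[psm] * config$dt, 0)
      new_state <- specify_state(cells$state, cells$ratio, config)
      switched <- new_state != cells$state
      if (any(switched)) {
        sw[[length(sw) + 1L]] <- tibble::tibble(
          time_h = t_now,
          cell_id = cells$cell_id[switched],
          ratio_at_switch = cells$ratio[switched],
          new_state = new_state[switched])
        cells$state <- new_state
      }
    }
    cells <- step_positions(cells, layout, config, config$dt)
    cells <- proliferate(cells, config, config$dt, time = t_now)
    if (step %% every == 0L || step == n_steps) {
      snaps[[step + 1L]] <- take(cells, t_now)
    }
  }

  snapshots <- dplyr::bind_rows(snaps)
  counts <- dplyr::count(snapshots, .data$time_h, .data$state, name = "n")
  switches <- if (length(sw)) dplyr::bind_rows(sw) else {
    tibble::tibble(time_h = numeric(), cell_id = integer(),
                   ratio_at_switch = numeric(), new_state = character())
  }
  structure(list(snapshots = snapshots, counts = counts, switches = switches,
                 config = config, layout = layout, seed = seed),
            class = "sim_result")
}

#' Extract trajectories from a simulation result
#'
#' Converts snapshots into the package-standard track table (positions in
#' micrometres), one track per cell, with the cell's fate at each frame as
#' its tissue label (progenitor mapped to `"PZ"`).
#'
#' @param result A `sim_result`.
#' @return A track tibble: `track_id`, `frame`, `t_hours`, `x_um`, `y_um`,
#'   `tissue`, with a `frame_interval` attribute in hours.
#' @export
tracks_of <- function(result) {
  stopifnot(inherits(result, "sim_result"))
  scale <- result$layout$unit_scale_um
  times <- sort(unique(result$snapshots$time_h))
  tr <- result$snapshots |>
    dplyr::transmute(
      track_id = .data$cell_id,
      frame = match(.data$time_h, times),
      t_hours = .data$time_h,
      x_um = .data$x_unit * scale,
      y_um = .data$y_unit * scale,
      tissue = dplyr::recode(.data$state, progenitor = "PZ")) |>
    dplyr::arrange(.data$track_id, .data$frame)
  attr(tr, "frame_interval") <- if (length(times) > 1) diff(times)[1] else NA_real_
  tr
}

#' @export
print.sim_result <- function(x, ...) {
  fin <- dplyr::filter(x$counts, .data$time_h == max(.data$time_h))
  cat("<sim_result>", x$config$regime, "regime,",
      max(x$snapshots$time_h), "h,", "seed", x$seed, "\n")
  cat("  final counts:",
      paste(fin$state, fin$n, sep = "=", collapse = ", "), "\n")
  cat("  fate switches:", nrow(x$switches), "\n")
  invisible(x)
}
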