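snapshot_at <- function(result, time_h) {
  s <- result$snapshots
  t_avail <- unique(s$time_h)
  t_pick <- t_avail[which.min(abs(t_avail - time_h))]
  s[s$time_h == t_pick, ]
}

#' Axis elongation over a time window
#'
#' The posterior edge of the progenitor zone is taken as the 95th percentile
#' of progenitor y per snapshot (robust to stray cells); elongation is the
#' posterior displacement of that edge over the window, in micrometres, and
#' the corresponding rate.
#'
#' @param result A `sim_result`.
#' @param window_hours Window length (from the first snapshot); default 10.
#' @return One-row tibble: `t0_h`, `t1_h`, `distance_um`, `rate_um_h`.
#' @export
elongation_rate <- function(result, window_hours = 10) {
  stopifnot(inherits(result, "sim_result"))
  edge <- function(time_h) {
    s <- snapshot_at(result, time_h)
    yp <- s$y_unit[s$state == "progenitor"]
    if (!length(yp)) stop("no progenitors in snapshot at t = ", time_h, " h",
                          call. = FALSE)
    quantile(yp, 0.95, names = FALSE)
  }
  t0 <- min(result$snapshots$time_h)
  t1 <- min(t0 + window_hours, max(result$snapshots$time_h))
  d_units <- edge(t1) - edge(t0)
  d_um <- units_to_um(d_units, result$layout)
  tibble::tibble(t0_h = t0, t1_h = t1, distance_um = d_um,
                 rate_um_h = d_um / (t1 - t0))
}

#' Net posterior displacement of resident progenitors
#'
#' Residents are cells present from the first to the last snapshot that keep
#' the progenitor fate throughout. Optionally restricted to those starting
#' in the central third of the PZ's AP span. Returns each resident's net y
#' displacement in micrometres (positive = posterior).
#'
#' @param result A `sim_result`.
#' @param central_third Restrict to residents starting in the central AP
#'   third of the initial progenitor span (default `TRUE`).
#' @return Tibble with `cell_id`, `y_displacement_um`; zero rows (with a
#'   `warning` attribute set) if there are no residents.
#' @export
resident_y_displacement <- function(result, central_third = TRUE) {
  stopifnot(inherits(result, "sim_result"))
  s <- result$snapshots
  n_snap <- length(unique(s$time_h))
  per_cell <- s |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(n = dplyr::n(),
                     always_prog = all(.data$state == "progenitor"),
                     y0 = dplyr::first(.data$y_unit),
                     y1 = dplyr::last(.data$y_unit),
                     .groups = "drop")
  res <- per_cell[per_cell$n == n_snap & per_cell$always_prog, ]
  if (central_third && nrow(res)) {
    s0 <- s[s$time_h == min(s$time_h) & s$state == "progenitor", ]
    span <- quantile(s0$y_unit, c(0.05, 0.95), names = FALSE)
    lo <- span[1] + diff(span) / 3
    hi <- span[1] + 2 * diff(span) / 3
    res <- res[res$y0 >= lo & res$y0 <= hi, ]
  }
  out <- tibble::tibble(
    cell_id = res$cell_id,
    y_displacement_um = units_to_um(res$y1 - res$y0, result$layout))
  if (!nrow(out)) attr(out, "warning") <- "no resident progenitors"
  out
}

#' Robust shape descriptor of the progenitor population
#'
#' AP length and ML width measured as 5th-95th percentile spans of
#' progenitor y and x, a robust proxy for the outlined PZ shape.
#'
#' @param cells Snapshot rows (needs `state`, `x_unit`, `y_unit`) or a cell
#'   tibble with `x_um`, `y_um`.
#' @param layout A `domain_layout` used to convert to micrometres when
#'   positions are in model units.
#' @return One-row tibble: `length_um`, `width_um`, `aspect`.
#' @export
shape_descriptor <- function(cells, layout = NULL) {
  if (all(c("x_unit", "y_unit") %in% names(cells))) {
    stopifnot(!is.null(layout))
    x <- units_to_um(cells$x_unit, layout)
    y <- units_to_um(cells$y_unit, layout)
  } else {
    x <- cells$x_um; y <- cells$y_um
  }
  if ("state" %in% names(cells)) {
    keep <- cells$state == "progenitor"
    x <- x[keep]; y <- y[keep]
  }
  if (length(x) < 2) stop("too few progenitors for a shape", call. = FALSE)
  len <- diff(quantile(y, c(0.05, 0.95), names = FALSE))
  wid <- diff(quantile(x, c(0.05, 0.95), names = FALSE))
  if (wid <= 0 || len <= 0) stop("degenerate shape extent", call. = FALSE)
  tibble::tibble(length_um = len, width_um = wid, aspect = len / wid)
}

#' Shape conservation percentage
#'
#' Similarity of the length/width aspect ratio between two time points:
#' `100 * min(a1/a0, a0/a1)`. 100% corresponds to an unchanged shape; the
#' measure is symmetric in its arguments and at most 100.
#'
#' @param shape_t0,shape_t1 Shape descriptors (see [shape_descriptor()]).
#' @return Percentage in (0, 100].
#' @export
shape_conservation <- function(shape_t0, shape_t1) {
  a0 <- shape_t0$aspect; a1 <- shape_t1$aspect
  if (!is.finite(a0) || !is.finite(a1) || a0 <= 0 || a1 <= 0) {
    stop("invalid aspect ratio", call. = FALSE)
  }
  100 * min(a1 / a0, a0 / a1)
}

#' Per-fate cell counts over time
#'
#' @param result A `sim_result`.
#' @return Tibble with `time_h`, `state`, `n` (zero-filled for absent
#'   fates); per-snapshot sums equal the total population.
#' @export
count_timeseries <- function(result) {
  stopifnot(inherits(result, "sim_result"))
  result$snapshots |>
    dplyr::count(.data$time_h, .data$state, name = "n") |>
    tidyr::complete(time_h = unique(result$snapshots$time_h),
                    state = FATES, fill = list(n = 0L))
}

#' Estimate a population doubling time from a count series
#'
#' Least-squares fit of ln(count) versus time; the doubling time is
#' ln(2) / slope. Non-growing series are flagged rather than reported as a
#' spurious time.
#'
#' @param counts Data frame with `time_h` and `n` (one fate), or a numeric
#'   vector with `times`.
#' @param times Time points (hours) when `counts` is a bare vector.
#' @return One-row tibble: `doubling_h`, `rate_per_h`, `r_squared`,
#'   `growing` (`FALSE` when the fitted slope is not positive, in which case
#'   `doubling_h` is `Inf` or negative).
#' @export
measure_doubling_time <- function(counts, times = NULL) {
  if (is.data.frame(counts)) {
    times <- counts$time_h
    n <- counts$n
  } else {
    n <- counts
  }
  stopifnot(length(n) >= 3, length(times) == length(n))
  if (any(n <= 0)) stop("counts must be positive for a log fit", call. = FALSE)
  fit <- lm(log(n) ~ times)
  slope <- coef(fit)[[2]]
  r2 <- suppressWarnings(summary(fit)$r.squared)  # flat series fit perfectly
  tibble::tibble(doubling_h = log(2) / slope, rate_per_h = slope,
                 r_squared = r2, growing = slope > 0)
}

#' Tissue integrity score
#'
#' Fraction of cells whose neighbors (within `radius_um`) are in strict
#' majority of the same fate; isolated cells count as intact. High scores
#' mean sharp, unmixed tissues; disabling motility (fates switch in place
#' and never sort) or disabling adhesion/non-mixing (fates interpenetrate)
#' degrades the score.
#'
#' @param snapshot Snapshot rows (`state` + `x_unit`/`y_unit`) or a cell
#'   tibble (`state` + `x_um`/`y_um`).
#' @param radius_um Neighborhood radius in micrometres.
#' @param layout A `domain_layout`, required for model-unit input.
#' @return Fraction in `[0, 1]`.
#' @export
tissue_integrity <- function(snapshot, radius_um = 20, layout = NULL) {
  if (all(c("x_unit", "y_unit") %in% names(snapshot))) {
    stopifnot(!is.null(layout))
    x <- units_to_um(snapshot$x_unit, layout)
    y <- units_to_um(snapshot$y_unit, layout)
  } else {
    x <- snapshot$x_um; y <- snapshot$y_um
  }
  ok <- majority_same_fate_cpp(x, y, fate_int(snapshot$state), radius_um)
  mean(ok)
}

#' @export
glance.sim_result <- function(x, ...) {
  fin <- snapshot_at(x, max(x$snapshots$time_h))
  n_by <- table(factor(fin$state, levels = FATES))
  el <- elongation_rate(x, window_hours = max(x$snapshots$time_h))
  tibble::tibble(
    regime = x$config$regime,
    duration_h = max(x$snapshots$time_h),
    n_progenitor = as.integer(n_by[["progenitor"]]),
    n_NT = as.integer(n_by[["NT"]]),
    n_PSM = as.integer(n_by[["PSM"]]),
    n_switches = nrow(x$switches),
    elongation_um = el$distance_um,
    elongation_um_h = el$rate_um_h)
}

#' @export
tidy.sim_result <- function(x, ...) x$snapshots
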