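#' Validate a track table
#'
#' The package-standard trajectory format: one row per cell per frame with
#' columns `track_id`, `frame`, `t_hours`, `x_um`, `y_um`, `tissue`.
#' Frames within a track must be strictly increasing and uniformly sampled;
#' every track needs at least two points to define a displacement.
#'
#' @param tracks A data frame in the track-table format.
#' @return The tracks as a tibble, invisibly checked; `frame_interval` (h)
#'   is attached as an attribute.
#' @export
as_track_table <- function(tracks) {
  need <- c("track_id", "frame", "t_hours", "x_um", "y_um", "tissue")
  missing <- setdiff(need, names(tracks))
  if (length(missing)) {
    stop("track table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tr <- dplyr::arrange(tibble::as_tibble(tracks), .data$track_id, .data$frame)
  by_track <- dplyr::summarise(
    dplyr::group_by(tr, .data$track_id),
    n = dplyr::n(),
    increasing = all(diff(.data$frame) > 0),
    dts = list(unique(round(diff(.data$t_hours), 9))),
    .groups = "drop")
  if (any(by_track$n < 2)) {
    stop("every track needs >= 2 points", call. = FALSE)
  }
  if (!all(by_track$increasing)) {
    stop("frames must be strictly increasing within each track",
         call. = FALSE)
  }
  dts <- unique(unlist(by_track$dts))
  if (length(dts) != 1L) {
    stop("tracks must be uniformly sampled (single frame interval); gaps ",
         "are an input error, not interpolated", call. = FALSE)
  }
  attr(tr, "frame_interval") <- dts
  tr
}

frame_interval_of <- function(tracks) {
  fi <- attr(tracks, "frame_interval")
  if (is.null(fi) || is.na(fi)) {
    fi <- unique(round(unlist(tapply(tracks$t_hours, tracks$track_id, diff)), 9))
    if (length(fi) != 1L) stop("non-uniform frame interval", call. = FALSE)
  }
  fi
}

#' Re-reference tracks to an external reference point
#'
#' Subtracts a reference time series (e.g. the position of the last-formed
#' somite) from every track, producing the "raw" frame in which tissue-scale
#' posterior motion is measured relative to that landmark.
#'
#' @param tracks A track table.
#' @param reference Data frame with `frame`, `x_um`, `y_um`: the reference
#'   position at every frame occurring in `tracks`.
#' @return The track table with positions relative to the reference.
#' @export
subtract_reference <- function(tracks, reference) {
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(reference)))
  missing <- setdiff(unique(tracks$frame), reference$frame)
  if (length(missing)) {
    stop("reference lacks frame(s): ",
         paste(sort(missing)[seq_len(min(5, length(missing)))],
               collapse = ", "),
         call. = FALSE)
  }
  i <- match(tracks$frame, reference$frame)
  out <- tracks
  out$x_um <- tracks$x_um - reference$x_um[i]
  out$y_um <- tracks$y_um - reference$y_um[i]
  out
}

#' Subtract collective tissue motion from tracks
#'
#' For each frame transition, the mean displacement of the reference-region
#' (ROI) tracks present on both sides of the transition is computed; the
#' cumulative mean motion is subtracted from every track. This produces the
#' "corrected" (local) frame in which the ROI's mean per-step displacement
#' is exactly zero, isolating cell-intrinsic movement from tissue drift.
#'
#' @param tracks A track table.
#' @param roi_tissue Tissue label(s) defining the ROI, or `NULL` to use
#'   `roi_ids`.
#' @param roi_ids Explicit track ids defining the ROI.
#' @return The corrected track table.
#' @export
correct_tissue_motion <- function(tracks, roi_tissue = NULL, roi_ids = NULL) {
  if (is.null(roi_ids)) {
    if (is.null(roi_tissue)) {
      stop("supply `roi_tissue` or `roi_ids`", call. = FALSE)
    }
    roi_ids <- unique(tracks$track_id[tracks$tissue %in% roi_tissue])
  }
  if (!length(roi_ids)) stop("empty ROI", call. = FALSE)
  frames <- sort(unique(tracks$frame))
  roi <- tracks[tracks$track_id %in% roi_ids, c("track_id", "frame", "x_um", "y_um")]
  cum_x <- cum_y <- setNames(numeric(length(frames)), frames)
  for (k in seq_along(frames)[-1]) {
    a <- roi[roi$frame == frames[k - 1], ]
    b <- roi[roi$frame == frames[k], ]
    common <- intersect(a$track_id, b$track_id)
    if (!length(common)) {
      stop("no ROI track spans the transition into frame ", frames[k],
           call. = FALSE)
    }
    ia <- match(common, a$track_id); ib <- match(common, b$track_id)
    cum_x[k] <- cum_x[k - 1] + mean(b$x_um[ib] - a$x_um[ia])
    cum_y[k] <- cum_y[k - 1] + mean(b$y_um[ib] - a$y_um[ia])
  }
  i <- match(tracks$frame, frames)
  out <- tracks
  out$x_um <- unname(tracks$x_um - cum_x[i])
  out$y_um <- unname(tracks$y_um - cum_y[i])
  out
}

track_steps <- function(tracks) {
  fi <- frame_interval_of(tracks)
  tracks |>
    dplyr::arrange(.data$track_id, .data$frame) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::mutate(dx = dplyr::lead(.data$x_um) - .data$x_um,
                  dy = dplyr::lead(.data$y_um) - .data$y_um) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$dx)) |>
    dplyr::mutate(step_len = sqrt(.data$dx^2 + .data$dy^2),
                  speed = .data$step_len / fi)
}

#' Per-track motility
#'
#' The motility of a track is its mean instantaneous speed: the average over
#' frame transitions of step length divided by the frame interval. The
#' alternative net-displacement definition (net distance travelled divided
#' by track duration) is available via `method = "net"`.
#'
#' @param tracks A track table.
#' @param method `"mean_step"` (default) or `"net"`.
#' @return Tibble with `track_id`, `tissue`, `motility_um_h`.
#' @export
motility_distribution <- function(tracks, method = c("mean_step", "net")) {
  method <- match.arg(method)
  if (method == "mean_step") {
    track_steps(tracks) |>
      dplyr::group_by(.data$track_id) |>
      dplyr::summarise(tissue = dplyr::first(.data$tissue),
                       motility_um_h = mean(.data$speed), .groups = "drop")
  } else {
    tracks |>
      dplyr::arrange(.data$track_id, .data$frame) |>
      dplyr::group_by(.data$track_id) |>
      dplyr::summarise(
        tissue = dplyr::first(.data$tissue),
        motility_um_h = sqrt((dplyr::last(.data$x_um) - dplyr::first(.data$x_um))^2 +
                               (dplyr::last(.data$y_um) - dplyr::first(.data$y_um))^2) /
          (dplyr::last(.data$t_hours) - dplyr::first(.data$t_hours)),
        .groups = "drop")
  }
}

#' Velocity-weighted angle distribution
#'
#' Histogram of step directions in which each frame-to-frame displacement
#' contributes weight proportional to its speed, so fast movements dominate
#' the rose diagram as they do visually. Angle 0 is the posterior (+y)
#' direction; angles lie in (-180, 180] degrees, with bins centred so that
#' one bin is centred on 0. Zero-length steps contribute nothing.
#'
#' @param tracks A track table.
#' @param n_bins Number of angular bins (>= 4); default 16.
#' @return Tibble with `angle_mid_deg` (bin centre), `weight` (sums to 1).
#' @export
angle_distribution <- function(tracks, n_bins = 16) {
  if (n_bins < 4) stop("`n_bins` must be >= 4", call. = FALSE)
  st <- track_steps(tracks)
  st <- st[st$step_len > 0, ]
  w <- 360 / n_bins
  # 0 deg = +y (posterior); clockwise positive toward +x
  theta <- atan2(st$dx, st$dy) * 180 / pi
  bin <- floor(((theta + w / 2) %% 360) / w)  # 0 .. n_bins-1, bin 0 centred at 0
  centre <- bin * w
  centre[centre > 180] <- centre[centre > 180] - 360
  agg <- tapply(st$speed, factor(centre, levels = sort(unique(c(
    seq(0, 180, by = w), seq(-180 + w, -w, by = w))))), sum, default = 0)
  centres <- as.numeric(names(agg))
  ord <- order(centres)
  total <- sum(agg)
  tibble::tibble(angle_mid_deg = centres[ord],
                 weight = if (total > 0) as.numeric(agg[ord]) / total
                          else rep(0, length(agg)))
}

#' Time-averaged mean squared displacement
#'
#' For each lag k (in frames), averages the squared displacement over all
#' overlapping windows of all tracks: the time average within tracks is
#' pooled across tracks with pair-count weighting, i.e. total sum of squared
#' displacements divided by total number of contributing pairs.
#'
#' @param tracks A track table.
#' @param max_lag_frames Largest lag; must be smaller than the shortest
#'   track length.
#' @return An `msd_curve` tibble: `lag_h`, `msd_um2`, `n_pairs`.
#' @export
time_averaged_msd <- function(tracks, max_lag_frames) {
  fi <- frame_interval_of(tracks)
  tr <- dplyr::arrange(tracks, .data$track_id, .data$frame)
  xs <- split(tr$x_um, tr$track_id)
  ys <- split(tr$y_um, tr$track_id)
  lens <- lengths(xs)
  if (max_lag_frames >= max(lens)) {
    stop("no track longer than `max_lag_frames` = ", max_lag_frames,
         call. = FALSE)
  }
  lags <- seq_len(max_lag_frames)
  msd <- npairs <- numeric(length(lags))
  for (k in lags) {
    tot <- 0; cnt <- 0
    for (i in which(lens > k)) {
      x <- xs[[i]]; y <- ys[[i]]; n <- lens[i]
      dx <- x[(k + 1):n] - x[1:(n - k)]
      dy <- y[(k + 1):n] - y[1:(n - k)]
      tot <- tot + sum(dx^2 + dy^2)
      cnt <- cnt + (n - k)
    }
    msd[k] <- tot / cnt
    npairs[k] <- cnt
  }
  out <- tibble::tibble(lag_h = lags * fi, msd_um2 = msd, n_pairs = npairs)
  class(out) <- c("msd_curve", class(out))
  out
}

#' Fit a diffusion coefficient to an MSD curve
#'
#' Least-squares line through the origin on MSD versus lag time (MSD(0) = 0
#' by construction, so no intercept is fitted). In 2D, slope = 4D. The
#' linearity score is the coefficient of determination of the fit; linear
#' (diffusive) MSDs score near 1, ballistic (quadratic) ones materially
#' lower.
#'
#' @param msd An `msd_curve` (from [time_averaged_msd()]), needing >= 3 lags.
#' @return A `diffusion_fit` list: `D_um2_h`, `slope`, `linearity`, and the
#'   curve; degenerate all-zero MSDs give `D = 0` with `linearity = NA`.
#' @export
fit_diffusion <- function(msd) {
  stopifnot(nrow(msd) >= 3)
  tau <- msd$lag_h
  y <- msd$msd_um2
  if (all(y == 0)) {
    fit <- list(D_um2_h = 0, slope = 0, linearity = NA_real_, msd = msd)
    class(fit) <- "diffusion_fit"
    return(fit)
  }
  slope <- sum(tau * y) / sum(tau^2)
  ss_res <- sum((y - slope * tau)^2)
  ss_tot <- sum((y - mean(y))^2)
  fit <- list(D_um2_h = slope / 4, slope = slope,
              linearity = 1 - ss_res / ss_tot, msd = msd)
  class(fit) <- "diffusion_fit"
  fit
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat("<diffusion_fit> D =", signif(x$D_um2_h, 4), "um^2/h,",
      "linearity R^2 =", signif(x$linearity, 4), "\n")
  invisible(x)
}

#' @export
tidy.diffusion_fit <- function(x, ...) {
  tibble::tibble(term = c("slope", "D_um2_h"),
                 estimate = c(x$slope, x$D_um2_h))
}

#' @export
glance.diffusion_fit <- function(x, ...) {
  tibble::tibble(D_um2_h = x$D_um2_h, linearity = x$linearity,
                 n_lags = nrow(x$msd))
}
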