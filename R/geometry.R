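#' Build the default posterior-body layout
#'
#' The 2D domain of the model: origin at the medial point of the anterior
#' wall, x increasing rightward, y increasing posteriorly (so posterior
#' displacement is a positive y increment). The neural tube (NT) sits
#' medially, flanked by the two PSM columns; the progenitor zone (PZ) abuts
#' all three posteriorly. The anterior wall and the two lateral walls are
#' blocked (somites/neuroepithelium anteriorly, lateral plate laterally);
#' the posterior edge is open.
#'
#' @param config A [sim_config()] carrying region extents (model units) and
#'   the physical scale (`unit_scale_um`, default 1 unit = 150 micrometres).
#' @return A `domain_layout`: list with `unit_scale_um`, `anterior_wall_y`,
#'   `lateral_wall_x_left/right`, `posterior_open`, and `regions`, a tibble
#'   of axis-aligned t = 0 rectangles (model units).
#' @export
build_default_layout <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  half <- config$nt_width / 2 + config$psm_width
  if (config$pz_width > 2 * half + 1e-9) {
    stop("PZ wider than the lateral wall span (NT width + 2 PSM widths)",
         call. = FALSE)
  }
  body_len <- max(config$nt_length, config$psm_length)
  regions <- tibble::tibble(
    region = c("NT", "PSM_left", "PSM_right", "PZ"),
    x_min = c(-config$nt_width / 2, -half, config$nt_width / 2,
              -config$pz_width / 2),
    x_max = c(config$nt_width / 2, -config$nt_width / 2, half,
              config$pz_width / 2),
    y_min = c(0, 0, 0, body_len),
    y_max = c(config$nt_length, config$psm_length, config$psm_length,
              body_len + config$pz_length)
  )
  layout <- list(
    unit_scale_um = config$unit_scale_um,
    anterior_wall_y = 0,
    lateral_wall_x_left = -half,
    lateral_wall_x_right = half,
    posterior_open = TRUE,
    regions = regions
  )
  class(layout) <- "domain_layout"
  validate_layout(layout)
  layout
}

validate_layout <- function(layout) {
  r <- layout$regions
  stopifnot(layout$unit_scale_um > 0)
  if (any(r$x_min < layout$lateral_wall_x_left - 1e-9) ||
      any(r$x_max > layout$lateral_wall_x_right + 1e-9)) {
    stop("region rectangles must lie within the lateral walls", call. = FALSE)
  }
  nt <- r[r$region == "NT", ]
  pl <- r[r$region == "PSM_left", ]
  pr <- r[r$region == "PSM_right", ]
  pz <- r[r$region == "PZ", ]
  if (!(pl$x_max <= nt$x_min && nt$x_max <= pr$x_min)) {
    stop("NT must lie strictly between the two PSM columns", call. = FALSE)
  }
  if (!(pz$y_min >= nt$y_max - 1e-9 && pz$y_min >= pl$y_max - 1e-9)) {
    stop("PZ must lie posterior to the NT and PSM", call. = FALSE)
  }
  invisible(layout)
}

#' Convert between model units and micrometres
#'
#' Conversions are exactly linear in the layout's `unit_scale_um`
#' (1 unit = 150 micrometres by default).
#'
#' @param d Distance(s).
#' @param layout A `domain_layout`.
#' @return Converted distance(s).
#' @export
units_to_um <- function(d, layout) d * layout$unit_scale_um

#' @rdname units_to_um
#' @export
um_to_units <- function(d, layout) d / layout$unit_scale_um

#' Region membership of points
#'
#' Labels each point with the tissue region it falls in. Points anterior to
#' the blocked anterior wall are `"anterior_block"`; points beyond the
#' lateral walls are `"outside"`. When a cell table (`occupancy`) is given,
#' moving tissue fronts are honoured: a point takes the fate of its nearest
#' occupant within `max_dist`, so regions follow the cells as tissues
#' elongate. Without an occupancy table the t = 0 rectangles are used.
#'
#' @param points Data frame with `x_unit`, `y_unit` columns (model units).
#' @param layout A `domain_layout`.
#' @param occupancy Optional data frame of current cells with `x_unit`,
#'   `y_unit`, `state` columns.
#' @param max_dist Search radius (model units) for the occupancy lookup.
#' @return Character vector: one of `"NT"`, `"PSM"`, `"PZ"`,
#'   `"anterior_block"`, `"outside"` per point.
#' @export
region_of <- function(points, layout, occupancy = NULL, max_dist = 0.2) {
  stopifnot(all(c("x_unit", "y_unit") %in% names(points)))
  x <- points$x_unit
  y <- points$y_unit
  lab <- rep("outside", length(x))
  anterior <- y < layout$anterior_wall_y
  lateral <- x < layout$lateral_wall_x_left | x > layout$lateral_wall_x_right
  inwall <- !anterior & !lateral
  if (is.null(occupancy)) {
    r <- layout$regions
    for (k in seq_len(nrow(r))) {
      inside <- inwall &
        x >= r$x_min[k] & x <= r$x_max[k] &
        y >= r$y_min[k] & y < r$y_max[k]
      lab[inside & lab == "outside"] <- sub("_(left|right)$", "", r$region[k])
    }
  } else {
    stopifnot(all(c("x_unit", "y_unit", "state") %in% names(occupancy)))
    fate_region <- c(progenitor = "PZ", NT = "NT", PSM = "PSM")
    for (i in which(inwall)) {
      d2 <- (occupancy$x_unit - x[i])^2 + (occupancy$y_unit - y[i])^2
      j <- which.min(d2)
      if (length(j) && d2[j] <= max_dist^2) {
        lab[i] <- fate_region[[occupancy$state[j]]]
      }
    }
  }
  lab[anterior] <- "anterior_block"
  lab
}

#' @export
print.domain_layout <- function(x, ...) {
  cat("<domain_layout> 1 unit =", x$unit_scale_um, "um;",
      "walls x in [", x$lateral_wall_x_left, ",", x$lateral_wall_x_right,
      "], anterior wall y =", x$anterior_wall_y,
      if (x$posterior_open) "(posterior open)", "\n")
  print(x$regions)
  invisible(x)
}
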