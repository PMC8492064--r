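#' Normalize immunodetection signals to DAPI
#'
#' Divides each nucleus's Sox2 and Bra intensities by its DAPI intensity to
#' compensate for signal loss with imaging depth. Nuclei with zero DAPI
#' cannot be normalized and are excluded, with the exclusion count reported
#' as an attribute.
#'
#' @param records Nucleus table with `sox2`, `bra`, `dapi` columns.
#' @return The table with `sox2` and `bra` replaced by DAPI-normalized
#'   values and a `dapi_norm` flag; attribute `n_excluded` counts dropped
#'   records.
#' @export
normalize_to_dapi <- function(records) {
  stopifnot(all(c("sox2", "bra", "dapi") %in% names(records)))
  bad <- !(records$dapi > 0)
  out <- tibble::as_tibble(records[!bad, ])
  out$sox2 <- out$sox2 / out$dapi
  out$bra <- out$bra / out$dapi
  out$dapi_norm <- TRUE
  attr(out, "n_excluded") <- sum(bad)
  out
}

#' Per-nucleus Sox2-to-Bra ratio
#'
#' Computes sox2/bra per nucleus (on normalized intensities). Zero-Bra
#' nuclei are excluded rather than stabilised with a pseudocount; the
#' exclusion count is reported as an attribute.
#'
#' @param records Nucleus table with `sox2` and `bra` columns (normalized;
#'   see [normalize_to_dapi()]).
#' @return The table with a `ratio` column; attribute `n_excluded`.
#' @export
sox2_bra_ratio <- function(records) {
  stopifnot(all(c("sox2", "bra") %in% names(records)))
  bad <- !(records$bra > 0)
  out <- tibble::as_tibble(records[!bad, ])
  out$ratio <- out$sox2 / out$bra
  attr(out, "n_excluded") <- sum(bad)
  out
}

#' Coefficient of variation
#'
#' 100 times the sample standard deviation divided by the mean; the
#' cell-to-cell variability statistic used to compare Sox2 and Bra level
#' spreads. Scale-invariant: CV(c x) = CV(x) for c > 0.
#'
#' @param values Numeric vector (>= 2 values, non-zero mean).
#' @return CV as a percentage.
#' @export
coefficient_of_variation <- function(values) {
  stopifnot(length(values) >= 2)
  m <- mean(values)
  if (m == 0) stop("CV undefined for zero mean", call. = FALSE)
  100 * sd(values) / m
}

#' Expression profile along a posterior-to-anterior path
#'
#' Divides a polyline path into `n_volumes` equal-length segments and
#' assigns every nucleus to the nearest segment centre (so volumes are
#' fixed, non-overlapping geometry, not equal-count bins). Returns
#' per-volume mean Sox2 and Bra plus cell counts, ordered posterior to
#' anterior (the order of the path's vertices).
#'
#' @param records Nucleus table with positions `x_um`, `y_um` (and
#'   optionally `z_um`) and channels `sox2`, `bra`.
#' @param path Matrix or data frame of ordered path vertices, columns
#'   `x_um`, `y_um` (and optionally `z_um`), running posterior to anterior.
#' @param n_volumes Number of volumes; default 7.
#' @return A `path_profile` tibble: `volume`, `s_um` (centre's distance
#'   along the path), `n`, `sox2_mean`, `bra_mean`.
#' @export
path_profile <- function(records, path, n_volumes = 7) {
  path <- as.data.frame(path)
  stopifnot(all(c("x_um", "y_um") %in% names(path)), nrow(path) >= 2,
            n_volumes >= 2)
  use_z <- "z_um" %in% names(path) && "z_um" %in% names(records)
  seg <- as.matrix(path[, c("x_um", "y_um", if (use_z) "z_um")])
  d <- sqrt(rowSums(diff(seg)^2))
  s_vertex <- c(0, cumsum(d))
  total <- s_vertex[length(s_vertex)]
  centres_s <- (seq_len(n_volumes) - 0.5) / n_volumes * total
  # interpolate centre coordinates along the polyline
  interp <- vapply(centres_s, function(s) {
    k <- max(which(s_vertex <= s + 1e-12))
    k <- min(k, nrow(seg) - 1)
    t <- (s - s_vertex[k]) / (s_vertex[k + 1] - s_vertex[k])
    seg[k, ] + t * (seg[k + 1, ] - seg[k, ])
  }, numeric(ncol(seg)))
  pts <- as.matrix(records[, c("x_um", "y_um", if (use_z) "z_um")])
  d2 <- vapply(seq_len(n_volumes), function(v) {
    rowSums(sweep(pts, 2, interp[, v])^2)
  }, numeric(nrow(pts)))
  assign <- max.col(-d2, ties.method = "first")
  counts <- tabulate(assign, nbins = n_volumes)
  if (any(counts == 0)) {
    stop("empty volume(s): ", paste(which(counts == 0), collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    volume = seq_len(n_volumes),
    s_um = centres_s,
    n = counts,
    sox2_mean = as.numeric(tapply(records$sox2, factor(assign, 1:n_volumes), mean)),
    bra_mean = as.numeric(tapply(records$bra, factor(assign, 1:n_volumes), mean)))
  class(out) <- c("path_profile", class(out))
  out
}

#' Signed fold change between profile positions
#'
#' With f = mean\[to\]/mean\[from\], reports +f when f >= 1 and -1/f
#' otherwise, so a doubling reads +2.0 and a halving -2.0. Antisymmetric:
#' swapping the endpoints flips the sign (for f != 1).
#'
#' @param profile_means Ordered positive means (e.g. a [path_profile()]
#'   column).
#' @param from_index,to_index Endpoint positions; default first to last.
#' @return Signed fold change.
#' @export
signed_fold_change <- function(profile_means, from_index = 1,
                               to_index = length(profile_means)) {
  a <- profile_means[from_index]
  b <- profile_means[to_index]
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0) {
    stop("profile means must be positive", call. = FALSE)
  }
  f <- b / a
  if (f >= 1) f else -1 / f
}

#' Digital transverse section
#'
#' Selects nuclei within a slab of the given thickness centred on
#' `y_center` (|y - y_center| <= thickness/2) and attaches each record's
#' Sox2/Bra ratio, returning the (x, z, ratio) triples used to render a
#' transverse section. Zero-Bra nuclei are excluded as in
#' [sox2_bra_ratio()].
#'
#' @param records Nucleus table (normalized) with `x_um`, `y_um`, `z_um`,
#'   `sox2`, `bra`.
#' @param y_center Section position along the AP axis (micrometres).
#' @param thickness Slab thickness in micrometres; default 40.
#' @return Tibble with `x_um`, `z_um`, `ratio`; zero rows (with a `warning`
#'   attribute) if the slab is empty.
#' @export
transverse_section_map <- function(records, y_center, thickness = 40) {
  stopifnot(thickness > 0)
  slab <- records[abs(records$y_um - y_center) <= thickness / 2, ]
  slab <- sox2_bra_ratio(slab)
  out <- tibble::tibble(x_um = slab$x_um,
                        z_um = if ("z_um" %in% names(slab)) slab$z_um
                               else NA_real_,
                        ratio = slab$ratio)
  if (!nrow(out)) attr(out, "warning") <- "empty section slab"
  out
}
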