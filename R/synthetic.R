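#' Synthetic-data generator configuration
#'
#' Parameters for the two generators that emulate the structure of the real
#' data the analysis stages consume: per-nucleus intensity tables with high
#' cell-to-cell Sox2/Bra variability in the PZ (plus an anterior-Sox2 /
#' posterior-Bra enrichment) and homogeneous NT/PSM tissues, and per-tissue
#' trajectories with a common posterior drift plus tissue-specific diffusive
#' motility.
#'
#' Defaults encode the study conditions: the PZ noise CVs are the published
#' cell-to-cell variabilities (Sox2 41.8%, Bra 30.75%); the PZ AP gradients
#' default to a 1.2-fold change across the PZ extent and DAPI noise to 5%,
#' chosen so the total measured CV after DAPI normalization stays within a
#' few points of the noise CV (log-normal moment composition); drifts and
#' diffusion coefficients order the tissues as observed (PZ fastest
#' posterior drift; corrected motility PZ ~ PSM >> NT).
#'
#' @param seed Default RNG seed.
#' @param n_nuclei Named per-tissue nucleus counts.
#' @param sox2_mean,bra_mean,dapi_mean Named per-tissue mean intensities
#'   (arbitrary fluorescence units).
#' @param sox2_cv,bra_cv,dapi_cv Named per-tissue cell-to-cell noise CVs, in
#'   percent.
#' @param sox2_fold_pz,bra_fold_pz Fold change of the PZ mean across its AP
#'   extent; Sox2 decreases posteriorly, Bra increases. Set to 1 for no
#'   gradient.
#' @param z_attenuation_um Depth constant of the shared exponential
#'   attenuation applied to all channels (gives DAPI normalization real
#'   work); `Inf` disables it.
#' @param regions Named list of per-tissue boxes, each
#'   `c(x_min, x_max, y_min, y_max, z_min, z_max)` in micrometres.
#' @param tracks_per_tissue,n_frames,frame_interval Track generator sizes.
#' @param drift_um_h Named list of per-tissue drift vectors `c(x, y)` in
#'   micron/h (y positive = posterior).
#' @param diffusion_um2_h Named per-tissue diffusion coefficients.
#' @return A `generator_config` list.
#' @export
generator_config <- function(
    seed = 1L,
    n_nuclei = c(PZ = 1000, NT = 1000, PSM = 1000),
    sox2_mean = c(PZ = 100, NT = 180, PSM = 20),
    bra_mean = c(PZ = 100, NT = 20, PSM = 180),
    dapi_mean = c(PZ = 200, NT = 200, PSM = 200),
    sox2_cv = c(PZ = 41.8, NT = 10, PSM = 10),
    bra_cv = c(PZ = 30.75, NT = 10, PSM = 10),
    dapi_cv = c(PZ = 5, NT = 5, PSM = 5),
    sox2_fold_pz = 1.2,
    bra_fold_pz = 1.2,
    z_attenuation_um = 100,
    regions = list(PZ = c(-270, 270, 600, 825, 0, 50),
                   NT = c(-75, 75, 0, 600, 0, 50),
                   PSM = c(75, 270, 0, 600, 0, 50)),
    tracks_per_tissue = c(PZ = 100, NT = 100, PSM = 100),
    n_frames = 100,
    frame_interval = 0.1,
    drift_um_h = list(PZ = c(0, 30), NT = c(0, 12), PSM = c(0, 18)),
    diffusion_um2_h = c(PZ = 30, NT = 4, PSM = 25)) {
  tissues <- c("PZ", "NT", "PSM")
  cfg <- list(seed = seed, n_nuclei = n_nuclei, sox2_mean = sox2_mean,
              bra_mean = bra_mean, dapi_mean = dapi_mean, sox2_cv = sox2_cv,
              bra_cv = bra_cv, dapi_cv = dapi_cv,
              sox2_fold_pz = sox2_fold_pz, bra_fold_pz = bra_fold_pz,
              z_attenuation_um = z_attenuation_um, regions = regions,
              tracks_per_tissue = tracks_per_tissue, n_frames = n_frames,
              frame_interval = frame_interval, drift_um_h = drift_um_h,
              diffusion_um2_h = diffusion_um2_h)
  for (f in c("n_nuclei", "sox2_mean", "bra_mean", "dapi_mean", "sox2_cv",
              "bra_cv", "dapi_cv", "tracks_per_tissue", "diffusion_um2_h")) {
    if (!all(tissues %in% names(cfg[[f]]))) {
      stop("`", f, "` must name all of ", paste(tissues, collapse = ", "),
           call. = FALSE)
    }
  }
  if (any(cfg$n_nuclei <= 0) || any(cfg$tracks_per_tissue <= 0)) {
    stop("counts must be positive", call. = FALSE)
  }
  if (any(c(cfg$sox2_cv, cfg$bra_cv, cfg$dapi_cv) < 0)) {
    stop("CV targets must be >= 0", call. = FALSE)
  }
  if (cfg$frame_interval <= 0 || cfg$n_frames < 2) {
    stop("need frame_interval > 0 and n_frames >= 2", call. = FALSE)
  }
  class(cfg) <- "generator_config"
  cfg
}

# Log-normal draw with exact mean m and CV c (percent): CV parameterization
# is exact for the log-normal, sdlog = sqrt(log(1 + (c/100)^2)).
rlnorm_cv <- function(n, m, cv_pct) {
  if (cv_pct == 0) return(rep(m, n))
  sdlog <- sqrt(log(1 + (cv_pct / 100)^2))
  rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic per-nucleus intensity table
#'
#' Intensities are log-normal around per-tissue means with the configured
#' noise CVs; PZ means are additionally modulated by the configured AP
#' gradients (Sox2 decreasing, Bra increasing posteriorly); all channels
#' share an exponential depth attenuation in z, which DAPI normalization
#' removes. Deterministic under a fixed seed.
#'
#' @param config A [generator_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return Nucleus tibble: `id`, `x_um`, `y_um`, `z_um`, `sox2`, `bra`,
#'   `dapi`, `tissue`.
#' @export
generate_nucleus_table <- function(config = generator_config(),
                                   seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  out <- lapply(c("PZ", "NT", "PSM"), function(tis) {
    n <- config$n_nuclei[[tis]]
    b <- config$regions[[tis]]
    x <- runif(n, b[1], b[2]); y <- runif(n, b[3], b[4])
    z <- runif(n, b[5], b[6])
    s_mod <- b_mod <- rep(1, n)
    if (tis == "PZ") {
      t_ap <- (y - b[3]) / (b[4] - b[3])          # 0 anterior, 1 posterior
      s_mod <- exp(log(config$sox2_fold_pz) * (0.5 - t_ap))
      b_mod <- exp(log(config$bra_fold_pz) * (t_ap - 0.5))
    }
    att <- if (is.finite(config$z_attenuation_um)) {
      exp(-z / config$z_attenuation_um)
    } else rep(1, n)
    tibble::tibble(
      id = paste0(tis, "_", seq_len(n)),
      x_um = x, y_um = y, z_um = z,
      sox2 = rlnorm_cv(n, config$sox2_mean[[tis]], config$sox2_cv[[tis]]) *
        s_mod * att,
      bra = rlnorm_cv(n, config$bra_mean[[tis]], config$bra_cv[[tis]]) *
        b_mod * att,
      dapi = rlnorm_cv(n, config$dapi_mean[[tis]], config$dapi_cv[[tis]]) *
        att,
      tissue = tis)
  })
  dplyr::bind_rows(out)
}

#' Generate synthetic trajectories with known drift and diffusion
#'
#' Each track is a cumulative sum of steps `drift * dt + Gaussian(0,
#' sqrt(2 D dt))` per axis, started uniformly inside its tissue's region.
#' Ground-truth drift and diffusion are configured per tissue, so parameter
#' recovery by the trajectory statistics can be tested exactly.
#' Deterministic under a fixed seed.
#'
#' @param config A [generator_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return A track tibble (`track_id`, `frame`, `t_hours`, `x_um`, `y_um`,
#'   `tissue`) with a `frame_interval` attribute.
#' @export
generate_tracks <- function(config = generator_config(),
                            seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  dt <- config$frame_interval
  nf <- config$n_frames
  next_id <- 0L
  out <- lapply(c("PZ", "NT", "PSM"), function(tis) {
    n <- config$tracks_per_tissue[[tis]]
    b <- config$regions[[tis]]
    drift <- config$drift_um_h[[tis]]
    s <- sqrt(2 * config$diffusion_um2_h[[tis]] * dt)
    purrr::map_dfr(seq_len(n), function(i) {
      x0 <- runif(1, b[1], b[2]); y0 <- runif(1, b[3], b[4])
      dx <- drift[1] * dt + rnorm(nf - 1, 0, s)
      dy <- drift[2] * dt + rnorm(nf - 1, 0, s)
      tibble::tibble(
        track_id = paste0(tis, "_", i),
        frame = seq_len(nf),
        t_hours = (seq_len(nf) - 1) * dt,
        x_um = c(x0, x0 + cumsum(dx)),
        y_um = c(y0, y0 + cumsum(dy)),
        tissue = tis)
    })
  })
  tr <- dplyr::bind_rows(out)
  attr(tr, "frame_interval") <- dt
  tr
}
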