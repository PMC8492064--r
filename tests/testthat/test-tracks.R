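test_that("track-table validation rejects malformed input", {
  good <- make_tracks(list(a = cbind(0:3, 0:3)))
  expect_s3_class(as_track_table(good), "tbl_df")
  expect_error(as_track_table(good[1, ]), ">= 2 points")
  bad <- good
  bad$frame[2] <- 1L
  expect_error(as_track_table(bad), "increasing")
  gap <- good
  gap$t_hours[4] <- 1.0
  expect_error(as_track_table(gap), "uniform")
  expect_error(as_track_table(good[, -1]), "lacks column")
})

test_that("reference subtraction removes the landmark's motion", {
  tr <- make_tracks(list(a = cbind(0:4, (0:4) * 2), b = cbind(1:5, 2:6)))
  zero <- tibble::tibble(frame = 1:5, x_um = 0, y_um = 0)
  expect_equal(subtract_reference(tr, zero), tr)
  # common drift shared with the reference: output static
  drift <- tibble::tibble(frame = 1:5, x_um = 0:4, y_um = (0:4) * 2)
  out <- subtract_reference(tr, drift)
  a <- out[out$track_id == "a", ]
  expect_true(all(a$x_um == 0) && all(a$y_um == 0))
  expect_error(subtract_reference(tr, drift[-3, ]), "frame")
})

test_that("tissue-motion correction zeroes the ROI mean step exactly", {
  # identical drift, no noise: corrected tracks are static
  tr <- make_tracks(list(a = cbind(0:9, 0:9), b = cbind(1:10, 0:9)))
  cor <- correct_tissue_motion(tr, roi_tissue = "PZ")
  expect_equal(diff(cor$x_um[cor$track_id == "a"]), rep(0, 9))
  expect_equal(diff(cor$y_um[cor$track_id == "b"]), rep(0, 9))

  # equal and opposite tracks: mean is zero, correction is a no-op
  opp <- make_tracks(list(a = cbind(0:9, 0), b = cbind(-(0:9), 0)))
  expect_equal(correct_tissue_motion(opp, roi_tissue = "PZ"), opp)

  # drift + diffusion: ROI mean per-step displacement exactly (0, 0)
  cfg <- generator_config(tracks_per_tissue = c(PZ = 20, NT = 2, PSM = 2),
                          n_frames = 30)
  tr2 <- generate_tracks(cfg, seed = 9)
  cor2 <- correct_tissue_motion(tr2, roi_tissue = "PZ")
  roi_steps <- track_steps_for_test(cor2[cor2$tissue == "PZ", ])
  mean_by_frame <- tapply(roi_steps$dy, roi_steps$frame, mean)
  expect_equal(max(abs(mean_by_frame)), 0, tolerance = 1e-9)
  expect_error(correct_tissue_motion(tr2, roi_tissue = "nope"), "empty ROI")
})

test_that("motility is mean step speed, with the Rayleigh closed form", {
  static <- make_tracks(list(a = cbind(rep(0, 5), rep(0, 5))))
  expect_equal(motility_distribution(static)$motility_um_h, 0)
  mover <- make_tracks(list(a = cbind(seq(0, 2.4, 0.6), rep(0, 5))))
  expect_equal(motility_distribution(mover)$motility_um_h, 6)

  # pure 2D Gaussian walk, per-axis step sd s: E[step length] = s sqrt(pi/2)
  s <- 2
  set.seed(10)
  walks <- lapply(1:60, function(i) {
    cbind(cumsum(c(0, rnorm(80, 0, s))), cumsum(c(0, rnorm(80, 0, s))))
  })
  names(walks) <- paste0("w", 1:60)
  tr <- make_tracks(walks)
  m <- motility_distribution(tr)
  expect_equal(mean(m$motility_um_h), s * sqrt(pi / 2) / 0.1,
               tolerance = 0.05)
  # net-displacement variant is bounded above by the mean-step variant
  m_net <- motility_distribution(tr, method = "net")
  expect_true(mean(m_net$motility_um_h) < mean(m$motility_um_h))
})

test_that("angle distribution is velocity-weighted and posterior-anchored", {
  post <- make_tracks(list(a = cbind(rep(0, 6), seq(0, 5, 1))))
  h <- angle_distribution(post, n_bins = 16)
  expect_equal(sum(h$weight), 1)
  expect_equal(h$weight[h$angle_mid_deg == 0], 1)

  # two steps: posterior at speed 2u, anterior at u -> posterior mass 2/3
  two <- make_tracks(list(a = cbind(c(0, 0, 0), c(0, 2, 1))))
  h2 <- angle_distribution(two, n_bins = 8)
  expect_equal(h2$weight[h2$angle_mid_deg == 0], 2 / 3)
  expect_equal(h2$weight[h2$angle_mid_deg == 180], 1 / 3)

  # isotropic random walk: uniform histogram by chi-square
  set.seed(11)
  walks <- lapply(1:40, function(i) {
    cbind(cumsum(c(0, rnorm(100))), cumsum(c(0, rnorm(100))))
  })
  names(walks) <- paste0("w", 1:40)
  h3 <- angle_distribution(make_tracks(walks), n_bins = 8)
  n_steps <- 40 * 100
  p <- suppressWarnings(
    chisq.test(round(h3$weight * n_steps))$p.value)
  expect_gt(p, 0.001)
  expect_error(angle_distribution(post, n_bins = 3), "n_bins")
})

test_that("time-averaged MSD matches ballistic and diffusive closed forms", {
  v <- 30  # um/h, frame 0.1 h
  ball <- make_tracks(list(a = cbind(seq(0, 30, 3), rep(0, 11))))
  msd <- time_averaged_msd(ball, 5)
  expect_equal(msd$msd_um2, (v * msd$lag_h)^2)
  expect_equal(msd$n_pairs, 10:6)

  static <- make_tracks(list(a = cbind(rep(1, 8), rep(2, 8))))
  expect_true(all(time_averaged_msd(static, 4)$msd_um2 == 0))

  s2 <- 4  # per-axis step variance
  set.seed(12)
  walks <- lapply(1:150, function(i) {
    cbind(cumsum(c(0, rnorm(100, 0, sqrt(s2)))),
          cumsum(c(0, rnorm(100, 0, sqrt(s2)))))
  })
  names(walks) <- paste0("w", seq_along(walks))
  m <- time_averaged_msd(make_tracks(walks), 10)
  expect_equal(m$msd_um2, 2 * s2 * (1:10), tolerance = 0.05)

  # invariance under global rotation + translation
  th <- 37 * pi / 180
  rot <- lapply(walks, function(p) {
    cbind(cos(th) * p[, 1] - sin(th) * p[, 2] + 100,
          sin(th) * p[, 1] + cos(th) * p[, 2] - 50)
  })
  m2 <- time_averaged_msd(make_tracks(rot), 10)
  expect_equal(m2$msd_um2, m$msd_um2, tolerance = 1e-9)
  expect_error(time_averaged_msd(make_tracks(walks), 200), "max_lag_frames")
})

test_that("diffusion fitting recovers D and flags non-linear MSDs", {
  lin <- tibble::tibble(lag_h = 1:5, msd_um2 = 4 * (1:5), n_pairs = 10)
  class(lin) <- c("msd_curve", class(lin))
  fit <- fit_diffusion(lin)
  expect_equal(fit$D_um2_h, 1)
  expect_equal(fit$linearity, 1)
  expect_equal(glance(fit)$D_um2_h, 1)

  ball <- tibble::tibble(lag_h = 1:6, msd_um2 = (10 * (1:6))^2, n_pairs = 10)
  class(ball) <- c("msd_curve", class(ball))
  expect_lt(fit_diffusion(ball)$linearity, 0.95)

  zero <- tibble::tibble(lag_h = 1:3, msd_um2 = 0, n_pairs = 5)
  fz <- fit_diffusion(zero)
  expect_equal(fz$D_um2_h, 0)
  expect_true(is.na(fz$linearity))

  # parameter recovery on generator output at 200 tracks x 100 frames
  cfg <- generator_config(
    tracks_per_tissue = c(PZ = 200, NT = 1, PSM = 1),
    drift_um_h = list(PZ = c(0, 0), NT = c(0, 0), PSM = c(0, 0)),
    diffusion_um2_h = c(PZ = 25, NT = 1, PSM = 1))
  tr <- generate_tracks(cfg, seed = 13)
  m <- time_averaged_msd(tr[tr$tissue == "PZ", ], 10)
  expect_equal(fit_diffusion(m)$D_um2_h, 25, tolerance = 0.15)
})
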