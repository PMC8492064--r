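test_that("initialization produces exact per-fate counts inside their regions", {
  cfg <- sim_config()
  set.seed(1)
  cells <- initialize_population(cfg)
  expect_identical(as.integer(table(factor(cells$state, FATES_levels()))),
                   c(1100L, 1200L, 3200L))
  lay <- build_default_layout(cfg)
  lab <- region_of(tibble::tibble(x_unit = cells$x_um / 150,
                                  y_unit = cells$y_um / 150), lay)
  expect_true(all(lab[cells$state == "progenitor"] == "PZ"))
  expect_true(all(lab[cells$state == "NT"] == "NT"))
  expect_true(all(lab[cells$state == "PSM"] == "PSM"))
  # specified fates start beyond their thresholds; random-regime draws in range
  expect_true(all(cells$ratio[cells$state == "NT"] > cfg$theta_high))
  expect_true(all(cells$ratio[cells$state == "PSM"] < cfg$theta_low))
})

test_that("random-regime ratios cover the configured interval and gradient is AP-ordered", {
  set.seed(2)
  cr <- initialize_population(sim_config(regime = "random"))
  rp <- cr$ratio[cr$state == "progenitor"]
  expect_true(all(rp >= 0.3 & rp <= 1.7))
  set.seed(2)
  cg <- initialize_population(sim_config(regime = "gradient"))
  prog <- cg[cg$state == "progenitor", ]
  # anterior Sox2-high, posterior Bra-low: strong negative rank correlation
  expect_lt(cor(prog$ratio, prog$y_um, method = "spearman"), -0.9)
})

test_that("population too dense for the cap fails initialization", {
  expect_error(initialize_population(sim_config(pz_length = 0.05)),
               "density cap")
})

test_that("ratio SDE has the OU fixed point, drift direction and stationary spread", {
  cfg <- sim_config(ratio_relaxation_kappa = 1, ratio_noise_sigma = 0.1)
  expect_equal(update_ratio(1, 1, cfg, dt = 0.1, noise = FALSE), 1)
  r2 <- update_ratio(1.4, 1, cfg, dt = 0.1, noise = FALSE)
  expect_true(r2 > 1 && r2 < 1.4)
  # Monte-Carlo stationary sd vs closed form sigma / sqrt(2 kappa)
  set.seed(3)
  r <- rep(1, 2000)
  for (i in 1:300) r <- update_ratio(r, 1, cfg, dt = 0.1)
  expect_equal(sd(r), 0.1 / sqrt(2), tolerance = 0.1)
  expect_true(all(update_ratio(c(0, 2), 1, cfg, dt = 10, noise = FALSE) >= 0))
})

test_that("fate specification is thresholded and irreversible", {
  cfg <- sim_config()
  expect_identical(specify_state("progenitor", 0.39, cfg), "PSM")
  expect_identical(specify_state("progenitor", 1.61, cfg), "NT")
  expect_identical(specify_state("progenitor", 1.0, cfg), "progenitor")
  expect_identical(specify_state("NT", 0.1, cfg), "NT")
  expect_identical(specify_state("PSM", 1.9, cfg), "PSM")
})

test_that("motility maps ratio bands to speeds and is non-increasing", {
  cfg <- sim_config()
  expect_equal(motility_of(0.2, "progenitor", cfg), cfg$v_high)
  expect_equal(motility_of(1.8, "progenitor", cfg), cfg$v_low)
  expect_equal(motility_of(1.0, "progenitor", cfg), cfg$v_mid)
  grid <- seq(0, 2, 0.01)
  v <- motility_of(grid, rep("progenitor", length(grid)), cfg)
  expect_true(all(diff(v) <= 1e-12))
  # step profile keeps the single plateau
  cfg2 <- sim_config(motility_profile = "step")
  expect_equal(motility_of(c(0.5, 1.0, 1.5), rep("progenitor", 3), cfg2),
               rep(cfg2$v_mid, 3))
  # specified fates override the ratio
  expect_equal(motility_of(1.0, "PSM", cfg), cfg$v_high)
  expect_equal(motility_of(1.0, "NT", cfg), cfg$v_low)
})

test_that("position update honors ablation flags, isotropy and the anterior wall", {
  cfg <- sim_config(motility_enabled = FALSE, interactions_enabled = FALSE)
  lay <- build_default_layout(cfg)
  set.seed(4)
  cells <- initialize_population(quick_config())
  moved <- step_positions(cells, lay, cfg)
  expect_identical(moved$x_um, cells$x_um)
  expect_identical(moved$y_um, cells$y_um)

  # a single isolated cell: mean step length = speed * dt, direction isotropic
  cfg1 <- sim_config()
  one <- cells[1, ]
  one$x_um <- 0; one$y_um <- 500; one$ratio <- 1.0; one$state <- "progenitor"
  set.seed(5)
  steps <- t(replicate(2000, {
    m <- step_positions(one, lay, cfg1)
    c(m$x_um - one$x_um, m$y_um - one$y_um)
  }))
  len <- sqrt(rowSums(steps^2))
  expect_equal(mean(len), cfg1$v_mid * cfg1$dt, tolerance = 1e-6)
  ang <- atan2(steps[, 2], steps[, 1])
  expect_gt(suppressWarnings(chisq.test(table(cut(ang, 8)))$p.value), 0.001)

  # candidate crossing the anterior wall is rejected: y never below the wall
  near <- one
  near$y_um <- 1
  set.seed(6)
  ys <- replicate(200, step_positions(near, lay, cfg1)$y_um)
  expect_true(all(ys >= 0))
  expect_true(any(ys == 1))  # some candidates rejected in place
})

test_that("proliferation is a per-fate binomial branching process", {
  cfg <- sim_config(doubling_times = c(progenitor = Inf, NT = Inf, PSM = Inf))
  set.seed(7)
  cells <- initialize_population(quick_config())
  expect_identical(nrow(proliferate(cells, cfg)), nrow(cells))

  # pure PSM population doubles in one doubling time (expectation at n = 3200)
  cfg2 <- sim_config()
  psm <- tibble::tibble(cell_id = 1:3200, parent_id = NA_integer_,
                        state = "PSM", ratio = 0.1, x_um = 0, y_um = 500,
                        birth_time = 0, anchor_offset = 0, deregulated = FALSE)
  set.seed(8)
  for (i in seq_len(round(8.75 / cfg2$dt))) {
    psm <- proliferate(psm, cfg2, time = i * cfg2$dt)
  }
  expect_equal(nrow(psm) / 3200, 2, tolerance = 0.05)
  # daughters inherit fate and ratio
  expect_true(all(psm$state == "PSM"))
  expect_true(all(psm$ratio == 0.1))
})

test_that("a zero-length run returns only the initial snapshot", {
  res <- run_simulation(sim_config(total_time = 0, population_scale = 0.1),
                        seed = 1)
  expect_identical(unique(res$snapshots$time_h), 0)
  expect_identical(nrow(res$snapshots), 550L)
})

test_that("identical seed and config reproduce the run exactly", {
  cfg <- quick_config()
  a <- run_simulation(cfg, seed = 11)
  b <- run_simulation(cfg, seed = 11)
  expect_identical(a$snapshots, b$snapshots)
  c <- run_simulation(cfg, seed = 12)
  expect_false(identical(a$snapshots, c$snapshots))
})

test_that("runs conserve cells, keep ratios bounded and fates irreversible", {
  res <- run_simulation(sim_config(population_scale = 0.2, total_time = 2),
                        seed = 13)
  s <- res$snapshots
  totals <- dplyr::count(s, time_h)$n
  expect_true(all(diff(totals) >= 0))
  expect_true(all(s$ratio >= 0 & s$ratio <= 2))
  lay <- res$layout
  expect_true(all(s$y_unit >= lay$anterior_wall_y))
  expect_true(all(s$x_unit >= lay$lateral_wall_x_left &
                    s$x_unit <= lay$lateral_wall_x_right))
  # once specified, never back: per-cell state sequences have at most one change
  changes <- s |>
    dplyr::arrange(cell_id, time_h) |>
    dplyr::group_by(cell_id) |>
    dplyr::summarise(
      n_change = sum(state != dplyr::lag(state), na.rm = TRUE),
      from_specified = any(state != "progenitor" &
                             dplyr::lead(state) == "progenitor", na.rm = TRUE))
  expect_true(all(changes$n_change <= 1))
  expect_false(any(changes$from_specified))
})

test_that("deregulation shifts anchors past the thresholds", {
  # faster relaxation so the anchor shift crosses the threshold in-window
  cfg <- sim_config(population_scale = 0.2, total_time = 2,
                    ratio_relaxation_kappa = 1)
  base <- run_simulation(cfg, seed = 14)
  bra <- run_simulation(sim_config(population_scale = 0.2, total_time = 2,
                                   ratio_relaxation_kappa = 1,
                                   deregulation = "bra_high"), seed = 14)
  n_of <- function(r, st) {
    v <- dplyr::filter(r$counts, time_h == 2, state == st)$n
    if (length(v)) v else 0L
  }
  expect_lt(n_of(bra, "progenitor"), n_of(base, "progenitor"))
  expect_gt(n_of(bra, "PSM"), n_of(base, "PSM"))
})
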