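snap <- function(time_h, y, state = "progenitor", x = 0) {
  tibble::tibble(time_h = time_h, cell_id = seq_along(y),
                 parent_id = NA_integer_, state = state, ratio = 1,
                 x_unit = x, y_unit = y)
}

test_that("elongation tracks the posterior progenitor edge in micrometres", {
  y0 <- seq(4, 5.5, length.out = 50)
  static <- fake_result(dplyr::bind_rows(snap(0, y0), snap(10, y0)))
  expect_equal(elongation_rate(static)$distance_um, 0)

  # rigid translation by +2 units = +300 um over 10 h
  shifted <- fake_result(dplyr::bind_rows(snap(0, y0), snap(10, y0 + 2)))
  el <- elongation_rate(shifted)
  expect_equal(el$distance_um, 300)
  expect_equal(el$rate_um_h, 30)

  # static non-progenitor cells do not affect the measure
  with_nt <- fake_result(dplyr::bind_rows(
    snap(0, y0), snap(0, rep(1, 30), state = "NT"),
    snap(10, y0 + 2), snap(10, rep(1, 30), state = "NT")))
  expect_equal(elongation_rate(with_nt)$distance_um, 300)

  no_prog <- fake_result(dplyr::bind_rows(snap(0, y0, state = "NT"),
                                          snap(10, y0, state = "NT")))
  expect_error(elongation_rate(no_prog), "no progenitors")
})

test_that("resident displacement excludes switching cells and reports microns", {
  y0 <- seq(4, 5.5, length.out = 30)
  s0 <- snap(0, y0)
  s1 <- snap(10, y0 + 0.4)
  s1$state[5] <- "NT"   # switched mid-run: excluded
  res <- fake_result(dplyr::bind_rows(s0, s1))
  out <- resident_y_displacement(res, central_third = FALSE)
  expect_false(5 %in% out$cell_id)
  expect_equal(unique(out$y_displacement_um), 60)

  static <- fake_result(dplyr::bind_rows(s0, snap(10, y0)))
  expect_true(all(resident_y_displacement(static)$y_displacement_um == 0))

  none <- fake_result(dplyr::bind_rows(snap(0, y0, state = "PSM"),
                                       snap(10, y0, state = "PSM")))
  empty <- resident_y_displacement(none)
  expect_identical(nrow(empty), 0L)
  expect_identical(attr(empty, "warning"), "no resident progenitors")
})

test_that("shape conservation is symmetric, bounded and 100 iff unchanged", {
  sh <- function(aspect) tibble::tibble(length_um = aspect * 100,
                                        width_um = 100, aspect = aspect)
  expect_equal(shape_conservation(sh(2), sh(2)), 100)
  expect_equal(shape_conservation(sh(2), sh(1)), 50)
  expect_equal(shape_conservation(sh(1), sh(2)), 50)
  for (a in c(0.5, 1.3, 3)) {
    expect_equal(shape_conservation(sh(1), sh(a)),
                 shape_conservation(sh(a), sh(1)))
    expect_lte(shape_conservation(sh(1), sh(a)), 100)
  }
  set.seed(20)
  cells <- tibble::tibble(state = "progenitor",
                          x_um = runif(200, 0, 100),
                          y_um = runif(200, 0, 300))
  d <- shape_descriptor(cells)
  expect_gt(d$aspect, 1)
})

test_that("count series partition the population and flag non-growth", {
  res <- run_simulation(quick_config(), seed = 21)
  ct <- count_timeseries(res)
  sums <- ct |> dplyr::group_by(time_h) |> dplyr::summarise(n = sum(n))
  totals <- dplyr::count(res$snapshots, time_h)
  expect_equal(sums$n, totals$n)

  expect_equal(measure_doubling_time(c(100, 200, 400),
                                     times = 0:2)$doubling_h, 1)
  flat <- measure_doubling_time(rep(50, 5), times = 0:4)
  expect_false(flat$growing)
  expect_error(measure_doubling_time(c(0, 1, 2), times = 0:2), "positive")
})

test_that("doubling-time estimation recovers the configured rates from runs", {
  for (fate in c("progenitor", "PSM")) {
    counts <- c(progenitor = 0, NT = 0, PSM = 0)
    counts[fate] <- sim_config()$initial_counts[fate]
    cfg <- sim_config(initial_counts = counts, motility_enabled = FALSE,
                      interactions_enabled = FALSE,
                      ratio_dynamics_enabled = FALSE,
                      total_time = 18, snapshot_interval = 0.5)
    r <- run_simulation(cfg, seed = 22)
    est <- measure_doubling_time(
      dplyr::filter(count_timeseries(r), state == fate))
    expect_equal(est$doubling_h, cfg$doubling_times[[fate]],
                 tolerance = 0.05)
    expect_gt(est$r_squared, 0.99)
  }
})

test_that("tissue integrity separates sorted from intermixed fates", {
  set.seed(23)
  n <- 300
  sorted <- tibble::tibble(
    state = rep(c("NT", "PSM"), each = n),
    x_um = c(runif(n, 0, 100), runif(n, 200, 300)),
    y_um = runif(2 * n, 0, 100))
  mixed <- sorted
  mixed$x_um <- runif(2 * n, 0, 300)
  expect_gt(tissue_integrity(sorted, 20), 0.95)
  expect_lt(tissue_integrity(mixed, 20), tissue_integrity(sorted, 20) - 0.2)
})
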