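geom <- pore_geometry(z_sf = 10, z_gate = -10)

straight_track <- function(z, dt = 0.1) {
  ion_tracks(tibble::tibble(
    time_ns = (seq_along(z) - 1) * dt, ion_id = 0L, species = "Na",
    valence = 1L, z_A = z))
}

test_that("a monotone traversal through both planes is one inward event", {
  ev <- detect_events(straight_track(seq(30, -30, by = -2)), geom)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$direction, "inward")
  expect_lt(ev$t_enter_ns, ev$t_exit_ns)
  ## interpolated crossing times sit where the path meets the planes
  expect_equal(ev$t_enter_ns, 0.1 * (30 - 10) / 2, tolerance = 1e-9)
  expect_equal(ev$t_exit_ns, 0.1 * (30 + 10) / 2, tolerance = 1e-9)
  ## reversed path: one outward event
  ev_rev <- detect_events(straight_track(seq(-30, 30, by = 2)), geom)
  expect_equal(ev_rev$direction, "outward")
})

test_that("an excursion past the filter that returns to bulk is no event", {
  z <- c(30, 20, 8, 5, 0, 5, 12, 30)
  expect_equal(nrow(detect_events(straight_track(z), geom)), 0)
  ## re-entry after a partial retreat inside the pore still counts once
  z2 <- c(30, 8, 9.5, 2, -12, -30)
  expect_equal(nrow(detect_events(straight_track(z2), geom)), 1)
})

test_that("time reversal swaps inward and outward counts", {
  wt <- make_walk_tracks(40, 300, sd_step = 4, seed = 13)
  ev <- detect_events(wt$tracks, geom)
  rev_tab <- dplyr::mutate(
    dplyr::arrange(tibble::as_tibble(wt$tracks), ion_id,
                   dplyr::desc(time_ns)),
    time_ns = rep(sort(unique(time_ns)), dplyr::n_distinct(ion_id)))
  ev_rev <- detect_events(ion_tracks(rev_tab), geom)
  expect_equal(sum(ev$direction == "inward"),
               sum(ev_rev$direction == "outward"))
  expect_equal(sum(ev$direction == "outward"),
               sum(ev_rev$direction == "inward"))
})

test_that("event detection matches the crossing-sequence oracle on walks", {
  wt <- make_walk_tracks(80, 300, sd_step = 3, drift = -0.4, seed = 17)
  ev <- detect_events(wt$tracks, geom)
  expected <- do.call(rbind, lapply(split(wt$truth, wt$truth$ion_id),
                                    function(d) {
    oracle_events(d$z_A[order(d$time_ns)], 10, -10)
  }))
  expect_equal(nrow(ev), nrow(expected))
  expect_equal(sum(ev$direction == "inward"),
               sum(expected$direction == "inward"))
})

test_that("wrapped coordinates give the same events as the continuous walk", {
  wt <- make_walk_tracks(40, 400, sd_step = 3, drift = -0.6,
                         z0_range = c(-20, 20), box = 44, seed = 23)
  ev_wrapped <- detect_events(wt$tracks, geom)
  ev_truth <- detect_events(ion_tracks(wt$truth), geom)
  ## the wrapped analysis must also count image traversals the non-periodic
  ## view of the finite window cannot see, so compare per-ion to the oracle
  expected <- do.call(rbind, lapply(split(wt$truth, wt$truth$ion_id),
                                    function(d) {
    oracle_events(d$z_A[order(d$time_ns)], 10, -10, period = 44)
  }))
  expect_equal(nrow(ev_wrapped), nrow(expected))
  expect_equal(sum(ev_wrapped$direction == "inward"),
               sum(expected$direction == "inward"))
  expect_gte(nrow(ev_wrapped), nrow(ev_truth))
})

test_that("counting conductance follows the charge-per-time formula", {
  ## linear in events, inversely proportional to time and |voltage|
  expect_equal(conductance_total(30, 1, 3000, -50),
               2 * conductance_total(15, 1, 3000, -50))
  expect_equal(conductance_total(15, 1, 6000, -50),
               conductance_total(15, 1, 3000, -50) / 2)
  expect_equal(conductance_total(15, 1, 3000, -100),
               conductance_total(15, 1, 3000, -50) / 2)
  expect_equal(conductance_total(10, 2, 1000, 200),
               2 * conductance_total(10, 1, 1000, 200))
  expect_equal(conductance_total(0, 1, 1000, -50), 0)
  expect_equal(conductance_total(6, -1, 3000, -610, opposing = TRUE),
               -conductance_total(6, 1, 3000, -610))
  expect_error(conductance_total(10, 1, 1000, 0), "0 mV")
  expect_error(conductance_total(10, 1, 0, -50), "t_total")
})

test_that("windowed conductance reduces to the total for uniform spacing", {
  ev0 <- tibble::tibble(t_exit_ns = numeric(), valence = integer())
  est0 <- conductance_windows(ev0, 1000, -50, valence = 1)
  expect_equal(est0$mean_pS, 0)
  expect_equal(est0$se_pS, 0)
  ev <- tibble::tibble(t_exit_ns = seq(5, 995, by = 10), valence = 1L)
  est <- conductance_windows(ev, 1000, -50, window_ns = 50, stride_ns = 25)
  expect_equal(est$mean_pS, conductance_total(100, 1, 1000, -50),
               tolerance = 1e-9)
  expect_equal(est$se_pS, 0, tolerance = 1e-9)
  expect_error(conductance_windows(ev, 40, -50, window_ns = 50), "window")
})

test_that("windowed mean and SE match a brute-force window enumeration", {
  t_exit <- withr::with_seed(31, sort(runif(200, 0, 2000)))
  ev <- tibble::tibble(t_exit_ns = t_exit, valence = 1L)
  est <- conductance_windows(ev, 2000, -130, window_ns = 50, stride_ns = 25)
  ref <- oracle_window_conductance(t_exit, 1, 2000, -130, 50, 25)
  expect_equal(est$mean_pS, ref$mean, tolerance = 1e-12)
  expect_equal(est$se_pS, ref$se, tolerance = 1e-12)
  td <- tidy(est)
  expect_equal(td$conductance_pS, est$mean_pS)
  expect_equal(glance(est)$n_windows, est$n_windows)
})

test_that("selectivity ratios handle zero denominators as sentinels", {
  expect_equal(selectivity_ratio(27, 13)$ratio, 27 / 13)
  expect_equal(selectivity_ratio(15, 0)$ratio, Inf)
  expect_true(is.nan(selectivity_ratio(0, 0)$ratio))
  ev_a <- tibble::tibble(t_exit_ns = 1:5)
  expect_equal(selectivity_ratio(ev_a, ev_a[0, ])$ratio, Inf)
})

test_that("raising the divalent funnel barrier raises the flux ratio", {
  ratios <- vapply(c(2, 6, 10), function(bar) {
    m <- trpm5_like_pore(voltage_mV = -300, funnel_barrier = bar)
    tr <- simulate_ions(m, sim_spec(dt_ns = 5e-4, n_steps = 150000L,
                                    save_stride = 40L, seed = 77L))
    ev <- detect_events(tr, trpm5_like_geometry())
    n_mono <- sum(ev$species == "Na" & ev$direction == "inward")
    n_di <- sum(ev$species == "Ca" & ev$direction == "inward")
    (n_mono + 1) / (n_di + 1)
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})
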