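flat_model <- function(n_ions = 10L, voltage = 0, d = 20,
                       z_range = c(-10, 10), span = c(-5, 5), valence = 1L) {
  pore_model(function(z) rep(0, length(z)), voltage_mV = voltage,
             membrane_span = span,
             species = tibble::tibble(name = "Na", valence = valence,
                                      diffusion_A2_ns = d, count = n_ions),
             z_range = z_range)
}

test_that("identical model and settings give bit-identical trajectories", {
  m <- trpm5_like_pore(voltage_mV = -200)
  s <- sim_spec(n_steps = 2000L, save_stride = 10L, seed = 42L,
                exclusion_A = 5)
  expect_identical(simulate_ions(m, s), simulate_ions(m, s))
  s2 <- sim_spec(n_steps = 2000L, save_stride = 10L, seed = 43L,
                 exclusion_A = 5)
  expect_false(identical(simulate_ions(m, s)$z_A, simulate_ions(m, s2)$z_A))
})

test_that("a flat landscape at zero voltage samples the box uniformly", {
  tr <- simulate_ions(flat_model(), sim_spec(n_steps = 20000L, seed = 3L))
  expect_lt(abs(mean(tr$z_A)), 1) # box centre is 0
  ## uniform sd over [-10, 10] is 20/sqrt(12) = 5.77
  expect_lt(abs(sd(tr$z_A) - 20 / sqrt(12)), 0.7)
  h <- hist(tr$z_A, breaks = seq(-10, 10, 2.5), plot = FALSE)
  expect_lt(max(abs(h$density - 1 / 20)) / (1 / 20), 0.5)
})

test_that("a harmonic well reaches the Boltzmann variance 1/kappa", {
  kappa <- 1
  m <- pore_model(function(z) 0.5 * kappa * z^2, voltage_mV = 0,
                  membrane_span = c(-5, 5),
                  species = tibble::tibble(name = "Na", valence = 1L,
                                           diffusion_A2_ns = 20, count = 40L),
                  z_range = c(-10, 10))
  tr <- simulate_ions(m, sim_spec(n_steps = 50000L, save_stride = 10L,
                                  seed = 2L))
  v <- var(tr$z_A[tr$time_ns > 2]) # discard the uniform-start transient
  expect_lt(abs(v - 1 / kappa), 0.05)
})

test_that("zero-voltage log-histogram recovers the generating potential", {
  dw <- function(z) {
    -2 * exp(-((z + 3)^2) / 8) - 2 * exp(-((z - 3)^2) / 8)
  }
  m <- pore_model(dw, voltage_mV = 0, membrane_span = c(-5, 5),
                  species = tibble::tibble(name = "Na", valence = 1L,
                                           diffusion_A2_ns = 20, count = 40L),
                  z_range = c(-10, 10))
  tr <- simulate_ions(m, sim_spec(n_steps = 100000L, save_stride = 20L,
                                  seed = 11L))
  en <- neg_log_density(axial_density(tr, z_range = c(-10, 10)))
  ok <- !en$mask
  uref <- dw(en$z_A[ok])
  dev <- en$energy_kbt[ok] - (uref - min(uref))
  dev <- dev - mean(dev) # additive-constant gauge
  expect_lt(sqrt(mean(dev^2)), 0.3)
})

test_that("negative voltage drives net inward flux and reversal flips it", {
  run_drift <- function(v) {
    tr <- simulate_ions(flat_model(voltage = v, z_range = c(-20, 20),
                                   span = c(-10, 10), n_ions = 20L),
                        sim_spec(n_steps = 10000L, seed = 5L))
    un <- unwrap_tracks(tr)
    mean(tapply(un$z_A, un$ion_id, function(z) z[length(z)] - z[1]))
  }
  expect_lt(run_drift(-300), -5)
  expect_gt(run_drift(300), 5)
})

test_that("doubling the valence doubles the voltage drift", {
  m <- pore_model(function(z) rep(0, length(z)), voltage_mV = -600,
                  membrane_span = c(-15, 15),
                  species = tibble::tibble(
                    name = c("m", "d"), valence = c(1L, 2L),
                    diffusion_A2_ns = 20, count = c(25L, 25L)),
                  z_range = c(-20, 20))
  tr <- simulate_ions(m, sim_spec(n_steps = 15000L, save_stride = 5L,
                                  seed = 9L))
  un <- as.data.frame(unwrap_tracks(tr))
  drift_of <- function(sp) {
    d <- un[un$species == sp, ]
    d <- d[order(d$ion_id, d$time_ns), ]
    steps <- unlist(tapply(d$z_A, d$ion_id, diff))
    from <- unlist(tapply(d$z_A, d$ion_id, function(z) head(z, -1)))
    in_span <- abs(wrap_z(from, -20, 20)) < 14 # both planes well inside
    mean(steps[in_span])
  }
  ratio <- drift_of("d") / drift_of("m")
  expect_lt(abs(ratio - 2), 0.2)
})

test_that("a mis-specified potential aborts with a diagnostic", {
  expect_error(
    pore_model(function(z) ifelse(z > 3, Inf, 0), voltage_mV = 0,
               membrane_span = c(-5, 5), z_range = c(-10, 10)),
    "non-finite")
})

test_that("umbrella windows sample the bias Gaussian on a flat landscape", {
  w <- make_umbrella_dataset(function(z) rep(0, length(z)),
                             k_spring = 1000, spacing_A = 0.25,
                             range_A = c(0, 0.25), n_samples = 4000,
                             seed = 4)
  expect_length(w, 2)
  sd_expected <- sqrt(1 / spring_kbt_per_A2(1000))
  expect_lt(abs(mean(w[[1]]$samples) - 0), 0.05)
  expect_lt(abs(sd(w[[1]]$samples) - sd_expected) / sd_expected, 0.05)
  expect_false(w[[1]]$overlap_warning)
  ## same seed, same samples
  w2 <- make_umbrella_dataset(function(z) rep(0, length(z)),
                              k_spring = 1000, spacing_A = 0.25,
                              range_A = c(0, 0.25), n_samples = 4000,
                              seed = 4)
  expect_identical(w[[1]]$samples, w2[[1]]$samples)
  ## windows too far apart for the spring are flagged
  w3 <- make_umbrella_dataset(function(z) rep(0, length(z)),
                              k_spring = 1000, spacing_A = 5,
                              range_A = c(0, 10), n_samples = 10, seed = 1)
  expect_true(w3[[1]]$overlap_warning)
})

test_that("umbrella windows round-trip through TSV + sidecar", {
  w <- make_umbrella_dataset(function(z) 0.1 * z^2, range_A = c(-1, 1),
                             n_samples = 50, seed = 2)
  dir <- withr::local_tempdir()
  write_umbrella_windows(w, dir)
  w2 <- read_umbrella_windows(dir)
  expect_equal(length(w2), length(w))
  expect_equal(w2[[3]]$center, w[[3]]$center)
  expect_equal(w2[[3]]$samples, w[[3]]$samples, tolerance = 1e-12)
})

test_that("coupled occupancy interpolates between independence and mirroring", {
  expect_error(make_coupled_occupancy(0.5, 0, n_frames = 0), "n_frames")
  expect_error(make_coupled_occupancy(0.5, 1.5, n_frames = 10), "coupling")
  occ <- make_coupled_occupancy(0.5, 1, n_frames = 500, seed = 8)
  ## full coupling: identical binary occupancy patterns
  expect_identical(occ$a$occupant_id >= 0, occ$b$occupant_id >= 0)
  ## ids come from independent counters but vacancy is the -1 sentinel
  expect_true(all(occ$a$occupant_id >= -1))
  occ0 <- make_coupled_occupancy(0.5, 0, n_frames = 500, seed = 8)
  expect_false(identical(occ0$a$occupant_id >= 0, occ0$b$occupant_id >= 0))
  ## determinism
  expect_identical(make_coupled_occupancy(0.3, 0.5, 200, seed = 1),
                   make_coupled_occupancy(0.3, 0.5, 200, seed = 1))
})

test_that("synthetic waters recover the requested shell statistics", {
  tr <- ion_tracks(tibble::tibble(
    time_ns = rep(c(0, 0.1), each = 3), ion_id = rep(0:2, 2),
    species = "Na", valence = 1L, x_A = rep(c(-8, 0, 8), 2),
    y_A = 0, z_A = rep(c(-5, 0, 5), 2)))
  none <- make_waters(tr, mean_count = 0, shell_radius_A = 3.1, seed = 1)
  expect_equal(nrow(none$waters), 0)
  expect_true(all(none$truth$n_shell == 0))
  many <- make_waters(tr, mean_count = 5, shell_radius_A = 3.1, seed = 1)
  counts <- vapply(seq_len(nrow(many$truth)), function(i) {
    tab <- as.data.frame(tr)[i, ]
    w <- many$waters[many$waters$time_ns == tab$time_ns, ]
    first_shell_count(c(tab$x_A, tab$y_A, tab$z_A), w, 3.1)
  }, integer(1))
  ## placement is exact: measured counts equal the generated truth
  expect_identical(counts, many$truth$n_shell)
  big <- make_waters(ion_tracks(tibble::tibble(
    time_ns = rep(seq(0, 9.9, 0.1), 2), ion_id = rep(0:1, each = 100),
    species = "Na", valence = 1L, x_A = 0, y_A = 0, z_A = 0)),
    mean_count = 5, seed = 3)
  expect_lt(abs(mean(big$truth$n_shell) - 5), 0.4)
  expect_identical(make_waters(tr, 2, seed = 7)$waters,
                   make_waters(tr, 2, seed = 7)$waters)
})
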