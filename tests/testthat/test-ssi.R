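test_that("occupancy series record the nearest resident ion per frame", {
  ## scripted pass of one ion through the site, second ion parked outside
  z_pass <- c(15, 12, 8, 3, 0, -2, -6, -12, -15, -18)
  tr <- ion_tracks(tibble::tibble(
    time_ns = rep((0:9) * 0.02, 2), ion_id = rep(c(3L, 9L), each = 10),
    species = "Na", valence = 1L,
    z_A = c(z_pass, rep(18, 10))))
  site <- binding_site("cavity", c(-8, 2))
  occ <- build_occupancy(tr, site, dt_ps = 20)
  expect_equal(occ$occupant_id, oracle_occupancy(tr, -8, 2))
  expect_equal(occ$occupant_id, c(-1L, -1L, -1L, -1L, 3L, 3L, 3L, -1L, -1L,
                                  -1L))
  ## in-range but never-visited site stays vacant throughout
  empty <- build_occupancy(tr, binding_site("high", c(16.5, 17.5)),
                           dt_ps = 20)
  expect_true(all(empty$occupant_id == -1))
  expect_error(build_occupancy(tr, binding_site("off", c(100, 120))),
               "outside")
})

test_that("occupancy ties go to the nearer ion unless the incumbent rule is on", {
  tr <- ion_tracks(tibble::tibble(
    time_ns = rep((0:3) * 0.02, 2), ion_id = rep(c(1L, 2L), each = 4),
    species = "Na", valence = 1L,
    ## ion 1 sits near the centre, ion 2 drifts in closer at the end
    z_A = c(-3.5, -3.5, -3.5, -3.5, 20, 0, -2.9, -3.1)))
  site <- binding_site("cavity", c(-8, 2))
  nearest <- build_occupancy(tr, site, dt_ps = 20)
  expect_equal(nearest$occupant_id, c(1L, 1L, 2L, 2L))
  expect_equal(nearest$occupant_id, oracle_occupancy(tr, -8, 2))
  first <- build_occupancy(tr, site, dt_ps = 20, tie_break = "first")
  expect_equal(first$occupant_id, c(1L, 1L, 1L, 1L))
})

test_that("transition streams classify all five symbol types", {
  const <- occupancy_series(rep(7L, 5))
  expect_true(all(transition_stream(const) == "stay_occupied"))
  expect_true(all(transition_stream(occupancy_series(rep(-1L, 5))) ==
                    "stay_vacant"))
  alt <- transition_stream(occupancy_series(c(-1L, 0L, -1L, 1L, -1L)))
  expect_equal(as.character(alt), c("bind", "release", "bind", "release"))
  ids <- withr::with_seed(11, sample(c(-1L, 0L, 1L, 2L), 300, replace = TRUE))
  st <- transition_stream(occupancy_series(ids))
  a <- ids[-300]
  b <- ids[-1]
  expect_equal(sum(st == "exchange"), sum(a >= 0 & b >= 0 & a != b))
  expect_equal(sum(st == "bind"), sum(a == -1 & b >= 0))
  expect_equal(sum(st == "release"), sum(a >= 0 & b == -1))
})

test_that("plug-in mutual information has the textbook identities", {
  occ <- make_coupled_occupancy(0.5, 1, n_frames = 800, seed = 3)
  sa <- transition_stream(occ$a)
  sb <- transition_stream(occ$b)
  h <- -sum(prop.table(table(sa)) * log2(pmax(prop.table(table(sa)), 1e-300)))
  expect_equal(ssi_bits(sa, sb), h, tolerance = 1e-12)
  expect_equal(ssi_bits(sa, sb), ssi_bits(sb, sa), tolerance = 1e-12)
  expect_equal(ssi_bits(rep("a", 50), rep("b", 50)), 0)
  ## random streams: symmetric, non-negative, bounded by the entropies
  for (seed in 1:5) {
    x <- withr::with_seed(seed, sample(letters[1:4], 200, replace = TRUE))
    y <- withr::with_seed(seed + 50, sample(letters[1:3], 200,
                                            replace = TRUE))
    mi <- ssi_bits(x, y)
    hx <- -sum(prop.table(table(x)) * log2(prop.table(table(x))))
    hy <- -sum(prop.table(table(y)) * log2(prop.table(table(y))))
    expect_gte(mi, 0)
    expect_lte(mi, min(hx, hy) + 1e-12)
    expect_equal(mi, ssi_bits(y, x), tolerance = 1e-12)
  }
  expect_error(ssi_bits(1:5, 1:6), "equal length")
})

test_that("a six-frame toy pair matches the hand-enumerated joint histogram", {
  a <- c("bind", "stay_occupied", "release", "stay_vacant", "bind",
         "release")
  b <- c("bind", "stay_occupied", "stay_occupied", "release", "bind",
         "release")
  ## joint histogram by hand: pairs (b,b) x2, (so,so), (r,so), (sv,r), (r,r)
  p <- c(2, 1, 1, 1, 1) / 6
  pa <- c(bind = 2, stay_occupied = 1, release = 2, stay_vacant = 1) / 6
  pb <- c(bind = 2, stay_occupied = 2, release = 2) / 6
  hand <- sum(p * log2(p / c(
    pa[["bind"]] * pb[["bind"]],
    pa[["stay_occupied"]] * pb[["stay_occupied"]],
    pa[["release"]] * pb[["stay_occupied"]],
    pa[["stay_vacant"]] * pb[["release"]],
    pa[["release"]] * pb[["release"]])))
  expect_equal(ssi_bits(a, b), hand, tolerance = 1e-12)
  expect_equal(oracle_mi_bits(a, b), hand, tolerance = 1e-12)
})

test_that("the noise threshold is zero for degenerate streams and reproducible", {
  expect_equal(noise_threshold(rep("s", 100), rep("s", 100)), 0)
  occ <- make_coupled_occupancy(0.5, 0, n_frames = 600, seed = 21)
  sa <- transition_stream(occ$a)
  sb <- transition_stream(occ$b)
  t1 <- noise_threshold(sa, sb, n_shuffles = 50, seed = 5)
  expect_identical(t1, noise_threshold(sa, sb, n_shuffles = 50, seed = 5))
  expect_gt(t1, 0)
  expect_error(noise_threshold(sa, sb, n_shuffles = 5), "n_shuffles")
})

test_that("full coupling yields exSSI near the stream entropy above noise", {
  occ <- make_coupled_occupancy(0.5, 1, n_frames = 3000, seed = 6)
  res <- exssi_from_occupancy(occ$a, occ$b, seed = 6)
  h <- -sum(prop.table(table(transition_stream(occ$a))) *
              log2(pmax(prop.table(table(transition_stream(occ$a))),
                        1e-300)))
  expect_gt(res$exssi_bits, 0)
  expect_lt(abs(res$exssi_bits - (h - res$noise_threshold_bits)) / h, 0.1)
  expect_true(res$single_replica)
  expect_true(is.na(res$se_bits))
  ## replicated input reports a standard error
  occ2 <- make_coupled_occupancy(0.5, 1, n_frames = 3000, seed = 7)
  rep2 <- exssi_from_occupancy(list(list(occ$a, occ$b),
                                    list(occ2$a, occ2$b)), seed = 6)
  expect_false(rep2$single_replica)
  expect_equal(rep2$n_replicas, 2)
  expect_false(is.na(rep2$se_bits))
  expect_equal(nrow(tidy(rep2)), 1)
})

test_that("pore knock-on coupling appears in exSSI and vanishes without dwell", {
  run_arm <- function(coupled, seed) {
    ko <- knockon_pore_model(coupled = coupled)
    tr <- simulate_ions(ko$model,
                        sim_spec(dt_ns = 5e-4, n_steps = 300000L,
                                 save_stride = 40L, seed = seed,
                                 exclusion_A = ko$exclusion_A))
    excess_ssi(tr, ko$site_upper, ko$site_lower, dt_ps = 500,
               seed = seed)$exssi_bits
  }
  mono <- vapply(31:33, function(s) run_arm(TRUE, s), numeric(1))
  di <- vapply(31:33, function(s) run_arm(FALSE, s), numeric(1))
  expect_gt(mean(mono), 0.04) # well above typical noise thresholds
  expect_lt(mean(di), 0.04) # indistinguishable from noise
  expect_gt(mean(mono), 2 * mean(di))
})
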