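#' Define a one-dimensional pore model for Brownian-dynamics sampling
#'
#' The model is a 1D energy landscape along the pore axis plus a linear
#' transmembrane-voltage ramp confined to the membrane span (mimicking
#' voltage focusing across the pore), a species table, and a periodic box.
#' Energies are in kBT throughout.
#'
#' @param potential either a single function `U(z)` returning energy in kBT,
#'   or a named list of such functions keyed by species name. Must be finite
#'   over `z_range`.
#' @param voltage_mV transmembrane voltage in mV; negative means the
#'   intracellular (low-z) side is negative, which drives cations inward
#'   (toward decreasing z).
#' @param membrane_span numeric length 2, `c(z_gate, z_sf)` in angstrom: the
#'   interval over which the voltage drops linearly. Outside it the
#'   electrostatic potential is flat.
#' @param species a data frame with columns `name`, `valence` (signed
#'   elementary charges), `diffusion_A2_ns` (> 0) and `count` (>= 0).
#' @param z_range numeric length 2, the periodic axial range in angstrom
#'   (`z_min < z_gate < z_sf < z_max`).
#' @param temperature_K temperature in kelvin.
#' @param cylinder_radius_A radius of the cylinder confining transverse (x,y)
#'   coordinates.
#' @return an object of class `pore_model`.
#' @export
pore_model <- function(potential, voltage_mV = 0,
                       membrane_span = c(-10, 10),
                       species = tibble(name = "Na", valence = 1L,
                                        diffusion_A2_ns = 20, count = 1L),
                       z_range = c(-20, 20), temperature_K = 310,
                       cylinder_radius_A = 8) {
  species <- as_tibble(species)
  stopifnot(all(c("name", "valence", "diffusion_A2_ns", "count") %in%
                  names(species)))
  if (any(species$diffusion_A2_ns <= 0)) abort("diffusion_A2_ns must be > 0")
  if (any(species$count < 0)) abort("species counts must be >= 0")
  if (!(z_range[1] < membrane_span[1] && membrane_span[1] < membrane_span[2] &&
        membrane_span[2] < z_range[2])) {
    abort("need z_min < z_gate < z_sf < z_max")
  }
  pots <- if (is.function(potential)) {
    setNames(rep(list(potential), nrow(species)), species$name)
  } else {
    missing_pot <- setdiff(species$name, names(potential))
    if (length(missing_pot) > 0) {
      abort(paste0("no potential supplied for species: ",
                   paste(missing_pot, collapse = ", ")))
    }
    potential[species$name]
  }
  zs <- seq(z_range[1], z_range[2], length.out = 257)
  for (nm in species$name) {
    u <- pots[[nm]](zs)
    if (!all(is.finite(u))) {
      abort(sprintf("potential for species '%s' is non-finite on z_range", nm))
    }
  }
  structure(
    list(potential = pots, voltage_mV = voltage_mV,
         membrane_span = membrane_span, species = species,
         z_range = z_range, temperature_K = temperature_K,
         cylinder_radius_A = cylinder_radius_A),
    class = "pore_model")
}

#' Simulation settings for the Brownian-dynamics generator
#'
#' @param dt_ns integration time step in ns.
#' @param n_steps number of integration steps (>= 1).
#' @param save_stride save every `save_stride`-th step (frame interval is
#'   `dt_ns * save_stride`).
#' @param seed integer RNG seed; identical model + spec give bit-identical
#'   output.
#' @param exclusion_A optional hard-core minimal inter-ion z distance in
#'   angstrom, enforced inside `exclusion_range`; `NULL` disables it.
#' @param exclusion_range numeric length 2 or `NULL`; z interval in which the
#'   single-file exclusion applies (default: membrane span extended 6 A on
#'   the extracellular side, covering the outer vestibule).
#' @return an object of class `sim_spec`.
#' @export
sim_spec <- function(dt_ns = 5e-4, n_steps = 1000L, save_stride = 10L,
                     seed = 1L, exclusion_A = NULL, exclusion_range = NULL) {
  if (dt_ns <= 0) abort("dt_ns must be > 0")
  if (n_steps < 1) abort("n_steps must be >= 1")
  if (save_stride < 1) abort("save_stride must be >= 1")
  structure(
    list(dt_ns = dt_ns, n_steps = as.integer(n_steps),
         save_stride = as.integer(save_stride), seed = as.integer(seed),
         exclusion_A = exclusion_A, exclusion_range = exclusion_range),
    class = "sim_spec")
}

#' Electrostatic potential profile of the voltage ramp, in kBT per unit charge
#'
#' Zero on the extracellular side (z >= z_sf), the full voltage energy on the
#' intracellular side (z <= z_gate), linear in between.
#'
#' @param z positions in angstrom.
#' @param model a [pore_model()].
#' @return vector of energies in kBT for a +1e charge.
#' @export
ramp_potential_kbt <- function(z, model) {
  v_kbt <- voltage_energy_kbt(model$voltage_mV, 1, model$temperature_K)
  z_gate <- model$membrane_span[1]
  z_sf <- model$membrane_span[2]
  frac <- pmin(pmax((z_sf - z) / (z_sf - z_gate), 0), 1)
  v_kbt * frac
}

## Tabulated deterministic force (kBT/A) per species on a uniform grid.
## The species potential is differentiated numerically (one-sided at the
## edges so the periodic wrap never contributes a spurious spike); the ramp
## slope is added analytically inside the membrane span.
force_table <- function(model, n_grid = 4096L) {
  zg <- seq(model$z_range[1], model$z_range[2], length.out = n_grid)
  dg <- zg[2] - zg[1]
  v_kbt <- voltage_energy_kbt(model$voltage_mV, 1, model$temperature_K)
  span <- model$membrane_span
  ramp_slope <- ifelse(zg > span[1] & zg < span[2],
                       v_kbt / (span[2] - span[1]), 0)
  fmat <- vapply(model$species$name, function(nm) {
    u <- model$potential[[nm]](zg)
    du <- numeric(n_grid)
    du[2:(n_grid - 1)] <- (u[3:n_grid] - u[1:(n_grid - 2)]) / (2 * dg)
    du[1] <- (u[2] - u[1]) / dg
    du[n_grid] <- (u[n_grid] - u[n_grid - 1]) / dg
    q <- model$species$valence[model$species$name == nm][1]
    f <- -du + q * ramp_slope # ramp energy falls toward low z when V < 0
    if (!all(is.finite(f))) {
      abort(sprintf("non-finite force for species '%s': potential mis-specified", nm))
    }
    f
  }, numeric(n_grid))
  list(z0 = zg[1], dg = dg, n = n_grid, f = fmat)
}

#' Simulate ions in the pore by overdamped Brownian dynamics
#'
#' Positions follow the overdamped Langevin update
#' `z <- z - D dt d/dz[U(z) + q phi(z)] + sqrt(2 D dt) xi` with `U` the
#' species potential in kBT, `phi` the linear voltage ramp and `xi` standard
#' normal noise; z is wrapped periodically into the axial range. Transverse
#' coordinates diffuse freely and are reflected into the confining cylinder;
#' they are only resolved at saved frames. An optional hard-core exclusion
#' rejects moves that would bring two ions closer than `exclusion_A` along z
#' inside the pore region, producing single-file, knock-on-like occupancy
#' coupling.
#'
#' @param model a [pore_model()].
#' @param spec a [sim_spec()].
#' @return an [ion_tracks()] table; frame times start at 0.
#' @export
simulate_ions <- function(model, spec) {
  stopifnot(inherits(model, "pore_model"), inherits(spec, "sim_spec"))
  sp <- model$species[model$species$count > 0, , drop = FALSE]
  n_ion <- sum(sp$count)
  if (n_ion == 0) abort("no ions to simulate (all counts are zero)")
  ft <- force_table(model)
  spi <- rep(seq_len(nrow(sp)), sp$count) # species index per ion
  d_coef <- sp$diffusion_A2_ns[spi]
  ddt <- d_coef * spec$dt_ns
  sig <- sqrt(2 * ddt)
  z_min <- model$z_range[1]
  box <- diff(model$z_range)
  excl <- spec$exclusion_A
  excl_range <- spec$exclusion_range %||%
    c(model$membrane_span[1], model$membrane_span[2] + 6)
  n_saved <- spec$n_steps %/% spec$save_stride + 1L
  zmat <- matrix(NA_real_, n_saved, n_ion)
  xmat <- matrix(NA_real_, n_saved, n_ion)
  ymat <- matrix(NA_real_, n_saved, n_ion)
  withr::with_seed(spec$seed, {
    z <- runif(n_ion, z_min, z_min + box)
    if (!is.null(excl)) { # start from a non-overlapping configuration
      z <- sort(z)
      for (i in seq_len(n_ion)[-1]) {
        if (z[i] - z[i - 1] < excl) z[i] <- z[i - 1] + excl
      }
      z <- wrap_z(z, z_min, z_min + box)
    }
    r0 <- sqrt(runif(n_ion)) * model$cylinder_radius_A
    th0 <- runif(n_ion, 0, 2 * pi)
    x <- r0 * cos(th0)
    y <- r0 * sin(th0)
    zmat[1, ] <- z; xmat[1, ] <- x; ymat[1, ] <- y
    inv_dg <- 1 / ft$dg
    k <- 1L
    sig_xy <- sqrt(2 * d_coef * spec$dt_ns * spec$save_stride)
    for (s in seq_len(spec$n_steps)) {
      idx <- as.integer((z - ft$z0) * inv_dg) + 1L
      idx[idx < 1L] <- 1L
      idx[idx > ft$n] <- ft$n
      f <- ft$f[idx + (spi - 1L) * ft$n]
      znew <- z + ddt * f + sig * rnorm(n_ion)
      znew <- wrap_z(znew, z_min, z_min + box)
      if (!is.null(excl)) {
        in_pore <- znew >= excl_range[1] & znew <= excl_range[2]
        if (sum(in_pore) > 1) {
          ord <- order(znew)
          zo <- znew[ord]; po <- in_pore[ord]
          both <- po[-length(po)] & po[-1]
          gap_new <- diff(zo)
          gap_old <- abs(z[ord[-1]] - z[ord[-length(ord)]])
          ## reject only approaching moves of a too-close pair, so that a
          ## pair already inside the core can still separate
          close <- both & gap_new < excl & gap_new < gap_old
          if (any(close)) {
            bad <- unique(c(ord[which(close)], ord[which(close) + 1L]))
            znew[bad] <- z[bad] # reject the move, keep previous position
          }
        }
      }
      z <- znew
      if (s %% spec$save_stride == 0L) {
        k <- k + 1L
        x <- x + sig_xy * rnorm(n_ion)
        y <- y + sig_xy * rnorm(n_ion)
        r <- sqrt(x^2 + y^2)
        over <- r > model$cylinder_radius_A
        if (any(over)) { # radial reflection into the cylinder
          rr <- (2 * model$cylinder_radius_A - r[over]) / r[over]
          rr[rr < 0] <- 0
          x[over] <- x[over] * rr
          y[over] <- y[over] * rr
        }
        zmat[k, ] <- z; xmat[k, ] <- x; ymat[k, ] <- y
      }
    }
  })
  times <- (seq_len(n_saved) - 1) * spec$dt_ns * spec$save_stride
  out <- tibble(
    time_ns = rep(times, n_ion),
    ion_id = rep(seq_len(n_ion) - 1L, each = n_saved),
    species = rep(sp$name[spi], each = n_saved),
    valence = rep(as.integer(sp$valence[spi]), each = n_saved),
    x_A = as.vector(xmat),
    y_A = as.vector(ymat),
    z_A = as.vector(zmat))
  ion_tracks(out, box_length_z = box, periodic = TRUE,
             voltage_mV = model$voltage_mV,
             temperature_K = model$temperature_K)
}

#' Reference pore energy landscapes
#'
#' Analytic 1D landscapes emulating the qualitative features reported for
#' monovalent-selective TRP-family pores: monovalent cations see a shallow
#' well at the extracellular pore vestibule (EPV) and a deeper well in the
#' central cavity with only a slight barrier at the intracellular gate,
#' whereas divalent cations see the same EPV well but a high "hydrophobic
#' funnel" barrier between the selectivity filter and the cavity instead of a
#' cavity well.
#'
#' @param epv_well,cavity_well well depths in kBT (positive numbers).
#' @param funnel_barrier divalent funnel barrier height in kBT.
#' @param gate_barrier slight barrier at the lower gate, kBT.
#' @return a named list of two functions, `monovalent(z)` and `divalent(z)`.
#' @export
trpm5_pore_potentials <- function(epv_well = 1.5, cavity_well = 2.5,
                                  funnel_barrier = 8, gate_barrier = 0.5) {
  gauss <- function(z, z0, s) exp(-((z - z0)^2) / (2 * s^2))
  mono <- function(z) {
    -epv_well * gauss(z, 13, 2) - cavity_well * gauss(z, -3, 2.5) +
      gate_barrier * gauss(z, -11, 1.5)
  }
  di <- function(z) {
    -epv_well * gauss(z, 13, 2) + funnel_barrier * gauss(z, 3, 2) +
      gate_barrier * gauss(z, -11, 1.5)
  }
  list(monovalent = mono, divalent = di)
}

#' A ready-made monovalent-selective pore model
#'
#' Combines [trpm5_pore_potentials()] with the package's default geometry
#' (selectivity filter plane at z = +10 A, intracellular gate at z = -10 A,
#' periodic axial range -20..20 A) and a dicationic species mix.
#'
#' @param voltage_mV transmembrane voltage in mV.
#' @param n_mono,n_di ion counts for the monovalent and divalent species.
#' @param d_mono,d_di diffusion coefficients, A^2/ns.
#' @param ... passed to [trpm5_pore_potentials()].
#' @return a [pore_model()].
#' @export
trpm5_like_pore <- function(voltage_mV = -340, n_mono = 12L, n_di = 8L,
                            d_mono = 20, d_di = 15, ...) {
  pots <- trpm5_pore_potentials(...)
  pore_model(
    potential = list(Na = pots$monovalent, Ca = pots$divalent),
    voltage_mV = voltage_mV,
    membrane_span = c(-10, 10),
    species = tibble(
      name = c("Na", "Ca"),
      valence = c(1L, 2L),
      diffusion_A2_ns = c(d_mono, d_di),
      count = c(as.integer(n_mono), as.integer(n_di))),
    z_range = c(-20, 20))
}

#' Knock-on test pore: two adjacent binding wells with single-file exclusion
#'
#' A compact scenario exhibiting (or suppressing) knock-on-coupled occupancy
#' of two binding regions. The coupled variant has two 4.5 kBT wells 5 A
#' apart inside the pore with a hard-core exclusion equal to their spacing,
#' so a resident ion leaving the lower well lets the upper resident drop in
#' within a fraction of a nanosecond (concerted, knock-on-like motion). The
#' uncoupled variant replaces the wells with a central barrier, so neither
#' site holds ions long enough for transitions to correlate.
#'
#' @param coupled logical: wells (TRUE) or barrier (FALSE).
#' @param voltage_mV transmembrane voltage, mV.
#' @param n_ions ion count.
#' @param well_kbt well depth (coupled) in kBT.
#' @param barrier_kbt barrier height (uncoupled) in kBT.
#' @return a list with `model` (a [pore_model()]), `exclusion_A`, and
#'   `site_upper`, `site_lower` ([binding_site()] definitions).
#' @export
knockon_pore_model <- function(coupled = TRUE, voltage_mV = -200,
                               n_ions = 6L, well_kbt = 4.5,
                               barrier_kbt = 6) {
  gauss <- function(z, z0, s) exp(-((z - z0)^2) / (2 * s^2))
  pot <- if (coupled) {
    function(z) -well_kbt * gauss(z, -5, 1.5) - well_kbt * gauss(z, 0, 1.5)
  } else {
    function(z) barrier_kbt * gauss(z, -2.5, 2)
  }
  list(
    model = pore_model(
      pot, voltage_mV = voltage_mV, membrane_span = c(-10, 10),
      species = tibble(name = "X", valence = 1L, diffusion_A2_ns = 20,
                       count = as.integer(n_ions)),
      z_range = c(-15, 15)),
    exclusion_A = 5,
    site_upper = binding_site("upper", c(-2.5, 3)),
    site_lower = binding_site("lower", c(-8, -2.5)))
}

#' Default pore geometry matching [trpm5_like_pore()]
#'
#' @return a [pore_geometry()] with the filter plane at +10 A and the gate at
#'   -10 A.
#' @export
trpm5_like_geometry <- function() {
  pore_geometry(z_sf = 10, z_gate = -10, pore_radius = 8)
}
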