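#' One umbrella-sampling window
#'
#' @param center restraint centre z_c in angstrom.
#' @param k_spring harmonic force constant in kJ mol^-1 nm^-2.
#' @param samples numeric vector of sampled z positions (angstrom).
#' @param temperature_K temperature in kelvin.
#' @param dt_ns nominal sample spacing in ns (used for the time column on
#'   disk).
#' @param overlap_warning logical; set when the window spacing was too wide
#'   for the spring, so neighbouring windows may not overlap.
#' @return an object of class `umbrella_window`.
#' @export
umbrella_window <- function(center, k_spring, samples, temperature_K = 310,
                            dt_ns = 0.001, overlap_warning = FALSE) {
  if (k_spring <= 0) abort("k_spring must be > 0")
  if (length(samples) < 1) abort("a window needs at least one sample")
  structure(
    list(center = center, k_spring = k_spring,
         samples = as.numeric(samples), temperature_K = temperature_K,
         dt_ns = dt_ns, overlap_warning = isTRUE(overlap_warning)),
    class = "umbrella_window")
}

#' @export
print.umbrella_window <- function(x, ...) {
  cat(sprintf("<umbrella_window> center %.3f A, k %.6g kJ/mol/nm^2, %d samples\n",
              x$center, x$k_spring, length(x$samples)))
  invisible(x)
}

#' Generate umbrella-sampling windows from an analytic potential
#'
#' Draws, for each window centre, samples from the biased Boltzmann density
#' `exp(-[U(z) + k/2 (z - z_c)^2] / kBT)` by inverse-CDF sampling on a fine
#' grid (exact up to grid resolution, and free of the equilibration and
#' autocorrelation concerns of a dynamical sampler). Window centres are
#' arithmetic with the given spacing; the defaults (1000 kJ mol^-1 nm^-2
#' springs every 0.25 A) follow common umbrella-sampling practice for
#' single-ion pore PMFs.
#'
#' @param potential function `U(z)` in kBT.
#' @param k_spring spring constant, kJ mol^-1 nm^-2.
#' @param spacing_A window spacing in angstrom (> 0).
#' @param range_A numeric length 2: centres run from `range_A[1]` to
#'   `range_A[2]` (at least two windows).
#' @param n_samples samples per window.
#' @param seed RNG seed.
#' @param temperature_K temperature in kelvin.
#' @return a list of [umbrella_window()] objects.
#' @export
make_umbrella_dataset <- function(potential, k_spring = 1000,
                                  spacing_A = 0.25, range_A,
                                  n_samples = 500, seed = 1,
                                  temperature_K = 310) {
  if (spacing_A <= 0) abort("spacing_A must be > 0")
  centers <- seq(range_A[1], range_A[2], by = spacing_A)
  if (length(centers) < 2) abort("range must cover at least two windows")
  k_kbt <- spring_kbt_per_A2(k_spring, temperature_K)
  bias_sd <- sqrt(1 / k_kbt)
  too_wide <- spacing_A > 3 * bias_sd
  pad <- 6 * bias_sd
  withr::with_seed(as.integer(seed), {
    lapply(centers, function(zc) {
      zg <- seq(zc - pad, zc + pad, length.out = 2001)
      w <- potential(zg) + 0.5 * k_kbt * (zg - zc)^2
      p <- exp(-(w - min(w)))
      cdf <- cumsum(p)
      cdf <- cdf / cdf[length(cdf)]
      u <- runif(n_samples)
      keep <- !duplicated(cdf)
      smp <- approx(cdf[keep], zg[keep], xout = u, rule = 2)$y
      umbrella_window(zc, k_spring, smp, temperature_K,
                      overlap_warning = too_wide)
    })
  })
}

#' Write / read umbrella windows
#'
#' Each window becomes one TSV (`window_###.tsv`, columns `time_ns`, `z_A`)
#' with a JSON sidecar (`window_###.json`) holding the centre, spring
#' constant, temperature and overlap flag.
#'
#' @param windows a list of [umbrella_window()] objects.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_umbrella_windows <- function(windows, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    stem <- file.path(dir, sprintf("window_%03d", i))
    readr::write_tsv(
      tibble(time_ns = (seq_along(w$samples) - 1) * w$dt_ns,
             z_A = w$samples),
      paste0(stem, ".tsv"))
    jsonlite::write_json(
      list(center = w$center, k_spring = w$k_spring,
           temperature_K = w$temperature_K, dt_ns = w$dt_ns,
           overlap_warning = w$overlap_warning),
      paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_umbrella_windows
#' @export
read_umbrella_windows <- function(dir) {
  metas <- sort(list.files(dir, pattern = "^window_\\d+\\.json$",
                           full.names = TRUE))
  if (length(metas) == 0) abort(paste0("no umbrella windows found in ", dir))
  lapply(metas, function(mp) {
    meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
    tab <- readr::read_tsv(sub("\\.json$", ".tsv", mp),
                           show_col_types = FALSE, progress = FALSE)
    umbrella_window(meta$center, meta$k_spring, tab$z_A,
                    temperature_K = meta$temperature_K %||% 310,
                    dt_ns = meta$dt_ns %||% 0.001,
                    overlap_warning = meta$overlap_warning %||% FALSE)
  })
}
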