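#' Generate synthetic first-shell water configurations around ions
#'
#' For every (frame, ion) record with 3D coordinates, draws
#' `Poisson(mean_count(z))` water oxygens placed uniformly inside the
#' first-shell sphere of radius `shell_radius_A` around the ion, plus
#' optional background waters placed uniformly in the bounding cylinder.
#' The Poisson draws are returned alongside as the ground truth for
#' oracle tests (background waters that happen to fall inside a shell are
#' not part of the truth).
#'
#' @param tracks an [ion_tracks()] table with finite `x_A`, `y_A`.
#' @param mean_count a function of z (angstrom) giving the expected
#'   first-shell count (>= 0), or a single number for a flat profile.
#' @param shell_radius_A placement radius in angstrom.
#' @param n_background background waters per frame.
#' @param seed RNG seed.
#' @param background_radius_A,background_z cylinder in which background
#'   waters are placed; default 12 A radius over the track z-range.
#' @return a list with `waters` (tibble: `time_ns`, `x_A`, `y_A`, `z_A`) and
#'   `truth` (tibble: `time_ns`, `ion_id`, `n_shell`).
#' @export
make_waters <- function(tracks, mean_count, shell_radius_A = 3.1,
                        n_background = 0, seed = 1,
                        background_radius_A = 12, background_z = NULL) {
  mfun <- if (is.function(mean_count)) mean_count else function(z) {
    rep(mean_count, length(z))
  }
  tab <- as_tibble(tracks)
  if (any(!is.finite(tab$x_A)) || any(!is.finite(tab$y_A))) {
    abort("make_waters needs 3D coordinates (finite x_A, y_A)")
  }
  mu <- mfun(tab$z_A)
  if (any(mu < 0)) abort("mean_count must be >= 0")
  zr <- background_z %||% range(tab$z_A)
  withr::with_seed(as.integer(seed), {
    n_shell <- rpois(nrow(tab), mu)
    total <- sum(n_shell)
    ## uniform points in the unit ball, scaled to the shell radius
    u <- runif(total)^(1 / 3) * shell_radius_A
    ct <- runif(total, -1, 1)
    ph <- runif(total, 0, 2 * pi)
    st <- sqrt(1 - ct^2)
    owner <- rep(seq_len(nrow(tab)), n_shell)
    shell <- tibble(
      time_ns = tab$time_ns[owner],
      x_A = tab$x_A[owner] + u * st * cos(ph),
      y_A = tab$y_A[owner] + u * st * sin(ph),
      z_A = tab$z_A[owner] + u * ct)
    bg <- NULL
    if (n_background > 0) {
      frames <- unique(tab$time_ns)
      nb <- n_background * length(frames)
      rb <- sqrt(runif(nb)) * background_radius_A
      tb <- runif(nb, 0, 2 * pi)
      bg <- tibble(
        time_ns = rep(frames, each = n_background),
        x_A = rb * cos(tb),
        y_A = rb * sin(tb),
        z_A = runif(nb, zr[1], zr[2]))
    }
    list(
      waters = dplyr::bind_rows(shell, bg) |>
        dplyr::arrange(.data$time_ns),
      truth = tibble(time_ns = tab$time_ns, ion_id = tab$ion_id,
                     n_shell = n_shell))
  })
}
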