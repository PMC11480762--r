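#' Potential of mean force by self-consistent WHAM
#'
#' Solves the standard weighted-histogram self-consistency equations on a
#' regular z grid, in kBT units:
#' `rho(z) = sum_i n_i(z) / sum_i N_i exp(f_i - w_i(z))` and
#' `f_i = -ln sum_z rho(z) exp(-w_i(z))`, with `w_i(z)` the harmonic window
#' bias. Iteration stops when the largest change of any window free energy
#' falls below `tol`; exceeding `max_iter` is reported as non-convergence,
#' never as silent success. The PMF is `-ln rho`, gauged to minimum zero.
#' Per-bin standard errors come from block analysis: each window's sample
#' series is cut into `n_blocks` contiguous blocks and WHAM is repeated per
#' block.
#'
#' @param windows a list of [umbrella_window()] objects (jointly covering
#'   the range, with overlapping neighbours).
#' @param bin_width_A histogram bin width, angstrom (default 0.25, matching
#'   the usual window spacing).
#' @param tol convergence tolerance on the window free energies, kBT.
#' @param max_iter maximum number of iterations.
#' @param n_blocks blocks for the error analysis; 0 skips it.
#' @return an object of class `pmf_profile`: tibble with `z_A`, `pmf_kbt`,
#'   `se_kbt`, plus attributes `iterations`, `residual`, `converged`,
#'   `residual_trace`, `window_f_kbt`.
#' @export
wham <- function(windows, bin_width_A = 0.25, tol = 1e-6, max_iter = 1e5,
                 n_blocks = 5) {
  stopifnot(length(windows) >= 1)
  temperature_K <- windows[[1]]$temperature_K
  zr <- range(unlist(lapply(windows, function(w) range(w$samples))))
  edges <- seq(zr[1] - 1e-9, zr[2] + bin_width_A, by = bin_width_A)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  core <- wham_core(windows, edges, mids, tol, max_iter, temperature_K)
  se <- rep(NA_real_, length(mids))
  if (n_blocks >= 2) {
    block_pmfs <- lapply(seq_len(n_blocks), function(b) {
      wb <- lapply(windows, function(w) {
        n <- length(w$samples)
        len <- n %/% n_blocks
        if (len < 1) abort("fewer samples than blocks in a window")
        idx <- ((b - 1) * len + 1):(b * len)
        umbrella_window(w$center, w$k_spring, w$samples[idx],
                        w$temperature_K, w$dt_ns)
      })
      wham_core(wb, edges, mids, tol * 10, max_iter, temperature_K)$pmf
    })
    bm <- do.call(cbind, block_pmfs)
    ## gauge-align each block PMF to the full one on shared finite bins
    for (b in seq_len(n_blocks)) {
      ok <- is.finite(bm[, b]) & is.finite(core$pmf)
      bm[, b] <- bm[, b] - mean(bm[ok, b] - core$pmf[ok])
    }
    se <- apply(bm, 1, function(v) {
      v <- v[is.finite(v)]
      if (length(v) >= 2) sd(v) / sqrt(length(v)) else NA_real_
    })
  }
  structure(
    tibble(z_A = mids, pmf_kbt = core$pmf, se_kbt = se),
    iterations = core$iterations, residual = core$residual,
    converged = core$converged, residual_trace = core$residual_trace,
    window_f_kbt = core$f, bin_width_A = bin_width_A,
    temperature_K = temperature_K,
    class = c("pmf_profile", class(tibble())))
}

wham_core <- function(windows, edges, mids, tol, max_iter, temperature_K) {
  n_win <- length(windows)
  n_bin <- length(mids)
  counts <- vapply(windows, function(w) {
    as.numeric(table(cut(w$samples, edges)))
  }, numeric(n_bin))
  n_tot_bin <- rowSums(counts)
  n_i <- vapply(windows, function(w) length(w$samples), numeric(1))
  ## bias energies w_i(z) in kBT at the bin centres
  bias <- vapply(windows, function(w) {
    0.5 * spring_kbt_per_A2(w$k_spring, temperature_K) *
      (mids - w$center)^2
  }, numeric(n_bin))
  ## coverage check: every bin between the outermost window centres must be
  ## sampled, otherwise neighbouring windows cannot be stitched together
  centers <- range(vapply(windows, function(w) w$center, numeric(1)))
  interior <- which(mids >= centers[1] & mids <= centers[2] & n_tot_bin > 0)
  gap <- if (length(interior) > 1) {
    setdiff(seq(min(interior), max(interior)),
            which(n_tot_bin > 0))
  } else integer()
  if (length(gap) > 0) {
    warn(sprintf("unsampled interior bins near z = %.2f A; windows may not overlap",
                 mids[gap[1]]))
  }
  f <- numeric(n_win)
  resid <- Inf
  trace <- numeric(0)
  it <- 0L
  while (it < max_iter && resid >= tol) {
    it <- it + 1L
    ## denominator: sum_i N_i exp(f_i - w_i(z)) per bin
    denom <- exp(sweep(-bias, 2, f + log(n_i), "+"))
    rho <- n_tot_bin / rowSums(denom)
    rho[!is.finite(rho)] <- 0
    f_new <- -log(colSums(rho * exp(-bias)))
    f_new <- f_new - f_new[1]
    resid <- max(abs(f_new - f))
    trace <- c(trace, resid)
    f <- f_new
  }
  denom <- exp(sweep(-bias, 2, f + log(n_i), "+"))
  rho <- n_tot_bin / rowSums(denom)
  pmf <- -log(rho)
  pmf[!is.finite(pmf)] <- NA_real_
  pmf <- pmf - min(pmf, na.rm = TRUE)
  list(pmf = pmf, f = f, iterations = it, residual = resid,
       converged = resid < tol, residual_trace = trace)
}

#' Standard error of the mean by block analysis
#'
#' Cuts a (possibly autocorrelated) sample series into `n_blocks` contiguous
#' blocks (truncating the remainder) and returns the standard error of the
#' block means, `sd(block means) / sqrt(n_blocks)`.
#'
#' @param samples numeric vector.
#' @param n_blocks number of blocks (>= 2).
#' @return standard error (numeric scalar).
#' @export
block_error <- function(samples, n_blocks = 5) {
  if (n_blocks < 2) abort("n_blocks must be >= 2")
  if (length(samples) < n_blocks) abort("fewer samples than blocks")
  len <- length(samples) %/% n_blocks
  means <- vapply(seq_len(n_blocks), function(b) {
    mean(samples[((b - 1) * len + 1):(b * len)])
  }, numeric(1))
  sd(means) / sqrt(n_blocks)
}

#' Write a PMF profile as TSV
#'
#' @param pmf a [wham()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pmf <- function(pmf, path) {
  readr::write_tsv(as_tibble(pmf), path)
  invisible(path)
}
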