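## Independent oracles used across the suite. Each deliberately takes a
## different algorithmic route from the package implementation it checks.

## Brute-force permeation-event oracle: classifies every frame into a
## region index r = floor((z - z_sf)/L) + floor((z - z_gate)/L) computed on
## the continuous (pre-wrap) path. Even r values are bulk regions, odd are
## pore interiors; every -2 jump between successive bulk values is one
## inward traversal, every +2 jump one outward traversal.
oracle_events <- function(z, z_sf, z_gate, period = Inf) {
  L <- if (is.finite(period)) period else 1e9
  r <- floor((z - z_sf) / L) + floor((z - z_gate) / L)
  r <- r[c(TRUE, diff(r) != 0)] # compress consecutive duplicates
  bulk <- r[r %% 2 == 0]
  if (length(bulk) < 2) {
    return(data.frame(direction = character(), exit_step = integer()))
  }
  d <- diff(bulk) / 2
  dirs <- unlist(lapply(d, function(k) {
    if (k == 0) character() else rep(if (k < 0) "inward" else "outward",
                                     abs(k))
  }))
  data.frame(direction = dirs)
}

## Maximum-likelihood WHAM oracle: minimizes the histogram WHAM negative
## log-likelihood over the window free energies with BFGS, a different
## numerical route from the package's self-consistent iteration.
oracle_wham <- function(windows, bin_width = 0.25) {
  zr <- range(unlist(lapply(windows, function(w) range(w$samples))))
  edges <- seq(zr[1] - 1e-9, zr[2] + bin_width, by = bin_width)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  counts <- sapply(windows, function(w) {
    as.numeric(table(cut(w$samples, edges)))
  })
  m_b <- rowSums(counts)
  n_i <- sapply(windows, function(w) length(w$samples))
  bias <- sapply(windows, function(w) {
    0.5 * spring_kbt_per_A2(w$k_spring, w$temperature_K) *
      (mids - w$center)^2
  })
  obj <- function(fr) {
    f <- c(0, fr)
    lse <- apply(sweep(-bias, 2, f + log(n_i), "+"), 1, function(r) {
      m <- max(r)
      m + log(sum(exp(r - m)))
    })
    sum(m_b * lse) - sum(n_i * f)
  }
  op <- optim(numeric(length(windows) - 1), obj, method = "BFGS",
              control = list(maxit = 5000, reltol = 1e-13))
  f <- c(0, op$par)
  denom <- rowSums(exp(sweep(-bias, 2, f + log(n_i), "+")))
  pmf <- -log(m_b / denom)
  list(z = mids, pmf = pmf - min(pmf[is.finite(pmf)], na.rm = TRUE))
}

## Hand/brute-force mutual information over the joint histogram, nats of
## base 2, via explicit double loop.
oracle_mi_bits <- function(a, b) {
  ua <- unique(a)
  ub <- unique(b)
  n <- length(a)
  mi <- 0
  for (x in ua) for (y in ub) {
    pxy <- sum(a == x & b == y) / n
    if (pxy > 0) {
      mi <- mi + pxy * log2(pxy / ((sum(a == x) / n) * (sum(b == y) / n)))
    }
  }
  mi
}

## Naive per-frame occupancy scan (nearest ion inside the site interval).
oracle_occupancy <- function(tracks, z_lo, z_hi) {
  tab <- as.data.frame(tracks)
  times <- sort(unique(tab$time_ns))
  center <- (z_lo + z_hi) / 2
  vapply(times, function(tm) {
    fr <- tab[tab$time_ns == tm & tab$z_A >= z_lo & tab$z_A <= z_hi, ]
    if (nrow(fr) == 0) return(-1L)
    as.integer(fr$ion_id[which.min(abs(fr$z_A - center))])
  }, integer(1))
}

## Brute-force windowed conductance: explicit loop over window starts.
oracle_window_conductance <- function(t_exit, valence, t_total, voltage,
                                      window, stride) {
  starts <- seq(0, t_total - window, by = stride)
  cond <- sapply(starts, function(s) {
    n <- sum(t_exit >= s & t_exit < s + window) +
      if (s + window == t_total) sum(t_exit == t_total) else 0
    n * abs(valence) * 1.602176634e-19 / (window * 1e-9) /
      (abs(voltage) * 1e-3) * 1e12
  })
  list(mean = mean(cond), se = sd(cond) / sqrt(length(cond)))
}

## A quick random-walk ion_tracks builder used by several tests.
make_walk_tracks <- function(n_ions, n_frames, sd_step = 1.5, drift = 0,
                             z0_range = c(-30, 30), box = NULL, seed = 1) {
  withr::with_seed(seed, {
    tabs <- lapply(seq_len(n_ions) - 1L, function(id) {
      z <- cumsum(c(runif(1, z0_range[1], z0_range[2]),
                    rnorm(n_frames - 1, drift, sd_step)))
      tibble::tibble(
        time_ns = (seq_len(n_frames) - 1) * 0.1, ion_id = id,
        species = "Na", valence = 1L, z_A = z)
    })
  })
  truth <- dplyr::bind_rows(tabs)
  if (is.null(box)) {
    list(tracks = ion_tracks(truth), truth = truth)
  } else {
    wrapped <- dplyr::mutate(truth, z_A = wrap_z(z_A, -box / 2, box / 2))
    list(tracks = ion_tracks(wrapped, box_length_z = box, periodic = TRUE),
         truth = truth)
  }
}
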