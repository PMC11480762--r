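#' Define a binding site on the pore axis
#'
#' @param label site label (e.g. "EPV", "cavity").
#' @param z_range numeric length 2, the z interval in angstrom
#'   (`z_low < z_high`).
#' @param radial_cutoff_A optional radial cutoff; ions farther than this from
#'   the pore axis are not counted as occupying the site.
#' @return an object of class `binding_site`.
#' @export
binding_site <- function(label, z_range, radial_cutoff_A = NULL) {
  if (!(z_range[1] < z_range[2])) abort("need z_low < z_high")
  structure(list(label = label, z_range = z_range,
                 radial_cutoff_A = radial_cutoff_A),
            class = "binding_site")
}

#' Build a binding-site occupancy series from a trajectory
#'
#' Resamples the trajectory to the occupancy time step and records, per
#' frame, the id of the ion inside the site (vacancy = `-1`). When several
#' ions are inside, the tie is broken by proximity to the site's z centre
#' (`tie_break = "nearest"`) or by letting the incumbent keep the site
#' (`tie_break = "first"`).
#'
#' @param tracks an [ion_tracks()] table.
#' @param site a [binding_site()].
#' @param dt_ps occupancy time step in picoseconds (default 20); must be a
#'   multiple of the frame spacing (nearest-frame resampling is applied
#'   otherwise).
#' @param tie_break `"nearest"` or `"first"`.
#' @return an [occupancy_series()].
#' @export
build_occupancy <- function(tracks, site, dt_ps = 20,
                            tie_break = c("nearest", "first")) {
  tie_break <- match.arg(tie_break)
  tab <- as_tibble(unwrap_tracks(tracks))
  zr <- range(tab$z_A, na.rm = TRUE)
  if (site$z_range[1] > zr[2] || site$z_range[2] < zr[1]) {
    abort(sprintf("site '%s' lies outside the data z range", site$label))
  }
  dt_track_ps <- track_dt_ns(tracks) * 1e3
  stride <- max(1L, as.integer(round(dt_ps / dt_track_ps)))
  times <- sort(unique(tab$time_ns))
  times <- times[seq(1, length(times), by = stride)]
  tab <- tab[tab$time_ns %in% times, , drop = FALSE]
  center <- mean(site$z_range)
  inside <- tab$z_A >= site$z_range[1] & tab$z_A <= site$z_range[2]
  if (!is.null(site$radial_cutoff_A)) {
    r <- sqrt(tab$x_A^2 + tab$y_A^2)
    inside <- inside & !is.na(r) & r <= site$radial_cutoff_A
  }
  occ <- tab[which(inside), c("time_ns", "ion_id", "z_A")]
  occ$dist <- abs(occ$z_A - center)
  nearest <- occ |>
    dplyr::group_by(.data$time_ns) |>
    dplyr::slice_min(.data$dist, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  ids <- rep(-1L, length(times))
  ids[match(nearest$time_ns, times)] <- nearest$ion_id
  if (tie_break == "first") {
    ## the incumbent keeps the site while it remains inside
    by_frame <- split(occ$ion_id, factor(occ$time_ns, levels = times))
    current <- -1L
    for (i in seq_along(times)) {
      present <- by_frame[[i]]
      if (length(present) == 0) {
        current <- -1L
      } else if (!(current %in% present)) {
        current <- ids[i] # nearest ion becomes the new incumbent
      }
      ids[i] <- current
    }
  }
  occupancy_series(ids, dt_ps = stride * dt_track_ps, site = site$label)
}

#' Transition stream of an occupancy series
#'
#' Classifies every consecutive frame pair into one of five symbols:
#' `stay_vacant`, `stay_occupied` (same ion), `bind` (-1 to an ion id),
#' `release` (id to -1), `exchange` (one id to a different id).
#'
#' @param series an [occupancy_series()] (or bare integer id vector).
#' @return a factor of length `n_frames - 1` over the five-symbol alphabet.
#' @export
transition_stream <- function(series) {
  ids <- if (is.data.frame(series)) series$occupant_id else as.integer(series)
  if (length(ids) < 2) abort("need at least two frames")
  a <- ids[-length(ids)]
  b <- ids[-1]
  sym <- dplyr::case_when(
    a == -1L & b == -1L ~ "stay_vacant",
    a == b ~ "stay_occupied",
    a == -1L ~ "bind",
    b == -1L ~ "release",
    TRUE ~ "exchange")
  factor(sym, levels = c("stay_vacant", "stay_occupied", "bind", "release",
                         "exchange"))
}

#' Plug-in mutual information between two discrete streams, in bits
#'
#' `I(A;B) = sum p(a,b) log2[p(a,b) / (p(a) p(b))]` over the joint empirical
#' distribution; symmetric and non-negative.
#'
#' @param stream_a,stream_b equal-length factors or vectors.
#' @return mutual information in bits.
#' @export
ssi_bits <- function(stream_a, stream_b) {
  if (length(stream_a) != length(stream_b)) {
    abort("streams must have equal length")
  }
  a <- as.integer(factor(stream_a))
  b <- as.integer(factor(stream_b))
  na <- max(a)
  joint <- tabulate(a + na * (b - 1L), nbins = na * max(b))
  n <- length(a)
  p <- joint / n
  pa <- tabulate(a, nbins = na) / n
  pb <- tabulate(b, nbins = max(b)) / n
  pp <- outer(pa, pb)[joint > 0]
  p <- p[joint > 0]
  sum(p * log2(p / pp))
}

## Shannon entropy of a stream, bits
stream_entropy_bits <- function(stream) {
  p <- table(stream)
  p <- p[p > 0] / length(stream)
  -sum(p * log2(p))
}

#' Statistical noise threshold for the SSI estimate
#'
#' Mutual information estimated from finite streams is positively biased
#' even for independent inputs. The threshold is the given quantile of
#' [ssi_bits()] over surrogate pairs in which one stream is circularly
#' shifted by a random offset: the shift destroys cross-correlation while
#' preserving each stream's marginal distribution and autocorrelation.
#'
#' @param stream_a,stream_b equal-length streams.
#' @param n_shuffles number of surrogate shifts (>= 10).
#' @param quantile_p quantile of the null distribution (default 0.95).
#' @param seed RNG seed.
#' @return threshold in bits (0 for zero-entropy streams).
#' @export
noise_threshold <- function(stream_a, stream_b, n_shuffles = 100,
                            quantile_p = 0.95, seed = 1) {
  if (n_shuffles < 10) abort("n_shuffles must be >= 10")
  if (stream_entropy_bits(stream_a) == 0 ||
      stream_entropy_bits(stream_b) == 0) {
    return(0)
  }
  n <- length(stream_b)
  withr::with_seed(as.integer(seed), {
    offs <- sample.int(n - 1L, n_shuffles, replace = TRUE)
    null_mi <- vapply(offs, function(k) {
      shifted <- c(stream_b[(k + 1):n], stream_b[1:k])
      ssi_bits(stream_a, shifted)
    }, numeric(1))
  })
  as.numeric(quantile(null_mi, quantile_p))
}

#' Excess state-specific information between two binding sites
#'
#' Full cooperativity pipeline: build occupancy series at the two sites,
#' reduce them to transition streams, compute the plug-in mutual information
#' (SSI) and subtract the shuffle-derived noise threshold, clipping at zero.
#' With a list of replica trajectories, per-replica values plus their mean
#' and standard error are reported; with a single replica the SE is `NA` and
#' flagged.
#'
#' @param tracks an [ion_tracks()] table, or a list of them (replicas).
#' @param site_a,site_b [binding_site()] definitions.
#' @param dt_ps occupancy time step, ps.
#' @param n_shuffles,quantile_p,seed noise-threshold settings, see
#'   [noise_threshold()].
#' @param tie_break occupancy tie-break rule, see [build_occupancy()].
#' @return an object of class `ssi_result`.
#' @export
excess_ssi <- function(tracks, site_a, site_b, dt_ps = 20, n_shuffles = 100,
                       quantile_p = 0.95, seed = 1,
                       tie_break = "nearest") {
  replicas <- if (inherits(tracks, "ion_tracks")) list(tracks) else tracks
  per_rep <- purrr::imap(replicas, function(tr, i) {
    occ_a <- build_occupancy(tr, site_a, dt_ps, tie_break)
    occ_b <- build_occupancy(tr, site_b, dt_ps, tie_break)
    exssi_from_occupancy(occ_a, occ_b, n_shuffles, quantile_p,
                         seed = as.integer(seed) + i - 1L)
  })
  combine_ssi(per_rep)
}

#' Excess SSI from ready-made occupancy series
#'
#' @param occ_a,occ_b [occupancy_series()] objects (or a list of such pairs
#'   passed as `occ_a`, for replicas).
#' @inheritParams excess_ssi
#' @return an object of class `ssi_result`.
#' @export
exssi_from_occupancy <- function(occ_a, occ_b = NULL, n_shuffles = 100,
                                 quantile_p = 0.95, seed = 1) {
  if (is.null(occ_b)) { # list of replica pairs
    per_rep <- purrr::imap(occ_a, function(pair, i) {
      exssi_from_occupancy(pair[[1]], pair[[2]], n_shuffles, quantile_p,
                           seed = as.integer(seed) + i - 1L)
    })
    return(combine_ssi(per_rep))
  }
  sa <- transition_stream(occ_a)
  sb <- transition_stream(occ_b)
  ssi <- ssi_bits(sa, sb)
  thr <- noise_threshold(sa, sb, n_shuffles, quantile_p, seed)
  structure(
    list(ssi_bits = ssi, noise_threshold_bits = thr,
         exssi_bits = max(ssi - thr, 0), n_frames = length(sa) + 1L,
         n_shuffles = n_shuffles, quantile_p = quantile_p, seed = seed,
         n_replicas = 1L, se_bits = NA_real_, single_replica = TRUE,
         replica_exssi_bits = max(ssi - thr, 0)),
    class = "ssi_result")
}

combine_ssi <- function(per_rep) {
  if (length(per_rep) == 1) return(per_rep[[1]])
  ex <- vapply(per_rep, function(r) r$exssi_bits, numeric(1))
  structure(
    list(ssi_bits = mean(vapply(per_rep, function(r) r$ssi_bits, numeric(1))),
         noise_threshold_bits =
           mean(vapply(per_rep, function(r) r$noise_threshold_bits,
                       numeric(1))),
         exssi_bits = mean(ex),
         n_frames = sum(vapply(per_rep, function(r) r$n_frames, numeric(1))),
         n_shuffles = per_rep[[1]]$n_shuffles,
         quantile_p = per_rep[[1]]$quantile_p, seed = per_rep[[1]]$seed,
         n_replicas = length(per_rep),
         se_bits = sd(ex) / sqrt(length(ex)), single_replica = FALSE,
         replica_exssi_bits = ex),
    class = "ssi_result")
}

#' @export
print.ssi_result <- function(x, ...) {
  cat(sprintf(
    "<ssi_result> SSI %.4f bits, noise threshold %.4f, exSSI %.4f%s (%d frames)\n",
    x$ssi_bits, x$noise_threshold_bits, x$exssi_bits,
    if (x$single_replica) " [single replica: SE undefined]"
    else sprintf(" +/- %.4f (n = %d)", x$se_bits, x$n_replicas),
    as.integer(x$n_frames)))
  invisible(x)
}

#' Write an occupancy series as TSV
#'
#' @param series an [occupancy_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_occupancy <- function(series, path) {
  readr::write_tsv(
    tibble(frame = series$frame, site = attr(series, "site"),
           occupant_id = series$occupant_id),
    path)
  invisible(path)
}
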