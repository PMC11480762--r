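#' Pore geometry: the two constriction planes
#'
#' The pore is the region between the two constrictions of the channel: the
#' selectivity-filter plane (`z_sf`, upper) and the intracellular gate plane
#' (`z_gate`, lower), with z = 0 at the membrane centre and positive z
#' pointing extracellular.
#'
#' @param z_sf axial position of the selectivity-filter constriction, angstrom.
#' @param z_gate axial position of the intracellular gate constriction.
#' @param pore_radius radial bound for being "in the pore", angstrom.
#' @return an object of class `pore_geometry`.
#' @export
pore_geometry <- function(z_sf, z_gate, pore_radius = 8) {
  if (!(z_gate < z_sf)) abort("need z_gate < z_sf")
  if (pore_radius <= 0) abort("pore_radius must be > 0")
  structure(list(z_sf = z_sf, z_gate = z_gate, pore_radius = pore_radius),
            class = "pore_geometry")
}

## linear-interpolated crossing time of `plane` on the segment (t1,z1)-(t2,z2)
crossing_time <- function(t1, t2, z1, z2, plane) {
  t1 + (plane - z1) / (z2 - z1) * (t2 - t1)
}

## Enumerate, for one ion's continuous path, every crossing of the plane
## family {plane + k * period}: returns image index k, direction (+1 up /
## -1 down) and interpolated time, ordered along the path.
plane_crossings <- function(tt, zz, plane, period) {
  n <- length(zz)
  z1 <- zz[-n]; z2 <- zz[-1]
  lo <- pmin(z1, z2); hi <- pmax(z1, z2)
  if (is.finite(period)) {
    k_lo <- ceiling((lo - plane) / period)
    k_hi <- floor((hi - plane) / period)
  } else {
    k_lo <- ifelse(lo <= plane & hi >= plane, 0L, 1L)
    k_hi <- ifelse(lo <= plane & hi >= plane, 0L, 0L)
  }
  seg <- which(k_hi >= k_lo)
  if (length(seg) == 0) {
    return(tibble(image = integer(), dir = integer(), time = numeric()))
  }
  out <- lapply(seg, function(i) {
    ks <- k_lo[i]:k_hi[i]
    pl <- plane + if (is.finite(period)) ks * period else 0
    ## exclude crossings where the segment merely starts on the plane
    keep <- (z1[i] - pl) * (z2[i] - pl) < 0 | z2[i] == pl
    ks <- ks[keep]; pl <- pl[keep]
    if (length(ks) == 0) return(NULL)
    tibble(image = as.integer(ks),
           dir = ifelse(z2[i] > z1[i], 1L, -1L),
           time = crossing_time(tt[i], tt[i + 1L], z1[i], z2[i], pl))
  })
  dplyr::bind_rows(out) |> dplyr::arrange(.data$time)
}

#' Detect complete permeation events
#'
#' An inward event is one complete traversal: the ion's continuous z path
#' crosses the selectivity-filter plane downward and subsequently crosses the
#' gate plane downward without first returning past the filter plane;
#' mirrored for outward events. Each traversal yields exactly one event and
#' events are disjoint in time per ion. Wrapped periodic coordinates are
#' unwrapped first; under a sustained driving force an ion can traverse the
#' pore repeatedly through its periodic images, so crossings are counted
#' against the full periodic family of constriction planes. Entry and exit
#' times are linearly interpolated between the frames flanking each plane
#' crossing.
#'
#' @param tracks an [ion_tracks()] table.
#' @param geometry a [pore_geometry()].
#' @return a tibble with one row per event: `ion_id`, `species`, `valence`,
#'   `direction` ("inward"/"outward"), `t_enter_ns`, `t_exit_ns`.
#' @export
detect_events <- function(tracks, geometry) {
  stopifnot(inherits(geometry, "pore_geometry"))
  meta <- track_meta(tracks)
  period <- if (meta$periodic) meta$box_length_z else Inf
  tracks <- unwrap_tracks(tracks)
  zr <- range(tracks$z_A, na.rm = TRUE)
  if (!is.finite(period) &&
      (geometry$z_sf <= zr[1] || geometry$z_gate >= zr[2])) {
    abort("geometry planes fall outside the z range of the data")
  }
  per_ion <- function(df) {
    df <- df[!is.na(df$z_A), , drop = FALSE]
    if (nrow(df) < 2) return(NULL)
    tt <- df$time_ns
    zz <- df$z_A
    cr <- dplyr::bind_rows(
      plane_crossings(tt, zz, geometry$z_sf, period) |>
        dplyr::mutate(plane = "sf"),
      plane_crossings(tt, zz, geometry$z_gate, period) |>
        dplyr::mutate(plane = "gate")) |>
      dplyr::arrange(.data$time)
    if (nrow(cr) == 0) return(NULL)
    pending_in <- list() # image -> time of last downward filter crossing
    pending_out <- list() # image -> time of last upward gate crossing
    out <- list()
    for (i in seq_len(nrow(cr))) {
      key <- as.character(cr$image[i])
      tm <- cr$time[i]
      if (cr$plane[i] == "sf") {
        if (cr$dir[i] < 0) { # filter crossed downward: inward attempt
          pending_in[[key]] <- tm
          pending_out[[key]] <- NULL
        } else { # filter crossed upward
          if (!is.null(pending_out[[key]])) { # completes an outward event
            out[[length(out) + 1]] <- c(pending_out[[key]], tm, 1)
            pending_out[[key]] <- NULL
          }
          pending_in[[key]] <- NULL
        }
      } else {
        if (cr$dir[i] > 0) { # gate crossed upward: outward attempt
          pending_out[[key]] <- tm
          pending_in[[key]] <- NULL
        } else { # gate crossed downward
          if (!is.null(pending_in[[key]])) { # completes an inward event
            out[[length(out) + 1]] <- c(pending_in[[key]], tm, -1)
            pending_in[[key]] <- NULL
          }
          pending_out[[key]] <- NULL
        }
      }
    }
    if (length(out) == 0) return(NULL)
    ev <- do.call(rbind, out)
    tibble(
      ion_id = df$ion_id[1], species = df$species[1],
      valence = df$valence[1],
      direction = ifelse(ev[, 3] < 0, "inward", "outward"),
      t_enter_ns = ev[, 1], t_exit_ns = ev[, 2])
  }
  events <- as_tibble(tracks) |>
    dplyr::arrange(.data$ion_id, .data$time_ns) |>
    dplyr::group_by(.data$ion_id) |>
    dplyr::group_map(~ per_ion(.x |> dplyr::mutate(ion_id = .y$ion_id))) |>
    dplyr::bind_rows()
  if (nrow(events) == 0) {
    events <- tibble(ion_id = integer(), species = character(),
                     valence = integer(), direction = character(),
                     t_enter_ns = numeric(), t_exit_ns = numeric())
  }
  dplyr::arrange(events, .data$t_exit_ns)
}

#' Total conductance from a permeation-event count
#'
#' Single-channel conductance from counting: `C = Np * |q| * e / (t * |V|)`,
#' with `Np` the number of complete permeation events, `q` the carrier
#' valence, `t` the aggregated trajectory time and `V` the transmembrane
#' voltage; returned in picosiemens. The reported value is positive for
#' carriers moving with the electrochemical driving force and negated for
#' opposing carriers (e.g. anion leak against the cation-inward convention).
#'
#' @param n_events number of permeation events (>= 0).
#' @param valence carrier valence in elementary charges (sign ignored).
#' @param t_total_ns aggregated trajectory time in ns (> 0). For
#'   double-membrane computational-electrophysiology setups this counts both
#'   channels (replicas x length x 2).
#' @param voltage_mV transmembrane voltage in mV (non-zero).
#' @param opposing logical; `TRUE` negates the contribution.
#' @return conductance in pS (numeric scalar, unrounded).
#' @export
conductance_total <- function(n_events, valence, t_total_ns, voltage_mV,
                              opposing = FALSE) {
  if (t_total_ns <= 0) abort("t_total_ns must be > 0")
  if (voltage_mV == 0) {
    abort("conductance is undefined at 0 mV; report event counts only")
  }
  if (n_events < 0) abort("n_events must be >= 0")
  amps <- n_events * abs(valence) * E_CHARGE_C / (t_total_ns * 1e-9)
  ps <- amps / (abs(voltage_mV) * 1e-3) * 1e12
  if (opposing) -ps else ps
}

#' Windowed conductance estimate
#'
#' Applies the counting formula in overlapping time windows (events assigned
#' to a window by their exit time) and reports the mean and standard error
#' over windows.
#'
#' @param events event table from [detect_events()] (or any tibble with
#'   `t_exit_ns` and `valence`).
#' @param t_total_ns total trajectory time in ns (windows tile `[0,
#'   t_total_ns]`).
#' @param voltage_mV transmembrane voltage, mV (non-zero).
#' @param window_ns window length, ns (default 50).
#' @param stride_ns window stride, ns (default `window_ns / 2`, i.e.
#'   overlapping windows).
#' @param valence carrier valence; defaults to the common valence of
#'   `events`.
#' @param channels number of channels the trajectory time already aggregates
#'   (events are pooled; per-window time is `window_ns * channels`).
#' @return an object of class `conductance_estimate`.
#' @export
conductance_windows <- function(events, t_total_ns, voltage_mV,
                                window_ns = 50, stride_ns = window_ns / 2,
                                valence = NULL, channels = 1) {
  if (window_ns > t_total_ns) abort("window_ns must not exceed t_total_ns")
  if (voltage_mV == 0) abort("conductance is undefined at 0 mV")
  if (is.null(valence)) {
    valence <- if (nrow(events) > 0) {
      v <- unique(abs(events$valence))
      if (length(v) > 1) abort("mixed valences; pass `valence` explicitly")
      v
    } else 1
  }
  starts <- seq(0, t_total_ns - window_ns, by = stride_ns)
  if (length(starts) == 0) abort("no complete windows fit in t_total_ns")
  n_w <- vapply(starts, function(s) {
    sum(events$t_exit_ns >= s & events$t_exit_ns < s + window_ns)
  }, numeric(1))
  ## last window is closed on the right so the final event is not dropped
  n_w[length(n_w)] <- n_w[length(n_w)] +
    sum(events$t_exit_ns == t_total_ns)
  cond <- vapply(n_w, conductance_total, numeric(1), valence = valence,
                 t_total_ns = window_ns * channels, voltage_mV = voltage_mV)
  structure(
    list(mean_pS = mean(cond),
         se_pS = if (length(cond) > 1) sd(cond) / sqrt(length(cond)) else 0,
         n_events = nrow(events), t_total_ns = t_total_ns,
         voltage_mV = voltage_mV, window_ns = window_ns,
         stride_ns = stride_ns, n_windows = length(cond),
         window_conductance_pS = cond),
    class = "conductance_estimate")
}

#' @export
print.conductance_estimate <- function(x, ...) {
  cat(sprintf(
    "<conductance_estimate> %.2f +/- %.2f pS (%d events, %g ns, %g mV, %g ns windows)\n",
    x$mean_pS, x$se_pS, x$n_events, x$t_total_ns, x$voltage_mV, x$window_ns))
  invisible(x)
}

#' Selectivity ratio from permeation-event totals
#'
#' Ratio of total permeation-event counts of two species under the same
#' condition (e.g. P_Na/P_Ca). A zero denominator with a positive numerator
#' yields the `Inf` sentinel; 0/0 is undefined (`NaN`).
#'
#' @param events_a,events_b event tables (or bare counts) for the numerator
#'   and denominator species.
#' @return a tibble of class `selectivity_ratio` with `numerator_count`,
#'   `denominator_count`, `ratio`.
#' @export
selectivity_ratio <- function(events_a, events_b) {
  n_a <- if (is.data.frame(events_a)) nrow(events_a) else as.numeric(events_a)
  n_b <- if (is.data.frame(events_b)) nrow(events_b) else as.numeric(events_b)
  if (n_a < 0 || n_b < 0) abort("counts must be >= 0")
  ratio <- if (n_b > 0) n_a / n_b else if (n_a > 0) Inf else NaN
  structure(
    tibble(numerator_count = n_a, denominator_count = n_b, ratio = ratio),
    class = c("selectivity_ratio", class(tibble())))
}
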