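#' Per-ion trajectory table
#'
#' The central data structure: one row per (frame, ion) with the ion's axial
#' position along the pore axis (z, in angstrom; positive values point to the
#' extracellular side, z = 0 is the membrane centre) and optional transverse
#' coordinates. Metadata that applies to the whole trajectory (periodic box
#' length, transmembrane voltage, temperature, label, replica) is carried as
#' attributes so the table itself stays a plain tibble.
#'
#' @param data a data frame with columns `time_ns`, `ion_id`, `species`,
#'   `valence`, `z_A` and optionally `x_A`, `y_A`. Missing positions are
#'   encoded as `NA`.
#' @param box_length_z periodic box length along z in angstrom, or `NA` for
#'   non-periodic data.
#' @param periodic logical; are z coordinates wrapped into the box?
#' @param voltage_mV transmembrane voltage in millivolts (negative =
#'   intracellular side negative).
#' @param temperature_K simulation temperature in kelvin.
#' @param label free-text condition label.
#' @param replica integer replica id.
#' @return a tibble of class `ion_tracks`.
#' @export
ion_tracks <- function(data, box_length_z = NA_real_, periodic = FALSE,
                       voltage_mV = 0, temperature_K = 310,
                       label = "", replica = 1L) {
  data <- as_tibble(data)
  required <- c("time_ns", "ion_id", "species", "valence", "z_A")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("ion_tracks is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"x_A" %in% names(data)) data$x_A <- NA_real_
  if (!"y_A" %in% names(data)) data$y_A <- NA_real_
  data$ion_id <- as.integer(data$ion_id)
  data$valence <- as.integer(data$valence)
  data$species <- as.character(data$species)
  for (col in c("time_ns", "x_A", "y_A", "z_A")) {
    data[[col]] <- as.numeric(data[[col]])
  }
  data <- data[, c("time_ns", "ion_id", "species", "valence",
                   "x_A", "y_A", "z_A")]
  data <- dplyr::arrange(data, .data$time_ns, .data$ion_id)
  validate_track_times(data)
  dup <- duplicated(data[, c("time_ns", "ion_id")])
  if (any(dup)) {
    i <- which(dup)[1]
    abort(sprintf(
      "duplicate (time, ion) record: ion %d at time %.6f ns (row %d)",
      data$ion_id[i], data$time_ns[i], i))
  }
  if (!is.finite(temperature_K) || temperature_K <= 0) {
    abort("temperature_K must be positive")
  }
  if (!is.finite(voltage_mV)) abort("voltage_mV must be finite")
  structure(
    data,
    box_length_z = box_length_z,
    periodic = isTRUE(periodic),
    voltage_mV = voltage_mV,
    temperature_K = temperature_K,
    label = label,
    replica = as.integer(replica),
    class = c("ion_tracks", class(tibble())))
}

validate_track_times <- function(data, tol = 1e-6) {
  times <- sort(unique(data$time_ns))
  if (length(times) >= 2) {
    dt <- diff(times)
    if (any(dt <= 0)) abort("frame times must be strictly increasing")
    if (diff(range(dt)) > tol) {
      abort(sprintf(
        "frame times must be uniformly spaced (spread %.3g ns > %.1g ns)",
        diff(range(dt)), tol))
    }
  }
  invisible(times)
}

#' @export
print.ion_tracks <- function(x, ...) {
  meta <- track_meta(x)
  cat(sprintf(
    "<ion_tracks> %d frames x %d ions, %s mV, %s K%s\n",
    dplyr::n_distinct(x$time_ns), dplyr::n_distinct(x$ion_id),
    format(meta$voltage_mV), format(meta$temperature_K),
    if (meta$periodic) sprintf(", periodic box %.6g A", meta$box_length_z) else ""))
  NextMethod()
}

#' Trajectory metadata
#'
#' @param tracks an [ion_tracks()] table.
#' @return a list with `box_length_z`, `periodic`, `voltage_mV`,
#'   `temperature_K`, `label`, `replica`.
#' @export
track_meta <- function(tracks) {
  list(
    box_length_z = attr(tracks, "box_length_z") %||% NA_real_,
    periodic = attr(tracks, "periodic") %||% FALSE,
    voltage_mV = attr(tracks, "voltage_mV") %||% 0,
    temperature_K = attr(tracks, "temperature_K") %||% 310,
    label = attr(tracks, "label") %||% "",
    replica = attr(tracks, "replica") %||% 1L)
}

#' Sampling interval of a trajectory in nanoseconds
#'
#' @param tracks an [ion_tracks()] table.
#' @return the (uniform) frame spacing in ns.
#' @export
track_dt_ns <- function(tracks) {
  times <- sort(unique(tracks$time_ns))
  if (length(times) < 2) abort("need at least two frames")
  mean(diff(times))
}

#' Total trajectory length in nanoseconds
#'
#' Last minus first frame time; the `t_traj` entering conductance estimates.
#'
#' @param tracks an [ion_tracks()] table.
#' @return trajectory length in ns.
#' @export
track_length_ns <- function(tracks) {
  diff(range(tracks$time_ns))
}

#' Write / read trajectory tables
#'
#' Trajectories are stored as a TSV (columns `time_ns`, `ion_id`, `species`,
#' `valence`, `x_A`, `y_A`, `z_A`) plus a JSON metadata sidecar
#' (`<path>.meta.json`) carrying the box length, periodicity, voltage,
#' temperature, label and replica. The pair round-trips through
#' [read_tracks()] field by field.
#'
#' @param tracks an [ion_tracks()] table.
#' @param path TSV file path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  meta <- track_meta(tracks)
  readr::write_tsv(as_tibble(tracks), path)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".meta.json")

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  data <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  known <- c("time_ns", "ion_id", "species", "valence", "x_A", "y_A", "z_A")
  extra <- setdiff(names(data), known)
  if (length(extra) > 0) {
    abort(paste0("unknown column(s) in trajectory file: ",
                 paste(extra, collapse = ", ")))
  }
  meta <- list()
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  }
  ion_tracks(
    data,
    box_length_z = meta$box_length_z %||% NA_real_,
    periodic = meta$periodic %||% FALSE,
    voltage_mV = meta$voltage_mV %||% 0,
    temperature_K = meta$temperature_K %||% 310,
    label = meta$label %||% "",
    replica = meta$replica %||% 1L)
}

#' Unwrap a periodically wrapped coordinate series
#'
#' Reconstructs a continuous trajectory from coordinates wrapped into a
#' periodic box by applying the minimum-image convention to successive
#' displacements. A true single-step displacement of half the box length or
#' more is not recoverable; steps whose minimum-image displacement comes
#' within `ambiguous_frac` of box/2 are flagged in the `"ambiguous_steps"`
#' attribute rather than silently unwrapped.
#'
#' @param z numeric vector of wrapped coordinates (one ion, time-ordered).
#' @param box_length_z periodic box length (> 0).
#' @param ambiguous_frac fraction of box/2 beyond which a displacement is
#'   flagged as possibly aliased.
#' @return the continuous series, same length as `z`, starting at `z[1]`.
#' @export
unwrap_z <- function(z, box_length_z, ambiguous_frac = 0.9) {
  if (!is.finite(box_length_z) || box_length_z <= 0) {
    abort("box_length_z must be positive")
  }
  if (length(z) < 2) return(z)
  dz <- diff(z)
  dz <- dz - box_length_z * round(dz / box_length_z)
  amb <- which(abs(dz) >= ambiguous_frac * box_length_z / 2)
  out <- z[1] + c(0, cumsum(dz))
  if (length(amb) > 0) {
    warn(sprintf(
      "%d step(s) approach half the box length; unwrapping may alias them",
      length(amb)))
  }
  attr(out, "ambiguous_steps") <- amb
  out
}

#' Wrap a coordinate into a periodic interval
#'
#' @param z numeric vector.
#' @param z_min,z_max interval bounds; length `z_max - z_min` is the box.
#' @return wrapped values in `[z_min, z_max)`.
#' @export
wrap_z <- function(z, z_min, z_max) {
  z_min + (z - z_min) %% (z_max - z_min)
}

#' Unwrap every ion in a trajectory table
#'
#' @param tracks an [ion_tracks()] table with the periodic flag set.
#' @return the same table with continuous `z_A` and the periodic flag cleared.
#' @export
unwrap_tracks <- function(tracks) {
  meta <- track_meta(tracks)
  if (!meta$periodic) return(tracks)
  if (!is.finite(meta$box_length_z)) {
    abort("periodic tracks need a finite box_length_z to unwrap")
  }
  out <- as_tibble(tracks) |>
    dplyr::group_by(.data$ion_id) |>
    dplyr::arrange(.data$time_ns, .by_group = TRUE) |>
    dplyr::mutate(z_A = as.numeric(unwrap_z(.data$z_A, meta$box_length_z))) |>
    dplyr::ungroup()
  ion_tracks(out, box_length_z = meta$box_length_z, periodic = FALSE,
             voltage_mV = meta$voltage_mV, temperature_K = meta$temperature_K,
             label = meta$label, replica = meta$replica)
}
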