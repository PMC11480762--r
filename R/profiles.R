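#' Gaussian smoothing of a regularly sampled series
#'
#' Discrete Gaussian filter with reflected boundaries, matching the standard
#' array-filter convention (kernel truncated at `truncate` standard
#' deviations). `sigma = 0` returns the input unchanged.
#'
#' @param x numeric vector.
#' @param sigma kernel standard deviation in samples (bins).
#' @param truncate kernel half-width in standard deviations.
#' @return smoothed vector, same length as `x`.
#' @export
gaussian_smooth <- function(x, sigma = 2, truncate = 4) {
  if (sigma <= 0) return(x)
  r <- as.integer(truncate * sigma + 0.5)
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- k / sum(k)
  n <- length(x)
  if (n == 1) return(x)
  ## reflect-pad: (... c b a | a b c ... ) on both ends
  idx <- c(rev(seq_len(min(r, n))), seq_len(n),
           n + 1 - rev(seq_len(min(r, n))))
  while (length(idx) < n + 2 * r) { # r wider than the series: keep reflecting
    idx <- c(rev(idx[seq_len(min(r, length(idx)))]), idx)
    idx <- idx[seq_len(n + 2 * r)]
  }
  xp <- x[idx[seq_len(n + 2 * r)]]
  as.numeric(stats::convolve(xp, rev(k), type = "filter"))
}

#' Axial ion density profile
#'
#' Histogram of per-frame z positions along the pore axis, per species.
#'
#' @param tracks an [ion_tracks()] table.
#' @param z_range numeric length 2; defaults to the data range.
#' @param bin_width_A bin width in angstrom (default 0.5).
#' @param species optional character vector restricting the species.
#' @param permeants_only if `TRUE`, keep only ions that complete at least one
#'   permeation event (requires `geometry`).
#' @param geometry a [pore_geometry()], needed for `permeants_only`.
#' @return a tibble of class `density_profile` with columns `z_A` (bin
#'   centre), `species`, `count`; bin edges in the `"edges"` attribute.
#' @export
axial_density <- function(tracks, z_range = NULL, bin_width_A = 0.5,
                          species = NULL, permeants_only = FALSE,
                          geometry = NULL) {
  if (bin_width_A <= 0) abort("bin_width_A must be > 0")
  tab <- as_tibble(unwrap_tracks(tracks))
  if (!is.null(species)) tab <- tab[tab$species %in% species, , drop = FALSE]
  if (permeants_only) {
    if (is.null(geometry)) abort("permeants_only requires a geometry")
    ev <- detect_events(tracks, geometry)
    keep <- unique(paste(ev$ion_id, ev$species))
    tab <- tab[paste(tab$ion_id, tab$species) %in% keep, , drop = FALSE]
  }
  tab <- tab[is.finite(tab$z_A), , drop = FALSE]
  zr <- z_range %||% range(tab$z_A)
  if (nrow(tab) == 0) {
    warn("empty selection: returning an empty density profile")
    zr <- z_range %||% c(0, bin_width_A)
  }
  edges <- seq(zr[1], zr[2] + bin_width_A * 0.999, by = bin_width_A)
  if (edges[length(edges)] < zr[2]) edges <- c(edges, edges[length(edges)] + bin_width_A)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  tab <- tab[tab$z_A >= edges[1] & tab$z_A <= edges[length(edges)], ,
             drop = FALSE]
  counts <- tab |>
    dplyr::mutate(bin = pmin(findInterval(.data$z_A, edges,
                                          rightmost.closed = TRUE),
                             length(mids))) |>
    dplyr::count(.data$species, .data$bin)
  grid <- tidyr::expand_grid(
    species = unique(tab$species) %||% character(),
    bin = seq_along(mids))
  out <- grid |>
    dplyr::left_join(counts, by = c("species", "bin")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$n, 0L),
                  z_A = mids[.data$bin]) |>
    dplyr::select("z_A", "species", "count") |>
    dplyr::arrange(.data$species, .data$z_A)
  structure(out, edges = edges, bin_width_A = bin_width_A,
            class = c("density_profile", class(tibble())))
}

#' Negative-log-density energy profile
#'
#' Estimates the (possibly nonequilibrium) energy surface experienced by the
#' ions as `E(z) = -ln n(z)` in kBT, after Gaussian smoothing of the counts,
#' gauged so that the minimum of each species' profile is zero. Minima
#' reflect binding sites; maxima indicate barriers. Bins with zero raw and
#' smoothed counts are masked rather than assigned `-ln 0`.
#'
#' @param profile a [axial_density()] result.
#' @param sigma_bins Gaussian smoothing sigma in bins (default 2).
#' @return a tibble of class `energy_profile` with columns `z_A`, `species`,
#'   `energy_kbt`, `mask` (`TRUE` = unsampled); sigma in the attributes.
#' @export
neg_log_density <- function(profile, sigma_bins = 2) {
  tab <- as_tibble(profile)
  if (all(tab$count == 0)) abort("all-zero density profile")
  out <- tab |>
    dplyr::group_by(.data$species) |>
    dplyr::arrange(.data$z_A, .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) {
      sm <- gaussian_smooth(df$count, sigma_bins)
      mask <- df$count == 0 | sm <= 0
      e <- rep(NA_real_, nrow(df))
      e[!mask] <- -log(sm[!mask])
      e[!mask] <- e[!mask] - min(e[!mask])
      tibble(z_A = df$z_A, energy_kbt = e, mask = mask)
    }) |>
    dplyr::ungroup() |>
    dplyr::select("z_A", "species", "energy_kbt", "mask")
  structure(out, sigma_bins = sigma_bins,
            bin_width_A = attr(profile, "bin_width_A"),
            class = c("energy_profile", class(tibble())))
}

#' Locate binding sites as minima of an energy profile
#'
#' A binding site is a local minimum of the smoothed negative-log-density
#' energy profile whose depth relative to the lower of its two flanking
#' maxima is at least `min_depth_kbt`. The extent is the z width over which
#' the energy stays within half the depth of the minimum.
#'
#' @param energy an [neg_log_density()] result.
#' @param min_depth_kbt minimum well depth in kBT (default 0.5).
#' @return a tibble with `species`, `z_min_A`, `depth_kbt`, `extent_A`,
#'   sorted by z within species; zero rows if no site qualifies.
#' @export
find_binding_sites <- function(energy, min_depth_kbt = 0.5) {
  tab <- as_tibble(energy)
  one_species <- function(df) {
    df <- df[!df$mask, , drop = FALSE]
    e <- df$energy_kbt
    z <- df$z_A
    n <- length(e)
    if (n < 3) return(NULL)
    out <- list()
    empty <- tibble(z_min_A = numeric(), depth_kbt = numeric(),
                    extent_A = numeric())
    for (i in 2:(n - 1)) {
      if (e[i] < e[i - 1] && e[i] <= e[i + 1]) {
        ## flanking maxima: highest point before the profile drops below e[i]
        left <- max(e[1:(i - 1)])
        right <- max(e[(i + 1):n])
        depth <- min(left, right) - e[i]
        if (is.finite(depth) && depth >= min_depth_kbt) {
          half <- e[i] + depth / 2
          lo <- i; while (lo > 1 && e[lo - 1] <= half) lo <- lo - 1
          hi <- i; while (hi < n && e[hi + 1] <= half) hi <- hi + 1
          out[[length(out) + 1]] <- tibble(
            z_min_A = z[i], depth_kbt = depth, extent_A = z[hi] - z[lo])
        }
      }
    }
    if (length(out) == 0) return(empty)
    dplyr::bind_rows(out)
  }
  res <- tab |>
    dplyr::group_by(.data$species) |>
    dplyr::arrange(.data$z_A, .by_group = TRUE) |>
    dplyr::group_modify(~ one_species(.x) %||%
                          tibble(z_min_A = numeric(), depth_kbt = numeric(),
                                 extent_A = numeric())) |>
    dplyr::ungroup()
  ## merge minima sharing both flanking maxima: keep the deeper one per basin
  res |>
    dplyr::group_by(.data$species) |>
    dplyr::arrange(.data$z_min_A, .by_group = TRUE) |>
    dplyr::ungroup()
}

#' First-solvation-shell water count for one ion
#'
#' Counts water oxygens within the species' first-shell radius of the ion
#' (boundary inclusive).
#'
#' @param ion_position numeric length 3 (`x`, `y`, `z` in angstrom).
#' @param water_positions matrix or data frame with columns `x_A`, `y_A`,
#'   `z_A` (or three unnamed columns).
#' @param radius_A shell radius in angstrom (> 0).
#' @return integer count.
#' @export
first_shell_count <- function(ion_position, water_positions, radius_A) {
  if (radius_A <= 0) abort("radius_A must be > 0")
  w <- as.data.frame(water_positions)
  if (nrow(w) == 0) return(0L)
  cols <- if (all(c("x_A", "y_A", "z_A") %in% names(w))) {
    c("x_A", "y_A", "z_A")
  } else names(w)[1:3]
  d2 <- (w[[cols[1]]] - ion_position[1])^2 +
    (w[[cols[2]]] - ion_position[2])^2 +
    (w[[cols[3]]] - ion_position[3])^2
  sum(d2 <= radius_A^2)
}

#' Per-species first-shell radii
#'
#' Defaults follow standard first-minimum radii of cation-water oxygen
#' radial distribution functions: Na+ 3.1 A, K+ 3.5 A, Ca2+ 3.0 A.
#'
#' @param radii named numeric vector of shell radii in angstrom.
#' @return an object of class `solvation_spec`.
#' @export
solvation_spec <- function(radii = c(Na = 3.1, K = 3.5, Ca = 3.0)) {
  if (any(radii <= 0)) abort("shell radii must be > 0")
  structure(list(radii = radii), class = "solvation_spec")
}

#' Solvation-shell profile along the pore axis
#'
#' For every (frame, ion) record, counts first-shell waters, then averages
#' the counts in z bins per species and Gaussian-smooths the binned means.
#' Bins never visited by an ion are masked.
#'
#' @param tracks an [ion_tracks()] table with 3D coordinates.
#' @param waters water oxygen coordinates: tibble with `time_ns`, `x_A`,
#'   `y_A`, `z_A`.
#' @param spec a [solvation_spec()].
#' @param bin_width_A z bin width (default 0.5).
#' @param sigma_bins Gaussian smoothing sigma in bins (default 2); use 0 for
#'   the raw binned means.
#' @param z_range optional z range; defaults to the track range.
#' @return a tibble of class `solvation_profile` with `z_A`, `species`,
#'   `mean_waters`, `mask`.
#' @export
solvation_profile <- function(tracks, waters, spec = solvation_spec(),
                              bin_width_A = 0.5, sigma_bins = 2,
                              z_range = NULL) {
  tab <- as_tibble(tracks)
  if (any(!is.finite(tab$x_A))) abort("solvation_profile needs 3D coordinates")
  unknown <- setdiff(unique(tab$species), names(spec$radii))
  if (length(unknown) > 0) {
    abort(paste0("no shell radius for species: ",
                 paste(unknown, collapse = ", ")))
  }
  wsplit <- split(as.data.frame(waters), waters$time_ns)
  tab$n_shell <- vapply(seq_len(nrow(tab)), function(i) {
    w <- wsplit[[as.character(tab$time_ns[i])]]
    if (is.null(w)) return(0L)
    first_shell_count(c(tab$x_A[i], tab$y_A[i], tab$z_A[i]), w,
                      spec$radii[[tab$species[i]]])
  }, integer(1))
  zr <- z_range %||% range(tab$z_A)
  edges <- seq(zr[1], zr[2] + bin_width_A * 0.999, by = bin_width_A)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  tab$bin <- pmin(pmax(findInterval(tab$z_A, edges, rightmost.closed = TRUE),
                       1L), length(mids))
  out <- tidyr::expand_grid(species = unique(tab$species),
                            bin = seq_along(mids)) |>
    dplyr::left_join(
      tab |>
        dplyr::group_by(.data$species, .data$bin) |>
        dplyr::summarise(mean_waters = mean(.data$n_shell), n = dplyr::n(),
                         .groups = "drop"),
      by = c("species", "bin")) |>
    dplyr::mutate(z_A = mids[.data$bin], mask = is.na(.data$mean_waters)) |>
    dplyr::group_by(.data$species) |>
    dplyr::arrange(.data$z_A, .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) {
      ok <- !df$mask
      sm <- df$mean_waters
      if (sum(ok) > 1) sm[ok] <- gaussian_smooth(df$mean_waters[ok], sigma_bins)
      df$mean_waters <- sm
      df
    }) |>
    dplyr::ungroup() |>
    dplyr::select("z_A", "species", "mean_waters", "mask")
  structure(out, bin_width_A = bin_width_A, sigma_bins = sigma_bins,
            class = c("solvation_profile", class(tibble())))
}

#' 3D cation density grid near a reference surface
#'
#' Voxelizes 3D ion positions that lie within `mask_radius_A` of any
#' reference point (for synthetic runs the reference is the pore cylinder
#' surface; for imported data, a user-supplied point set such as protein
#' atoms).
#'
#' @param positions tibble with `x_A`, `y_A`, `z_A`.
#' @param spacing_A voxel edge length (> 0).
#' @param reference_points tibble with `x_A`, `y_A`, `z_A`.
#' @param mask_radius_A inclusion radius around the reference points
#'   (default 10).
#' @return an object of class `density_grid_3d`: list with `origin`,
#'   `spacing_A`, `counts` (3D array), `n_masked_out`.
#' @export
density_grid_3d <- function(positions, spacing_A, reference_points,
                            mask_radius_A = 10) {
  if (spacing_A <= 0) abort("spacing_A must be > 0")
  p <- as.data.frame(positions)[, c("x_A", "y_A", "z_A")]
  r <- as.data.frame(reference_points)[, c("x_A", "y_A", "z_A")]
  keep <- rep(FALSE, nrow(p))
  if (mask_radius_A > 0 && nrow(r) > 0 && nrow(p) > 0) {
    r2 <- mask_radius_A^2
    for (j in seq_len(nrow(r))) { # reference sets are small; loop over them
      keep <- keep | ((p$x_A - r$x_A[j])^2 + (p$y_A - r$y_A[j])^2 +
                        (p$z_A - r$z_A[j])^2 <= r2)
    }
  }
  kept <- p[keep, , drop = FALSE]
  if (nrow(kept) == 0) {
    warn("no positions within the mask radius: empty 3D grid")
    return(structure(list(origin = c(0, 0, 0), spacing_A = spacing_A,
                          counts = array(0, c(1, 1, 1)),
                          n_masked_out = nrow(p)),
                     class = "density_grid_3d"))
  }
  origin <- floor(vapply(kept, min, numeric(1)) / spacing_A) * spacing_A
  idx <- lapply(seq_len(3), function(d) {
    as.integer(floor((kept[[d]] - origin[d]) / spacing_A)) + 1L
  })
  dims <- vapply(idx, max, integer(1))
  counts <- array(0L, dims)
  lin <- idx[[1]] + dims[1] * (idx[[2]] - 1L) +
    dims[1] * dims[2] * (idx[[3]] - 1L)
  tl <- tabulate(lin, nbins = prod(dims))
  counts[] <- tl
  structure(list(origin = unname(origin), spacing_A = spacing_A,
                 counts = counts, n_masked_out = nrow(p) - nrow(kept)),
            class = "density_grid_3d")
}

#' Write a 3D density grid as an OpenDX volumetric map
#'
#' Plain-text OpenDX format readable by common molecular viewers.
#'
#' @param grid a [density_grid_3d()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dx <- function(grid, path) {
  d <- dim(grid$counts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %g %g %g", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %g 0 0", grid$spacing_A),
    sprintf("delta 0 %g 0", grid$spacing_A),
    sprintf("delta 0 0 %g", grid$spacing_A),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  ## OpenDX runs the z index fastest
  vals <- as.vector(aperm(grid$counts, c(3, 2, 1)))
  writeLines(vapply(split(vals, ceiling(seq_along(vals) / 3)),
                    function(v) paste(format(v, trim = TRUE), collapse = " "),
                    character(1)), con)
  invisible(path)
}
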