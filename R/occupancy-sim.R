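#' Binding-site occupancy series
#'
#' A per-frame record of which ion occupies a binding site: a non-negative
#' integer ion id when occupied, the sentinel `-1` when vacant.
#'
#' @param occupant_id integer vector of ids (>= 0) or `-1`.
#' @param dt_ps frame spacing in picoseconds (default 20).
#' @param site site label.
#' @return a tibble of class `occupancy_series` with columns `frame`,
#'   `occupant_id`.
#' @export
occupancy_series <- function(occupant_id, dt_ps = 20, site = "") {
  occupant_id <- as.integer(occupant_id)
  if (length(occupant_id) < 1) abort("occupancy series must be non-empty")
  if (any(occupant_id < -1L)) abort("occupant ids must be >= 0 or the -1 sentinel")
  if (dt_ps <= 0) abort("dt_ps must be > 0")
  structure(
    tibble(frame = seq_along(occupant_id), occupant_id = occupant_id),
    dt_ps = dt_ps, site = site,
    class = c("occupancy_series", class(tibble())))
}

#' Generate a pair of coupled two-state occupancy series
#'
#' Emulates knock-on-coupled binding at two pore sites. Site A is a two-state
#' Markov chain with stationary occupancy `p_occ` and mean dwell `dwell_frames`.
#' Site B carries its own independent chain; at every frame, with probability
#' `coupling`, B's occupancy state is slaved to A's instead. `coupling = 0`
#' therefore gives two independent chains, `coupling = 1` makes every
#' transition at A appear at B in the same frame, and intermediate values
#' interpolate the mirroring probability. Each new binding event receives a
#' fresh ion id from a global counter; vacancy is the `-1` sentinel.
#'
#' @param p_occ stationary occupancy probability of either site.
#' @param coupling mirroring probability in `[0, 1]`.
#' @param n_frames number of frames (>= 1).
#' @param dt_ps frame spacing in ps.
#' @param seed RNG seed.
#' @param dwell_frames mean occupied dwell time in frames.
#' @return a list of two [occupancy_series()] (`$a`, `$b`).
#' @export
make_coupled_occupancy <- function(p_occ = 0.5, coupling = 0, n_frames,
                                   dt_ps = 20, seed = 1, dwell_frames = 10) {
  if (coupling < 0 || coupling > 1) abort("coupling must be in [0, 1]")
  if (n_frames < 1) abort("n_frames must be >= 1")
  ## per-frame leave/enter probabilities with stationary occupancy p_occ
  p_leave <- 1 / dwell_frames
  p_enter <- p_leave * p_occ / (1 - p_occ)
  if (p_enter > 1) abort("p_occ too high for this dwell time")
  step_chain <- function(state, u) {
    if (state) u >= p_leave else u < p_enter
  }
  withr::with_seed(as.integer(seed), {
    a_state <- logical(n_frames)
    c_state <- logical(n_frames) # B's own (uncoupled) dynamics
    a_state[1] <- runif(1) < p_occ
    c_state[1] <- runif(1) < p_occ
    if (n_frames > 1) {
      ua <- runif(n_frames - 1)
      uc <- runif(n_frames - 1)
      for (t in 2:n_frames) {
        a_state[t] <- step_chain(a_state[t - 1], ua[t - 1])
        c_state[t] <- step_chain(c_state[t - 1], uc[t - 1])
      }
    }
    mirror <- runif(n_frames) < coupling
    b_state <- ifelse(mirror, a_state, c_state)
    list(a = states_to_ids(a_state, dt_ps, "A"),
         b = states_to_ids(b_state, dt_ps, "B"))
  })
}

## Turn a logical occupancy vector into an id series: each maximal occupied
## run is one binding event and receives the next id from a counter.
states_to_ids <- function(state, dt_ps, site) {
  ids <- rep(-1L, length(state))
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  counter <- 0L
  for (j in seq_along(r$values)) {
    if (r$values[j]) {
      ids[starts[j]:ends[j]] <- counter
      counter <- counter + 1L
    }
  }
  occupancy_series(ids, dt_ps = dt_ps, site = site)
}
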