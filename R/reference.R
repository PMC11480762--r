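#' Reported permeation-event counts for TRPM5 in-silico electrophysiology
#'
#' Loads the bundled table of permeation-event counts reported from published
#' molecular-dynamics electrophysiology simulations of the TRPM5 channel:
#' computational-electrophysiology (CompEL, double-membrane, dicationic
#' solution; aggregated time counts both channels: 3 replicas x 500 ns x 2 =
#' 3000 ns) and applied-field conditions (single channel, 3 x 250 ns =
#' 750 ns), wild type and the F904T filter mutant. These counts are the
#' worked-example inputs for the conductance and selectivity arithmetic.
#'
#' @return a tibble with columns `protocol`, `voltage_mV`, `solution`,
#'   `species`, `valence`, `n_events`, `t_total_ns`, `opposing` (carrier
#'   opposing the cation-inward convention), `reported_pS` (rounded
#'   conductance as originally reported; `NA` where only counts were given).
#' @export
trpm5_reported_events <- function() {
  path <- system.file("extdata", "trpm5_reported_events.csv",
                      package = "permeon", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Recompute reference conductances and selectivities from event counts
#'
#' Applies the counting conductance formula to every reported condition of
#' [trpm5_reported_events()] and diffs the (integer-rounded) results against
#' the reported values. Conductance is undefined at 0 mV; those rows keep
#' their event counts and report `NA`. Selectivity ratios are computed
#' per condition as total monovalent over total divalent events.
#'
#' @return a list with `conductance` (per-row tibble, columns `computed_pS`,
#'   `computed_pS_rounded`, `matches_reported`), `selectivity` (per-voltage
#'   tibble with the monovalent/divalent event-count ratio), and `totals`
#'   (event-count bookkeeping: CompEL total and all-condition total).
#' @export
reproduce_reference_conductances <- function() {
  tab <- trpm5_reported_events()
  cond <- tab |>
    dplyr::mutate(
      computed_pS = purrr::pmap_dbl(
        list(.data$n_events, .data$valence, .data$t_total_ns,
             .data$voltage_mV, .data$opposing),
        function(n, q, t, v, opp) {
          if (v == 0) return(NA_real_)
          conductance_total(n, q, t, v, opposing = opp)
        }),
      computed_pS_rounded = round(.data$computed_pS),
      matches_reported = .data$computed_pS_rounded == .data$reported_pS)
  sel <- tab |>
    dplyr::filter(.data$species %in% c("Na", "Ca")) |>
    dplyr::mutate(kind = ifelse(.data$valence == 2, "divalent",
                                "monovalent")) |>
    dplyr::group_by(.data$protocol, .data$voltage_mV, .data$kind) |>
    dplyr::summarise(n = sum(.data$n_events), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "kind", values_from = "n",
                       values_fill = 0) |>
    dplyr::rowwise() |>
    dplyr::mutate(ratio = selectivity_ratio(.data$monovalent,
                                            .data$divalent)$ratio) |>
    dplyr::ungroup()
  totals <- tibble(
    compel_events = sum(tab$n_events[tab$protocol == "compel"]),
    all_events = sum(tab$n_events))
  list(conductance = cond, selectivity = sel, totals = totals)
}
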