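# permeon

In-silico electrophysiology of ion-channel permeation, in R.

permeon is for computational biophysicists who run (or reanalyse)
molecular-dynamics simulations of ion channels under a transmembrane
voltage and want the standard permeation statistics as tested, composable
functions rather than one-off scripts. It was built around the analysis of
monovalent-cation selectivity in the TRPM5 channel pore, but every stage
operates on a plain tabular trajectory (time, ion id, species, valence,
x/y/z in Å) and a two-plane pore geometry, so it applies to any
single-pore system.

## What it computes

* **Permeation events** — complete traversals of the pore, defined by
  sequential crossing of the selectivity-filter and gate planes with no
  intervening return, correctly counted through periodic images under
  sustained flux (`detect_events()`).
* **Conductance** from event counting,

  C = N_p · |q| · e / (t_traj · |V_tm|),

  in pS, with mean ± SE from overlapping 50-ns windows
  (`conductance_total()`, `conductance_windows()`), and **selectivity**
  as the ratio of species event totals (`selectivity_ratio()`).
* **Axial densities and −log-density energy profiles** in kBT with
  Gaussian smoothing (σ = 2 bins), masked unsampled bins, binding-site
  minima, first-solvation-shell water counts (Na⁺ 3.1 Å, K⁺ 3.5 Å,
  Ca²⁺ 3.0 Å) and 3D density maps in OpenDX text format.
* **Permeation cooperativity** as excess state-specific information:
  plug-in mutual information between five-symbol occupancy-transition
  streams of two binding sites (20-ps occupancy step, −1 vacancy
  sentinel), minus a circular-shift noise threshold (`excess_ssi()`).
* **Potentials of mean force** from umbrella-sampling windows by
  self-consistent WHAM (0.25 Å bins, 1e−6 kBT tolerance) with
  block-analysis errors (`wham()`, `block_error()`).
* A **Brownian-dynamics pore generator** (`simulate_ions()`,
  `trpm5_like_pore()`, `knockon_pore_model()`, `make_umbrella_dataset()`,
  `make_coupled_occupancy()`, `make_waters()`) that produces every input
  the pipeline needs, so the whole machinery is testable without MD data.

Results come back as tibbles or small S3 objects with `tidy()`/`glance()`
methods and `autoplot()`/`plot_tracks()` figures, and chain with the pipe.

## Worked example

Conductance arithmetic on reported event counts (the bundled
`trpm5_reported_events()` table carries the published TRPM5 counts;
aggregated CompEL time is 3000 ns = 3 replicas × 500 ns × 2 channels):

```r
library(permeon)

conductance_total(15, valence = 1, t_total_ns = 3000, voltage_mV = -50)
#> [1] 16.02177   # rounds to the reported 16 pS

rr <- reproduce_reference_conductances()
dplyr::filter(rr$conductance, protocol == "compel", voltage_mV == -610) |>
  dplyr::select(species, n_events, computed_pS_rounded, reported_pS)
#> # A tibble: 3 × 4
#>   species n_events computed_pS_rounded reported_pS
#> 1 Na           115                  10          10
#> 2 Ca           168                  29          29
#> 3 Cl             6                  -1          -1
rr$totals
#> # A tibble: 1 × 2
#>   compel_events all_events
#> 1           374        724
```

End-to-end on a synthetic pore (the generator is qualitative: it
reproduces selectivity and cooperativity phenotypes, not absolute MD
kinetics, so synthetic conductances are much larger than experimental
ones):

```r
rep <- run_pipeline(list(
  seed = 1, out_dir = "run1",
  model = list(voltage_mV = -340),
  simulate = list(n_steps = 100000L, save_stride = 40L),
  conductance = list(window_ns = 10, stride_ns = 5)))

rep$results$conductance$Na$conductance_pS  # windowed mean, pS
#> [1] 398
rep$results$selectivity$ratio              # monovalent / divalent events
#> [1] 1.666667
```

`run1/` then holds the trajectory, events, profiles and a `report.json`
that is byte-identical across reruns with the same config and seed. The
same stages are scriptable via `inst/cli/permeon`
(`permeon run|simulate|events|conductance|ssi|wham|reproduce`).

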