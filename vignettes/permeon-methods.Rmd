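---
title: "Methods: in-silico electrophysiology of pore permeation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in-silico electrophysiology of pore permeation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permeon)
library(dplyr)
```

permeon analyses ion permeation through a membrane channel pore from
per-ion coordinate time series. This vignette explains the statistical
machinery, the choices behind its defaults, and what the synthetic-data
generator does and does not emulate.

## The data model

Everything downstream consumes one tabular object, `ion_tracks()`: one row
per (frame, ion) with the axial coordinate `z_A` (Å, z = 0 at the membrane
centre, positive pointing extracellular) and optional transverse
coordinates. The pore itself is reduced to two constriction planes
(`pore_geometry()`): the selectivity-filter plane `z_sf` above and the
intracellular-gate plane `z_gate` below. Trajectory-wide metadata (periodic
box, voltage, temperature) rides along as attributes, and the on-disk
format is a TSV plus a JSON sidecar — deliberately language-neutral, so any
MD toolchain can produce it. Binary MD formats are out of core scope; an
adapter only has to emit this table.

## Permeation events and conductance

An inward permeation event is one complete traversal: the continuous z
path crosses `z_sf` downward and then `z_gate` downward without first
returning above `z_sf` (mirrored for outward). The criterion has no
minimum dwell time; entry and exit times are interpolated linearly between
the flanking frames. Under a sustained driving force in a periodic box an
ion traverses the pore's periodic images repeatedly, so `detect_events()`
counts crossings against the full plane families `z_sf + kL`, `z_gate +
kL` — a detail that matters as soon as the flux is non-zero.

Conductance is estimated by counting:

$$C = \frac{N_p \, |q| \, e}{t_{\mathrm{traj}} \, |V_{tm}|}$$

with $N_p$ complete events, $q$ the carrier valence, $t_{\mathrm{traj}}$
the aggregated trajectory time and $V_{tm}$ the transmembrane voltage.
For double-membrane computational-electrophysiology setups
$t_{\mathrm{traj}}$ counts both channels (replicas × length × 2); this is
required to reproduce the bundled reference table
(`trpm5_reported_events()`). `conductance_windows()` applies the same
formula in overlapping windows (default 50 ns, stride 25 ns — the stride
is our choice; only "overlapping" is prescribed by the windowed-SE
convention) and reports mean ± SE over windows. Carriers moving against
the cation-inward convention (anion leak, outward cation events)
contribute with a negative sign. Conductances are only rounded to integer
pS in reports, never internally. Selectivity is the ratio of total event
counts of two species; a zero denominator yields the `Inf` sentinel, 0/0
is undefined.

One wrinkle in the reference table: at −380 mV the reported selectivity
(1.9) does not equal the ratio of the printed totals (32/19 ≈ 1.7),
because the published value averaged per-replica ratios whose per-replica
counts are not printed. We implement the totals-based definition and
report both sides rather than resolving the discrepancy.

## Density, energy and solvation profiles

`axial_density()` histograms per-frame z positions (default bin 0.5 Å, our
choice; the profile literature gives only a unitless smoothing "sigma of
2", which we read as 2 bins, the convention of standard array filters).
`neg_log_density()` turns counts into an energy-like profile
$E(z) = -\ln n(z)$ in kBT after Gaussian smoothing (reflected boundaries,
kernel truncated at 4σ), gauged so the minimum is zero. Bins with zero
counts are masked, never pseudo-counted. Under equilibrium sampling this
is Boltzmann inversion and must recover the generating potential — the
test suite enforces < 0.3 kBT RMS on well-sampled bins; under voltage it
is a nonequilibrium energy estimate whose minima still mark binding sites.

Binding sites are formalised as local minima of the smoothed profile at
least 0.5 kBT deep relative to the lower flanking maximum (visual
identification from time series is not reproducible; this operationalises
it). Solvation structure is summarised as the mean number of water oxygens
within the species' first-shell radius (Na⁺ 3.1 Å, K⁺ 3.5 Å, Ca²⁺ 3.0 Å —
first minima of the respective cation–water RDFs), binned along z with the
same smoothing; the shell boundary is inclusive. 3D densities near a
reference point set (the pore cylinder for synthetic data, protein atoms
for imported data; default mask 10 Å) are voxelised and exported as
OpenDX text maps.

## Cooperativity as excess state-specific information

Knock-on-like permeation shows up as correlated occupancy transitions at
two binding sites. `build_occupancy()` resamples the trajectory to a 20 ps
step and records the occupant ion id per frame (−1 when vacant; ties go to
the ion nearest the site centre, or to the incumbent under the
alternative rule). `transition_stream()` reduces consecutive frame pairs
to a five-symbol alphabet (stay-vacant, stay-occupied, bind, release,
exchange), and `ssi_bits()` is the plug-in mutual information between the
two symbol streams in bits. This is a re-derivation of the
state-specific-information idea for discrete occupancy transitions, not a
port of any particular implementation.

Finite streams give positively biased MI even under independence, so
`noise_threshold()` builds a null by circularly shifting one stream by
random offsets — preserving each stream's marginals and autocorrelation
while destroying cross-correlation — and takes the 0.95 quantile of the
null MI (the quantile, shift count and null model are configurable; a
quantile was chosen over the null mean because it gives the subtraction a
direct false-positive interpretation). Excess SSI is
`max(SSI − threshold, 0)`; the raw SSI and threshold are always reported
alongside, and with replicas the mean ± SE over replicas. Because the
threshold is a 95% quantile, uncoupled pairs yield exSSI exactly zero in
about 95% of seeds — the suite checks ≥ 90%.

## Umbrella sampling and WHAM

`make_umbrella_dataset()` draws window samples directly from the biased
Boltzmann density by inverse-CDF sampling on a fine grid (exact up to grid
resolution; no equilibration or autocorrelation artefacts), with the
conventional defaults of 1000 kJ mol⁻¹ nm⁻² springs every 0.25 Å. `wham()`
solves the standard self-consistency equations on a 0.25 Å grid (matching
the window spacing) to a tolerance of 1e−6 kBT on the window free
energies, capped at 1e5 iterations; hitting the cap is reported as
non-convergence, never silent success, and unsampled interior bins between
window centres trigger a non-overlap warning. Per-bin standard errors come
from block analysis (5 blocks by default): each window's series is cut
into contiguous blocks and WHAM is repeated per block. Decorrelating the
input is the caller's responsibility; `block_error()` quantifies residual
correlation only crudely. Temperature defaults to 310 K for all unit
conversions. The tests cross-check the self-consistent solution against an
independent maximum-likelihood WHAM (BFGS on the window free energies) to
0.2 kBT and require a 4 kBT double-well barrier to be recovered within
0.5 kBT.

## What the synthetic generator emulates

`simulate_ions()` integrates overdamped (Brownian) Langevin dynamics,

$$z_{t+\Delta t} = z_t - D\,\Delta t\,\partial_z[U(z) + q\,\phi(z)]
  + \sqrt{2 D \Delta t}\,\xi,$$

with `U` a per-species 1D landscape in kBT, φ a linear voltage ramp
confined to the membrane span (mimicking voltage focusing across the
pore), periodic wrapping in z, and transverse coordinates diffusing inside
a reflecting cylinder. Overdamped rather than inertial dynamics is enough
because every analysis consumes positions only, and it has the correct
stationary distribution by construction. Inter-ion interaction is reduced
to an optional hard-core z exclusion inside the pore region — sufficient
to produce single-file, knock-on-like coupling — implemented as rejection
of moves that shrink a violating pair's gap (rejecting all moves of such
pairs can deadlock two overlapping ions permanently, which is why only
approaching moves are rejected).

`trpm5_like_pore()` encodes the monovalent-selective landscape: a shallow
extracellular-vestibule well for all cations, a cavity well for
monovalents, and a high "hydrophobic funnel" barrier between filter and
cavity for divalents (8 kBT by default — the funnel strength is a free
knob, since no quantitative coupling model is published; it was chosen so
the divalent pathway is blocked at low voltage but conducts when the
electrostatic tilt becomes comparable to the barrier). With it, monovalent
flux dominates at low voltage and the monovalent/divalent flux ratio falls
as |V| rises — the qualitative selectivity phenotype — using 12 monovalent
and 8 divalent ions, diffusion coefficients of 20 and 15 Å²/ns (bulk
cation diffusivity reduced for confinement), a 40 Å periodic box and a
±10 Å membrane span. `knockon_pore_model()` is a compact two-well variant
whose exclusion distance equals the well spacing, so release of the lower
resident and arrival of the upper one are concerted; it drives the
cooperative (exSSI ≫ noise) versus non-cooperative (exSSI ≈ noise)
contrast.

The generator does **not** emulate: explicit water or protein, ion–ion
electrostatics, inertial or memory effects, radial structure of real
pores, or absolute MD kinetics. Tests passing on synthetic data therefore
validate the *statistical machinery* — event counting, Boltzmann/WHAM
inversion, MI estimation — not force-field realism. The published
MD-derived profile and PMF figures are not desk-reproducible; the bundled
reference event-count table is reproduced exactly because it is pure
arithmetic on printed counts.

## Numerical choices and problem sizes

Time step 5e−4 ns with diffusion 20 Å²/ns gives a per-step noise of
0.14 Å, small against the 1.5–2.5 Å landscape features; the force is
tabulated on a 4096-point grid and interpolated by bin lookup. Seeds fan
out from one global seed by fixed offsets per stage so every stage is
independently reproducible; identical seeds give bit-identical output. The
test suite uses 75–150 ns equivalent trajectories with 6–40 ions —
enough for the stated tolerances (e.g. Boltzmann RMS < 0.3 kBT needs a few
hundred effective samples per 0.5 Å bin) while keeping the whole suite in
the minutes range. Degenerate inputs are errors, not guesses: conductance
at 0 mV, all-zero density profiles, occupancy sites outside the data
range, fewer block samples than blocks.

## Known limitations

- The event criterion ignores the radial bound when transverse coordinates
  are absent; a wide-pore system with off-axis leak paths would need them.
- The exclusion interaction is not a faithful hard-rod propagator; it is a
  rejection scheme whose stationary distribution is only approximately
  Boltzmann at high density. It exists to create occupancy coupling, not
  to model ion–ion energetics.
- Plug-in MI is biased upward for small samples; the shuffle threshold
  compensates on average but exSSI for very short streams remains noisy.
- WHAM assumes uncorrelated window samples; block errors only flag, not
  repair, correlation.
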