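# tmesim

Lattice Metropolis Monte Carlo simulation of multicellular self-assembly in
bioprinted tumor-microenvironment (TME) constructs.

Extrusion-bioprinted TME models — a hydrogel spheroid loaded with cancer
cells, embraced by hydrogel rings loaded with peritumoral cells (tumor-
associated fibroblasts and immune cells) — reorganize spontaneously after
printing: cells migrate, form heterotypic aggregates, and proliferate.
`tmesim` implements the computational model used to study which
hierarchy of adhesion energies explains those rearrangements: a 3D
cubic-lattice model driven by the differential adhesion hypothesis plus
stochastic proliferation of superficial cells. It is aimed at researchers in
tissue engineering and computational morphogenesis who want a reproducible,
scriptable version of this class of model.

## The model

Every lattice site (spacing = 1 cell diameter ≈ 10 µm) holds one particle:
medium (σ = 0), hydrogel (1), a peritumoral cell (2), or a cancer cell (3).
Bonds act over the nn = 26 Moore neighbors with works of cohesion
ε<sub>σσ</sub> and adhesion ε<sub>σσ′</sub> (units of E<sub>T</sub>), giving
the energy

E = Σ<sub>σ&lt;σ′</sub> γ<sub>σσ′</sub> N<sub>σσ′</sub> − (nn/2) Σ<sub>σ</sub> ε<sub>σσ</sub> N<sub>σ</sub>,  γ<sub>σσ′</sub> = (ε<sub>σσ</sub> + ε<sub>σ′σ′</sub>)/2 − ε<sub>σσ′</sub>

Each Monte Carlo step (MCS) gives every *interfacial* cell one chance to
proliferate (probability p₃ for cancer, p₂ for peritumoral cells; the
daughter replaces a random medium/hydrogel neighbor, and buried cells cannot
divide) or to attempt a swap with a neighbor of a different type, accepted
by the Metropolis rule P = min(1, exp(−ΔE/E<sub>T</sub>)). Five interaction
presets (`set1` … `set5`) covering infiltration, surface wrapping, plain
aggregation, no aggregation, and cancer-cell escape ship with the package,
along with rasterizers for the printed toroidal and triple-layered
geometries and Bernoulli cell seeding at volume fraction 10⁻³
(10⁶ cells/mL). See the vignette in `vignettes/tme-simulation.Rmd` for the
full account.

## Worked example

```r
library(tmesim)
set.seed(1)
lat <- build_toroidal(scale = 1 / 3)     # the reduced (1:3) toroidal model
lat
#> <tme_lattice 65 x 65 x 25, scale 0.3333333, mcs 0>
#>   medium 62408 | hydrogel 43178 | peritumoral 36 | cancer 3 | biomaterial 0

sim <- run_simulation(lat, "set1", simulation_params(n_mcs = 5000, seed = 1))
glance(sim)
#> # A tibble: 1 × 12
#>   n_mcs E_initial  E_final N2_final N3_final proliferations moves_accepted
#>    5000   -417338 -418176.       94       14             69         235992
#>   moves_rejected infiltration_index wrapping_index escape_fraction mean_cluster_size
#>           101398             0.0532          0.453               0              2.16
```

The construct was seeded with 3 cancer and 36 peritumoral cells; after 5000
MCS under `set1` (strong cancer–peritumoral adhesion, γ₂₃ = −0.3) the
populations have grown to 14 and 94 via superficial proliferation, the
energy has descended, about 5% of peritumoral cells have infiltrated the
initial tumor zone, and cells have condensed into clusters (mean size 2.2,
largest 44). `tidy(sim)` returns the full per-checkpoint trajectory,
`autoplot(sim)` plots it, and `write_xyz()` exports VMD-readable snapshots.

A command-line front end with `build`, `run`, `metrics` and `convert`
subcommands is provided:

```sh
Rscript inst/scripts/tmesim run --preset set1 --scale 1/3 --mcs 20000 \
    --seed 7 --out results/run1
```

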