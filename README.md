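# langmuir

Analysis of **Langmuir monolayers** — insoluble films at the air–water
interface — for membrane biophysicists studying lipid–polymer
interactions on a film balance. The package covers the full desk
workflow for three kinds of records:

* **Pressure–area isotherms** Π(A): monotonization, interpolation
  A(Π), lift-off area, compressibility modulus
  C<sub>s</sub><sup>−1</sup> = −A·dΠ/dA, and LE–LC transition onset.
* **Co-spread mixed films**: the ideal-mixing additivity rule
  A<sub>calc</sub>(Π) = x<sub>polymer</sub>·A<sub>polymer</sub>(Π) +
  x<sub>lipid</sub>·A<sub>lipid</sub>(Π), per-lipid area shifts
  ΔA(Π) = A<sub>mix</sub> − A<sub>lipid</sub>, the excess area of mixing
  ΔA(Π) = A<sub>exp</sub> − A<sub>calc</sub>, and the convergence
  (complete squeeze-out) pressure at which mixed and pure isotherms
  coincide.
* **Adsorption experiments**: biexponential insertion kinetics
  Π(t) = π<sub>eq</sub> − Σ aᵢ·e<sup>−t/τᵢ</sup>, the pressure increase
  ΔΠ = Π<sub>max</sub> − Π<sub>ini</sub>, and the **maximum insertion
  pressure** (exclusion pressure Π<sub>e</sub>) from the x-intercept of
  the ΔΠ vs Π<sub>ini</sub> line.
* **Epifluorescence micrographs**: condensed-domain segmentation, exact
  area fractions and 8-connected domain counts, and the isotherm-based
  coverage prediction φ = A<sub>lipid</sub>(Π)/A<sub>mix,per lipid</sub>(Π).

A seeded synthetic-data module generates every input the analyses
consume — a fluorinated-DPPC-like lipid isotherm (lift-off at
110 Å²/molecule, plateau onset at 9 mN/m), pancake→brush polymer
isotherms with squeeze-out at 32.5 (`gp_like`) or 42.4 mN/m
(`fgp_like`), mixed films with a prescribed excess, two-regime
adsorption traces, and domain images with known area fraction — each
with a ground-truth record, so the whole pipeline is testable end to
end. Units throughout: Å², mN/m, s, °C.

## Worked example

```r
library(langmuir)

## a noisy seeded compression run of the lipid preset
lipid_raw <- simulate_lipid_isotherm(noise_sd_pressure = 0.1, seed = 42)
transition_onset(lipid_raw)
#> <transition_features>
#>   lift-off area        : 110.1 A^2
#>   transition onset Pi_t: 9.021 mN/m at 74.33 A^2
#>   plateau end area     : 61.48 A^2
#>   max recorded pressure: 55.01 mN/m
```

The detected landmarks sit at the programmed preset values: the film
lifts off at 110 Å² per molecule and the LE–LC coexistence plateau
begins at 9 mN/m.

```r
## a 10:1 lipid:polymer co-spread film vs the pure lipid
lipid <- monotonize(simulate_lipid_isotherm())
gp    <- monotonize(simulate_polymer_isotherm(polymer_film_params("gp_like")))
mix   <- mole_fractions(10, 1)
mixed <- monotonize(simulate_mixed_isotherm(lipid, gp, mix,
                                            noise_sd_pressure = 0.1, seed = 42))

area_shift_vs_lipid(mixed, lipid, c(4, 9, 15, 25), mix = mix)
#> <excess_area_series> reference = pure_lipid, mixture = 10:1, 4 pressures
#>   pressure delta_area
#> 1        4  114.00779
#> 2        9   54.61567
#> 3       15   30.51759
#> 4       25   14.72691
convergence_pressure(mixed, lipid)
#> [1] 33.47263
```

ΔA is the extra apparent area per lipid occupied by polymer residing in
the film; it shrinks with pressure as polymer is pushed out and the
mixed isotherm rejoins the pure lipid near the programmed squeeze-out
pressure (32.5 mN/m, detected at 33.5 — the logistic squeeze-out tail
adds ≈ +1 mN/m). For comparison, the corresponding experimental study
of a fluorinated-lipid/triblock-copolymer system reports per-lipid
shifts at 25 mN/m of 13.3 Å² (plain polymer, nearly expelled) vs
47.5 Å² (fluorous-anchored polymer, still resident) for 10:1 films.

```r
## maximum insertion pressure from a seeded adsorption series
pis <- seq(5, 40, by = 5)
dp  <- sapply(seq_along(pis), function(k)
  delta_pi(simulate_adsorption_trace(pis[k], noise_sd = 0.1, seed = 42 + k)))
mip_from_series(pis, dp)
#> <mip_result>
#>   MIP (Pi_e) : 42.77 +/- 0.05115 mN/m
#>   line       : Delta Pi = 24.18 -0.5655 * Pi_ini  (n = 8)
```

The fitted exclusion pressure recovers the generator's programmed
42.4 mN/m; the intercept 24.2 mN/m is the zero-coverage limit (the
polymer's equilibrium adsorption pressure at a bare surface).

```r
## domain imaging: segmented vs isotherm-predicted LC coverage
img <- simulate_micrograph(target_phi = 0.5, noise_sd = 8, seed = 42)
domain_stats(segment_dark_domains(img, "otsu"))
#> <domain_stats> phi = 0.5032, 25 domain(s), mean area 1319 px^2
predicted_lc_coverage(16, lipid, mixed)
#> [1] 0.678  (with attribute transition_complete = TRUE)
```

Segmentation recovers the programmed 50 % dark coverage within half a
percent. When a mixed film's per-lipid area is exactly twice the pure
lipid's, the predicted coverage is exactly 0.5.

## Command line

Every module is reachable through one entry point:

```sh
Rscript -e 'langmuir::run_cli()' simulate-isotherm --preset fdppc_like --seed 1 --out runs/iso
Rscript -e 'langmuir::run_cli()' analyze-isotherm --input runs/iso/isotherm.csv --out runs/feat
Rscript -e 'langmuir::run_cli()' mix --lipid lipid.csv --polymer gp.csv \
    --experimental mix10.csv --ratio 10:1 --pressures 4,9,15,25 --out runs/mix
```

Subcommands: `simulate-isotherm`, `simulate-adsorption`,
`simulate-image`, `analyze-isotherm`, `mix`, `mip`, `kinetics`,
`image-stats`. Flags `--seed`, `--preset`, `--out`, `--config`,
`--log-level` are uniform; precedence is CLI > config file > defaults,
and every run writes a `run_summary.json` embedding the merged config
and package version, so reruns are bitwise reproducible. All file
formats are plain text (CSV isotherms/traces with `#` metadata, ASCII
PGM images, JSON summaries and ground-truth sidecars).

## Further reading

`vignettes/monolayer-analysis.Rmd` documents the models and their
assumptions, every tunable parameter with units and defaults, what the
synthetic generators do and do not emulate, numerical edge-case
handling, and known limitations.
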