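# ddaflux

Steady-state carbon and nitrogen fluxes in diatom–diazotroph
associations (DDAs).

DDAs — a host diatom carrying filamentous cyanobacterial symbionts —
are among the dominant N₂-fixing systems of the oligotrophic ocean.
Each symbiont trichome combines vegetative cells, which photosynthesize
but cannot fix N₂, with heterocysts, which fix N₂ (at a carbon cost)
but cannot fix carbon. `ddaflux` is a coarse-grained cell flux model of
this symbiosis for researchers in marine microbial ecology and
biogeochemistry who want to quantify how ambient ammonium, growth rate,
trichome number and light shape the metabolism of, and the nutrient
exchange inside, one association.

## Model

Each elemental pool is assumed to be at steady state — supply equals
consumption per association and day:

```
C:  F_pho,D + F_pho,V = mu * [Q_C,V (1+E_V) + Q_C,H (1+E_H) + Q_C,D (1+E_D)] + F_C,fix
N:  F_N,fix + V_NH4   = mu * (Q_N,V + Q_N,H + Q_N,D)
```

with Monod ammonium uptake by the diatom,
`V_NH4 = Vmax * Q_C,D * [NH4+] / ([NH4+] + Km)`, and a fixation carbon
cost `F_C,fix = F_N,fix * f_C:N`. Here `mu` is the shared growth rate
(d⁻¹), `Q_C,x`/`Q_N,x` are per-association carbon/nitrogen quotas of
diatom (D), pooled vegetative cells (V) and pooled heterocysts (H)
(pmol), and `E_x` is the respiration-to-biosynthesis ratio. Quotas come
from allometric volume-to-carbon regressions and a uniform Redfield
C:N of 6.6. Photosynthesis splits between diatom and vegetative cells
in proportion to their nitrogen quotas (or, in light mode, to their
light-limited capacities). The solved state yields the two
inter-partner transfers — carbon diatom→trichome, nitrogen
trichome→diatom — and two closed-form ammonium thresholds: the
*no-transfer* concentration (net N transfer changes sign) and the
*zero-fixation* concentration (uptake covers the whole association's
nitrogen demand).

The fixation carbon cost `f_C:N` is not fixed a priori; it is
calibrated at run time by least squares against two reference
carbon-transfer percentages (22.7 % at 0 and 11.1 % at 0.04 mmol m⁻³
ammonium, at mu = 0.51 d⁻¹), giving ≈ 2.07 pmol C (pmol N)⁻¹.

## Worked example

```r
library(ddaflux)

sol <- solve_steady_state(dda_scenario(mu = 0.51, nh4 = 0.01))
sol
#> DDA steady-state fluxes (pmol d^-1 per association)
#>   scenario: mu = 0.51 d^-1, NH4+ = 0.01 mmol m^-3
#>          uptake      fixation_N fixation_C_cost  photosynthesis      pho_diatom
#>          0.3024          0.9979          2.0630         13.9100         11.8200
#>  pho_vegetative      C_transfer      N_transfer
#>          2.0830          2.7770          0.6908
#>   C transfer 20% of C supply; N transfer 53.1% of N supply
```

At 0.01 mmol m⁻³ ammonium and an average growth rate, uptake
(0.30 pmol N d⁻¹) covers under a quarter of the nitrogen demand, so the
heterocysts must fix 1.0 pmol N d⁻¹; paying the fixation carbon bill
pushes required photosynthesis to 13.9 pmol C d⁻¹, of which the diatom
performs 11.8 and exports 2.78 pmol C d⁻¹ (20 % of supply) to the
trichomes, receiving 0.69 pmol N d⁻¹ back.

```r
budget(sol)$n_supply
#>  fixation    uptake
#>  76.74092  23.25908

no_transfer_concentration(0.51, dda_physiology(),
                          build_quotas(dda_composition()))
#> [1] 0.03447103   # mmol m^-3: above this, excess N flows to the trichomes

sweep_scenarios(list(nh4 = c(0, 0.02, 0.04)))[, c("nh4", "c_transfer_percent")]
#>    nh4 c_transfer_percent
#> 1 0.00           22.76798
#> 2 0.02           17.03354
#> 3 0.04           10.71210
```

The same operations are scriptable from a shell via `exec/ddaflux`
(`solve`, `budget`, `sweep`, `thresholds` subcommands; YAML config plus
flag overrides).

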