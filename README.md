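# pikarem

Camera traps count photographs, not animals. For unmarked small mammals
such as the plateau pika (*Ochotona curzoniae*) on the Qinghai–Tibet
Plateau, the random encounter model (REM) turns a capture tally into a
density estimate without identifying individuals:

```
D = (y / t) · π / (v · r · (2 + θ))
```

where `y` is the number of independent photographs, `t` the camera-days,
`v` the animal's daily travel distance, and `(r, θ)` the radius and angle
of the camera's detection zone. How trustworthy that estimate is depends
on how capture frequency really responds to density and behavior — which
is hard to probe in the field and easy to probe in silico.

`pikarem` is a digital twin of a pika population built for exactly that
question:

* **territory** — burrow-system territories as a bounded Voronoi
  (Thiessen) tessellation of a square landscape; each cell gets 9–11
  surface entrances (≥ 2 m apart) and 4–6 resident pikas;
* **movement** — per-pika daily ground activity: a time budget `t_tol`
  spent in 0.5-min steps with two-intensity Gaussian speeds (high:
  N(20, 2), low: N(2, 0.2) m/min), uniform random headings, a 1 m
  return-to-burrow rule and a toroidal boundary;
* **detection** — virtual cameras whose arc-sector detection zone
  (r = 8 m, θ = 0.96 rad) is replaced by the equal-area isosceles
  triangle (side 8.66 m, area 30.72 m²); captures are counted per time
  step whose movement segment intersects the zone (an entry-transition
  rule is also available);
* **estimation** — the REM, the mean capture rate
  `P = Σ q_ij / (T · N)`, the density-free activity index
  `λ = P / D` (hectares) and its REM closed form `λ = v·r·(2+θ)/π`;
* **experiments** — seeded Monte Carlo sweeps of density (via occupancy
  ranges), activity time and movement speeds, reproducing the simulated
  P-vs-D slope ≈ 0.225 and the density-stability of λ.

Everything is driven by one root seed through named child streams, so
every run is bit-reproducible from its manifest.

## Worked example

Estimate densities from the packaged field tallies (six cameras, one
week), then compare a simulated landscape against the REM:

```r
library(pikarem)
pikarem_cli("report")
#>                   location working_days n_photographs daily_captures density_per_ha
#>  100 m from the river bank            6           271             45            200
#>  300 m from the river bank            7           270             39            171
#>    On the side of the road            4           130             32            144
#>         Gentle sunny slope            7           201             29            127
#>          Steep sunny slope            6           105             18             77
#>     Benchland of the river            5           161             32            142
#> closed-form lambda at v = 300 m/day: 0.226 ha
```

The daily capture rate at the densest site is 45 photographs/day; at
0.3 km/day travel distance the REM converts that into 200 pikas per
hectare. The full simulation ties the two ends together:

```r
cfg <- sim_config(seed = 1)          # 1,000 m square, 2,500 burrow systems
rec <- run_trial(cfg, seed = 1)
rec[c("n_pikas", "D_true", "P", "lambda")]
#>   n_pikas D_true        P    lambda
#> 1   12454 124.54 33.95833 0.2726701
```

A landscape of ~12,500 pikas (125/ha) yields ~34 captures per camera-day,
i.e. λ ≈ 0.27–0.30 ha at the default 20-min activity budget — the same
order as the closed form, and stable across densities (see the methods
vignette in `vignettes/`).

A shell launcher is installed with the package
(`system.file("scripts", "pikarem", package = "pikarem")`) exposing the
`simulate`, `sweep`, `estimate` and `report` subcommands.

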