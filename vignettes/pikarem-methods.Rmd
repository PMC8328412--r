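---
title: "pikarem: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pikarem: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pikarem)
```

## The problem

The random encounter model (REM) estimates the density of unmarked
animals from camera-trap capture rates,

$$D = \frac{y}{t}\,\frac{\pi}{v\,r\,(2+\theta)},$$

with $y$ independent photographs over $t$ camera-days, daily travel
distance $v$, and a detection zone of radius $r$ and angle $\theta$.
Its reliability hinges on a behavioral assumption: that capture
frequency scales linearly with density at fixed behavior. `pikarem`
tests that assumption mechanistically for plateau pikas by simulating an
entire population — territories, daily movement, and virtual cameras —
and measuring the *activity intensity per population density*

$$\lambda = P / D \quad [\mathrm{ha}],$$

where $P$ is the mean daily capture rate per camera. Under the REM,
$\lambda = v r (2+\theta)/\pi$ regardless of density; a density-stable
simulated $\lambda$ is therefore direct support for REM-style
inference.

## The landscape model

The habitat is a square of side $L$ tessellated into burrow-system
territories by a bounded Voronoi diagram: $n$ control points are drawn,
and each territory is the set of locations nearer its control point
than any other, clipped to the square. Cells are computed exactly by
half-plane (perpendicular-bisector) clipping of the bounding square in
order of neighbor distance, with a security-radius stop: once the next
site is farther than twice the current cell's maximal vertex distance,
no remaining site can cut the cell. Tests verify area conservation
($\sum$ areas $= L^2$ to $10^{-6}$ relative) and the nearest-site
property against a brute-force oracle.

Each cell receives a uniform number of entrances in
$[H_{\min}, H_{\max}]$, placed by sequential dart throwing (uniform in
the cell, accepted at $\ge l_{\min}$ from previous entrances), and a
uniform number of resident pikas in $[Q_{\min}, Q_{\max}]$. At the
defaults this yields an expected density of
$2{,}500 \times 5 / 100\,\mathrm{ha} = 125$ pikas per hectare.

**Hard-core control points.** Pure uniform (Poisson) control points
produce a heavy small-cell tail: across 2,500 cells, a few fall below
$\sim$35 m², where 9–11 entrances at 2 m spacing cannot be placed by
bounded rejection sampling, and generation of almost every landscape
would abort. Since real family territories have a viable minimum size
and their centers never coincide, control points are drawn by
sequential inhibition with a hard-core spacing `l_sys` (default 10 m).
Every cell then contains a disc of radius `l_sys`/2 ($\ge 78.5$ m²),
which comfortably packs 11 entrances at 2 m spacing. Placement remains
bounded-attempt: a genuinely infeasible cell raises an error naming its
area rather than silently relaxing the spacing.

## The movement model

Each day every pika starts inside its burrow with a ground-time budget
$t_{tol}$, spent in steps of $\Delta t = 0.5$ min (matching the
camera's 30-s recording time). An excursion begins at a uniformly
chosen entrance of the pika's own system. Per step:

* intensity is high with probability $p_{high}$ (running) or low
  (foraging, resting), redrawn independently every step;
* speed is Gaussian, $N(v_{large}, \sigma_{large})$ or
  $N(v_{small}, \sigma_{small})$ m/min, truncated at zero (at the
  defaults the truncation probability is $\Phi(-10)$, i.e. nil), and
  the displacement $s_t = \min(v_t \Delta t, d_{max})$;
* the heading is uniform on $[0, 2\pi)$ and the position update is
  $x_t = x_{t-1} + s_t\cos\varphi$, $y_t = y_{t-1} + s_t\sin\varphi$,
  wrapped torus-style into $[0, L)^2$;
* if the step ends strictly closer than $l_{home}$ (1 m) to an
  own-system entrance the pika re-enters the burrow; with budget left
  it re-emerges from a fresh random entrance on the next step.

Only outside time consumes budget, so each pika takes exactly
$\lfloor t_{tol}/\Delta t\rfloor$ steps per day and the expected daily
distance is

$$E[\text{distance}] = t_{tol}\,[\,p_{high} v_{large} + (1-p_{high}) v_{small}\,].$$

$p_{high}$ is not observable from the source material; it defaults to
$0.5$, which gives $E = 15 \times 11 = 165$ m at $t_{tol} = 15$ min —
matching the published population mean of 166 m (range 100–250 m) that
the acceptance suite re-measures. In-burrow dwell times are not
modeled: they cannot trigger cameras, and no dwell distribution is
available. Two deliberate edge rules: the return comparison is strict
(`<`), and a pika stranded far from home by the toroidal wrap simply
keeps walking until its budget runs out.

## The detection model

The field camera's arc-sector zone ($r = 8$ m, $\theta = 0.96$ rad; the
occasionally printed "mrad" is a typo) is replaced by the equal-area
isosceles triangle sharing apex and apex angle: equal sides
$s = \sqrt{\theta r^2/\sin\theta} = 8.66$ m, area
$\theta r^2/2 = 30.72$ m². Segment–triangle intersection is exact
(closed boundary, orientation predicates with a $10^{-9}$ m tolerance);
steps that wrap across the boundary seam are split into their two
real-space pieces first, so counts are invariant to seam placement.
Six cameras sit on a 2×3 grid at quarter-points of the square with
seeded random orientations; the layout is fully overridable.

**Capture-counting rule — the main calibration question.** Two rules
are implemented:

* `"step"` (default): the camera fires once per time step whose
  movement segment intersects the zone. For a segment of length $s$
  with uniform position and orientation, the per-step firing
  probability is $[A + s\,\mathcal{P}/\pi]/L^2$ (Minkowski dilation of
  the triangle, area $A = 30.72$ m², perimeter
  $\mathcal{P} = 24.7$ m), giving the expectation
  $$\lambda_{step} \approx n_{steps}\,\big(A + \bar s\,\mathcal{P}/\pi\big)\times 10^{-4}
  \approx 0.22\ \mathrm{ha}\ (t_{tol}{=}15),\quad 0.30\ \mathrm{ha}\ (t_{tol}{=}20),$$
  which is precisely the published regime (slope 0.225 at
  $t_{tol} = 15$; group means in $[0.28, 0.30]$ at $t_{tol} = 20$).
  This is also the natural reading of a trigger whose recording time
  equals the step length — the step length was chosen to match it.
* `"entry"`: fire only on an outside→inside transition (or a full
  traversal within one step); consecutive steps inside count once,
  a later re-entry counts again — the analogue of de-duplicating
  "independent photographs" in the field. Entries are a strict subset
  of hitting steps (multi-step dwells collapse to one event), so this
  rule yields systematically smaller counts — roughly the dilation
  factor $\approx 2$ lower at the defaults — and cannot reach the
  published λ level.

The default is therefore `"step"`; the acceptance suite measures λ
under it, and the per-path tests pin both rules' semantics on
constructed trajectories. Note an asymmetry worth remembering when
comparing simulated $P$ with field $P$: field tallies are
de-duplicated, simulated step counts are not; the published comparison
pools them regardless, and so does ours.

## Reproducibility

All randomness flows from one root seed through named child streams
(`"control-points"`, `"system-17"`, `"pikas"`, `"cameras"`,
`"day-3"`, …) via a documented 31-based string hash modulo $2^{31}-1$
(`derive_seed()`). Entrance placement is therefore order-independent
across systems, trials of a sweep are independent by construction, and
`run_manifest()` records every child seed actually used. Re-running
`run_trial()` with the same config and seed is bit-identical.

## What the generator emulates — and what it does not

The synthetic world reproduces the *statistical* texture the REM cares
about: territory mosaic, entrance clustering, two-mode movement, a
fixed daily activity budget, and detection-zone geometry. It does not
emulate: diurnal activity peaks (all steps are exchangeable within a
day), behavioral interaction between pikas or with cameras (no
avoidance/attraction), imperfect detection (every zone intersection
fires), underground tunnel topology, terrain or vegetation covariates.
A green λ-stability test therefore establishes that *given* this
behavioral model, capture rate is proportional to density — it does not
validate the behavioral model against wild pikas beyond the
daily-distance and capture-frequency summaries the acceptance suite
checks.

## Numerical choices

* Geometry tolerance $10^{-9}$ m (coordinates are O($10^3$) m, well
  within double precision); point-in-polygon and intersection tests are
  closed (boundary counts as inside).
* Voronoi cells are convex by construction; clipping keeps CCW
  orientation, and duplicate control points raise an error.
* Entrance and control-point sampling are bounded-attempt (10,000 darts
  per cell; 1,000 × n candidates) and fail loudly, never silently
  relaxing a spacing constraint.
* `rem_density()` takes $v$ in km/day (field convention) and converts
  internally; `lambda_closed_form()` takes m/day. All results are kept
  at full precision; Table-style rounding happens only in report code.
* The P-vs-D fit defaults to OLS with intercept (the published fit does
  not say); the through-origin slope is always reported alongside.

## Known limitations

* λ at $t_{tol} = 20$ sits at the upper edge of the published interval:
  entrance-proximity "hovering" (excursions start at entrances, and a
  zone near an entrance cluster is re-crossed often) adds a few percent
  above the uniform-field expectation of 0.296 ha, and per-camera rates
  differ persistently within a trial for the same reason. Group means
  over 15 trials land within a few thousandths of the interval edge on
  either side, so the density-stability acceptance check is sensitive
  to the seed.
* Camera orientations are drawn once per configuration, not per trial;
  sweeps inherit a small common orientation effect.
* The movement engine advances the whole population in lockstep
  vectorized steps; per-pika trajectories are only materialized on
  request (`record = TRUE`), which is memory-heavy for full-scale runs.
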