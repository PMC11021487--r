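---
title: "Modeling microvascular network flow and collateral capacity with microvasc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling microvascular network flow and collateral capacity with microvasc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microvasc)
library(dplyr)
```

## The problem

Skin microvascular networks are hybrids of bifurcating trees and arcade
(collateral) vessels that interconnect adjacent branches, creating loops
and redundant flow pathways. When a vessel is occluded — for instance by
laser cauterization in an intravital window preparation — flow
redistributes through these arcades, sometimes reversing direction, and
the network subsequently remodels its diameters. Intravital imaging gives
segment geometry (diameter, length) and per-segment flow *directions*,
but not the pressures at the vessels crossing the edge of the imaging
field of view (FOV). Those unknown boundary pressures are exactly what
determines how flow redistributes.

`microvasc` implements the full inference chain: a steady-state Poiseuille
solver on the vessel graph, a simulated-annealing inverse procedure that
estimates the unknown boundary pressures from observed flow directions, a
restart-ensemble uncertainty index that flags collateral-capable vessels,
in-silico ablation experiments with flow-reversal detection, and the
descriptive diameter-remodeling statistics used for longitudinal
measurements.

## Forward model

Each vessel segment is a rigid cylinder carrying steady laminar flow of a
Newtonian fluid. The flow in the segment joining nodes $i$ and $j$ is

$$Q_{ij} = \frac{P_i - P_j}{R_{ij}}, \qquad
  R_{ij} = \frac{128\, L_{ij}\, \mu}{\pi D_{ij}^4},$$

with $\mu = 3\ \mathrm{cP}$ by default, a standard effective viscosity for
blood in microvessels. Mass conservation at every node $i$ that is not a
boundary node reads

$$\frac{P_i - P_v}{R_{TA}} + \sum_{j} \frac{P_i - P_j}{R_{ij}} = 0,$$

where the first term is a lumped *terminal* pathway of resistance
$R_{TA}$ through the unresolved capillary bed to a compartment at constant
pressure $P_v$. For an arterial network $P_v$ is the downstream venous
reference; the same machinery solves venous networks, with the leak term
acting as a distributed inflow from the capillary bed and $P_v$
reinterpreted as a capillary pressure above the vein pressures. The leak
attaches to every non-boundary node by default (`leak = "all"`), to
terminal nodes only (`"terminal_only"`), or not at all (`"none"`), for
sensitivity analyses.

Assumptions worth keeping in mind: fixed diameters (no shear- or
pressure-driven adaptation), Newtonian rheology (no Fåhræus–Lindqvist
correction), rigid walls, and a single known pressure at the largest
vessel entering the FOV.

### Numerical formulation

Files carry micrometres; everything internal is SI (m, Pa, Pa·s,
m$^3$/s), which avoids silent $10^{-6}$ unit errors. The nodal system is
symmetric positive definite and is factorized once by sparse Cholesky
(`Matrix`). Because the matrix depends only on geometry while the
boundary pressures enter only the right-hand side, the solution is an
affine map $P_\text{unknown} = p_0 + M\,p_\text{boundary}$; the annealer
precomputes $p_0$ and $M$ and each of its iterations is a small dense
matrix–vector product rather than a fresh factorization. Solved states
report the maximum nodal mass-balance residual; on all test networks it
sits at machine precision, many orders below the $10^{-12}$ (relative to
boundary throughflow) bound the tests assert.

Flows are normalized so the reference vessel — by default the
largest-diameter segment — carries a magnitude of 1000, the convention
used for flow maps. A segment is classified stagnant (direction 0) when
its |flow| falls below the stagnation tolerance, default
$10^{-6} \times$ the reference flow. The degenerate all-pressures-equal
state solves to an all-zero flow field and skips normalization rather
than failing.

### Defaults with units

| parameter | default | why |
|---|---|---|
| viscosity $\mu$ | $3\times10^{-3}$ Pa·s | effective blood viscosity in microvessels |
| $R_{TA}$ | $100 \times$ median segment resistance | leak small relative to through-flow; must be set deliberately in studies |
| $P_v$ | 0 Pa (gauge), arterial | only pressure *differences* matter (see invariances) |
| inlet pressure | 8000 Pa ($\approx 60$ mmHg) | arteriolar scale; sets the overall gauge |
| stagnation tolerance | $10^{-6} \times$ reference flow | separates numerically-zero collateral flow from real flow |

Two exact invariances make the direction-based results insensitive to the
absolute pressure scale, which is not observable from imaging: adding a
constant to all boundary pressures and $P_v$ changes no flow, and scaling
all offsets from $P_v$ by $k$ scales every flow by $k$ without changing
any direction. Both are asserted as property tests. The magnitude of the
terminal leak, however, does depend on $R_{TA}$, which is why it is a
deliberate configuration entry rather than a hidden constant.

## The inverse problem: simulated annealing

The unknown boundary pressures are estimated by minimizing an error
function $E$: the number of segments whose computed flow direction
differs from the observed one. Unobserved or stagnant segments
(`observed_direction = 0`) contribute nothing. Optional weightings
multiply each mismatch by |normalized flow|, by diameter (µm), or both;
the unweighted count is the default.

Each run starts from a uniform random guess within the pressure bounds
(default: the interval between $P_v$ and the inlet pressure, where
FOV-edge pressures must physically lie) and performs 5000 updates. A
proposal perturbs every unknown pressure independently and is accepted
when it does not worsen $E$; a worsening of $\Delta E$ is accepted with
probability $\exp(-\Delta E / T)$ under a geometrically cooled pseudo
temperature $T(n) = T_0\,\alpha^n$. Defaults: $T_0 = n_\text{obs}/2$
(the error starts at the scale of a substantial mismatch count) and
$\alpha$ such that $T(5000) = 10^{-3}\,T_0$, i.e. effectively greedy at
the end. Ties ($\Delta E = 0$) are accepted, which deliberately lets the
chain wander across degenerate optima — the ensemble is designed to
expose exactly that degeneracy.

### Proposal distribution

The proposal scale shrinks with the fit: each increment has scale
parameter $s = \text{proposal\_scale} \times E / n_\text{obs}$ (default
`proposal_scale` = the width of the pressure bounds), so the search takes
large steps while the fit is poor and fine steps near a solution, and is
exactly stationary at $E = 0$. We use **Cauchy** rather than Gaussian
increments. With Gaussian steps, a run that reaches $E = 1$ late in the
schedule has a typical step of only $s \approx$ bounds$/n_\text{obs}$ and
a nearly frozen temperature, and can fail to cross to the basin that
flips the final segment; on tracing-scale test networks this left a
seed-dependent 5–45% of restarts stuck at $E = 1$. The Cauchy tail
produces occasional long jumps at the same scale parameter and removes
the problem entirely (all restarts reach $E = 0$ on the closed-loop
networks) while preserving the error-scaled step contract. Both the
distribution's scale and the bounds are exposed in
`annealing_config()`.

### Restart ensemble and the uncertainty index

The whole optimization is repeated from fresh random initial guesses —
100 restarts by default, with independent substream seeds derived from
one master seed so the entire ensemble is bit-reproducible. Each restart
contributes the normalized flow field of its best-fit pressures. Because
many boundary-pressure settings reproduce the same observed directions,
segments differ in how tightly the observations pin their flow:

* **uncertainty index** = SD / |mean| of a segment's normalized flow
  across restarts. Segments whose mean flow is below the stagnation
  tolerance receive an `Inf` sentinel (direction entirely unconstrained)
  and rank above all finite indices; segments with zero spread get 0.
* **direction consistency** = fraction of restarts agreeing with the
  modal direction (by construction $\ge 1/3$).

High-uncertainty, low-flow segments are the dormant collaterals: vessels
able to carry flow in either direction depending on distant pressures.
`rank_collateral_candidates()` orders segments by the index (sentinels
first, ties broken by lower |mean flow|).

## Ablation analysis

`apply_ablation()` removes occluded segments from the flow graph
(cauterization; removal avoids the ill-conditioning of a huge finite
resistance), dropping orphaned nodes; a finite-resistance mode
(`mode = "resistance"`) supports partial occlusions. Ablations that
orphan the inlet or isolate a component from every boundary node are
rejected by name. The post-ablation solve reuses the pre-ablation
boundary pressures — the acute redistribution under unchanged distal
conditions; `reanneal = TRUE` instead re-estimates pressures against
post-ablation observations. Both states are normalized against the same
reference segment so the maps share a scale.

`compare_states()` flags a segment as *reversed* only when both its pre-
and post-ablation flows exceed the stagnation tolerance and differ in
sign: a segment that merely stagnates, or that turns on from ~zero, is
not a reversal. `evaluate_prediction()` quantifies the central claim —
that high-uncertainty segments are the ones that reverse — as top-$k$
precision/recall with a seeded permutation p-value (random size-$k$
segment sets, $10^4$ draws by default).

## Remodeling statistics

Longitudinal diameter records are long-format tibbles
(`segment_id, vessel_class, day, diameter_um[, x_um, y_um]`). The
statistics are deliberately simple and fully specified:

* percent change $100\,(D_t - D_0)/D_0$ against the day-0 pre-ablation
  baseline (scale invariant by construction);
* histograms with bins *centered* on multiples of the bin width
  (half-open $[c - w/2,\, c + w/2)$), excluding vessels at or below the
  11 µm resolvable limit of the imaging;
* region summaries (mean, sample $n-1$ SD, $n$) over three equidistant
  radial classes: distance from each segment's recorded position to the
  nearest ablation site, with the maximum distance split into equal
  thirds (proximal/medial/distal); a segment exactly on a cut point goes
  to the nearer (lower) class.

## The synthetic generator

Real tracings are not redistributable, so every pipeline stage is
validated on synthetic networks that emulate their statistical structure:

* a bifurcating tree below a single trunk (150 µm arterial / 250 µm
  venous) with a Murray-like diameter taper of $2^{-1/3}$ per
  generation, floored at 11 µm, and segment lengths drawn from
  150–400 µm;
* arcade cross-links between adjacent same-depth nodes of neighbouring
  subtrees, one taper step narrower than the branches they join;
* a subset of leaves marked as FOV boundary crossings with ground-truth
  pressures drawn uniformly from the inner 80% band between $P_v$ and
  the inlet pressure (the 10% margins avoid degenerate zero-flow
  boundaries);
* forward-simulated direction observations, with a configurable fraction
  blanked to mimic unobservable segments.

Everything is deterministic under a seed. The canonical test instances
are: a 3-node toy; a two-resistor series circuit with analytically known
flow; a 9-segment two-arcade ladder whose arcades are the top-uncertainty
segments and reverse when the central trunk is ablated; a small
convergent venous fixture in which trunk ablation reroutes flow without
reversals; and a tracing-scale network (depth 6, 20 arcades, 12 unknown
boundary crossings; 147 segments) for the closed-loop recovery checks.
The suite runs that closed loop at 20 restarts of 5000 updates each; the
package defaults remain 100 restarts.

What passing these tests shows — and does not show. The closed loop
demonstrates that the inverse machinery recovers direction fields that a
Poiseuille network actually generated, and that the uncertainty index
localizes onto structurally redundant segments. It cannot show that real
skin microvasculature satisfies the model's assumptions: the generator
has no explicit capillary anastomoses between the arterial and venous
trees (they are abstracted into $R_{TA}$), no vessel tortuosity, no
measurement noise in diameters, and its remodeling fixture *programs*
the injected effect sizes (mean immediate increases of 14% for arteries
and 23% for veins, day-20 maxima of 2.5× and 3.3×, and a collateral
venule peaking at +379%) rather than deriving them from a mechanism —
it exists to verify the metrics in closed loop, labelled synthetic
throughout.

## Known limitations

* Directions are compared as ternary signs; partial information such as
  relative velocities (e.g. from decorrelation flowmetry) is not used.
* $R_{TA}$, $P_v$ and the inlet pressure set the leak magnitude and the
  overall pressure scale and are not identifiable from directions alone;
  results reported here are direction- and normalization-based.
* The venous no-reversal behaviour is a property of convergent venous
  topology with low-pressure drains, demonstrated on the constructed
  fixture; it is not a theorem about all venous networks.
* Explicit artery–vein connections are not supported; the two trees are
  solved separately, coupled only through the terminal pathway.

## A minimal session

```{r example, eval = FALSE}
fx <- fixture_two_arcade()
net <- forward_observe(fx$network, fx$bc)

ens <- run_ensemble(net, fx$bc, annealing_config(restarts = 20, seed = 1))
rank_collateral_candidates(ens)

exp <- ablation_experiment(fx$network, fx$bc, fx$trunk_segment)
tidy(exp$comparison)
evaluate_prediction(rank_collateral_candidates(ens), exp$comparison)
```
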