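---
title: "Models and methods behind mutualaid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mutualaid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutualaid)
```

This vignette documents the models implemented in **mutualaid**, the
assumptions behind them, the parameters that matter, and the places where
the design was genuinely open and a choice had to be made.

## 1. Expected rescue values

The atom of the capability evaluation is the per-person expected rescue
value, the product of three factors tabulated by decade age band and
gender: relative physical *strength* (a man in his teens/twenties = 1), the
*executing rate* observed in real post-earthquake rescue work, and a
gendered daily *activity rate* (the two genders' rates sum to 1 within each
band). `rescue_rate_table()` carries the seven bands; `expected_value()`
performs the lookup.

Two conventions matter:

* **The 4-decimal cell is the canonical value.** The published per-person
  values are 4-decimal numbers (0.1995 for a 40-year-old man), and
  published sums over residents are sums of those cells (0.1995 + 0.0609 =
  0.2604 for a 40-year-old couple, where the exact products would give
  0.26045...). `expected_value()` therefore rounds the product half-up to
  4 decimals, so every downstream aggregate reproduces published accounting
  exactly.
* **Eligibility.** Elementary and junior-high students are not rescuers:
  the default eligibility age is 16 (Japanese junior high school ends at
  15). The simulator's children setting lowers it to 10, matching the
  option of letting 10–15-year-olds take part in mutual assistance.
  Residents who themselves need assistance always score 0, as do ages
  below the youngest band.

## 2. Distance weight and building-unit capability

The weight applied to a neighbour building's value at distance $D$ is

$$dw(D) = \frac{\log_{10}(1+X)}{2\,(\log_{10}(1+D)+1)}, \qquad 0 \le D \le X,$$

zero beyond the range limit $X$ (default 100 m, the distance within which
residents are assumed able to discover a person needing help). The printed
source formula for this weight is typographically ambiguous (the placement
of the constant 2 and the logarithm base cannot be recovered from the
typeset text); the reading above reproduces the printed token order as a
numerator/denominator pair and has the attractive normalisation
$dw(0) = \log_{10}(101)/2 \approx 1.002$. It is exposed as a choice, not
asserted as the original authors' intent: the log base is an argument
(`log_base`, default 10 for the $dw(0)\approx 1$ property), and the
capability divisor below is likewise configurable. The weight is strictly
decreasing and continuous on $[0, X]$ (steepest near 0 at about $-0.44$/m)
and drops to 0 past $X$ by construction.

Building-unit capability is

$$\mathrm{capability}(i) = \frac{1}{5} \sum_j Rr_j \, dw(D_{ij}),$$

taken over buildings $j$ within $X$ of $i$ whose straight segment to $i$
crosses no barrier feature. The printed constant 5 is kept literally as a
divisor (argument `divisor`), permitting sensitivity checks. Further
conventions, each of which was open:

* **Own residents count.** Whether building $i$'s own residents contribute
  to its capability is unstated in the source; the default includes them at
  $D = 0$ (`include_self = TRUE`), on the view that a household's own
  rescuers are part of its capability.
* **Barrier semantics.** A neighbour is excluded iff the straight segment
  between centroids intersects any barrier feature — sight-line occlusion,
  not detour routing. This matches the intent of "features that are
  difficult to cross" without requiring a pedestrian network at the GIS
  evaluation stage.
* **Distances** are Euclidean between centroids in projected metre
  coordinates; inputs must already be projected (nothing geodesic is
  computed anywhere).

## 3. Group-unit accounting

Where a district is organised into small neighbourhood groups with strong
ties, distance is assumed not to limit assistance within a group, so
ability is the plain sum of member expected values (`group_accounts()`,
optionally with surveyed ability values supplied). Two surpluses are
reported: case 1 subtracts everyone needing assistance; case 2 first
deducts children under 10, who can be carried or led by a single adult.
Children under 10 are always counted among those needing assistance for
this accounting, whether or not the roster flags them, which guarantees
`surplus_case2 − surplus_case1 = n_under10` per group. District totals are
exact sums; presentation rounding (half away from zero; 4 decimals for
per-group rows, matching the published precision) is applied only at the
reporting edge.

## 4. Hazard models

Hazards are resolved **before** the evacuation and frozen into a
`hazard_timeline`, which the simulator consumes read-only. This separation
is what lets users compare what-if evacuation scenarios under an identical
damage situation. Three RNG streams (collapse, fire origins, fire spread)
are derived independently from the timeline seed, so toggling one hazard
does not shift another's draws.

* **Grid.** Damage lives on a fixed 3 m × 3 m cell grid (building / road /
  open, building-first where footprints overlap roads); evacuation lives on
  the road network as a link graph. Cell indices are 0-offset row-major
  from the extent's lower-left.
* **Collapse.** Bernoulli per building with probability looked up by
  structure and construction-year band, scaled by floor count. The source
  names only the covariates, not the values; the shipped defaults encode
  the qualitative ordering practitioners expect (pre-1981 wood worst at
  0.30, post-2000 reinforced concrete best at 0.02, probability rising
  with storeys) and are deliberately a configuration item — real studies
  must supply their own fragility table.
* **Rubble.** A collapsed building intrudes
  $\min(\text{road width},\, k \cdot \text{floors} \cdot 3\,\mathrm{m})$
  onto each adjacent link ($k$ = 0.5 by default; a crude building-height
  proxy, since only the passability threshold is specified by the model
  this follows). A link is blocked iff the residual width is strictly
  under 0.6 m — exactly 0.6 m remains passable. Rubble exists from step 0
  and never changes. The base scenario treats rubble as *passable*
  (residents thread between piles); the `rubble_blocking = "impassable"`
  setting enforces the 0.6 m rule.
* **Fire.** Wind-biased 8-neighbour cellular automaton on building cells
  only (open and road cells never ignite). Each burning cell ignites each
  unburned neighbouring building cell per second with probability
  $p_\text{base} \cdot \max(0,\, 1 + b\,w\cos\theta)$ clipped to $[0,1]$,
  where $w$ is wind speed, $b$ the bias per m/s (default 0.15) and
  $\theta$ the angle between spread direction and downwind direction.
  Origins are drawn uniformly without replacement among building cells.
  Cells burn out after `burn_duration` (default 120 s). The default
  $p_\text{base} = 0.005$/s yields a calm-air front speed of a few tens of
  metres per hour, the order observed in dense wooden urban districts; the
  original fire model this replaces lives in an external reference, so all
  constants here are configuration, not claims. A burning building blocks
  its adjacent links (fire obstruction is always impassable) and dooms
  occupants who have not yet left.

## 5. The evacuation simulator

One step is one second. Households are the moving unit — families do not
evacuate apart, and a unit containing a child under 10 never diverts to a
rescue (priority on evacuation). Movement is continuous along links
(metres of offset at the scenario walking speed), not cell hopping; the
grid is consulted only for hazard state. Start times are drawn uniformly
per household over `start_window` (default 0–120 s; the parameter exists
in the source but no window is printed, so a short staggering window was
chosen to avoid the unrealistic simultaneous start it explicitly rules
out).

Destination choice is the network-shortest path to the nearest designated
site avoiding links known blocked, ties broken by smallest site id. A unit
that meets a newly blocked link replans from the node before it; if no
route to any site remains, the unit awaits public help.

Victims are of two kinds: occupants of collapsed buildings (buried with
probability `buried_prob`, default 1 — the buried fraction is unstated, so
the conservative default makes every present occupant of a collapsed
building a victim) and residents flagged as needing evacuation support.
An evacuating unit that perceives a waiting victim within
`perception_range` (straight line, occluded by barriers) diverts, travels
to the victim, and joins the gathered pool. The victim is
rescued/supported the moment the pool's summed expected values **strictly
exceed** `rescue_threshold` (default 1); rescue is instantaneous and the
victim then evacuates with the rescuers. If the threshold is not exceeded
by `rescue_give_up` (default 300 s) the rescuers resume evacuation and the
victim awaits public help. Following the literal phrasing "after a lapse
of 5 min from earthquake generation", the give-up clock runs from $t = 0$
by default; `give_up_from = "rescue_start"` provides the per-attempt
alternative. A household that starts with one of its own members waiting
as a victim engages that victim immediately at departure (families know
their own), but only while mutual assistance is active.

A perception range of 0 disables mutual assistance entirely — this is the
"absence of mutual assistance" comparison case, and it guarantees exactly
zero people receiving assistance rather than a small residual.

Morning runs place all roster members at home; evening runs drop residents
flagged as commuters. Assistance-need flags missing from a roster are
drawn per age band (0.1 for 60–69, 0.2 for 70 and over, 0.05 otherwise);
children under 10 are never flagged (they move with a parent).

Terminal states are absorbing: *evacuated*, *awaiting public support*
(unrescued victims, routeless units, anyone unresolved at the horizon) and
*casualty* (agents and victims overtaken by fire in their building). The
counts of the three always sum to the number present. Whether
rescued-then-evacuated victims count in the successful-evacuation total is
unstated in the source; they do by default
(`count_rescued_in_success = TRUE`).

## 6. Batch statistics

Over a batch of $n$ runs (ten by convention): (a) residents present,
(b) summed successful evacuations, (c) $= ((b)/n)/(a) \times 100$,
(d) summed victims, (e) summed rescued/supported, (f) $= (e)/(d) \times
100$. Percentages are presented round-half-up at 2 decimals, with raw
fractions also returned; (f) with $(d) = 0$ is undefined (`NA`), not 0.
Published instances of these tables are not always exactly consistent with
their own footnote formulas (presentation rounding); the package computes
the formulas.

## 7. The synthetic town generator

No input data ship with real geometry, so `generate_town()` fabricates a
self-contained district: a rectangular street grid (3 × 5 blocks of
60 m × 45 m by default, one neighbourhood group per block, 15 groups),
eight 9 m × 9 m buildings per block with structure/floors/year attributes
skewed toward old wooden low-rise stock, two evacuation sites at opposite
corners, an optional river-like mid-town barrier, and a 398-resident
roster of mixed households whose commuter fraction (0.43 of ages 20–64)
leaves roughly 300 present in the evening variant — the morning/evening
populations of the reference district this emulates. Generation is exactly
reproducible under the spec seed, and generated networks are connected by
construction.

What the generator does **not** emulate: irregular street geometry,
dead-ends and width heterogeneity of real districts, multi-building
parcels, daytime visitor populations, and spatial clustering of vulnerable
residents. Tests passing on synthetic towns therefore validate the
mechanics and invariants of the models, not predictions for any real
district.

The separate `group_fixture()` reproduces the published 15-group
accounting example's per-group counts exactly; the per-group ability
values behind that example depend on unpublished member ages, so they are
provided as data (`group_fixture_abilities()`) to be supplied as the
`ability` override rather than recomputed.

## 8. Numerical and degenerate-input conventions

* Reported values round half away from zero (`round_half_up()`); internal
  arithmetic is exact doubles except the 4-decimal canonicalisation of
  per-person expected values (§1).
* Site ties break to the smallest site id; victim-detection ties break to
  the nearest victim, then the smallest victim index.
* Empty buildings and empty groups score 0; an empty roster, a dangling
  building reference, negative distances, unknown genders, infeasible town
  specs and a timeline shorter than the scenario horizon are errors, not
  silent defaults.
* All randomness flows through integer seeds; sub-streams are derived with
  a multiplicative scramble kept below $2^{31}$.

## 9. Problem sizes used by the test suite

The suite exercises the full pipeline on compact instances chosen to keep
a complete run in tens of seconds: engine and property tests use a
2 × 3-block town of ~140 residents with a 480 s horizon, the
perception-monotonicity property uses 50 paired-seed run pairs, fire
Monte-Carlo checks use a 15 × 15-cell burnable field with 20–25
replicates, and oracle comparisons (capability double loop, exhaustive
path enumeration) run on ≤ 36 buildings and ≤ 20-node graphs. These sizes
are the package's own testing choices; nothing in the models depends on
them.

## 10. Known limitations

* No congestion, panic, or capacity effects on links or at sites; agents
  do not interact except through rescue.
* No initial firefighting by residents (deliberately out of scope) and no
  public rescue-team model — "awaiting public support" is a terminal
  label, not a modelled process.
* The fire and collapse defaults are plausible placeholders, not
  calibrated fragility/spread models; studies must configure them.
* Barrier handling is sight-line occlusion at the capability stage and
  perception stage only; barriers do not reshape the road network itself
  (a road crossing a river is assumed to be a bridge).
* Rescued victims move at the unit's scenario speed; assisted movement is
  not slowed.
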