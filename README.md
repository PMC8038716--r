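# mutualaid

Support tooling for drafting Community Disaster Management Plans (CDMPs):
a quantitative evaluator of neighbourhood **mutual-assistance (rescue)
capability** coupled to a **one-second-step multi-agent earthquake
evacuation simulator**.

After a major earthquake in a dense urban district, many residents —
elderly people, people with disabilities, occupants buried under collapsed
buildings — cannot evacuate without help from neighbours, and public rescue
teams cannot reach everyone in time. Planners and neighbourhood
associations therefore need to know *where* mutual-assistance capability
falls short and *how much* difference neighbourly rescue makes. This
package provides both instruments for that workflow: a GIS-style capability
map to extract low-capability areas, and an agent-based simulator to show
the effect of mutual assistance on evacuation outcomes under fixed,
precomputed damage scenarios.

## The model

**Per-person expected rescue value.** Each resident's capacity to rescue is

```
Rr = strength × executing rate × activity rate
```

by decade age band and gender (e.g. a 40-year-old man: 0.93 × 0.298 × 0.72
= 0.1995). Elementary/junior-high-aged children and residents who
themselves need assistance score 0. A building's value `Rr_j` is the sum
over its residents.

**Building-unit capability.** Neighbours within a range limit X (default
100 m) contribute their `Rr_j`, decayed by distance and divided by a scale
constant:

```
dw(D) = log10(1 + X) / (2 · (log10(1 + D) + 1)),  0 ≤ D ≤ X  (else 0)
capability(i) = Σ_j Rr_j · dw(D_ij) / 5
```

Neighbours whose straight sight line crosses an impassable barrier (river,
railway, wide trunk road) are excluded.

**Group-unit accounting.** For districts organised into small groups with
strong community ties, ability is the unweighted sum of member expected
values, and surplus/shortage is reported against the count of people
needing assistance (case 1) and against that count minus children under 10
(case 2 — an infant can be carried by one adult).

**Evacuation simulator.** Households evacuate along the road network to the
nearest designated site (1 s = 1 step). Beforehand, a hazard timeline is
precomputed and frozen: building collapse (Bernoulli per building from
structure/floors/year), rubble that blocks a road when the residual width
drops under 0.6 m, and a wind-biased cellular-automaton fire on a 3 m grid.
Evacuating agents who perceive a victim within the perception range divert
and gather; the victim is rescued when the gathered expected values sum to
more than 1, abandoned when rescuers give up 5 min after the quake. Agents
in burning buildings, unrescuable victims, and agents cut off from every
route await public help.

## Worked example

```r
library(mutualaid)

# group-unit accounting on the bundled 15-group reference fixture
acc <- group_accounts(group_fixture(), ability = group_fixture_abilities())
district_totals(acc)
#>   n_groups n_assist n_under10 ability surplus_case1 surplus_case2
#> 1       15       47        14 30.1786      -16.8214       -2.8214

# synthetic district, morning scenario, ten simulation runs
town  <- generate_town(town_spec(seed = 1))
batch <- run_batch(town, scenario(), n_runs = 10, master_seed = 1)
summarize_batch(batch)
#> <batch_summary> over 10 runs
#>  (a) residents:                   398
#>  (b) successful evacuations:      3050
#>  (c) evacuation success rate:     76.63%
#>  (d) requiring mutual assistance: 961
#>  (e) receiving mutual assistance: 112
#>  (f) assistance success rate:     11.65%
```

The district totals say the 15 groups jointly muster an ability of 30.18
against 47 people needing assistance — a shortage of 16.82 (or 2.82 once
under-10s are deducted), which is the quantity a CDMP discussion starts
from. The batch summary says that with mutual assistance enabled, on
average 305 of 398 residents reach a site per run (76.63%), and 112 of the
961 victim-cases across the ten runs were rescued or supported by
neighbours (11.65%). Re-running with `scenario(perception_range = 0)`
switches mutual assistance off and drives (e) and (f) to exactly zero —
the comparison that makes the effect of mutual assistance visible.

A command-line interface covers the same workflow
(`inst/cli/mutualaid synth | capability | hazard | simulate | report`);
per-building capability maps and per-building helped/unhelped counts are
written as GeoJSON for map display.

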