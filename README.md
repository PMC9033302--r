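# isofoodweb

Trophic-niche and functional-diversity analysis of soil animal food webs
from bulk stable isotope data (δ13C, δ15N).

Soil communities route energy through a "fast" channel based on freshly
fixed plant carbon and a "slow" channel based on microbially processed
detritus. Bulk isotope ratios separate the two: Δ15N (animal δ15N minus the
local leaf-litter δ15N) rises ~3–4‰ per trophic level, and Δ13C tracks the
basal carbon source. `isofoodweb` turns per-sample isotope tables into
per-community diversity metrics and land-use contrast statistics:

* **Calibration and aggregation** — δ values calibrated against the
  plot-specific litter baseline (Δ = animal − litter), litter/soil layers
  merged, one mean niche per taxon × plot.
* **Thirteen isotopic metrics per community** — min, max, range and average
  position per isotope on raw ‰ values; richness (convex-hull area),
  divergence, dispersion, evenness and uniqueness in a [0, 1]-scaled
  two-isotope space, each computed from a *community* perspective
  (all taxa weighted equally, wᵢ = 1/S) and an *energetic* perspective
  (taxa weighted by their share wᵢ = Bᵢ/ΣBⱼ of summed community
  metabolism, with metabolic rates B from group-specific allometric
  regressions ln B = ln b₀ + a·ln mass − E/kT).
* **Contrast statistics** — Welch t contrasts of each taxon against a
  reference system, additive two-way ANOVA (system + landscape) with Tukey
  HSD compact letters, and a from-scratch rank-based ANOSIM permutation
  test, R = (r̄_between − r̄_within)/(n(n−1)/4).
* **A seeded scenario generator** emulating a replicated land-use design
  (2 landscapes × 4 systems × 4 plots, 23 taxon groups), so the entire
  pipeline runs and is testable with no external data.

The metric definitions follow the functional-diversity framework
(divergence from the hull-vertex centroid, dispersion around the weighted
centroid, minimum-spanning-tree evenness, nearest-neighbour uniqueness);
formulas and all numerical conventions are in the package vignette
(`vignettes/isotopic-foodweb-metrics.Rmd`).

## Worked example

```r
library(isofoodweb)

# the fixed rainforest mean-niche community (23 groups)
fx <- generate_worked_rainforest()
one_dim_metrics(fx$D13C)$range   # 3.0  (Δ13C spans 3.4–6.4 ‰)
one_dim_metrics(fx$D15N)$range   # 14.2 (Δ15N spans −5.0–9.2 ‰)

# a full synthetic study: simulate, preprocess, weight, measure, compare
res <- run_all("out", scenario = scenario_config(seed = 7))
nrow(res$metrics)        # 32  (one row of 13 metrics per community)
res$anosim_community     # ANOSIM: R = 0.348, p = 0.001 (999 permutations)
res$anosim_energetic     # ANOSIM: R = 0.226, p = 0.001 (999 permutations)
```

The last two lines are the package's core comparison: land-use systems
separate strongly when every taxon counts equally (community perspective),
but much less once taxa are weighted by metabolism — the dominant
earthworms keep their detrital niche in plantations and anchor the
energetic metrics. A run writes `metrics.csv` (one row per community),
`niches.csv`, `contrasts.csv`, `anova_tukey.csv`, `anosim.json` and a JSON
manifest per stage into the output directory.

A thin command-line wrapper with `simulate` / `metrics` / `compare` / `all`
subcommands is installed at `inst/cli/isofoodweb.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/isofoodweb.R", package="isofoodweb"))')" all --out out --seed 7
```

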