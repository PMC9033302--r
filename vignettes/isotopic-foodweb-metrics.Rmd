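---
title: "Isotopic functional diversity of soil food webs: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotopic functional diversity of soil food webs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific problem

Bulk stable isotope ratios of soil animals carry two complementary trophic
signals. The nitrogen ratio (δ15N) rises by roughly 3–4‰ per trophic level
and therefore proxies trophic position; the carbon ratio (δ13C) changes
little with trophic transfer but tracks the basal carbon source — animals
enriched in 13C rely on "old", microbially processed detrital carbon (the
slow, brown energy channel), while depleted animals rely on freshly fixed
plant carbon (the fast, green channel). Because absolute δ values vary from
site to site with the local vegetation and litter, consumer values are only
comparable across sites after calibration against a local baseline.

`isofoodweb` implements this workflow for whole communities of high-rank
soil animal groups sampled across replicated land-use systems: calibration
against plot litter, aggregation to one trophic niche per group and plot,
isotopic diversity metrics from an unweighted and a metabolism-weighted
perspective, and land-use contrast statistics. A seeded scenario generator
emulates the sampling design of a replicated tropical land-use study, so
every stage can be exercised and tested without any external data.

## From raw ratios to trophic niches

Isotope ratios R (13C/12C or 15N/14N) are expressed in delta notation,
δ = (R_sample/R_standard − 1) × 1000 (‰), against V-PDB (carbon) and
atmospheric N2 (nitrogen). Calibrated values are

Δ13C = δ13C_animal − δ13C_litter,  Δ15N = δ15N_animal − δ15N_litter,

with the litter value specific to the sample's plot. The sign convention is
animal minus litter, so consumers above the litter baseline are positive;
a litter sample calibrated against itself gives exactly 0, and calibration
is invariant to any constant offset applied to both animal and litter
values (both properties are unit-tested).

Litter- and soil-extracted samples of the same group and plot are merged
before aggregation (their isotope values do not differ systematically at
the level of high-rank groups). Aggregation takes the plain arithmetic mean
over samples; an alternative that weights each pooled sample by its number
of individuals is available (`aggregate_weighted_by_n` in the run
configuration) but is off by default, since merging without stated weights
is the simplest defensible reading of a group-level analysis.

## Metabolism weights

The energetic perspective weights each group by its share of summed
community metabolism, w_i = B_i / Σ_j B_j. Metabolic rates can be supplied
precomputed (one total per taxon and plot) or derived from body
measurements using group-specific allometric regressions:

mass = exp(c0 + c1·ln length + c2·ln width),
ln B = ln b0 + a·ln mass − E/(kT),

with k = 8.617×10⁻⁵ eV/K and a default temperature of 298.15 K (a tropical
lowland soil assumption, overridable per call). The shipped coefficient
table (`inst/extdata/allometric_coefficients_synthetic.csv`) contains
placeholder values that document the schema; real analyses should supply
published regression coefficients for their groups. Groups present
isotopically but missing from the metabolism table receive weight 0 and are
retained, so the community perspective stays complete; a community whose
weights are all zero is an error because weighted metrics are then
undefined.

## The thirteen isotopic metrics

One-dimensional metrics — minimum, maximum, range, and the unweighted and
weighted average position — are computed per isotope on raw per-mil Δ
values. Multidimensional metrics are computed in a common isotope space in
which each axis is min–max scaled to [0, 1] using the extremes over *all*
communities of the run jointly, so both isotopes contribute equally.
Scaling never clips: a value outside the fitted ensemble is an error, which
can only happen if the ensemble was fitted on different data.

For S groups at scaled positions p_i with weights w_i (Σw_i = 1):

* **Isotopic richness (IRic)** — area of the convex hull; 0 for S < 3 or
  collinear points. The only metric without a weighted variant, since the
  hull ignores weights by construction.
* **Isotopic divergence (IDiv)** — with G the unweighted centroid of the
  hull vertices, dG_i = ‖p_i − G‖ and d̄G their unweighted mean over all S
  points: IDiv = (Δd + d̄G)/(Δ|d| + d̄G), where Δd = Σ w_i (dG_i − d̄G) and
  Δ|d| = Σ w_i |dG_i − d̄G|. Near 1 when weight sits on extreme niches,
  near 0 when it sits at the centre.
* **Isotopic dispersion (IDis)** — distances d_i to the *weighted* centroid,
  scaled by their maximum: IDis = Σ w_i d_i / max d_i; a scaled
  multidimensional variance. 0 when all points coincide.
* **Isotopic evenness (IEve)** — over the S−1 branches of the Euclidean
  minimum spanning tree, EW_l = dist(i,j)/(w_i + w_j) and
  PEW_l = EW_l/Σ EW: IEve = (Σ min(PEW_l, 1/(S−1)) − 1/(S−1))/(1 − 1/(S−1)).
* **Isotopic uniqueness (IUni)** — nearest-neighbour distances NND_i scaled
  by their maximum: IUni = Σ w_i NND_i / max NND_i; the inverse of average
  isotopic redundancy.

Each of IDiv/IDis/IEve/IUni is computed twice: unweighted (w_i = 1/S, the
community perspective) and metabolism-weighted (the energetic perspective).
With min, max, range and the average position per isotope, plus richness,
this yields the thirteen per-community metric kinds the package reports.

Numerical conventions worth stating explicitly:

* Degenerate communities produce missing values with reasons, never errors:
  S < 3 (no hull, no MST), collinear points (degenerate hull), fully
  coincident points (IDis = IUni = 0 by convention; IEve undefined).
* MST ties are broken by lexicographic (i, j) edge order, so results are
  deterministic under permutation-stable input ordering.
* A spanning-tree branch may join two zero-weight taxa (taxa isotopically
  present but energetically absent). Its branch weight EW would be
  undefined; the denominator is floored at machine epsilon, the resulting
  huge EW is capped by the min(PEW, 1/(S−1)) term, and evenness is pushed
  down — the defensible reading of "metabolism clusters elsewhere".
* Equal-weight equivalence holds to 1e-12: calling any weighted metric with
  w_i = 1/S reproduces the unweighted value exactly. This is enforced by a
  property test and is the reason the two perspectives are comparable.

Because the scaling ensemble is refit for every run, IRic (and the other
scaled metrics) are *relative* to that run's ensemble. Two consequences:
values from different runs are not directly comparable unless computed
under a shared ensemble (pass an `ensemble` to `compute_metrics_table()`),
and widening all niches in a scenario does not widen scaled richness unless
measured against a fixed ensemble — the package's parameter-recovery test
therefore fits one ensemble across all spread levels before comparing.

## Land-use contrast statistics

* **Per-taxon contrasts** — Welch (unequal-variance) two-sample t-tests of
  each group's plot-level Δ values in each non-reference system against the
  reference system (default rainforest), reported as other minus reference
  with raw-p significance stars (* < 0.05, ** < 0.01). Contrasts with fewer
  than 2 plots on either side are retained with `NA` statistics and a
  reason rather than silently dropped. p values are deliberately not
  adjusted by default (taxon-level stars are descriptive); a
  Benjamini–Hochberg option exists.
* **Per-metric ANOVA** — additive two-factor analysis of variance
  (system + landscape, no interaction; the landscape factor absorbs the
  regional block effect), followed by Tukey HSD on the land-use factor and
  a compact letter display. Letters are the maximal cliques of the
  "not significantly different" graph, so they can never contradict a
  significant pair. Zero-variance input yields a single shared letter.
* **ANOSIM** — analysis of similarities written from first principles:
  metric columns are z-standardised (constant columns dropped), distances
  are Euclidean, converted to ranks (ties averaged), and
  R = (r̄_between − r̄_within)/(n(n−1)/4). The p value is
  (1 + #{permuted R ≥ observed})/(1 + n_perm) over seeded label
  permutations (999 by default). Because R is rank-based it is invariant
  under monotone transforms of the distances; this, agreement with an
  exhaustive enumeration at n = 6, and agreement of R with an independent
  implementation are all asserted by tests.

The community-perspective ANOSIM profile contains all thirteen unweighted
metrics (min/max/range and richness cannot be weighted and so belong to
this perspective); the energetic profile contains the six weighted
variants. Communities with undefined metrics are excluded from the
profile's complete cases.

## What the scenario generator emulates

Defaults encode a replicated land-use design: 2 landscapes × 4 systems
(rainforest, jungle rubber, rubber, oil palm) × 4 plots = 32 communities
from a pool of 23 high-rank groups. Choices, with reasoning:

* **Fixed niche pool.** Rainforest group means span 3.4–6.4‰ in Δ13C and
  −5.0 (Pauropoda) to 9.2‰ (Diplura) in Δ15N, with micropredators above
  macropredators and earthworms (Annelida) among the most 13C-enriched
  groups. Niches are Gaussian around these means (between-plot SD 0.5‰,
  within-plot sample SD 0.8‰ — typical bulk-tissue spreads); Gaussian is
  chosen for transparency, not realism of tails.
* **Community size.** Groups per community are 6 + Binomial(11, p) with p
  set per system so means grade 15 / 13.5 / 11 / 9.7 along the land-use
  gradient (biodiversity erodes under conversion) while averaging 12.3 over
  the design and always staying in 6–17. Annelida is always present.
* **Carbon shift.** In converted systems every group except Annelida is
  depleted by a per-system shift of −1 / −2 / −3‰ (jungle rubber / rubber /
  oil palm): a switch toward the fast plant-carbon channel graded by
  land-use intensity, while earthworms keep their detrital niche.
* **Nitrogen structure.** The jungle-rubber trophic ladder is stretched by
  ×1.16 around the pool mean (longest food chains at intermediate
  disturbance) and oil-palm non-Annelida Δ15N is depressed by 1‰ (feeding
  on 15N-depleted algae and lichens under open canopies).
* **Metabolism.** Non-Annelida totals are log-normal with sdlog 2 — shares
  of 23 high-rank groups realistically span orders of magnitude — and the
  Annelida total is set to the configured share of the community total
  (15.4% in rainforest, 78% in plantations) up to mean-one noise, so the
  dominance holds in expectation.
* **Litter baselines** are Gaussian, δ13C ≈ −29‰, δ15N ≈ 0‰ (typical C3
  leaf litter); these are generator conveniences.

With these defaults the qualitative signature of interest emerges from the
pipeline rather than being asserted: the community-perspective ANOSIM R
exceeds the energetic-perspective R in 9 of 10 seeds (because weighted
metrics are anchored to the unshifted, dominant earthworms), and
concentrating weight on a single taxon drives dispersion toward 0 while
leaving all unweighted metrics untouched.

What the generator does *not* emulate: true per-taxon variances and
covariances, within-group species turnover, spatial subplot structure,
measurement error models beyond a single SD, and any environmental
covariates. Passing tests on synthetic data therefore demonstrate that the
estimators and statistics behave correctly under the emulated design — not
that any particular field system will show these effect sizes.

## Problem sizes used by the test and acceptance suites

The property suites run 1,000 random communities for the bounds checks,
brute-force oracles at S ≤ 10 (convex hull), S ≤ 7 (spanning trees) and
n = 6 (exhaustive ANOSIM null), 5 × 10 scenario replicates for parameter
recovery, and 10 replicate scenarios for the perspective contrast; these
sizes give stable results for the properties being checked while keeping a
full run comfortably fast.

## Known limitations

* Two isotope dimensions only; no ellipse-based niche statistics.
* No isotopic fractionation or lipid corrections; calibration assumes the
  litter baseline is the appropriate reference for every group at a plot.
* Tukey HSD on the additive model uses the standard balanced-design
  approximation for moderately unbalanced data.
* The compact letter display is a description of the pairwise test matrix,
  not an inference procedure in its own right.
* ANOSIM on z-standardised Euclidean distances is one defensible choice of
  dissimilarity; rank-based R limits, but does not remove, sensitivity to
  that choice.
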