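Package: isofoodweb
Title: Isotopic Functional Diversity of Soil Food Webs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of soil animal food webs from bulk stable isotope data
    (delta13C, delta15N). Animal values are calibrated against the plot-level
    leaf-litter baseline, aggregated to one trophic niche per taxon and plot,
    and summarised by one-dimensional (minimum, maximum, range, average
    position) and multidimensional isotopic diversity metrics (richness,
    divergence, dispersion, evenness, uniqueness), each computed from an
    unweighted "community" perspective and from an "energetic" perspective in
    which taxa are weighted by their share of summed community metabolism.
    Includes allometric estimation of metabolic rates from body dimensions,
    land-use contrast statistics (Welch t contrasts against a reference
    system, additive two-way ANOVA with Tukey compact letters, a rank-based
    ANOSIM permutation test), and a seeded synthetic-scenario generator that
    emulates a replicated multi-landscape land-use design so the whole
    pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
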