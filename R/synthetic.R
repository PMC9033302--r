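# Synthetic scenario generator.
#
# Emulates a replicated tropical land-use design: 2 landscapes x 4 land-use
# systems (rainforest, jungle rubber, rubber, oil palm) x 4 plots = 32
# communities drawn from a pool of 23 high-rank soil animal groups, 6-17
# groups per community (mean 12.3). Trophic niches are Gaussian per taxon and
# system around a fixed pool of rainforest mean positions; in the converted
# systems most taxa are shifted to lower D13C (1-3 per mil, graded by
# land-use intensity so that oil palm is the most depleted) while earthworms
# (Annelida) keep their niche and take a dominant share of community
# metabolism (15.4% of summed metabolism in rainforest, 78% in the converted
# systems, in expectation).

#' Pool of rainforest mean trophic niches for the 23 groups
#'
#' Fixed per-taxon mean litter-calibrated values used by the generator and by
#' [generate_worked_rainforest()]. D13C means span 3.4 (Coleoptera,
#' Oribatida) to 6.4 (Orthoptera, Pauropoda) per mil; D15N means span -5.0
#' (Pauropoda) to 9.2 (Diplura) per mil, with micropredators (Diplura,
#' Pseudoscorpiones, Mesostigmata) above macropredators (Chilopoda,
#' Formicidae, Araneae).
#'
#' @return `data.frame` with columns `taxon, D13C, D15N` (23 rows).
#' @export
taxon_niche_pool <- function() {
  df <- data.frame(
    taxon = c("Oribatida", "Collembola", "Symphyla", "Protura", "Annelida",
              "Blattodea", "Diplopoda", "Isopoda", "Isoptera", "Psocoptera",
              "Hemiptera", "Lepidoptera", "Orthoptera", "Thysanoptera",
              "Diptera", "Coleoptera", "Pseudoscorpiones", "Mesostigmata",
              "Diplura", "Formicidae", "Chilopoda", "Araneae", "Pauropoda"),
    D13C = c(3.4, 4.0, 5.2, 4.8, 5.8, 4.2, 4.5, 5.0, 4.3, 4.1,
             3.9, 3.8, 6.4, 4.4, 5.5, 3.4, 5.4, 4.9, 6.0, 4.6,
             5.9, 4.7, 6.4),
    D15N = c(1.5, 2.0, 5.5, -3.5, 3.0, -0.5, 0.0, 6.0, -1.0, -1.5,
             -2.0, 0.5, -2.5, 1.0, 4.5, 2.5, 8.0, 6.5, 9.2, 4.0,
             6.2, 5.0, -5.0),
    stringsAsFactors = FALSE
  )
  df
}

#' Scenario configuration
#'
#' Defaults encode the emulated study design; see the package vignette for
#' the reasoning behind each value.
#'
#' @param seed integer seed controlling every random draw.
#' @param n_landscapes number of landscapes (replicated blocks).
#' @param systems land-use system labels.
#' @param plots_per_system_per_landscape replicate plots per cell.
#' @param taxa_range smallest/largest number of groups per community.
#' @param taxa_mean expected number of groups per community; either one
#'   number for all systems or a named vector per system. The default grades
#'   richness down with land-use intensity (biodiversity erosion under
#'   conversion) while averaging 12.3 over the whole design.
#' @param d13C_shift_plantation additive D13C shift (per mil) applied to all
#'   taxa except Annelida in non-rainforest systems; either a single number
#'   for all converted systems or a named vector per system. The default
#'   grades the depletion by land-use intensity within the 1-3 per mil band.
#' @param annelida_share expected Annelida share of summed community
#'   metabolism, named for `"rainforest"` and `"plantation"` (all other
#'   systems).
#' @param d15N_shift per-system additive D15N shift (per mil) for
#'   non-Annelida taxa; the default depresses trophic positions in oil palm.
#' @param d15N_spread per-system multiplier on the deviation of each taxon's
#'   D15N mean from the pool average; values above 1 stretch the trophic
#'   ladder (longest food chain in the agroforest system).
#' @param niche_sd between-plot SD (per mil) of a taxon's niche around its
#'   system mean, applied to both isotopes.
#' @param sample_sd within-plot measurement/sample SD (per mil).
#' @param soil_layer_prob probability that a taxon-plot also yields a soil
#'   layer sample (a litter sample is always taken).
#' @param metab_sdlog log-normal SD of non-Annelida metabolism totals.
#' @param litter_d13C,litter_d15N,litter_sd Gaussian litter baseline
#'   parameters (per mil), typical of C3 leaf litter.
#' @return named list of class `iso_scenario_config`.
#' @export
scenario_config <- function(seed = 1L,
                            n_landscapes = 2L,
                            systems = LAND_USE_SYSTEMS,
                            plots_per_system_per_landscape = 4L,
                            taxa_range = c(6L, 17L),
                            taxa_mean = c(rainforest = 15, jungle_rubber = 13.5,
                                          rubber = 11, oil_palm = 9.7),
                            d13C_shift_plantation = c(jungle_rubber = -1,
                                                      rubber = -2,
                                                      oil_palm = -3),
                            annelida_share = c(rainforest = 0.154, plantation = 0.78),
                            d15N_shift = c(jungle_rubber = 0, rubber = 0,
                                           oil_palm = -1),
                            d15N_spread = c(jungle_rubber = 1.16, rubber = 1,
                                            oil_palm = 1),
                            niche_sd = 0.5,
                            sample_sd = 0.8,
                            soil_layer_prob = 0.6,
                            metab_sdlog = 2,
                            litter_d13C = -29,
                            litter_d15N = 0,
                            litter_sd = 0.5) {
  pool <- taxon_niche_pool()
  if (taxa_range[2] > nrow(pool)) {
    stop("taxa_per_plot upper bound exceeds the taxon pool size (",
         nrow(pool), ")", call. = FALSE)
  }
  if (taxa_range[1] < 1 || taxa_range[1] > taxa_range[2]) {
    stop("invalid taxa_range", call. = FALSE)
  }
  if (length(taxa_mean) == 1 && is.null(names(taxa_mean))) {
    taxa_mean <- stats::setNames(rep(taxa_mean, length(systems)), systems)
  }
  if (!all(systems %in% names(taxa_mean))) {
    stop("taxa_mean must name every system (or be a single number)", call. = FALSE)
  }
  if (any(taxa_mean < taxa_range[1]) || any(taxa_mean > taxa_range[2])) {
    stop("taxa_mean must lie within taxa_range", call. = FALSE)
  }
  if (any(annelida_share <= 0) || any(annelida_share >= 1)) {
    stop("annelida_share must be in (0, 1)", call. = FALSE)
  }
  converted <- setdiff(systems, "rainforest")
  if (length(d13C_shift_plantation) == 1 && is.null(names(d13C_shift_plantation))) {
    d13C_shift_plantation <- stats::setNames(
      rep(d13C_shift_plantation, length(converted)), converted)
  }
  if (!all(converted %in% names(d13C_shift_plantation))) {
    stop("d13C_shift_plantation must name every non-rainforest system",
         call. = FALSE)
  }
  for (nm in c("d15N_shift", "d15N_spread")) {
    v <- get(nm)
    if (length(v) == 1 && is.null(names(v))) {
      v <- stats::setNames(rep(v, length(converted)), converted)
      assign(nm, v)
    }
    if (!all(converted %in% names(v))) {
      stop(nm, " must name every non-rainforest system", call. = FALSE)
    }
  }
  cfg <- list(seed = as.integer(seed), n_landscapes = as.integer(n_landscapes),
              systems = systems,
              plots_per_system_per_landscape = as.integer(plots_per_system_per_landscape),
              taxa_range = as.integer(taxa_range), taxa_mean = taxa_mean,
              d13C_shift_plantation = d13C_shift_plantation,
              annelida_share = annelida_share,
              d15N_shift = d15N_shift, d15N_spread = d15N_spread,
              niche_sd = niche_sd, sample_sd = sample_sd,
              soil_layer_prob = soil_layer_prob, metab_sdlog = metab_sdlog,
              litter_d13C = litter_d13C, litter_d15N = litter_d15N,
              litter_sd = litter_sd)
  class(cfg) <- "iso_scenario_config"
  cfg
}

# Number of taxa for one community: lower bound + binomial spread chosen so
# the expectation equals the system's taxa_mean while staying inside
# taxa_range.
.draw_taxa_count <- function(cfg, sys) {
  span <- cfg$taxa_range[2] - cfg$taxa_range[1]
  p <- (cfg$taxa_mean[[sys]] - cfg$taxa_range[1]) / span
  cfg$taxa_range[1] + stats::rbinom(1, span, p)
}

#' Generate a full synthetic scenario
#'
#' Draws litter baselines, community composition, per-plot taxon niches,
#' isotope samples (litter layer always, soil layer with probability
#' `soil_layer_prob`), and per-taxon metabolism totals with the configured
#' Annelida dominance enforced in expectation. Fully reproducible from
#' `config$seed`.
#'
#' @param config a [scenario_config()].
#' @return list with elements `isotope`, `baseline`, `metabolism`
#'   (data frames in the package's CSV schemas) and `config`.
#' @export
generate_scenario <- function(config = scenario_config()) {
  stopifnot(inherits(config, "iso_scenario_config"))
  set.seed(config$seed)
  pool <- taxon_niche_pool()
  landscapes <- paste0("landscape_", seq_len(config$n_landscapes))

  iso_rows <- list(); base_rows <- list(); met_rows <- list()
  plot_no <- 0L
  for (ls in landscapes) {
    for (sys in config$systems) {
      for (rep_i in seq_len(config$plots_per_system_per_landscape)) {
        plot_no <- plot_no + 1L
        plot <- sprintf("P%02d", plot_no)
        base <- data.frame(
          plot = plot,
          d13C_litter = stats::rnorm(1, config$litter_d13C, config$litter_sd),
          d15N_litter = stats::rnorm(1, config$litter_d15N, config$litter_sd),
          stringsAsFactors = FALSE
        )
        base_rows[[plot_no]] <- base

        n_taxa <- .draw_taxa_count(config, sys)
        others <- setdiff(pool$taxon, "Annelida")
        taxa <- c("Annelida", sample(others, n_taxa - 1))
        taxa <- sort(taxa)

        # plot-level niche per taxon: system mean + Gaussian plot effect
        pi_idx <- match(taxa, pool$taxon)
        mu_c <- pool$D13C[pi_idx]
        mu_n <- pool$D15N[pi_idx]
        if (sys != "rainforest") {
          not_worm <- taxa != "Annelida"
          mu_c[not_worm] <- mu_c[not_worm] + config$d13C_shift_plantation[[sys]]
          pool_n_mean <- mean(pool$D15N)
          mu_n[not_worm] <- pool_n_mean +
            config$d15N_spread[[sys]] * (mu_n[not_worm] - pool_n_mean) +
            config$d15N_shift[[sys]]
        }
        plot_c <- mu_c + stats::rnorm(n_taxa, 0, config$niche_sd)
        plot_n <- mu_n + stats::rnorm(n_taxa, 0, config$niche_sd)

        for (t in seq_len(n_taxa)) {
          layers <- c("litter",
                      if (stats::runif(1) < config$soil_layer_prob) "soil")
          for (layer in layers) {
            iso_rows[[length(iso_rows) + 1]] <- data.frame(
              taxon = taxa[t], plot = plot, landscape = ls, system = sys,
              layer = layer,
              d13C = base$d13C_litter + plot_c[t] +
                stats::rnorm(1, 0, config$sample_sd),
              d15N = base$d15N_litter + plot_n[t] +
                stats::rnorm(1, 0, config$sample_sd),
              n_individuals = sample(3:15, 1),
              stringsAsFactors = FALSE
            )
          }
        }

        # metabolism totals: log-normal for non-Annelida; Annelida fixed to
        # the configured share of the community total, up to mild noise with
        # mean 1 so the share holds in expectation
        share <- if (sys == "rainforest") config$annelida_share[["rainforest"]]
                 else config$annelida_share[["plantation"]]
        m <- stats::rlnorm(n_taxa, meanlog = 0, sdlog = config$metab_sdlog)
        others_sum <- sum(m[taxa != "Annelida"])
        noise <- exp(stats::rnorm(1, -0.15^2 / 2, 0.15))
        m[taxa == "Annelida"] <- share / (1 - share) * others_sum * noise
        met_rows[[plot_no]] <- data.frame(taxon = taxa, plot = plot,
                                          metabolism = m,
                                          stringsAsFactors = FALSE)
      }
    }
  }
  list(isotope = do.call(rbind, iso_rows),
       baseline = do.call(rbind, base_rows),
       metabolism = do.call(rbind, met_rows),
       config = config)
}

#' Write a generated scenario to CSV files
#'
#' @param scenario output of [generate_scenario()].
#' @param dir output directory (created if needed).
#' @return named character vector of the three file paths, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(isotope = file.path(dir, "isotope_samples.csv"),
             baseline = file.path(dir, "litter_baseline.csv"),
             metabolism = file.path(dir, "metabolism.csv"))
  for (nm in names(paths)) {
    df <- scenario[[nm]]
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
    utils::write.csv(df, paths[[nm]], row.names = FALSE, quote = TRUE)
  }
  invisible(paths)
}

#' Worked rainforest mean-niche community
#'
#' The fixed pool of 23 rainforest mean niches as a single community (one
#' plot, equal weights). Its D13C means span 3.4 to 6.4 per mil (range 3.0)
#' and its D15N means span -5.0 (Pauropoda) to 9.2 (Diplura) per mil
#' (range 14.2).
#'
#' @return niche `data.frame` with columns `taxon, plot, landscape, system,
#'   D13C, D15N, weight`.
#' @export
generate_worked_rainforest <- function() {
  pool <- taxon_niche_pool()
  data.frame(taxon = pool$taxon, plot = "rainforest_mean",
             landscape = "pooled", system = "rainforest",
             D13C = pool$D13C, D15N = pool$D15N,
             weight = 1 / nrow(pool), stringsAsFactors = FALSE)
}
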