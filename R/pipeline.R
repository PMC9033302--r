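# Orchestration: simulate -> preprocess -> metabolism -> metrics -> compare,
# each stage writing its outputs plus a JSON run manifest. The thin CLI in
# inst/cli/isofoodweb.R maps subcommands onto these functions.

.manifest <- function(out_dir, stage, config, outputs, t0, warnings = character(0)) {
  man <- list(
    stage = stage,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed %||% NA,
    config = config[setdiff(names(config), "systems")],
    outputs = as.list(outputs),
    elapsed_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3),
    warnings = as.list(warnings)
  )
  missing <- outputs[!file.exists(unlist(outputs))]
  if (length(missing) > 0) {
    stop("pipeline stage ", stage, " did not produce: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  path <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Run the scenario simulation stage
#'
#' @param config a [scenario_config()] (or arguments for one via `...`).
#' @param out_dir output directory.
#' @param ... passed to [scenario_config()] when `config` is `NULL`.
#' @return named vector of written file paths, invisibly.
#' @export
run_simulate <- function(out_dir, config = NULL, ...) {
  t0 <- Sys.time()
  if (is.null(config)) config <- scenario_config(...)
  scn <- generate_scenario(config)
  paths <- write_scenario(scn, out_dir)
  .manifest(out_dir, "simulate", unclass(config), paths, t0)
  iso_log("simulate: wrote ", length(paths), " files to ", out_dir)
  invisible(paths)
}

#' Run the metrics stage
#'
#' Reads the three input tables, calibrates samples against the plot litter
#' baseline, merges layers, aggregates to one niche per taxon and plot,
#' attaches metabolism weights, fits the global scaling ensemble and writes
#' the per-community metrics table (plus the calibrated niche table, which
#' the compare stage's taxon contrasts need).
#'
#' @param isotope_path,baseline_path,metabolism_path input CSVs
#'   (schemas in [read_isotope_table()] etc.).
#' @param out_dir output directory.
#' @param config run configuration from [read_run_config()].
#' @return list with `metrics` and `niches` data frames, invisibly.
#' @export
run_metrics <- function(isotope_path, baseline_path, metabolism_path,
                        out_dir, config = read_run_config()) {
  t0 <- Sys.time()
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  samples <- read_isotope_table(isotope_path)
  baselines <- read_litter_baseline(baseline_path)
  metab <- read_metabolism_table(metabolism_path)

  samples <- calibrate(samples, baselines)
  samples <- merge_layers(samples)
  niches <- aggregate_to_niche(samples,
                               weight_by_n = isTRUE(config$aggregate_weighted_by_n))
  niches <- assign_metabolism_weights(niches, metab)
  if (identical(config$scaling, "per_system")) {
    # non-default: each land-use system scaled to its own extremes
    metrics <- do.call(rbind, lapply(split(niches, niches$system),
                                     compute_metrics_table))
    metrics <- metrics[order(metrics$plot), , drop = FALSE]
    rownames(metrics) <- NULL
  } else {
    metrics <- compute_metrics_table(niches)
  }

  metrics_path <- file.path(out_dir, "metrics.csv")
  niches_path <- file.path(out_dir, "niches.csv")
  write_metrics(metrics_path, metrics)
  utils::write.csv(niches, niches_path, row.names = FALSE)
  .manifest(out_dir, "metrics", unclass(config),
            c(metrics = metrics_path, niches = niches_path), t0)
  iso_log("metrics: ", nrow(metrics), " communities, ",
          nrow(niches), " taxon-plot niches")
  invisible(list(metrics = metrics, niches = niches))
}

# Metric profile columns for the two ANOSIM perspectives. The community
# profile is every unweighted metric (the 13 per-community metrics seen from
# the community perspective, incl. the one-dimensional minima/maxima/ranges
# and richness, which have no weighted variant); the energetic profile is
# every metabolism-weighted variant.
.community_metric_cols <- c("d13C_min", "d13C_max", "d13C_range", "d13C_mean_u",
                            "d15N_min", "d15N_max", "d15N_range", "d15N_mean_u",
                            "IRic", "IDiv_u", "IDis_u", "IEve_u", "IUni_u")
.energetic_metric_cols <- c("d13C_mean_w", "d15N_mean_w",
                            "IDiv_w", "IDis_w", "IEve_w", "IUni_w")

#' Run the comparison stage
#'
#' Per-taxon Welch contrasts against the reference system, additive two-way
#' ANOVA with Tukey letters for every metric, and ANOSIM on the community
#' and the energetic metric profiles.
#'
#' @param metrics per-community metrics `data.frame` (or CSV path).
#' @param niches niche `data.frame` (or CSV path) for taxon contrasts;
#'   `NULL` skips them.
#' @param out_dir output directory.
#' @param config run configuration from [read_run_config()].
#' @return list with `contrasts`, `anova`, `anosim_community`,
#'   `anosim_energetic`, invisibly.
#' @export
run_compare <- function(metrics, niches = NULL, out_dir,
                        config = read_run_config()) {
  t0 <- Sys.time()
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.character(metrics)) metrics <- read_metrics(metrics)
  if (is.character(niches)) niches <- utils::read.csv(niches, stringsAsFactors = FALSE)

  outputs <- c()
  contrasts <- NULL
  if (!is.null(niches)) {
    contrasts <- reference_contrasts(niches, reference = config$reference_system,
                                     p_adjust = config$p_adjust)
    cpath <- file.path(out_dir, "contrasts.csv")
    utils::write.csv(contrasts, cpath, row.names = FALSE)
    outputs <- c(outputs, contrasts = cpath)
  }

  metric_cols <- intersect(c(.community_metric_cols, .energetic_metric_cols,
                             "d13C_min", "d13C_max", "d13C_range",
                             "d15N_min", "d15N_max", "d15N_range", "IRic"),
                           names(metrics))
  anova_rows <- list()
  for (mc in metric_cols) {
    dat <- data.frame(value = metrics[[mc]], system = metrics$system,
                      landscape = metrics$landscape)
    dat <- dat[is.finite(dat$value), , drop = FALSE]
    if (nrow(dat) < 4 || length(unique(dat$system)) < 2 ||
        length(unique(dat$landscape)) < 2) next
    res <- two_way_anova_tukey(dat)
    sys_row <- res$anova[res$anova$term == "system", ]
    anova_rows[[mc]] <- data.frame(
      metric = mc, F_system = sys_row$F, p_system = sys_row$p,
      letters = paste(names(res$letters), res$letters, sep = ":",
                      collapse = " "),
      stringsAsFactors = FALSE)
  }
  anova_tab <- do.call(rbind, anova_rows)
  apath <- file.path(out_dir, "anova_tukey.csv")
  utils::write.csv(anova_tab, apath, row.names = FALSE)
  outputs <- c(outputs, anova = apath)

  run_anosim <- function(cols) {
    m <- metrics[, cols, drop = FALSE]
    keep <- stats::complete.cases(m)
    anosim_test(m[keep, , drop = FALSE], metrics$system[keep],
                n_perm = config$n_permutations, seed = config$seed)
  }
  an_c <- run_anosim(intersect(.community_metric_cols, names(metrics)))
  an_e <- run_anosim(intersect(.energetic_metric_cols, names(metrics)))
  anosim_path <- file.path(out_dir, "anosim.json")
  jsonlite::write_json(
    list(community = list(R = an_c$R, p = an_c$p, n_perm = an_c$n_perm),
         energetic = list(R = an_e$R, p = an_e$p, n_perm = an_e$n_perm),
         seed = config$seed),
    anosim_path, auto_unbox = TRUE, digits = NA)
  outputs <- c(outputs, anosim = anosim_path)

  .manifest(out_dir, "compare", unclass(config), outputs, t0)
  iso_log(sprintf("compare: ANOSIM community R = %.3f (p = %.4g), energetic R = %.3f (p = %.4g)",
                  an_c$R, an_c$p, an_e$R, an_e$p))
  invisible(list(contrasts = contrasts, anova = anova_tab,
                 anosim_community = an_c, anosim_energetic = an_e))
}

#' Run the whole pipeline end to end
#'
#' @param out_dir output directory.
#' @param scenario a [scenario_config()]; its seed also seeds the ANOSIM
#'   permutations unless `config` overrides it.
#' @param config run configuration from [read_run_config()].
#' @return the [run_compare()] result plus `metrics` and `niches`, invisibly.
#' @export
run_all <- function(out_dir, scenario = scenario_config(),
                    config = read_run_config()) {
  config$seed <- config$seed %||% scenario$seed
  run_simulate(out_dir, config = scenario)
  mt <- run_metrics(file.path(out_dir, "isotope_samples.csv"),
                    file.path(out_dir, "litter_baseline.csv"),
                    file.path(out_dir, "metabolism.csv"),
                    out_dir, config = config)
  cmp <- run_compare(mt$metrics, mt$niches, out_dir, config = config)
  invisible(c(mt, cmp))
}
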