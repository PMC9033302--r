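# CSV readers and writers for the three input tables and the metrics output.
# All files are UTF-8, comma-separated, "." decimal, with a header row; column
# names are part of the interchange contract and are validated strictly.

#' Read a table of animal stable isotope samples
#'
#' Expects columns `taxon, plot, landscape, system, layer, d13C, d15N,
#' n_individuals`: one row per measured (possibly pooled) animal sample.
#' Rows with missing (`NA`) isotope values are rejected with a warning that
#' names the offending row numbers; a non-numeric isotope column is an error,
#' as is a `system` label outside `systems` or a `layer` outside
#' litter/soil/merged.
#'
#' @param path path to a CSV file.
#' @param systems allowed land-use system labels.
#' @return a `data.frame` of accepted samples, with attribute `n_rejected`
#'   giving the number of dropped rows (accepted + rejected = rows in file).
#' @export
read_isotope_table <- function(path, systems = LAND_USE_SYSTEMS) {
  if (!file.exists(path)) stop("isotope table not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .assert_columns(df, c("taxon", "plot", "landscape", "system", "layer",
                        "d13C", "d15N", "n_individuals"), "isotope table")
  if (nrow(df) == 0) {
    iso_log("isotope table ", path, " is empty (header only)", level = "WARN")
    attr(df, "n_rejected") <- 0L
    return(df)
  }
  .assert_numeric_column(df, "d13C", "isotope table")
  .assert_numeric_column(df, "d15N", "isotope table")
  .assert_numeric_column(df, "n_individuals", "isotope table")

  bad_system <- setdiff(unique(df$system), systems)
  if (length(bad_system) > 0) {
    stop("unknown system label(s) in isotope table: ",
         paste(bad_system, collapse = ", "), call. = FALSE)
  }
  bad_layer <- setdiff(unique(df$layer), SAMPLE_LAYERS)
  if (length(bad_layer) > 0) {
    stop("unknown layer label(s) in isotope table: ",
         paste(bad_layer, collapse = ", "), call. = FALSE)
  }
  if (any(df$n_individuals < 1)) {
    stop("n_individuals must be >= 1 in isotope table", call. = FALSE)
  }

  incomplete <- !is.finite(df$d13C) | !is.finite(df$d15N)
  if (any(incomplete)) {
    iso_log("rejecting ", sum(incomplete), " row(s) with missing isotope values: rows ",
            paste(which(incomplete), collapse = ", "), level = "WARN")
    df <- df[!incomplete, , drop = FALSE]
    rownames(df) <- NULL
  }
  attr(df, "n_rejected") <- sum(incomplete)
  df
}

#' Read per-plot litter baseline values
#'
#' Expects columns `plot, d13C_litter, d15N_litter`, exactly one row per plot.
#'
#' @param path path to a CSV file.
#' @return a `data.frame` with one row per plot.
#' @export
read_litter_baseline <- function(path) {
  if (!file.exists(path)) stop("litter baseline not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .assert_columns(df, c("plot", "d13C_litter", "d15N_litter"), "litter baseline")
  .assert_numeric_column(df, "d13C_litter", "litter baseline")
  .assert_numeric_column(df, "d15N_litter", "litter baseline")
  dup <- unique(df$plot[duplicated(df$plot)])
  if (length(dup) > 0) {
    stop("duplicated plot id(s) in litter baseline: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) > 0 && any(!is.finite(df$d13C_litter) | !is.finite(df$d15N_litter))) {
    stop("non-finite litter baseline values", call. = FALSE)
  }
  df
}

#' Read a precomputed community-metabolism table
#'
#' Expects columns `taxon, plot, metabolism` (summed metabolic rate of the
#' group at the plot, any consistent energy-rate unit). Zero entries are kept:
#' a taxon may be present isotopically but energetically negligible.
#'
#' @param path path to a CSV file.
#' @return a `data.frame` with columns `taxon, plot, metabolism`.
#' @export
read_metabolism_table <- function(path) {
  if (!file.exists(path)) stop("metabolism table not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .assert_columns(df, c("taxon", "plot", "metabolism"), "metabolism table")
  .assert_numeric_column(df, "metabolism", "metabolism table")
  if (nrow(df) > 0 && any(!is.finite(df$metabolism))) {
    stop("non-finite metabolism values", call. = FALSE)
  }
  if (nrow(df) > 0 && any(df$metabolism < 0)) {
    stop("negative metabolism values are not allowed", call. = FALSE)
  }
  dup <- duplicated(df[, c("taxon", "plot")])
  if (any(dup)) {
    stop("duplicated (taxon, plot) pair(s) in metabolism table", call. = FALSE)
  }
  df
}

#' Write (and read back) a per-community metrics table
#'
#' One row per community, stable column order, full double precision so that
#' a write/read round trip reproduces values to better than 1e-12.
#'
#' @param path output CSV path.
#' @param results `data.frame` of per-community metrics
#'   (as from [compute_metrics_table()]).
#' @return `path`, invisibly.
#' @export
write_metrics <- function(path, results) {
  if (!is.data.frame(results) || nrow(results) == 0) {
    stop("no metrics results to write", call. = FALSE)
  }
  out <- results
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) {
    ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  })
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  if (!file.exists(path)) stop("metrics table not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a run-configuration YAML file
#'
#' Missing keys fall back to documented defaults; the permutation count and
#' seed are validated. The configuration is echoed to the log so that runs
#' are self-describing.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return a named list with class `iso_run_config`.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- list(
    reference_system = "rainforest",
    scaling = "global",           # global across all communities in the run
    n_permutations = 999L,
    seed = 1L,
    temperature_K = 298.15,
    aggregate_weighted_by_n = FALSE,
    p_adjust = "none",
    log_level = "INFO"
  )
  cfg <- defaults
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  cfg$n_permutations <- as.integer(cfg$n_permutations)
  cfg$seed <- as.integer(cfg$seed)
  if (is.na(cfg$n_permutations) || cfg$n_permutations < 99L) {
    stop("n_permutations must be an integer >= 99", call. = FALSE)
  }
  if (is.na(cfg$seed)) stop("seed must be an integer", call. = FALSE)
  if (!cfg$scaling %in% c("global", "per_system")) {
    stop("scaling must be 'global' or 'per_system'", call. = FALSE)
  }
  class(cfg) <- "iso_run_config"
  iso_log("run config: ", paste(names(cfg), unlist(lapply(cfg, format)),
                                sep = "=", collapse = " "), level = "DEBUG")
  cfg
}
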