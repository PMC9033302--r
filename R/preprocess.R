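# From raw isotope ratios to one litter-calibrated trophic niche per
# taxon x plot.

#' Convert isotope ratios to delta notation
#'
#' `delta = (R_sample / R_standard - 1) * 1000` (per mil). The standards are
#' Vienna PeeDee Belemnite for 13C/12C and atmospheric N2 for 15N/14N.
#'
#' @param r_sample heavy/light isotope ratio of the sample (dimensionless).
#' @param r_standard heavy/light isotope ratio of the reference standard.
#' @return delta value(s) in per mil.
#' @export
delta_value <- function(r_sample, r_standard) {
  if (any(!is.finite(r_sample)) || any(!is.finite(r_standard)) ||
      any(r_sample <= 0) || any(r_standard <= 0)) {
    stop("isotope ratios must be finite and strictly positive", call. = FALSE)
  }
  (r_sample / r_standard - 1) * 1000
}

#' Calibrate animal delta values to the plot litter baseline
#'
#' For every sample, subtracts the litter delta13C and delta15N of the same
#' plot: `D13C = d13C - d13C_litter`, `D15N = d15N - d15N_litter`. Values
#' above the litter baseline are positive; D15N rises by roughly 3-4 per mil
#' per trophic level, D13C tracks the basal carbon resource.
#'
#' @param samples isotope sample `data.frame` (see [read_isotope_table()]).
#' @param baselines litter baseline `data.frame` (see [read_litter_baseline()]).
#' @return `samples` with extra numeric columns `D13C` and `D15N`.
#' @export
calibrate <- function(samples, baselines) {
  .assert_columns(samples, c("plot", "d13C", "d15N"), "samples")
  .assert_columns(baselines, c("plot", "d13C_litter", "d15N_litter"), "baselines")
  missing_plots <- setdiff(unique(samples$plot), baselines$plot)
  if (length(missing_plots) > 0) {
    stop("no litter baseline for plot(s): ",
         paste(sort(missing_plots), collapse = ", "), call. = FALSE)
  }
  idx <- match(samples$plot, baselines$plot)
  samples$D13C <- samples$d13C - baselines$d13C_litter[idx]
  samples$D15N <- samples$d15N - baselines$d15N_litter[idx]
  samples
}

#' Merge litter and soil layers for analysis
#'
#' Litter- and soil-extracted samples are measured separately but analysed
#' jointly; this relabels every record `layer = "merged"` so that subsequent
#' aggregation pools them within taxon x plot.
#'
#' @param samples isotope sample `data.frame`.
#' @return the same records with `layer` set to `"merged"`.
#' @export
merge_layers <- function(samples) {
  if (nrow(samples) > 0) samples$layer <- "merged"
  samples
}

#' Aggregate calibrated samples to one niche per taxon and plot
#'
#' Computes the mean `D13C` and `D15N` across all samples of a taxon at a
#' plot. By default the plain arithmetic mean over samples; with
#' `weight_by_n = TRUE` samples are weighted by the number of pooled
#' individuals (`n_individuals`).
#'
#' @param samples calibrated sample `data.frame` (columns `D13C`, `D15N`).
#' @param weight_by_n weight sample means by `n_individuals`?
#' @return a `data.frame` with one row per (taxon, plot): columns `taxon,
#'   plot, landscape, system, D13C, D15N, n_samples`. Idempotent: aggregating
#'   an already aggregated table returns it unchanged (up to `n_samples`).
#' @export
aggregate_to_niche <- function(samples, weight_by_n = FALSE) {
  .assert_columns(samples, c("taxon", "plot", "D13C", "D15N"), "calibrated samples")
  if (nrow(samples) == 0) {
    return(data.frame(taxon = character(), plot = character(),
                      landscape = character(), system = character(),
                      D13C = numeric(), D15N = numeric(),
                      n_samples = integer(), stringsAsFactors = FALSE))
  }
  if (!"landscape" %in% names(samples)) samples$landscape <- NA_character_
  if (!"system" %in% names(samples)) samples$system <- NA_character_
  key <- interaction(samples$taxon, samples$plot, drop = TRUE, lex.order = TRUE)
  w <- if (weight_by_n) as.numeric(samples$n_individuals) else rep(1, nrow(samples))
  wmean <- function(x, wt) sum(x * wt) / sum(wt)
  pieces <- lapply(split(seq_len(nrow(samples)), key), function(i) {
    data.frame(
      taxon = samples$taxon[i[1]],
      plot = samples$plot[i[1]],
      landscape = samples$landscape[i[1]],
      system = samples$system[i[1]],
      D13C = wmean(samples$D13C[i], w[i]),
      D15N = wmean(samples$D15N[i], w[i]),
      n_samples = length(i),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$plot, out$taxon), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}
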