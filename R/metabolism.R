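# Allometric metabolic rates and community-metabolism weights.
#
# Individual metabolic rate follows the standard mass/temperature scaling
#   ln B = ln_b0 + a * ln(M) - E / (k * T)
# with M fresh body mass (mg), T absolute temperature (K), E an activation
# energy (eV) and k the Boltzmann constant. Body mass is obtained from length
# and width via a group-specific power law. Coefficient tables are user
# inputs (see inst/extdata/allometric_coefficients_synthetic.csv for the
# schema with placeholder values); no published regression constants are
# hard-coded here.

BOLTZMANN_EV <- 8.617e-5  # eV / K

#' Fresh body mass from body dimensions
#'
#' `mass = exp(c0 + c1 * ln(length) + c2 * ln(width))`, in mg when the
#' coefficients were fitted on mm and mg.
#'
#' @param length body length (mm), positive.
#' @param width body width (mm), positive.
#' @param c0,c1,c2 group-specific power-law coefficients.
#' @return body mass, same length as the inputs.
#' @export
body_mass <- function(length, width, c0, c1, c2) {
  if (any(length <= 0) || any(width <= 0)) {
    stop("body dimensions must be strictly positive", call. = FALSE)
  }
  exp(c0 + c1 * log(length) + c2 * log(width))
}

#' Individual metabolic rate from body mass
#'
#' @param mass fresh body mass (mg), positive.
#' @param ln_b0 intercept (ln of the rate unit, e.g. ln(J/h)).
#' @param a allometric mass exponent.
#' @param E activation energy (eV), `>= 0`.
#' @param temperature_K absolute temperature (K).
#' @return metabolic rate `B > 0`, strictly increasing in mass for `a > 0`
#'   and in temperature for `E > 0`.
#' @export
metabolic_rate <- function(mass, ln_b0, a, E = 0, temperature_K = 298.15) {
  if (any(mass <= 0)) stop("mass must be strictly positive", call. = FALSE)
  if (any(temperature_K <= 0)) stop("temperature must be positive (K)", call. = FALSE)
  if (any(E < 0)) stop("activation energy must be >= 0", call. = FALSE)
  exp(ln_b0 + a * log(mass) - E / (BOLTZMANN_EV * temperature_K))
}

#' Read an allometric coefficient table
#'
#' Columns: `taxon, c0, c1, c2, ln_b0, a, E`.
#'
#' @param path CSV path.
#' @return `data.frame` of per-group coefficients.
#' @export
read_allometric_coeffs <- function(path) {
  if (!file.exists(path)) stop("coefficient table not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .assert_columns(df, c("taxon", "c0", "c1", "c2", "ln_b0", "a", "E"),
                  "allometric coefficient table")
  if (any(duplicated(df$taxon))) {
    stop("duplicated taxon in coefficient table", call. = FALSE)
  }
  df
}

#' Summed community metabolism per taxon and plot
#'
#' Takes individual body measurements (columns `taxon, plot, length, width,
#' count`), computes each row's individual metabolic rate via [body_mass()]
#' and [metabolic_rate()] with the group's coefficients, multiplies by
#' `count`, and sums within taxon x plot.
#'
#' @param measurements body-measurement `data.frame`.
#' @param coeffs coefficient table from [read_allometric_coeffs()].
#' @param temperature_K assumed temperature (K) for the Arrhenius term.
#' @return `data.frame` with columns `taxon, plot, metabolism`.
#' @export
community_metabolism <- function(measurements, coeffs, temperature_K = 298.15) {
  .assert_columns(measurements, c("taxon", "plot", "length", "width", "count"),
                  "body measurements")
  if (nrow(measurements) == 0) {
    return(data.frame(taxon = character(), plot = character(),
                      metabolism = numeric(), stringsAsFactors = FALSE))
  }
  idx <- match(measurements$taxon, coeffs$taxon)
  if (anyNA(idx)) {
    stop("no allometric coefficients for taxon/taxa: ",
         paste(sort(unique(measurements$taxon[is.na(idx)])), collapse = ", "),
         call. = FALSE)
  }
  mass <- body_mass(measurements$length, measurements$width,
                    coeffs$c0[idx], coeffs$c1[idx], coeffs$c2[idx])
  rate <- metabolic_rate(mass, coeffs$ln_b0[idx], coeffs$a[idx],
                         coeffs$E[idx], temperature_K)
  total <- rate * measurements$count
  agg <- stats::aggregate(total,
                          by = list(taxon = measurements$taxon,
                                    plot = measurements$plot),
                          FUN = sum)
  names(agg)[3] <- "metabolism"
  agg[order(agg$plot, agg$taxon), , drop = FALSE]
}

#' Normalise metabolism totals to weights
#'
#' @param totals non-negative metabolism totals for the taxa of one plot.
#' @return weights `w = totals / sum(totals)`, summing to 1. Errors if all
#'   totals are zero (weighted metrics would be undefined).
#' @export
metabolism_weights <- function(totals) {
  if (length(totals) == 0) stop("no metabolism totals supplied", call. = FALSE)
  if (any(totals < 0)) stop("metabolism totals must be >= 0", call. = FALSE)
  s <- sum(totals)
  if (s <= 0) stop("all metabolism totals are zero; weights undefined", call. = FALSE)
  totals / s
}

#' Attach metabolism weights to a niche table
#'
#' Joins the per-(taxon, plot) metabolism table onto the niche table and
#' normalises within each plot. Taxa present isotopically but absent from the
#' metabolism table receive metabolism 0 (weight 0) and are retained, so the
#' community perspective stays complete; each such case is logged.
#'
#' @param niches niche `data.frame` from [aggregate_to_niche()].
#' @param metabolism `data.frame` with columns `taxon, plot, metabolism`.
#' @return `niches` with extra columns `metabolism` and `weight`
#'   (weights sum to 1 within each plot).
#' @export
assign_metabolism_weights <- function(niches, metabolism) {
  .assert_columns(niches, c("taxon", "plot"), "niche table")
  .assert_columns(metabolism, c("taxon", "plot", "metabolism"), "metabolism table")
  key_n <- paste(niches$taxon, niches$plot, sep = "\r")
  key_m <- paste(metabolism$taxon, metabolism$plot, sep = "\r")
  idx <- match(key_n, key_m)
  if (anyNA(idx)) {
    missing <- unique(paste0(niches$taxon[is.na(idx)], "@", niches$plot[is.na(idx)]))
    iso_log("no metabolism entry for ", length(missing),
            " taxon-plot pair(s); assigned weight 0: ",
            paste(missing, collapse = ", "), level = "WARN")
  }
  niches$metabolism <- ifelse(is.na(idx), 0, metabolism$metabolism[idx])
  niches$weight <- NA_real_
  for (p in unique(niches$plot)) {
    rows <- which(niches$plot == p)
    niches$weight[rows] <- metabolism_weights(niches$metabolism[rows])
  }
  niches
}
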