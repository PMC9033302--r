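# Land-use contrast statistics: per-taxon Welch t contrasts against a
# reference system, additive two-way ANOVA with Tukey compact letters on the
# land-use factor, and a rank-based ANOSIM permutation test.

.p_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Welch t contrasts of each taxon's niche against a reference system
#'
#' For every taxon, isotope axis and non-reference land-use system with at
#' least `min_n` plot-level values on both sides, runs a Welch two-sample
#' t-test of the taxon's plot-level Delta values in that system against the
#' reference system. The reported difference is other-system minus
#' reference, so negative values mean depletion relative to the reference.
#' Raw p values are starred (* < 0.05, ** < 0.01); optional
#' Benjamini-Hochberg adjustment across all contrasts via
#' `p_adjust = "BH"` (off by default).
#'
#' @param niches niche `data.frame` (one row per taxon x plot) with columns
#'   `taxon, plot, system, D13C, D15N`.
#' @param reference reference system label (default `"rainforest"`).
#' @param isotopes which Delta columns to contrast.
#' @param min_n minimum plots per side; contrasts below it are kept as rows
#'   with `NA` statistics and a `reason`.
#' @param p_adjust `"none"` (raw p, as starred) or `"BH"`.
#' @return `data.frame` with columns `taxon, isotope, system, reference,
#'   n_sys, n_ref, mean_diff, t, df, p, stars, reason`.
#' @export
reference_contrasts <- function(niches, reference = "rainforest",
                                isotopes = c("D13C", "D15N"),
                                min_n = 2, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  .assert_columns(niches, c("taxon", "system", isotopes), "niche table")
  if (!reference %in% niches$system) {
    stop("reference system '", reference, "' not present in the data", call. = FALSE)
  }
  others <- setdiff(unique(niches$system), reference)
  rows <- list()
  for (taxon in sort(unique(niches$taxon))) {
    tdat <- niches[niches$taxon == taxon, , drop = FALSE]
    for (iso in isotopes) {
      ref_vals <- tdat[[iso]][tdat$system == reference]
      for (sys in others) {
        sys_vals <- tdat[[iso]][tdat$system == sys]
        row <- data.frame(taxon = taxon, isotope = iso, system = sys,
                          reference = reference,
                          n_sys = length(sys_vals), n_ref = length(ref_vals),
                          mean_diff = NA_real_, t = NA_real_, df = NA_real_,
                          p = NA_real_, stars = "", reason = "",
                          stringsAsFactors = FALSE)
        if (length(sys_vals) < min_n || length(ref_vals) < min_n) {
          row$reason <- sprintf("insufficient replication (n_sys=%d, n_ref=%d, need %d)",
                                length(sys_vals), length(ref_vals), min_n)
          iso_log("skipping contrast ", taxon, "/", iso, "/", sys, ": ", row$reason,
                  level = "DEBUG")
        } else if (stats::sd(sys_vals) == 0 && stats::sd(ref_vals) == 0 &&
                   mean(sys_vals) == mean(ref_vals)) {
          # identical constant groups: no evidence of a difference
          row$mean_diff <- 0; row$t <- 0; row$df <- NA_real_; row$p <- 1
        } else {
          tt <- stats::t.test(sys_vals, ref_vals, var.equal = FALSE)
          row$mean_diff <- mean(sys_vals) - mean(ref_vals)
          row$t <- unname(tt$statistic)
          row$df <- unname(tt$parameter)
          row$p <- tt$p.value
        }
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  if (p_adjust == "BH") out$p <- stats::p.adjust(out$p, method = "BH")
  out$stars <- .p_stars(out$p)
  rownames(out) <- NULL
  out
}

# Compact letter display from a pairwise "not significantly different"
# relation: the maximal cliques of the NSD graph are exactly the letter
# groups. Letters are ordered so that 'a' contains the largest group mean.
.compact_letters <- function(groups, p_matrix, means, alpha = 0.05) {
  k <- length(groups)
  nsd <- matrix(TRUE, k, k, dimnames = list(groups, groups))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      ok <- is.na(p_matrix[i, j]) || p_matrix[i, j] > alpha
      nsd[i, j] <- nsd[j, i] <- ok
    }
  }
  g <- igraph::graph_from_adjacency_matrix(nsd, mode = "undirected", diag = FALSE)
  cliques <- igraph::max_cliques(g)
  # order cliques by the largest mean they contain, descending
  ord <- order(-vapply(cliques, function(cl) max(means[as.integer(cl)]), numeric(1)))
  cliques <- cliques[ord]
  letters_out <- stats::setNames(rep("", k), groups)
  for (ci in seq_along(cliques)) {
    members <- groups[as.integer(cliques[[ci]])]
    letters_out[members] <- paste0(letters_out[members], letters[ci])
  }
  # present letters of each group in alphabetical order
  vapply(letters_out, function(s) paste(sort(strsplit(s, "")[[1]]), collapse = ""),
         character(1))
}

#' Additive two-way ANOVA with Tukey letters on the land-use factor
#'
#' Fits `value ~ system + landscape` (no interaction), reports the F table,
#' Tukey HSD pairwise comparisons among land-use systems, and a compact
#' letter display: systems sharing a letter are not significantly different
#' at `alpha`.
#'
#' @param data `data.frame` with columns `value`, `system`, `landscape`
#'   (one row per community).
#' @param alpha significance level for the letters.
#' @return list with elements `anova` (data frame), `tukey` (pairwise data
#'   frame), `letters` (named character vector per system).
#' @export
two_way_anova_tukey <- function(data, alpha = 0.05) {
  .assert_columns(data, c("value", "system", "landscape"), "ANOVA input")
  data <- data[is.finite(data$value), , drop = FALSE]
  data$system <- factor(data$system)
  data$landscape <- factor(data$landscape)
  if (nlevels(data$system) < 2) stop("factor 'system' needs >= 2 levels", call. = FALSE)
  if (nlevels(data$landscape) < 2) stop("factor 'landscape' needs >= 2 levels", call. = FALSE)
  sys_levels <- levels(data$system)
  means <- tapply(data$value, data$system, mean)

  if (stats::sd(data$value) == 0) {
    # zero variance: no differences anywhere, one shared letter
    k <- length(sys_levels)
    pairs <- t(utils::combn(sys_levels, 2))
    tukey <- data.frame(pair = paste(pairs[, 2], pairs[, 1], sep = "-"),
                        diff = 0, p_adj = 1, stringsAsFactors = FALSE)
    return(list(
      anova = data.frame(term = c("system", "landscape", "Residuals"),
                         df = c(k - 1, nlevels(data$landscape) - 1,
                                nrow(data) - k - nlevels(data$landscape) + 1),
                         F = c(NA_real_, NA_real_, NA_real_),
                         p = c(NA_real_, NA_real_, NA_real_)),
      tukey = tukey,
      letters = stats::setNames(rep("a", k), sys_levels)
    ))
  }

  fit <- stats::aov(value ~ system + landscape, data = data)
  tab <- summary(fit)[[1]]
  anova_df <- data.frame(term = trimws(rownames(tab)), df = tab[["Df"]],
                         F = tab[["F value"]], p = tab[["Pr(>F)"]],
                         stringsAsFactors = FALSE)
  hsd <- stats::TukeyHSD(fit, which = "system")$system
  tukey <- data.frame(pair = rownames(hsd), diff = hsd[, "diff"],
                      p_adj = hsd[, "p adj"], stringsAsFactors = FALSE,
                      row.names = NULL)

  pmat <- matrix(NA_real_, length(sys_levels), length(sys_levels),
                 dimnames = list(sys_levels, sys_levels))
  for (r in seq_len(nrow(tukey))) {
    pr <- strsplit(tukey$pair[r], "-", fixed = TRUE)[[1]]
    pmat[pr[1], pr[2]] <- pmat[pr[2], pr[1]] <- tukey$p_adj[r]
  }
  letters_out <- .compact_letters(sys_levels, pmat, means, alpha)
  list(anova = anova_df, tukey = tukey, letters = letters_out)
}

#' Analysis of similarities (ANOSIM) on community metric profiles
#'
#' Rank-based permutation test of whether between-group dissimilarities
#' exceed within-group dissimilarities. Metric columns are z-standardised
#' (constant columns dropped with a warning), dissimilarity is Euclidean,
#' and with `r_b`/`r_w` the mean between/within ranks,
#' `R = (r_b - r_w) / (n (n - 1) / 4)`. The p value is
#' `(1 + #{permuted R >= observed R}) / (1 + n_perm)`.
#'
#' @param x numeric matrix or data frame, one row per community (metric
#'   profile), or a `dist` object (used as-is, no standardisation).
#' @param grouping group label per row (e.g. land-use system).
#' @param n_perm number of label permutations (>= 99).
#' @param seed integer seed for the permutations; set for reproducibility.
#' @param standardize z-score columns before computing distances.
#' @return object of class `iso_anosim`: list with `R`, `p`, `n_perm`,
#'   `seed`, `perm_R`.
#' @export
anosim_test <- function(x, grouping, n_perm = 999, seed = NULL,
                        standardize = TRUE) {
  grouping <- as.character(grouping)
  if (length(unique(grouping)) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(table(grouping) < 2)) stop("every group needs >= 2 members", call. = FALSE)
  if (n_perm < 99) stop("n_perm must be >= 99", call. = FALSE)

  if (inherits(x, "dist")) {
    d <- x
  } else {
    x <- as.matrix(x)
    if (!all(is.finite(x))) stop("metric matrix contains non-finite values", call. = FALSE)
    if (standardize) {
      sds <- apply(x, 2, stats::sd)
      if (any(sds == 0)) {
        iso_log("dropping ", sum(sds == 0), " constant metric column(s) before ANOSIM",
                level = "WARN")
        x <- x[, sds > 0, drop = FALSE]
        sds <- sds[sds > 0]
      }
      if (ncol(x) == 0) stop("no non-constant metric columns", call. = FALSE)
      x <- scale(x)
    }
    d <- stats::dist(x)
  }
  n <- attr(d, "Size")
  if (length(grouping) != n) stop("grouping length must match rows", call. = FALSE)
  rnk <- rank(as.vector(d))
  # logical vector marking within-group pairs, in dist order
  pair_i <- unlist(lapply(seq_len(n - 1), function(i) rep(i, n - i)))
  pair_j <- unlist(lapply(seq_len(n - 1), function(i) seq(i + 1, n)))
  denom <- n * (n - 1) / 4

  stat_R <- function(g) {
    within <- g[pair_i] == g[pair_j]
    (mean(rnk[!within]) - mean(rnk[within])) / denom
  }
  R_obs <- stat_R(grouping)

  if (!is.null(seed)) set.seed(seed)
  perm_R <- vapply(seq_len(n_perm), function(k) stat_R(sample(grouping)), numeric(1))
  p <- (1 + sum(perm_R >= R_obs)) / (1 + n_perm)
  structure(list(R = R_obs, p = p, n_perm = n_perm, seed = seed,
                 perm_R = perm_R),
            class = "iso_anosim")
}

#' @export
print.iso_anosim <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.3f, p = %.4g (%d permutations)\n",
              x$R, x$p, x$n_perm))
  invisible(x)
}
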