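# The isotopic diversity metrics.
#
# One-dimensional metrics (minimum, maximum, range, average position) are
# computed on raw per-mil Delta values. Multidimensional metrics are computed
# in a common [0,1] x [0,1] isotope space obtained by min-max scaling each
# axis over ALL communities of a run jointly, so both isotopes contribute
# equally. Every multidimensional metric except richness has an unweighted
# ("community", w_i = 1/S) and a metabolism-weighted ("energetic") variant:
#
#   richness   IRic  convex hull area of the S points (cannot be weighted)
#   divergence IDiv  weighted dominance of points far from the hull-vertex
#                    centroid G: with dG_i = |p_i - G|, dbar = mean(dG),
#                    Dd = sum w_i (dG_i - dbar), Dd_abs = sum w_i |dG_i - dbar|,
#                    IDiv = (Dd + dbar) / (Dd_abs + dbar)
#   dispersion IDis  weighted mean distance to the weighted centroid O,
#                    scaled by the maximum distance: sum(w_i d_i) / max d_i
#   evenness   IEve  regularity of the minimum spanning tree: branch weights
#                    EW_l = dist(i,j) / (w_i + w_j), PEW_l = EW_l / sum EW,
#                    IEve = (sum min(PEW_l, 1/(S-1)) - 1/(S-1)) / (1 - 1/(S-1))
#   uniqueness IUni  weighted mean nearest-neighbour distance scaled by its
#                    maximum: sum(w_i NND_i) / max NND_i (inverse redundancy)

#' Fit the global scaling ensemble
#'
#' Records the per-axis minimum and maximum of `D13C` and `D15N` over every
#' taxon-plot record supplied (normally all communities of a run jointly).
#'
#' @param niches niche `data.frame` with columns `D13C`, `D15N`.
#' @return an object of class `iso_scaling` with fields `c_min, c_max,
#'   n_min, n_max`.
#' @export
fit_scaling <- function(niches) {
  .assert_columns(niches, c("D13C", "D15N"), "niche table")
  if (nrow(niches) < 2) stop("need at least 2 records to fit scaling", call. = FALSE)
  ens <- list(c_min = min(niches$D13C), c_max = max(niches$D13C),
              n_min = min(niches$D15N), n_max = max(niches$D15N))
  if (ens$c_max <= ens$c_min) {
    stop("degenerate D13C axis: max equals min", call. = FALSE)
  }
  if (ens$n_max <= ens$n_min) {
    stop("degenerate D15N axis: max equals min", call. = FALSE)
  }
  structure(ens, class = "iso_scaling")
}

#' @export
print.iso_scaling <- function(x, ...) {
  cat(sprintf("isotope scaling ensemble: D13C [%.3f, %.3f], D15N [%.3f, %.3f]\n",
              x$c_min, x$c_max, x$n_min, x$n_max))
  invisible(x)
}

#' Scale niches into the common [0,1] isotope space
#'
#' @param niches niche `data.frame` with `D13C`, `D15N`.
#' @param ensemble scaling ensemble from [fit_scaling()].
#' @return `niches` with scaled coordinate columns `c` and `n` in `[0, 1]`.
#'   Values outside the ensemble range are an error (no clipping).
#' @export
scale_niches <- function(niches, ensemble) {
  stopifnot(inherits(ensemble, "iso_scaling"))
  out_c <- niches$D13C < ensemble$c_min | niches$D13C > ensemble$c_max
  out_n <- niches$D15N < ensemble$n_min | niches$D15N > ensemble$n_max
  if (any(out_c) || any(out_n)) {
    stop("niche values outside the fitted scaling ensemble", call. = FALSE)
  }
  niches$c <- (niches$D13C - ensemble$c_min) / (ensemble$c_max - ensemble$c_min)
  niches$n <- (niches$D15N - ensemble$n_min) / (ensemble$n_max - ensemble$n_min)
  niches
}

#' One-dimensional isotopic metrics for one axis
#'
#' Computed on raw per-mil Delta values. `range = max - min`; `mean_u` is the
#' arithmetic mean across taxa; `mean_w` the metabolism-weighted mean
#' `sum(w_i x_i)` (NA when no weights are supplied). Minimum, maximum and
#' range have no weighted variant.
#'
#' @param values per-taxon Delta values (per mil), non-empty.
#' @param weights optional weights summing to 1.
#' @return named list `min, max, range, mean_u, mean_w`.
#' @export
one_dim_metrics <- function(values, weights = NULL) {
  if (length(values) == 0) stop("empty value list", call. = FALSE)
  mw <- if (is.null(weights)) NA_real_ else {
    stopifnot(length(weights) == length(values))
    sum(weights * values)
  }
  list(min = min(values), max = max(values), range = max(values) - min(values),
       mean_u = mean(values), mean_w = mw)
}

# Shoelace area of a polygon given in vertex order.
.polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Isotopic richness: convex hull area
#'
#' Area of the convex hull of the community's points in scaled isotope space.
#' Zero for fewer than three points or collinear points. The only
#' multidimensional metric without a weighted variant.
#'
#' @param pts numeric matrix with one row per taxon, two columns.
#' @return hull area (squared scaled-isotope units), `>= 0`.
#' @export
convex_hull_area <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 3) return(0)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(h) < 3) return(0)
  .polygon_area(pts[h, 1], pts[h, 2])
}

# Hull vertex indices, or NULL when the hull is degenerate (< 3 vertices).
.hull_vertices <- function(pts) {
  if (nrow(pts) < 3) return(NULL)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(h) < 3) return(NULL)
  if (.polygon_area(pts[h, 1], pts[h, 2]) <= 0) return(NULL)
  h
}

#' Isotopic divergence
#'
#' How much of the weight sits on taxa far from the centre of the occupied
#' isotope space. `G` is the unweighted centroid of the convex hull vertices;
#' distances of all `S` points to `G` are compared with their unweighted mean.
#' 1 when all points are equidistant from `G`; near 0 when almost all weight
#' is at the centre.
#'
#' @param pts numeric matrix (S x 2) of scaled coordinates.
#' @param weights weights summing to 1.
#' @return IDiv in `[0, 1]`, or `NA` with attribute `reason` when the hull is
#'   degenerate (S < 3 or collinear points).
#' @export
isotopic_divergence <- function(pts, weights) {
  pts <- as.matrix(pts)
  h <- .hull_vertices(pts)
  if (is.null(h)) {
    return(structure(NA_real_, reason = "degenerate hull (S < 3 or collinear)"))
  }
  G <- colMeans(pts[h, , drop = FALSE])
  dG <- sqrt((pts[, 1] - G[1])^2 + (pts[, 2] - G[2])^2)
  dbar <- mean(dG)
  dd <- sum(weights * (dG - dbar))
  dd_abs <- sum(weights * abs(dG - dbar))
  (dd + dbar) / (dd_abs + dbar)
}

#' Isotopic dispersion
#'
#' Weighted mean distance to the weighted centroid, scaled by the maximum
#' such distance — a scaled multidimensional variance. Approaches 1 when taxa
#' with contrasting isotope values carry similar weight; approaches 0 when
#' the weight concentrates at the centre of gravity. 0 when all points
#' coincide.
#'
#' @inheritParams isotopic_divergence
#' @return IDis in `[0, 1]`, or `NA` with a reason for S < 2.
#' @export
isotopic_dispersion <- function(pts, weights) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 2) return(structure(NA_real_, reason = "S < 2"))
  O <- c(sum(weights * pts[, 1]), sum(weights * pts[, 2]))
  d <- sqrt((pts[, 1] - O[1])^2 + (pts[, 2] - O[2])^2)
  m <- max(d)
  if (m == 0) return(0)
  sum(weights * d) / m
}

# Euclidean minimum spanning tree via Prim's algorithm, deterministic:
# among equally short candidate edges the lexicographically smallest (i, j)
# pair wins. Returns a (S-1) x 3 matrix [i, j, dist].
.mst_edges <- function(pts) {
  pts <- as.matrix(pts)
  S <- nrow(pts)
  dmat <- as.matrix(stats::dist(pts))
  in_tree <- c(1L, rep(NA_integer_, S - 1))
  n_in <- 1L
  used <- rep(FALSE, S); used[1] <- TRUE
  edges <- matrix(0, nrow = S - 1, ncol = 3,
                  dimnames = list(NULL, c("i", "j", "dist")))
  for (e in seq_len(S - 1)) {
    best <- NULL
    for (i in sort(which(used))) {
      for (j in which(!used)) {
        cand <- c(i, j, dmat[i, j])
        if (is.null(best) || cand[3] < best[3] ||
            (cand[3] == best[3] && (cand[1] < best[1] ||
             (cand[1] == best[1] && cand[2] < best[2])))) {
          best <- cand
        }
      }
    }
    edges[e, ] <- best
    used[best[2]] <- TRUE
  }
  edges
}

#' Isotopic evenness
#'
#' Regularity of the distribution of taxa (or metabolism) in isotope space,
#' from the Euclidean minimum spanning tree over the S points. 1 when the
#' weighted branch lengths are perfectly even; near 0 when taxa or weight
#' cluster tightly.
#'
#' @inheritParams isotopic_divergence
#' @return IEve in `[0, 1]`, or `NA` with a reason for S < 3 or fully
#'   coincident points.
#' @export
isotopic_evenness <- function(pts, weights) {
  pts <- as.matrix(pts)
  S <- nrow(pts)
  if (S < 3) return(structure(NA_real_, reason = "S < 3"))
  edges <- .mst_edges(pts)
  wsum <- weights[edges[, "i"]] + weights[edges[, "j"]]
  # a branch may join two zero-weight taxa; floor the denominator so the
  # branch gets a very large EW (capped below) rather than NaN
  ew <- edges[, "dist"] / pmax(wsum, .Machine$double.eps)
  tot <- sum(ew)
  if (tot == 0) return(structure(NA_real_, reason = "all points coincident"))
  pew <- ew / tot
  thr <- 1 / (S - 1)
  (sum(pmin(pew, thr)) - thr) / (1 - thr)
}

#' Isotopic uniqueness
#'
#' Inverse of the average isotopic redundancy: the weighted mean
#' nearest-neighbour distance, scaled by the maximum nearest-neighbour
#' distance. 1 when every taxon is as isolated as the most isolated one; 0
#' when all points coincide.
#'
#' @inheritParams isotopic_divergence
#' @return IUni in `[0, 1]`, or `NA` with a reason for S < 2.
#' @export
isotopic_uniqueness <- function(pts, weights) {
  pts <- as.matrix(pts)
  S <- nrow(pts)
  if (S < 2) return(structure(NA_real_, reason = "S < 2"))
  dmat <- as.matrix(stats::dist(pts))
  diag(dmat) <- Inf
  nnd <- apply(dmat, 1, min)
  m <- max(nnd)
  if (m == 0) return(0)
  sum(weights * nnd) / m
}

#' All 13 isotopic metrics for one community
#'
#' Runs the one-dimensional metrics on raw Delta values and every
#' multidimensional metric on globally scaled coordinates, twice: unweighted
#' (`w_i = 1/S`, community perspective) and metabolism-weighted (energetic
#' perspective). Richness and min/max/range are computed once (they cannot be
#' weighted). Undefined metrics are carried as `NA` with the reasons
#' collected in `undefined_reason`, never raised as errors.
#'
#' @param community niche `data.frame` for one plot: columns `taxon, plot,
#'   system, landscape, D13C, D15N` and optionally `weight` (summing to 1).
#' @param ensemble scaling ensemble from [fit_scaling()].
#' @return a one-row `data.frame` (see [compute_metrics_table()] for the
#'   column set).
#' @export
compute_all_metrics <- function(community, ensemble) {
  .assert_columns(community, c("taxon", "plot", "D13C", "D15N"), "community")
  if (nrow(community) == 0) stop("empty community", call. = FALSE)
  if (anyDuplicated(community$taxon)) {
    stop("duplicated taxa within community ", community$plot[1], call. = FALSE)
  }
  S <- nrow(community)
  w_u <- rep(1 / S, S)
  has_w <- "weight" %in% names(community) && !anyNA(community$weight)
  w_m <- if (has_w) community$weight else NULL
  if (has_w && abs(sum(w_m) - 1) > 1e-9) {
    stop("metabolism weights must sum to 1 within the community", call. = FALSE)
  }

  c13 <- one_dim_metrics(community$D13C, w_m)
  n15 <- one_dim_metrics(community$D15N, w_m)

  scaled <- scale_niches(community, ensemble)
  pts <- cbind(scaled$c, scaled$n)

  reasons <- character(0)
  take <- function(x, label) {
    r <- attr(x, "reason")
    if (!is.null(r)) reasons <<- c(reasons, paste0(label, ": ", r))
    as.numeric(x)
  }

  metric_pair <- function(fun, label) {
    u <- take(fun(pts, w_u), paste0(label, "_u"))
    w <- if (has_w) take(fun(pts, w_m), paste0(label, "_w")) else NA_real_
    if (!has_w) reasons <<- unique(c(reasons, "weighted variants: no metabolism weights"))
    c(u = u, w = w)
  }

  idiv <- metric_pair(isotopic_divergence, "IDiv")
  idis <- metric_pair(isotopic_dispersion, "IDis")
  ieve <- metric_pair(isotopic_evenness, "IEve")
  iuni <- metric_pair(isotopic_uniqueness, "IUni")

  data.frame(
    plot = community$plot[1],
    system = if ("system" %in% names(community)) community$system[1] else NA_character_,
    landscape = if ("landscape" %in% names(community)) community$landscape[1] else NA_character_,
    S = S,
    d13C_min = c13$min, d13C_max = c13$max, d13C_range = c13$range,
    d13C_mean_u = c13$mean_u, d13C_mean_w = c13$mean_w,
    d15N_min = n15$min, d15N_max = n15$max, d15N_range = n15$range,
    d15N_mean_u = n15$mean_u, d15N_mean_w = n15$mean_w,
    IRic = convex_hull_area(pts),
    IDiv_u = idiv["u"], IDiv_w = idiv["w"],
    IDis_u = idis["u"], IDis_w = idis["w"],
    IEve_u = ieve["u"], IEve_w = ieve["w"],
    IUni_u = iuni["u"], IUni_w = iuni["w"],
    undefined_reason = paste(reasons, collapse = "; "),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Metrics for every community of a run
#'
#' Splits the niche table by plot, fits the global scaling ensemble across
#' all communities (unless one is supplied), and computes the full metric set
#' per community.
#'
#' @param niches niche `data.frame` covering all plots of the run, with
#'   `weight` attached for the energetic perspective (see
#'   [assign_metabolism_weights()]).
#' @param ensemble optional pre-fitted scaling ensemble.
#' @return a `data.frame` with one row per plot.
#' @export
compute_metrics_table <- function(niches, ensemble = NULL) {
  if (is.null(ensemble)) ensemble <- fit_scaling(niches)
  out <- do.call(rbind, lapply(split(niches, niches$plot),
                               compute_all_metrics, ensemble = ensemble))
  rownames(out) <- NULL
  out[order(out$plot), , drop = FALSE]
}
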