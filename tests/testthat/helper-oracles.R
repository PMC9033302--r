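# Independent brute-force oracles and small fixture builders used across the
# test files. Oracles deliberately share no code with the package internals.

# Convex hull area by first principles: a point is a hull vertex iff it is
# not strictly inside (or on the boundary of) any triangle formed by three
# OTHER points; order the vertices by angle around their centroid, shoelace.
brute_hull_area <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 3) return(0)
  sign_area <- function(a, b, c) {
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  }
  in_triangle <- function(p, a, b, c) {
    d1 <- sign_area(p, a, b); d2 <- sign_area(p, b, c); d3 <- sign_area(p, c, a)
    neg <- (d1 < 0) | (d2 < 0) | (d3 < 0)
    pos <- (d1 > 0) | (d2 > 0) | (d3 > 0)
    !(neg && pos)
  }
  is_vertex <- rep(TRUE, n)
  for (p in seq_len(n)) {
    others <- setdiff(seq_len(n), p)
    if (length(others) < 3) next
    for (tri in utils::combn(others, 3, simplify = FALSE)) {
      if (abs(sign_area(pts[tri[1], ], pts[tri[2], ], pts[tri[3], ])) < 1e-14) next
      if (in_triangle(pts[p, ], pts[tri[1], ], pts[tri[2], ], pts[tri[3], ])) {
        # strict interior only: boundary points do not change the area,
        # so removing them is still correct for an area oracle
        is_vertex[p] <- FALSE
        break
      }
    }
  }
  v <- pts[is_vertex, , drop = FALSE]
  if (nrow(v) < 3) return(0)
  ctr <- colMeans(v)
  ord <- order(atan2(v[, 2] - ctr[2], v[, 1] - ctr[1]))
  v <- v[ord, , drop = FALSE]
  m <- nrow(v)
  j <- c(m, seq_len(m - 1))
  abs(sum(v[j, 1] * v[, 2] - v[, 1] * v[j, 2])) / 2
}

# Minimum spanning tree total length by exhaustion: try every (S-1)-subset
# of the complete graph's edges and keep the cheapest one that is a
# connected spanning forest. Only feasible for small S.
brute_mst_length <- function(pts) {
  pts <- as.matrix(pts)
  S <- nrow(pts)
  dmat <- as.matrix(dist(pts))
  edges <- utils::combn(S, 2)
  ne <- ncol(edges)
  best <- Inf
  spans <- function(sel) {
    reach <- rep(FALSE, S); reach[1] <- TRUE
    repeat {
      grew <- FALSE
      for (k in sel) {
        i <- edges[1, k]; j <- edges[2, k]
        if (xor(reach[i], reach[j])) { reach[i] <- reach[j] <- TRUE; grew <- TRUE }
      }
      if (!grew) break
    }
    all(reach)
  }
  for (sel in utils::combn(ne, S - 1, simplify = FALSE)) {
    if (!spans(sel)) next
    tot <- sum(dmat[cbind(edges[1, sel], edges[2, sel])])
    if (tot < best) best <- tot
  }
  best
}

# Exact ANOSIM null for two groups of 3 in 6 objects: all 20 distinct label
# splits, R computed directly from ranked distances.
exhaustive_anosim <- function(d, grouping) {
  n <- attr(d, "Size")
  rnk <- rank(as.vector(d))
  pair_i <- unlist(lapply(seq_len(n - 1), function(i) rep(i, n - i)))
  pair_j <- unlist(lapply(seq_len(n - 1), function(i) seq(i + 1, n)))
  stat <- function(g) {
    within <- g[pair_i] == g[pair_j]
    (mean(rnk[!within]) - mean(rnk[within])) / (n * (n - 1) / 4)
  }
  obs <- stat(grouping)
  labels <- unique(grouping)
  stopifnot(length(labels) == 2, all(table(grouping) == 3), n == 6)
  null_R <- apply(utils::combn(6, 3), 2, function(idx) {
    g <- rep(labels[2], 6); g[idx] <- labels[1]
    stat(g)
  })
  list(R = obs, null_R = null_R,
       p_exact = mean(null_R >= obs))
}

# A reproducible random community in scaled isotope space.
random_community <- function(S, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pts <- cbind(runif(S), runif(S))
  w <- rexp(S); w <- w / sum(w)
  list(pts = pts, w = w)
}

# In-code CSV fixtures for the reader tests.
write_tmp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

iso_header <- "taxon,plot,landscape,system,layer,d13C,d15N,n_individuals"

# Small fully-valid isotope fixture: 2 plots, 2 taxa, litter+soil layers.
small_isotope_fixture <- function() {
  write_tmp_csv(c(
    iso_header,
    "Annelida,P1,landscape_1,rainforest,litter,-26.1,2.4,5",
    "Annelida,P1,landscape_1,rainforest,soil,-25.7,2.8,4",
    "Oribatida,P1,landscape_1,rainforest,litter,-27.0,1.1,10",
    "Annelida,P2,landscape_1,oil_palm,litter,-27.5,3.0,6",
    "Oribatida,P2,landscape_1,oil_palm,litter,-28.2,0.4,12"
  ))
}

small_baseline_fixture <- function() {
  write_tmp_csv(c(
    "plot,d13C_litter,d15N_litter",
    "P1,-29.5,0.2",
    "P2,-28.9,-0.3"
  ))
}

small_metabolism_fixture <- function() {
  write_tmp_csv(c(
    "taxon,plot,metabolism",
    "Annelida,P1,10",
    "Oribatida,P1,2",
    "Annelida,P2,40",
    "Oribatida,P2,1"
  ))
}
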