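test_that("scaling ensemble maps extremes to 0 and 1 and rejects degenerate axes", {
  niches <- data.frame(D13C = c(3.4, 5.0, 6.4), D15N = c(-5, 2.1, 9.2))
  ens <- fit_scaling(niches)
  expect_equal(ens$c_min, 3.4)
  expect_equal(ens$c_max, 6.4)
  sc <- scale_niches(niches, ens)
  expect_equal(sc$c, c(0, (5 - 3.4) / 3, 1), tolerance = 1e-12)
  expect_equal(sc$n, c(0, 0.5, 1), tolerance = 1e-12)

  flat <- data.frame(D13C = c(2, 2), D15N = c(1, 3))
  expect_error(fit_scaling(flat), "degenerate")
  outside <- data.frame(D13C = 7, D15N = 0)
  expect_error(scale_niches(outside, ens), "outside")
})

test_that("one-dimensional metrics: range is max minus min, weighted mean uses the weights", {
  m <- one_dim_metrics(c(3.4, 5.1, 6.4))
  expect_equal(m$range, 3.0)
  expect_equal(m$mean_u, mean(c(3.4, 5.1, 6.4)))
  expect_true(is.na(m$mean_w))

  m2 <- one_dim_metrics(c(2, 4), weights = c(1, 0))
  expect_equal(m2$mean_w, 2)
  expect_error(one_dim_metrics(numeric(0)), "empty")
})

test_that("convex hull area matches simple geometry and the brute-force oracle", {
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(convex_hull_area(square), 1.0)
  collinear <- rbind(c(0, 0), c(0.5, 0.5), c(1, 1))
  expect_equal(convex_hull_area(collinear), 0.0)
  expect_equal(convex_hull_area(rbind(c(0, 0), c(1, 1))), 0)

  set.seed(101)
  for (i in 1:25) {
    S <- sample(3:10, 1)
    pts <- cbind(runif(S), runif(S))
    expect_equal(convex_hull_area(pts), brute_hull_area(pts), tolerance = 1e-10)
  }
})

test_that("hull area is rigid-motion invariant and non-decreasing under point addition", {
  set.seed(102)
  pts <- cbind(runif(8), runif(8))
  a0 <- convex_hull_area(pts)
  for (theta in c(0.3, 1.2, 2.9)) {
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    moved <- sweep(pts %*% R, 2, c(3.7, -1.2), "+")
    expect_equal(convex_hull_area(moved), a0, tolerance = 1e-10)
  }
  for (i in 1:10) {
    bigger <- rbind(pts, cbind(runif(1, -0.5, 1.5), runif(1, -0.5, 1.5)))
    expect_gte(convex_hull_area(bigger), a0 - 1e-12)
    pts <- bigger
    a0 <- convex_hull_area(pts)
  }
})

test_that("isotopic divergence matches closed forms", {
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  # all points equidistant from the hull centroid: IDiv = 1 for any weights
  expect_equal(isotopic_divergence(square, rep(0.25, 4)), 1)
  expect_equal(isotopic_divergence(square, c(0.7, 0.1, 0.1, 0.1)), 1)

  # square corners at weight 0.025 each plus centre point at 0.9: 5/77 exactly
  pts <- rbind(square, c(0.5, 0.5))
  w <- c(rep(0.025, 4), 0.9)
  expect_equal(isotopic_divergence(pts, w), 5 / 77, tolerance = 1e-12)

  # degenerate hull is NA with a reason, not an error
  coll <- rbind(c(0, 0), c(0.5, 0.5), c(1, 1))
  out <- isotopic_divergence(coll, rep(1 / 3, 3))
  expect_true(is.na(out))
  expect_match(attr(out, "reason"), "degenerate")
})

test_that("isotopic dispersion: circle gives 1, coincident points 0, monopolised weight drives it to 0", {
  theta <- seq(0, 2 * pi, length.out = 9)[-9]
  circle <- cbind(cos(theta), sin(theta))
  expect_equal(isotopic_dispersion(circle, rep(1 / 8, 8)), 1, tolerance = 1e-12)

  same <- matrix(0.3, nrow = 4, ncol = 2)
  expect_equal(isotopic_dispersion(same, rep(0.25, 4)), 0)

  # two-point community: closed form sum(w d)/max d with O the weighted centroid
  two <- rbind(c(0, 0), c(1, 0))
  for (w1 in c(0.5, 0.9, 0.99, 0.999)) {
    w <- c(w1, 1 - w1)
    # distances to O = (1-w1, 0): d = (1-w1, w1); max = max of the two
    expected <- (w1 * (1 - w1) + (1 - w1) * w1) / max(w1, 1 - w1)
    expect_equal(isotopic_dispersion(two, w), expected, tolerance = 1e-12)
  }
  expect_lt(isotopic_dispersion(two, c(0.999, 0.001)), 0.01)
})

test_that("isotopic evenness: equal spacing gives 1, clustering lowers it, MST matches exhaustive search", {
  line <- rbind(c(0, 0), c(1, 0), c(2, 0))
  expect_equal(isotopic_evenness(line, rep(1 / 3, 3)), 1, tolerance = 1e-12)

  # one tight pair far from a third point: branch lengths very uneven
  clustered <- rbind(c(0, 0), c(0, 0.01), c(1, 0))
  expect_lt(isotopic_evenness(clustered, rep(1 / 3, 3)), 0.5)

  out <- isotopic_evenness(rbind(c(0, 0), c(1, 0)), c(0.5, 0.5))
  expect_true(is.na(out))

  set.seed(103)
  for (i in 1:15) {
    S <- sample(4:6, 1)
    pts <- cbind(runif(S), runif(S))
    edges <- isofoodweb:::.mst_edges(pts)
    expect_equal(sum(edges[, "dist"]), brute_mst_length(pts), tolerance = 1e-10)
  }
})

test_that("the MST agrees with vegan's spanning tree on larger communities", {
  skip_if_not_installed("vegan")
  set.seed(104)
  for (i in 1:5) {
    S <- sample(8:15, 1)
    pts <- cbind(runif(S), runif(S))
    edges <- isofoodweb:::.mst_edges(pts)
    sp <- vegan::spantree(dist(pts))
    expect_equal(sum(edges[, "dist"]), sum(sp$dist), tolerance = 1e-10)
  }
})

test_that("isotopic uniqueness matches its nearest-neighbour definition", {
  two <- rbind(c(0, 0), c(3, 4))
  expect_equal(isotopic_uniqueness(two, c(0.5, 0.5)), 1)
  expect_equal(isotopic_uniqueness(two, c(0.9, 0.1)), 1)  # both NNDs equal

  same <- matrix(1, nrow = 3, ncol = 2)
  expect_equal(isotopic_uniqueness(same, rep(1 / 3, 3)), 0)

  # tight cluster of 3 plus one distant point, equal weights:
  # NND = (0.01, 0.01, 0.01, ~1); brute-force table frozen by hand
  pts <- rbind(c(0, 0), c(0.01, 0), c(0, 0.01), c(1, 0))
  nnd <- c(0.01, 0.01, 0.01, sqrt((1 - 0.01)^2))
  expected <- sum(0.25 * nnd) / max(nnd)
  expect_equal(isotopic_uniqueness(pts, rep(0.25, 4)), expected, tolerance = 1e-12)
})

test_that("multidimensional metrics stay within [0,1] over many random communities", {
  set.seed(105)
  for (i in 1:300) {
    cm <- random_community(sample(3:15, 1))
    vals <- c(isotopic_divergence(cm$pts, cm$w),
              isotopic_dispersion(cm$pts, cm$w),
              isotopic_evenness(cm$pts, cm$w),
              isotopic_uniqueness(cm$pts, cm$w))
    vals <- vals[!is.na(vals)]
    expect_true(all(vals >= -1e-12 & vals <= 1 + 1e-12))
  }
})

test_that("equal metabolism weights reproduce the unweighted variant of every metric", {
  set.seed(106)
  ref <- data.frame(D13C = c(-1, 2), D15N = c(-1, 2))
  ens <- fit_scaling(ref)
  for (i in 1:20) {
    S <- sample(3:12, 1)
    cm <- random_community(S)
    niches <- data.frame(taxon = paste0("t", seq_len(S)), plot = "P1",
                         system = "rainforest", landscape = "landscape_1",
                         D13C = cm$pts[, 1], D15N = cm$pts[, 2],
                         weight = rep(1 / S, S))
    res <- compute_all_metrics(niches, ens)
    for (stem in c("IDiv", "IDis", "IEve", "IUni")) {
      expect_equal(res[[paste0(stem, "_w")]], res[[paste0(stem, "_u")]],
                   tolerance = 1e-12)
    }
    expect_equal(res$d13C_mean_w, res$d13C_mean_u, tolerance = 1e-12)
    expect_equal(res$d15N_mean_w, res$d15N_mean_u, tolerance = 1e-12)
  }
})

test_that("compute_all_metrics handles sizes, equal weights, and degenerate communities", {
  niches <- data.frame(
    taxon = c("Annelida", "Oribatida", "Diplura", "Collembola"),
    plot = "P1", system = "rainforest", landscape = "landscape_1",
    D13C = c(5.8, 3.4, 6.0, 4.0), D15N = c(3.0, 1.5, 9.2, 2.0),
    weight = rep(0.25, 4))
  ref <- data.frame(D13C = c(0, 8), D15N = c(-6, 10))
  ens <- fit_scaling(rbind(niches[, c("D13C", "D15N")], ref))
  res <- compute_all_metrics(niches, ens)

  # all 13 metric kinds present: 2x5 one-dimensional + IRic + 2x4 variants
  one_dim <- c("d13C_min", "d13C_max", "d13C_range", "d13C_mean_u", "d13C_mean_w",
               "d15N_min", "d15N_max", "d15N_range", "d15N_mean_u", "d15N_mean_w")
  multi <- c("IRic", "IDiv_u", "IDiv_w", "IDis_u", "IDis_w",
             "IEve_u", "IEve_w", "IUni_u", "IUni_w")
  expect_true(all(c(one_dim, multi) %in% names(res)))
  expect_equal(res$d13C_range, res$d13C_max - res$d13C_min)

  # equal metabolism weights: weighted equals unweighted everywhere
  for (stem in c("IDiv", "IDis", "IEve", "IUni")) {
    expect_equal(res[[paste0(stem, "_w")]], res[[paste0(stem, "_u")]],
                 tolerance = 1e-12)
  }
  expect_equal(res$d13C_mean_w, res$d13C_mean_u, tolerance = 1e-12)

  # S = 1: one-dimensional metrics defined, multidimensional missing
  single <- niches[1, ]
  single$weight <- 1
  res1 <- compute_all_metrics(single, ens)
  expect_equal(res1$d13C_range, 0)
  expect_equal(res1$IRic, 0)
  expect_true(is.na(res1$IDiv_u))
  expect_true(is.na(res1$IDis_u))
  expect_true(is.na(res1$IEve_u))
  expect_true(is.na(res1$IUni_u))
  expect_match(res1$undefined_reason, "S < ")
})

test_that("concentrating weight on one taxon drives dispersion to zero, leaving unweighted metrics unchanged", {
  set.seed(107)
  cm <- random_community(8)
  w_eq <- rep(1 / 8, 8)
  base_u <- isotopic_dispersion(cm$pts, w_eq)
  prev <- Inf
  for (eps in c(0.3, 0.1, 0.01, 0.001)) {
    w <- rep(eps / 7, 8); w[1] <- 1 - eps
    idis <- isotopic_dispersion(cm$pts, w)
    expect_lt(idis, prev)
    prev <- idis
    # unweighted value never moves
    expect_equal(isotopic_dispersion(cm$pts, w_eq), base_u, tolerance = 1e-15)
  }
  expect_lt(prev, 0.05)
})
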