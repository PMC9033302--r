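test_that("Welch contrast matches the closed-form t on two plots per group", {
  niches <- data.frame(
    taxon = "Annelida",
    plot = paste0("P", 1:4),
    system = c("oil_palm", "oil_palm", "rainforest", "rainforest"),
    D13C = c(1, 2, 3, 4), D15N = c(1, 2, 3, 4))
  res <- reference_contrasts(niches, reference = "rainforest")
  row <- res[res$isotope == "D13C", ]
  # Welch t on {1,2} vs {3,4}: t = -2*sqrt(2), df = 2, direction other - ref
  expect_equal(row$t, -2 * sqrt(2), tolerance = 1e-12)
  expect_equal(row$df, 2, tolerance = 1e-12)
  expect_equal(row$mean_diff, -2)
})

test_that("identical groups give t = 0 and p = 1; separated groups give p << 0.01", {
  same <- data.frame(taxon = "Oribatida", plot = paste0("P", 1:8),
                     system = rep(c("rubber", "rainforest"), each = 4),
                     D13C = rep(c(1, 2, 3, 4), 2),
                     D15N = rep(c(1, 2, 3, 4), 2))
  res <- reference_contrasts(same, reference = "rainforest")
  expect_true(all(res$t == 0))
  expect_true(all(res$p == 1))
  expect_true(all(res$stars == ""))

  set.seed(31)
  sep <- data.frame(taxon = "Oribatida", plot = paste0("P", 1:8),
                    system = rep(c("rubber", "rainforest"), each = 4),
                    D13C = c(rnorm(4, 0, 0.01), rnorm(4, 1, 0.01)),
                    D15N = c(rnorm(4, 0, 0.01), rnorm(4, 1, 0.01)))
  res2 <- reference_contrasts(sep, reference = "rainforest")
  expect_true(all(res2$p < 0.01))
  expect_true(all(res2$stars == "**"))
})

test_that("contrasts with insufficient replication are kept with a reason, not dropped", {
  niches <- data.frame(taxon = "Diplura", plot = paste0("P", 1:3),
                       system = c("oil_palm", "rainforest", "rainforest"),
                       D13C = 1:3, D15N = 1:3)
  res <- reference_contrasts(niches, reference = "rainforest")
  expect_true(all(is.na(res$p)))
  expect_match(res$reason[1], "insufficient replication")
})

test_that("two-way ANOVA F statistics match a direct sum-of-squares decomposition", {
  set.seed(41)
  grid <- expand.grid(system = LAND_USE_SYSTEMS,
                      landscape = c("landscape_1", "landscape_2"),
                      rep = 1:4)
  effects <- c(rainforest = 0, jungle_rubber = 1, rubber = 2, oil_palm = 0.5)
  grid$value <- effects[as.character(grid$system)] +
    ifelse(grid$landscape == "landscape_1", 0.3, -0.3) + rnorm(nrow(grid), 0, 0.7)

  res <- two_way_anova_tukey(grid)

  # balanced design: sequential SS equal classical factor SS
  grand <- mean(grid$value)
  ss <- function(f) sum(tapply(grid$value, grid[[f]],
                               function(v) length(v) * (mean(v) - grand)^2))
  ss_sys <- ss("system"); ss_ls <- ss("landscape")
  fitted_add <- grand +
    (tapply(grid$value, grid$system, mean)[as.character(grid$system)] - grand) +
    (tapply(grid$value, grid$landscape, mean)[as.character(grid$landscape)] - grand)
  ss_res <- sum((grid$value - fitted_add)^2)
  df_res <- nrow(grid) - 4 - 2 + 1
  F_sys <- (ss_sys / 3) / (ss_res / df_res)
  F_ls <- (ss_ls / 1) / (ss_res / df_res)

  expect_equal(res$anova$F[res$anova$term == "system"], F_sys, tolerance = 1e-10)
  expect_equal(res$anova$F[res$anova$term == "landscape"], F_ls, tolerance = 1e-10)
})

test_that("Tukey letters form a display consistent with the pairwise p matrix", {
  set.seed(42)
  for (i in 1:8) {
    grid <- expand.grid(system = LAND_USE_SYSTEMS,
                        landscape = c("landscape_1", "landscape_2"), rep = 1:4)
    shift <- sample(c(0, 0, 3, 10), 4)
    names(shift) <- LAND_USE_SYSTEMS
    grid$value <- shift[as.character(grid$system)] + rnorm(nrow(grid))
    res <- two_way_anova_tukey(grid)
    for (r in seq_len(nrow(res$tukey))) {
      pr <- strsplit(res$tukey$pair[r], "-", fixed = TRUE)[[1]]
      shared <- intersect(strsplit(res$letters[[pr[1]]], "")[[1]],
                          strsplit(res$letters[[pr[2]]], "")[[1]])
      if (res$tukey$p_adj[r] <= 0.05) {
        expect_length(shared, 0)
      } else {
        expect_gt(length(shared), 0)
      }
    }
  }
})

test_that("a strongly shifted system receives its own letter; equal values share one letter", {
  grid <- expand.grid(system = LAND_USE_SYSTEMS,
                      landscape = c("landscape_1", "landscape_2"), rep = 1:4)
  set.seed(43)
  grid$value <- rnorm(nrow(grid), 0, 1) +
    ifelse(grid$system == "oil_palm", 10, 0)
  res <- two_way_anova_tukey(grid)
  op <- res$letters[["oil_palm"]]
  others <- unlist(res$letters[setdiff(LAND_USE_SYSTEMS, "oil_palm")])
  expect_false(any(grepl(op, others, fixed = TRUE)))

  flat <- grid; flat$value <- 5
  res2 <- two_way_anova_tukey(flat)
  expect_true(all(res2$letters == "a"))
})

test_that("ANOSIM gives R = 1 for fully separated groups and near-zero R on shuffled labels", {
  set.seed(51)
  x <- rbind(matrix(rnorm(20, 0, 0.1), ncol = 2),
             matrix(rnorm(20, 10, 0.1), ncol = 2))
  g <- rep(c("a", "b"), each = 10)
  res <- anosim_test(x, g, n_perm = 199, seed = 1)
  expect_equal(res$R, 1)
  expect_lte(res$p, 0.01)

  # structureless data, random labels: mean R over replicates close to 0
  rs <- sapply(1:20, function(i) {
    set.seed(200 + i)
    xx <- matrix(rnorm(48), ncol = 2)
    anosim_test(xx, sample(rep(c("a", "b", "c"), each = 8)),
                n_perm = 99, seed = i)$R
  })
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("ANOSIM permutation p agrees with exhaustive enumeration at n = 6", {
  set.seed(52)
  x <- rbind(matrix(rnorm(6, 0), ncol = 2), matrix(rnorm(6, 1.5), ncol = 2))
  g <- rep(c("a", "b"), each = 3)
  d <- dist(scale(x))
  oracle <- exhaustive_anosim(d, g)
  res <- anosim_test(x, g, n_perm = 999, seed = 3)
  expect_equal(res$R, oracle$R, tolerance = 1e-12)
  # the permutation p must sit within Monte-Carlo error of the exact value
  se <- sqrt(oracle$p_exact * (1 - oracle$p_exact) / 999)
  expect_lt(abs(res$p - oracle$p_exact), 4 * se + 2 / 1000)
})

test_that("ANOSIM R matches vegan and is invariant to monotone distance transforms", {
  skip_if_not_installed("vegan")
  set.seed(53)
  x <- matrix(rnorm(64), ncol = 2)
  x[1:16, ] <- x[1:16, ] + 1.2
  g <- rep(c("a", "b"), each = 16)
  d <- dist(x)
  mine <- anosim_test(d, g, n_perm = 99, seed = 1)
  veg <- vegan::anosim(d, g, permutations = 99)
  expect_equal(mine$R, unname(veg$statistic), tolerance = 1e-12)

  squared <- d^2  # monotone transform: identical ranks, identical R
  expect_equal(anosim_test(squared, g, n_perm = 99, seed = 1)$R, mine$R,
               tolerance = 1e-12)
})

test_that("ANOSIM output is bit-identical across runs with a fixed seed", {
  set.seed(54)
  x <- matrix(rnorm(40), ncol = 2)
  g <- rep(c("a", "b"), each = 10)
  r1 <- anosim_test(x, g, n_perm = 199, seed = 99)
  r2 <- anosim_test(x, g, n_perm = 199, seed = 99)
  expect_identical(r1$perm_R, r2$perm_R)
  expect_identical(r1$p, r2$p)
})
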