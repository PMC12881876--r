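test_that("shape PCA has the spectral properties of a covariance eigendecomposition", {
  set.seed(4)
  Y <- matrix(rnorm(12 * 30), 12, 30)
  rownames(Y) <- sprintf("s%02d", 1:12)
  pca <- shape_pca(Y)
  expect_equal(sum(pca$percent_variance), 100, tolerance = 1e-6)
  expect_true(all(diff(pca$percent_variance) <= 1e-12))
  # scores are uncorrelated
  cv <- cov(pca$scores)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-10)
  # full reconstruction recovers the inputs
  rec <- pca$scores %*% t(pca$loadings) + matrix(pca$consensus, 12, 30, byrow = TRUE)
  expect_equal(rec, Y, tolerance = 1e-8, ignore_attr = TRUE)
  # two distinct specimens: a single axis carries all variance
  p2 <- shape_pca(Y[1:2, ])
  expect_equal(p2$percent_variance[1], 100, tolerance = 1e-9)
  expect_error(shape_pca(Y[1, , drop = FALSE]), "at least 2")
})

test_that("RRPP ANOVA identifies saturated, null and degenerate designs", {
  # two noiseless clusters split by the factor: R2 -> 1, p at resolution
  Y <- rbind(
    matrix(rep(c(1, 0, 0, 0), each = 6), 6),
    matrix(rep(c(0, 1, 0, 0), each = 6), 6)
  )
  d <- data.frame(grp = factor(rep(c("a", "b"), each = 6)))
  a <- procrustes_anova(Y, ~grp, d, n_perm = 199, seed = 1)
  tab <- tidy(a)
  expect_gt(tab$R2[tab$term == "grp"], 0.999)
  # p at the permutation resolution: only group-preserving shuffles (rare
  # under random permutation of 12 rows) can tie the saturated F
  expect_gte(tab$p_perm[tab$term == "grp"], 1 / 200)
  expect_lte(tab$p_perm[tab$term == "grp"], 3 / 200)
  # R2 partition sums to 1
  expect_equal(sum(tab$R2[tab$term != "Total"]), 1, tolerance = 1e-9)
  # constant response: R2 zero and F flagged undefined
  Yc <- matrix(1, 12, 4)
  ac <- procrustes_anova(Yc, ~grp, d, n_perm = 99, seed = 1)
  expect_equal(tidy(ac)$R2[1], 0)
  expect_true(is.na(tidy(ac)$F[1]))
  # seeded reproducibility at 1/(n_perm+1) resolution
  set.seed(10)
  Yr <- matrix(rnorm(12 * 4), 12, 4)
  p1 <- tidy(procrustes_anova(Yr, ~grp, d, n_perm = 99, seed = 7))$p_perm[1]
  p2 <- tidy(procrustes_anova(Yr, ~grp, d, n_perm = 99, seed = 7))$p_perm[1]
  expect_identical(p1, p2)
  expect_equal(round(p1 * 100) / 100, p1, tolerance = 1e-12)
})

test_that("single-covariate R2 equals the squared fitted-observed correlation", {
  set.seed(5)
  n <- 25
  x <- rnorm(n)
  Y <- outer(x, c(1, -2, 0.5)) + matrix(rnorm(n * 3, 0, 0.3), n, 3)
  d <- data.frame(x = x)
  a <- procrustes_anova(Y, ~x, d, n_perm = 0, seed = 1)
  r2 <- tidy(a)$R2[1]
  # squared correlation between fitted and observed shape vectors
  fit <- lm(Y ~ x)
  Yc <- scale(Y, scale = FALSE)
  Fc <- scale(fitted(fit), scale = FALSE)
  r2_corr <- sum(Yc * Fc)^2 / (sum(Yc^2) * sum(Fc^2))
  expect_equal(r2, r2_corr, tolerance = 1e-9)
})

test_that("RRPP matches an established permutation MANOVA on distances", {
  skip_if_not_installed("vegan")
  set.seed(6)
  Y <- matrix(rnorm(18 * 6), 18, 6)
  d <- data.frame(g = factor(rep(letters[1:3], each = 6)))
  mine <- tidy(procrustes_anova(Y, ~g, d, n_perm = 0, seed = 1))
  veg <- vegan::adonis2(dist(Y) ~ g, data = d, permutations = 2)
  expect_equal(mine$SS[1], veg$SumOfSqs[1], tolerance = 1e-9)
  expect_equal(mine$F[1], veg$F[1], tolerance = 1e-9)
  expect_equal(mine$R2[1], veg$R2[1], tolerance = 1e-9)
})

test_that("phylogenetic MANOVA reduces to ordinary ANOVA on a star tree", {
  n <- 12
  star <- ape::read.tree(text = paste0(
    "(", paste(sprintf("t%d:1", 1:n), collapse = ","), ");"
  ))
  set.seed(7)
  Y <- matrix(rnorm(n * 5), n, 5)
  rownames(Y) <- star$tip.label
  d <- data.frame(
    species = star$tip.label,
    g = factor(rep(c("a", "b"), each = n / 2))
  )
  a0 <- tidy(procrustes_anova(Y, ~g, d, n_perm = 99, seed = 3))
  a1 <- tidy(pgls_manova(Y, ~g, d, star, n_perm = 99, seed = 3))
  expect_equal(a1$F[1], a0$F[1], tolerance = 1e-8)
  expect_equal(a1$R2[1], a0$R2[1], tolerance = 1e-8)
  expect_equal(a1$p_perm[1], a0$p_perm[1])
  expect_error(
    pgls_manova(Y, ~g, data.frame(species = paste0("x", 1:n), g = d$g), star),
    "not in tree"
  )
})

test_that("disparity follows the n-divisor Procrustes-variance convention", {
  set.seed(8)
  Y <- matrix(rnorm(20 * 6), 20, 6)
  g <- rep(c("a", "b"), each = 10)
  d <- shape_disparity(Y, g, dims = 2, n_perm = 99, seed = 2)
  pv <- d$group_variances$procrustes_variance
  expect_true(all(pv >= 0))
  expect_equal(d$pairwise_abs_diffs["a", "b"], abs(diff(pv)))
  expect_equal(d$pairwise_abs_diffs, t(d$pairwise_abs_diffs))
  expect_equal(unname(diag(d$pairwise_abs_diffs)), c(0, 0))
  # duplicating every member of a group leaves its variance unchanged
  Y2 <- rbind(Y, Y[g == "a", ])
  g2 <- c(g, rep("a", 10))
  d2 <- shape_disparity(Y2, g2, dims = 2, n_perm = 0)
  expect_equal(
    d2$group_variances$procrustes_variance[1], pv[1],
    tolerance = 1e-12
  )
  # identical specimens: zero disparity everywhere
  d0 <- shape_disparity(matrix(1, 10, 6), rep(c("a", "b"), 5), dims = 2, n_perm = 0)
  expect_equal(d0$group_variances$procrustes_variance, c(0, 0))
  # allometric residual adjustment removes size-driven disparity
  sizes <- seq(1, 3, length.out = 20)
  Ys <- Y + outer(sizes, rep(3, 6))
  da <- shape_disparity(Ys, g, log_sizes = sizes, dims = 2, adjust = "residual", n_perm = 0)
  dn <- shape_disparity(Ys, g, dims = 2, n_perm = 0)
  expect_lt(
    max(da$group_variances$procrustes_variance),
    max(dn$group_variances$procrustes_variance)
  )
  # undersized groups are excluded from pairwise testing
  dsm <- shape_disparity(Y, c(rep("a", 19), "b"), dims = 2, n_perm = 19, seed = 1)
  expect_true("b" %in% dsm$excluded_groups)
})

test_that("trajectory comparison recovers construction and the null", {
  set.seed(9)
  n_per <- 8
  x <- rep(seq(0, 1, length.out = n_per), 3)
  sp <- rep(c("s1", "s2", "s3"), each = n_per)
  # s1 and s2 share a trajectory; s3 is orthogonal with low noise
  b1 <- c(1, 0, 0, 0)
  b3 <- c(0, 0, 1, 0)
  Y <- rbind(
    outer(x[1:n_per], b1), outer(x[1:n_per], b1),
    outer(x[1:n_per], b3)
  ) + matrix(rnorm(3 * n_per * 4, 0, 0.02), ncol = 4)
  tr <- trajectory_analysis(Y, sp, x, n_perm = 199, seed = 3)
  pairs <- tidy(tr)
  ang_13 <- pairs$angle_deg[pairs$species_1 == "s1" & pairs$species_2 == "s3"]
  expect_equal(ang_13, 90, tolerance = 5)
  expect_lt(pairs$p_angle_adj[pairs$species_1 == "s1" & pairs$species_2 == "s3"], 0.05)
  expect_gt(pairs$p_angle_adj[pairs$species_1 == "s1" & pairs$species_2 == "s2"], 0.05)
  # Bonferroni is the defining multiple of the raw p
  expect_equal(pairs$p_angle_adj, pmin(1, pairs$p_angle * nrow(pairs)))
  expect_equal(tr$significant_pair_count, sum(
    pairs$p_angle_adj < 0.05 | pairs$p_length_adj < 0.05
  ))
  # species without a size range are excluded with a warning
  Yb <- rbind(Y, matrix(rnorm(3 * 4), 3, 4))
  expect_warning(
    trajectory_analysis(
      Yb, c(sp, rep("s4", 3)), c(x, rep(1, 3)),
      n_perm = 19, seed = 1
    ),
    "s4"
  )
})

test_that("spearman association matches hand-computed ranks", {
  expect_equal(spearman_assoc(1:10, (1:10)^2)$rho, 1)
  expect_equal(spearman_assoc(1:10, -(1:10)^3)$rho, -1)
  expect_equal(spearman_assoc(c(1, 2, 3), c(2, 1, 3))$rho, 0.5, tolerance = 1e-12)
  expect_true(is.na(spearman_assoc(rep(1, 5), 1:5)$rho))
  expect_error(spearman_assoc(1:2, 1:2), "at least 3")
})
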