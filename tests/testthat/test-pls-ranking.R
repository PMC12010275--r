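test_that("zscore operations normalize, drop degenerate columns, are idempotent", {
  set.seed(1)
  m <- cbind(a = rnorm(40, 5, 2), b = rnorm(40, -3, 7))
  z <- zscore_columns(m)
  expect_equal(colMeans(z), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(apply(z, 2, sd), c(a = 1, b = 1), tolerance = 1e-12)
  expect_equal(zscore_columns(z), z, tolerance = 1e-12)

  m2 <- cbind(m, flat = rep(2, 40))
  expect_warning(z2 <- zscore_columns(m2), "zero-variance")
  expect_equal(colnames(z2), c("a", "b"))

  expect_equal(sd(zscore_vector(rnorm(20, 9, 4))), 1, tolerance = 1e-12)
  expect_error(zscore_vector(rep(1, 5)), "zero-variance")
})

test_that("plsr_fit satisfies the univariate closed form and variance accounting", {
  set.seed(2)
  # single predictor equal to y: component 1 explains all of y
  y <- zscore_vector(rnorm(30))
  X1 <- matrix(y, dimnames = list(NULL, "g1"))
  m1 <- plsr_fit(X1, y, K = 1)
  expect_equal(m1$explained_variance_y[1], 1, tolerance = 1e-12)

  # component-1 weights are proportional to X'y (cosine similarity 1)
  for (s in 1:5) {
    set.seed(s)
    X <- matrix(rnorm(30 * 200), 30, 200,
                dimnames = list(NULL, sprintf("g%03d", 1:200)))
    X <- zscore_columns(X)
    yy <- zscore_vector(rnorm(30))
    m <- plsr_fit(X, yy, K = 5)
    w_cf <- crossprod(X, yy)
    cosine <- sum(m$weights[, 1] * w_cf) /
      sqrt(sum(m$weights[, 1]^2) * sum(w_cf^2))
    expect_equal(cosine, 1, tolerance = 1e-10)
    # scores pairwise orthogonal
    g <- crossprod(m$scores)
    expect_lt(max(abs(g[upper.tri(g)])) /
                min(diag(g)), 1e-8)
    # explained y variance non-negative, cumulative <= 1
    expect_true(all(m$explained_variance_y >= -1e-12))
    expect_lte(sum(m$explained_variance_y), 1 + 1e-12)
  }
  expect_error(plsr_fit(matrix(rnorm(20), 10, 2), rnorm(10), K = 10),
               "invalid argument")
})

test_that("explained variance is invariant to gene order and column sign flips", {
  set.seed(3)
  X <- zscore_columns(matrix(rnorm(25 * 80), 25, 80,
                             dimnames = list(NULL, sprintf("g%02d", 1:80))))
  y <- zscore_vector(rnorm(25))
  ev <- plsr_fit(X, y, K = 4)$explained_variance_y
  perm <- sample(80)
  expect_equal(plsr_fit(X[, perm], y, K = 4)$explained_variance_y, ev,
               tolerance = 1e-10)
  flip <- X %*% diag(sample(c(-1, 1), 80, replace = TRUE))
  colnames(flip) <- colnames(X)
  expect_equal(plsr_fit(flip, y, K = 4)$explained_variance_y, ev,
               tolerance = 1e-10)
})

test_that("align_weights enforces the positive-correlation convention", {
  set.seed(4)
  X <- zscore_columns(matrix(rnorm(30 * 50), 30, 50,
                             dimnames = list(NULL, sprintf("g%02d", 1:50))))
  y <- zscore_vector(rnorm(30))
  m <- plsr_fit(X, y, K = 2)
  r1 <- cor(m$scores[, 1], y)
  expect_gt(r1, 0)                      # NIPALS component 1: never negative
  w <- align_weights(m, y, 1)
  expect_equal(w, m$weights[, 1])       # positive correlation: unchanged

  # simulate the sign-indeterminate fit: jointly negated component
  m_neg <- m
  m_neg$weights[, 1] <- -m$weights[, 1]
  m_neg$scores[, 1] <- -m$scores[, 1]
  w_neg <- align_weights(m_neg, y, 1)
  expect_equal(w_neg, m$weights[, 1])   # flip restores the convention

  expect_error(align_weights(m, y, 5), "component index")
})

test_that("gene_z_scores recovers planted genes and top weights correlate positively", {
  a <- gen_atlas(c(16, 16, 16), 83, seed = 51)
  set.seed(52)
  y <- as.numeric(scale(a$centroids[, 1])) + rnorm(83, 0, 0.3)
  ph <- regional_phenotype(1:83, y)
  coup <- c(setNames(rep(0.8, 25), sprintf("POS%02d", 1:25)),
            setNames(rep(-0.8, 25), sprintf("NEG%02d", 1:25)))
  ex <- gen_expression(a, ph, 1000, coup, spatial_range = 5, seed = 53)
  su <- generate_surrogates(ph, a$centroids, n_null = 100, seed = 54)
  rk <- gene_z_scores(ex$expression, y, su, k = 1)

  # diffuse gradient phenotype: a deliberately hard setting, so check tail
  # separation rather than perfect classification
  extreme <- ceiling(0.05 * nrow(rk))
  in_tail <- names(coup) %in% rk$gene[order(-abs(rk$z))][1:extreme]
  expect_gte(mean(in_tail), 0.75)
  decoy_z <- abs(rk$z[!rk$gene %in% names(coup)])
  planted_z <- abs(rk$z[rk$gene %in% names(coup)])
  expect_gt(median(planted_z), quantile(decoy_z, 0.99))

  # aligned convention: the top gene's expression correlates positively
  expect_gt(cor(ex$expression[, rk$gene[1]], y), 0)
  expect_lt(cor(ex$expression[, rk$gene[nrow(rk)]], y), 0)

  rk2 <- gene_z_scores(ex$expression, y, su, k = 1)
  expect_identical(rk$gene, rk2$gene)

  val <- validate_ranking(ex$expression, y, rk, k_top = 5)
  expect_true(all(val$slope[val$end == "top"] > 0))
  expect_true(all(val$slope[val$end == "bottom"] < 0))
  expect_error(validate_ranking(ex$expression, y, rk, k_top = 600),
               "invalid argument")

  # a gene identical to the phenotype validates with r = 1
  Xg <- cbind(ex$expression[, 1:10], ycopy = y)
  rk_small <- rk[1:20, ]
  class(rk_small) <- class(rk)
  rk_small$gene[1] <- "ycopy"
  v2 <- validate_ranking(Xg, y, rk_small, k_top = 1)
  expect_equal(v2$r[v2$gene == "ycopy"], 1, tolerance = 1e-12)
})

test_that("null gene Z statistics are calibrated and rankings are stable", {
  a <- gen_atlas(c(14, 14, 14), 60, seed = 61)
  set.seed(62)
  y <- as.numeric(scale(a$centroids[, 2])) + rnorm(60, 0, 0.4)
  ph <- regional_phenotype(1:60, y)
  ex <- gen_expression(a, ph, 600, numeric(0), spatial_range = 5, seed = 63)
  su <- generate_surrogates(ph, a$centroids, n_null = 100, seed = 64)
  rk <- gene_z_scores(ex$expression, y, su, k = 1)
  expect_gt(sd(rk$z), 0.5)          # null calibration sanity band
  expect_lt(sd(rk$z), 2)

  # ranking stability across two independent surrogate ensembles
  coup <- c(setNames(rep(0.8, 20), sprintf("P%02d", 1:20)),
            setNames(rep(-0.8, 20), sprintf("N%02d", 1:20)))
  ex2 <- gen_expression(a, ph, 600, coup, spatial_range = 5, seed = 65)
  suA <- generate_surrogates(ph, a$centroids, n_null = 200, seed = 66)
  suB <- generate_surrogates(ph, a$centroids, n_null = 200, seed = 67)
  rkA <- gene_z_scores(ex2$expression, y, suA, k = 1)
  rkB <- gene_z_scores(ex2$expression, y, suB, k = 1)
  zA <- setNames(rkA$z, rkA$gene)[names(coup)]
  zB <- setNames(rkB$z, rkB$gene)[names(coup)]
  expect_gt(cor(zA, zB, method = "spearman"), 0.9)
})
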