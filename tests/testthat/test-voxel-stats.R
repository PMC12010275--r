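test_that("smooth_gaussian preserves constants, fwhm=0 is identity, kernels normalize", {
  shape <- c(12, 12, 12)
  mask <- array(TRUE, shape)
  const <- array(3.7, shape)
  expect_equal(smooth_gaussian(const, mask, 3), const, tolerance = 1e-12)

  set.seed(1)
  v <- array(rnorm(prod(shape)), shape)
  expect_equal(smooth_gaussian(v, mask, 0), v)

  # unit impulse far from the edge: smoothed volume sums to 1
  imp <- array(0, c(21, 21, 21))
  imp[11, 11, 11] <- 1
  sm <- smooth_gaussian(imp, array(TRUE, c(21, 21, 21)), 3)
  expect_equal(sum(sm), 1, tolerance = 1e-6)

  # constant stays constant under an irregular mask (renormalization)
  mask2 <- array(FALSE, shape); mask2[3:9, 4:10, 2:11] <- TRUE
  sm2 <- smooth_gaussian(array(5, shape), mask2, 4)
  expect_equal(sm2[mask2], rep(5, sum(mask2)), tolerance = 1e-12)
  expect_true(all(sm2[!mask2] == 0))

  expect_error(smooth_gaussian(v, mask, -1), "fwhm")
})

test_that("fit_glm_tmap matches the two-sample t and the hand-computed case", {
  # hand case: groups A = {0,1}, B = {1,2}, no covariates -> t = sqrt(2)
  shape <- c(2, 2, 2)
  cohort <- structure(list(
    data = matrix(rep(c(0, 1, 1, 2), 8), nrow = 4),
    group = c(0L, 0L, 1L, 1L),
    covariates = data.frame(row.names = 1:4),
    mask = array(TRUE, shape), shape = shape), class = "voxel_cohort")
  tm <- fit_glm_tmap(cohort)
  expect_equal(as.vector(tm$values), rep(sqrt(2), 8), tolerance = 1e-10)

  # with zero-slope covariates the group t equals the textbook two-sample t
  a <- gen_atlas(c(10, 10, 10), 5, seed = 1)
  sim <- gen_cohort(a, 10, effect_size = 0.5, effect_regions = 1,
                    covariate_slopes = c(age = 0, sex = 0), seed = 2)
  co <- sim$cohort
  co$covariates <- data.frame(row.names = seq_along(co$group))
  tm2 <- fit_glm_tmap(co)
  g <- co$group
  idx <- sample(seq_len(prod(co$shape)), 1000)
  t_ref <- vapply(idx, function(j)
    unname(t.test(co$data[g == 1, j], co$data[g == 0, j],
                  var.equal = TRUE)$statistic), numeric(1))
  expect_equal(tm2$values[idx], t_ref, tolerance = 1e-10)

  # collinear covariate -> design error
  bad <- co
  bad$covariates <- data.frame(dup = as.numeric(co$group))
  expect_error(fit_glm_tmap(bad), "design")
})

test_that("tfce_enhance matches the analytic single-voxel value in both modes", {
  shape <- c(8, 8, 8)
  v <- array(0, shape); v[4, 4, 4] <- 1
  sm <- structure(list(values = v, kind = "t", mask = array(TRUE, shape)),
                  class = "stat_map")
  # exact integral: 1^E * integral_0^1 h^2 dh = 1/3, exactly
  e <- tfce_enhance(sm, tfce_params(E = 0.5, H = 2))
  expect_equal(e$values[4, 4, 4], 1 / 3, tolerance = 1e-12)
  # step approximation at dh = 0.001 agrees to well under 0.5%
  e2 <- tfce_enhance(sm, tfce_params(E = 0.5, H = 2, dh = 0.001))
  expect_lt(abs(e2$values[4, 4, 4] - 1 / 3) / (1 / 3), 0.005)

  zero <- structure(list(values = array(0, shape), kind = "t",
                         mask = array(TRUE, shape)), class = "stat_map")
  expect_true(all(tfce_enhance(zero)$values == 0))
})

test_that("tfce_enhance agrees with independent oracles on random maps", {
  for (s in c(11, 12)) {
    v6 <- random_tmap(c(6, 6, 6), seed = s)
    sm <- structure(list(values = v6, kind = "t",
                         mask = array(TRUE, c(6, 6, 6))),
                    class = "stat_map")
    got <- tfce_enhance(sm)$values
    # exact interval-summation reference (independent implementation)
    want <- tfce_exact_oracle(v6, 0.5, 2)
    expect_equal(got, want, tolerance = 1e-10)
    # literal fine-step summation converges to the same values
    fine <- tfce_oracle(v6, 0.5, 2, max(abs(v6)) / 2000)
    rel <- abs(got - fine) / pmax(abs(fine), 1e-3 * max(abs(fine)))
    expect_lt(max(rel), 0.01)
  }
})

test_that("TFCE is odd and scales as lambda^(H+1) on fixed components", {
  v <- random_tmap(c(8, 8, 8), seed = 21)
  mask <- array(TRUE, c(8, 8, 8))
  smap <- function(x) structure(list(values = x, kind = "t", mask = mask),
                                class = "stat_map")
  p <- tfce_params()
  e1 <- tfce_enhance(smap(v), p)$values
  # two-sided symmetry: negation is exact
  expect_identical(tfce_enhance(smap(-v), p)$values, -e1)
  # scaling the map by lambda keeps component structure, so the exact
  # TFCE integral scales by lambda^(H+1)
  lam <- 2.5
  e2 <- tfce_enhance(smap(lam * v), p)$values
  expect_equal(e2, lam^3 * e1, tolerance = 1e-10)
})

test_that("permutation_fwe controls error, floors p, detects a planted blob, is deterministic", {
  a <- gen_atlas(c(12, 12, 12), 8, seed = 5)
  sim <- gen_cohort(a, 20, effect_size = 3, effect_regions = 1, seed = 6)
  p <- permutation_fwe(sim$cohort, tfce_params(n_perm = 200, seed = 7))
  expect_true(all(p$values >= 1 / 201))
  blob <- sim$truth$effect_mask
  expect_true(all(p$values[blob] < 0.05))
  p2 <- permutation_fwe(sim$cohort, tfce_params(n_perm = 200, seed = 7))
  expect_identical(p$values, p2$values)
  expect_error(tfce_params(n_perm = 0), "n_perm")
})

test_that("parcellate averages per label and flags empty regions", {
  a <- gen_atlas(c(10, 10, 10), 7, seed = 8)
  mask <- array(TRUE, c(10, 10, 10))
  cst <- structure(list(values = array(4.2, c(10, 10, 10)), kind = "tfce",
                        mask = mask), class = "stat_map")
  expect_equal(parcellate(cst, a)$values, rep(4.2, 7))

  set.seed(3)
  v <- array(rnorm(1000), c(10, 10, 10))
  got <- parcellate(structure(list(values = v, kind = "tfce", mask = mask),
                              class = "stat_map"), a)$values
  want <- vapply(1:7, function(r) mean(v[a$label_volume == r]), numeric(1))
  expect_equal(got, want, tolerance = 1e-12)

  # region fully outside the mask -> NA with warning
  m2 <- mask; m2[a$label_volume == 3] <- FALSE
  expect_warning(
    ph <- parcellate(structure(list(values = v, kind = "tfce", mask = m2),
                               class = "stat_map"), a),
    "no in-mask")
  expect_true(is.na(ph$values[3]))
  expect_false(anyNA(ph$values[-3]))
})
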