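test_that("design matrices have the stated columns and contrasts", {
  cohort <- make_cohort(10, "HC")
  seed <- rnorm(10)
  d <- build_design(cohort, seed, "within_group", "HC")
  expect_equal(dim(d$X), c(10L, 8L))
  expect_equal(d$contrast, "v_seed")
  expect_equal(colnames(d$X),
               c("intercept", "v_seed", "age", "sex", "education", "bdi",
                 "isi", "tiv"))

  two <- rbind(make_cohort(8, "HC", 1), make_cohort(8, "SCD", 2))
  two$id <- sprintf("s%02d", 1:16)
  two <- as_cohort_table(two)
  seed2 <- rnorm(16)
  di <- build_design(two, seed2, "interaction", c("HC", "SCD"))
  expect_equal(ncol(di$X), 10L)
  expect_equal(di$contrast, "v_seed_x_group")
  # case group coded 1, seed centred before the product
  expect_equal(unname(di$X[, "group"]),
               as.integer(two$group == "SCD"))
  expect_equal(mean(di$X[, "v_seed"]), 0, tolerance = 1e-12)

  # duplicated covariate information is a rank-deficiency error
  dup <- make_cohort(12, "HC")
  dup$bdi <- dup$education
  expect_error(build_design(as_cohort_table(dup), rnorm(12),
                            "within_group", "HC"), "collinear|rank")
  expect_error(build_design(cohort, seed, "within_group", "XX"), "XX")
})

test_that("a perfectly seed-determined voxel gives beta1 = 1 and flagged t", {
  n <- 20
  cohort <- make_cohort(n, "HC")
  set.seed(4)
  seed <- abs(rnorm(n)) + 1
  nvox <- 8
  vals <- matrix(abs(rnorm(n * nvox)) + 0.5, n)
  vals[, 3] <- seed  # voxel exactly equal to V_seed
  stack <- make_stack(vals, c(nvox, 1, 1))
  d <- build_design(cohort, seed, "within_group", "HC")
  f <- fit_voxelwise(stack, d)
  expect_equal(unname(f$beta["v_seed", 3]), 1, tolerance = 1e-8)
  expect_lt(max(abs(f$residuals[, 3])), 1e-10)
  expect_true(f$flag_infinite[3])
  expect_true(is.infinite(f$t[3]) && f$t[3] > 0)
})

test_that("voxel-wise OLS equals the brute-force normal-equations oracle", {
  set.seed(10)
  for (rep in 1:10) {
    n <- 20
    cohort <- make_cohort(n, "HC", seed = rep)
    seed <- rnorm(n)
    vals <- matrix(abs(rnorm(n * 6)) + 0.5, n)
    stack <- make_stack(vals, c(6, 1, 1))
    d <- build_design(cohort, seed, "within_group", "HC")
    f <- fit_voxelwise(stack, d)
    ci <- match("v_seed", colnames(d$X))
    for (v in 1:6) {
      o <- ols_oracle(d$X, vals[, v], ci)
      expect_equal(unname(f$beta[, v]), o$beta, tolerance = 1e-8)
      expect_equal(unname(f$t[v]), unname(o$t), tolerance = 1e-8)
      expect_equal(f$dof, o$dof)
    }
  }
})

test_that("null voxels produce near-null t statistics", {
  n <- 100
  cohort <- make_cohort(n, "HC", seed = 31)
  set.seed(32)
  seed <- rnorm(n)
  vals <- matrix(abs(rnorm(n * 2000)) + 2, n)
  stack <- make_stack(vals, c(20, 10, 10))
  f <- fit_voxelwise(stack, build_design(cohort, seed, "within_group", "HC"))
  expect_lt(mean(abs(f$beta["v_seed", ])), 0.1)
  expect_gte(mean(abs(f$t) < 4), 0.99)
})

test_that("residuals are orthogonal to every design column", {
  n <- 30
  cohort <- make_cohort(n, "SCD", seed = 12)
  set.seed(13)
  seed <- rnorm(n)
  vals <- matrix(abs(rnorm(n * 40)) + 1, n)
  stack <- make_stack(vals, c(10, 2, 2))
  d <- build_design(cohort, seed, "within_group", "SCD")
  # unit-scale the design columns for a meaningful bound
  f <- fit_voxelwise(stack, d)
  Xs <- scale(d$X[, -1])
  expect_lt(max(abs(t(Xs) %*% f$residuals)), 1e-8)
})

test_that("interaction t is invariant to group/seed recoding", {
  n <- 15
  two <- rbind(make_cohort(n, "HC", 21), make_cohort(n, "SCD", 22))
  two$id <- sprintf("s%02d", 1:(2 * n))
  two <- as_cohort_table(two)
  set.seed(23)
  seed <- rnorm(2 * n)
  y <- abs(rnorm(2 * n)) + 1
  d <- build_design(two, seed, "interaction", c("HC", "SCD"))
  t_pkg <- ols_oracle(d$X, y, match("v_seed_x_group", colnames(d$X)))$t
  # affine recodings of the group indicator and uncentred seed
  for (recode in list(c(-1, 1), c(1, 2), c(3, 7))) {
    g <- ifelse(two$group == "SCD", recode[2], recode[1])
    X2 <- cbind(1, seed, g, seed * g,
                as.matrix(two[, c("age", "sex", "education", "bdi",
                                  "isi", "tiv")]))
    t_alt <- ols_oracle(X2, y, 4)$t
    expect_equal(unname(t_alt), unname(t_pkg), tolerance = 1e-8)
  }
})

test_that("interaction t within the planted seed parcel is strong on truth", {
  cfg <- small_config(group_sizes = c(HC = 20L, SCD = 20L, MIG = 3L),
                      rho = list(target_a = c(HC = 0.9, SCD = 0, MIG = 0),
                                 target_b = c(HC = 0, SCD = 0, MIG = 0)))
  sim <- generate_cohort(cfg, 77)
  v <- seed_means(sim$stack, seed_roi("s", sim$truth$parcels$hippocampus))
  f <- fit_voxelwise(sim$stack,
                     build_design(sim$cohort, v, "interaction",
                                  c("HC", "SCD")))
  tm <- t_map(f)
  in_target <- mean(tm[sim$truth$parcels$target_a], na.rm = TRUE)
  elsewhere <- mean(tm[sim$truth$parcels$target_b], na.rm = TRUE)
  # HC covariance drop in SCD drives the interaction negative in target_a
  expect_lt(in_target, -1.5)
  expect_lt(in_target, elsewhere)
  expect_lt(abs(elsewhere), 2.5)  # target_b carries no signal
})

test_that("smoothness estimation recovers the applied kernel", {
  shape <- c(24, 24, 24)
  mask <- array(TRUE, dim = shape)
  set.seed(40)
  # white noise: rougher than 1.5 voxels
  wn <- t(sapply(1:8, function(i) rnorm(prod(shape))))
  sm_wn <- estimate_smoothness(wn, mask, 3)
  expect_true(all(sm_wn$fwhm_mm < 4.5))
  # 6 mm kernel on a 3 mm grid: recovered within [4.5, 7.5]
  sm6 <- t(sapply(1:8, function(i)
    as.numeric(smooth_volume(array(rnorm(prod(shape)), shape), 6, 3))))
  est <- estimate_smoothness(sm6, mask, 3)
  expect_gt(est$fwhm_geo_mm, 4.5)
  expect_lt(est$fwhm_geo_mm, 7.5)
  # constant residuals are undefined
  expect_error(estimate_smoothness(matrix(1, 4, prod(shape)), mask, 3),
               "constant")
  # an axis thinner than 2 voxels is reported missing
  thin_mask <- array(TRUE, dim = c(1, 10, 10))
  thin <- matrix(rnorm(300), 3)
  est_thin <- estimate_smoothness(thin, thin_mask, 3)
  expect_true(is.na(est_thin$fwhm_mm[1]))
})
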