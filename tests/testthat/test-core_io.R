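test_that("subject tables round-trip and validate their schema", {
  cohort <- make_cohort(5, "SCD")
  cohort$scd_duration <- c(1, 4, NA, 8, 2)
  path <- tempfile(fileext = ".tsv")
  write_cohort_table(cohort, path)
  back <- read_subject_table(path)
  expect_s3_class(back, "cohort_table")
  expect_equal(back$id, cohort$id)
  expect_equal(back$group, cohort$group)
  for (col in c("age", "sex", "education", "bdi", "isi", "tiv"))
    expect_equal(back[[col]], cohort[[col]], tolerance = 1e-12)
  expect_equal(back$scd_duration, cohort$scd_duration)

  # missing required column is named in the error
  df <- as.data.frame(cohort)
  df$tiv <- NULL
  p2 <- tempfile(fileext = ".tsv")
  write.table(df, p2, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_subject_table(p2), "tiv")

  # non-numeric covariate reports the row
  df2 <- as.data.frame(cohort)
  df2$age <- as.character(df2$age)
  df2$age[3] <- "forty"
  expect_error(as_cohort_table(df2), "row 3")

  # unknown group label rejected
  df3 <- as.data.frame(cohort)
  df3$group <- "PATIENT"
  expect_error(as_cohort_table(df3), "PATIENT")
})

test_that("GM stacks read/write NIfTI volumes faithfully", {
  grid <- volume_grid(c(10, 12, 10), {
    a <- diag(c(2, 2, 2, 1)); a[1:3, 4] <- c(-9, -11, -9); a
  })
  set.seed(7)
  vals <- matrix(runif(5 * prod(grid$shape)), 5)
  stack <- gmv_stack(vals, grid, paste0("s", 1:5))
  dir <- tempfile()
  paths <- write_gmv_stack(stack, dir)
  mask_path <- file.path(dir, "mask.nii.gz")
  write_stat_map(array(1, dim = grid$shape), grid, mask_path)
  back <- read_gm_stack(paths, mask_path)
  expect_equal(n_subjects(back), 5)
  expect_equal(back$subject_ids, stack$subject_ids)
  expect_lt(max(abs(back$values - stack$values)), 1e-6)
  expect_equal(back$grid$affine, grid$affine, tolerance = 1e-5)

  # a volume on a different grid is refused by name
  other <- volume_grid(grid$shape, diag(c(3, 3, 3, 1)))
  bad <- file.path(dir, "bad.nii.gz")
  write_stat_map(array(0.5, dim = grid$shape), other, bad)
  expect_error(read_gm_stack(c(paths, bad = bad), mask_path), "bad")
})

test_that("stat maps round-trip and reject mismatched shapes", {
  grid <- volume_grid(c(6, 7, 8), diag(c(1.5, 1.5, 1.5, 1)))
  set.seed(1)
  tmap <- array(rnorm(prod(grid$shape)), dim = grid$shape)
  p <- tempfile(fileext = ".nii.gz")
  write_stat_map(tmap, grid, p)
  back <- read_stat_map(p)
  expect_lt(max(abs(back$values - tmap)), 1e-6)
  expect_equal(back$grid$voxel_size_mm, grid$voxel_size_mm,
               tolerance = 1e-5)

  write_stat_map(array(0, dim = grid$shape), grid, p)
  expect_equal(sum(read_stat_map(p)$values), 0)

  expect_error(write_stat_map(array(0, dim = c(2, 2, 2)), grid, p),
               "shape")
})

test_that("EFC attains its extremes and matches hand evaluation", {
  # all intensity in one voxel: entropy of a point mass
  x <- array(0, dim = c(4, 4, 4)); x[2, 3, 1] <- 5
  expect_equal(compute_efc(x), 0)
  # perfectly uniform volume: maximal entropy
  expect_equal(compute_efc(array(2.5, dim = c(5, 5, 5))), 1,
               tolerance = 1e-12)
  # two-voxel hand evaluations of the normalised-entropy formula
  efc_hand <- function(x) {
    b <- x / sqrt(sum(x^2))
    -sum(ifelse(b > 0, b * log(b), 0)) / (sqrt(length(x)) * log(sqrt(length(x))))
  }
  expect_equal(compute_efc(c(1, 1)), efc_hand(c(1, 1)))
  expect_equal(compute_efc(c(1, 1)), 1, tolerance = 1e-12)
  expect_equal(compute_efc(c(3, 4)), efc_hand(c(3, 4)), tolerance = 1e-12)

  expect_error(compute_efc(array(0, dim = c(3, 3, 3))), "all-zero")
})

test_that("EFC is scale invariant and bounded by its extremes", {
  set.seed(42)
  for (i in 1:20) {
    x <- array(rexp(64), dim = c(4, 4, 4))
    e <- compute_efc(x)
    expect_equal(compute_efc(x * runif(1, 0.1, 50)), e, tolerance = 1e-12)
    expect_gte(e, 0)
    expect_lte(e, 1)
  }
})

test_that("sample homogeneity flags deviant subjects deterministically", {
  set.seed(3)
  pattern <- runif(200)
  vals <- matrix(rep(pattern, 5), 5, byrow = TRUE)
  stack <- make_stack(vals, c(200, 1, 1))
  hom <- sample_homogeneity(stack)
  expect_true(all(abs(hom$homogeneity - 1) < 1e-12))
  expect_false(any(hom$outlier_flag))

  # one negated subject has minimal homogeneity and is flagged at z_cut 2
  # (brute-force pairwise correlations confirm the per-subject means)
  vals2 <- matrix(rep(pattern, 11), 11, byrow = TRUE) +
    matrix(rnorm(11 * 200, 0, 0.01), 11)
  vals2[4, ] <- -pattern + rnorm(200, 0, 0.01)
  vals2 <- vals2 - min(vals2)  # keep values non-negative
  stack2 <- make_stack(vals2, c(200, 1, 1))
  hom2 <- sample_homogeneity(stack2, z_cut = 2)
  expect_equal(which.min(hom2$homogeneity), 4L)
  expect_true(hom2$outlier_flag[4])
  expect_false(any(hom2$outlier_flag[-4]))
  brute <- sapply(1:11, function(i)
    mean(sapply((1:11)[-i], function(j) cor(vals2[i, ], vals2[j, ]))))
  expect_equal(hom2$homogeneity, brute, tolerance = 1e-12)

  # mean homogeneity invariant under subject reordering
  perm <- sample(11)
  stack3 <- make_stack(vals2[perm, ], c(200, 1, 1))
  hom3 <- sample_homogeneity(stack3)
  expect_equal(sort(hom3$homogeneity), sort(hom2$homogeneity),
               tolerance = 1e-12)

  # constant subject is flagged with a reason
  vals4 <- vals2
  vals4[2, ] <- 0.7
  hom4 <- sample_homogeneity(make_stack(vals4, c(200, 1, 1)))
  expect_true(hom4$outlier_flag[2])
  expect_match(hom4$reason[2], "constant")

  # fewer than 3 subjects is a precondition failure (stack refuses)
  expect_error(make_stack(vals[1:2, ], c(200, 1, 1)), "3 subjects")
})

test_that("qc_report combines EFC with homogeneity", {
  sim <- generate_cohort(small_config(), 5)
  rep <- qc_report(sim$stack)
  expect_equal(nrow(rep), 30)
  expect_true(all(rep$efc > 0 & rep$efc < 1))
  # a clean synthetic cohort should not be flagged wholesale
  expect_lt(mean(rep$outlier_flag), 0.2)
  p <- tempfile(fileext = ".tsv")
  write_qc_report(rep, p)
  expect_true(file.exists(p))
})
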