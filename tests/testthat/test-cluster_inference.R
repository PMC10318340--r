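test_that("critical cluster size equals direct enumeration of the tail", {
  sizes <- c(1, 1, 1, 2, 9, 9, 9, 9, 9, 9)
  expect_equal(critical_cluster_size(sizes, 0.05), 10L)
  # nothing ever reaches 1 when all maxima are 0
  expect_equal(critical_cluster_size(rep(0L, 200), 0.05), 1L)
  expect_equal(critical_cluster_size(rep(0L, 200), 0.999), 1L)

  # brute-force enumeration oracle on random size lists
  set.seed(14)
  for (i in 1:25) {
    s <- rpois(200, sample(2:30, 1))
    alpha <- runif(1, 0.01, 0.3)
    k_oracle <- NA
    for (k in 1:(max(s) + 1)) {
      if (mean(s >= k) <= alpha) { k_oracle <- k; break }
    }
    expect_equal(critical_cluster_size(s, alpha), as.integer(k_oracle))
  }

  # non-increasing in alpha
  s <- rpois(500, 12)
  ks <- sapply(c(0.01, 0.05, 0.1, 0.25), function(a)
    critical_cluster_size(s, a))
  expect_true(all(diff(ks) <= 0))
  expect_error(critical_cluster_size(s, 0), "alpha")
})

test_that("null cluster simulation is deterministic and validates inputs", {
  mask <- array(TRUE, dim = c(12, 12, 12))
  a <- simulate_null_clusters(mask, 3, 6, 0.01, n_sim = 100, rng_seed = 5)
  b <- simulate_null_clusters(mask, 3, 6, 0.01, n_sim = 100, rng_seed = 5)
  expect_identical(a$sizes, b$sizes)
  c2 <- simulate_null_clusters(mask, 3, 6, 0.01, n_sim = 100, rng_seed = 6)
  expect_false(identical(a$sizes, c2$sizes))

  expect_error(simulate_null_clusters(mask, 3, 6, 0.5, n_sim = 100),
               "voxel_p")
  expect_error(simulate_null_clusters(mask, 3, 200, 0.01, n_sim = 100),
               "kernel")
})

test_that("unsmoothed null simulation matches an independent R oracle", {
  mask <- array(TRUE, dim = c(20, 20, 20))
  n_sim <- 100
  got <- simulate_null_clusters(mask, 3, 0, 0.005, n_sim = n_sim,
                                connectivity = 26, rng_seed = 77)
  # replay the identical RNG stream and recompute with the R flood fill
  set.seed(77)
  cut <- qnorm(1 - 0.005)
  frac <- numeric(n_sim)
  for (s in 1:n_sim) {
    noise <- rnorm(prod(dim(mask)))
    z <- (noise - mean(noise)) / sd(noise)
    supra <- array(z > cut, dim = dim(mask))
    frac[s] <- mean(supra)
    if (s <= 10) {  # exact flood-fill comparison on the first sims
      labs <- label_oracle(supra, 26)
      expect_equal(got$sizes[s],
                   if (any(supra)) max(tabulate(labs[labs > 0])) else 0L)
    }
  }
  # binomial expectation for the mean suprathreshold fraction
  p <- 0.005
  se <- sqrt(p * (1 - p) / prod(dim(mask))) / sqrt(n_sim)
  expect_lt(abs(mean(frac) - p), 3 * se + 1e-4)
})

test_that("critical size grows with smoothness", {
  mask <- array(TRUE, dim = c(20, 20, 20))
  ks <- sapply(c(0, 4, 8), function(f)
    critical_cluster_size(
      simulate_null_clusters(mask, 3, f, 0.01, n_sim = 300, rng_seed = 8),
      0.05))
  expect_true(all(diff(ks) >= 0))
})

test_that("cluster thresholding retains blobs by extent", {
  grid <- mni_like_grid(c(20, 20, 20), 3)
  tm <- array(0, dim = grid$shape)
  # one 300-voxel suprathreshold blob (10 x 10 x 3)
  tm[6:15, 6:15, 9:11] <- 5
  tm[8, 9, 10] <- 7.5  # peak
  res <- threshold_map(tm, grid, dof = 70, voxel_p = 0.005, k_min = 235)
  expect_equal(nrow(res$table), 1L)
  expect_equal(res$table$size, 300L)
  expect_equal(res$table$max_t, 7.5)
  expect_equal(res$table$direction, "positive")
  expect_equal(unname(c(res$table$peak_x, res$table$peak_y,
                        res$table$peak_z)),
               unname(voxel_world(grid, which(tm == 7.5))[1, ]))
  res2 <- threshold_map(tm, grid, dof = 70, voxel_p = 0.005, k_min = 301)
  expect_equal(nrow(res2$table), 0L)
  expect_false(any(res2$mask_pos))

  # negative blobs are reported in their own direction
  res3 <- threshold_map(-tm, grid, dof = 70, voxel_p = 0.005, k_min = 235)
  expect_equal(res3$table$direction, "negative")
  expect_equal(res3$table$max_t, -7.5)

  expect_error(threshold_map(tm, grid, dof = 0, voxel_p = 0.005,
                             k_min = 10), "dof")
})

test_that("connectivity defines adjacency for diagonal neighbours", {
  grid <- mni_like_grid(c(8, 8, 8), 3)
  tm <- array(0, dim = grid$shape)
  tm[3, 3, 3] <- 5
  tm[4, 4, 4] <- 5  # touches only diagonally
  r26 <- threshold_map(tm, grid, 50, 0.005, k_min = 1, connectivity = 26)
  expect_equal(nrow(r26$table), 1L)
  expect_equal(r26$table$size, 2L)
  r6 <- threshold_map(tm, grid, 50, 0.005, k_min = 1, connectivity = 6)
  expect_equal(nrow(r6$table), 2L)
  expect_equal(r6$table$size, c(1L, 1L))
})

test_that("component labelling equals the R flood-fill oracle", {
  set.seed(15)
  for (conn in c(6L, 18L, 26L)) {
    m <- array(runif(9 * 8 * 7) < 0.35, dim = c(9, 8, 7))
    got <- seedscn:::label_components_cpp(as.vector(m), dim(m), conn)
    want <- label_oracle(m, conn)
    # same partition: identical multiset of sizes and same co-membership
    expect_equal(sort(tabulate(got[got > 0])),
                 sort(tabulate(want[want > 0])))
    expect_equal(max(got), max(want))
    relab <- tapply(want[m], got[m], function(x) length(unique(x)))
    expect_true(all(relab == 1))
  }
})

test_that("empirical FWE p comes from the null tail", {
  grid <- mni_like_grid(c(16, 16, 16), 3)
  mask <- array(TRUE, dim = grid$shape)
  nd <- simulate_null_clusters(mask, 3, 6, 0.005, n_sim = 200, rng_seed = 2)
  tm <- array(0, dim = grid$shape)
  tm[4:9, 4:9, 4:9] <- 4
  res <- threshold_map(tm, grid, 60, 0.005, k_min = 1, mask = mask,
                       null_dist = nd)
  expect_equal(res$table$p_fwe, mean(nd$sizes >= res$table$size))
})

test_that("conjunction is the voxel-wise intersection", {
  set.seed(16)
  a <- array(runif(4 * 5 * 6) < 0.4, dim = c(4, 5, 6))
  b <- array(runif(4 * 5 * 6) < 0.4, dim = c(4, 5, 6))
  cj <- conjunction(a, b)
  # exhaustive voxel loop oracle
  for (v in seq_along(a)) expect_equal(cj[v], a[v] && b[v])
  # idempotent, commutative, contained in both
  expect_identical(conjunction(a, a), a)
  expect_identical(conjunction(a, b), conjunction(b, a))
  expect_true(all(!cj[!a]) && all(!cj[!b]))
  # disjoint masks intersect to nothing
  expect_false(any(conjunction(a, a & !a)))
  expect_error(conjunction(a, array(TRUE, dim = c(2, 2, 2))), "grid")
})
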