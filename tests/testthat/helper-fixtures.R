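# Shared fixtures and independent brute-force oracles.

# tiny cohort with controllable covariates
make_cohort <- function(n, group = "HC", seed = 1) {
  set.seed(seed)
  as_cohort_table(data.frame(
    id = sprintf("s%02d", seq_len(n)),
    group = group,
    age = rnorm(n, 43, 11),
    sex = rbinom(n, 1, 0.5),
    education = rnorm(n, 15, 3),
    bdi = rnorm(n, 8, 4),
    isi = rnorm(n, 9, 5),
    tiv = rnorm(n, 1.4, 0.12)
  ))
}

# stack with directly specified voxel values (n x nvox matrix)
make_stack <- function(values, shape = NULL, voxel = 2) {
  if (is.null(shape)) {
    nv <- ncol(values)
    shape <- c(nv, 1L, 1L)
  }
  grid <- volume_grid(shape, {
    a <- diag(c(rep(voxel, 3), 1))
    a[1:3, 4] <- -(shape - 1) / 2 * voxel
    a
  })
  gmv_stack(values, grid, sprintf("s%02d", seq_len(nrow(values))))
}

# small synthetic config for fast tests
small_config <- function(group_sizes = c(HC = 10L, SCD = 10L, MIG = 10L),
                         ...) {
  g <- mni_like_grid(c(30L, 36L, 30L), 3)
  synthetic_config(grid = g, group_sizes = group_sizes, ...)
}

# independent OLS oracle: normal equations, textbook formulas
ols_oracle <- function(X, y, contrast_col) {
  xtx <- t(X) %*% X
  beta <- solve(xtx, t(X) %*% y)
  res <- y - X %*% beta
  dof <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / dof
  se <- sqrt(s2 * solve(xtx)[contrast_col, contrast_col])
  list(beta = as.numeric(beta), t = beta[contrast_col] / se, dof = dof,
       residuals = as.numeric(res))
}

# independent connected-component oracle: recursive flood fill in R
label_oracle <- function(mask, connectivity) {
  shape <- dim(mask)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  m <- rowSums(abs(offs))
  offs <- offs[m > 0 & m <= switch(as.character(connectivity),
                                   "6" = 1, "18" = 2, "26" = 3), ,
               drop = FALSE]
  labels <- array(0L, dim = shape)
  cur <- 0L
  for (v in which(mask)) {
    if (labels[v] != 0L) next
    cur <- cur + 1L
    queue <- v
    labels[v] <- cur
    while (length(queue)) {
      u <- queue[1]
      queue <- queue[-1]
      us <- arrayInd(u, shape)
      for (o in seq_len(nrow(offs))) {
        w <- us + offs[o, ]
        if (any(w < 1) || any(w > shape)) next
        wl <- w[1] + (w[2] - 1) * shape[1] + (w[3] - 1) * shape[1] * shape[2]
        if (mask[wl] && labels[wl] == 0L) {
          labels[wl] <- cur
          queue <- c(queue, wl)
        }
      }
    }
  }
  labels
}

# independent partial-correlation oracle via correlation-matrix inversion
partial_cor_oracle <- function(a, b, covs) {
  m <- cbind(a, b, covs)
  om <- solve(cor(m))
  r <- -om[1, 2] / sqrt(om[1, 1] * om[2, 2])
  n <- nrow(m)
  q <- ncol(covs)
  tval <- r * sqrt((n - 2 - q) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tval), n - 2 - q))
}
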