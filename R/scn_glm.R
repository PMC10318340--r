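# Voxel-wise OLS models: within-group seed covariance (beta1 contrast)
# and two-group seed-by-group interaction (beta3 contrast), plus residual
# spatial smoothness estimation.

#' Build a voxel-wise SCN design matrix
#'
#' The within-group model regresses voxel GM on the seed signal plus the
#' six nuisance covariates (age, sex, education, BDI, ISI, TIV), with the
#' seed column as contrast. The interaction model, fitted on two groups,
#' adds a 0/1 group indicator (second listed group coded 1) and the
#' product of the mean-centred seed signal with that indicator; the
#' product column is the contrast, so its coefficient is the
#' between-group difference in seed-covariance slope. Centring the seed
#' before forming the product keeps main effects interpretable; the
#' contrast t value is invariant to affine recodings of either factor.
#'
#' @param cohort a `cohort_table`.
#' @param seed seed signal: numeric vector aligned to cohort rows (e.g.
#'   from [seed_means()]).
#' @param model `"within_group"` or `"interaction"`.
#' @param groups for `within_group`, a single group label; for
#'   `interaction`, a pair `c(reference, case)`.
#' @return object of class `scn_design` with fields `X` (n x p matrix),
#'   `contrast` (column name), `rows` (cohort row indices used), `model`,
#'   `groups`, `subject_ids`.
#' @export
build_design <- function(cohort, seed,
                         model = c("within_group", "interaction"),
                         groups) {
  model <- match.arg(model)
  stopifnot(inherits(cohort, "cohort_table"))
  if (length(seed) != nrow(cohort))
    stop("`seed` must be aligned to the cohort rows")
  n_groups <- if (model == "within_group") 1L else 2L
  if (length(groups) != n_groups)
    stop("`", model, "` model needs ", n_groups, " group label(s)")
  if (!all(groups %in% levels(cohort$group)))
    stop("unknown group label(s): ",
         paste(setdiff(groups, levels(cohort$group)), collapse = ", "))
  rows <- which(cohort$group %in% groups)
  if (length(rows) == 0L) stop("no subjects in the requested group(s)")
  covs <- as.matrix(cohort[rows, glm_covariates])
  if (anyNA(covs)) stop("covariates must be complete")
  v <- seed[rows]

  if (model == "within_group") {
    X <- cbind(intercept = 1, v_seed = v, covs)
    contrast <- "v_seed"
  } else {
    g01 <- as.integer(cohort$group[rows] == groups[2])
    if (all(g01 == 0L) || all(g01 == 1L))
      stop("interaction model needs subjects in both groups")
    vc <- v - mean(v)
    X <- cbind(intercept = 1, v_seed = vc, group = g01,
               v_seed_x_group = vc * g01, covs)
    contrast <- "v_seed_x_group"
  }
  p <- ncol(X)
  if (length(rows) < p + 2L)
    stop("too few subjects (", length(rows), ") for ", p,
         " design columns")
  qrX <- qr(X)
  if (qrX$rank < p) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  structure(list(X = X, contrast = contrast, rows = rows, model = model,
                 groups = groups, subject_ids = cohort$id[rows]),
            class = "scn_design")
}

#' Fit a voxel-wise OLS model
#'
#' For every in-mask voxel, ordinary-least-squares coefficients of the
#' design, the t statistic of the contrast column (`t = beta_c /
#' SE(beta_c)`, `dof = n - p`), and the residual maps retained for
#' smoothness estimation. Voxels with zero residual variance get a
#' signed-infinite t sentinel and are flagged.
#'
#' @param stack a [gmv_stack] whose subject order matches the cohort the
#'   design was built from.
#' @param design an `scn_design`.
#' @return object of class `scn_fit` with fields `beta` (p x V matrix
#'   over in-mask voxels), `t`, `se`, `residuals` (n x V), `dof`,
#'   `contrast`, `contrast_role` (`"beta1"` or `"beta3"`), `mask_idx`,
#'   `grid`, `mask`, `flag_infinite`.
#' @export
fit_voxelwise <- function(stack, design) {
  stopifnot(inherits(stack, "gmv_stack"), inherits(design, "scn_design"))
  if (!all(design$subject_ids %in% stack$subject_ids))
    stop("design subjects missing from the stack")
  srows <- match(design$subject_ids, stack$subject_ids)
  mask_idx <- which(as.vector(stack$mask))
  if (length(mask_idx) == 0L) stop("mask is empty")
  Y <- stack$values[srows, mask_idx, drop = FALSE]
  X <- design$X
  n <- nrow(X)
  p <- ncol(X)
  qrX <- qr(X)
  beta <- qr.coef(qrX, Y)
  resid <- Y - X %*% beta
  dof <- n - p
  if (dof < 1L) stop("non-positive degrees of freedom")
  sigma2 <- colSums(resid^2) / dof
  xtx_inv <- solve(crossprod(X))
  ci <- match(design$contrast, colnames(X))
  se <- sqrt(sigma2 * xtx_inv[ci, ci])
  bc <- beta[ci, ]
  flag <- se <= sqrt(.Machine$double.eps) * (abs(bc) + 1)
  tval <- bc / se
  tval[flag] <- ifelse(bc[flag] == 0, 0, sign(bc[flag]) * Inf)
  structure(list(beta = beta, t = tval, se = se, residuals = resid,
                 dof = dof, contrast = design$contrast,
                 contrast_role = if (design$model == "within_group")
                   "beta1" else "beta3",
                 mask_idx = mask_idx, grid = stack$grid,
                 mask = stack$mask, flag_infinite = flag,
                 model = design$model, groups = design$groups),
            class = "scn_fit")
}

#' Contrast t map as a 3D array
#'
#' @param fit an `scn_fit`.
#' @return numeric array of the grid shape, `NA` outside the mask.
#' @export
t_map <- function(fit) {
  out <- array(NA_real_, dim = fit$grid$shape)
  out[fit$mask_idx] <- fit$t
  out
}

#' Estimate residual spatial smoothness
#'
#' Classical Gaussian-field estimator from first spatial differences:
#' each residual map is standardised within the mask and the
#' lag-one-voxel autocorrelation along axis d is recovered from the
#' variance of its differences, `rho_1 = 1 - var(Delta_d) / 2`; the
#' implied smoothing-kernel FWHM is `voxel_size_d * sqrt(-2 log 2 /
#' log(rho_1))`, averaged (pooled variances) over residual maps and
#' clipped at 0 when the ratio leaves `(0, 1)`. Axes where the mask is
#' thinner than 2 voxels are reported as `NA`.
#'
#' @param fit an `scn_fit`, or an n x V residual matrix over in-mask
#'   voxels (then `mask`, `voxel_size_mm` must be given).
#' @param mask logical array (defaults to the fit's mask).
#' @param voxel_size_mm voxel size (defaults to the fit's grid).
#' @return object of class `smoothness_estimate`: `fwhm_mm` (per axis)
#'   and `fwhm_geo_mm` (geometric mean over defined axes).
#' @export
estimate_smoothness <- function(fit, mask = NULL, voxel_size_mm = NULL) {
  if (inherits(fit, "scn_fit")) {
    resid <- fit$residuals
    mask <- fit$mask
    voxel_size_mm <- fit$grid$voxel_size_mm
    mask_idx <- fit$mask_idx
  } else {
    resid <- as.matrix(fit)
    if (is.null(mask) || is.null(voxel_size_mm))
      stop("`mask` and `voxel_size_mm` are required with a raw residual matrix")
    mask_idx <- which(as.vector(mask))
    if (ncol(resid) != length(mask_idx))
      stop("residual columns must match the in-mask voxels")
  }
  if (nrow(resid) < 2L) stop("need at least 2 residual maps")
  voxel_size_mm <- rep(voxel_size_mm, length.out = 3)
  shape <- dim(mask)
  sds <- apply(resid, 1L, sd)
  if (any(sds == 0 | !is.finite(sds)))
    stop("smoothness is undefined for constant residual maps")

  # standardized residuals over in-mask voxels, all subjects at once
  z <- (resid - rowMeans(resid)) / sds
  # voxel pairs (v, v + e_ax) with both members in the mask, expressed as
  # positions into the in-mask column space
  col_of <- integer(prod(shape))
  col_of[mask_idx] <- seq_along(mask_idx)
  stride <- c(1L, shape[1], shape[1] * shape[2])
  sub <- arrayInd(mask_idx, shape)
  ss_diff <- c(0, 0, 0)
  n_diff <- c(0, 0, 0)
  for (ax in 1:3) {
    if (shape[ax] < 2L) next
    ok <- sub[, ax] < shape[ax]
    v_hi <- mask_idx[ok] + stride[ax]
    in_mask_hi <- col_of[v_hi] > 0L
    lo <- col_of[mask_idx[ok]][in_mask_hi]
    hi <- col_of[v_hi[in_mask_hi]]
    if (length(lo) == 0L) next
    d <- z[, hi, drop = FALSE] - z[, lo, drop = FALSE]
    ss_diff[ax] <- sum(d^2)
    n_diff[ax] <- length(d)
  }
  fwhm <- rep(NA_real_, 3)
  for (ax in 1:3) {
    if (n_diff[ax] < 2) next
    var_d <- ss_diff[ax] / n_diff[ax]
    ratio <- 1 - var_d / 2
    if (ratio <= 0) {
      fwhm[ax] <- 0
    } else if (ratio >= 1) {
      fwhm[ax] <- Inf
    } else {
      fwhm[ax] <- voxel_size_mm[ax] * sqrt(-2 * log(2) / log(ratio))
    }
  }
  ok <- is.finite(fwhm)
  geo <- if (any(ok)) exp(mean(log(pmax(fwhm[ok], 1e-12)))) else NA_real_
  structure(list(fwhm_mm = fwhm, fwhm_geo_mm = geo),
            class = "smoothness_estimate")
}

#' @export
print.smoothness_estimate <- function(x, ...) {
  cat("smoothness_estimate: FWHM =",
      paste(signif(x$fwhm_mm, 4), collapse = " x "),
      "mm (geometric mean", signif(x$fwhm_geo_mm, 4), "mm)\n")
  invisible(x)
}
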