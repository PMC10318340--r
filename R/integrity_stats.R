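# Deconstructed Pearson correlation: per-subject structural-covariance
# integrity for seed-cluster pairs, and partial correlations of integrity
# with clinical variables.

#' Per-group mean GM signal over a cluster
#'
#' @param stack a [gmv_stack].
#' @param cluster_mask logical array (non-empty) of cluster voxels.
#' @param cohort a `cohort_table` aligned to the stack's subject order.
#' @param group group label; its subjects must number at least 3.
#' @return named numeric vector of per-subject cluster means (group
#'   subjects only, stack order preserved).
#' @export
cluster_mean_signal <- function(stack, cluster_mask, cohort, group) {
  vox <- which(as.vector(cluster_mask))
  if (length(vox) == 0L) stop("cluster mask is empty")
  if (!all(cohort$id == stack$subject_ids))
    stop("cohort rows must match the stack's subject order")
  rows <- which(cohort$group == group)
  if (length(rows) < 3L) stop("group '", group, "' has fewer than 3 subjects")
  setNames(rowMeans(stack$values[rows, vox, drop = FALSE]),
           stack$subject_ids[rows])
}

#' Deconstructed Pearson correlation (per-subject integrity)
#'
#' Decomposes the group Pearson correlation of two regional measures
#' into per-subject contributions: with z scores computed from the group
#' mean and sample standard deviation (N - 1 denominator),
#' `partial_p_i = z_X_i * z_Y_i`, and `r = sum_i partial_p_i / (N - 1)`.
#' Each `partial_p_i` indexes subject i's structural-covariance
#' integrity for the region pair; the decomposition identity
#' `sum partial_p = (N - 1) r` holds exactly.
#'
#' @param x,y numeric vectors of length `>= 3`, non-constant, aligned by
#'   subject.
#' @param seed,cluster,group optional labels stored with the result.
#' @return object of class `integrity_result`: `partial_p`, `r`, `n`,
#'   and the group means/SDs used for z-scoring.
#' @export
partial_p_decomposition <- function(x, y, seed = NA_character_,
                                    cluster = NA_character_,
                                    group = NA_character_) {
  if (length(x) != length(y)) stop("`x` and `y` must be aligned")
  n <- length(x)
  if (n < 3L) stop("need at least 3 subjects")
  if (anyNA(x) || anyNA(y)) stop("missing values in the region measures")
  sx <- sd(x)
  sy <- sd(y)
  if (sx == 0 || sy == 0)
    stop("decomposition undefined for a constant vector")
  zx <- (x - mean(x)) / sx
  zy <- (y - mean(y)) / sy
  pp <- zx * zy
  if (!is.null(names(x))) names(pp) <- names(x)
  structure(list(partial_p = pp, r = sum(pp) / (n - 1), n = n,
                 mean_x = mean(x), mean_y = mean(y), sd_x = sx, sd_y = sy,
                 seed = seed, cluster = cluster, group = group),
            class = "integrity_result")
}

#' @export
print.integrity_result <- function(x, ...) {
  cat(sprintf("integrity_result: r = %.3f over N = %d subjects\n",
              x$r, x$n))
  invisible(x)
}

#' Residualize a vector on covariates
#'
#' OLS residuals of `v` on an intercept plus the covariate columns.
#'
#' @param v numeric vector.
#' @param covariates numeric matrix (rows aligned to `v`); `NULL` means
#'   intercept only (centring).
#' @return numeric vector of residuals.
#' @export
residualize <- function(v, covariates = NULL) {
  X <- if (is.null(covariates)) matrix(1, length(v), 1L)
       else cbind(1, as.matrix(covariates))
  if (nrow(X) != length(v)) stop("covariate rows must align with `v`")
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("covariate matrix (with intercept) is rank deficient")
  as.numeric(qr.resid(qrX, v))
}

#' Exclusion ids by trimming extremes of a variable
#'
#' Implements a configurable trim rule: exclude the `k_low` subjects
#' with the lowest and the `k_high` subjects with the highest values of
#' a variable (ties broken by original order). Subjects with missing
#' values are not candidates.
#'
#' @param values numeric vector of the trimming variable.
#' @param ids subject identifiers aligned to `values`.
#' @param k_low,k_high numbers to trim at each end.
#' @return character vector of excluded ids.
#' @export
trim_exclusions <- function(values, ids, k_low = 3L, k_high = 4L) {
  stopifnot(length(values) == length(ids))
  ok <- which(!is.na(values))
  if (k_low + k_high >= length(ok))
    stop("trim counts exceed the number of non-missing subjects")
  ord <- ok[order(values[ok])]
  excl <- c(if (k_low > 0) head(ord, k_low),
            if (k_high > 0) rev(ord)[seq_len(k_high)])
  as.character(ids[excl])
}

#' Partial Pearson correlation with nuisance covariates
#'
#' Residualizes both variables on an intercept plus the covariates over
#' the retained subjects, correlates the residuals, and tests with
#' `t = r sqrt((n - 2 - q) / (1 - r^2))` on `n - 2 - q` degrees of
#' freedom, q the number of covariates (two-sided, uncorrected — for
#' exploratory investigation).
#'
#' @param a,b numeric vectors aligned by subject.
#' @param covariates numeric matrix of nuisance covariates (or `NULL`).
#' @param ids subject identifiers (default index strings).
#' @param exclude ids to drop before the analysis.
#' @return object of class `partial_corr_result`: `r`, `p`, `t`,
#'   `n_effective`, `df`, `covariate_names`, `excluded`.
#' @export
partial_correlation <- function(a, b, covariates = NULL, ids = NULL,
                                exclude = NULL) {
  n0 <- length(a)
  if (length(b) != n0) stop("`a` and `b` must be aligned")
  if (is.null(ids)) ids <- as.character(seq_len(n0))
  keep <- !(ids %in% exclude)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n0) stop("covariate rows must align")
  }
  ok <- keep & !is.na(a) & !is.na(b) &
    (if (is.null(covariates)) TRUE else complete.cases(covariates))
  q <- if (is.null(covariates)) 0L else ncol(covariates)
  n <- sum(ok)
  if (n <= q + 2L)
    stop("insufficient subjects after exclusion (n = ", n,
         ", covariates = ", q, ")")
  ra <- residualize(a[ok], if (q) covariates[ok, , drop = FALSE])
  rb <- residualize(b[ok], if (q) covariates[ok, , drop = FALSE])
  r <- cor(ra, rb)
  df <- n - 2L - q
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tval), df)
  structure(list(r = r, p = p, t = tval, n_effective = n, df = df,
                 covariate_names = colnames(covariates),
                 excluded = ids[!keep]),
            class = "partial_corr_result")
}

#' @export
print.partial_corr_result <- function(x, ...) {
  cat(sprintf(
    "partial_corr_result: r = %.3f, p = %.4g (n = %d, %d covariates, exploratory)\n",
    x$r, x$p, x$n_effective, length(x$covariate_names)))
  invisible(x)
}
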