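# Monte-Carlo cluster-extent null simulation, FWE cluster thresholding,
# and conjunction by map intersection.

#' Simulate the null distribution of maximum cluster size
#'
#' Per simulation: white Gaussian noise on the grid, smoothed to the
#' stated FWHM (stationary Gaussian kernel at the geometric-mean FWHM
#' when a [estimate_smoothness()] object is supplied), standardised
#' within the mask, thresholded one-sided at `z_(1 - voxel_p)`, and the
#' largest connected suprathreshold component recorded. Deterministic
#' under `rng_seed`.
#'
#' @param mask logical 3D array.
#' @param voxel_size_mm voxel size in mm (scalar or length 3).
#' @param fwhm_mm smoothness: a scalar FWHM in mm or a
#'   `smoothness_estimate`.
#' @param voxel_p one-sided voxel-level p threshold, in `(0, 0.5)`.
#' @param n_sim number of simulations (`>= 100`).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param rng_seed integer seed.
#' @return object of class `null_cluster_dist` with the simulated
#'   maximum sizes and the simulation parameters.
#' @export
simulate_null_clusters <- function(mask, voxel_size_mm, fwhm_mm, voxel_p,
                                   n_sim = 10000L, connectivity = 26L,
                                   rng_seed = 1L) {
  mask <- as.array(mask)
  if (!any(mask)) stop("mask is empty")
  if (!(voxel_p > 0 && voxel_p < 0.5))
    stop("`voxel_p` must be in (0, 0.5)")
  if (n_sim < 100L) stop("`n_sim` must be >= 100")
  connectivity <- match.arg(as.character(connectivity), c("6", "18", "26"))
  connectivity <- as.integer(connectivity)
  if (inherits(fwhm_mm, "smoothness_estimate")) fwhm_mm <- fwhm_mm$fwhm_geo_mm
  if (!is.finite(fwhm_mm) || fwhm_mm < 0)
    stop("`fwhm_mm` must be a finite non-negative FWHM")
  shape <- dim(mask)
  vox <- rep(voxel_size_mm, length.out = 3)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / vox
  if (any(ceiling(4 * sigma_vox) >= shape))
    stop("smoothing kernel larger than the grid")
  cut <- qnorm(1 - voxel_p)
  mvec <- as.logical(mask)
  midx <- which(mvec)
  set.seed(rng_seed)
  sizes <- integer(n_sim)
  dimi <- as.integer(shape)
  # The simulated field must actually carry the stated FWHM, so noise is
  # generated on a grid padded by the kernel radius and cropped back:
  # the cropped field is stationary with the exact kernel ACF, free of
  # boundary-induced extra smoothness.
  pad <- as.integer(ceiling(4 * sigma_vox) * (sigma_vox > 0))
  pshape <- dimi + 2L * pad
  crop <- lapply(1:3, function(ax) seq.int(pad[ax] + 1L,
                                           pad[ax] + dimi[ax]))
  for (s in seq_len(n_sim)) {
    noise <- rnorm(prod(pshape))
    if (fwhm_mm > 0) {
      noise <- smooth3d_cpp(noise, pshape, sigma_vox)
      noise <- array(noise, dim = pshape)[crop[[1]], crop[[2]], crop[[3]]]
    }
    z <- as.numeric(noise)
    v <- z[midx]
    z[midx] <- (v - mean(v)) / sd(v)
    sizes[s] <- max_suprathreshold_cluster_cpp(z, dimi, mvec, cut,
                                               connectivity)
  }
  structure(list(sizes = sizes, fwhm_mm = fwhm_mm, voxel_p = voxel_p,
                 connectivity = connectivity, n_sim = n_sim,
                 mask_voxels = length(midx), rng_seed = rng_seed),
            class = "null_cluster_dist")
}

#' Critical cluster size at a family-wise alpha
#'
#' The smallest extent k (in voxels) such that the fraction of null
#' simulations whose maximum cluster reaches k is at most `alpha`.
#'
#' @param dist a `null_cluster_dist` (or plain integer vector of
#'   simulated maximum sizes).
#' @param alpha cluster-level FWE rate, in `(0, 1)` (default 0.05).
#' @return integer `k >= 1`.
#' @export
critical_cluster_size <- function(dist, alpha = 0.05) {
  if (!(alpha > 0 && alpha < 1)) stop("`alpha` must be in (0, 1)")
  sizes <- if (inherits(dist, "null_cluster_dist")) dist$sizes else dist
  n <- length(sizes)
  for (k in seq_len(max(sizes) + 1L)) {
    if (sum(sizes >= k) / n <= alpha) return(as.integer(k))
  }
  as.integer(max(sizes) + 1L)
}

#' Threshold a t map into FWE-significant clusters
#'
#' Separately for the positive and negative directions, thresholds the
#' map at the one-sided t critical value for `voxel_p` with `dof`
#' degrees of freedom, labels connected components at the stated
#' connectivity, and keeps components of at least `k_min` voxels. Each
#' retained cluster reports its peak (world mm of the largest-|t|
#' voxel), extent, peak t value and, when a null distribution is given,
#' the empirical cluster FWE p (fraction of null maxima at least as
#' large).
#'
#' @param t_arr numeric 3D t array (`NA` allowed outside the mask), e.g.
#'   from [t_map()].
#' @param grid the [volume_grid] of the map.
#' @param dof residual degrees of freedom (`>= 1`).
#' @param voxel_p one-sided voxel-level p threshold.
#' @param k_min minimum cluster extent in voxels (`>= 1`), e.g. from
#'   [critical_cluster_size()].
#' @param connectivity 6, 18 or 26 (default 26).
#' @param mask logical array (default: where `t_arr` is finite).
#' @param null_dist optional `null_cluster_dist` for empirical FWE p.
#' @return object of class `cluster_result`: `table` (data frame with
#'   direction, peak x/y/z, size, max_t, p_fwe), `mask_pos`/`mask_neg`
#'   (binary significant-voxel arrays per direction) and the threshold
#'   settings.
#' @export
threshold_map <- function(t_arr, grid, dof, voxel_p = 0.005, k_min,
                          connectivity = 26L, mask = NULL,
                          null_dist = NULL) {
  if (dof < 1L) stop("`dof` must be >= 1")
  if (k_min < 1L) stop("`k_min` must be >= 1")
  t_arr <- as.array(t_arr)
  if (!all(dim(t_arr) == grid$shape))
    stop("t map shape does not match the grid")
  if (is.null(mask)) mask <- is.finite(t_arr) | is.infinite(t_arr)
  mask <- array(as.logical(mask) & !is.na(t_arr), dim = grid$shape)
  connectivity <- as.integer(match.arg(as.character(connectivity),
                                       c("6", "18", "26")))
  tc <- qt(1 - voxel_p, dof)
  dimi <- as.integer(grid$shape)

  one_direction <- function(sgn) {
    tt <- sgn * t_arr
    supra <- mask & !is.na(tt) & tt > tc
    labels <- label_components_cpp(as.vector(supra), dimi, connectivity)
    rows <- list()
    keep_mask <- array(FALSE, dim = grid$shape)
    if (any(supra)) {
      tab <- tabulate(labels[labels > 0])
      for (lab in which(tab >= k_min)) {
        vox <- which(labels == lab)
        peak <- vox[which.max(tt[vox])]
        w <- voxel_world(grid, peak)
        p_fwe <- if (!is.null(null_dist))
          sum(null_dist$sizes >= tab[lab]) / length(null_dist$sizes)
        else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          direction = if (sgn > 0) "positive" else "negative",
          peak_x = w[1, "x"], peak_y = w[1, "y"], peak_z = w[1, "z"],
          size = tab[lab], max_t = t_arr[peak], p_fwe = p_fwe)
        keep_mask[vox] <- TRUE
      }
    }
    list(rows = rows, mask = keep_mask)
  }

  pos <- one_direction(1)
  neg <- one_direction(-1)
  tab <- do.call(rbind, c(pos$rows, neg$rows))
  if (is.null(tab))
    tab <- data.frame(direction = character(0), peak_x = numeric(0),
                      peak_y = numeric(0), peak_z = numeric(0),
                      size = integer(0), max_t = numeric(0),
                      p_fwe = numeric(0))
  rownames(tab) <- NULL
  structure(list(table = tab, mask_pos = pos$mask, mask_neg = neg$mask,
                 k_min = as.integer(k_min), voxel_p = voxel_p, dof = dof,
                 connectivity = connectivity, t_crit = tc),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result: voxel p <", x$voxel_p, ", k_min =", x$k_min,
      ", t_crit =", signif(x$t_crit, 4), "\n")
  print(x$table)
  invisible(x)
}

#' Write a cluster table to TSV
#' @param result a `cluster_result`.
#' @param path output file path.
#' @export
write_cluster_table <- function(result, path) {
  write.table(result$table, path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Conjunction of two significance masks
#'
#' Voxel-wise logical AND of two FWE-corrected significant-voxel masks
#' on the same grid; applied separately per direction by the caller
#' (shared decreases and shared increases are intersected independently).
#'
#' @param sig_mask_a,sig_mask_b logical arrays of identical shape.
#' @return logical array, `a & b`.
#' @export
conjunction <- function(sig_mask_a, sig_mask_b) {
  a <- as.array(sig_mask_a)
  b <- as.array(sig_mask_b)
  if (!identical(dim(a), dim(b)))
    stop("conjunction masks must share a grid")
  a & b
}
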