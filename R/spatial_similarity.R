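# Pearson spatial similarity of unthresholded t maps with a
# spin-permutation significance test on a spherical projection.

#' Construct a spherical map
#'
#' @param coords n x 3 matrix of unit vectors (norm within 1e-6 of 1).
#' @param values per-vertex scalar values.
#' @param valid optional logical vector of valid vertices (default:
#'   finite values).
#' @return object of class `sphere_map`.
#' @export
sphere_map <- function(coords, values, valid = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("`coords` must be n x 3")
  nrm <- sqrt(rowSums(coords^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop("vertex coordinates must lie on the unit sphere (within 1e-6)")
  if (length(values) != nrow(coords))
    stop("`values` must have one entry per vertex")
  if (is.null(valid)) valid <- is.finite(values)
  valid <- as.logical(valid) & is.finite(values)
  structure(list(coords = coords, values = as.numeric(values),
                 valid = valid),
            class = "sphere_map")
}

#' Project a volumetric map onto sphere vertices
#'
#' Assigns each vertex the value of the voxel given by a precomputed
#' vertex-to-voxel lookup table; vertices mapping outside the mask are
#' marked invalid.
#'
#' @param t_arr numeric 3D array.
#' @param mask logical array of the same shape.
#' @param vertices n x 3 unit-sphere coordinates.
#' @param lookup integer vector of 1-based linear voxel indices, one per
#'   vertex.
#' @return a [sphere_map].
#' @export
project_to_sphere <- function(t_arr, mask, vertices, lookup) {
  t_arr <- as.array(t_arr)
  mask <- as.array(mask)
  lookup <- as.integer(lookup)
  if (length(lookup) != nrow(vertices))
    stop("`lookup` must have one voxel index per vertex")
  if (any(lookup < 1L) || any(lookup > length(t_arr)))
    stop("lookup indices outside the grid")
  values <- as.vector(t_arr)[lookup]
  valid <- as.vector(mask)[lookup] & is.finite(values)
  if (!any(valid)) stop("no vertex maps inside the mask")
  sphere_map(vertices, values, valid)
}

#' Nearest-mask-voxel lookup for a synthetic spherical projection
#'
#' Builds a vertex-to-voxel table by placing a sphere of radius
#' `radius_frac` times the half-extent of the mask's bounding box at the
#' mask centroid and taking, for each vertex, the nearest in-mask voxel
#' (world coordinates). This is deliberately simple plumbing: it stands
#' in for a cortical surface projection when none is available.
#'
#' @param grid a [volume_grid].
#' @param mask logical array.
#' @param n_vertices number of Fibonacci-sphere vertices.
#' @param radius_frac sphere radius as a fraction of the half-extent.
#' @return list with `vertices` (n x 3) and `lookup` (integer vector).
#' @export
volume_sphere_lookup <- function(grid, mask, n_vertices = 1500L,
                                 radius_frac = 0.7) {
  midx <- which(as.vector(mask))
  w <- voxel_world(grid, midx)
  centre <- colMeans(w)
  half_extent <- (apply(w, 2L, max) - apply(w, 2L, min)) / 2
  radius <- radius_frac * mean(half_extent)
  vertices <- fibonacci_sphere(n_vertices)
  lookup <- integer(n_vertices)
  target <- sweep(vertices * radius, 2L, centre, "+")
  for (v in seq_len(n_vertices)) {
    d2 <- (w[, 1] - target[v, 1])^2 + (w[, 2] - target[v, 2])^2 +
      (w[, 3] - target[v, 3])^2
    lookup[v] <- midx[which.min(d2)]
  }
  list(vertices = vertices, lookup = lookup)
}

#' Uniform random rotation matrices
#'
#' Uniform over SO(3), via normalised Gaussian quaternions.
#'
#' @param n number of rotations.
#' @return 3 x 3 x n array.
#' @export
random_rotations <- function(n) {
  q <- matrix(rnorm(4L * n), n, 4L)
  q <- q / sqrt(rowSums(q^2))
  out <- array(0, dim = c(3L, 3L, n))
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  out[1, 1, ] <- 1 - 2 * (y^2 + z^2)
  out[1, 2, ] <- 2 * (x * y - w * z)
  out[1, 3, ] <- 2 * (x * z + w * y)
  out[2, 1, ] <- 2 * (x * y + w * z)
  out[2, 2, ] <- 1 - 2 * (x^2 + z^2)
  out[2, 3, ] <- 2 * (y * z - w * x)
  out[3, 1, ] <- 2 * (x * z - w * y)
  out[3, 2, ] <- 2 * (y * z + w * x)
  out[3, 3, ] <- 1 - 2 * (x^2 + y^2)
  out
}

#' Spin permutation test of spatial similarity
#'
#' Observed statistic: Pearson correlation of the two maps over vertices
#' valid in both. Each permutation draws a uniform random 3D rotation,
#' rotates map B's vertex coordinates, reassigns its values to the
#' nearest original vertex by great-circle distance (ties broken by
#' lowest vertex index), and recomputes the correlation over pairwise
#' valid vertices, preserving the maps' spatial autocorrelation under
#' the null. Two-sided p uses `|r|` with the add-one convention
#' `p = (1 + #\{|r_null| >= |r_obs|\}) / (1 + n_perm)`, so `p > 0`.
#'
#' @param map_a,map_b [sphere_map]s on the same vertex set, non-constant
#'   on their valid vertices.
#' @param n_perm number of permutations (`>= 100`; default 1000).
#' @param rng_seed integer seed; results are deterministic given a seed.
#' @return object of class `spin_result`: `r`, `null_r`, `p`, `n_perm`,
#'   `rng_seed`.
#' @export
spin_permutation_test <- function(map_a, map_b, n_perm = 1000L,
                                  rng_seed = 1L) {
  stopifnot(inherits(map_a, "sphere_map"), inherits(map_b, "sphere_map"))
  if (nrow(map_a$coords) != nrow(map_b$coords) ||
      max(abs(map_a$coords - map_b$coords)) > 1e-8)
    stop("maps must share a vertex set")
  if (n_perm < 100L) stop("`n_perm` must be >= 100")
  both <- map_a$valid & map_b$valid
  if (sum(both) < 3L) stop("fewer than 3 jointly valid vertices")
  if (sd(map_a$values[map_a$valid]) == 0 ||
      sd(map_b$values[map_b$valid]) == 0)
    stop("correlation undefined for a constant map")
  r_obs <- cor(map_a$values[both], map_b$values[both])
  set.seed(rng_seed)
  rot <- random_rotations(n_perm)
  null_r <- spin_null_r_cpp(map_a$coords, map_a$values, map_a$valid,
                            map_b$values, map_b$valid,
                            as.numeric(rot), as.integer(n_perm))
  exceed <- sum(!is.na(null_r) & abs(null_r) >= abs(r_obs))
  p <- (1 + exceed) / (1 + n_perm)
  structure(list(r = r_obs, null_r = null_r, p = p,
                 n_perm = as.integer(n_perm), rng_seed = rng_seed),
            class = "spin_result")
}

#' @export
print.spin_result <- function(x, ...) {
  cat(sprintf("spin_result: r = %.3f, p = %.4g (%d permutations)\n",
              x$r, x$p, x$n_perm))
  invisible(x)
}
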