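# Synthetic multi-subject cohort generator: planted seed-target structural
# covariance with group-specific strengths, covariate effects, Gaussian
# spatial smoothness, and spherical-map fixtures for the spin test.

#' MNI-like desk-scale grid
#'
#' A small axis-aligned grid with isotropic voxels whose world origin is
#' centred, so the y axis (posterior-anterior) spans negative to positive
#' mm as in MNI space. The default 30 x 36 x 30 grid at 3 mm keeps whole
#' simulation studies at minutes scale while leaving room for
#' hippocampus-like seed boxes in the y in [-42, -2] band.
#'
#' @param shape grid shape (default `c(30, 36, 30)`).
#' @param voxel_size_mm isotropic voxel size in mm (default 3).
#' @return a [volume_grid].
#' @export
mni_like_grid <- function(shape = c(30L, 36L, 30L), voxel_size_mm = 3) {
  affine <- diag(c(rep(voxel_size_mm, 3), 1))
  affine[1:3, 4] <- -(shape - 1) / 2 * voxel_size_mm
  volume_grid(shape, affine)
}

box_voxels <- function(grid, i, j, k) {
  idx <- as.matrix(expand.grid(i = i, j = j, k = k))
  as.integer(idx[, 1] + (idx[, 2] - 1L) * grid$shape[1] +
               (idx[, 3] - 1L) * prod(grid$shape[1:2]))
}

#' Default parcel layout for the synthetic cohort
#'
#' Three disjoint boxes on an [mni_like_grid]: a `hippocampus` seed parcel
#' spanning the long-axis band y in about [-40, -5] mm (so that the
#' anterior/posterior world-coordinate split yields non-empty
#' subdivisions on both sides of the gap), and two target parcels
#' (`target_a`, `target_b`) placed in opposite lateral quadrants.
#'
#' @param grid a [volume_grid] from [mni_like_grid()].
#' @return named list of integer voxel-index vectors.
#' @export
default_parcel_layout <- function(grid = mni_like_grid()) {
  stopifnot(all(grid$shape >= c(30L, 30L, 30L)))
  list(
    hippocampus = box_voxels(grid, 11:20, 5:17, 8:14),
    target_a = box_voxels(grid, 22:29, 22:29, 8:15),
    target_b = box_voxels(grid, 2:9, 22:29, 16:23)
  )
}

#' Configuration of the synthetic cohort generator
#'
#' Defines the statistical structure the SCN analysis assumes: a latent
#' per-subject factor expressed in a seed parcel, target parcels whose
#' expression correlates with the seed latent at group-specific loadings
#' `rho`, linear covariate effects on GM, voxel noise, and Gaussian
#' smoothing. Group sizes default to 37/38/48 (HC/SCD/MIG).
#'
#' @param grid a [volume_grid] (default [mni_like_grid()]).
#' @param group_sizes named integer vector over HC/SCD/MIG; each `>= 3`.
#' @param parcels named list of disjoint voxel-index vectors; must include
#'   `seed_parcel`.
#' @param seed_parcel name of the seed parcel (default `"hippocampus"`).
#' @param rho named list: for each non-seed target parcel, a named numeric
#'   vector of per-group seed-target loadings in `[-1, 1]`.
#' @param loading amplitude `a` of the latent expression in GM units
#'   (default 0.1; GM base is 0.5).
#' @param base baseline GM density inside the mask (default 0.5).
#' @param noise_sd voxel-wise Gaussian noise SD before smoothing
#'   (default 0.05).
#' @param fwhm_mm smoothing kernel FWHM in mm (default 6); `0` disables.
#' @param covariate_effects named numeric vector of per-unit linear
#'   effects of centred age, sex and TIV applied to every voxel.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(grid = mni_like_grid(),
                             group_sizes = c(HC = 37L, SCD = 38L, MIG = 48L),
                             parcels = default_parcel_layout(grid),
                             seed_parcel = "hippocampus",
                             rho = list(
                               target_a = c(HC = 0.6, SCD = 0.6, MIG = 0.6),
                               target_b = c(HC = 0.6, SCD = 0.6, MIG = 0.6)),
                             loading = 0.1,
                             base = 0.5,
                             noise_sd = 0.05,
                             fwhm_mm = 6,
                             covariate_effects = c(age = -0.001, sex = 0.01,
                                                   tiv = 0.05)) {
  stopifnot(inherits(grid, "volume_grid"))
  if (is.null(names(group_sizes)) ||
      !all(names(group_sizes) %in% canonical_groups))
    stop("`group_sizes` must be named with HC/SCD/MIG")
  if (any(group_sizes < 3L)) stop("each group needs at least 3 subjects")
  if (!seed_parcel %in% names(parcels))
    stop("`parcels` must contain the seed parcel '", seed_parcel, "'")
  all_vox <- unlist(parcels, use.names = FALSE)
  if (anyDuplicated(all_vox)) stop("parcels must be disjoint")
  if (any(all_vox < 1L) || any(all_vox > prod(grid$shape)))
    stop("parcel voxel indices outside the grid")
  targets <- setdiff(names(parcels), seed_parcel)
  if (!all(names(rho) %in% targets))
    stop("`rho` names must be target parcels")
  for (tg in names(rho)) {
    r <- rho[[tg]]
    if (!all(names(group_sizes) %in% names(r)))
      stop("rho for '", tg, "' must cover every group")
    if (any(abs(r) > 1)) stop("|rho| must be <= 1")
  }
  if (fwhm_mm < 0) stop("`fwhm_mm` must be >= 0")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  structure(list(grid = grid, group_sizes = group_sizes, parcels = parcels,
                 seed_parcel = seed_parcel, rho = rho, loading = loading,
                 base = base, noise_sd = noise_sd, fwhm_mm = fwhm_mm,
                 covariate_effects = covariate_effects),
            class = "synthetic_config")
}

#' Gaussian smoothing of a 3D volume
#'
#' Separable Gaussian convolution at the stated FWHM with a normalised
#' kernel and half-sample symmetric (reflective) boundary, which
#' conserves the volume's total mass.
#'
#' @param volume numeric 3D array.
#' @param fwhm_mm kernel FWHM in mm (scalar or per-axis length 3).
#' @param voxel_size_mm voxel size in mm (scalar or length 3).
#' @return smoothed array of the same shape.
#' @export
smooth_volume <- function(volume, fwhm_mm, voxel_size_mm) {
  volume <- as.array(volume)
  stopifnot(length(dim(volume)) == 3L)
  fwhm <- rep(fwhm_mm, length.out = 3)
  vox <- rep(voxel_size_mm, length.out = 3)
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / vox
  if (all(sigma <= 0)) return(volume)
  smooth3d_cpp(as.numeric(volume), as.integer(dim(volume)), sigma)
}

rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  pmin(pmax(rnorm(n, mean, sd), lower), upper)
}

draw_covariates <- function(group, n) {
  # Marginals follow the study-population demographics (age ~ N(43, 11),
  # ~65% female, TIV ~ N(1.43 l, 0.15)); depression/insomnia scores use
  # group-specific clipped normals.
  bdi_pars <- list(HC = c(7.8, 5.5), SCD = c(11.6, 8.0), MIG = c(6.1, 5.3))
  isi_pars <- list(HC = c(9.4, 5.9), SCD = c(10.9, 6.2), MIG = c(6.8, 5.6))
  scdq_pars <- list(HC = c(4.3, 2.2), SCD = c(14.8, 5.3), MIG = c(4.2, 2.2))
  df <- data.frame(
    group = rep(group, n),
    age = rtruncnorm(n, 43, 11, 20, 65),
    sex = rbinom(n, 1L, 0.65),
    education = rtruncnorm(n, 15, 3, 6, 22),
    bdi = rtruncnorm(n, bdi_pars[[group]][1], bdi_pars[[group]][2], 0, 63),
    isi = rtruncnorm(n, isi_pars[[group]][1], isi_pars[[group]][2], 0, 28),
    tiv = rtruncnorm(n, 1.43, 0.15, 0.9, 2.1),
    scdq = round(rtruncnorm(n, scdq_pars[[group]][1],
                            scdq_pars[[group]][2], 0, 24)),
    stringsAsFactors = FALSE
  )
  df$scd_duration <- if (group == "SCD")
    rtruncnorm(n, 5.3, 8.0, 0.25, 40) else NA_real_
  df$mig_duration <- if (group == "MIG")
    rtruncnorm(n, 15.4, 9.4, 0.5, 45) else NA_real_
  df$mig_frequency <- if (group == "MIG")
    rtruncnorm(n, 6.4, 5.4, 1, 28) else NA_real_
  df$midas <- if (group == "MIG")
    rtruncnorm(n, 20.84, 14.03, 0, 90) else NA_real_
  df$vas <- if (group == "MIG")
    rtruncnorm(n, 7.27, 2.06, 0, 10) else NA_real_
  df
}

#' Generate a synthetic cohort
#'
#' Draws a per-subject standard-normal latent `L`; seed-parcel voxels get
#' `base + a * L`, and each target parcel gets
#' `base + a * (rho_g * L + sqrt(1 - rho_g^2) * U)` with an independent
#' standard-normal `U`, so the planted seed-target correlation in group g
#' is `rho_g`. Linear covariate effects (centred age, sex, TIV) and voxel
#' Gaussian noise are added, and each subject map is smoothed at the
#' configured FWHM (mass-conserving reflective convolution). Values are
#' floored at zero. Identical seeds give bit-identical output.
#'
#' @param config a [synthetic_config].
#' @param rng_seed integer seed.
#' @return list with elements `cohort` (a `cohort_table`), `stack` (a
#'   [gmv_stack]) and `truth` (parcels, per-group planted correlations,
#'   and the parcels whose loading differs between some group pair).
#' @export
generate_cohort <- function(config, rng_seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(rng_seed)
  grid <- config$grid
  nvox <- prod(grid$shape)
  groups <- names(config$group_sizes)

  cov_list <- lapply(groups, function(g)
    draw_covariates(g, config$group_sizes[[g]]))
  cohort <- do.call(rbind, cov_list)
  n <- nrow(cohort)
  cohort <- cbind(id = sprintf("sub-%03d", seq_len(n)), cohort)
  cohort <- as_cohort_table(cohort)

  eff <- config$covariate_effects
  eff_term <- numeric(n)
  if (!is.na(eff["age"]))
    eff_term <- eff_term + eff[["age"]] * (cohort$age - 43)
  if (!is.na(eff["sex"]))
    eff_term <- eff_term + eff[["sex"]] * (cohort$sex - 0.65)
  if (!is.na(eff["tiv"]))
    eff_term <- eff_term + eff[["tiv"]] * (cohort$tiv - 1.43)

  seed_vox <- config$parcels[[config$seed_parcel]]
  targets <- names(config$rho)
  values <- matrix(0, n, nvox)
  latent <- rnorm(n)
  for (i in seq_len(n)) {
    g <- as.character(cohort$group[i])
    v <- rep(config$base + eff_term[i], nvox)
    v[seed_vox] <- v[seed_vox] + config$loading * latent[i]
    for (tg in targets) {
      r <- config$rho[[tg]][[g]]
      u <- rnorm(1)
      expr <- r * latent[i] + sqrt(max(0, 1 - r^2)) * u
      tv <- config$parcels[[tg]]
      v[tv] <- v[tv] + config$loading * expr
    }
    if (config$noise_sd > 0) v <- v + rnorm(nvox, 0, config$noise_sd)
    if (config$fwhm_mm > 0)
      v <- smooth_volume(array(v, dim = grid$shape), config$fwhm_mm,
                         grid$voxel_size_mm)
    values[i, ] <- pmax(as.numeric(v), 0)
  }

  stack <- gmv_stack(values, grid, cohort$id)

  diff_parcels <- character(0)
  for (tg in targets) {
    r <- config$rho[[tg]][groups]
    if (max(r) - min(r) > 1e-12) diff_parcels <- c(diff_parcels, tg)
  }
  truth <- list(parcels = config$parcels, seed_parcel = config$seed_parcel,
                rho = config$rho, difference_parcels = diff_parcels,
                latent = setNames(latent, cohort$id))
  list(cohort = cohort, stack = stack, truth = truth)
}

#' Write synthetic study inputs to disk
#'
#' Writes the cohort TSV, one NIfTI per subject, the mask, an integer
#' atlas built from the parcel layout with its label TSV, and a JSON
#' ground-truth manifest.
#'
#' @param sim result of [generate_cohort()].
#' @param dir output directory.
#' @return invisibly, the list of written paths.
#' @export
write_study_inputs <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  grid <- sim$stack$grid
  paths <- list(
    cohort = file.path(dir, "participants.tsv"),
    mask = file.path(dir, "mask.nii.gz"),
    atlas = file.path(dir, "atlas.nii.gz"),
    labels = file.path(dir, "atlas_labels.tsv"),
    truth = file.path(dir, "ground_truth.json"),
    volumes = file.path(dir, "gmv")
  )
  write_cohort_table(sim$cohort, paths$cohort)
  write_stat_map(array(as.numeric(sim$stack$mask), dim = grid$shape),
                 grid, paths$mask)
  atlas <- parcels_to_atlas(sim$truth$parcels, grid)
  write_stat_map(atlas$volume, grid, paths$atlas)
  write.table(atlas$labels, paths$labels, sep = "\t", row.names = FALSE,
              quote = FALSE)
  jsonlite::write_json(
    list(seed_parcel = sim$truth$seed_parcel, rho = sim$truth$rho,
         difference_parcels = sim$truth$difference_parcels),
    paths$truth, auto_unbox = TRUE, digits = NA)
  paths$volumes <- write_gmv_stack(sim$stack, paths$volumes)
  invisible(paths)
}

#' Build an integer atlas volume from a parcel layout
#'
#' @param parcels named list of voxel-index vectors.
#' @param grid a [volume_grid].
#' @return list with `volume` (integer array) and `labels` (data frame
#'   with columns `label`, `name`).
#' @export
parcels_to_atlas <- function(parcels, grid) {
  vol <- array(0L, dim = grid$shape)
  for (i in seq_along(parcels)) vol[parcels[[i]]] <- i
  list(volume = vol,
       labels = data.frame(label = seq_along(parcels),
                           name = names(parcels),
                           stringsAsFactors = FALSE))
}

#' Quasi-uniform unit-sphere sampling (Fibonacci lattice)
#'
#' @param n number of vertices.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Generate a smooth spherical map fixture pair
#'
#' Two spatially smooth scalar fields on a Fibonacci sphere sampling with
#' population correlation `target_r`. Fields are built by smoothing
#' vertex-wise white noise with a great-circle Gaussian kernel of the
#' stated angular FWHM, then mixing: `B = target_r * A + sqrt(1 -
#' target_r^2) * A_perp`, with both components standardised.
#'
#' @param n_vertices number of vertices (`>= 100`).
#' @param fwhm_deg angular smoothing FWHM in degrees (default 20).
#' @param target_r population correlation of the two maps, `|r| <= 1`.
#' @param rng_seed integer seed; identical seeds give identical maps.
#' @return list with `coords` (n x 3), `map_a`, `map_b`.
#' @export
generate_sphere_fixture <- function(n_vertices, fwhm_deg = 20, target_r,
                                    rng_seed = 1L) {
  if (n_vertices < 100L) stop("`n_vertices` must be >= 100")
  if (abs(target_r) > 1) stop("|target_r| must be <= 1")
  set.seed(rng_seed)
  coords <- fibonacci_sphere(n_vertices)
  sigma <- (fwhm_deg * pi / 180) / (2 * sqrt(2 * log(2)))
  cosang <- tcrossprod(coords)
  theta <- acos(pmin(pmax(cosang, -1), 1))
  K <- exp(-0.5 * (theta / sigma)^2)
  za <- rnorm(n_vertices)
  zb <- rnorm(n_vertices)
  fa <- as.numeric(scale(K %*% za))
  fb <- as.numeric(scale(K %*% zb))
  map_b <- if (abs(target_r) == 1) sign(target_r) * fa
           else target_r * fa + sqrt(1 - target_r^2) * fb
  list(coords = coords, map_a = fa, map_b = map_b)
}
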