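# Study orchestration: QC -> seeds -> within-group SCNs -> interaction
# contrasts -> cluster FWE -> conjunction -> spin similarity -> integrity
# and clinical correlations, plus replicated simulation studies for
# calibration and power analysis.

#' Study configuration
#'
#' Collects the analysis settings; the defaults reproduce the standard
#' thresholds (voxel-level p < 0.005, cluster FWE alpha 0.05, 10,000
#' Monte-Carlo simulations, 1,000 spin permutations, connectivity 26).
#'
#' @param simulate a [synthetic_config] to generate inputs, or `NULL`
#'   when real inputs are supplied.
#' @param stack_paths,table_path,atlas_path,mask_path input file paths
#'   (ignored when `simulate` is given).
#' @param seed_labels atlas label ids of the seed structure (default 1,
#'   the first parcel of a synthetic atlas).
#' @param y_anterior,y_posterior long-axis world-y intervals in mm.
#' @param voxel_p one-sided voxel-level threshold (default 0.005).
#' @param cluster_alpha cluster FWE rate (default 0.05).
#' @param n_sim Monte-Carlo null simulations (default 10000).
#' @param n_perm spin permutations (default 1000).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param contrasts list of group pairs `c(reference, case)`.
#' @param n_sphere_vertices vertices of the synthetic spherical
#'   projection used for spin similarity.
#' @param trim named list for the clinical-correlation trim rule
#'   (`variable`, `k_low`, `k_high`); `NULL` disables trimming.
#' @param rng_seed integer seed for every stochastic stage.
#' @param out_dir optional output directory for artifacts.
#' @return an object of class `study_config`.
#' @export
study_config <- function(simulate = NULL, stack_paths = NULL,
                         table_path = NULL, atlas_path = NULL,
                         mask_path = NULL, seed_labels = 1L,
                         y_anterior = c(-18, -2),
                         y_posterior = c(-42, -24), voxel_p = 0.005,
                         cluster_alpha = 0.05, n_sim = 10000L,
                         n_perm = 1000L, connectivity = 26L,
                         contrasts = list(c("HC", "SCD"), c("HC", "MIG")),
                         n_sphere_vertices = 1000L,
                         trim = list(variable = "scd_duration",
                                     k_low = 3L, k_high = 4L),
                         rng_seed = 1L, out_dir = NULL) {
  if (is.null(simulate) &&
      (is.null(stack_paths) || is.null(table_path) ||
       is.null(atlas_path) || is.null(mask_path)))
    stop("either a `simulate` block or all four input paths are required")
  structure(list(simulate = simulate, stack_paths = stack_paths,
                 table_path = table_path, atlas_path = atlas_path,
                 mask_path = mask_path, seed_labels = seed_labels,
                 y_anterior = y_anterior, y_posterior = y_posterior,
                 voxel_p = voxel_p, cluster_alpha = cluster_alpha,
                 n_sim = n_sim, n_perm = n_perm,
                 connectivity = connectivity, contrasts = contrasts,
                 n_sphere_vertices = n_sphere_vertices, trim = trim,
                 rng_seed = rng_seed, out_dir = out_dir),
            class = "study_config")
}

derive_seed <- function(rng_seed, k) {
  as.integer((as.numeric(rng_seed) + 7919 * k) %% 2147483647)
}

#' Within-group seed-covariance analysis
#'
#' Fits the within-group voxel-wise model for one seed and group,
#' estimates residual smoothness, simulates (or reuses) the null
#' maximum-cluster-size distribution, and thresholds the seed-covariance
#' t map at the FWE-corrected cluster extent.
#'
#' @param stack a [gmv_stack]; subject order must match `cohort`.
#' @param cohort a `cohort_table`.
#' @param seed_signal full-cohort seed signal from [seed_means()].
#' @param group group label.
#' @param voxel_p,alpha,n_sim,connectivity,rng_seed threshold settings.
#' @param null_dist optional precomputed `null_cluster_dist`.
#' @return list: `fit`, `smoothness`, `null_dist`, `k_min`, `clusters`.
#' @export
within_group_scn <- function(stack, cohort, seed_signal, group,
                             voxel_p = 0.005, alpha = 0.05,
                             n_sim = 2000L, connectivity = 26L,
                             rng_seed = 1L, null_dist = NULL) {
  design <- build_design(cohort, seed_signal, "within_group", group)
  fit <- fit_voxelwise(stack, design)
  sm <- estimate_smoothness(fit)
  if (is.null(null_dist))
    null_dist <- simulate_null_clusters(stack$mask,
                                        stack$grid$voxel_size_mm, sm,
                                        voxel_p, n_sim, connectivity,
                                        rng_seed)
  k_min <- critical_cluster_size(null_dist, alpha)
  clusters <- threshold_map(t_map(fit), stack$grid, fit$dof, voxel_p,
                            k_min, connectivity, stack$mask, null_dist)
  list(fit = fit, smoothness = sm, null_dist = null_dist, k_min = k_min,
       clusters = clusters)
}

#' Seed-by-group interaction analysis
#'
#' Fits the two-group interaction model for one seed and case-control
#' pair and thresholds the interaction t map at the FWE-corrected
#' cluster extent. With the case group coded 1, a covariance decrease in
#' the case group drives the interaction coefficient negative, so the
#' `negative` direction corresponds to reference > case.
#'
#' @inheritParams within_group_scn
#' @param groups pair `c(reference, case)`.
#' @return list: `fit`, `smoothness`, `null_dist`, `k_min`, `clusters`,
#'   and direction labels `dir_ref_gt_case`/`dir_ref_lt_case`.
#' @export
interaction_scn <- function(stack, cohort, seed_signal, groups,
                            voxel_p = 0.005, alpha = 0.05,
                            n_sim = 2000L, connectivity = 26L,
                            rng_seed = 1L, null_dist = NULL) {
  design <- build_design(cohort, seed_signal, "interaction", groups)
  fit <- fit_voxelwise(stack, design)
  sm <- estimate_smoothness(fit)
  if (is.null(null_dist))
    null_dist <- simulate_null_clusters(stack$mask,
                                        stack$grid$voxel_size_mm, sm,
                                        voxel_p, n_sim, connectivity,
                                        rng_seed)
  k_min <- critical_cluster_size(null_dist, alpha)
  clusters <- threshold_map(t_map(fit), stack$grid, fit$dof, voxel_p,
                            k_min, connectivity, stack$mask, null_dist)
  list(fit = fit, smoothness = sm, null_dist = null_dist, k_min = k_min,
       clusters = clusters, dir_ref_gt_case = "negative",
       dir_ref_lt_case = "positive")
}

load_study_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    sim <- generate_cohort(config$simulate, config$rng_seed)
    atlas <- parcels_to_atlas(sim$truth$parcels, sim$stack$grid)
    list(cohort = sim$cohort, stack = sim$stack, atlas = atlas$volume,
         atlas_labels = atlas$labels, truth = sim$truth)
  } else {
    cohort <- read_subject_table(config$table_path)
    stack <- read_gm_stack(config$stack_paths, config$mask_path)
    if (!all(cohort$id == stack$subject_ids))
      stop("subject table order does not match the stack")
    a <- read_stat_map(config$atlas_path)
    list(cohort = cohort, stack = stack,
         atlas = array(as.integer(round(a$values)), dim = a$grid$shape),
         atlas_labels = NULL, truth = NULL)
  }
}

clinical_variables_for <- function(group) {
  switch(group,
         SCD = c("scd_duration", "scdq"),
         MIG = c("mig_duration", "mig_frequency", "midas", "vas"),
         character(0))
}

#' Run the full seed-based SCN study
#'
#' Executes every stage in order for both seeds (anterior, posterior)
#' and all configured case-control contrasts: quality control,
#' long-axis seed construction, within-group SCN maps per group,
#' anterior-posterior spin similarity per group, seed-by-group
#' interaction contrasts with Monte-Carlo cluster FWE correction,
#' conjunction of the corrected case-control maps across contrasts, and
#' per-subject integrity indices with exploratory clinical partial
#' correlations for every significant interaction cluster. Identical
#' config and seed give identical reports.
#'
#' @param config a [study_config].
#' @return an object of class `study_report`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  stage <- "inputs"
  report <- list(config = config)
  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  inputs <- run_stage("inputs", load_study_inputs(config))
  cohort <- inputs$cohort
  stack <- inputs$stack
  grid <- stack$grid

  report$qc <- run_stage("qc", qc_report(stack))

  rois <- run_stage("seed_roi",
                    long_axis_split(inputs$atlas, grid, config$seed_labels,
                                    config$y_anterior, config$y_posterior))
  seeds <- run_stage("seed_signal",
                     lapply(rois, function(r) seed_means(stack, r)))

  groups <- intersect(levels(cohort$group), unique(as.character(cohort$group)))
  k <- 0L
  report$within_group <- run_stage("within_group", {
    out <- list()
    for (sd_name in names(rois)) {
      for (g in groups) {
        k <- k + 1L
        out[[paste(sd_name, g, sep = ".")]] <-
          within_group_scn(stack, cohort, seeds[[sd_name]], g,
                           config$voxel_p, config$cluster_alpha,
                           config$n_sim, config$connectivity,
                           derive_seed(config$rng_seed, k))
      }
    }
    out
  })

  report$spin <- run_stage("spin", {
    proj <- volume_sphere_lookup(grid, stack$mask,
                                 config$n_sphere_vertices)
    out <- list()
    for (g in groups) {
      ma <- project_to_sphere(t_map(report$within_group[[paste0("anterior.", g)]]$fit),
                              stack$mask, proj$vertices, proj$lookup)
      mb <- project_to_sphere(t_map(report$within_group[[paste0("posterior.", g)]]$fit),
                              stack$mask, proj$vertices, proj$lookup)
      out[[g]] <- spin_permutation_test(ma, mb, config$n_perm,
                                        derive_seed(config$rng_seed, 100L + match(g, groups)))
    }
    out
  })

  report$interaction <- run_stage("interaction", {
    out <- list()
    j <- 200L
    for (sd_name in names(rois)) {
      for (ct in config$contrasts) {
        if (!all(ct %in% groups)) next
        j <- j + 1L
        out[[paste(sd_name, paste(ct, collapse = "_vs_"), sep = ".")]] <-
          interaction_scn(stack, cohort, seeds[[sd_name]], ct,
                          config$voxel_p, config$cluster_alpha,
                          config$n_sim, config$connectivity,
                          derive_seed(config$rng_seed, j))
      }
    }
    out
  })

  report$conjunction <- run_stage("conjunction", {
    out <- list()
    for (sd_name in names(rois)) {
      keys <- grep(paste0("^", sd_name, "\\."), names(report$interaction),
                   value = TRUE)
      if (length(keys) == 2L) {
        a <- report$interaction[[keys[1]]]$clusters
        b <- report$interaction[[keys[2]]]$clusters
        out[[sd_name]] <- list(
          shared_decrease = conjunction(a$mask_neg, b$mask_neg),
          shared_increase = conjunction(a$mask_pos, b$mask_pos))
      }
    }
    out
  })

  report$integrity <- run_stage("integrity", {
    rows <- list()
    for (key in names(report$interaction)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      sd_name <- parts[1]
      ct <- strsplit(parts[2], "_vs_", fixed = TRUE)[[1]]
      res <- report$interaction[[key]]
      tab <- res$clusters$table
      if (nrow(tab) == 0L) next
      for (ci in seq_len(nrow(tab))) {
        dir <- tab$direction[ci]
        cl_mask <- clip_cluster_mask(res$clusters, dir, tab, ci, grid)
        for (g in unique(c(ct))) {
          cms <- cluster_mean_signal(stack, cl_mask, cohort, g)
          rows_g <- which(cohort$group == g)
          dec <- partial_p_decomposition(seeds[[sd_name]][rows_g], cms,
                                         seed = sd_name,
                                         cluster = paste0(key, "#", ci),
                                         group = g)
          clin <- clinical_variables_for(g)
          for (cv in clin) {
            vals <- cohort[[cv]][rows_g]
            if (all(is.na(vals))) next
            excl <- character(0)
            if (!is.null(config$trim) && cv == config$trim$variable) {
              excl <- tryCatch(
                trim_exclusions(vals, cohort$id[rows_g],
                                config$trim$k_low, config$trim$k_high),
                error = function(e) character(0))
            }
            pc <- tryCatch(
              partial_correlation(dec$partial_p, vals,
                                  as.matrix(cohort[rows_g, glm_covariates]),
                                  ids = cohort$id[rows_g], exclude = excl),
              error = function(e) NULL)
            if (is.null(pc)) next
            rows[[length(rows) + 1L]] <- data.frame(
              seed = sd_name, contrast = parts[2], cluster = ci,
              direction = dir, group = g, variable = cv, r = pc$r,
              p = pc$p, n = pc$n_effective, group_r = dec$r,
              note = "exploratory, uncorrected",
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(seed = character(0), contrast = character(0),
                 cluster = integer(0), direction = character(0),
                 group = character(0), variable = character(0),
                 r = numeric(0), p = numeric(0), n = integer(0),
                 group_r = numeric(0), note = character(0))
  })

  report$provenance <- list(rng_seed = config$rng_seed,
                            voxel_p = config$voxel_p,
                            cluster_alpha = config$cluster_alpha,
                            n_sim = config$n_sim, n_perm = config$n_perm,
                            connectivity = config$connectivity,
                            package_version =
                              as.character(utils::packageVersion("seedscn")))
  class(report) <- "study_report"

  if (!is.null(config$out_dir))
    write_study_report(report, stack, config$out_dir)
  report
}

# Rebuild the voxel mask of one row of a cluster table (clusters of the
# same direction are separated by re-labelling the direction mask).
clip_cluster_mask <- function(clusters, dir, tab, ci, grid) {
  m <- if (dir == "positive") clusters$mask_pos else clusters$mask_neg
  labels <- label_components_cpp(as.vector(m), as.integer(grid$shape),
                                 clusters$connectivity)
  # identify the component containing the row's peak
  peak_world <- c(tab$peak_x[ci], tab$peak_y[ci], tab$peak_z[ci])
  inv <- solve(grid$affine)
  v <- round(inv %*% c(peak_world, 1))[1:3] + 1
  lab <- labels[v[1], v[2], v[3]]
  array(labels == lab & lab > 0, dim = grid$shape)
}

#' Write the study report artifacts
#'
#' Writes QC and integrity tables (TSV), cluster tables per analysis
#' (TSV), significant and conjunction masks plus unthresholded t maps
#' (NIfTI), spin results (JSON) and a provenance JSON under `dir`.
#'
#' @param report a `study_report`.
#' @param stack the analysed [gmv_stack] (for the grid).
#' @param dir output directory.
#' @export
write_study_report <- function(report, stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  grid <- stack$grid
  write_qc_report(report$qc, file.path(dir, "qc.tsv"))
  for (key in names(report$within_group)) {
    res <- report$within_group[[key]]
    write_stat_map(t_map(res$fit), grid,
                   file.path(dir, paste0("tmap_within_", key, ".nii.gz")))
    write_cluster_table(res$clusters,
                        file.path(dir, paste0("clusters_within_", key, ".tsv")))
  }
  for (key in names(report$interaction)) {
    res <- report$interaction[[key]]
    write_stat_map(t_map(res$fit), grid,
                   file.path(dir, paste0("tmap_interaction_", key, ".nii.gz")))
    write_cluster_table(res$clusters,
                        file.path(dir, paste0("clusters_interaction_", key, ".tsv")))
  }
  for (key in names(report$conjunction)) {
    cj <- report$conjunction[[key]]
    write_stat_map(array(as.numeric(cj$shared_decrease), dim = grid$shape),
                   grid, file.path(dir, paste0("conjunction_decrease_", key, ".nii.gz")))
    write_stat_map(array(as.numeric(cj$shared_increase), dim = grid$shape),
                   grid, file.path(dir, paste0("conjunction_increase_", key, ".nii.gz")))
  }
  jsonlite::write_json(
    lapply(report$spin, function(s)
      list(r = s$r, p = s$p, n_perm = s$n_perm)),
    file.path(dir, "spin.json"), auto_unbox = TRUE, digits = NA)
  write.table(report$integrity, file.path(dir, "integrity.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(report$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Replicated interaction simulation study
#'
#' Repeats the generate -> seed -> interaction -> cluster-FWE pipeline
#' over seeded replicate cohorts, recording for each replicate whether
#' any significant cluster survived and how the reference > case
#' significant mask overlaps the planted difference parcels. Null
#' distributions are cached by smoothness (FWHM rounded to
#' `null_cache_res` mm), since replicate cohorts share the generator's
#' smoothness up to estimation noise.
#'
#' @param n_reps number of replicate cohorts.
#' @param config a [synthetic_config].
#' @param contrasts list of group pairs to fit per replicate.
#' @param rng_seed base seed; replicate r uses a seed derived from it.
#' @param voxel_p,alpha,n_sim,connectivity threshold settings.
#' @param null_cache_res FWHM rounding (mm) for null-distribution reuse.
#' @return data frame with one row per replicate and contrast: `rep`,
#'   `contrast`, `any_sig`, `n_clusters`, `k_min`, `fwhm_mm`,
#'   `overlap_frac` (fraction of the planted difference parcel covered
#'   by the reference > case mask), `conj_decrease_nonempty`,
#'   `conj_overlap_frac` (conjunction across contrasts, per replicate).
#' @export
simulate_study_replicates <- function(n_reps, config,
                                      contrasts = list(c("HC", "SCD")),
                                      rng_seed = 1L, voxel_p = 0.005,
                                      alpha = 0.05, n_sim = 2000L,
                                      connectivity = 26L,
                                      null_cache_res = 0.5) {
  null_cache <- new.env(parent = emptyenv())
  rows <- list()
  for (r in seq_len(n_reps)) {
    sim <- generate_cohort(config, derive_seed(rng_seed, r))
    roi <- seed_roi("seed", sim$truth$parcels[[sim$truth$seed_parcel]])
    sig <- seed_means(sim$stack, roi)
    diff_parcels <- sim$truth$difference_parcels
    diff_vox <- unlist(sim$truth$parcels[diff_parcels], use.names = FALSE)
    neg_masks <- list()
    for (ct in contrasts) {
      design <- build_design(sim$cohort, sig, "interaction", ct)
      fit <- fit_voxelwise(sim$stack, design)
      sm <- estimate_smoothness(fit)
      key <- sprintf("f%.1f", round(sm$fwhm_geo_mm / null_cache_res) *
                       null_cache_res)
      if (is.null(null_cache[[key]]))
        null_cache[[key]] <- simulate_null_clusters(
          sim$stack$mask, sim$stack$grid$voxel_size_mm, sm, voxel_p,
          n_sim, connectivity, derive_seed(rng_seed, 500000L + r))
      nd <- null_cache[[key]]
      k_min <- critical_cluster_size(nd, alpha)
      cl <- threshold_map(t_map(fit), sim$stack$grid, fit$dof, voxel_p,
                          k_min, connectivity, sim$stack$mask, nd)
      ov <- if (length(diff_vox))
        mean(as.vector(cl$mask_neg)[diff_vox]) else NA_real_
      neg_masks[[paste(ct, collapse = "_vs_")]] <- cl$mask_neg
      rows[[length(rows) + 1L]] <- data.frame(
        rep = r, contrast = paste(ct, collapse = "_vs_"),
        any_sig = nrow(cl$table) > 0, n_clusters = nrow(cl$table),
        k_min = k_min, fwhm_mm = sm$fwhm_geo_mm, overlap_frac = ov,
        conj_decrease_nonempty = NA, conj_overlap_frac = NA_real_)
    }
    if (length(neg_masks) >= 2L) {
      cj <- Reduce(conjunction, neg_masks)
      idx <- which(vapply(rows, function(x) x$rep[1] == r, logical(1)))
      for (i in idx) {
        rows[[i]]$conj_decrease_nonempty <- any(cj)
        rows[[i]]$conj_overlap_frac <- if (length(diff_vox))
          mean(as.vector(cj)[diff_vox]) else NA_real_
      }
    }
  }
  do.call(rbind, rows)
}
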