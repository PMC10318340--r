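# Data model and I/O: voxel grids, gray-matter volume stacks, subject
# tables, NIfTI readers/writers, and scan-quality metrics.

#' Construct a volume grid
#'
#' A `volume_grid` couples a 3D array shape with a 4x4 affine mapping
#' 0-based voxel indices (voxel centres) to world coordinates in mm. The
#' world frame is assumed MNI-like, with the second axis (y) running
#' posterior to anterior.
#'
#' @param shape integer vector of length 3, all positive.
#' @param affine 4x4 numeric matrix, invertible; last row `(0,0,0,1)`.
#' @return An object of class `volume_grid` with fields `shape`, `affine`
#'   and `voxel_size_mm` (Euclidean norms of the affine's spatial columns).
#' @export
volume_grid <- function(shape, affine) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("`shape` must be 3 positive integers")
  affine <- matrix(as.numeric(affine), nrow(as.matrix(affine)))
  if (!all(dim(affine) == c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix")
  det_a <- det(affine)
  if (!is.finite(det_a) || abs(det_a) < .Machine$double.eps)
    stop("`affine` must be invertible")
  voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(voxel_size <= 0))
    stop("voxel sizes derived from `affine` must be positive")
  structure(list(shape = shape, affine = affine,
                 voxel_size_mm = voxel_size),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("volume_grid:", paste(x$shape, collapse = " x "),
      "voxels,", paste(signif(x$voxel_size_mm, 4), collapse = " x "),
      "mm\n")
  invisible(x)
}

#' World coordinates of voxels
#'
#' Maps 1-based linear voxel indices to world mm via the grid affine,
#' using the voxel-centre convention (0-based index i maps through the
#' affine directly).
#'
#' @param grid a [volume_grid].
#' @param ind integer vector of 1-based linear voxel indices.
#' @return numeric matrix with columns x, y, z (mm).
#' @export
voxel_world <- function(grid, ind) {
  sub <- arrayInd(ind, grid$shape)
  w <- grid$affine %*% rbind(t(sub) - 1, 1)
  out <- t(w[1:3, , drop = FALSE])
  colnames(out) <- c("x", "y", "z")
  out
}

canonical_groups <- c("HC", "SCD", "MIG")
glm_covariates <- c("age", "sex", "education", "bdi", "isi", "tiv")
clinical_columns <- c("scd_duration", "scdq", "mig_duration",
                      "mig_frequency", "midas", "vas")

#' Validate a cohort table
#'
#' Checks a per-subject data frame against the cohort schema: an `id`
#' column (unique), a `group` column drawn from HC/SCD/MIG, the six model
#' covariates (age, sex, education, bdi, isi, tiv) complete and numeric,
#' and optional clinical columns (scd_duration, scdq, mig_duration,
#' mig_frequency, midas, vas) in which missing values are preserved.
#'
#' @param df a data frame.
#' @return the validated data frame with class `cohort_table`.
#' @export
as_cohort_table <- function(df) {
  df <- as.data.frame(df)
  required <- c("id", "group", glm_covariates)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("subject table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id))
    stop("subject ids must be unique")
  grp <- toupper(trimws(as.character(df$group)))
  bad <- !grp %in% canonical_groups
  if (any(bad))
    stop("unrecognised group label(s): ",
         paste(unique(df$group[bad]), collapse = ", "),
         " (expected HC, SCD or MIG)")
  df$group <- factor(grp, levels = canonical_groups)
  for (col in glm_covariates) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(as.character(v)))
      bad_row <- which(is.na(vn) & !is.na(v))
      if (length(bad_row))
        stop("non-numeric value in covariate '", col, "' at row ",
             bad_row[1])
      v <- vn
    }
    if (anyNA(v))
      stop("missing value in required covariate '", col, "' at row ",
           which(is.na(v))[1])
    df[[col]] <- v
  }
  if (any(df$tiv <= 0))
    stop("TIV must be positive")
  for (col in intersect(clinical_columns, names(df)))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Read a subject table
#'
#' Reads a delimited text file (TSV by default; comma-separated when the
#' extension is `.csv`) with one row per subject and validates it with
#' [as_cohort_table()].
#'
#' @param path file path.
#' @param required_columns columns that must be present; defaults to the
#'   schema minimum (`id`, `group` and the six model covariates).
#' @return a `cohort_table`.
#' @export
read_subject_table <- function(path,
                               required_columns = c("id", "group",
                                                    glm_covariates)) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, header = TRUE,
                   stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(required_columns, names(df))
  if (length(missing_cols))
    stop("subject table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  as_cohort_table(df)
}

#' Write a cohort table to TSV
#'
#' @param cohort a `cohort_table`.
#' @param path output file path.
#' @export
write_cohort_table <- function(cohort, path) {
  write.table(as.data.frame(cohort), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Construct a gray-matter volume stack
#'
#' Couples per-subject vectorised GM volume values with their common grid,
#' subject identifiers and an analysis mask. Values must be finite and
#' non-negative inside the mask; subject order is authoritative and must
#' match the cohort table row order.
#'
#' @param values numeric matrix, subjects x voxels (column-major voxel
#'   order of the grid).
#' @param grid a [volume_grid].
#' @param subject_ids character vector, unique, one per row of `values`.
#' @param mask logical array of the grid's shape (default: all voxels).
#' @return An object of class `gmv_stack`.
#' @export
gmv_stack <- function(values, grid, subject_ids,
                      mask = array(TRUE, dim = grid$shape)) {
  values <- as.matrix(values)
  nvox <- prod(grid$shape)
  if (ncol(values) != nvox)
    stop("`values` must have one column per grid voxel")
  if (nrow(values) < 3L)
    stop("a GMV stack requires at least 3 subjects")
  subject_ids <- as.character(subject_ids)
  if (length(subject_ids) != nrow(values) || anyDuplicated(subject_ids))
    stop("`subject_ids` must be unique and match the number of rows")
  mask <- array(as.logical(mask), dim = grid$shape)
  if (!any(mask)) stop("mask is empty")
  inmask <- values[, as.vector(mask), drop = FALSE]
  if (any(!is.finite(inmask)) || any(inmask < 0))
    stop("GM values inside the mask must be finite and non-negative")
  rownames(values) <- subject_ids
  structure(list(values = values, grid = grid, subject_ids = subject_ids,
                 mask = mask),
            class = "gmv_stack")
}

#' @export
print.gmv_stack <- function(x, ...) {
  cat("gmv_stack:", nrow(x$values), "subjects,",
      paste(x$grid$shape, collapse = " x "), "voxels,",
      sum(x$mask), "in mask\n")
  invisible(x)
}

#' Number of subjects in a stack
#' @param stack a `gmv_stack`.
#' @export
n_subjects <- function(stack) nrow(stack$values)

grid_from_nifti <- function(img) {
  volume_grid(dim(img)[1:3], RNifti::xform(img))
}

affines_match <- function(a, b, tol = 1e-4) {
  all(abs(a - b) < tol)
}

#' Read a stack of GM volume NIfTI maps
#'
#' Reads per-subject modulated GM volume maps from NIfTI files sharing a
#' grid with the mask, and stacks them in the given order.
#'
#' @param paths ordered character vector of NIfTI file paths; names, when
#'   present, become subject ids (otherwise base file names are used).
#' @param mask_path path of the analysis mask NIfTI (non-zero = in mask).
#' @return a [gmv_stack].
#' @export
read_gm_stack <- function(paths, mask_path) {
  mimg <- RNifti::readNifti(mask_path)
  grid <- grid_from_nifti(mimg)
  mask <- array(as.array(mimg) != 0, dim = grid$shape)
  ids <- names(paths)
  if (is.null(ids)) ids <- sub("\\.nii(\\.gz)?$", "", basename(paths))
  values <- matrix(NA_real_, length(paths), prod(grid$shape))
  for (i in seq_along(paths)) {
    img <- RNifti::readNifti(paths[i])
    if (!all(dim(img)[1:3] == grid$shape) ||
        !affines_match(RNifti::xform(img), grid$affine))
      stop("volume does not match the mask grid (shape/affine): ",
           paths[i])
    values[i, ] <- as.vector(as.array(img))
  }
  gmv_stack(values, grid, ids, mask)
}

#' Write per-subject stack volumes to NIfTI files
#'
#' @param stack a [gmv_stack].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths (by subject id).
#' @export
write_gmv_stack <- function(stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(stack$subject_ids, ".nii.gz"))
  for (i in seq_len(nrow(stack$values)))
    write_stat_map(array(stack$values[i, ], dim = stack$grid$shape),
                   stack$grid, paths[i])
  names(paths) <- stack$subject_ids
  paths
}

#' Write a statistical map to NIfTI
#'
#' Writes a grid-shaped array (e.g. an unthresholded t map, suitable for
#' repository upload) with the grid's affine; re-reading reproduces the
#' values within float tolerance.
#'
#' @param values numeric array shaped like `grid`.
#' @param grid a [volume_grid].
#' @param path output `.nii`/`.nii.gz` path.
#' @export
write_stat_map <- function(values, grid, path) {
  values <- as.array(values)
  if (!all(dim(values) == grid$shape))
    stop("`values` shape does not match the grid")
  img <- RNifti::asNifti(values)
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a statistical map from NIfTI
#'
#' @param path NIfTI file path.
#' @return list with `values` (array) and `grid` ([volume_grid]).
#' @export
read_stat_map <- function(path) {
  img <- RNifti::readNifti(path)
  list(values = array(as.vector(as.array(img)), dim = dim(img)[1:3]),
       grid = grid_from_nifti(img))
}

#' Entropy focus criterion (EFC)
#'
#' Shannon entropy of voxel intensities, used as a head-motion/quality
#' index. With `b_j = x_j / sqrt(sum x_j^2)` over the N in-analysis
#' voxels, EFC = (-sum b_j log b_j) / (sqrt(N) log sqrt(N)), using
#' 0 log 0 = 0. The normalisation puts EFC in `[0, 1]`: 0 for all
#' intensity in a single voxel, 1 for a perfectly uniform volume. EFC is
#' invariant to positive rescaling of the intensities.
#'
#' @param volume numeric array (or vector) of non-negative intensities.
#' @param mask optional logical array restricting the in-analysis voxels;
#'   default is the whole volume.
#' @return EFC value in `[0, 1]`.
#' @export
compute_efc <- function(volume, mask = NULL) {
  x <- if (is.null(mask)) as.vector(volume) else as.vector(volume)[as.vector(mask)]
  if (any(!is.finite(x)) || any(x < 0))
    stop("intensities must be finite and non-negative")
  n <- length(x)
  if (n < 2L) stop("EFC needs at least 2 in-analysis voxels")
  nrm <- sqrt(sum(x^2))
  if (nrm == 0) stop("EFC is undefined for an all-zero volume")
  b <- x / nrm
  pos <- b > 0
  ent <- -sum(b[pos] * log(b[pos]))
  ent / (sqrt(n) * log(sqrt(n)))
}

#' Covariance-based sample homogeneity
#'
#' Per subject, the mean Pearson correlation of its masked voxel vector
#' with every other subject's. A subject is flagged as a potential
#' outlier when its homogeneity lies more than `z_cut` standard
#' deviations below the sample mean. Subjects with constant voxel
#' vectors have undefined homogeneity and are flagged with a reason.
#'
#' @param stack a [gmv_stack] with at least 3 subjects.
#' @param z_cut outlier cut in standard deviations (default 2).
#' @return a data frame of class `qc_report` with columns `id`,
#'   `homogeneity`, `outlier_flag`, `reason`.
#' @export
sample_homogeneity <- function(stack, z_cut = 2) {
  n <- n_subjects(stack)
  if (n < 3L) stop("sample homogeneity requires at least 3 subjects")
  v <- stack$values[, as.vector(stack$mask), drop = FALSE]
  sds <- apply(v, 1L, sd)
  constant <- sds == 0 | !is.finite(sds)
  cm <- suppressWarnings(cor(t(v)))
  diag(cm) <- NA
  homog <- rowMeans(cm, na.rm = TRUE)
  homog[constant] <- NA_real_
  mu <- mean(homog, na.rm = TRUE)
  s <- sd(homog, na.rm = TRUE)
  flag <- !is.na(homog) & s > 0 & homog < mu - z_cut * s
  flag[constant] <- TRUE
  reason <- ifelse(constant, "constant voxel vector",
                   ifelse(flag, sprintf("homogeneity > %g SD below mean",
                                        z_cut), ""))
  out <- data.frame(id = stack$subject_ids, homogeneity = homog,
                    outlier_flag = flag, reason = reason,
                    stringsAsFactors = FALSE)
  class(out) <- c("qc_report", "data.frame")
  out
}

#' Per-subject QC report
#'
#' Combines the entropy focus criterion of each subject volume with the
#' covariance-based homogeneity measure.
#'
#' @param stack a [gmv_stack].
#' @param z_cut homogeneity outlier cut (default 2).
#' @param efc_mask `"volume"` (default) to compute EFC over the whole
#'   volume, or `"mask"` to restrict it to the stack's analysis mask.
#' @return a `qc_report` data frame with columns `id`, `efc`,
#'   `homogeneity`, `outlier_flag`, `reason`.
#' @export
qc_report <- function(stack, z_cut = 2, efc_mask = c("volume", "mask")) {
  efc_mask <- match.arg(efc_mask)
  m <- if (efc_mask == "mask") stack$mask else NULL
  efc <- vapply(seq_len(n_subjects(stack)), function(i)
    compute_efc(array(stack$values[i, ], dim = stack$grid$shape), m),
    numeric(1))
  hom <- sample_homogeneity(stack, z_cut = z_cut)
  out <- cbind(hom[, "id", drop = FALSE], efc = efc,
               hom[, c("homogeneity", "outlier_flag", "reason")])
  class(out) <- c("qc_report", "data.frame")
  out
}

#' Write a QC report to TSV
#' @param report a `qc_report`.
#' @param path output file path.
#' @export
write_qc_report <- function(report, path) {
  write.table(as.data.frame(report), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
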