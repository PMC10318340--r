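# Anterior/posterior seed ROIs by world-coordinate long-axis cutoffs, and
# per-subject seed mean GMV extraction.

#' Construct a seed ROI
#'
#' @param name ROI name.
#' @param voxels integer vector of 1-based linear voxel indices (non-empty).
#' @param y_range_mm closed world-y interval the voxels were drawn from
#'   (optional, for provenance).
#' @param labels source atlas label ids (optional).
#' @return an object of class `seed_roi`.
#' @export
seed_roi <- function(name, voxels, y_range_mm = NULL, labels = NULL) {
  voxels <- as.integer(voxels)
  if (length(voxels) == 0L) stop("ROI '", name, "' is empty")
  structure(list(name = name, voxels = sort(unique(voxels)),
                 y_range_mm = y_range_mm, labels = labels),
            class = "seed_roi")
}

#' @export
print.seed_roi <- function(x, ...) {
  cat("seed_roi '", x$name, "': ", length(x$voxels), " voxels",
      if (!is.null(x$y_range_mm))
        paste0(", y in [", x$y_range_mm[1], ", ", x$y_range_mm[2], "] mm"),
      "\n", sep = "")
  invisible(x)
}

#' Split an atlas region along the long (y) axis
#'
#' Classifies every voxel carrying one of the listed atlas labels by the
#' world y coordinate of its centre: voxels with y inside `y_anterior`
#' (default `[-18, -2]` mm) form the anterior ROI and voxels inside
#' `y_posterior` (default `[-42, -24]` mm) form the posterior ROI, both
#' endpoints inclusive. Voxels in the gap belong to neither. Left and
#' right hemisphere voxels are merged into a single bilateral ROI unless
#' `hemisphere` restricts to one side (world x < 0 is left).
#'
#' @param atlas integer-labelled array shaped like `grid`.
#' @param grid the [volume_grid] of the atlas.
#' @param labels integer label ids to include (e.g. left+right
#'   hippocampus).
#' @param y_anterior closed interval in mm for the anterior ROI.
#' @param y_posterior closed interval in mm for the posterior ROI; must
#'   not overlap `y_anterior`.
#' @param hemisphere `"both"` (default), `"left"` or `"right"`.
#' @return list with elements `anterior` and `posterior`, both
#'   [seed_roi] objects.
#' @export
long_axis_split <- function(atlas, grid, labels,
                            y_anterior = c(-18, -2),
                            y_posterior = c(-42, -24),
                            hemisphere = c("both", "left", "right")) {
  hemisphere <- match.arg(hemisphere)
  atlas <- as.array(atlas)
  if (!all(dim(atlas) == grid$shape))
    stop("atlas shape does not match the grid")
  y_anterior <- sort(as.numeric(y_anterior))
  y_posterior <- sort(as.numeric(y_posterior))
  if (max(min(y_anterior), min(y_posterior)) <=
      min(max(y_anterior), max(y_posterior)))
    stop("anterior and posterior y intervals must be disjoint")
  present <- unique(as.vector(atlas))
  unknown <- setdiff(labels, present)
  if (length(unknown))
    stop("label id(s) not present in atlas: ",
         paste(unknown, collapse = ", "))
  cand <- which(as.vector(atlas) %in% labels)
  w <- voxel_world(grid, cand)
  if (hemisphere == "left") cand <- cand[w[, "x"] < 0]
  if (hemisphere == "right") cand <- cand[w[, "x"] >= 0]
  w <- voxel_world(grid, cand)
  ant <- cand[w[, "y"] >= y_anterior[1] & w[, "y"] <= y_anterior[2]]
  post <- cand[w[, "y"] >= y_posterior[1] & w[, "y"] <= y_posterior[2]]
  if (length(ant) == 0L)
    stop("no labelled voxels with world y in [", y_anterior[1], ", ",
         y_anterior[2], "] mm (anterior)")
  if (length(post) == 0L)
    stop("no labelled voxels with world y in [", y_posterior[1], ", ",
         y_posterior[2], "] mm (posterior)")
  list(anterior = seed_roi("anterior", ant, y_anterior, labels),
       posterior = seed_roi("posterior", post, y_posterior, labels))
}

#' Per-subject mean GMV over a seed ROI
#'
#' The seed signal `V_seed`: for each subject, the arithmetic mean of GM
#' values over the ROI voxels, in stack subject order.
#'
#' @param stack a [gmv_stack].
#' @param roi a [seed_roi] (or integer voxel-index vector).
#' @return named numeric vector, one value per subject.
#' @export
seed_means <- function(stack, roi) {
  voxels <- if (inherits(roi, "seed_roi")) roi$voxels else as.integer(roi)
  nvox <- prod(stack$grid$shape)
  if (any(voxels < 1L) || any(voxels > nvox))
    stop("ROI voxel indices outside the stack grid")
  outside <- sum(!as.vector(stack$mask)[voxels])
  if (outside > 0)
    warning(outside, " ROI voxel(s) lie outside the analysis mask")
  setNames(rowMeans(stack$values[, voxels, drop = FALSE]),
           stack$subject_ids)
}

#' Write an ROI as a binary NIfTI mask
#'
#' @param roi a [seed_roi].
#' @param grid the [volume_grid] of the analysis.
#' @param path output path.
#' @export
write_roi_mask <- function(roi, grid, path) {
  vol <- array(0, dim = grid$shape)
  vol[roi$voxels] <- 1
  write_stat_map(vol, grid, path)
}
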