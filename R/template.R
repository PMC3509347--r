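# Iterative unbiased population-template construction, probabilistic label
# maps, and automatic per-hemisphere search-region (ROI) definition.

#' Half-open voxel box
#'
#' `lo`/`hi` are 0-based voxel indices; the box covers `[lo, hi)`.
#' @param lo,hi Integer vectors of length 3.
#' @export
voxel_box <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (any(hi <= lo)) stop("empty voxel box")
  list(lo = lo, hi = hi)
}

#' Crop a volume, label map or deformation field to a voxel box
#' @param v Image object.
#' @param box A [voxel_box()].
#' @export
crop_box <- function(v, box) {
  i <- lapply(1:3, function(a) (box$lo[a] + 1):box$hi[a])
  or <- v$origin + box$lo * v$spacing
  if (is_labelmap(v))
    labelmap(v$labels[i[[1]], i[[2]], i[[3]], drop = FALSE], v$spacing, or)
  else if (inherits(v, "amy_defield"))
    defield(v$disp[i[[1]], i[[2]], i[[3]], , drop = FALSE], v$spacing, or)
  else
    volume(v$data[i[[1]], i[[2]], i[[3]], drop = FALSE], v$spacing, or)
}

#' Paste cropped labels back into a full-size label map
#' @param full Full-grid `amy_labelmap` to copy.
#' @param sub Cropped `amy_labelmap`.
#' @param box The [voxel_box()] `sub` was cropped with.
#' @export
paste_box <- function(full, sub, box) {
  i <- lapply(1:3, function(a) (box$lo[a] + 1):box$hi[a])
  lab <- full$labels
  lab[i[[1]], i[[2]], i[[3]]] <- sub$labels
  labelmap(lab, full$spacing, full$origin)
}

#' Probabilistic label map from warped binary segmentations
#'
#' Mean of the per-subject binary masks for `label`, smoothed with a 1 mm
#' Gaussian filter and clipped to `[0, 1]`.
#'
#' @param warped_labels List of `amy_labelmap`s on the template grid.
#' @param label Structure label.
#' @param sigma_mm Smoothing sigma in mm.
#' @return An `amy_volume` of probabilities.
#' @export
probabilistic_label_map <- function(warped_labels, label = 1L, sigma_mm = 1.0) {
  g <- grid_of(warped_labels[[1]])
  acc <- array(0, g)
  for (lm in warped_labels) {
    check_same_grid(lm, warped_labels[[1]])
    acc <- acc + (lm$labels == label)
  }
  pv <- volume(acc / length(warped_labels), warped_labels[[1]]$spacing,
               warped_labels[[1]]$origin)
  sm <- gaussian_smooth(pv, sigma_mm)
  volume(pmin(pmax(sm$data, 0), 1), pv$spacing, pv$origin)
}

#' Automatic search-region box around a probabilistic structure map
#'
#' Tight bounding box of the superthreshold support, dilated by
#' `margin_mm` (rounded up to voxels per axis) and clipped to the grid.
#'
#' @param prob Probability `amy_volume`.
#' @param threshold Support threshold.
#' @param margin_mm Margin added on every side, in mm.
#' @return A [voxel_box()].
#' @export
amygdala_roi <- function(prob, threshold = 0.01, margin_mm = 4) {
  idx <- which(prob$data > threshold, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("no support above threshold ", threshold)
  m <- ceiling(margin_mm / prob$spacing)
  lo <- pmax(apply(idx, 2, min) - 1 - m, 0)
  hi <- pmin(apply(idx, 2, max) + m, dim(prob$data))
  voxel_box(lo, hi)
}

#' Iterative population template with probabilistic labels and ROIs
#'
#' Initialization is the voxelwise mean after rigid alignment of every
#' subject to the first one. Each outer iteration deformably registers all
#' subjects to the current template, averages the warped images, and
#' subtracts the mean displacement (the standard unbiasing step, applied
#' here by warping the average through the negated mean field). After the
#' outer loop a final registration pass provides the per-subject fields
#' used to project the manual labels, which are averaged, smoothed at 1 mm
#' and boxed into per-hemisphere search regions.
#'
#' @param train List of subject cases (`image` should be intensity
#'   normalized, `truth` their label maps).
#' @param n_outer Outer template iterations.
#' @param schedule,params Registration configuration.
#' @param roi_threshold,roi_margin_mm Search-region parameters.
#' @param label_sigma_mm Label-map smoothing sigma.
#' @return An `amy_template`: `image`, `prob` (left/right volumes), `roi`
#'   (left/right boxes), per-subject `fields`, `rigids`, `msd_trace`.
#' @export
build_template <- function(train, n_outer = 3, schedule = reg_schedule(),
                           params = default_reg_params(),
                           roi_threshold = 0.01, roi_margin_mm = 4,
                           label_sigma_mm = 1.0) {
  n <- length(train)
  if (n < 2) stop("template construction needs >= 2 subjects")
  ref <- train[[1]]$image
  rigids <- vector("list", n)
  aligned <- vector("list", n)
  aligned_truth <- vector("list", n)
  for (i in seq_len(n)) {
    if (i == 1) {
      rigids[[i]] <- rigid_transform(center = ref$origin +
                                       (dim(ref$data) - 1) / 2 * ref$spacing)
      aligned[[i]] <- train[[i]]$image
      aligned_truth[[i]] <- train[[i]]$truth
    } else {
      rigids[[i]] <- rigid_register(train[[i]]$image, ref)
      aligned[[i]] <- apply_rigid(train[[i]]$image, rigids[[i]], ref)
      aligned_truth[[i]] <- apply_rigid(train[[i]]$truth, rigids[[i]], ref)
    }
  }
  tmpl <- volume(Reduce(`+`, lapply(aligned, values_of)) / n,
                 ref$spacing, ref$origin)
  g <- dim(ref$data)
  msd_trace <- matrix(NA_real_, n_outer, n)
  for (outer in seq_len(n_outer)) {
    fields <- vector("list", n)
    warped_sum <- array(0, g)
    mean_disp <- array(0, c(g, 3))
    for (i in seq_len(n)) {
      rr <- diffeo_register(aligned[[i]], tmpl, schedule, params)
      fields[[i]] <- rr$field
      msd_trace[outer, i] <- rr$metric_trace[length(rr$metric_trace)]
      warped_sum <- warped_sum + apply_deformation(aligned[[i]], rr$field)$data
      mean_disp <- mean_disp + rr$field$disp
    }
    avg <- volume(warped_sum / n, ref$spacing, ref$origin)
    mean_disp <- mean_disp / n
    tmpl <- apply_deformation(avg, defield(-mean_disp, ref$spacing, ref$origin))
  }
  fields <- lapply(seq_len(n), function(i)
    diffeo_register(aligned[[i]], tmpl, schedule, params)$field)
  warped_truth <- lapply(seq_len(n), function(i)
    apply_deformation(aligned_truth[[i]], fields[[i]], "nearest"))
  prob <- list(left = probabilistic_label_map(warped_truth, 1L, label_sigma_mm),
               right = probabilistic_label_map(warped_truth, 2L, label_sigma_mm))
  roi <- lapply(prob, amygdala_roi, threshold = roi_threshold,
                margin_mm = roi_margin_mm)
  structure(list(image = tmpl, prob = prob, roi = roi, fields = fields,
                 rigids = rigids, msd_trace = msd_trace,
                 aligned = aligned, aligned_truth = aligned_truth,
                 subject_ids = vapply(train, `[[`, "", "id")),
            class = "amy_template")
}

#' Rebuild a working template object from a template directory
#'
#' A template directory persists only the template image, probability maps
#' and ROI boxes; the per-atlas warps needed for segmentation are
#' recomputed here by registering each atlas once to the stored template
#' image (rigid to the template grid, then deformable).
#'
#' @param dir Directory written by [write_template()].
#' @param train Atlas subject cases (normalized images + truth labels).
#' @param schedule,params Registration configuration.
#' @return An `amy_template`.
#' @export
read_template <- function(dir, train, schedule = reg_schedule(),
                          params = default_reg_params()) {
  img <- read_volume(file.path(dir, "image.nii.gz"))
  prob <- list(left = read_volume(file.path(dir, "prob_L.nii.gz")),
               right = read_volume(file.path(dir, "prob_R.nii.gz")))
  rj <- jsonlite::read_json(file.path(dir, "rois.json"), simplifyVector = TRUE)
  roi <- lapply(rj, function(b) voxel_box(b$lo, b$hi))
  n <- length(train)
  aligned <- vector("list", n); aligned_truth <- vector("list", n)
  fields <- vector("list", n); rigids <- vector("list", n)
  for (i in seq_len(n)) {
    rigids[[i]] <- rigid_register(train[[i]]$image, img)
    aligned[[i]] <- apply_rigid(train[[i]]$image, rigids[[i]], img)
    aligned_truth[[i]] <- apply_rigid(train[[i]]$truth, rigids[[i]], img)
    fields[[i]] <- diffeo_register(aligned[[i]], img, schedule, params)$field
  }
  structure(list(image = img, prob = prob, roi = roi, fields = fields,
                 rigids = rigids, msd_trace = NULL, aligned = aligned,
                 aligned_truth = aligned_truth,
                 subject_ids = vapply(train, `[[`, "", "id")),
            class = "amy_template")
}

#' Write a template directory (image, probability maps, ROI boxes)
#' @param tmpl An `amy_template`.
#' @param dir Output directory.
#' @export
write_template <- function(tmpl, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(tmpl$image, file.path(dir, "image.nii.gz"))
  write_volume(tmpl$prob$left, file.path(dir, "prob_L.nii.gz"))
  write_volume(tmpl$prob$right, file.path(dir, "prob_R.nii.gz"))
  jsonlite::write_json(lapply(tmpl$roi, function(b)
    list(lo = b$lo, hi = b$hi)),
    file.path(dir, "rois.json"), auto_unbox = FALSE, digits = NA)
  invisible(dir)
}
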