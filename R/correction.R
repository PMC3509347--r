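# AdaBoost-based detection and correction of systematic label-fusion
# errors. A working region is learned from where the initial segmentations
# of training subjects disagree with their ground truth; inside it a
# boosted ensemble of decision stumps classifies voxels as correctly
# labeled or mislabeled from appearance, contextual and spatial features,
# and flagged voxels have their binary structure label flipped.

#' Working region of the corrector (bias detection)
#'
#' Union over training subjects of the voxels where the initial
#' segmentation and the truth disagree on `label`, dilated by a Euclidean
#' ball of `dilation_mm`. An empty union yields an empty mask (with a
#' warning): the corrector is then the identity.
#'
#' @param initial_segs,truths Matched lists of `amy_labelmap`s in a common
#'   space.
#' @param label Structure label.
#' @param dilation_mm Dilation radius in mm.
#' @return An `amy_labelmap` mask (1 = corrector may edit).
#' @export
detect_bias_region <- function(initial_segs, truths, label = 1L,
                               dilation_mm = 2) {
  stopifnot(length(initial_segs) == length(truths))
  g <- grid_of(initial_segs[[1]])
  acc <- array(0L, g)
  for (i in seq_along(initial_segs)) {
    check_same_grid(initial_segs[[i]], truths[[i]])
    acc <- acc | xor(initial_segs[[i]]$labels == label,
                     truths[[i]]$labels == label)
  }
  sp <- initial_segs[[1]]$spacing
  if (!any(acc)) {
    warning("no disagreement voxels; corrector will be the identity")
    return(labelmap(array(0L, g), sp, initial_segs[[1]]$origin))
  }
  out <- cpp_dilate_offsets(array(as.integer(acc), g),
                            ball_offsets(dilation_mm, sp))
  labelmap(out, sp, initial_segs[[1]]$origin)
}

ball_offsets <- function(radius_mm, spacing) {
  r <- floor(radius_mm / spacing)
  off <- as.matrix(expand.grid(x = -r[1]:r[1], y = -r[2]:r[2], z = -r[3]:r[3]))
  keep <- sqrt((off[, 1] * spacing[1])^2 + (off[, 2] * spacing[2])^2 +
                 (off[, 3] * spacing[3])^2) <= radius_mm + 1e-9
  storage.mode(off) <- "integer"
  off[keep, , drop = FALSE]
}

gradient_magnitude <- function(dat) {
  g2 <- array(0, dim(dat))
  for (a in 1:3) {
    n <- dim(dat)[a]
    hi <- pmin(seq_len(n) + 1, n)
    lo <- pmax(seq_len(n) - 1, 1)
    ix <- function(sel) switch(a, dat[sel, , , drop = FALSE],
                               dat[, sel, , drop = FALSE],
                               dat[, , sel, drop = FALSE])
    g2 <- g2 + ((ix(hi) - ix(lo)) / (hi - lo))^2
  }
  sqrt(g2)
}

corrector_feature_names <- c("intensity",
                             paste0("nbr_", c("xm", "xp", "ym", "yp", "zm", "zp")),
                             "grad_mag", "initial_label",
                             "count_3", "count_5", "vote",
                             "off_x", "off_y", "off_z")

#' Corrector feature table
#'
#' One row per voxel of the working mask (lexicographic voxel order).
#' Appearance features: intensity, the six face-neighbour intensities
#' (edge-replicated) and gradient magnitude. Contextual: the initial
#' binary label, structure counts in the 3^3 and 5^3 neighbourhoods, and
#' the fusion vote fraction. Spatial: the voxel offset from the ROI-box
#' centre in mm.
#'
#' @param image Test/subject image (`amy_volume`).
#' @param initial Initial segmentation (`amy_labelmap`).
#' @param votes Vote-fraction `amy_volume` from fusion.
#' @param roi_box [voxel_box()] providing the spatial reference frame.
#' @param label Structure label.
#' @param mask Optional working mask (`amy_labelmap` or logical array);
#'   defaults to every voxel of `roi_box`.
#' @return List: `X` (feature matrix), `voxels` (n x 3 1-based indices),
#'   `feature_names`.
#' @export
extract_features <- function(image, initial, votes, roi_box, label = 1L,
                             mask = NULL) {
  g <- dim(image$data)
  msk <- array(FALSE, g)
  if (is.null(mask)) {
    i <- lapply(1:3, function(a) (roi_box$lo[a] + 1):roi_box$hi[a])
    msk[i[[1]], i[[2]], i[[3]]] <- TRUE
  } else {
    msk <- if (is_labelmap(mask)) mask$labels != 0L else mask
  }
  vox <- which(msk, arr.ind = TRUE)
  if (nrow(vox) == 0) stop("empty working mask")
  dat <- image$data
  bin <- array(as.numeric(initial$labels == label), g)
  shift <- function(a, dlt) {
    n <- g[a]
    sel <- pmin(pmax(seq_len(n) + dlt, 1), n)
    switch(a, dat[sel, , , drop = FALSE], dat[, sel, , drop = FALSE],
           dat[, , sel, drop = FALSE])
  }
  planes <- list(dat,
                 shift(1, -1), shift(1, 1), shift(2, -1), shift(2, 1),
                 shift(3, -1), shift(3, 1),
                 gradient_magnitude(dat), bin,
                 cpp_box_sum(bin, 1L), cpp_box_sum(bin, 2L), votes$data)
  X <- vapply(planes, function(p) p[msk], numeric(nrow(vox)))
  ctr <- (roi_box$lo + roi_box$hi - 1) / 2   # 0-based box centre
  for (a in 1:3) X <- cbind(X, (vox[, a] - 1 - ctr[a]) * image$spacing[a])
  colnames(X) <- corrector_feature_names
  if (anyNA(X) || any(!is.finite(X))) {
    bad <- which(!is.finite(X), arr.ind = TRUE)[1, ]
    stop("non-finite feature '", corrector_feature_names[bad[2]],
         "' at voxel ", paste(vox[bad[1], ], collapse = ","))
  }
  list(X = X, voxels = vox, feature_names = corrector_feature_names)
}

#' Fit a per-feature standardizer (training statistics only)
#'
#' Zero-variance features are dropped (reported via message).
#' @param X Feature matrix.
#' @export
fit_standardizer <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  keep <- sdv > 1e-12
  if (any(!keep))
    message("dropping zero-variance feature(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
  list(mean = mu, sd = sdv, keep = keep, names = colnames(X))
}

apply_standardizer <- function(std, X) {
  if (!identical(colnames(X), std$names)) stop("feature schema mismatch")
  Xs <- sweep(X[, std$keep, drop = FALSE], 2, std$mean[std$keep], "-")
  sweep(Xs, 2, std$sd[std$keep], "/")
}

#' Train a discrete AdaBoost stump ensemble
#'
#' Classic discrete AdaBoost: per round the decision stump minimizing the
#' weighted error over all features and candidate thresholds (midpoints of
#' sorted distinct values) is selected; `alpha_t = 0.5 log((1-eps)/eps)`;
#' weights are multiplicatively updated and renormalized. Training stops
#' early when no stump beats chance (`eps >= 0.5 - 1e-9`) or the weighted
#' error hits zero. Initial weights are uniform (`1/n`) by default: in the
#' working region only a minority of voxels is mislabeled, and a
#' class-balanced start trades so much precision for recall that flipping
#' the flagged voxels worsens the segmentation; `class_balance = TRUE`
#' restores the balanced variant (each class summing to 1/2).
#'
#' @param X Standardized feature matrix.
#' @param y Logical (or 0/1) vector: `TRUE` = mislabeled voxel.
#' @param T Maximum boosting rounds.
#' @param class_balance Balance the initial weights per class.
#' @return A `boost_model` with stumps, `eps`/`train_err` traces and the
#'   feature names used.
#' @export
train_adaboost <- function(X, y, T = 100L, class_balance = FALSE) {
  y <- as.logical(y)
  if (length(unique(y)) < 2) stop("both classes must be present for training")
  yy <- ifelse(y, 1L, -1L)
  w0 <- if (class_balance) ifelse(y, 0.5 / sum(y), 0.5 / sum(!y))
        else rep(1 / length(y), length(y))
  fit <- cpp_adaboost_train(as.matrix(X), yy, w0, as.integer(T))
  structure(list(feature = fit$feature + 1L, threshold = fit$threshold,
                 polarity = fit$polarity, alpha = fit$alpha,
                 eps = fit$eps, train_err = fit$train_err,
                 feature_names = colnames(X), rounds = length(fit$alpha)),
            class = "boost_model")
}

#' Ensemble score and decision
#'
#' `score = sum_t alpha_t h_t(x)`; a voxel is flagged as mislabeled when
#' the score is strictly positive (ties keep the initial label).
#'
#' @param model A `boost_model`.
#' @param X Feature matrix on the model's schema.
#' @export
predict_boost <- function(model, X) {
  if (!identical(colnames(X), model$feature_names))
    stop("feature schema mismatch (count/order)")
  if (model$rounds == 0) return(rep(FALSE, nrow(X)))
  s <- cpp_boost_score(as.matrix(X), model$feature - 1L, model$threshold,
                       as.integer(model$polarity), model$alpha)
  s > 0
}

#' Full corrector bundle for one hemisphere
#'
#' Packages the boosted ensemble with its standardizer, working-region
#' mask, ROI box and structure label so it can be applied or serialized as
#' a unit.
#'
#' @param model A `boost_model`.
#' @param standardizer From [fit_standardizer()].
#' @param mask Working-region `amy_labelmap` (reference space).
#' @param roi_box [voxel_box()] of the search region.
#' @param label Structure label corrected.
#' @export
corrector <- function(model, standardizer, mask, roi_box, label) {
  structure(list(model = model, standardizer = standardizer, mask = mask,
                 roi_box = roi_box, label = as.integer(label)),
            class = "amy_corrector")
}

identity_corrector <- function(mask, roi_box, label) {
  corrector(structure(list(feature = integer(0), threshold = numeric(0),
                           polarity = integer(0), alpha = numeric(0),
                           eps = numeric(0), train_err = numeric(0),
                           feature_names = corrector_feature_names,
                           rounds = 0L), class = "boost_model"),
            NULL, mask, roi_box, label)
}

#' Apply a trained corrector to a segmentation
#'
#' Voxels of the working region classified as mislabeled have their binary
#' structure label flipped; everything outside the working region is
#' untouched. Returns the corrected map and the flip mask (flipping the
#' same mask again restores the input).
#'
#' @param initial Initial `amy_labelmap`.
#' @param corr An [corrector()].
#' @param image,votes The inputs fusion saw (same space as `initial`).
#' @param mask Optional working-mask override (e.g. the reference-space
#'   mask warped into this subject's space).
#' @param roi_box Optional subject-space ROI box for the spatial features.
#' @return List: `labels`, `flipped` (logical array).
#' @export
correct_segmentation <- function(initial, corr, image, votes, mask = NULL,
                                 roi_box = NULL) {
  msk <- if (is.null(mask)) corr$mask else mask
  mlog <- if (is_labelmap(msk)) msk$labels != 0L else msk
  if (is.null(roi_box)) roi_box <- corr$roi_box
  flips <- array(FALSE, dim(initial$labels))
  if (any(mlog) && corr$model$rounds > 0) {
    fe <- extract_features(image, initial, votes, roi_box, corr$label,
                           mask = mlog)
    Xs <- apply_standardizer(corr$standardizer, fe$X)
    flag <- predict_boost(corr$model, Xs)
    flips[fe$voxels[flag, , drop = FALSE]] <- TRUE
  }
  lab <- initial$labels
  on_flip <- flips & lab == corr$label
  off_flip <- flips & lab != corr$label
  lab[on_flip] <- 0L
  lab[off_flip] <- corr$label
  list(labels = labelmap(lab, initial$spacing, initial$origin),
       flipped = flips)
}

#' Serialize / load a corrector as JSON
#'
#' Numeric values are written at full precision so a reloaded model makes
#' bit-identical predictions.
#'
#' @param corr An [corrector()].
#' @param path JSON file path.
#' @export
save_corrector <- function(corr, path) {
  obj <- list(model = unclass(corr$model),
              standardizer = corr$standardizer,
              mask = list(dim = dim(corr$mask$labels),
                          on = which(corr$mask$labels != 0L),
                          spacing = corr$mask$spacing,
                          origin = corr$mask$origin),
              roi_box = corr$roi_box, label = corr$label)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_corrector
#' @export
load_corrector <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  mask_arr <- array(0L, o$mask$dim)
  mask_arr[o$mask$on] <- 1L
  std <- o$standardizer
  if (!is.null(std)) std$keep <- as.logical(std$keep)
  model <- structure(c(o$model[c("feature", "threshold", "polarity", "alpha",
                                 "eps", "train_err", "feature_names")],
                       list(rounds = length(o$model$alpha))),
                     class = "boost_model")
  model$feature <- as.integer(model$feature)
  model$polarity <- as.integer(model$polarity)
  corrector(model, std,
            labelmap(mask_arr, o$mask$spacing, o$mask$origin),
            voxel_box(o$roi_box$lo, o$roi_box$hi), o$label)
}
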