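# Locally similarity-weighted multi-atlas label voting. Every warped atlas
# votes at every voxel; its vote is weighted by the inverse patch distance
# between the test image and the warped atlas image around that voxel, so
# atlases that locally resemble the test subject dominate.

#' Warped atlas container
#' @param id Atlas identifier.
#' @param image Atlas image warped into the test frame (`amy_volume`).
#' @param labels Atlas labels carried by the same warp (`amy_labelmap`).
#' @export
warped_atlas <- function(id, image, labels) {
  if (!identical(dim(image$data), dim(labels$labels)))
    stop("warped atlas image and labels are misaligned")
  list(id = id, image = image, labels = labels)
}

#' Default label-fusion parameters
#'
#' `patch_radius` is the half-width of the local comparison cube (radius 2
#' = 5^3 voxels), `beta` the inverse-distance exponent, `eps` the guard
#' keeping weights finite on perfect matches.
#' @export
default_fusion_params <- function() {
  list(patch_radius = 2L, beta = 2, eps = 1e-6)
}

#' Local similarity weight map for one atlas
#'
#' `w(x) = (eps + sum_patch (I_test - I_atlas)^2)^(-beta)` with the patch
#' cube clipped at the volume borders. Always finite and strictly positive.
#'
#' @param test Test image (`amy_volume`).
#' @param atlas A [warped_atlas()] (or an `amy_volume`).
#' @param patch_radius,beta,eps See [default_fusion_params()].
#' @export
weight_map <- function(test, atlas, patch_radius = 2L, beta = 2, eps = 1e-6) {
  aimg <- if (is.list(atlas) && !is.null(atlas$image)) atlas$image else atlas
  if (!identical(dim(test$data), dim(aimg$data)))
    stop("test and atlas grids differ")
  ssd <- cpp_box_sum((test$data - aimg$data)^2, as.integer(patch_radius))
  volume((eps + ssd)^(-beta), test$spacing, test$origin)
}

#' Similarity-weighted voxelwise label voting
#'
#' Per voxel: `vote(x) = sum_i w_i(x) [labels_i(x) = label] / sum_i w_i(x)`;
#' the structure is assigned where the vote fraction is >= 0.5 (the tie
#' goes to the structure, a documented deterministic choice). Voting is
#' binary structure-vs-rest, independent per hemisphere.
#'
#' @param test Test image (`amy_volume`).
#' @param atlases List of [warped_atlas()] on the test grid.
#' @param label Structure label voted on.
#' @param params See [default_fusion_params()].
#' @return List: `labels` (`amy_labelmap` with 0/`label`), `votes`
#'   (`amy_volume` of vote fractions in [0, 1]).
#' @export
weighted_vote <- function(test, atlases, label = 1L,
                          params = default_fusion_params()) {
  if (length(atlases) < 2) stop("label fusion needs >= 2 atlases")
  num <- array(0, dim(test$data))
  den <- array(0, dim(test$data))
  for (at in atlases) {
    w <- weight_map(test, at, params$patch_radius, params$beta, params$eps)$data
    num <- num + w * (at$labels$labels == label)
    den <- den + w
  }
  if (any(den <= 0)) stop("internal error: vanishing total weight")
  votes <- num / den
  lab <- array(0L, dim(test$data))
  lab[votes >= 0.5] <- as.integer(label)
  list(labels = labelmap(lab, test$spacing, test$origin),
       votes = volume(votes, test$spacing, test$origin))
}

#' Fuse both hemispheres inside their search regions
#'
#' Runs [weighted_vote()] independently for each structure inside its ROI
#' box and assembles a full-grid segmentation. A voxel claimed by both
#' hemispheres goes to the higher vote fraction (left wins exact ties; a
#' message reports how many voxels needed the tie-break).
#'
#' @param test Full-grid test image.
#' @param atlases List of full-grid [warped_atlas()]s.
#' @param rois List of [voxel_box()]s named `left`, `right`.
#' @param labels Structure labels, default `c(left = 1, right = 2)`.
#' @param params See [default_fusion_params()].
#' @return List: `labels` (full-grid `amy_labelmap`), `votes` (full-grid
#'   per-structure vote `amy_volume`s).
#' @export
fuse_segmentation <- function(test, atlases, rois,
                              labels = c(left = 1L, right = 2L),
                              params = default_fusion_params()) {
  g <- dim(test$data)
  out <- array(0L, g)
  votes_full <- list()
  claim <- list()
  for (st in names(labels)) {
    box <- rois[[st]]
    tc <- crop_box(test, box)
    ac <- lapply(atlases, function(at)
      warped_atlas(at$id, crop_box(at$image, box), crop_box(at$labels, box)))
    wv <- weighted_vote(tc, ac, labels[[st]], params)
    vf <- array(0, g)
    i <- lapply(1:3, function(a) (box$lo[a] + 1):box$hi[a])
    vf[i[[1]], i[[2]], i[[3]]] <- wv$votes$data
    votes_full[[st]] <- volume(vf, test$spacing, test$origin)
    claim[[st]] <- vf >= 0.5
  }
  both <- claim$left & claim$right
  n_both <- sum(both)
  lw <- votes_full$left$data; rw <- votes_full$right$data
  out[claim$left] <- labels[["left"]]
  out[claim$right] <- labels[["right"]]
  if (n_both > 0) {
    message(n_both, " voxel(s) claimed by both hemispheres; resolved by vote")
    out[both] <- ifelse(lw[both] >= rw[both], labels[["left"]], labels[["right"]])
  }
  list(labels = labelmap(out, test$spacing, test$origin), votes = votes_full)
}
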