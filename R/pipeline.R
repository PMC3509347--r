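# End-to-end orchestration: normalize -> template -> per-subject rigid +
# deformable alignment -> ROI-restricted per-atlas registration at the
# coarse/middle/fine schedule -> similarity-weighted voting -> AdaBoost
# correction (leave-one-out trained on the atlas set) -> evaluation.
#
# Everything is deterministic given (inputs, config): no stage uses RNG.

#' Pipeline configuration
#'
#' All tunables of every stage with their defaults. Unknown keys are
#' rejected.
#'
#' @param ... Overrides of the default entries.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    schedule_levels = list(c(4L, 80L), c(2L, 80L), c(1L, 30L)),
    reg_params = default_reg_params(),
    fusion_params = default_fusion_params(),
    n_outer = 3L,               # template outer iterations
    roi_threshold = 0.01,
    roi_margin_mm = 4,
    label_sigma_mm = 1.0,
    boost_rounds = 100L,
    bias_dilation_mm = 2,
    correction = TRUE,
    normalize = TRUE)
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  cfg
}

normalize_case <- function(s) {
  img <- normalize_intensity(s$image, head_mask(s$image))
  list(id = s$id, image = img, truth = s$truth)
}

# ROI box of a template-space box warped into subject space through the
# template->subject field S (on the subject grid), padded by one voxel.
warp_roi_box <- function(box, S) {
  g <- grid_of(S)
  m <- array(0L, g)
  i <- lapply(1:3, function(a) (box$lo[a] + 1):box$hi[a])
  m[i[[1]], i[[2]], i[[3]]] <- 1L
  wm <- apply_deformation(labelmap(m, S$spacing, S$origin), S, "nearest")
  idx <- which(wm$labels != 0L, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("search region warped to empty")
  lo <- pmax(apply(idx, 2, min) - 2, 0)
  hi <- pmin(apply(idx, 2, max) + 1, g)
  voxel_box(lo, hi)
}

warp_mask <- function(mask, S) {
  apply_deformation(mask, S, "nearest")
}

# Segment one subject (already on the template-aligned grid) with the
# atlases `atlas_idx` of `tmpl`. S is the template->subject field on the
# subject grid. Returns the fused segmentation plus everything the
# corrector needs.
segment_in_space <- function(img, tmpl, S, atlas_idx, config) {
  sched <- reg_schedule(config$schedule_levels)
  n_levels <- length(sched$factors)
  init_w <- lapply(atlas_idx, function(i) {
    f <- compose_fields(S, tmpl$fields[[i]])
    list(image = apply_deformation(tmpl$aligned[[i]], f),
         truth = apply_deformation(tmpl$aligned_truth[[i]], f, "nearest"))
  })
  g <- dim(img$data)
  out <- array(0L, g)
  votes_full <- list()
  claim <- list()
  roi_sub <- list()
  labels <- c(left = 1L, right = 2L)
  for (st in names(labels)) {
    box <- warp_roi_box(tmpl$roi[[st]], S)
    roi_sub[[st]] <- box
    tc <- crop_box(img, box)
    atl <- lapply(seq_along(init_w), function(k) {
      wi <- crop_box(init_w[[k]]$image, box)
      wl <- crop_box(init_w[[k]]$truth, box)
      rr <- diffeo_register(wi, tc, sched, config$reg_params)
      warped_atlas(tmpl$subject_ids[atlas_idx[k]],
                   apply_deformation(wi, rr$field),
                   apply_deformation(wl, rr$field, "nearest"))
    })
    wv <- weighted_vote(tc, atl, labels[[st]], config$fusion_params)
    vf <- array(0, g)
    i <- lapply(1:3, function(a) (box$lo[a] + 1):box$hi[a])
    vf[i[[1]], i[[2]], i[[3]]] <- wv$votes$data
    votes_full[[st]] <- volume(vf, img$spacing, img$origin)
    claim[[st]] <- vf >= 0.5
  }
  both <- claim$left & claim$right
  out[claim$left] <- 1L
  out[claim$right] <- 2L
  if (any(both)) {
    lw <- votes_full$left$data; rw <- votes_full$right$data
    out[both] <- ifelse(lw[both] >= rw[both], 1L, 2L)
  }
  list(labels = labelmap(out, img$spacing, img$origin),
       votes = votes_full, roi = roi_sub,
       warps_per_hemisphere = length(atlas_idx) * n_levels,
       levels = n_levels)
}

train_correctors <- function(tmpl, config) {
  n <- length(tmpl$aligned)
  loo <- vector("list", n)
  for (j in seq_len(n)) {
    S <- diffeo_register(tmpl$image, tmpl$aligned[[j]],
                         reg_schedule(config$schedule_levels),
                         config$reg_params)$field
    seg <- segment_in_space(tmpl$aligned[[j]], tmpl, S,
                            setdiff(seq_len(n), j), config)
    loo[[j]] <- c(seg, list(S = S))
  }
  labels <- c(left = 1L, right = 2L)
  correctors <- list()
  for (st in names(labels)) {
    lb <- labels[[st]]
    # bias detection in template space: push each subject's disagreement
    # through its subject->template field from the template build
    xors_t <- lapply(seq_len(n), function(j) {
      x <- array(as.integer(xor(loo[[j]]$labels$labels == lb,
                                tmpl$aligned_truth[[j]]$labels == lb)),
                 dim(tmpl$image$data))
      xm <- labelmap(x, tmpl$image$spacing, tmpl$image$origin)
      apply_deformation(xm, tmpl$fields[[j]], "nearest")
    })
    mask_t <- suppressWarnings(
      detect_bias_region(xors_t,
                         lapply(xors_t, function(m)
                           labelmap(array(0L, dim(m$labels)), m$spacing,
                                    m$origin)),
                         label = 1L, dilation_mm = config$bias_dilation_mm))
    if (!any(mask_t$labels)) {
      correctors[[st]] <- identity_corrector(mask_t, tmpl$roi[[st]], lb)
      next
    }
    Xs <- list(); ys <- list()
    for (j in seq_len(n)) {
      mask_j <- warp_mask(mask_t, loo[[j]]$S)
      if (!any(mask_j$labels)) next
      fe <- extract_features(tmpl$aligned[[j]], loo[[j]]$labels,
                             loo[[j]]$votes[[st]], loo[[j]]$roi[[st]], lb,
                             mask = mask_j)
      mis <- xor(loo[[j]]$labels$labels == lb,
                 tmpl$aligned_truth[[j]]$labels == lb)[mask_j$labels != 0L]
      Xs[[length(Xs) + 1]] <- fe$X
      ys[[length(ys) + 1]] <- mis
    }
    X <- do.call(rbind, Xs)
    y <- unlist(ys)
    if (length(unique(y)) < 2) {
      correctors[[st]] <- identity_corrector(mask_t, tmpl$roi[[st]], lb)
      next
    }
    std <- fit_standardizer(X)
    model <- train_adaboost(apply_standardizer(std, X), y,
                            config$boost_rounds)
    correctors[[st]] <- corrector(model, std, mask_t, tmpl$roi[[st]], lb)
  }
  list(correctors = correctors, loo = loo)
}

#' Run the full segmentation pipeline on a cohort
#'
#' @param train,test Lists of subject cases (`id`, `image`, `truth`), e.g.
#'   from [simulate_cohort()] or [read_cohort()]; `test` truths are used
#'   only for evaluation.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory: segmentations (NIfTI), run
#'   manifest (JSON) and metrics report (CSV/JSON) are written there.
#' @return List: `template`, `correctors`, `segmentations` (per test
#'   subject: initial/corrected `amy_labelmap`s in native space), `report`
#'   ([evaluate_cohort()] output), `manifest`.
#' @export
run_pipeline <- function(train, test, config = pipeline_config(),
                         out_dir = NULL) {
  t0 <- proc.time()[3]
  log_stage <- function(...) message(sprintf("[%7.1fs] ", proc.time()[3] - t0),
                                     ...)
  if (config$normalize) {
    log_stage("normalizing ", length(train), "+", length(test), " images")
    train <- lapply(train, normalize_case)
    test_n <- lapply(test, normalize_case)
  } else test_n <- test
  log_stage("building template from ", length(train), " subjects")
  tmpl <- build_template(train, n_outer = config$n_outer,
                         schedule = reg_schedule(config$schedule_levels),
                         params = config$reg_params,
                         roi_threshold = config$roi_threshold,
                         roi_margin_mm = config$roi_margin_mm,
                         label_sigma_mm = config$label_sigma_mm)
  correctors <- NULL
  if (config$correction) {
    log_stage("training correctors (leave-one-out over ", length(train),
              " atlases)")
    correctors <- train_correctors(tmpl, config)$correctors
  }
  segs <- list()
  manifest_subjects <- list()
  for (k in seq_along(test_n)) {
    s <- test_n[[k]]
    log_stage("segmenting ", s$id)
    tr <- rigid_register(s$image, tmpl$image)
    aligned <- apply_rigid(s$image, tr, tmpl$image)
    S <- diffeo_register(tmpl$image, aligned,
                         reg_schedule(config$schedule_levels),
                         config$reg_params)$field
    seg <- segment_in_space(aligned, tmpl, S, seq_along(train), config)
    final_aligned <- seg$labels
    if (config$correction) {
      for (st in c("left", "right")) {
        co <- correctors[[st]]
        mask_s <- warp_mask(co$mask, S)
        cr <- correct_segmentation(final_aligned, co, aligned,
                                   seg$votes[[st]], mask = mask_s,
                                   roi_box = seg$roi[[st]])
        final_aligned <- cr$labels
      }
    }
    inv <- invert_rigid(tr)
    to_native <- function(lm) apply_rigid(lm, inv, test[[k]]$image)
    segs[[s$id]] <- list(id = s$id,
                         initial = to_native(seg$labels),
                         corrected = to_native(final_aligned))
    manifest_subjects[[s$id]] <- list(
      id = s$id, n_atlases = length(train), levels = seg$levels,
      warps_per_hemisphere = seg$warps_per_hemisphere)
  }
  report <- NULL
  have_truth <- length(test) > 0 && !is.null(test[[1]]$truth)
  if (have_truth) {
    auto <- lapply(segs, `[[`, "corrected")
    ref <- lapply(test, `[[`, "truth")
    names(ref) <- vapply(test, `[[`, "", "id")
    report <- evaluate_cohort(auto, ref)
  }
  manifest <- list(n_train = length(train), n_test = length(test),
                   subjects = manifest_subjects,
                   config = config_for_json(config))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (sg in segs) {
      write_volume(sg$initial, file.path(out_dir, paste0(sg$id, "_seg_initial.nii.gz")))
      write_volume(sg$corrected, file.path(out_dir, paste0(sg$id, "_seg.nii.gz")))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(report))
      write_metrics(report, csv = file.path(out_dir, "report.csv"),
                    json = file.path(out_dir, "report.json"))
  }
  log_stage("done")
  list(template = tmpl, correctors = correctors, segmentations = segs,
       report = report, manifest = manifest, config = config)
}

#' Default demonstration cohort
#'
#' A small seeded 48^3 phantom cohort (5 atlas + 2 test subjects) sized so
#' the full pipeline runs in a few minutes on one CPU; used by the README
#' example and the end-to-end determinism check.
#'
#' @param seed Cohort seed.
#' @export
demo_cohort <- function(seed = 7L) {
  simulate_cohort(5, 2, phantom_params(seed = seed), seed = seed)
}

config_for_json <- function(cfg) {
  cfg$schedule_levels <- lapply(cfg$schedule_levels, as.integer)
  cfg
}
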