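# helpers for building small labelled scenes
box_seg <- function(n, lo, hi, label = 1L) {
  arr <- array(0L, rep(n, 3))
  arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- label
  labelmap(arr)
}

dilate_lm <- function(lm, label = 1L) {
  d <- amyseg:::cpp_dilate_offsets(array(as.integer(lm$labels == label),
                                         dim(lm$labels)),
                                   amyseg:::ball_offsets(1, lm$spacing))
  out <- lm$labels
  out[d == 1L] <- label
  labelmap(out, lm$spacing, lm$origin)
}

test_that("bias detection unions disagreements and dilates with a ball", {
  truth <- box_seg(16, c(6, 6, 6), c(9, 9, 9))
  expect_warning(m0 <- detect_bias_region(list(truth), list(truth)),
                 "identity")
  expect_true(all(m0$labels == 0L))

  # one mislabeled voxel, 2 mm dilation at 1 mm spacing
  seg <- truth
  seg$labels[12, 12, 12] <- 1L
  m <- detect_bias_region(list(seg), list(truth), dilation_mm = 2)
  pt <- array(0L, c(16, 16, 16)); pt[12, 12, 12] <- 1L
  expect_identical(m$labels != 0L, oracle_dilate(pt, 2, c(1, 1, 1)))

  # mask always contains every disagreement voxel, across subjects
  seg2 <- truth
  seg2$labels[6, 6, 6] <- 0L
  mm <- detect_bias_region(list(seg, seg2), list(truth, truth), dilation_mm = 1)
  dis <- (seg$labels != truth$labels) | (seg2$labels != truth$labels)
  expect_true(all(mm$labels[dis] != 0L))
})

test_that("feature extraction produces the documented schema", {
  n <- 14
  set.seed(6)
  img <- volume(array(rnorm(n^3, 100, 10), rep(n, 3)))
  seg <- box_seg(n, c(5, 5, 5), c(9, 9, 9))
  votes <- volume(array(as.numeric(seg$labels == 1L), rep(n, 3)))
  box <- voxel_box(c(2, 2, 2), c(13, 13, 13))   # odd extent, centre at voxel 7
  fe <- extract_features(img, seg, votes, box, 1L)
  expect_equal(ncol(fe$X), 15)
  expect_equal(nrow(fe$X), 11^3)
  # voxel at the box centre has zero spatial offset
  ctr_row <- which(fe$voxels[, 1] == 8 & fe$voxels[, 2] == 8 & fe$voxels[, 3] == 8)
  expect_equal(unname(fe$X[ctr_row, c("off_x", "off_y", "off_z")]), c(0, 0, 0))
  # a voxel strictly inside the structure counts 27 neighbours in the 3^3 cube
  in_row <- which(fe$voxels[, 1] == 7 & fe$voxels[, 2] == 7 & fe$voxels[, 3] == 7)
  expect_equal(unname(fe$X[in_row, "count_3"]), 27)
  expect_equal(unname(fe$X[in_row, "count_5"]), 125)
  # standardization drops zero-variance features with a message
  cimg <- volume(array(5, rep(n, 3)))
  fec <- extract_features(cimg, seg, votes, box, 1L)
  expect_message(std <- fit_standardizer(fec$X), "zero-variance")
  expect_false(all(std$keep))
  expect_true(any(!std$keep[1:8]))          # appearance features constant
})

test_that("adaboost obeys its closed forms and bounds", {
  # eps = 0.1 -> alpha = 0.5 ln 9
  X <- matrix(c(rep(0, 9), rep(1, 1), rep(1, 9), rep(0, 1)), ncol = 1)
  colnames(X) <- "f"
  y <- rep(c(TRUE, FALSE), each = 10)
  m <- train_adaboost(X, y, T = 1)
  expect_equal(m$eps[1], 0.1, tolerance = 1e-12)
  expect_equal(m$alpha[1], 0.5 * log(9), tolerance = 1e-12)

  # linearly separable 1-D set: zero training error after one round
  X2 <- matrix(c(rnorm(20, -3), rnorm(20, 3)), ncol = 1)
  colnames(X2) <- "f"
  y2 <- rep(c(FALSE, TRUE), each = 20)
  m2 <- train_adaboost(X2, y2, T = 10)
  expect_equal(m2$train_err[1], 0)
  expect_equal(m2$rounds, 1)                # eps = 0 stops training

  # a feature carrying no signal cannot beat chance: training halts
  X3 <- matrix(rep(c(1, 2), each = 10), ncol = 1)
  colnames(X3) <- "f"
  y3 <- rep(c(TRUE, FALSE), 10)                 # 50/50 within each value
  m3 <- train_adaboost(X3, y3, T = 5)
  expect_equal(m3$rounds, 0)

  # exponential bound prod_t 2 sqrt(eps (1 - eps)) on random data
  set.seed(44)
  X4 <- matrix(rnorm(200 * 5), 200, 5)
  colnames(X4) <- paste0("f", 1:5)
  y4 <- (X4[, 1] + 0.5 * X4[, 3] + rnorm(200, sd = 0.8)) > 0
  m4 <- train_adaboost(X4, y4, T = 40)
  bound <- cumprod(2 * sqrt(m4$eps * (1 - m4$eps)))
  expect_true(all(m4$train_err <= bound + 1e-12))
  expect_true(all(diff(cummin(m4$train_err)) <= 0))  # non-increasing min
  expect_error(train_adaboost(X4, rep(TRUE, 200)), "both classes")
})

test_that("boost models serialize to JSON with identical predictions", {
  set.seed(17)
  n <- 14
  img <- volume(array(rnorm(n^3, 100, 10), rep(n, 3)))
  seg <- box_seg(n, c(5, 5, 5), c(9, 9, 9))
  truth <- box_seg(n, c(5, 5, 5), c(10, 10, 10))
  votes <- volume(array(as.numeric(seg$labels == 1L), rep(n, 3)))
  box <- voxel_box(c(2, 2, 2), c(13, 13, 13))
  mask <- detect_bias_region(list(seg), list(truth), dilation_mm = 2)
  fe <- extract_features(img, seg, votes, box, 1L, mask = mask)
  yy <- xor(seg$labels == 1L, truth$labels == 1L)[mask$labels != 0L]
  std <- fit_standardizer(fe$X)
  model <- train_adaboost(apply_standardizer(std, fe$X), yy, T = 25)
  corr <- corrector(model, std, mask, box, 1L)
  path <- file.path(tempdir(), "model_L.json")
  save_corrector(corr, path)
  corr2 <- load_corrector(path)
  expect_identical(corr2$mask$labels, corr$mask$labels)
  Xs <- apply_standardizer(std, fe$X)
  expect_identical(predict_boost(corr2$model, Xs), predict_boost(model, Xs))

  # applying the corrector: outside-mask voxels never change, flips involutive
  res <- correct_segmentation(seg, corr, img, votes)
  outside <- corr$mask$labels == 0L
  expect_identical(res$labels$labels[outside], seg$labels[outside])
  twice <- res$labels$labels
  twice[res$flipped & res$labels$labels == 1L] <- 0L
  twice[res$flipped & res$labels$labels != 1L] <- 1L
  # flipping the recorded mask again returns the initial segmentation
  flip_back <- res$labels$labels
  flip_back[res$flipped] <- ifelse(res$labels$labels[res$flipped] == 1L, 0L, 1L)
  expect_identical(flip_back, seg$labels)
})

test_that("the corrector learns a systematic dilation bias", {
  # fusion that systematically dilates the truth by one voxel: train on
  # n - 1 subjects, correct the held-out one
  set.seed(55)
  n <- 20
  improvements <- c()
  for (seedi in 1:3) {
    subs <- lapply(1:6, function(i) {
      lo <- 6 + ((seedi * 7 + i) %% 3); hi <- lo + 3 + (i %% 2)
      truth <- box_seg(n, rep(lo, 3), rep(hi, 3))
      img <- volume(array(rnorm(n^3, 100, 5), rep(n, 3)) +
                      80 * (truth$labels == 1L))
      init <- dilate_lm(truth)
      votes <- volume(array(as.numeric(init$labels == 1L), rep(n, 3)))
      list(truth = truth, img = img, init = init, votes = votes)
    })
    box <- voxel_box(c(1, 1, 1), c(15, 15, 15))
    held <- 6
    tr_idx <- 1:5
    mask <- detect_bias_region(lapply(subs[tr_idx], `[[`, "init"),
                               lapply(subs[tr_idx], `[[`, "truth"),
                               dilation_mm = 2)
    Xs <- list(); ys <- list()
    for (i in tr_idx) {
      fe <- extract_features(subs[[i]]$img, subs[[i]]$init, subs[[i]]$votes,
                             box, 1L, mask = mask)
      Xs[[i]] <- fe$X
      ys[[i]] <- xor(subs[[i]]$init$labels == 1L,
                     subs[[i]]$truth$labels == 1L)[mask$labels != 0L]
    }
    X <- do.call(rbind, Xs); y <- unlist(ys)
    std <- fit_standardizer(X)
    model <- train_adaboost(apply_standardizer(std, X), y, T = 50)
    corr <- corrector(model, std, mask, box, 1L)
    res <- correct_segmentation(subs[[held]]$init, corr, subs[[held]]$img,
                                subs[[held]]$votes)
    d0 <- dice(subs[[held]]$init, subs[[held]]$truth, 1L)
    d1 <- dice(res$labels, subs[[held]]$truth, 1L)
    improvements <- c(improvements, d1 > d0)
  }
  expect_gte(sum(improvements), 2)
})
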