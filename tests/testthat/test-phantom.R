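test_that("base phantom is mirror-symmetric with lateralized structures", {
  base <- base_default()
  n1 <- sum(base$truth$labels == 1L)
  n2 <- sum(base$truth$labels == 2L)
  expect_gt(n1, 0)
  expect_identical(n1, n2)                      # mirror symmetry
  idx1 <- which(base$truth$labels == 1L, arr.ind = TRUE)
  idx2 <- which(base$truth$labels == 2L, arr.ind = TRUE)
  mid <- (dim(base$truth$labels)[1] + 1) / 2
  expect_lt(mean(idx1[, 1]), mid)
  expect_gt(mean(idx2[, 1]), mid)
  # structures are brighter than gray matter, darker than white
  tm <- default_params()$tissue_means
  sval <- unique(base$image$data[base$truth$labels > 0])
  expect_equal(sval, tm[["gray"]] + default_params()$structure_contrast)
})

test_that("noiseless base image has distinct modes per tissue", {
  base <- base_default()
  vals <- sort(unique(as.vector(base$image$data)))
  counts <- sapply(vals, function(v) sum(base$image$data == v))
  # every tissue present in bulk: >= 3 in-head intensity modes + background
  expect_gte(sum(counts > 100), 4)
})

test_that("random diffeomorphisms are seeded, invertibility-safe and scale to zero", {
  p <- default_params()
  expect_equal(random_diffeomorphism(p, 5, amplitude = 0)$disp,
               zero_field(p$shape)$disp)
  d1 <- random_diffeomorphism(p, 1)
  d2 <- random_diffeomorphism(p, 1)
  expect_identical(d1$disp, d2$disp)            # bit-identical reproducibility
  expect_gt(max(abs(d1$disp - random_diffeomorphism(p, 2)$disp)), 0.1)
})

test_that("a sweep of random fields keeps the Jacobian strictly positive", {
  p <- default_params()
  worst <- Inf
  for (s in 1:200) {
    d <- random_diffeomorphism(p, 1000 + s)
    worst <- min(worst, min(jacobian_determinant(d)$data))
  }
  expect_gt(worst, 0)
})

test_that("subject simulation composes warp, bias and noise as stated", {
  p0 <- phantom_params(warp_amplitude = 0, bias_strength = 0, noise_sd = 0)
  base <- make_base_phantom(p0)
  s0 <- simulate_subject(base, p0, 3)
  expect_equal(s0$image$data, base$image$data)   # degenerate limit is exact
  expect_identical(s0$truth$labels, base$truth$labels)

  p <- default_params()
  base <- base_default()
  s <- simulate_subject(base, p, 17)
  # truth is transported with the SAME field as the image
  expect_identical(s$truth$labels,
                   apply_deformation(base$truth, s$field, "nearest")$labels)
  expect_true(all(c(1L, 2L) %in% s$truth$labels))
})

test_that("cohort volume variability sits in the expected range", {
  co <- cached("cohort_cov", simulate_cohort(20, 0, default_params(), seed = 77))
  vols <- unlist(lapply(co$train, function(s)
    c(sum(s$truth$labels == 1L), sum(s$truth$labels == 2L))))
  cv <- sd(vols) / mean(vols)
  expect_gt(cv, 0.02)
  expect_lt(cv, 0.25)
})

test_that("cohorts are reproducible and carry a usable manifest", {
  p <- small_params(24)
  dir <- file.path(tempdir(), "cohort_repro")
  co1 <- simulate_cohort(2, 1, p, seed = 7, out_dir = dir)
  co2 <- simulate_cohort(2, 1, p, seed = 7)
  expect_identical(co1$train[[1]]$image$data, co2$train[[1]]$image$data)
  expect_identical(co1$test[[1]]$truth$labels, co2$test[[1]]$truth$labels)
  # three distinct images
  imgs <- c(lapply(co1$train, `[[`, "image"), lapply(co1$test, `[[`, "image"))
  expect_gt(max(abs(imgs[[1]]$data - imgs[[2]]$data)), 1)
  expect_gt(max(abs(imgs[[2]]$data - imgs[[3]]$data)), 1)
  # manifest roundtrip
  back <- read_cohort(dir)
  expect_length(back$train, 2)
  expect_length(back$test, 1)
  expect_equal(back$train[[1]]$image$data, co1$train[[1]]$image$data,
               tolerance = 1e-4)
  expect_identical(back$test[[1]]$truth$labels, co1$test[[1]]$truth$labels)
  expect_error(simulate_cohort(1, 1, p), ">= 2")
  expect_error(read_cohort(file.path(tempdir(), "missing_dir")), "manifest")
})

test_that("a full-size cohort generates within the time budget", {
  t0 <- proc.time()[3]
  co <- simulate_cohort(20, 35, default_params(), seed = 42)
  elapsed <- proc.time()[3] - t0
  expect_lt(elapsed, 120)
  expect_length(co$train, 20)
  expect_length(co$test, 35)
  ok <- vapply(c(co$train, co$test), function(s)
    all(c(1L, 2L) %in% s$truth$labels), TRUE)
  expect_true(all(ok))
})
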