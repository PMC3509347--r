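test_that("constructors enforce invariants", {
  expect_error(volume(array(1, c(2, 2, 2)), spacing = c(1, 0, 1)), "positive")
  expect_error(volume(matrix(1, 2, 2)), "3D")
  bad <- array(1, c(2, 2, 2)); bad[1] <- NaN
  expect_error(volume(bad), "NA")
  expect_error(labelmap(array(0.5, c(2, 2, 2))), "integer")
  expect_error(defield(array(0, c(2, 2, 2))), "nx, ny, nz, 3")
})

test_that("NIfTI roundtrip is float32-lossless for volumes, exact for labels", {
  v <- textured_volume(11, spacing = c(1, 1, 1.2))
  v$origin <- c(-5, 2, 0.5)
  path <- file.path(tempdir(), "v.nii.gz")
  write_volume(v, path)
  v2 <- read_volume(path)
  expect_lt(max(abs(v2$data - v$data)), 1e-5)        # float32 storage
  expect_equal(v2$spacing, v$spacing, tolerance = 1e-6)
  expect_equal(v2$origin, v$origin, tolerance = 1e-6)

  lm <- random_mask(10, 0.4)
  lm$labels[2, 3, 4] <- 2L
  lp <- file.path(tempdir(), "l.nii")
  write_volume(lm, lp)
  lm2 <- read_labels(lp)
  expect_identical(lm2$labels, lm$labels)             # exact voxel counts
  expect_identical(table(lm2$labels), table(lm$labels))
})

test_that("written NIfTI files are readable by an independent implementation", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  v <- textured_volume(7, spacing = c(0.9, 1, 1.1))
  path <- file.path(tempdir(), "oracle.nii.gz")
  write_volume(v, path)
  script <- paste0(
    "import nibabel as nib, numpy as np, sys\n",
    "img = nib.load(sys.argv[1])\n",
    "d = np.asanyarray(img.dataobj)\n",
    "print('x'.join(str(s) for s in d.shape), float(d.sum()),\n",
    "      ' '.join(str(z) for z in img.header.get_zooms()))\n")
  sf <- file.path(tempdir(), "check_nii.py")
  writeLines(script, sf)
  out <- system2("python", c(sf, path), stdout = TRUE, stderr = TRUE)
  skip_if(!is.null(attr(out, "status")), "nibabel unavailable")
  parts <- strsplit(out[length(out)], "\\s+")[[1]]
  expect_identical(parts[1], "7x7x7")
  expect_equal(as.numeric(parts[2]), sum(v$data), tolerance = 1e-4)
  expect_equal(as.numeric(parts[3:5]), c(0.9, 1, 1.1), tolerance = 1e-6)
})

test_that("label reading applies the integrality tolerance rule", {
  d <- array(0, c(3, 3, 3)); d[1, 1, 1] <- 1 + 1e-7
  p <- file.path(tempdir(), "near_int.nii")
  write_volume(volume(d), p)
  expect_warning(lm <- read_labels(p), "rounded")
  expect_identical(lm$labels[1, 1, 1], 1L)

  d[2, 2, 2] <- 0.5
  write_volume(volume(d), p)
  expect_error(read_labels(p), "0.5")
})

test_that("I/O errors are reported", {
  expect_error(read_volume(file.path(tempdir(), "nope.nii")), "not found")
  expect_error(write_volume(textured_volume(4),
                            file.path(tempdir(), "no_dir_here", "x.nii")),
               "directory")
})

test_that("resample subsamples by block averaging and restores by interpolation", {
  v <- textured_volume(8)
  expect_identical(resample(v, 1)$data, v$data)
  cv <- volume(array(3.25, c(8, 8, 8)))
  expect_equal(resample(cv, 2)$data, array(3.25, c(4, 4, 4)))
  sub <- resample(v, 2)
  expect_equal(dim(sub$data), c(4, 4, 4))
  expect_equal(sub$spacing, v$spacing * 2)
  expect_equal(sub$data, oracle_block_mean(v$data, 2), tolerance = 1e-12)
  # odd size: ceil(9/2) = 5 with partial edge blocks
  v9 <- textured_volume(9)
  expect_equal(resample(v9, 2)$data, oracle_block_mean(v9$data, 2),
               tolerance = 1e-12)
  rest <- resample(sub, 2, "restore", shape = c(8, 8, 8))
  expect_equal(dim(rest$data), c(8, 8, 8))
  expect_error(resample(v, 0), "positive")
})

test_that("gaussian smoothing matches a dense convolution oracle", {
  v <- textured_volume(9)
  expect_identical(gaussian_smooth(v, 0)$data, v$data)
  # impulse response on a 9^3 grid
  imp <- array(0, c(9, 9, 9)); imp[5, 5, 5] <- 1
  vi <- volume(imp)
  sm <- gaussian_smooth(vi, 1)
  expect_equal(sm$data, oracle_dense_gauss(imp, 1), tolerance = 1e-12)
  # intensity conservation for interior-supported blob
  blob <- array(0, c(15, 15, 15)); blob[7:9, 7:9, 7:9] <- 2.5
  sb <- gaussian_smooth(volume(blob), 1)
  expect_equal(sum(sb$data), sum(blob), tolerance = 1e-6 * sum(blob))
  # anisotropic spacing: sigma in mm converted through spacing
  va <- volume(imp, spacing = c(2, 1, 1))
  sma <- gaussian_smooth(va, c(2, 1, 1))
  expect_equal(sma$data, oracle_dense_gauss(imp, 1), tolerance = 1e-12)
  expect_error(gaussian_smooth(v, -1), "non-negative")
})

test_that("apply_deformation implements out(x) = in(x + disp(x))", {
  v <- textured_volume(8)
  z <- zero_field(c(8, 8, 8))
  expect_equal(apply_deformation(v, z)$data, v$data, tolerance = 1e-12)
  expect_equal(apply_deformation(v, z, "nearest")$data, v$data)

  # uniform +1 voxel shift along axis 1: out[i,,] = in[i+1,,]
  d <- zero_field(c(8, 8, 8)); d$disp[, , , 1] <- 1
  w <- apply_deformation(v, d)
  expect_equal(w$data[1:7, , ], v$data[2:8, , ], tolerance = 1e-12)
  expect_equal(w$data[8, , ], v$data[8, , ], tolerance = 1e-12)  # edge policy

  lm <- random_mask(8)
  expect_error(apply_deformation(lm, d, "trilinear"), "nearest")
  wl <- apply_deformation(lm, d, "nearest")
  expect_identical(wl$labels[1:7, , ], lm$labels[2:8, , ])
  expect_true(all(wl$labels[8, , ] == 0L))             # labels OOB -> background

  expect_error(apply_deformation(v, zero_field(c(7, 8, 8))), "match")
})

test_that("jacobian determinant has the closed-form values", {
  z <- zero_field(c(6, 6, 6))
  expect_equal(jacobian_determinant(z)$data, array(1, c(6, 6, 6)),
               tolerance = 1e-12)
  tshift <- zero_field(c(6, 6, 6)); tshift$disp[, , , 2] <- 1.7
  expect_equal(jacobian_determinant(tshift)$data, array(1, c(6, 6, 6)),
               tolerance = 1e-12)
  # disp(x) = 0.1 x per axis -> det = 1.1^3
  lin <- zero_field(c(7, 7, 7))
  lin$disp[, , , 1] <- 0.1 * array(rep(0:6, times = 49), c(7, 7, 7))
  lin$disp[, , , 2] <- 0.1 * array(rep(rep(0:6, each = 7), times = 7), c(7, 7, 7))
  lin$disp[, , , 3] <- 0.1 * array(rep(0:6, each = 49), c(7, 7, 7))
  jd <- jacobian_determinant(lin)$data
  expect_equal(jd[2:6, 2:6, 2:6], array(1.1^3, c(5, 5, 5)), tolerance = 1e-10)
})

test_that("field composition is inner-then-outer with translations adding", {
  set.seed(9)
  d <- defield(array(rnorm(6^3 * 3, sd = 0.3), c(6, 6, 6, 3)))
  z <- zero_field(c(6, 6, 6))
  expect_equal(compose_fields(z, d)$disp, d$disp, tolerance = 1e-12)
  expect_equal(compose_fields(d, z)$disp, d$disp, tolerance = 1e-12)
  a <- zero_field(c(6, 6, 6)); a$disp[, , , 1] <- 0.6
  b <- zero_field(c(6, 6, 6)); b$disp[, , , 1] <- 0.9; b$disp[, , , 3] <- -0.4
  ab <- compose_fields(a, b)
  expect_equal(ab$disp[, , , 1], array(1.5, c(6, 6, 6)), tolerance = 1e-12)
  expect_equal(ab$disp[, , , 3], array(-0.4, c(6, 6, 6)), tolerance = 1e-12)
})

test_that("warping via a composed field matches sequential warping", {
  p <- small_params(24)
  base <- make_base_phantom(p)
  sm <- gaussian_smooth(base$image, 3)      # smooth image, interpolation-friendly
  d1 <- random_diffeomorphism(p, 11, amplitude = 1.5)
  d2 <- random_diffeomorphism(p, 12, amplitude = 1.5)
  seq_w <- apply_deformation(apply_deformation(sm, d1), d2)
  comp_w <- apply_deformation(sm, compose_fields(d2, d1))
  # boundary voxels differ by edge-replication policy; compare the interior
  int <- 4:21
  err <- max(abs(seq_w$data[int, int, int] - comp_w$data[int, int, int]))
  expect_lt(err / diff(range(sm$data)), 0.02)
})
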