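#' @useDynLib amyseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif quantile sd
#' @importFrom utils write.csv
NULL

# ---- containers -------------------------------------------------------------

#' 3D scalar volume
#'
#' The image currency of the pipeline: a 3D array of intensities plus the
#' voxel size (mm) and the world coordinate of voxel (1,1,1). Voxel indices
#' are treated as canonical axis-aligned coordinates; world = origin +
#' (index - 1) * spacing. No orientation-code handling is attempted.
#'
#' @param data 3D numeric array.
#' @param spacing Per-axis voxel size in mm, strictly positive, length 3.
#' @param origin World coordinate of the first voxel, length 3.
#' @return An object of class `amy_volume`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as_array3(data)
  stopifnot(length(spacing) == 3, length(origin) == 3)
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  if (anyNA(data)) stop("volume data contains NA/NaN")
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "amy_volume")
}

#' Integer label map aligned with a volume
#'
#' Labels 0 (background), 1 (left structure), 2 (right structure) by
#' convention, but any non-negative integers are accepted.
#'
#' @param labels 3D integer-valued array.
#' @inheritParams volume
#' @return An object of class `amy_labelmap`.
#' @export
labelmap <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  labels <- as_array3(labels)
  if (anyNA(labels)) stop("label data contains NA")
  if (max(abs(labels - round(labels))) > 0)
    stop("label map must be integer-valued")
  stopifnot(length(spacing) == 3, length(origin) == 3)
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  structure(list(labels = array(as.integer(round(labels)), dim(labels)),
                 spacing = as.numeric(spacing), origin = as.numeric(origin)),
            class = "amy_labelmap")
}

#' Dense deformation field on a fixed grid
#'
#' Displacements are stored in voxel units of the fixed grid so that
#' composition and interpolation stay pure index arithmetic;
#' `apply_deformation()` resamples `input(x + disp(x))`.
#'
#' @param disp 4D array `[nx, ny, nz, 3]` of displacements (voxel units).
#' @inheritParams volume
#' @return An object of class `amy_defield`.
#' @export
defield <- function(disp, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  d <- dim(disp)
  if (length(d) != 4 || d[4] != 3) stop("disp must be [nx, ny, nz, 3]")
  if (anyNA(disp)) stop("deformation field contains NA")
  structure(list(disp = disp, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "amy_defield")
}

#' Zero deformation field on a given grid
#' @param dim Grid dimensions (length 3).
#' @inheritParams volume
#' @export
zero_field <- function(dim, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  defield(array(0, c(dim, 3)), spacing, origin)
}

as_array3 <- function(x) {
  if (is.null(dim(x))) stop("data must be a 3D array")
  if (length(dim(x)) != 3) stop("data must be a 3D array")
  if (any(dim(x) < 1)) stop("all dimensions must be >= 1")
  storage.mode(x) <- "double"
  x
}

grid_of <- function(v) {
  if (inherits(v, "amy_labelmap")) dim(v$labels)
  else if (inherits(v, "amy_defield")) dim(v$disp)[1:3]
  else dim(v$data)
}

values_of <- function(v) if (inherits(v, "amy_labelmap")) v$labels else v$data

is_labelmap <- function(v) inherits(v, "amy_labelmap")

#' @export
print.amy_volume <- function(x, ...) {
  cat(sprintf("<amy_volume %s, spacing %s mm, range [%.4g, %.4g]>\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.amy_labelmap <- function(x, ...) {
  tb <- table(x$labels)
  cat(sprintf("<amy_labelmap %s: %s>\n",
              paste(dim(x$labels), collapse = "x"),
              paste(sprintf("%s=%d", names(tb), as.integer(tb)), collapse = " ")))
  invisible(x)
}

# ---- NIfTI-1 I/O ------------------------------------------------------------
# Minimal single-file NIfTI-1 support (.nii / .nii.gz): float32 volumes,
# int16 labels, diagonal sform, canonical axis order. Enough for the
# synthetic cohorts and for interchange with standard neuroimaging tools.

nifti_dtypes <- list(`2` = list(what = "integer", size = 1, signed = FALSE),
                     `4` = list(what = "integer", size = 2, signed = TRUE),
                     `8` = list(what = "integer", size = 4, signed = TRUE),
                     `16` = list(what = "double", size = 4, signed = TRUE),
                     `64` = list(what = "double", size = 8, signed = TRUE),
                     `512` = list(what = "integer", size = 2, signed = FALSE))

open_nii <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

read_nifti_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- open_nii(path, "rb")
  on.exit(close(con))
  hdr_sz <- readBin(con, "integer", 1, 4, endian = "little")
  endian <- "little"
  if (hdr_sz != 348) {
    hdr_sz_sw <- readBin(writeBin(as.integer(hdr_sz), raw(), 4, endian = "swap"),
                         "integer", 1, 4)
    if (hdr_sz_sw == 348) endian <- "big"
    else stop("not a NIfTI-1 file (sizeof_hdr = ", hdr_sz, "): ", path)
  }
  readBin(con, "raw", 36)                       # unused header fields
  dims <- readBin(con, "integer", 8, 2, endian = endian)
  readBin(con, "raw", 14)                       # intent fields
  datatype <- readBin(con, "integer", 1, 2, endian = endian)
  readBin(con, "integer", 1, 2, endian = endian) # bitpix
  readBin(con, "integer", 1, 2, endian = endian) # slice_start
  pixdim <- readBin(con, "numeric", 8, 4, endian = endian)
  vox_offset <- readBin(con, "numeric", 1, 4, endian = endian)
  scl_slope <- readBin(con, "numeric", 1, 4, endian = endian)
  scl_inter <- readBin(con, "numeric", 1, 4, endian = endian)
  readBin(con, "raw", 120 - 112 - 8)            # slice_end..xyzt_units..
  readBin(con, "raw", 132)                      # through intent_name start
  # positions: we consumed 4+36+16+14+2+2+2+32+4+4+4 = 120 bytes, then 132 more
  # -> at byte 252 (qform_code)
  qform_code <- readBin(con, "integer", 1, 2, endian = endian)
  sform_code <- readBin(con, "integer", 1, 2, endian = endian)
  readBin(con, "numeric", 3, 4, endian = endian)  # quaternions
  qoffset <- readBin(con, "numeric", 3, 4, endian = endian)
  srow <- matrix(readBin(con, "numeric", 12, 4, endian = endian), 3, 4, byrow = TRUE)
  readBin(con, "raw", 16)                       # intent_name
  magic <- rawToChar(readBin(con, "raw", 4))
  if (!startsWith(magic, "n+1")) stop("unsupported NIfTI magic: ", magic)
  ndim <- dims[1]
  if (ndim < 3) stop("only 3D NIfTI images are supported")
  if (ndim > 3 && any(dims[5:(1 + ndim)] > 1))
    stop("only 3D NIfTI images are supported")
  shape <- dims[2:4]
  dt <- nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", datatype)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(shape)
  vals <- readBin(con, dt$what, n, dt$size, signed = dt$signed, endian = endian)
  if (length(vals) < n) stop("truncated NIfTI data in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  spacing <- abs(pixdim[2:4])
  spacing[spacing == 0] <- 1
  origin <- c(0, 0, 0)
  if (sform_code > 0) origin <- srow[, 4]
  else if (qform_code > 0) origin <- qoffset
  list(data = array(as.double(vals), shape), spacing = spacing, origin = origin)
}

#' Read a NIfTI-1 volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return An [volume()] object.
#' @export
read_volume <- function(path) {
  r <- read_nifti_raw(path)
  volume(r$data, r$spacing, r$origin)
}

#' Read a NIfTI-1 label map
#'
#' Values within `tol` of an integer are rounded (with a warning when the
#' deviation is nonzero); values further away raise an error naming them.
#'
#' @inheritParams read_volume
#' @param tol Integrality tolerance.
#' @return A [labelmap()] object.
#' @export
read_labels <- function(path, tol = 1e-6) {
  r <- read_nifti_raw(path)
  dev <- abs(r$data - round(r$data))
  if (max(dev) > tol) {
    bad <- unique(signif(r$data[dev > tol], 8))
    stop("non-integral label values beyond tolerance: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (max(dev) > 0)
    warning("label values rounded to nearest integer (max deviation ",
            signif(max(dev), 3), ")")
  labelmap(round(r$data), r$spacing, r$origin)
}

#' Write a volume or label map as single-file NIfTI-1
#'
#' Volumes are written as float32, label maps as int16; spacing and origin
#' go into pixdim and a diagonal sform.
#'
#' @param v An `amy_volume` or `amy_labelmap`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(v, path) {
  if (!dir.exists(dirname(path))) stop("directory does not exist: ", dirname(path))
  lab <- is_labelmap(v)
  dat <- values_of(v)
  shape <- dim(dat)
  con <- tryCatch(open_nii(path, "wb"), error = function(e)
    stop("cannot open for writing: ", path))
  ok <- FALSE
  on.exit({ close(con); if (!ok && file.exists(path)) unlink(path) })
  wi <- function(x, size) writeBin(as.integer(x), con, size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, 4, endian = "little")
  wi(348, 4)
  writeBin(raw(36), con)
  wi(c(3, shape, 1, 1, 1, 1), 2)               # dim[0..7]
  writeBin(raw(14), con)                        # intent_p1..3, intent_code
  wi(if (lab) 4 else 16, 2)                     # datatype
  wi(if (lab) 16 else 32, 2)                    # bitpix
  wi(0, 2)                                      # slice_start
  wf(c(1, v$spacing, 1, 1, 1, 1))               # pixdim
  wf(352)                                       # vox_offset
  wf(1); wf(0)                                  # scl_slope, scl_inter
  writeBin(raw(1 + 1 + 1 + 1), con)             # slice_end..xyzt_units
  wf(0); wf(0); wf(0); wf(0)                    # cal_max..toffset
  wi(0, 4); wi(0, 4)                            # glmax, glmin
  desc <- charToRaw("amyseg")
  writeBin(c(desc, raw(80 - length(desc))), con)
  writeBin(raw(24), con)                        # aux_file
  wi(0, 2); wi(1, 2)                            # qform_code, sform_code
  wf(c(0, 0, 0))                                # quaternions
  wf(v$origin)                                  # qoffsets
  sr <- cbind(diag(v$spacing), v$origin)
  wf(t(sr))                                     # srow_x, srow_y, srow_z
  writeBin(raw(16), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con) # magic
  writeBin(raw(4), con)                         # extension flag -> offset 352
  if (lab) {
    if (max(abs(dat)) > 32767) stop("label values exceed int16 range")
    writeBin(as.integer(dat), con, 2, endian = "little")
  } else {
    writeBin(as.numeric(dat), con, 4, endian = "little")
  }
  ok <- TRUE
  invisible(path)
}

# ---- grid operations --------------------------------------------------------

#' Resample a volume by an integer factor
#'
#' `subsample` block-averages into a grid of `ceiling(dim / factor)` voxels
#' (spacing multiplied by the factor); `restore` trilinearly interpolates
#' back onto a target shape. Block centres are aligned so that a
#' subsample-then-restore pair is spatially consistent.
#'
#' @param v An `amy_volume`.
#' @param factor Positive integer subsampling factor.
#' @param mode `"subsample"` or `"restore"`.
#' @param shape Target shape for `mode = "restore"`.
#' @return A new `amy_volume`.
#' @export
resample <- function(v, factor, mode = c("subsample", "restore"), shape = NULL) {
  mode <- match.arg(mode)
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1) stop("factor must be a positive integer")
  if (mode == "subsample") {
    if (factor == 1) return(v)
    out <- cpp_block_mean(v$data, factor)
    volume(out, v$spacing * factor, v$origin + (factor - 1) / 2 * v$spacing)
  } else {
    if (is.null(shape)) stop("restore mode needs a target shape")
    if (all(shape == dim(v$data)) && factor == 1) return(v)
    # fine voxel j maps to coarse coordinate (j - (f-1)/2) / f
    a <- rep(1 / factor, 3)
    b <- rep(-(factor - 1) / 2 / factor, 3)
    out <- cpp_resample_grid(v$data, as.integer(shape), a, b)
    volume(out, v$spacing / factor, v$origin - (factor - 1) / 2 * v$spacing / factor)
  }
}

#' Gaussian smoothing with physical sigma
#'
#' Separable convolution; `sigma_mm` is converted to voxel units through the
#' spacing. Boundaries are handled by edge replication, so total intensity
#' of an interior-supported blob is conserved.
#'
#' @param v An `amy_volume`.
#' @param sigma_mm Standard deviation in mm, scalar or per-axis.
#' @export
gaussian_smooth <- function(v, sigma_mm) {
  sigma_mm <- rep_len(as.numeric(sigma_mm), 3)
  if (any(sigma_mm < 0)) stop("sigma must be non-negative")
  if (all(sigma_mm == 0)) return(v)
  volume(cpp_gauss_smooth(v$data, sigma_mm / v$spacing), v$spacing, v$origin)
}

#' Warp an image through a deformation field
#'
#' `out(x) = in(x + disp(x))`. Label maps are always resampled with
#' nearest-neighbour (a request for trilinear is an error); out-of-bounds
#' samples take the background label 0 for label maps and the replicated
#' edge value for volumes.
#'
#' @param v An `amy_volume` or `amy_labelmap`.
#' @param d An `amy_defield` on the same (fixed/output) grid.
#' @param interp `"trilinear"` or `"nearest"`.
#' @export
apply_deformation <- function(v, d, interp = c("trilinear", "nearest")) {
  interp <- match.arg(interp)
  if (!identical(as.integer(grid_of(v)), as.integer(grid_of(d))))
    stop("deformation field grid does not match image grid")
  if (is_labelmap(v)) {
    if (interp == "trilinear")
      stop("label maps must be warped with nearest-neighbour interpolation")
    out <- cpp_warp(array(as.double(v$labels), dim(v$labels)), d$disp,
                    TRUE, FALSE, 0)
    labelmap(out, v$spacing, v$origin)
  } else {
    out <- cpp_warp(v$data, d$disp, interp == "nearest", TRUE, 0)
    volume(out, v$spacing, v$origin)
  }
}

#' Jacobian determinant of a deformation field
#'
#' Determinant of the map `x -> x + disp(x)` from central differences
#' (one-sided at the boundary). Strictly positive everywhere means the
#' discrete map is locally invertible, the guarantee "diffeomorphic"
#' promises.
#'
#' @param d An `amy_defield`.
#' @return An `amy_volume` of determinant values.
#' @export
jacobian_determinant <- function(d) {
  dm <- grid_of(d)
  if (any(dm < 3)) stop("grid must have at least 3 voxels per axis")
  volume(cpp_jacobian(d$disp, as.integer(dm)), d$spacing, d$origin)
}

#' Compose two deformation fields
#'
#' `compose(outer, inner)` is inner-then-outer in resampling semantics:
#' warping by the result equals warping by `inner` and then resampling the
#' warped image through `outer`:
#' `disp(x) = disp_outer(x) + disp_inner(x + disp_outer(x))`.
#'
#' @param outer,inner `amy_defield`s on the same grid.
#' @export
compose_fields <- function(outer, inner) {
  if (!identical(as.integer(grid_of(outer)), as.integer(grid_of(inner))))
    stop("deformation fields are on different grids")
  defield(cpp_compose(outer$disp, inner$disp, as.integer(grid_of(outer))),
          outer$spacing, outer$origin)
}
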