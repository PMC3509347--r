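# Shared fixtures and independent oracles. Fixtures are generated in code
# (seeded) and cached for the duration of the test session.

.fix <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fix[[key]])) assign(key, force(expr), envir = .fix)
  .fix[[key]]
}

default_params <- function() phantom_params()

small_params <- function(shape = 32) phantom_params(shape = rep(shape, 3))

base_default <- function() cached("base48", make_base_phantom(default_params()))

# a small deterministic test volume with texture
textured_volume <- function(n = 9, seed = 4, spacing = c(1, 1, 1)) {
  set.seed(seed)
  volume(array(rnorm(n^3), rep(n, 3)), spacing)
}

random_mask <- function(n = 8, p = 0.3, seed = 1) {
  set.seed(seed)
  labelmap(array(as.integer(runif(n^3) < p), rep(n, 3)))
}

# ---- oracles ---------------------------------------------------------------

# explicit-loop block averaging
oracle_block_mean <- function(arr, f) {
  d <- dim(arr)
  od <- ceiling(d / f)
  out <- array(0, od)
  for (k in seq_len(od[3])) for (j in seq_len(od[2])) for (i in seq_len(od[1])) {
    xs <- ((i - 1) * f + 1):min(i * f, d[1])
    ys <- ((j - 1) * f + 1):min(j * f, d[2])
    zs <- ((k - 1) * f + 1):min(k * f, d[3])
    out[i, j, k] <- mean(arr[xs, ys, zs])
  }
  out
}

# dense 3D Gaussian convolution with edge replication
oracle_dense_gauss <- function(arr, sigma) {
  d <- dim(arr)
  r <- ceiling(4 * sigma)
  k1 <- exp(-0.5 * (-r:r)^2 / sigma^2)
  k1 <- k1 / sum(k1)
  out <- array(0, d)
  cl <- function(v, n) pmin(pmax(v, 1), n)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    acc <- 0
    for (dz in -r:r) for (dy in -r:r) for (dx in -r:r)
      acc <- acc + k1[dx + r + 1] * k1[dy + r + 1] * k1[dz + r + 1] *
        arr[cl(i + dx, d[1]), cl(j + dy, d[2]), cl(k + dz, d[3])]
    out[i, j, k] <- acc
  }
  out
}

# per-voxel patch SSD by explicit loops (clipped cube)
oracle_patch_ssd <- function(a, b, r) {
  d <- dim(a)
  out <- array(0, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    xs <- max(1, i - r):min(d[1], i + r)
    ys <- max(1, j - r):min(d[2], j + r)
    zs <- max(1, k - r):min(d[3], k + r)
    out[i, j, k] <- sum((a[xs, ys, zs] - b[xs, ys, zs])^2)
  }
  out
}

# morphological dilation with a Euclidean ball, explicit loops
oracle_dilate <- function(mask, radius_mm, spacing) {
  d <- dim(mask)
  out <- array(FALSE, d)
  r <- floor(radius_mm / spacing)
  on <- which(mask != 0, arr.ind = TRUE)
  for (q in seq_len(nrow(on))) {
    for (dz in -r[3]:r[3]) for (dy in -r[2]:r[2]) for (dx in -r[1]:r[1]) {
      if (sqrt((dx * spacing[1])^2 + (dy * spacing[2])^2 +
               (dz * spacing[3])^2) > radius_mm + 1e-9) next
      i <- on[q, 1] + dx; j <- on[q, 2] + dy; k <- on[q, 3] + dz
      if (i >= 1 && j >= 1 && k >= 1 && i <= d[1] && j <= d[2] && k <= d[3])
        out[i, j, k] <- TRUE
    }
  }
  out
}

# two-way ANOVA mean squares via stats::aov (independent of package code)
oracle_icc <- function(ratings, kind) {
  n <- nrow(ratings); k <- ncol(ratings)
  df <- data.frame(y = as.vector(ratings),
                   subj = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  av <- summary(stats::aov(y ~ subj + rater, data = df))[[1]]
  msr <- av["subj", "Mean Sq"]
  msc <- av["rater", "Mean Sq"]
  mse <- av["Residuals", "Mean Sq"]
  denom <- msr + (k - 1) * mse
  if (kind == "absolute") denom <- denom + k / n * (msc - mse)
  (msr - mse) / denom
}

# counting-based overlap oracles
oracle_dice <- function(A, B) {
  if (sum(A) + sum(B) == 0) return(1)
  2 * sum(A & B) / (sum(A) + sum(B))
}
oracle_jaccard <- function(A, B) {
  if (sum(A | B) == 0) return(1)
  sum(A & B) / sum(A | B)
}

make_lm <- function(arr, spacing = c(1, 1, 1)) labelmap(arr, spacing)
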