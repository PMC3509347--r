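test_that("dice and jaccard match direct counting", {
  a <- array(0L, c(4, 4, 4)); b <- array(0L, c(4, 4, 4))
  a[1:4, 1, 1] <- 1L                       # |A| = 4
  b[2:4, 1, 1] <- 1L; b[1, 2, 1] <- 1L     # |B| = 4, |A n B| = 3
  la <- make_lm(a); lb <- make_lm(b)
  expect_equal(dice(la, lb, 1), 0.75)      # 2*3/8
  expect_equal(jaccard(la, lb, 1), 0.6)    # 3/5
  expect_equal(dice(la, la, 1), 1)
  expect_equal(jaccard(la, la, 1), 1)
  dis <- make_lm(array(c(1L, rep(0L, 63)), c(4, 4, 4)))
  dis2 <- make_lm(array(c(0L, 1L, rep(0L, 62)), c(4, 4, 4)))
  expect_equal(dice(dis, dis2, 1), 0)
  # empty-vs-empty convention
  z <- make_lm(array(0L, c(4, 4, 4)))
  expect_equal(dice(z, z, 1), 1)
  expect_equal(jaccard(z, z, 1), 1)
  expect_error(dice(la, make_lm(array(0L, c(5, 4, 4))), 1), "grids")
})

test_that("overlap metrics are symmetric and satisfy J = D/(2-D)", {
  for (s in 1:60) {
    A <- random_mask(6, runif(1, 0.1, 0.6), seed = s)
    B <- random_mask(6, runif(1, 0.1, 0.6), seed = s + 1000)
    d <- dice(A, B, 1); j <- jaccard(A, B, 1)
    expect_equal(d, dice(B, A, 1))
    expect_equal(j, jaccard(B, A, 1))
    expect_lt(abs(j - d / (2 - d)), 1e-12)
    expect_equal(d, oracle_dice(A$labels == 1, B$labels == 1))
    expect_equal(j, oracle_jaccard(A$labels == 1, B$labels == 1))
  }
})

test_that("pearson matches stats::cor and handles degenerate input", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson(x, 2 * x + 1), 1)
  expect_equal(pearson(x, -x), -1)
  y <- c(1, 2, 3, 10)
  expect_equal(pearson(x, y), stats::cor(x, y), tolerance = 1e-12)
  set.seed(99)
  for (i in 1:50) {
    a <- rnorm(7); b <- rnorm(7)
    expect_equal(pearson(a, b), stats::cor(a, b), tolerance = 1e-10)
  }
  expect_error(pearson(x, rep(1, 4)), "variance")
  expect_error(pearson(1:2, 1:2), "n >= 3")
})

test_that("ICC matches a two-way ANOVA oracle", {
  r1 <- c(3, 5, 9, 2, 7)
  tab <- cbind(r1, r1)
  expect_equal(icc(tab, "consistency"), 1)
  expect_equal(icc(tab, "absolute"), 1)
  shifted <- cbind(r1, r1 + 2)
  expect_equal(icc(shifted, "consistency"), 1, tolerance = 1e-12)
  expect_lt(icc(shifted, "absolute"), 1)
  expect_equal(icc(shifted, "absolute"), oracle_icc(shifted, "absolute"),
               tolerance = 1e-10)
  tab4 <- cbind(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(icc(tab4, "consistency"), oracle_icc(tab4, "consistency"),
               tolerance = 1e-10)
  expect_equal(icc(tab4, "absolute"), oracle_icc(tab4, "absolute"),
               tolerance = 1e-10)
  set.seed(12)
  for (i in 1:40) {
    tt <- matrix(rnorm(2 * sample(4:12, 1)), ncol = 2)
    expect_equal(icc(tt, "consistency"), oracle_icc(tt, "consistency"),
                 tolerance = 1e-10)
    expect_equal(icc(tt, "absolute"), oracle_icc(tt, "absolute"),
                 tolerance = 1e-10)
  }
})

test_that("consistency ICC dominates absolute ICC when raters disagree systematically", {
  set.seed(5)
  for (i in 1:25) {
    base <- rnorm(8, 100, 10)
    tt <- cbind(base + rnorm(8), base + rnorm(8) + runif(1, 0, 5))
    n <- nrow(tt); k <- 2
    gm <- mean(tt)
    msc <- n * sum((colMeans(tt) - gm)^2) / (k - 1)
    msr <- k * sum((rowMeans(tt) - gm)^2) / (n - 1)
    mse <- (sum((tt - gm)^2) - (n - 1) * msr - (k - 1) * msc) / ((n - 1) * (k - 1))
    if (msc >= mse) {
      expect_gte(icc(tt, "consistency"), icc(tt, "absolute") - 1e-12)
    } else {
      # MSC < MSE: the shift term is negative and the order may reverse
      expect_lt(abs(icc(tt, "absolute") - oracle_icc(tt, "absolute")), 1e-10)
    }
  }
})

test_that("cohort evaluation assembles rows and summaries correctly", {
  set.seed(71)
  mk_case <- function(seed, spacing = c(1, 1, 1.2)) {
    arr <- array(0L, c(10, 10, 10))
    arr[sample(500, 40 + 5 * (seed %% 7))] <- 1L      # varying volumes
    arr[500 + sample(400, 30 + 4 * (seed %% 5))] <- 2L
    labelmap(arr, spacing)
  }
  ref <- lapply(1:5, mk_case)
  names(ref) <- paste0("s", 1:5)
  rep_id <- evaluate_cohort(ref, ref)
  expect_true(all(rep_id$rows$dice == 1))
  expect_true(all(rep_id$rows$jaccard == 1))
  expect_equal(rep_id$cohort$left$pearson_r, 1)
  expect_equal(rep_id$cohort$left$icc_consistency, 1)
  expect_equal(rep_id$cohort$right$icc_absolute, 1)
  # volume = count x voxel volume
  one <- array(0L, c(10, 10, 10)); one[1:100] <- 1L
  lo <- labelmap(one, c(1, 1, 1.2))
  r1 <- evaluate_cohort(list(a = lo, b = lo, c = lo), list(a = lo, b = lo, c = lo))
  expect_equal(r1$rows$auto_volume_mm3[r1$rows$structure == "left"],
               rep(120, 3))
  # row identity for perturbed cohorts
  auto <- lapply(1:5, function(i) mk_case(i + 50))
  names(auto) <- paste0("s", 1:5)
  rp <- evaluate_cohort(auto, ref)
  expect_true(all(abs(rp$rows$jaccard - rp$rows$dice / (2 - rp$rows$dice))
                  < 1e-12))
  names(auto)[2] <- "zz"
  expect_error(evaluate_cohort(auto, ref), "zz")
})

test_that("report writers emit CSV and JSON", {
  arr <- array(0L, c(6, 6, 6)); arr[1:20] <- 1L; arr[30:45] <- 2L
  lm <- labelmap(arr)
  rp <- evaluate_cohort(list(a = lm, b = lm, c = lm),
                        list(a = lm, b = lm, c = lm))
  csv <- file.path(tempdir(), "rep.csv"); js <- file.path(tempdir(), "rep.json")
  write_metrics(rp, csv, js)
  back <- read.csv(csv)
  expect_equal(nrow(back), 6)
  expect_true(all(c("dice", "jaccard", "auto_volume_mm3") %in% names(back)))
  j <- jsonlite::read_json(js)
  expect_length(j$rows, 6)
})
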