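# Segmentation agreement battery: spatial overlap (Dice, Jaccard), volume
# agreement (Pearson r, two-way single-measures ICCs) and cohort reporting.

check_same_grid <- function(a, b) {
  if (!identical(as.integer(grid_of(a)), as.integer(grid_of(b))))
    stop("label maps are on different grids")
}

#' Dice overlap coefficient
#'
#' `2|A n B| / (|A| + |B|)` over voxels carrying `label`. When both masks
#' are empty the coefficient is defined as 1 (perfect agreement on
#' absence); this situation does not arise for real anatomy.
#'
#' @param a,b `amy_labelmap`s on the same grid.
#' @param label Label value compared (default 1).
#' @export
dice <- function(a, b, label = 1L) {
  check_same_grid(a, b)
  A <- a$labels == label; B <- b$labels == label
  sa <- sum(A); sb <- sum(B)
  if (sa + sb == 0) return(1)
  2 * sum(A & B) / (sa + sb)
}

#' Jaccard overlap coefficient
#'
#' `|A n B| / |A u B|`; 1 when both masks are empty. Related to Dice by
#' `J = D / (2 - D)`.
#'
#' @inheritParams dice
#' @export
jaccard <- function(a, b, label = 1L) {
  check_same_grid(a, b)
  A <- a$labels == label; B <- b$labels == label
  u <- sum(A | B)
  if (u == 0) return(1)
  sum(A & B) / u
}

#' Pearson correlation between two volume series
#'
#' Plain sample correlation computed from sums (no dependency on
#' `stats::cor`, which serves as the independent oracle in the tests).
#'
#' @param x,y Numeric vectors, length >= 3.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) stop("need matched n >= 3")
  xd <- x - mean(x); yd <- y - mean(y)
  vx <- sum(xd^2); vy <- sum(yd^2)
  if (vx == 0 || vy == 0) stop("zero variance in input")
  sum(xd * yd) / sqrt(vx * vy)
}

#' Intraclass correlation (two-way, single measures)
#'
#' McGraw-Wong forms for an n subjects x k raters table:
#' consistency ICC(C,1) = (MSR - MSE) / (MSR + (k-1) MSE);
#' absolute agreement ICC(A,1) =
#' (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE)),
#' with MSR/MSC/MSE the rows/columns/error mean squares of the two-way
#' ANOVA. Consistency ignores systematic rater offsets, absolute agreement
#' penalizes them.
#'
#' @param ratings n x k numeric matrix (k = 2 raters typically).
#' @param kind `"consistency"` or `"absolute"`.
#' @export
icc <- function(ratings, kind = c("consistency", "absolute")) {
  kind <- match.arg(kind)
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 3 || k < 2) stop("need >= 3 subjects and >= 2 raters")
  gm <- mean(ratings)
  rm <- rowMeans(ratings); cm <- colMeans(ratings)
  ssr <- k * sum((rm - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sst <- sum((ratings - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse
  if (kind == "absolute") denom <- denom + k / n * (msc - mse)
  if (abs(denom) < 1e-300) stop("degenerate ratings table (zero denominator)")
  (msr - mse) / denom
}

#' Evaluate a segmented cohort against reference segmentations
#'
#' Computes per subject and per structure Dice, Jaccard and volumes (mm^3,
#' voxel count x voxel volume), plus cohort-level Pearson r and both ICCs
#' of automated vs reference volumes for each structure.
#'
#' @param auto,reference Named lists of `amy_labelmap`s; names are subject
#'   ids and must match.
#' @param labels Structure labels, default `c(left = 1, right = 2)`.
#' @return A `metrics_report`: list with `rows` (data.frame) and `cohort`
#'   (per-structure summary list).
#' @export
evaluate_cohort <- function(auto, reference, labels = c(left = 1, right = 2)) {
  if (is.null(names(auto))) names(auto) <- paste0("s", seq_along(auto))
  if (is.null(names(reference))) names(reference) <- paste0("s", seq_along(reference))
  miss <- c(setdiff(names(auto), names(reference)),
            setdiff(names(reference), names(auto)))
  if (length(miss)) stop("unmatched subject ids: ", paste(miss, collapse = ", "))
  ids <- names(auto)
  rows <- do.call(rbind, lapply(ids, function(id) {
    a <- auto[[id]]; r <- reference[[id]]
    vv <- prod(a$spacing)
    do.call(rbind, lapply(seq_along(labels), function(li) {
      lb <- labels[li]
      data.frame(id = id, structure = names(labels)[li],
                 dice = dice(a, r, lb), jaccard = jaccard(a, r, lb),
                 auto_volume_mm3 = sum(a$labels == lb) * vv,
                 reference_volume_mm3 = sum(r$labels == lb) * prod(r$spacing),
                 stringsAsFactors = FALSE)
    }))
  }))
  cohort <- lapply(names(labels), function(st) {
    sub <- rows[rows$structure == st, ]
    vols <- cbind(sub$reference_volume_mm3, sub$auto_volume_mm3)
    smry <- list(mean_dice = mean(sub$dice), sd_dice = sd(sub$dice),
                 mean_jaccard = mean(sub$jaccard), sd_jaccard = sd(sub$jaccard))
    if (nrow(sub) >= 3 && sd(vols[, 1]) > 0 && sd(vols[, 2]) > 0) {
      smry$pearson_r <- pearson(vols[, 1], vols[, 2])
      smry$icc_consistency <- icc(vols, "consistency")
      smry$icc_absolute <- icc(vols, "absolute")
    }
    smry
  })
  names(cohort) <- names(labels)
  structure(list(rows = rows, cohort = cohort), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Segmentation agreement report\n")
  for (st in names(x$cohort)) {
    co <- x$cohort[[st]]
    cat(sprintf("  %-6s Dice %.3f +- %.3f  Jaccard %.3f +- %.3f",
                st, co$mean_dice, co$sd_dice, co$mean_jaccard, co$sd_jaccard))
    if (!is.null(co$pearson_r))
      cat(sprintf("  r %.3f  ICC(C) %.3f  ICC(A) %.3f",
                  co$pearson_r, co$icc_consistency, co$icc_absolute))
    cat("\n")
  }
  invisible(x)
}

#' Write a metrics report to CSV (rows) and JSON (rows + cohort summary)
#' @param report A `metrics_report`.
#' @param csv,json Output paths (either may be `NULL`).
#' @export
write_metrics <- function(report, csv = NULL, json = NULL) {
  if (!is.null(csv)) write.csv(report$rows, csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(list(rows = report$rows, cohort = report$cohort),
                         json, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(report)
}
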