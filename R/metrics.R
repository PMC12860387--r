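#' Pearson correlation coefficient
#'
#' Standard Pearson formula. Constant input vectors make the correlation
#' undefined and raise an error rather than returning `NA` silently.
#'
#' @param x,y equal-length numeric vectors (length >= 2).
#' @return correlation in `[-1, 1]`.
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y)) stop_arg("length mismatch")
  if (length(x) < 2) stop_arg("need at least 2 elements")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_arg("correlation undefined for a constant vector")
  stats::cor(x, y)
}

#' Global-statistics structural similarity
#'
#' SSIM computed from the global means, variances and covariance of the two
#' maps (no sliding window), the dialect appropriate for spatial expression
#' maps scaled per gene to `[0, 1]`:
#' `((2 mu_a mu_b + C1) (2 cov + C2)) / ((mu_a^2 + mu_b^2 + C1) (var_a + var_b + C2))`.
#' Default constants are the standard `C1 = 0.01^2`, `C2 = 0.03^2` for unit
#' dynamic range. Variances and the covariance use the population (1/n)
#' convention.
#'
#' @param a,b equal-shape numeric vectors/matrices, pre-scaled to `[0, 1]`.
#' @param C1,C2 stabilising constants.
#' @return similarity value in `(-1, 1]`.
#' @export
ssim <- function(a, b, C1 = 0.01^2, C2 = 0.03^2) {
  if (!all(dim(as.matrix(a)) == dim(as.matrix(b)))) stop_arg("shape mismatch")
  a <- as.numeric(a); b <- as.numeric(b)
  n <- length(a)
  mua <- mean(a); mub <- mean(b)
  va <- sum((a - mua)^2) / n
  vb <- sum((b - mub)^2) / n
  cab <- sum((a - mua) * (b - mub)) / n
  ((2 * mua * mub + C1) * (2 * cab + C2)) /
    ((mua^2 + mub^2 + C1) * (va + vb + C2))
}

#' Root mean squared error
#'
#' @param x,y equal-length numeric vectors.
#' @return `sqrt(mean((x - y)^2))`.
#' @export
rmse <- function(x, y) {
  if (length(x) == 0) stop_arg("empty input")
  if (length(x) != length(y)) stop_arg("length mismatch")
  sqrt(mean((x - y)^2))
}

#' Rasterise per-spot values onto the coordinate grid
#'
#' Spots are snapped to the integer lattice implied by their coordinates
#' (grid pitch = smallest positive coordinate gap per axis). Occupied cells
#' map one-to-one to spots; unoccupied cells are `NA` and excluded from any
#' downstream statistics.
#'
#' @param values numeric per-spot vector.
#' @param coords a [spot_coords] data.frame.
#' @return matrix (rows = y lattice, cols = x lattice) with `NA` holes.
#' @export
rasterize_spots <- function(values, coords) {
  if (length(values) != nrow(coords)) stop_arg("length mismatch")
  snap <- function(v) {
    u <- sort(unique(v))
    pitch <- if (length(u) > 1) min(diff(u)) else 1
    round((v - min(v)) / pitch) + 1L
  }
  ix <- snap(coords$x); iy <- snap(coords$y)
  key <- paste(iy, ix)
  if (anyDuplicated(key)) stop_arg("two spots snapped to the same lattice cell")
  grid <- matrix(NA_real_, max(iy), max(ix))
  grid[cbind(iy, ix)] <- values
  grid
}

#' Metric report over concatenated fold predictions
#'
#' Predictions from all folds are concatenated and the metrics are computed
#' once on the aggregate (never averaged over folds): Pearson correlation and
#' RMSE per spot across columns, then averaged; SSIM per gene/type on
#' max-normalised spatial maps, then averaged. Spots whose true row is
#' constant have no defined correlation and are excluded from the PCC mean
#' (their count is reported).
#'
#' @param predictions a matrix, or a list of per-fold matrices whose row
#'   names (spot ids) jointly cover every spot of `truth` exactly once.
#' @param truth matrix of true values (proportions or expression), spot ids
#'   as row names.
#' @param coords optional [spot_coords] for the SSIM rasterisation; without
#'   coordinates SSIM is computed on the per-gene vectors directly.
#' @return object of class `metric_report`: `pcc_mean`, `ssim_mean`, `rmse`,
#'   per-spot and per-column breakdowns, `n_undefined_pcc`.
#' @export
evaluate_folds <- function(predictions, truth, coords = NULL) {
  truth <- as.matrix(unclass(truth))
  if (is.list(predictions) && !is.matrix(predictions)) {
    pred <- do.call(rbind, lapply(predictions, function(p) as.matrix(unclass(p))))
  } else pred <- as.matrix(unclass(predictions))
  if (is.null(rownames(pred)) || is.null(rownames(truth)))
    stop_arg("predictions and truth need spot ids as row names")
  if (anyDuplicated(rownames(pred)))
    stop_arg("duplicate spot across folds: ",
             rownames(pred)[duplicated(rownames(pred))][1])
  missing <- setdiff(rownames(truth), rownames(pred))
  if (length(missing) > 0)
    stop_arg("spots missing from predictions: ", paste(head(missing, 3), collapse = ", "))
  pred <- pred[rownames(truth), , drop = FALSE]
  n_spots <- nrow(truth)
  per_spot_pcc <- rep(NA_real_, n_spots)
  per_spot_rmse <- numeric(n_spots)
  for (i in seq_len(n_spots)) {
    ti <- truth[i, ]; pi <- pred[i, ]
    per_spot_rmse[i] <- rmse(ti, pi)
    if (stats::sd(ti) > 0 && stats::sd(pi) > 0)
      per_spot_pcc[i] <- stats::cor(ti, pi)
  }
  # per-gene/type SSIM on max-normalised maps
  per_col_ssim <- numeric(ncol(truth))
  for (j in seq_len(ncol(truth))) {
    tj <- truth[, j]; pj <- pred[, j]
    mt <- max(tj); mp <- max(pj)
    tj <- if (mt > 0) tj / mt else tj
    pj <- if (mp > 0) pj / mp else pj
    if (!is.null(coords)) {
      gt <- rasterize_spots(tj, coords); gp <- rasterize_spots(pj, coords)
      occ <- !is.na(gt)
      per_col_ssim[j] <- ssim(gt[occ], gp[occ])
    } else {
      per_col_ssim[j] <- ssim(tj, pj)
    }
  }
  structure(list(
    pcc_mean = mean(per_spot_pcc, na.rm = TRUE),
    ssim_mean = mean(per_col_ssim),
    rmse = mean(per_spot_rmse),
    per_spot_pcc = per_spot_pcc,
    per_spot_rmse = per_spot_rmse,
    per_col_ssim = per_col_ssim,
    n_undefined_pcc = sum(is.na(per_spot_pcc))
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("metric_report: PCC %.4f | SSIM %.4f | RMSE %.4f (%d spots, %d undefined PCC)\n",
              x$pcc_mean, x$ssim_mean, x$rmse,
              length(x$per_spot_rmse), x$n_undefined_pcc))
  invisible(x)
}
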