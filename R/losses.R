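#' Deconvolution loss (categorical cross-entropy over proportion rows)
#'
#' `-sum_i sum_j y_ij log(yhat_ij)`, summed over spots and cell types (not
#' averaged). Predicted probabilities are clamped at `1e-12` before the log;
#' terms with `y_ij = 0` contribute zero (the usual `0 log 0 = 0`
#' convention), so a one-hot prediction equal to a one-hot truth scores
#' exactly zero. Negative predictions are a numeric-guard error.
#'
#' @param y true proportions (rows on the simplex).
#' @param yhat predicted proportions (non-negative rows).
#' @return non-negative scalar.
#' @export
loss_deconv <- function(y, yhat) {
  y <- as.matrix(unclass(y)); yhat <- as.matrix(unclass(yhat))
  if (!all(dim(y) == dim(yhat))) stop_arg("shape mismatch")
  if (any(yhat < 0))
    stop_arg("predicted proportions must be non-negative ",
             "(zeros are clamped at 1e-12 before the log)")
  -sum(y * log(pmax(yhat, 1e-12)))
}

#' Auxiliary pathology classification loss (categorical cross-entropy)
#'
#' Identical form to [loss_deconv()], applied to one-hot pathology labels and
#' predicted class probabilities.
#'
#' @param y one-hot labels.
#' @param yhat predicted class probabilities.
#' @return non-negative scalar.
#' @export
loss_hist <- function(y, yhat) loss_deconv(unclass(y), yhat)

#' Reconstruction loss (squared error)
#'
#' `sum_ij (target_ij - recon_ij)^2` under `"sum"` reduction; `"mean"`
#' divides by the number of entries (the default used during training, for
#' scale stability across batch sizes).
#'
#' @param target,recon spots x genes matrices.
#' @param reduction `"mean"` or `"sum"`.
#' @return non-negative scalar.
#' @export
loss_recon <- function(target, recon, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  target <- as.matrix(target); recon <- as.matrix(recon)
  if (!all(dim(target) == dim(recon))) stop_arg("shape mismatch")
  s <- sum((target - recon)^2)
  if (reduction == "mean") s / length(target) else s
}

#' Domain matching loss (binary cross-entropy)
#'
#' `-(1/R) * (sum_i log p_real_i + sum_j log(1 - p_simu_j))` with
#' `R = length(real_probs) + length(simu_probs)`: real spots carry domain
#' indicator 1, simulated spots 0, and both terms sit under a single `1/R`
#' average. Probabilities are clamped to `[1e-12, 1 - 1e-12]`.
#'
#' @param real_probs discriminator probabilities on real-domain rows.
#' @param simu_probs discriminator probabilities on simulated-domain rows.
#' @return non-negative scalar.
#' @export
loss_match <- function(real_probs, simu_probs) {
  if (any(c(real_probs, simu_probs) < 0 | c(real_probs, simu_probs) > 1))
    stop_arg("probabilities must lie in [0, 1]")
  pr <- clamp_prob(real_probs)
  ps <- clamp_prob(simu_probs)
  R <- length(pr) + length(ps)
  -(sum(log(pr)) + sum(log(1 - ps))) / R
}

#' Loss weight bundle
#' @param lambda1,lambda2,lambda3 non-negative weights of the pathology,
#'   reconstruction and domain-matching terms.
#' @return list of class `loss_weights`.
#' @export
loss_weights <- function(lambda1 = 0.1, lambda2 = 0.1, lambda3 = 0.01) {
  if (any(c(lambda1, lambda2, lambda3) < 0)) stop_arg("lambdas must be >= 0")
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3),
            class = "loss_weights")
}

#' Total training objective
#'
#' `L_deconv + lambda1 * L_hist + lambda2 * L_recon + lambda3 * L_match`.
#'
#' @param components list (or named vector) with elements `deconv`, `hist`,
#'   `recon`, `match`.
#' @param w a [loss_weights()].
#' @return scalar total loss.
#' @export
total_loss <- function(components, w) {
  stopifnot(inherits(w, "loss_weights"))
  components <- as.list(components)
  components$deconv + w$lambda1 * components$hist +
    w$lambda2 * components$recon + w$lambda3 * components$match
}
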