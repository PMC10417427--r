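# Soft Tversky index and Focal Tversky loss. The Tversky index generalizes
# Dice (alpha = beta = 0.5) and Jaccard (alpha = beta = 1) by weighting
# false positives (alpha) and false negatives (beta) separately; the focal
# exponent gamma < 1 sharpens the gradient as the index approaches 1,
# keeping pressure on hard, small foreground regions.

#' Tversky loss configuration
#'
#' @param alpha false-positive weight (>= 0).
#' @param beta false-negative weight (>= 0); `alpha + beta` must be
#'   positive. Defaults 0.7/0.3 penalize false positives harder, favoring
#'   recall of small foreground structures.
#' @param gamma focal exponent (> 0); 1 recovers the plain Tversky loss.
#' @param smooth additive smoothing of numerator and denominator.
#' @return A `tversky_config` object.
#' @export
tversky_config <- function(alpha = 0.7, beta = 0.3, gamma = 0.75,
                           smooth = 1e-6) {
  stopifnot(alpha >= 0, beta >= 0, alpha + beta > 0, gamma > 0, smooth > 0)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, smooth = smooth),
            class = "tversky_config")
}

#' Soft Tversky index
#'
#' `TI = (sum(p*g) + s) / (sum(p*g) + alpha*sum(p*(1-g)) +
#' beta*sum((1-p)*g) + s)` for foreground probabilities p and a binary
#' target g.
#'
#' @param pred_probs numeric array of foreground probabilities in [0, 1].
#' @param target binary array (same shape).
#' @param cfg a [tversky_config()].
#' @return Scalar index in [0, 1].
#' @export
soft_tversky_index <- function(pred_probs, target, cfg = tversky_config()) {
  p <- as.numeric(pred_probs)
  g <- as.numeric(target != 0)
  if (length(p) != length(g) ||
      (!is.null(dim(pred_probs)) && !is.null(dim(target)) &&
       !identical(dim(pred_probs), dim(target)))) {
    stop("pred and target shapes differ")
  }
  tp <- sum(p * g)
  fp <- sum(p * (1 - g))
  fn <- sum((1 - p) * g)
  (tp + cfg$smooth) / (tp + cfg$alpha * fp + cfg$beta * fn + cfg$smooth)
}

#' Focal Tversky loss
#'
#' `loss = (1 - TI)^gamma`; gamma = 1 reduces to the Tversky loss and a
#' perfect prediction gives 0 (up to smoothing).
#'
#' @inheritParams soft_tversky_index
#' @return Scalar loss in [0, 1].
#' @export
focal_tversky_loss <- function(pred_probs, target, cfg = tversky_config()) {
  ti <- soft_tversky_index(pred_probs, target, cfg)
  (1 - ti)^cfg$gamma
}

# gradient of the focal Tversky loss wrt the foreground probabilities;
# used by the training loop.
focal_tversky_grad <- function(pred_probs, target, cfg = tversky_config()) {
  p <- as.numeric(pred_probs)
  g <- as.numeric(target != 0)
  tp <- sum(p * g)
  fp <- sum(p * (1 - g))
  fn <- sum((1 - p) * g)
  num <- tp + cfg$smooth
  den <- tp + cfg$alpha * fp + cfg$beta * fn + cfg$smooth
  ti <- num / den
  # dTI/dp_i = (g_i * den - num * (g_i + alpha*(1-g_i) - beta*g_i)) / den^2
  dden <- g + cfg$alpha * (1 - g) - cfg$beta * g
  dti <- (g * den - num * dden) / den^2
  dl <- if (cfg$gamma == 1) -dti else
    -cfg$gamma * (max(1 - ti, 1e-12))^(cfg$gamma - 1) * dti
  array(dl, dim = if (is.null(dim(pred_probs))) length(p) else dim(pred_probs))
}
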