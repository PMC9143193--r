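#' Trade-off weights of the generator objective
#'
#' The generator minimizes
#' `lambda1 * L_adv + lambda2 * L_con + lambda3 * L_per + lambda4 * L_att`;
#' the defaults (1, 100, 1000, 1) are the published setting.
#'
#' @param lambda1,lambda2,lambda3,lambda4 non-negative scalars.
#' @return list of class `hazegan_weights`.
#' @export
loss_weights <- function(lambda1 = 1, lambda2 = 100, lambda3 = 1000,
                         lambda4 = 1) {
  w <- c(lambda1, lambda2, lambda3, lambda4)
  if (any(!is.finite(w)) || any(w < 0))
    stop("loss weights must be finite and non-negative")
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 lambda4 = lambda4), class = "hazegan_weights")
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  invisible(TRUE)
}

#' L1 content loss
#'
#' Mean absolute difference over all channels and pixels (and the batch,
#' batches being averaged arithmetically).
#'
#' @param pred,target equally shaped arrays.
#' @return scalar.
#' @export
content_loss <- function(pred, target) {
  check_same_shape(pred, target)
  mean(abs(target - pred))
}

content_loss_grad <- function(pred, target) {
  sign(pred - target) / length(pred)
}

#' Perceptual loss in a frozen feature space
#'
#' Squared L2 distance between the tapped feature maps of `pred` and
#' `target`, normalized by the spatial extent `Wf * Hf` of the feature map
#' only (no channel normalization), averaged over the batch.
#'
#' @param pred,target image batches.
#' @param fx a [feature_extractor()].
#' @return scalar.
#' @export
perceptual_loss <- function(pred, target, fx) {
  check_same_shape(as_batch(pred), as_batch(target))
  fp <- fx_forward(fx, as_batch(pred))$feat
  ft <- fx_forward(fx, as_batch(target))$feat
  d <- dim(fp)
  sum((ft - fp)^2) / (d[1L] * d[2L]) / d[4L]
}

# loss + gradient wrt pred in one pass (shares the forward caches);
# `target_feat` allows reuse of precomputed target features.
perceptual_loss_with_grad <- function(pred, target, fx, target_feat = NULL) {
  fwd <- fx_forward(fx, pred, keep_cache = TRUE)
  ft <- if (is.null(target_feat)) fx_forward(fx, target)$feat else target_feat
  d <- dim(fwd$feat)
  diff <- fwd$feat - ft
  loss <- sum(diff^2) / (d[1L] * d[2L]) / d[4L]
  gfeat <- 2 * diff / (d[1L] * d[2L]) / d[4L]
  list(loss = loss, grad = fx_backward(fx, fwd$cache, gfeat))
}

#' Multi-level attention loss
#'
#' Sum over the five levels of the squared L2 norm of the difference
#' between predicted and target attention maps. As printed the sum is not
#' normalized by map size (making its scale resolution-dependent);
#' `normalize = TRUE` divides each level by its cell count instead.
#' Batches are averaged arithmetically.
#'
#' @param predicted,target lists of five equally shaped arrays.
#' @param normalize divide each level by its number of cells.
#' @return scalar.
#' @export
attention_loss <- function(predicted, target, normalize = FALSE) {
  if (length(predicted) != 5L || length(target) != 5L)
    stop("attention stacks must have exactly 5 levels")
  total <- 0
  for (l in 1:5) {
    a <- as_batch(predicted[[l]])
    m <- as_batch(target[[l]])
    check_same_shape(a, m)
    s <- sum((a - m)^2) / dim(a)[4L]
    if (normalize) s <- s / prod(dim(a)[1:3])
    total <- total + s
  }
  total
}

attention_loss_grad <- function(predicted, target, normalize = FALSE) {
  lapply(1:5, function(l) {
    a <- as_batch(predicted[[l]])
    m <- as_batch(target[[l]])
    g <- 2 * (a - m) / dim(a)[4L]
    if (normalize) g <- g / prod(dim(a)[1:3])
    g
  })
}

check_scores <- function(s) {
  if (any(s <= 0) || any(s >= 1))
    stop("discriminator scores must lie strictly in (0, 1)")
  invisible(TRUE)
}

#' Adversarial loss of the generator
#'
#' The saturating form `E[log(1 - D(x, G(x)))]`, minimized as the
#' discriminator score of the generated pair approaches 1. The
#' non-saturating alternative `-E[log D]` (which gives stronger gradients
#' early in training) is available via `saturating = FALSE`; the default
#' is the printed saturating form.
#'
#' @param d_scores discriminator scores on generated pairs, in (0, 1).
#' @param saturating use the `log(1 - D)` form.
#' @return scalar.
#' @export
adversarial_loss_g <- function(d_scores, saturating = TRUE) {
  check_scores(d_scores)
  if (saturating) mean(log(1 - d_scores)) else -mean(log(d_scores))
}

adversarial_loss_g_grad <- function(d_scores, saturating = TRUE) {
  if (saturating) -1 / ((1 - d_scores) * length(d_scores))
  else -1 / (d_scores * length(d_scores))
}

#' Discriminator loss
#'
#' The negation of `E[log D(x, y)] + E[log(1 - D(x, G(x)))]` so that the
#' trainer minimizes it; the optimum (real scores at 1, fake scores at 0)
#' has loss 0.
#'
#' @param real_scores,fake_scores score vectors in (0, 1).
#' @return scalar.
#' @export
discriminator_loss <- function(real_scores, fake_scores) {
  check_scores(real_scores)
  check_scores(fake_scores)
  -(mean(log(real_scores)) + mean(log(1 - fake_scores)))
}

discriminator_loss_grads <- function(real_scores, fake_scores) {
  list(real = -1 / (real_scores * length(real_scores)),
       fake = 1 / ((1 - fake_scores) * length(fake_scores)))
}

#' Weighted total generator loss
#'
#' @param parts list or vector with components `adv`, `con`, `per`, `att`.
#' @param weights a [loss_weights()].
#' @return scalar.
#' @export
total_generator_loss <- function(parts, weights = loss_weights()) {
  weights$lambda1 * parts[["adv"]] + weights$lambda2 * parts[["con"]] +
    weights$lambda3 * parts[["per"]] + weights$lambda4 * parts[["att"]]
}
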