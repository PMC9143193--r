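#' Frozen convolutional feature extractor for the perceptual loss
#'
#' The perceptual loss compares images in the feature space of a frozen
#' VGG19-layout network tapped at the fourth convolution of the fifth block
#' (the conventional reading of the index pair \{5, 4\}). Two modes exist:
#'
#' * `"pretrained"` — classic ImageNet-pretrained VGG19 features. No weight
#'   file ships with this package, so constructing this mode stops with an
#'   error directing the caller to `"random_seeded"`.
#' * `"random_seeded"` — the same layout with He-initialized random weights
#'   under a fixed seed, frozen. Random convolutional features are a valid
#'   perceptual basis (they preserve multi-scale image structure through
#'   random projections) and make the whole pipeline runnable with zero
#'   downloads. He initialization (not the 0.02-std Gaussian used for the
#'   trainable networks) keeps activation magnitudes stable across the 16
#'   convolutions up to the tap point.
#'
#' `width_mult` scales all channel widths; scaled-down profiles use a thin
#' extractor. The network is never updated: no gradient ever reaches its
#' weights, only the input-gradient is back-propagated.
#'
#' @param mode `"pretrained"` or `"random_seeded"`.
#' @param seed seed for the random mode.
#' @param width_mult multiplier on the VGG19 channel widths (64, 128, 256,
#'   512, 512).
#' @param tap `c(block, conv)` tap point; default block 5, conv 4.
#' @return list of class `hazegan_fx` with `weights`, `layout`, `tap`.
#' @export
feature_extractor <- function(mode = c("pretrained", "random_seeded"),
                              seed = 1L, width_mult = 1,
                              tap = c(block = 5L, conv = 4L)) {
  mode <- match.arg(mode)
  if (mode == "pretrained")
    stop("no pretrained VGG19 weights are available in this installation; ",
         "construct the extractor with mode = \"random_seeded\" instead")
  conv_per_block <- c(2L, 2L, 4L, 4L, 4L)
  widths <- pmax(1L, as.integer(round(c(64, 128, 256, 512, 512) * width_mult)))
  tb <- as.integer(tap[[1L]]); tc <- as.integer(tap[[2L]])
  stopifnot(tb >= 1L, tb <= 5L, tc >= 1L, tc <= conv_per_block[tb])
  with_seed(seed, {
    w <- list()
    cin <- 3L
    for (b in seq_len(tb)) {
      nconv <- if (b == tb) tc else conv_per_block[b]
      for (k in seq_len(nconv)) {
        cout <- widths[b]
        sd <- sqrt(2 / (9 * cin))  # He init for 3x3 kernels
        w[[paste0("b", b, ".c", k)]] <- init_w(c(3, 3, cin, cout), sd = sd)
        cin <- cout
      }
    }
    structure(list(weights = w, conv_per_block = conv_per_block,
                   tap = c(block = tb, conv = tc), mode = mode,
                   width_mult = width_mult),
              class = "hazegan_fx")
  })
}

#' Forward pass of the frozen extractor
#'
#' Convolutions are 3x3 with unit stride and padding, each followed by a
#' ReLU; 2x2 max-pooling separates the blocks. The returned feature map is
#' the post-activation output of the tap convolution.
#'
#' @param fx extractor from [feature_extractor()].
#' @param x image batch (H, W, 3, N); sides must be divisible by
#'   `2^(tap_block - 1)`.
#' @param keep_cache keep activations for [fx_backward()].
#' @return list with `feat` (Hf, Wf, Cf, N) and `cache`.
#' @export
fx_forward <- function(fx, x, keep_cache = FALSE) {
  x <- as_batch(x)
  tb <- fx$tap[["block"]]; tc <- fx$tap[["conv"]]
  caches <- list()
  i <- 0L
  for (b in seq_len(tb)) {
    nconv <- if (b == tb) tc else fx$conv_per_block[b]
    for (k in seq_len(nconv)) {
      i <- i + 1L
      w <- fx$weights[[paste0("b", b, ".c", k)]]
      a <- conv_fwd(x, w, NULL, pad = 1L)
      if (keep_cache) caches[[i]] <- list(x = x, a = a, w = w, type = "conv")
      x <- relu_fwd(a)
    }
    if (b < tb) {
      mp <- maxpool2_fwd(x)
      i <- i + 1L
      if (keep_cache) caches[[i]] <- list(idx = mp$idx, H = dim(x)[1L],
                                          W = dim(x)[2L], type = "pool")
      x <- mp$y
    }
  }
  list(feat = x, cache = if (keep_cache) caches else NULL)
}

#' Gradient of the extractor output with respect to its input
#'
#' The weights are frozen, so only the input gradient is computed.
#'
#' @param fx extractor.
#' @param cache cache from [fx_forward()].
#' @param gfeat gradient wrt the tapped feature map.
#' @return gradient array shaped like the extractor input.
#' @export
fx_backward <- function(fx, cache, gfeat) {
  g <- gfeat
  for (i in rev(seq_along(cache))) {
    ca <- cache[[i]]
    if (ca$type == "pool") {
      g <- maxpool2_bwd(g, ca$idx, ca$H, ca$W)
    } else {
      g <- relu_bwd(g, ca$a)
      g <- conv_bwd(ca$x, ca$w, g, pad = 1L, want_gb = FALSE,
                    want_gw = FALSE)$gx
    }
  }
  g
}
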