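#' Discriminator configuration
#'
#' The conditional discriminator consumes the channel concatenation of the
#' noisy input and a candidate (real clean or generated) image — 6 channels
#' in total — and returns a single score in (0, 1) per pair. Its body is an
#' ordinary CNN: four stride-2 convolution blocks with channel widths
#' `base_channels * (1, 2, 4, 8)`, LeakyReLU(0.2) activations and batch
#' normalization on all blocks but the first, then a 3x3 convolution to one
#' channel, a global spatial average and a sigmoid.
#'
#' @param in_channels input channels (6 = noisy 3 + candidate 3).
#' @param base_channels width of the first block (64; scaled-down profiles
#'   use less).
#' @return list of class `hazegan_dconfig`.
#' @export
discriminator_config <- function(in_channels = 6L, base_channels = 64L) {
  structure(list(in_channels = as.integer(in_channels),
                 base_channels = as.integer(base_channels)),
            class = "hazegan_dconfig")
}

#' Construct a discriminator with freshly initialized weights
#' @param config a [discriminator_config()].
#' @param seed integer seed for the Gaussian(0, 0.02) initialization.
#' @return list with `params`, `buffers`, `config`.
#' @export
discriminator_init <- function(config = discriminator_config(), seed = 1L) {
  with_seed(seed, {
    p <- list()
    bf <- list()
    b <- config$base_channels
    widths <- c(config$in_channels, b, 2L * b, 4L * b, 8L * b)
    for (l in 1:4) {
      p[[paste0("d", l, ".W")]] <- init_w(c(4, 4, widths[l], widths[l + 1L]))
      p[[paste0("d", l, ".b")]] <- numeric(widths[l + 1L])
      if (l > 1L) {
        p[[paste0("d", l, ".bn.g")]] <- rep(1, widths[l + 1L])
        p[[paste0("d", l, ".bn.b")]] <- numeric(widths[l + 1L])
        bf[[paste0("d", l, ".bn.mean")]] <- numeric(widths[l + 1L])
        bf[[paste0("d", l, ".bn.var")]] <- rep(1, widths[l + 1L])
      }
    }
    p[["head.W"]] <- init_w(c(3, 3, widths[5L], 1))
    p[["head.b"]] <- numeric(1)
    structure(list(params = p, buffers = bf, config = config),
              class = "hazegan_discriminator")
  })
}

#' Discriminator forward pass
#'
#' @param d discriminator.
#' @param noisy,candidate two (H, W, 3, N) batches (or single 3-D images) of
#'   equal shape; they are concatenated along the channel axis.
#' @param train use batch statistics (TRUE) or running statistics (FALSE).
#' @param keep_cache keep activations for [discriminator_backward()].
#' @return list with `scores` (length-N vector in (0, 1)), `cache`,
#'   `buffers`.
#' @export
discriminator_forward <- function(d, noisy, candidate, train = FALSE,
                                  keep_cache = train) {
  noisy <- as_batch(noisy)
  candidate <- as_batch(candidate)
  if (!identical(dim(noisy), dim(candidate)))
    stop("noisy and candidate shapes differ")
  x <- cat_ch(noisy, candidate)
  p <- d$params
  bf <- d$buffers
  caches <- list()
  for (l in 1:4) {
    a <- conv_fwd(x, p[[paste0("d", l, ".W")]], p[[paste0("d", l, ".b")]],
                  stride = 2L, pad = 1L)
    r <- lrelu_fwd(a)
    if (l > 1L) {
      bn <- bn_fwd(r, p[[paste0("d", l, ".bn.g")]], p[[paste0("d", l, ".bn.b")]],
                   rs = list(mean = bf[[paste0("d", l, ".bn.mean")]],
                             var = bf[[paste0("d", l, ".bn.var")]]),
                   train = train)
      bf[[paste0("d", l, ".bn.mean")]] <- bn$rs$mean
      bf[[paste0("d", l, ".bn.var")]] <- bn$rs$var
      out <- bn$y
      bncache <- bn$cache
    } else {
      out <- r
      bncache <- NULL
    }
    caches[[l]] <- list(x = x, a = a, bn = bncache)
    x <- out
  }
  h <- conv_fwd(x, p[["head.W"]], p[["head.b"]], pad = 1L)
  hw <- prod(dim(h)[1:2])
  logits <- apply(h, 4L, sum) / hw
  scores <- sigmoid_fwd(logits)
  cache <- if (keep_cache)
    list(blocks = caches, head_in = x, hdim = dim(h), scores = scores)
  else NULL
  list(scores = scores, cache = cache, buffers = bf)
}

#' Discriminator backward pass
#'
#' @param d discriminator.
#' @param cache cache from a `keep_cache = TRUE` forward pass.
#' @param gscores gradient wrt the output scores (length N).
#' @param want_gx also return the gradient wrt the 6-channel input (needed
#'   to train the generator through the adversarial term).
#' @return list with `grads` and (optionally) `gx` (H, W, 6, N).
#' @export
discriminator_backward <- function(d, cache, gscores, want_gx = FALSE) {
  p <- d$params
  glogit <- gscores * cache$scores * (1 - cache$scores)
  hd <- cache$hdim
  hw <- prod(hd[1:2])
  gh <- array(rep(glogit / hw, each = hw), dim = hd)
  grads <- list()
  hb <- conv_bwd(cache$head_in, p[["head.W"]], gh, pad = 1L)
  grads[["head.W"]] <- hb$gw
  grads[["head.b"]] <- hb$gb
  gx <- hb$gx
  for (l in 4:1) {
    ca <- cache$blocks[[l]]
    if (l > 1L) {
      bb <- bn_bwd(gx, ca$bn)
      grads[[paste0("d", l, ".bn.g")]] <- bb$ggamma
      grads[[paste0("d", l, ".bn.b")]] <- bb$gbeta
      gr <- bb$gx
    } else gr <- gx
    ga <- lrelu_bwd(gr, ca$a)
    cb <- conv_bwd(ca$x, p[[paste0("d", l, ".W")]], ga, stride = 2L, pad = 1L,
                   want_gx = (l > 1L) || want_gx)
    grads[[paste0("d", l, ".W")]] <- cb$gw
    grads[[paste0("d", l, ".b")]] <- cb$gb
    gx <- cb$gx
  }
  list(grads = grads, gx = if (want_gx) gx else NULL)
}
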