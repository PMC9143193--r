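#' Generator configuration
#'
#' The denoising generator is a five-level U-Net. Each encoder level applies
#' two groups of 3x3 convolution + ReLU + batch normalization; levels are
#' separated by 2x2 max-pooling, channel width doubling at each deeper level
#' from `base_channels`. A single spatial-attention module (one shared 7x7
#' convolution over the channel-wise max/avg pooled maps, followed by a
#' sigmoid) gates every encoder output before it is passed to the decoder;
#' the same weights serve all five levels, so the attention mechanism adds
#' exactly `attn_kernel^2 * 2` trainable parameters. The decoder mirrors the
#' encoder with bilinear up-sampling + 3x3 convolution (halving channels),
#' concatenation with the attended skip features, and two convolution
#' groups; a final linear 1x1 convolution produces the output image.
#'
#' @param levels number of resolution levels (5).
#' @param base_channels channel width of the first level (paper setting 32).
#' @param in_channels,out_channels image channels (3; grayscale inputs are
#'   replicated at the I/O boundary).
#' @param attn_kernel side of the shared attention convolution kernel (7).
#' @return a list of class `hazegan_gconfig`.
#' @export
generator_config <- function(levels = 5L, base_channels = 32L,
                             in_channels = 3L, out_channels = 3L,
                             attn_kernel = 7L) {
  stopifnot(levels >= 2L, base_channels >= 1L, attn_kernel %% 2L == 1L)
  structure(list(levels = as.integer(levels),
                 base_channels = as.integer(base_channels),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 attn_kernel = as.integer(attn_kernel)),
            class = "hazegan_gconfig")
}

# Zero-mean Gaussian weight init, std 0.02 (conditional-GAN convention).
init_w <- function(dims, sd = 0.02) array(stats::rnorm(prod(dims), 0, sd), dims)

enc_channels <- function(config, l) config$base_channels * 2L^(l - 1L)

#' Construct a generator with freshly initialized weights
#'
#' @param config a [generator_config()].
#' @param seed integer seed controlling the weight initialization.
#' @return list with `params` (named weight arrays), `buffers` (batch-norm
#'   running statistics) and `config`.
#' @export
generator_init <- function(config = generator_config(), seed = 1L) {
  with_seed(seed, {
    p <- list()
    bf <- list()
    L <- config$levels
    for (l in seq_len(L)) {
      cin <- if (l == 1L) config$in_channels else enc_channels(config, l - 1L)
      cout <- enc_channels(config, l)
      p[[paste0("enc", l, ".c1.W")]] <- init_w(c(3, 3, cin, cout))
      p[[paste0("enc", l, ".c1.b")]] <- numeric(cout)
      p[[paste0("enc", l, ".bn1.g")]] <- rep(1, cout)
      p[[paste0("enc", l, ".bn1.b")]] <- numeric(cout)
      p[[paste0("enc", l, ".c2.W")]] <- init_w(c(3, 3, cout, cout))
      p[[paste0("enc", l, ".c2.b")]] <- numeric(cout)
      p[[paste0("enc", l, ".bn2.g")]] <- rep(1, cout)
      p[[paste0("enc", l, ".bn2.b")]] <- numeric(cout)
      for (j in 1:2) {
        bf[[paste0("enc", l, ".bn", j, ".mean")]] <- numeric(cout)
        bf[[paste0("enc", l, ".bn", j, ".var")]] <- rep(1, cout)
      }
    }
    # shared spatial-attention convolution: 2 pooled channels -> 1, no bias
    k <- config$attn_kernel
    p[["attn.W"]] <- init_w(c(k, k, 2, 1))
    for (l in seq_len(L - 1L)) {
      cup_in <- enc_channels(config, l + 1L)
      cup_out <- enc_channels(config, l)
      p[[paste0("up", l, ".W")]] <- init_w(c(3, 3, cup_in, cup_out))
      p[[paste0("up", l, ".b")]] <- numeric(cup_out)
      cc_in <- 2L * cup_out
      p[[paste0("dec", l, ".c1.W")]] <- init_w(c(3, 3, cc_in, cup_out))
      p[[paste0("dec", l, ".c1.b")]] <- numeric(cup_out)
      p[[paste0("dec", l, ".bn1.g")]] <- rep(1, cup_out)
      p[[paste0("dec", l, ".bn1.b")]] <- numeric(cup_out)
      p[[paste0("dec", l, ".c2.W")]] <- init_w(c(3, 3, cup_out, cup_out))
      p[[paste0("dec", l, ".c2.b")]] <- numeric(cup_out)
      p[[paste0("dec", l, ".bn2.g")]] <- rep(1, cup_out)
      p[[paste0("dec", l, ".bn2.b")]] <- numeric(cup_out)
      for (j in 1:2) {
        bf[[paste0("dec", l, ".bn", j, ".mean")]] <- numeric(cup_out)
        bf[[paste0("dec", l, ".bn", j, ".var")]] <- rep(1, cup_out)
      }
    }
    p[["out.W"]] <- init_w(c(1, 1, config$base_channels, config$out_channels))
    p[["out.b"]] <- numeric(config$out_channels)
    structure(list(params = p, buffers = bf, config = config),
              class = "hazegan_generator")
  })
}

#' Trainable parameters contributed by the attention mechanism
#'
#' The five attention modules share one bias-free convolution mapping the
#' two channel-pooled maps to one attention map, so the count is
#' `kernel^2 * 2` (98 for the default 7x7 kernel) regardless of how many
#' levels reuse it.
#'
#' @param config a [generator_config()].
#' @return integer parameter count.
#' @export
attention_param_count <- function(config = generator_config()) {
  as.integer(config$attn_kernel^2 * 2L)
}

#' Total trainable parameter count of a model
#' @param model a generator or discriminator object.
#' @return integer.
#' @export
n_params <- function(model) sum(vapply(model$params, length, integer(1)))

#' Apply the spatial-attention gate to a feature map
#'
#' Channel-wise max-pooling and average-pooling reduce the features to two
#' single-channel maps; their concatenation passes through the shared
#' convolution and a sigmoid to give the attention map `Ms`, which then
#' re-weights every channel of the input.
#'
#' @param f feature array (H, W, C) or batch (H, W, C, N).
#' @param w attention convolution weights, dim (k, k, 2, 1).
#' @return list with `f_out` (gated features) and `ms` (attention map),
#'   shaped like the input.
#' @export
spatial_attention <- function(f, w) {
  squeeze <- length(dim(f)) == 3L
  x <- as_batch(f)
  k <- dim(w)[1L]
  cp <- chanpool_fwd(x)
  s <- conv_fwd(cat_ch(cp$mp, cp$ap), w, NULL, pad = (k - 1L) / 2L)
  ms <- sigmoid_fwd(s)
  out <- gate_mul(x, ms)
  if (squeeze) {
    dim(out) <- dim(out)[1:3]
    dim(ms) <- dim(ms)[1:3]
  }
  list(f_out = out, ms = ms)
}

check_gen_input <- function(x, config) {
  d <- dim(x)
  div <- 2L^(config$levels - 1L)
  if (d[1L] %% div != 0L || d[2L] %% div != 0L)
    stop("input sides must be divisible by ", div, ", got ",
         d[1L], "x", d[2L])
  if (d[3L] != config$in_channels)
    stop("expected ", config$in_channels, " channels, got ", d[3L])
  invisible(TRUE)
}

# One encoder/decoder convolution group pair: conv3x3 -> ReLU -> BN, twice.
block_fwd <- function(x, p, bf, id, train) {
  a1 <- conv_fwd(x, p[[paste0(id, ".c1.W")]], p[[paste0(id, ".c1.b")]], pad = 1L)
  r1 <- relu_fwd(a1)
  b1 <- bn_fwd(r1, p[[paste0(id, ".bn1.g")]], p[[paste0(id, ".bn1.b")]],
               rs = list(mean = bf[[paste0(id, ".bn1.mean")]],
                         var = bf[[paste0(id, ".bn1.var")]]),
               train = train)
  a2 <- conv_fwd(b1$y, p[[paste0(id, ".c2.W")]], p[[paste0(id, ".c2.b")]], pad = 1L)
  r2 <- relu_fwd(a2)
  b2 <- bn_fwd(r2, p[[paste0(id, ".bn2.g")]], p[[paste0(id, ".bn2.b")]],
               rs = list(mean = bf[[paste0(id, ".bn2.mean")]],
                         var = bf[[paste0(id, ".bn2.var")]]),
               train = train)
  list(out = b2$y,
       cache = list(x = x, a1 = a1, bn1 = b1$cache, n1 = b1$y, a2 = a2,
                    bn2 = b2$cache, id = id),
       rs1 = b1$rs, rs2 = b2$rs)
}

block_bwd <- function(gout, cache, p, grads) {
  id <- cache$id
  g2 <- bn_bwd(gout, cache$bn2)
  grads[[paste0(id, ".bn2.g")]] <- grads[[paste0(id, ".bn2.g")]] %+0% g2$ggamma
  grads[[paste0(id, ".bn2.b")]] <- grads[[paste0(id, ".bn2.b")]] %+0% g2$gbeta
  ga2 <- relu_bwd(g2$gx, cache$a2)
  c2 <- conv_bwd(cache$n1, p[[paste0(id, ".c2.W")]], ga2, pad = 1L)
  grads[[paste0(id, ".c2.W")]] <- grads[[paste0(id, ".c2.W")]] %+0% c2$gw
  grads[[paste0(id, ".c2.b")]] <- grads[[paste0(id, ".c2.b")]] %+0% c2$gb
  g1 <- bn_bwd(c2$gx, cache$bn1)
  grads[[paste0(id, ".bn1.g")]] <- grads[[paste0(id, ".bn1.g")]] %+0% g1$ggamma
  grads[[paste0(id, ".bn1.b")]] <- grads[[paste0(id, ".bn1.b")]] %+0% g1$gbeta
  ga1 <- relu_bwd(g1$gx, cache$a1)
  c1 <- conv_bwd(cache$x, p[[paste0(id, ".c1.W")]], ga1, pad = 1L)
  grads[[paste0(id, ".c1.W")]] <- grads[[paste0(id, ".c1.W")]] %+0% c1$gw
  grads[[paste0(id, ".c1.b")]] <- grads[[paste0(id, ".c1.b")]] %+0% c1$gb
  list(gx = c1$gx, grads = grads)
}

# accumulate-with-NULL helper
`%+0%` <- function(a, b) if (is.null(a)) b else a + b

#' Generator forward pass
#'
#' @param g a generator from [generator_init()].
#' @param x input batch, array (H, W, 3, N) with values in \[0, 1\]
#'   (2-D/3-D inputs are promoted to a batch of one).
#' @param train logical; `TRUE` uses batch statistics in the normalization
#'   layers and updates the running statistics, `FALSE` (inference) uses the
#'   stored running statistics.
#' @param keep_cache keep the intermediate activations needed by
#'   [generator_backward()].
#' @return list with `denoised` (same shape as `x`, unclipped), `attn`
#'   (five attention maps, level sides halving from the input side),
#'   `cache` and the updated `buffers`.
#' @export
generator_forward <- function(g, x, train = FALSE, keep_cache = train) {
  x <- as_batch(x)
  check_gen_input(x, g$config)
  p <- g$params
  bf <- g$buffers
  L <- g$config$levels
  k <- g$config$attn_kernel
  kp <- (k - 1L) / 2L

  enc_cache <- vector("list", L)
  attn_cache <- vector("list", L)
  pool_cache <- vector("list", L - 1L)
  eatt <- vector("list", L)
  attn_maps <- vector("list", L)
  inp <- x
  for (l in seq_len(L)) {
    blk <- block_fwd(inp, p, bf, paste0("enc", l), train)
    bf[[paste0("enc", l, ".bn1.mean")]] <- blk$rs1$mean
    bf[[paste0("enc", l, ".bn1.var")]] <- blk$rs1$var
    bf[[paste0("enc", l, ".bn2.mean")]] <- blk$rs2$mean
    bf[[paste0("enc", l, ".bn2.var")]] <- blk$rs2$var
    e <- blk$out
    cp <- chanpool_fwd(e)
    cat2 <- cat_ch(cp$mp, cp$ap)
    s <- conv_fwd(cat2, p[["attn.W"]], NULL, pad = kp)
    ms <- sigmoid_fwd(s)
    eatt[[l]] <- gate_mul(e, ms)
    attn_maps[[l]] <- ms
    if (keep_cache) {
      enc_cache[[l]] <- blk$cache
      attn_cache[[l]] <- list(e = e, idx = cp$idx, cat2 = cat2, ms = ms,
                              C = dim(e)[3L])
    }
    if (l < L) {
      mp <- maxpool2_fwd(e)
      if (keep_cache) pool_cache[[l]] <- list(idx = mp$idx, H = dim(e)[1L],
                                              W = dim(e)[2L])
      inp <- mp$y
    }
  }

  dec_cache <- vector("list", L - 1L)
  d <- eatt[[L]]
  for (l in rev(seq_len(L - 1L))) {
    hs <- dim(eatt[[l]])[1L]
    ws <- dim(eatt[[l]])[2L]
    u <- bilinear_fwd(d, hs, ws)
    u2 <- conv_fwd(u, p[[paste0("up", l, ".W")]], p[[paste0("up", l, ".b")]],
                   pad = 1L)
    cc <- cat_ch(eatt[[l]], u2)
    blk <- block_fwd(cc, p, bf, paste0("dec", l), train)
    bf[[paste0("dec", l, ".bn1.mean")]] <- blk$rs1$mean
    bf[[paste0("dec", l, ".bn1.var")]] <- blk$rs1$var
    bf[[paste0("dec", l, ".bn2.mean")]] <- blk$rs2$mean
    bf[[paste0("dec", l, ".bn2.var")]] <- blk$rs2$var
    if (keep_cache)
      dec_cache[[l]] <- list(u = u, block = blk$cache,
                             c_skip = dim(eatt[[l]])[3L],
                             h_prev = dim(d)[1L], w_prev = dim(d)[2L])
    d <- blk$out
  }
  y <- conv_fwd(d, p[["out.W"]], p[["out.b"]], pad = 0L)

  cache <- if (keep_cache)
    list(enc = enc_cache, attn = attn_cache, pool = pool_cache,
         dec = dec_cache, d1 = d)
  else NULL
  list(denoised = y, attn = attn_maps, cache = cache, buffers = bf)
}

#' Generator backward pass
#'
#' Back-propagates a gradient with respect to the denoised output and
#' (optionally) gradients with respect to the five predicted attention maps
#' through the whole network, accumulating the shared attention-convolution
#' gradient across all levels.
#'
#' @param g generator.
#' @param cache cache from [generator_forward()] with `keep_cache = TRUE`.
#' @param gy gradient wrt the denoised output (H, W, 3, N).
#' @param gattn optional list of five gradients wrt the attention maps.
#' @return named list of parameter gradients.
#' @export
generator_backward <- function(g, cache, gy, gattn = NULL) {
  p <- g$params
  L <- g$config$levels
  k <- g$config$attn_kernel
  kp <- (k - 1L) / 2L
  grads <- list()

  ob <- conv_bwd(cache$d1, p[["out.W"]], gy, pad = 0L)
  grads[["out.W"]] <- ob$gw
  grads[["out.b"]] <- ob$gb
  gd <- ob$gx

  g_eatt <- vector("list", L)
  for (l in seq_len(L - 1L)) {
    dc <- cache$dec[[l]]
    bb <- block_bwd(gd, dc$block, p, grads)
    grads <- bb$grads
    sp <- split_ch(bb$gx, dc$c_skip)
    g_eatt[[l]] <- sp$a
    ub <- conv_bwd(dc$u, p[[paste0("up", l, ".W")]], sp$b, pad = 1L)
    grads[[paste0("up", l, ".W")]] <- ub$gw
    grads[[paste0("up", l, ".b")]] <- ub$gb
    gd <- bilinear_bwd(ub$gx, dc$h_prev, dc$w_prev)
  }
  g_eatt[[L]] <- gd

  g_pool_in <- NULL  # gradient flowing into encoder level l via the pooled path
  for (l in rev(seq_len(L))) {
    ac <- cache$attn[[l]]
    ge_mul <- gate_mul(g_eatt[[l]], ac$ms)
    gms <- gate_sum_ch(g_eatt[[l]] * ac$e)
    if (!is.null(gattn) && !is.null(gattn[[l]]))
      gms <- gms + gattn[[l]]
    gs <- sigmoid_bwd(gms, ac$ms)
    ab <- conv_bwd(ac$cat2, p[["attn.W"]], gs, pad = kp, want_gb = FALSE)
    grads[["attn.W"]] <- grads[["attn.W"]] %+0% ab$gw
    sp <- split_ch(ab$gx, 1L)
    ge <- ge_mul + chanpool_bwd(sp$a, sp$b, ac$idx, ac$C)
    if (!is.null(g_pool_in)) ge <- ge + g_pool_in
    bb <- block_bwd(ge, cache$enc[[l]], p, grads)
    grads <- bb$grads
    if (l > 1L) {
      pc <- cache$pool[[l - 1L]]
      g_pool_in <- maxpool2_bwd(bb$gx, pc$idx, pc$H, pc$W)
    }
  }
  grads
}

#' Denoise one image with a trained generator
#'
#' Runs the generator in inference mode and clips the result to \[0, 1\]
#' (the clip happens only at this image boundary, never inside the losses).
#'
#' @param g generator.
#' @param img array (H, W, 3) or batch (H, W, 3, N) in \[0, 1\].
#' @return denoised image(s), same shape, clipped to \[0, 1\].
#' @export
denoise <- function(g, img) {
  squeeze <- length(dim(img)) == 3L
  out <- generator_forward(g, as_batch(img), train = FALSE,
                           keep_cache = FALSE)$denoised
  out[out < 0] <- 0
  out[out > 1] <- 1
  if (squeeze) dim(out) <- dim(out)[1:3]
  out
}
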