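#' @useDynLib hazegan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- shape helpers -----------------------------------------------------

#' Coerce an image-like object to the internal (H, W, C, N) batch layout
#'
#' Accepts a 2-D matrix (one grayscale image), a 3-D array (H, W, C) or a
#' full 4-D batch and returns a 4-D array.
#' @param x matrix or array.
#' @return numeric array with dim (H, W, C, N).
#' @keywords internal
as_batch <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected a matrix or array")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("expected 2-, 3- or 4-dimensional input")
  x
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# ---- convolution / pooling / resize (Rcpp-backed) ----------------------

conv_fwd <- function(x, w, b = NULL, stride = 1L, pad = 0L) {
  .cpp_conv2d_fwd(x, w, if (is.null(b)) numeric(0) else b,
                  as.integer(stride), as.integer(pad))
}

conv_bwd <- function(x, w, gy, stride = 1L, pad = 0L,
                     want_gx = TRUE, want_gb = TRUE, want_gw = TRUE) {
  .cpp_conv2d_bwd(x, w, gy, as.integer(stride), as.integer(pad),
                  want_gx, want_gb, want_gw)
}

maxpool2_fwd <- function(x) .cpp_maxpool2_fwd(x)
maxpool2_bwd <- function(gy, idx, H, W) .cpp_maxpool2_bwd(gy, idx, H, W)

bilinear_fwd <- function(x, Ho, Wo)
  .cpp_bilinear_fwd(x, as.integer(Ho), as.integer(Wo))
bilinear_bwd <- function(gy, H, W)
  .cpp_bilinear_bwd(gy, as.integer(H), as.integer(W))

avgpool2 <- function(x) .cpp_avgpool2(x)

# ---- elementwise activations -------------------------------------------

relu_fwd <- function(x) .cpp_relu_fwd(x)
relu_bwd <- function(gy, x) .cpp_relu_bwd(gy, x)

lrelu_fwd <- function(x, alpha = 0.2) .cpp_lrelu_fwd(x, alpha)
lrelu_bwd <- function(gy, x, alpha = 0.2) .cpp_lrelu_bwd(gy, x, alpha)

sigmoid_fwd <- function(x) 1 / (1 + exp(-x))
# derivative expressed in terms of the forward output s
sigmoid_bwd <- function(gy, s) gy * s * (1 - s)

# ---- batch normalization -----------------------------------------------

# Per-channel batch norm over (H, W, N). Returns output plus the cache
# needed by bn_bwd; `rs` carries running statistics for inference mode.
bn_fwd <- function(x, gamma, beta, rs = NULL, train = TRUE,
                   eps = 1e-5, momentum = 0.1) {
  out <- .cpp_bn_fwd(x, gamma, beta,
                     if (is.null(rs)) numeric(dim(x)[3L]) else rs$mean,
                     if (is.null(rs)) rep(1, dim(x)[3L]) else rs$var,
                     train, eps)
  if (train && !is.null(rs)) {
    rs$mean <- (1 - momentum) * rs$mean + momentum * out$mu
    rs$var <- (1 - momentum) * rs$var + momentum * out$var
  }
  list(y = out$y,
       cache = list(xhat = out$xhat, var = out$var, gamma = gamma,
                    train = train, eps = eps),
       rs = rs)
}

bn_bwd <- function(gy, cache) {
  out <- .cpp_bn_bwd(gy, cache$xhat, cache$gamma, cache$var, cache$train,
                     cache$eps)
  list(gx = out$gx, ggamma = out$ggamma, gbeta = out$gbeta)
}

# ---- channel-axis pooling (spatial attention input) --------------------

# Max and mean over the channel axis: (H,W,C,N) -> two (H,W,1,N) maps.
chanpool_fwd <- function(x) .cpp_chanpool_fwd(x)

chanpool_bwd <- function(gmp, gap, idx, C) {
  .cpp_chanpool_bwd(gmp, gap, idx, as.integer(C))
}

# ---- channel concatenation ---------------------------------------------

cat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- array(0, dim = c(da[1L], da[2L], da[3L] + db[3L], da[4L]))
  y[, , seq_len(da[3L]), ] <- a
  y[, , da[3L] + seq_len(db[3L]), ] <- b
  y
}

split_ch <- function(g, C1) {
  d <- dim(g)
  list(a = array(g[, , seq_len(C1), , drop = FALSE],
                 dim = c(d[1L], d[2L], C1, d[4L])),
       b = array(g[, , (C1 + 1):d[3L], , drop = FALSE],
                 dim = c(d[1L], d[2L], d[3L] - C1, d[4L])))
}

# Broadcast-multiply a (H,W,1,N) gate over channels of (H,W,C,N).
gate_mul <- function(x, g) .cpp_gate_mul(x, g)

# sum over the channel axis -> (H,W,1,N)
gate_sum_ch <- function(x) .cpp_sum_ch(x)
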