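# Shared fixtures, all generated in code under fixed seeds.

tiny_scene <- function(seed = 7L, side = 64L, n_blobs = 3L)
  generate_scene(side, side, n_blobs, seed = seed)

tiny_pair <- function(seed = 11L, side = 64L) {
  sc <- tiny_scene(seed = seed, side = side)
  paired_sample(sc$image, noise_config(), seed = seed + 100L)
}

# brute-force scalar-loop convolution (independent oracle, double precision)
brute_conv <- function(x, w, b = NULL, stride = 1L, pad = 0L) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  wd <- dim(w); kh <- wd[1]; kw <- wd[2]; Cout <- wd[4]
  Ho <- (H + 2 * pad - kh) %/% stride + 1L
  Wo <- (W + 2 * pad - kw) %/% stride + 1L
  y <- array(0, c(Ho, Wo, Cout, N))
  for (n in seq_len(N)) for (co in seq_len(Cout))
    for (ow in seq_len(Wo)) for (oh in seq_len(Ho)) {
      acc <- if (is.null(b)) 0 else b[co]
      for (c in seq_len(C)) for (kj in seq_len(kw)) for (ki in seq_len(kh)) {
        hh <- (oh - 1L) * stride - pad + (ki - 1L) + 1L
        ww <- (ow - 1L) * stride - pad + (kj - 1L) + 1L
        if (hh >= 1L && hh <= H && ww >= 1L && ww <= W)
          acc <- acc + x[hh, ww, c, n] * w[ki, kj, c, co]
      }
      y[oh, ow, co, n] <- acc
    }
  y
}
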