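#' Parametric haze-spot specification
#'
#' A haze spot is a disc-shaped occlusion described by the atmospheric
#' scattering model `I = J*t + A*(1 - t)`: inside the disc the transmission
#' `t` drops below 1 and the observed intensity blends towards the
#' atmospheric light `A`. Three radial profiles are supported:
#'
#' * `uniform` — constant `t` in \[0.1, 0.4\] and `A` in \[0.6, 1\] over the
#'   whole disc.
#' * `linear` — `t = d*T_edge + (1-d)*T_center` with `T_center = 0.1`,
#'   `T_edge = 0.4`; `A` interpolates from 1 (center) to 0.6 (edge) but is
#'   clamped to 1 wherever the interpolated value exceeds a per-spot plateau
#'   threshold drawn from (0.75, 0.85), reproducing the flat-topped profile
#'   of real spots; the resulting `A` map is smoothed with a normalized
#'   5x5 Gaussian kernel.
#' * `exponential` — `t = exp(min((d - 0.5) * 4, 0))` (full occlusion decay
#'   only inside half the radius) and `A = exp(-theta * d)` with a per-spot
#'   `theta` in (0.3, 0.7).
#'
#' `d` is the distance to the spot center normalized by the radius and
#' clamped at 1, so every profile reduces to the identity (`t = 1`) outside
#' its disc.
#'
#' @param form `"uniform"`, `"linear"` or `"exponential"`.
#' @param center numeric `(row, col)` in pixels; may lie anywhere in (or
#'   near the border of) the frame.
#' @param radius positive radius in pixels.
#' @param params named list of form-specific parameters (see above). Missing
#'   entries take the published defaults; supplied entries are validated
#'   against their stated ranges.
#' @return list of class `hazegan_noise_spec`.
#' @export
noise_spec <- function(form = c("uniform", "linear", "exponential"),
                       center, radius, params = list()) {
  form <- match.arg(form)
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("invalid spec: radius must be a positive scalar")
  if (length(center) != 2L) stop("invalid spec: center must be (row, col)")
  defaults <- switch(form,
    uniform = list(t = 0.25, A = 0.8),
    linear = list(t_center = 0.1, t_edge = 0.4, a_center = 1, a_edge = 0.6,
                  plateau_threshold = 0.8),
    exponential = list(theta = 0.5))
  params <- utils::modifyList(defaults, params)
  if (form == "uniform") {
    if (params$t < 0.1 || params$t > 0.4)
      stop("invalid spec: uniform t must lie in [0.1, 0.4]")
    if (params$A < 0.6 || params$A > 1)
      stop("invalid spec: uniform A must lie in [0.6, 1]")
  } else if (form == "linear") {
    if (params$plateau_threshold <= 0.75 || params$plateau_threshold >= 0.85)
      stop("invalid spec: plateau_threshold must lie in (0.75, 0.85)")
  } else {
    if (params$theta <= 0.3 || params$theta >= 0.7)
      stop("invalid spec: theta must lie in (0.3, 0.7)")
  }
  structure(list(form = form, center = as.numeric(center),
                 radius = as.numeric(radius), params = params),
            class = "hazegan_noise_spec")
}

#' Radius-normalized distance to a spot center
#'
#' @param shape integer `(H, W)`.
#' @param center `(row, col)` in pixels.
#' @param radius positive radius in pixels.
#' @return H x W matrix with `d = min(dist / radius, 1)`: 0 at the center,
#'   1 on and outside the disc boundary.
#' @export
normalized_distance <- function(shape, center, radius) {
  if (radius <= 0) stop("invalid spec: radius must be positive")
  H <- shape[1L]; W <- shape[2L]
  dr <- (seq_len(H) - center[1L])^2
  dc <- (seq_len(W) - center[2L])^2
  d <- sqrt(outer(dr, dc, "+")) / radius
  d[d > 1] <- 1
  d
}

# normalized 5x5 Gaussian kernel, replicate-padded convolution
gaussian_blur5 <- function(m, sigma = 1) {
  g <- stats::dnorm(-2:2, sd = sigma)
  k <- outer(g, g)
  k <- k / sum(k)
  H <- nrow(m); W <- ncol(m)
  pad <- m[c(1, 1, seq_len(H), H, H), c(1, 1, seq_len(W), W, W)]
  x <- array(pad, dim = c(H + 4L, W + 4L, 1L, 1L))
  w <- array(k, dim = c(5L, 5L, 1L, 1L))
  out <- conv_fwd(x, w, NULL, pad = 0L)
  matrix(out, H, W)
}

#' Rasterize a haze-spot specification into transmission and light maps
#'
#' @param spec a [noise_spec()].
#' @param shape integer `(H, W)`.
#' @param blur_sigma standard deviation (pixels) of the 5x5 Gaussian used
#'   to smooth the linear form's atmospheric-light map.
#' @return list of class `hazegan_noise_field` with `t_map` (in (0, 1\],
#'   exactly 1 outside the disc) and `a_map` (in \[0, 1\]).
#' @export
noise_field <- function(spec, shape, blur_sigma = 1) {
  d <- normalized_distance(shape, spec$center, spec$radius)
  # the disc includes its rim: pixels at exactly one radius take the
  # profile value (0.4 for the linear form), anything beyond is identity
  dr <- (seq_len(shape[1L]) - spec$center[1L])^2
  dc <- (seq_len(shape[2L]) - spec$center[2L])^2
  inside <- sqrt(outer(dr, dc, "+")) <= spec$radius
  p <- spec$params
  if (spec$form == "uniform") {
    t_map <- ifelse(inside, p$t, 1)
    a_map <- matrix(p$A, shape[1L], shape[2L])
  } else if (spec$form == "linear") {
    t_map <- ifelse(inside, d * p$t_edge + (1 - d) * p$t_center, 1)
    a_lin <- d * p$a_edge + (1 - d) * p$a_center
    a_map <- ifelse(a_lin > p$plateau_threshold, p$a_center, a_lin)
    a_map <- gaussian_blur5(a_map, sigma = blur_sigma)
  } else {
    t_map <- exp(pmin((d - 0.5) * 4, 0))
    a_map <- exp(-p$theta * d)
  }
  structure(list(t_map = t_map, a_map = a_map, spec = spec),
            class = "hazegan_noise_field")
}

#' @rdname noise_field
#' @export
uniform_field <- function(spec, shape) {
  stopifnot(spec$form == "uniform")
  noise_field(spec, shape)
}

#' @rdname noise_field
#' @param ... passed on to [noise_field()] (e.g. `blur_sigma`).
#' @export
linear_field <- function(spec, shape, ...) {
  stopifnot(spec$form == "linear")
  noise_field(spec, shape, ...)
}

#' @rdname noise_field
#' @export
exponential_field <- function(spec, shape) {
  stopifnot(spec$form == "exponential")
  noise_field(spec, shape)
}

#' Apply the atmospheric scattering model to a clean image
#'
#' Computes `I = J*t + A*(1 - t)` per pixel (per channel for multi-channel
#' images). Since the output is a convex combination of `J` and `A`, it
#' stays within \[0, 1\] for inputs in \[0, 1\].
#'
#' @param clean matrix (H, W) or array (H, W, C) in \[0, 1\].
#' @param field a `hazegan_noise_field` (or any list with `t_map`/`a_map`
#'   matching the image plane).
#' @return corrupted image, same shape as `clean`.
#' @export
apply_scattering <- function(clean, field) {
  t_map <- field$t_map
  a_map <- field$a_map
  d <- dim(clean)
  if (!identical(dim(t_map), d[1:2])) stop("shape mismatch")
  if (length(d) == 2L) return(clean * t_map + a_map * (1 - t_map))
  out <- clean
  for (c in seq_len(d[3L])) out[, , c] <- clean[, , c] * t_map +
      a_map * (1 - t_map)
  out
}

#' Noise-sampling configuration
#'
#' @param min_spots,max_spots inclusive range of the number of spots per
#'   frame (3 to 8).
#' @param form_probs sampling probabilities of the uniform / linear /
#'   exponential forms (0.2, 0.4, 0.4).
#' @param radius_frac range of the spot radius as a fraction of
#'   `min(H, W)`.
#' @param blur_sigma Gaussian sigma for the linear form's light map.
#' @return list of class `hazegan_noise_config`.
#' @export
noise_config <- function(min_spots = 3L, max_spots = 8L,
                         form_probs = c(uniform = 0.2, linear = 0.4,
                                        exponential = 0.4),
                         radius_frac = c(0.05, 0.25), blur_sigma = 1) {
  stopifnot(min_spots >= 0L, max_spots >= min_spots,
            length(form_probs) == 3L, abs(sum(form_probs) - 1) < 1e-12,
            length(radius_frac) == 2L, radius_frac[1L] > 0)
  structure(list(min_spots = as.integer(min_spots),
                 max_spots = as.integer(max_spots),
                 form_probs = form_probs, radius_frac = radius_frac,
                 blur_sigma = blur_sigma),
            class = "hazegan_noise_config")
}

#' Draw a random set of haze-spot specifications for one frame
#'
#' The spot count is uniform on `{min_spots, ..., max_spots}`; each spot's
#' form follows `form_probs`; centers are uniform over the frame; radii are
#' uniform over `radius_frac * min(H, W)`; form parameters are uniform over
#' their stated ranges (uniform spots: `t ~ U[0.1, 0.4]`,
#' `A ~ U[0.6, 1]`; linear spots: plateau threshold `~ U(0.75, 0.85)`;
#' exponential spots: `theta ~ U(0.3, 0.7)`).
#'
#' @param shape integer `(H, W)`.
#' @param config a [noise_config()].
#' @param seed optional seed; when given the draw is reproducible and the
#'   caller's RNG state is left untouched.
#' @return list of [noise_spec()] objects.
#' @export
sample_specs <- function(shape, config = noise_config(), seed = NULL) {
  draw <- function() {
    n <- sample(config$min_spots:config$max_spots, 1L)
    lo <- config$radius_frac[1L] * min(shape)
    hi <- config$radius_frac[2L] * min(shape)
    lapply(seq_len(n), function(i) {
      form <- sample(c("uniform", "linear", "exponential"), 1L,
                     prob = config$form_probs)
      center <- c(stats::runif(1, 1, shape[1L]), stats::runif(1, 1, shape[2L]))
      radius <- stats::runif(1, lo, hi)
      params <- switch(form,
        uniform = list(t = stats::runif(1, 0.1, 0.4),
                       A = stats::runif(1, 0.6, 1)),
        linear = list(plateau_threshold = stats::runif(1, 0.75, 0.85)),
        exponential = list(theta = stats::runif(1, 0.3, 0.7)))
      noise_spec(form, center, radius, params)
    })
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Composite haze spots onto a clean image
#'
#' All spot fields are combined before the scattering model is applied
#' once: the combined transmission is the minimum over spots and the
#' atmospheric light is taken from the spot achieving that minimum (the
#' strongest occluder wins; exact ties resolve to the brighter light).
#' This rule is deterministic and independent of spot order. Pixels under
#' no spot keep `t = 1` and are returned unchanged.
#'
#' @param clean matrix (H, W) or array (H, W, C) in \[0, 1\].
#' @param specs list of [noise_spec()] objects (empty list allowed).
#' @param blur_sigma see [noise_field()].
#' @return list with `noisy` (same shape as `clean`), `t_map`, `a_map`.
#' @export
corrupt <- function(clean, specs, blur_sigma = 1) {
  d <- dim(clean)
  shape <- d[1:2]
  t_comb <- matrix(1, shape[1L], shape[2L])
  a_comb <- matrix(0, shape[1L], shape[2L])
  for (spec in specs) {
    f <- noise_field(spec, shape, blur_sigma = blur_sigma)
    sel <- f$t_map < t_comb | (f$t_map == t_comb & f$a_map > a_comb)
    t_comb[sel] <- f$t_map[sel]
    a_comb[sel] <- f$a_map[sel]
  }
  noisy <- apply_scattering(clean, list(t_map = t_comb, a_map = a_comb))
  list(noisy = noisy, t_map = t_comb, a_map = a_comb)
}

#' Multi-level target attention stack
#'
#' The level-1 target is the element-wise absolute difference between the
#' noisy and clean images (channel-averaged for multi-channel input), so it
#' is zero exactly where the corruption left the image untouched; deeper
#' levels halve the side by 2x2 pooling (average by default; max available)
#' to match the attention-map resolutions of the generator.
#'
#' @param noisy,clean equally shaped images; sides divisible by
#'   `2^(levels-1)`.
#' @param levels number of levels (5).
#' @param pool `"avg"` or `"max"` down-sampling operator.
#' @return list of `levels` matrices, sides halving at each level.
#' @export
target_attention_stack <- function(noisy, clean, levels = 5L,
                                   pool = c("avg", "max")) {
  pool <- match.arg(pool)
  if (!identical(dim(noisy), dim(clean))) stop("shape mismatch")
  d <- dim(noisy)
  div <- 2L^(levels - 1L)
  if (d[1L] %% div != 0L || d[2L] %% div != 0L)
    stop("image sides must be divisible by ", div)
  m <- abs(noisy - clean)
  if (length(d) == 3L) m <- apply(m, c(1, 2), mean)
  out <- vector("list", levels)
  out[[1L]] <- m
  for (l in 2:levels) {
    prev <- out[[l - 1L]]
    x <- array(prev, dim = c(dim(prev), 1L, 1L))
    nxt <- if (pool == "avg") avgpool2(x) else maxpool2_fwd(x)$y
    out[[l]] <- matrix(nxt, dim(prev)[1L] / 2L, dim(prev)[2L] / 2L)
  }
  out
}

#' Build one paired training sample from a clean frame
#'
#' Draws a seeded spot set, corrupts the clean image and computes the
#' 5-level target attention stack.
#'
#' @param clean matrix (H, W) in \[0, 1\].
#' @param config a [noise_config()].
#' @param seed seed for the spot draw.
#' @return list of class `hazegan_pair` with `clean`, `noisy`, `specs`,
#'   `attention_targets`.
#' @export
paired_sample <- function(clean, config = noise_config(), seed = NULL) {
  specs <- sample_specs(dim(clean)[1:2], config, seed = seed)
  co <- corrupt(clean, specs, blur_sigma = config$blur_sigma)
  structure(list(clean = clean, noisy = co$noisy, specs = specs,
                 attention_targets = target_attention_stack(co$noisy, clean)),
            class = "hazegan_pair")
}

#' Build a paired dataset from synthetic scenes
#'
#' @param scenes list of scenes from [generate_dataset()] (or plain
#'   matrices in \[0, 1\]).
#' @param config a [noise_config()].
#' @param seed master seed; sample i uses `seed + i - 1`.
#' @return list of `hazegan_pair` objects.
#' @export
make_paired_dataset <- function(scenes, config = noise_config(), seed = 0L) {
  lapply(seq_along(scenes), function(i) {
    img <- if (is.list(scenes[[i]])) scenes[[i]]$image else scenes[[i]]
    paired_sample(img, config, seed = seed + i - 1L)
  })
}
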