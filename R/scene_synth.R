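#' Parameters of the synthetic infrared scene generator
#'
#' Scenes emulate night-time infrared frames of a group-housed pig pen:
#' bright elliptical animal blobs (infrared pigs radiate and appear bright)
#' on a darker low-frequency textured floor. The defaults put the
#' background mean near 0.25 and blob intensities near 0.7, mimicking the
#' bright-animal/dark-floor contrast of real frames.
#'
#' @param bg_mean mean background intensity.
#' @param bg_amplitude half-range of the background texture around its mean.
#' @param bg_texture_scale side (pixels) of one low-frequency texture cell;
#'   the texture is smoothed uniform noise up-sampled bilinearly.
#' @param fg_mean,fg_sd blob intensity distribution (clipped to
#'   \[0.5, 0.95\]).
#' @param axis_frac range of ellipse semi-axes as fractions of `min(H, W)`.
#' @param edge_sigma Gaussian sigma (pixels) softening blob edges.
#' @return list of class `hazegan_scene_params`.
#' @export
scene_params <- function(bg_mean = 0.25, bg_amplitude = 0.08,
                         bg_texture_scale = 8, fg_mean = 0.7, fg_sd = 0.05,
                         axis_frac = c(0.08, 0.18), edge_sigma = 1.5) {
  structure(list(bg_mean = bg_mean, bg_amplitude = bg_amplitude,
                 bg_texture_scale = bg_texture_scale, fg_mean = fg_mean,
                 fg_sd = fg_sd, axis_frac = axis_frac,
                 edge_sigma = edge_sigma),
            class = "hazegan_scene_params")
}

check_scene_size <- function(height, width) {
  if (height < 32L || width < 32L || height %% 16L != 0L || width %% 16L != 0L)
    stop("invalid size: height and width must be >= 32 and divisible by 16")
  invisible(TRUE)
}

#' Generate one synthetic infrared scene with ground-truth boxes
#'
#' Fully deterministic under `seed`: the same call reproduces the same
#' pixels bit for bit. Blobs are rotated ellipses with Gaussian-softened
#' edges, composited over the textured background by per-pixel maximum
#' (overlapping animals stay individually boxed). Boxes are axis-aligned
#' bounding boxes of the hard ellipse masks, in 0-based pixel edge
#' coordinates (`x` along columns, `y` along rows).
#'
#' @param height,width frame size; must be >= 32 and divisible by 16 (four
#'   2x downsamplings in the denoiser).
#' @param n_blobs number of animal blobs (>= 0).
#' @param seed integer seed.
#' @param params a [scene_params()].
#' @return list of class `hazegan_scene` with `image` (H x W matrix in
#'   \[0, 1\]), `boxes` (data.frame x_min, y_min, x_max, y_max), `seed`,
#'   `params`.
#' @export
generate_scene <- function(height, width, n_blobs = 4L, seed = 1L,
                           params = scene_params()) {
  check_scene_size(height, width)
  if (n_blobs < 0L) stop("n_blobs must be >= 0")
  with_seed(seed, {
    # low-frequency background texture: coarse uniform noise, bilinear up
    ch <- max(2L, ceiling(height / params$bg_texture_scale))
    cw <- max(2L, ceiling(width / params$bg_texture_scale))
    coarse <- matrix(stats::runif(ch * cw, params$bg_mean - params$bg_amplitude,
                                  params$bg_mean + params$bg_amplitude),
                     ch, cw)
    bg <- bilinear_fwd(array(coarse, dim = c(ch, cw, 1L, 1L)), height, width)
    img <- matrix(bg, height, width)

    boxes <- data.frame(x_min = numeric(0), y_min = numeric(0),
                        x_max = numeric(0), y_max = numeric(0))
    mn <- min(height, width)
    rows <- matrix(seq_len(height), height, width)
    cols <- matrix(seq_len(width), height, width, byrow = TRUE)
    for (i in seq_len(n_blobs)) {
      a <- stats::runif(1, params$axis_frac[1L], params$axis_frac[2L]) * mn
      b <- stats::runif(1, params$axis_frac[1L], params$axis_frac[2L]) * mn
      cy <- stats::runif(1, 3, height - 2)
      cx <- stats::runif(1, 3, width - 2)
      phi <- stats::runif(1, 0, pi)
      intensity <- min(0.95, max(0.5, stats::rnorm(1, params$fg_mean,
                                                   params$fg_sd)))
      dy <- rows - cy
      dx <- cols - cx
      u <- (dx * cos(phi) + dy * sin(phi)) / a
      v <- (-dx * sin(phi) + dy * cos(phi)) / b
      mask <- (u * u + v * v) <= 1
      if (!any(mask)) next
      soft <- gaussian_blur5(mask * 1, sigma = params$edge_sigma)
      img <- pmax(img, intensity * soft)
      rr <- range(rows[mask])
      cc <- range(cols[mask])
      boxes <- rbind(boxes, data.frame(x_min = cc[1L] - 1, y_min = rr[1L] - 1,
                                       x_max = cc[2L], y_max = rr[2L]))
    }
    img[img < 0] <- 0
    img[img > 1] <- 1
    structure(list(image = img, boxes = boxes, seed = seed, params = params),
              class = "hazegan_scene")
  })
}

#' Generate a reproducible sequence of synthetic scenes
#'
#' Frame i is generated with seed `seed + i - 1`, so fixtures are stable
#' across platforms and any sub-sequence can be regenerated independently.
#'
#' @param n_frames number of frames (>= 1).
#' @param height,width frame size.
#' @param n_blobs blobs per frame: a single count or a `(min, max)` range
#'   sampled per frame.
#' @param seed master seed.
#' @param params a [scene_params()].
#' @return list of `hazegan_scene` objects.
#' @export
generate_dataset <- function(n_frames, height = 64L, width = 64L,
                             n_blobs = c(2L, 6L), seed = 0L,
                             params = scene_params()) {
  if (n_frames < 1L) stop("n_frames must be >= 1")
  lapply(seq_len(n_frames), function(i) {
    fseed <- seed + i - 1L
    nb <- if (length(n_blobs) == 2L)
      with_seed(fseed * 2L + 1L, sample(n_blobs[1L]:n_blobs[2L], 1L))
    else n_blobs
    generate_scene(height, width, nb, seed = fseed, params = params)
  })
}

#' Write scenes to disk as 8-bit PNGs with box files
#'
#' @param scenes list of scenes.
#' @param dir output directory (created if absent).
#' @param format `"yolo"` (class x_center y_center w h, normalized) or
#'   `"csv"` (absolute-pixel x_min, y_min, x_max, y_max).
#' @return invisibly, the written image paths.
#' @export
write_scene_dataset <- function(scenes, dir, format = c("yolo", "csv")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(scenes))
  for (i in seq_along(scenes)) {
    stem <- sprintf("frame_%04d", i)
    paths[i] <- file.path(dir, paste0(stem, ".png"))
    png::writePNG(scenes[[i]]$image, paths[i])
    bpath <- file.path(dir, paste0(stem, if (format == "yolo") ".txt"
                                   else ".csv"))
    write_boxes(scenes[[i]]$boxes, bpath, format = format,
                image_dim = dim(scenes[[i]]$image))
  }
  invisible(paths)
}
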