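#' Load an image as a normalized 3-channel array
#'
#' Reads 8- or 16-bit PNG or TIFF, normalizes to \[0, 1\] by the format's
#' maximum code value, and duplicates single-channel (grayscale) data into
#' three identical channels — the downstream denoiser and detector both
#' expect 3-channel input. Alpha channels are discarded.
#'
#' @param path image file (.png, .tif/.tiff).
#' @return array (H, W, 3) in \[0, 1\].
#' @export
load_gray_as_3ch <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext))
  d <- dim(img)
  if (is.null(d) || length(d) == 2L) {
    gray <- img
  } else if (d[3L] == 2L) {
    gray <- img[, , 1L]          # gray + alpha
  } else if (d[3L] >= 3L) {
    out <- img[, , 1:3]
    return(out)
  } else {
    gray <- img[, , 1L]
  }
  array(rep(gray, 3L), dim = c(dim(gray), 3L))
}

#' Write an internal \[0, 1\] image as an 8-bit grayscale PNG
#'
#' Multi-channel input is averaged to one channel first; values are
#' clipped to \[0, 1\].
#'
#' @param img matrix or (H, W, C) array.
#' @param path output path.
#' @export
write_image <- function(img, path) {
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  img[img < 0] <- 0
  img[img > 1] <- 1
  png::writePNG(img, path)
  invisible(path)
}

#' Bilinear resize to a square side
#'
#' The aspect ratio is not preserved: rectangular camera frames are mapped
#' onto a square model input.
#'
#' @param image matrix (H, W) or array (H, W, C).
#' @param side output side in pixels; must be divisible by 16.
#' @return resized image, same channel structure.
#' @export
resize_to <- function(image, side = 512L) {
  if (side < 16L || side %% 16L != 0L)
    stop("invalid size: side must be divisible by 16")
  d <- dim(image)
  if (length(d) == 2L) {
    out <- bilinear_fwd(array(image, dim = c(d, 1L, 1L)), side, side)
    return(matrix(out, side, side))
  }
  out <- bilinear_fwd(array(image, dim = c(d, 1L)), side, side)
  array(out, dim = c(side, side, d[3L]))
}

#' Write boxes to a YOLO-style text file or absolute-pixel CSV
#'
#' YOLO format: one `class x_center y_center width height [score]` row per
#' box, coordinates normalized by the image size. CSV format: absolute
#' pixel `x_min, y_min, x_max, y_max[, score]`.
#'
#' @param boxes data.frame with x_min, y_min, x_max, y_max and optionally
#'   score.
#' @param path output file.
#' @param format `"yolo"` or `"csv"`.
#' @param image_dim `(H, W)`, required for YOLO normalization.
#' @export
write_boxes <- function(boxes, path, format = c("yolo", "csv"),
                        image_dim = NULL) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(boxes, path, row.names = FALSE)
    return(invisible(path))
  }
  if (is.null(image_dim)) stop("image_dim is required for YOLO format")
  H <- image_dim[1L]; W <- image_dim[2L]
  lines <- character(nrow(boxes))
  has_score <- "score" %in% names(boxes)
  for (i in seq_len(nrow(boxes))) {
    b <- boxes[i, ]
    vals <- c(0,
              (b$x_min + b$x_max) / 2 / W, (b$y_min + b$y_max) / 2 / H,
              (b$x_max - b$x_min) / W, (b$y_max - b$y_min) / H)
    if (has_score) vals <- c(vals, b$score)
    lines[i] <- paste(format(vals, digits = 8, trim = TRUE,
                             scientific = FALSE), collapse = " ")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read boxes written by [write_boxes()]
#'
#' @param path box file (.txt YOLO or .csv).
#' @param image_dim `(H, W)`, required to denormalize YOLO rows.
#' @return data.frame with x_min, y_min, x_max, y_max and score when
#'   present.
#' @export
read_boxes <- function(path, image_dim = NULL) {
  if (!file.exists(path)) stop("cannot read boxes: ", path)
  if (tolower(tools::file_ext(path)) == "csv")
    return(utils::read.csv(path))
  if (is.null(image_dim)) stop("image_dim is required for YOLO format")
  H <- image_dim[1L]; W <- image_dim[2L]
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- data.frame(x_min = numeric(0), y_min = numeric(0),
                    x_max = numeric(0), y_max = numeric(0))
  if (length(lines) == 0L) return(out)
  rows <- lapply(strsplit(trimws(lines), "\\s+"), as.numeric)
  has_score <- length(rows[[1L]]) >= 6L
  for (r in rows) {
    cx <- r[2L] * W; cy <- r[3L] * H; w <- r[4L] * W; h <- r[5L] * H
    row <- data.frame(x_min = cx - w / 2, y_min = cy - h / 2,
                      x_max = cx + w / 2, y_max = cy + h / 2)
    if (has_score) row$score <- r[6L]
    out <- rbind(out, row)
  }
  out
}
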