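#' Greenness of a single pixel
#'
#' The green chromatic coordinate of one pixel: the ratio of the green
#' channel to the sum of all three channels, `G / (R + G + B)`. The ratio
#' is undefined for a pure black pixel (channel sum zero); such pixels are
#' marked excluded (`NA`) rather than assigned a value.
#'
#' @param p integer vector `c(R, G, B)` with channels in 0-255.
#' @return a fraction in `[0, 1]`, or `NA_real_` for a black pixel.
#' @examples
#' pixel_greenness(c(0, 255, 0))    # 1
#' pixel_greenness(c(100, 100, 100)) # 1/3
#' pixel_greenness(c(0, 0, 0))      # NA (excluded)
#' @export
pixel_greenness <- function(p) {
  stopifnot(length(p) == 3, all(p >= 0), all(p <= 255))
  s <- sum(p)
  if (s == 0) return(NA_real_)
  p[2] / s
}

#' Mean greenness index of an image
#'
#' Computes the per-pixel greenness ratio `G / (R + G + B)` and averages it
#' over all pixels with a positive channel sum. This is the
#' ratio-then-mean order: each pixel's ratio is formed first and the mean
#' is taken across pixels, which differs from dividing mean channels.
#'
#' @param pixels a numeric array `height x width x 3` with channel values
#'   in 0-255 (R, G, B slices), or an `n x 3` matrix of pixels.
#' @return a list with `greenness` (fraction), `n_used` and `n_excluded`
#'   (pixel counts; black pixels are excluded).
#' @examples
#' img <- array(100, dim = c(4, 4, 3))
#' image_greenness(img)$greenness  # exactly 1/3
#' @export
image_greenness <- function(pixels) {
  if (is.matrix(pixels) && ncol(pixels) == 3) {
    r <- pixels[, 1]; g <- pixels[, 2]; b <- pixels[, 3]
  } else if (is.array(pixels) && length(dim(pixels)) == 3 && dim(pixels)[3] == 3) {
    r <- as.vector(pixels[, , 1]); g <- as.vector(pixels[, , 2])
    b <- as.vector(pixels[, , 3])
  } else {
    stop("pixels must be an h x w x 3 array or an n x 3 matrix")
  }
  if (any(r < 0 | r > 255 | g < 0 | g > 255 | b < 0 | b > 255)) {
    stop("channel values must lie in [0, 255]")
  }
  s <- r + g + b
  valid <- s > 0
  if (!any(valid)) stop("no valid pixels: image is entirely black")
  list(
    greenness = mean(g[valid] / s[valid]),
    n_used = sum(valid),
    n_excluded = sum(!valid)
  )
}

#' Read an image file as an RGB channel array
#'
#' Decodes a PNG (via the \pkg{png} package) or JPEG (via \pkg{EBImage},
#' if installed) into a `height x width x 3` array of 8-bit channel values
#' (0-255). Grayscale images are expanded to `R = G = B`; an alpha channel
#' is dropped. Channels are used exactly as decoded - no gamma
#' linearization or white-balance correction is applied.
#'
#' @param path path to a `.png`, `.jpg` or `.jpeg` file.
#' @return numeric array `height x width x 3`, values in 0-255.
#' @export
read_image_rgb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("JPEG decoding requires the EBImage package")
    }
    eb <- EBImage::readImage(path)
    img <- EBImage::imageData(eb)
    if (length(dim(img)) == 3) img <- aperm(img, c(2, 1, 3)) else img <- t(img)
  } else {
    stop("unsupported image format: .", ext)
  }
  if (length(dim(img) %||% 2) == 2 || is.matrix(img)) {
    img <- array(rep(img, 3), dim = c(dim(img), 3))  # grayscale -> R=G=B
  } else if (dim(img)[3] == 2) {
    img <- array(rep(img[, , 1], 3), dim = c(dim(img)[1:2], 3))  # gray+alpha
  } else if (dim(img)[3] >= 4) {
    img <- img[, , 1:3, drop = FALSE]  # drop alpha
  }
  round(img * 255)
}

#' Compute greenness observations for a corpus
#'
#' Decodes every image referenced by the records and returns one greenness
#' observation per decodable file, labelled with park, year and month taken
#' from the record timestamp. Files that cannot be decoded are skipped and
#' reported in the `errors` attribute of the result.
#'
#' @param records a manifest data.frame as returned by [load_manifest()] or
#'   [filter_corpus()] (columns `record_id`, `park`, `timestamp`,
#'   `filepath`, `bytes`).
#' @return a data.frame with columns `record_id`, `park`, `year`, `month`,
#'   `greenness`, `n_pixels_used`, `n_pixels_excluded`, plus an `errors`
#'   attribute (data.frame `record_id`, `reason`; zero rows when all
#'   files decoded).
#' @export
corpus_greenness <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  n <- nrow(records)
  greenness <- numeric(n)
  used <- integer(n)
  excluded <- integer(n)
  ok <- logical(n)
  reasons <- character(n)
  for (i in seq_len(n)) {
    res <- tryCatch(
      image_greenness(read_image_rgb(records$filepath[i])),
      error = function(e) conditionMessage(e)
    )
    if (is.character(res)) {
      reasons[i] <- res
    } else {
      ok[i] <- TRUE
      greenness[i] <- res$greenness
      used[i] <- res$n_used
      excluded[i] <- res$n_excluded
    }
  }
  if (!any(ok)) stop("no decodable images in corpus")
  ts <- as.Date(records$timestamp)
  out <- data.frame(
    record_id = records$record_id[ok],
    park = records$park[ok],
    year = as.integer(format(ts[ok], "%Y")),
    month = as.integer(format(ts[ok], "%m")),
    greenness = greenness[ok],
    n_pixels_used = used[ok],
    n_pixels_excluded = excluded[ok],
    stringsAsFactors = FALSE
  )
  attr(out, "errors") <- data.frame(
    record_id = records$record_id[!ok],
    reason = reasons[!ok],
    stringsAsFactors = FALSE
  )
  out
}
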