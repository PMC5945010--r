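#' Generate a synthetic image with controlled mean greenness
#'
#' Builds an RGB image whose mean greenness index is controlled by a single
#' target value. Every pixel has a fixed channel sum `S = 300`:
#' `G = clip(round((target + eps) * S), 0, 255)` with per-pixel noise
#' `eps ~ Normal(0, pixel_noise_sd)` (rounding half away from zero), and
#' the remainder `S - G` is split between R and B, any odd unit going to R.
#' The realized mean greenness is recomputed from the finished pixels with
#' [image_greenness()] - the same formula the analysis applies - so the
#' returned `realized_greenness`, not the target, is the image's ground
#' truth.
#'
#' @param target_greenness target mean greenness, a fraction; with the
#'   noise level it must satisfy `target +/- 3 * pixel_noise_sd` within
#'   (0.05, 0.95) so the green channel stays far from the 0/255 clip.
#' @param width,height image dimensions in pixels, `>= 1`.
#' @param pixel_noise_sd standard deviation of the per-pixel greenness
#'   noise (unitless fraction).
#' @param seed integer seed; the construction is reproducible given
#'   (target, dimensions, noise, seed).
#' @return a list with `pixels` (integer array `height x width x 3`,
#'   values 0-255) and `realized_greenness`.
#' @examples
#' img <- generate_image(1 / 3, 8, 8, pixel_noise_sd = 0, seed = 1)
#' img$realized_greenness  # exactly 1/3: every pixel is (100, 100, 100)
#' @export
generate_image <- function(target_greenness, width, height,
                           pixel_noise_sd = 0.05, seed = 1L) {
  stopifnot(
    is.numeric(target_greenness), length(target_greenness) == 1,
    width >= 1, height >= 1, pixel_noise_sd >= 0
  )
  if (target_greenness - 3 * pixel_noise_sd <= 0.05 ||
      target_greenness + 3 * pixel_noise_sd >= 0.95) {
    stop("unattainable target: target +/- 3*noise_sd must lie within (0.05, 0.95)")
  }
  n <- as.integer(width) * as.integer(height)
  S <- 300
  g_frac <- withr::with_seed(as.integer(seed), {
    target_greenness + stats::rnorm(n, 0, pixel_noise_sd)
  })
  G <- pmin(pmax(round_half_away(g_frac * S), 0), 255)
  rem <- S - G
  R <- ceiling(rem / 2)  # odd remainder unit goes to R
  B <- floor(rem / 2)
  pixels <- array(0L, dim = c(height, width, 3))
  pixels[, , 1] <- as.integer(R)
  pixels[, , 2] <- as.integer(G)
  pixels[, , 3] <- as.integer(B)
  list(
    pixels = pixels,
    realized_greenness = image_greenness(pixels)$greenness
  )
}

#' Write a pixel array to an image file
#'
#' PNG encoding (the default throughout the package) is lossless, so the
#' greenness recomputed from the file equals the generated value exactly.
#' JPEG is supported through \pkg{EBImage} for realism but is lossy.
#'
#' @param pixels integer array `height x width x 3`, values 0-255.
#' @param path output path; format chosen by extension (`.png`, `.jpg`).
#' @param quality JPEG quality in (0, 100]; ignored for PNG.
#' @return `path`, invisibly.
#' @export
write_image <- function(pixels, path, quality = 90) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(pixels / 255, target = path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("JPEG encoding requires the EBImage package")
    }
    EBImage::writeImage(EBImage::Image(aperm(pixels / 255, c(2, 1, 3)),
                                       colormode = "Color"),
                        path, quality = quality)
  } else {
    stop("unsupported image format: .", ext)
  }
  invisible(path)
}
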