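#' Generate a synthetic image corpus with known ground truth
#'
#' Simulates the image corpus the analysis pipeline consumes. For each park
#' and each simulated month, `monthly_counts[m]` clean images are drawn with
#' per-image target greenness `Normal(mu(m), image_noise_sd)`, where `mu` is
#' the park's cosine seasonal profile. Three contaminant classes are
#' injected on top of the clean images, mirroring the pathologies of
#' social-media corpora:
#'
#' * `duplicate` - exact byte copies of clean images (spam reposts),
#' * `undersized` - valid but tiny files below the corpus filter's size
#'   threshold (thumbnails, low-quality images),
#' * `ad` - advertisement images whose greenness reflects the park at its
#'   peak month regardless of posting month (stock summer imagery posted
#'   off-season).
#'
#' The number injected per park-month is `Binomial(n_clean, r / (1 - R))`
#' where `r` is the class rate and `R` the sum of all three rates, so each
#' class makes up an expected fraction `r` of the final manifest.
#'
#' Timestamps are ISO-8601 dates on day 15 of the posting month; a
#' duplicate shares its source's month, and its record id sorts after the
#' source's, so the deterministic filter tie-break retains the original.
#'
#' @param profiles a list of [park_profile()] objects.
#' @param out_dir output directory (created if needed); images are written
#'   under `out_dir/images/<park-slug>/`, plus `manifest.csv` and
#'   `truth.csv`.
#' @param seed integer root seed; per-(park, month) child seeds are derived
#'   from it, so generation is bit-reproducible and independent of park
#'   order.
#' @param year_span number of simulated months (multiples of 12; the
#'   default 24 covers two calendar years, pooled by month label
#'   downstream).
#' @param start_year first simulated calendar year.
#' @param image_width,image_height dimensions of clean and advertisement
#'   images. At the 80 px default with `pixel_noise_sd = 0.05`, PNG files
#'   are always larger than the 10,240-byte filter threshold.
#' @param pixel_noise_sd per-pixel greenness noise inside each image.
#' @param write_images if `FALSE`, no image files are written (manifest
#'   `bytes` are then nominal: 15,000 for full-size records, 2,048 for
#'   undersized ones) but record-level realized greenness is still
#'   simulated pixel-exactly. Useful for fast Monte-Carlo studies of the
#'   statistical stages; the on-disk filter stage requires real files.
#' @param format `"png"` (lossless; default) or `"jpeg"`.
#' @return a list with `manifest` (data.frame `record_id`, `park`,
#'   `timestamp`, `filepath`, `bytes`), `truth` (data.frame `record_id`,
#'   `class`, `target_greenness`, `realized_greenness`, `true_month_mean`)
#'   and `out_dir`. Both tables are also written as CSV under `out_dir`.
#' @export
generate_corpus <- function(profiles,
                            out_dir,
                            seed = 1L,
                            year_span = 24L,
                            start_year = 2014L,
                            image_width = 80L,
                            image_height = 80L,
                            pixel_noise_sd = 0.05,
                            write_images = TRUE,
                            format = c("png", "jpeg")) {
  format <- match.arg(format)
  if (inherits(profiles, "park_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) > 0,
            all(vapply(profiles, inherits, logical(1), "park_profile")),
            year_span >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (write_images) {
    dir.create(file.path(out_dir, "images"), showWarnings = FALSE)
  }

  blocks <- list()
  for (profile in profiles) {
    mu <- seasonal_profile(profile)$month_means
    slug <- gsub("[^a-z0-9]+", "-", tolower(profile$park_name))
    if (write_images) {
      dir.create(file.path(out_dir, "images", slug), showWarnings = FALSE)
    }
    rate_sum <- profile$ad_contamination_rate + profile$duplicate_rate +
      profile$undersized_rate
    for (mi in seq_len(year_span)) {
      cal <- calendar_month(mi)
      yr <- start_year + (mi - 1L) %/% 12L
      n_clean <- profile$monthly_counts[cal]
      if (n_clean == 0L) next
      cs <- child_seed(seed, profile$park_name, yr, cal)
      block <- withr::with_seed(cs, {
        n_ad <- stats::rbinom(1, n_clean,
                              profile$ad_contamination_rate / (1 - rate_sum))
        n_dup <- stats::rbinom(1, n_clean,
                               profile$duplicate_rate / (1 - rate_sum))
        n_und <- stats::rbinom(1, n_clean,
                               profile$undersized_rate / (1 - rate_sum))
        targets_clean <- rnorm_attainable(n_clean, mu[cal],
                                          profile$image_noise_sd, pixel_noise_sd)
        dup_sources <- if (n_dup > 0) sample.int(n_clean, n_dup, replace = TRUE) else integer(0)
        targets_und <- rnorm_attainable(n_und, mu[cal],
                                        profile$image_noise_sd, pixel_noise_sd)
        img_seeds <- sample.int(2^30, n_clean + n_ad + n_und)
        list(n_ad = n_ad, n_dup = n_dup, n_und = n_und,
             targets_clean = targets_clean, dup_sources = dup_sources,
             targets_und = targets_und, img_seeds = img_seeds)
      })
      targets <- c(block$targets_clean,
                   rep(mu[profile$peak_month], block$n_ad),
                   block$targets_und)
      classes <- c(rep("clean", n_clean), rep("ad", block$n_ad),
                   rep("undersized", block$n_und))
      widths <- ifelse(classes == "undersized", 4L, as.integer(image_width))
      heights <- ifelse(classes == "undersized", 4L, as.integer(image_height))
      n_gen <- length(targets)
      realized <- numeric(n_gen)
      ids <- sprintf("%s-%04d%02d-%04d", slug, yr, cal, seq_len(n_gen + block$n_dup))
      ext <- if (format == "png") "png" else "jpg"
      paths <- file.path("images", slug, paste0(ids, ".", ext))
      bytes <- integer(n_gen + block$n_dup)
      for (k in seq_len(n_gen)) {
        img <- generate_image(targets[k], widths[k], heights[k],
                              pixel_noise_sd, seed = block$img_seeds[k])
        realized[k] <- img$realized_greenness
        if (write_images) {
          write_image(img$pixels, file.path(out_dir, paths[k]))
          bytes[k] <- as.integer(file.size(file.path(out_dir, paths[k])))
        } else {
          bytes[k] <- if (classes[k] == "undersized") 2048L else 15000L
        }
      }
      # duplicates: exact byte copies of clean images from this park-month
      if (block$n_dup > 0) {
        for (j in seq_len(block$n_dup)) {
          src <- block$dup_sources[j]
          k <- n_gen + j
          realized[k] <- realized[src]
          targets <- c(targets, targets[src])
          classes <- c(classes, "duplicate")
          if (write_images) {
            file.copy(file.path(out_dir, paths[src]), file.path(out_dir, paths[k]))
            bytes[k] <- bytes[src]
          } else {
            bytes[k] <- 15000L
          }
        }
      }
      blocks[[length(blocks) + 1L]] <- data.frame(
        record_id = ids,
        park = profile$park_name,
        timestamp = sprintf("%04d-%02d-15", yr, cal),
        filepath = paths,
        bytes = bytes,
        class = classes,
        target_greenness = targets,
        realized_greenness = realized,
        true_month_mean = mu[cal],
        stringsAsFactors = FALSE
      )
    }
  }
  all_rows <- do.call(rbind, blocks)
  if (anyDuplicated(all_rows$record_id)) stop("record id collision in corpus")
  manifest <- all_rows[, c("record_id", "park", "timestamp", "filepath", "bytes")]
  truth <- all_rows[, c("record_id", "class", "target_greenness",
                        "realized_greenness", "true_month_mean")]
  rownames(manifest) <- rownames(truth) <- NULL
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  list(manifest = manifest, truth = truth, out_dir = out_dir)
}

# Image-level greenness noise: Gaussian truncated SYMMETRICALLY about the
# month mean so that (a) every drawn target satisfies generate_image()'s
# attainability precondition (target +/- 3*pixel_noise_sd inside
# (0.05, 0.95)) and (b) the expected target still equals the month mean.
# Inverse-CDF sampling keeps the RNG draw count fixed at n.
rnorm_attainable <- function(n, mu, sd, pixel_noise_sd) {
  if (n == 0) return(numeric(0))
  if (sd == 0) return(rep(mu, n))
  lo <- 0.05 + 3 * pixel_noise_sd + 1e-9
  hi <- 0.95 - 3 * pixel_noise_sd - 1e-9
  half_width <- min(mu - lo, hi - mu)
  if (half_width <= 0) stop("month mean ", mu, " is unattainable at this noise level")
  p <- stats::pnorm(c(-half_width, half_width), 0, sd)
  stats::qnorm(stats::runif(n, p[1], p[2]), 0, sd) + mu
}

#' Greenness observations straight from a synthetic truth table
#'
#' Builds the observation table the statistical stages consume directly
#' from a synthetic corpus's ground truth, bypassing image encoding and
#' decoding. Because PNG round-trips 8-bit pixels exactly, this equals the
#' file-based route ([filter_corpus()] then [corpus_greenness()]) on a PNG
#' corpus: duplicate and undersized records are dropped (the filter removes
#' them) and clean plus advertisement records are kept with their realized
#' greenness. Intended for fast Monte-Carlo study of the aggregation
#' stages.
#'
#' @param corpus the list returned by [generate_corpus()].
#' @return an observation data.frame matching [corpus_greenness()] output
#'   (without pixel-count columns).
#' @export
truth_observations <- function(corpus) {
  keep <- corpus$truth$class %in% c("clean", "ad")
  m <- corpus$manifest[keep, ]
  ts <- as.Date(m$timestamp)
  data.frame(
    record_id = m$record_id,
    park = m$park,
    year = as.integer(format(ts, "%Y")),
    month = as.integer(format(ts, "%m")),
    greenness = corpus$truth$realized_greenness[keep],
    stringsAsFactors = FALSE
  )
}
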