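#' Define the data-generating profile of a park
#'
#' A park profile holds every parameter of the synthetic corpus generator
#' for one park: the true seasonal greenness cycle (a cosine with a given
#' base level, amplitude, and peak month), the image-to-image noise, the
#' posting volume per calendar month, and the contamination rates for
#' advertisement images, exact duplicates, and undersized files.
#'
#' @param park_name character; park label used in manifests and outputs.
#' @param base_greenness annual mean greenness, a fraction in (0, 1).
#' @param seasonal_amplitude half-range of the seasonal cycle, `>= 0`.
#'   `base_greenness + seasonal_amplitude` and
#'   `base_greenness - seasonal_amplitude` must stay inside (0, 1).
#' @param peak_month calendar month (1-12) at which the cycle peaks.
#' @param image_noise_sd standard deviation of the image-level greenness
#'   noise around the monthly mean. The default 0.034 yields a monthly
#'   coefficient of variation near 0.1 for greenness levels near 0.34,
#'   the dispersion typical of uncurated social-media corpora.
#' @param monthly_counts integer vector of 12 non-negative per-month image
#'   counts (per simulated year); must sum to a positive number.
#' @param ad_contamination_rate expected fraction of the park's manifest that
#'   is "advertisement" images: images whose greenness reflects the peak
#'   month regardless of posting month.
#' @param duplicate_rate expected fraction of the manifest that is exact
#'   byte-level duplicates of clean images.
#' @param undersized_rate expected fraction of the manifest that is valid
#'   but tiny files (below the corpus filter's size threshold).
#' @return an object of class `park_profile`.
#' @seealso [seasonal_profile()], [generate_corpus()], [default_park_profiles()]
#' @export
park_profile <- function(park_name,
                         base_greenness,
                         seasonal_amplitude,
                         peak_month,
                         image_noise_sd = 0.034,
                         monthly_counts = rep(30L, 12L),
                         ad_contamination_rate = 0,
                         duplicate_rate = 0,
                         undersized_rate = 0) {
  stopifnot(
    is.character(park_name), length(park_name) == 1, nzchar(park_name),
    is.numeric(base_greenness), length(base_greenness) == 1,
    base_greenness > 0, base_greenness < 1,
    is.numeric(seasonal_amplitude), seasonal_amplitude >= 0,
    peak_month %in% 1:12,
    is.numeric(image_noise_sd), image_noise_sd >= 0,
    length(monthly_counts) == 12, all(monthly_counts >= 0),
    sum(monthly_counts) > 0,
    ad_contamination_rate >= 0, ad_contamination_rate <= 1,
    duplicate_rate >= 0, duplicate_rate <= 1,
    undersized_rate >= 0, undersized_rate <= 1
  )
  if (base_greenness + seasonal_amplitude >= 1 ||
      base_greenness - seasonal_amplitude <= 0) {
    stop("base_greenness +/- seasonal_amplitude must stay within (0, 1)")
  }
  rate_sum <- ad_contamination_rate + duplicate_rate + undersized_rate
  if (rate_sum >= 1) {
    stop("contamination rates must sum to less than 1")
  }
  structure(
    list(
      park_name = park_name,
      base_greenness = base_greenness,
      seasonal_amplitude = seasonal_amplitude,
      peak_month = as.integer(peak_month),
      image_noise_sd = image_noise_sd,
      monthly_counts = as.integer(monthly_counts),
      ad_contamination_rate = ad_contamination_rate,
      duplicate_rate = duplicate_rate,
      undersized_rate = undersized_rate
    ),
    class = "park_profile"
  )
}

#' @export
print.park_profile <- function(x, ...) {
  cat(sprintf(
    "<park_profile> %s: base %.3f, amplitude %.3f, peak month %d, %d images/yr\n",
    x$park_name, x$base_greenness, x$seasonal_amplitude, x$peak_month,
    sum(x$monthly_counts)
  ))
  invisible(x)
}

#' True monthly mean greenness implied by a park profile
#'
#' Evaluates the cosine seasonal cycle
#' `mu(m) = base + amplitude * cos(2 * pi * (m - peak_month) / 12)`
#' at every calendar month. This is the ground-truth curve that the
#' aggregation stage is expected to recover from a synthetic corpus.
#'
#' @param profile a [park_profile()].
#' @return an object of class `seasonal_profile`: a list with `park_name`
#'   and `month_means`, a length-12 numeric vector of fractions in (0, 1).
#' @examples
#' p <- park_profile("Acadia", 0.34, 0.04, peak_month = 7)
#' seasonal_profile(p)$month_means
#' @export
seasonal_profile <- function(profile) {
  stopifnot(inherits(profile, "park_profile"))
  m <- 1:12
  mu <- profile$base_greenness +
    profile$seasonal_amplitude * cos(2 * pi * (m - profile$peak_month) / 12)
  if (any(mu <= 0) || any(mu >= 1)) {
    stop("seasonal profile leaves (0, 1); reduce amplitude or recenter base")
  }
  structure(
    list(park_name = profile$park_name, month_means = mu),
    class = "seasonal_profile"
  )
}

#' @export
print.seasonal_profile <- function(x, ...) {
  cat(sprintf("<seasonal_profile> %s\n", x$park_name))
  print(round(stats::setNames(x$month_means, month.abb), 4))
  invisible(x)
}

#' Default eight-park study scenario
#'
#' Park profiles calibrated to the seasonal structure reported for eight
#' heavily visited US national parks: forested parks with summer (JJA) mean
#' greenness near 0.34 and winter (DJF) means lower by roughly 0.05-0.1;
#' Great Smoky Mountains the greenest in summer (above 0.36, with an October
#' posting bump from fall-foliage visitors); Grand Canyon the least green
#' (below 0.32) with no seasonal cycle; Rocky Mountain the strongest cycle;
#' and Glacier carrying a high advertisement-contamination rate, which
#' spuriously raises its off-season greenness. Posting volume peaks in
#' July for every park. Duplicate and undersized rates each default to
#' 0.015, so the corpus filter removes about 3% of records.
#'
#' @param duplicate_rate,undersized_rate contamination rates shared by all
#'   parks (fractions of the final manifest).
#' @return a named list of [park_profile()] objects.
#' @export
default_park_profiles <- function(duplicate_rate = 0.015,
                                  undersized_rate = 0.015) {
  counts <- as.integer(round_half_away(35 + 25 * cos(2 * pi * (1:12 - 7) / 12)))
  smoky_counts <- counts
  smoky_counts[10] <- smoky_counts[10] + 20L  # October fall-foliage peak
  spec <- list(
    list("Acadia",                0.304, 0.040, 0.02, counts),
    list("Glacier",               0.313, 0.030, 0.12, counts),
    list("Grand Canyon",          0.316, 0.000, 0.02, counts),
    list("Grand Teton",           0.308, 0.035, 0.02, counts),
    list("Olympic",               0.312, 0.030, 0.02, counts),
    list("Rocky Mountain",        0.295, 0.050, 0.02, counts),
    list("Great Smoky Mountains", 0.325, 0.045, 0.02, smoky_counts),
    list("Yosemite",              0.312, 0.035, 0.02, counts)
  )
  profiles <- lapply(spec, function(s) {
    park_profile(
      park_name = s[[1]],
      base_greenness = s[[2]],
      seasonal_amplitude = s[[3]],
      peak_month = 7L,
      image_noise_sd = 0.034,
      monthly_counts = s[[5]],
      ad_contamination_rate = s[[4]],
      duplicate_rate = duplicate_rate,
      undersized_rate = undersized_rate
    )
  })
  stats::setNames(profiles, vapply(spec, `[[`, character(1), 1))
}

#' Reference coordinates of the default parks
#'
#' Approximate centers (decimal degrees) of the eight parks in the default
#' scenario, used to place each park's synthetic NDVI grid and to select
#' grid cells within a radius of the park center.
#'
#' @return a data.frame with columns `park`, `lat`, `lon`.
#' @export
default_park_centers <- function() {
  data.frame(
    park = c("Acadia", "Glacier", "Grand Canyon", "Grand Teton",
             "Olympic", "Rocky Mountain", "Great Smoky Mountains", "Yosemite"),
    lat = c(44.35, 48.70, 36.06, 43.79, 47.80, 40.40, 35.60, 37.85),
    lon = c(-68.21, -113.80, -112.14, -110.68, -123.60, -105.70, -83.50, -119.55),
    stringsAsFactors = FALSE
  )
}
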