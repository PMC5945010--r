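# Shared fixtures: small park profiles and corpora built in code at test time.

tiny_profile <- function(park = "TestPark",
                         base = 0.33,
                         amplitude = 0.03,
                         counts = rep(5L, 12),
                         image_noise_sd = 0.02,
                         ...) {
  park_profile(park, base, amplitude, peak_month = 7L,
               image_noise_sd = image_noise_sd,
               monthly_counts = as.integer(counts), ...)
}

# A small on-disk corpus; returns the generate_corpus() result.
tiny_corpus <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                        profile = tiny_profile(), seed = 42,
                        year_span = 12, ...) {
  generate_corpus(profile, dir, seed = seed, year_span = year_span, ...)
}

# Independent naive oracle for the greenness index: double loop over pixels.
naive_image_greenness <- function(pixels) {
  total <- 0
  used <- 0L
  for (i in seq_len(dim(pixels)[1])) {
    for (j in seq_len(dim(pixels)[2])) {
      s <- pixels[i, j, 1] + pixels[i, j, 2] + pixels[i, j, 3]
      if (s > 0) {
        total <- total + pixels[i, j, 2] / s
        used <- used + 1L
      }
    }
  }
  total / used
}

# Random RGB image with occasional pure-black pixels.
random_test_image <- function(h, w, p_black = 0.05) {
  px <- array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
  black <- matrix(stats::runif(h * w) < p_black, h, w)
  for (k in 1:3) px[, , k][black] <- 0L
  px
}
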