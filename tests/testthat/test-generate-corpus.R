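test_that("a contamination-free corpus is all clean with forced counts", {
  dir <- withr::local_tempdir()
  prof <- tiny_profile(counts = c(2L, 1L, 0L, 3L, 2L, 1L, 4L, 2L, 1L, 0L, 1L, 2L))
  corp <- generate_corpus(prof, dir, seed = 1, year_span = 12)
  expect_equal(nrow(corp$manifest), sum(prof$monthly_counts))
  expect_true(all(corp$truth$class == "clean"))
  # truth partitions the manifest exactly
  expect_setequal(corp$truth$record_id, corp$manifest$record_id)
  expect_equal(anyDuplicated(corp$manifest$record_id), 0L)
  # month with zero configured count yields no records
  months <- as.integer(substr(corp$manifest$timestamp, 6, 7))
  expect_false(any(months %in% c(3, 10)))
})

test_that("injected duplicates are exact byte copies that sort after their source", {
  dir <- withr::local_tempdir()
  prof <- tiny_profile(counts = rep(20L, 12), duplicate_rate = 0.1)
  corp <- generate_corpus(prof, dir, seed = 7, year_span = 6)
  dups <- corp$truth$record_id[corp$truth$class == "duplicate"]
  expect_gt(length(dups), 0)
  md5 <- tools::md5sum(file.path(dir, corp$manifest$filepath))
  names(md5) <- corp$manifest$record_id
  for (id in dups) {
    twins <- names(md5)[md5 == md5[[id]]]
    expect_gte(length(twins), 2)
    # at least one byte-identical partner with a smaller (earlier) id
    expect_true(any(setdiff(twins, id) < id))
  }
})

test_that("undersized contaminants fall below the 10 kB threshold and clean files above", {
  dir <- withr::local_tempdir()
  prof <- tiny_profile(counts = rep(8L, 12), undersized_rate = 0.1,
                       image_noise_sd = 0.03)
  corp <- generate_corpus(prof, dir, seed = 3, year_span = 12)
  und <- corp$truth$class == "undersized"
  expect_gt(sum(und), 0)
  expect_true(all(corp$manifest$bytes[und] < 10240))
  expect_true(all(corp$manifest$bytes[!und] >= 10240))
})

test_that("corpus generation is bit-reproducible and order-independent across parks", {
  dir_a <- withr::local_tempdir()
  dir_b <- withr::local_tempdir()
  p1 <- tiny_profile("Alpha", 0.32, 0.03, counts = rep(4L, 12),
                     duplicate_rate = 0.05, ad_contamination_rate = 0.05)
  p2 <- tiny_profile("Beta", 0.30, 0.02, counts = rep(3L, 12))
  a <- generate_corpus(list(p1, p2), dir_a, seed = 9, year_span = 12)
  b <- generate_corpus(list(p2, p1), dir_b, seed = 9, year_span = 12)
  ord <- function(df) df[order(df$record_id), ]
  expect_equal(ord(a$manifest)$record_id, ord(b$manifest)$record_id)
  expect_equal(ord(a$truth)$realized_greenness, ord(b$truth)$realized_greenness)
  md5_a <- unname(tools::md5sum(file.path(dir_a, ord(a$manifest)$filepath)))
  md5_b <- unname(tools::md5sum(file.path(dir_b, ord(b$manifest)$filepath)))
  expect_identical(md5_a, md5_b)
})

test_that("clean-image truth means recover the configured monthly profile", {
  dir <- withr::local_tempdir()
  prof <- tiny_profile(base = 0.34, amplitude = 0.04, counts = rep(60L, 12),
                       image_noise_sd = 0.02)
  corp <- generate_corpus(prof, dir, seed = 5, year_span = 12,
                          write_images = FALSE)
  mu <- seasonal_profile(prof)$month_means
  months <- as.integer(substr(corp$manifest$timestamp, 6, 7))
  for (m in c(1, 4, 7)) {
    sel <- months == m & corp$truth$class == "clean"
    # Monte-Carlo tolerance: 4 * image_noise_sd / sqrt(60)
    expect_lt(abs(mean(corp$truth$realized_greenness[sel]) - mu[m]),
              4 * 0.02 / sqrt(60))
    expect_equal(unique(corp$truth$true_month_mean[sel]), mu[m])
  }
})

test_that("advertisement images carry peak-month greenness in any posting month", {
  dir <- withr::local_tempdir()
  prof <- tiny_profile(base = 0.33, amplitude = 0.03,
                       counts = rep(30L, 12), ad_contamination_rate = 0.15)
  corp <- generate_corpus(prof, dir, seed = 13, year_span = 12,
                          write_images = FALSE)
  mu <- seasonal_profile(prof)$month_means
  ads <- corp$truth$class == "ad"
  months <- as.integer(substr(corp$manifest$timestamp, 6, 7))
  expect_gt(sum(ads & months %in% c(12, 1, 2)), 0)
  # ad targets equal mu(peak) regardless of posting month
  expect_true(all(corp$truth$target_greenness[ads] == mu[7]))
  expect_true(all(abs(corp$truth$realized_greenness[ads] - mu[7]) < 0.005))
})

test_that("fast mode (write_images = FALSE) matches the file-based realized values", {
  dir_a <- withr::local_tempdir()
  dir_b <- withr::local_tempdir()
  prof <- tiny_profile(counts = rep(3L, 12), duplicate_rate = 0.05)
  a <- generate_corpus(prof, dir_a, seed = 21, year_span = 12, write_images = TRUE)
  b <- generate_corpus(prof, dir_b, seed = 21, year_span = 12, write_images = FALSE)
  expect_identical(a$truth$record_id, b$truth$record_id)
  expect_identical(a$truth$realized_greenness, b$truth$realized_greenness)
  expect_false(any(file.exists(file.path(dir_b, b$manifest$filepath))))
})
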