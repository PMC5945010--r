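write_tiny_manifest <- function(rows, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "manifest.csv")
  header <- "record_id,park,timestamp,filepath,bytes"
  writeLines(c(header, rows), path)
  path
}

test_that("an empty manifest loads as an empty record table", {
  path <- write_tiny_manifest(character(0))
  records <- load_manifest(path)
  expect_equal(nrow(records), 0)
  expect_equal(nrow(attr(records, "row_errors")), 0)
})

test_that("malformed rows are rejected into the row-error report", {
  path <- write_tiny_manifest(c(
    "a1,ParkA,2014-06-15,img/a1.png,12000",
    "a2,ParkA,not-a-date,img/a2.png,12000",
    "a3,,2014-06-15,img/a3.png,12000",
    "a4,ParkA,2014-07-15,img/a4.png,-5"
  ))
  records <- load_manifest(path)
  expect_equal(records$record_id, "a1")
  errs <- attr(records, "row_errors")
  expect_setequal(errs$record_id, c("a2", "a3", "a4"))
  expect_equal(errs$reason[errs$record_id == "a2"], "unparseable timestamp")
  expect_equal(errs$reason[errs$record_id == "a3"], "missing park")
})

test_that("duplicate record ids and bad headers are fatal", {
  path <- write_tiny_manifest(c(
    "a1,ParkA,2014-06-15,img/a1.png,12000",
    "a1,ParkA,2014-07-15,img/a2.png,12000"
  ))
  expect_error(load_manifest(path), "duplicate record_id")
  bad <- file.path(withr::local_tempdir(), "bad.csv")
  writeLines(c("id,park,when,file,size", "a,b,c,d,1"), bad)
  expect_error(load_manifest(bad), "malformed manifest header")
  expect_error(load_manifest(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("a synthetic manifest loads with one record per row", {
  corp <- tiny_corpus(profile = tiny_profile(counts = rep(4L, 12),
                                             duplicate_rate = 0.1))
  records <- load_manifest(file.path(corp$out_dir, "manifest.csv"))
  expect_equal(nrow(records), nrow(corp$manifest))
  expect_true(all(file.exists(records$filepath)))
})

test_that("size filter removes strictly-undersized files; earliest duplicate wins", {
  dir <- withr::local_tempdir()
  write_px <- function(name, value, n = 6) {
    img <- array(value / 255, dim = c(n, n, 3))
    png::writePNG(img, file.path(dir, name))
    file.size(file.path(dir, name))
  }
  b1 <- write_px("a.png", 100)
  b2 <- write_px("b.png", 100)   # byte-identical to a.png
  b3 <- write_px("c.png", 120)
  records <- data.frame(
    record_id = c("r-2", "r-1", "r-3"),
    park = "P",
    timestamp = as.Date(c("2014-06-15", "2014-05-15", "2014-06-15")),
    filepath = file.path(dir, c("a.png", "b.png", "c.png")),
    bytes = c(b1, b2, b3),
    stringsAsFactors = FALSE
  )
  out <- filter_corpus(records, min_bytes = 10240)
  # everything is tiny here: all removed as undersized
  expect_equal(out$report$n_undersized_removed, 3)
  expect_equal(out$report$n_retained, 0)

  out <- filter_corpus(records, min_bytes = 1)
  # a.png and b.png identical; r-1 has the earlier timestamp and is kept
  expect_setequal(out$retained$record_id, c("r-1", "r-3"))
  expect_equal(out$report$n_duplicates_removed, 1)
  expect_equal(out$report$removed$reason[out$report$removed$record_id == "r-2"],
               "duplicate")
})

test_that("timestamp ties among duplicates break by smallest record id", {
  dir <- withr::local_tempdir()
  img <- array(0.5, dim = c(5, 5, 3))
  png::writePNG(img, file.path(dir, "x.png"))
  file.copy(file.path(dir, "x.png"), file.path(dir, "y.png"))
  records <- data.frame(
    record_id = c("zz", "aa"),
    park = "P",
    timestamp = as.Date(c("2014-06-15", "2014-06-15")),
    filepath = file.path(dir, c("x.png", "y.png")),
    bytes = rep(file.size(file.path(dir, "x.png")), 2),
    stringsAsFactors = FALSE
  )
  out <- filter_corpus(records, min_bytes = 1)
  expect_equal(out$retained$record_id, "aa")
})

test_that("filter accounting reconciles, is idempotent and order-invariant", {
  corp <- tiny_corpus(profile = tiny_profile(
    counts = rep(6L, 12), duplicate_rate = 0.08, undersized_rate = 0.08))
  records <- load_manifest(file.path(corp$out_dir, "manifest.csv"))
  out <- filter_corpus(records)
  rep1 <- out$report
  expect_equal(rep1$n_input,
               rep1$n_retained + rep1$n_duplicates_removed +
                 rep1$n_undersized_removed + rep1$n_unreadable)
  # exactly the injected contaminants are removed
  expect_setequal(
    rep1$removed$record_id,
    corp$truth$record_id[corp$truth$class %in% c("duplicate", "undersized")])
  # idempotence
  again <- filter_corpus(out$retained)
  expect_equal(again$report$n_retained, rep1$n_retained)
  expect_equal(nrow(again$report$removed), 0)
  # order invariance of the retained set
  shuffled <- records[rev(seq_len(nrow(records))), ]
  out2 <- filter_corpus(shuffled)
  expect_setequal(out2$retained$record_id, out$retained$record_id)
})

test_that("missing files are removed and reported as unreadable", {
  corp <- tiny_corpus(profile = tiny_profile(counts = rep(2L, 12)))
  records <- load_manifest(file.path(corp$out_dir, "manifest.csv"))
  unlink(records$filepath[1])
  out <- filter_corpus(records)
  expect_equal(out$report$n_unreadable, 1)
  expect_equal(out$report$removed$reason[
    out$report$removed$record_id == records$record_id[1]], "unreadable")
  expect_equal(out$report$n_retained, nrow(records) - 1)
})
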