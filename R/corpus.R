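#' Load an image-corpus manifest
#'
#' Reads the manifest CSV dialect (`record_id,park,timestamp,filepath,bytes`,
#' ISO-8601 timestamps) into a record table. Rows with a missing park label
#' or an unparseable timestamp are rejected and collected into a per-row
#' error report; a duplicated `record_id` is fatal, since downstream
#' accounting relies on unique ids. Relative `filepath`s are resolved
#' against the manifest's directory.
#'
#' @param path manifest CSV path.
#' @return a data.frame of records (`record_id`, `park`, `timestamp` as
#'   `Date`, `filepath`, `bytes`) with a `row_errors` attribute
#'   (data.frame `row`, `record_id`, `reason`).
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("record_id", "park", "timestamp", "filepath", "bytes")
  if (!identical(names(raw)[seq_along(required)], required)) {
    stop("malformed manifest header; expected: ", paste(required, collapse = ","))
  }
  if (nrow(raw) == 0) {
    out <- data.frame(record_id = character(0), park = character(0),
                      timestamp = as.Date(character(0)),
                      filepath = character(0), bytes = integer(0),
                      stringsAsFactors = FALSE)
    attr(out, "row_errors") <- data.frame(row = integer(0),
                                          record_id = character(0),
                                          reason = character(0))
    return(out)
  }
  if (anyDuplicated(raw$record_id)) {
    stop("duplicate record_id in manifest: ",
         raw$record_id[duplicated(raw$record_id)][1])
  }
  ts <- as.Date(substr(raw$timestamp, 1, 10), format = "%Y-%m-%d")
  bytes <- suppressWarnings(as.integer(raw$bytes))
  bad_park <- is.na(raw$park) | !nzchar(trimws(raw$park))
  bad_ts <- is.na(ts)
  bad_bytes <- is.na(bytes) | bytes < 0
  bad <- bad_park | bad_ts | bad_bytes
  reason <- rep("", nrow(raw))
  reason[bad_bytes] <- "invalid byte count"
  reason[bad_ts] <- "unparseable timestamp"
  reason[bad_park] <- "missing park"
  filepath <- ifelse(grepl("^(/|[A-Za-z]:)", raw$filepath), raw$filepath,
                     file.path(dirname(path), raw$filepath))
  out <- data.frame(
    record_id = raw$record_id[!bad],
    park = raw$park[!bad],
    timestamp = ts[!bad],
    filepath = filepath[!bad],
    bytes = bytes[!bad],
    stringsAsFactors = FALSE
  )
  attr(out, "row_errors") <- data.frame(
    row = which(bad), record_id = raw$record_id[bad], reason = reason[bad],
    stringsAsFactors = FALSE
  )
  out
}

#' Filter a corpus: drop undersized files and exact duplicates
#'
#' Applies the two corpus-cleaning rules used before any greenness
#' computation: (1) records whose file is smaller than `min_bytes`
#' (default 10,240 bytes, i.e. 10 kB binary) are removed; (2) among each
#' set of byte-identical files (MD5 content hash), only the
#' earliest-timestamped record is retained, ties broken by the
#' lexicographically smallest `record_id`. Records whose file is missing
#' or unreadable are removed with reason `"unreadable"` and reported
#' separately. The retained set does not depend on input order.
#'
#' @param records a manifest data.frame from [load_manifest()].
#' @param min_bytes size threshold in bytes; strictly smaller files are
#'   removed.
#' @return a list with `retained` (data.frame of surviving records, input
#'   order preserved) and `report`, a `filter_report` list with counts
#'   `n_input`, `n_undersized_removed`, `n_duplicates_removed`,
#'   `n_unreadable`, `n_retained` and a data.frame `removed`
#'   (`record_id`, `reason`).
#' @export
filter_corpus <- function(records, min_bytes = 10240L) {
  stopifnot(is.data.frame(records), min_bytes >= 0)
  n_input <- nrow(records)
  exists <- file.exists(records$filepath)
  unreadable_ids <- records$record_id[!exists]
  rec <- records[exists, , drop = FALSE]

  undersized <- rec$bytes < min_bytes
  undersized_ids <- rec$record_id[undersized]
  rec <- rec[!undersized, , drop = FALSE]

  dup_ids <- character(0)
  if (nrow(rec) > 0) {
    hashes <- unname(tools::md5sum(rec$filepath))
    # order-independent tie-break: earliest timestamp, then smallest id
    ord <- order(hashes, rec$timestamp, rec$record_id)
    keep_first <- !duplicated(hashes[ord])
    dup_ids <- rec$record_id[ord][!keep_first]
    rec <- rec[!(rec$record_id %in% dup_ids), , drop = FALSE]
  }

  removed <- data.frame(
    record_id = c(unreadable_ids, undersized_ids, dup_ids),
    reason = c(rep("unreadable", length(unreadable_ids)),
               rep("undersized", length(undersized_ids)),
               rep("duplicate", length(dup_ids))),
    stringsAsFactors = FALSE
  )
  report <- structure(
    list(
      n_input = n_input,
      n_undersized_removed = length(undersized_ids),
      n_duplicates_removed = length(dup_ids),
      n_unreadable = length(unreadable_ids),
      n_retained = nrow(rec),
      min_bytes = as.integer(min_bytes),
      removed = removed
    ),
    class = "filter_report"
  )
  stopifnot(report$n_input == report$n_retained + nrow(removed))
  list(retained = rec, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    paste0("<filter_report> %d records in: %d retained, %d duplicates, ",
           "%d undersized (< %d bytes), %d unreadable\n"),
    x$n_input, x$n_retained, x$n_duplicates_removed,
    x$n_undersized_removed, x$min_bytes, x$n_unreadable
  ))
  invisible(x)
}

#' Write a filter report as CSV
#'
#' @param report a `filter_report` from [filter_corpus()].
#' @param path output CSV path (one row of counts); the per-record removal
#'   list is written alongside as `<path base>_removed.csv`.
#' @export
write_filter_report <- function(report, path) {
  counts <- data.frame(
    n_input = report$n_input,
    n_duplicates_removed = report$n_duplicates_removed,
    n_undersized_removed = report$n_undersized_removed,
    n_unreadable = report$n_unreadable,
    n_retained = report$n_retained,
    min_bytes = report$min_bytes
  )
  utils::write.csv(counts, path, row.names = FALSE)
  removed_path <- paste0(tools::file_path_sans_ext(path), "_removed.csv")
  utils::write.csv(report$removed, removed_path, row.names = FALSE)
  invisible(path)
}
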