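#' Round half away from zero
#'
#' Deterministic rounding used throughout the synthetic image construction,
#' in contrast to [base::round()]'s round-half-to-even.
#'
#' @param x numeric vector.
#' @return `x` rounded to the nearest integer, ties going away from zero.
#' @keywords internal
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Derive a reproducible child seed from a root seed and string labels
#'
#' Statistics for different groups (park, month, season) are computed under
#' independently seeded RNG streams so that results do not depend on the
#' iteration order over groups. The child seed is a deterministic hash of
#' the root seed and the labels, kept within the 32-bit integer range.
#'
#' @param root_seed integer root seed.
#' @param ... character or numeric labels identifying the stream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(root_seed, ...) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1)
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.numeric(root_seed) %% m
  labels <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                         character(1)), collapse = "\r")
  for (code in utf8ToInt(labels)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

# month index (1-based, possibly > 12 across years) -> calendar month 1..12
calendar_month <- function(month_index) {
  ((month_index - 1L) %% 12L) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
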