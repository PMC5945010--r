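#' Bootstrap settings
#'
#' @param n_reps number of bootstrap resamples (default 10,000, the
#'   convention for the percentile intervals reported throughout).
#' @param alpha two-sided miscoverage level; 0.05 gives 95% intervals.
#' @param seed integer root seed. Group-level statistics derive
#'   per-group child seeds from it (see [child_seed()]), so results do not
#'   depend on the order groups are processed in.
#' @return an object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_reps = 10000L, alpha = 0.05, seed = 1L) {
  stopifnot(n_reps >= 1, alpha > 0, alpha < 1, is.numeric(seed))
  structure(list(n_reps = as.integer(n_reps), alpha = alpha,
                 seed = as.integer(seed)),
            class = "bootstrap_config")
}

#' Percentile-bootstrap confidence interval of a statistic
#'
#' Draws `n_reps` resamples of the data, each of the original sample size
#' and with replacement, recomputes the statistic on each, and reports the
#' empirical `alpha/2` and `1 - alpha/2` quantiles as the confidence
#' interval. The point estimate is the statistic computed on the original
#' sample. With a single observation the interval degenerates to that
#' value and is flagged.
#'
#' @param values non-empty numeric vector.
#' @param statistic a function of a numeric vector returning one number;
#'   the sample mean by default (a fast vectorized path is used for it).
#' @param cfg a [bootstrap_config()].
#' @return a list: `estimate`, `ci_low`, `ci_high`, `n`, `degenerate`
#'   (TRUE when n = 1), and the method metadata (`n_reps`, `alpha`,
#'   `method = "percentile"`).
#' @export
bootstrap_ci <- function(values, statistic = mean, cfg = bootstrap_config()) {
  stopifnot(inherits(cfg, "bootstrap_config"))
  if (length(values) == 0) stop("bootstrap_ci: empty input")
  if (anyNA(values)) stop("bootstrap_ci: NA in input")
  estimate <- statistic(values)
  n <- length(values)
  if (n == 1) {
    return(list(estimate = estimate, ci_low = estimate, ci_high = estimate,
                n = 1L, degenerate = TRUE, n_reps = cfg$n_reps,
                alpha = cfg$alpha, method = "percentile"))
  }
  stats_boot <- withr::with_seed(cfg$seed, {
    idx <- sample.int(n, n * cfg$n_reps, replace = TRUE)
    if (identical(statistic, mean)) {
      .colMeans(values[idx], n, cfg$n_reps)
    } else {
      apply(matrix(values[idx], nrow = n), 2, statistic)
    }
  })
  ci <- stats::quantile(stats_boot, c(cfg$alpha / 2, 1 - cfg$alpha / 2),
                        names = FALSE)
  list(estimate = estimate, ci_low = ci[1], ci_high = ci[2], n = n,
       degenerate = FALSE, n_reps = cfg$n_reps, alpha = cfg$alpha,
       method = "percentile")
}
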