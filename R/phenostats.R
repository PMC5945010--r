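#' Monthly park-level greenness statistics
#'
#' Pools observations by (park, calendar month) across years and computes,
#' for each non-empty pool, the mean greenness, its percentile-bootstrap
#' confidence interval, the pool size, and the coefficient of variation
#' (sample SD / mean). Months with no observations are simply absent from
#' the output, never reported as zero. Each pool is bootstrapped under its
#' own child seed derived from `cfg$seed` and the group labels.
#'
#' @param obs observation data.frame with columns `park`, `month`,
#'   `greenness` (e.g. from [corpus_greenness()] or
#'   [truth_observations()]).
#' @param cfg a [bootstrap_config()].
#' @return a data.frame with columns `park`, `period` (calendar month,
#'   integer 1-12), `mean`, `ci_low`, `ci_high`, `n`, `cv`, `degenerate`.
#' @export
monthly_stats <- function(obs, cfg = bootstrap_config()) {
  stopifnot(all(c("park", "month", "greenness") %in% names(obs)))
  groups <- unique(obs[, c("park", "month")])
  groups <- groups[order(groups$park, groups$month), , drop = FALSE]
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    park <- groups$park[i]
    month <- groups$month[i]
    v <- obs$greenness[obs$park == park & obs$month == month]
    aggregate_row(v, park, month, cfg, child_seed(cfg$seed, "month", park, month))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Seasonal (JJA / DJF) park-level greenness statistics
#'
#' Pools observations by park and season using calendar-month labels
#' across the full year span (December is not shifted across year
#' boundaries), and computes the same statistics as [monthly_stats()].
#' A park-season with no observations is absent from the output, with a
#' warning.
#'
#' @inheritParams monthly_stats
#' @param seasons named list of calendar-month vectors defining the season
#'   pools; the default is meteorological summer (June-August) and winter
#'   (December-February).
#' @return a data.frame with columns `park`, `period` (season label),
#'   `mean`, `ci_low`, `ci_high`, `n`, `cv`, `degenerate`.
#' @export
seasonal_stats <- function(obs, cfg = bootstrap_config(),
                           seasons = list(JJA = c(6, 7, 8), DJF = c(12, 1, 2))) {
  stopifnot(all(c("park", "month", "greenness") %in% names(obs)),
            length(names(seasons)) == length(seasons))
  parks <- sort(unique(obs$park))
  rows <- list()
  for (park in parks) {
    for (season in names(seasons)) {
      v <- obs$greenness[obs$park == park & obs$month %in% seasons[[season]]]
      if (length(v) == 0) {
        warning("no observations for ", park, " in ", season, "; entry omitted")
        next
      }
      rows[[length(rows) + 1L]] <- aggregate_row(
        v, park, season, cfg, child_seed(cfg$seed, "season", park, season))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

aggregate_row <- function(v, park, period, cfg, seed) {
  # resample the sorted pool so results are invariant to input row order
  v <- sort(v)
  ci <- bootstrap_ci(v, mean, bootstrap_config(cfg$n_reps, cfg$alpha, seed))
  data.frame(
    park = park, period = period,
    mean = ci$estimate, ci_low = ci$ci_low, ci_high = ci$ci_high,
    n = ci$n,
    cv = if (length(v) > 1) stats::sd(v) / mean(v) else NA_real_,
    degenerate = ci$degenerate,
    stringsAsFactors = FALSE
  )
}

#' Summer-winter greenness contrast per park
#'
#' Bootstraps the difference in mean greenness between the summer and
#' winter pools of each park (each replicate resamples the two pools
#' independently) and reports the percentile interval of the difference.
#' The contrast is flagged significant at the `1 - alpha` level when the
#' interval excludes zero. For reference against the visual reading of
#' interval plots, `overlap_significant` additionally records whether the
#' two seasons' own confidence intervals fail to overlap (a more
#' conservative criterion). Parks missing either pool are omitted with a
#' warning.
#'
#' @inheritParams seasonal_stats
#' @param summer,winter calendar-month vectors defining the two pools.
#' @return a data.frame with columns `park`, `diff_mean` (summer minus
#'   winter), `diff_ci_low`, `diff_ci_high`, `significant_95`,
#'   `overlap_significant`, `n_summer`, `n_winter`.
#' @export
season_contrast <- function(obs, cfg = bootstrap_config(),
                            summer = c(6, 7, 8), winter = c(12, 1, 2)) {
  stopifnot(all(c("park", "month", "greenness") %in% names(obs)))
  parks <- sort(unique(obs$park))
  rows <- list()
  for (park in parks) {
    s <- obs$greenness[obs$park == park & obs$month %in% summer]
    w <- obs$greenness[obs$park == park & obs$month %in% winter]
    if (length(s) == 0 || length(w) == 0) {
      warning("missing season pool for ", park, "; contrast omitted")
      next
    }
    s <- sort(s)  # order invariance, as in aggregate_row
    w <- sort(w)
    seed <- child_seed(cfg$seed, "contrast", park)
    diffs <- withr::with_seed(seed, {
      si <- sample.int(length(s), length(s) * cfg$n_reps, replace = TRUE)
      wi <- sample.int(length(w), length(w) * cfg$n_reps, replace = TRUE)
      .colMeans(s[si], length(s), cfg$n_reps) -
        .colMeans(w[wi], length(w), cfg$n_reps)
    })
    ci <- stats::quantile(diffs, c(cfg$alpha / 2, 1 - cfg$alpha / 2),
                          names = FALSE)
    s_ci <- bootstrap_ci(s, mean, bootstrap_config(
      cfg$n_reps, cfg$alpha, child_seed(cfg$seed, "season", park, "JJA")))
    w_ci <- bootstrap_ci(w, mean, bootstrap_config(
      cfg$n_reps, cfg$alpha, child_seed(cfg$seed, "season", park, "DJF")))
    rows[[length(rows) + 1L]] <- data.frame(
      park = park,
      diff_mean = mean(s) - mean(w),
      diff_ci_low = ci[1], diff_ci_high = ci[2],
      significant_95 = ci[1] > 0 || ci[2] < 0,
      overlap_significant = s_ci$ci_low > w_ci$ci_high ||
        w_ci$ci_low > s_ci$ci_high,
      n_summer = length(s), n_winter = length(w),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
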