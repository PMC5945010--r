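#' Select NDVI grid cells near a park center
#'
#' Keeps cells whose Euclidean distance in degree space,
#' `sqrt(dlat^2 + dlon^2)`, is at most `radius_deg` from the center
#' (boundary inclusive, with a 1e-9 degree tolerance against floating-point
#' jitter on lattice boundaries). A square lat/lon box of half-width
#' `radius_deg` is available as an alternative interpretation.
#'
#' @param cells NDVI grid data.frame (`lat`, `lon`, `month`, `ndvi`).
#' @param center numeric `c(lat, lon)` of the park center.
#' @param radius_deg selection radius in degrees (default 0.5).
#' @param method `"radius"` (Euclidean, default) or `"box"`.
#' @param park optional park name used in the empty-selection error.
#' @return the subset of `cells` within range.
#' @export
select_park_cells <- function(cells, center, radius_deg = 0.5,
                              method = c("radius", "box"), park = NULL) {
  method <- match.arg(method)
  stopifnot(length(center) == 2, radius_deg > 0)
  dlat <- cells$lat - center[1]
  dlon <- cells$lon - center[2]
  tol <- 1e-9
  inside <- if (method == "radius") {
    sqrt(dlat^2 + dlon^2) <= radius_deg + tol
  } else {
    abs(dlat) <= radius_deg + tol & abs(dlon) <= radius_deg + tol
  }
  if (!any(inside)) {
    stop("no NDVI cells within ", radius_deg, " degrees of ",
         if (is.null(park)) "the park center" else park)
  }
  cells[inside, , drop = FALSE]
}

#' Monthly mean NDVI over a cell selection
#'
#' @param cells NDVI cells (typically from [select_park_cells()]).
#' @return a data.frame `month`, `ndvi_mean`, `n_cells`; months with no
#'   cells are absent.
#' @export
monthly_ndvi <- function(cells) {
  if (nrow(cells) == 0) stop("empty NDVI cell selection")
  months <- sort(unique(cells$month))
  data.frame(
    month = months,
    ndvi_mean = vapply(months, function(m) mean(cells$ndvi[cells$month == m]),
                       numeric(1)),
    n_cells = vapply(months, function(m) sum(cells$month == m), integer(1))
  )
}

#' Pair park-month greenness means with park-month NDVI means
#'
#' For each park, selects the NDVI cells within `radius_deg` of its center,
#' aggregates them by month, and joins the result to the park's monthly
#' greenness means. Park-months missing either series are skipped; nothing
#' is imputed.
#'
#' @param monthly data.frame from [monthly_stats()] (columns `park`,
#'   `period`, `mean`).
#' @param ndvi_grid NDVI grid data.frame covering all parks.
#' @param centers data.frame `park`, `lat`, `lon` (e.g.
#'   [default_park_centers()]).
#' @param radius_deg cell-selection radius in degrees.
#' @param method passed to [select_park_cells()].
#' @return a data.frame `park`, `month`, `greenness_mean`, `ndvi_mean`.
#' @export
pair_series <- function(monthly, ndvi_grid, centers, radius_deg = 0.5,
                        method = "radius") {
  stopifnot(all(c("park", "period", "mean") %in% names(monthly)),
            all(c("park", "lat", "lon") %in% names(centers)))
  rows <- list()
  for (i in seq_len(nrow(centers))) {
    park <- centers$park[i]
    g <- monthly[monthly$park == park, ]
    if (nrow(g) == 0) next
    cells <- select_park_cells(ndvi_grid, c(centers$lat[i], centers$lon[i]),
                               radius_deg, method, park = park)
    nd <- monthly_ndvi(cells)
    common <- intersect(g$period, nd$month)
    if (length(common) == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      park = park,
      month = as.integer(common),
      greenness_mean = g$mean[match(common, g$period)],
      ndvi_mean = nd$ndvi_mean[match(common, nd$month)],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pooled greenness-NDVI correlation with bootstrap uncertainty
#'
#' Computes Pearson and Spearman correlations over all (park, month) pairs
#' pooled together, and a percentile-bootstrap confidence interval for the
#' Pearson coefficient by resampling pairs with replacement. Per-park
#' correlations are deliberately not computed: with only 12 months per
#' park such coefficients are too unstable to be informative. The Spearman
#' coefficient is reported as a point estimate only.
#'
#' @param pairs data.frame from [pair_series()] (columns `greenness_mean`,
#'   `ndvi_mean`); at least 3 rows.
#' @param cfg a [bootstrap_config()].
#' @return a one-row data.frame: `pearson_r`, `pearson_ci_low`,
#'   `pearson_ci_high`, `spearman_rho`, `n_pairs`, `n_reps`, `alpha`,
#'   `method`.
#' @export
correlate_series <- function(pairs, cfg = bootstrap_config()) {
  stopifnot(all(c("greenness_mean", "ndvi_mean") %in% names(pairs)))
  x <- pairs$greenness_mean
  y <- pairs$ndvi_mean
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs to correlate")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("degenerate series: zero variance")
  r <- stats::cor(x, y)
  rho <- stats::cor(x, y, method = "spearman")
  boot_r <- withr::with_seed(child_seed(cfg$seed, "correlation"), {
    vapply(seq_len(cfg$n_reps), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      if (stats::sd(x[idx]) == 0 || stats::sd(y[idx]) == 0) NA_real_
      else stats::cor(x[idx], y[idx])
    }, numeric(1))
  })
  boot_r <- boot_r[!is.na(boot_r)]
  ci <- stats::quantile(boot_r, c(cfg$alpha / 2, 1 - cfg$alpha / 2),
                        names = FALSE)
  data.frame(
    pearson_r = r, pearson_ci_low = ci[1], pearson_ci_high = ci[2],
    spearman_rho = rho, n_pairs = n,
    n_reps = cfg$n_reps, alpha = cfg$alpha, method = "percentile",
    stringsAsFactors = FALSE
  )
}
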