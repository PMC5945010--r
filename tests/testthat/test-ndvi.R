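lattice_cells <- function(center, step = 0.1, n_half = 5) {
  offs <- step * (-n_half:n_half)
  g <- expand.grid(lat = center[1] + offs, lon = center[2] + offs,
                   month = 1L, KEEP.OUT.ATTRS = FALSE)
  g$ndvi <- 0.5
  g
}

test_that("radius selection is boundary-inclusive and matches brute force", {
  center <- c(40.4, -105.7)
  cells <- lattice_cells(center)
  sel <- select_park_cells(cells, center, 0.5)
  # brute-force scan oracle
  brute <- cells[sqrt((cells$lat - center[1])^2 + (cells$lon - center[2])^2)
                 <= 0.5 + 1e-9, ]
  expect_equal(nrow(sel), 81)  # lattice points with i^2 + j^2 <= 25
  expect_equal(sel, brute)
  # center cell and exact-boundary cell included
  expect_true(any(sel$lat == center[1] & sel$lon == center[2]))
  expect_true(any(abs(sel$lat - center[1] - 0.5) < 1e-9 &
                    sel$lon == center[2]))
})

test_that("selection agrees with brute force across random lattices", {
  withr::local_seed(31)
  for (i in 1:10) {
    center <- c(runif(1, 30, 50), runif(1, -125, -65))
    step <- sample(c(0.05, 0.1, 0.25), 1)
    r <- runif(1, 0.2, 0.8)
    cells <- lattice_cells(center, step, sample(3:8, 1))
    brute <- cells[sqrt((cells$lat - center[1])^2 +
                          (cells$lon - center[2])^2) <= r + 1e-9, ]
    if (nrow(brute) == 0) {
      expect_error(select_park_cells(cells, center, r))
    } else {
      expect_equal(select_park_cells(cells, center, r), brute)
    }
  }
})

test_that("box selection keeps the full square neighborhood", {
  center <- c(40, -105)
  cells <- lattice_cells(center)
  sel <- select_park_cells(cells, center, 0.5, method = "box")
  expect_equal(nrow(sel), 121)
  expect_error(select_park_cells(cells, c(0, 0), 0.5), "no NDVI cells")
})

test_that("monthly NDVI means aggregate cells per month, absent months dropped", {
  cells <- data.frame(lat = 40, lon = -105,
                      month = c(1, 1, 2), ndvi = c(0.2, 0.4, 0.9))
  m <- monthly_ndvi(cells)
  expect_equal(m$ndvi_mean[m$month == 1], 0.3)
  expect_equal(m$n_cells, c(2L, 1L))
  expect_setequal(m$month, c(1, 2))
})

test_that("pairing joins park-months present in both series", {
  monthly <- data.frame(park = "P", period = c(1, 2, 3),
                        mean = c(0.30, 0.32, 0.34))
  grid <- rbind(
    data.frame(lat = 40, lon = -105, month = c(1, 2), ndvi = c(0.3, 0.4)),
    data.frame(lat = 40, lon = -105, month = 12, ndvi = 0.1)
  )
  centers <- data.frame(park = "P", lat = 40, lon = -105)
  pairs <- pair_series(monthly, grid, centers)
  expect_equal(pairs$month, c(1L, 2L))  # month 3 and 12 unmatched
  expect_equal(pairs$ndvi_mean, c(0.3, 0.4))
})

test_that("perfect linear coupling yields exactly unit correlations", {
  g <- seq(0.25, 0.40, length.out = 24)
  pairs <- data.frame(greenness_mean = g, ndvi_mean = 2 * g + 1)
  res <- correlate_series(pairs, bootstrap_config(500, seed = 1))
  expect_equal(res$pearson_r, 1)
  expect_equal(res$spearman_rho, 1)
  expect_equal(res$n_pairs, 24)
})

test_that("independent noise gives a near-zero r whose CI straddles zero", {
  withr::local_seed(17)
  pairs <- data.frame(greenness_mean = rnorm(300, 0.33, 0.03),
                      ndvi_mean = rnorm(300, 0.4, 0.1))
  res <- correlate_series(pairs, bootstrap_config(2000, seed = 2))
  expect_lt(abs(res$pearson_r), 0.15)
  expect_lt(res$pearson_ci_low, 0)
  expect_gt(res$pearson_ci_high, 0)
})

test_that("Pearson is affine-invariant; Spearman is monotone-invariant", {
  withr::local_seed(23)
  g <- rnorm(50, 0.33, 0.03)
  v <- 0.1 + 0.8 * g + rnorm(50, 0, 0.02)
  cfg <- bootstrap_config(500, seed = 4)
  base <- correlate_series(data.frame(greenness_mean = g, ndvi_mean = v), cfg)
  affine <- correlate_series(
    data.frame(greenness_mean = g, ndvi_mean = 3 * v - 0.2), cfg)
  expect_equal(affine$pearson_r, base$pearson_r)
  mono <- correlate_series(
    data.frame(greenness_mean = g, ndvi_mean = exp(v)), cfg)
  expect_equal(mono$spearman_rho, base$spearman_rho)
})

test_that("degenerate and undersized pair sets are rejected", {
  expect_error(correlate_series(
    data.frame(greenness_mean = c(1, 2), ndvi_mean = c(1, 2))), "at least 3")
  expect_error(correlate_series(
    data.frame(greenness_mean = rep(0.3, 10), ndvi_mean = rnorm(10))),
    "degenerate")
})
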