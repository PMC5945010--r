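#' Default pipeline configuration
#'
#' A flat key-value configuration driving the simulate / analyze / report
#' stages. All analysis thresholds are overridable here; the defaults are
#' the study values: a 10,240-byte size filter, a 0.5-degree NDVI selection
#' radius, 10,000 bootstrap replicates at alpha 0.05, and JJA / DJF season
#' pools.
#'
#' @param out_dir run directory; simulated inputs go to `out_dir/data`,
#'   analysis outputs to `out_dir/results`.
#' @param seed root seed for every random stage.
#' @param n_reps,alpha bootstrap settings.
#' @param min_bytes corpus size-filter threshold (bytes).
#' @param radius_deg NDVI cell-selection radius (degrees).
#' @param radius_method `"radius"` or `"box"` cell selection.
#' @param summer_months,winter_months calendar months of the season pools.
#' @param year_span,start_year simulated period (months, first year).
#' @param image_width,image_height,pixel_noise_sd,image_format synthetic
#'   image parameters (see [generate_corpus()]).
#' @param write_images whether `run_simulate` writes image files (set
#'   `FALSE` for statistics-only experiments; `run_analyze` then reads
#'   greenness from the truth table instead of decoding files).
#' @return a named list of class `run_config`.
#' @export
default_config <- function(out_dir = "phenogreen-run",
                           seed = 1L,
                           n_reps = 10000L,
                           alpha = 0.05,
                           min_bytes = 10240L,
                           radius_deg = 0.5,
                           radius_method = "radius",
                           summer_months = c(6L, 7L, 8L),
                           winter_months = c(12L, 1L, 2L),
                           year_span = 24L,
                           start_year = 2014L,
                           image_width = 80L,
                           image_height = 80L,
                           pixel_noise_sd = 0.05,
                           image_format = "png",
                           write_images = TRUE) {
  structure(
    list(out_dir = out_dir, seed = as.integer(seed),
         n_reps = as.integer(n_reps), alpha = alpha,
         min_bytes = as.integer(min_bytes), radius_deg = radius_deg,
         radius_method = radius_method,
         summer_months = as.integer(summer_months),
         winter_months = as.integer(winter_months),
         year_span = as.integer(year_span),
         start_year = as.integer(start_year),
         image_width = as.integer(image_width),
         image_height = as.integer(image_height),
         pixel_noise_sd = pixel_noise_sd,
         image_format = image_format,
         write_images = isTRUE(write_images)),
    class = "run_config"
  )
}

#' Load a pipeline configuration from a YAML file
#'
#' The file is a flat key-value document; keys not present fall back to
#' [default_config()] values, and unknown keys are a configuration error.
#'
#' @param path YAML config path.
#' @param ... overrides applied after the file (e.g. `seed`, `out_dir`).
#' @return a `run_config` list.
#' @export
load_run_config <- function(path = NULL, ...) {
  base <- default_config()
  overrides <- list(...)
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    file_cfg <- yaml::read_yaml(path)
    unknown <- setdiff(names(file_cfg), names(base))
    if (length(unknown) > 0) {
      stop("unknown config keys: ", paste(unknown, collapse = ", "))
    }
    base[names(file_cfg)] <- file_cfg
  }
  unknown <- setdiff(names(overrides), names(base))
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  base[names(overrides)] <- overrides
  do.call(default_config, base[setdiff(names(base), character(0))])
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}

#' Simulate the full synthetic study inputs
#'
#' Generates the default eight-park image corpus (manifest, truth table,
#' image files) and a synthetic NDVI grid around every park center, all
#' under `out_dir/data`, together with a `scenario.yaml` describing the
#' run (seed, configuration hash, per-park profile parameters).
#'
#' @param config a `run_config` (see [default_config()]).
#' @param profiles park profiles; defaults to [default_park_profiles()].
#' @param centers park centers; defaults to [default_park_centers()].
#' @param ndvi_spec_fn function mapping a center `c(lat, lon)` to an
#'   [ndvi_coupling_spec()]; defaults to the standard coupling.
#' @return a list with `manifest`, `truth`, `ndvi_grid`, `data_dir`,
#'   invisibly.
#' @export
run_simulate <- function(config = default_config(),
                         profiles = default_park_profiles(),
                         centers = default_park_centers(),
                         ndvi_spec_fn = ndvi_coupling_spec) {
  data_dir <- file.path(config$out_dir, "data")
  dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)
  corpus <- generate_corpus(
    profiles, data_dir, seed = config$seed,
    year_span = config$year_span, start_year = config$start_year,
    image_width = config$image_width, image_height = config$image_height,
    pixel_noise_sd = config$pixel_noise_sd,
    write_images = config$write_images,
    format = config$image_format
  )
  grids <- lapply(seq_len(nrow(centers)), function(i) {
    park <- centers$park[i]
    prof <- profiles[[which(vapply(profiles, `[[`, character(1), "park_name") == park)]]
    generate_ndvi_grid(
      ndvi_spec_fn(c(centers$lat[i], centers$lon[i])),
      seasonal_profile(prof),
      seed = child_seed(config$seed, "ndvi", park)
    )
  })
  ndvi_grid <- do.call(rbind, grids)
  write_ndvi_grid(ndvi_grid, file.path(data_dir, "ndvi_grid.csv"))
  utils::write.csv(centers, file.path(data_dir, "park_centers.csv"),
                   row.names = FALSE)
  scenario <- list(
    seed = config$seed,
    config_hash = config_hash(config),
    n_parks = length(profiles),
    n_records = nrow(corpus$manifest),
    parks = lapply(profiles, function(p) {
      list(base_greenness = p$base_greenness,
           seasonal_amplitude = p$seasonal_amplitude,
           peak_month = p$peak_month,
           image_noise_sd = p$image_noise_sd,
           ad_contamination_rate = p$ad_contamination_rate,
           duplicate_rate = p$duplicate_rate,
           undersized_rate = p$undersized_rate)
    })
  )
  yaml::write_yaml(scenario, file.path(data_dir, "scenario.yaml"))
  invisible(list(manifest = corpus$manifest, truth = corpus$truth,
                 ndvi_grid = ndvi_grid, data_dir = data_dir))
}

#' Run the full analysis chain on simulated or external inputs
#'
#' Executes filter -> greenness -> monthly and seasonal statistics ->
#' summer-winter contrasts -> NDVI comparison, writing every result as CSV
#' under `out_dir/results` plus a `run_manifest.yaml` sidecar carrying the
#' seed, configuration hash and echo, package version, and per-stage
#' record counts. Any stage failure is re-raised with the stage name.
#'
#' When the corpus was simulated with `write_images = FALSE`, the
#' greenness stage reads realized values from the truth table (exact for
#' PNG corpora) instead of decoding files, and the duplicate/undersized
#' classes are dropped by truth-table class rather than by hashing.
#'
#' @param config a `run_config` whose `out_dir/data` holds the inputs
#'   (`manifest.csv`, `ndvi_grid.csv`, `park_centers.csv`, images).
#' @return a list with `observations`, `monthly`, `seasonal`, `contrasts`,
#'   `pairs`, `correlation`, `filter_report`, `results_dir`.
#' @export
run_analyze <- function(config = default_config()) {
  data_dir <- file.path(config$out_dir, "data")
  results_dir <- file.path(config$out_dir, "results")
  dir.create(results_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  cfg <- bootstrap_config(config$n_reps, config$alpha, config$seed)

  filter_report <- NULL
  if (config$write_images) {
    records <- stage("load_manifest",
                     load_manifest(file.path(data_dir, "manifest.csv")))
    filtered <- stage("filter", filter_corpus(records, config$min_bytes))
    filter_report <- filtered$report
    write_filter_report(filter_report,
                        file.path(results_dir, "filter_report.csv"))
    obs <- stage("greenness", corpus_greenness(filtered$retained))
  } else {
    obs <- stage("greenness_from_truth", {
      manifest <- load_manifest(file.path(data_dir, "manifest.csv"))
      truth <- utils::read.csv(file.path(data_dir, "truth.csv"),
                               stringsAsFactors = FALSE)
      truth_observations(list(manifest = manifest, truth = truth))
    })
  }
  utils::write.csv(obs, file.path(results_dir, "observations.csv"),
                   row.names = FALSE)

  seasons <- list(config$summer_months, config$winter_months)
  names(seasons) <- c("JJA", "DJF")
  monthly <- stage("monthly_stats", monthly_stats(obs, cfg))
  seasonal <- stage("seasonal_stats", seasonal_stats(obs, cfg, seasons))
  contrasts <- stage("season_contrast",
                     season_contrast(obs, cfg, config$summer_months,
                                     config$winter_months))
  boot_meta <- function(df) {
    df$n_reps <- cfg$n_reps; df$alpha <- cfg$alpha
    df$seed <- cfg$seed; df$method <- "percentile"
    df
  }
  utils::write.csv(boot_meta(monthly),
                   file.path(results_dir, "monthly_stats.csv"), row.names = FALSE)
  utils::write.csv(boot_meta(seasonal),
                   file.path(results_dir, "seasonal_stats.csv"), row.names = FALSE)
  utils::write.csv(boot_meta(contrasts),
                   file.path(results_dir, "season_contrasts.csv"), row.names = FALSE)

  ndvi_grid <- stage("ndvi_load",
                     load_ndvi_grid(file.path(data_dir, "ndvi_grid.csv")))
  centers <- utils::read.csv(file.path(data_dir, "park_centers.csv"),
                             stringsAsFactors = FALSE)
  pairs <- stage("pair_series",
                 pair_series(monthly, ndvi_grid, centers,
                             config$radius_deg, config$radius_method))
  correlation <- stage("correlate", correlate_series(pairs, cfg))
  utils::write.csv(pairs, file.path(results_dir, "paired_series.csv"),
                   row.names = FALSE)
  utils::write.csv(correlation, file.path(results_dir, "correlation.csv"),
                   row.names = FALSE)

  run_manifest <- list(
    package_version = as.character(utils::packageVersion("phenogreen")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = config_hash(config),
    config = unclass(config),
    counts = list(
      observations = nrow(obs),
      park_months = nrow(monthly),
      pairs = nrow(pairs),
      filtered_input = if (is.null(filter_report)) NA else filter_report$n_input,
      filtered_retained = if (is.null(filter_report)) NA else filter_report$n_retained
    )
  )
  yaml::write_yaml(run_manifest, file.path(results_dir, "run_manifest.yaml"))
  invisible(list(observations = obs, monthly = monthly, seasonal = seasonal,
                 contrasts = contrasts, pairs = pairs,
                 correlation = correlation, filter_report = filter_report,
                 results_dir = results_dir))
}

#' Render a plain-text summary of an analysis run
#'
#' Writes `report.md` under `out_dir/results`: seasonal means with their
#' intervals and significance flags, the monthly greenness table (absent
#' months shown as a dash), and the pooled correlation row.
#'
#' @param config the `run_config` of a completed [run_analyze()] run.
#' @return the report text as a character vector, invisibly; also written
#'   to `out_dir/results/report.md`.
#' @export
run_report <- function(config = default_config()) {
  results_dir <- file.path(config$out_dir, "results")
  need <- file.path(results_dir,
                    c("seasonal_stats.csv", "monthly_stats.csv",
                      "season_contrasts.csv", "correlation.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing) > 0) {
    stop("analysis outputs missing; run run_analyze() first: ",
         paste(basename(missing), collapse = ", "))
  }
  seasonal <- utils::read.csv(need[1], stringsAsFactors = FALSE)
  monthly <- utils::read.csv(need[2], stringsAsFactors = FALSE)
  contrasts <- utils::read.csv(need[3], stringsAsFactors = FALSE)
  correlation <- utils::read.csv(need[4], stringsAsFactors = FALSE)

  # prefer the run manifest's metadata: it reflects the analyze-time config
  manifest_path <- file.path(results_dir, "run_manifest.yaml")
  meta <- config
  if (file.exists(manifest_path)) {
    rm_meta <- yaml::read_yaml(manifest_path)
    meta$seed <- rm_meta$seed %||% config$seed
    meta$n_reps <- rm_meta$config$n_reps %||% config$n_reps
    meta$alpha <- rm_meta$config$alpha %||% config$alpha
  }
  fmt <- function(x) sprintf("%.3f", x)
  lines <- c(
    "# Greenness phenology report",
    "",
    sprintf("Seed %d, %d bootstrap replicates, alpha %.2f.",
            meta$seed, meta$n_reps, meta$alpha),
    "",
    "## Seasonal greenness (mean [95% CI], n)",
    "",
    "| Park | JJA | DJF | Summer - winter | Significant |",
    "|---|---|---|---|---|"
  )
  parks <- sort(unique(seasonal$park))
  cell <- function(df, park, period) {
    row <- df[df$park == park & df$period == period, ]
    if (nrow(row) == 0) return("–")
    sprintf("%s [%s, %s] (n=%d)", fmt(row$mean), fmt(row$ci_low),
            fmt(row$ci_high), row$n)
  }
  for (park in parks) {
    ct <- contrasts[contrasts$park == park, ]
    diff_txt <- if (nrow(ct) == 0) "–" else
      sprintf("%s [%s, %s]", fmt(ct$diff_mean), fmt(ct$diff_ci_low),
              fmt(ct$diff_ci_high))
    sig_txt <- if (nrow(ct) == 0) "–" else if (ct$significant_95) "yes" else "no"
    lines <- c(lines, sprintf("| %s | %s | %s | %s | %s |", park,
                              cell(seasonal, park, "JJA"),
                              cell(seasonal, park, "DJF"),
                              diff_txt, sig_txt))
  }
  lines <- c(lines, "", "## Monthly greenness means", "",
             paste0("| Park | ", paste(month.abb, collapse = " | "), " |"),
             paste0("|---", strrep("|---", 12), "|"))
  for (park in parks) {
    vals <- vapply(1:12, function(m) {
      row <- monthly[monthly$park == park & monthly$period == m, ]
      if (nrow(row) == 0) "–" else fmt(row$mean)
    }, character(1))
    lines <- c(lines, paste0("| ", park, " | ",
                             paste(vals, collapse = " | "), " |"))
  }
  lines <- c(
    lines, "", "## Greenness vs NDVI (pooled park-months)", "",
    sprintf("Pearson r = %.2f (95%% CI %.2f to %.2f), Spearman rho = %.2f, n = %d pairs.",
            correlation$pearson_r, correlation$pearson_ci_low,
            correlation$pearson_ci_high, correlation$spearman_rho,
            correlation$n_pairs)
  )
  writeLines(lines, file.path(results_dir, "report.md"))
  invisible(lines)
}
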