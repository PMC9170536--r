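#' Run the full dance-inference pipeline from a YAML config
#'
#' Orchestrates decode -> cloud simulation -> field assignment ->
#' recruitment / attractiveness / seasonal statistics / QC, writing all
#' output tables and a run manifest (seed, parameters, warnings) to an
#' artifact directory. The same config and seed always reproduce the
#' same outputs: every stochastic stage draws from a substream derived
#' from the single pipeline seed.
#'
#' Config keys: `seed`; `hive: {lat, lon}`; `runs_csv`; optional
#' `calibration` (YAML, see [read_calibration()]); `fieldmaps`, a list of
#' `{path, year}`; `bloom_calendar` (YAML); optional `crops`, `n_draws`,
#' `n_reps`, `n_models`, `max_radius_m`, `out_dir`.
#'
#' @param config path to a YAML config, or an equivalent named list.
#' @param out_dir output directory (overrides the config's `out_dir`).
#' @return the artifact directory path, invisibly; the directory holds
#'   `vectors.csv`, `clouds.csv`, `recruitment.csv`, `attractiveness.csv`,
#'   `distance_summary.csv`, `monthly_tests.csv`, `qc_report.csv` and
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    yaml::read_yaml(config)
  } else config

  need <- c("seed", "hive", "runs_csv", "fieldmaps", "bloom_calendar")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) abort(sprintf("config is missing: %s", paste(miss, collapse = ", ")))
  for (p in c(cfg$runs_csv, cfg$bloom_calendar, cfg$calibration,
              purrr::map_chr(cfg$fieldmaps, "path"))) {
    if (!is.null(p) && !file.exists(p)) abort(sprintf("input file not found: %s", p))
  }
  n_draws <- cfg$n_draws %||% 1000
  n_reps <- cfg$n_reps %||% 10000
  n_models <- cfg$n_models %||% 1000
  if (n_draws < 1 || n_reps < 1 || n_models < 1) {
    abort("n_draws, n_reps and n_models must all be >= 1.")
  }
  seed <- cfg$seed
  out_dir <- out_dir %||% cfg$out_dir %||% abort("no output directory given.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  warnings_log <- character()
  wcollect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  cal <- if (!is.null(cfg$calibration)) read_calibration(cfg$calibration)
         else calibration_model()
  calendar <- read_bloom_calendar(cfg$bloom_calendar)
  runs <- read_waggle_runs(cfg$runs_csv)
  fmaps <- purrr::map(cfg$fieldmaps, function(fm) {
    read_fieldmap(fm$path, cfg$hive$lat, cfg$hive$lon, fm$year)
  })

  vectors <- wcollect(decode_dances(runs, cfg$hive$lat, cfg$hive$lon, cal))
  clouds <- wcollect(simulate_clouds(vectors, cal, n_draws = n_draws, seed = seed,
                                     hive_lat = cfg$hive$lat, hive_lon = cfg$hive$lon))

  crops <- unlist(cfg$crops %||% list("peanut", "soybean", "corn", "cotton"))
  recruit <- purrr::map(fmaps, function(fm) {
    v <- vectors[vectors$year == fm$year, ]
    cl <- clouds[clouds$dance_id %in% v$dance_id, ]
    wcollect(recruitment_table(v, cl, fm, calendar, crops = crops,
                               n_reps = n_reps, seed = derive_seed(seed, fm$year),
                               max_radius_m = cfg$max_radius_m))
  }) %>% bind_rows()

  attract <- wcollect(fit_attractiveness(vectors, clouds, fmaps,
                                         n_models = n_models, seed = seed,
                                         max_radius_m = cfg$max_radius_m))

  dist_all <- distance_summary(vectors)
  dist_year <- distance_summary(vectors, by = "year")
  dist_ym <- distance_summary(vectors, by = c("year", "month"))
  mtests <- purrr::map(sort(unique(vectors$year)), function(yr) {
    t <- monthly_distance_test(vectors, yr)
    t$groups %>% mutate(year = yr, chi2 = t$chi2, df = t$df,
                        p_value = t$p_value)
  }) %>% bind_rows()

  qc <- qc_rank(intra_dance_sd(runs))

  wr <- function(x, f) write.csv(x, file.path(out_dir, f), row.names = FALSE)
  wr(vectors, "vectors.csv")
  wr(clouds, "clouds.csv")
  wr(recruit, "recruitment.csv")
  wr(tidy(attract), "attractiveness.csv")
  wr(bind_rows(dist_all %>% mutate(group = "all"),
               dist_year %>% mutate(group = "year"),
               dist_ym %>% mutate(group = "year_month")), "distance_summary.csv")
  wr(mtests, "monthly_tests.csv")
  wr(qc, "qc_report.csv")

  manifest <- list(
    seed = seed, n_draws = n_draws, n_reps = n_reps, n_models = n_models,
    n_dances = nrow(vectors), crops = crops,
    calibration = unclass(cal),
    warnings = warnings_log,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
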