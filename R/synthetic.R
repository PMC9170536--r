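#' Configuration of the forward dance-data generator
#'
#' The generator emulates the data-generating process upstream of the
#' pipeline: a hive in a row-crop landscape, fields of peanut, soybean,
#' corn and cotton within easy foraging range, foragers choosing where to
#' forage with per-crop, per-month attractiveness, and hand-decoded
#' four-run dance records with intra-dance measurement noise on top of
#' the duration-distance calibration.
#'
#' Defaults mirror the study system the pipeline was built around: a
#' hive in southeastern Virginia (April-October season, filming
#' 09:30-12:30 EDT), crop covers of 6-11% each within 2 km, full-bloom
#' windows in July-August, a 4-fold July preference for peanut with
#' smaller July boosts for corn and cotton and an August boost for
#' soybean, and about 1700 decoded dances per season.
#'
#' @param hive_lat,hive_lon hive coordinates (default: rural Suffolk, VA).
#' @param years season years to generate.
#' @param season_start,season_end month-day bounds of the filming season.
#' @param filming_window local clock window `c(start, end)` ("HH:MM:SS").
#' @param utc_offset hours offset of local clock from UTC (EDT = -4).
#' @param n_dances decoded dances per season.
#' @param field_spec tibble `(crop, target_pct, n_fields, band_min_m,
#'   band_max_m)`: per-crop land-cover target within 2 km and the
#'   distance band fields are placed in.
#' @param bloom tibble `(crop, start_md, end_md)` month-day full-bloom
#'   windows (applied to every year).
#' @param attract_weights tibble `(crop, month, weight)` multiplicative
#'   attractiveness; unlisted crop-months have weight 1, "other" always 1.
#' @param other_distance_model distance law of non-crop foraging:
#'   `"gamma"` (realistic, mostly-local recruitment) or `"uniform"`
#'   (spatially uniform density over the disc of radius
#'   `max_distance_m`; useful for null calibration).
#' @param other_distance_shape,other_distance_scale_m gamma parameters of
#'   the distance distribution of non-crop foraging (median ~0.7 km).
#' @param field_choice_decay_m among a crop's fields, selection weight is
#'   area times `exp(-distance/decay)`, encoding the preference for
#'   nearer fields of equal quality; `NULL` for area-proportional choice.
#' @param month_distance_scale named multiplier on the non-crop distance
#'   scale per month, encoding seasonal forage availability: recruitment
#'   reaches further in spring and early summer dearth and contracts in
#'   July when the surrounding row crops are in full bloom.
#' @param max_distance_m truncation radius for non-crop foraging.
#' @param cal a [calibration_model()] used to forward-simulate durations.
#' @param run_duration_sd_s,run_angle_sd_deg intra-dance SD of the four
#'   runs around the dance's true duration/angle.
#' @param angle_offset_deg plumb-line offset baked into the written
#'   angles (the decoder must undo it).
#' @param fps camera frame rate.
#' @return a `generator_config` list.
#' @export
generator_config <- function(
    hive_lat = 36.6851, hive_lon = -76.7671,
    years = c(2018L, 2019L),
    season_start = "04-10", season_end = "10-25",
    filming_window = c("09:30:00", "12:30:00"),
    utc_offset = -4,
    n_dances = 1700,
    field_spec = tibble(
      crop = c("peanut", "soybean", "corn", "cotton"),
      target_pct = c(6, 10, 10, 9),
      n_fields = c(4L, 4L, 4L, 4L),
      band_min_m = 300, band_max_m = 1700
    ),
    bloom = tibble(
      crop = c("peanut", "soybean", "corn", "cotton"),
      start_md = c("07-01", "07-15", "07-01", "07-10"),
      end_md = c("08-15", "08-20", "07-25", "08-20")
    ),
    attract_weights = tibble(
      crop = c("peanut", "peanut", "corn", "cotton", "cotton", "soybean"),
      month = c(7L, 8L, 7L, 7L, 9L, 8L),
      weight = c(4, 2, 3, 2, 2, 2)
    ),
    other_distance_model = c("gamma", "uniform"),
    other_distance_shape = 2, other_distance_scale_m = 260,
    field_choice_decay_m = 700,
    month_distance_scale = c("4" = 1.2, "5" = 1.15, "6" = 1.3, "7" = 0.65,
                             "8" = 1.1, "9" = 1.0, "10" = 1.0),
    max_distance_m = 8500,
    cal = calibration_model(),
    run_duration_sd_s = 0.06, run_angle_sd_deg = 10,
    angle_offset_deg = 1.5, fps = 30) {
  other_distance_model <- match.arg(other_distance_model)
  if (any(attract_weights$weight < 0)) abort("attractiveness weights must be >= 0.")
  if (run_duration_sd_s < 0 || run_angle_sd_deg < 0) abort("run noise SDs must be >= 0.")
  structure(
    list(hive_lat = hive_lat, hive_lon = hive_lon, years = as.integer(years),
         season_start = season_start, season_end = season_end,
         filming_window = filming_window, utc_offset = utc_offset,
         n_dances = n_dances, field_spec = as_tibble(field_spec),
         bloom = as_tibble(bloom), attract_weights = as_tibble(attract_weights),
         other_distance_model = other_distance_model,
         month_distance_scale = month_distance_scale,
         field_choice_decay_m = field_choice_decay_m,
         other_distance_shape = other_distance_shape,
         other_distance_scale_m = other_distance_scale_m,
         max_distance_m = max_distance_m, cal = cal,
         run_duration_sd_s = run_duration_sd_s,
         run_angle_sd_deg = run_angle_sd_deg,
         angle_offset_deg = angle_offset_deg, fps = fps),
    class = "generator_config"
  )
}

#' Generate a synthetic crop-field landscape
#'
#' Places non-overlapping axis-aligned rectangular fields in the
#' configured distance bands until each crop's land cover within the 2 km
#' disc matches its target (fields are kept wholly inside the disc, so
#' realized cover equals the sum of field areas and lands within 1
#' percentage point of the target by construction).
#'
#' @param cfg a [generator_config()].
#' @param year year stamped on the map.
#' @param seed integer seed.
#' @return list with `fmap` (a [field_map()]) and `calendar` (a
#'   [bloom_calendar()] for all configured years).
#' @export
generate_landscape <- function(cfg, year = cfg$years[[1]], seed = 1) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(derive_seed(seed, year))
  disc_r <- 2000
  rects <- list() # each: c(xmin, xmax, ymin, ymax)
  rows <- list()
  for (i in seq_len(nrow(cfg$field_spec))) {
    spec <- cfg$field_spec[i, ]
    area_target <- spec$target_pct / 100 * pi * disc_r^2
    area_each <- area_target / spec$n_fields
    for (f in seq_len(spec$n_fields)) {
      placed <- FALSE
      for (try in seq_len(4000)) {
        aspect <- runif(1, 0.6, 1.7)
        w <- sqrt(area_each * aspect); h <- area_each / w
        d <- runif(1, spec$band_min_m, spec$band_max_m)
        b <- runif(1, 0, 360)
        cx <- d * sin(deg2rad(b)); cy <- d * cos(deg2rad(b))
        r <- c(cx - w / 2, cx + w / 2, cy - h / 2, cy + h / 2)
        # wholly inside the disc?
        corners <- expand.grid(x = r[1:2], y = r[3:4])
        if (any(sqrt(corners$x^2 + corners$y^2) > disc_r)) next
        # no overlap with already placed rectangles (with a 20 m buffer)
        clash <- any(vapply(rects, function(o) {
          r[1] < o[2] + 20 && o[1] < r[2] + 20 && r[3] < o[4] + 20 && o[3] < r[4] + 20
        }, logical(1)))
        if (clash) next
        rects[[length(rects) + 1]] <- r
        rows[[length(rows) + 1]] <- tibble(
          field_id = sprintf("%s_%d_%d", spec$crop, year, f),
          crop = spec$crop,
          polygon = list(cbind(east_m = c(r[1], r[2], r[2], r[1]),
                               north_m = c(r[3], r[3], r[4], r[4])))
        )
        placed <- TRUE
        break
      }
      if (!placed) {
        abort(sprintf("could not pack field %d of crop %s: infeasible layout.",
                      f, spec$crop))
      }
    }
  }
  fields <- if (length(rows)) bind_rows(rows) else
    tibble(field_id = character(), crop = character(), polygon = list())
  fmap <- field_map(fields, cfg$hive_lat, cfg$hive_lon, year,
                    coords = "local")
  calendar <- bloom_calendar(
    tidyr::crossing(tibble(year = cfg$years), cfg$bloom) %>%
      mutate(full_bloom_start = as.Date(paste0(.data$year, "-", .data$start_md)),
             full_bloom_end = as.Date(paste0(.data$year, "-", .data$end_md))) %>%
      select("crop", "year", "full_bloom_start", "full_bloom_end")
  )
  list(fmap = fmap, calendar = calendar)
}

# month-specific category probabilities: cover x weight, "other" weight 1
category_probs <- function(cfg, fmap, month) {
  cover <- land_cover_fraction(fmap, 2000)
  w <- setNames(rep(1, nrow(cover)), as.character(cover$crop))
  aw <- cfg$attract_weights[cfg$attract_weights$month == month, ]
  w[aw$crop] <- aw$weight
  p <- cover$percent * w[as.character(cover$crop)]
  if (sum(p) <= 0) abort("all-zero category weights.")
  setNames(p / sum(p), as.character(cover$crop))
}

#' Generate a season of true foraging events
#'
#' For each dance a foraging category (crop or "other") is drawn with
#' probability proportional to land cover times the month's
#' attractiveness weight, then a point is placed uniformly within that
#' category (inside a random field of the crop, or in the non-crop
#' landscape with a gamma-distributed distance). Timestamps fall
#' uniformly within the filming window across the season.
#'
#' @param cfg a [generator_config()].
#' @param fmap landscape from [generate_landscape()].
#' @param seed integer seed.
#' @param n_dances number of dances (default `cfg$n_dances`).
#' @return truth tibble: `dance_id`, `colony_id`, `date`, `time_local`,
#'   `utc_offset`, `year`, `month`, `true_crop`, `true_east_m`,
#'   `true_north_m`, `true_distance_m`, `true_bearing_deg`.
#' @export
generate_season <- function(cfg, fmap, seed = 1, n_dances = cfg$n_dances) {
  stopifnot(inherits(cfg, "generator_config"))
  year <- fmap$year
  set.seed(derive_seed(seed, year * 7 + 1))
  d0 <- as.Date(paste0(year, "-", cfg$season_start))
  d1 <- as.Date(paste0(year, "-", cfg$season_end))
  dates <- sort(d0 + sample.int(as.integer(d1 - d0) + 1, n_dances, replace = TRUE) - 1)
  t0 <- as.numeric(as.difftime(cfg$filming_window[[1]], units = "secs"))
  t1 <- as.numeric(as.difftime(cfg$filming_window[[2]], units = "secs"))
  secs <- floor(runif(n_dances, t0, t1))
  times <- sprintf("%02d:%02d:%02d", secs %/% 3600, (secs %% 3600) %/% 60, secs %% 60)
  months <- as.integer(format(dates, "%m"))

  field_areas <- purrr::map_dbl(fmap$fields$polygon,
                                ~ shoelace_area(.x[, 1], .x[, 2]))
  field_dist <- purrr::map_dbl(fmap$fields$polygon,
                               ~ sqrt(mean(.x[, 1])^2 + mean(.x[, 2])^2))
  pt <- matrix(NA_real_, n_dances, 2)
  crop_lab <- character(n_dances)
  probs_by_month <- purrr::map(setNames(sort(unique(months)), sort(unique(months))),
                               ~ category_probs(cfg, fmap, .x))
  for (i in seq_len(n_dances)) {
    p <- probs_by_month[[as.character(months[[i]])]]
    cat_i <- sample(names(p), 1, prob = p)
    crop_lab[[i]] <- cat_i
    if (cat_i == "other") {
      repeat {
        d <- if (cfg$other_distance_model == "uniform") {
          # uniform density over the disc of radius max_distance_m
          cfg$max_distance_m * sqrt(runif(1))
        } else {
          sc <- cfg$month_distance_scale[[as.character(months[[i]])]] %||% 1
          stats::rgamma(1, shape = cfg$other_distance_shape,
                        scale = cfg$other_distance_scale_m * sc)
        }
        if (d > cfg$max_distance_m || d < 20) next
        b <- runif(1, 0, 360)
        x <- d * sin(deg2rad(b)); y <- d * cos(deg2rad(b))
        if (assign_points(x, y, fmap) == "other") break
      }
    } else {
      idx <- which(fmap$fields$crop == cat_i)
      w <- field_areas[idx]
      if (!is.null(cfg$field_choice_decay_m)) {
        # foraging economics: among a crop's fields, nearer ones are
        # preferred, with an exponential distance decay
        w <- w * exp(-field_dist[idx] / cfg$field_choice_decay_m)
      }
      fi <- if (length(idx) == 1) idx else sample(idx, 1, prob = w)
      poly <- fmap$fields$polygon[[fi]]
      x <- runif(1, min(poly[, 1]), max(poly[, 1]))
      y <- runif(1, min(poly[, 2]), max(poly[, 2]))
    }
    pt[i, ] <- c(x, y)
  }
  tibble(
    dance_id = sprintf("%d_%04d", year, seq_len(n_dances)),
    colony_id = sample(c("A", "B", "C"), n_dances, replace = TRUE),
    date = as.character(dates),
    time_local = times,
    utc_offset = cfg$utc_offset,
    year = year,
    month = months,
    true_crop = crop_lab,
    true_east_m = pt[, 1],
    true_north_m = pt[, 2],
    true_distance_m = sqrt(pt[, 1]^2 + pt[, 2]^2),
    true_bearing_deg = wrap_bearing(rad2deg(atan2(pt[, 1], pt[, 2])))
  )
}

#' Forward-simulate run-level dance records from foraging truths
#'
#' Inverts the decoding model: each dance gets four waggle runs whose
#' durations scatter around the calibration line at the true distance
#' (quantized to whole frames, rounding half-up) and whose
#' vertical-referenced angles scatter around `true bearing - solar
#' azimuth`, minus the configured plumb-line offset, with two left and
#' two right turns. With all noise SDs at zero, decoding recovers the
#' truths exactly up to frame quantization.
#'
#' @param truths tibble from [generate_season()].
#' @param cfg a [generator_config()].
#' @param seed integer seed.
#' @return run-level tibble in the decoder's input dialect.
#' @export
generate_runs <- function(truths, cfg, seed = 1) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(derive_seed(seed, 4242))
  az <- solar_azimuth(cfg$hive_lat, cfg$hive_lon, truths$date,
                      truths$time_local, truths$utc_offset)
  n <- nrow(truths)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    true_dur <- expected_duration(truths$true_distance_m[[i]], cfg$cal)
    dur <- true_dur + rnorm(4, 0, cfg$run_duration_sd_s)
    frames <- pmax(1, floor(dur * cfg$fps + 0.5)) # round half-up
    gap <- sample(30:60, 4, replace = TRUE)
    start <- cumsum(c(sample(50:200, 1), head(frames, 3) + head(gap, 3)))
    true_angle <- truths$true_bearing_deg[[i]] - az[[i]]
    ang <- wrap_angle(true_angle + rnorm(4, 0, cfg$run_angle_sd_deg) -
                        cfg$angle_offset_deg)
    rows[[i]] <- tibble(
      dance_id = truths$dance_id[[i]],
      colony_id = truths$colony_id[[i]],
      date = truths$date[[i]],
      time_local = truths$time_local[[i]],
      utc_offset = truths$utc_offset[[i]],
      fps = cfg$fps,
      angle_offset_deg = cfg$angle_offset_deg,
      run_index = 1:4,
      start_frame = start,
      end_frame = start + frames,
      angle_deg = ang,
      turn_direction = c("left", "right", "left", "right")
    )
  }
  bind_rows(rows)
}

#' Generate a full synthetic study (landscape + truths + runs) per year
#'
#' @param cfg a [generator_config()].
#' @param seed integer pipeline seed.
#' @return list with `fmaps` (named by year), `calendar`, `truths`,
#'   `runs` (truths and runs pooled across years).
#' @export
generate_dataset <- function(cfg = generator_config(), seed = 1) {
  per_year <- purrr::map(cfg$years, function(yr) {
    land <- generate_landscape(cfg, year = yr, seed = seed)
    truths <- generate_season(cfg, land$fmap, seed = seed)
    runs <- generate_runs(truths, cfg, seed = derive_seed(seed, yr))
    list(fmap = land$fmap, calendar = land$calendar,
         truths = truths, runs = runs)
  })
  list(
    fmaps = setNames(purrr::map(per_year, "fmap"), cfg$years),
    calendar = per_year[[1]]$calendar,
    truths = bind_rows(purrr::map(per_year, "truths")),
    runs = bind_rows(purrr::map(per_year, "runs"))
  )
}

# local east/north back to lon/lat for file export
local_to_lonlat <- function(east_m, north_m, hive_lat, hive_lon) {
  d <- sqrt(east_m^2 + north_m^2)
  b <- wrap_bearing(rad2deg(atan2(east_m, north_m)))
  ll <- geosphere::destPoint(cbind(hive_lon, hive_lat), b, d)
  tibble(lon = ll[, 1], lat = ll[, 2])
}

#' Export a field map to GeoJSON or KML
#'
#' Polygon vertices are reprojected from the hive-centered plane back to
#' lon/lat; crop and year travel as feature properties (GeoJSON) or
#' ExtendedData (KML), the same dialects [read_fieldmap()] ingests.
#'
#' @param fmap a [field_map()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fieldmap_geojson <- function(fmap, path) {
  feats <- purrr::map(seq_len(nrow(fmap$fields)), function(i) {
    p <- fmap$fields$polygon[[i]]
    ll <- local_to_lonlat(p[, 1], p[, 2], fmap$hive_lat, fmap$hive_lon)
    ring <- purrr::map(seq_len(nrow(ll) + 1), function(j) {
      k <- if (j > nrow(ll)) 1 else j
      c(ll$lon[[k]], ll$lat[[k]])
    })
    list(type = "Feature",
         properties = list(field_id = fmap$fields$field_id[[i]],
                           crop = fmap$fields$crop[[i]],
                           year = fmap$year),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' @rdname write_fieldmap_geojson
#' @export
write_fieldmap_kml <- function(fmap, path) {
  pm <- purrr::map_chr(seq_len(nrow(fmap$fields)), function(i) {
    p <- fmap$fields$polygon[[i]]
    ll <- local_to_lonlat(p[, 1], p[, 2], fmap$hive_lat, fmap$hive_lon)
    coords <- paste(sprintf("%.8f,%.8f,0", c(ll$lon, ll$lon[[1]]),
                            c(ll$lat, ll$lat[[1]])), collapse = " ")
    sprintf(paste0(
      "<Placemark><name>%s</name><ExtendedData>",
      "<Data name=\"crop\"><value>%s</value></Data>",
      "<Data name=\"year\"><value>%d</value></Data></ExtendedData>",
      "<Polygon><outerBoundaryIs><LinearRing><coordinates>%s</coordinates>",
      "</LinearRing></outerBoundaryIs></Polygon></Placemark>"),
      fmap$fields$field_id[[i]], fmap$fields$crop[[i]], fmap$year, coords)
  })
  xml <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    "<kml xmlns=\"http://www.opengis.net/kml/2.2\"><Document>\n",
    paste(pm, collapse = "\n"), "\n</Document></kml>\n")
  writeLines(xml, path)
  invisible(path)
}
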