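## Crop-field maps. Polygons are stored and queried in the hive-centered
## metric plane (east/north in meters); ingestion from KML/GeoJSON
## reprojects lon/lat vertices through the same local plane used for the
## dance geometry.

CROP_LEVELS <- c("peanut", "soybean", "corn", "cotton", "other")

shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# proper-intersection test between segments p1-p2 and p3-p4 (shared
# endpoints between adjacent edges do not count)
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

is_simple_polygon <- function(x, y) {
  n <- length(x)
  if (n < 3) return(FALSE)
  pts <- cbind(x, y)
  edges <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      # skip adjacent edges (share a vertex)
      if (abs(i - j) <= 1 || (i == 1 && j == n)) next
      if (segments_cross(pts[edges[i, 1], ], pts[edges[i, 2], ],
                         pts[edges[j, 1], ], pts[edges[j, 2], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Build a crop-field map in the hive-centered plane
#'
#' @param fields a tibble/data.frame with columns `field_id`, `crop`
#'   (one of peanut, soybean, corn, cotton, other) and a list-column
#'   `polygon` of two-column matrices of vertices. Vertex columns are
#'   interpreted as (lon, lat) unless `coords = "local"`, in which case
#'   they are hive-centered (east_m, north_m).
#' @param hive_lat,hive_lon hive coordinates, decimal degrees.
#' @param year calendar year the map is valid for.
#' @param coords `"lonlat"` (default) or `"local"`.
#' @return a `field_map` object: fields tibble (with local-plane polygon
#'   matrices), hive coordinates, year.
#' @export
field_map <- function(fields, hive_lat, hive_lon, year,
                      coords = c("lonlat", "local")) {
  coords <- match.arg(coords)
  fields <- as_tibble(fields)
  need <- c("field_id", "crop", "polygon")
  if (!all(need %in% names(fields))) {
    abort(sprintf("`fields` must have columns %s", paste(need, collapse = ", ")))
  }
  if (any(is.na(fields$crop)) || !all(fields$crop %in% CROP_LEVELS)) {
    abort(sprintf("every field needs a crop label in {%s}",
                  paste(CROP_LEVELS, collapse = ", ")))
  }
  fields$polygon <- purrr::map2(fields$polygon, fields$field_id, function(p, id) {
    p <- as.matrix(p)
    if (ncol(p) != 2 || nrow(p) < 3) {
      abort(sprintf("field '%s': polygon needs >= 3 two-column vertices.", id))
    }
    # drop an explicitly closed last vertex
    if (all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
    if (coords == "lonlat") {
      loc <- lonlat_to_local(p[, 1], p[, 2], hive_lat, hive_lon)
      p <- cbind(east_m = loc$east_m, north_m = loc$north_m)
    } else {
      colnames(p) <- c("east_m", "north_m")
    }
    if (!is_simple_polygon(p[, 1], p[, 2])) {
      abort(sprintf("field '%s': polygon is self-intersecting.", id))
    }
    p
  })

  fmap <- structure(
    list(fields = fields, hive_lat = hive_lat, hive_lon = hive_lon,
         year = as.integer(year)),
    class = "field_map"
  )
  ov <- overlapping_fields(fmap)
  if (nrow(ov)) {
    warn(sprintf(
      "%d field pair(s) overlap (e.g. %s / %s); points are resolved by file order.",
      nrow(ov), ov$a[[1]], ov$b[[1]]))
  }
  fmap
}

# cheap overlap screen: a vertex of one polygon strictly inside another
overlapping_fields <- function(fmap) {
  f <- fmap$fields
  out <- list()
  if (nrow(f) < 2) return(tibble(a = character(), b = character()))
  for (i in seq_len(nrow(f) - 1)) {
    for (j in seq(i + 1, nrow(f))) {
      pi <- f$polygon[[i]]; pj <- f$polygon[[j]]
      inside_ij <- sp::point.in.polygon(pj[, 1], pj[, 2], pi[, 1], pi[, 2]) == 1
      inside_ji <- sp::point.in.polygon(pi[, 1], pi[, 2], pj[, 1], pj[, 2]) == 1
      if (any(inside_ij) || any(inside_ji)) {
        out[[length(out) + 1]] <- tibble(a = f$field_id[[i]], b = f$field_id[[j]])
      }
    }
  }
  bind_rows(out, tibble(a = character(), b = character()))
}

#' @export
print.field_map <- function(x, ...) {
  cat(sprintf("<field_map> %d field(s), year %d, hive (%.4f, %.4f)\n",
              nrow(x$fields), x$year, x$hive_lat, x$hive_lon))
  print(count(x$fields, .data$crop))
  invisible(x)
}

#' Load a crop-field map from KML or GeoJSON
#'
#' KML polygon placemarks carry the crop in `ExtendedData` (`crop`,
#' optional `year`) or, failing that, as the placemark name. GeoJSON
#' features carry `crop` / `year` / `field_id` in `properties`. Features
#' tagged with a different year than requested are skipped.
#'
#' @param path path to a `.kml`, `.geojson` or `.json` file.
#' @param hive_lat,hive_lon hive coordinates.
#' @param year year to select (and stamp on the map).
#' @return a [field_map()].
#' @export
read_fieldmap <- function(path, hive_lat, hive_lon, year) {
  ext <- tolower(tools::file_ext(path))
  fields <- switch(ext,
    kml = parse_kml_fields(path),
    geojson = ,
    json = parse_geojson_fields(path),
    abort(sprintf("unsupported field-map format '.%s' (use KML or GeoJSON).", ext))
  )
  if (!is.null(fields$year)) {
    keep <- is.na(fields$year) | fields$year == year
    fields <- fields[keep, setdiff(names(fields), "year")]
  }
  if (!nrow(fields)) abort(sprintf("no polygon features for year %s in '%s'.", year, path))
  field_map(fields, hive_lat, hive_lon, year)
}

parse_kml_fields <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(k = "http://www.opengis.net/kml/2.2")
  pm <- xml2::xml_find_all(doc, ".//k:Placemark[.//k:Polygon]", ns)
  if (!length(pm)) {
    # tolerate KML without the default namespace
    pm <- xml2::xml_find_all(doc, ".//Placemark[.//Polygon]")
    ns <- NULL
  }
  find1 <- function(node, xp) {
    if (is.null(ns)) xml2::xml_find_first(node, xp)
    else xml2::xml_find_first(node, gsub("(^|/)(\\w)", "\\1k:\\2", xp), ns)
  }
  rows <- purrr::imap(pm, function(node, i) {
    name <- xml2::xml_text(find1(node, ".//name"))
    ed <- function(key) {
      xp <- sprintf(".//%sData[@name='%s']/%svalue",
                    if (is.null(ns)) "" else "k:", key,
                    if (is.null(ns)) "" else "k:")
      v <- if (is.null(ns)) xml2::xml_find_first(node, xp)
           else xml2::xml_find_first(node, xp, ns)
      xml2::xml_text(v)
    }
    crop <- ed("crop")
    if (is.na(crop) || !nzchar(crop)) crop <- tolower(trimws(name))
    yr <- suppressWarnings(as.integer(ed("year")))
    coords <- xml2::xml_text(find1(node, ".//coordinates"))
    if (is.na(coords)) abort(sprintf("placemark %d has no coordinates.", i))
    toks <- strsplit(trimws(coords), "[[:space:]]+")[[1]]
    m <- do.call(rbind, lapply(strsplit(toks, ","), function(v) as.numeric(v[1:2])))
    tibble(
      field_id = if (!is.na(name) && nzchar(name)) name else paste0("field_", i),
      crop = tolower(crop), year = yr, polygon = list(m)
    )
  })
  out <- bind_rows(rows)
  if (any(is.na(out$crop) | !nzchar(out$crop))) abort("KML placemark without a crop label.")
  out
}

parse_geojson_fields <- function(path) {
  g <- jsonlite::read_json(path)
  if (is.null(g$features)) abort("GeoJSON must be a FeatureCollection.")
  rows <- purrr::imap(g$features, function(f, i) {
    if (!identical(f$geometry$type, "Polygon")) return(NULL)
    props <- f$properties %||% list()
    crop <- props$crop
    if (is.null(crop)) abort(sprintf("feature %d lacks a 'crop' property.", i))
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(v) c(v[[1]], v[[2]])))
    tibble(
      field_id = as.character(props$field_id %||% props$name %||% paste0("field_", i)),
      crop = tolower(crop),
      year = suppressWarnings(as.integer(props$year %||% NA)),
      polygon = list(m)
    )
  })
  bind_rows(purrr::compact(rows))
}

#' Assign points to crop labels
#'
#' Each point takes the crop of the first field (file order) whose polygon
#' contains it; points on a boundary count as inside; everything else is
#' `"other"`. Optionally a region-of-interest radius can be applied:
#' points beyond it are labelled `"other"` (default) or dropped
#' (`beyond = "drop"`).
#'
#' @param east_m,north_m point coordinates in the hive-centered plane.
#' @param fmap a [field_map()].
#' @param max_radius_m optional region-of-interest radius.
#' @param beyond what to do with points beyond `max_radius_m`: label
#'   `"other"` or mark `NA` (`"drop"`).
#' @return character vector of crop labels (NA for dropped points).
#' @export
assign_points <- function(east_m, north_m, fmap,
                          max_radius_m = NULL, beyond = c("other", "drop")) {
  beyond <- match.arg(beyond)
  stopifnot(inherits(fmap, "field_map"))
  lab <- rep("other", length(east_m))
  unassigned <- rep(TRUE, length(east_m))
  for (i in seq_len(nrow(fmap$fields))) {
    if (!any(unassigned)) break
    p <- fmap$fields$polygon[[i]]
    idx <- which(unassigned)
    hit <- sp::point.in.polygon(east_m[idx], north_m[idx], p[, 1], p[, 2]) > 0
    lab[idx[hit]] <- fmap$fields$crop[[i]]
    unassigned[idx[hit]] <- FALSE
  }
  if (!is.null(max_radius_m)) {
    far <- sqrt(east_m^2 + north_m^2) > max_radius_m
    lab[far] <- if (beyond == "other") "other" else NA_character_
  }
  lab
}

## Sutherland-Hodgman clip of an arbitrary simple polygon against a convex
## clip polygon (here: a regular 720-gon approximating the disc).
clip_polygon_convex <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (is.null(out) || nrow(out) == 0) return(NULL)
    a <- clip[i, ]
    b <- clip[if (i == nc) 1 else i + 1, ]
    inside <- function(p) (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1]) >= 0
    inter <- function(p, q) {
      # intersection of segment p-q with infinite line a-b
      dc <- c(a[1] - b[1], a[2] - b[2])
      dp <- c(p[1] - q[1], p[2] - q[2])
      n1 <- a[1] * b[2] - a[2] * b[1]
      n2 <- p[1] * q[2] - p[2] * q[1]
      den <- dc[1] * dp[2] - dc[2] * dp[1]
      c((n1 * dp[1] - n2 * dc[1]) / den, (n1 * dp[2] - n2 * dc[2]) / den)
    }
    inp <- out
    out <- matrix(numeric(0), ncol = 2)
    n <- nrow(inp)
    for (j in seq_len(n)) {
      p <- inp[j, ]
      q <- inp[if (j == n) 1 else j + 1, ]
      pin <- inside(p); qin <- inside(q)
      if (pin) {
        out <- rbind(out, p)
        if (!qin) out <- rbind(out, inter(p, q))
      } else if (qin) {
        out <- rbind(out, inter(p, q))
      }
    }
  }
  if (nrow(out) < 3) NULL else out
}

disc_polygon <- function(radius_m, n = 720) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(radius_m * cos(th), radius_m * sin(th))
}

#' Land-cover fraction of each crop within a disc around the hive
#'
#' Percent of the disc of radius `radius_m` covered by each crop's fields
#' (polygon-clipped areas over the disc area pi r^2); `"other"` is the
#' complement, so the percentages sum to 100.
#'
#' @param fmap a [field_map()].
#' @param radius_m disc radius in meters (2000 m captures the large
#'   majority of communicated foraging).
#' @return tibble with `crop`, `area_m2`, `percent`, one row per crop
#'   level including `"other"`.
#' @export
land_cover_fraction <- function(fmap, radius_m = 2000) {
  stopifnot(inherits(fmap, "field_map"))
  if (radius_m <= 0) abort("`radius_m` must be > 0.")
  disc <- disc_polygon(radius_m)
  disc_area <- pi * radius_m^2
  areas <- setNames(numeric(length(CROP_LEVELS)), CROP_LEVELS)
  for (i in seq_len(nrow(fmap$fields))) {
    p <- fmap$fields$polygon[[i]]
    # ensure counter-clockwise orientation for the clipper
    if (sum((p[c(2:nrow(p), 1), 1] - p[, 1]) * (p[c(2:nrow(p), 1), 2] + p[, 2])) > 0) {
      p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
    }
    clipped <- clip_polygon_convex(p, disc)
    if (!is.null(clipped)) {
      areas[[fmap$fields$crop[[i]]]] <- areas[[fmap$fields$crop[[i]]]] +
        shoelace_area(clipped[, 1], clipped[, 2])
    }
  }
  areas[["other"]] <- disc_area - sum(areas[names(areas) != "other"])
  tibble(
    crop = factor(CROP_LEVELS, levels = CROP_LEVELS),
    area_m2 = as.numeric(areas),
    percent = 100 * as.numeric(areas) / disc_area
  )
}

#' Bin weighted points onto a square grid anchored at the hive
#'
#' Cells are half-open squares `[i c, (i+1) c) x [j c, (j+1) c)` anchored
#' at the hive origin. Each point contributes its weight (by default a
#' dance's cloud draws each carry `1/n_draws`, so a dance contributes one
#' unit in total) and cell values are expressed as percent of the total
#' weight, which therefore sums to 100 across cells.
#'
#' @param points tibble with `east_m`, `north_m`.
#' @param cell_m cell side, meters.
#' @param weights per-point weights; defaults to equal split over rows of
#'   the same `dance_id` when that column is present, else equal weights.
#' @return tibble `(i, j, east_min, north_min, percent)`.
#' @export
grid_bin <- function(points, cell_m = 25, weights = NULL) {
  if (cell_m <= 0) abort("`cell_m` must be > 0.")
  points <- as_tibble(points)
  if (is.null(weights)) {
    if ("dance_id" %in% names(points)) {
      points <- points %>%
        group_by(.data$dance_id) %>%
        mutate(.w = 1 / n()) %>%
        ungroup()
      weights <- points$.w
    } else {
      weights <- rep(1, nrow(points))
    }
  }
  tot <- sum(weights)
  points %>%
    mutate(
      i = floor(.data$east_m / cell_m),
      j = floor(.data$north_m / cell_m),
      .w = weights
    ) %>%
    group_by(.data$i, .data$j) %>%
    summarise(percent = 100 * sum(.data$.w) / tot, .groups = "drop") %>%
    mutate(east_min = .data$i * cell_m, north_min = .data$j * cell_m) %>%
    select("i", "j", "east_min", "north_min", "percent") %>%
    arrange(.data$i, .data$j)
}
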