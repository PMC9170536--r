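#' Bloom calendar for row crops
#'
#' Records, per crop and year, the full-bloom window: the period when more
#' than 75% of that crop's fields are actively flowering. Dates outside
#' the window stratify the season into pre- and post-bloom.
#'
#' @param calendar tibble with columns `crop`, `year`,
#'   `full_bloom_start`, `full_bloom_end` (Dates or ISO strings).
#' @return a `bloom_calendar` tibble.
#' @export
bloom_calendar <- function(calendar) {
  calendar <- as_tibble(calendar)
  need <- c("crop", "year", "full_bloom_start", "full_bloom_end")
  if (!all(need %in% names(calendar))) {
    abort(sprintf("bloom calendar needs columns %s", paste(need, collapse = ", ")))
  }
  calendar <- calendar %>%
    mutate(
      year = as.integer(.data$year),
      full_bloom_start = as.Date(.data$full_bloom_start),
      full_bloom_end = as.Date(.data$full_bloom_end)
    )
  if (any(calendar$full_bloom_start >= calendar$full_bloom_end)) {
    abort("full_bloom_start must precede full_bloom_end.")
  }
  mo <- as.integer(format(calendar$full_bloom_start, "%m"))
  mo_end <- as.integer(format(calendar$full_bloom_end, "%m"))
  if (any(mo < 4 | mo_end > 10)) {
    warn("bloom interval(s) outside the April-October foraging season.")
  }
  class(calendar) <- c("bloom_calendar", class(calendar))
  calendar
}

#' Read a bloom calendar from YAML
#'
#' Layout: top-level years, each a map of crop -> `{start, end}` dates.
#'
#' @param path YAML file path.
#' @return a [bloom_calendar()].
#' @export
read_bloom_calendar <- function(path) {
  y <- yaml::read_yaml(path)
  rows <- purrr::imap(y, function(crops, yr) {
    purrr::imap(crops, function(iv, crop) {
      tibble(crop = crop, year = as.integer(yr),
             full_bloom_start = iv$start, full_bloom_end = iv$end)
    }) %>% bind_rows()
  }) %>% bind_rows()
  bloom_calendar(rows)
}

#' @rdname read_bloom_calendar
#' @param calendar a [bloom_calendar()].
#' @export
write_bloom_calendar <- function(calendar, path) {
  split_years <- split(calendar, calendar$year)
  y <- purrr::map(split_years, function(d) {
    setNames(purrr::map(seq_len(nrow(d)), function(i) {
      list(start = as.character(d$full_bloom_start[[i]]),
           end = as.character(d$full_bloom_end[[i]]))
    }), d$crop)
  })
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Bloom period of a date for a crop
#'
#' Boundary dates belong to the full-bloom window (closed interval).
#'
#' @param date Date(s) (or ISO strings).
#' @param crop crop label.
#' @param year calendar year.
#' @param calendar a [bloom_calendar()].
#' @return factor with levels `pre`, `during`, `post`.
#' @export
bloom_period <- function(date, crop, year, calendar) {
  date <- as.Date(date)
  row <- calendar[calendar$crop == crop & calendar$year == year, ]
  if (!nrow(row)) {
    abort(sprintf("bloom calendar has no entry for crop '%s' in %s.", crop, year))
  }
  out <- ifelse(date < row$full_bloom_start[[1]], "pre",
                ifelse(date > row$full_bloom_end[[1]], "post", "during"))
  factor(out, levels = c("pre", "during", "post"))
}
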