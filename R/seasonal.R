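#' Summaries of communicated foraging distance
#'
#' Communicated distance is a proxy for forage availability: bees recruit
#' further afield when food is scarce near the hive. This summarises the
#' decoded distances (km) overall or by grouping columns.
#'
#' @param vectors decoded dance tibble with `distance_m` (plus any
#'   grouping columns requested).
#' @param by character vector of grouping column names (empty = pooled).
#' @return tibble with `n`, `median_km`, `min_km`, `max_km`, `q95_km` per
#'   group. The median uses the even-n midpoint convention and the 95th
#'   percentile linear interpolation between order statistics.
#' @export
distance_summary <- function(vectors, by = character()) {
  if (!nrow(vectors)) abort("`vectors` is empty.")
  vectors %>%
    group_by(dplyr::across(dplyr::all_of(by))) %>%
    summarise(
      n = n(),
      median_km = median(.data$distance_m) / 1000,
      min_km = min(.data$distance_m) / 1000,
      max_km = max(.data$distance_m) / 1000,
      q95_km = unname(quantile(.data$distance_m, 0.95)) / 1000,
      .groups = "drop"
    )
}

## Dunn post hoc z-tests on pooled ranks (the standard companion to the
## Kruskal-Wallis omnibus), with tie correction.
dunn_pairs <- function(x, g) {
  g <- droplevels(as.factor(g))
  n <- tapply(x, g, length)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  N <- length(x)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  purrr::map(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[[a]] + 1 / n[[b]]))
    z <- (rbar[[a]] - rbar[[b]]) / se
    tibble(group1 = a, group2 = b, z = z,
           p_value = 2 * stats::pnorm(-abs(z)))
  }) %>%
    bind_rows() %>%
    mutate(p_adj = p.adjust(.data$p_value, method = "holm"))
}

## compact letter display by insert-and-absorb: groups sharing a letter
## are not significantly different
compact_letters <- function(groups, sig_pairs) {
  cols <- list(groups) # start: one letter containing everyone
  for (k in seq_len(nrow(sig_pairs))) {
    a <- sig_pairs$group1[[k]]; b <- sig_pairs$group2[[k]]
    for (ci in rev(seq_along(cols))) {
      if (a %in% cols[[ci]] && b %in% cols[[ci]]) {
        cols[[length(cols) + 1]] <- setdiff(cols[[ci]], a)
        cols[[ci]] <- setdiff(cols[[ci]], b)
      }
    }
    # absorb columns that are subsets of another
    keep <- rep(TRUE, length(cols))
    for (i in seq_along(cols)) {
      for (j in seq_along(cols)) {
        if (i != j && keep[i] && keep[j] && all(cols[[i]] %in% cols[[j]])) {
          keep[i] <- FALSE
          break
        }
      }
    }
    cols <- cols[keep]
  }
  # stable letter order: by first appearance of each column's first group
  ord <- order(purrr::map_int(cols, ~ min(match(.x, groups))))
  cols <- cols[ord]
  vapply(groups, function(gr) {
    paste0(letters[which(purrr::map_lgl(cols, ~ gr %in% .x))], collapse = "")
  }, character(1))
}

#' Rank-based test of foraging distance across months
#'
#' Kruskal-Wallis omnibus test of communicated distance across the months
#' of one year (7 filming months give df = 6), followed by pairwise Dunn
#' tests with Holm adjustment rendered as a compact letter display:
#' months sharing a letter do not differ at `alpha`.
#'
#' @param vectors decoded dance tibble (`distance_m`, `month`, `year`).
#' @param year year to test.
#' @param alpha significance level for the letter display.
#' @return a `wd_month_test`: list with `chi2`, `df`, `p_value`, `n`,
#'   tibble `groups` (month, n, median_km, letter) and tibble `pairs`.
#' @export
monthly_distance_test <- function(vectors, year, alpha = 0.05) {
  v <- vectors[vectors$year == year, ]
  group_distance_test(v$distance_m,
                      month_label(v$month),
                      label = "month", year = year, alpha = alpha)
}

group_distance_test <- function(distance_m, g, label, year, alpha) {
  g <- droplevels(as.factor(g))
  tab <- table(g)
  if (length(tab) < 2 || any(tab < 2)) {
    abort(sprintf("need >= 2 %s groups with >= 2 observations each.", label))
  }
  kw <- kruskal.test(distance_m, g)
  pr <- dunn_pairs(distance_m, g)
  sig <- pr[pr$p_adj < alpha, ]
  lets <- compact_letters(levels(g), sig)
  groups <- tibble(
    group = levels(g),
    n = as.integer(tab),
    median_km = as.numeric(tapply(distance_m, g, median)) / 1000,
    letter = unname(lets)
  )
  names(groups)[1] <- label
  res <- list(chi2 = unname(kw$statistic), df = unname(kw$parameter),
              p_value = kw$p.value, n = length(distance_m),
              year = year, groups = groups, pairs = pr, alpha = alpha)
  class(res) <- "wd_month_test"
  res
}

#' @export
print.wd_month_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: chi2 = %.2f, df = %d, p = %.3g, n = %d (year %s)\n",
              x$chi2, x$df, x$p_value, x$n, x$year))
  print(x$groups)
  invisible(x)
}

#' @export
tidy.wd_month_test <- function(x, ...) x$groups

#' @export
glance.wd_month_test <- function(x, ...) {
  tibble(chi2 = x$chi2, df = x$df, p_value = x$p_value, n = x$n, year = x$year)
}

#' Median foraging distance by bloom interval for one crop
#'
#' Groups a year's dances into pre/during/post full bloom of the given
#' crop and applies the same rank-test machinery as
#' [monthly_distance_test()]. If the crop drives availability, the
#' medians follow a down-up-down pattern in distance terms: distance
#' drops when the crop blooms and rises again after.
#'
#' @param vectors decoded dance tibble.
#' @param calendar a [bloom_calendar()].
#' @param crop crop of interest.
#' @param year year to analyse.
#' @param alpha significance level for letters.
#' @return a `wd_month_test` whose groups are bloom periods; periods with
#'   no dances are flagged in `empty_periods`.
#' @export
bloom_interval_medians <- function(vectors, calendar, crop, year, alpha = 0.05) {
  v <- vectors[vectors$year == year, ]
  if (!nrow(v)) abort(sprintf("no dances for year %s.", year))
  period <- bloom_period(v$date, crop, year, calendar)
  empty <- levels(period)[table(period) == 0]
  res <- group_distance_test(v$distance_m, period,
                             label = "period", year = year, alpha = alpha)
  res$crop <- crop
  res$empty_periods <- empty
  if (length(empty)) {
    warn(sprintf("bloom period(s) with no dances for %s %s: %s",
                 crop, year, paste(empty, collapse = ", ")))
  }
  res
}
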