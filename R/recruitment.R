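#' Percent recruitment to a crop class, with resampling CI
#'
#' For each of `n_reps` repetitions, one simulated location is picked
#' uniformly (with replacement) from every dance's probability cloud and
#' the percentage of dances landing in fields of the target crop class is
#' computed. The distribution of the `n_reps` percentages is summarised
#' by its median (point estimate) and 2.5th/97.5th percentiles (95% CI);
#' the mean is reported alongside.
#'
#' @param clouds cloud tibble from [simulate_clouds()].
#' @param fmap a [field_map()].
#' @param crop_set character vector of crop labels counted as "in fields
#'   of interest".
#' @param n_reps number of resampling repetitions.
#' @param seed integer seed for the resampling stream.
#' @param max_radius_m optional region-of-interest radius passed to
#'   [assign_points()] (draws beyond it count as "other").
#' @return a one-row tibble: `point_pct` (median), `mean_pct`, `lo_pct`,
#'   `hi_pct`, `n_dances`, `n_reps`.
#' @export
percent_recruitment <- function(clouds, fmap, crop_set,
                                n_reps = 10000, seed = 1,
                                max_radius_m = NULL) {
  if (!nrow(clouds)) abort("`clouds` is empty.")
  if (n_reps < 1) abort("`n_reps` must be >= 1.")
  lab <- assign_points(clouds$east_m, clouds$north_m, fmap,
                       max_radius_m = max_radius_m)
  pcts <- resample_percentages(clouds$dance_id, lab %in% crop_set, n_reps, seed)
  tibble(
    point_pct = median(pcts),
    mean_pct = mean(pcts),
    lo_pct = unname(quantile(pcts, 0.025)),
    hi_pct = unname(quantile(pcts, 0.975)),
    n_dances = dplyr::n_distinct(clouds$dance_id),
    n_reps = n_reps
  )
}

# core resampler: per rep, one draw per dance; returns n_reps percentages
resample_percentages <- function(dance_id, in_set, n_reps, seed) {
  ids <- unique(dance_id)
  n_dances <- length(ids)
  # draws per dance (equal when clouds come from simulate_clouds)
  split_in <- split(in_set, factor(dance_id, levels = ids))
  n_draws <- lengths(split_in)
  set.seed(derive_seed(seed, 0))
  if (length(unique(n_draws)) == 1) {
    m <- matrix(unlist(split_in, use.names = FALSE), nrow = n_draws[[1]])
    pcts <- numeric(n_reps)
    block <- max(1L, min(n_reps, floor(2e6 / n_dances)))
    done <- 0L
    offs <- (seq_len(n_dances) - 1) * n_draws[[1]]
    while (done < n_reps) {
      k <- min(block, n_reps - done)
      idx <- matrix(sample.int(n_draws[[1]], n_dances * k, replace = TRUE),
                    nrow = n_dances)
      vals <- matrix(m[idx + offs], nrow = n_dances)
      pcts[done + seq_len(k)] <- 100 * colMeans(vals)
      done <- done + k
    }
    pcts
  } else {
    vapply(seq_len(n_reps), function(r) {
      100 * mean(vapply(split_in, function(v) v[[sample.int(length(v), 1)]],
                        logical(1)))
    }, numeric(1))
  }
}

#' Percent recruitment by bloom period
#'
#' Stratifies dances into pre/during/post full bloom using the target
#' crop's own bloom window, then runs [percent_recruitment()] per
#' stratum. An empty stratum yields a row of `NA` estimates flagged
#' `undefined`.
#'
#' @param vectors decoded dance tibble (needs `dance_id`, `date`, `year`).
#' @param clouds cloud tibble from [simulate_clouds()].
#' @param fmap a [field_map()].
#' @param calendar a [bloom_calendar()].
#' @param crop crop of interest (also the crop class counted, unless
#'   `crop_set` overrides it).
#' @param crop_set crop labels counted in the numerator.
#' @inheritParams percent_recruitment
#' @return a `wd_recruitment` tibble with one row per period.
#' @export
recruitment_by_bloom <- function(vectors, clouds, fmap, calendar, crop,
                                 crop_set = crop, n_reps = 10000, seed = 1,
                                 max_radius_m = NULL) {
  year <- fmap$year
  vecs <- vectors[vectors$year == year, ]
  if (!nrow(vecs)) abort(sprintf("no dances for year %d.", year))
  period <- bloom_period(vecs$date, crop, year, calendar)
  out <- purrr::map(levels(period), function(p) {
    ids <- vecs$dance_id[period == p]
    cl <- clouds[clouds$dance_id %in% ids, ]
    if (!nrow(cl)) {
      return(tibble(crop = crop, year = year, period = p,
                    point_pct = NA_real_, mean_pct = NA_real_,
                    lo_pct = NA_real_, hi_pct = NA_real_,
                    n_dances = 0L, n_reps = n_reps, undefined = TRUE))
    }
    est <- percent_recruitment(cl, fmap, crop_set, n_reps = n_reps,
                               seed = derive_seed(seed, match(p, levels(period))),
                               max_radius_m = max_radius_m)
    dplyr::bind_cols(tibble(crop = crop, year = year, period = p), est,
                     tibble(undefined = FALSE))
  }) %>% bind_rows()
  out$period <- factor(out$period, levels = c("pre", "during", "post"))
  class(out) <- c("wd_recruitment", class(out))
  out
}

#' Recruitment table across crops (Table-2 style)
#'
#' One row per crop: its land-cover percent within `radius_m` and the
#' point estimate and CI of percent recruitment pre/during/post bloom.
#'
#' @inheritParams recruitment_by_bloom
#' @param crops crops to tabulate.
#' @param radius_m land-cover disc radius.
#' @return a wide tibble mirroring the published layout.
#' @export
recruitment_table <- function(vectors, clouds, fmap, calendar,
                              crops = c("peanut", "soybean", "corn", "cotton"),
                              n_reps = 10000, seed = 1, radius_m = 2000,
                              max_radius_m = NULL) {
  cover <- land_cover_fraction(fmap, radius_m)
  purrr::imap(setNames(crops, crops), function(crop, nm) {
    est <- recruitment_by_bloom(vectors, clouds, fmap, calendar, crop,
                                n_reps = n_reps,
                                seed = derive_seed(seed, match(crop, crops)),
                                max_radius_m = max_radius_m)
    wide <- est %>%
      select("period", "point_pct", "lo_pct", "hi_pct") %>%
      tidyr::pivot_wider(names_from = "period",
                         values_from = c("point_pct", "lo_pct", "hi_pct"),
                         names_glue = "{period}_{.value}")
    dplyr::bind_cols(
      tibble(crop = crop, year = fmap$year,
             landcover_pct = cover$percent[cover$crop == crop]),
      wide
    )
  }) %>% bind_rows()
}
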