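#' Label each dance with a crop outcome from one sampled cloud draw
#'
#' Draws one simulated location per dance uniformly from its cloud,
#' assigns the crop label of the containing field (or "other"), and pairs
#' it with that draw's distance (km), the dance's month and year. Using
#' the sampled draw's own distance keeps outcome and covariate consistent
#' within a model run.
#'
#' @param vectors decoded dance tibble (`dance_id`, `month`, `year`).
#' @param clouds cloud tibble from [simulate_clouds()].
#' @param fmaps a [field_map()] or a list of them (one per year; each
#'   dance is assigned with its own year's map).
#' @param seed integer seed.
#' @param max_radius_m optional region-of-interest radius (see
#'   [assign_points()]).
#' @return tibble `(dance_id, outcome, month, distance_km, year)`.
#' @export
label_dances <- function(vectors, clouds, fmaps, seed = 1, max_radius_m = NULL) {
  fmaps <- as_fieldmap_list(fmaps)
  set.seed(derive_seed(seed, 1))
  picked <- clouds %>%
    group_by(.data$dance_id) %>%
    dplyr::slice_sample(n = 1) %>%
    ungroup()
  picked <- left_join(picked,
                      vectors %>% select("dance_id", "month", "year"),
                      by = "dance_id")
  out <- purrr::map(fmaps, function(fm) {
    sub <- picked[picked$year == fm$year, ]
    if (!nrow(sub)) return(NULL)
    sub$outcome <- assign_points(sub$east_m, sub$north_m, fm,
                                 max_radius_m = max_radius_m)
    sub
  }) %>% bind_rows()
  out %>%
    mutate(distance_km = .data$distance_m / 1000) %>%
    select("dance_id", "outcome", "month", "distance_km", "year") %>%
    arrange(.data$dance_id)
}

as_fieldmap_list <- function(fmaps) {
  if (inherits(fmaps, "field_map")) fmaps <- list(fmaps)
  stopifnot(all(purrr::map_lgl(fmaps, inherits, "field_map")))
  fmaps
}

month_label <- function(m) factor(month.abb[m], levels = month.abb[sort(unique(m))])

#' Distance-corrected crop attractiveness (repeated multinomial fits)
#'
#' Fits, `n_models` times, a multinomial logistic regression of the crop
#' outcome (reference category "other") on month (reference April, or the
#' earliest month present), distance (km, linear) and a year indicator,
#' each time labelling every dance from a fresh draw of its probability
#' cloud. Exponentiated medians of the per-run coefficients give the
#' odds-ratio point estimates; the 2.5th/97.5th percentiles give the CI,
#' so the interval carries the dance-communication uncertainty rather
#' than a single fit's standard errors.
#'
#' Runs in which an outcome category never occurs are dropped (their
#' count is reported). Runs showing separation (any |log-odds| above
#' `separation_cutoff`) are refitted with a small ridge penalty and
#' flagged.
#'
#' @inheritParams label_dances
#' @param n_models number of repeated fits.
#' @param year_effect `"fixed"` (year indicator inside each fit; the
#'   default) or `"stratified"` (independent fits per year).
#' @param separation_cutoff |coefficient| beyond which a run is treated
#'   as separated and refitted with ridge `decay`.
#' @param decay ridge penalty used for flagged runs.
#' @return a `wd_attractiveness` object; see [tidy.wd_attractiveness()].
#' @export
fit_attractiveness <- function(vectors, clouds, fmaps, n_models = 1000,
                               seed = 1, year_effect = c("fixed", "stratified"),
                               max_radius_m = NULL,
                               separation_cutoff = 10, decay = 1e-3) {
  year_effect <- match.arg(year_effect)
  fmaps <- as_fieldmap_list(fmaps)
  if (length(unique(vectors$month)) < 2) {
    abort("attractiveness model needs dances from at least 2 months (no month contrast).")
  }
  if (year_effect == "stratified") {
    out <- purrr::map(fmaps, function(fm) {
      v <- vectors[vectors$year == fm$year, ]
      cl <- clouds[clouds$dance_id %in% v$dance_id, ]
      fit <- fit_attractiveness(v, cl, fm, n_models = n_models,
                                seed = derive_seed(seed, fm$year),
                                year_effect = "fixed",
                                max_radius_m = max_radius_m,
                                separation_cutoff = separation_cutoff,
                                decay = decay)
      fit$estimates$year <- fm$year
      fit
    })
    est <- bind_rows(purrr::map(out, "estimates"))
    res <- list(estimates = est, n_models = n_models,
                n_used = sum(purrr::map_int(out, "n_used")),
                n_dropped = sum(purrr::map_int(out, "n_dropped")),
                n_ridge = sum(purrr::map_int(out, "n_ridge")),
                year_effect = "stratified")
    class(res) <- "wd_attractiveness"
    return(res)
  }

  months <- month_label(vectors$month)
  ref_month <- levels(months)[[1]]
  multi_year <- length(unique(vectors$year)) > 1
  fml <- if (multi_year) outcome ~ month + distance_km + year_f
         else outcome ~ month + distance_km

  # label every stored draw once; each model run then resamples one
  # labelled draw per dance
  store <- build_label_store(vectors, clouds, fmaps, max_radius_m)
  cats <- c("other", setdiff(CROP_LEVELS, "other"))
  cats <- cats[cats %in% unique(c("other", assignable_crops(fmaps)))]

  coef_runs <- vector("list", n_models)
  n_dropped <- 0L
  n_ridge <- 0L
  for (r in seq_len(n_models)) {
    set.seed(derive_seed(seed, 1000 + r))
    pick <- store$offset + ceiling(runif(length(store$offset)) * store$n_draws)
    outcome <- store$labels[pick]
    if (!all(cats %in% unique(outcome))) { n_dropped <- n_dropped + 1L; next }
    dat <- tibble(
      outcome = factor(outcome, levels = cats),
      month = factor(month.abb[store$month], levels = levels(months)),
      distance_km = store$dist_km[pick],
      year_f = factor(store$year)
    )
    fit <- suppressWarnings(
      nnet::multinom(fml, data = dat, trace = FALSE, maxit = 300))
    cf <- coef(fit)
    if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1,
                                       dimnames = list(cats[-1], names(cf)))
    if (any(abs(cf) > separation_cutoff)) {
      n_ridge <- n_ridge + 1L
      fit <- suppressWarnings(
        nnet::multinom(fml, data = dat, trace = FALSE, maxit = 300, decay = decay))
      cf <- coef(fit)
      if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1,
                                         dimnames = list(cats[-1], names(cf)))
    }
    coef_runs[[r]] <- cf
  }
  coef_runs <- purrr::compact(coef_runs)
  n_used <- length(coef_runs)
  if (!n_used) abort("all model runs were degenerate (an outcome category never occurred).")
  if (n_dropped > 0) {
    inform(sprintf("%d of %d runs dropped (outcome category absent); %d refit with ridge.",
                   n_dropped, n_models, n_ridge))
  }

  terms <- colnames(coef_runs[[1]])
  crops_fit <- rownames(coef_runs[[1]])
  est <- purrr::map(crops_fit, function(cr) {
    purrr::map(terms, function(tm) {
      v <- purrr::map_dbl(coef_runs, ~ .x[cr, tm])
      tibble(crop = cr, term = tm,
             odds_ratio = exp(median(v)),
             lo = exp(unname(quantile(v, 0.025))),
             hi = exp(unname(quantile(v, 0.975))),
             n_models_used = n_used)
    }) %>% bind_rows()
  }) %>% bind_rows()
  est <- est %>% mutate(term = sub("^month", "", .data$term),
                        term = sub("^year_f", "year ", .data$term))

  res <- list(estimates = est, n_models = n_models, n_used = n_used,
              n_dropped = n_dropped, n_ridge = n_ridge,
              reference = list(outcome = "other", month = ref_month),
              year_effect = "fixed")
  class(res) <- "wd_attractiveness"
  res
}

assignable_crops <- function(fmaps) {
  unique(unlist(purrr::map(fmaps, ~ unique(.x$fields$crop))))
}

# one-off labelling of every cloud draw, arranged per dance for O(1)
# resampling inside the repeated-fit loop
build_label_store <- function(vectors, clouds, fmaps, max_radius_m = NULL) {
  fmaps <- as_fieldmap_list(fmaps)
  cl <- clouds %>%
    left_join(vectors %>% select("dance_id", "month", "year"),
              by = "dance_id") %>%
    arrange(.data$dance_id, .data$draw)
  map_years <- purrr::map_int(fmaps, "year")
  cl <- cl[cl$year %in% map_years, ]
  if (!nrow(cl)) abort("no clouds match the field maps' years.")
  lab <- rep(NA_character_, nrow(cl))
  for (fm in fmaps) {
    sel <- cl$year == fm$year
    lab[sel] <- assign_points(cl$east_m[sel], cl$north_m[sel], fm,
                              max_radius_m = max_radius_m)
  }
  rle_id <- rle(cl$dance_id)
  n_draws <- rle_id$lengths
  offset <- cumsum(c(0, n_draws[-length(n_draws)]))
  first <- offset + 1
  list(
    dance_id = rle_id$values,
    n_draws = n_draws,
    offset = offset,
    labels = lab,
    dist_km = cl$distance_m / 1000,
    month = cl$month[first],
    year = cl$year[first]
  )
}

#' @export
print.wd_attractiveness <- function(x, ...) {
  cat(sprintf("<wd_attractiveness> %d/%d model runs used (%d dropped, %d ridge-refit)\n",
              x$n_used, x$n_models, x$n_dropped, x$n_ridge))
  if (!is.null(x$reference)) {
    cat(sprintf("  reference outcome '%s', reference month %s\n",
                x$reference$outcome, x$reference$month))
  }
  print(x$estimates, n = 20)
  invisible(x)
}

#' Tidy a repeated-fit attractiveness object
#'
#' @param x a `wd_attractiveness` object.
#' @param ... unused.
#' @return tibble `(crop, term, odds_ratio, lo, hi, n_models_used)`, the
#'   exponentiated median and percentile bounds across model runs.
#' @export
tidy.wd_attractiveness <- function(x, ...) x$estimates

#' @rdname tidy.wd_attractiveness
#' @return `glance()`: a one-row tibble with run bookkeeping.
#' @export
glance.wd_attractiveness <- function(x, ...) {
  tibble(n_models = x$n_models, n_used = x$n_used,
         n_dropped = x$n_dropped, n_ridge = x$n_ridge,
         year_effect = x$year_effect)
}
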