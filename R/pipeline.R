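#' Assemble a pipeline run configuration
#'
#' Collects every tunable of the analysis in one place; all stage functions
#' take their defaults from here when driven through the pipeline runners.
#' Configurations serialize losslessly to JSON ([write_config()] /
#' [read_config()]) and are identified by an MD5 hash of their canonical
#' JSON form, which every artifact manifest carries.
#'
#' @param years Consecutive analysis years (default 1982:2020).
#' @param split_year First year of the second period (default 2002).
#' @param alpha Trend significance level (default 0.1).
#' @param drying_threshold Water variables that must agree for drying
#'   (default 2 of 4).
#' @param require_significant_drying Count only significant trends toward
#'   drying agreement (default `TRUE`).
#' @param delta_aic,adjr2_min,ic Attribution model-selection settings
#'   (defaults 2, 0.36, `"aic"`).
#' @param n_draws Bootstrap draws for period-mean changes (default 300).
#' @param lai_threshold Decadal-mean LAI study mask threshold (default 0.5).
#' @param min_models,min_agree Ensemble voting settings (defaults 5 and 3).
#' @param attribution_years Years used for attribution (`NULL` = all years).
#' @param water_vars Water-related predictors for the rank map.
#' @param focus_boxes Named list of focus boxes (`lat`/`lon` ranges).
#' @param seed Base seed for all stochastic stages.
#'
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(years = 1982:2020, split_year = 2002, alpha = 0.1,
                       drying_threshold = 2, require_significant_drying = TRUE,
                       delta_aic = 2, adjr2_min = 0.36, ic = "aic",
                       n_draws = 300, lai_threshold = 0.5,
                       min_models = 5, min_agree = 3,
                       attribution_years = NULL,
                       water_vars = water_variables(),
                       focus_boxes = list(), seed = 42) {
  stopifnot(
    alpha > 0, alpha < 1, drying_threshold >= 0, drying_threshold <= 4,
    delta_aic > 0, adjr2_min >= 0, adjr2_min < 1, n_draws >= 1,
    lai_threshold >= 0, min_models >= 1, min_agree >= 1,
    ic %in% c("aic", "aicc")
  )
  years <- as.integer(years)
  if (!(split_year > min(years) && split_year <= max(years))) {
    abort("`split_year` must split `years` into two non-empty periods.")
  }
  structure(
    list(
      years = years, split_year = as.integer(split_year), alpha = alpha,
      drying_threshold = drying_threshold,
      require_significant_drying = require_significant_drying,
      delta_aic = delta_aic, adjr2_min = adjr2_min, ic = ic,
      n_draws = as.integer(n_draws), lai_threshold = lai_threshold,
      min_models = as.integer(min_models), min_agree = as.integer(min_agree),
      attribution_years = if (is.null(attribution_years)) NULL else as.integer(attribution_years),
      water_vars = water_vars, focus_boxes = focus_boxes,
      seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "<run_config> %d-%d split %d | alpha %.2g | drying >=%d/4 | dAIC<%.3g adjR2>%.3g (%s) | seed %d\n",
    min(x$years), max(x$years), x$split_year, x$alpha, x$drying_threshold,
    x$delta_aic, x$adjr2_min, x$ic, x$seed
  ))
  invisible(x)
}

config_json <- function(config) {
  jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA, null = "null")
}

#' @rdname run_config
#' @param config A `run_config` object.
#' @param path File path for the JSON serialization.
#' @export
write_config <- function(config, path) {
  writeLines(as.character(config_json(config)), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::fromJSON(readr::read_file(path), simplifyVector = TRUE)
  raw$focus_boxes <- lapply(raw$focus_boxes, function(b) lapply(b, as.numeric))
  do.call(run_config, raw)
}

#' @rdname run_config
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  unname(tools::md5sum(tmp))
}

# period year vectors from a config
config_periods <- function(config) {
  list(
    first = config$years[config$years < config$split_year],
    second = config$years[config$years >= config$split_year]
  )
}

# per-cell dryness index column from net radiation and precipitation
add_dryness_index <- function(drivers) {
  mutate(drivers, dryness_index = as.numeric(
    compute_dryness_index(.data$net_radiation, .data$precipitation)
  ))
}

#' Stacked trend results for the four water-related variables
#'
#' Runs [grid_trends()] on soil moisture, precipitation, VPD and the dryness
#' index (computed from net radiation and precipitation) over the given
#' years, returning one long tibble ready for [classify_drying()].
#'
#' @param drivers Wide driver tibble (see [generate_driver_suite()]).
#' @param years Year subset.
#' @param alpha Significance level.
#' @return Tibble with a `variable` column over the four water variables.
#' @export
water_trends <- function(drivers, years = NULL, alpha = 0.1) {
  d <- add_dryness_index(drivers)
  vars <- c("soil_moisture", "precipitation", "vpd", "dryness_index")
  bind_rows(lapply(vars, function(v) {
    mutate(as_tibble(grid_trends(d, value = v, years = years, alpha = alpha)),
           variable = v, .before = 1)
  }))
}

write_stage <- function(tables, out_dir) {
  for (nm in names(tables)) {
    write_grid_csv(as_tibble(tables[[nm]]), file.path(out_dir, paste0(nm, ".csv")))
  }
}

#' Run the observational analysis end to end
#'
#' For each of the two periods: per-cell LAI and water-variable trends,
#' greenness categories under the decadal LAI mask, drying agreement,
#' browning/drying coincidence, area statistics, browning-by-agreement
#' summary, and Cramer's V between the greenness map and each water
#' variable's trend categories. The dryness-index period-mean change is
#' tested with the permutation bootstrap (aridity being a long-term climatic
#' property rather than a year-by-year trend). Driver attribution runs once
#' over `config$attribution_years`. Reruns with the same inputs and config
#' are bit-identical.
#'
#' @param drivers Wide driver tibble over the config years.
#' @param lai Tibble `lat`, `lon`, `year`, `lai`.
#' @param config A [run_config()].
#' @param out_dir Optional directory: artifacts are written as CSV plus a
#'   `manifest.json` carrying the config, its hash and per-stage cell counts.
#'
#' @return (Invisibly if writing) a named list of result tables:
#'   `trends_lai_<period>`, `water_trends_<period>`, `greenness_<period>`,
#'   `drying_<period>`, `coincidence_<period>`, `summary_<period>`,
#'   `aridity_change`, `attribution`, plus `area_stats` and `cramers_v`.
#' @export
run_observational_pipeline <- function(drivers, lai, config = run_config(),
                                       out_dir = NULL) {
  periods <- config_periods(config)
  out <- list()
  area_rows <- list()
  cv_rows <- list()
  for (pn in names(periods)) {
    yrs <- periods[[pn]]
    lai_tr <- grid_trends(lai, value = "lai", years = yrs, alpha = config$alpha)
    wt <- water_trends(drivers, years = yrs, alpha = config$alpha)
    gr <- classify_greenness(lai_tr, lai, lai_threshold = config$lai_threshold)
    dr <- classify_drying(wt, threshold = config$drying_threshold,
                          require_significant = config$require_significant_drying)
    co <- coincidence_map(gr, dr)
    out[[paste0("trends_lai_", pn)]] <- lai_tr
    out[[paste0("water_trends_", pn)]] <- wt
    out[[paste0("greenness_", pn)]] <- gr
    out[[paste0("drying_", pn)]] <- dr
    out[[paste0("coincidence_", pn)]] <- co
    out[[paste0("summary_", pn)]] <- browning_drying_summary(gr, dr)
    study <- gr$category != "masked"
    dr_full <- left_join(as_tibble(gr), as_tibble(dr)[, c("lat", "lon", "drying")],
                         by = c("lat", "lon"))
    area_rows[[pn]] <- tibble(
      period = pn,
      drying_fraction = area_fraction(
        dr_full, !is.na(.data$drying) & .data$drying, .data$category != "masked"
      ),
      browning_fraction = area_fraction(
        dr_full, .data$category == "browning_significant", .data$category != "masked"
      ),
      drying_within_browning = if (any(dr_full$category == "browning_significant")) {
        area_fraction(dr_full, !is.na(.data$drying) & .data$drying,
                      .data$category == "browning_significant")
      } else NA_real_
    )
    # spatial correspondence of greenness vs. each water variable's trend map
    gr_codes <- dplyr::if_else(study, as.character(gr$category), NA_character_)
    cv_rows[[pn]] <- wt %>%
      group_by(.data$variable) %>%
      summarise(cramers_v = {
        tr_cat <- paste0(
          ifelse(.data$slope >= 0, "increasing", "decreasing"), "_",
          ifelse(.data$significant, "significant", "nonsignificant")
        )
        key <- match(paste(gr$lat, gr$lon), paste(.data$lat, .data$lon))
        suppressWarnings(cramers_v(gr_codes, tr_cat[key]))
      }, .groups = "drop") %>%
      mutate(period = pn, .before = 1)
  }
  out$aridity_change <- grid_change(
    add_dryness_index(drivers), value = "dryness_index",
    split_year = config$split_year, n_draws = config$n_draws, seed = config$seed
  )
  out$attribution <- attribute_grid(
    left_join(drivers, lai, by = c("lat", "lon", "year")),
    years = config$attribution_years, delta_aic = config$delta_aic,
    adjr2_min = config$adjr2_min, ic = config$ic, water_vars = config$water_vars
  )
  out$area_stats <- bind_rows(area_rows)
  out$cramers_v <- bind_rows(cv_rows)
  out$dominant_coverage <- bind_rows(c(
    list(overall = mutate(dominant_coverage(out$attribution), box = "overall", .before = 1)),
    lapply(names(config$focus_boxes), function(nm) {
      mutate(dominant_coverage(out$attribution, config$focus_boxes[[nm]]),
             box = nm, .before = 1)
    })
  ))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_stage(out, out_dir)
    manifest <- list(
      kind = "observational", config = unclass(config),
      config_hash = config_hash(config),
      package_version = as.character(utils::packageVersion("vegdry")),
      cells = list(
        total = dplyr::n_distinct(paste(lai$lat, lai$lon)),
        masked_second = sum(out$greenness_second$category == "masked"),
        attributed = sum(out$attribution$status == "attributed"),
        no_satisfactory_model = sum(out$attribution$status == "no_satisfactory_model")
      )
    )
    writeLines(
      as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA, null = "null")),
      file.path(out_dir, "manifest.json")
    )
    return(invisible(out))
  }
  out
}

#' Run the ensemble analysis end to end
#'
#' Applies the per-member stages (greenness, drying, coincidence, summary,
#' attribution) to each ensemble member and summarizes across members:
#' modal greenness category (with the minimum-members rule), fraction of
#' members simulating drying, fraction with coinciding browning and drying,
#' multi-model mean browning-by-agreement table, and the modal dominant
#' driver (with the minimum-agreement rule).
#'
#' @param members Named list; each element a list with `drivers` and `lai`
#'   tibbles on a shared grid.
#' @param config A [run_config()].
#' @param out_dir Optional output directory (CSV + manifest, as for
#'   [run_observational_pipeline()]).
#'
#' @return (Invisibly if writing) list with per-period ensemble tables
#'   `modal_greenness_<period>`, `drying_fraction_<period>`,
#'   `coincidence_fraction_<period>`, `summary_multimodel_<period>`, and
#'   `modal_driver`, plus `member_results` (per-member stage outputs).
#' @export
run_ensemble_pipeline <- function(members, config = run_config(), out_dir = NULL) {
  if (length(members) < 1) abort("at least one ensemble member is required.")
  if (is.null(names(members))) names(members) <- paste0("member_", seq_along(members))
  periods <- config_periods(config)
  member_results <- lapply(names(members), function(nm) {
    m <- members[[nm]]
    if (!all(c("drivers", "lai") %in% names(m))) {
      abort(sprintf("ensemble member `%s` must provide `drivers` and `lai`.", nm))
    }
    res <- list()
    for (pn in names(periods)) {
      yrs <- periods[[pn]]
      lai_tr <- grid_trends(m$lai, value = "lai", years = yrs, alpha = config$alpha)
      wt <- water_trends(m$drivers, years = yrs, alpha = config$alpha)
      gr <- classify_greenness(lai_tr, m$lai, lai_threshold = config$lai_threshold)
      dr <- classify_drying(wt, threshold = config$drying_threshold,
                            require_significant = config$require_significant_drying)
      res[[paste0("greenness_", pn)]] <- gr
      res[[paste0("drying_", pn)]] <- dr
      res[[paste0("coincidence_", pn)]] <- coincidence_map(gr, dr)
      res[[paste0("summary_", pn)]] <- browning_drying_summary(gr, dr)
    }
    res$attribution <- attribute_grid(
      left_join(m$drivers, m$lai, by = c("lat", "lon", "year")),
      years = config$attribution_years, delta_aic = config$delta_aic,
      adjr2_min = config$adjr2_min, ic = config$ic, water_vars = config$water_vars
    )
    res
  })
  names(member_results) <- names(members)
  out <- list(member_results = member_results)
  for (pn in names(periods)) {
    grs <- lapply(member_results, `[[`, paste0("greenness_", pn))
    drs <- lapply(member_results, `[[`, paste0("drying_", pn))
    cos <- lapply(member_results, `[[`, paste0("coincidence_", pn))
    out[[paste0("modal_greenness_", pn)]] <-
      modal_trend_category(grs, min_models = config$min_models)
    out[[paste0("drying_fraction_", pn)]] <- drying_model_fraction(drs)
    out[[paste0("coincidence_fraction_", pn)]] <- cos %>%
      lapply(function(co) mutate(as_tibble(co),
                                 coinciding = .data$category == "browning_and_drying",
                                 has_data = .data$category != "masked")) %>%
      bind_rows() %>%
      dplyr::filter(.data$has_data) %>%
      group_by(.data$lat, .data$lon) %>%
      summarise(n_models = dplyr::n(), fraction = mean(.data$coinciding), .groups = "drop")
    out[[paste0("summary_multimodel_", pn)]] <-
      multimodel_mean_summary(lapply(member_results, `[[`, paste0("summary_", pn)))
  }
  out$modal_driver <- modal_dominant_driver(
    lapply(member_results, `[[`, "attribution"), min_agree = config$min_agree
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_stage(out[setdiff(names(out), "member_results")], out_dir)
    for (nm in names(member_results)) {
      mdir <- file.path(out_dir, nm)
      dir.create(mdir, showWarnings = FALSE)
      write_stage(member_results[[nm]], mdir)
    }
    manifest <- list(
      kind = "ensemble", config = unclass(config),
      config_hash = config_hash(config),
      package_version = as.character(utils::packageVersion("vegdry")),
      members = names(members)
    )
    writeLines(
      as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA, null = "null")),
      file.path(out_dir, "manifest.json")
    )
    return(invisible(out))
  }
  out
}
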