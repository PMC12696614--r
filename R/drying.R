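#' Vapor pressure deficit from air and dew-point temperature
#'
#' Magnus-form saturation vapor pressure
#' `es(T) = 0.6108 * exp(17.27 * T / (T + 237.3))` evaluated at the air
#' temperature, the actual vapor pressure as the same expression at the dew
#' point, and `VPD = es - ea`. With the 0.6108 coefficient both pressures are
#' in kPa. Super-saturated inputs (`Td > T`) would give negative VPD; these
#' are clipped to zero and counted in attribute `"n_clipped"`.
#'
#' @param temperature Air temperature at 2 m, degrees Celsius.
#' @param dew_point Dew-point temperature, degrees Celsius.
#' @param pascals Multiply the result by 1000 (report in Pa instead of kPa).
#'
#' @return Numeric VPD (kPa by default), same shape as the inputs.
#' @export
#' @examples
#' compute_vpd(25, 15)
#' compute_vpd(10, 10) # saturated air: 0
compute_vpd <- function(temperature, dew_point, pascals = FALSE) {
  if (any(temperature <= -237.3, na.rm = TRUE) || any(dew_point <= -237.3, na.rm = TRUE)) {
    abort("temperatures at or below -237.3 degC are outside the Magnus formula's domain.")
  }
  es <- 0.6108 * exp(17.27 * temperature / (temperature + 237.3))
  ea <- 0.6108 * exp(17.27 * dew_point / (dew_point + 237.3))
  vpd <- es - ea
  n_clipped <- sum(vpd < 0, na.rm = TRUE)
  vpd <- pmax(vpd, 0)
  if (pascals) vpd <- vpd * 1000
  attr(vpd, "n_clipped") <- n_clipped
  vpd
}

# seconds in a Julian year; used to express annual precipitation as a flux
seconds_per_year <- function() 365.25 * 86400

#' Dryness index: net radiation over energy-equivalent precipitation
#'
#' `DI = Rn / (lambda * P)` with the latent heat of vaporization
#' `lambda = 2.45 MJ kg-1` converting annual precipitation (mm yr-1, i.e.
#' kg m-2 yr-1) into an energy flux in W m-2. Values above 1 indicate an
#' energy surplus relative to water supply. Cells with zero (or negative)
#' precipitation are returned missing; their count is in attribute
#' `"n_missing"`.
#'
#' @param net_radiation Net radiation, W m-2.
#' @param precipitation Annual precipitation, mm yr-1.
#' @return Dimensionless index, same shape as the inputs.
#' @export
#' @examples
#' compute_dryness_index(120, 800)
compute_dryness_index <- function(net_radiation, precipitation) {
  lambda <- 2.45e6 # J kg-1
  bad <- !is.na(precipitation) & precipitation <= 0
  p_flux <- precipitation * lambda / seconds_per_year() # W m-2
  idx <- net_radiation / p_flux
  idx[bad] <- NA_real_
  attr(idx, "n_missing") <- sum(bad)
  idx
}

#' Classify per-cell drying agreement across the four water variables
#'
#' Drying means decreasing water availability or increasing water demand:
#' soil moisture and precipitation flag drying on a (significant) decreasing
#' trend, VPD and the dryness index on a (significant) increasing trend. A
#' cell is drying when at least `threshold` of the four variables agree
#' (default 2 of 4).
#'
#' @param trends Tibble with columns `lat`, `lon`, `variable`, `direction`,
#'   `significant` — per-cell trend results (e.g. stacked [grid_trends()]
#'   outputs) for the variables `soil_moisture`, `precipitation`, `vpd`,
#'   `dryness_index`.
#' @param threshold Minimum number of agreeing variables (default 2).
#' @param require_significant Require trend significance for a drying flag
#'   (default `TRUE`); `FALSE` gives the sensitivity variant in which any
#'   drying-direction trend counts.
#'
#' @return Tibble of class `vd_drying`, one row per cell: the four logical
#'   flags (`soil_moisture_drying`, ...), `agreement`, `drying`. Cells
#'   missing any of the four variables are dropped.
#' @export
classify_drying <- function(trends, threshold = 2, require_significant = TRUE) {
  water_vars <- c("soil_moisture", "precipitation", "vpd", "dryness_index")
  supply <- c("soil_moisture", "precipitation")
  trends <- dplyr::filter(trends, .data$variable %in% water_vars)
  flags <- trends %>%
    mutate(
      dry_dir = ifelse(.data$variable %in% supply,
                       .data$direction == "decreasing",
                       .data$direction == "increasing"),
      flag = .data$dry_dir & (!require_significant | .data$significant)
    ) %>%
    select("lat", "lon", "variable", "flag") %>%
    tidyr::pivot_wider(names_from = "variable", values_from = "flag",
                       names_glue = "{variable}_drying")
  need <- paste0(water_vars, "_drying")
  missing_cols <- setdiff(need, names(flags))
  if (length(missing_cols)) {
    abort(paste0("trend results are missing water variable(s): ",
                 paste(sub("_drying$", "", missing_cols), collapse = ", ")))
  }
  out <- flags %>%
    dplyr::filter(dplyr::if_all(dplyr::all_of(need), ~ !is.na(.x))) %>%
    mutate(
      agreement = rowSums(dplyr::pick(dplyr::all_of(need))),
      drying = .data$agreement >= threshold
    )
  class(out) <- c("vd_drying", class(out))
  attr(out, "threshold") <- threshold
  out
}

# default decade windows: calendar decades (1981-1990, 1991-2000, ...)
default_decades <- function(years) {
  split(years, floor((years - 1) / 10))
}

#' Classify per-cell greenness trend categories with the study mask
#'
#' Cells are masked out of the study area when the decadal mean LAI falls
#' below `lai_threshold` (default 0.5) in any of the decade windows;
#' otherwise the category is the sign of the Theil-Sen LAI slope crossed
#' with Mann-Kendall significance. A zero slope ties to nonsignificant
#' greening (a fifth "flat" class is not carried).
#'
#' @param lai_trend A [grid_trends()] result for LAI.
#' @param lai Tibble `lat`, `lon`, `year`, plus the LAI column.
#' @param value Name of the LAI column (default `"lai"`).
#' @param decades List of integer year vectors defining the decade windows;
#'   default: calendar decades covering the data years.
#' @param lai_threshold Mask threshold on decadal mean LAI (default 0.5).
#'
#' @return Tibble of class `vd_greenness`: `lat`, `lon`, `category` (factor
#'   with levels greening/browning x significant/nonsignificant, `masked`).
#' @export
classify_greenness <- function(lai_trend, lai, value = "lai",
                               decades = default_decades(unique(lai$year)),
                               lai_threshold = 0.5) {
  decade_id <- rep(NA_integer_, length(lai$year))
  for (i in seq_along(decades)) decade_id[lai$year %in% decades[[i]]] <- i
  dm <- lai %>%
    mutate(decade = decade_id) %>%
    dplyr::filter(!is.na(.data$decade)) %>%
    group_by(.data$lat, .data$lon) %>%
    summarise(
      masked = any(tapply(.data[[value]], .data$decade, mean, na.rm = TRUE) < lai_threshold) ||
        dplyr::n_distinct(.data$decade) < length(decades),
      .groups = "drop"
    )
  out <- lai_trend %>%
    left_join(dm, by = c("lat", "lon")) %>%
    mutate(
      category = dplyr::case_when(
        is.na(.data$masked) | .data$masked ~ "masked",
        is.na(.data$slope) ~ "masked",
        .data$slope < 0 & .data$significant ~ "browning_significant",
        .data$slope < 0 ~ "browning_nonsignificant",
        .data$significant ~ "greening_significant",
        TRUE ~ "greening_nonsignificant"
      ),
      category = factor(.data$category, levels = greenness_levels())
    ) %>%
    select("lat", "lon", "category")
  class(out) <- c("vd_greenness", class(out))
  out
}

#' Map where browning coincides with drying
#'
#' @param greenness A [classify_greenness()] result.
#' @param drying A [classify_drying()] result on the same grid.
#' @param require_significant_browning Count only significant browning as
#'   browning (default `TRUE`); `FALSE` also counts nonsignificant browning.
#'
#' @return Tibble of class `vd_coincidence`: `lat`, `lon`, `category`
#'   (factor: `browning_and_drying`, `browning_only`, `drying_only`,
#'   `neither`, `masked`).
#' @export
coincidence_map <- function(greenness, drying, require_significant_browning = TRUE) {
  joined <- left_join(
    as_tibble(greenness), as_tibble(drying)[, c("lat", "lon", "drying")],
    by = c("lat", "lon")
  )
  if (nrow(joined) != nrow(greenness) ||
      !all(paste(drying$lat, drying$lon) %in% paste(greenness$lat, greenness$lon))) {
    abort("greenness and drying maps do not share a grid.")
  }
  browning_cats <- if (require_significant_browning) {
    "browning_significant"
  } else {
    c("browning_significant", "browning_nonsignificant")
  }
  out <- joined %>%
    mutate(
      browning = .data$category %in% browning_cats,
      dry = !is.na(.data$drying) & .data$drying,
      category = dplyr::case_when(
        .data$category == "masked" ~ "masked",
        .data$browning & .data$dry ~ "browning_and_drying",
        .data$browning ~ "browning_only",
        .data$dry ~ "drying_only",
        TRUE ~ "neither"
      ),
      category = factor(.data$category, levels = coincidence_levels())
    ) %>%
    select("lat", "lon", "category")
  class(out) <- c("vd_coincidence", class(out))
  out
}

#' Latitude-weighted area fraction of a mask
#'
#' Fraction of area covered by `mask` within the reference region `within`,
#' with each cell weighted by the cosine of its center latitude:
#' `sum(cos(lat) * mask) / sum(cos(lat) * within)`.
#'
#' @param data Tibble with a `lat` column.
#' @param mask Tidy-evaluated logical expression selecting the numerator cells.
#' @param within Optional logical expression for the reference region
#'   (default: all rows of `data`).
#'
#' @return Fraction in \[0, 1\].
#' @export
#' @examples
#' d <- tibble::tibble(lat = c(0, 60), hit = c(FALSE, TRUE))
#' area_fraction(d, hit) # 0.5 / 1.5
area_fraction <- function(data, mask, within = NULL) {
  m <- eval_tidy(enquo(mask), data)
  wq <- enquo(within)
  w <- if (quo_is_null(wq)) rep(TRUE, nrow(data)) else eval_tidy(wq, data)
  cw <- cos(data$lat * pi / 180)
  denom <- sum(cw * (w & !is.na(w)))
  if (denom == 0) abort("the reference region `within` has zero area.")
  sum(cw * (m & w), na.rm = TRUE) / denom
}

#' Cramer's V between two categorical maps
#'
#' `V = sqrt(chi2 / (N * (min(r, c) - 1)))` from the cell-count contingency
#' table of the two maps over their shared non-missing cells. Degenerate
#' tables (fewer than two observed categories on either side) return `NA`
#' with a warning.
#'
#' @param a,b Factors or vectors of equal length (per-cell categories).
#' @return V in \[0, 1\], or `NA` for a degenerate table.
#' @export
cramers_v <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  tab <- table(droplevels(factor(a[keep])), droplevels(factor(b[keep])))
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    warn("degenerate contingency table: fewer than 2 categories on one side.")
    return(NA_real_)
  }
  chi2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic)
  unname(sqrt(chi2 / (sum(tab) * (min(dim(tab)) - 1))))
}

#' Browning area partitioned by drying agreement
#'
#' Cosine-latitude-weighted area of (significant) browning cells, split by
#' the number of water variables agreeing on drying (0-4). The per-class
#' areas sum exactly to the total browning area.
#'
#' @param greenness A [classify_greenness()] result.
#' @param drying A [classify_drying()] result on the same grid.
#' @param include_nonsignificant Also count nonsignificant browning
#'   (default `FALSE`).
#'
#' @return Tibble: `agreement` (0-4), `area` (sum of cosine weights),
#'   `area_fraction` (share of the unmasked study area).
#' @export
browning_drying_summary <- function(greenness, drying, include_nonsignificant = FALSE) {
  browning_cats <- if (include_nonsignificant) {
    c("browning_significant", "browning_nonsignificant")
  } else {
    "browning_significant"
  }
  joined <- left_join(
    as_tibble(greenness), as_tibble(drying)[, c("lat", "lon", "agreement")],
    by = c("lat", "lon")
  ) %>%
    mutate(w = cos(.data$lat * pi / 180))
  study_area <- sum(joined$w[joined$category != "masked"])
  br <- joined %>%
    dplyr::filter(.data$category %in% browning_cats, !is.na(.data$agreement))
  out <- tibble(agreement = 0:4) %>%
    left_join(
      br %>% group_by(.data$agreement) %>% summarise(area = sum(.data$w), .groups = "drop"),
      by = "agreement"
    ) %>%
    mutate(
      area = tidyr::replace_na(.data$area, 0),
      area_fraction = .data$area / study_area
    )
  out
}
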