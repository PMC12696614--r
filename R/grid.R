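#' Define a regular lat/lon grid with an annual time axis
#'
#' @param lats Numeric vector of cell-center latitudes (degrees north),
#'   regularly spaced, within \[-90, 90\].
#' @param lons Numeric vector of cell-center longitudes (degrees east),
#'   within \[-180, 180).
#' @param years Integer vector of strictly consecutive calendar years
#'   (at least 10).
#'
#' @return An object of class `grid_spec`: a list with elements `lats`,
#'   `lons`, `years`.
#' @export
#' @examples
#' g <- grid_spec(lats = seq(-28.5, 28.5, by = 3),
#'                lons = seq(-43.5, 43.5, by = 3),
#'                years = 1982:2020)
grid_spec <- function(lats, lons, years) {
  years <- as.integer(years)
  if (length(years) < 10 || any(diff(years) != 1L)) {
    abort("`years` must be at least 10 strictly consecutive calendar years.")
  }
  if (any(lats < -90 | lats > 90)) abort("`lats` must lie within [-90, 90].")
  if (any(lons < -180 | lons >= 180)) abort("`lons` must lie within [-180, 180).")
  if (length(lats) * length(lons) < 2) abort("grid must have at least 2 cells.")
  structure(
    list(lats = as.numeric(lats), lons = as.numeric(lons), years = years),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d x %d cells, years %d-%d (%d)\n",
    length(x$lats), length(x$lons), min(x$years), max(x$years), length(x$years)
  ))
  invisible(x)
}

#' Describe how one annual field is generated
#'
#' A field is a per-cell linear trend plus stationary AR(1) noise:
#' `value(t) = baseline + trend * (year - first_year) + e(t)` with
#' `e(t) = phi * e(t-1) + innovation`, the noise initialized from its
#' stationary distribution (standard deviation `sd / sqrt(1 - phi^2)`), so
#' there is no burn-in transient. Rectangular lat/lon boxes can override the
#' trend (and optionally the baseline) regionally; overlapping boxes resolve
#' last-listed-wins.
#'
#' @param baseline Baseline level, in the variable's units.
#' @param trend Linear trend per year.
#' @param phi AR(1) coefficient in \[0, 1).
#' @param sd Innovation standard deviation (>= 0).
#' @param regions Optional list of region overrides; each a list with
#'   `lat = c(min, max)`, `lon = c(min, max)` and any of `trend`, `baseline`.
#'
#' @return An object of class `field_spec`.
#' @export
field_spec <- function(baseline = 0, trend = 0, phi = 0, sd = 0, regions = list()) {
  if (phi < 0 || phi >= 1) abort("AR(1) coefficient `phi` must lie in [0, 1) for a stationary noise process.")
  if (sd < 0) abort("innovation `sd` must be >= 0.")
  structure(
    list(baseline = baseline, trend = trend, phi = phi, sd = sd, regions = regions),
    class = "field_spec"
  )
}

# per-cell trend/baseline matrices after region overrides (last wins)
cell_params <- function(grid, spec) {
  nlat <- length(grid$lats)
  nlon <- length(grid$lons)
  trend <- matrix(spec$trend, nlat, nlon)
  baseline <- matrix(spec$baseline, nlat, nlon)
  for (rg in spec$regions) {
    in_lat <- grid$lats >= rg$lat[1] & grid$lats <= rg$lat[2]
    in_lon <- grid$lons >= rg$lon[1] & grid$lons <= rg$lon[2]
    if (!is.null(rg$trend)) trend[in_lat, in_lon] <- rg$trend
    if (!is.null(rg$baseline)) baseline[in_lat, in_lon] <- rg$baseline
  }
  list(trend = trend, baseline = baseline)
}

# AR(1) noise matrix (ncell x nyears), stationary initialization
ar1_noise <- function(ncell, nyears, phi, sd) {
  if (sd == 0) return(matrix(0, ncell, nyears))
  noise <- matrix(0, ncell, nyears)
  noise[, 1] <- rnorm(ncell, 0, sd / sqrt(1 - phi^2))
  if (nyears > 1) {
    innov <- matrix(rnorm(ncell * (nyears - 1), 0, sd), ncell, nyears - 1)
    for (t in 2:nyears) noise[, t] <- phi * noise[, t - 1] + innov[, t - 1]
  }
  noise
}

#' Generate one gridded annual field
#'
#' Deterministic trend plus AR(1) noise per grid cell; identical
#' `(grid, spec, seed)` reproduce bit-identical output. The caller's RNG
#' state is left untouched.
#'
#' @param grid A [grid_spec()].
#' @param spec A [field_spec()].
#' @param seed Integer seed.
#' @param variable Name stored in the `variable` column.
#'
#' @return A tibble with columns `lat`, `lon`, `year`, `value` (one row per
#'   cell-year), carrying the variable name in attribute `"variable"`.
#' @export
#' @examples
#' g <- grid_spec(seq(0, 9), seq(0, 9), 1991:2010)
#' sm <- generate_annual_field(g, field_spec(0.3, -0.002, phi = 0.3, sd = 0.02), seed = 1)
generate_annual_field <- function(grid, spec, seed, variable = "value") {
  stopifnot(inherits(grid, "grid_spec"), inherits(spec, "field_spec"))
  nlat <- length(grid$lats); nlon <- length(grid$lons); nyr <- length(grid$years)
  ncell <- nlat * nlon
  par <- cell_params(grid, spec)
  tvec <- grid$years - grid$years[1]
  det <- as.vector(par$baseline) + outer(as.vector(par$trend), tvec) # ncell x nyr
  noise <- withr::with_seed(seed, ar1_noise(ncell, nyr, spec$phi, spec$sd))
  vals <- det + noise
  out <- tibble(
    lat = rep(rep(grid$lats, times = nlon), times = nyr),
    lon = rep(rep(grid$lons, each = nlat), times = nyr),
    year = rep(grid$years, each = ncell),
    value = as.vector(vals)
  )
  attr(out, "variable") <- variable
  out
}

#' Default field specifications for the ten canonical predictors
#'
#' Baselines and noise levels are chosen as desk-scale stand-ins for a humid
#' tropical-to-temperate cell: volumetric soil moisture around 0.30, annual
#' precipitation around 800 mm, temperature in Kelvin (so that divide-by-max
#' normalization maps onto (0, 1\]), VPD below 1 kPa, radiation in W m-2 and
#' cover fractions in \[0, 1\]. The two annual-extreme entries
#' (`soil_moisture_annual_min`, `temperature_annual_max`) are *offset*
#' specifications: the extreme field is derived from its parent annual mean by
#' subtracting (resp. adding) a strictly nonnegative offset field generated
#' from that spec, which guarantees min <= mean and max >= mean at every
#' cell-year.
#'
#' @return Named list of [field_spec()] objects over [canonical_predictors()].
#' @export
default_driver_specs <- function() {
  list(
    soil_moisture = field_spec(0.30, 0, phi = 0.3, sd = 0.02),
    precipitation = field_spec(800, 0, phi = 0.2, sd = 50),
    vpd = field_spec(0.80, 0, phi = 0.3, sd = 0.05),
    temperature = field_spec(288, 0, phi = 0.3, sd = 0.30),
    net_radiation = field_spec(120, 0, phi = 0.2, sd = 8),
    shortwave_radiation = field_spec(200, 0, phi = 0.2, sd = 10),
    tree_cover = field_spec(0.50, 0, phi = 0.5, sd = 0.01),
    crop_fraction = field_spec(0.20, 0, phi = 0.5, sd = 0.01),
    soil_moisture_annual_min = field_spec(0.08, 0, phi = 0.3, sd = 0.02),
    temperature_annual_max = field_spec(10, 0, phi = 0.3, sd = 0.30)
  )
}

#' Generate the full suite of annual driver fields
#'
#' One field per canonical predictor, each with its own deterministic
#' sub-seed (`seed + 101 * position`), so adding or regenerating one variable
#' never perturbs the noise of another. The annual extremes are derived from
#' their parent fields (see [default_driver_specs()]), enforcing
#' `soil_moisture_annual_min <= soil_moisture` and
#' `temperature_annual_max >= temperature` everywhere. If `specs` provides a
#' `dew_point` spec instead of `vpd`, VPD is computed from temperature and
#' dew point with [compute_vpd()] (temperatures in Kelvin are converted).
#'
#' @param grid A [grid_spec()].
#' @param specs Named list of [field_spec()] covering [canonical_predictors()]
#'   (or `dew_point` in place of `vpd`).
#' @param seed Integer seed.
#'
#' @return A wide tibble: `lat`, `lon`, `year`, plus one column per predictor.
#' @export
generate_driver_suite <- function(grid, specs = default_driver_specs(), seed = 1) {
  preds <- canonical_predictors()
  use_dewpoint <- !("vpd" %in% names(specs)) && ("dew_point" %in% names(specs))
  needed <- setdiff(preds, if (use_dewpoint) "vpd" else character())
  missing <- setdiff(needed, names(specs))
  if (length(missing)) {
    abort(paste0("missing field_spec for predictor(s): ", paste(missing, collapse = ", ")))
  }
  sub_seed <- function(name) {
    seed + 101L * match(name, c(preds, "dew_point"))
  }
  fields <- list()
  base_vars <- setdiff(needed, c("soil_moisture_annual_min", "temperature_annual_max"))
  for (v in base_vars) {
    fields[[v]] <- generate_annual_field(grid, specs[[v]], sub_seed(v), v)$value
  }
  if (use_dewpoint) {
    td <- generate_annual_field(grid, specs$dew_point, sub_seed("dew_point"), "dew_point")$value
    tair <- fields$temperature
    in_kelvin <- mean(tair) > 200
    fields$vpd <- compute_vpd(
      if (in_kelvin) tair - 273.15 else tair,
      if (in_kelvin) td - 273.15 else td
    )
  }
  # derived annual extremes: nonnegative offset from the parent mean field
  off_min <- generate_annual_field(
    grid, specs$soil_moisture_annual_min,
    sub_seed("soil_moisture_annual_min"), "sm_min_offset"
  )$value
  fields$soil_moisture_annual_min <- fields$soil_moisture - pmax(off_min, 0)
  off_max <- generate_annual_field(
    grid, specs$temperature_annual_max,
    sub_seed("temperature_annual_max"), "tmax_offset"
  )$value
  fields$temperature_annual_max <- fields$temperature + pmax(off_max, 0)

  ncell <- length(grid$lats) * length(grid$lons)
  frame <- tibble(
    lat = rep(rep(grid$lats, times = length(grid$lons)), times = length(grid$years)),
    lon = rep(rep(grid$lons, each = length(grid$lats)), times = length(grid$years)),
    year = rep(grid$years, each = ncell)
  )
  dplyr::bind_cols(frame, as_tibble(fields[preds]))
}

#' Describe the linear coupling of LAI to its drivers
#'
#' @param intercept Intercept beta0 (LAI units).
#' @param coefficients Named numeric vector of coefficients over (a subset of)
#'   [canonical_predictors()]; unnamed predictors get coefficient 0.
#' @param noise_sd Standard deviation of the iid Gaussian LAI noise.
#' @param regions Optional list of per-region overrides; each a list with
#'   `lat`, `lon` ranges and any of `coefficients` (named vector) and
#'   `intercept`.
#'
#' @return An object of class `coupling_spec`.
#' @export
coupling_spec <- function(intercept = 2, coefficients = c(), noise_sd = 0.05,
                          regions = list()) {
  bad <- setdiff(names(coefficients), canonical_predictors())
  if (length(bad)) {
    abort(paste0("unknown predictor(s) in `coefficients`: ", paste(bad, collapse = ", ")))
  }
  beta <- setNames(numeric(10), canonical_predictors())
  beta[names(coefficients)] <- coefficients
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  structure(
    list(intercept = intercept, coefficients = beta, noise_sd = noise_sd, regions = regions),
    class = "coupling_spec"
  )
}

#' Generate LAI as a known linear response to normalized drivers
#'
#' LAI at each cell and year is
#' `beta0 + sum_i beta_i * x_i(t) / max_t x_i(t) + eps`, using the same
#' divide-by-maximum normalization (per cell, over years) as the attribution
#' stage, with iid Gaussian noise. Negative values are clipped to zero; the
#' number of clipped cell-years is stored in attribute `"n_clipped"`.
#'
#' @param drivers Wide driver tibble from [generate_driver_suite()].
#' @param coupling A [coupling_spec()].
#' @param seed Integer seed for the LAI noise.
#'
#' @return Tibble `lat`, `lon`, `year`, `lai`.
#' @export
generate_lai <- function(drivers, coupling, seed = 1) {
  stopifnot(inherits(coupling, "coupling_spec"))
  preds <- canonical_predictors()
  missing <- setdiff(preds, names(drivers))
  if (length(missing)) {
    abort(paste0("drivers are missing predictor column(s): ", paste(missing, collapse = ", ")))
  }
  if (all(coupling$coefficients == 0) && coupling$noise_sd == 0 &&
      all(vapply(coupling$regions, function(r) is.null(r$coefficients), logical(1)))) {
    warn("all coupling coefficients and the noise sd are zero: LAI is constant.")
  }
  d <- dplyr::arrange(drivers, .data$lon, .data$lat, .data$year)
  cell <- paste(d$lat, d$lon, sep = "|")
  # per-cell, per-column divide-by-max normalization
  norm <- vapply(preds, function(v) {
    x <- d[[v]]
    mx <- stats::ave(x, cell, FUN = max)
    x / mx
  }, numeric(nrow(d)))
  beta_mat <- matrix(rep(coupling$coefficients, each = nrow(d)), nrow = nrow(d))
  b0 <- rep(coupling$intercept, nrow(d))
  for (rg in coupling$regions) {
    in_box <- d$lat >= rg$lat[1] & d$lat <= rg$lat[2] &
      d$lon >= rg$lon[1] & d$lon <= rg$lon[2]
    if (!is.null(rg$intercept)) b0[in_box] <- rg$intercept
    if (!is.null(rg$coefficients)) {
      for (v in names(rg$coefficients)) {
        beta_mat[in_box, match(v, preds)] <- rg$coefficients[[v]]
      }
    }
  }
  lai <- b0 + rowSums(norm * beta_mat)
  if (coupling$noise_sd > 0) {
    lai <- lai + withr::with_seed(seed, rnorm(length(lai), 0, coupling$noise_sd))
  }
  n_clipped <- sum(lai < 0)
  lai <- pmax(lai, 0)
  out <- tibble(lat = d$lat, lon = d$lon, year = d$year, lai = lai)
  attr(out, "n_clipped") <- n_clipped
  attr(out, "variable") <- "lai"
  out
}

#' Read / write gridded annual tables
#'
#' The on-disk schema shared by every stage is a plain CSV in long or wide
#' cell-year layout: columns `lat`, `lon`, `year`, plus one column per
#' variable.
#'
#' @param data Tibble to write.
#' @param path File path.
#' @return `read_grid_csv()` returns a tibble; `write_grid_csv()` returns
#'   `path` invisibly.
#' @export
write_grid_csv <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
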