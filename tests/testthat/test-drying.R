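magnus <- function(tc) 0.6108 * exp(17.27 * tc / (tc + 237.3)) # independent evaluator

test_that("VPD identities and oracle evaluation", {
  expect_equal(compute_vpd(10, 10), 0, ignore_attr = TRUE) # saturated air
  expect_equal(magnus(0), 0.6108) # exponent vanishes at 0 degC
  expect_equal(compute_vpd(25, 15), magnus(25) - magnus(15), ignore_attr = TRUE)
  expect_equal(compute_vpd(25, 15, pascals = TRUE),
               1000 * (magnus(25) - magnus(15)), ignore_attr = TRUE)
  expect_error(compute_vpd(-240, -250), "domain|Magnus")
})

test_that("VPD is nonnegative, clips super-saturation, increases with temperature", {
  v <- compute_vpd(c(20, 10), c(25, 5)) # first pair super-saturated
  expect_equal(v[1], 0)
  expect_gt(v[2], 0)
  expect_equal(attr(v, "n_clipped"), 1)
  temps <- seq(-5, 40, by = 0.5)
  vpds <- compute_vpd(temps, rep(-10, length(temps)))
  expect_true(all(diff(vpds) > 0))
})

test_that("dryness index is linear in radiation, inverse in precipitation", {
  expect_equal(compute_dryness_index(240, 800), 2 * compute_dryness_index(120, 800),
               ignore_attr = TRUE)
  # construct P so that lambda * P equals Rn as a flux: index exactly 1
  rn <- 150
  p_eq <- rn * (365.25 * 86400) / 2.45e6
  expect_equal(compute_dryness_index(rn, p_eq), 1, ignore_attr = TRUE)
  # independent unit conversion: mm/yr -> kg m-2 s-1 times latent heat J/kg
  withr::with_seed(2, {
    rn <- runif(50, 50, 200)
    p <- runif(50, 100, 2000)
    expected <- rn / ((p / (365.25 * 86400)) * 2.45e6)
    expect_equal(compute_dryness_index(rn, p), expected, ignore_attr = TRUE)
  })
  z <- compute_dryness_index(c(100, 100), c(0, 500))
  expect_true(is.na(z[1]))
  expect_equal(attr(z, "n_missing"), 1)
})

make_water_trends <- function(dirs, sigs = rep(TRUE, 4)) {
  vars <- c("soil_moisture", "precipitation", "vpd", "dryness_index")
  tibble::tibble(
    variable = vars, lat = 0, lon = 0,
    direction = dirs, significant = sigs,
    slope = ifelse(dirs == "increasing", 1, ifelse(dirs == "decreasing", -1, 0))
  )
}

test_that("drying classification counts agreement in the drying direction", {
  all_dry <- make_water_trends(c("decreasing", "decreasing", "increasing", "increasing"))
  d <- classify_drying(all_dry)
  expect_equal(d$agreement, 4)
  expect_true(d$drying)

  all_wet <- make_water_trends(c("increasing", "increasing", "decreasing", "decreasing"))
  d2 <- classify_drying(all_wet)
  expect_equal(d2$agreement, 0)
  expect_false(d2$drying)

  # exactly soil moisture down + VPD up significant: 2 of 4 meets the threshold
  two <- make_water_trends(c("decreasing", "increasing", "increasing", "increasing"),
                           sigs = c(TRUE, FALSE, TRUE, FALSE))
  d3 <- classify_drying(two)
  expect_equal(d3$agreement, 2)
  expect_true(d3$drying)
  expect_false(classify_drying(two, threshold = 3)$drying)

  # sensitivity variant: the nonsignificant dryness-index rise now counts too
  d4 <- classify_drying(two, require_significant = FALSE)
  expect_equal(d4$agreement, 3) # precipitation trends up (wetting), rest dry

  expect_error(classify_drying(all_dry[all_dry$variable != "vpd", ]), "vpd")
})

test_that("greenness classification applies the decadal LAI mask", {
  years <- 1981:2020
  grid2 <- tidyr::expand_grid(lat = 0, lon = c(0, 3), year = years)
  dec <- floor((years - 1) / 10)
  dec_idx <- match(dec, sort(unique(dec)))
  # cell at lon 0: always 0.3 (masked); lon 3: decadal means 0.6,0.6,0.6,0.4 (masked)
  grid2$lai <- ifelse(grid2$lon == 0, 0.3, c(0.6, 0.6, 0.6, 0.4)[dec_idx])
  tr <- grid_trends(grid2, value = "lai")
  gr <- classify_greenness(tr, grid2)
  expect_equal(as.character(gr$category), c("masked", "masked"))

  # strong noise-free positive trend well above the mask threshold
  grid3 <- tidyr::expand_grid(lat = c(0, 3), lon = 0, year = years)
  grid3$lai <- 1 + 0.05 * (grid3$year - 1981)
  gr2 <- classify_greenness(grid_trends(grid3, value = "lai"), grid3)
  expect_true(all(gr2$category == "greening_significant"))

  # browning: strong negative trend, means still above 0.5
  grid4 <- tidyr::expand_grid(lat = c(0, 3), lon = 0, year = years)
  grid4$lai <- 4 - 0.05 * (grid4$year - 1981)
  gr3 <- classify_greenness(grid_trends(grid4, value = "lai"), grid4)
  expect_true(all(gr3$category == "browning_significant"))
})

test_that("coincidence map categories and the monotone relaxation property", {
  gr <- make_greenness(
    c("browning_significant", "browning_nonsignificant",
      "greening_nonsignificant", "masked"),
    lats = rep(c(0, 3), each = 2), lons = rep(c(0, 3), 2)
  )
  drying <- tibble::tibble(
    lat = rep(c(0, 3), each = 2), lon = rep(c(0, 3), 2),
    agreement = c(4, 2, 0, 4), drying = c(TRUE, TRUE, FALSE, TRUE)
  )
  co <- coincidence_map(gr, drying)
  at <- function(m, lat, lon) as.character(m$category[m$lat == lat & m$lon == lon])
  expect_equal(at(co, 0, 0), "browning_and_drying")
  expect_equal(at(co, 0, 3), "drying_only") # nonsignificant browning not counted
  expect_equal(at(co, 3, 0), "neither")
  expect_equal(at(co, 3, 3), "masked")

  co_relaxed <- coincidence_map(gr, drying, require_significant_browning = FALSE)
  expect_equal(at(co_relaxed, 0, 3), "browning_and_drying")
  strict_set <- co$category == "browning_and_drying"
  relaxed_set <- co_relaxed$category == "browning_and_drying"
  expect_true(all(!strict_set | relaxed_set)) # strict subset of relaxed, cell-wise

  alien <- dplyr::mutate(drying, lon = lon + 99)
  expect_error(coincidence_map(gr, alien), "grid")
})

test_that("masked greenness propagates to the coincidence map", {
  gr <- structure(
    tibble::tibble(lat = 0, lon = 0,
                   category = factor("masked", levels = vegdry:::greenness_levels())),
    class = c("vd_greenness", class(tibble::tibble()))
  )
  drying <- tibble::tibble(lat = 0, lon = 0, agreement = 4, drying = TRUE)
  expect_equal(as.character(coincidence_map(gr, drying)$category), "masked")
})

test_that("area fractions use cosine-latitude weights", {
  d <- tibble::tibble(lat = c(0, 60), hit = c(TRUE, TRUE))
  expect_equal(area_fraction(d, hit), 1)
  d2 <- tibble::tibble(lat = c(0, 60), hit = c(FALSE, TRUE))
  expect_equal(area_fraction(d2, hit), 0.5 / 1.5) # weights 1 and 0.5
  withr::with_seed(4, {
    d3 <- tibble::tibble(lat = runif(200, -60, 60), hit = runif(200) < 0.3)
    w <- cos(d3$lat * pi / 180)
    expect_equal(area_fraction(d3, hit), sum(w * d3$hit) / sum(w))
  })
  expect_error(area_fraction(d2, hit, within = lat > 80), "zero area")
})

test_that("Cramer's V matches the contingency-table formula and is label-invariant", {
  a <- rep(c("x", "y"), each = 20)
  expect_equal(cramers_v(a, a), 1)

  # fixed 2x2 table: counts 30,10 / 10,30 -> chi2 = 80*(30*30-10*10)^2/(40*40*40*40)
  a2 <- rep(c("p", "p", "q", "q"), times = c(30, 10, 10, 30))
  b2 <- rep(c("u", "v", "u", "v"), times = c(30, 10, 10, 30))
  n <- 80
  chi2 <- n * (30 * 30 - 10 * 10)^2 / (40 * 40 * 40 * 40)
  expect_equal(cramers_v(a2, b2), sqrt(chi2 / n))

  relabeled <- c(p = "zebra", q = "aard")[a2]
  expect_equal(cramers_v(relabeled, b2), cramers_v(a2, b2))

  withr::with_seed(11, {
    big_a <- sample(letters[1:4], 20000, replace = TRUE)
    big_b <- sample(letters[1:4], 20000, replace = TRUE)
    expect_lt(cramers_v(big_a, big_b), 0.05) # independence
  })
  expect_warning(v <- cramers_v(rep("x", 10), rep(c("u", "v"), 5)), "degenerate")
  expect_true(is.na(v))
})

test_that("browning area partitions exactly across agreement classes", {
  withr::with_seed(6, {
    cells <- tidyr::expand_grid(lat = seq(-30, 30, by = 10), lon = seq(0, 50, by = 10))
    gr <- structure(
      dplyr::mutate(cells, category = factor(
        sample(vegdry:::greenness_levels(), dplyr::n(), replace = TRUE),
        levels = vegdry:::greenness_levels()
      )),
      class = c("vd_greenness", class(tibble::tibble()))
    )
    dr <- dplyr::mutate(cells, agreement = sample(0:4, dplyr::n(), replace = TRUE),
                        drying = agreement >= 2)
    s <- browning_drying_summary(gr, dr)
    total <- sum(cos(gr$lat[gr$category == "browning_significant"] * pi / 180))
    expect_equal(sum(s$area), total, tolerance = 1e-12)
    expect_equal(nrow(s), 5)

    none <- browning_drying_summary(
      structure(dplyr::mutate(cells, category = factor("greening_significant",
        levels = vegdry:::greenness_levels())),
        class = c("vd_greenness", class(tibble::tibble()))), dr)
    expect_true(all(none$area == 0))
  })
})
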