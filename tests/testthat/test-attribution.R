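test_that("divide-by-max normalization and its guards", {
  pm <- normalize_predictors(data.frame(a = c(2, 4, 8), b = c(1, 2, 3)))
  expect_equal(unname(pm$x[, "a"]), c(0.25, 0.5, 1))
  expect_equal(unname(apply(pm$x, 2, max)), c(1, 1))

  pm2 <- normalize_predictors(data.frame(a = c(2, 4, 8), flat = c(3, 3, 3)))
  expect_equal(pm2$dropped_constant, "flat")
  expect_false("flat" %in% colnames(pm2$x))

  expect_warning(
    pm3 <- normalize_predictors(data.frame(a = c(2, 4, 8), celsius = c(-5, -2, -1))),
    "Kelvin"
  )
  expect_equal(pm3$rejected, "celsius")

  pm4 <- normalize_predictors(data.frame(a = c(2, NA, 8, 4), b = 1:4))
  expect_equal(pm4$n_dropped_rows, 1)
  expect_equal(nrow(pm4$x), 3)

  withr::with_seed(1, {
    m <- matrix(runif(60, 0.1, 5), 15, 4)
    expect_equal(unname(apply(normalize_predictors(m)$x, 2, max)), rep(1, 4))
  })
})

test_that("all-subsets fit enumerates 2^p models and finds exact fits", {
  withr::with_seed(2, {
    x <- matrix(runif(15 * 4, 0.5, 1.5), 15, 4,
                dimnames = list(NULL, paste0("v", 1:4)))
    y <- x[, 1] * 2 + rnorm(15, 0, 0.01)
  })
  rec <- fit_all_subsets(y, x)
  expect_equal(nrow(rec), 16) # 2^4 including intercept-only
  expect_true(any(vapply(rec$predictors, length, 1L) == 0))

  # noiseless response: the true single-predictor subset is an exact fit
  y0 <- 3 + 1.5 * normalize_predictors(x)$x[, "v1"]
  rec0 <- fit_all_subsets(y0, x)
  singles <- rec0[rec0$n_predictors == 1, ]
  best_single <- singles[which.min(singles$aic), ]
  expect_equal(best_single$predictors[[1]], "v1")
  expect_equal(best_single$adj_r2, 1, tolerance = 1e-9)

  expect_error(fit_all_subsets(y[1:10], x[1:10, ]), "12 observations")
})

test_that("AIC differences agree with stats::AIC on lm fits", {
  withr::with_seed(3, {
    x <- matrix(runif(20 * 3, 0.5, 1.5), 20, 3,
                dimnames = list(NULL, c("a", "b", "c")))
    y <- 1 + x[, 1] - 0.5 * x[, 3] + rnorm(20, 0, 0.2)
  })
  pm <- normalize_predictors(x)
  rec <- fit_all_subsets(y, pm)
  # independent route: lm() + stats::AIC per subset; the additive constant
  # n*(log(2*pi)+1) cancels in differences
  ref_aic <- vapply(rec$predictors, function(pr) {
    d <- as.data.frame(pm$x)
    fit <- if (length(pr) == 0) stats::lm(y ~ 1, data = d) else {
      stats::lm(stats::reformulate(pr, "y"), data = cbind(d, y = y))
    }
    stats::AIC(fit)
  }, numeric(1))
  expect_equal(rec$aic - min(rec$aic), ref_aic - min(ref_aic), tolerance = 1e-8)
})

test_that("known 3-predictor model is recovered with accurate coefficients", {
  withr::with_seed(4, {
    x <- matrix(runif(39 * 10, 0.5, 1.5), 39, 10,
                dimnames = list(NULL, canonical_predictors()))
    pm <- normalize_predictors(x)
    truth <- c(soil_moisture = 1.2, vpd = -0.8, tree_cover = 0.5)
    y <- 2 + as.vector(pm$x[, names(truth)] %*% truth) + rnorm(39, 0, 0.05)
  })
  rec <- fit_all_subsets(y, pm)
  best <- rec[1, ]
  expect_true(all(names(truth) %in% best$predictors[[1]]))
  # coefficients of the true subset within 3 standard errors (lm as the oracle)
  d <- as.data.frame(pm$x[, names(truth)])
  fit <- stats::lm(y ~ ., data = cbind(d, y = y))
  se <- summary(fit)$coefficients[names(truth), "Std. Error"]
  est <- stats::coef(fit)[names(truth)]
  expect_true(all(abs(est - truth) < 3 * se))
  mask_true <- sum(2^(match(names(truth), colnames(pm$x)) - 1))
  pkg_coefs <- attr(rec, "coefs")[[mask_true + 1]]
  expect_equal(unname(pkg_coefs[-1][order(match(names(truth), colnames(pm$x)))]),
               unname(est), tolerance = 1e-8)
})

test_that("model selection applies both cuts strictly", {
  rec <- tibble::tibble(
    mask = 1:4, predictors = list("a", "b", "c", "d"), n_predictors = 1,
    rss = 1, r2 = 0.5, adj_r2 = c(0.50, 0.40, 0.36, 0.20),
    aic = c(10, 11.9, 10.5, 12)
  )
  sel <- select_models(rec)
  expect_equal(sel$aic, c(10, 11.9)) # dAIC 1.9 in, 0.36 and low-adjR2 out
  expect_equal(nrow(select_models(rec, delta_aic = 2, adjr2_min = 0.5)), 0)
  rec2 <- rec
  rec2$aic <- c(10, 12, 10.5, 12) # dAIC exactly 2 is excluded
  sel2 <- select_models(rec2) # row 3 also fails adjR2 = 0.36 (strict >)
  expect_equal(sel2$aic, 10)
  expect_error(select_models(rec[0, ]), "empty")
})

test_that("Akaike weights closed forms", {
  expect_equal(akaike_weights(rep(5, 4)), rep(0.25, 4))
  w <- akaike_weights(c(100, 102))
  expect_equal(w[1] / w[2], exp(1))
  withr::with_seed(5, {
    aics <- runif(20, 50, 150)
    expect_equal(sum(akaike_weights(aics)), 1, tolerance = 1e-12)
    expect_equal(akaike_weights(aics + 1234), akaike_weights(aics), tolerance = 1e-12)
  })
  expect_error(akaike_weights(numeric()), "empty")
  expect_error(akaike_weights(c(1, Inf)), "finite")
})

test_that("LMG shares: orthogonality, single predictor, permutation oracle", {
  # exactly orthogonal predictors: shares equal the marginal R^2s
  n <- 24
  x1 <- rep(c(-1, 1), n / 2)
  x2 <- rep(c(-1, -1, 1, 1), n / 4)
  y <- 2 * x1 + 1 * x2
  sh <- lmg_importance(y, cbind(a = x1, b = x2))
  r2a <- summary(stats::lm(y ~ x1))$r.squared
  r2b <- summary(stats::lm(y ~ x2))$r.squared
  expect_equal(unname(sh), c(r2a, r2b), tolerance = 1e-10)
  expect_equal(sum(sh), 1, tolerance = 1e-10)

  withr::with_seed(6, {
    xs <- matrix(rnorm(20), 20, 1, dimnames = list(NULL, "only"))
    ys <- xs[, 1] + rnorm(20, 0, 0.5)
  })
  expect_equal(unname(lmg_importance(ys, xs)),
               summary(stats::lm(ys ~ xs))$r.squared, tolerance = 1e-10)

  # correlated 3-predictor set against brute-force ordering enumeration
  withr::with_seed(7, {
    z <- rnorm(30)
    xc <- cbind(p = z + rnorm(30, 0, 0.5), q = z + rnorm(30, 0, 0.8), r = rnorm(30))
    yc <- z + rnorm(30, 0, 0.4)
  })
  expect_equal(lmg_importance(yc, xc), lmg_brute(yc, xc), tolerance = 1e-8)
  expect_equal(sum(lmg_importance(yc, xc)),
               summary(stats::lm(yc ~ xc))$r.squared, tolerance = 1e-8)

  expect_error(lmg_importance(yc, cbind(a = xc[, 1], b = xc[, 1])), "collinear")
})

test_that("cell attribution: single-model rule, noise rejection, driver recovery", {
  # a dominant single predictor: importance equals the selected model's R^2
  withr::with_seed(8, {
    x <- matrix(runif(39 * 3, 0.5, 1.5), 39, 3,
                dimnames = list(NULL, c("soil_moisture", "precipitation", "vpd")))
    pm <- normalize_predictors(x)
    y <- 1 + 3 * pm$x[, "vpd"] + rnorm(39, 0, 0.05)
  })
  cell <- attribute_cell(y, x, water_vars = water_variables())
  expect_equal(cell$status, "attributed")
  expect_equal(cell$dominant, "vpd")
  expect_equal(cell$water_rank, 1L)
  rec <- fit_all_subsets(y, x)
  sel <- select_models(rec)
  if (nrow(sel) == 1 && sel$n_predictors == 1) {
    expect_equal(max(cell$importance), sel$r2, tolerance = 1e-10)
  }

  # pure noise: overwhelmingly no satisfactory model at n = 39, 10 predictors
  statuses <- vapply(1:5, function(s) {
    withr::with_seed(100 + s, {
      xs <- random_cell_drivers(39, seed = 200 + s)
      yn <- rnorm(39)
    })
    attribute_cell(yn, xs)$status
  }, character(1))
  expect_true(mean(statuses == "no_satisfactory_model") >= 0.8)

  expect_equal(attribute_cell(rnorm(8), random_cell_drivers(8))$status,
               "insufficient_data")
})

test_that("attribution is exactly invariant to positive rescaling of a raw predictor", {
  withr::with_seed(9, {
    x <- random_cell_drivers(39, seed = 77)
    pmx <- normalize_predictors(x)
    y <- 1 + 2 * pmx$x[, "soil_moisture"] - pmx$x[, "vpd"] + rnorm(39, 0, 0.08)
  })
  a <- attribute_cell(y, x)
  x2 <- x
  x2[, "soil_moisture"] <- x2[, "soil_moisture"] * 1000
  b <- attribute_cell(y, x2)
  expect_identical(a$dominant, b$dominant)
  expect_equal(a$importance, b$importance, tolerance = 1e-12)
})

test_that("grid attribution recovers regional driver regimes", {
  g <- grid_spec(seq(0, 9, by = 3), seq(0, 9, by = 3), 1982:2020)
  drivers <- generate_driver_suite(g, seed = 31)
  region_beta <- setNames(rep(0, 10), canonical_predictors())
  region_beta["tree_cover"] <- 1
  coupling <- coupling_spec(
    intercept = 2, coefficients = c(soil_moisture = 1), noise_sd = 0.002,
    regions = list(list(lat = c(6, 9), lon = c(0, 9), coefficients = region_beta))
  )
  lai <- generate_lai(drivers, coupling, seed = 32)
  att <- attribute_grid(dplyr::left_join(drivers, lai, by = c("lat", "lon", "year")))
  att$region <- ifelse(att$lat >= 6, "tree", "sm")
  ok <- att[att$status == "attributed", ]
  sm_cells <- ok[ok$region == "sm", ]
  tree_cells <- ok[ok$region == "tree", ]
  expect_gte(mean(sm_cells$dominant == "soil_moisture"), 0.9)
  expect_gte(mean(tree_cells$dominant == "tree_cover"), 0.9)

  cov <- dominant_coverage(att)
  expect_equal(sum(cov$coverage), 1, tolerance = 1e-12)

  short <- dplyr::filter(dplyr::left_join(drivers, lai, by = c("lat", "lon", "year")),
                         year <= 1990)
  att_short <- attribute_grid(short)
  expect_true(all(att_short$status == "insufficient_data"))
})
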