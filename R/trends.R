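#' Mann-Kendall trend test
#'
#' Nonparametric monotonic-trend test on an annual series. The score is
#' `S = sum_{i<j} sign(x_j - x_i)`; its variance includes the tie correction
#' `sum_k t_k (t_k - 1)(2 t_k + 5)`; the normal deviate uses the continuity
#' correction (`(S - 1)/sqrt(var_S)` for positive S, `(S + 1)/sqrt(var_S)`
#' for negative S) and the p-value is two-sided. Alongside the test, the
#' Theil-Sen slope is reported as the trend magnitude. Missing values are
#' dropped listwise with their time points.
#'
#' @param x Numeric series (annual values, in time order).
#' @param alpha Significance level; trends with `p < alpha` are flagged
#'   significant (default 0.1, chosen to accommodate the large natural
#'   variability of short annual hydro-meteorological series).
#' @param t Optional numeric time coordinate (defaults to the series index);
#'   used for the Theil-Sen slope denominator.
#'
#' @return An object of class `mk_test`: list with `n`, `s`, `var_s`, `z`,
#'   `p_value`, `slope`, `significant`, `direction`
#'   (`"increasing"`/`"decreasing"`/`"none"`) and `alpha`.
#'   Use [generics::tidy()] for a one-row tibble.
#' @export
#' @examples
#' tidy(mann_kendall(c(1, 3, 2, 4, 5, 7, 6, 8)))
mann_kendall <- function(x, alpha = 0.1, t = seq_along(x)) {
  keep <- !is.na(x)
  x <- x[keep]; t <- t[keep]
  n <- length(x)
  if (n < 4) abort("Mann-Kendall test needs at least 4 non-missing values.")
  dif <- outer(x, x, "-")
  s <- sum(sign(dif[lower.tri(dif)])) # rows i > cols j: sign(x_i - x_j), j < i
  ties <- table(x)
  var_s <- (n * (n - 1) * (2 * n + 5) - sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  z <- if (s > 0) {
    (s - 1) / sqrt(var_s)
  } else if (s < 0) {
    (s + 1) / sqrt(var_s)
  } else 0
  if (var_s == 0) z <- 0 # fully tied series
  p <- 2 * pnorm(-abs(z))
  structure(
    list(
      n = n, s = s, var_s = var_s, z = z, p_value = p,
      slope = theil_sen(x, t),
      significant = p < alpha,
      direction = if (s > 0) "increasing" else if (s < 0) "decreasing" else "none",
      alpha = alpha
    ),
    class = "mk_test"
  )
}

#' @export
print.mk_test <- function(x, ...) {
  cat(sprintf(
    "Mann-Kendall: n = %d, S = %d, z = %.3f, p = %.4g, Theil-Sen slope = %.4g (%s%s)\n",
    x$n, x$s, x$z, x$p_value, x$slope, x$direction,
    if (x$significant) sprintf(", significant at %.2g", x$alpha) else ""
  ))
  invisible(x)
}

#' Theil-Sen slope
#'
#' Median of all pairwise slopes `(x_j - x_i) / (t_j - t_i)`, `i < j`.
#'
#' @inheritParams mann_kendall
#' @return Slope in units per unit time.
#' @export
#' @examples
#' theil_sen(c(0, 0, 3)) # pairwise slopes 0, 1.5, 3 -> 1.5
theil_sen <- function(x, t = seq_along(x)) {
  keep <- !is.na(x)
  x <- x[keep]; t <- t[keep]
  if (length(unique(t)) < 2) abort("Theil-Sen slope needs at least 2 distinct time points.")
  dx <- outer(x, x, "-")
  dt <- outer(t, t, "-")
  median(dx[lower.tri(dx)] / dt[lower.tri(dt)])
}

#' Mean difference between two halves of a series
#'
#' `mean(second half) - mean(first half)`; the long-term change statistic
#' used for aridity, which is a climatic property rather than a year-by-year
#' trend.
#'
#' @param x Numeric series.
#' @param split_index First index of the second half.
#' @return Numeric difference.
#' @export
period_mean_difference <- function(x, split_index) {
  if (split_index < 2 || split_index > length(x)) {
    abort("`split_index` must leave both halves non-empty.")
  }
  first <- x[seq_len(split_index - 1)]
  second <- x[split_index:length(x)]
  mean(second, na.rm = TRUE) - mean(first, na.rm = TRUE)
}

#' Bootstrap significance of a period-mean change
#'
#' Pools both halves and, for each of `n_draws` draws, randomly partitions
#' the pooled values (without replacement by default — a permutation null)
#' into pseudo-halves of the original sizes, recording their mean difference.
#' The observed difference is significant when it exceeds the 90th percentile
#' or falls below the 10th percentile of the null differences.
#'
#' @inheritParams period_mean_difference
#' @param n_draws Number of random draws (default 300).
#' @param seed Integer seed; fixed seeds give deterministic results.
#' @param replace Draw pseudo-halves with replacement instead of
#'   partitioning the pool.
#' @param probs Lower/upper percentile bounds of the null (default 0.1/0.9).
#'
#' @return An object of class `change_test`: list with `observed`, `null`
#'   (length `n_draws`), `lower`, `upper`, `significant`, `n1`, `n2`.
#' @export
bootstrap_change_significance <- function(x, split_index, n_draws = 300, seed = 1,
                                          replace = FALSE, probs = c(0.1, 0.9)) {
  if (n_draws < 1) abort("`n_draws` must be >= 1.")
  first <- x[seq_len(split_index - 1)]
  second <- x[split_index:length(x)]
  first <- first[!is.na(first)]; second <- second[!is.na(second)]
  n1 <- length(first); n2 <- length(second)
  if (n1 < 2 || n2 < 2) abort("both halves need at least 2 non-missing values.")
  pool <- c(first, second)
  observed <- mean(second) - mean(first)
  null <- withr::with_seed(seed, {
    vapply(seq_len(n_draws), function(i) {
      if (replace) {
        mean(sample(pool, n2, replace = TRUE)) - mean(sample(pool, n1, replace = TRUE))
      } else {
        idx <- sample.int(n1 + n2)
        mean(pool[idx[(n1 + 1):(n1 + n2)]]) - mean(pool[idx[seq_len(n1)]])
      }
    }, numeric(1))
  })
  qs <- quantile(null, probs, names = FALSE)
  structure(
    list(
      observed = observed, null = null, lower = qs[1], upper = qs[2],
      significant = observed > qs[2] || observed < qs[1], n1 = n1, n2 = n2
    ),
    class = "change_test"
  )
}

#' @export
print.change_test <- function(x, ...) {
  cat(sprintf(
    "Period-mean change: observed = %.4g, null [%0.4g, %0.4g] (%d draws)%s\n",
    x$observed, x$lower, x$upper, length(x$null),
    if (x$significant) ", significant" else ""
  ))
  invisible(x)
}

#' Per-cell trends over a gridded annual variable
#'
#' Applies [mann_kendall()] (and the Theil-Sen slope) cell by cell. Cells
#' with fewer than `min_years` valid values are returned with missing
#' statistics.
#'
#' @param data Tibble with columns `lat`, `lon`, `year` and the value column.
#' @param value Name of the value column (string; default `"value"`).
#' @param years Optional integer range of years to use (default all).
#' @param alpha Significance level (default 0.1).
#' @param min_years Minimum valid years per cell (default 10).
#'
#' @return A tibble of class `vd_trends`, one row per cell: `lat`, `lon`,
#'   `n`, `s`, `var_s`, `z`, `p_value`, `slope`, `significant`, `direction`.
#' @export
grid_trends <- function(data, value = "value", years = NULL, alpha = 0.1,
                        min_years = 10) {
  if (!value %in% names(data)) abort(paste0("column `", value, "` not found."))
  if (!is.null(years)) {
    if (!any(data$year %in% years)) abort("`years` selects no data.")
    data <- dplyr::filter(data, .data$year %in% !!years)
  }
  out <- data %>%
    group_by(.data$lat, .data$lon) %>%
    summarise(res = list(cell_trend(.data[[value]], .data$year, alpha, min_years)),
              .groups = "drop") %>%
    tidyr::unnest_wider("res")
  class(out) <- c("vd_trends", class(out))
  attr(out, "alpha") <- alpha
  out
}

cell_trend <- function(x, year, alpha, min_years) {
  if (sum(!is.na(x)) < max(4, min_years)) {
    return(list(
      n = sum(!is.na(x)), s = NA_integer_, var_s = NA_real_, z = NA_real_,
      p_value = NA_real_, slope = NA_real_, significant = NA, direction = NA_character_
    ))
  }
  mk <- mann_kendall(x, alpha = alpha, t = year)
  list(
    n = mk$n, s = mk$s, var_s = mk$var_s, z = mk$z, p_value = mk$p_value,
    slope = mk$slope, significant = mk$significant, direction = mk$direction
  )
}

#' Per-cell bootstrap change tests over a gridded annual variable
#'
#' The gridded analog of [bootstrap_change_significance()]: for each cell the
#' second-minus-first period-mean difference is tested against its
#' permutation null. Cell seeds are derived deterministically from `seed`.
#'
#' @inheritParams grid_trends
#' @param split_year First year of the second period.
#' @param n_draws,seed,replace See [bootstrap_change_significance()].
#' @return Tibble: `lat`, `lon`, `observed`, `lower`, `upper`, `significant`.
#' @export
grid_change <- function(data, value = "value", split_year, n_draws = 300,
                        seed = 1, replace = FALSE) {
  data %>%
    group_by(.data$lat, .data$lon) %>%
    summarise(res = list({
      x <- .data[[value]][order(.data$year)]
      yr <- sort(.data$year)
      cell_seed <- (seed + 7919L * dplyr::cur_group_id()) %% .Machine$integer.max
      ct <- bootstrap_change_significance(
        x, match(split_year, yr), n_draws = n_draws, seed = cell_seed, replace = replace
      )
      list(observed = ct$observed, lower = ct$lower, upper = ct$upper,
           significant = ct$significant)
    }), .groups = "drop") %>%
    tidyr::unnest_wider("res")
}
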