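#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Mann-Kendall test
#'
#' @param x An `mk_test` object from [mann_kendall()].
#' @param ... Unused.
#' @return One-row tibble with the test statistics.
#' @export
tidy.mk_test <- function(x, ...) {
  tibble(
    s = x$s, var_s = x$var_s, z = x$z, p_value = x$p_value,
    slope = x$slope, significant = x$significant, direction = x$direction
  )
}

#' @rdname tidy.mk_test
#' @export
glance.mk_test <- function(x, ...) {
  tibble(n = x$n, alpha = x$alpha, p_value = x$p_value, significant = x$significant)
}

#' Tidy a period-mean change test
#'
#' @param x A `change_test` object from [bootstrap_change_significance()].
#' @param ... Unused.
#' @return One-row tibble with the observed difference, null bounds and flag.
#' @export
tidy.change_test <- function(x, ...) {
  tibble(
    observed = x$observed, lower = x$lower, upper = x$upper,
    significant = x$significant
  )
}

#' @rdname tidy.change_test
#' @export
glance.change_test <- function(x, ...) {
  tibble(n1 = x$n1, n2 = x$n2, n_draws = length(x$null), significant = x$significant)
}

#' Tidy a per-cell attribution
#'
#' `tidy()` returns one row per predictor with its Akaike-weighted LMG
#' importance and rank; `glance()` returns the one-row cell summary.
#'
#' @param x A `cell_attribution` object from [attribute_cell()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cell_attribution <- function(x, ...) {
  out <- tibble(
    predictor = names(x$importance),
    importance = unname(x$importance)
  )
  out$rank <- if (x$status == "attributed") match(out$predictor, x$ranking) else NA_integer_
  arrange(out, .data$rank)
}

#' @rdname tidy.cell_attribution
#' @export
glance.cell_attribution <- function(x, ...) {
  tibble(
    status = x$status, dominant = x$dominant, tie = x$tie,
    water_rank = x$water_rank, best_adj_r2 = x$best_adj_r2,
    n_models = x$n_models
  )
}
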