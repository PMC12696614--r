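#' Normalize a predictor matrix by column maxima
#'
#' Each retained column is divided by its maximum so values fall in (0, 1]
#' for positive data (the reason temperatures are expected in Kelvin: a
#' nonpositive column maximum makes the map meaningless and the column is
#' rejected). Rows containing any missing value are dropped listwise.
#' Constant columns carry no information for regression and are flagged and
#' dropped from the model search.
#'
#' @param x Data frame or matrix of raw predictors (rows = years).
#'
#' @return An object of class `predictor_matrix`: list with `x` (normalized
#'   matrix), `maxima` (named original column maxima), `dropped_constant`
#'   (names of zero-variance columns, removed), `rejected` (names of columns
#'   with nonpositive maxima, removed), `n_dropped_rows`.
#' @export
#' @examples
#' normalize_predictors(data.frame(a = c(2, 4, 8), b = c(1, 2, 3)))
normalize_predictors <- function(x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  keep_rows <- stats::complete.cases(x)
  n_dropped <- sum(!keep_rows)
  x <- x[keep_rows, , drop = FALSE]
  maxima <- apply(x, 2, max)
  rejected <- colnames(x)[maxima <= 0]
  if (length(rejected)) {
    warn(paste0(
      "column(s) with nonpositive maximum rejected (divide-by-max needs positive ",
      "data; convert units, e.g. Celsius to Kelvin): ",
      paste(rejected, collapse = ", ")
    ))
  }
  x <- x[, maxima > 0, drop = FALSE]
  xn <- sweep(x, 2, apply(x, 2, max), "/")
  constant <- apply(xn, 2, function(col) max(col) - min(col) < 1e-12)
  dropped <- colnames(xn)[constant]
  structure(
    list(
      x = xn[, !constant, drop = FALSE],
      maxima = maxima[maxima > 0][!constant],
      dropped_constant = dropped,
      rejected = rejected,
      n_dropped_rows = n_dropped
    ),
    class = "predictor_matrix"
  )
}

#' @export
print.predictor_matrix <- function(x, ...) {
  cat(sprintf(
    "<predictor_matrix> %d rows x %d predictors (%d constant dropped, %d rejected, %d rows dropped)\n",
    nrow(x$x), ncol(x$x), length(x$dropped_constant), length(x$rejected), x$n_dropped_rows
  ))
  invisible(x)
}

# R^2 (and RSS) of every predictor subset, indexed by bitmask + 1.
# Cached crossproducts make each subset a small linear solve; rank-deficient
# subsets come back NA and are skipped downstream.
all_subsets_r2 <- function(y, xn) {
  n <- length(y)
  p <- ncol(xn)
  xa <- cbind(`(Intercept)` = 1, xn)
  xtx <- crossprod(xa)
  xty <- drop(crossprod(xa, y))
  yty <- sum(y * y)
  tss <- sum((y - mean(y))^2)
  nmask <- 2^p
  rss <- numeric(nmask)
  coefs <- vector("list", nmask)
  bit_idx <- lapply(seq_len(nmask) - 1L, function(m) which(bitwAnd(m, bitwShiftL(1L, 0:(p - 1))) > 0L))
  for (m in seq_len(nmask)) {
    idx <- c(1L, bit_idx[[m]] + 1L)
    b <- tryCatch(solve(xtx[idx, idx, drop = FALSE], xty[idx]),
                  error = function(e) NULL)
    if (is.null(b) || anyNA(b)) {
      rss[m] <- NA_real_
    } else {
      r <- yty - sum(b * xty[idx])
      rss[m] <- max(r, 0) # guard tiny negative round-off
      coefs[[m]] <- b
    }
  }
  list(rss = rss, r2 = 1 - rss / tss, coefs = coefs, bit_idx = bit_idx,
       n = n, p = p, tss = tss)
}

# information criterion from RSS: AIC = n log(RSS/n) + 2k, k = p_subset + 2
# (intercept + residual variance); AICc adds the small-sample correction.
ic_from_rss <- function(rss, n, n_pred, ic = c("aic", "aicc")) {
  ic <- match.arg(ic)
  k <- n_pred + 2
  # exact-fit guard: log(0) would be -Inf; floor RSS at machine-level noise
  val <- n * log(pmax(rss, 1e-300) / n) + 2 * k
  if (ic == "aicc") val <- val + 2 * k * (k + 1) / pmax(n - k - 1, 1e-9)
  val
}

#' Fit every predictor subset by ordinary least squares
#'
#' Tests all `2^p` combinations of predictors (including the intercept-only
#' model) and ranks them by AIC, computed as `n log(RSS/n) + 2k` with `k`
#' counting the intercept, the slope coefficients and the residual variance.
#' Collinearity sorts itself out through the ranking: subsets with strongly
#' overlapping information content gain little likelihood for their extra
#' parameters and rank lower. Rank-deficient subsets are skipped with a
#' diagnostic count.
#'
#' @param y Response series (e.g. annual LAI at one cell).
#' @param x A [normalize_predictors()] result, or a raw data frame/matrix
#'   (normalized internally).
#' @param ic `"aic"` (default) or `"aicc"` (small-sample correction).
#'
#' @return A tibble of class `vd_subsets`, one row per subset, sorted by AIC:
#'   `predictors` (list column), `n_predictors`, `rss`, `r2`, `adj_r2`,
#'   `aic`, `delta_aic`, `mask` (bitmask over the predictor columns).
#'   Attributes: `"r2_table"` (R^2 for every bitmask, reused for exact LMG
#'   shares), `"predictor_names"`, `"n"`, `"n_skipped"`, `"coefs"`.
#' @export
fit_all_subsets <- function(y, x, ic = c("aic", "aicc")) {
  ic <- match.arg(ic)
  if (!inherits(x, "predictor_matrix")) x <- normalize_predictors(x)
  xn <- x$x
  n <- length(y)
  if (nrow(xn) != n) abort("`y` and the predictor matrix must have the same number of rows.")
  if (n < 12) abort("all-subsets regression needs at least 12 observations.")
  p <- ncol(xn)
  if (p > 12) abort("at most 12 predictors are supported (2^p subsets).")
  fits <- all_subsets_r2(y, xn)
  n_pred <- vapply(fits$bit_idx, length, integer(1))
  aic <- ic_from_rss(fits$rss, n, n_pred, ic)
  adj_r2 <- 1 - (1 - fits$r2) * (n - 1) / (n - n_pred - 1)
  ok <- !is.na(fits$rss)
  out <- tibble(
    mask = seq_len(2^p) - 1L,
    predictors = lapply(fits$bit_idx, function(i) colnames(xn)[i]),
    n_predictors = n_pred,
    rss = fits$rss,
    r2 = fits$r2,
    adj_r2 = adj_r2,
    aic = aic
  )[ok, ]
  out$delta_aic <- out$aic - min(out$aic)
  out <- arrange(out, .data$aic)
  class(out) <- c("vd_subsets", class(out))
  attr(out, "r2_table") <- fits$r2
  attr(out, "predictor_names") <- colnames(xn)
  attr(out, "n") <- n
  attr(out, "n_skipped") <- sum(!ok)
  attr(out, "coefs") <- fits$coefs
  attr(out, "ic") <- ic
  out
}

#' Select the model ensemble by AIC difference and adjusted R-squared
#'
#' Keeps models whose AIC difference from the top-ranked model is less than
#' `delta_aic` (strict) and whose adjusted R-squared exceeds `adjr2_min`
#' (strict). The adjusted R-squared floor ensures satisfactory predictive
#' power before any attribution is attempted; an empty selection means no
#' satisfactory model exists at that cell.
#'
#' @param records A [fit_all_subsets()] result.
#' @param delta_aic AIC-difference cut (default 2).
#' @param adjr2_min Adjusted R-squared floor (default 0.36, a compromise
#'   between commonly used 0.26 and 0.4 benchmarks).
#'
#' @return The selected subset of `records` (possibly zero rows).
#' @export
select_models <- function(records, delta_aic = 2, adjr2_min = 0.36) {
  if (nrow(records) == 0) abort("`records` is empty.")
  delta <- records$aic - min(records$aic)
  records[delta < delta_aic & records$adj_r2 > adjr2_min, ]
}

#' Akaike weights
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_i = AIC_i - min(AIC)`; invariant to adding a constant to all AICs.
#'
#' @param aic Numeric vector of (finite) AIC values.
#' @return Weights summing to 1.
#' @export
#' @examples
#' akaike_weights(c(100, 102)) # ratio e
akaike_weights <- function(aic) {
  if (length(aic) == 0) abort("`aic` is empty.")
  if (any(!is.finite(aic))) abort("AIC values must be finite.")
  w <- exp(-(aic - min(aic)) / 2)
  w / sum(w)
}

# LMG shares for the model whose predictors are `bits` (indices into the
# full predictor set), from the precomputed all-subsets R^2 table.
# share(k) = sum over subsets S of the other predictors of
#   |S|! (m - |S| - 1)! / m! * (R^2(S + k) - R^2(S))
lmg_from_r2 <- function(bits, r2_table) {
  m <- length(bits)
  shares <- numeric(m)
  if (m == 0) return(shares)
  fact <- factorial(0:m)
  pow <- bitwShiftL(1L, bits - 1L)
  for (si in 0:(2^m - 1)) {
    in_s <- bitwAnd(si, bitwShiftL(1L, 0:(m - 1))) > 0L
    s_size <- sum(in_s)
    if (s_size == m) next
    s_mask <- sum(pow[in_s])
    w <- fact[s_size + 1] * fact[m - s_size] / fact[m + 1]
    r2_s <- if (s_size == 0) 0 else r2_table[s_mask + 1]
    for (k in which(!in_s)) {
      shares[k] <- shares[k] + w * (r2_table[s_mask + pow[k] + 1] - r2_s)
    }
  }
  shares
}

#' Lindeman-Merenda-Gold relative importance
#'
#' Decomposes the R-squared of a multiple regression among its predictors by
#' averaging, over all `p!` orderings, each predictor's sequential
#' R-squared increase when it enters the model. Computed exactly through the
#' subset-size-weighted formula over the `2^(p-1)` subsets of the other
#' predictors; shares are nonnegative-in-expectation and sum exactly to the
#' full model's R-squared.
#'
#' @param y Response vector.
#' @param x Data frame or matrix of the model's predictors (already on the
#'   scale to be fitted; no normalization is applied here).
#'
#' @return Named numeric vector of variance shares, one per predictor.
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
#' y <- x[, 1] + 0.5 * x[, 2] + rnorm(20, 0, 0.3)
#' lmg_importance(y, x)
lmg_importance <- function(y, x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  p <- ncol(x)
  if (p > 12) abort("exact LMG enumeration supports at most 12 predictors.")
  fits <- all_subsets_r2(y, x)
  if (anyNA(fits$r2)) abort("collinear predictor subset: LMG shares are undefined.")
  setNames(lmg_from_r2(seq_len(p), fits$r2), colnames(x))
}

#' Attribute inter-annual LAI dynamics at one cell
#'
#' Runs the full per-cell attribution: all-subsets regression on the
#' normalized predictors, selection of the model ensemble (AIC difference
#' and adjusted R-squared cuts), Akaike weighting, and LMG variance shares.
#' The importance of predictor `k` is the Akaike-weighted average of its LMG
#' share across the selected models, with share 0 in models that exclude it
#' (set `renormalize_absent = TRUE` to instead average only over models
#' containing the predictor). If the selection is a single single-predictor
#' model, that predictor is the most important with importance equal to the
#' model's R-squared — the weighted average reduces to exactly that.
#'
#' @param y Response series.
#' @param x Raw predictor data frame/matrix or [normalize_predictors()] result.
#' @param delta_aic,adjr2_min See [select_models()].
#' @param ic `"aic"` or `"aicc"`.
#' @param water_vars Predictors counted as water-related for the rank map.
#' @param tie_tol Absolute tolerance on weighted importance for declaring a
#'   tie for dominance (default 1e-9).
#' @param renormalize_absent Average each predictor's share only over models
#'   that contain it (default `FALSE`).
#'
#' @return An object of class `cell_attribution`: list with `status`
#'   (`"attributed"`, `"no_satisfactory_model"`, `"insufficient_data"`),
#'   `importance` (named over all candidate predictors), `dominant`, `tie`,
#'   `ranking`, `water_rank`, `best_adj_r2`, `n_models`. Use `tidy()` /
#'   `glance()` for tibble views.
#' @export
attribute_cell <- function(y, x, delta_aic = 2, adjr2_min = 0.36,
                           ic = c("aic", "aicc"),
                           water_vars = water_variables(),
                           tie_tol = 1e-9, renormalize_absent = FALSE) {
  ic <- match.arg(ic)
  if (!inherits(x, "predictor_matrix")) x <- normalize_predictors(x)
  empty <- function(status, best = NA_real_) {
    structure(
      list(
        status = status,
        importance = setNames(rep(NA_real_, ncol(x$x)), colnames(x$x)),
        dominant = NA_character_, tie = NA, ranking = character(),
        water_rank = NA_integer_, best_adj_r2 = best, n_models = 0L
      ),
      class = "cell_attribution"
    )
  }
  if (length(y) < 12 || nrow(x$x) < 12 || ncol(x$x) == 0) return(empty("insufficient_data"))
  records <- fit_all_subsets(y, x, ic = ic)
  best_adj <- max(records$adj_r2, na.rm = TRUE)
  sel <- select_models(records, delta_aic = delta_aic, adjr2_min = adjr2_min)
  if (nrow(sel) == 0) return(empty("no_satisfactory_model", best_adj))
  w <- akaike_weights(sel$aic)
  r2_table <- attr(records, "r2_table")
  pred_names <- attr(records, "predictor_names")
  p <- length(pred_names)
  importance <- setNames(numeric(p), pred_names)
  present_w <- setNames(numeric(p), pred_names)
  for (i in seq_len(nrow(sel))) {
    bits <- which(bitwAnd(sel$mask[i], bitwShiftL(1L, 0:(p - 1))) > 0L)
    if (length(bits) == 0) next
    shares <- lmg_from_r2(bits, r2_table)
    importance[bits] <- importance[bits] + w[i] * shares
    present_w[bits] <- present_w[bits] + w[i]
  }
  if (renormalize_absent) {
    importance <- ifelse(present_w > 0, importance / present_w, 0)
  }
  ranking <- names(sort(importance, decreasing = TRUE))
  top <- max(importance)
  tie <- sum(importance >= top - tie_tol) >= 2
  water_present <- intersect(water_vars, pred_names)
  water_rank <- if (length(water_present)) min(match(water_present, ranking)) else NA_integer_
  structure(
    list(
      status = "attributed", importance = importance,
      dominant = ranking[1], tie = tie, ranking = ranking,
      water_rank = as.integer(water_rank), best_adj_r2 = best_adj,
      n_models = nrow(sel)
    ),
    class = "cell_attribution"
  )
}

#' @export
print.cell_attribution <- function(x, ...) {
  if (x$status != "attributed") {
    cat(sprintf("<cell_attribution> %s\n", x$status))
  } else {
    cat(sprintf(
      "<cell_attribution> dominant = %s%s (importance %.3f), %d model(s), best adj R2 = %.3f\n",
      x$dominant, if (x$tie) " [tie]" else "", max(x$importance), x$n_models, x$best_adj_r2
    ))
  }
  invisible(x)
}

#' Attribute LAI dynamics across a grid
#'
#' Runs [attribute_cell()] at every grid cell of a wide cell-year table.
#'
#' @param data Wide tibble with `lat`, `lon`, `year`, the response column and
#'   the predictor columns.
#' @param response Name of the response column (default `"lai"`).
#' @param predictors Predictor column names (default [canonical_predictors()]).
#' @param years Optional year subset.
#' @inheritParams attribute_cell
#'
#' @return A tibble of class `vd_attribution`, one row per cell: `lat`,
#'   `lon`, `status`, `dominant`, `tie`, `water_rank`, `best_adj_r2`,
#'   `n_models`, plus one `importance_<predictor>` column per predictor.
#' @export
attribute_grid <- function(data, response = "lai",
                           predictors = canonical_predictors(),
                           years = NULL, delta_aic = 2, adjr2_min = 0.36,
                           ic = c("aic", "aicc"),
                           water_vars = water_variables(), tie_tol = 1e-9) {
  ic <- match.arg(ic)
  missing_cols <- setdiff(c(response, predictors), names(data))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!is.null(years)) data <- dplyr::filter(data, .data$year %in% !!years)
  cells <- data %>%
    arrange(.data$year) %>%
    group_by(.data$lat, .data$lon) %>%
    tidyr::nest() %>%
    ungroup()
  res <- purrr::map(cells$data, function(d) {
    y <- d[[response]]
    keep <- !is.na(y)
    cell <- suppressWarnings(attribute_cell(
      y[keep], as.matrix(d[keep, predictors, drop = FALSE]),
      delta_aic = delta_aic, adjr2_min = adjr2_min, ic = ic,
      water_vars = water_vars, tie_tol = tie_tol
    ))
    imp <- setNames(rep(NA_real_, length(predictors)), predictors)
    if (cell$status == "attributed") imp[names(cell$importance)] <- cell$importance
    c(
      list(
        status = cell$status, dominant = cell$dominant, tie = cell$tie,
        water_rank = cell$water_rank, best_adj_r2 = cell$best_adj_r2,
        n_models = cell$n_models
      ),
      setNames(as.list(imp), paste0("importance_", predictors))
    )
  })
  out <- dplyr::bind_cols(
    cells[, c("lat", "lon")],
    dplyr::bind_rows(lapply(res, as_tibble))
  )
  class(out) <- c("vd_attribution", class(out))
  out
}

#' Area coverage of dominant drivers
#'
#' Cosine-latitude-weighted share of attributed (non-tie) cells per dominant
#' predictor, optionally restricted to a focus box. Shares over
#' `{dominant predictors, tie}` partition the attributed area.
#'
#' @param attribution An [attribute_grid()] result.
#' @param focus_box Optional list with `lat = c(min, max)`,
#'   `lon = c(min, max)` restricting the region.
#'
#' @return Tibble: `dominant` (predictor name or `"tie"`), `coverage`.
#' @export
dominant_coverage <- function(attribution, focus_box = NULL) {
  d <- as_tibble(attribution)
  if (!is.null(focus_box)) {
    d <- dplyr::filter(
      d,
      .data$lat >= focus_box$lat[1], .data$lat <= focus_box$lat[2],
      .data$lon >= focus_box$lon[1], .data$lon <= focus_box$lon[2]
    )
  }
  d <- d %>%
    dplyr::filter(.data$status == "attributed") %>%
    mutate(
      w = cos(.data$lat * pi / 180),
      label = ifelse(.data$tie, "tie", .data$dominant)
    )
  if (nrow(d) == 0) return(tibble(dominant = character(), coverage = numeric()))
  d %>%
    group_by(dominant = .data$label) %>%
    summarise(coverage = sum(.data$w), .groups = "drop") %>%
    mutate(coverage = .data$coverage / sum(.data$coverage)) %>%
    arrange(dplyr::desc(.data$coverage))
}
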