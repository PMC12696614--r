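#' Most frequent greenness trend category across an ensemble
#'
#' Per-cell voting over the members' greenness maps: a member contributes
#' data at a cell when its own category there is not `masked`. Cells with
#' data from fewer than `min_models` members are flagged
#' `insufficient_models`; cells where two or more categories share the
#' maximal count are flagged `tie`.
#'
#' @param members List of [classify_greenness()] maps (one per model).
#' @param min_models Minimum members with data per cell (default 5).
#'
#' @return Tibble, one row per cell: `lat`, `lon`, `n_models`,
#'   `modal_category`, `modal_count`, `status`
#'   (`"ok"`, `"insufficient_models"`, `"tie"`).
#' @export
modal_trend_category <- function(members, min_models = 5) {
  stacked <- stack_members(members, "category")
  stacked %>%
    dplyr::filter(.data$category != "masked") %>%
    group_by(.data$lat, .data$lon) %>%
    summarise(res = list(vote(as.character(.data$category))), .groups = "drop") %>%
    tidyr::unnest_wider("res") %>%
    mutate(
      status = dplyr::case_when(
        .data$n_models < min_models ~ "insufficient_models",
        .data$tie ~ "tie",
        TRUE ~ "ok"
      ),
      modal_category = ifelse(.data$status == "insufficient_models",
                              NA_character_, .data$modal_category)
    ) %>%
    select("lat", "lon", "n_models", "modal_category", "modal_count", "status")
}

#' Fraction of members simulating drying
#'
#' Per cell, the number of members whose drying flag is true divided by the
#' number of members with data at that cell.
#'
#' @param members List of [classify_drying()] maps (one per model).
#' @return Tibble: `lat`, `lon`, `n_models`, `fraction`.
#' @export
drying_model_fraction <- function(members) {
  stack_members(members, "drying") %>%
    dplyr::filter(!is.na(.data$drying)) %>%
    group_by(.data$lat, .data$lon) %>%
    summarise(
      n_models = dplyr::n(),
      fraction = mean(.data$drying),
      .groups = "drop"
    )
}

#' Most frequent dominant driver across an ensemble
#'
#' Per-cell voting over the members' attribution maps (only cells a member
#' actually attributed count as data). Cells where the modal count falls
#' below `min_agree` are flagged `low_agreement`; ties (two or more drivers
#' modal across the same number of members) are a distinct `tie` status.
#'
#' @param members List of [attribute_grid()] maps (one per model).
#' @param min_agree Minimum members agreeing on the modal driver (default 3).
#'
#' @return Tibble: `lat`, `lon`, `n_models`, `modal_driver`, `modal_count`,
#'   `status` (`"ok"`, `"low_agreement"`, `"tie"`).
#' @export
modal_dominant_driver <- function(members, min_agree = 3) {
  stack_members(members, c("status", "dominant")) %>%
    dplyr::filter(.data$status == "attributed", !is.na(.data$dominant)) %>%
    group_by(.data$lat, .data$lon) %>%
    summarise(res = list(vote(.data$dominant)), .groups = "drop") %>%
    tidyr::unnest_wider("res") %>%
    mutate(
      status = dplyr::case_when(
        .data$tie ~ "tie",
        .data$modal_count < min_agree ~ "low_agreement",
        TRUE ~ "ok"
      )
    ) %>%
    rename(modal_driver = "modal_category") %>%
    select("lat", "lon", "n_models", "modal_driver", "modal_count", "status")
}

#' Multi-model mean of per-member summary tables
#'
#' Element-wise arithmetic mean of per-member [browning_drying_summary()]
#' tables (or any tables sharing the same class column).
#'
#' @param tables List of tibbles sharing a `agreement` column and numeric
#'   columns to average.
#' @return Tibble with the shared class column and averaged numeric columns.
#' @export
multimodel_mean_summary <- function(tables) {
  if (length(tables) == 0) abort("no tables supplied.")
  key <- tables[[1]]$agreement
  for (tb in tables) {
    if (!identical(tb$agreement, key)) abort("tables do not share the same class structure.")
  }
  dplyr::bind_rows(tables) %>%
    group_by(.data$agreement) %>%
    summarise(across(dplyr::where(is.numeric), mean), .groups = "drop")
}

# bind member maps with a member id, checking grids match
stack_members <- function(members, cols) {
  if (length(members) < 1) abort("at least one member map is required.")
  ref <- dplyr::arrange(as_tibble(members[[1]])[, c("lat", "lon")], .data$lat, .data$lon)
  for (i in seq_along(members)) {
    mi <- dplyr::arrange(as_tibble(members[[i]])[, c("lat", "lon")], .data$lat, .data$lon)
    if (!isTRUE(all.equal(ref, mi))) abort(sprintf("member %d is on a different grid.", i))
  }
  dplyr::bind_rows(lapply(seq_along(members), function(i) {
    as_tibble(members[[i]])[, c("lat", "lon", cols)] %>% mutate(member = i)
  }))
}

# modal category with tie detection
vote <- function(x) {
  counts <- sort(table(x), decreasing = TRUE)
  list(
    n_models = length(x),
    modal_category = names(counts)[1],
    modal_count = as.integer(counts[1]),
    tie = length(counts) >= 2 && counts[2] == counts[1]
  )
}
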