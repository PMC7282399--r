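#' Score ordinal item responses into domain scores
#'
#' Converts long-format ordinal item responses into per-child, per-domain raw
#' and standardised scaled scores. Each answered item is min-max normalised
#' onto \[0, 1\] as `(score - 1) / (scale_points - 1)`, so 3-point and
#' 5-point items contribute on a common footing; the scaled score is 100
#' times the mean of the normalised responses over *answered* items in the
#' domain (missing responses are prorated, not zero-filled). The raw mean is
#' the mean of answered item scores in original item-scale units.
#'
#' @param responses Data frame with columns `child_id`, `item_id`, `score`
#'   (ordinal integer in `1..scale_points`), one row per answered item.
#'   Optionally a column `age_months` carried through per child.
#' @param item_map An [nda_item_map()]. Items in `responses` absent from the
#'   map are an error, as are scores outside the item's scale range.
#'
#' @return A tibble with one row per (child, domain present in the map):
#'   `child_id`, `domain`, `raw_mean`, `scaled` (in \[0, 100\], `NA` when no
#'   item in the domain was answered), `n_items_answered`, `completeness`.
#'
#' @examples
#' map <- nda_item_map(data.frame(item_id = c("a", "b"),
#'                                domain = "cognitive", scale_points = 5))
#' resp <- data.frame(child_id = "c1", item_id = c("a", "b"), score = c(3, 5))
#' score_assessments(resp, map)  # scaled = 100 * (2/4 + 4/4)/2 = 75
#' @export
score_assessments <- function(responses, item_map = nda_item_map()) {
  responses <- tibble::as_tibble(responses)
  required <- c("child_id", "item_id", "score")
  missing_cols <- setdiff(required, names(responses))
  if (length(missing_cols) > 0) {
    abort(paste0("responses lack column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  responses$child_id <- as.character(responses$child_id)

  unknown <- setdiff(unique(responses$item_id), item_map$item_id)
  if (length(unknown) > 0) {
    abort(paste0("responses reference items absent from the item map: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }

  joined <- dplyr::inner_join(responses, item_map, by = "item_id")
  bad <- joined$score < 1 | joined$score > joined$scale_points |
    joined$score != round(joined$score)
  bad[is.na(joined$score)] <- FALSE
  if (any(bad, na.rm = TRUE)) {
    off <- joined[which(bad)[1], ]
    abort(sprintf(
      "response out of range: child %s, item %s scored %s on a %d-point scale",
      off$child_id, off$item_id, format(off$score), off$scale_points))
  }
  joined <- joined[!is.na(joined$score), ]

  n_domain_items <- dplyr::count(item_map, .data$domain, name = "n_items")

  per_domain <- joined |>
    dplyr::mutate(unit = (.data$score - 1) / (.data$scale_points - 1)) |>
    dplyr::group_by(.data$child_id, .data$domain) |>
    dplyr::summarise(
      raw_mean = mean(.data$score),
      scaled = 100 * mean(.data$unit),
      n_items_answered = dplyr::n(),
      .groups = "drop"
    )

  # complete the grid: every child gets a row for every domain in the map
  grid <- tidyr::expand_grid(
    child_id = unique(responses$child_id),
    domain = unique(item_map$domain)
  )
  out <- grid |>
    dplyr::left_join(per_domain, by = c("child_id", "domain")) |>
    dplyr::left_join(n_domain_items, by = "domain") |>
    dplyr::mutate(
      n_items_answered = dplyr::coalesce(.data$n_items_answered, 0L),
      completeness = .data$n_items_answered / .data$n_items
    ) |>
    dplyr::select("child_id", "domain", "raw_mean", "scaled",
                  "n_items_answered", "completeness") |>
    dplyr::arrange(.data$child_id,
                   factor(.data$domain, levels = NDA_DOMAINS))
  out
}

#' Flag records with incomplete domain coverage
#'
#' A record is incomplete when any domain's answered-item fraction falls
#' below `min_fraction` (the comparison is inclusive: completeness exactly at
#' the threshold counts as complete).
#'
#' @param scores Output of [score_assessments()].
#' @param min_fraction Minimum acceptable per-domain completeness, in (0, 1].
#' @return A tibble with one row per child: `child_id`, `complete` (logical),
#'   `incomplete_domains` (list-column of offending domain names).
#' @export
flag_completeness <- function(scores, min_fraction = 0.8) {
  stopifnot(is.numeric(min_fraction), length(min_fraction) == 1,
            min_fraction > 0, min_fraction <= 1)
  scores |>
    dplyr::group_by(.data$child_id) |>
    dplyr::summarise(
      complete = all(.data$completeness >= min_fraction),
      incomplete_domains = list(.data$domain[.data$completeness < min_fraction]),
      .groups = "drop"
    )
}
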