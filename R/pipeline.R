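#' Run the full standards-construction pipeline
#'
#' Chains the analysis stages: score item responses into scaled domain
#' scores, apply the prescriptive exclusion cascade to the cohort, estimate
#' pooled Harrell-Davis centiles on the normative subsample, build the
#' screening chart, and (optionally) run the cohort-normality checks
#' (between-site variance share per domain, sex comparison).
#'
#' @param cohort Child-level cohort tibble (see [read_cohort_csv()]).
#' @param responses Long-format item responses (see [read_items_csv()]).
#' @param item_map An [nda_item_map()].
#' @param rules An [exclusion_rules()] set.
#' @param centiles Centile probabilities for the pooled table.
#' @param min_normative_n Error if the normative sample is smaller than
#'   this.
#' @param validate Also compute per-domain between-site variance shares and
#'   the sex comparison on the normative sample.
#' @return List of class `nda_pipeline`: `scores` (all children),
#'   `cascade` (an `nda_cascade`), `normative_scores`, `centile_table`,
#'   `chart`, and when `validate = TRUE` `between_site` and
#'   `sex_comparison` tibbles, plus a `manifest` of per-stage record
#'   counts.
#' @export
run_standards_pipeline <- function(cohort, responses,
                                   item_map = nda_item_map(),
                                   rules = exclusion_rules(),
                                   centiles = c(3, 5, 10, 25, 50, 75, 90, 95, 97) / 100,
                                   min_normative_n = 20,
                                   validate = TRUE) {
  scores <- score_assessments(responses, item_map)
  cascade <- apply_cascade(cohort, rules)
  if (cascade$audit$n_retained < min_normative_n) {
    abort(sprintf(
      "normative sample has %d children (< %d); a larger cohort is needed",
      cascade$audit$n_retained, min_normative_n))
  }
  normative <- scores |>
    dplyr::semi_join(cascade$retained, by = "child_id") |>
    dplyr::left_join(
      cascade$retained[c("child_id", "site", "sex")], by = "child_id")

  tab <- build_centile_table(normative, centiles = centiles)
  chart <- standards_chart(tab)

  out <- list(
    scores = scores,
    cascade = cascade,
    normative_scores = normative,
    centile_table = tab,
    chart = chart
  )
  if (validate) {
    out$between_site <- normative |>
      dplyr::group_by(domain = .data$domain) |>
      dplyr::group_modify(function(d, key) {
        glance(variance_components(d, "scaled", "site"))
      }) |>
      dplyr::ungroup()
    out$sex_comparison <- compare_by_sex_by_domain(normative)
  }
  out$manifest <- tibble::tibble(
    stage = c("responses", "children_scored", "cohort_in",
              "normative", "domains"),
    n = c(nrow(responses), dplyr::n_distinct(scores$child_id),
          cascade$audit$n_input, cascade$audit$n_retained,
          nrow(tab))
  )
  structure(out, class = "nda_pipeline")
}

#' @export
print.nda_pipeline <- function(x, ...) {
  cat("Standards-construction pipeline\n")
  print(x$manifest, n = Inf)
  invisible(x)
}
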