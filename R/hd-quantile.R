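#' Harrell-Davis order-statistic weights
#'
#' The Harrell-Davis estimator of the q-th quantile is a weighted average of
#' all order statistics. The weight on the i-th order statistic is the
#' increment of the regularized incomplete beta function
#' `I_x(a, b)` over the cell `[(i-1)/n, i/n]`, with shapes `a = (n+1) q` and
#' `b = (n+1)(1 - q)` — equivalently, the mass the Beta(a, b) distribution
#' assigns to that cell. Full-sample weights are used (no truncation).
#'
#' @param n Sample size (>= 1).
#' @param q Probability in (0, 1).
#' @return Numeric vector of `n` nonnegative weights summing to 1.
#' @examples
#' hd_weights(5, 0.5)   # symmetric, centre weight largest
#' @export
hd_weights <- function(n, q) {
  if (length(n) != 1 || is.na(n) || n < 1 || n != round(n)) {
    abort("n must be a single integer >= 1")
  }
  if (length(q) != 1 || is.na(q) || q <= 0 || q >= 1) {
    abort("q must lie strictly between 0 and 1")
  }
  a <- (n + 1) * q
  b <- (n + 1) * (1 - q)
  # I_x(a, b) is the Beta(a, b) CDF; increments over the n cells of [0, 1]
  edges <- pbeta(seq.int(0L, n) / n, a, b)
  w <- diff(edges)
  w[w < 0] <- 0   # guard against tiny negative rounding residue
  w
}

#' Harrell-Davis distribution-free quantile estimate
#'
#' @param x Numeric sample (finite values; `NA` removed when
#'   `na.rm = TRUE`).
#' @param q Probability in (0, 1); vectorised over `q`.
#' @param na.rm Drop `NA` values before estimation.
#' @return Estimates `sum(w_i * x_(i))`, one per `q`; each lies within
#'   `[min(x), max(x)]`.
#' @examples
#' hd_quantile(c(1, 2, 3), 0.5)            # 2
#' hd_quantile(rnorm(100), c(0.1, 0.9))
#' @export
hd_quantile <- function(x, q, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) == 0) abort("empty sample")
  if (any(!is.finite(x))) abort("sample contains non-finite values")
  if (any(q <= 0 | q >= 1)) abort("q must lie strictly between 0 and 1")
  xs <- sort(x)
  n <- length(xs)
  vapply(q, function(p) sum(hd_weights(n, p) * xs), numeric(1))
}

#' Pooled per-domain centile table
#'
#' Estimates Harrell-Davis centiles of the scaled domain scores, pooling all
#' children with equal weight (one pooled sample per domain; no site
#' weighting). Domains with fewer observations than `min_n` are still
#' computed but flagged low-confidence.
#'
#' @param scores Data frame with a domain column and a score column, one row
#'   per child x domain (e.g. the output of [score_assessments()] on the
#'   normative cohort). Rows with missing scores are dropped.
#' @param centiles Centile probabilities in (0, 1). The default is the union
#'   of the centile sets a standards table typically reports.
#' @param domain,value Column names (strings) holding the domain label and
#'   the score.
#' @param min_n Minimum per-domain n before the `low_confidence` flag is set.
#' @return A tibble of class `centile_table`, one row per domain, with
#'   columns `domain`, `n`, `low_confidence`, and one `c<k>` column per
#'   requested centile (monotone non-decreasing across each row).
#' @examples
#' sc <- data.frame(domain = "cognitive", scaled = runif(200, 0, 100))
#' build_centile_table(sc, centiles = c(0.03, 0.5, 0.97))
#' @export
build_centile_table <- function(scores,
                                centiles = c(3, 5, 10, 25, 50, 75, 90, 95, 97) / 100,
                                domain = "domain", value = "scaled",
                                min_n = 20) {
  stopifnot(all(centiles > 0 & centiles < 1))
  centiles <- sort(unique(centiles))
  labels <- centile_label(centiles)

  df <- tibble::tibble(
    domain = as.character(scores[[domain]]),
    value = scores[[value]]
  )
  df <- df[!is.na(df$value), , drop = FALSE]
  if (nrow(df) == 0) abort("no non-missing scores to estimate centiles from")

  out <- df |>
    dplyr::group_by(domain = .data$domain) |>
    dplyr::summarise(
      n = dplyr::n(),
      est = list(stats::setNames(hd_quantile(.data$value, centiles), labels)),
      .groups = "drop"
    ) |>
    dplyr::mutate(low_confidence = .data$n < min_n) |>
    tidyr::unnest_wider("est") |>
    dplyr::select("domain", "n", "low_confidence", dplyr::all_of(labels)) |>
    dplyr::arrange(factor(.data$domain,
                          levels = union(NDA_DOMAINS, unique(.data$domain))))
  structure(out, class = c("centile_table", class(out)),
            centiles = centiles, source = "computed from cohort")
}

centile_label <- function(q) {
  paste0("c", formatC(100 * q, format = "fg"))
}

#' @describeIn build_centile_table long-format view: one row per
#'   (domain, centile) with columns `domain`, `centile`, `q`, `value`.
#' @param x A `centile_table`.
#' @param ... Unused.
#' @method tidy centile_table
#' @export
tidy.centile_table <- function(x, ...) {
  q <- attr(x, "centiles")
  labels <- centile_label(q)
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(dplyr::all_of(labels), names_to = "centile",
                        values_to = "value") |>
    dplyr::mutate(q = q[match(.data$centile, labels)]) |>
    dplyr::select("domain", "centile", "q", "value")
}

#' Write a centile table to CSV (rows = domains, columns = centile labels)
#'
#' @param x A `centile_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_centile_csv <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path)
  invisible(path)
}

#' Compare score distributions between two groups (Wilcoxon rank-sum)
#'
#' Two-sided Wilcoxon rank-sum comparison, used to check that boys' and
#' girls' scaled scores are similar enough to pool. The exact null
#' distribution is enumerated when both groups have at most `exact_max`
#' observations and there are no ties; otherwise the normal approximation
#' with mid-rank tie correction and continuity correction is used.
#'
#' @param x,y Numeric samples for the two groups (e.g. girls, boys).
#' @param exact_max Largest per-group n for which the exact method is used.
#' @return One-row tibble: `statistic` (rank-sum W for `x`), `p_value`,
#'   `n_x`, `n_y`, `method` (`"exact"` or `"normal_tie_corrected"`).
#' @examples
#' compare_by_sex(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
#' @export
compare_by_sex <- function(x, y, exact_max = 10) {
  if (length(x) == 0 || length(y) == 0) abort("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- length(x) <= exact_max && length(y) <= exact_max && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided",
                exact = use_exact, correct = TRUE)
  )
  p <- wt$p.value
  # all pooled values tied: rank-sum variance is 0, no evidence of shift
  if (is.nan(p)) p <- 1
  tibble::tibble(
    statistic = unname(wt$statistic),
    p_value = p,
    n_x = length(x),
    n_y = length(y),
    method = if (use_exact) "exact" else "normal_tie_corrected"
  )
}

#' Per-domain sex comparison of scaled scores
#'
#' @param scores Data frame with columns `domain`, a score column and a
#'   two-level group column.
#' @param value,group Column names (strings) for the score and the grouping
#'   factor (e.g. sex).
#' @return Tibble with one row per domain, as in [compare_by_sex()].
#' @export
compare_by_sex_by_domain <- function(scores, value = "scaled", group = "sex") {
  lv <- sort(unique(as.character(scores[[group]])))
  if (length(lv) != 2) abort("grouping column must have exactly two levels")
  scores |>
    dplyr::group_by(domain = .data$domain) |>
    dplyr::group_modify(function(d, key) {
      g <- as.character(d[[group]])
      v <- d[[value]]
      keep <- !is.na(v)
      compare_by_sex(v[keep & g == lv[1]], v[keep & g == lv[2]])
    }) |>
    dplyr::ungroup()
}
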