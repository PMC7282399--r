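#' Between-site variance decomposition
#'
#' One-way random-effects decomposition of a score into between-site and
#' within-site components, by ANOVA method of moments: the within-site
#' variance is the pooled within-site mean square, the between-site variance
#' is `max(0, (MS_between - MS_within) / n0)` where
#' `n0 = (N - sum(n_j^2)/N) / (k - 1)` is the effective group size for
#' unbalanced designs. A small between-site share justifies pooling sites
#' into one normative sample.
#'
#' @param data Data frame with one row per child.
#' @param value,site Column names (strings) of the score and the site label.
#' @return Object of class `variance_decomposition`: a list with
#'   `sigma2_between`, `sigma2_within`, `between_share`, `n_sites`,
#'   `n_per_site` (tibble), `n0`. Sites with fewer than 2 children are
#'   dropped with a warning; fewer than 2 usable sites is an error.
#' @examples
#' d <- data.frame(site = rep(c("a", "b"), each = 50),
#'                 scaled = rnorm(100))
#' variance_components(d, "scaled", "site")$between_share
#' @export
variance_components <- function(data, value = "scaled", site = "site") {
  y <- data[[value]]
  g <- as.character(data[[site]])
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]; g <- g[keep]

  tab <- table(g)
  small <- names(tab)[tab < 2]
  if (length(small) > 0) {
    warn(paste0("dropping site(s) with fewer than 2 children: ",
                paste(small, collapse = ", ")))
    keep2 <- !(g %in% small)
    y <- y[keep2]; g <- g[keep2]
    tab <- table(g)
  }
  k <- length(tab)
  if (k < 2) abort("variance decomposition needs at least 2 usable sites")

  n_j <- as.numeric(tab)
  N <- sum(n_j)
  fit <- aov(y ~ factor(g))
  ms <- summary(fit)[[1]][["Mean Sq"]]
  ms_between <- ms[1]
  ms_within <- ms[2]
  n0 <- (N - sum(n_j^2) / N) / (k - 1)
  sigma2_between <- max(0, (ms_between - ms_within) / n0)
  sigma2_within <- ms_within
  structure(list(
    sigma2_between = sigma2_between,
    sigma2_within = sigma2_within,
    between_share = sigma2_between / (sigma2_between + sigma2_within),
    n_sites = k,
    n_per_site = tibble::tibble(site = names(tab), n = as.integer(tab)),
    n0 = n0
  ), class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf(
    "Variance decomposition over %d sites:\n  between %.4f  within %.4f  between-share %.1f%%\n",
    x$n_sites, x$sigma2_between, x$sigma2_within, 100 * x$between_share))
  invisible(x)
}

#' @describeIn variance_components one-row tibble of the components.
#' @param x A `variance_decomposition`.
#' @param ... Unused.
#' @method glance variance_decomposition
#' @export
glance.variance_decomposition <- function(x, ...) {
  tibble::tibble(
    sigma2_between = x$sigma2_between,
    sigma2_within = x$sigma2_within,
    between_share = x$between_share,
    n_sites = x$n_sites,
    n0 = x$n0
  )
}

#' Packaged normative ranges (vision norms, milestone windows)
#'
#' Editable configuration constants shipped with the package: default
#' normative ranges for the Cardiff vision tests and the WHO windows of
#' achievement for six gross motor milestones.
#'
#' @return `vision_norms()`: tibble `measure`, `lower`, `upper`, `source`.
#'   `who_milestone_windows()`: tibble `milestone`, `lower`, `upper`
#'   (months).
#' @export
vision_norms <- function() {
  tibble::as_tibble(read_normative_ranges()$vision_norms)
}

#' @rdname vision_norms
#' @export
who_milestone_windows <- function() {
  tibble::as_tibble(read_normative_ranges()$milestone_windows)
}

read_normative_ranges <- function() {
  path <- system.file("extdata", "normative_ranges.json",
                      package = "ndastandards", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Vision centiles with direction-aware labelling
#'
#' Harrell-Davis centiles for visual acuity (logMAR) and contrast
#' sensitivity (contrast per cent). Both measures are scored
#' lower-is-better, so centile *labels* are mirrored: the value reported at
#' the 90th centile is the 10th quantile of the raw values — better (lower)
#' performance appears at higher centile labels, giving the decreasing
#' column pattern a vision-centile table shows. The median verdict checks
#' whether the reported c50 lies within the configured normative range.
#'
#' @param vision Data frame with columns `child_id`, `acuity_logmar`,
#'   `contrast_percent` (either measure may be missing for a child).
#' @param norms Normative ranges, as [vision_norms()].
#' @param centiles Centile probabilities for the labels reported.
#' @param mirror Measures whose labels are mirrored (default both).
#' @return List with `centiles` (tibble measure x centile label) and
#'   `verdicts` (tibble `measure`, `c50`, `lower`, `upper`, `in_norm`).
#' @export
vision_centile_check <- function(vision, norms = vision_norms(),
                                 centiles = c(10, 25, 50, 75, 90) / 100,
                                 mirror = c("acuity_logmar",
                                            "contrast_percent")) {
  measures <- intersect(c("acuity_logmar", "contrast_percent"),
                        names(vision))
  if (length(measures) == 0) abort("no vision measure columns found")
  labels <- centile_label(sort(centiles))

  cent <- purrr::map_dfr(measures, function(m) {
    v <- vision[[m]]
    v <- v[!is.na(v)]
    if (length(v) == 0) abort(paste0("no observations for ", m))
    q <- sort(centiles)
    q_eff <- if (m %in% mirror) 1 - q else q
    est <- hd_quantile(v, q_eff)
    tibble::tibble(measure = m, centile = labels, q = q, value = est,
                   n = length(v))
  })

  verdicts <- cent |>
    dplyr::filter(.data$centile == "c50") |>
    dplyr::left_join(norms[c("measure", "lower", "upper")], by = "measure") |>
    dplyr::mutate(in_norm = .data$value >= .data$lower &
                    .data$value <= .data$upper) |>
    dplyr::select("measure", c50 = "value", "lower", "upper", "in_norm")

  list(centiles = cent, verdicts = verdicts)
}

#' Proportion of children inside milestone achievement windows
#'
#' For each gross motor milestone, the fraction of children whose reported
#' achievement age falls inside the normative window (inclusive bounds).
#' Children reported as never having achieved a milestone count as outside
#' its window; children with no report for a milestone are excluded from its
#' denominator.
#'
#' @param milestones Data frame with columns `child_id`, `milestone`,
#'   `age_months` (numeric, `NA` = no report) and optionally
#'   `never_observed` (logical). In CSV input the literal `"never"` in the
#'   age column is parsed to `never_observed = TRUE`.
#' @param windows Tibble as [who_milestone_windows()].
#' @return Tibble `milestone`, `n`, `n_within`, `proportion_within`
#'   (`NA` when no data for that milestone).
#' @export
milestone_window_check <- function(milestones,
                                   windows = who_milestone_windows()) {
  milestones <- tibble::as_tibble(milestones)
  if (!"never_observed" %in% names(milestones)) {
    milestones$never_observed <- FALSE
  }
  unknown <- setdiff(unique(milestones$milestone), windows$milestone)
  if (length(unknown) > 0) {
    abort(paste0("unknown milestone name(s): ",
                 paste(unknown, collapse = ", ")))
  }
  if (any(!is.na(milestones$age_months) & milestones$age_months <= 0)) {
    abort("achievement ages must be positive")
  }
  windows |>
    dplyr::left_join(milestones, by = "milestone") |>
    dplyr::group_by(.data$milestone) |>
    dplyr::summarise(
      n = sum(!is.na(.data$age_months) | isTRUE_vec(.data$never_observed)),
      n_within = sum(!is.na(.data$age_months) &
                       !isTRUE_vec(.data$never_observed) &
                       .data$age_months >= .data$lower &
                       .data$age_months <= .data$upper),
      proportion_within = ifelse(.data$n > 0, .data$n_within / .data$n,
                                 NA_real_),
      .groups = "drop"
    )
}

#' Descriptive cohort summary
#'
#' Per-variable summaries in standards-paper style: `mean (SD)` and
#' `median (IQR)` for numeric variables, `n (%)` per level for categorical
#' and logical variables.
#'
#' @param cohort Data frame of child-level records.
#' @param vars Variables to summarise (default: all except `child_id`).
#' @return Tibble `variable`, `level`, `n`, `statistic`, `formatted`.
#' @export
describe_cohort <- function(cohort, vars = NULL) {
  cohort <- tibble::as_tibble(cohort)
  if (nrow(cohort) == 0) {
    return(tibble::tibble(variable = character(), level = character(),
                          n = integer(), statistic = character(),
                          formatted = character()))
  }
  if (is.null(vars)) vars <- setdiff(names(cohort), "child_id")
  purrr::map_dfr(vars, function(v) {
    x <- cohort[[v]]
    if (is.numeric(x)) {
      x <- x[!is.na(x)]
      qs <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
      tibble::tibble(
        variable = v, level = NA_character_, n = length(x),
        statistic = c("mean (SD)", "median (IQR)"),
        formatted = c(
          sprintf("%.1f (%.2f)", mean(x), sd(x)),
          sprintf("%.1f (%.1f-%.1f)", qs[2], qs[1], qs[3])
        )
      )
    } else {
      x <- as.character(x)
      x <- x[!is.na(x)]
      tab <- table(x)
      tibble::tibble(
        variable = v, level = names(tab), n = as.integer(tab),
        statistic = "n (%)",
        formatted = sprintf("%d (%.1f%%)", as.integer(tab),
                            100 * as.integer(tab) / length(x))
      )
    }
  })
}
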