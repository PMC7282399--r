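#' Domain score directions
#'
#' For every domain except negative behaviour, higher scaled scores reflect
#' better outcomes; for negative behaviour lower scores are better.
#'
#' @return Tibble with columns `domain`, `direction`.
#' @export
domain_directions <- function() {
  tibble::tibble(
    domain = NDA_DOMAINS,
    direction = ifelse(NDA_DOMAINS %in% NDA_LOWER_IS_BETTER,
                       "lower_is_better", "higher_is_better")
  )
}

#' Build a screening standards chart
#'
#' A standards chart holds, per domain, the four zone boundaries (3rd, 10th,
#' 90th and 97th centiles of the normative scaled-score distribution) plus
#' the score direction. Charts can be built from a [build_centile_table()]
#' result or from any data frame carrying `domain`, `c3`, `c10`, `c90`,
#' `c97` columns.
#'
#' @param centiles A `centile_table` or data frame with columns `domain`,
#'   `c3`, `c10`, `c90`, `c97`.
#' @param directions Tibble mapping `domain` to `direction`
#'   (default [domain_directions()]; unknown domains default to
#'   higher-is-better).
#' @param provenance Provenance tag stored on the chart.
#' @return Tibble of class `standards_chart` with columns `domain`, `c3`,
#'   `c10`, `c90`, `c97`, `direction`.
#' @export
standards_chart <- function(centiles, directions = domain_directions(),
                            provenance = "computed from cohort") {
  df <- tibble::as_tibble(centiles)
  need <- c("domain", "c3", "c10", "c90", "c97")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("chart source lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- df[need]
  out <- dplyr::left_join(out, directions, by = "domain")
  out$direction[is.na(out$direction)] <- "higher_is_better"
  bad <- with(out, c3 > c10 | c10 > c90 | c90 > c97)
  if (any(bad)) {
    abort(paste0("boundaries must satisfy c3 <= c10 <= c90 <= c97; violated for: ",
                 paste(out$domain[bad], collapse = ", ")))
  }
  structure(out, class = c("standards_chart", class(out)),
            provenance = provenance)
}

#' The packaged published standards chart
#'
#' Boundary values for the six domains as printed in the published
#' international standards table (normative pooled cohort of 1181 children),
#' shipped as a JSON fixture with the package.
#'
#' @param full When `TRUE`, return the complete published centile table
#'   (c3/c10/c25/c50/c75/c90/c97) as a tibble instead of the four-boundary
#'   chart.
#' @return A `standards_chart` (or a tibble when `full = TRUE`).
#' @examples
#' published_standards()
#' normality_threshold(published_standards())
#' @export
published_standards <- function(full = FALSE) {
  path <- system.file("extdata", "published_standards.json",
                      package = "ndastandards", mustWork = TRUE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  tab <- tibble::as_tibble(j$domains)
  if (full) return(tab)
  standards_chart(tab, provenance = j$source)
}

#' Direction-aware normality threshold
#'
#' The threshold for developmental normality is the 10th centile for
#' higher-is-better domains (normal scores satisfy `score >= c10`) and the
#' 90th centile for lower-is-better domains (`score <= c90`). Both
#' comparisons are inclusive.
#'
#' @param chart A [standards_chart()].
#' @param domains Domains to report (default: all in the chart).
#' @return Tibble with columns `domain`, `threshold`, `comparison`
#'   (`">="` or `"<="`).
#' @examples
#' normality_threshold(published_standards(), "cognitive")  # 38.5, ">="
#' @export
normality_threshold <- function(chart, domains = NULL) {
  stopifnot(inherits(chart, "standards_chart"))
  if (is.null(domains)) domains <- chart$domain
  unknown <- setdiff(domains, chart$domain)
  if (length(unknown) > 0) {
    abort(paste0("domain(s) not in chart: ", paste(unknown, collapse = ", ")))
  }
  rows <- chart[match(domains, chart$domain), ]
  higher <- rows$direction == "higher_is_better"
  tibble::tibble(
    domain = rows$domain,
    threshold = ifelse(higher, rows$c10, rows$c90),
    comparison = ifelse(higher, ">=", "<=")
  )
}

zone_levels <- c("normal", "monitor", "urgent")

classify_zone <- function(score, c3, c10, c90, c97, direction) {
  higher <- direction == "higher_is_better"
  zone <- ifelse(
    higher,
    ifelse(score >= c10, "normal", ifelse(score >= c3, "monitor", "urgent")),
    ifelse(score <= c90, "normal", ifelse(score <= c97, "monitor", "urgent"))
  )
  factor(zone, levels = zone_levels)
}

#' Classify scaled scores into screening zones
#'
#' Maps each score to one of three zones. For higher-is-better domains:
#' normal (`score >= c10`), monitor / "yellow" (`c3 <= score < c10`), urgent
#' / "orange" (`score < c3`). For lower-is-better domains the rule mirrors:
#' normal (`score <= c90`), monitor (`c90 < score <= c97`), urgent
#' (`score > c97`). Every score in \[0, 100\] maps to exactly one zone; when
#' neighbouring boundaries coincide the monitor band is empty and
#' classification stays total.
#'
#' @param scores Data frame with a `domain` column and a score column
#'   (additional columns such as `child_id` are carried through).
#' @param chart A [standards_chart()].
#' @param value Name of the score column (default `"scaled"`).
#' @return `scores` as a tibble with added columns `zone`
#'   (factor normal/monitor/urgent), `boundary_lower`, `boundary_upper` (the
#'   boundary interval applied), and `referral` (`"none"`, `"routine"`,
#'   `"urgent"`).
#' @examples
#' chart <- published_standards()
#' classify_scores(data.frame(domain = "cognitive", scaled = 30), chart)
#' @export
classify_scores <- function(scores, chart, value = "scaled") {
  stopifnot(inherits(chart, "standards_chart"))
  scores <- tibble::as_tibble(scores)
  unknown <- setdiff(unique(scores$domain), chart$domain)
  if (length(unknown) > 0) {
    abort(paste0("domain(s) not in chart: ", paste(unknown, collapse = ", ")))
  }
  v <- scores[[value]]
  if (any(!is.na(v) & (v < 0 | v > 100))) {
    abort("scores must lie in [0, 100]")
  }
  idx <- match(scores$domain, chart$domain)
  zone <- classify_zone(v, chart$c3[idx], chart$c10[idx],
                        chart$c90[idx], chart$c97[idx],
                        chart$direction[idx])
  higher <- chart$direction[idx] == "higher_is_better"
  scores$zone <- zone
  scores$boundary_lower <- ifelse(higher, chart$c3[idx], chart$c90[idx])
  scores$boundary_upper <- ifelse(higher, chart$c10[idx], chart$c97[idx])
  # scores past the normality threshold warrant further assessment; scores
  # past the extreme (3rd/97th) boundary warrant specialist referral too
  scores$referral <- dplyr::case_when(
    is.na(zone) ~ NA_character_,
    zone == "normal" ~ "none",
    zone == "monitor" ~ "further_assessment",
    zone == "urgent" ~ "further_assessment_and_referral"
  )
  scores
}

#' Render a screening report
#'
#' Produces a structured per-domain screening report from classified scores:
#' a plain-text table plus a JSON-serialisable list, with referral guidance
#' for any domain outside the normal zone.
#'
#' @param results Output of [classify_scores()].
#' @param chart The [standards_chart()] used.
#' @param value Score column name.
#' @param path Optional path; when given, the JSON report is written there.
#' @return Invisibly, the report list (`chart_provenance`, `results`,
#'   `flags`).
#' @export
render_chart <- function(results, chart, value = "scaled", path = NULL) {
  stopifnot(inherits(chart, "standards_chart"))
  results <- tibble::as_tibble(results)
  flagged <- results[!is.na(results$zone) & results$zone != "normal", ]
  report <- list(
    chart_provenance = attr(chart, "provenance") %||% "unspecified",
    n_results = nrow(results),
    results = results,
    flags = flagged
  )

  cat("Developmental screening report\n")
  cat("chart: ", report$chart_provenance, "\n", sep = "")
  if (nrow(results) > 0) {
    for (i in seq_len(nrow(results))) {
      cat(sprintf("  %-20s %6.1f  [%s]  boundaries %.1f-%.1f\n",
                  results$domain[i], results[[value]][i],
                  as.character(results$zone[i]),
                  results$boundary_lower[i], results$boundary_upper[i]))
    }
  }
  if (nrow(flagged) > 0) {
    cat(sprintf("  %d domain(s) flagged for further assessment\n",
                nrow(flagged)))
  }
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(report)
}

#' Plot a standards chart with optional individual scores
#'
#' Draws the three-band screening chart: per domain, the urgent band (worse
#' than the 3rd centile, or than the 97th for lower-is-better domains), the
#' monitor band, and the normal band, with any supplied scores overlaid.
#'
#' @param object A [standards_chart()].
#' @param scores Optional data frame with `domain` and a score column to
#'   overlay.
#' @param value Score column name in `scores`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot standards_chart
#' @export
autoplot.standards_chart <- function(object, scores = NULL,
                                     value = "scaled", ...) {
  higher <- object$direction == "higher_is_better"
  bands <- dplyr::bind_rows(
    tibble::tibble(domain = object$domain, zone = "urgent",
                   ymin = ifelse(higher, 0, object$c97),
                   ymax = ifelse(higher, object$c3, 100)),
    tibble::tibble(domain = object$domain, zone = "monitor",
                   ymin = ifelse(higher, object$c3, object$c90),
                   ymax = ifelse(higher, object$c10, object$c97)),
    tibble::tibble(domain = object$domain, zone = "normal",
                   ymin = ifelse(higher, object$c10, 0),
                   ymax = ifelse(higher, 100, object$c90))
  )
  bands$zone <- factor(bands$zone, levels = rev(zone_levels))
  p <- ggplot2::ggplot(bands) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = 0.6, xmax = 1.4, ymin = .data$ymin, ymax = .data$ymax,
      fill = .data$zone)) +
    ggplot2::facet_wrap(~domain, nrow = 1) +
    ggplot2::scale_fill_manual(values = c(
      normal = "grey92", monitor = "#f7d154", urgent = "#f08c21")) +
    ggplot2::scale_x_continuous(breaks = NULL) +
    ggplot2::labs(x = NULL, y = "standardised scaled score",
                  fill = "zone") +
    ggplot2::theme_minimal()
  if (!is.null(scores)) {
    pts <- tibble::as_tibble(scores)
    pts$x <- 1
    p <- p + ggplot2::geom_point(
      data = pts,
      ggplot2::aes(x = .data$x, y = .data[[value]]),
      size = 2)
  }
  p
}
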