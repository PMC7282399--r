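#' CBCL clinical-range flag
#'
#' A child is in the CBCL clinical range when either available subscale
#' centile (attentional problems, emotional reactivity) lies strictly above
#' the clinical cut-off (97th centile by default; scoring exactly at the
#' threshold does not flag). A missing subscale is treated as non-flagging;
#' when both subscales are missing the flag is indeterminate (`NA`), and
#' such records are routed to incomplete-assessment handling by the cascade.
#'
#' @param attention_centile,emotional_centile CBCL subscale centiles in
#'   \[0, 100\], `NA` when unavailable. Vectorised.
#' @param cutoff Clinical centile cut-off (default 97).
#' @return Logical vector (`NA` where both subscales are missing).
#' @examples
#' cbcl_clinical_flag(98, 50)   # TRUE
#' cbcl_clinical_flag(97, 97)   # FALSE: strictly above the threshold flags
#' cbcl_clinical_flag(NA, 99)   # TRUE
#' @export
cbcl_clinical_flag <- function(attention_centile, emotional_centile,
                               cutoff = 97) {
  ok <- function(x) !is.na(x) & x >= 0 & x <= 100
  if (any(!ok(attention_centile) & !is.na(attention_centile)) ||
      any(!ok(emotional_centile) & !is.na(emotional_centile))) {
    abort("CBCL centiles must lie in [0, 100]")
  }
  both_missing <- is.na(attention_centile) & is.na(emotional_centile)
  flag <- (ok(attention_centile) & attention_centile > cutoff) |
    (ok(emotional_centile) & emotional_centile > cutoff)
  flag[both_missing] <- NA
  flag
}

#' Exclusion rules for the prescriptive cascade
#'
#' Builds the ordered rule set used by [apply_cascade()]. The default order
#' mirrors a participant-flow diagram: preterm birth, significant postnatal
#' or neurological morbidity, maternal mental-health diagnosis in pregnancy,
#' incomplete assessment, assessment outside the instrument's validity
#' window, and CBCL clinical range last (it is evaluated among otherwise
#' eligible children).
#'
#' @param ga_cutoff_weeks Retain iff gestational age >= this (default 37.0;
#'   "born before 37+0 weeks" is excluded).
#' @param age_window Inclusive assessment-age window in months
#'   (default `c(22, 30)`, the instrument's validity range).
#' @param cbcl_cutoff CBCL clinical centile cut-off (default 97).
#' @param active Character vector of reason codes to activate (default all).
#' @return Tibble of class `nda_rules` with columns `reason`, `active`, and a
#'   `params` list-column.
#' @export
exclusion_rules <- function(ga_cutoff_weeks = 37.0,
                            age_window = c(22, 30),
                            cbcl_cutoff = 97,
                            active = NULL) {
  rules <- tibble::tibble(
    reason = c("PRETERM", "POSTNATAL_NEURO_MORBIDITY",
               "MATERNAL_MENTAL_HEALTH", "INCOMPLETE_ASSESSMENT",
               "OUT_OF_AGE_WINDOW", "CBCL_CLINICAL_RANGE"),
    params = list(
      list(ga_cutoff_weeks = ga_cutoff_weeks), list(), list(), list(),
      list(age_window = age_window), list(cbcl_cutoff = cbcl_cutoff)
    )
  )
  rules$active <- if (is.null(active)) TRUE else rules$reason %in% active
  structure(rules, class = c("nda_rules", class(rules)))
}

#' Parse "weeks+days" gestational age to decimal weeks
#'
#' @param x Character vector like `"36+6"`, or numeric (returned as-is).
#' @return Numeric decimal weeks (`36 + 6/7` for `"36+6"`).
#' @export
ga_weeks <- function(x) {
  if (is.numeric(x)) return(x)
  parts <- strsplit(as.character(x), "+", fixed = TRUE)
  vapply(parts, function(p) {
    as.numeric(p[1]) + if (length(p) > 1) as.numeric(p[2]) / 7 else 0
  }, numeric(1))
}

rule_matches <- function(cohort, reason, params) {
  switch(reason,
    PRETERM = !is.na(cohort$ga_weeks) &
      cohort$ga_weeks < params$ga_cutoff_weeks,
    POSTNATAL_NEURO_MORBIDITY = isTRUE_vec(cohort$neuro_morbidity),
    MATERNAL_MENTAL_HEALTH = isTRUE_vec(cohort$maternal_mh),
    INCOMPLETE_ASSESSMENT = {
      flag <- cbcl_clinical_flag(cohort$cbcl_attention_centile,
                                 cohort$cbcl_emotional_centile)
      !isTRUE_vec(cohort$assessment_complete) | is.na(flag)
    },
    OUT_OF_AGE_WINDOW = is.na(cohort$age_months) |
      cohort$age_months < params$age_window[1] |
      cohort$age_months > params$age_window[2],
    CBCL_CLINICAL_RANGE = {
      flag <- cbcl_clinical_flag(cohort$cbcl_attention_centile,
                                 cohort$cbcl_emotional_centile,
                                 cutoff = params$cbcl_cutoff)
      !is.na(flag) & flag
    },
    abort(paste0("unknown exclusion reason code: ", reason))
  )
}

isTRUE_vec <- function(x) !is.na(x) & (x %in% c(TRUE, 1L, 1))

#' Apply the prescriptive exclusion cascade
#'
#' Screens a cohort against an ordered set of exclusion rules. Each excluded
#' child is attributed to the *first* matching rule (flow-diagram
#' accounting); which children are retained does not depend on rule order,
#' only the attribution does. The returned audit satisfies the conservation
#' invariant `n_input = n_retained + sum(per-rule counts)`.
#'
#' @param cohort Data frame with columns `child_id`, `site`, `sex`,
#'   `ga_weeks`, `neuro_morbidity`, `maternal_mh`, `cbcl_attention_centile`,
#'   `cbcl_emotional_centile`, `age_months`, `assessment_complete`.
#' @param rules An [exclusion_rules()] tibble (inactive rules are skipped).
#' @return An object of class `nda_cascade`: a list with `retained` (tibble
#'   of retained children), `excluded` (tibble with an `exclusion_reason`
#'   column), and `audit` (n_input, per-rule counts, n_retained, per-site
#'   retained counts, the rule order applied).
#' @examples
#' fix <- participant_flow_fixture()
#' res <- apply_cascade(fix$cohort)
#' glance(res)   # n_retained = 1181
#' @export
apply_cascade <- function(cohort, rules = exclusion_rules()) {
  cohort <- tibble::as_tibble(cohort)
  if (!inherits(rules, "nda_rules")) {
    bad <- setdiff(rules$reason,
                   c("PRETERM", "POSTNATAL_NEURO_MORBIDITY",
                     "MATERNAL_MENTAL_HEALTH", "INCOMPLETE_ASSESSMENT",
                     "OUT_OF_AGE_WINDOW", "CBCL_CLINICAL_RANGE"))
    if (length(bad) > 0) {
      abort(paste0("unknown exclusion reason code: ",
                   paste(bad, collapse = ", ")))
    }
  }
  rules <- rules[rules$active, , drop = FALSE]
  if (nrow(rules) == 0 && nrow(cohort) > 0) {
    warn("no active exclusion rules; retaining the full cohort")
  }

  reason <- rep(NA_character_, nrow(cohort))
  for (k in seq_len(nrow(rules))) {
    m <- rule_matches(cohort, rules$reason[k], rules$params[[k]])
    m[is.na(m)] <- FALSE
    reason[is.na(reason) & m] <- rules$reason[k]
  }

  retained <- cohort[is.na(reason), , drop = FALSE]
  excluded <- cohort[!is.na(reason), , drop = FALSE]
  excluded$exclusion_reason <- reason[!is.na(reason)]

  n_excl <- vapply(rules$reason,
                   function(r) sum(reason == r, na.rm = TRUE),
                   integer(1))
  counts <- tibble::tibble(reason = rules$reason,
                           n_excluded = unname(n_excl))
  per_site <- if ("site" %in% names(retained)) {
    dplyr::count(retained, .data$site, name = "n_retained")
  } else {
    tibble::tibble(site = character(), n_retained = integer())
  }

  audit <- list(
    n_input = nrow(cohort),
    exclusions = counts,
    n_retained = nrow(retained),
    per_site = per_site,
    rule_order = rules$reason
  )
  stopifnot(audit$n_input == audit$n_retained + sum(counts$n_excluded))

  structure(list(retained = retained, excluded = excluded, audit = audit),
            class = "nda_cascade")
}

#' @export
print.nda_cascade <- function(x, ...) {
  a <- x$audit
  cat("Prescriptive exclusion cascade\n")
  cat(sprintf("  input: %d  retained: %d  excluded: %d\n",
              a$n_input, a$n_retained, a$n_input - a$n_retained))
  for (i in seq_len(nrow(a$exclusions))) {
    cat(sprintf("  %-26s %5d\n", a$exclusions$reason[i],
                a$exclusions$n_excluded[i]))
  }
  invisible(x)
}

#' @describeIn apply_cascade per-rule exclusion counts as a tibble.
#' @param x An `nda_cascade` object.
#' @param ... Unused.
#' @method tidy nda_cascade
#' @export
tidy.nda_cascade <- function(x, ...) x$audit$exclusions

#' @describeIn apply_cascade one-row summary (n_input, n_excluded,
#'   n_retained, retention fraction).
#' @method glance nda_cascade
#' @export
glance.nda_cascade <- function(x, ...) {
  a <- x$audit
  tibble::tibble(
    n_input = a$n_input,
    n_excluded = a$n_input - a$n_retained,
    n_retained = a$n_retained,
    retention = a$n_retained / a$n_input
  )
}

#' Write a cascade audit to JSON
#'
#' @param x An `nda_cascade` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cascade_audit <- function(x, path) {
  stopifnot(inherits(x, "nda_cascade"))
  a <- x$audit
  jsonlite::write_json(
    list(
      n_input = a$n_input,
      exclusions = a$exclusions,
      n_retained = a$n_retained,
      per_site = a$per_site,
      rule_order = a$rule_order
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
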