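# Independent oracle for the Harrell-Davis weights: adaptive numerical
# integration of the Beta((n+1)q, (n+1)(1-q)) density over each cell
# [(i-1)/n, i/n]. Deliberately avoids pbeta, the route the implementation
# uses.
oracle_hd_weights <- function(n, q) {
  a <- (n + 1) * q
  b <- (n + 1) * (1 - q)
  dens <- function(x) stats::dbeta(x, a, b)
  # the density is singular at 0 when a < 1 (and at 1 when b < 1); for the
  # boundary cells integrate in the substituted variable t = x^a
  # (resp. t = (1-x)^b), under which the integrand is bounded:
  # dbeta(x) dx = (1 - t^(1/a))^(b-1) / (a B(a, b)) dt
  left_tail <- function(upper) {
    stats::integrate(function(t) (1 - t^(1 / a))^(b - 1) / (a * beta(a, b)),
                     0, upper^a, rel.tol = 1e-12)$value
  }
  right_tail <- function(lower) {
    stats::integrate(function(t) (1 - t^(1 / b))^(a - 1) / (b * beta(a, b)),
                     0, (1 - lower)^b, rel.tol = 1e-12)$value
  }
  vapply(seq_len(n), function(i) {
    lo <- (i - 1) / n
    hi <- i / n
    if (lo == 0 && a < 1 && hi < 1) {
      left_tail(hi)
    } else if (hi == 1 && b < 1 && lo > 0) {
      right_tail(lo)
    } else if (lo == 0 && hi == 1) {
      1
    } else {
      stats::integrate(dens, lo, hi, rel.tol = 1e-12)$value
    }
  }, numeric(1))
}

# one-domain item maps used across scoring tests
one_domain_map <- function(n_five = 2, n_three = 0, domain = "cognitive") {
  nda_item_map(data.frame(
    item_id = sprintf("it%02d", seq_len(n_five + n_three)),
    domain = domain,
    scale_points = c(rep(5L, n_five), rep(3L, n_three))
  ))
}

# a fully healthy child record, overridable field by field
healthy_child <- function(child_id = "c1", ...) {
  rec <- list(
    child_id = child_id, site = "siteA", sex = "female",
    ga_weeks = 39.5, neuro_morbidity = FALSE, maternal_mh = FALSE,
    cbcl_attention_centile = 50, cbcl_emotional_centile = 50,
    age_months = 24.5, assessment_complete = TRUE
  )
  over <- list(...)
  rec[names(over)] <- over
  tibble::as_tibble(rec)
}

random_cohort <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    child_id = sprintf("r%04d", seq_len(n)),
    site = sample(c("a", "b", "c"), n, TRUE),
    sex = sample(c("female", "male"), n, TRUE),
    ga_weeks = runif(n, 32, 42),
    neuro_morbidity = runif(n) < 0.2,
    maternal_mh = runif(n) < 0.2,
    cbcl_attention_centile = runif(n, 0, 100),
    cbcl_emotional_centile = runif(n, 0, 100),
    age_months = runif(n, 20, 32),
    assessment_complete = runif(n) < 0.9
  )
}
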