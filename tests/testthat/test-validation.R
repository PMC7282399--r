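test_that("two-site closed-form decomposition is exact", {
  d <- data.frame(site = c("a", "a", "b", "b"), scaled = c(0, 0, 1, 1))
  vc <- variance_components(d)
  expect_equal(vc$sigma2_within, 0)
  expect_equal(vc$between_share, 1)
  # balanced MoM arithmetic: MSB = n0 * var(site means) = 1, MSW = 0,
  # n0 = 2, so sigma2_between = (1 - 0)/2 = var(c(0, 1)) = 0.5
  expect_equal(vc$sigma2_between, 0.5)
})

test_that("a planted between-site share is recovered", {
  d <- simulate_site_scores(n_sites = 5, n_per_site = 400,
                            between_share = 0.10, seed = 42)
  vc <- variance_components(d)
  expect_lt(abs(vc$between_share - 0.10), 0.03)

  null <- simulate_site_scores(n_sites = 5, n_per_site = 400,
                               between_share = 0, seed = 43)
  expect_lt(variance_components(null)$between_share, 0.02)
})

test_that("between-share is scale invariant and variance is conserved", {
  set.seed(14)
  d <- simulate_site_scores(n_sites = 4, n_per_site = 100,
                            between_share = 0.2, seed = 14)
  vc <- variance_components(d)
  d2 <- d; d2$scaled <- d$scaled * 7.3
  expect_equal(variance_components(d2)$between_share, vc$between_share,
               tolerance = 1e-10)
  # balanced design: components approximately partition the total variance
  expect_equal(vc$sigma2_between + vc$sigma2_within, stats::var(d$scaled),
               tolerance = 0.05 * stats::var(d$scaled))
})

test_that("degenerate site structures error or warn as specified", {
  expect_error(variance_components(
    data.frame(site = "a", scaled = c(1, 2, 3))), "at least 2")
  expect_warning(vc <- variance_components(data.frame(
    site = c("a", "a", "b", "b", "tiny"), scaled = c(1, 2, 3, 4, 5))),
    "fewer than 2")
  expect_equal(vc$n_sites, 2)
})

test_that("milestone proportions count windows inclusively", {
  w <- who_milestone_windows()
  expect_equal(nrow(w), 6)
  all_in <- data.frame(child_id = c("a", "b"), milestone = "walking_alone",
                       age_months = c(8.2, 17.6))   # window edges included
  expect_equal(
    milestone_window_check(all_in)$proportion_within[
      milestone_window_check(all_in)$milestone == "walking_alone"], 1)

  one_out <- data.frame(child_id = letters[1:4],
                        milestone = "standing_alone",
                        age_months = c(7, 10, 12, 20))
  res <- milestone_window_check(one_out)
  expect_equal(res$proportion_within[res$milestone == "standing_alone"],
               0.75)
  # milestones with no data report NA with zero denominator
  expect_true(is.na(res$proportion_within[res$milestone == "walking_alone"]))

  never <- data.frame(child_id = c("a", "b"), milestone = "walking_alone",
                      age_months = c(12, NA),
                      never_observed = c(FALSE, TRUE))
  resn <- milestone_window_check(never)
  expect_equal(resn$proportion_within[resn$milestone == "walking_alone"],
               0.5)                     # never-observed counts outside
  expect_error(milestone_window_check(
    data.frame(child_id = "a", milestone = "flying", age_months = 9)),
    "unknown milestone")
})

test_that("vision centiles mirror labels for lower-is-better measures", {
  const <- data.frame(child_id = "a", acuity_logmar = rep(0.2, 30),
                      contrast_percent = rep(1.5, 30))
  res <- vision_centile_check(const)
  expect_true(all(res$centiles$value[res$centiles$measure == "acuity_logmar"]
                  == 0.2))
  expect_true(all(res$verdicts$in_norm))

  sym <- data.frame(child_id = 1:3, acuity_logmar = c(0.1, 0.2, 0.3),
                    contrast_percent = c(1.0, 1.5, 2.0))
  res2 <- vision_centile_check(sym)
  cc <- res2$centiles[res2$centiles$measure == "contrast_percent", ]
  expect_equal(cc$value[cc$centile == "c50"], 1.5)
  # mirrored labelling: higher centile label = better (lower) value
  ac <- res2$centiles[res2$centiles$measure == "acuity_logmar", ]
  expect_false(is.unsorted(rev(ac$value)))

  set.seed(31)
  syn <- generate_cohort(cohort_config(sites = c(a = 150, b = 150)),
                         seed = 31, ground_truth = FALSE)
  res3 <- vision_centile_check(syn$vision)
  a50 <- res3$verdicts$c50[res3$verdicts$measure == "acuity_logmar"]
  expect_lt(abs(a50 - 0.2), 0.1)   # generator median is 0.2 logMAR
  expect_error(vision_centile_check(
    data.frame(child_id = "a", acuity_logmar = NA_real_)), "no observations")
})

test_that("cohort description uses the standards-paper formats", {
  d <- data.frame(child_id = letters[1:4], age_months = c(22, 23, 24, 25),
                  sex = c("f", "f", "m", "m"))
  out <- describe_cohort(d)
  mean_row <- out[out$variable == "age_months" &
                    out$statistic == "mean (SD)", ]
  expect_equal(mean_row$formatted, "23.5 (1.29)")
  sex_rows <- out[out$variable == "sex", ]
  expect_equal(sort(sex_rows$formatted), c("2 (50.0%)", "2 (50.0%)"))
  expect_equal(nrow(describe_cohort(d[0, ])), 0)
  single <- describe_cohort(d[1, ])
  expect_true(all(single$n[single$variable == "age_months"] == 1))
})
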