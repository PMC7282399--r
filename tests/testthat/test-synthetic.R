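small_config <- function(...) {
  cohort_config(sites = c(a = 60, b = 60), gt_draws = 2e3, ...)
}

test_that("generation is deterministic in the seed and varies across seeds", {
  cfg <- small_config()
  a <- generate_cohort(cfg, seed = 5, ground_truth = FALSE)
  b <- generate_cohort(cfg, seed = 5, ground_truth = FALSE)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$responses, b$responses)
  expect_identical(a$vision, b$vision)
  expect_identical(a$milestones, b$milestones)
  c <- generate_cohort(cfg, seed = 6, ground_truth = FALSE)
  expect_false(identical(a$responses$score, c$responses$score))
})

test_that("a degenerate midpoint generator scores exactly 50 everywhere", {
  cfg <- cohort_config(
    sites = c(a = 20), site_effect_sd = 0, child_sd = 0,
    item_noise_sd = 0,
    latent_mean = c(cognitive = 0, fine_motor = 0, gross_motor = 0,
                    language = 0, positive_behaviour = 0,
                    negative_behaviour = 0),
    sex_effect = c(cognitive = 0, fine_motor = 0, gross_motor = 0,
                   language = 0, positive_behaviour = 0,
                   negative_behaviour = 0),
    preterm_rate = 0, morbidity_rate = 0, maternal_mh_rate = 0,
    cbcl_clinical_rate = 0, incomplete_rate = 0, out_of_window_rate = 0,
    gt_draws = 500)
  syn <- generate_cohort(cfg, seed = 1, ground_truth = FALSE)
  sc <- score_assessments(syn$responses, cfg$item_map)
  expect_true(all(sc$scaled == 50))
  # the oracle agrees for every quantile
  tq <- true_quantile(cfg, "cognitive", c(0.03, 0.5, 0.97), n_draws = 500)
  expect_equal(tq, rep(50, 3))
})

test_that("the ground-truth oracle is reproducible and monotone", {
  cfg <- small_config()
  q <- c(0.1, 0.5, 0.9)
  t1 <- true_quantile(cfg, "language", q, n_draws = 5e3)
  t2 <- true_quantile(cfg, "language", q, n_draws = 5e3)
  expect_identical(t1, t2)           # fixed oracle seed
  expect_false(is.unsorted(t1))
  # the oracle stream does not disturb user RNG state
  set.seed(77); before <- runif(1)
  set.seed(77); invisible(true_quantile(cfg, "language", 0.5, n_draws = 1e3))
  expect_equal(runif(1), before)
})

test_that("planted eligibility-flag counts are internally consistent", {
  cfg <- cohort_config(sites = c(a = 400, b = 400), gt_draws = 1e3)
  syn <- generate_cohort(cfg, seed = 12, ground_truth = FALSE)
  planted <- syn$ground_truth$planted_exclusions
  expect_equal(planted$preterm, sum(syn$cohort$ga_weeks < 37))
  expect_equal(planted$morbidity, sum(syn$cohort$neuro_morbidity))
  expect_equal(planted$cbcl_clinical,
               sum(cbcl_clinical_flag(syn$cohort$cbcl_attention_centile,
                                      syn$cohort$cbcl_emotional_centile),
                   na.rm = TRUE))
  # empirical rates sit near the configured rates (3 SE binomial bands)
  n <- nrow(syn$cohort)
  for (pair in list(c(planted$preterm, cfg$preterm_rate),
                    c(planted$morbidity, cfg$morbidity_rate),
                    c(planted$cbcl_clinical, cfg$cbcl_clinical_rate))) {
    se <- sqrt(pair[2] * (1 - pair[2]) / n)
    expect_lt(abs(pair[1] / n - pair[2]), 3 * se + 1e-9)
  }
})

test_that("assessment ages follow the configured distribution", {
  syn <- generate_cohort(cohort_config(sites = c(a = 600, b = 600),
                                       gt_draws = 1e3),
                         seed = 3, ground_truth = FALSE)
  age <- syn$cohort$age_months
  expect_lt(abs(mean(age) - 24.8), 0.3)
  in_window <- mean(age >= 22 & age <= 30)
  expect_gt(in_window, 0.98)
})

test_that("the participant-flow fixture reproduces the published counts", {
  fix <- participant_flow_fixture()
  expect_equal(nrow(fix$cohort), 1339)
  res <- apply_cascade(fix$cohort)
  counts <- tidy(res)
  expect_equal(res$audit$n_retained, 1181)
  expect_equal(counts$n_excluded[counts$reason == "PRETERM"], 54L)
  expect_equal(counts$n_excluded[counts$reason == "CBCL_CLINICAL_RANGE"],
               28L)
  # the published per-site contributions describe the eligible sample
  pre_cbcl <- apply_cascade(fix$cohort, exclusion_rules(
    active = setdiff(exclusion_rules()$reason, "CBCL_CLINICAL_RANGE")))
  expect_equal(pre_cbcl$audit$n_retained, 1209)
  site_totals <- pre_cbcl$audit$per_site
  expect_equal(
    site_totals$n_retained[match(c("brazil", "india", "italy", "kenya", "uk"),
                                 site_totals$site)],
    c(147L, 305L, 296L, 301L, 160L))
})

test_that("generated cohorts round-trip through the CSV writers/readers", {
  dir <- withr::local_tempdir()
  syn <- generate_cohort(small_config(), seed = 9, ground_truth = FALSE)
  write_cohort_csvs(syn, dir)

  cohort <- read_cohort_csv(file.path(dir, "cohort.csv"))
  expect_equal(as.data.frame(cohort), as.data.frame(syn$cohort))
  items <- read_items_csv(file.path(dir, "items.csv"))
  expect_equal(as.data.frame(items), as.data.frame(syn$responses))
  vision <- read_vision_csv(file.path(dir, "vision.csv"))
  expect_equal(as.data.frame(vision), as.data.frame(syn$vision))
  ms <- read_milestones_csv(file.path(dir, "milestones.csv"))
  expect_equal(ms$never_observed, syn$milestones$never_observed)
  expect_equal(ms$age_months, syn$milestones$age_months, tolerance = 1e-9)
})

test_that("config validation rejects impossible parameters", {
  expect_error(cohort_config(preterm_rate = 1.2), "rates")
  expect_error(cohort_config(child_sd = -1), "standard deviations")
  expect_error(cohort_config(thresholds_5 = c(1, 0.5, 2, 3)),
               "strictly increasing")
  expect_error(cohort_config(thresholds_3 = c(0, 1, 2)), "2 for 3-point")
})
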