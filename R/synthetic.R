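#' Configuration for the synthetic multi-site cohort generator
#'
#' Defines the generative model for a synthetic five-site cohort with the
#' statistical structure the standards-construction analysis assumes.
#' Ordinal item responses arise from a latent-ability model: for child `c`
#' and item `j` in domain `d`,
#' `u = mu_d + site effect + sex effect + child effect + item noise`, and
#' the response is the ordinal bin of `u` under the item's thresholds
#' (4 thresholds for 5-point items, 2 for 3-point items). Asymmetric
#' threshold placement produces the skewness/kurtosis and ceiling effects
#' real scaled-score distributions show. Site effects follow a
#' random-intercept structure, drawn once per site per domain.
#'
#' @param sites Named integer vector: children per site. The default is five
#'   sites of 300 (1500 children, the scale of a multi-country normative
#'   cohort).
#' @param female_prob Probability a child is female (default 0.52).
#' @param latent_mean Named per-domain latent means (latent SD units).
#' @param child_sd,item_noise_sd Latent child-effect and item-noise SDs.
#' @param site_effect_sd Site random-intercept SD. The default targets a
#'   between-site share of ~5% of latent variance
#'   (`sqrt(0.05/0.95)` with `child_sd = 1`).
#' @param plant_site_effects When `TRUE`, the drawn per-domain site effects
#'   are centred and rescaled so their *sample* variance equals
#'   `site_effect_sd^2` exactly — useful when a known between-site share
#'   must be recovered from few sites.
#' @param sex_effect Named list of per-domain latent shifts applied to
#'   females (negative values shift males up). Defaults: small positive
#'   cognitive/language shifts for girls and a small positive
#'   negative-behaviour shift for boys.
#' @param thresholds_5,thresholds_3 Ordinal cut-points for 5- and 3-point
#'   items (strictly increasing).
#' @param preterm_rate,morbidity_rate,maternal_mh_rate Planted exclusion
#'   flag rates.
#' @param cbcl_clinical_rate Fraction of children planted strictly above the
#'   97th CBCL centile.
#' @param incomplete_rate Fraction with incomplete assessments.
#' @param age_mean,age_sd Assessment-age distribution in months
#'   (default 24.8, 1.6), truncated to the validity window.
#' @param age_window Validity window in months.
#' @param out_of_window_rate Fraction planted with assessment ages outside
#'   the window.
#' @param item_map The [nda_item_map()] items are generated for.
#' @param gt_draws Monte-Carlo draws used for the ground-truth quantiles
#'   attached to a generated cohort.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(
    sites = c(brazil = 300, india = 300, italy = 300, kenya = 300, uk = 300),
    female_prob = 0.52,
    latent_mean = c(cognitive = 0.6, fine_motor = 1.0, gross_motor = 0.8,
                    language = 0.4, positive_behaviour = 1.0,
                    negative_behaviour = -1.2),
    child_sd = 1,
    item_noise_sd = 0.8,
    site_effect_sd = sqrt(0.05 / 0.95),
    plant_site_effects = FALSE,
    sex_effect = c(cognitive = 0.1, fine_motor = 0, gross_motor = 0,
                   language = 0.1, positive_behaviour = 0,
                   negative_behaviour = -0.1),
    thresholds_5 = c(-1.5, -0.5, 0.5, 1.5),
    thresholds_3 = c(-0.8, 0.8),
    preterm_rate = 0.031,
    morbidity_rate = 0.030,
    maternal_mh_rate = 0.027,
    cbcl_clinical_rate = 0.021,
    incomplete_rate = 0.005,
    age_mean = 24.8, age_sd = 1.6,
    age_window = c(22, 30),
    out_of_window_rate = 0.005,
    item_map = nda_item_map(),
    gt_draws = 2e5) {
  rates <- c(preterm_rate, morbidity_rate, maternal_mh_rate,
             cbcl_clinical_rate, incomplete_rate, out_of_window_rate,
             female_prob)
  if (any(rates < 0 | rates > 1)) abort("rates must lie in [0, 1]")
  if (child_sd < 0 || item_noise_sd < 0 || site_effect_sd < 0 || age_sd < 0) {
    abort("standard deviations must be >= 0")
  }
  if (is.unsorted(thresholds_5, strictly = TRUE) ||
      is.unsorted(thresholds_3, strictly = TRUE)) {
    abort("thresholds must be strictly increasing")
  }
  if (length(thresholds_5) != 4 || length(thresholds_3) != 2) {
    abort("need 4 thresholds for 5-point items and 2 for 3-point items")
  }
  missing_dom <- setdiff(unique(item_map$domain), names(latent_mean))
  if (length(missing_dom) > 0) {
    abort(paste0("latent_mean missing for domain(s): ",
                 paste(missing_dom, collapse = ", ")))
  }
  structure(mget(names(formals())), class = "cohort_config")
}

bin_ordinal <- function(u, thresholds) {
  1L + findInterval(u, thresholds)
}

item_thresholds <- function(config, scale_points) {
  if (scale_points == 5L) config$thresholds_5 else config$thresholds_3
}

# scaled scores for a matrix of children x (items of one domain), given the
# per-child latent values; returns the per-child 0-100 scaled mean
scaled_from_latent <- function(latent, items, config) {
  acc <- numeric(length(latent))
  for (j in seq_len(nrow(items))) {
    u <- latent + rnorm(length(latent), 0, config$item_noise_sd)
    resp <- bin_ordinal(u, item_thresholds(config, items$scale_points[j]))
    acc <- acc + (resp - 1) / (items$scale_points[j] - 1)
  }
  100 * acc / nrow(items)
}

draw_site_effects <- function(config, domains) {
  k <- length(config$sites)
  eff <- matrix(rnorm(k * length(domains), 0, config$site_effect_sd),
                nrow = k, dimnames = list(names(config$sites), domains))
  if (config$plant_site_effects && config$site_effect_sd > 0 && k > 1) {
    eff <- apply(eff, 2, function(e) {
      e <- e - mean(e)
      s <- sd(e)
      if (s > 0) e * config$site_effect_sd / s else e
    })
    rownames(eff) <- names(config$sites)
  }
  eff
}

#' Generate a synthetic multi-site cohort
#'
#' Draws a full synthetic cohort under a [cohort_config()]: child-level
#' eligibility records, long-format ordinal item responses, vision and
#' milestone data, and a ground-truth object holding the realized site
#' effects, the planted exclusion counts, and Monte-Carlo scaled-score
#' quantiles of the generative distribution (conditioned on the realized
#' site effects). Output is deterministic given `seed`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed for all cohort randomness.
#' @param ground_truth Compute the Monte-Carlo ground-truth quantiles
#'   (set `FALSE` to skip the oracle for speed).
#' @param centiles Centile probabilities stored in the ground truth.
#' @return List of class `nda_cohort` with elements `cohort`, `responses`,
#'   `vision`, `milestones`, `ground_truth`, `config`, `seed`.
#' @examples
#' cfg <- cohort_config(sites = c(a = 60, b = 60), gt_draws = 1e3)
#' syn <- generate_cohort(cfg, seed = 1)
#' head(syn$cohort)
#' @export
generate_cohort <- function(config = cohort_config(), seed,
                            ground_truth = TRUE,
                            centiles = c(3, 5, 10, 25, 50, 75, 90, 95, 97) / 100) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)

  n <- sum(config$sites)
  site <- rep(names(config$sites), times = config$sites)
  child_id <- sprintf("ch%05d", seq_len(n))
  sex <- ifelse(runif(n) < config$female_prob, "female", "male")
  domains <- unique(config$item_map$domain)

  site_eff <- draw_site_effects(config, domains)

  # --- eligibility attributes -------------------------------------------
  preterm <- runif(n) < config$preterm_rate
  ga <- ifelse(preterm,
               runif(n, 30, 36.99),
               truncnorm_draw(n, 39.6, 1.2, lower = 37))
  neuro_morbidity <- runif(n) < config$morbidity_rate
  maternal_mh <- runif(n) < config$maternal_mh_rate
  cbcl_clin <- runif(n) < config$cbcl_clinical_rate
  which_sub <- runif(n) < 0.5
  cbcl_att <- ifelse(cbcl_clin & which_sub, runif(n, 97.01, 100),
                     runif(n, 0, 97))
  cbcl_emo <- ifelse(cbcl_clin & !which_sub, runif(n, 97.01, 100),
                     runif(n, 0, 97))
  out_window <- runif(n) < config$out_of_window_rate
  age <- ifelse(out_window,
                ifelse(runif(n) < 0.5, runif(n, 20.5, 21.9),
                       runif(n, 30.1, 32)),
                truncnorm_draw(n, config$age_mean, config$age_sd,
                               lower = config$age_window[1],
                               upper = config$age_window[2]))
  complete <- runif(n) >= config$incomplete_rate

  cohort <- tibble::tibble(
    child_id = child_id, site = site, sex = sex,
    ga_weeks = round(ga, 3),
    neuro_morbidity = neuro_morbidity,
    maternal_mh = maternal_mh,
    cbcl_attention_centile = round(cbcl_att, 2),
    cbcl_emotional_centile = round(cbcl_emo, 2),
    age_months = round(age, 2),
    assessment_complete = complete
  )

  # --- ordinal item responses ------------------------------------------
  responses <- purrr::map_dfr(domains, function(d) {
    items <- config$item_map[config$item_map$domain == d, , drop = FALSE]
    latent <- config$latent_mean[[d]] +
      site_eff[site, d] +
      ifelse(sex == "female", config$sex_effect[[d]], 0) +
      rnorm(n, 0, config$child_sd)
    purrr::map_dfr(seq_len(nrow(items)), function(j) {
      u <- latent + rnorm(n, 0, config$item_noise_sd)
      tibble::tibble(
        child_id = child_id,
        item_id = items$item_id[j],
        score = bin_ordinal(u, item_thresholds(config, items$scale_points[j]))
      )
    })
  }) |> dplyr::arrange(.data$child_id, .data$item_id)

  # --- vision and milestones -------------------------------------------
  acuity_levels <- c(0.0, 0.1, 0.2, 0.3, 0.4)
  acuity_probs <- c(0.05, 0.30, 0.45, 0.18, 0.02)
  contrast_levels <- c(0.8, 1.0, 1.5, 1.8, 2.0, 2.5)
  contrast_probs <- c(0.06, 0.24, 0.33, 0.15, 0.18, 0.04)
  vision <- tibble::tibble(
    child_id = child_id,
    acuity_logmar = sample(acuity_levels, n, TRUE, acuity_probs),
    contrast_percent = sample(contrast_levels, n, TRUE, contrast_probs)
  )

  ms_params <- tibble::tribble(
    ~milestone, ~mean, ~sd,
    "sitting_without_support",  6.0, 1.1,
    "standing_with_assistance", 7.5, 1.4,
    "hands_and_knees_crawling", 8.4, 1.6,
    "walking_with_assistance",  9.4, 1.7,
    "standing_alone",          11.0, 1.9,
    "walking_alone",           12.1, 1.8
  )
  milestones <- purrr::pmap_dfr(ms_params, function(milestone, mean, sd) {
    never <- runif(n) < 0.002
    tibble::tibble(
      child_id = child_id,
      milestone = milestone,
      age_months = ifelse(never, NA_real_,
                          round(truncnorm_draw(n, mean, sd, lower = 0.5), 1)),
      never_observed = never
    )
  })

  planted <- list(
    preterm = sum(preterm),
    morbidity = sum(neuro_morbidity),
    maternal_mh = sum(maternal_mh),
    cbcl_clinical = sum(cbcl_clin),
    incomplete = sum(!complete),
    out_of_window = sum(out_window)
  )

  gt_quantiles <- NULL
  if (ground_truth) {
    gt_quantiles <- purrr::map_dfr(domains, function(d) {
      tq <- true_quantile(config, d, centiles,
                          n_draws = config$gt_draws,
                          site_effects = site_eff[, d])
      tibble::tibble(domain = d, q = centiles,
                     centile = centile_label(centiles), value = tq)
    })
  }

  structure(list(
    cohort = cohort,
    responses = responses,
    vision = vision,
    milestones = milestones,
    ground_truth = list(
      quantiles = gt_quantiles,
      site_effects = site_eff,
      target_between_share = config$site_effect_sd^2 /
        (config$site_effect_sd^2 + config$child_sd^2),
      planted_exclusions = planted
    ),
    config = config,
    seed = seed
  ), class = "nda_cohort")
}

truncnorm_draw <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Ground-truth scaled-score quantiles by Monte Carlo
#'
#' Simulates the scaled-score generative distribution for one domain at
#' scale (default one million draws under a fixed oracle seed, independent
#' of cohort seeds) and returns its empirical quantiles. When `site_effects`
#' is supplied (the realized per-site intercepts of a generated cohort) the
#' oracle conditions on them, mixing sites by their configured sizes;
#' otherwise site effects are integrated over by drawing fresh ones per
#' child.
#'
#' @param config A [cohort_config()].
#' @param domain Domain name.
#' @param q Probabilities in (0, 1) (vectorised).
#' @param n_draws Monte-Carlo draws.
#' @param site_effects Optional named numeric vector of realized site
#'   effects for this domain.
#' @param oracle_seed Fixed seed for the oracle stream.
#' @return Numeric quantiles, one per `q`.
#' @export
true_quantile <- function(config, domain, q, n_draws = 1e6,
                          site_effects = NULL, oracle_seed = 104729) {
  stopifnot(inherits(config, "cohort_config"))
  if (any(q <= 0 | q >= 1)) abort("q must lie strictly between 0 and 1")
  items <- config$item_map[config$item_map$domain == domain, , drop = FALSE]
  if (nrow(items) == 0) abort(paste0("no items for domain ", domain))

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(oracle_seed)

  chunk <- 1e5
  draws <- numeric(0)
  remaining <- n_draws
  site_prob <- config$sites / sum(config$sites)
  while (remaining > 0) {
    m <- min(chunk, remaining)
    se <- if (is.null(site_effects)) {
      rnorm(m, 0, config$site_effect_sd)
    } else {
      site_effects[sample(names(site_prob), m, TRUE, site_prob)]
    }
    sexf <- runif(m) < config$female_prob
    latent <- config$latent_mean[[domain]] + se +
      ifelse(sexf, config$sex_effect[[domain]], 0) +
      rnorm(m, 0, config$child_sd)
    draws <- c(draws, scaled_from_latent(latent, items, config))
    remaining <- remaining - m
  }
  unname(quantile(draws, q, type = 8))
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Continuous site-score fixture with an exactly planted between-site share
#'
#' Generates one continuous score per child across `n_sites` sites where the
#' site intercepts are rescaled to an exact sample variance, so the planted
#' between-site variance share is known precisely even with few sites. Used
#' to validate [variance_components()] parameter recovery.
#'
#' @param n_sites,n_per_site Design size.
#' @param between_share Planted share of total variance between sites,
#'   in \[0, 1).
#' @param total_sd Total score SD.
#' @param seed Seed.
#' @return Tibble with columns `site`, `scaled`.
#' @export
simulate_site_scores <- function(n_sites = 5, n_per_site = 500,
                                 between_share = 0.10, total_sd = 10,
                                 seed = 1) {
  stopifnot(between_share >= 0, between_share < 1, n_sites >= 2)
  set.seed(seed)
  sigma_b <- total_sd * sqrt(between_share)
  sigma_w <- total_sd * sqrt(1 - between_share)
  eff <- rnorm(n_sites)
  eff <- eff - mean(eff)
  if (sigma_b > 0 && sd(eff) > 0) eff <- eff * sigma_b / sd(eff) else eff <- eff * 0
  tibble::tibble(
    site = rep(sprintf("site%02d", seq_len(n_sites)), each = n_per_site),
    scaled = rep(eff, each = n_per_site) +
      rnorm(n_sites * n_per_site, 0, sigma_w)
  )
}

#' Participant-flow replication fixture
#'
#' A deterministic cohort of 1339 assessed children engineered to reproduce
#' the published participant flow: 54 children born before 37+0 weeks, 40
#' with significant postnatal/neurological morbidity and 36 with a maternal
#' mental-health diagnosis (the 40/36 split of the 130 pre-eligibility
#' exclusions beyond the 54 preterm is a package convention — the published
#' flow does not give it), leaving 1209 eligible children; among these,
#' exactly 28 score strictly above the 97th CBCL centile on one subscale,
#' leaving 1181 in the normative sample.
#'
#' The published per-site contributions — Brazil 147, India 305, Italy 296,
#' Kenya 301, UK 160 — sum to 1209 (and the printed percentages are
#' fractions of 1209), so they describe the *eligible* sample before the
#' CBCL exclusion. The fixture therefore plants those totals at the
#' eligible stage; the site split of the 28 CBCL-excluded children
#' (3/7/7/7/4) and of the 130 earlier exclusions (round-robin) are package
#' conventions.
#'
#' @return List with `cohort` (tibble of 1339 children) and
#'   `expected_audit` (list of the published counts).
#' @examples
#' fix <- participant_flow_fixture()
#' res <- apply_cascade(fix$cohort)
#' res$audit$n_retained  # 1181
#' @export
participant_flow_fixture <- function() {
  eligible_sites <- c(brazil = 147, india = 305, italy = 296,
                      kenya = 301, uk = 160)   # sums to 1209
  cbcl_sites <- c(brazil = 3, india = 7, italy = 7, kenya = 7, uk = 4)
  n_excl <- c(preterm = 54, morbidity = 40, maternal_mh = 36)
  n_total <- sum(eligible_sites) + sum(n_excl)  # 1339

  base <- function(n, prefix) tibble::tibble(
    child_id = sprintf("%s%04d", prefix, seq_len(n)),
    ga_weeks = 39.5,
    neuro_morbidity = FALSE,
    maternal_mh = FALSE,
    cbcl_attention_centile = 50,
    cbcl_emotional_centile = 50,
    age_months = 24.5,
    assessment_complete = TRUE
  )

  eligible <- base(sum(eligible_sites), "eli")
  eligible$site <- rep(names(eligible_sites), times = eligible_sites)
  # plant the 28 CBCL clinical-range children inside the eligible sample
  cbcl_idx <- unlist(lapply(names(cbcl_sites), function(s) {
    which(eligible$site == s)[seq_len(cbcl_sites[[s]])]
  }))
  half <- seq_along(cbcl_idx) %% 2 == 0
  eligible$cbcl_attention_centile[cbcl_idx[half]] <- 98.5
  eligible$cbcl_emotional_centile[cbcl_idx[!half]] <- 99.2

  preterm <- base(n_excl[["preterm"]], "pre")
  preterm$ga_weeks <- rep(c(33.0, 35.5, 36.857), length.out = nrow(preterm))

  morbid <- base(n_excl[["morbidity"]], "mor")
  morbid$neuro_morbidity <- TRUE

  mmh <- base(n_excl[["maternal_mh"]], "mmh")
  mmh$maternal_mh <- TRUE

  excluded <- dplyr::bind_rows(preterm, morbid, mmh)
  excluded$site <- rep(names(eligible_sites), length.out = nrow(excluded))

  cohort <- dplyr::bind_rows(eligible, excluded)
  cohort$sex <- rep(c("female", "male"), length.out = nrow(cohort))
  cohort <- cohort[c("child_id", "site", "sex", "ga_weeks",
                     "neuro_morbidity", "maternal_mh",
                     "cbcl_attention_centile", "cbcl_emotional_centile",
                     "age_months", "assessment_complete")]
  stopifnot(nrow(cohort) == 1339)

  list(
    cohort = cohort,
    expected_audit = list(
      n_assessed = n_total,
      n_eligible = 1209,
      n_retained = 1181,
      preterm = 54, morbidity = 40, maternal_mh = 36, cbcl = 28,
      site_totals_eligible = eligible_sites
    )
  )
}
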