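test_that("packaged chart returns the published normality thresholds", {
  ch <- published_standards()
  th <- normality_threshold(ch)
  expected <- tibble::tibble(
    domain = c("cognitive", "fine_motor", "gross_motor", "language",
               "positive_behaviour", "negative_behaviour"),
    threshold = c(38.5, 25.7, 51.7, 17.8, 51.4, 50.0),
    comparison = c(rep(">=", 5), "<="))
  expect_equal(th[match(expected$domain, th$domain), ], expected)
})

test_that("a degenerate chart with equal boundaries still thresholds", {
  flat <- standards_chart(tibble::tibble(
    domain = c("cognitive", "negative_behaviour"),
    c3 = 40, c10 = 40, c90 = 40, c97 = 40))
  th <- normality_threshold(flat)
  expect_equal(th$threshold, c(40, 40))
  expect_equal(th$comparison, c(">=", "<="))
  expect_error(normality_threshold(flat, "language"), "not in chart")
})

test_that("zone classification reproduces the screening rules at boundaries", {
  ch <- published_standards()
  cases <- tibble::tribble(
    ~domain, ~scaled, ~zone,
    "cognitive", 38.5, "normal",    # c10 inclusive
    "cognitive", 30.0, "monitor",   # 27.4 <= 30 < 38.5
    "cognitive", 27.4, "monitor",   # c3 belongs to monitor
    "cognitive", 27.39, "urgent",   # strictly below c3
    "cognitive", 100, "normal",
    "negative_behaviour", 50.0, "normal",   # c90 inclusive
    "negative_behaviour", 60.0, "monitor",  # 50 < 60 <= 76.5
    "negative_behaviour", 76.5, "monitor",  # c97 belongs to monitor
    "negative_behaviour", 80.0, "urgent",   # strictly above c97
    "negative_behaviour", 0.0, "normal"
  )
  res <- classify_scores(cases[c("domain", "scaled")], ch)
  expect_equal(as.character(res$zone), cases$zone)
  expect_equal(res$referral[res$zone == "normal"],
               rep("none", sum(cases$zone == "normal")))
})

test_that("collapsed monitor bands classify totally", {
  # published negative-behaviour row has c3 = c10 = 0: monitor band empty
  ch <- published_standards()
  res <- classify_scores(
    data.frame(domain = "negative_behaviour", scaled = c(0, 0.01, 25)), ch)
  expect_false(any(is.na(res$zone)))
})

test_that("every score maps to exactly one zone on random valid charts", {
  set.seed(21)
  for (rep in 1:20) {
    b <- sort(runif(4, 0, 100))
    if (rep %% 4 == 0) b[2] <- b[1]          # boundary ties
    if (rep %% 5 == 0) b[3] <- b[4]
    dir <- sample(c("higher_is_better", "lower_is_better"), 1)
    ch <- standards_chart(
      tibble::tibble(domain = "cognitive", c3 = b[1], c10 = b[2],
                     c90 = b[3], c97 = b[4]),
      directions = tibble::tibble(domain = "cognitive", direction = dir))
    grid <- c(0, 100, b, pmax(0, b - 1e-9), pmin(100, b + 1e-9),
              runif(50, 0, 100))
    res <- classify_scores(data.frame(domain = "cognitive", scaled = grid), ch)
    expect_false(any(is.na(res$zone)))

    # zone never moves toward urgent as the score improves
    ord <- order(grid)
    ranked <- as.integer(factor(res$zone[ord],
                                levels = c("urgent", "monitor", "normal")))
    if (dir == "lower_is_better") ranked <- rev(ranked)
    expect_false(is.unsorted(ranked))

    # normality threshold agrees with the normal/monitor boundary
    th <- normality_threshold(ch)
    at <- classify_scores(
      data.frame(domain = "cognitive", scaled = th$threshold), ch)
    expect_equal(as.character(at$zone), "normal")
  }
})

test_that("invalid classification inputs are rejected", {
  ch <- published_standards()
  expect_error(classify_scores(
    data.frame(domain = "cognitive", scaled = 101), ch), "\\[0, 100\\]")
  expect_error(classify_scores(
    data.frame(domain = "unknown_dom", scaled = 50), ch), "not in chart")
  expect_error(standards_chart(tibble::tibble(
    domain = "cognitive", c3 = 50, c10 = 40, c90 = 60, c97 = 70)),
    "c3 <= c10")
})

test_that("screening reports carry zones and flags", {
  ch <- published_standards()
  empty <- render_chart(
    classify_scores(data.frame(domain = character(),
                               scaled = numeric()), ch), ch)
  expect_equal(empty$n_results, 0)
  expect_equal(nrow(empty$flags), 0)

  profile <- classify_scores(
    data.frame(domain = ch$domain,
               scaled = c(80, 90, 85, 70, 95, 20)), ch)
  out <- withr::local_tempfile(fileext = ".json")
  rep6 <- render_chart(profile, ch, path = out)
  expect_equal(rep6$n_results, 6)
  expect_equal(nrow(rep6$flags), 0)         # all normal: no referral flags
  expect_true(file.exists(out))

  flagged <- classify_scores(
    data.frame(domain = "cognitive", scaled = 20), ch)
  rep1 <- render_chart(flagged, ch)
  expect_equal(nrow(rep1$flags), 1)
})

test_that("autoplot draws the three-band chart", {
  p <- ggplot2::autoplot(published_standards(),
                         scores = data.frame(domain = "cognitive",
                                             scaled = 42))
  expect_s3_class(p, "ggplot")
})
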