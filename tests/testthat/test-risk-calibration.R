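test_that("threshold container and group assignment follow the boundary rules", {
  th <- risk_thresholds(0.333, 0.606)
  expect_error(risk_thresholds(0.7, 0.3), "t_low")
  expect_error(risk_thresholds(0, 0.5), "t_low")

  expect_equal(as.character(assign_risk_group(0.2, th)), "low")
  # scores exactly at a threshold fall in the upper group
  expect_equal(as.character(assign_risk_group(c(0.333, 0.606), th)),
               c("intermediate", "high"))
  expect_equal(as.character(assign_risk_group(c(0, 0.5, 1),
                                              risk_thresholds(1/3, 2/3))),
               c("low", "intermediate", "high"))
  expect_error(assign_risk_group(1.2, th), "\\[0, 1\\]")
})

test_that("threshold fitting recovers planted 3-component boundaries", {
  withr::local_seed(3)
  s <- c(stats::rnorm(280, 0.2, 0.05), stats::rnorm(230, 0.45, 0.05),
         stats::rnorm(90, 0.75, 0.05))
  s <- pmin(pmax(s, 0.001), 0.999)
  th <- fit_thresholds(s)
  expect_gte(th$t_low, 0.28)
  expect_lte(th$t_low, 0.40)
  expect_gte(th$t_high, 0.55)
  expect_lte(th$t_high, 0.68)

  expect_error(suppressWarnings(fit_thresholds(rep(0.5, 100))), "identical")
  # quantile fallback produces tertiles on demand
  th_q <- fit_thresholds(s, fallback = "quantile")
  expect_s3_class(th_q, "risk_thresholds")
})

test_that("proportion-based grouping uses largest-remainder apportionment", {
  g <- assign_groups_by_proportion(seq(0.1, 1, length.out = 10),
                                   c(low = 0.5, intermediate = 0.3, high = 0.2))
  expect_equal(as.integer(table(g)), c(5, 3, 2))

  # fractional boundaries: n = 7 with (0.462, 0.386, 0.152) -> (3, 3, 1)
  g7 <- assign_groups_by_proportion(seq_len(7) / 10,
                                    c(0.462, 0.386, 0.152))
  expect_equal(as.integer(table(g7)), c(3, 3, 1))

  # monotone: a higher score is never in a lower group
  s <- c(0.9, 0.1, 0.5, 0.7, 0.3)
  gm <- assign_groups_by_proportion(s, c(0.4, 0.4, 0.2))
  expect_true(all(diff(as.integer(gm)[order(s)]) >= 0))
})

test_that("down-sampling reproduces the printed cohort arithmetic", {
  ev <- rep(c(TRUE, FALSE), c(143, 429))  # 572 samples, 25.0% prevalence
  expect_equal(mean(ev), 0.25)
  idx <- downsample_to_prevalence(ev, target = 0.15, seed = 4)
  expect_length(idx, 505)
  expect_equal(sum(ev[idx]), 76)

  # stopping rule: one more removal would overshoot; brute-force check on
  # the toy case 5 events / 10 samples / target 0.25 -> 4 removals
  ev10 <- rep(c(TRUE, FALSE), each = 5)
  idx10 <- downsample_to_prevalence(ev10, target = 0.25, seed = 9)
  expect_length(idx10, 6)
  expect_equal(sum(ev10[idx10]), 1)

  # already at target: identity
  ev_ok <- rep(c(TRUE, FALSE), c(3, 17))
  expect_length(downsample_to_prevalence(ev_ok, target = 0.15), 20)

  expect_error(downsample_to_prevalence(ev, target = 0), "target")
})

test_that("group-rate estimation satisfies the conservation identity", {
  withr::local_seed(21)
  n <- 400
  s <- stats::runif(n)
  ev <- stats::runif(n) < (0.05 + 0.4 * s)  # risk increases with score
  th <- risk_thresholds(1/3, 2/3)
  gr <- estimate_group_rates(s, ev, thresholds = th, target = 0.15,
                             n_iterations = 50, seed = 6)
  expect_equal(sum(gr$proportion), 1, tolerance = 1e-10)
  expect_false(is.unsorted(gr$relapse_rate))
  expect_gt(attr(gr, "monotone_fraction"), 0.9)

  # proportion-weighted mean of group rates equals the retained overall rate
  keep <- downsample_to_prevalence(ev, target = 0.15, seed = 31)
  grp <- assign_risk_group(s[keep], th)
  rates <- tapply(ev[keep], grp, mean)
  props <- as.numeric(table(grp)) / length(keep)
  expect_equal(sum(props * rates), mean(ev[keep]), tolerance = 1e-12)
  expect_lte(mean(ev[keep]), 0.15 + 5e-4)
})

test_that("loess calibration curve is flat under independence and monotone on monotone input", {
  withr::local_seed(33)
  n <- 1500
  s <- stats::runif(n)
  ev <- stats::runif(n) < 0.15  # outcome independent of score
  cv <- relapse_likelihood_curve(s, ev)
  grid <- cv$grid[cv$grid$score >= 0.1 & cv$grid$score <= 0.9, ]
  expect_true(all(grid$lower <= 0.15 + 0.02 & grid$upper >= 0.15 - 0.02))

  # noiseless monotone bin fractions produce a monotone lookup
  s2 <- rep(seq(0.01, 0.99, length.out = 50), each = 20)
  ev2 <- rep(FALSE, length(s2))
  ev2[stats::ave(seq_along(s2), s2, FUN = seq_along) <=
        round(20 * rep(seq(0.05, 0.6, length.out = 50), each = 20))] <- TRUE
  cv2 <- relapse_likelihood_curve(s2, ev2)
  fitv <- predict(cv2, seq(0.05, 0.95, by = 0.05))$likelihood
  expect_false(is.unsorted(fitv))

  # out-of-support lookups are clamped and flagged
  lk <- predict(cv, c(-0.5, 2))
  expect_true(all(lk$extrapolated))
  expect_true(all(lk$likelihood >= 0 & lk$likelihood <= 1))
})

test_that("calibration bundle round-trips through JSON", {
  withr::local_seed(44)
  n <- 300
  s <- stats::runif(n)
  ev <- stats::runif(n) < (0.1 + 0.5 * s)
  cal <- calibrate_rfrs(s, ev, thresholds = risk_thresholds(1/3, 2/3),
                        n_iterations = 20, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(cal, path)
  cal2 <- read_calibration(path)
  expect_equal(cal2$thresholds$t_low, cal$thresholds$t_low)
  expect_equal(cal2$group_rates$relapse_rate, cal$group_rates$relapse_rate)
  expect_equal(predict(cal2$curve, c(0.2, 0.5, 0.8)),
               predict(cal$curve, c(0.2, 0.5, 0.8)))
  expect_equal(fraction_at_or_below(cal2$curve, c(0.05, 0.1)),
               fraction_at_or_below(cal$curve, c(0.05, 0.1)))
})
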