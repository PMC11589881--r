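test_that("the insertion statistic satisfies its boundary identities and worked example", {
  # AMS blocked nothing -> 0% inserted
  expect_equal(percent_insertion(data.frame(peg_untreated = 80, peg_nem = 20,
                                            peg_ams = 80))$percent_insertion, 0)
  # AMS blocked as much as NEM -> 100% inserted
  expect_equal(percent_insertion(data.frame(peg_untreated = 80, peg_nem = 20,
                                            peg_ams = 20))$percent_insertion, 100)
  got <- percent_insertion(data.frame(peg_untreated = 90, peg_nem = 10,
                                      peg_ams = 30))
  expect_equal(got$percent_insertion, 75)
  expect_false(got$clamped)
})

test_that("degenerate lanes are rejected and out-of-range values clamped with a flag", {
  expect_error(percent_insertion(data.frame(peg_untreated = 0, peg_nem = 0,
                                            peg_ams = 0)), "peg_untreated")
  expect_error(percent_insertion(data.frame(peg_untreated = 50, peg_nem = 60,
                                            peg_ams = 30)),
               "degenerate denominator")
  expect_error(percent_insertion(data.frame(peg_untreated = 110, peg_nem = 10,
                                            peg_ams = 30)), "\\[0, 100\\]")
  # noise pushing AMS below NEM drives the raw statistic above 100
  over <- percent_insertion(data.frame(peg_untreated = 90, peg_nem = 10,
                                       peg_ams = 5))
  expect_true(over$clamped)
  expect_equal(over$percent_insertion, 100)
  expect_gt(over$percent_insertion_raw, 100)
})

test_that("the statistic is scale-invariant and monotone decreasing in the AMS lane", {
  base <- c(peg_untreated = 90, peg_nem = 10, peg_ams = 30)
  p0 <- percent_insertion(as.data.frame(t(base)))$percent_insertion
  for (f in c(0.25, 0.5, 1.1)) {
    scaled <- as.data.frame(t(base * f))
    expect_equal(percent_insertion(scaled)$percent_insertion, p0)
  }
  ams_grid <- seq(10, 90, by = 10)
  vals <- percent_insertion(data.frame(peg_untreated = 90, peg_nem = 10,
                                       peg_ams = ams_grid))$percent_insertion
  expect_true(all(diff(vals) < 0))
})

test_that("densitometry calibration fits through the origin and spots saturation", {
  ds <- data.frame(dilution_factor = c(1, 2, 4),
                   band_intensity = c(1000, 500, 250))
  cal <- calibrate_densitometry(ds)
  expect_equal(cal$slope, 1000)
  expect_equal(cal$r_squared, 1)
  expect_false(cal$saturation_warning)
  expect_equal(cal$correct(500), 0.5)

  sat <- data.frame(dilution_factor = c(1, 2, 4, 8),
                    band_intensity = c(600, 500, 250, 125)) # top band capped
  expect_warning(cal2 <- calibrate_densitometry(sat), "saturated")
  expect_true(cal2$saturation_warning)
  expect_lt(cal2$r_squared, 1)

  expect_error(calibrate_densitometry(ds[1:2, ]), "at least 3")
  expect_error(calibrate_densitometry(
    data.frame(dilution_factor = c(1, 2, 3), band_intensity = c(9, 5, 3))),
    "geometric")
})

test_that("percent PEGylation from calibrated band pairs matches its definition", {
  ds <- data.frame(dilution_factor = c(1, 2, 4),
                   band_intensity = c(1000, 500, 250))
  cal <- calibrate_densitometry(ds)
  expect_equal(percent_pegylation(300, 700), 30)
  expect_equal(percent_pegylation(300, 700, cal),
               100 * (300 / 1000) / (300 / 1000 + 700 / 1000))
  expect_error(percent_pegylation(0, 0), "both bands are zero")
})

test_that("replicate aggregation reports mean and SEM with small-n warnings", {
  agg <- aggregate_insertion(c(70, 80, 90))
  expect_equal(agg$mean_insertion, 80)
  expect_equal(agg$sem, 10 / sqrt(3))
  expect_equal(aggregate_insertion(rep(55, 4))$sem, 0)
  expect_warning(one <- aggregate_insertion(42), ">= 3")
  expect_true(is.na(one$sem))
  expect_error(suppressWarnings(aggregate_insertion(numeric())), "no replicates")
})

test_that("inverse-constructed gels recover the true insertion exactly without noise", {
  for (truth in c(0, 25, 75, 100)) {
    g <- make_gels(truth, noise_cv = 0, n_replicates = 3, seed = 1)
    expect_equal(percent_insertion(g)$percent_insertion, rep(truth, 3))
  }
})

test_that("the estimator recovers true insertion within 2 points at 5% band noise", {
  g <- make_gels(70, noise_cv = 0.05, n_replicates = 500, seed = 42)
  est <- mean(percent_insertion(g)$percent_insertion)
  expect_lt(abs(est - 70), 2)
})
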