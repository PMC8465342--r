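test_that("the measurement error model is max(cv*Ip, floor)", {
  expect_equal(measurement_sd(50, cv = 0.06, floor = 1), 3)
  expect_equal(measurement_sd(0, cv = 0.06, floor = 1), 1)
  ip <- seq(0, 100, by = 0.5)
  expect_true(all(diff(measurement_sd(ip)) >= 0))  # non-decreasing
  expect_error(measurement_sd(50, cv = 0), "cv")
  expect_error(measurement_sd(-1), ">= 0")
})

test_that("zero-noise datasets equal the noise-free simulation; seeds reproduce", {
  sub <- virtual_subject(median_kin(), median_abs())
  ds0 <- generate_dataset(sub, ipk_model("3C"), cv = 0, seed = 1)
  expect_equal(ds0$insulin, attr(ds0, "Ip_true"))
  expect_equal(nrow(ds0), 145)  # 10-min sampling over 24 h

  ds1 <- generate_dataset(sub, ipk_model("3C"), seed = 42)
  ds2 <- generate_dataset(sub, ipk_model("3C"), seed = 42)
  expect_identical(ds1$insulin, ds2$insulin)
  ds3 <- generate_dataset(sub, ipk_model("3C"), seed = 43)
  expect_false(identical(ds1$insulin, ds3$insulin))
})

test_that("measurement noise is zero-mean Gaussian with the stated SD", {
  # replicate the same time point many times on a short horizon
  sub <- virtual_subject(median_kin(), median_abs())
  des <- infusion_profile(15.625, bolus_times = 60, bolus_doses = 7500)
  draws <- vapply(1:500, function(s) {
    ds <- generate_dataset(sub, ipk_model("3C"), design = des,
                           sampling_interval = 60, horizon = 240, seed = s)
    ds$insulin[3]  # t = 120, well after the bolus
  }, 0)
  ds <- generate_dataset(sub, ipk_model("3C"), design = des,
                         sampling_interval = 60, horizon = 240, cv = 0)
  mu <- ds$insulin[3]
  sd_true <- max(0.06 * mu, 1)
  expect_lt(abs(mean(draws) - mu), 3 * sd_true / sqrt(500))
  expect_lt(abs(sd(draws) / sd_true - 1), 0.05)
})

test_that("standardized generator noise passes a normality check across seeds", {
  sub <- virtual_subject(median_kin(), median_abs())
  pvals <- vapply(1:20, function(s) {
    ds <- generate_dataset(sub, ipk_model("3C"), sampling_interval = 3,
                           horizon = 1440, seed = 100 + s)
    z <- (ds$insulin - attr(ds, "Ip_true")) / ds$sd
    shapiro.test(z)$p.value
  }, 0)
  expect_gte(mean(pvals >= 0.01), 0.95)
})

test_that("negative draws are truncated at zero and flagged", {
  # near-zero insulin with huge noise floor forces truncation
  kin <- median_kin()
  sub <- virtual_subject(kin, median_abs(), daily_dose = 1e-4)
  ds <- generate_dataset(sub, ipk_model("3C"), floor = 50, seed = 5)
  expect_true(length(attr(ds, "truncated")) > 0)
  expect_true(all(ds$insulin >= 0))
})

test_that("dataset CSV + JSON sidecar round-trips", {
  sub <- virtual_subject(median_kin(), median_abs())
  ds <- generate_dataset(sub, ipk_model("3C"), seed = 9)
  f <- tempfile(fileext = ".csv")
  write_dataset_csv(ds, f)
  back <- read_dataset_csv(f)
  expect_equal(back$insulin, ds$insulin)
  expect_equal(back$sd, ds$sd)
  expect_equal(attr(back, "meal_times"), attr(ds, "meal_times"))
  tb <- attr(back, "truth")
  expect_equal(format(tb$model), "3C")
  expect_equal(tb$kin$VI, 3.4)
  expect_equal(tb$abs[[1]]$ka2, 0.028)
  unlink(c(f, paste0(f, ".json")))
})

test_that("population draws center on the medians and honour feasibility", {
  pop0 <- sample_population(5, dispersion = 0, seed = 1)
  for (s in pop0) {
    expect_equal(s$kin$VI, 3.4)
    expect_equal(s$abs[[1]]$ka2, 0.028)
    # meal_variability 0: identical absorption at all meals
    expect_equal(s$abs[[1]]$ka2, s$abs[[3]]$ka2)
  }
  pop <- sample_population(1000, dispersion = 0.3, seed = 2)
  ka2 <- vapply(pop, function(s) s$abs[[1]]$ka2, 0)
  expect_lt(abs(median(ka2) / 0.028 - 1), 0.05)
  # every draw satisfies the structural constraints
  for (s in pop[1:50]) expect_gt(derive_m4(s$kin), 0)
  popv <- sample_population(3, dispersion = 0, meal_variability = 0.2,
                            seed = 3)
  expect_false(popv[[1]]$abs[[1]]$ka2 == popv[[1]]$abs[[2]]$ka2)
})
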