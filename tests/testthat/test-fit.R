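truth_values <- list(VI = 3.4, m1 = 0.15, CL = 1.16, HEb = 0.59, aI = 16e-5,
                     ka1.1 = 0.010, ka2.1 = 0.028, ka1.2 = 0.010,
                     ka2.2 = 0.028, ka1.3 = 0.010, ka2.3 = 0.028)

test_that("the objective is zero at truth on noise-free data and rises away from it", {
  sub <- virtual_subject(median_kin(), median_abs())
  ds0 <- generate_dataset(sub, ipk_model("3C"), cv = 0, seed = 1)
  flat <- ipk_priors(NULL, NULL, NULL, NULL)
  f <- map_objective(ipk_model("3C"), ds0, flat)
  expect_equal(f(truth_values), 0, tolerance = 1e-12)
  for (nm in c("VI", "m1", "HEb", "ka2.2", "aI")) {
    v <- truth_values
    v[[nm]] <- v[[nm]] * 1.2
    expect_gt(f(v), f(truth_values))
  }
})

test_that("the log-normal prior penalty is quadratic in log space, zero at the median", {
  sub <- virtual_subject(median_kin(), median_abs())
  ds0 <- generate_dataset(sub, ipk_model("3C"), cv = 0, seed = 1)
  flat <- ipk_priors(NULL, NULL, NULL, NULL)
  pri <- ipk_priors(VI = c(3.4, 1), m1 = NULL, CL = NULL, HEb = NULL)
  f0 <- map_objective(ipk_model("3C"), ds0, flat)
  f1 <- map_objective(ipk_model("3C"), ds0, pri)
  expect_equal(f1(truth_values), f0(truth_values))  # zero at the median
  v <- truth_values
  v$VI <- 3.4 * 2
  sdlog2 <- log(1 + 1^2)
  expect_equal(f1(v) - f0(v), log(2)^2 / (2 * sdlog2), tolerance = 1e-9)
})

test_that("weighted residuals follow their definition", {
  expect_equal(weighted_residuals(data.frame(insulin = 53, sd = 3), 50), 1)
  d <- data.frame(insulin = c(5, 10), sd = c(1, 2))
  expect_equal(weighted_residuals(d, c(5, 10)), c(0, 0))
  expect_error(weighted_residuals(data.frame(insulin = 1, sd = 0), 1),
               "SD")
  expect_error(weighted_residuals(d, 1), "lengths")
})

test_that("a one-parameter fit matches a brute-force grid search", {
  kin <- median_kin(aI = 0)
  ka1_true <- 0.012
  sub <- virtual_subject(kin, absorption_params(ka1 = ka1_true))
  ds <- generate_dataset(sub, ipk_model("1A"), seed = 21)
  flat <- ipk_priors(NULL, NULL, NULL, NULL)
  ctl <- quick_control(fix = c(VI = 3.4, m1 = 0.15, CL = 1.16, HEb = 0.59),
                       meal_varying = FALSE)
  f <- map_objective(ipk_model("1A"), ds, flat, ctl)
  grid <- exp(seq(log(0.002), log(0.06), length.out = 241))
  obj <- vapply(grid, function(k) f(list(ka1.1 = k)), 0)
  k_grid <- grid[which.min(obj)]
  fit <- ipk_fit(ds, "1A", flat, ctl)
  step <- log(grid[2] / grid[1])
  expect_lt(abs(log(fit$estimates[["ka1.1"]] / k_grid)), step)
  expect_lte(fit$objective, min(obj) + 1e-8)
})

test_that("noise-free self-consistency: truth-centred priors recover truth within 1%", {
  sub <- virtual_subject(median_kin(), median_abs())
  ds0 <- generate_dataset(sub, ipk_model("3C"), cv = 0, seed = 1)
  pri <- ipk_priors(c(3.4, 1), c(0.15, 1), c(1.16, 1), c(0.59, 1))
  fit <- ipk_fit(ds0, "3C", pri,
                 quick_control(start = list(ka1 = 0.01, ka2 = 0.028,
                                            aI = 16e-5)))
  est <- fit$estimates[names(truth_values)]
  expect_lt(max(abs(est / unlist(truth_values) - 1)), 0.01)
  expect_lt(fit$wrss, 1e-6)
})

test_that("simplification rule (ii): ka1 below the floor collapses to zero and refits", {
  kin <- median_kin()
  sub <- virtual_subject(kin, absorption_params(ka1 = 0, ka2 = 0.028))
  ds <- generate_dataset(sub, ipk_model("3C"), seed = 31)
  pri <- ipk_priors(c(3.4, 1), c(0.15, 1), c(1.16, 1), c(0.59, 1))
  fit <- ipk_fit(ds, "3C", pri,
                 quick_control(meal_varying = FALSE,
                               start = list(ka2 = 0.028, aI = 16e-5)))
  expect_true(fit$collapse$ka1_zero[1])
  expect_equal(fit$estimates[["ka1.1"]], 0)
  expect_false("ka1.1" %in% names(fit$cv))     # collapsed: no CV
  expect_equal(fit$P, length(fit$map$free))
  expect_false("ka1.1" %in% fit$map$free)
})

test_that("simplification rule (i): kd virtually equal to ka2 is tied and P reduced", {
  kin <- median_kin(aI = 0)
  sub <- virtual_subject(kin, absorption_params(ka2 = 0.028, kd = 0.028))
  ds <- generate_dataset(sub, ipk_model("2A"), seed = 32)
  pri <- ipk_priors(c(3.4, 1), c(0.15, 1), c(1.16, 1), c(0.59, 1))
  fit <- ipk_fit(ds, "2A", pri,
                 quick_control(meal_varying = FALSE,
                               start = list(ka2 = 0.028, delta = 0.05)))
  expect_true(fit$collapse$kd_tie[1])
  expect_equal(fit$estimates[["kd.1"]], fit$estimates[["ka2.1"]])
  expect_equal(fit$P, 5)  # VI, m1, CL, HEb, ka2 (delta collapsed)
})

test_that("CVs follow their definition and flag imprecision", {
  # CV% = 100 * posterior sd / estimate; log-coordinates make this exact
  fake <- structure(list(cv = c(ka2.1 = 20, aG = 150, VI = Inf)),
                    class = "ipk_fit")
  expect_equal(unname(parameter_cv(fake)["ka2.1"]), 20)
  expect_equal(precision_fraction(list(fake)), 100 / 3)  # only one < 100
})

test_that("a correct fit to noisy data leaves unit-scale weighted residuals", {
  sub <- virtual_subject(median_kin(), median_abs())
  ds <- generate_dataset(sub, ipk_model("3C"), seed = 33)
  pri <- ipk_priors(c(3.4, 1), c(0.15, 1), c(1.16, 1), c(0.59, 1))
  fit <- ipk_fit(ds, "3C", pri,
                 quick_control(meal_varying = FALSE,
                               start = list(ka1 = 0.01, ka2 = 0.028,
                                            aI = 16e-5)))
  expect_gt(sd(fit$residuals), 0.7)
  expect_lt(sd(fit$residuals), 1.3)
  expect_true(fit$runs$pass)
  # accessors are consistent
  expect_equal(residuals(fit), (ds$insulin - fitted(fit)) / ds$sd)
  expect_equal(unname(coef(fit)["ka2.1"]),
               unname(fit$estimates["ka2.1"]))
  s <- summary(fit)
  expect_s3_class(s, "summary.ipk_fit")
  expect_true(all(c("estimate", "cv_pct") %in% colnames(s$coefficients)))
})

test_that("denser sampling never degrades the information-based CVs", {
  # deterministic version of the information-content property: the
  # Gauss-Newton CVs evaluated at truth shrink (or stay) when the sampling
  # grid is refined
  sub <- virtual_subject(median_kin(), median_abs())
  pri <- ipk_priors(c(3.4, 1), c(0.15, 1), c(1.16, 1), c(0.59, 1))
  ctl <- quick_control(meal_varying = FALSE)
  cv_at_truth <- function(interval) {
    ds <- generate_dataset(sub, ipk_model("3C"), cv = 0,
                           sampling_interval = interval)
    fc <- ipkin:::fit_context(ipk_model("3C"), ds, ctl)
    map <- ipkin:::build_map(ipk_model("3C"), 1, ctl, pri)
    vals <- list(VI = 3.4, m1 = 0.15, CL = 1.16, HEb = 0.59, aI = 16e-5,
                 ka1.1 = 0.010, ka2.1 = 0.028)
    ipkin:::fit_precision(vals, map, fc, pri, ctl)$cv
  }
  cv10 <- cv_at_truth(10)
  cv5 <- cv_at_truth(5)
  expect_true(all(cv5 <= cv10 * 1.001))
})

test_that("vcov transforms from log to natural scale by the delta method", {
  sub <- virtual_subject(median_kin(), median_abs())
  ds <- generate_dataset(sub, ipk_model("3C"), seed = 34)
  pri <- ipk_priors(c(3.4, 1), c(0.15, 1), c(1.16, 1), c(0.59, 1))
  fit <- ipk_fit(ds, "3C", pri,
                 quick_control(meal_varying = FALSE,
                               start = list(ka1 = 0.01, ka2 = 0.028,
                                            aI = 16e-5)))
  Vl <- vcov(fit, log = TRUE)
  Vn <- vcov(fit)
  j <- match("ka2.1", colnames(Vl))
  expect_equal(sqrt(Vn[j, j]), fit$estimates[["ka2.1"]] * sqrt(Vl[j, j]),
               tolerance = 1e-10)
  expect_equal(unname(100 * sqrt(Vl[j, j])), unname(fit$cv["ka2.1"]))
})
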