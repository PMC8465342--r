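test_that("a basal-only run started at steady state stays there", {
  kin <- median_kin()
  sim <- ipk_simulate(ipk_model("3C"), median_abs(), kin,
                      infusion_profile(15.625))
  expect_lt(max(abs(sim$Ip / attr(sim, "Ipb") - 1)), 0.001)
  expect_lt(max(abs(sim$RaI - 15.625)), 0.001 * 15.625)
  expect_equal(sim$HE, rep(0.59, nrow(sim)), tolerance = 1e-6)
})

test_that("single-compartment bolus flux matches the closed form", {
  # Model 1, bolus D into an empty IP space, no basal:
  # RaI(t) = ka1 * D * exp(-ka1 t)
  kin <- median_kin(aI = 0)
  D <- 7500
  ka1 <- 0.012
  inf <- infusion_profile(0, bolus_times = 0, bolus_doses = D)
  sim <- ipk_simulate(ipk_model("1A"), absorption_params(ka1 = ka1), kin,
                      inf, horizon = 360, times = seq(0, 360, by = 5))
  expect_equal(sim$RaI, ka1 * D * exp(-ka1 * sim$time), tolerance = 1e-6)
})

test_that("IP mass balance holds to solver accuracy on a 24-h run", {
  kin <- median_kin()
  des <- open_loop_design(0.60, 75)
  infused <- total_dose(des, 1440)
  for (code in c("1C", "2C", "3C")) {
    abs <- if (code == "2C") absorption_params(ka2 = 0.028, kd = 0.05)
           else median_abs()
    sim <- ipk_simulate(ipk_model(code), abs, kin, des)
    n <- nrow(sim)
    ip_t <- sim$Qip1 + ifelse(is.na(sim$Qip2), 0, sim$Qip2)
    bal <- (ip_t[n] - ip_t[1]) + (sim$cumRa[n] - sim$cumRa[1])
    expect_equal(bal / infused, 1, tolerance = 1e-6)
    expect_true(all(sim[, c("Qip1", "Qp", "Ql")] > -1e-9, na.rm = TRUE))
  }
  # trapezoidal audit of the reported RaI trace on a fine grid (square-wave
  # boluses keep RaI continuous, which a quadrature of outputs requires)
  dsq <- open_loop_design(0.60, 75, bolus_duration = 2)
  simf <- ipk_simulate(ipk_model("3C"), median_abs(), kin, dsq,
                       times = seq(0, 1440, by = 0.25))
  tr <- sum(diff(simf$time) * (head(simf$RaI, -1) + tail(simf$RaI, -1)) / 2)
  ip_t <- simf$Qip1 + simf$Qip2
  expect_equal((ip_t[nrow(simf)] - ip_t[1] + tr) / infused, 1,
               tolerance = 1e-6)
})

test_that("the constant-extraction model matches its matrix exponential", {
  kin <- median_kin(aI = 0)
  abs <- median_abs()
  inf_b <- 15.625
  D <- 7500
  inf <- infusion_profile(inf_b, bolus_times = 0, bolus_doses = D)
  times <- seq(0, 360, by = 10)
  sim <- ipk_simulate(ipk_model("3A"), abs, kin, inf, horizon = 360,
                      times = times)
  ss <- basal_steady_state(ipk_model("3A"), abs, kin, inf_b)
  y0 <- unname(ss[c("Qip1", "Qip2", "Qp", "Ql")]) + c(D, 0, 0, 0)
  ref <- lti_solution(times, y0, abs, kin, inf_b, absorption = 3)
  got <- as.matrix(sim[, c("Qip1", "Qip2", "Qp", "Ql")])
  expect_equal(unname(got), unname(ref), tolerance = 1e-6)
})

test_that("variant reductions hold: M3(ka1=0) = M2(kd=ka2); M2(kd large) -> M1", {
  kin <- median_kin()
  des <- open_loop_design(0.60, 75)
  ka2 <- 0.028
  s3 <- ipk_simulate(ipk_model("3C"), absorption_params(ka1 = 0, ka2 = ka2),
                     kin, des)
  s2 <- ipk_simulate(ipk_model("2C"),
                     absorption_params(ka2 = ka2, kd = ka2), kin, des)
  expect_equal(s3$Ip, s2$Ip, tolerance = 1e-7)

  # asymptotic: fast transfer makes the proximal compartment transparent
  s2f <- ipk_simulate(ipk_model("2C"),
                      absorption_params(ka2 = ka2, kd = 100 * ka2), kin, des)
  s1 <- ipk_simulate(ipk_model("1C"), absorption_params(ka1 = ka2), kin, des)
  expect_lt(max(abs(s2f$Ip / s1$Ip - 1)), 0.02)
})

test_that("square-wave boluses conserve dose and approach the impulse limit", {
  kin <- median_kin()
  imp <- open_loop_design(0.60, 75)
  sq <- open_loop_design(0.60, 75, bolus_duration = 1)
  expect_equal(total_dose(sq), total_dose(imp))
  si <- ipk_simulate(ipk_model("3C"), median_abs(), kin, imp)
  ss <- ipk_simulate(ipk_model("3C"), median_abs(), kin, sq)
  n <- nrow(ss)
  expect_equal(ss$cumRa[n], si$cumRa[n], tolerance = 1e-3)
  expect_lt(max(abs(ss$Ip - si$Ip) / max(si$Ip)), 0.05)
})

test_that("hepatic extraction stays in the clamp interval and clamping is reported", {
  kin <- median_kin(aI = 5e-3)  # absurdly strong control forces clamping
  des <- open_loop_design(0.60, 75)
  expect_message(
    sim <- ipk_simulate(ipk_model("3C"), median_abs(), kin, des),
    "clamped")
  expect_true(all(sim$HE >= 0 & sim$HE <= 0.95))
  expect_gt(attr(sim, "he_clamped"), 0)
  # m3 >= 0 follows from HE >= 0
  expect_true(all(sim$HE / (1 - sim$HE) * kin$m1 >= 0))
})

test_that("glucose-driven extraction (variant B) responds to the meal excursions", {
  kin <- median_kin(aI = 0, aG = 1e-3, Gb = 120)
  des <- open_loop_design(0.60, 75)
  glu <- glucose_profile(Gb = 120, amplitudes = 80)
  sim <- ipk_simulate(ipk_model("3B"), median_abs(), kin, des, glucose = glu)
  expect_equal(sim$HE[1], 0.59, tolerance = 1e-9)
  expect_lt(min(sim$HE), 0.59 - 1e-3 * 60)  # HE falls when glucose rises
  expect_error(ipk_simulate(ipk_model("3B"), median_abs(), kin, des),
               "glucose")
})

test_that("simulation output writes the tidy CSV contract", {
  sim <- ipk_simulate(ipk_model("3C"), median_abs(), median_kin(),
                      open_loop_design(0.60, 75))
  f <- tempfile(fileext = ".csv")
  write_sim_csv(sim, f)
  tab <- read.csv(f)
  expect_named(tab, c("time_min", "Qip1", "Qip2", "Qp", "Ql", "Ip_mU_per_L",
                      "RaI_mU_per_min", "HE"))
  expect_equal(tab$Ip_mU_per_L, sim$Ip)
  unlink(f)
})
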