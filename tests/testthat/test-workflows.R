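test_that("the simulation workflow writes the trajectory contract deterministically", {
  cfg <- list(model = "3C",
              kinetics = list(VI = 3.4, m1 = 0.15, CL = 1.16, HEb = 0.59,
                              aI = 16e-5),
              absorption = list(ka1 = 0.010, ka2 = 0.028),
              seed = 4)
  d1 <- tempfile("wf1")
  d2 <- tempfile("wf2")
  out1 <- workflow_simulate(cfg, d1)
  out2 <- workflow_simulate(cfg, d2)
  tab <- read.csv(out1[["trajectory"]])
  expect_named(tab, c("time_min", "Qip1", "Qip2", "Qp", "Ql", "Ip_mU_per_L",
                      "RaI_mU_per_min", "HE"))
  expect_identical(readLines(out1[["trajectory"]]),
                   readLines(out2[["trajectory"]]))
  meta <- jsonlite::read_json(out1[["meta"]])
  expect_equal(meta$seed, 4)
  expect_match(meta$config_md5, "^[0-9a-f]{32}$")
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("config validation names the missing field", {
  expect_error(workflow_simulate(list(model = "3C")), "kinetics")
  cfgB <- list(model = "3B",
               kinetics = list(VI = 3.4, m1 = 0.15, CL = 1.16, HEb = 0.59,
                               aG = 1e-3),
               absorption = list(ka1 = 0.010, ka2 = 0.028))
  expect_error(workflow_simulate(cfgB, tempfile()), "glucose")
})

test_that("a JSON config round-trips through the workflow", {
  cfg <- list(model = "1A",
              kinetics = list(VI = 3.4, m1 = 0.15, CL = 1.16, HEb = 0.59),
              absorption = list(ka1 = 0.012),
              horizon = 360, output_interval = 30)
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, f, auto_unbox = TRUE, digits = NA)
  d <- tempfile("wfjson")
  out <- workflow_simulate(f, d)
  tab <- read.csv(out[["trajectory"]])
  expect_equal(nrow(tab), 13)
  expect_true(all(is.na(tab$Qip2)))
  unlink(c(f, d), recursive = TRUE)
})

test_that("a two-replicate noise-free recovery returns the truth and logs seeds", {
  rec <- suppressWarnings(recovery_experiment(
    n_subjects = 2, seed = 17, cv = 0, prior_decenter = 1,
    control = quick_control(start = list(ka1 = 0.01, ka2 = 0.028,
                                         aI = 16e-5))))
  expect_s3_class(rec, "ipk_recovery")
  expect_lt(max(abs(rec$summary$rel_error)), 0.01)
  expect_length(rec$data_seeds, 2)
  expect_length(rec$fit_seeds, 2)

  d <- tempfile("rec")
  rec2 <- suppressWarnings(workflow_recover(
    list(n_subjects = 2, seed = 17, cv = 0, prior_decenter = 1,
         control = list(n_starts = 1, maxit = 800)), d))
  expect_true(file.exists(file.path(d, "estimates.csv")))
  expect_true(file.exists(file.path(d, "summary.csv")))
  meta <- jsonlite::read_json(file.path(d, "meta.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$seed, 17)
  expect_length(meta$data_seeds, 2)
  expect_true(is.finite(meta$ka1_collapse_fraction))
  unlink(d, recursive = TRUE)
})
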