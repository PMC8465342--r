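published_summary <- data.frame(
  model = c("1A", "2A", "3A", "1B", "2B", "3B", "1C", "2C", "3C"),
  runs_pass = c(7, 7, 6, 8, 8, 8, 8, 7, 8),
  n_subjects = 8,
  precision_pct = c(100, 86, 97, 92, 80, 89, 97, 91, 96),
  median_bic = c(183, 178, 177, 168, 176, 177, 171, 176, 170))

test_that("BIC reduces to WRSS + P log N under known error variance", {
  expect_equal(ipk_bic(100, 96, 0), 100)
  expect_equal(ipk_bic(100, 96, 10), 100 + 10 * log(96))
  expect_equal(ipk_bic(100, 96, 10), 145.64, tolerance = 1e-4)
  # a parameter that buys no fit strictly raises BIC
  expect_gt(ipk_bic(100, 96, 11), ipk_bic(100, 96, 10))
  expect_error(ipk_bic(10, 0, 0), "n")
  expect_error(ipk_bic(10, 5, 5), "p < n")
})

test_that("precision fraction pools parameters across subjects", {
  mk <- function(cvs) structure(list(cv = cvs), class = "ipk_fit")
  fits <- list(mk(rep(50, 48)), mk(c(rep(60, 48), rep(150, 4))))
  expect_equal(precision_fraction(fits), 96)
  expect_equal(precision_fraction(list(mk(c(10, 20)))), 100)
  expect_equal(precision_fraction(list(mk(c(10, Inf)))), 50)
  expect_error(precision_fraction(list(NULL)), "no converged")
})

test_that("the lexicographic filter selects 3C from the published battery summary", {
  sel <- rank_models(published_summary)
  expect_equal(sel$selected, "3C")
  expect_setequal(sel$trace$runs_stage$kept, c("1B", "2B", "3B", "1C", "3C"))
  # precision stage keeps 97% and 96% but drops 92% (tolerance 2 points)
  expect_setequal(sel$trace$precision_stage$kept, c("1C", "3C"))
  expect_true("1B" %in% sel$trace$precision_stage$eliminated)
  # the runner-up loses on BIC 171 vs 170
  expect_equal(sel$trace$bic_stage$eliminated, "1C")
  expect_false(sel$tie)
})

test_that("ranking is invariant to row order and common BIC shifts", {
  set.seed(7)
  for (i in 1:5) {
    shuffled <- published_summary[sample(9), ]
    expect_equal(rank_models(shuffled)$selected, "3C")
  }
  shifted <- published_summary
  shifted$median_bic <- shifted$median_bic + 123.4
  expect_equal(rank_models(shifted)$selected, "3C")
})

test_that("filter dominance and ties behave as documented", {
  tab <- data.frame(model = c("X", "Y", "Z"),
                    runs_pass = c(8, 7, 7),
                    precision_pct = c(50, 100, 100),
                    median_bic = c(500, 100, 90))
  # only X survives stage 1, later stages never see Y/Z
  sel <- rank_models(tab)
  expect_equal(sel$selected, "X")
  expect_setequal(sel$trace$runs_stage$eliminated, c("Y", "Z"))

  tie <- data.frame(model = c("A", "B"), runs_pass = c(8, 8),
                    precision_pct = c(96, 96), median_bic = c(170, 170),
                    P = c(9, 8))
  sel <- rank_models(tie)
  expect_true(sel$tie)
  expect_equal(sel$selected, "B")  # fewer parameters wins the tie
  expect_error(rank_models(published_summary[0, ]), "empty")
})

test_that("between-meal comparison: identical values give p = 1, shifts are detected", {
  same <- expand.grid(subject = 1:8, meal = 1:3)
  same$parameter <- "ka2"
  same$value <- 0.028
  res <- compare_meals(same)
  expect_equal(res$p_value, 1)
  expect_false(res$significant)

  # under the true null the Kruskal-Wallis rejection rate is ~ alpha
  set.seed(11)
  rej <- vapply(1:200, function(i) {
    d <- expand.grid(subject = 1:8, meal = 1:3)
    d$parameter <- "ka2"
    d$value <- rlnorm(24, log(0.028), 0.4)
    compare_meals(d)$significant
  }, TRUE)
  expect_gt(mean(rej), 0.005)
  expect_lt(mean(rej), 0.10)

  # a five-fold shift of one meal in all subjects is caught most of the time
  set.seed(12)
  rej5 <- vapply(1:50, function(i) {
    d <- expand.grid(subject = 1:8, meal = 1:3)
    d$parameter <- "ka2"
    d$value <- rlnorm(24, log(0.028), 0.3) * ifelse(d$meal == 2, 5, 1)
    compare_meals(d)$significant
  }, TRUE)
  expect_gt(mean(rej5), 0.8)

  pw <- compare_meals(same, pairwise = TRUE)
  expect_equal(nrow(attr(pw, "pairwise")), 3)
  expect_error(compare_meals(same[same$subject < 3, ]), "three subjects")
})

test_that("markdown rendering mirrors the report columns", {
  lines <- report_markdown(published_summary)
  expect_length(lines, 11)
  expect_match(lines[11], "3C \\| 8/8 \\| 96% \\| 170")
})
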