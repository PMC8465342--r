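#' Bayesian Information Criterion under known-variance Gaussian error
#'
#' With the measurement SDs known, `-2 log L = WRSS` up to a data-only
#' constant that is shared by all models fitted to the same data, so the
#' criterion reduces to `BIC = WRSS + P * log(N)` and the constant is
#' dropped.
#'
#' @param wrss weighted residual sum of squares.
#' @param n number of data points (> 0).
#' @param p number of free parameters (0 <= p < n).
#' @return the BIC value.
#' @examples
#' ipk_bic(100, 96, 10)  # 145.64
#' @export
ipk_bic <- function(wrss, n, p) {
  if (n <= 0) stop("n must be > 0", call. = FALSE)
  if (p < 0 || p >= n) stop("need 0 <= p < n", call. = FALSE)
  wrss + p * log(n)
}

#' Fraction of parameters estimated with CV below 100%
#'
#' Pools all estimated parameters across a list of fits (of the same model
#' to different subjects) and returns the percentage with CV below 100%.
#' Collapsed parameters are excluded from both counts; infinite CVs count
#' as imprecise.
#'
#' @param fits list of `"ipk_fit"` objects (failed fits, stored as `NULL`
#'   or error conditions, are skipped).
#' @return percentage in `[0, 100]`.
#' @export
precision_fraction <- function(fits) {
  cvs <- unlist(lapply(fits, function(f)
    if (inherits(f, "ipk_fit")) f$cv else NULL))
  if (!length(cvs)) stop("no converged fits", call. = FALSE)
  100 * sum(cvs < 100) / length(cvs)
}

#' Fit the nine-model battery across subjects
#'
#' Fits every model of the battery (or a subset) to each subject's dataset
#' and computes the assessment quantities: runs test on the weighted
#' residuals, parameter CVs and BIC. Individual fit failures are recorded
#' per cell, not dropped.
#'
#' @param datasets list of `"ipk_dataset"` objects, one per subject.
#' @param priors an [ipk_priors()].
#' @param control an [ipk_control()]; its `seed` (plus offsets) makes the
#'   battery deterministic.
#' @param models list of [ipk_model()]s; default all nine.
#' @return An object of class `"ipk_battery"`: a model x subject list of
#'   fits (or error conditions) plus the inputs.
#' @seealso [selection_report()], [rank_models()]
#' @export
run_battery <- function(datasets, priors = ipk_priors(),
                        control = ipk_control(),
                        models = ipk_battery_models()) {
  stopifnot(length(datasets) >= 1)
  if (inherits(models, "ipk_model")) models <- list(models)
  if (is.null(names(models)))
    names(models) <- vapply(models, format, "")
  base_seed <- control$seed %||% 1L
  fits <- lapply(names(models), function(mc) {
    lapply(seq_along(datasets), function(s) {
      ctl <- control
      ctl$seed <- (base_seed + 7919L * match(mc, names(models)) +
                     104729L * s) %% .Machine$integer.max
      tryCatch(ipk_fit(datasets[[s]], models[[mc]], priors, ctl),
               error = function(e) e)
    })
  })
  names(fits) <- names(models)
  structure(list(fits = fits, models = models, n_subjects = length(datasets)),
            class = "ipk_battery")
}

#' @export
print.ipk_battery <- function(x, ...) {
  cat("IP model battery:", length(x$models), "models x", x$n_subjects,
      "subjects\n")
  print(selection_report(x))
  invisible(x)
}

#' Assessment summary of a battery
#'
#' One row per model: subjects passing the runs test, percentage of
#' parameters estimated with CV < 100% (pooled over subjects), and the
#' median BIC — the three columns of the selection protocol.
#'
#' @param battery an `"ipk_battery"`.
#' @param alpha runs-test level.
#' @return data frame with columns `model`, `runs_pass`, `n_subjects`,
#'   `precision_pct`, `median_bic`, `n_failed`.
#' @export
selection_report <- function(battery, alpha = 0.05) {
  rows <- lapply(names(battery$fits), function(mc) {
    fl <- battery$fits[[mc]]
    ok <- vapply(fl, inherits, TRUE, "ipk_fit")
    data.frame(model = mc,
               runs_pass = sum(vapply(fl[ok], function(f)
                 f$runs$p >= alpha, TRUE)),
               n_subjects = battery$n_subjects,
               precision_pct = if (any(ok)) precision_fraction(fl[ok])
                               else NA_real_,
               median_bic = if (any(ok)) median(vapply(fl[ok], `[[`, 0,
                                                       "bic"))
                            else NA_real_,
               n_failed = sum(!ok))
  })
  do.call(rbind, rows)
}

#' Select a model from assessment summaries
#'
#' The lexicographic selection protocol: (1) keep the models with the
#' maximal number of subjects passing the runs test; (2) among those, keep
#' the models within `precision_tol` percentage points of the best
#' parameter-precision fraction; (3) among the survivors, pick the lowest
#' median BIC. Ties on BIC are broken toward fewer free parameters when a
#' `P` column is supplied, and reported as ties in the trace otherwise.
#'
#' @param report a data frame with columns `model`, `runs_pass`,
#'   `precision_pct`, `median_bic` (e.g. from [selection_report()]),
#'   optionally `P`.
#' @param precision_tol stage-2 tolerance in percentage points (default 2).
#' @return list with `selected` (model code), `trace` (per-stage survivor
#'   sets) and `tie` (logical).
#' @examples
#' # the published summary of the battery on the eight-patient study
#' tab <- data.frame(
#'   model = c("1A","2A","3A","1B","2B","3B","1C","2C","3C"),
#'   runs_pass = c(7,7,6,8,8,8,8,7,8),
#'   precision_pct = c(100,86,97,92,80,89,97,91,96),
#'   median_bic = c(183,178,177,168,176,177,171,176,170))
#' rank_models(tab)$selected  # "3C"
#' @export
rank_models <- function(report, precision_tol = 2) {
  if (!nrow(report)) stop("empty report", call. = FALSE)
  trace <- list()
  s1 <- report[report$runs_pass == max(report$runs_pass), , drop = FALSE]
  trace$runs_stage <- list(kept = s1$model,
                           eliminated = setdiff(report$model, s1$model))
  s2 <- s1[s1$precision_pct >= max(s1$precision_pct) - precision_tol, ,
           drop = FALSE]
  trace$precision_stage <- list(kept = s2$model,
                                eliminated = setdiff(s1$model, s2$model))
  s3 <- s2[s2$median_bic == min(s2$median_bic), , drop = FALSE]
  trace$bic_stage <- list(kept = s3$model,
                          eliminated = setdiff(s2$model, s3$model))
  tie <- nrow(s3) > 1
  if (tie && !is.null(s3$P)) s3 <- s3[order(s3$P), , drop = FALSE]
  list(selected = s3$model[1], trace = trace, tie = tie)
}

#' Between-meal comparison of absorption parameters
#'
#' Kruskal-Wallis test of the per-meal absorption parameter estimates
#' across meal periods (one group per meal, subjects as observations),
#' optionally followed by paired Wilcoxon signed-rank tests for the meal
#' pairs.
#'
#' @param estimates a data frame with columns `subject`, `meal`,
#'   `parameter`, `value` (long format), or a matrix subjects x meals for a
#'   single parameter.
#' @param alpha significance level.
#' @param pairwise also run paired two-sample Wilcoxon signed-rank tests.
#' @return data frame with one row per parameter: `parameter`, `p_value`,
#'   `significant`; pairwise results attached as attribute `"pairwise"`.
#' @export
compare_meals <- function(estimates, alpha = 0.05, pairwise = FALSE) {
  if (is.matrix(estimates)) {
    estimates <- data.frame(
      subject = rep(seq_len(nrow(estimates)), ncol(estimates)),
      meal = rep(seq_len(ncol(estimates)), each = nrow(estimates)),
      parameter = "value", value = as.vector(estimates))
  }
  if (length(unique(estimates$meal)) < 2)
    stop("need at least two meal groups", call. = FALSE)
  if (length(unique(estimates$subject)) < 3)
    stop("need at least three subjects", call. = FALSE)
  res <- do.call(rbind, lapply(split(estimates, estimates$parameter),
    function(d) {
      if (length(unique(d$value)) == 1)
        return(data.frame(parameter = d$parameter[1], p_value = 1,
                          significant = FALSE))
      kw <- kruskal.test(d$value, factor(d$meal))
      data.frame(parameter = d$parameter[1], p_value = kw$p.value,
                 significant = kw$p.value < alpha)
    }))
  rownames(res) <- NULL
  if (pairwise) {
    pw <- do.call(rbind, lapply(split(estimates, estimates$parameter),
      function(d) {
        meals <- sort(unique(d$meal))
        cmb <- utils::combn(meals, 2)
        do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
          a <- d[d$meal == cmb[1, j], ]
          b <- d[d$meal == cmb[2, j], ]
          b <- b[match(a$subject, b$subject), ]
          p <- if (all(a$value == b$value)) 1 else
            suppressWarnings(wilcox.test(a$value, b$value,
                                         paired = TRUE)$p.value)
          data.frame(parameter = d$parameter[1], meal_a = cmb[1, j],
                     meal_b = cmb[2, j], p_value = p)
        }))
      }))
    rownames(pw) <- NULL
    attr(res, "pairwise") <- pw
  }
  res
}

#' Render a selection report as a Markdown table
#'
#' @param report data frame from [selection_report()].
#' @param file optional path; when given the table is written there.
#' @return the Markdown lines, invisibly when written to file.
#' @export
report_markdown <- function(report, file = NULL) {
  hdr <- paste("| Model | Residual independence | Parameters with CV < 100%",
               "| Median BIC |")
  sep <- "|---|---|---|---|"
  rows <- sprintf("| %s | %d/%d | %.0f%% | %.0f |", report$model,
                  report$runs_pass, report$n_subjects,
                  report$precision_pct, report$median_bic)
  lines <- c(hdr, sep, rows)
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
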