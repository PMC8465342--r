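#' @export
print.ipk_fit <- function(x, ...) {
  cat("MAP fit of IP insulin model ", format(x$model), "\n",
      "  N = ", x$N, " samples, P = ", x$P, " free parameters\n",
      "  WRSS = ", signif(x$wrss, 5), ", BIC = ", signif(x$bic, 5), "\n",
      sep = "")
  print(signif(x$estimates, 4))
  invisible(x)
}

#' Summarise a MAP fit
#'
#' Estimates with their CVs, the collapse flags, WRSS, BIC and the runs
#' test on the weighted residuals.
#'
#' @param object an `"ipk_fit"`.
#' @param ... unused.
#' @return An object of class `"summary.ipk_fit"` with a `coefficients`
#'   table (estimate, CV%, precise flag).
#' @export
summary.ipk_fit <- function(object, ...) {
  est <- object$estimates
  cv <- object$cv[match(names(est), names(object$cv))]
  tab <- data.frame(estimate = est, cv_pct = cv,
                    precise = ifelse(is.na(cv), NA, cv < 100),
                    row.names = names(est))
  structure(list(model = object$model, coefficients = tab,
                 wrss = object$wrss, bic = object$bic, N = object$N,
                 P = object$P, runs = object$runs,
                 collapse = object$collapse,
                 cv_includes_prior = object$cv_includes_prior,
                 convergence = object$convergence),
            class = "summary.ipk_fit")
}

#' @export
print.summary.ipk_fit <- function(x, ...) {
  cat("MAP fit of IP insulin model ", format(x$model), "\n\n", sep = "")
  tab <- x$coefficients
  tab$estimate <- signif(tab$estimate, 4)
  tab$cv_pct <- round(tab$cv_pct, 1)
  print(tab)
  cat("\nWRSS ", signif(x$wrss, 5), ", BIC ", signif(x$bic, 5),
      " (N = ", x$N, ", P = ", x$P, ")\n", sep = "")
  cat("Runs test on weighted residuals: p = ", signif(x$runs$p, 3),
      if (x$runs$pass) " (residuals consistent with randomness)"
      else " (residual randomness rejected)", "\n", sep = "")
  if (any(x$collapse$ka1_zero))
    cat("ka1 collapsed to 0 in meal period(s): ",
        paste(which(x$collapse$ka1_zero), collapse = ", "), "\n", sep = "")
  if (any(x$collapse$kd_tie))
    cat("kd tied to ka2 in meal period(s): ",
        paste(which(x$collapse$kd_tie), collapse = ", "), "\n", sep = "")
  cat("CVs ", if (!x$cv_includes_prior) "do not ",
      "include the prior precision\n", sep = "")
  invisible(x)
}

#' @export
coef.ipk_fit <- function(object, ...) object$estimates

#' Posterior covariance of the estimates
#'
#' @param object an `"ipk_fit"`.
#' @param log return the covariance in log-parameter coordinates (the
#'   native scale of the information matrix); otherwise the delta-method
#'   natural-scale covariance.
#' @param ... unused.
#' @return covariance matrix over the free parameters, or `NULL` when the
#'   information matrix was singular.
#' @export
vcov.ipk_fit <- function(object, log = FALSE, ...) {
  V <- object$vcov_log
  if (is.null(V) || log) return(V)
  est <- object$estimates[colnames(V)]
  D <- diag(est, nrow = length(est))
  structure(D %*% V %*% D, dimnames = dimnames(V))
}

#' @export
fitted.ipk_fit <- function(object, ...) object$fitted

#' Residuals of a MAP fit
#'
#' @param object an `"ipk_fit"`.
#' @param type `"weighted"` (default; `(y - yhat)/SD`) or `"response"`
#'   (mU/L).
#' @param ... unused.
#' @export
residuals.ipk_fit <- function(object, type = c("weighted", "response"),
                              ...) {
  type <- match.arg(type)
  if (type == "weighted") object$residuals
  else object$residuals * object$dataset$sd
}

#' Predict plasma insulin from a MAP fit
#'
#' Simulates the fitted model at new output times (same infusion design and
#' glucose input as the fitted dataset).
#'
#' @param object an `"ipk_fit"`.
#' @param times output grid (min); default the dataset's sample times.
#' @param ... unused.
#' @return data frame `time`, `Ip` (and the full `"ipk_sim"` columns).
#' @export
predict.ipk_fit <- function(object, times = NULL, ...) {
  ds <- object$dataset
  if (is.null(times)) return(data.frame(time = ds$time, Ip = object$fitted))
  pars <- values_to_params(object$values, object$model, object$n_sets,
                           object$control$m2, object$fc$Gb)
  glucose <- if (object$model$he == "B") cbind(ds$time, ds$glucose)
  ipk_simulate(object$model, pars$abs, pars$kin, attr(ds, "infusion"),
               glucose = glucose, horizon = max(c(times, ds$time)),
               times = times, meal_times = attr(ds, "meal_times"),
               he_clamp = object$control$he_clamp, quiet = TRUE)
}

#' Plot a MAP fit
#'
#' Data with error bars and the model prediction (top), weighted residuals
#' with the `[-1, 1]` band (bottom).
#'
#' @param x an `"ipk_fit"`.
#' @param ... passed to the top panel's `plot`.
#' @export
plot.ipk_fit <- function(x, ...) {
  ds <- x$dataset
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1) + 0.1)
  on.exit(graphics::par(old))
  fine <- predict(x, times = seq(0, max(ds$time), by = 2))
  graphics::plot(ds$time, ds$insulin, pch = 16, cex = 0.6,
                 xlab = "time (min)", ylab = "plasma insulin (mU/L)", ...)
  graphics::arrows(ds$time, ds$insulin - ds$sd, ds$time, ds$insulin + ds$sd,
                   angle = 90, code = 3, length = 0.02,
                   col = grDevices::grey(0.6))
  graphics::lines(fine$time, fine$Ip, col = 2, lwd = 2)
  graphics::plot(ds$time, x$residuals, pch = 16, cex = 0.6,
                 xlab = "time (min)", ylab = "weighted residual")
  graphics::abline(h = 0, lty = 2)
  graphics::abline(h = c(-1, 1), lty = 3)
  invisible(x)
}

#' Simulate replicate datasets from a fitted model
#'
#' Parametric-bootstrap style: regenerates noisy datasets from the fitted
#' parameter values under the fitted error SDs.
#'
#' @param object an `"ipk_fit"`.
#' @param nsim number of replicate datasets.
#' @param seed RNG seed.
#' @param ... unused.
#' @return list of `"ipk_dataset"` objects.
#' @export
simulate.ipk_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  ds <- object$dataset
  lapply(seq_len(nsim), function(i) {
    y <- object$fitted + rnorm(object$N, 0, ds$sd)
    trunc <- which(y < 0)
    y[trunc] <- 0
    out <- ds
    out$insulin <- y
    attr(out, "truncated") <- trunc
    out
  })
}

#' Serialize a fit to JSON
#'
#' Estimates, CVs, WRSS/BIC, collapse flags and convergence metadata in a
#' plain JSON object (predictions/residuals go to CSV via
#' [write_fit_csv()]).
#'
#' @param fit an `"ipk_fit"`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_fit_json <- function(fit, file) {
  obj <- list(model = format(fit$model),
              estimates = as.list(fit$estimates),
              cv_pct = as.list(fit$cv),
              wrss = fit$wrss, bic = fit$bic, N = fit$N, P = fit$P,
              runs_test = list(p = fit$runs$p, pass = fit$runs$pass),
              collapse = fit$collapse,
              cv_includes_prior = fit$cv_includes_prior,
              convergence = fit$convergence)
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(file)
}

#' @rdname write_fit_json
#' @export
write_fit_csv <- function(fit, file) {
  write.csv(data.frame(time_min = fit$dataset$time,
                       insulin_mU_per_L = fit$dataset$insulin,
                       sd_mU_per_L = fit$dataset$sd,
                       predicted_mU_per_L = fit$fitted,
                       weighted_residual = fit$residuals),
            file, row.names = FALSE)
  invisible(file)
}
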