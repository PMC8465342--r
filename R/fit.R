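#' Log-normal priors on the whole-body kinetics parameters
#'
#' MAP estimation uses a priori information on the whole-body insulin
#' kinetics parameters `VI`, `m1`, `CL` and `HEb` (each a log-normal prior
#' given as median and CV); the IP absorption parameters and the
#' extraction-control gains `aG`/`aI` get flat, positivity-constrained
#' priors. Setting an entry to `NULL` makes that parameter's prior flat too.
#'
#' Defaults centre on the package's population values with 100% CV; a
#' recovery experiment that should not be handed the answer can de-centre
#' them (see [recovery_experiment()]).
#'
#' @param VI,m1,CL,HEb each `c(median, cv)` or `NULL` (flat).
#' @return An object of class `"ipk_priors"`.
#' @examples
#' ipk_priors(VI = c(5.1, 1), m1 = c(0.22, 1))
#' @export
ipk_priors <- function(VI = c(3.4, 1), m1 = c(0.15, 1),
                       CL = c(1.16, 1), HEb = c(0.59, 1)) {
  pr <- list(VI = VI, m1 = m1, CL = CL, HEb = HEb)
  pr <- pr[!vapply(pr, is.null, TRUE)]
  for (nm in names(pr)) {
    v <- pr[[nm]]
    if (length(v) != 2 || any(!is.finite(v)) || any(v <= 0))
      stop("prior for ", nm, " must be c(median, cv), both > 0",
           call. = FALSE)
    pr[[nm]] <- list(median = v[1], cv = v[2],
                     sdlog = sqrt(log(1 + v[2]^2)))
  }
  structure(pr, class = "ipk_priors")
}

#' Fitting configuration
#'
#' Bundles every tunable of the MAP fit. `m2`, the fractional hepatic plasma
#' flow, is fixed (not estimated) to make the battery a priori identifiable.
#' The two post-hoc simplification rules are controlled by `kd_tie_tol`
#' (absorption variant 2: set `kd = ka2` when their absolute relative
#' difference is below it) and `ka1_floor` (variant 3: set `ka1 = 0` when it
#' is estimated below the floor); when a rule triggers, the reduced model is
#' refitted.
#'
#' @param m2 fixed fractional rate of hepatic plasma flow (1/min).
#' @param meal_varying estimate one absorption-parameter set per meal
#'   period (default) or a single shared set.
#' @param he_clamp allowed hepatic-extraction interval.
#' @param kd_tie_tol relative-difference threshold of simplification rule
#'   (i) (default 1%).
#' @param ka1_floor absolute threshold of simplification rule (ii)
#'   (default 1e-3 1/min).
#' @param n_starts number of optimizer starts (first at the prior centres /
#'   default starts, the rest jittered).
#' @param start_jitter SD of the log-space jitter of the extra starts.
#' @param maxit,reltol Nelder-Mead iteration cap and relative convergence
#'   tolerance per start.
#' @param polish finish with a quasi-Newton (BFGS) stage from the best
#'   point: the posterior has flat ridges along correlated kinetics
#'   parameters where Nelder-Mead terminates early.
#' @param polish_maxit iteration cap of the polish stage.
#' @param fd_step relative step of the central finite differences used for
#'   the posterior information matrix.
#' @param include_prior_in_cv include the prior precision in the
#'   information matrix when computing parameter CVs (reported in the fit's
#'   metadata).
#' @param seed seed for the jittered starts.
#' @param rtol,atol ODE solver tolerances.
#' @param start named list of starting values for the flat-prior parameters
#'   (`ka1`, `ka2`, `delta` with `kd = ka2 * (1 + delta)`, `aG`, `aI`) and
#'   fallback starts for kinetics parameters without priors.
#' @param fix named numeric vector of parameters to hold fixed at the given
#'   values (full names, e.g. `c(VI = 3.4, "ka2.1" = 0.028)`).
#' @return An object of class `"ipk_control"`.
#' @export
ipk_control <- function(m2 = 0.268, meal_varying = TRUE,
                        he_clamp = c(0, 0.95), kd_tie_tol = 0.01,
                        ka1_floor = 1e-3, n_starts = 5, start_jitter = 0.5,
                        maxit = 1500, reltol = 1e-8, polish = TRUE,
                        polish_maxit = 150,
                        fd_step = 1e-4, include_prior_in_cv = TRUE,
                        seed = NULL, rtol = 1e-8, atol = 1e-10,
                        start = list(), fix = NULL) {
  start <- modifyList(list(ka1 = 0.01, ka2 = 0.02, delta = 1,
                           aG = 1e-3, aI = 1e-4,
                           VI = 3.4, m1 = 0.15, CL = 1.16, HEb = 0.5),
                      start)
  structure(list(m2 = m2, meal_varying = meal_varying, he_clamp = he_clamp,
                 kd_tie_tol = kd_tie_tol, ka1_floor = ka1_floor,
                 n_starts = n_starts, start_jitter = start_jitter,
                 maxit = maxit, reltol = reltol, polish = polish,
                 polish_maxit = polish_maxit, fd_step = fd_step,
                 include_prior_in_cv = include_prior_in_cv, seed = seed,
                 rtol = rtol, atol = atol, start = start, fix = fix),
            class = "ipk_control")
}

# ---- parameter mapping ----------------------------------------------------

# Full natural-parameter name set for a model with n_sets absorption sets.
param_names_for <- function(model, n_sets) {
  kin <- c("VI", "m1", "CL", "HEb",
           if (model$he == "B") "aG", if (model$he == "C") "aI")
  abs <- unlist(lapply(seq_len(n_sets), function(p) paste0(
    switch(model$absorption, "ka1", c("ka2", "delta"), c("ka1", "ka2")),
    ".", p)))
  c(kin, abs)
}

base_name <- function(nm) sub("\\.[0-9]+$", "", nm)

# Build the free-parameter map. `collapse` is a list with logical vectors
# ka1_zero and kd_tie (one entry per set).
build_map <- function(model, n_sets, control, priors, collapse = NULL) {
  all_names <- param_names_for(model, n_sets)
  fixed <- list()
  if (!is.null(control$fix))
    for (nm in names(control$fix)) fixed[[nm]] <- unname(control$fix[nm])
  if (!is.null(collapse)) {
    for (p in which(collapse$ka1_zero)) fixed[[paste0("ka1.", p)]] <- 0
    for (p in which(collapse$kd_tie))  fixed[[paste0("delta.", p)]] <- 0
  }
  free <- setdiff(all_names, names(fixed))
  kinds <- ifelse(free == "HEb", "logit", "log")
  starts <- vapply(free, function(nm) {
    bn <- base_name(nm)
    if (bn %in% names(priors)) priors[[bn]]$median else control$start[[bn]]
  }, 0)
  theta0 <- log(starts)
  theta0[kinds == "logit"] <- stats::qlogis(starts[kinds == "logit"])
  list(model = model, n_sets = n_sets, free = free, kinds = kinds,
       fixed = fixed, theta0 = unname(theta0), all_names = all_names)
}

theta_to_values <- function(map, theta) {
  vals <- map$fixed
  for (j in seq_along(map$free)) {
    vals[[map$free[j]]] <- if (map$kinds[j] == "logit")
      stats::plogis(theta[j]) else exp(theta[j])
  }
  vals
}

# Natural values -> (kin, abs_list); `values` must contain the full name set.
values_to_params <- function(values, model, n_sets, m2, Gb = NA_real_,
                             validate = FALSE) {
  kin <- list(VI = values$VI, m1 = values$m1, CL = values$CL,
              HEb = values$HEb, m2 = m2,
              aG = values$aG %||% 0, aI = values$aI %||% 0, Gb = Gb)
  class(kin) <- "ipk_kin"
  if (validate)
    kin <- kinetics_params(values$VI, values$m1, values$CL, values$HEb, m2,
                           values$aG %||% 0, values$aI %||% 0, Gb)
  abs_list <- lapply(seq_len(n_sets), function(p) {
    a <- switch(model$absorption,
      list(ka1 = values[[paste0("ka1.", p)]], ka2 = NA_real_, kd = NA_real_),
      {
        ka2 <- values[[paste0("ka2.", p)]]
        list(ka1 = NA_real_, ka2 = ka2,
             kd = ka2 * (1 + values[[paste0("delta.", p)]]))
      },
      list(ka1 = values[[paste0("ka1.", p)]],
           ka2 = values[[paste0("ka2.", p)]], kd = NA_real_))
    class(a) <- "ipk_abs"
    a
  })
  list(kin = kin, abs = abs_list)
}

prior_penalty <- function(values, priors) {
  pen <- 0
  for (nm in names(priors))
    if (!is.null(values[[nm]]))
      pen <- pen + (log(values[[nm]]) - log(priors[[nm]]$median))^2 /
        (2 * priors[[nm]]$sdlog^2)
  pen
}

# ---- objective ------------------------------------------------------------

#' Negative log-posterior of an IP insulin model on a dataset
#'
#' Returns the MAP objective as a function of a *named list/vector of
#' natural parameter values*: half the weighted residual sum of squares
#' under the known-SD Gaussian error model plus the log-normal prior
#' penalties, `0.5 * sum(((y - yhat)/SD)^2) + sum((log th - log median)^2 /
#' (2 sdlog^2))`. Exposed mainly for diagnostics and brute-force checks of
#' the optimizer; [ipk_fit()] minimises this same quantity.
#'
#' Parameter names follow the fit's convention: `VI`, `m1`, `CL`, `HEb`,
#' `aG`/`aI`, and per-meal-period absorption entries `ka1.1`, `ka2.1`,
#' `delta.1` (variant 2 uses `kd = ka2 * (1 + delta)`), ... Values missing
#' from the argument fall back to `control$fix`.
#'
#' @param model an [ipk_model()].
#' @param dataset an `"ipk_dataset"`.
#' @param priors an [ipk_priors()] (use `ipk_priors(NULL, NULL, NULL, NULL)`
#'   for a pure weighted-least-squares objective).
#' @param control an [ipk_control()].
#' @return A function `f(values) -> scalar`.
#' @examples
#' \donttest{
#' kin <- kinetics_params(VI = 3.4, m1 = 0.15, CL = 1.16, HEb = 0.59,
#'                        aI = 16e-5)
#' sub <- virtual_subject(kin, absorption_params(ka1 = 0.01, ka2 = 0.028))
#' ds <- generate_dataset(sub, ipk_model("3C"), cv = 0, seed = 1)
#' f <- map_objective(ipk_model("3C"), ds,
#'                    priors = ipk_priors(NULL, NULL, NULL, NULL),
#'                    control = ipk_control(meal_varying = FALSE))
#' f(list(VI = 3.4, m1 = 0.15, CL = 1.16, HEb = 0.59, aI = 16e-5,
#'        ka1.1 = 0.01, ka2.1 = 0.028))  # 0: truth on noise-free data
#' }
#' @export
map_objective <- function(model, dataset, priors = ipk_priors(),
                          control = ipk_control()) {
  fc <- fit_context(model, dataset, control)
  function(values) {
    values <- as.list(values)
    vals <- modifyList(as.list(control$fix %||% list()), values)
    nlp_values(vals, fc, priors, control)
  }
}

# Static pieces shared by every objective evaluation on one dataset.
fit_context <- function(model, dataset, control) {
  meal_times <- attr(dataset, "meal_times") %||% numeric()
  infusion <- attr(dataset, "infusion")
  if (is.null(infusion))
    stop("dataset carries no infusion profile", call. = FALSE)
  horizon <- max(dataset$time)
  n_periods <- length(period_breaks(meal_times, horizon)) + 1L
  glucose <- NULL
  Gb <- NA_real_
  if (model$he == "B") {
    if (is.null(dataset$glucose) || anyNA(dataset$glucose))
      stop("HE variant B needs a glucose trace in the dataset (column ",
           "`glucose`)", call. = FALSE)
    glucose <- cbind(dataset$time, dataset$glucose)
    Gb <- dataset$glucose[1]
  }
  ctx <- make_sim_context(model, infusion, glucose, horizon,
                          times = dataset$time, meal_times = meal_times,
                          he_clamp = control$he_clamp,
                          rtol = control$rtol, atol = control$atol)
  list(model = model, ctx = ctx, dataset = dataset, Gb = Gb,
       n_periods = n_periods,
       n_sets = if (control$meal_varying) n_periods else 1L)
}

# Objective at a full named value list (infeasible sets get a large finite
# penalty so derivative-free optimizers survive excursions).
nlp_values <- function(vals, fc, priors, control) {
  # plausibility guards: excursions far outside the physical range are
  # penalised without invoking the solver (rate constants above 5/min or
  # volumes outside [0.1, 500] L would only stall the integrator)
  excess <- 0
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.finite(v)) return(1e10)
    hi <- switch(base_name(nm), VI = 500, m1 = 10, CL = 100, HEb = 1,
                 aG = 1, aI = 1, 5)
    lo <- if (base_name(nm) == "VI") 0.1 else 0
    if (v > hi) excess <- excess + log1p(v - hi)
    if (v < lo) excess <- excess + log1p(lo - v)
  }
  if (excess > 0) return(1e8 * (1 + excess))
  m4v <- vals$CL / vals$VI - vals$HEb * control$m2
  if (!is.finite(m4v) || m4v <= 0)
    return(1e10 * (1 + max(0, -m4v)))
  pars <- values_to_params(vals, fc$model, fc$n_sets, control$m2, fc$Gb)
  sim <- try(sim_core(fc$ctx, pars$abs, pars$kin), silent = TRUE)
  if (inherits(sim, "try-error")) {
    warning("simulation failed during estimation; penalised",
            call. = FALSE)
    return(1e10)
  }
  Ip <- sim[, "Qp"] / vals$VI
  0.5 * sum(((fc$dataset$insulin - Ip) / fc$dataset$sd)^2) +
    prior_penalty(vals, priors)
}

predicted_Ip <- function(vals, fc, control) {
  pars <- values_to_params(vals, fc$model, fc$n_sets, control$m2, fc$Gb)
  sim <- sim_core(fc$ctx, pars$abs, pars$kin)
  sim[, "Qp"] / vals$VI
}

#' Weighted residuals
#'
#' Elementwise `(data - model prediction) / SD`, the standardised residuals
#' of the known-SD Gaussian error model.
#'
#' @param dataset an `"ipk_dataset"` (or any data frame with `insulin` and
#'   `sd` columns).
#' @param prediction predicted plasma insulin at the dataset's sample times.
#' @return numeric residual series, one per sample.
#' @examples
#' weighted_residuals(data.frame(insulin = 53, sd = 3), 50)  # 1
#' @export
weighted_residuals <- function(dataset, prediction) {
  if (length(prediction) != nrow(dataset))
    stop("prediction and dataset lengths differ", call. = FALSE)
  if (any(dataset$sd <= 0)) stop("zero or negative SD", call. = FALSE)
  (dataset$insulin - prediction) / dataset$sd
}

# ---- fitting --------------------------------------------------------------

run_starts <- function(obj, map, control) {
  n <- length(map$theta0)
  starts <- list(map$theta0)
  if (control$n_starts > 1) {
    for (s in seq_len(control$n_starts - 1))
      starts[[s + 1]] <- map$theta0 + rnorm(n, 0, control$start_jitter)
  }
  best <- NULL
  evals <- 0L
  for (th0 in starts) {
    o <- optim(th0, obj, method = if (n > 1) "Nelder-Mead" else "Brent",
               lower = if (n == 1) th0 - 10 else -Inf,
               upper = if (n == 1) th0 + 10 else Inf,
               control = if (n > 1)
                 list(maxit = control$maxit, reltol = control$reltol)
               else list())
    evals <- evals + o$counts[1]
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (control$polish && n > 1) {
    # alternating quasi-Newton / simplex polish: the posterior has long
    # flat ridges along correlated kinetics parameters where either
    # method alone can terminate early
    for (cycle in 1:3) {
      v0 <- best$value
      o <- try(optim(best$par, obj, method = "BFGS",
                     control = list(maxit = control$polish_maxit,
                                    reltol = control$reltol)),
               silent = TRUE)
      if (!inherits(o, "try-error")) {
        evals <- evals + o$counts[1] + (2 * n + 1) * o$counts[2]
        if (o$value < best$value) best <- o
      }
      o <- optim(best$par, obj, method = "Nelder-Mead",
                 control = list(maxit = control$maxit,
                                reltol = control$reltol))
      evals <- evals + o$counts[1]
      if (o$value < best$value) best <- o
      if (v0 - best$value < 1e-5) break
    }
  }
  best$evals <- evals
  best
}

# Apply the two simplification rules to the current estimates; returns an
# updated collapse list or NULL when nothing new triggered.
check_simplification <- function(values, model, n_sets, collapse, control) {
  changed <- FALSE
  for (p in seq_len(n_sets)) {
    if (model$absorption == 3 && !collapse$ka1_zero[p]) {
      if (values[[paste0("ka1.", p)]] < control$ka1_floor) {
        collapse$ka1_zero[p] <- TRUE
        changed <- TRUE
      }
    }
    if (model$absorption == 2 && !collapse$kd_tie[p]) {
      ka2 <- values[[paste0("ka2.", p)]]
      kd <- ka2 * (1 + values[[paste0("delta.", p)]])
      if (abs(kd - ka2) / ka2 < control$kd_tie_tol) {
        collapse$kd_tie[p] <- TRUE
        changed <- TRUE
      }
    }
  }
  if (changed) collapse else NULL
}

#' Fit an IP insulin model by MAP estimation
#'
#' Maximum a posteriori estimation of one of the nine battery models on a
#' plasma-insulin dataset: the negative log-posterior (weighted least
#' squares under the known-SD Gaussian error model plus log-normal prior
#' penalties on `VI`, `m1`, `CL`, `HEb`) is minimised in log-parameter space
#' (logit for `HEb`; variant 2 enforces `kd >= ka2` through
#' `kd = ka2 * (1 + delta)`, `delta > 0`) by multi-start Nelder-Mead.
#' Absorption parameters are estimated per meal period when
#' `control$meal_varying` is `TRUE`.
#'
#' After convergence the two simplification rules are applied and the
#' reduced model refitted when one triggers: (i) variant 2 sets `kd = ka2`
#' when their relative difference is below `kd_tie_tol`; (ii) variant 3
#' sets `ka1 = 0` when it falls below `ka1_floor`. Collapsed parameters are
#' excluded from the free-parameter count `P` and get no CV.
#'
#' Precision: the posterior information matrix in log-parameter coordinates
#' (Gauss-Newton sensitivity term from central finite differences on the
#' simulator, plus the prior precision) is inverted; `CV% = 100 * sd(log
#' theta)`, the delta-method relative SD of the estimate.
#'
#' @param dataset an `"ipk_dataset"` ([generate_dataset()], [ipk_dataset()]
#'   or [read_dataset_csv()]).
#' @param model an [ipk_model()] (or a code like `"3C"`).
#' @param priors an [ipk_priors()].
#' @param control an [ipk_control()].
#' @return An object of class `"ipk_fit"`, with `summary()`, `coef()`,
#'   `vcov()`, `fitted()`, `residuals()`, `predict()`, `plot()` and
#'   `simulate()` methods.
#' @examples
#' \donttest{
#' kin <- kinetics_params(VI = 3.4, m1 = 0.15, CL = 1.16, HEb = 0.59,
#'                        aI = 16e-5)
#' sub <- virtual_subject(kin, absorption_params(ka1 = 0.010, ka2 = 0.028))
#' ds <- generate_dataset(sub, ipk_model("3C"), seed = 42)
#' fit <- ipk_fit(ds, "3C", control = ipk_control(n_starts = 1))
#' summary(fit)
#' }
#' @export
ipk_fit <- function(dataset, model, priors = ipk_priors(),
                    control = ipk_control()) {
  if (is.character(model)) model <- ipk_model(model)
  stopifnot(inherits(dataset, "ipk_dataset"))
  if (!is.null(control$seed)) set.seed(control$seed)
  fc <- fit_context(model, dataset, control)
  n_sets <- fc$n_sets
  collapse <- list(ka1_zero = rep(FALSE, n_sets),
                   kd_tie = rep(FALSE, n_sets))

  fit_round <- function(collapse, theta_init = NULL) {
    map <- build_map(model, n_sets, control, priors, collapse)
    if (!is.null(theta_init)) {
      keep <- intersect(names(theta_init), map$free)
      map$theta0[match(keep, map$free)] <- theta_init[keep]
    }
    obj <- function(theta)
      nlp_values(theta_to_values(map, theta), fc, priors, control)
    best <- run_starts(obj, map, control)
    list(map = map, best = best,
         values = theta_to_values(map, best$par))
  }

  round <- fit_round(collapse)
  for (iter in 1:3) {
    new_collapse <- check_simplification(round$values, model, n_sets,
                                         collapse, control)
    if (is.null(new_collapse)) break
    collapse <- new_collapse
    theta_init <- setNames(round$best$par, round$map$free)
    round <- fit_round(collapse, theta_init)
  }

  map <- round$map
  values <- round$values
  yhat <- predicted_Ip(values, fc, control)
  resid <- weighted_residuals(dataset, yhat)
  wrss <- sum(resid^2)
  P <- length(map$free)
  N <- nrow(dataset)

  prec <- fit_precision(values, map, fc, priors, control)
  estimates <- reported_estimates(values, model, n_sets)

  fit <- structure(list(
    model = model, dataset = dataset, priors = priors, control = control,
    map = map, values = values, theta = round$best$par,
    estimates = estimates, cv = prec$cv, vcov_log = prec$vcov_log,
    fitted = yhat, residuals = resid, wrss = wrss, P = P, N = N,
    bic = ipk_bic(wrss, N, P),
    objective = round$best$value,
    convergence = list(code = round$best$convergence,
                       evals = round$best$evals,
                       n_starts = control$n_starts),
    collapse = collapse, n_sets = n_sets, fc = fc,
    cv_includes_prior = control$include_prior_in_cv,
    runs = runs_test(resid)), class = "ipk_fit")
  fit
}

# Natural-scale reported estimates: delta replaced by kd, collapsed
# parameters at their collapsed values.
reported_estimates <- function(values, model, n_sets) {
  nms <- param_names_for(model, n_sets)
  out <- c()
  for (nm in nms) {
    if (base_name(nm) == "delta") {
      p <- sub("^delta\\.", "", nm)
      out[paste0("kd.", p)] <-
        values[[paste0("ka2.", p)]] * (1 + values[[nm]])
    } else out[nm] <- values[[nm]]
  }
  out
}

# report-coordinate names: free names with delta.p -> kd.p
report_names <- function(map) sub("^delta\\.", "kd.", map$free)

# Perturb one reported parameter multiplicatively by `f`, returning the
# updated full value list (kd perturbation re-expressed through delta).
perturb_value <- function(values, nm, f) {
  if (grepl("^kd\\.", nm)) {
    p <- sub("^kd\\.", "", nm)
    ka2 <- values[[paste0("ka2.", p)]]
    kd <- ka2 * (1 + values[[paste0("delta.", p)]])
    values[[paste0("delta.", p)]] <- kd * f / ka2 - 1
  } else values[[nm]] <- values[[nm]] * f
  values
}

# Posterior precision in log-parameter coordinates.
fit_precision <- function(values, map, fc, priors, control) {
  rn <- report_names(map)
  P <- length(rn)
  N <- nrow(fc$dataset)
  h <- control$fd_step
  S <- matrix(0, N, P, dimnames = list(NULL, rn))
  ok <- TRUE
  for (j in seq_len(P)) {
    up <- try(predicted_Ip(perturb_value(values, rn[j], exp(h)), fc,
                           control), silent = TRUE)
    dn <- try(predicted_Ip(perturb_value(values, rn[j], exp(-h)), fc,
                           control), silent = TRUE)
    if (inherits(up, "try-error") || inherits(dn, "try-error")) {
      ok <- FALSE
      break
    }
    S[, j] <- (up - dn) / (2 * h)
  }
  if (!ok)
    return(list(cv = setNames(rep(Inf, P), rn), vcov_log = NULL))
  M <- crossprod(S / fc$dataset$sd)
  if (control$include_prior_in_cv)
    for (nm in intersect(names(priors), rn))
      M[nm, nm] <- M[nm, nm] + 1 / priors[[nm]]$sdlog^2
  V <- try(solve(M), silent = TRUE)
  if (inherits(V, "try-error") || any(diag(as.matrix(V)) < 0))
    return(list(cv = setNames(rep(Inf, P), rn), vcov_log = NULL))
  list(cv = setNames(100 * sqrt(diag(V)), rn), vcov_log = V)
}

#' Parameter coefficients of variation of a fit
#'
#' `CV% = 100 * sd(estimate) / estimate`, from the inverse posterior
#' information matrix in log-parameter coordinates (so the CV is exactly the
#' log-space posterior SD times 100). A CV above 100% flags a parameter as
#' estimated with poor precision; a singular information matrix yields
#' infinite CVs. Collapsed parameters carry no CV.
#'
#' @param fit an `"ipk_fit"`.
#' @return named CV% vector over the free parameters.
#' @export
parameter_cv <- function(fit) fit$cv
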