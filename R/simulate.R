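#' @title Forward simulation of the IP insulin models
#' @description Internal machinery: a static "context" (segmentation,
#' glucose forcing, solver settings) built once per dataset/design, and a
#' lean core that integrates the ODEs for one parameter set. [ipk_simulate()]
#' is the user-facing wrapper; the MAP fitter reuses the context across
#' thousands of objective evaluations.
#' @name simulate-internal
#' @noRd
NULL

# Normalise a glucose input to a 2-column forcing matrix on [0, horizon].
glucose_forcing <- function(glucose, horizon, Gb_fallback = 120) {
  if (is.null(glucose)) {
    return(cbind(c(0, horizon), rep(Gb_fallback, 2)))
  }
  if (inherits(glucose, "ipk_glucose")) {
    tg <- seq(0, horizon, by = 1)
    return(cbind(tg, glucose_at(glucose, tg)))
  }
  if (is.function(glucose)) {
    tg <- seq(0, horizon, by = 1)
    return(cbind(tg, glucose(tg)))
  }
  m <- as.matrix(glucose[, 1:2])
  if (max(m[, 1]) < horizon || min(m[, 1]) > 0)
    stop("glucose trace does not cover the simulation horizon",
         call. = FALSE)
  m
}

# Meal-period index of each time: period p runs from meal-bolus p to
# meal-bolus p+1; the first period starts at t = 0.
period_breaks <- function(meal_times, horizon) {
  mt <- sort(meal_times)
  mt <- mt[mt > 0 & mt < horizon]
  if (length(mt) <= 1) return(numeric())
  mt[-1]
}

make_sim_context <- function(model, infusion, glucose = NULL, horizon = 1440,
                             times = seq(0, horizon, by = 10),
                             meal_times = NULL, he_clamp = c(0, 0.95),
                             rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "ipk_model"), inherits(infusion, "ipk_infusion"))
  times <- sort(unique(as.numeric(times)))
  if (min(times) < 0 || max(times) > horizon)
    stop("output times must lie in [0, horizon]", call. = FALSE)
  if (is.null(meal_times)) meal_times <- infusion$boluses$time
  pb <- period_breaks(meal_times, horizon)
  n_periods <- length(pb) + 1L

  if (model$he == "B" && is.null(glucose))
    stop("HE variant B needs a glucose trace (argument `glucose`)",
         call. = FALSE)
  forc <- glucose_forcing(glucose, horizon,
                          Gb_fallback = if (inherits(glucose, "ipk_glucose"))
                            glucose$Gb else 120)

  b <- infusion$boluses
  sq_end <- b$time[b$duration > 0] + b$duration[b$duration > 0]
  breaks <- sort(unique(c(0, horizon, pb,
                          infusion$basal_breaks[infusion$basal_breaks > 0],
                          b$time, sq_end)))
  breaks <- breaks[breaks >= 0 & breaks <= horizon]

  list(model = model, infusion = infusion, horizon = horizon, times = times,
       breaks = breaks, period_breaks = pb, n_periods = n_periods,
       forc = forc, he_clamp = he_clamp, rtol = rtol, atol = atol,
       glucose = glucose)
}

# Absorption parameters in the parms slots for one meal period.
abs_slots <- function(abs) {
  c(ka1 = if (is.na(abs$ka1)) 0 else abs$ka1,
    ka2 = if (is.na(abs$ka2)) 0 else abs$ka2,
    kd  = if (is.na(abs$kd))  0 else abs$kd)
}

# Integrate the model over the context's segmentation. `abs_list` is a list
# of absorption_params, one per meal period (recycled if length 1).
# Returns a matrix with columns time, Qip1, Qip2, Qp, Ql, cumRa, RaI, HE.
sim_core <- function(ctx, abs_list, kin, init = NULL) {
  model <- ctx$model
  if (inherits(abs_list, "ipk_abs")) abs_list <- list(abs_list)
  abs_list <- rep_len(abs_list, ctx$n_periods)
  m4 <- derive_m4(kin)
  Gb <- if (model$he == "B") kin$Gb else 0
  if (model$he == "B" && !is.finite(Gb))
    stop("HE variant B needs basal glucose Gb in the kinetics parameters",
         call. = FALSE)

  inf_b0 <- basal_rate_at(ctx$infusion, 0)
  ss <- basal_steady_state(model, abs_list[[1]], kin, inf_b0)
  Qlb <- ss[["Ql"]]
  y <- c(Qip1 = ss[["Qip1"]],
         Qip2 = if (is.na(ss[["Qip2"]])) 0 else ss[["Qip2"]],
         Qp = ss[["Qp"]], Ql = ss[["Ql"]], cumRa = 0)
  if (!is.null(init)) y[names(init)] <- init

  parms <- c(absv = model$absorption,
             hev = match(model$he, c("A", "B", "C")),
             ka1 = 0, ka2 = 0, kd = 0,
             m1 = kin$m1, m2 = kin$m2, m4 = m4, HEb = kin$HEb,
             aI = kin$aI, aG = kin$aG, Gb = Gb, Qlb = Qlb,
             hemin = ctx$he_clamp[1], hemax = ctx$he_clamp[2], inf = 0)

  bol <- ctx$infusion$boluses
  brk <- ctx$breaks
  nseg <- length(brk) - 1L
  out_rows <- vector("list", nseg)
  for (s in seq_len(nseg)) {
    t0 <- brk[s]; t1 <- brk[s + 1]
    # impulse boluses at the segment start
    imp <- bol$time == t0 & bol$duration == 0
    if (any(imp)) y["Qip1"] <- y[["Qip1"]] + sum(bol$dose[imp])
    # constant rate on this segment: basal + active square-wave boluses
    rate <- basal_rate_at(ctx$infusion, t0)
    sq <- bol$duration > 0 & bol$time <= t0 & (bol$time + bol$duration) > t0
    if (any(sq)) rate <- rate + sum(bol$dose[sq] / bol$duration[sq])
    period <- findInterval(t0, ctx$period_breaks) + 1L
    parms[c("ka1", "ka2", "kd")] <- abs_slots(abs_list[[period]])
    parms["inf"] <- rate

    seg_times <- sort(unique(c(t0, ctx$times[ctx$times > t0 & ctx$times < t1],
                               t1)))
    sol <- deSolve::lsoda(y = y, times = seg_times, func = "ipk_derivs",
                          parms = parms, dllname = "ipkin",
                          initfunc = "ipk_init", initforc = "ipk_forc",
                          forcings = ctx$forc,
                          fcontrol = list(method = "linear", rule = 2),
                          nout = 2, outnames = c("RaI", "HE"),
                          rtol = ctx$rtol, atol = ctx$atol)
    if (attr(sol, "istate")[1] < 0)
      stop("ODE solver failed on segment [", t0, ", ", t1, "]",
           call. = FALSE)
    y <- sol[nrow(sol), 2:6]
    keep <- sol[, 1] %in% ctx$times & (sol[, 1] < t1 | s == nseg)
    out_rows[[s]] <- sol[keep, , drop = FALSE]
  }
  out <- do.call(rbind, out_rows)
  attr(out, "Qlb") <- Qlb
  attr(out, "Ipb") <- attr(ss, "Ipb")
  out
}

#' Simulate plasma insulin after IP insulin delivery
#'
#' Integrates one of the nine IP absorption + whole-body kinetics models
#' forward from its basal steady state under a basal-bolus infusion profile.
#' Boluses are delivered as instantaneous additions to the first IP
#' compartment (integration restarts at every bolus and every meal-period
#' parameter switch); a square-wave option is available via the infusion
#' profile's `bolus_durations`. The solver is `deSolve::lsoda` on a compiled
#' right-hand side; an auxiliary state accumulates the absorption flux so
#' the IP mass balance can be audited at solver accuracy.
#'
#' @param model an [ipk_model()].
#' @param abs an [absorption_params()] set, or a list of them (one per meal
#'   period) when absorption varies meal-by-meal. Meal periods run from one
#'   meal bolus to the next; the first starts at t = 0.
#' @param kin an [kinetics_params()] set.
#' @param infusion an [infusion_profile()].
#' @param glucose exogenous glucose input, required for HE variant B: an
#'   [glucose_profile()], a function of time, or a 2-column (time, mg/dL)
#'   matrix/data frame covering the horizon.
#' @param horizon simulation length (min).
#' @param times output grid (min), distinct from the solver's internal steps.
#' @param meal_times meal-period boundaries; defaults to the infusion's
#'   bolus times.
#' @param he_clamp allowed hepatic-extraction interval; the affine HE laws
#'   are clamped here because the liver degradation rate diverges as HE
#'   approaches 1. A message reports if clamping was active.
#' @param rtol,atol solver tolerances.
#' @param init optional named overrides of the initial state (mU), e.g.
#'   `c(Qip1 = 0)`.
#' @param quiet suppress the clamping message.
#' @return A data frame of class `"ipk_sim"` with columns `time` (min),
#'   `Qip1`, `Qip2`, `Qp`, `Ql` (mU), `cumRa` (mU, integrated absorption
#'   flux), `RaI` (mU/min), `HE` (fraction) and `Ip` (mU/L, equal to
#'   `Qp / VI`). `Qip2` is `NA` for absorption variant 1. Attributes carry
#'   the basal state (`Qlb`, `Ipb`), the model and the parameters.
#' @examples
#' kin <- kinetics_params(VI = 3.4, m1 = 0.15, CL = 1.16, HEb = 0.59,
#'                        aI = 16e-5)
#' abs <- absorption_params(ka1 = 0.010, ka2 = 0.028)
#' des <- open_loop_design(0.60, 75)
#' sim <- ipk_simulate(ipk_model("3C"), abs, kin, des)
#' head(sim)
#' @export
ipk_simulate <- function(model, abs, kin, infusion, glucose = NULL,
                         horizon = 1440, times = seq(0, horizon, by = 10),
                         meal_times = NULL, he_clamp = c(0, 0.95),
                         rtol = 1e-8, atol = 1e-10, init = NULL,
                         quiet = FALSE) {
  ctx <- make_sim_context(model, infusion, glucose, horizon, times,
                          meal_times, he_clamp, rtol, atol)
  m <- sim_core(ctx, abs, kin, init = init)
  res <- as.data.frame(m)
  names(res) <- c("time", "Qip1", "Qip2", "Qp", "Ql", "cumRa", "RaI", "HE")
  res$Ip <- res$Qp / kin$VI
  if (model$absorption == 1) res$Qip2 <- NA_real_

  # was the affine HE law clamped anywhere on the output grid?
  clamped <- 0L
  if (model$he == "C") {
    raw <- -kin$aI * (res$Ql - attr(m, "Qlb")) + kin$HEb
    clamped <- sum(raw < he_clamp[1] | raw > he_clamp[2])
  } else if (model$he == "B") {
    g <- stats::approx(ctx$forc[, 1], ctx$forc[, 2], xout = res$time,
                       rule = 2)$y
    raw <- -kin$aG * (g - kin$Gb) + kin$HEb
    clamped <- sum(raw < he_clamp[1] | raw > he_clamp[2])
  }
  if (clamped > 0 && !quiet)
    message("hepatic extraction clamped to [", he_clamp[1], ", ",
            he_clamp[2], "] at ", clamped, " output times")

  structure(res, class = c("ipk_sim", "data.frame"),
            model = model, kin = kin, abs = abs, infusion = infusion,
            Qlb = attr(m, "Qlb"), Ipb = attr(m, "Ipb"),
            he_clamped = clamped)
}

#' @export
print.ipk_sim <- function(x, ...) {
  mod <- attr(x, "model")
  cat("IP insulin simulation (model ", format(mod), "), ",
      nrow(x), " output times over ", max(x$time), " min\n",
      "  basal Ip ", signif(attr(x, "Ipb"), 4), " mU/L; Ip range [",
      signif(min(x$Ip), 4), ", ", signif(max(x$Ip), 4), "] mU/L\n",
      sep = "")
  invisible(x)
}

#' @export
plot.ipk_sim <- function(x, which = c("Ip", "RaI", "HE"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  old <- graphics::par(mfrow = c(length(which), 1),
                       mar = c(4, 4, 1.5, 1) + 0.1)
  on.exit(graphics::par(old))
  labs <- c(Ip = "plasma insulin (mU/L)", RaI = "absorption flux (mU/min)",
            HE = "hepatic extraction")
  for (w in which)
    graphics::plot(x$time, x[[w]], type = "l", xlab = "time (min)",
                   ylab = labs[[w]], ...)
  invisible(x)
}

#' Write a simulation to CSV
#'
#' Tidy per-time rows: `time_min, Qip1, Qip2, Qp, Ql, Ip_mU_per_L,
#' RaI_mU_per_min, HE`.
#'
#' @param sim an `"ipk_sim"` object.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_sim_csv <- function(sim, file) {
  out <- data.frame(time_min = sim$time, Qip1 = sim$Qip1, Qip2 = sim$Qip2,
                    Qp = sim$Qp, Ql = sim$Ql, Ip_mU_per_L = sim$Ip,
                    RaI_mU_per_min = sim$RaI, HE = sim$HE)
  write.csv(out, file, row.names = FALSE)
  invisible(file)
}
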