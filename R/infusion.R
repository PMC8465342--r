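#' Basal-bolus IP infusion profile
#'
#' A piecewise-constant basal infusion plus impulsive (or short square-wave)
#' meal boluses, in mU and minutes. Boluses with `duration = 0` are delivered
#' as instantaneous additions to the first IP compartment; a positive
#' duration spreads the dose as a constant extra rate over
#' `[time, time + duration)`.
#'
#' @param basal_rates basal rates (mU/min), one per interval between
#'   `basal_breaks`.
#' @param basal_breaks left endpoints of the basal intervals (min); must
#'   start at 0 and be strictly increasing.
#' @param bolus_times bolus instants (min).
#' @param bolus_doses bolus doses (mU), same length as `bolus_times`.
#' @param bolus_durations per-bolus square-wave durations (min); 0 = impulse.
#' @return An object of class `"ipk_infusion"`.
#' @seealso [open_loop_design()], [total_dose()]
#' @examples
#' infusion_profile(15.625, bolus_times = c(480, 780, 1140),
#'                  bolus_doses = rep(7500, 3))
#' @export
infusion_profile <- function(basal_rates, basal_breaks = 0,
                             bolus_times = numeric(), bolus_doses = numeric(),
                             bolus_durations = 0) {
  basal_rates <- as.numeric(basal_rates)
  basal_breaks <- as.numeric(basal_breaks)
  if (length(basal_breaks) != length(basal_rates) || basal_breaks[1] != 0 ||
      is.unsorted(basal_breaks, strictly = TRUE))
    stop("basal_breaks must start at 0, be strictly increasing and match ",
         "basal_rates in length", call. = FALSE)
  if (any(!is.finite(basal_rates)) || any(basal_rates < 0))
    stop("basal rates must be finite and >= 0", call. = FALSE)
  n <- length(bolus_times)
  if (length(bolus_doses) != n)
    stop("bolus_times and bolus_doses must have the same length",
         call. = FALSE)
  bolus_durations <- rep_len(as.numeric(bolus_durations), n)
  if (n) {
    if (any(bolus_doses < 0) || any(bolus_durations < 0))
      stop("bolus doses and durations must be >= 0", call. = FALSE)
    o <- order(bolus_times)
    bolus_times <- as.numeric(bolus_times)[o]
    bolus_doses <- as.numeric(bolus_doses)[o]
    bolus_durations <- bolus_durations[o]
  }
  structure(list(basal_rates = basal_rates, basal_breaks = basal_breaks,
                 boluses = data.frame(time = as.numeric(bolus_times),
                                      dose = as.numeric(bolus_doses),
                                      duration = bolus_durations)),
            class = "ipk_infusion")
}

#' Basal rate at given times (excluding boluses)
#' @noRd
basal_rate_at <- function(profile, t) {
  idx <- findInterval(t, profile$basal_breaks)
  idx[idx < 1L] <- 1L
  profile$basal_rates[idx]
}

#' Total delivered dose of an infusion profile
#'
#' Integral of the basal rate over `[0, horizon]` plus the sum of bolus
#' doses falling in the horizon. Used as the delivered-dose audit in tests.
#'
#' @param profile an [infusion_profile()].
#' @param horizon end of the delivery window (min).
#' @return total dose in mU.
#' @export
total_dose <- function(profile, horizon = 1440) {
  edges <- c(profile$basal_breaks, horizon)
  edges <- pmin(edges, horizon)
  widths <- pmax(diff(edges), 0)
  basal <- sum(widths * profile$basal_rates)
  b <- profile$boluses
  basal + sum(b$dose[b$time < horizon])
}

#' @export
print.ipk_infusion <- function(x, ...) {
  cat("IP infusion profile:\n  basal:",
      paste0(signif(x$basal_rates, 4), " mU/min from t=", x$basal_breaks,
             collapse = "; "),
      "\n  boluses:", if (nrow(x$boluses)) paste0(
        signif(x$boluses$dose / 1000, 4), " U at t=", x$boluses$time,
        ifelse(x$boluses$duration > 0,
               paste0(" (over ", x$boluses$duration, " min)"), ""),
        collapse = "; ") else "none", "\n")
  invisible(x)
}

#' Open-loop basal-bolus design for a 24-h study day
#'
#' Builds the infusion profile of the hospitalized open-loop protocol: a
#' constant basal rate plus one bolus per meal, from the patient's daily
#' insulin requirement. A fraction `bolus_fraction` of the daily dose is
#' split across the meal boluses (equal thirds by default) and the rest is
#' delivered as constant basal over 24 h, so the delivered total equals
#' `daily_dose * body_mass` exactly.
#'
#' @param daily_dose daily insulin requirement (U/kg/day); the cohort the
#'   generator emulates averaged 0.60 U/kg/day.
#' @param body_mass body mass (kg).
#' @param meal_times meal bolus instants (min into the day).
#' @param bolus_fraction fraction of the daily dose given as boluses,
#'   in (0, 1); `0` is accepted and gives a pure-basal day.
#' @param bolus_split relative bolus sizes (recycled/normalised); default
#'   equal.
#' @param bolus_duration square-wave bolus duration (min); 0 = impulse.
#' @return An [infusion_profile()] (doses internally in mU).
#' @examples
#' d <- open_loop_design(0.60, 75, bolus_fraction = 0.5)
#' total_dose(d) / 1000  # 45 U
#' @export
open_loop_design <- function(daily_dose = 0.60, body_mass = 75,
                             meal_times = c(480, 780, 1140),
                             bolus_fraction = 0.5, bolus_split = NULL,
                             bolus_duration = 0) {
  if (daily_dose <= 0 || body_mass <= 0)
    stop("daily_dose and body_mass must be > 0", call. = FALSE)
  if (bolus_fraction < 0 || bolus_fraction >= 1)
    stop("bolus_fraction must lie in [0, 1)", call. = FALSE)
  if (any(meal_times < 0) || any(meal_times >= 1440))
    stop("meal_times must lie in [0, 1440)", call. = FALSE)
  total_mU <- daily_dose * body_mass * 1000
  basal <- (1 - bolus_fraction) * total_mU / 1440
  if (bolus_fraction == 0 || !length(meal_times))
    return(infusion_profile(basal))
  if (is.null(bolus_split)) bolus_split <- rep(1, length(meal_times))
  bolus_split <- bolus_split / sum(bolus_split)
  doses <- bolus_fraction * total_mU * bolus_split
  infusion_profile(basal, bolus_times = meal_times, bolus_doses = doses,
                   bolus_durations = bolus_duration)
}
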