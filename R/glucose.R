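#' Exogenous plasma glucose profile
#'
#' A smooth parametric glucose trace: basal level plus one postprandial
#' excursion per meal, shaped as a log-normal bump that peaks `t_peak`
#' minutes after the meal and decays back to basal. Glucose is an exogenous
#' input here (no glucose-insulin feedback is modelled); it only enters the
#' hepatic-extraction law of HE variant B. An optional multiplicative jitter
#' on the amplitudes (drawn once, given `seed`) adds day-to-day variation;
#' with `jitter = 0` the trace is fully deterministic.
#'
#' @param Gb basal glucose (mg/dL, >= 40); the trace starts at `Gb`.
#' @param meal_times meal instants (min).
#' @param amplitudes peak excursion heights above basal (mg/dL, >= 0),
#'   recycled over meals.
#' @param t_peak time-to-peak of each excursion (min).
#' @param width log-scale shape width of the bump (dimensionless).
#' @param jitter multiplicative log-normal CV applied to the amplitudes.
#' @param seed RNG seed for the jitter draw.
#' @return An object of class `"ipk_glucose"`: callable via
#'   [glucose_at()], with fields `Gb`, `meal_times`, `amplitudes`.
#' @examples
#' g <- glucose_profile(120, amplitudes = 80)
#' max(glucose_at(g, seq(0, 1440, by = 1)))
#' @export
glucose_profile <- function(Gb = 120, meal_times = c(480, 780, 1140),
                            amplitudes = 60, t_peak = 60, width = 0.5,
                            jitter = 0, seed = NULL) {
  if (!is.finite(Gb) || Gb < 40)
    stop("basal glucose Gb must be >= 40 mg/dL", call. = FALSE)
  amplitudes <- rep_len(as.numeric(amplitudes), length(meal_times))
  if (any(amplitudes < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  if (jitter > 0) {
    if (!is.null(seed)) set.seed(seed)
    sdlog <- sqrt(log(1 + jitter^2))
    amplitudes <- amplitudes * rlnorm(length(amplitudes),
                                      meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  structure(list(Gb = Gb, meal_times = as.numeric(meal_times),
                 amplitudes = amplitudes, t_peak = t_peak, width = width,
                 seed = seed),
            class = "ipk_glucose")
}

#' Evaluate a glucose profile
#'
#' @param profile an [glucose_profile()] object, or `NULL` (treated as a
#'   flat trace at `Gb = 120`).
#' @param t times (min).
#' @return glucose concentrations (mg/dL), same length as `t`.
#' @export
glucose_at <- function(profile, t) {
  if (is.null(profile)) return(rep(120, length(t)))
  g <- rep(profile$Gb, length(t))
  for (i in seq_along(profile$meal_times)) {
    s <- t - profile$meal_times[i]
    pos <- which(s > 0)
    if (length(pos))
      g[pos] <- g[pos] + profile$amplitudes[i] *
        exp(-(log(s[pos] / profile$t_peak))^2 / (2 * profile$width^2))
  }
  g
}

#' @export
print.ipk_glucose <- function(x, ...) {
  cat("Glucose profile: basal", x$Gb, "mg/dL;",
      if (length(x$meal_times)) paste0("excursions +",
        paste(signif(x$amplitudes, 3), collapse = "/+"), " mg/dL at t=",
        paste(x$meal_times, collapse = "/")) else "flat", "\n")
  invisible(x)
}
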