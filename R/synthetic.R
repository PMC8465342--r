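#' Measurement standard deviation of a plasma insulin sample
#'
#' The assay error model: zero-mean uncorrelated Gaussian noise with known
#' SD, here a constant coefficient of variation with an absolute floor,
#' `SD = max(cv * Ip, floor)` — typical of plasma-insulin immunoassays.
#' Both numbers are configurable stand-ins; fits take whatever per-sample
#' SDs the dataset carries.
#'
#' @param Ip plasma insulin (mU/L, >= 0; vectorised).
#' @param cv proportional error (fraction, > 0).
#' @param floor minimum SD (mU/L).
#' @return per-sample SDs (mU/L).
#' @examples
#' measurement_sd(50)        # 3 mU/L at the default 6% CV
#' @export
measurement_sd <- function(Ip, cv = 0.06, floor = 1) {
  if (cv <= 0) stop("cv must be > 0", call. = FALSE)
  if (any(Ip < 0, na.rm = TRUE)) stop("Ip must be >= 0", call. = FALSE)
  pmax(cv * Ip, floor)
}

#' A virtual study subject
#'
#' Bundles the kinetics parameters, per-meal absorption parameters, basal
#' design inputs and body mass of one simulated patient. Parameter
#' feasibility (positive derived `m4`, `HEb` in (0,1)) is checked on
#' construction.
#'
#' @param kin an [kinetics_params()] set.
#' @param abs an [absorption_params()] set or a list of them (one per meal).
#' @param daily_dose daily insulin requirement (U/kg/day).
#' @param body_mass body mass (kg; dose scaling only).
#' @return An object of class `"ipk_subject"`.
#' @export
virtual_subject <- function(kin, abs, daily_dose = 0.60, body_mass = 75) {
  check_feasible(kin)
  if (inherits(abs, "ipk_abs")) abs <- list(abs)
  stopifnot(all(vapply(abs, inherits, TRUE, "ipk_abs")))
  structure(list(kin = kin, abs = abs, daily_dose = daily_dose,
                 body_mass = body_mass),
            class = "ipk_subject")
}

#' @export
print.ipk_subject <- function(x, ...) {
  cat("Virtual subject:", x$body_mass, "kg,", x$daily_dose, "U/kg/day\n")
  cat("  kinetics: VI", signif(x$kin$VI, 3), "L, m1", signif(x$kin$m1, 3),
      ", CL", signif(x$kin$CL, 3), "L/min, HEb", signif(x$kin$HEb, 3), "\n")
  ka2 <- vapply(x$abs, `[[`, 0, "ka2")
  cat("  absorption per meal: ka2", paste(signif(ka2, 3), collapse = "/"),
      "1/min\n")
  invisible(x)
}

#' Generate a noisy plasma-insulin dataset from a virtual subject
#'
#' Emulates the 24-h hospitalized open-loop day: the subject's model is
#' simulated noise-free from its basal steady state under the basal-bolus
#' design, then independent zero-mean Gaussian measurement noise with SD
#' from [measurement_sd()] is added at the sampling times. Negative draws
#' are truncated at zero and flagged. The generating truth is stored so
#' recovery experiments can compare estimates against it.
#'
#' @param subject a [virtual_subject()].
#' @param model the generating [ipk_model()].
#' @param design an [infusion_profile()]; defaults to the subject's
#'   [open_loop_design()].
#' @param glucose an [glucose_profile()] (stored with the data; required by
#'   fits of HE variant B).
#' @param sampling_interval plasma sampling interval (min).
#' @param horizon study length (min).
#' @param cv,floor measurement-error model, see [measurement_sd()].
#' @param seed RNG seed; the dataset is bit-reproducible given it.
#' @return A data frame of class `"ipk_dataset"` with columns `time`,
#'   `insulin` (mU/L), `sd` (mU/L), `glucose` (mg/dL), and attributes
#'   `meal_times`, `infusion`, `glucose_profile`, `truth` (model, kin, abs),
#'   `seed`, `truncated` (indices of truncated draws) and `Ip_true`.
#' @examples
#' kin <- kinetics_params(VI = 3.4, m1 = 0.15, CL = 1.16, HEb = 0.59,
#'                        aI = 16e-5)
#' sub <- virtual_subject(kin, absorption_params(ka1 = 0.010, ka2 = 0.028))
#' ds <- generate_dataset(sub, ipk_model("3C"), seed = 1)
#' @export
generate_dataset <- function(subject, model, design = NULL, glucose = NULL,
                             sampling_interval = 10, horizon = 1440,
                             cv = 0.06, floor = 1, seed = NULL) {
  stopifnot(inherits(subject, "ipk_subject"), inherits(model, "ipk_model"))
  if (is.null(design))
    design <- open_loop_design(subject$daily_dose, subject$body_mass)
  if (is.null(glucose)) glucose <- glucose_profile()
  if (model$he == "B" && !is.finite(subject$kin$Gb))
    subject$kin$Gb <- glucose$Gb
  times <- seq(0, horizon, by = sampling_interval)
  sim <- ipk_simulate(model, subject$abs, subject$kin, design,
                      glucose = glucose, horizon = horizon, times = times,
                      quiet = TRUE)
  Ip_true <- sim$Ip
  # cv = 0 is the noise-free limit; SDs fall back to the floor so the
  # dataset still carries usable weights
  sds <- pmax(cv * Ip_true, floor)
  if (!is.null(seed)) set.seed(seed)
  y <- if (cv > 0) Ip_true + rnorm(length(Ip_true), 0, sds) else Ip_true
  truncated <- which(y < 0)
  y[truncated] <- 0
  ds <- data.frame(time = times, insulin = y, sd = sds,
                   glucose = glucose_at(glucose, times))
  structure(ds, class = c("ipk_dataset", "data.frame"),
            meal_times = design$boluses$time, infusion = design,
            glucose_profile = glucose,
            truth = list(model = model, kin = subject$kin, abs = subject$abs),
            seed = seed, truncated = truncated, Ip_true = Ip_true,
            cv = cv, floor = floor)
}

#' @export
print.ipk_dataset <- function(x, ...) {
  cat("IP insulin dataset: ", nrow(x), " samples over ", max(x$time),
      " min; insulin ", signif(min(x$insulin), 3), "-",
      signif(max(x$insulin), 3), " mU/L\n", sep = "")
  mt <- attr(x, "meal_times")
  if (length(mt)) cat("  meals at t =", paste(mt, collapse = ", "), "min\n")
  if (!is.null(attr(x, "truth"))) cat("  synthetic (truth stored), seed",
                                      attr(x, "seed") %||% NA, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a dataset from raw vectors (e.g. read from file)
#'
#' @param time sampling times (min, strictly increasing).
#' @param insulin measured plasma insulin (mU/L, >= 0).
#' @param sd per-sample measurement SDs (mU/L, > 0); if missing, filled
#'   from [measurement_sd()].
#' @param glucose plasma glucose at the sampling times (mg/dL; needed only
#'   for HE variant B).
#' @param infusion the [infusion_profile()] the subject received.
#' @param meal_times meal instants; default the infusion's bolus times.
#' @return an `"ipk_dataset"`.
#' @export
ipk_dataset <- function(time, insulin, sd = NULL, glucose = NA_real_,
                        infusion, meal_times = NULL) {
  if (is.unsorted(time, strictly = TRUE))
    stop("sample times must be strictly increasing", call. = FALSE)
  if (any(insulin < 0)) stop("measured insulin must be >= 0", call. = FALSE)
  if (is.null(sd)) sd <- measurement_sd(insulin)
  if (any(sd <= 0)) stop("measurement SDs must be > 0", call. = FALSE)
  ds <- data.frame(time = time, insulin = insulin, sd = sd,
                   glucose = glucose)
  structure(ds, class = c("ipk_dataset", "data.frame"),
            meal_times = meal_times %||% infusion$boluses$time,
            infusion = infusion)
}

#' Write / read a dataset as CSV plus a JSON sidecar
#'
#' The CSV holds the per-sample table (`time_min, insulin_mU_per_L,
#' sd_mU_per_L, glucose_mg_per_dL`); the sidecar (`<file>.json`) holds the
#' design, meal times, seed and — for synthetic data — the generating truth.
#'
#' @param dataset an `"ipk_dataset"`.
#' @param file CSV path.
#' @return `file` invisibly (`write_dataset_csv`); the rebuilt
#'   `"ipk_dataset"` (`read_dataset_csv`).
#' @export
write_dataset_csv <- function(dataset, file) {
  write.csv(data.frame(time_min = dataset$time,
                       insulin_mU_per_L = dataset$insulin,
                       sd_mU_per_L = dataset$sd,
                       glucose_mg_per_dL = dataset$glucose),
            file, row.names = FALSE)
  inf <- attr(dataset, "infusion")
  truth <- attr(dataset, "truth")
  side <- list(meal_times = attr(dataset, "meal_times"),
               seed = attr(dataset, "seed"),
               infusion = list(basal_rates = inf$basal_rates,
                               basal_breaks = inf$basal_breaks,
                               bolus_times = inf$boluses$time,
                               bolus_doses = inf$boluses$dose,
                               bolus_durations = inf$boluses$duration),
               truth = if (!is.null(truth)) list(
                 model = format(truth$model),
                 kin = unclass(truth$kin),
                 abs = lapply(truth$abs, unclass)))
  jsonlite::write_json(side, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(file)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(file) {
  tab <- read.csv(file)
  side <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  inf <- infusion_profile(side$infusion$basal_rates,
                          side$infusion$basal_breaks,
                          side$infusion$bolus_times %||% numeric(),
                          side$infusion$bolus_doses %||% numeric(),
                          side$infusion$bolus_durations %||% 0)
  ds <- ipk_dataset(tab$time_min, tab$insulin_mU_per_L, tab$sd_mU_per_L,
                    tab$glucose_mg_per_dL, infusion = inf,
                    meal_times = side$meal_times)
  if (!is.null(side$truth)) {
    tk <- side$truth$kin
    kin <- kinetics_params(tk$VI, tk$m1, tk$CL, tk$HEb,
                           tk$m2 %||% 0.268, tk$aG %||% 0, tk$aI %||% 0,
                           tk$Gb %||% NA_real_)
    ta <- side$truth$abs
    if (is.data.frame(ta)) ta <- split(ta, seq_len(nrow(ta)))
    abs <- lapply(ta, function(a)
      absorption_params(a$ka1 %||% NA_real_, a$ka2 %||% NA_real_,
                        a$kd %||% NA_real_))
    names(abs) <- NULL
    attr(ds, "truth") <- list(model = ipk_model(side$truth$model),
                              kin = kin, abs = abs)
  }
  attr(ds, "seed") <- side$seed
  ds
}

#' Draw a virtual-subject population around median parameters
#'
#' Subjects are drawn log-normally around the supplied median parameter
#' values (the log-normal median equals its centre, so the population
#' medians are the supplied ones by construction). Optional meal-by-meal
#' multiplicative perturbation of the absorption rates emulates
#' intra-subject between-meal variability. Draws violating the structural
#' feasibility constraints (`m4 > 0`, `HEb` in (0,1), `kd >= ka2`) are
#' redrawn, up to `max_retries` per subject.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param median_params named list of population medians; defaults to the
#'   selected-model population values used throughout the package
#'   (`VI = 3.4`, `m1 = 0.15`, `CL = 1.16`, `HEb = 0.59`, `aI = 16e-5`,
#'   `ka1 = 0.010`, `ka2 = 0.028`).
#' @param dispersion between-subject log-normal CV (fraction).
#' @param meal_variability between-meal log-normal CV applied to `ka1`,
#'   `ka2` (and `kd`) per meal; 0 gives identical absorption at all meals.
#' @param n_meals meals per day.
#' @param daily_dose,body_mass design inputs passed to each subject.
#' @param seed RNG seed.
#' @param max_retries redraw budget per subject before erroring.
#' @return list of [virtual_subject()]s.
#' @examples
#' pop <- sample_population(3, dispersion = 0.2, seed = 1)
#' @export
sample_population <- function(n_subjects,
                              median_params = list(VI = 3.4, m1 = 0.15,
                                                   CL = 1.16, HEb = 0.59,
                                                   aI = 16e-5, ka1 = 0.010,
                                                   ka2 = 0.028),
                              dispersion = 0.3, meal_variability = 0,
                              n_meals = 3, daily_dose = 0.60, body_mass = 75,
                              seed = NULL, max_retries = 100) {
  stopifnot(n_subjects >= 1)
  if (!is.null(seed)) set.seed(seed)
  sdlog <- sqrt(log(1 + dispersion^2))
  msd <- sqrt(log(1 + meal_variability^2))
  draw1 <- function(m) if (sdlog == 0) m else m * exp(rnorm(1, 0, sdlog))
  lapply(seq_len(n_subjects), function(i) {
    for (try in seq_len(max_retries)) {
      kin <- try(kinetics_params(VI = draw1(median_params$VI),
                                 m1 = draw1(median_params$m1),
                                 CL = draw1(median_params$CL),
                                 HEb = draw1(median_params$HEb),
                                 aI = draw1(median_params$aI %||% 0)),
                 silent = TRUE)
      if (inherits(kin, "try-error")) next
      feas <- try(check_feasible(kin), silent = TRUE)
      if (inherits(feas, "try-error")) next
      ka1 <- draw1(median_params$ka1 %||% 0.010)
      ka2 <- draw1(median_params$ka2 %||% 0.028)
      abs <- lapply(seq_len(n_meals), function(m) {
        f1 <- if (msd == 0) 1 else exp(rnorm(1, 0, msd))
        f2 <- if (msd == 0) 1 else exp(rnorm(1, 0, msd))
        absorption_params(ka1 = ka1 * f1, ka2 = ka2 * f2)
      })
      return(virtual_subject(kin, abs, daily_dose, body_mass))
    }
    stop("could not draw a feasible subject after ", max_retries,
         " attempts", call. = FALSE)
  })
}
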