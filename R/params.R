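#' Absorption parameters for one meal period
#'
#' Rate constants of the IP absorption subsystem, all in 1/min. Which ones a
#' model uses depends on the absorption variant: M1 uses `ka1` only; M2 uses
#' `kd` and `ka2` under the convention `kd >= ka2` (the two are interchangeable
#' in the likelihood, so the ordering pins the labelling); M3 uses `ka1` and
#' `ka2`. When absorption is allowed to vary meal-by-meal, one set is
#' attached per meal period.
#'
#' @param ka1 absorption rate from the first IP compartment (1/min, >= 0).
#' @param ka2 absorption rate from the second IP compartment (1/min, > 0
#'   where used).
#' @param kd transfer rate between the two IP compartments (1/min, M2 only).
#' @return An object of class `"ipk_abs"`.
#' @examples
#' absorption_params(ka1 = 0.010, ka2 = 0.028)
#' @export
absorption_params <- function(ka1 = NA_real_, ka2 = NA_real_, kd = NA_real_) {
  p <- list(ka1 = as.numeric(ka1), ka2 = as.numeric(ka2), kd = as.numeric(kd))
  for (nm in names(p)) {
    v <- p[[nm]]
    if (length(v) != 1L) stop(nm, " must be a single value", call. = FALSE)
    if (!is.na(v) && (!is.finite(v) || v < 0))
      stop(nm, " must be finite and non-negative", call. = FALSE)
  }
  if (!is.na(p$kd) && !is.na(p$ka2) && p$kd < p$ka2 &&
      (p$ka2 - p$kd) > 1e-12 * p$ka2)
    stop("kd must be >= ka2 (the two are interchangeable; the ordering is a ",
         "labelling convention)", call. = FALSE)
  structure(p, class = "ipk_abs")
}

#' Whole-body insulin kinetics parameters
#'
#' Parameters of the two-compartment plasma/liver insulin kinetics model and
#' of the hepatic-extraction (HE) laws. `m2`, the fractional rate of hepatic
#' plasma flow, is fixed by convention (default 0.268 1/min) to make the
#' battery a priori identifiable. The peripheral degradation rate `m4` is
#' derived from the post-hepatic clearance via [derive_m4()], and the basal
#' liver degradation rate `m3b` from `HEb` and `m1` via [derive_m3_basal()].
#'
#' @param VI insulin distribution volume (L, > 0).
#' @param m1 liver-to-plasma insulin transfer rate (1/min, > 0).
#' @param CL post-hepatic insulin clearance (L/min, > 0); ties `m4` through
#'   `CL = (HEb * m2 + m4) * VI`.
#' @param HEb basal hepatic insulin extraction, a fraction in (0, 1).
#' @param m2 fractional rate of hepatic plasma flow (1/min, fixed).
#' @param aG glucose control on HE (dL/mg, >= 0; HE variant B only).
#' @param aI liver-insulin control on HE (1/mU, >= 0; HE variant C only).
#' @param Gb basal plasma glucose (mg/dL; HE variant B only).
#' @return An object of class `"ipk_kin"`.
#' @examples
#' kinetics_params(VI = 3.4, m1 = 0.15, CL = 1.16, HEb = 0.59, aI = 16e-5)
#' @export
kinetics_params <- function(VI, m1, CL, HEb, m2 = 0.268,
                            aG = 0, aI = 0, Gb = NA_real_) {
  k <- list(VI = as.numeric(VI), m1 = as.numeric(m1), CL = as.numeric(CL),
            HEb = as.numeric(HEb), m2 = as.numeric(m2),
            aG = as.numeric(aG), aI = as.numeric(aI), Gb = as.numeric(Gb))
  for (nm in c("VI", "m1", "CL", "m2"))
    if (!is.finite(k[[nm]]) || k[[nm]] <= 0)
      stop(nm, " must be finite and > 0", call. = FALSE)
  if (!is.finite(k$HEb) || k$HEb <= 0 || k$HEb >= 1)
    stop("HEb must lie strictly in (0, 1)", call. = FALSE)
  for (nm in c("aG", "aI"))
    if (!is.finite(k[[nm]]) || k[[nm]] < 0)
      stop(nm, " must be finite and >= 0", call. = FALSE)
  structure(k, class = "ipk_kin")
}

#' Peripheral degradation rate from the post-hepatic clearance
#'
#' Inverts `CL = (HEb * m2 + m4) * VI` for `m4`, the rate of insulin
#' degradation in the periphery.
#'
#' @param kin an [kinetics_params()] object (or any list with `CL`, `VI`,
#'   `HEb`, `m2`).
#' @return `m4` in 1/min.
#' @examples
#' derive_m4(kinetics_params(VI = 3.4, m1 = 0.15, CL = 1.16, HEb = 0.59))
#' @export
derive_m4 <- function(kin) {
  m4 <- kin$CL / kin$VI - kin$HEb * kin$m2
  if (!is.finite(m4) || m4 <= 0)
    stop("degenerate kinetics: CL/VI <= HEb*m2 gives a non-positive ",
         "peripheral degradation rate m4", call. = FALSE)
  m4
}

#' Basal liver insulin degradation rate
#'
#' Evaluates `m3 = HE / (1 - HE) * m1` at the basal extraction `HEb`.
#'
#' @inheritParams derive_m4
#' @return `m3b` in 1/min.
#' @examples
#' derive_m3_basal(kinetics_params(VI = 3.4, m1 = 0.15, CL = 1.16, HEb = 0.59))
#' @export
derive_m3_basal <- function(kin) {
  if (!is.finite(kin$HEb) || kin$HEb <= 0 || kin$HEb >= 1)
    stop("HEb must lie strictly in (0, 1)", call. = FALSE)
  kin$HEb / (1 - kin$HEb) * kin$m1
}

#' Hepatic extraction under a given HE variant
#'
#' Evaluates the hepatic extraction fraction: constant (`A`), glucose-
#' controlled (`B`, `-aG * (G - Gb) + HEb`) or liver-insulin-controlled
#' (`C`, `-aI * (Ql - Qlb) + HEb`). The affine laws can leave the physical
#' range, so the result is clamped to `clamp` (the kinetics equations
#' diverge as HE approaches 1).
#'
#' @param he_variant "A", "B" or "C".
#' @param kin an [kinetics_params()] object.
#' @param Ql liver insulin mass (mU; variant C).
#' @param Qlb basal liver insulin mass (mU; variant C).
#' @param G plasma glucose (mg/dL; variant B). `Gb` is taken from `kin`.
#' @param clamp numeric length-2, the allowed `[min, max]` HE interval.
#' @return The extraction fraction (vectorised over `Ql` / `G`).
#' @examples
#' kin <- kinetics_params(VI = 3.4, m1 = 0.15, CL = 1.16, HEb = 0.59,
#'                        aI = 16e-5)
#' hepatic_extraction("C", kin, Ql = 556, Qlb = 56)
#' @export
hepatic_extraction <- function(he_variant, kin, Ql = NULL, Qlb = NULL,
                               G = NULL, clamp = c(0, 0.95)) {
  he_variant <- toupper(he_variant)
  he <- switch(he_variant,
    A = kin$HEb,
    B = {
      if (is.null(G)) stop("HE variant B needs a glucose value", call. = FALSE)
      if (!is.finite(kin$Gb)) stop("HE variant B needs basal glucose Gb",
                                   call. = FALSE)
      -kin$aG * (G - kin$Gb) + kin$HEb
    },
    C = {
      if (is.null(Ql) || is.null(Qlb))
        stop("HE variant C needs the liver insulin mass Ql and its basal ",
             "value Qlb", call. = FALSE)
      -kin$aI * (Ql - Qlb) + kin$HEb
    },
    stop("unknown HE variant: ", he_variant, call. = FALSE)
  )
  pmin(pmax(he, clamp[1]), clamp[2])
}

#' Check a full parameter set for structural feasibility
#'
#' @param kin an [kinetics_params()] object.
#' @return `TRUE` invisibly; errors describe the violated constraint.
#' @noRd
check_feasible <- function(kin) {
  derive_m4(kin)        # errors when CL/VI <= HEb*m2
  derive_m3_basal(kin)  # errors when HEb outside (0,1)
  invisible(TRUE)
}
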