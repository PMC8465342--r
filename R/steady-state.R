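#' Basal steady state of an IP insulin model
#'
#' The unique state with all derivatives zero under a constant infusion
#' `inf_b`. At that state the absorption flux equals the infusion
#' (`RaI = inf_b`) for every absorption variant, and the plasma/liver masses
#' solve the linear system `(m2 + m4) Qpb = m1 Qlb` and
#' `(m1 + m3b) Qlb = m2 Qpb + inf_b` with `m3b` evaluated at `HEb` (all
#' three HE laws reduce to `HEb` at basal). Used as the initial condition of
#' every simulation, so no burn-in is needed.
#'
#' @param model an [ipk_model()].
#' @param abs an [absorption_params()] set (the first meal period's, if
#'   meal-varying).
#' @param kin an [kinetics_params()] set.
#' @param inf_b constant basal infusion rate (mU/min, >= 0).
#' @return A named numeric vector with `Qip1`, `Qip2`, `Qp`, `Ql` (mU) and
#'   the basal plasma concentration `Ipb` (mU/L) as attribute `"Ipb"`.
#'   `Qip2` is `NA` for absorption variant 1, which has no second
#'   compartment.
#' @examples
#' kin <- kinetics_params(VI = 3.4, m1 = 0.15, CL = 1.16, HEb = 0.59)
#' abs <- absorption_params(ka1 = 0.010, ka2 = 0.028)
#' basal_steady_state(ipk_model("3A"), abs, kin, inf_b = 15.6)
#' @export
basal_steady_state <- function(model, abs, kin, inf_b) {
  if (!is.finite(inf_b) || inf_b < 0)
    stop("inf_b must be finite and >= 0", call. = FALSE)
  m4 <- derive_m4(kin)
  m3b <- derive_m3_basal(kin)

  ip <- switch(model$absorption,
    {
      if (inf_b > 0 && abs$ka1 <= 0)
        stop("no steady state: positive infusion with zero absorption",
             call. = FALSE)
      c(Qip1 = if (inf_b == 0) 0 else inf_b / abs$ka1, Qip2 = NA_real_)
    },
    {
      if (inf_b > 0 && (abs$kd <= 0 || abs$ka2 <= 0))
        stop("no steady state: positive infusion with zero absorption",
             call. = FALSE)
      c(Qip1 = if (inf_b == 0) 0 else inf_b / abs$kd,
        Qip2 = if (inf_b == 0) 0 else inf_b / abs$ka2)
    },
    {
      ktot <- abs$ka1 + abs$ka2
      if (inf_b > 0 && ktot <= 0)
        stop("no steady state: positive infusion with zero absorption",
             call. = FALSE)
      q <- if (inf_b == 0) 0 else inf_b / ktot
      c(Qip1 = q, Qip2 = q)
    })

  # (m2+m4) Qpb = m1 Qlb ; (m1+m3b) Qlb = m2 Qpb + inf_b
  denom <- (kin$m1 + m3b) - kin$m2 * kin$m1 / (kin$m2 + m4)
  Qlb <- inf_b / denom
  Qpb <- kin$m1 * Qlb / (kin$m2 + m4)
  out <- c(ip, Qp = Qpb, Ql = Qlb)
  attr(out, "Ipb") <- Qpb / kin$VI
  out
}
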