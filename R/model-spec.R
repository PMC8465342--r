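#' Model specification for the IP insulin model battery
#'
#' The battery crosses three linear models of intraperitoneal (IP) insulin
#' absorption with three descriptions of hepatic insulin extraction (HE) on
#' top of a shared two-compartment model of whole-body insulin kinetics,
#' giving nine candidate models.
#'
#' Absorption variants:
#' \describe{
#'   \item{M1}{single IP compartment; absorption to the liver at rate `ka1`.}
#'   \item{M2}{two IP compartments in series; transfer at rate `kd`,
#'     absorption from the second compartment at rate `ka2` (with the
#'     identifiability convention `kd >= ka2`).}
#'   \item{M3}{two IP compartments with absorption from both: rate `ka1`
#'     from the first and `ka2` from the second; the inter-compartment
#'     transfer also runs at rate `ka2`.}
#' }
#'
#' Hepatic-extraction variants:
#' \describe{
#'   \item{A}{constant extraction, `HE(t) = HEb`.}
#'   \item{B}{extraction modulated by plasma glucose,
#'     `HE(t) = -aG * (G(t) - Gb) + HEb`.}
#'   \item{C}{extraction modulated by liver insulin mass,
#'     `HE(t) = -aI * (Ql(t) - Qlb) + HEb`.}
#' }
#'
#' @param absorption IP absorption variant: 1, 2 or 3 (or "M1", "M2", "M3").
#' @param he hepatic-extraction variant: "A", "B" or "C". May be omitted if
#'   `absorption` is a combined code such as `"3C"`.
#'
#' @return An object of class `"ipk_model"` with fields `absorption` (integer
#'   1..3) and `he` (character "A"/"B"/"C"). `format()` returns the compact
#'   code (e.g. `"3C"`), which round-trips through `ipk_model()`.
#'
#' @examples
#' ipk_model("3C")
#' ipk_model(2, "B")
#' @export
ipk_model <- function(absorption, he = NULL) {
  if (is.null(he) && is.character(absorption) && length(absorption) == 1L &&
      grepl("^M?[123][ABC]$", absorption)) {
    code <- sub("^M", "", absorption)
    absorption <- substr(code, 1, 1)
    he <- substr(code, 2, 2)
  }
  if (is.character(absorption)) absorption <- sub("^M", "", absorption)
  absorption <- suppressWarnings(as.integer(absorption))
  if (length(absorption) != 1L || is.na(absorption) || !absorption %in% 1:3)
    stop("absorption variant must be 1, 2 or 3", call. = FALSE)
  if (is.null(he) || length(he) != 1L || !toupper(he) %in% c("A", "B", "C"))
    stop("hepatic-extraction variant must be \"A\", \"B\" or \"C\"",
         call. = FALSE)
  structure(list(absorption = absorption, he = toupper(he)),
            class = "ipk_model")
}

#' @export
format.ipk_model <- function(x, ...) paste0(x$absorption, x$he)

#' @export
print.ipk_model <- function(x, ...) {
  abs_desc <- c("one-compartment IP absorption (ka1)",
                "two-compartment IP absorption, distal exit (kd, ka2)",
                "two-compartment IP absorption, exits from both (ka1, ka2)")
  he_desc <- c(A = "constant hepatic extraction",
               B = "glucose-controlled hepatic extraction (aG)",
               C = "liver-insulin-controlled hepatic extraction (aI)")
  cat("IP insulin kinetics model ", format(x), ":\n",
      "  absorption: Model ", x$absorption, " - ", abs_desc[x$absorption], "\n",
      "  extraction: Model ", x$he, " - ", he_desc[[x$he]], "\n", sep = "")
  invisible(x)
}

#' All nine models of the battery
#'
#' @return A list of the nine `ipk_model` objects, named by their codes
#'   ("1A", "2A", ..., "3C").
#' @examples
#' names(ipk_battery_models())
#' @export
ipk_battery_models <- function() {
  specs <- list()
  for (he in c("A", "B", "C"))
    for (a in 1:3)
      specs[[paste0(a, he)]] <- ipk_model(a, he)
  specs
}

#' Names of the absorption parameters a variant uses
#' @noRd
abs_param_names <- function(absorption) {
  switch(absorption, c("ka1"), c("kd", "ka2"), c("ka1", "ka2"))
}
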