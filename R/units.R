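#' Convert analyte concentrations between mg/dL and mmol/L
#'
#' Clinical chemistry reports glucose and lipids either in mass units
#' (mg/dL) or molar units (mmol/L). The conversion factor is the molar
#' mass scaled to the deciliter: glucose 18.016, triglycerides 88.57
#' (average triglyceride), cholesterol 38.67 mg/dL per mmol/L. These
#' factors reproduce the usual dual-unit diagnostic thresholds after
#' rounding: glucose 100 mg/dL = 5.55 mmol/L, triglycerides 150 mg/dL =
#' 1.7 mmol/L, HDL cholesterol 50 mg/dL = 1.3 mmol/L.
#'
#' @param value numeric vector of concentrations, `>= 0`.
#' @param analyte one of `"glucose"`, `"triglycerides"`, `"cholesterol"`.
#' @return numeric vector in the target unit.
#' @examples
#' mgdl_to_mmol(150, "triglycerides")  # 1.69
#' mmol_to_mgdl(mgdl_to_mmol(97, "glucose"), "glucose")  # 97
#' @export
mgdl_to_mmol <- function(value, analyte) {
  value / .conversion_factor(analyte, value)
}

#' @rdname mgdl_to_mmol
#' @export
mmol_to_mgdl <- function(value, analyte) {
  value * .conversion_factor(analyte, value)
}

# mg/dL per mmol/L
.analyte_factors <- c(glucose = 18.016, triglycerides = 88.57,
                      cholesterol = 38.67)

.conversion_factor <- function(analyte, value) {
  if (length(analyte) != 1L || !analyte %in% names(.analyte_factors)) {
    stop(sprintf("unknown analyte '%s'; expected one of %s",
                 paste(analyte, collapse = ", "),
                 paste(sQuote(names(.analyte_factors)), collapse = ", ")),
         call. = FALSE)
  }
  if (any(!is.finite(value)) || any(value < 0)) {
    stop("concentration values must be finite and non-negative",
         call. = FALSE)
  }
  .analyte_factors[[analyte]]
}
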