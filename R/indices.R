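#' Body mass index
#'
#' @param body_mass_kg body mass in kg, `> 0`.
#' @param stature_m stature in metres, `> 0`.
#' @return BMI in kg/m^2.
#' @export
bmi <- function(body_mass_kg, stature_m) {
  .check_positive(body_mass_kg = body_mass_kg, stature_m = stature_m)
  body_mass_kg / stature_m^2
}

#' Waist-to-hip ratio
#'
#' @param wc_cm waist circumference, cm.
#' @param hc_cm hip circumference, cm.
#' @return dimensionless ratio WC/HC.
#' @export
whr <- function(wc_cm, hc_cm) {
  .check_positive(wc_cm = wc_cm, hc_cm = hc_cm)
  wc_cm / hc_cm
}

#' Waist-to-height ratio
#'
#' Both arguments are in centimetres. A stature below 3 is rejected as a
#' probable metre-valued input, the most common unit mistake with this
#' ratio.
#'
#' @param wc_cm waist circumference, cm.
#' @param stature_cm stature, cm (not metres).
#' @return dimensionless ratio WC/height.
#' @export
wthr <- function(wc_cm, stature_cm) {
  .check_positive(wc_cm = wc_cm, stature_cm = stature_cm)
  if (any(stature_cm < 3)) {
    stop("stature_cm looks like a value in metres; supply centimetres",
         call. = FALSE)
  }
  wc_cm / stature_cm
}

#' Body mass fat index
#'
#' BMFI combines overall size (BMI), relative adiposity (fat-mass
#' fraction) and central adiposity (waist circumference in metres). The
#' fat-mass term enters as a fraction in \[0, 1\]; callers holding a
#' percentage must divide by 100 (values above 1 are rejected).
#'
#' @param bmi BMI, kg/m^2.
#' @param fm_fraction fat mass as a fraction of body mass, in \[0, 1\].
#' @param wc_m waist circumference, metres.
#' @return BMFI in kg/m.
#' @export
bmfi <- function(bmi, fm_fraction, wc_m) {
  .check_positive(bmi = bmi, wc_m = wc_m)
  if (any(!is.finite(fm_fraction)) || any(fm_fraction < 0) ||
      any(fm_fraction > 1)) {
    stop("fm_fraction must lie in [0, 1]; divide a percentage by 100",
         call. = FALSE)
  }
  bmi * fm_fraction * wc_m
}

#' Visceral adiposity index (female formula)
#'
#' VAI = (WC / (36.58 + 1.89 BMI)) * (TG / 0.81) * (1.52 / HDL), the
#' sex-specific composite for women, with both lipids in mmol/L. Only the
#' female branch is implemented; the study population is women-only and
#' the `sex` argument is reserved.
#'
#' @param wc_cm waist circumference, cm.
#' @param bmi BMI, kg/m^2.
#' @param tg_mmol fasting triglycerides, mmol/L, `> 0`.
#' @param hdl_mmol HDL cholesterol, mmol/L, `> 0`.
#' @param sex `"female"` (the only implemented branch).
#' @return dimensionless VAI score.
#' @export
vai <- function(wc_cm, bmi, tg_mmol, hdl_mmol, sex = "female") {
  if (!identical(sex, "female")) {
    stop("only the female VAI formula is implemented", call. = FALSE)
  }
  .check_positive(wc_cm = wc_cm, bmi = bmi, tg_mmol = tg_mmol,
                  hdl_mmol = hdl_mmol)
  (wc_cm / (36.58 + 1.89 * bmi)) * (tg_mmol / 0.81) * (1.52 / hdl_mmol)
}

#' Cardiometabolic index
#'
#' CMI = WtHR * TG / HDL with both lipids in mmol/L.
#'
#' @param wthr waist-to-height ratio, dimensionless.
#' @param tg_mmol fasting triglycerides, mmol/L, `> 0`.
#' @param hdl_mmol HDL cholesterol, mmol/L, `> 0`.
#' @return dimensionless CMI score.
#' @export
cmi <- function(wthr, tg_mmol, hdl_mmol) {
  .check_positive(wthr = wthr, tg_mmol = tg_mmol, hdl_mmol = hdl_mmol)
  wthr * tg_mmol / hdl_mmol
}

#' Compute the five-index panel for one subject
#'
#' Orchestrates the scalar index functions for a single subject record,
#' performing the internal unit conversions (waist cm to m for BMFI,
#' triglycerides and HDL mg/dL to mmol/L for VAI and CMI). The fat-mass
#' fraction is taken from `fm_fraction` if present, otherwise derived as
#' `fm_kg / body_mass_kg`.
#'
#' @param record a named list or one-row data.frame with fields
#'   `stature_m`, `body_mass_kg`, `wc_cm`, `hc_cm`, `tg_mgdl`,
#'   `hdl_mgdl`, and at least one of `fm_kg` / `fm_fraction`; an optional
#'   `subject_id` is used in error messages.
#' @return a list with elements `whr`, `wthr`, `bmfi`, `vai`, `cmi`.
#' @seealso [compute_indices()] for the vectorised cohort version.
#' @export
index_panel <- function(record) {
  record <- as.list(record)
  id <- if (!is.null(record$subject_id)) record$subject_id else "<unknown>"
  required <- c("stature_m", "body_mass_kg", "wc_cm", "hc_cm",
                "tg_mgdl", "hdl_mgdl")
  present <- vapply(required, function(f) {
    !is.null(record[[f]]) && !is.na(record[[f]])
  }, logical(1))
  if (!all(present)) {
    stop(sprintf("subject %s: missing required field(s) %s", id,
                 paste(sQuote(required[!present]), collapse = ", ")),
         call. = FALSE)
  }
  fmf <- .fm_fraction(record, id)

  b <- bmi(record$body_mass_kg, record$stature_m)
  tg <- mgdl_to_mmol(record$tg_mgdl, "triglycerides")
  hdl <- mgdl_to_mmol(record$hdl_mgdl, "cholesterol")
  wthr_val <- wthr(record$wc_cm, record$stature_m * 100)
  list(
    whr = whr(record$wc_cm, record$hc_cm),
    wthr = wthr_val,
    bmfi = bmfi(b, fmf, record$wc_cm / 100),
    vai = vai(record$wc_cm, b, tg, hdl),
    cmi = cmi(wthr_val, tg, hdl)
  )
}

# fat-mass fraction from whichever of fm_fraction / fm_kg is available;
# when both are present they must agree to within 0.005.
.fm_fraction <- function(record, id) {
  frac <- record$fm_fraction
  kg <- record$fm_kg
  has_frac <- !is.null(frac) && !all(is.na(frac))
  has_kg <- !is.null(kg) && !all(is.na(kg))
  if (!has_frac && !has_kg) {
    stop(sprintf(
      "subject %s: missing required field(s) 'fm_kg' or 'fm_fraction'",
      id), call. = FALSE)
  }
  if (has_frac && has_kg) {
    derived <- kg / record$body_mass_kg
    if (any(abs(derived - frac) > 0.005, na.rm = TRUE)) {
      stop(sprintf(
        "subject %s: fm_kg/body_mass_kg and fm_fraction disagree by > 0.005",
        id), call. = FALSE)
    }
  }
  if (has_frac) frac else kg / record$body_mass_kg
}

.check_positive <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (any(!is.finite(v)) || any(v <= 0)) {
      stop(sprintf("'%s' must be finite and > 0", nm), call. = FALSE)
    }
  }
  invisible(TRUE)
}
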