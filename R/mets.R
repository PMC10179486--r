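#' Evaluate the IDF metabolic-syndrome criteria for a cohort
#'
#' Applies the five International Diabetes Federation risk-factor
#' thresholds for women: waist circumference >= 80 cm; fasting plasma
#' glucose >= 100 mg/dL or on glucose-lowering treatment; SBP >= 130 or
#' DBP >= 85 mmHg or on antihypertensive treatment; triglycerides
#' >= 150 mg/dL or on TG-lowering treatment; HDL-C < 50 mg/dL or on
#' HDL-raising treatment. Boundary semantics are `>=` everywhere except
#' the strict `<` for HDL. Glucose is compared in mg/dL, its source
#' unit, so no conversion rounding can move a subject across the
#' boundary.
#'
#' Two operationalisations of the syndrome are available:
#' \describe{
#'   \item{`"any3"`}{(default) MetS when three or more of the five
#'     criteria are met, waist circumference counted as an ordinary
#'     criterion.}
#'   \item{`"canonical"`}{the textbook IDF rule: central obesity is
#'     mandatory, plus at least two of the remaining four.}
#' }
#'
#' @param cohort a validated cohort data.frame (see [validate_cohort()]).
#' @param variant `"any3"` or `"canonical"`.
#' @return a data.frame with `subject_id`, the five criterion logicals
#'   (`central_obesity`, `hyperglycemia`, `elevated_bp`, `elevated_tg`,
#'   `reduced_hdl`), `n_criteria` (0--5) and `mets`.
#' @export
classify_mets <- function(cohort, variant = c("any3", "canonical")) {
  variant <- match.arg(variant)
  cohort <- validate_cohort(cohort)
  need <- c("wc_cm", "glucose_mgdl", "sbp", "dbp", "tg_mgdl",
            "hdl_mgdl")
  for (f in need) {
    bad <- which(is.na(cohort[[f]]))
    if (length(bad)) {
      stop(sprintf("subject %s (row %d): missing criterion input '%s'",
                   cohort$subject_id[bad[1L]], bad[1L], f),
           call. = FALSE)
    }
  }
  res <- data.frame(
    subject_id = cohort$subject_id,
    central_obesity = cohort$wc_cm >= 80,
    hyperglycemia = cohort$glucose_mgdl >= 100 | cohort$on_glucose_drug,
    elevated_bp = cohort$sbp >= 130 | cohort$dbp >= 85 |
      cohort$on_bp_drug,
    elevated_tg = cohort$tg_mgdl >= 150 | cohort$on_tg_drug,
    reduced_hdl = cohort$hdl_mgdl < 50 | cohort$on_hdl_drug,
    stringsAsFactors = FALSE
  )
  res$n_criteria <- res$central_obesity + res$hyperglycemia +
    res$elevated_bp + res$elevated_tg + res$reduced_hdl
  res$mets <- switch(variant,
    any3 = res$n_criteria >= 3L,
    canonical = res$central_obesity &
      (res$n_criteria - res$central_obesity) >= 2L
  )
  res
}

#' Evaluate the IDF criteria for a single subject
#'
#' Single-record convenience wrapper around [classify_mets()].
#'
#' @param record a named list or one-row data.frame with the criterion
#'   inputs (`wc_cm`, `glucose_mgdl`, `sbp`, `dbp`, `tg_mgdl`,
#'   `hdl_mgdl`) and drug flags; missing drug flags default to `FALSE`.
#' @inheritParams classify_mets
#' @return a one-row data.frame as from [classify_mets()].
#' @export
evaluate_idf_criteria <- function(record, variant = c("any3",
                                                      "canonical")) {
  record <- as.list(record)
  defaults <- list(subject_id = "<subject>", age = NA_real_,
                   stature_m = 1.6, body_mass_kg = 80, hc_cm = 100,
                   fm_kg = NA_real_)
  for (nm in names(defaults)) {
    if (is.null(record[[nm]])) record[[nm]] <- defaults[[nm]]
  }
  for (nm in .drug_columns) {
    if (is.null(record[[nm]]) || is.na(record[[nm]])) {
      record[[nm]] <- FALSE
    }
  }
  need <- c("wc_cm", "glucose_mgdl", "sbp", "dbp", "tg_mgdl",
            "hdl_mgdl")
  miss <- need[vapply(need, function(f) is.null(record[[f]]) ||
                        is.na(record[[f]]), logical(1))]
  if (length(miss)) {
    stop(sprintf("subject %s: missing criterion input(s) %s",
                 record$subject_id,
                 paste(sQuote(miss), collapse = ", ")), call. = FALSE)
  }
  df <- as.data.frame(record[c("subject_id", "age", "stature_m",
                               "body_mass_kg", "wc_cm", "hc_cm",
                               "fm_kg", "sbp", "dbp", "glucose_mgdl",
                               "tg_mgdl", "hdl_mgdl", .drug_columns)],
                      stringsAsFactors = FALSE)
  classify_mets(df, variant = match.arg(variant))
}

#' Cohort-level criterion prevalence
#'
#' Counts and proportions for each IDF criterion plus the overall MetS
#' prevalence.
#'
#' @inheritParams classify_mets
#' @return a data.frame with one row per criterion (and a final `mets`
#'   row): `criterion`, `count`, `proportion`.
#' @export
cohort_criterion_prevalence <- function(cohort,
                                        variant = c("any3",
                                                    "canonical")) {
  if (NROW(cohort) == 0L) stop("empty cohort", call. = FALSE)
  cls <- classify_mets(cohort, variant = match.arg(variant))
  items <- c("central_obesity", "hyperglycemia", "elevated_bp",
             "elevated_tg", "reduced_hdl", "mets")
  counts <- vapply(items, function(f) sum(cls[[f]]), integer(1))
  data.frame(criterion = items, count = as.integer(counts),
             proportion = counts / nrow(cls), row.names = NULL,
             stringsAsFactors = FALSE)
}
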