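#' @keywords internal
"_PACKAGE"

# Canonical cohort CSV schema: one header row, one row per subject.
.cohort_columns <- c("subject_id", "age", "stature_m", "body_mass_kg",
                     "wc_cm", "hc_cm", "fm_kg", "sbp", "dbp",
                     "glucose_mgdl", "tg_mgdl", "hdl_mgdl",
                     "on_glucose_drug", "on_bp_drug", "on_tg_drug",
                     "on_hdl_drug")
.drug_columns <- c("on_glucose_drug", "on_bp_drug", "on_tg_drug",
                   "on_hdl_drug")

#' Read a subject-level cohort CSV
#'
#' Expects the canonical schema (columns `subject_id`, `age`,
#' `stature_m`, `body_mass_kg`, `wc_cm`, `hc_cm`, `fm_kg`, `sbp`, `dbp`,
#' `glucose_mgdl`, `tg_mgdl`, `hdl_mgdl` and the four 0/1 drug-treatment
#' flags). Lines starting with `#` are treated as comments; the
#' generator uses them to record the seed. The file is validated on
#' read; violations abort with the offending row numbers.
#'
#' @param path path to a CSV file.
#' @return a validated data.frame, drug flags as logicals.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  validate_cohort(df)
}

#' Write a cohort to CSV
#'
#' Only the canonical schema columns are written, drug flags as 0/1.
#' Optional `comments` (e.g. seed provenance) are emitted as leading
#' `#` lines.
#'
#' @param cohort a cohort data.frame.
#' @param path output path.
#' @param comments character vector of comment lines (without `#`).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, comments = character()) {
  out <- cohort[, .cohort_columns]
  for (col in .drug_columns) out[[col]] <- as.integer(out[[col]])
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(out, con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Validate a cohort data.frame against the canonical schema
#'
#' Checks column presence, coerces drug flags to logical, and enforces
#' row-level invariants (positive stature, body mass, circumferences and
#' HDL; non-negative glucose and triglycerides; fat mass consistent with
#' body mass where both fat-mass encodings are present). Violations are
#' reported with their row numbers.
#'
#' @param cohort a data.frame in the cohort schema.
#' @return the validated data.frame, invisibly usable downstream.
#' @export
validate_cohort <- function(cohort) {
  missing_cols <- setdiff(.cohort_columns, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing column(s): ",
         paste(sQuote(missing_cols), collapse = ", "), call. = FALSE)
  }
  for (col in .drug_columns) {
    v <- cohort[[col]]
    if (is.logical(v)) next
    if (!all(v %in% c(0L, 1L, NA))) {
      stop(sprintf("column '%s' must be 0/1", col), call. = FALSE)
    }
    cohort[[col]] <- as.logical(v)
  }
  problems <- character()
  flag <- function(bad, what) {
    rows <- which(bad)
    if (length(rows)) {
      problems <<- c(problems, sprintf(
        "%s (row %s)", what,
        paste(utils::head(rows, 5L), collapse = ", ")))
    }
  }
  nz <- function(v) !is.na(v) & v <= 0
  flag(nz(cohort$stature_m), "stature_m must be > 0")
  flag(nz(cohort$body_mass_kg), "body_mass_kg must be > 0")
  flag(nz(cohort$wc_cm), "wc_cm must be > 0")
  flag(nz(cohort$hc_cm), "hc_cm must be > 0")
  flag(nz(cohort$hdl_mgdl), "hdl_mgdl must be > 0")
  flag(!is.na(cohort$tg_mgdl) & cohort$tg_mgdl < 0,
       "tg_mgdl must be >= 0")
  flag(!is.na(cohort$glucose_mgdl) & cohort$glucose_mgdl < 0,
       "glucose_mgdl must be >= 0")
  if (!is.null(cohort$fm_fraction)) {
    both <- !is.na(cohort$fm_fraction) & !is.na(cohort$fm_kg)
    flag(both & abs(cohort$fm_kg / cohort$body_mass_kg -
                      cohort$fm_fraction) > 0.005,
         "fm_kg / body_mass_kg disagrees with fm_fraction")
  }
  if (length(problems)) {
    stop("invalid cohort:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  cohort
}

#' Add the five index columns to a cohort
#'
#' Vectorised counterpart of [index_panel()]: appends `whr`, `wthr`,
#' `bmfi`, `vai` and `cmi` columns, preserving the input rows. Rows with
#' a missing required field abort with the subject id and field name.
#'
#' @param cohort a validated cohort data.frame.
#' @return `cohort` with five extra columns.
#' @export
compute_indices <- function(cohort) {
  cohort <- validate_cohort(cohort)
  need <- c("stature_m", "body_mass_kg", "wc_cm", "hc_cm", "tg_mgdl",
            "hdl_mgdl", "fm_kg")
  for (f in need) {
    bad <- which(is.na(cohort[[f]]))
    if (f == "fm_kg" && !is.null(cohort$fm_fraction)) {
      bad <- which(is.na(cohort$fm_kg) & is.na(cohort$fm_fraction))
    }
    if (length(bad)) {
      stop(sprintf("subject %s (row %d): missing required field '%s'",
                   cohort$subject_id[bad[1L]], bad[1L], f),
           call. = FALSE)
    }
  }
  fmf <- if (!is.null(cohort$fm_fraction)) {
    ifelse(is.na(cohort$fm_fraction),
           cohort$fm_kg / cohort$body_mass_kg, cohort$fm_fraction)
  } else {
    cohort$fm_kg / cohort$body_mass_kg
  }
  b <- bmi(cohort$body_mass_kg, cohort$stature_m)
  tg <- mgdl_to_mmol(cohort$tg_mgdl, "triglycerides")
  hdl <- mgdl_to_mmol(cohort$hdl_mgdl, "cholesterol")
  cohort$whr <- whr(cohort$wc_cm, cohort$hc_cm)
  cohort$wthr <- wthr(cohort$wc_cm, cohort$stature_m * 100)
  cohort$bmfi <- bmfi(b, fmf, cohort$wc_cm / 100)
  cohort$vai <- vai(cohort$wc_cm, b, tg, hdl)
  cohort$cmi <- cmi(cohort$wthr, tg, hdl)
  cohort
}
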