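.index_names <- c("WHR", "WtHR", "BMFI", "VAI", "CMI")
.index_cols <- c(WHR = "whr", WtHR = "wthr", BMFI = "bmfi",
                 VAI = "vai", CMI = "cmi")

#' Evaluate adiposity indexes as diagnostic markers for MetS
#'
#' Runs the full accuracy analysis on a cohort: computes the requested
#' indexes, labels subjects by the IDF classifier, and for each index
#' builds the empirical ROC curve with DeLong AUC confidence interval,
#' selects the operating cutoff (Youden-optimal unless a fixed cutoff
#' is supplied), and derives the cutoff-level diagnostic summary
#' (sensitivity, specificity, PPV, NPV, likelihood ratios, Youden's J)
#' together with the positivity rate. All pairwise AUC differences are
#' tested with the paired DeLong test; the p-values are unadjusted.
#'
#' @param cohort a cohort data.frame (indexes are computed if absent).
#' @param indices subset of `c("WHR", "WtHR", "BMFI", "VAI", "CMI")`.
#' @param variant IDF variant passed to [classify_mets()].
#' @param conf_level confidence level for AUC and proportion intervals.
#' @param cutoffs optional named numeric vector of fixed cutoffs (names
#'   among `indices`); indexes not named fall back to the Youden
#'   cutoff.
#' @param labels optional logical vector of disease labels, overriding
#'   the IDF classification (e.g. an external diagnosis).
#' @return an object of class `index_evaluation`: list with `summary`
#'   (one row per index: auc, se, ci, cutoff, cutoff_policy, counts,
#'   sensitivity, specificity, ppv, npv, plr, nlr, youden,
#'   positivity_rate), `comparisons` (matrix of pairwise DeLong
#'   p-values), `roc` (named list of `roc_curve` objects), `n_pos`,
#'   `n_neg`, `variant`, `conf_level`.
#' @export
evaluate_indices <- function(cohort, indices = .index_names,
                             variant = c("any3", "canonical"),
                             conf_level = 0.95, cutoffs = NULL,
                             labels = NULL) {
  variant <- match.arg(variant)
  indices <- match.arg(indices, .index_names, several.ok = TRUE)
  if (!all(.index_cols[indices] %in% names(cohort))) {
    cohort <- compute_indices(cohort)
  }
  if (is.null(labels)) {
    labels <- classify_mets(cohort, variant = variant)$mets
  }
  if (!any(labels) || all(labels)) {
    missing_class <- if (all(labels)) "MetS-negative" else
      "MetS-positive"
    stop("cohort contains no ", missing_class,
         " subjects; cannot evaluate", call. = FALSE)
  }
  rocs <- list()
  rows <- list()
  for (ix in indices) {
    scores <- cohort[[.index_cols[[ix]]]]
    r <- roc_curve(scores, labels, conf_level = conf_level)
    rocs[[ix]] <- r
    if (!is.null(cutoffs) && ix %in% names(cutoffs)) {
      cutoff <- cutoffs[[ix]]
      policy <- "fixed"
    } else {
      cutoff <- youden_optimal_cutoff(r)$cutoff
      policy <- "youden"
    }
    ds <- diagnostic_summary(confusion_at_cutoff(scores, labels,
                                                 cutoff),
                             cutoff = cutoff, conf_level = conf_level)
    rows[[ix]] <- data.frame(
      index = ix, auc = r$auc, auc_se = r$auc_se,
      auc_ci_lower = r$auc_ci[1], auc_ci_upper = r$auc_ci[2],
      cutoff = cutoff, cutoff_policy = policy,
      sensitivity = ds$sensitivity, specificity = ds$specificity,
      ppv = ds$ppv, npv = ds$npv, plr = ds$plr, nlr = ds$nlr,
      youden = ds$youden,
      positivity_rate = positivity_rate(scores, cutoff),
      tp = ds$counts[["tp"]], fp = ds$counts[["fp"]],
      tn = ds$counts[["tn"]], fn = ds$counts[["fn"]],
      stringsAsFactors = FALSE)
  }
  comp <- matrix(NA_real_, length(indices), length(indices),
                 dimnames = list(indices, indices))
  if (length(indices) > 1L) {
    for (i in seq_along(indices)) {
      for (j in seq_along(indices)) {
        if (i >= j) next
        cmp <- compare_auc_delong(
          cohort[[.index_cols[[indices[i]]]]],
          cohort[[.index_cols[[indices[j]]]]], labels)
        comp[i, j] <- comp[j, i] <- cmp$p
      }
    }
  }
  structure(list(summary = do.call(rbind,
                                   c(rows, make.row.names = FALSE)),
                 comparisons = comp, roc = rocs,
                 n_pos = sum(labels), n_neg = sum(!labels),
                 variant = variant, conf_level = conf_level),
            class = "index_evaluation")
}

#' @export
print.index_evaluation <- function(x, ...) {
  cat(sprintf(
    "Index evaluation: %d MetS+ / %d MetS- subjects (IDF variant '%s')\n",
    x$n_pos, x$n_neg, x$variant))
  s <- x$summary
  tab <- data.frame(index = s$index,
                    AUC = sprintf("%.2f", s$auc),
                    CI = sprintf("(%.2f-%.2f)", s$auc_ci_lower,
                                 s$auc_ci_upper),
                    cutoff = sprintf("%.2f", s$cutoff),
                    Se = sprintf("%.1f%%", 100 * s$sensitivity),
                    Sp = sprintf("%.1f%%", 100 * s$specificity),
                    PPV = sprintf("%.1f%%", 100 * s$ppv),
                    NPV = sprintf("%.1f%%", 100 * s$npv),
                    PLR = sprintf("%.2f", s$plr),
                    NLR = sprintf("%.2f", s$nlr),
                    Youden = sprintf("%.2f", s$youden))
  print(tab, row.names = FALSE)
  cat("Pairwise DeLong p-values are unadjusted.\n")
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Emits three artefacts under `dir`: `evaluation.json` (full
#' precision), `evaluation.csv` (one row per index, rendered at the
#' usual table precisions: AUC 2 d.p., proportions 1 d.p. as percent,
#' likelihood ratios and Youden 2 d.p.), and `roc_points.csv` (the ROC
#' coordinates of every index, for plotting).
#'
#' @param evaluation an `index_evaluation`.
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_evaluation_report <- function(evaluation, dir) {
  stopifnot(inherits(evaluation, "index_evaluation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- evaluation$summary
  jsonlite::write_json(
    list(summary = s, comparisons = evaluation$comparisons,
         n_pos = evaluation$n_pos, n_neg = evaluation$n_neg,
         variant = evaluation$variant,
         conf_level = evaluation$conf_level,
         note = "pairwise AUC comparison p-values are unadjusted"),
    file.path(dir, "evaluation.json"), auto_unbox = TRUE, digits = NA,
    matrix = "columnmajor", na = "null")
  rendered <- data.frame(
    index = s$index,
    auc = sprintf("%.2f", s$auc),
    auc_ci_lower = sprintf("%.2f", s$auc_ci_lower),
    auc_ci_upper = sprintf("%.2f", s$auc_ci_upper),
    cutoff = sprintf("%.4g", s$cutoff),
    sensitivity_pct = sprintf("%.1f", 100 * s$sensitivity),
    specificity_pct = sprintf("%.1f", 100 * s$specificity),
    ppv_pct = sprintf("%.1f", 100 * s$ppv),
    npv_pct = sprintf("%.1f", 100 * s$npv),
    plr = sprintf("%.2f", s$plr),
    nlr = sprintf("%.2f", s$nlr),
    youden = sprintf("%.2f", s$youden),
    positivity_rate_pct = sprintf("%.1f", 100 * s$positivity_rate),
    stringsAsFactors = FALSE)
  utils::write.csv(rendered, file.path(dir, "evaluation.csv"),
                   row.names = FALSE, quote = FALSE)
  pts <- do.call(rbind, lapply(names(evaluation$roc), function(ix) {
    r <- evaluation$roc[[ix]]
    data.frame(index = ix, threshold = r$thresholds, fpr = r$fpr,
               tpr = r$tpr, stringsAsFactors = FALSE)
  }))
  utils::write.csv(pts, file.path(dir, "roc_points.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
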