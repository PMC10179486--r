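#' Empirical ROC curve with DeLong confidence interval
#'
#' Builds the empirical ROC curve of a continuous score against binary
#' disease labels, higher scores meaning more disease-like. The curve is
#' traced over every distinct score value (plus an infinite sentinel so
#' it starts at (0, 0) and ends at (1, 1)); the area is the trapezoid
#' area under the curve, which for the empirical curve equals the
#' Mann--Whitney probability that a random positive outscores a random
#' negative, ties at half credit. The standard error and the
#' normal-approximation confidence interval (truncated to \[0, 1\]) use
#' the DeLong structural-components variance.
#'
#' @param scores numeric vector of marker values, finite.
#' @param labels logical (or 0/1) disease labels, at least one of each
#'   class.
#' @param conf_level confidence level for the AUC interval.
#' @return an object of class `roc_curve`: list with `thresholds`
#'   (descending, starting at `Inf`), `fpr`, `tpr`, `auc`, `auc_se`,
#'   `auc_ci`, `conf_level`, `n_pos`, `n_neg`, plus the input `scores`
#'   and `labels` for downstream cutoff analysis.
#' @examples
#' r <- roc_curve(c(1, 2, 2, 3), c(FALSE, FALSE, TRUE, TRUE))
#' r$auc  # 0.875
#' @export
roc_curve <- function(scores, labels, conf_level = 0.95) {
  labels <- .check_roc_input(scores, labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pos <- scores[labels]
  neg <- scores[!labels]
  tpr <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg >= t), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  v <- .delong_components(scores, labels)
  se <- sqrt(v$var)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(1, pmax(0, v$auc + c(-1, 1) * z * se))
  structure(list(thresholds = thr, fpr = fpr, tpr = tpr, auc = auc,
                 auc_se = se, auc_ci = ci, conf_level = conf_level,
                 n_pos = length(pos), n_neg = length(neg),
                 scores = scores, labels = labels),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf(
    "Empirical ROC curve: %d positives, %d negatives\n  AUC = %.3f (%g%% CI %.3f-%.3f, DeLong)\n",
    x$n_pos, x$n_neg, x$auc, 100 * x$conf_level, x$auc_ci[1],
    x$auc_ci[2]))
  invisible(x)
}

#' Mann--Whitney AUC by exhaustive pair counting
#'
#' Direct mean over all (positive, negative) pairs of the tie-aware
#' kernel 1\[pos > neg\] + 0.5 * 1\[pos = neg\]. Quadratic in the class
#' sizes; serves as the independent oracle for the trapezoid area of
#' [roc_curve()].
#'
#' @inheritParams roc_curve
#' @return AUC in \[0, 1\].
#' @export
auc_mann_whitney <- function(scores, labels) {
  labels <- .check_roc_input(scores, labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  k <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(k)
}

# DeLong structural components via midranks (O(n log n)).
# V10[i] = mean_j psi(X_i, Y_j), V01[j] = mean_i psi(X_i, Y_j) with
# psi the tie-aware Mann-Whitney kernel.
.delong_components <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  m <- length(pos)
  n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  auc <- mean(v10)
  s10 <- if (m > 1) stats::var(v10) else 0
  s01 <- if (n > 1) stats::var(v01) else 0
  list(auc = auc, v10 = v10, v01 = v01,
       var = s10 / m + s01 / n)
}

#' DeLong confidence interval for an AUC
#'
#' @inheritParams roc_curve
#' @return list with `auc`, `se`, `ci` (length-2), `conf_level`.
#' @export
auc_delong_ci <- function(scores, labels, conf_level = 0.95) {
  labels <- .check_roc_input(scores, labels)
  if (sum(labels) < 2L || sum(!labels) < 2L) {
    stop("DeLong variance needs at least 2 positives and 2 negatives",
         call. = FALSE)
  }
  v <- .delong_components(scores, labels)
  se <- sqrt(v$var)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(auc = v$auc, se = se,
       ci = pmin(1, pmax(0, v$auc + c(-1, 1) * z * se)),
       conf_level = conf_level)
}

#' Paired DeLong test comparing two AUCs on the same subjects
#'
#' Tests the difference between the AUCs of two markers measured on the
#' same subjects with the same disease labels, using the DeLong
#' covariance of the two AUC estimators. Two-sided p-value from the
#' normal reference.
#'
#' @param scores_a,scores_b numeric score vectors, same subjects, same
#'   order.
#' @param labels logical disease labels shared by both markers.
#' @return an object of class `auc_comparison`: list with `auc_a`,
#'   `auc_b`, `difference`, `se_difference`, `z`, `p`.
#' @export
compare_auc_delong <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b)) {
    stop("scores_a and scores_b must have the same length",
         call. = FALSE)
  }
  labels <- .check_roc_input(scores_a, labels)
  .check_roc_input(scores_b, labels)
  a <- .delong_components(scores_a, labels)
  b <- .delong_components(scores_b, labels)
  m <- sum(labels)
  n <- sum(!labels)
  cov_ab <- 0
  if (m > 1) cov_ab <- cov_ab + stats::cov(a$v10, b$v10) / m
  if (n > 1) cov_ab <- cov_ab + stats::cov(a$v01, b$v01) / n
  diff <- a$auc - b$auc
  se <- sqrt(max(0, a$var + b$var - 2 * cov_ab))
  if (se == 0) {
    z <- 0
    p <- 1
  } else {
    z <- diff / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_a = a$auc, auc_b = b$auc, difference = diff,
                 se_difference = se, z = z, p = p),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf(
    "Paired DeLong AUC comparison\n  AUC A = %.3f, AUC B = %.3f, difference = %+.3f\n  z = %.3f, two-sided p = %.4g\n",
    x$auc_a, x$auc_b, x$difference, x$z, x$p))
  invisible(x)
}

#' Youden-optimal cutoff from a ROC curve
#'
#' Maximises Youden's J = sensitivity + specificity - 1 over all
#' candidate cutoffs, with positivity defined as score strictly greater
#' than the cutoff. Candidates are every distinct score value plus
#' `-Inf` (call everyone positive, J = 0), so the returned J is never
#' negative. Ties are broken toward the smallest maximising cutoff.
#'
#' @param roc a `roc_curve` object.
#' @return list with `cutoff` and `youden`.
#' @export
youden_optimal_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  pos <- roc$scores[roc$labels]
  neg <- roc$scores[!roc$labels]
  cand <- c(-Inf, sort(unique(roc$scores)))
  j <- vapply(cand, function(ct) {
    mean(pos > ct) + mean(neg <= ct) - 1
  }, numeric(1))
  # smallest cutoff within numerical tolerance of the maximum, so a
  # float-noise difference between mathematically tied J values cannot
  # move the tie-break
  best <- which(j >= max(j) - 1e-12)[1L]
  list(cutoff = cand[best], youden = j[best])
}

#' Confusion counts at a cutoff
#'
#' Positive call if and only if score strictly exceeds the cutoff.
#'
#' @inheritParams roc_curve
#' @param cutoff positivity threshold.
#' @return named integer vector `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_at_cutoff <- function(scores, labels, cutoff) {
  labels <- .check_roc_input(scores, labels, require_both = FALSE)
  call_pos <- scores > cutoff
  c(tp = sum(call_pos & labels), fp = sum(call_pos & !labels),
    tn = sum(!call_pos & !labels), fn = sum(!call_pos & labels))
}

#' Fraction of subjects called positive at a cutoff
#'
#' @param scores numeric vector of marker values.
#' @param cutoff positivity threshold (strict `>`).
#' @return proportion in \[0, 1\].
#' @export
positivity_rate <- function(scores, cutoff) {
  if (!length(scores)) stop("empty scores", call. = FALSE)
  mean(scores > cutoff)
}

#' Cutoff-level diagnostic summary
#'
#' Computes sensitivity, specificity, predictive values, likelihood
#' ratios and Youden's J either from a confusion-count vector (as
#' returned by [confusion_at_cutoff()]) or directly from stated
#' sensitivity and specificity. Predictive values follow Bayes' rule at
#' `prevalence` when it is supplied; with counts and no prevalence the
#' empirical prevalence (TP + FN) / total is used, which makes the Bayes
#' form coincide with the count ratios TP/(TP+FP) and TN/(TN+FN).
#' Ratios with a zero denominator (e.g. the positive likelihood ratio
#' at specificity 1) are returned as `Inf`, R's explicit marker for an
#' unbounded ratio, or `NaN` when genuinely undefined (0/0).
#'
#' Sensitivity and specificity from counts also carry exact
#' Clopper--Pearson confidence intervals.
#'
#' @param counts named vector with `tp`, `fp`, `tn`, `fn` (or `NULL`
#'   when `sensitivity`/`specificity` are given).
#' @param sensitivity,specificity proportions in \[0, 1\], used when
#'   `counts` is `NULL`.
#' @param prevalence optional prevalence override for PPV/NPV.
#' @param cutoff optional cutoff value, carried through for reporting.
#' @param conf_level confidence level for the Clopper--Pearson
#'   intervals.
#' @return an object of class `diagnostic_summary`.
#' @examples
#' diagnostic_summary(sensitivity = 0.738, specificity = 0.814,
#'                    prevalence = 542 / 876)
#' @export
diagnostic_summary <- function(counts = NULL, sensitivity = NULL,
                               specificity = NULL, prevalence = NULL,
                               cutoff = NA_real_, conf_level = 0.95) {
  se_ci <- sp_ci <- c(NA_real_, NA_real_)
  if (!is.null(counts)) {
    stopifnot(all(c("tp", "fp", "tn", "fn") %in% names(counts)))
    tp <- counts[["tp"]]; fp <- counts[["fp"]]
    tn <- counts[["tn"]]; fn <- counts[["fn"]]
    if (tp + fn == 0 || tn + fp == 0) {
      stop("need at least one subject in each disease class",
           call. = FALSE)
    }
    sensitivity <- tp / (tp + fn)
    specificity <- tn / (tn + fp)
    if (is.null(prevalence)) prevalence <- (tp + fn) / sum(counts)
    se_ci <- .clopper_pearson(tp, tp + fn, conf_level)
    sp_ci <- .clopper_pearson(tn, tn + fp, conf_level)
    counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  } else {
    if (is.null(sensitivity) || is.null(specificity)) {
      stop("supply either counts or sensitivity + specificity",
           call. = FALSE)
    }
    if (is.null(prevalence)) {
      stop("prevalence is required when summarising from rates",
           call. = FALSE)
    }
  }
  ppv <- sensitivity * prevalence /
    (sensitivity * prevalence + (1 - specificity) * (1 - prevalence))
  npv <- specificity * (1 - prevalence) /
    (specificity * (1 - prevalence) + (1 - sensitivity) * prevalence)
  plr <- if (specificity < 1) sensitivity / (1 - specificity) else
    if (sensitivity > 0) Inf else NaN
  nlr <- if (specificity > 0) (1 - sensitivity) / specificity else
    if (sensitivity < 1) Inf else NaN
  structure(list(cutoff = cutoff, sensitivity = sensitivity,
                 specificity = specificity, ppv = ppv, npv = npv,
                 plr = plr, nlr = nlr,
                 youden = sensitivity + specificity - 1,
                 prevalence = prevalence, counts = counts,
                 sensitivity_ci = se_ci, specificity_ci = sp_ci,
                 conf_level = conf_level),
            class = "diagnostic_summary")
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  cat(sprintf(
    paste0("Diagnostic summary at cutoff %s\n",
           "  Se %.1f%%  Sp %.1f%%  PPV %.1f%%  NPV %.1f%%\n",
           "  PLR %.2f  NLR %.2f  Youden %.2f  (prevalence %.1f%%)\n"),
    format(x$cutoff), 100 * x$sensitivity, 100 * x$specificity,
    100 * x$ppv, 100 * x$npv, x$plr, x$nlr, x$youden,
    100 * x$prevalence))
  invisible(x)
}

.clopper_pearson <- function(successes, n, conf_level) {
  alpha <- 1 - conf_level
  lower <- if (successes == 0) 0 else
    stats::qbeta(alpha / 2, successes, n - successes + 1)
  upper <- if (successes == n) 1 else
    stats::qbeta(1 - alpha / 2, successes + 1, n - successes)
  c(lower, upper)
}

.check_roc_input <- function(scores, labels, require_both = TRUE) {
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) {
      stop("numeric labels must be 0/1", call. = FALSE)
    }
    labels <- labels == 1
  }
  if (!is.logical(labels)) stop("labels must be logical or 0/1",
                                call. = FALSE)
  if (length(scores) != length(labels)) {
    stop("scores and labels must have the same length", call. = FALSE)
  }
  if (any(!is.finite(scores))) stop("scores must be finite",
                                    call. = FALSE)
  if (any(is.na(labels))) stop("labels must not be NA", call. = FALSE)
  if (require_both && (!any(labels) || all(labels))) {
    stop("labels contain a single class; need both positives and negatives",
         call. = FALSE)
  }
  labels
}
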