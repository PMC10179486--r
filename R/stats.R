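#' Pearson correlation with coefficient of determination
#'
#' Product-moment correlation between two variables with the squared
#' coefficient (R^2) reported alongside, and a two-sided p-value from
#' the t transform `r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of
#' freedom.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`, each with
#'   non-zero variance.
#' @return list with `r`, `r2`, `p`, `n`.
#' @export
pearson_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length",
                                   call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero-variance input", call. = FALSE)
  }
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  list(r = r, r2 = r^2, p = p, n = n)
}

#' Two-sample t-test
#'
#' Welch's unequal-variance t-test by default (the two MetS groups have
#' unequal sizes and variances); a pooled-variance option is available.
#' Thin wrapper over [stats::t.test()] returning the statistic, degrees
#' of freedom, and two-sided p-value.
#'
#' @param x,y numeric samples, each `n >= 2`.
#' @param pooled use the pooled-variance (Student) test instead of
#'   Welch.
#' @return list with `t`, `df`, `p`.
#' @export
two_sample_t <- function(x, y, pooled = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    }
    stop("both groups are constant; t statistic undefined",
         call. = FALSE)
  }
  tt <- stats::t.test(x, y, var.equal = pooled)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Standard-deviation-score outlier screen
#'
#' Flags values whose absolute distance from the sample mean exceeds
#' `cutoff_sds` sample standard deviations, both moments computed over
#' the full sample (the flagged point included).
#'
#' @param values numeric vector, `n >= 3`, non-zero SD.
#' @param cutoff_sds the SD-score cutoff; default 4.5.
#' @return logical vector of flags.
#' @export
sds_outlier_screen <- function(values, cutoff_sds = 4.5) {
  if (length(values) < 3L) stop("need at least 3 values", call. = FALSE)
  s <- stats::sd(values)
  if (is.na(s) || s == 0) stop("zero-SD sample; SD scores undefined",
                               call. = FALSE)
  abs(values - mean(values)) / s > cutoff_sds
}

#' Two-group descriptive table with per-variable t-tests
#'
#' Mean and SD per group plus the Welch two-sided p-value for each
#' variable, in the shape of a clinical descriptive table comparing the
#' MetS- and MetS+ groups.
#'
#' @param data data.frame of numeric variables.
#' @param group vector with exactly two distinct values, one per row of
#'   `data`.
#' @param variables columns to summarise; defaults to all numeric
#'   columns.
#' @return data.frame with `variable`, per-group `mean_*` / `sd_*`, and
#'   `p`.
#' @export
group_descriptives <- function(data, group, variables = NULL) {
  if (NROW(data) != length(group)) {
    stop("group must have one label per row of data", call. = FALSE)
  }
  levels <- unique(group[!is.na(group)])
  if (length(levels) != 2L) {
    stop("exactly two groups required; got ",
         paste(sQuote(levels), collapse = ", "), call. = FALSE)
  }
  if (is.null(variables)) {
    variables <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  bad <- setdiff(variables, names(data))
  if (length(bad)) stop("unknown variable(s): ",
                        paste(sQuote(bad), collapse = ", "),
                        call. = FALSE)
  g1 <- group == levels[1L]
  g2 <- group == levels[2L]
  rows <- lapply(variables, function(v) {
    x <- data[[v]][g1]
    y <- data[[v]][g2]
    p <- tryCatch(two_sample_t(x, y)$p, error = function(e) NA_real_)
    data.frame(variable = v,
               mean_1 = mean(x, na.rm = TRUE),
               sd_1 = stats::sd(x[!is.na(x)]),
               mean_2 = mean(y, na.rm = TRUE),
               sd_2 = stats::sd(y[!is.na(y)]),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:5] <- c(paste0(c("mean_", "sd_"), levels[1L]),
                       paste0(c("mean_", "sd_"), levels[2L]))
  out
}
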