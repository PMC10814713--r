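# Paired before/after analysis of blood-gas parameters: descriptive
# rows, Pearson pair correlations, paired samples t-tests, and
# closed-form recomputation of t-test columns from printed summary
# moments (mean difference, SD, n).

drop_missing <- function(x) x[!is.na(x)]

#' Descriptive statistics for one clinical parameter
#'
#' Range, min, max, mean, sample SD, and skewness with its standard
#' error — one row of a clinical descriptives table.  Skewness is the
#' adjusted Fisher-Pearson coefficient G1 (the SPSS/Excel convention),
#' with SE `sqrt(6n(n-1) / ((n-2)(n+1)(n+3)))`.
#'
#' @param values Numeric vector; `NA`s are dropped.
#' @param name Optional label for the parameter.
#' @param unit Optional unit label.
#' @return A one-row data frame with columns `name`, `unit`, `n`,
#'   `range`, `min`, `max`, `mean`, `sd`, `skewness`, `se_skewness`.
#'   Skewness is `NA` for a constant series.
#' @examples
#' describe_series(c(770, 2100, 3250), name = "weight", unit = "g")
#' @export
describe_series <- function(values, name = "", unit = "") {
  x <- drop_missing(as.numeric(values))
  if (length(x) == 0L) {
    stop("describe_series needs at least one non-missing value", call. = FALSE)
  }
  n <- length(x)
  s <- if (n > 1L) sd(x) else 0
  skew <- se_skew <- NA_real_
  if (n >= 3L && s > 0) {
    skew <- e1071::skewness(x, type = 2)  # adjusted Fisher-Pearson G1
    se_skew <- sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
  }
  data.frame(name = name, unit = unit, n = n,
             range = max(x) - min(x), min = min(x), max = max(x),
             mean = mean(x), sd = s,
             skewness = skew, se_skewness = se_skew,
             stringsAsFactors = FALSE)
}

complete_pairs <- function(before, after) {
  b <- as.numeric(before); a <- as.numeric(after)
  if (length(b) != length(a)) {
    stop("before and after series must be aligned (same length)",
         call. = FALSE)
  }
  ok <- !is.na(b) & !is.na(a)
  list(before = b[ok], after = a[ok], n = sum(ok))
}

#' Pearson correlation of a before/after pair
#'
#' Pairwise deletion first (rows with any missing value are dropped),
#' then the sample Pearson correlation with its two-tailed p-value from
#' the t distribution on n - 2 degrees of freedom.
#'
#' @param before,after Aligned numeric vectors.
#' @return A list with `r`, `p`, and `n` (complete pairs used).
#' @export
pearson_pair <- function(before, after) {
  cp <- complete_pairs(before, after)
  if (cp$n < 3L) {
    stop("pearson_pair needs at least 3 complete pairs", call. = FALSE)
  }
  if (sd(cp$before) == 0 || sd(cp$after) == 0) {
    stop("correlation is undefined: a series has zero variance",
         call. = FALSE)
  }
  ct <- cor.test(cp$before, cp$after, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = cp$n)
}

#' Paired samples t-test on before/after measurements
#'
#' Differences are defined as `before - after` (so a falling parameter
#' gives a positive mean difference).  Rows with a missing value in
#' either series are dropped pairwise, which is why degrees of freedom
#' can differ across parameters of the same cohort.  Equivalent to a
#' one-sample t-test of the differences against zero.
#'
#' @param before,after Aligned numeric vectors.
#' @param alpha Significance level for the confidence interval
#'   (default 0.05, i.e. a 95\% CI).
#' @return A list of class `"paired_result"`: `n_pairs`, `mean_before`,
#'   `sd_before`, `mean_after`, `sd_after`, `r`, `r_pvalue`,
#'   `mean_diff`, `sd_diff`, `se_diff`, `ci_low`, `ci_high`, `t`, `df`,
#'   `p_two_tailed`.  With constant differences `t` and `p` are `NA`.
#' @export
paired_test <- function(before, after, alpha = 0.05) {
  cp <- complete_pairs(before, after)
  if (cp$n < 2L) {
    stop("paired_test needs at least 2 complete pairs", call. = FALSE)
  }
  d <- cp$before - cp$after
  n <- cp$n
  sd_d <- sd(d)
  corr <- tryCatch(pearson_pair(cp$before, cp$after),
                   error = function(e) list(r = NA_real_, p = NA_real_))
  if (sd_d == 0) {
    tcrit <- qt(1 - alpha / 2, df = n - 1L)
    res <- list(t = NA_real_, p = NA_real_,
                ci = mean(d) + c(-1, 1) * tcrit * 0)
  } else {
    tt <- t.test(d, mu = 0, conf.level = 1 - alpha)
    res <- list(t = unname(tt$statistic), p = tt$p.value,
                ci = as.numeric(tt$conf.int))
  }
  structure(list(
    n_pairs = n,
    mean_before = mean(cp$before), sd_before = sd(cp$before),
    mean_after = mean(cp$after), sd_after = sd(cp$after),
    r = corr$r, r_pvalue = corr$p,
    mean_diff = mean(d), sd_diff = sd_d, se_diff = sd_d / sqrt(n),
    ci_low = res$ci[1], ci_high = res$ci[2],
    t = res$t, df = n - 1L, p_two_tailed = res$p
  ), class = "paired_result")
}

#' @export
print.paired_result <- function(x, ...) {
  cat(sprintf("Paired samples t-test (n = %d pairs, df = %d)\n",
              x$n_pairs, x$df))
  cat(sprintf("  before: %.3f +/- %.3f   after: %.3f +/- %.3f   r = %s\n",
              x$mean_before, x$sd_before, x$mean_after, x$sd_after,
              ifelse(is.na(x$r), "undefined", sprintf("%.3f", x$r))))
  cat(sprintf("  diff:   %.3f +/- %.3f   SE %.3f   95%% CI [%.3f, %.3f]\n",
              x$mean_diff, x$sd_diff, x$se_diff, x$ci_low, x$ci_high))
  cat(sprintf("  t = %s, p (2-tailed) = %s\n",
              ifelse(is.na(x$t), "undefined", sprintf("%.3f", x$t)),
              ifelse(is.na(x$p_two_tailed), "undefined",
                     format(x$p_two_tailed, digits = 3))))
  invisible(x)
}

#' Paired t-test columns from printed summary moments
#'
#' Recomputes the derived columns of a paired-differences table from
#' only the printed mean difference, its SD, and the pair count:
#' standard error, confidence interval, t statistic and two-tailed
#' p-value.  Useful to audit published tables where the raw data are
#' unavailable.
#'
#' @param mean_diff Mean of the paired differences.
#' @param sd_diff Sample SD of the differences (> 0).
#' @param n Number of pairs (>= 2).
#' @param alpha Significance level (default 0.05).
#' @return A list with `se`, `ci_low`, `ci_high`, `t`, `df`, `p`.
#' @examples
#' # mean difference -7.97 +/- 6.55 over 32 pairs
#' paired_from_summary(-7.97, 6.55, 32)
#' @export
paired_from_summary <- function(mean_diff, sd_diff, n, alpha = 0.05) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) {
    stop("paired_from_summary needs n >= 2", call. = FALSE)
  }
  if (!is.finite(sd_diff) || sd_diff <= 0) {
    stop("sd_diff must be a positive number", call. = FALSE)
  }
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly between 0 and 1", call. = FALSE)
  }
  se <- sd_diff / sqrt(n)
  tcrit <- qt(1 - alpha / 2, df = n - 1L)
  tval <- mean_diff / se
  list(se = se,
       ci_low = mean_diff - tcrit * se,
       ci_high = mean_diff + tcrit * se,
       t = tval,
       df = n - 1L,
       p = 2 * pt(-abs(tval), df = n - 1L))
}

#' Paired analysis of every before/after column pair in a table
#'
#' Scans a patient table for `<param>_before` / `<param>_after` column
#' pairs and runs [paired_test()] on each, returning one row per
#' parameter in the layout of a paired-differences table.
#'
#' @param df Data frame, one row per patient.
#' @param alpha Significance level.
#' @return Data frame with one row per parameter: `parameter`,
#'   `n_pairs`, `mean_before`, `sd_before`, `mean_after`, `sd_after`,
#'   `r`, `r_pvalue`, `mean_diff`, `sd_diff`, `se_diff`, `ci_low`,
#'   `ci_high`, `t`, `df`, `p_two_tailed`.
#' @export
paired_analysis <- function(df, alpha = 0.05) {
  nms <- names(df)
  params <- sub("_before$", "", grep("_before$", nms, value = TRUE))
  params <- params[paste0(params, "_after") %in% nms]
  if (!length(params)) {
    stop("no <param>_before / <param>_after column pairs found",
         call. = FALSE)
  }
  rows <- lapply(params, function(p) {
    res <- paired_test(df[[paste0(p, "_before")]],
                       df[[paste0(p, "_after")]], alpha = alpha)
    cbind(data.frame(parameter = p, stringsAsFactors = FALSE),
          as.data.frame(unclass(res)))
  })
  do.call(rbind, rows)
}
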