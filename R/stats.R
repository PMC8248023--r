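# Longitudinal statistics: paired t-tests with effect sizes, FDR
# correction, repeated-measures correlation, and cluster bootstrap
# confidence intervals (resampling unit = subject with both timepoints).

#' Paired t-test with Cohen's d
#'
#' The difference is `values_t2 - values_t1` per subject; d is the mean
#' difference divided by the SD of the differences, so its sign matches t.
#'
#' @param values_t1,values_t2 Equal-length numeric vectors aligned by
#'   subject (length >= 3).
#' @return One-row data frame: `t`, `df`, `p`, `d`, `mean_diff`.
#' @export
paired_t_with_d <- function(values_t1, values_t2) {
  stopifnot(length(values_t1) == length(values_t2), length(values_t1) >= 3)
  d <- values_t2 - values_t1
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (all(d == 0)) {
      return(data.frame(t = 0, df = length(d) - 1, p = 1, d = 0,
                        mean_diff = 0))
    }
    stop("zero-variance nonzero differences", call. = FALSE)
  }
  tt <- stats::t.test(values_t2, values_t1, paired = TRUE)
  data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, d = mean(d) / sdd, mean_diff = mean(d))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement (delegates to
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p_values Numeric vector in \[0, 1\].
#' @return Adjusted q-values, same length and order.
#' @export
fdr_bh <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}

#' Repeated-measures correlation
#'
#' The common within-subject association between x and y, from an ANCOVA
#' with subject as factor and a shared slope:
#' `r_rm = sign(slope) * sqrt(SS_x / (SS_x + SS_error))`, with x entered
#' after the subject factor. Degrees of freedom are `N (k - 1) - 1` for
#' balanced designs with k repeated measures (in general, the error df of
#' the ANCOVA). Subjects with fewer than two observations are dropped with
#' a warning.
#'
#' @param subject_ids Factor-coercible vector of subject identifiers.
#' @param x,y Numeric vectors, same length as `subject_ids`.
#' @return One-row data frame: `r_rm`, `df`, `p`, `slope`.
#' @export
rmcorr <- function(subject_ids, x, y) {
  stopifnot(length(subject_ids) == length(x), length(x) == length(y))
  tab <- table(subject_ids)
  single <- names(tab)[tab < 2]
  if (length(single)) {
    warning("dropping ", length(single), " subject(s) with one observation")
    keep <- !(subject_ids %in% single)
    subject_ids <- subject_ids[keep]
    x <- x[keep]
    y <- y[keep]
  }
  subj <- factor(subject_ids)
  if (nlevels(subj) < 3) stop("need >= 3 subjects", call. = FALSE)
  fit <- stats::lm(y ~ subj + x)
  an <- stats::anova(fit)
  ss_x <- an["x", "Sum Sq"]
  ss_err <- an["Residuals", "Sum Sq"]
  df_err <- an["Residuals", "Df"]
  slope <- stats::coef(fit)[["x"]]
  r <- sign(slope) * sqrt(ss_x / (ss_x + ss_err))
  tstat <- r * sqrt(df_err / max(1 - r^2, .Machine$double.eps))
  data.frame(r_rm = r, df = df_err,
             p = 2 * stats::pt(-abs(tstat), df_err), slope = slope)
}

#' Cluster bootstrap percentile confidence interval
#'
#' Subjects are resampled with replacement, each carrying all of its
#' repeated measures, and the statistic is recomputed per draw. Draws on
#' which the statistic is undefined (error or non-finite) are redrawn, up
#' to a cap, and counted.
#'
#' @param subject_records Named list, one element per subject, each holding
#'   that subject's records in any form the statistic understands.
#' @param statistic Function taking a list of subject records (a resample)
#'   and returning one number.
#' @param n_draws Number of bootstrap draws (default 10000, minimum 1000).
#' @param alpha 1 - confidence level (default 0.05).
#' @param seed Integer seed.
#' @return List: `lower`, `upper`, `draws` (the statistic values),
#'   `n_redrawn`.
#' @export
bootstrap_ci <- function(subject_records, statistic, n_draws = 10000,
                         alpha = 0.05, seed = 1L) {
  stopifnot(n_draws >= 1000, length(subject_records) >= 2)
  set.seed(seed)
  ns <- length(subject_records)
  vals <- numeric(n_draws)
  n_redrawn <- 0L
  for (b in seq_len(n_draws)) {
    ok <- FALSE
    for (attempt in 1:100) {
      idx <- sample.int(ns, ns, replace = TRUE)
      v <- tryCatch(statistic(subject_records[idx]),
                    error = function(e) NA_real_)
      if (length(v) == 1 && is.finite(v)) {
        ok <- TRUE
        break
      }
      n_redrawn <- n_redrawn + 1L
    }
    if (!ok) stop("statistic undefined on 100 consecutive resamples",
                  call. = FALSE)
    vals[b] <- v
  }
  qs <- stats::quantile(vals, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                        type = 7)
  list(lower = qs[1], upper = qs[2], draws = vals, n_redrawn = n_redrawn)
}
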