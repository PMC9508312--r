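#' Kolmogorov-Smirnov normality screen
#'
#' One-sample KS distance of the sample to a normal distribution with the
#' sample's own mean and standard deviation.  Because the parameters are
#' estimated from the same data, the returned p-value is conservative
#' (the Lilliefors correction is not applied); this mirrors common practice
#' of KS-screening before t-tests and is flagged in the result.
#'
#' @param x numeric sample, n >= 4, non-constant.
#' @return list with `statistic`, `p`, and `note` (the estimated-parameter
#'   caveat).
#' @export
ks_normality <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 4L) stop("need n >= 4")
  if (stats::sd(x) == 0) stop("constant sample")
  kt <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  list(statistic = unname(kt$statistic), p = unname(kt$p.value),
       note = "parameters estimated from the sample; p is conservative")
}

#' Pooled-variance two-sample t-test
#'
#' Classical equal-variance two-sample t with `df = n1 + n2 - 2`, computed
#' either from raw samples or from printed summary statistics
#' (mean, sd, n per group).  The sign convention is group1 minus group2;
#' pass the control group first to get t on the (control - patient) scale.
#'
#' @param x1,x2 numeric samples; or `NULL` when using summaries.
#' @param s1,s2 optional summaries, each `c(mean, sd, n)`.
#' @param metric optional metric name carried on the result.
#' @return list of class `pdc_ttest`: `metric`, `mean1`, `sd1`, `n1`,
#'   `mean2`, `sd2`, `n2`, `t`, `df`, `p`.
#' @export
pooled_t <- function(x1 = NULL, x2 = NULL, s1 = NULL, s2 = NULL,
                     metric = NA_character_) {
  if (!is.null(x1)) s1 <- c(mean(x1), stats::sd(x1), length(x1))
  if (!is.null(x2)) s2 <- c(mean(x2), stats::sd(x2), length(x2))
  if (is.null(s1) || is.null(s2)) stop("need two samples or two summaries")
  m1 <- s1[[1]]; sd1 <- s1[[2]]; n1 <- s1[[3]]
  m2 <- s2[[1]]; sd2 <- s2[[2]]; n2 <- s2[[3]]
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group")
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("zero pooled variance")
  tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  p <- 2 * stats::pt(-abs(tstat), df)
  structure(list(metric = metric, mean1 = m1, sd1 = sd1, n1 = n1,
                 mean2 = m2, sd2 = sd2, n2 = n2,
                 t = tstat, df = df, p = p),
            class = "pdc_ttest")
}

#' @export
print.pdc_ttest <- function(x, ...) {
  cat(sprintf("pooled t: t = %.4f, df = %d, p = %.4f\n", x$t, x$df, x$p))
  invisible(x)
}

#' Pearson chi-square on a 2x2 table
#'
#' Without continuity correction, df = 1; the form used for a sex-by-group
#' contingency comparison.
#'
#' @param table 2x2 matrix of counts.
#' @return list with `statistic`, `df`, `p`.
#' @export
chi2_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(table < 0) || sum(table) == 0) stop("invalid counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero marginal")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: sort ascending, take the running minimum of
#' `p_(k) * m / k` from the largest rank down, cap at 1, and restore the
#' input order.  Identical to `p.adjust(method = "BH")`, exposed with an
#' explicit family identifier so every correction family in an analysis is
#' a deliberate, reproducible grouping.
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @param family identifier attached to the result.
#' @return numeric vector of adjusted p-values with a `family` attribute.
#' @export
bh_fdr <- function(p, family = NA_character_) {
  if (length(p) == 0L) stop("empty p-value list")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "BH")
  attr(adj, "family") <- family
  adj
}

#' Pearson correlation with least-squares line
#'
#' @param x,y paired numeric vectors, n >= 3, both non-constant.
#' @return list of class `pdc_cor`: `r`, `p` (two-sided, via the t
#'   transform with n - 2 df), `slope`, `intercept`, `n`.
#' @export
pearson_with_fit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  fit <- stats::lm.fit(cbind(1, x), y)
  structure(list(r = unname(ct$estimate), p = unname(ct$p.value),
                 slope = unname(fit$coefficients[2L]),
                 intercept = unname(fit$coefficients[1L]), n = n),
            class = "pdc_cor")
}

#' @export
print.pdc_cor <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f (p = %.4f, n = %d); y = %.3f + %.3f x\n",
              x$r, x$p, x$n, x$intercept, x$slope))
  invisible(x)
}

#' Compare groups on a set of metrics with one FDR family
#'
#' Runs the pooled t-test (control minus patient) on every column of the
#' per-subject metric matrix and BH-adjusts the p-values as one correction
#' family.
#'
#' @param values data.frame or matrix, one row per subject, one column per
#'   metric.
#' @param group character vector ("control"/"patient") aligned with rows.
#' @param family correction family identifier.
#' @return data.frame: metric, control mean/sd, patient mean/sd, t, df, p,
#'   p_corrected, family.
#' @export
group_compare <- function(values, group, family = NA_character_) {
  values <- as.data.frame(values)
  if (nrow(values) != length(group)) stop("group does not match rows")
  ctrl <- group == "control"
  rows <- lapply(names(values), function(m) {
    tt <- pooled_t(values[[m]][ctrl], values[[m]][!ctrl], metric = m)
    data.frame(metric = m,
               control_mean = tt$mean1, control_sd = tt$sd1,
               patient_mean = tt$mean2, patient_sd = tt$sd2,
               t = tt$t, df = tt$df, p = tt$p)
  })
  out <- do.call(rbind, rows)
  out$p_corrected <- as.numeric(bh_fdr(out$p, family = family))
  out$family <- family
  out
}
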