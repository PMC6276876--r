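#' Two-sample Student's t-test (pooled variance)
#'
#' Classic pooled-variance two-sample t with a two-sided p-value. When both
#' groups are constant with equal means the test is degenerate and `p = 1`
#' is reported by convention (t = 0); constant groups with different means
#' give `p = 0`.
#'
#' @param sample_a,sample_b numeric vectors, n >= 2 each.
#' @return object of class `fq_test`: `statistic` (t), `dof`, `p_value`,
#'   `method = "ttest"`, `means`.
#' @export
ttest2 <- function(sample_a, sample_b) {
  if (length(sample_a) < 2 || length(sample_b) < 2)
    stop("each group needs at least 2 observations")
  va <- stats::var(sample_a); vb <- stats::var(sample_b)
  dof <- length(sample_a) + length(sample_b) - 2
  if (va == 0 && vb == 0) {
    eq <- mean(sample_a) == mean(sample_b)
    return(structure(list(statistic = if (eq) 0 else Inf, dof = dof,
                          p_value = if (eq) 1 else 0, method = "ttest",
                          means = c(mean(sample_a), mean(sample_b))),
                     class = "fq_test"))
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = TRUE)
  structure(list(statistic = unname(ht$statistic), dof = unname(ht$parameter),
                 p_value = ht$p.value, method = "ttest",
                 means = unname(ht$estimate)),
            class = "fq_test")
}

#' One-way ANOVA with post hoc Tukey HSD
#'
#' F-test across k groups with (k - 1, N - k) degrees of freedom, followed
#' by Tukey's honestly-significant-difference procedure (studentized-range
#' adjusted pairwise p-values).
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2),
#'   or a data.frame with columns `value` and `group`.
#' @return object of class `fq_test`: `statistic` (F), `dof` = c(df1, df2),
#'   `p_value`, `method = "anova"`, `tukey` (data.frame `comparison, diff,
#'   lwr, upr, p_adj`).
#' @export
anova_tukey <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("value", "group") %in% names(groups)))
    groups <- split(groups$value, groups$group)
  }
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, 0L) < 2)) stop("every group needs n >= 2")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   group = factor(rep(names(groups),
                                      vapply(groups, length, 0L))))
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  fstat <- an[["F value"]][1]
  pval <- an[["Pr(>F)"]][1]
  if (is.na(fstat)) { fstat <- 0; pval <- 1 }   # all groups identical
  tk <- tryCatch({
    th <- stats::TukeyHSD(fit)$group
    data.frame(comparison = rownames(th), diff = th[, "diff"],
               lwr = th[, "lwr"], upr = th[, "upr"],
               p_adj = ifelse(is.nan(th[, "p adj"]), 1, th[, "p adj"]),
               row.names = NULL)
  }, error = function(e) NULL)
  structure(list(statistic = fstat, dof = unname(an[["Df"]]),
                 p_value = pval, method = "anova", tukey = tk),
            class = "fq_test")
}

#' @export
print.fq_test <- function(x, ...) {
  if (x$method == "ttest") {
    cat(sprintf("two-sample t-test (pooled): t = %.4g, df = %d, p = %.4g\n",
                x$statistic, x$dof, x$p_value))
  } else {
    cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
                x$dof[1], x$dof[2], x$statistic, x$p_value))
    if (!is.null(x$tukey)) {
      cat("Tukey HSD:\n")
      print(x$tukey, digits = 4)
    }
  }
  invisible(x)
}

#' Cohen's d with the maximal-SD convention
#'
#' Standardized effect size `d = |mean_1 - mean_2| / s`. The default
#' denominator convention takes `s` as the maximal standard deviation of
#' the analyzed dataset: the largest group SD among the compared pair, or
#' among all groups of `dataset` when the pair is part of a larger
#' multi-group comparison. Under this convention `d <= 0.5` is read as a
#' low effect size and `d >= 1` as a large one. Alternatives: the pooled-SD
#' textbook convention, and a `max_sd_half` variant dividing by `2 s` (for
#' the ambiguous rendering of the defining formula in some sources).
#'
#' @param sample_a,sample_b numeric vectors, n >= 2 each.
#' @param s_convention `"max_sd"` (default), `"pooled"`, or `"max_sd_half"`.
#' @param dataset optional list of all groups of the analyzed dataset from
#'   which the maximal SD is taken (defaults to the compared pair).
#' @return object of class `effect_size`: `mean_1, mean_2, s, d, convention`.
#' @export
cohens_d <- function(sample_a, sample_b,
                     s_convention = c("max_sd", "pooled", "max_sd_half"),
                     dataset = NULL) {
  s_convention <- match.arg(s_convention)
  if (length(sample_a) < 2 || length(sample_b) < 2)
    stop("each group needs at least 2 observations")
  m1 <- mean(sample_a); m2 <- mean(sample_b)
  if (s_convention == "pooled") {
    n1 <- length(sample_a); n2 <- length(sample_b)
    s <- sqrt(((n1 - 1) * stats::var(sample_a) + (n2 - 1) * stats::var(sample_b)) /
                (n1 + n2 - 2))
  } else {
    grps <- if (is.null(dataset)) list(sample_a, sample_b) else dataset
    s <- max(vapply(grps, stats::sd, 0))
  }
  if (!is.finite(s) || s == 0) stop("zero standard deviation: d undefined")
  d <- abs(m1 - m2) / s
  if (s_convention == "max_sd_half") d <- d / 2
  structure(list(mean_1 = m1, mean_2 = m2, s = s, d = d,
                 convention = s_convention),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  lab <- if (x$d >= 1) "large" else if (x$d <= 0.5) "low" else "intermediate"
  cat(sprintf("Cohen's d = %.3g (%s; s = %.4g, convention '%s')\n",
              x$d, lab, x$s, x$convention))
  invisible(x)
}

#' Boxplot summary statistics
#'
#' Quartiles by linear interpolation (quantile type 7), outliers beyond
#' 1.5 IQR from the quartiles, whiskers to the most extreme non-outlier
#' points, and notches (median comparison intervals) at
#' `median +/- 1.57 * IQR / sqrt(n)`. `whiskers = "extremes"` reproduces
#' the literal reading of legends whose whiskers extend to the most extreme
#' data points while still marking outliers.
#'
#' @param sample numeric vector (n >= 1).
#' @param whiskers `"tukey"` (default, 1.5 IQR rule) or `"extremes"`.
#' @return list of class `box_summary`: `median, q25, q75, whisker_lo,
#'   whisker_hi, outliers, notch_lo, notch_hi, n`.
#' @export
box_summary <- function(sample, whiskers = c("tukey", "extremes")) {
  whiskers <- match.arg(whiskers)
  sample <- sample[is.finite(sample)]
  if (!length(sample)) stop("empty sample")
  q <- stats::quantile(sample, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  out <- sample < q[1] - 1.5 * iqr | sample > q[3] + 1.5 * iqr
  inl <- sample[!out]
  wlo <- if (whiskers == "tukey") min(inl) else min(sample)
  whi <- if (whiskers == "tukey") max(inl) else max(sample)
  n <- length(sample)
  structure(list(median = q[2], q25 = q[1], q75 = q[3],
                 whisker_lo = wlo, whisker_hi = whi,
                 outliers = sample[out],
                 notch_lo = q[2] - 1.57 * iqr / sqrt(n),
                 notch_hi = q[2] + 1.57 * iqr / sqrt(n),
                 n = n),
            class = "box_summary")
}

#' @export
print.box_summary <- function(x, ...) {
  cat(sprintf("box_summary (n = %d): median %.4g [q25 %.4g, q75 %.4g], whiskers [%.4g, %.4g], %d outlier(s)\n",
              x$n, x$median, x$q25, x$q75, x$whisker_lo, x$whisker_hi,
              length(x$outliers)))
  invisible(x)
}
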