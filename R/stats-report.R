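#' Mean and standard error of the mean
#'
#' SEM uses the n-1 denominator standard deviation divided by sqrt(n), as in
#' "mean +/- SEM" figure reporting.
#'
#' @param values Numeric vector.
#' @return List with `mean`, `sem` (NA-flagged for n < 2) and `n`.
#' @export
mean_sem <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (!n) return(list(mean = NA_real_, sem = NA_real_, n = 0L))
  list(mean = mean(values),
       sem = if (n > 1) stats::sd(values) / sqrt(n) else NA_real_,
       n = n)
}

#' Significance stars at the conventional thresholds
#'
#' `*` p < 0.05, `**` p < 0.01, `***` p < 0.001, `ns` otherwise.
#'
#' @param p p-value(s).
#' @return Character vector of star codes.
#' @export
p_stars <- function(p) {
  vapply(p, function(pp) {
    if (!is.finite(pp)) return(NA_character_)
    if (pp < 0.001) "***" else if (pp < 0.01) "**" else if (pp < 0.05) "*"
    else "ns"
  }, character(1))
}

test_result <- function(test, statistic, p_value, groups) {
  structure(list(test = test, statistic = statistic, p_value = p_value,
                 groups = groups,
                 significant_0.05 = is.finite(p_value) && p_value < 0.05,
                 significant_0.01 = is.finite(p_value) && p_value < 0.01,
                 significant_0.001 = is.finite(p_value) && p_value < 0.001,
                 stars = p_stars(p_value)),
            class = "axokin_test")
}

#' @export
print.axokin_test <- function(x, ...) {
  cat(sprintf("%s [%s]: statistic = %.4g, p = %.4g (%s)\n", x$test,
              paste(x$groups, collapse = " vs "), x$statistic, x$p_value,
              x$stars))
  invisible(x)
}

#' Unpaired two-tailed independent two-sample t-test
#'
#' Student's equal-variance t by default (Welch available by flag); two-sided.
#'
#' @param a,b Numeric vectors, each n >= 2.
#' @param labels Group labels for the report.
#' @param welch Use the Welch (unequal-variance) form.
#' @return An `axokin_test` result with the t statistic and p-value.
#' @export
ttest_two <- function(a, b, labels = c("a", "b"), welch = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  ht <- stats::t.test(a, b, var.equal = !welch, alternative = "two.sided")
  test_result(if (welch) "Welch t-test" else "Student t-test (unpaired, two-tailed)",
              unname(ht$statistic), ht$p.value, labels)
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each n >= 2).
#' @return List with `omnibus` (an `axokin_test` with the F statistic) and
#'   `pairwise`: a data frame of Tukey-adjusted pairwise comparisons
#'   (`comparison`, `diff`, `p_adj`, `stars`).
#' @export
anova_tukey <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  stopifnot(all(vapply(groups, length, integer(1)) >= 2))
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, integer(1))))
  )
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  fstat <- an[["F value"]][1]
  p <- an[["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$group
  pairwise <- data.frame(comparison = rownames(tk),
                         diff = tk[, "diff"],
                         p_adj = tk[, "p adj"],
                         stars = p_stars(tk[, "p adj"]),
                         row.names = NULL)
  list(omnibus = test_result("one-way ANOVA", fstat, p, names(groups)),
       pairwise = pairwise)
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS test against a normal with the sample's own mean and sd.
#' Because the reference parameters are estimated from the same sample, the
#' nominal KS p-value is conservative (the Lilliefors correction is not
#' applied); the result carries that caveat, and samples of n < 5 are flagged
#' underpowered.
#'
#' @param values Numeric vector.
#' @return An `axokin_test` with elements `underpowered` and `caveat` added.
#' @export
ks_normality <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) stop("need n >= 2", call. = FALSE)
  ht <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), stats::sd(values)))
  out <- test_result("Kolmogorov-Smirnov normality (estimated parameters)",
                     unname(ht$statistic), ht$p.value, "sample vs normal")
  out$underpowered <- n < 5
  out$caveat <- "reference mean/sd estimated from the sample; p is conservative"
  out
}

#' Two-group comparison report
#'
#' Bundles the descriptive layer (mean +/- SEM per group), the percent and
#' fold change of the treated group relative to control, the normality check,
#' and the two-sample t-test, in the JSON-ready shape used by the analysis
#' drivers.
#'
#' @param control,treated Numeric vectors of per-cell (or per-neuron) values.
#' @param labels Length-2 labels, control first.
#' @return List: `groups`, `means`, `sems`, `n`, `percent_change`,
#'   `fold_change`, `test` (statistic, p, stars), `normality` p-values.
#' @export
compare_groups <- function(control, treated,
                           labels = c("control", "treated")) {
  mc <- mean_sem(control); mt <- mean_sem(treated)
  tt <- ttest_two(control, treated, labels)
  list(groups = labels,
       means = c(mc$mean, mt$mean),
       sems = c(mc$sem, mt$sem),
       n = c(mc$n, mt$n),
       percent_change = percent_change(mc$mean, mt$mean),
       fold_change = fold_change(mt$mean, mc$mean),
       test = list(name = tt$test, statistic = tt$statistic,
                   p = tt$p_value, stars = tt$stars),
       normality = list(control = ks_normality(control)$p_value,
                        treated = ks_normality(treated)$p_value))
}
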