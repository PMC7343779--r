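#' Multivariate GLM (MANCOVA) for group effects on cortical measures
#'
#' Tests the multivariate effect of a diagnostic factor on a set of outcome
#' measures after partialling out covariates, via Wilks' Lambda with Rao's F
#' approximation, plus the univariate between-subjects F test for each
#' outcome from the same linear model. Covariates are entered before the
#' factor, so the factor's (sequential) test is adjusted for them.
#'
#' @param data Data frame with one row per subject.
#' @param outcomes Character vector of outcome column names.
#' @param group Name of the factor column (e.g. diagnosis).
#' @param covariates Character vector of covariate column names (numeric or
#'   categorical; categorical covariates such as scanner are dummy-coded
#'   with the first level as reference).
#' @return A `mancova_fit` object; `tidy()` returns the per-outcome F tests,
#'   `glance()` the multivariate Wilks test.
#' @export
#' @examples
#' set.seed(1)
#' d <- data.frame(g = rep(c("a", "b"), each = 20),
#'                 y1 = rnorm(40), y2 = rnorm(40), age = rnorm(40, 65, 5))
#' fit <- mancova(d, outcomes = c("y1", "y2"), group = "g", covariates = "age")
#' glance(fit)
mancova <- function(data, outcomes, group, covariates = character()) {
  stopifnot(is.data.frame(data), length(outcomes) >= 1L)
  miss <- setdiff(c(outcomes, group, covariates), names(data))
  if (length(miss)) {
    abort(paste("columns not in data:", paste(miss, collapse = ", ")),
          class = "cortexdti_design_error")
  }
  df <- as.data.frame(data)
  df[[group]] <- factor(df[[group]])
  for (cv in covariates) {
    if (is.character(df[[cv]]) || is.logical(df[[cv]])) df[[cv]] <- factor(df[[cv]])
  }
  rhs_terms <- c(covariates, group)
  rhs <- paste(vapply(rhs_terms, function(t) sprintf("`%s`", t), ""), collapse = " + ")
  Y <- as.matrix(df[, outcomes, drop = FALSE])
  mm <- stats::model.matrix(stats::as.formula(paste("~", rhs)), df)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    dropped <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1L):ncol(mm)]]
    abort(paste("design matrix rank deficient; collinear columns:",
                paste(dropped, collapse = ", ")),
          class = "cortexdti_design_error")
  }
  n <- nrow(df); p <- ncol(mm)
  if (n <= p + length(outcomes)) {
    abort("too few subjects for the requested design",
          class = "cortexdti_design_error")
  }
  fit <- lm(stats::as.formula(paste("Y ~", rhs)), data = df)

  an <- stats::anova(fit, test = "Wilks")
  grow <- grep(sprintf("`?%s`?$", group), rownames(an))
  grow <- grow[length(grow)]
  multivariate <- tibble(
    term = group, statistic = "Wilks-F",
    wilks = an[grow, "Wilks"],
    value = an[grow, "approx F"],
    df1 = an[grow, "num Df"], df2 = an[grow, "den Df"],
    p_value = an[grow, "Pr(>F)"]
  )

  per_outcome <- purrr::map_dfr(outcomes, function(y) {
    f1 <- lm(stats::as.formula(paste(sprintf("`%s` ~", y), rhs)), data = df)
    a1 <- stats::anova(f1)
    r <- grep(sprintf("`?%s`?$", group), rownames(a1))
    r <- r[length(r)]
    tibble(
      term = group, outcome = y, statistic = "F",
      value = a1[r, "F value"],
      df1 = a1[r, "Df"], df2 = a1[nrow(a1), "Df"],
      p_value = a1[r, "Pr(>F)"]
    )
  })

  structure(
    list(multivariate = multivariate, per_outcome = per_outcome,
         model = fit, n = n, outcomes = outcomes, group = group,
         covariates = covariates),
    class = "mancova_fit"
  )
}

#' @export
print.mancova_fit <- function(x, ...) {
  m <- x$multivariate
  cat(sprintf("<mancova_fit> %s on %d outcomes, n = %d\n", x$group,
              length(x$outcomes), x$n))
  cat(sprintf("  Wilks = %.4f, F(%g, %g) = %.3f, p = %.3g\n",
              m$wilks, m$df1, m$df2, m$value, m$p_value))
  invisible(x)
}

#' @exportS3Method
tidy.mancova_fit <- function(x, ...) x$per_outcome

#' @exportS3Method
glance.mancova_fit <- function(x, ...) x$multivariate

#' Independent two-sample t test
#'
#' Pooled-variance (Student) t test by default, as conventional for
#' demographic group comparisons.
#'
#' @param data Data frame.
#' @param outcome Name of the numeric outcome column.
#' @param group Name of the two-level grouping column.
#' @param var_equal Pool variances (default TRUE).
#' @return One-row tibble: statistic, df, estimate (group1 - group2),
#'   p_value.
#' @export
ttest_ind <- function(data, outcome, group, var_equal = TRUE) {
  g <- factor(data[[group]])
  if (nlevels(g) != 2L) {
    abort("t test needs exactly 2 groups", class = "cortexdti_design_error")
  }
  x <- data[[outcome]][g == levels(g)[1L]]
  y <- data[[outcome]][g == levels(g)[2L]]
  if (length(x) < 2L || length(y) < 2L) {
    abort("each group needs n >= 2", class = "cortexdti_variance_error")
  }
  tt <- t.test(x, y, var.equal = var_equal)
  tibble(outcome = outcome, statistic = unname(tt$statistic),
         df = unname(tt$parameter), estimate = mean(x) - mean(y),
         p_value = tt$p.value)
}

#' Pearson chi-square test on a contingency table
#'
#' @param tab Contingency table (matrix), e.g. 2 x 2 gender by group counts.
#' @param correct Apply Yates continuity correction (default FALSE, the
#'   Pearson statistic).
#' @return One-row tibble: statistic, df, p_value.
#' @export
chi_square <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (all(tab == 0)) {
    abort("empty contingency table", class = "cortexdti_contract_error")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = ct$p.value)
}

#' One-way ANOVA
#'
#' @param data Data frame.
#' @param outcome Numeric outcome column name.
#' @param group Grouping column name (>= 2 levels).
#' @return One-row tibble: statistic (F), df1, df2, p_value.
#' @export
anova_oneway <- function(data, outcome, group) {
  g <- factor(data[[group]])
  if (any(table(g) < 2L)) {
    abort("every group needs n >= 2 for a variance estimate",
          class = "cortexdti_variance_error")
  }
  fit <- aov(stats::as.formula(sprintf("`%s` ~ g", outcome)),
             data = cbind(data, g = g))
  a <- stats::anova(fit)
  tibble(outcome = outcome, statistic = a[1, "F value"],
         df1 = a[1, "Df"], df2 = a[2, "Df"], p_value = a[1, "Pr(>F)"])
}

#' Pairwise post-hoc comparisons with pooled within-group variance
#'
#' Fisher-LSD style pairwise two-sample t tests using the pooled error
#' variance (and residual degrees of freedom) from the omnibus one-way
#' ANOVA. P values are returned unadjusted so the caller can pool an entire
#' family (e.g. regions x group pairs) into a single FDR correction with
#' [fdr_bh()].
#'
#' @param data Data frame.
#' @param outcome Numeric outcome column name.
#' @param group Grouping column name (>= 2 levels).
#' @return Tibble with one row per unordered group pair: group1, group2,
#'   estimate (mean1 - mean2), statistic, df, p_value.
#' @export
posthoc_pairwise <- function(data, outcome, group) {
  g <- factor(data[[group]])
  if (nlevels(g) < 2L) {
    abort("need >= 2 groups", class = "cortexdti_design_error")
  }
  if (any(table(g) < 2L)) {
    abort("every group needs n >= 2 for a variance estimate",
          class = "cortexdti_variance_error")
  }
  y <- data[[outcome]]
  fit <- aov(y ~ g)
  mse <- stats::deviance(fit) / stats::df.residual(fit)
  dfe <- stats::df.residual(fit)
  lv <- levels(g)
  pairs <- utils::combn(lv, 2L)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    na <- sum(g == a); nb <- sum(g == b)
    est <- mean(y[g == a]) - mean(y[g == b])
    se <- sqrt(mse * (1 / na + 1 / nb))
    stat <- est / se
    tibble(outcome = outcome, group1 = a, group2 = b, estimate = est,
           statistic = stat, df = dfe,
           p_value = 2 * pt(-abs(stat), dfe))
  })
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment of a family of p values with rejection flags at
#' level `q`.
#'
#' @param p Numeric vector of raw p values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return Tibble with columns `p_value`, `p_adjusted`, `significant`
#'   (adjusted p <= q), in the input order. Empty input gives an empty
#'   tibble.
#' @export
#' @examples
#' fdr_bh(c(0.01, 0.02, 0.03, 0.04))  # all adjusted to 0.04, all significant
fdr_bh <- function(p, q = 0.05) {
  if (length(p) == 0L) {
    return(tibble(p_value = numeric(), p_adjusted = numeric(),
                  significant = logical()))
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p values must lie in [0, 1]", class = "cortexdti_contract_error")
  }
  adj <- p.adjust(p, method = "BH")
  tibble(p_value = p, p_adjusted = adj, significant = adj <= q)
}
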