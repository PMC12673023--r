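# Cohort statistics: one-way ANOVA with a Bonferroni-style gate, Tukey HSD,
# univariate -> multivariate regression with VIF screening, Pearson
# correlation, and a chi-square helper for categorical baselines.

#' One-way ANOVA
#'
#' Classical between/within-group F test.
#'
#' @param data a data frame.
#' @param value,group unquoted column names (numeric outcome, group label).
#' @return One-row tibble: statistic (F), df_between, df_within, p_value.
#'   With zero variance everywhere (all groups identical) the convention
#'   F = 0, p = 1 is returned.
#' @export
anova_oneway <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  if (nlevels(g) < 2) abort_input("need at least 2 groups")
  if (any(table(g) < 2)) abort_input("each group needs n >= 2")
  fit <- aov(v ~ g)
  s <- summary(fit)[[1]]
  F <- s[["F value"]][1]
  p <- s[["Pr(>F)"]][1]
  if (!is.finite(F)) {
    ss_between <- s[["Sum Sq"]][1]
    if (ss_between < 1e-12) { F <- 0; p <- 1 } else { F <- Inf; p <- 0 }
  }
  tibble(statistic = F, df_between = s[["Df"]][1], df_within = s[["Df"]][2],
         p_value = p)
}

#' Significance gate at a fixed threshold
#'
#' Flags p-values strictly below the threshold (default 0.005, the
#' multiplicity-corrected gate used for the imaging-parameter ANOVAs).
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @param threshold significance threshold.
#' @return Logical vector.
#' @export
bonferroni_gate <- function(p_values, threshold = 0.005) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    abort_input("p-values must lie in [0, 1]")
  p_values < threshold
}

#' Tukey honestly-significant-difference pairwise tests
#'
#' @inheritParams anova_oneway
#' @return Tibble of pairwise contrasts: estimate, conf.low, conf.high,
#'   adjusted p (studentized range).
#' @export
tukey_hsd <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  if (nlevels(g) < 2) abort_input("need at least 2 groups")
  tk <- TukeyHSD(aov(v ~ g))$g
  tibble(contrast = rownames(tk), estimate = tk[, "diff"],
         conf.low = tk[, "lwr"], conf.high = tk[, "upr"],
         p_value = tk[, "p adj"])
}

#' Pearson correlation
#'
#' @param data a data frame.
#' @param x,y unquoted numeric column names.
#' @return One-row tibble: estimate (r), statistic (t), p_value, n.
#' @export
pearson_cor <- function(data, x, y) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  ok <- is.finite(xv) & is.finite(yv)
  if (sum(ok) < 3) abort_input("need n >= 3 complete pairs")
  if (sd(xv[ok]) == 0 || sd(yv[ok]) == 0)
    abort_input("zero variance in x or y")
  ct <- stats::cor.test(xv[ok], yv[ok], method = "pearson")
  tibble(estimate = unname(ct$estimate), statistic = unname(ct$statistic),
         p_value = ct$p.value, n = sum(ok))
}

#' Univariate-to-multivariate linear regression with VIF screening
#'
#' Each predictor is first fitted alone; predictors with univariate
#' p < `promote_threshold` enter one multivariate ordinary-least-squares
#' model. Collinear predictors are then removed one at a time (highest
#' variance inflation factor first) until all VIF <= `vif_threshold`.
#' Complete cases are required; rows with missing values are an error, not
#' silently dropped.
#'
#' @param data a data frame.
#' @param outcome outcome column name (string).
#' @param predictors character vector of predictor column names.
#' @param promote_threshold univariate p-value required to enter the
#'   multivariate model.
#' @param vif_threshold maximum tolerated variance inflation factor.
#' @return An `aorta_regression` object (see [tidy()] / [glance()]).
#' @export
regress <- function(data, outcome, predictors, promote_threshold = 0.05,
                    vif_threshold = 5) {
  cols <- c(outcome, predictors)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    abort_input(paste("columns not in data:",
                      paste(missing_cols, collapse = ", ")))
  if (!all(complete.cases(data[cols])))
    abort_input("missing values in outcome/predictors; complete cases required")
  if (nrow(data) <= length(predictors) + 2)
    abort_input("need n > number of predictors + 2")

  uni_fit <- function(p) {
    fit <- lm(reformulate(p, response = outcome), data = data)
    ci <- confint(fit)
    tibble(term = p, estimate = coef(fit)[[p]], conf.low = ci[p, 1],
           conf.high = ci[p, 2],
           p_value = summary(fit)$coefficients[p, 4])
  }
  univariate <- dplyr::bind_rows(lapply(predictors, uni_fit))
  promoted <- univariate$term[univariate$p_value < promote_threshold]

  dropped <- tibble(term = character(), vif = numeric())
  multivariate <- NULL
  r2 <- NA_real_
  fit <- NULL
  if (length(promoted) >= 1) {
    keep <- promoted
    repeat {
      fit <- lm(reformulate(keep, response = outcome), data = data)
      if (any(is.na(coef(fit))))
        stop("rank-deficient design matrix in multivariate model")
      vifs <- if (length(keep) >= 2) car::vif(fit) else
        setNames(1, keep)
      if (max(vifs) <= vif_threshold || length(keep) == 1) break
      worst <- names(which.max(vifs))
      dropped <- dplyr::bind_rows(dropped,
                                  tibble(term = worst,
                                         vif = unname(max(vifs))))
      keep <- setdiff(keep, worst)
    }
    ci <- confint(fit)
    multivariate <- tibble(term = keep,
                           estimate = coef(fit)[keep],
                           conf.low = ci[keep, 1], conf.high = ci[keep, 2],
                           p_value = summary(fit)$coefficients[keep, 4],
                           vif = unname(vifs[keep]))
    r2 <- summary(fit)$r.squared
  }
  structure(list(univariate = univariate, multivariate = multivariate,
                 dropped = dropped, r_squared = r2, outcome = outcome,
                 promote_threshold = promote_threshold,
                 vif_threshold = vif_threshold, n = nrow(data), fit = fit),
            class = "aorta_regression")
}

#' @export
print.aorta_regression <- function(x, ...) {
  cat(sprintf("<aorta_regression> outcome: %s (n = %d)\n", x$outcome, x$n))
  cat("univariate:\n"); print(x$univariate)
  if (!is.null(x$multivariate)) {
    cat(sprintf("multivariate (R^2 = %.3f):\n", x$r_squared))
    print(x$multivariate)
  } else cat("no predictor passed the univariate gate\n")
  if (nrow(x$dropped)) {
    cat("dropped for collinearity:\n"); print(x$dropped)
  }
  invisible(x)
}

#' @export
tidy.aorta_regression <- function(x, ...) {
  uni <- dplyr::mutate(x$univariate, model = "univariate", vif = NA_real_)
  if (is.null(x$multivariate)) return(uni)
  dplyr::bind_rows(uni, dplyr::mutate(x$multivariate, model = "multivariate"))
}

#' @export
glance.aorta_regression <- function(x, ...) {
  tibble(r_squared = x$r_squared, n = x$n,
         n_promoted = if (is.null(x$multivariate)) 0L else
           nrow(x$multivariate),
         n_dropped_vif = nrow(x$dropped))
}

#' Chi-square test for a categorical baseline variable
#'
#' Plain Pearson chi-square on the contingency table, without Yates
#' continuity correction.
#'
#' @param data a data frame.
#' @param var,group unquoted categorical column names.
#' @return One-row tibble: statistic, df, p_value.
#' @export
chisq_categorical <- function(data, var, group) {
  tab <- table(dplyr::pull(data, {{ var }}), dplyr::pull(data, {{ group }}))
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = ct$p.value)
}
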