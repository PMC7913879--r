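#' Kolmogorov-Smirnov normality screen
#'
#' One-sample KS test of a sample against a normal distribution with the
#' sample's own mean and standard deviation, p-value from the asymptotic KS
#' distribution. Because the parameters are estimated from the same sample
#' the p-value is approximate (anticonservative); the Lilliefors correction
#' is deliberately not applied so the screen matches the plain test reported
#' by standard statistics software.
#'
#' @param values Numeric sample, `n >= 5`, non-constant.
#' @return One-row tibble: `statistic`, `p_value`, `n`.
#' @export
ks_normality <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 5L) {
    stop_pdff("KS normality screen needs at least 5 values.",
              "pdff_domain_error")
  }
  s <- sd(values)
  if (s == 0) {
    stop_pdff("sample is constant; normality is undefined.",
              "pdff_degenerate_error")
  }
  kt <- suppressWarnings(ks.test(values, "pnorm", mean(values), s))
  tibble(statistic = unname(kt$statistic), p_value = kt$p.value,
         n = length(values))
}

#' Unpaired pooled-variance t-test between sexes
#'
#' Classic Student two-sample t-test (equal-variance pooling), two-sided.
#'
#' @param x,y Numeric samples for the two groups, each `n >= 2`, with
#'   positive pooled variance.
#' @return One-row tibble: `t`, `df`, `p_value`, `mean_x`, `mean_y`.
#' @export
sex_compare <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop_pdff("each group needs at least 2 values.", "pdff_domain_error")
  }
  if (var(x) + var(y) == 0) {
    stop_pdff("pooled variance is zero; t-test undefined.",
              "pdff_degenerate_error")
  }
  tt <- t.test(x, y, var.equal = TRUE)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, mean_x = mean(x), mean_y = mean(y))
}

#' Bonferroni-corrected significance level
#'
#' `alpha / m` for a family of `m` comparisons. The full-precision value is
#' returned; the two-significant-figure rounding conventionally reported
#' (e.g. 0.05 / 24 -> 0.0021) is attached as attribute `"rounded"`.
#'
#' @param alpha Family-wise level in (0, 1).
#' @param m Number of comparisons, `>= 1`.
#' @return Numeric corrected level with attribute `rounded`.
#' @examples
#' attr(bonferroni_alpha(0.05, 24), "rounded")  # 0.0021
#' @export
bonferroni_alpha <- function(alpha = 0.05, m = 24) {
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha >= 1) {
    stop_pdff("`alpha` must be a single value in (0, 1).",
              "pdff_domain_error")
  }
  if (length(m) != 1L || is.na(m) || m < 1) {
    stop_pdff("`m` must be a single comparison count >= 1.",
              "pdff_domain_error")
  }
  out <- alpha / m
  attr(out, "rounded") <- signif(out, 2)
  out
}

#' Bonferroni-corrected Pearson correlation screen
#'
#' Pearson r and two-sided p-value (exact t reference, `df = n - 2`) of each
#' candidate variable against one outcome, flagged significant when
#' `p < alpha / m`, sorted by decreasing `|r|`. Zero-variance variables are
#' kept in the output with `r = NA` and `degenerate = TRUE`, excluded from
#' the ranking.
#'
#' @param data Data frame (cohort table).
#' @param outcome Name of the outcome column.
#' @param variables Character vector of candidate columns; defaults to the
#'   24-member strength-screen family (2 mean PDFF + 22 texture features).
#' @param alpha Family-wise level (default 0.05).
#' @param m Family size for the correction (default `length(variables)`).
#' @return Tibble of class `pdff_screen`: `variable`, `outcome`, `n`, `r`,
#'   `p_value`, `significant`, `degenerate`.
#' @export
correlation_screen <- function(data, outcome, variables = NULL,
                               alpha = 0.05, m = NULL) {
  variables <- variables %||%
    setdiff(cohort_predictors(), c("age", "bmi"))
  if (!outcome %in% names(data)) {
    stop_pdff(paste0("no column `", outcome, "` in `data`."),
              "pdff_schema_error")
  }
  missing_vars <- setdiff(variables, names(data))
  if (length(missing_vars) > 0) {
    stop_pdff(paste0("missing columns: ",
                     paste(missing_vars, collapse = ", ")),
              "pdff_schema_error")
  }
  m <- m %||% length(variables)
  a_corr <- bonferroni_alpha(alpha, m)
  y0 <- data[[outcome]]
  rows <- purrr::map(variables, function(v) {
    x <- data[[v]]
    ok <- !is.na(x) & !is.na(y0)
    n <- sum(ok)
    if (n < 3L) {
      stop_pdff(paste0("fewer than 3 complete pairs for ", v, "."),
                "pdff_domain_error")
    }
    x <- x[ok]
    y <- y0[ok]
    if (sd(x) == 0 || sd(y) == 0) {
      return(tibble(variable = v, outcome = outcome, n = n, r = NA_real_,
                    p_value = NA_real_, significant = FALSE,
                    degenerate = TRUE))
    }
    r <- sum((x - mean(x)) * (y - mean(y))) /
      ((n - 1) * sd(x) * sd(y))
    r <- max(min(r, 1), -1)
    p <- if (abs(r) == 1) 0 else {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      2 * pt(-abs(tstat), df = n - 2)
    }
    tibble(variable = v, outcome = outcome, n = n, r = r, p_value = p,
           significant = p < a_corr, degenerate = FALSE)
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(is.na(out$r), -abs(out$r)), ]
  attr(out, "alpha") <- alpha
  attr(out, "m") <- m
  attr(out, "alpha_corrected") <- as.numeric(a_corr)
  class(out) <- c("pdff_screen", class(out))
  out
}

# Partial-F p-value for adding each column of `candidates` to the model
# with predictors `included`. Returns a named vector of p-values.
partial_f_add <- function(data, outcome, included, candidates) {
  n <- nrow(data)
  rss <- function(preds) {
    f <- if (length(preds) == 0) paste(outcome, "~ 1")
         else paste(outcome, "~", paste(preds, collapse = " + "))
    sum(lm(stats::as.formula(f), data = data)$residuals^2)
  }
  rss0 <- rss(included)
  vapply(candidates, function(v) {
    rss1 <- rss(c(included, v))
    df2 <- n - length(included) - 2
    if (df2 <= 0) return(NA_real_)
    if (rss1 <= 0) return(0)
    fstat <- (rss0 - rss1) / (rss1 / df2)
    pf(fstat, 1, df2, lower.tail = FALSE)
  }, numeric(1))
}

#' Stepwise multivariate linear regression by partial F-tests
#'
#' Bidirectional stepwise selection in the style of classic statistics
#' packages: at each iteration the excluded candidate with the smallest
#' partial-F p-value is entered if `p < p_in`, then the included predictor
#' with the largest partial-F p-value is removed if `p > p_out`. Ties break
#' on the smaller p, then alphabetically; a visited-state set guards
#' against entry/removal cycles. If no candidate ever passes entry the
#' intercept-only model is returned (not an error).
#'
#' @param data Cohort table (data frame).
#' @param outcome Outcome column name (e.g. `"mvic_ext"`).
#' @param candidates Candidate predictor columns; defaults to
#'   [cohort_predictors()].
#' @param p_in Entry threshold on the partial-F p-value (default 0.05).
#' @param p_out Removal threshold (default 0.10); must be `>= p_in`.
#' @return An object of class `stepwise_lm`: list with `fit` (the final
#'   `lm`), `outcome`, `selected`, `trace` (tibble of step, action,
#'   variable, p_value), `r2`, `r2_adj`, `n`, `p_in`, `p_out`. Use
#'   [tidy()] / [glance()] to extract coefficient and fit summaries.
#' @export
stepwise_regression <- function(data, outcome, candidates = NULL,
                                p_in = 0.05, p_out = 0.10) {
  candidates <- candidates %||% cohort_predictors()
  miss <- setdiff(c(outcome, candidates), names(data))
  if (length(miss) > 0) {
    stop_pdff(paste0("missing columns: ", paste(miss, collapse = ", ")),
              "pdff_schema_error")
  }
  if (p_out < p_in) {
    stop_pdff("`p_out` must be >= `p_in`.", "pdff_config_error")
  }
  keep_rows <- stats::complete.cases(data[, c(outcome, candidates)])
  data <- data[keep_rows, , drop = FALSE]
  n <- nrow(data)
  candidates <- candidates[vapply(candidates,
                                  function(v) sd(data[[v]]) > 0, logical(1))]

  included <- character(0)
  trace <- list()
  seen <- character(0)
  step_i <- 0L
  repeat {
    changed <- FALSE
    # forward step; skipped once the current model is numerically exact
    # (otherwise every remaining candidate reports p = 0 in the noiseless
    # limit and spurious terms would enter)
    tss <- sum((data[[outcome]] - mean(data[[outcome]]))^2)
    rss_now <- if (length(included) == 0) tss else
      sum(lm(stats::as.formula(paste(outcome, "~",
        paste(included, collapse = " + "))), data = data)$residuals^2)
    excl <- setdiff(candidates, included)
    if (length(excl) > 0 && n > length(included) + 2 &&
        rss_now > 1e-10 * tss) {
      pv <- partial_f_add(data, outcome, included, excl)
      pv <- pv[!is.na(pv)]
      if (length(pv) > 0) {
        ord <- order(pv, names(pv))
        best <- names(pv)[ord[1]]
        if (pv[best] < p_in) {
          included <- c(included, best)
          step_i <- step_i + 1L
          trace[[length(trace) + 1L]] <-
            tibble(step = step_i, action = "add", variable = best,
                   p_value = unname(pv[best]))
          changed <- TRUE
        }
      }
    }
    # backward step: partial F of each included term given the others
    if (length(included) > 0) {
      pv <- vapply(included, function(v) {
        unname(partial_f_add(data, outcome, setdiff(included, v), v))
      }, numeric(1))
      ord <- order(-pv, names(pv))
      worst <- included[ord[1]]
      if (!is.na(pv[worst]) && pv[worst] > p_out) {
        included <- setdiff(included, worst)
        step_i <- step_i + 1L
        trace[[length(trace) + 1L]] <-
          tibble(step = step_i, action = "remove", variable = worst,
                 p_value = unname(pv[worst]))
        changed <- TRUE
      }
    }
    state <- paste(sort(included), collapse = "|")
    if (!changed || state %in% seen) break
    seen <- c(seen, state)
  }

  f <- if (length(included) == 0) paste(outcome, "~ 1")
       else paste(outcome, "~", paste(included, collapse = " + "))
  fit <- lm(stats::as.formula(f), data = data)
  r2 <- summary(fit)$r.squared
  k <- length(included)
  structure(list(fit = fit, outcome = outcome, selected = included,
                 trace = dplyr::bind_rows(trace),
                 r2 = r2,
                 r2_adj = if (k == 0) r2 else adjusted_r2(r2, n, k),
                 n = n, p_in = p_in, p_out = p_out),
            class = "stepwise_lm")
}

#' Adjusted coefficient of determination
#'
#' `1 - (1 - r2) * (n - 1) / (n - k - 1)` for a model with `k` predictors
#' fitted to `n` observations.
#'
#' @param r2 Unadjusted R-squared.
#' @param n Number of observations.
#' @param k Number of predictors (excluding the intercept); `n > k + 1`.
#' @return Adjusted R-squared.
#' @examples
#' adjusted_r2(0.5, 26, 2)  # 0.4565...
#' @export
adjusted_r2 <- function(r2, n, k) {
  if (n <= k + 1) {
    stop_pdff("adjusted R^2 requires n > k + 1.", "pdff_domain_error")
  }
  1 - (1 - r2) * (n - 1) / (n - k - 1)
}

#' @export
print.stepwise_lm <- function(x, ...) {
  cat("Stepwise linear model for", x$outcome, "\n")
  cat("  selected:", if (length(x$selected)) paste(x$selected,
      collapse = ", ") else "(intercept only)", "\n")
  cat(sprintf("  R^2 = %.3f, adjusted R^2 = %.3f, n = %d\n",
              x$r2, x$r2_adj, x$n))
  invisible(x)
}

#' Tidy the coefficients of a stepwise model
#'
#' @param x A [stepwise_regression()] result.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`.
#' @exportS3Method generics::tidy
tidy.stepwise_lm <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble(term = rownames(cf), estimate = cf[, 1], std_error = cf[, 2],
         statistic = cf[, 3], p_value = cf[, 4])
}

#' One-row fit summary of a stepwise model
#'
#' @param x A [stepwise_regression()] result.
#' @param ... Unused.
#' @return Tibble with `outcome`, `r2`, `r2_adj`, `n`, `k`, `n_steps`.
#' @exportS3Method generics::glance
glance.stepwise_lm <- function(x, ...) {
  tibble(outcome = x$outcome, r2 = x$r2, r2_adj = x$r2_adj, n = x$n,
         k = length(x$selected), n_steps = nrow(x$trace))
}

#' Sex-comparison table of cohort variables
#'
#' Pooled t-test of every requested variable between females and males,
#' with Bonferroni flags — the descriptive sex-difference table of a cohort.
#'
#' @param data Cohort table with a `sex` column (`"male"`/`"female"`).
#' @param variables Columns to compare; defaults to age, BMI, mean PDFF and
#'   the 22 texture features.
#' @param alpha Family-wise level.
#' @param m Family size for the Bonferroni flag (default
#'   `length(variables)`).
#' @return Tibble: `variable`, male/female means and SDs, `t`, `df`,
#'   `p_value`, `significant`.
#' @export
cohort_sex_table <- function(data, variables = NULL, alpha = 0.05,
                             m = NULL) {
  variables <- variables %||% cohort_predictors()
  m <- m %||% length(variables)
  a_corr <- bonferroni_alpha(alpha, m)
  male <- data[data$sex == "male", ]
  female <- data[data$sex == "female", ]
  purrr::map(variables, function(v) {
    tt <- sex_compare(male[[v]], female[[v]])
    tibble(variable = v,
           mean_male = mean(male[[v]]), sd_male = sd(male[[v]]),
           mean_female = mean(female[[v]]), sd_female = sd(female[[v]]),
           t = tt$t, df = tt$df, p_value = tt$p_value,
           significant = tt$p_value < a_corr)
  }) |> dplyr::bind_rows()
}
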