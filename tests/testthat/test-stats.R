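test_that("KS screen accepts normal samples and near-perfect fits", {
  set.seed(123)
  x <- rnorm(1e4, 5, 2)
  res <- ks_normality(x)
  expect_gt(res$p_value, 0.05)

  n <- 100
  q <- qnorm((seq_len(n) - 0.5) / n)
  expect_lt(ks_normality(q)$statistic, 1 / n + 0.01)

  expect_error(ks_normality(c(1, 2, 3)), class = "pdff_domain_error")
  expect_error(ks_normality(rep(2, 10)), class = "pdff_degenerate_error")
})

test_that("the pooled t-test matches its closed form and antisymmetry", {
  same <- sex_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  res <- sex_compare(c(1, 2, 3, 4), c(3, 4, 5, 6))
  expect_equal(res$t, -2.19089023, tolerance = 1e-6)
  expect_equal(res$df, 6)

  flip <- sex_compare(c(3, 4, 5, 6), c(1, 2, 3, 4))
  expect_equal(flip$t, -res$t)
  expect_equal(flip$p_value, res$p_value)

  expect_error(sex_compare(1, c(1, 2)), class = "pdff_domain_error")
  expect_error(sex_compare(rep(1, 4), rep(1, 4)),
               class = "pdff_degenerate_error")
})

test_that("Bonferroni correction reproduces the printed levels", {
  a24 <- bonferroni_alpha(0.05, 24)
  expect_equal(as.numeric(a24), 0.05 / 24)
  expect_equal(attr(a24, "rounded"), 0.0021)
  expect_equal(attr(bonferroni_alpha(0.05, 22), "rounded"), 0.0023)
  expect_equal(as.numeric(bonferroni_alpha(0.05, 1)), 0.05)
  expect_error(bonferroni_alpha(1.2, 5), class = "pdff_domain_error")
})

test_that("the correlation screen matches a covariance-formula oracle", {
  set.seed(31)
  n <- 26
  df <- tibble::tibble(y = rnorm(n))
  for (v in paste0("v", 1:6)) df[[v]] <- rnorm(n)
  scr <- correlation_screen(df, "y", paste0("v", 1:6), alpha = 0.05, m = 6)
  for (v in paste0("v", 1:6)) {
    x <- df[[v]]
    r_oracle <- sum((x - mean(x)) * (df$y - mean(df$y))) /
      sqrt(sum((x - mean(x))^2) * sum((df$y - mean(df$y))^2))
    expect_equal(scr$r[scr$variable == v], r_oracle, tolerance = 1e-12)
    p_oracle <- cor.test(x, df$y)$p.value
    expect_equal(scr$p_value[scr$variable == v], p_oracle,
                 tolerance = 1e-10)
  }
  expect_identical(scr$variable, scr$variable[order(-abs(scr$r))])
})

test_that("exact linear relations give |r| = 1 and degenerates are flagged", {
  df <- tibble::tibble(x = 1:10, y = 2 * (1:10) + 1, z = -(1:10),
                       const = rep(4, 10))
  scr <- correlation_screen(df, "y", c("x", "z", "const"))
  expect_equal(scr$r[scr$variable == "x"], 1)
  expect_equal(scr$r[scr$variable == "z"], -1)
  expect_true(scr$degenerate[scr$variable == "const"])
  expect_true(is.na(scr$r[scr$variable == "const"]))
})

test_that("a perfect predictor is selected alone with adjusted R^2 = 1", {
  set.seed(40)
  df <- tibble::tibble(x1 = rnorm(20), noise = rnorm(20))
  df$y <- df$x1
  m <- stepwise_regression(df, "y", c("x1", "noise"))
  expect_identical(m$selected, "x1")
  expect_equal(m$r2_adj, 1, tolerance = 1e-9)
})

test_that("a planted two-predictor model is recovered from noise", {
  set.seed(2718)
  n <- 100
  df <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n), n1 = rnorm(n),
                       n2 = rnorm(n), n3 = rnorm(n))
  df$y <- 2 * df$x1 - 3 * df$x2 + rnorm(n, 0, 0.5)
  m <- stepwise_regression(df, "y", c("x1", "x2", "n1", "n2", "n3"))
  expect_true(all(c("x1", "x2") %in% m$selected))
  co <- tidy(m)
  expect_lt(abs(co$estimate[co$term == "x1"] - 2) / 2, 0.1)
  expect_lt(abs(co$estimate[co$term == "x2"] + 3) / 3, 0.1)
})

test_that("the returned model satisfies the entry and removal conditions", {
  set.seed(55)
  n <- 60
  df <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                       x4 = rnorm(n))
  df$y <- df$x1 + 0.4 * df$x2 + rnorm(n)
  m <- stepwise_regression(df, "y", paste0("x", 1:4))
  adds <- m$trace[m$trace$action == "add", ]
  expect_true(all(adds$p_value < m$p_in))
  # post hoc: every retained predictor's removal p is <= p_out
  for (v in m$selected) {
    rest <- setdiff(m$selected, v)
    f0 <- if (length(rest) == 0) "y ~ 1" else
      paste("y ~", paste(rest, collapse = " + "))
    rss0 <- sum(lm(as.formula(f0), df)$residuals^2)
    rss1 <- sum(m$fit$residuals^2)
    fstat <- (rss0 - rss1) / (rss1 / (n - length(m$selected) - 1))
    p <- pf(fstat, 1, n - length(m$selected) - 1, lower.tail = FALSE)
    expect_lte(p, m$p_out)
  }
})

test_that("with all-noise candidates something enters at the expected rate", {
  set.seed(808)
  n_seeds <- 300
  entered <- logical(n_seeds)
  for (s in seq_len(n_seeds)) {
    df <- as.data.frame(matrix(rnorm(100 * 11), 100, 11))
    names(df) <- c("y", paste0("x", 1:10))
    m <- stepwise_regression(df, "y", paste0("x", 1:10))
    entered[s] <- length(m$selected) > 0
  }
  # candidate minimum p below 0.05 happens with prob ~ 1 - 0.95^10 = 0.40
  expect_gt(mean(entered), 0.40 - 0.09)
  expect_lt(mean(entered), 0.40 + 0.09)
})

test_that("the intercept-only model is returned when nothing qualifies", {
  set.seed(3)
  df <- tibble::tibble(y = rnorm(30), x1 = rep(c(1, 2), 15))
  df$x1 <- df$x1 + rnorm(30, 0, 1e-9)  # non-constant but uninformative
  m <- stepwise_regression(df, "y", "x1", p_in = 1e-6)
  expect_identical(m$selected, character(0))
  expect_identical(nrow(m$trace), 0L)
})

test_that("adjusted R^2 follows its formula and decreases with k", {
  expect_equal(adjusted_r2(0.5, 26, 2), 1 - 0.5 * 25 / 23)
  expect_equal(round(adjusted_r2(0.5, 26, 2), 4), 0.4565)
  expect_equal(adjusted_r2(1, 50, 7), 1)
  expect_equal(adjusted_r2(0.37, 40, 0), 0.37)
  ks <- 0:8
  vals <- vapply(ks, function(k) adjusted_r2(0.8, 30, k), numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_error(adjusted_r2(0.5, 5, 4), class = "pdff_domain_error")
})

test_that("the sex table flags large differences and spares null ones", {
  set.seed(14)
  n <- 40
  df <- tibble::tibble(sex = rep(c("male", "female"), each = n / 2),
                       shifted = c(rnorm(n / 2, 0), rnorm(n / 2, 3)),
                       null1 = rnorm(n), null2 = rnorm(n))
  tab <- cohort_sex_table(df, c("shifted", "null1", "null2"), m = 24)
  expect_true(tab$significant[tab$variable == "shifted"])
  expect_false(any(tab$significant[tab$variable != "shifted"]))
})
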