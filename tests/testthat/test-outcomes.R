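test_that("2x2 tables are assembled from event counts and totals", {
  t <- make_table(63, 115, 105, 272)
  expect_identical(unclass(t), c(a = 63L, b = 52L, c = 105L, d = 167L))
  t0 <- make_table(0, 10, 0, 10)
  expect_identical(unclass(t0), c(a = 0L, b = 10L, c = 0L, d = 10L))
  expect_error(make_table(11, 10, 0, 10), "exceed")
  expect_error(make_table(-1, 10, 0, 10), "nonnegative")
})

test_that("the odds ratio inverts exactly under outcome transposition", {
  t <- make_table(63, 115, 105, 272)
  # swap events and non-events in both rows
  t_swap <- make_table(52, 115, 167, 272)
  expect_equal(odds_ratio(t) * odds_ratio(t_swap), 1, tolerance = 1e-12)
  tk <- make_table(9, 18, 9, 18)
  expect_equal(as.numeric(odds_ratio(tk)), 1)
})

test_that("zero cells trigger the Haldane-Anscombe correction", {
  t <- make_table(0, 10, 5, 10)
  or <- odds_ratio(t)
  expect_true(is.finite(or))
  expect_true(isTRUE(attr(or, "haldane")))
  expect_equal(as.numeric(or), (0.5 * 5.5) / (10.5 * 5.5), tolerance = 1e-12)
  expect_error(odds_ratio(make_table(0, 0, 0, 0)), "all-zero")
  ci <- woolf_ci(t)
  expect_true(all(is.finite(ci)))
})

test_that("Woolf intervals bracket the OR and shrink with sample size", {
  t1 <- make_table(63, 115, 105, 272)
  or <- as.numeric(odds_ratio(t1))
  widths <- vapply(c(1, 2, 4), function(k) {
    tk <- make_table(63 * k, 115 * k, 105 * k, 272 * k)
    ci <- woolf_ci(tk)
    expect_lte(ci[["low"]], as.numeric(odds_ratio(tk)))
    expect_gte(ci[["high"]], as.numeric(odds_ratio(tk)))
    log(ci[["high"]]) - log(ci[["low"]])
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  # symmetric table: interval is log-symmetric around 1
  ci_sym <- woolf_ci(make_table(9, 18, 9, 18))
  expect_equal(log(ci_sym[["high"]]), -log(ci_sym[["low"]]),
               tolerance = 1e-12)
  expect_error(woolf_ci(t1, level = 1.2), "level")
})

test_that("the chi-square statistic matches the classical implementation", {
  cases <- list(c(63, 115, 105, 272), c(45, 70, 140, 272),
                c(10, 73, 35, 140), c(3, 12, 9, 20))
  for (cs in cases) {
    t <- make_table(cs[1], cs[2], cs[3], cs[4])
    mine <- chi_square_test(t)
    m <- matrix(unclass(t), 2, 2, byrow = TRUE)
    ref <- suppressWarnings(chisq.test(m, correct = FALSE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    yates <- chi_square_test(t, continuity_correction = TRUE)
    ref_y <- suppressWarnings(chisq.test(m, correct = TRUE))
    expect_equal(yates$statistic, unname(ref_y$statistic), tolerance = 1e-10)
  }
  # invariance under row and column swaps
  t <- make_table(63, 115, 105, 272)
  t_rows <- make_table(105, 272, 63, 115)
  t_cols <- make_table(52, 115, 167, 272)
  expect_equal(chi_square_test(t)$statistic,
               chi_square_test(t_rows)$statistic, tolerance = 1e-12)
  expect_equal(chi_square_test(t)$statistic,
               chi_square_test(t_cols)$statistic, tolerance = 1e-12)
  # degenerate: uniform table, zero margin
  k <- make_table(9, 18, 9, 18)
  expect_equal(chi_square_test(k)$statistic, 0)
  expect_equal(chi_square_test(k)$p_value, 1)
  expect_error(chi_square_test(make_table(0, 0, 5, 10)), "margin")
})

test_that("rates format with half-up rounding to one decimal place", {
  expect_equal(outcome_rates(63, 115)$percent, 54.8)
  expect_equal(outcome_rates(45, 115)$percent, 39.1)
  expect_equal(outcome_rates(0, 20)$percent, 0)
  expect_equal(outcome_rates(21, 400)$percent, 5.3)  # 5.25 rounds up
  expect_equal(outcome_rates(63, 115)$formatted, "63/115 (54.8%)")
  expect_error(outcome_rates(5, 0), "positive")
  expect_error(outcome_rates(11, 10), "events")
})

test_that("logistic regression with no covariates equals the crude OR", {
  records <- data.frame(
    group = rep(c("rsERT", "FET"), c(115, 272)),
    clinical = c(rep(c(TRUE, FALSE), c(63, 52)),
                 rep(c(TRUE, FALSE), c(105, 167))))
  fit <- fit_logistic(records, "clinical", exposed = "rsERT")
  crude <- as.numeric(odds_ratio(make_table(63, 115, 105, 272)))
  expect_equal(fit$odds_ratio, crude, tolerance = 1e-6)
  ci <- woolf_ci(make_table(63, 115, 105, 272))
  expect_equal(fit$ci_low, ci[["low"]], tolerance = 1e-4)
  expect_equal(fit$ci_high, ci[["high"]], tolerance = 1e-4)
})

test_that("adjusted fits agree with the reference GLM implementation", {
  withr::with_seed(41, {
    n <- 600
    rec <- data.frame(
      group = rep(c("FET", "rsERT"), each = n / 2),
      maternal_age = rnorm(n, 33, 4),
      bmi = rnorm(n, 22, 3),
      n_embryos = sample(1:2, n, replace = TRUE))
    lp <- -1.2 + 0.7 * (rec$group == "rsERT") + 0.04 * (rec$maternal_age - 33) -
      0.05 * (rec$bmi - 22) + 0.3 * (rec$n_embryos - 1)
    rec$clinical <- runif(n) < plogis(lp)
  })
  fit <- fit_logistic(rec, "clinical",
                      covariates = c("maternal_age", "bmi", "n_embryos"),
                      exposed = "rsERT")
  ref <- glm(clinical ~ I(group == "rsERT") + maternal_age + bmi + n_embryos,
             data = rec, family = binomial)
  expect_equal(fit$coefficients$estimate, unname(coef(ref)),
               tolerance = 1e-8)
  expect_equal(fit$coefficients$se,
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
})

test_that("a known group effect is recovered within three standard errors", {
  withr::with_seed(43, {
    n <- 4000
    rec <- data.frame(group = rep(c("FET", "rsERT"), each = n / 2),
                      maternal_age = rnorm(n, 33, 4))
    lp <- -0.5 + 0.6 * (rec$group == "rsERT") + 0.05 * (rec$maternal_age - 33)
    rec$clinical <- runif(n) < plogis(lp)
  })
  fit <- fit_logistic(rec, "clinical", covariates = "maternal_age",
                      exposed = "rsERT")
  i <- match("group", fit$coefficients$term)
  est <- fit$coefficients$estimate[i]
  se <- fit$coefficients$se[i]
  expect_lt(abs(est - 0.6), 3 * se)
})

test_that("separated data raise an error instead of a wild estimate", {
  rec <- data.frame(group = rep(c("FET", "rsERT"), each = 10),
                    clinical = rep(c(FALSE, TRUE), each = 10))
  expect_error(fit_logistic(rec, "clinical"), "converge|separat")
  # rank-deficient design
  rec2 <- data.frame(group = rep(c("FET", "rsERT"), each = 10),
                     x1 = 1:20, x2 = 2 * (1:20),
                     clinical = rep(c(TRUE, FALSE), 10))
  expect_error(fit_logistic(rec2, "clinical", covariates = c("x1", "x2")),
               "rank")
})

test_that("the outcome table conditions biochemical rates on positive hCG", {
  tab <- outcome_table(
    list(n = 115, hcg = 73, biochemical = 10, clinical = 63),
    list(n = 272, hcg = 140, biochemical = 35, clinical = 105))
  expect_equal(tab$outcome, c("Positive hCG", "Biochemical pregnancy",
                              "Clinical pregnancy"))
  expect_equal(tab$exposed[2], "10/73 (13.7%)")
  expect_equal(tab$unexposed[2], "35/140 (25.0%)")
  expect_equal(round(tab$odds_ratio, 2), c(1.64, 0.48, 1.93))
  expect_equal(round(tab$odds_ratio[2], 3), 0.476)
})
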