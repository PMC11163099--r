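test_that("a perfect line is recovered exactly with boundary inference", {
  d <- data.frame(x = c(1, 2, 4, 7), y = 2 * c(1, 2, 4, 7) + 1)
  f <- fit_qspr(d, "y", "x")
  expect_equal(f$A, 1)
  expect_equal(f$B, 2)
  expect_equal(f$se_estimate, 0)
  expect_equal(f$r_abs, 1)
  expect_true(is.infinite(f$f_stat))
  expect_equal(f$p_value, 0)
  expect_true(f$boundary)
  expect_true(f$significant)
})

test_that("OLS matches the normal-equation and lm() oracles on random data", {
  withr::with_seed(88, {
    x <- rnorm(8, 50, 10)
    y <- 3 - 0.4 * x + rnorm(8, 0, 2)
  })
  d <- data.frame(x = x, y = y)
  f <- fit_qspr(d, "y", "x")

  # normal equations solved independently
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(f$A, beta[1], tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(f$B, beta[2], tolerance = 1e-9, ignore_attr = TRUE)

  lmfit <- lm(y ~ x, data = d)
  expect_equal(unname(coef(lmfit)), c(f$A, f$B), tolerance = 1e-9)
  s <- summary(lmfit)
  expect_equal(f$r2, s$r.squared, tolerance = 1e-9)
  expect_equal(f$f_stat, unname(s$fstatistic[1]), tolerance = 1e-9)
  expect_equal(f$se_estimate, s$sigma, tolerance = 1e-9)
  expect_equal(tidy(f)$std.error, unname(s$coefficients[, 2]), tolerance = 1e-9)

  # internal consistency
  expect_equal(sum(f$residuals), 0, tolerance = 1e-9 * sd(y))
  expect_equal(predict(f, f$x_mean), f$y_mean)
  expect_equal(f$r2, f$r_abs^2, tolerance = 1e-12)
  expect_equal(f$f_stat, f$r2 * (f$n - 2) / (1 - f$r2), tolerance = 1e-9)
  expect_equal(f$r2, 1 - sum(f$residuals^2) / sum((y - mean(y))^2), tolerance = 1e-9)
  # slope t statistic squared equals the model F statistic
  expect_equal(tidy(f)$statistic[2]^2, f$f_stat, tolerance = 1e-9)
})

test_that("degenerate and undersized inputs raise typed errors", {
  expect_error(fit_qspr(data.frame(x = 1:2, y = 2:3), "y", "x"),
               class = "tiqspr_error_insufficient_data")
  expect_error(fit_qspr(data.frame(x = c(1, 1, 1), y = 1:3), "y", "x"),
               class = "tiqspr_error_degenerate_predictor")
  expect_error(fit_qspr(data.frame(x = 1:3, y = c(2, 2, 2)), "y", "x"),
               class = "tiqspr_error_degenerate_response")
  expect_error(fit_qspr(data.frame(x = 1:3), "y", "x"),
               class = "tiqspr_error_schema")
})

test_that("F upper tail matches quadrature of the density and is monotone", {
  expect_equal(f_upper_tail(0, 1, 3), 1)
  grid <- seq(0, 50, by = 2.5)
  for (df2 in c(3, 5, 10)) {
    vals <- f_upper_tail(grid, 1, df2)
    expect_true(all(diff(vals) < 0))
    for (f in c(0.5, 5, 14.7216, 37.5)) {
      quad <- stats::integrate(function(x) stats::df(x, 1, df2),
                               lower = f, upper = Inf, rel.tol = 1e-10)$value
      expect_equal(f_upper_tail(f, 1, df2), quad, tolerance = 1e-6)
    }
  }
  expect_error(f_upper_tail(-1, 1, 3), class = "tiqspr_error_domain")
  expect_error(f_upper_tail(Inf, 1, 3), class = "tiqspr_error_domain")
  expect_error(f_upper_tail(1, 0, 3), class = "tiqspr_error_domain")
})

test_that("correlation table reports |r| and annotates degenerate columns", {
  d <- fixture_data()
  ct <- correlation_table(d)
  expect_equal(ct$melting_point[ct$index == "F"], 0.911434835, tolerance = 1e-6)
  expect_equal(ct$melting_point[ct$index == "M1"], 0.844704869, tolerance = 1e-6)
  expect_true(all(ct$melting_point >= 0 & ct$melting_point <= 1))
  expect_true(all(ct$formula_weight <= 0.25)) # weak-correlation regime

  d2 <- d
  d2$formula_weight <- 350
  expect_warning(ct2 <- correlation_table(d2), "Degenerate")
  expect_true(all(is.na(ct2$formula_weight)))
  expect_false(anyNA(ct2$melting_point))

  expect_error(correlation_table(d[1:2, ]),
               class = "tiqspr_error_insufficient_data")
})

test_that("prediction tables give actual plus one column per index", {
  d <- fixture_data()
  models <- fit_qspr_models(d)
  expect_equal(nrow(models), 22L)
  expect_true(all(models$B[models$property == "melting_point"] < 0))

  pt <- prediction_table(models, d, "melting_point")
  expect_equal(names(pt), c("compound", "actual", index_ids()))
  expect_equal(nrow(pt), 5L)
  expect_equal(pt$actual, d$melting_point)
  # centroid property: mean prediction equals mean actual for every index
  for (ix in index_ids()) expect_equal(mean(pt[[ix]]), mean(pt$actual))

  sub <- prediction_table(fit_qspr_models(d, indices = "F"), d, "melting_point")
  expect_equal(names(sub), c("compound", "actual", "F"))
  expect_error(prediction_table(models, d, "boiling_point"),
               class = "tiqspr_error_schema")
})
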