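test_that("least-squares coefficients agree with brute-force minimization", {
  # 9-run toy fit of a 4-term two-factor model checked against direct
  # numerical minimization of the SSE
  tf <- toy_factors()
  withr::with_seed(11, {
    d <- full_factorial(tf)
    d$y <- 3 + 2 * code_value(tf, "a", d$a) - 1.5 * code_value(tf, "b", d$b) +
      rnorm(nrow(d), 0, 0.3)
  })
  X <- ffd_model_matrix(d, tf)
  fit <- ffd_fit(d, y, tf)
  oracle <- brute_force_ols(X, d$y)
  expect_equal(unname(coef(fit$lm)), oracle, tolerance = 1e-6)
})

test_that("residuals are orthogonal to every model-matrix column", {
  for (r in c("dpph", "htc")) {
    fit <- ffd_fit(oak, r)
    X <- ffd_model_matrix(oak)
    dots <- crossprod(X, resid(fit$lm))
    expect_lt(max(abs(dots)), 1e-6 * sd(oak[[r]]))
    expect_equal(fit$df_residual, 19)
  }
})

test_that("a constant response fits with zero effects and an intercept", {
  d <- full_factorial(oak_factors())
  d$y <- 7
  fit <- ffd_fit(d, y)
  cf <- coef(fit$lm)
  expect_equal(unname(cf["(Intercept)"]), 7)
  expect_equal(unname(cf[-1]), rep(0, 7), tolerance = 1e-12)
})

test_that("refitting the model to its own fitted values is idempotent", {
  fit <- ffd_fit(oak, dpph)
  d2 <- oak
  d2$dpph <- fitted(fit$lm)
  fit2 <- ffd_fit(d2, dpph)
  expect_equal(coef(fit2$lm), coef(fit$lm), tolerance = 1e-9)
  expect_equal(glance(fit2)$r.squared, 1, tolerance = 1e-9)
})

test_that("the intercept offsets the grand mean by the time-axis imbalance", {
  # only the time column has nonzero mean on this design, so
  # b0 = ybar - b3 * mean(x3)
  for (r in c("dpph", "frap", "tpc", "tfc", "ctc", "htc")) {
    fit <- ffd_fit(oak, r)
    cf <- coef(fit$lm)
    expect_equal(unname(cf["(Intercept)"]),
                 mean(oak[[r]]) - unname(cf["time"]) * (-5 / 21),
                 tolerance = 1e-9)
  }
})

test_that("rank-deficient and undersized designs are rejected", {
  d <- full_factorial(oak_factors())[1:9, ]
  d$y <- rnorm(9)
  expect_error(ffd_fit(d[1:8, ], y), class = "oakextract_domain_error")
  collapsed <- d
  collapsed$ethanol <- collapsed$temperature * 2 / 3 # perfectly confounded
  expect_error(expect_warning(ffd_fit(collapsed, y)))
})

test_that("fit statistics follow their defining formulas", {
  fit <- ffd_fit(oak, frap)
  g <- glance(fit)
  y <- oak$frap
  e <- resid(fit$lm)
  sst <- sum((y - mean(y))^2)
  expect_equal(g$r.squared, 1 - sum(e^2) / sst)
  expect_equal(g$adj.r.squared, 1 - (1 - g$r.squared) * 26 / 19)
  expect_equal(g$press, sum((e / (1 - hatvalues(fit$lm)))^2))
  expect_equal(g$pred.r.squared, 1 - g$press / sst)
  expect_equal(g$sigma, sqrt(sum(e^2) / 19))
  expect_equal(g$cv.pct, 100 * g$sigma / mean(y))
  expect_equal(g$adequate.precision,
               (max(fitted(fit$lm)) - min(fitted(fit$lm))) / sqrt(8 * fit$mse / 27))
  # ordering invariants
  expect_lte(g$adj.r.squared, g$r.squared)
  expect_gte(g$press, sum(e^2))
})

test_that("dropping the interaction terms never increases R-squared", {
  for (r in c("dpph", "tfc")) {
    full <- ffd_fit(oak, r)
    coded <- code_factors(oak, suffix = "")[c("temperature", "ethanol", "time")]
    coded$y <- oak[[r]]
    mains <- lm(y ~ temperature + ethanol + time, coded)
    expect_lte(summary(mains)$r.squared, glance(full)$r.squared)
  }
})

test_that("predictions carry fit SE and new-observation intervals", {
  fit <- ffd_fit(oak, dpph)
  centre <- data.frame(temperature = 50, ethanol = 20, time = 13.5)
  pc <- predict(fit, centre)
  # all coded terms vanish at the cube centre, so the fit is b0
  expect_equal(pc$.fitted, unname(coef(fit$lm)["(Intercept)"]))
  expect_false(pc$.extrapolated)

  pt <- predict(fit, data.frame(temperature = 80, ethanol = 40, time = 19.8))
  x <- c(1, 1, 1, 0.6, 1, 0.6, 0.6, 0.6)
  se_fit <- sqrt(drop(t(x) %*% fit$xtx_inverse %*% x) * fit$mse)
  expect_equal(pt$.se_fit, se_fit, tolerance = 1e-9)
  half <- qt(0.975, 19) * sqrt(fit$mse + se_fit^2)
  expect_equal(pt$.pi_upper - pt$.fitted, half, tolerance = 1e-9)
  expect_equal(pt$.fitted - pt$.pi_lower, half, tolerance = 1e-9)
  expect_true(pt$.pi_lower < pt$.fitted && pt$.fitted < pt$.pi_upper)

  out <- predict(fit, data.frame(temperature = 90, ethanol = 40, time = 24))
  expect_true(out$.extrapolated)
})

test_that("augment exports observed, fitted, residual and leverage per run", {
  fit <- ffd_fit(oak, tpc)
  aug <- augment(fit)
  expect_equal(nrow(aug), 27)
  expect_equal(aug$.resid, aug$tpc - aug$.fitted)
  expect_equal(sum(aug$.hat), 8, tolerance = 1e-9) # trace of the hat matrix
  expect_true(all(aug$.hat > 0 & aug$.hat < 1))
})
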