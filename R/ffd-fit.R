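#' Fit the factorial linear-with-interactions response model
#'
#' Ordinary least squares of one assay response on the coded factors:
#' intercept, main effects, all two-factor interactions and the
#' highest-order interaction (8 terms for three factors). Coefficients
#' are in response units per coded unit, so their magnitudes are directly
#' comparable across factors. Alongside the usual per-term inference the
#' fit carries the response-surface diagnostics used to judge model
#' adequacy: PRESS and predicted R-squared (exact leave-one-out via the
#' leverage shortcut), the coefficient of variation, and adequate
#' precision, the signal-to-noise ratio
#' \eqn{(\max\hat y - \min\hat y)/\sqrt{p\,MSE/n}} for which values above
#' 4 indicate a model able to navigate the design space.
#'
#' @param data Response table with natural-unit factor columns and the
#'   response column.
#' @param response Response column, bare name or string.
#' @param factors Factor-specification tibble (see [factor_spec()]).
#' @return An object of class `ffd_fit`. Use [tidy()] for coefficients
#'   and p-values, [glance()] for fit statistics, [augment()] for per-run
#'   fitted values, residuals and leverages, and [predict.ffd_fit()] for
#'   new settings.
#' @examples
#' fit <- ffd_fit(oak_runs(), dpph)
#' tidy(fit)
#' glance(fit)
#' @export
ffd_fit <- function(data, response, factors = oak_factors()) {
  response <- col_name(enquo(response))
  if (!response %in% names(data)) {
    abort(sprintf("Response column '%s' not found.", response),
          class = "oakextract_schema_error")
  }
  p <- 2L^nrow(factors)
  n <- nrow(data)
  if (n < p + 1L) {
    abort(sprintf("Need at least %d runs to fit %d terms with error df.", p + 1L, p),
          class = "oakextract_domain_error")
  }

  coded <- code_factors(data, factors, suffix = "")[factors$name]
  coded[[response]] <- data[[response]]
  form <- stats::as.formula(
    paste(response, "~", paste(factors$name, collapse = " * "))
  )
  lmfit <- lm(form, data = coded)
  X <- model.matrix(lmfit)
  if (lmfit$rank < ncol(X)) {
    abort("Design is rank deficient; the interaction model cannot be fitted.",
          class = "oakextract_singular_design")
  }

  res <- resid(lmfit)
  h <- hatvalues(lmfit)
  df_res <- lmfit$df.residual
  sse <- sum(res^2)
  mse <- sse / df_res
  if (any(h >= 1 - 1e-12)) {
    press <- NA_real_
    warn("A leverage of 1 makes PRESS undefined; predicted R-squared is NA.")
  } else {
    press <- sum((res / (1 - h))^2)
  }

  structure(
    list(
      lm = lmfit,
      response = response,
      factors = factors,
      data = tibble::as_tibble(data),
      coded = tibble::as_tibble(coded),
      n = n,
      p = ncol(X),
      df_residual = df_res,
      mse = mse,
      press = press,
      leverages = h,
      xtx_inverse = solve(crossprod(X))
    ),
    class = "ffd_fit"
  )
}

#' @export
print.ffd_fit <- function(x, ...) {
  cat(sprintf("Full factorial fit: %s ~ %s\n", x$response,
              paste(x$factors$name, collapse = " * ")))
  cat(sprintf("%d runs, %d terms, residual df %d\n", x$n, x$p, x$df_residual))
  g <- glance(x)
  cat(sprintf("R2 %.4f | adj %.4f | pred %.4f | adeq. precision %.2f\n",
              g$r.squared, g$adj.r.squared, g$pred.r.squared, g$adequate.precision))
  invisible(x)
}

#' Per-term coefficients and inference of a factorial fit
#'
#' @param x An `ffd_fit`.
#' @param alpha Significance level for the `significant` flag.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value` and `significant`.
#' @export
tidy.ffd_fit <- function(x, alpha = 0.05, ...) {
  cf <- coef(summary(x$lm))
  tibble::tibble(
    term = rownames(cf),
    estimate = cf[, "Estimate"],
    std.error = cf[, "Std. Error"],
    statistic = cf[, "t value"],
    p.value = cf[, "Pr(>|t|)"],
    significant = cf[, "Pr(>|t|)"] < alpha
  )
}

#' One-row fit statistics of a factorial fit
#'
#' `sigma` is the residual standard deviation (root MSE), `cv.pct` the
#' coefficient of variation `100 * sigma / mean`, `press` the
#' leave-one-out prediction error sum of squares, and
#' `adequate.precision` the fitted-range signal-to-noise ratio. The
#' `adequate` flag is `FALSE` when the predicted R-squared is not
#' positive, marking a model that predicts new runs worse than the grand
#' mean and should be excluded from optimization.
#'
#' @param x An `ffd_fit`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.ffd_fit <- function(x, ...) {
  y <- x$lm$model[[x$response]]
  sst <- sum((y - mean(y))^2)
  sse <- sum(resid(x$lm)^2)
  r2 <- 1 - sse / sst
  adj <- 1 - (1 - r2) * (x$n - 1) / (x$n - x$p)
  pred <- 1 - x$press / sst
  sigma <- sqrt(x$mse)
  ap <- (max(fitted(x$lm)) - min(fitted(x$lm))) / sqrt(x$p * x$mse / x$n)
  tibble::tibble(
    response = x$response,
    n = x$n,
    sigma = sigma,
    mean = mean(y),
    cv.pct = 100 * sigma / mean(y),
    r.squared = r2,
    adj.r.squared = adj,
    pred.r.squared = pred,
    press = x$press,
    adequate.precision = ap,
    df.residual = x$df_residual,
    adequate = !is.na(pred) && pred > 0
  )
}

#' Per-run observations, fitted values, residuals and leverages
#'
#' @param x An `ffd_fit`.
#' @param ... Unused.
#' @return The training table plus `.fitted`, `.resid`, `.hat` and
#'   `.std.resid` columns (internally studentized residuals, the basis of
#'   the residual normal-probability plot).
#' @export
augment.ffd_fit <- function(x, ...) {
  out <- x$data
  out$.fitted <- unname(fitted(x$lm))
  out$.resid <- unname(resid(x$lm))
  out$.hat <- unname(x$leverages)
  out$.std.resid <- out$.resid / (sqrt(x$mse) * sqrt(1 - out$.hat))
  out
}

#' Predict assay responses at new extraction settings
#'
#' Evaluates the fitted factorial model at natural-unit settings,
#' returning the standard error of the fitted mean and a
#' new-observation prediction interval
#' \eqn{\hat y \pm t_{1-\alpha/2,\,df}\sqrt{MSE(1 + x^T(X^TX)^{-1}x)}}.
#' Settings outside the design cube are allowed and flagged.
#'
#' @param object An `ffd_fit`.
#' @param newdata Data frame of natural-unit factor settings; defaults to
#'   the training runs.
#' @param level Prediction-interval coverage.
#' @param ... Unused.
#' @return A tibble with `.fitted`, `.se_fit`, `.pi_lower`, `.pi_upper`
#'   and `.extrapolated`.
#' @examples
#' fit <- ffd_fit(oak_runs(), dpph)
#' predict(fit, data.frame(temperature = 80, ethanol = 40, time = 24))
#' @export
predict.ffd_fit <- function(object, newdata = NULL, level = 0.95, ...) {
  if (is.null(newdata)) newdata <- object$data
  coded <- code_factors(newdata, object$factors, suffix = "")[object$factors$name]
  pr <- predict(object$lm, newdata = coded, se.fit = TRUE)
  tcrit <- qt(1 - (1 - level) / 2, object$df_residual)
  se_pred <- sqrt(object$mse + pr$se.fit^2)
  tibble::tibble(
    .fitted = unname(pr$fit),
    .se_fit = unname(pr$se.fit),
    .pi_lower = unname(pr$fit - tcrit * se_pred),
    .pi_upper = unname(pr$fit + tcrit * se_pred),
    .extrapolated = apply(abs(as.matrix(coded)) > 1 + 1e-8, 1, any)
  )
}

#' Diagnostic plots for a factorial fit
#'
#' Observed versus fitted responses and the residual normal-probability
#' plot, side by side.
#'
#' @param object An `ffd_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ffd_fit <- function(object, ...) {
  aug <- augment(object)
  aug$observed <- aug[[object$response]]
  long <- dplyr::bind_rows(
    tibble::tibble(panel = "observed vs fitted", x = aug$.fitted, y = aug$observed),
    tibble::tibble(
      panel = "normal probability of residuals",
      x = stats::qnorm(stats::ppoints(nrow(aug)))[rank(aug$.resid)],
      y = aug$.resid
    )
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(
      x = "fitted value / normal quantile",
      y = paste0(object$response, " / residual"),
      title = sprintf("Factorial model diagnostics: %s", object$response)
    )
}
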