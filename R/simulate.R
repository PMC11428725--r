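#' Simulate factorial response tables with known ground truth
#'
#' Generates a response over the full factorial design from a
#' linear-plus-interaction surface on the coded scale, with optional
#' quadratic curvature on the first factor and homoscedastic Gaussian
#' noise:
#' \eqn{y = Xb + q\,(x_1^2 - \overline{x_1^2}) + \varepsilon},
#' \eqn{\varepsilon \sim N(0, \sigma^2)}. With `quad_amplitude = 0` the
#' generating surface lies inside the factorial model family, so fitting
#' recovers the true coefficients exactly at zero noise; a nonzero
#' curvature term puts the truth outside it, the regime where a neural
#' model can outperform the factorial regression. The curvature term is
#' centred so it does not shift the intercept.
#'
#' @param coefficients Named vector of true coefficients on the coded
#'   scale. Names must match the model-matrix terms (e.g.
#'   `"(Intercept)"`, `"temperature"`, `"temperature:ethanol"`, ...);
#'   omitted terms are zero.
#' @param noise_sd Standard deviation of the response noise (response
#'   units, >= 0); the noise applies to run means, emulating assay means
#'   of triplicates.
#' @param quad_amplitude Coefficient of the centred `x1^2` curvature
#'   term.
#' @param factors Factor-specification tibble.
#' @param seed Integer seed; the same seed always yields the same table.
#' @param response_name Name of the generated response column.
#' @return The full factorial design tibble plus the response column.
#' @examples
#' simulate_runs(c(`(Intercept)` = 215, temperature = 83), noise_sd = 48, seed = 1)
#' @export
simulate_runs <- function(coefficients,
                          noise_sd = 0,
                          quad_amplitude = 0,
                          factors = oak_factors(),
                          seed = 0,
                          response_name = "y") {
  if (noise_sd < 0) {
    abort("noise_sd must be non-negative.", class = "oakextract_domain_error")
  }
  design <- full_factorial(factors)
  X <- ffd_model_matrix(design, factors)
  b <- setNames(numeric(ncol(X)), colnames(X))
  unknown <- setdiff(names(coefficients), names(b))
  if (length(unknown)) {
    abort(paste0("Unknown coefficient term(s): ", paste(unknown, collapse = ", ")),
          class = "oakextract_schema_error")
  }
  b[names(coefficients)] <- coefficients
  x1 <- code_value(factors, factors$name[1], design[[factors$name[1]]])
  surface <- as.vector(X %*% b) + quad_amplitude * (x1^2 - mean(x1^2))
  eps <- withr::with_seed(seed, rnorm(nrow(design), 0, noise_sd))
  design[[response_name]] <- surface + eps
  design
}

#' Coefficient-recovery experiment on synthetic designs
#'
#' Repeatedly simulates a factorial table and refits the model,
#' reporting per-term bias and the fraction of nominal 95% confidence
#' intervals covering the generating coefficients. Under a linear truth
#' with Gaussian noise the coverage should sit at 0.95 up to Monte Carlo
#' error; curvature or the wrong noise model shows up as coverage loss
#' and bias.
#'
#' @param coefficients,noise_sd,quad_amplitude,factors As in
#'   [simulate_runs()].
#' @param reps Number of simulated tables (>= 1).
#' @param seed Seed of the first replicate; replicate `i` uses
#'   `seed + i - 1`.
#' @param level Confidence level of the intervals.
#' @return A tibble with one row per model term: `true`, `mean_estimate`,
#'   `bias` and `coverage`.
#' @examples
#' recovery_experiment(c(`(Intercept)` = 200, temperature = 80),
#'   noise_sd = 40, reps = 50
#' )
#' @export
recovery_experiment <- function(coefficients,
                                noise_sd,
                                quad_amplitude = 0,
                                factors = oak_factors(),
                                reps = 200,
                                seed = 0,
                                level = 0.95) {
  if (reps < 1L) {
    abort("reps must be at least 1.", class = "oakextract_domain_error")
  }
  design <- full_factorial(factors)
  X <- ffd_model_matrix(design, factors)
  b_true <- setNames(numeric(ncol(X)), colnames(X))
  b_true[names(coefficients)] <- coefficients

  results <- purrr::map(seq_len(reps), function(i) {
    tab <- simulate_runs(coefficients, noise_sd, quad_amplitude, factors,
                         seed = seed + i - 1L)
    fit <- ffd_fit(tab, "y", factors)
    ci <- confint(fit$lm, level = level)
    est <- coef(fit$lm)
    list(est = est, cover = b_true >= ci[, 1] & b_true <= ci[, 2])
  })
  est_mat <- do.call(rbind, purrr::map(results, "est"))
  cov_mat <- do.call(rbind, purrr::map(results, "cover"))
  tibble::tibble(
    term = colnames(est_mat),
    true = unname(b_true[colnames(est_mat)]),
    mean_estimate = colMeans(est_mat),
    bias = colMeans(est_mat) - unname(b_true[colnames(est_mat)]),
    coverage = colMeans(cov_mat)
  )
}
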