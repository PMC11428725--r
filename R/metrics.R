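#' Agreement metrics between predicted and experimental responses
#'
#' Mean absolute error, root mean square error and the coefficient of
#' determination \eqn{R^2 = 1 - \sum(Y_{pre}-Y_{exp})^2 /
#' \sum(Y_m-Y_{exp})^2}, where \eqn{Y_m} is the mean of the experimental
#' values. Note this is agreement with the experimental mean as
#' reference, not a regression of predictions on observations, so it can
#' be negative for a model worse than the grand mean.
#'
#' @param data Data frame holding both columns.
#' @param truth Experimental (observed) column, bare name or string.
#' @param estimate Model-predicted column.
#' @return A one-row tibble with `n`, `mae`, `rmse`, `r.squared`.
#' @examples
#' preds <- dplyr::inner_join(oak_runs(), oak_model_predictions(),
#'   by = c("run", "temperature", "ethanol", "time")
#' )
#' regression_metrics(preds, dpph, dpph_ffd)
#' @export
regression_metrics <- function(data, truth, estimate) {
  truth <- col_name(enquo(truth))
  estimate <- col_name(enquo(estimate))
  missing <- setdiff(c(truth, estimate), names(data))
  if (length(missing)) {
    abort(paste0("Column(s) not found: ", paste(missing, collapse = ", ")),
          class = "oakextract_schema_error")
  }
  metrics_vec(data[[estimate]], data[[truth]])
}

metrics_vec <- function(pred, obs) {
  if (length(pred) != length(obs) || length(obs) < 2L) {
    abort("Prediction and experimental vectors must have equal length >= 2.",
          class = "oakextract_domain_error")
  }
  sst <- sum((mean(obs) - obs)^2)
  if (sst == 0) {
    abort("Experimental values have zero variance; R-squared is undefined.",
          class = "oakextract_domain_error")
  }
  err <- pred - obs
  tibble::tibble(
    n = length(obs),
    mae = mean(abs(err)),
    rmse = sqrt(mean(err^2)),
    r.squared = 1 - sum(err^2) / sst
  )
}

#' Factorial-versus-neural predictive comparison
#'
#' Assembles, for each response, the experimental values and the two
#' models' per-run predictions, and scores both models by MAE, RMSE and
#' R-squared. The factorial predictions come from fitted [ffd_fit()]
#' models; the neural predictions from any per-run prediction table
#' (e.g. [predict.mlp_fit()] output, or the published predictions in
#' [oak_model_predictions()]).
#'
#' @param data Response table with experimental values.
#' @param ffd_fits Named list of `ffd_fit` objects (names = response
#'   columns).
#' @param ann_predictions Data frame with one prediction column per
#'   response, named like the responses, rows aligned with `data`.
#' @return A `model_comparison`: `$values` holds the per-run long table
#'   (`run`, `response`, `observed`, `ffd`, `ann`); `$metrics` the
#'   per-response, per-model metric table. [tidy()] returns the metrics;
#'   [autoplot()] draws observed-versus-predicted panels.
#' @examples
#' runs <- oak_runs()
#' fits <- list(dpph = ffd_fit(runs, dpph))
#' ann <- dplyr::rename(oak_model_predictions(), dpph = dpph_ann)
#' comparison <- model_comparison(runs, fits, ann)
#' tidy(comparison)
#' @export
model_comparison <- function(data, ffd_fits, ann_predictions) {
  responses <- names(ffd_fits)
  if (is.null(responses)) {
    abort("ffd_fits must be a named list keyed by response.",
          class = "oakextract_schema_error")
  }
  missing <- setdiff(responses, names(ann_predictions))
  if (length(missing)) {
    abort(paste0("ann_predictions lacks column(s): ", paste(missing, collapse = ", ")),
          class = "oakextract_alignment_error")
  }
  if (nrow(ann_predictions) != nrow(data)) {
    abort("ann_predictions and data must cover the same runs.",
          class = "oakextract_alignment_error")
  }
  run <- if ("run" %in% names(data)) data$run else seq_len(nrow(data))

  values <- purrr::map_dfr(responses, function(r) {
    tibble::tibble(
      run = run,
      response = r,
      observed = data[[r]],
      ffd = predict(ffd_fits[[r]], data)$.fitted,
      ann = ann_predictions[[r]]
    )
  })
  metrics <- values |>
    tidyr::pivot_longer(c("ffd", "ann"), names_to = "model", values_to = "pred") |>
    dplyr::group_by(.data$response, .data$model) |>
    dplyr::reframe(metrics_vec(.data$pred, .data$observed))

  structure(list(values = values, metrics = metrics), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Factorial vs neural predictive comparison\n")
  print(x$metrics, n = Inf)
  invisible(x)
}

#' @param x,object A `model_comparison`.
#' @param ... Unused.
#' @rdname model_comparison
#' @export
tidy.model_comparison <- function(x, ...) {
  x$metrics
}

#' @rdname model_comparison
#' @export
autoplot.model_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(object$values, c("ffd", "ann"),
                              names_to = "model", values_to = "pred")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$observed, y = .data$pred,
                                     colour = .data$model)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~response, scales = "free") +
    ggplot2::labs(x = "experimental", y = "predicted")
}
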