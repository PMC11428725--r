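#' Define a three-level extraction factor
#'
#' A factor is described by its low, centre and high settings in natural
#' units. Regression is carried out on the coded scale
#' \eqn{c = (x - (low + high)/2) / ((high - low)/2)}, which maps `low` to
#' -1 and `high` to +1 exactly. The centre level need not code to 0: an
#' asymmetric middle level (such as 6 h between 3 h and 24 h) keeps its
#' true coded position rather than being relabelled 0.
#'
#' @param name Factor name; becomes the column name in designs and models.
#' @param low,mid,high The three levels, in natural units, strictly
#'   increasing.
#' @param units Unit label, for printing and reports only.
#' @return A one-row tibble with columns `name`, `low`, `mid`, `high`,
#'   `units`.
#' @examples
#' factor_spec("temperature", 20, 50, 80, units = "°C")
#' @export
factor_spec <- function(name, low, mid, high, units = "") {
  stopifnot(is.character(name), length(name) == 1L)
  if (!all(is.finite(c(low, mid, high)))) {
    abort("Factor levels must be finite numbers.", class = "oakextract_invalid_factor")
  }
  if (low == high) {
    abort(
      sprintf("Factor '%s' is degenerate: low == high (%g).", name, low),
      class = "oakextract_invalid_factor"
    )
  }
  if (!(low < mid && mid < high)) {
    abort(
      sprintf("Factor '%s' needs low < mid < high, got (%g, %g, %g).", name, low, mid, high),
      class = "oakextract_invalid_factor"
    )
  }
  tibble::tibble(name = name, low = low, mid = mid, high = high, units = units)
}

#' The wood-chip extraction factors
#'
#' The three extraction variables of the packaged Turkey oak study:
#' temperature (20, 50, 80 degC), ethanol fraction of the hydroalcoholic
#' solvent (0, 20, 40 % EtOH/H2O) and extraction time (3, 6, 24 h).
#'
#' @return A three-row factor-specification tibble (see [factor_spec()]).
#' @examples
#' oak_factors()
#' @export
oak_factors <- function() {
  dplyr::bind_rows(
    factor_spec("temperature", 20, 50, 80, units = "°C"),
    factor_spec("ethanol", 0, 20, 40, units = "% EtOH/H2O"),
    factor_spec("time", 3, 6, 24, units = "h")
  )
}

one_factor <- function(factors, name) {
  row <- factors[factors$name == name, , drop = FALSE]
  if (nrow(row) != 1L) {
    abort(sprintf("Factor '%s' not found in the specification.", name),
          class = "oakextract_invalid_factor")
  }
  if (row$low == row$high) {
    abort(sprintf("Factor '%s' is degenerate: low == high.", name),
          class = "oakextract_invalid_factor")
  }
  row
}

#' Convert between natural and coded factor units
#'
#' `code_value()` maps natural units onto the coded scale
#' \eqn{(x - centre)/halfrange}; `decode_value()` is its exact inverse.
#' Values outside `[low, high]` are permitted (coded magnitude exceeds 1)
#' so fitted models can be probed slightly beyond the design region.
#'
#' @param factors A factor-specification tibble (e.g. [oak_factors()]).
#' @param name Name of the factor to transform.
#' @param x Natural-unit values (vectorized).
#' @param coded Coded values (vectorized).
#' @return A numeric vector of the same length as the input.
#' @examples
#' code_value(oak_factors(), "time", 6) # -0.714..., not 0
#' decode_value(oak_factors(), "time", 1) # 24
#' @export
code_value <- function(factors, name, x) {
  f <- one_factor(factors, name)
  (x - (f$low + f$high) / 2) / ((f$high - f$low) / 2)
}

#' @rdname code_value
#' @export
decode_value <- function(factors, name, coded) {
  f <- one_factor(factors, name)
  coded * (f$high - f$low) / 2 + (f$low + f$high) / 2
}

#' Add coded columns to a data frame of natural-unit settings
#'
#' @param data A data frame containing one column per factor, in natural
#'   units.
#' @param factors Factor-specification tibble.
#' @param suffix Suffix appended to the coded column names.
#' @return `data` with one additional `<name><suffix>` column per factor.
#' @examples
#' code_factors(full_factorial(oak_factors()), oak_factors())
#' @export
code_factors <- function(data, factors = oak_factors(), suffix = "_coded") {
  missing <- setdiff(factors$name, names(data))
  if (length(missing)) {
    abort(paste0("Missing factor column(s): ", paste(missing, collapse = ", ")),
          class = "oakextract_schema_error")
  }
  for (nm in factors$name) {
    data[[paste0(nm, suffix)]] <- code_value(factors, nm, data[[nm]])
  }
  tibble::as_tibble(data)
}

#' Enumerate the three-level full factorial design
#'
#' All `3^k` combinations of the factor levels, in the canonical run
#' order of the study: the first factor varies slowest and the last
#' fastest, so with [oak_factors()] run 1 is (20 degC, 0 %, 3 h) and run
#' 27 is (80 degC, 40 %, 24 h).
#'
#' @param factors Factor-specification tibble with at least one row.
#' @param coded Add coded columns (`_coded` suffix)?
#' @return A tibble with a `run` column and one natural-unit column per
#'   factor; `3^k` rows.
#' @examples
#' full_factorial(oak_factors())
#' @export
full_factorial <- function(factors = oak_factors(), coded = FALSE) {
  if (nrow(factors) == 0L) {
    abort("At least one factor is required.", class = "oakextract_invalid_factor")
  }
  levels <- purrr::map(seq_len(nrow(factors)),
                       function(i) unlist(factors[i, c("low", "mid", "high")], use.names = FALSE))
  names(levels) <- factors$name
  grid <- tidyr::expand_grid(!!!levels)
  out <- dplyr::bind_cols(tibble::tibble(run = seq_len(nrow(grid))), grid)
  if (coded) out <- code_factors(out, factors)
  out
}

#' Model matrix of the full-interaction factorial regression
#'
#' Builds the regressor matrix of the linear-with-interactions model on
#' the coded scale: intercept, main effects, all two-factor interactions
#' and the highest-order interaction (8 columns for three factors).
#' Interaction columns are elementwise products of the coded main-effect
#' columns.
#'
#' @param data Data frame with natural-unit factor columns.
#' @param factors Factor-specification tibble.
#' @return A numeric matrix with `2^k` named columns, rows aligned with
#'   `data`.
#' @examples
#' ffd_model_matrix(full_factorial(oak_factors()))[c(1, 14, 27), ]
#' @export
ffd_model_matrix <- function(data, factors = oak_factors()) {
  coded <- code_factors(data, factors, suffix = "")[factors$name]
  form <- stats::as.formula(paste("~", paste(factors$name, collapse = " * ")))
  model.matrix(form, data = coded)
}
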