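#' The 27-run Turkey oak wood-chip extraction dataset
#'
#' Mean assay responses (and their standard deviations, `*_sd` columns)
#' for each run of the 3^3 factorial extraction experiment on *Quercus
#' cerris* wood chips: extraction yield (`yield`, %), DPPH radical
#' scavenging activity (`dpph`, mg TE/g), ferric reducing antioxidant
#' power (`frap`, mg TE/g), total phenolic content (`tpc`, mg GAE/g),
#' total flavonoid content (`tfc`, mg QE/g), condensed tannin content
#' (`ctc`, mg TAE/g) and hydrolyzable tannin content (`htc`, mg TAE/g).
#'
#' Where the source report printed two slightly different values for the
#' same run mean (its run-level table versus its model-comparison table),
#' the higher-precision model-comparison values are used; only those
#' reproduce the published grand means and error metrics exactly.
#'
#' @return A 27-row tibble: `run`, the three factor settings in natural
#'   units, and mean/sd pairs for the seven responses.
#' @examples
#' oak_runs()
#' @export
oak_runs <- function() {
  path <- system.file("extdata", "oak_extraction_runs.csv", package = "oakextract")
  read_response_table(path)
}

#' Published factorial and neural-network predictions for the oak dataset
#'
#' The per-run DPPH, FRAP and TPC predictions of the study's own fitted
#' factorial (`*_ffd`) and neural-network (`*_ann`) models, as printed in
#' its model-comparison table. The neural-network columns cannot be
#' regenerated without the original trained weights, so they are shipped
#' as data; they let the factorial-vs-neural comparison metrics be
#' recomputed exactly.
#'
#' @return A 27-row tibble: `run`, factor settings, and six prediction
#'   columns.
#' @examples
#' oak_model_predictions()
#' @export
oak_model_predictions <- function() {
  path <- system.file("extdata", "oak_model_predictions.csv", package = "oakextract")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read a factorial response table from CSV
#'
#' Expects a header row, one row per run, comma separators and period
#' decimals. Validates that the factor columns are present, that all
#' response cells are numeric and non-negative, and that `run` (if
#' present) is unique.
#'
#' @param path Path to a CSV file.
#' @param factors Factor-specification tibble naming the required factor
#'   columns.
#' @return A tibble with one row per run.
#' @export
read_response_table <- function(path, factors = oak_factors()) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (nrow(tab) == 0L || ncol(tab) == 0L) {
    abort(sprintf("'%s' contains no data rows.", path), class = "oakextract_schema_error")
  }
  missing <- setdiff(factors$name, names(tab))
  if (length(missing)) {
    abort(paste0("Missing required column(s): ", paste(missing, collapse = ", ")),
          class = "oakextract_schema_error")
  }
  for (col in names(tab)) {
    vals <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(!is.na(tab[[col]]) & is.na(vals))
    if (length(bad)) {
      abort(
        sprintf("Non-numeric value '%s' in column '%s', row %d.",
                tab[[col]][bad[1]], col, bad[1]),
        class = "oakextract_parse_error"
      )
    }
    tab[[col]] <- vals
  }
  if ("run" %in% names(tab) && anyDuplicated(tab$run)) {
    abort("Duplicate run identifiers in the table.", class = "oakextract_validation_error")
  }
  resp <- setdiff(names(tab), c("run", factors$name))
  neg <- resp[purrr::map_lgl(resp, function(cl) any(tab[[cl]] < 0, na.rm = TRUE))]
  if (length(neg)) {
    abort(paste0("Negative response values in column(s): ", paste(neg, collapse = ", ")),
          class = "oakextract_validation_error")
  }
  tab
}

#' Gravimetric extraction yield
#'
#' Yield as the percentage of dried extract mass recovered from the
#' milled wood input: `100 * dried_mass / input_mass`.
#'
#' @param dried_mass Mass of the dried extract (g), non-negative.
#' @param input_mass Mass of milled wood extracted (g), positive.
#' @return Yield in percent.
#' @examples
#' yield_percent(0.285, 10) # 2.85 %
#' @export
yield_percent <- function(dried_mass, input_mass) {
  if (any(input_mass <= 0)) {
    abort("input_mass must be positive.", class = "oakextract_domain_error")
  }
  if (any(dried_mass < 0)) {
    abort("dried_mass must be non-negative.", class = "oakextract_domain_error")
  }
  100 * dried_mass / input_mass
}

#' Pearson correlation matrix of assay responses
#'
#' Sample Pearson correlations between run-mean responses, the basis for
#' choosing which assays to carry into multi-response modelling.
#'
#' @param data Response table (e.g. [oak_runs()]).
#' @param responses Character vector of response column names.
#' @return A symmetric correlation matrix with unit diagonal.
#' @examples
#' response_correlations(oak_runs(), c("dpph", "frap", "tpc"))
#' @export
response_correlations <- function(data,
                                  responses = c("tpc", "tfc", "htc", "frap", "dpph")) {
  missing <- setdiff(responses, names(data))
  if (length(missing)) {
    abort(paste0("Response column(s) not found: ", paste(missing, collapse = ", ")),
          class = "oakextract_schema_error")
  }
  if (nrow(data) < 3L) {
    abort("At least 3 runs are required for correlation.", class = "oakextract_domain_error")
  }
  m <- as.matrix(data[responses])
  degenerate <- responses[apply(m, 2, function(x) var(x) == 0)]
  if (length(degenerate)) {
    abort(paste0("Zero-variance response(s), correlation undefined: ",
                 paste(degenerate, collapse = ", ")),
          class = "oakextract_domain_error")
  }
  cor(m)
}
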