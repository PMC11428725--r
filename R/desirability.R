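#' Larger-is-better desirability transform
#'
#' Maps a predicted response onto `[0, 1]` relative to a lower bound
#' `low` (worthless at or below) and a target `target` (fully desirable
#' at or above): `0` below `low`, `((y - low)/(target - low))^weight`
#' between, `1` above `target`. Predictions above the target are capped
#' at 1, so a model extrapolating past the best observed response does
#' not dominate the composite.
#'
#' @param y Predicted response values (vectorized).
#' @param low Response value with zero desirability.
#' @param target Response value with full desirability; must exceed `low`.
#' @param weight Positive exponent shaping the ramp (1 = linear).
#' @return Desirabilities in `[0, 1]`.
#' @examples
#' desirability_score(c(100, 250, 400), low = 41.88, target = 365.78)
#' @export
desirability_score <- function(y, low, target, weight = 1) {
  if (!(low < target)) {
    abort("Desirability needs low < target.", class = "oakextract_domain_error")
  }
  if (weight <= 0) {
    abort("Desirability weight must be positive.", class = "oakextract_domain_error")
  }
  pmin(pmax((y - low) / (target - low), 0), 1)^weight
}

#' Composite desirability
#'
#' Geometric mean of per-response desirabilities; zero whenever any
#' response is fully undesirable.
#'
#' @param d Numeric vector of desirabilities in `[0, 1]`.
#' @return A single value in `[0, 1]`.
#' @examples
#' composite_desirability(c(1, 1, 0.854))
#' @export
composite_desirability <- function(d) {
  if (length(d) == 0L) {
    abort("Composite desirability of an empty set is undefined.",
          class = "oakextract_domain_error")
  }
  if (any(d < -1e-12 | d > 1 + 1e-12)) {
    abort("Desirabilities must lie in [0, 1].", class = "oakextract_domain_error")
  }
  if (any(d == 0)) return(0)
  exp(mean(log(d)))
}

#' Multi-response optimization of extraction settings
#'
#' Finds the factor settings that maximize the composite desirability of
#' the model-predicted responses over the design cube. Each response's
#' desirability ramps from its observed minimum (`low`) to its observed
#' maximum (`target`) unless explicit limits are supplied. The search is
#' deterministic: composite desirability is evaluated on a
#' `grid_n`-per-axis coded grid, the best `n_starts` grid points seed
#' Nelder-Mead refinements (coordinates clamped to the cube), and ties
#' are broken towards lexicographically smallest coded coordinates.
#'
#' @param fits Named list of [ffd_fit()] objects, one per response to
#'   maximize; all must share the same factor specification.
#' @param limits Optional tibble with columns `response`, `low`,
#'   `target` (and optionally `weight`) overriding the observed-range
#'   defaults.
#' @param grid_n Grid resolution per coded axis for seeding.
#' @param n_starts Number of grid seeds refined by Nelder-Mead.
#' @return An `ffd_optimum`: use [tidy()] for the per-response
#'   predictions and desirabilities, [glance()] for the optimal settings
#'   and composite desirability.
#' @examples
#' runs <- oak_runs()
#' fits <- list(
#'   dpph = ffd_fit(runs, dpph), frap = ffd_fit(runs, frap),
#'   tpc = ffd_fit(runs, tpc)
#' )
#' opt <- optimize_desirability(fits)
#' glance(opt)
#' @export
optimize_desirability <- function(fits, limits = NULL, grid_n = 11, n_starts = 20) {
  if (length(fits) == 0L) {
    abort("At least one fitted response is required.", class = "oakextract_domain_error")
  }
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- purrr::map_chr(fits, "response")
  }
  factors <- fits[[1]]$factors
  k <- nrow(factors)

  goals <- purrr::imap_dfr(fits, function(f, nm) {
    y <- f$data[[f$response]]
    tibble::tibble(response = nm, low = min(y), target = max(y), weight = 1)
  })
  if (!is.null(limits)) {
    limits <- tibble::as_tibble(limits)
    if (!"weight" %in% names(limits)) limits$weight <- 1
    goals <- dplyr::rows_update(goals, limits[names(limits) %in% names(goals)],
                                by = "response")
  }

  predict_at <- function(coded_mat) {
    nat <- purrr::map_dfc(seq_len(k), function(j) {
      tibble::tibble(!!factors$name[j] := decode_value(factors, factors$name[j],
                                                       coded_mat[, j]))
    })
    preds <- vapply(names(fits), function(nm) predict(fits[[nm]], nat)$.fitted,
                    numeric(nrow(coded_mat)))
    matrix(preds, nrow = nrow(coded_mat), dimnames = list(NULL, names(fits)))
  }
  objective <- function(coded_mat) {
    preds <- predict_at(coded_mat)
    dmat <- vapply(seq_along(fits), function(i) {
      g <- goals[goals$response == names(fits)[i], ]
      desirability_score(preds[, i], g$low, g$target, g$weight)
    }, numeric(nrow(coded_mat)))
    dmat <- matrix(dmat, nrow = nrow(coded_mat))
    apply(dmat, 1, composite_desirability)
  }

  axes <- rep(list(seq(-1, 1, length.out = grid_n)), k)
  names(axes) <- factors$name
  grid <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  grid_d <- objective(grid)

  if (all(grid_d == 0)) {
    warn("Composite desirability is zero everywhere on the grid; returning the first grid point.")
    best_coded <- grid[1, ]
    best_d <- 0
  } else {
    ord <- order(-grid_d, apply(grid, 1, paste, collapse = ","))
    starts <- grid[head(ord, n_starts), , drop = FALSE]
    clamp <- function(x) pmin(pmax(x, -1), 1)
    refined <- purrr::map(seq_len(nrow(starts)), function(i) {
      res <- optim(starts[i, ], function(x) -objective(matrix(clamp(x), nrow = 1)),
                   method = "Nelder-Mead",
                   control = list(reltol = 1e-10, maxit = 500))
      x <- clamp(res$par)
      list(coded = x, d = objective(matrix(x, nrow = 1)))
    })
    ds <- round(purrr::map_dbl(refined, "d"), 10)
    cand <- purrr::map(refined, "coded")
    best_idx <- which(ds == max(ds))
    if (length(best_idx) > 1L) {
      keys <- purrr::map_chr(cand[best_idx],
                             function(x) paste(sprintf("%+.8f", x), collapse = ","))
      best_idx <- best_idx[order(keys)][1]
    }
    best_coded <- cand[[best_idx]]
    best_d <- refined[[best_idx]]$d
    best_grid_d <- max(grid_d)
    if (best_d < best_grid_d - 1e-12) {
      # never worse than the best seed: fall back to it
      best_coded <- grid[which.max(grid_d), ]
      best_d <- best_grid_d
    }
  }

  preds <- predict_at(matrix(best_coded, nrow = 1))[1, ]
  per_resp <- goals
  per_resp$.fitted <- unname(preds[per_resp$response])
  per_resp$desirability <- purrr::pmap_dbl(
    list(per_resp$.fitted, per_resp$low, per_resp$target, per_resp$weight),
    desirability_score
  )
  settings <- tibble::tibble(
    factor = factors$name,
    units = factors$units,
    coded = unname(best_coded),
    value = purrr::map2_dbl(factors$name, best_coded,
                            function(nm, cc) decode_value(factors, nm, cc))
  )
  structure(
    list(settings = settings, responses = per_resp,
         composite = best_d, grid_best = max(grid_d)),
    class = "ffd_optimum"
  )
}

#' @export
print.ffd_optimum <- function(x, ...) {
  cat("Desirability optimum\n")
  for (i in seq_len(nrow(x$settings))) {
    cat(sprintf("  %s = %.3f %s (coded %+.3f)\n", x$settings$factor[i],
                x$settings$value[i], x$settings$units[i], x$settings$coded[i]))
  }
  for (i in seq_len(nrow(x$responses))) {
    cat(sprintf("  %s: predicted %.2f, d = %.4f\n", x$responses$response[i],
                x$responses$.fitted[i], x$responses$desirability[i]))
  }
  cat(sprintf("Composite desirability D = %.4f\n", x$composite))
  invisible(x)
}

#' @param x An `ffd_optimum`.
#' @param ... Unused.
#' @rdname optimize_desirability
#' @export
tidy.ffd_optimum <- function(x, ...) {
  tibble::as_tibble(x$responses)
}

#' @rdname optimize_desirability
#' @export
glance.ffd_optimum <- function(x, ...) {
  out <- tibble::as_tibble(setNames(as.list(x$settings$value), x$settings$factor))
  out$composite.desirability <- x$composite
  out
}

#' @param object An `ffd_optimum`.
#' @rdname optimize_desirability
#' @export
autoplot.ffd_optimum <- function(object, ...) {
  df <- tibble::as_tibble(object$responses)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$response, y = .data$desirability)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$composite, linetype = 2) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = "individual desirability",
                  title = sprintf("Composite desirability D = %.3f", object$composite))
}
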