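#' @name mlp-internals
#' @noRd
NULL

sigmoid <- function(z) plogis(z)

mlp_dims <- function(n_in, hidden, n_out) {
  c(W1 = hidden * n_in, b1 = hidden, W2 = n_out * hidden, b2 = n_out)
}

mlp_unflatten <- function(theta, n_in, hidden, n_out) {
  d <- mlp_dims(n_in, hidden, n_out)
  stopifnot(length(theta) == sum(d))
  i <- 0L
  W1 <- matrix(theta[i + seq_len(d["W1"])], nrow = hidden); i <- i + d[["W1"]]
  b1 <- theta[i + seq_len(d["b1"])]; i <- i + d[["b1"]]
  W2 <- matrix(theta[i + seq_len(d["W2"])], nrow = n_out); i <- i + d[["W2"]]
  b2 <- theta[i + seq_len(d["b2"])]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

mlp_flatten <- function(params) {
  c(as.vector(params$W1), params$b1, as.vector(params$W2), params$b2)
}

# Forward pass. X is n x n_in in scaled units; returns hidden activations
# and outputs. Identity activations are supported so the trainer can be
# cross-checked against linear least squares.
mlp_forward <- function(params, X, activation = c("logistic", "identity")) {
  activation <- match.arg(activation)
  act <- if (activation == "logistic") sigmoid else identity
  Z1 <- sweep(X %*% t(params$W1), 2, params$b1, "+")
  H <- act(Z1)
  Z2 <- sweep(H %*% t(params$W2), 2, params$b2, "+")
  list(hidden = H, output = act(Z2))
}

# Jacobian of the stacked outputs with respect to the flattened weights,
# by backpropagation. Rows ordered sample-major: for sample i the n_out
# outputs are rows (i-1)*n_out + 1..n_out.
mlp_jacobian <- function(params, X, activation = c("logistic", "identity")) {
  activation <- match.arg(activation)
  n <- nrow(X)
  n_in <- ncol(X)
  hidden <- length(params$b1)
  n_out <- length(params$b2)
  fw <- mlp_forward(params, X, activation)
  H <- fw$hidden
  Y <- fw$output
  dact <- function(a) if (activation == "logistic") a * (1 - a) else rep(1, length(a))

  P <- sum(mlp_dims(n_in, hidden, n_out))
  J <- matrix(0, nrow = n * n_out, ncol = P)
  iW1 <- seq_len(hidden * n_in)
  ib1 <- hidden * n_in + seq_len(hidden)
  iW2 <- hidden * n_in + hidden + seq_len(n_out * hidden)
  ib2 <- hidden * n_in + hidden + n_out * hidden + seq_len(n_out)

  for (i in seq_len(n)) {
    h <- H[i, ]
    dy <- dact(Y[i, ])          # n_out
    dh <- dact(h)               # hidden
    for (k in seq_len(n_out)) {
      row <- (i - 1L) * n_out + k
      # output-layer weights and bias
      dW2 <- matrix(0, nrow = n_out, ncol = hidden)
      dW2[k, ] <- dy[k] * h
      J[row, iW2] <- as.vector(dW2)
      db2 <- numeric(n_out); db2[k] <- dy[k]
      J[row, ib2] <- db2
      # backprop into hidden layer
      delta_h <- dy[k] * params$W2[k, ] * dh       # hidden
      J[row, iW1] <- as.vector(outer(delta_h, X[i, ]))
      J[row, ib1] <- delta_h
    }
  }
  J
}

scaler_new <- function(x_min, x_max, lo, hi) {
  if (any(x_max <= x_min)) {
    abort("Scaler needs max > min for every variable.", class = "oakextract_domain_error")
  }
  list(min = x_min, max = x_max, lo = lo, hi = hi)
}

scaler_apply <- function(s, M) {
  sweep(sweep(M, 2, s$min, "-"), 2, (s$max - s$min) / (s$hi - s$lo), "/") + s$lo
}

scaler_invert <- function(s, M) {
  sweep(sweep(M - s$lo, 2, (s$max - s$min) / (s$hi - s$lo), "*"), 2, s$min, "+")
}

pooled_r <- function(obs, pred) {
  cor(as.vector(obs), as.vector(pred))
}

#' Train a small multilayer perceptron by Levenberg-Marquardt
#'
#' Fits a feed-forward network (inputs -> `hidden` logistic units ->
#' outputs through a logistic output layer) mapping the extraction
#' factors to several assay responses at once. Inputs are min-max scaled
#' to `[-1, 1]`; targets to `[0.1, 0.9]` so the sigmoid output layer is
#' not driven into saturation. The data are split at random (by `seed`)
#' into training/validation/test subsets (19/4/4 for the 27-run design).
#' Each epoch solves the damped Gauss-Newton system
#' \eqn{(J^TJ + \mu I)\delta = J^Te} on the training subset, decreasing
#' \eqn{\mu} after an accepted step and increasing it after a rejected
#' one; training stops when the validation MSE has not improved for
#' `patience` epochs (or at `max_epochs`), and the returned weights are
#' those of the best validation epoch.
#'
#' @param data Response table with factor and response columns.
#' @param responses Character vector of response columns (network
#'   outputs).
#' @param factors Factor-specification tibble naming the input columns.
#' @param hidden Number of hidden units.
#' @param seed Integer seed controlling the split and weight
#'   initialization (uniform in \[-0.5, 0.5\]).
#' @param split Train/validation/test fractions, summing to 1.
#' @param max_epochs,patience Epoch cap and early-stopping patience
#'   (`patience = 0` stops at the first epoch that fails to improve the
#'   validation MSE).
#' @param mu_init,mu_inc,mu_dec Initial damping factor and its
#'   multipliers after rejected/accepted steps.
#' @param mu_max Damping ceiling; a step that cannot be accepted below it
#'   ends training (error if no epoch was ever accepted).
#' @param activation Transfer function for both layers; `"identity"`
#'   turns the network into an overparameterized linear map, used to
#'   cross-check the trainer against ordinary least squares.
#' @return An `mlp_fit` with weights at the best validation epoch, the
#'   scalers, the split membership and a per-epoch `history` tibble.
#'   Methods: [predict.mlp_fit()], [tidy()] (history), [glance()]
#'   (per-subset MSE and correlation), [autoplot()] (training curves).
#' @examples
#' \donttest{
#' fit <- mlp_train(oak_runs(), hidden = 10, seed = 1)
#' glance(fit)
#' }
#' @export
mlp_train <- function(data,
                      responses = c("dpph", "frap", "tpc"),
                      factors = oak_factors(),
                      hidden = 10,
                      seed = 0,
                      split = c(0.70, 0.15, 0.15),
                      max_epochs = 1000,
                      patience = 6,
                      mu_init = 1e-3,
                      mu_inc = 10,
                      mu_dec = 0.1,
                      mu_max = 1e10,
                      activation = c("logistic", "identity")) {
  activation <- match.arg(activation)
  missing <- setdiff(c(factors$name, responses), names(data))
  if (length(missing)) {
    abort(paste0("Missing column(s): ", paste(missing, collapse = ", ")),
          class = "oakextract_schema_error")
  }
  n <- nrow(data)
  if (n < 9L) {
    abort("At least 9 runs are required to train the network.",
          class = "oakextract_domain_error")
  }
  stopifnot(abs(sum(split) - 1) < 1e-8)

  Xnat <- as.matrix(data[factors$name])
  Tnat <- as.matrix(data[responses])
  sx <- scaler_new(apply(Xnat, 2, min), apply(Xnat, 2, max), -1, 1)
  sy <- scaler_new(apply(Tnat, 2, min), apply(Tnat, 2, max), 0.1, 0.9)
  Xs <- scaler_apply(sx, Xnat)
  Ts <- scaler_apply(sy, Tnat)

  n_in <- ncol(Xs)
  n_out <- ncol(Ts)
  n_train <- round(split[1] * n)
  n_val <- round(split[2] * n)
  n_test <- n - n_train - n_val

  state <- withr::with_seed(seed, {
    idx <- sample.int(n)
    theta <- runif(sum(mlp_dims(n_in, hidden, n_out)), -0.5, 0.5)
    list(idx = idx, theta = theta)
  })
  subset <- rep("train", n)
  subset[state$idx[n_train + seq_len(n_val)]] <- "validation"
  subset[state$idx[n_train + n_val + seq_len(n_test)]] <- "test"
  i_tr <- which(subset == "train")
  i_va <- which(subset == "validation")
  i_te <- which(subset == "test")

  mse_of <- function(theta, rows) {
    if (length(rows) == 0L) return(NA_real_)
    out <- mlp_forward(mlp_unflatten(theta, n_in, hidden, n_out),
                       Xs[rows, , drop = FALSE], activation)$output
    mean((Ts[rows, , drop = FALSE] - out)^2)
  }

  theta <- state$theta
  mu <- mu_init
  sse_tr <- mse_of(theta, i_tr)
  history <- vector("list", max_epochs)
  best_val <- Inf
  best_theta <- theta
  best_epoch <- 0L
  stall <- 0L
  epochs_run <- 0L
  stopped <- "max_epochs"
  any_accepted <- FALSE

  for (epoch in seq_len(max_epochs)) {
    params <- mlp_unflatten(theta, n_in, hidden, n_out)
    out <- mlp_forward(params, Xs[i_tr, , drop = FALSE], activation)$output
    e <- as.vector(t(Ts[i_tr, , drop = FALSE] - out))  # sample-major, matches jacobian rows
    J <- mlp_jacobian(params, Xs[i_tr, , drop = FALSE], activation)
    A <- crossprod(J)
    g <- crossprod(J, e)

    accepted <- FALSE
    while (mu <= mu_max) {
      delta <- tryCatch(solve(A + mu * diag(nrow(A)), g), error = function(cnd) NULL)
      if (!is.null(delta)) {
        trial <- theta + as.vector(delta)
        trial_sse <- mse_of(trial, i_tr)
        if (is.finite(trial_sse) && trial_sse < sse_tr) {
          theta <- trial
          sse_tr <- trial_sse
          mu <- max(mu * mu_dec, 1e-20)
          accepted <- TRUE
          any_accepted <- TRUE
          break
        }
      }
      mu <- mu * mu_inc
    }

    if (!accepted) {
      if (!any_accepted) {
        abort("Levenberg-Marquardt failed: damping overflow before any accepted step.",
              class = "oakextract_training_failure")
      }
      stopped <- "mu_overflow"
      break
    }

    epochs_run <- epoch
    mse_tr <- mse_of(theta, i_tr)
    mse_va <- mse_of(theta, i_va)
    mse_te <- mse_of(theta, i_te)
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, mse_train = mse_tr, mse_val = mse_va, mse_test = mse_te, mu = mu
    )
    if (!is.na(mse_va) && mse_va < best_val) {
      best_val <- mse_va
      best_theta <- theta
      best_epoch <- epoch
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall > patience) {
        stopped <- "early_stopping"
        break
      }
    }
  }
  if (length(i_va) == 0L) {
    best_theta <- theta
    best_epoch <- epochs_run
  }

  history <- dplyr::bind_rows(history[!purrr::map_lgl(history, is.null)])
  params <- mlp_unflatten(best_theta, n_in, hidden, n_out)

  fit <- structure(
    list(
      params = params, theta = best_theta,
      n_in = n_in, hidden = hidden, n_out = n_out,
      responses = responses, factors = factors,
      scaler_x = sx, scaler_y = sy,
      subset = subset, data = tibble::as_tibble(data),
      history = history, best_epoch = best_epoch, epochs_run = epochs_run,
      stopped = stopped, seed = seed, activation = activation,
      config = list(split = split, max_epochs = max_epochs, patience = patience,
                    mu_init = mu_init, mu_inc = mu_inc, mu_dec = mu_dec)
    ),
    class = "mlp_fit"
  )
  fit
}

#' Predict assay responses with a trained network
#'
#' @param object An `mlp_fit`.
#' @param newdata Data frame with the factor columns in natural units;
#'   defaults to the training table.
#' @param ... Unused.
#' @return A tibble with one column per response, in assay units.
#' @export
predict.mlp_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  X <- scaler_apply(object$scaler_x, as.matrix(newdata[object$factors$name]))
  out <- mlp_forward(object$params, X, object$activation)$output
  out <- scaler_invert(object$scaler_y, out)
  colnames(out) <- object$responses
  tibble::as_tibble(out)
}

#' @export
print.mlp_fit <- function(x, ...) {
  cat(sprintf("MLP %d-%d-%d (%s), Levenberg-Marquardt, seed %d\n",
              x$n_in, x$hidden, x$n_out, x$activation, x$seed))
  cat(sprintf("Stopped after %d epochs (%s); best validation epoch %d\n",
              x$epochs_run, x$stopped, x$best_epoch))
  g <- glance(x)
  cat(sprintf("R (train/val/test): %.3f / %.3f / %.3f\n",
              g$r_train, g$r_val, g$r_test))
  invisible(x)
}

#' Per-epoch training history of a network fit
#'
#' @param x An `mlp_fit`.
#' @param ... Unused.
#' @return A tibble with per-epoch train/validation/test MSE (scaled
#'   units) and the damping factor.
#' @export
tidy.mlp_fit <- function(x, ...) {
  x$history
}

#' One-row summary of a network fit
#'
#' MSEs are in scaled target units; `r_*` are pooled Pearson
#' correlations between observed and predicted responses in assay units.
#'
#' @param x An `mlp_fit`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.mlp_fit <- function(x, ...) {
  pred <- as.matrix(predict(x))
  obs <- as.matrix(x$data[x$responses])
  r_for <- function(which) {
    rows <- x$subset == which
    if (!any(rows)) return(NA_real_)
    pooled_r(obs[rows, , drop = FALSE], pred[rows, , drop = FALSE])
  }
  at_best <- x$history[x$history$epoch == x$best_epoch, ]
  tibble::tibble(
    hidden = x$hidden, seed = x$seed,
    epochs = x$epochs_run, best_epoch = x$best_epoch, stopped = x$stopped,
    mse_train = at_best$mse_train[1], mse_val = at_best$mse_val[1],
    mse_test = at_best$mse_test[1],
    r_train = r_for("train"), r_val = r_for("validation"), r_test = r_for("test"),
    r_all = pooled_r(obs, pred)
  )
}

#' @param object An `mlp_fit`.
#' @param ... Unused.
#' @describeIn mlp_train Training-history curves (train/validation/test
#'   MSE per epoch, best validation epoch marked).
#' @export
autoplot.mlp_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, dplyr::starts_with("mse_"),
                              names_prefix = "mse_",
                              names_to = "subset", values_to = "mse")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$mse,
                                     colour = .data$subset)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(y = "MSE (scaled units)",
                  title = sprintf("Best validation performance at epoch %d",
                                  object$best_epoch))
}

#' Search the hidden-layer size
#'
#' Trains the network at each candidate hidden size with several seeds
#' and picks the size whose best run has the highest validation
#' R-squared (pooled across responses, assay units). Ties go to the
#' smallest size.
#'
#' @param data Response table.
#' @param hidden Integer vector of candidate hidden sizes.
#' @param n_seeds Seeds tried per size (`seed`, `seed + 1`, ...).
#' @param seed First seed.
#' @param ... Passed to [mlp_train()].
#' @return A list with `best_hidden` and a per-run `scores` tibble.
#' @export
mlp_topology_search <- function(data, hidden = 8:12, n_seeds = 5, seed = 0, ...) {
  grid <- tidyr::expand_grid(hidden = hidden, seed = seed + seq_len(n_seeds) - 1L)
  scores <- purrr::pmap_dfr(grid, function(hidden, seed) {
    glance(mlp_train(data, hidden = hidden, seed = seed, ...))
  })
  per_size <- scores |>
    dplyr::mutate(r2_val = .data$r_val^2) |>
    dplyr::group_by(.data$hidden) |>
    dplyr::summarise(r2_val = max(.data$r2_val, na.rm = TRUE), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$r2_val), .data$hidden)
  list(best_hidden = per_size$hidden[1], scores = scores, by_size = per_size)
}

#' Prediction-error histogram of a network fit
#'
#' Residuals (observed minus predicted, assay units) pooled across the
#' responses, binned into `bins` equal-width intervals spanning the
#' residual range, with counts split by train/validation/test
#' membership. Mirrors the error-histogram diagnostic used to judge
#' whether a trained network's errors concentrate near zero.
#'
#' @param fit An `mlp_fit`.
#' @param bins Number of bins.
#' @return A tibble with `bin_lower`, `bin_upper`, `bin_mid`, `subset`,
#'   `count`. Counts sum to `n_runs * n_responses`.
#' @export
mlp_error_histogram <- function(fit, bins = 20) {
  pred <- as.matrix(predict(fit))
  obs <- as.matrix(fit$data[fit$responses])
  res_mat <- obs - pred
  rng <- range(res_mat)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = bins + 1)
  df <- tibble::tibble(
    resid = as.vector(res_mat),
    subset = rep(fit$subset, times = ncol(res_mat))
  )
  df$bin <- cut(df$resid, breaks = edges, include.lowest = TRUE, labels = FALSE)
  counts <- df |>
    dplyr::count(.data$subset, .data$bin, name = "count")
  full <- tidyr::expand_grid(subset = unique(fit$subset), bin = seq_len(bins)) |>
    dplyr::left_join(counts, by = c("subset", "bin")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L),
                  bin_lower = edges[.data$bin],
                  bin_upper = edges[.data$bin + 1L],
                  bin_mid = (.data$bin_lower + .data$bin_upper) / 2)
  dplyr::select(full, "bin", "bin_lower", "bin_upper", "bin_mid", "subset", "count")
}
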