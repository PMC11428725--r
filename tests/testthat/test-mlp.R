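unflatten <- oakextract:::mlp_unflatten
flatten <- oakextract:::mlp_flatten
forward <- oakextract:::mlp_forward
jacobian <- oakextract:::mlp_jacobian

random_params <- function(n_in, hidden, n_out, seed) {
  withr::with_seed(seed, {
    unflatten(runif(hidden * n_in + hidden + n_out * hidden + n_out, -0.5, 0.5),
              n_in, hidden, n_out)
  })
}

test_that("the forward pass follows the two-sigmoid-layer architecture", {
  p <- list(W1 = matrix(0, 4, 3), b1 = rep(0, 4),
            W2 = matrix(0, 3, 4), b2 = rep(0, 3))
  X <- matrix(runif(15, -1, 1), ncol = 3)
  out <- forward(p, X)$output
  expect_equal(out, matrix(0.5, 5, 3)) # sigma(0) = 0.5 everywhere

  # permuting hidden units together with their weights leaves outputs unchanged
  p <- random_params(3, 5, 3, seed = 7)
  perm <- c(3, 5, 1, 4, 2)
  p2 <- list(W1 = p$W1[perm, ], b1 = p$b1[perm], W2 = p$W2[, perm], b2 = p$b2)
  expect_equal(forward(p2, X)$output, forward(p, X)$output, tolerance = 1e-12)
})

test_that("the backprop Jacobian matches central finite differences", {
  for (seed in 1:3) {
    n_in <- 2; hidden <- 4; n_out <- 3
    p <- random_params(n_in, hidden, n_out, seed)
    X <- withr::with_seed(100 + seed, matrix(runif(5 * n_in, -1, 1), ncol = n_in))
    J <- jacobian(p, X)
    th <- flatten(p)
    eps <- 1e-6
    fd <- vapply(seq_along(th), function(j) {
      tp <- th; tm <- th
      tp[j] <- tp[j] + eps
      tm[j] <- tm[j] - eps
      yp <- forward(unflatten(tp, n_in, hidden, n_out), X)$output
      ym <- forward(unflatten(tm, n_in, hidden, n_out), X)$output
      as.vector(t(yp - ym)) / (2 * eps)
    }, numeric(nrow(J)))
    expect_lt(max(abs(J - fd)), 1e-6)
  }
})

test_that("min-max scaling round-trips exactly", {
  s <- oakextract:::scaler_new(c(0, 10), c(5, 30), 0.1, 0.9)
  M <- cbind(runif(20, 0, 5), runif(20, 10, 30))
  S <- oakextract:::scaler_apply(s, M)
  expect_true(all(S >= 0.1 - 1e-12 & S <= 0.9 + 1e-12))
  expect_equal(oakextract:::scaler_invert(s, S), M, tolerance = 1e-12)
  expect_error(oakextract:::scaler_new(c(1, 2), c(1, 3), 0, 1),
               class = "oakextract_domain_error")
})

test_that("with identity activations the trainer reaches the least-squares fit", {
  tf <- oak_factors()
  withr::with_seed(5, {
    toy <- full_factorial(tf)
    toy$u <- 1 + 0.3 * toy$temperature + rnorm(27, 0, 2)
    toy$v <- 10 - 0.2 * toy$time + rnorm(27, 0, 2)
  })
  fit <- mlp_train(toy, responses = c("u", "v"), hidden = 4, seed = 1,
                   activation = "identity", split = c(1, 0, 0),
                   max_epochs = 300)
  pred <- predict(fit)
  for (r in c("u", "v")) {
    ols <- fitted(lm(reformulate(tf$name, r), toy))
    expect_equal(pred[[r]], unname(ols), tolerance = 1e-6)
  }
})

test_that("an overparameterized net interpolates a noiseless linear surface", {
  tab <- simulate_runs(
    c(`(Intercept)` = 200, temperature = 80, ethanol = 60, time = 10),
    noise_sd = 0, seed = 6, response_name = "y1"
  )
  tab$y2 <- tab$y1 * 0.5 + 20
  tab$y3 <- 300 - tab$y1 * 0.3
  fit <- mlp_train(tab, responses = c("y1", "y2", "y3"), hidden = 10, seed = 3,
                   split = c(1, 0, 0), max_epochs = 400)
  final <- fit$history$mse_train[nrow(fit$history)]
  expect_lt(final, 1e-3)
})

test_that("the split honours the 19/4/4 partition and the seed", {
  f1 <- mlp_train(oak, hidden = 8, seed = 4, max_epochs = 5)
  expect_equal(sum(f1$subset == "train"), 19)
  expect_equal(sum(f1$subset == "validation"), 4)
  expect_equal(sum(f1$subset == "test"), 4)
  f2 <- mlp_train(oak, hidden = 8, seed = 4, max_epochs = 5)
  expect_identical(f1$subset, f2$subset)
  expect_identical(f1$theta, f2$theta)
  f3 <- mlp_train(oak, hidden = 8, seed = 5, max_epochs = 5)
  expect_false(identical(f1$subset, f3$subset))
})

test_that("reported weights always achieve the minimum recorded validation MSE", {
  for (seed in c(1, 2, 9)) {
    fit <- mlp_train(oak, hidden = 10, seed = seed, max_epochs = 60)
    h <- fit$history
    expect_equal(fit$best_epoch, h$epoch[which.min(h$mse_val)])
    g <- glance(fit)
    expect_equal(g$mse_val, min(h$mse_val))
    # recompute the validation MSE from the stored weights
    pred <- as.matrix(predict(fit))
    obs <- as.matrix(fit$data[fit$responses])
    rows <- fit$subset == "validation"
    Ts <- oakextract:::scaler_apply(fit$scaler_y, obs)
    Ps <- oakextract:::scaler_apply(fit$scaler_y, pred)
    expect_equal(mean((Ts[rows, ] - Ps[rows, ])^2), min(h$mse_val),
                 tolerance = 1e-10)
  }
})

test_that("zero patience stops at the first validation-MSE increase", {
  fit <- mlp_train(oak, hidden = 10, seed = 1, patience = 0, max_epochs = 200)
  h <- fit$history
  expect_equal(fit$stopped, "early_stopping")
  # every epoch before the last improved the best-so-far validation MSE
  expect_equal(fit$epochs_run, nrow(h))
  expect_true(all(diff(cummin(h$mse_val))[-(nrow(h) - 1)] < 0))
  expect_equal(fit$best_epoch, nrow(h) - 1)
})

test_that("topology search scores sizes reproducibly and honours ties", {
  res <- mlp_topology_search(oak, hidden = c(9, 10), n_seeds = 2, seed = 1,
                             max_epochs = 40)
  expect_true(res$best_hidden %in% c(9, 10))
  expect_equal(nrow(res$scores), 4)
  res2 <- mlp_topology_search(oak, hidden = c(9, 10), n_seeds = 2, seed = 1,
                              max_epochs = 40)
  expect_identical(res$scores, res2$scores)
  single <- mlp_topology_search(oak, hidden = 10, n_seeds = 1, max_epochs = 10)
  expect_equal(single$best_hidden, 10)
})

test_that("the error histogram conserves counts and concentrates near zero", {
  fit <- mlp_train(oak, hidden = 10, seed = 1)
  h <- mlp_error_histogram(fit)
  expect_equal(sum(h$count), 27 * 3)
  expect_equal(dplyr::n_distinct(h$bin), 20)
  # majority of pooled residuals in the central half of the bins
  central <- h$bin_mid >= quantile(range(h$bin_mid), 0.25) &
    h$bin_mid <= quantile(range(h$bin_mid), 0.75)
  expect_gt(sum(h$count[central]), sum(h$count) / 2)

  # near-perfect model: all residuals in the bins containing ~zero errors
  tab <- simulate_runs(c(`(Intercept)` = 100, temperature = 50), noise_sd = 0,
                       seed = 1, response_name = "y1")
  tab$y2 <- tab$y1
  tab$y3 <- tab$y1
  pf <- mlp_train(tab, responses = c("y1", "y2", "y3"), hidden = 10, seed = 2,
                  split = c(1, 0, 0), max_epochs = 400)
  hp <- mlp_error_histogram(pf)
  spread <- max(hp$bin_upper) - min(hp$bin_lower)
  expect_lt(spread, 0.05 * diff(range(tab$y1)))
})

test_that("training rejects malformed inputs", {
  expect_error(mlp_train(oak[1:5, ]), class = "oakextract_domain_error")
  expect_error(mlp_train(dplyr::select(oak, -"dpph")),
               class = "oakextract_schema_error")
})
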