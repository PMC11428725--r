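# Shared fixtures for the test suite. Everything is built in code; the
# only file fixtures are the two packaged CSVs.

oak <- oak_runs()

oak_fits <- function(responses = c("dpph", "frap", "tpc")) {
  fits <- lapply(responses, function(r) ffd_fit(oak, r))
  names(fits) <- responses
  fits
}

# A tiny two-factor specification for toy fits.
toy_factors <- function() {
  dplyr::bind_rows(
    factor_spec("a", -2, 0, 2),
    factor_spec("b", 10, 20, 30)
  )
}

# Brute-force least squares by direct numerical minimization of the sum of
# squared errors; the independent oracle for the OLS fitter.
brute_force_ols <- function(X, y) {
  sse <- function(b) sum((y - X %*% b)^2)
  init <- rep(0, ncol(X))
  res <- optim(init, sse, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-14))
  res$par
}
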